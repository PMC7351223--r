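#' Preprocessing parameters
#'
#' Defaults follow the study protocol: pooled-QC coefficient-of-variation
#' filter at 0.3, binary log transform, cross-building summed log2 intensity
#' filter at 100 (strictly greater kept), and half-minimum fill per feature
#' per building.
#'
#' @param cv_max maximum pooled-QC CV (SD/mean) a feature may have.
#' @param min_sum_log features whose summed log2 intensity across all
#'   buildings and days is `<= min_sum_log` are removed.
#' @param correction_scale scale on which the run-order correction is applied:
#'   `"log2"` (default, following the processing order: the transform precedes
#'   the correction) or `"raw"`.
#' @param ddof degrees-of-freedom convention for the QC CV standard deviation:
#'   0 = population (default), 1 = sample.
#' @return List of class `preprocess_params`.
#' @export
preprocess_params <- function(cv_max = 0.3, min_sum_log = 100,
                              correction_scale = c("log2", "raw"),
                              ddof = 0) {
  stopifnot(cv_max > 0, min_sum_log >= 0, ddof %in% c(0, 1))
  structure(list(cv_max = cv_max, min_sum_log = min_sum_log,
                 correction_scale = match.arg(correction_scale),
                 ddof = ddof),
            class = "preprocess_params")
}

sd_ddof <- function(x, ddof = 0) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2 - (ddof == 0)) return(NA_real_)
  if (ddof == 0) sqrt(sum((x - mean(x))^2) / n) else stats::sd(x)
}

#' Binary log transform
#'
#' Every observed positive intensity is replaced by its base-2 logarithm.
#' Zeros become missing (`NA`) — a zero raw intensity means "not observed",
#' and is later filled by [blank_subtract_fill()] — and missing stays missing.
#'
#' @param table a `feature_table` on raw scale.
#' @return The table on `log2` scale.
#' @export
log2_transform <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$scale != "raw") stop("log2_transform expects a raw-scale table")
  x <- table$intensities
  if (any(x < 0, na.rm = TRUE)) stop("negative raw intensity")
  x[!is.na(x) & x == 0] <- NA
  x <- log2(x)
  feature_table(table$features, table$samples, x, scale = "log2")
}

#' Pooled-QC coefficient-of-variation filter
#'
#' Features whose pooled-QC CV (SD/mean) exceeds `cv_max` are removed:
#' a feature the instrument cannot measure reproducibly on an identical
#' pooled sample is not interpretable in study samples.
#'
#' @param table a `feature_table` containing QC samples.
#' @param cv_max CV threshold (strictly greater removed).
#' @param ddof SD convention (0 population, 1 sample).
#' @return List with `table` (filtered) and `removed` (feature ids).
#' @export
qc_cv_filter <- function(table, cv_max = 0.3, ddof = 0) {
  stopifnot(inherits(table, "feature_table"))
  qc <- table$samples$role == "qc"
  if (sum(qc) < 2) stop("need at least 2 QC samples for the CV filter")
  q <- table$intensities[, qc, drop = FALSE]
  cv <- apply(q, 1, function(v) {
    s <- sd_ddof(v, ddof)
    m <- mean(v, na.rm = TRUE)
    if (is.na(s) || is.na(m) || m == 0) return(NA_real_)
    s / m
  })
  drop <- !is.na(cv) & cv > cv_max
  list(table = ft_subset(table, features = which(!drop)),
       removed = table$features$feature_id[drop],
       cv = cv)
}

# Local QC mean for each study sample: the two run-order-flanking QC values
# (mean); before the first / after the last QC the single nearest QC is used.
local_qc_mean <- function(values, ro_sample, ro_qc) {
  ord <- order(ro_qc)
  ro_qc <- ro_qc[ord]
  values <- values[ord]
  vapply(ro_sample, function(r) {
    lo <- which(ro_qc < r)
    hi <- which(ro_qc > r)
    if (length(lo) && length(hi)) {
      (values[max(lo)] + values[min(hi)]) / 2
    } else if (length(lo)) {
      values[max(lo)]
    } else {
      values[min(hi)]
    }
  }, numeric(1))
}

#' Run-order drift correction against pooled QC samples
#'
#' Corrects each study intensity X to X' = X * (R / C), where R is the global
#' mean of the feature over all QC samples and C the local mean over the two
#' run-order-flanking QC samples (the single nearest QC at batch edges).
#' Correction is per batch; QC and blank samples pass through unchanged.
#'
#' @param table a `feature_table` (log2 or raw scale, see
#'   [preprocess_params()]`$correction_scale`).
#' @return The corrected `feature_table`.
#' @export
run_order_correct <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  s <- table$samples
  if (!any(s$role == "qc")) stop("no QC samples present")
  x <- table$intensities
  for (b in unique(s$batch)) {
    qc_i <- which(s$role == "qc" & s$batch == b)
    st_i <- which(s$role == "study" & s$batch == b)
    if (!length(st_i)) next
    if (!length(qc_i)) stop("batch ", b, " has study samples but no QC")
    for (f in seq_len(nrow(x))) {
      qv <- x[f, qc_i]
      ok <- !is.na(qv)
      if (!any(ok)) next
      R <- mean(qv[ok])
      C <- local_qc_mean(qv[ok], s$run_order[st_i], s$run_order[qc_i][ok])
      if (any(C == 0, na.rm = TRUE)) stop("local QC mean C = 0")
      x[f, st_i] <- x[f, st_i] * (R / C)
    }
  }
  feature_table(table$features, table$samples, x, scale = table$scale)
}

#' Blank subtraction and half-minimum fill
#'
#' Subtracts the per-feature mean blank intensity from every study value;
#' any resulting value below zero, and any originally missing value, is
#' replaced by half the minimum of that feature's remaining observed values in
#' the given building. Returns per-building tables (the fill is per building).
#'
#' @param table a `feature_table` with study + blank samples.
#' @param allow_no_blank if `TRUE` and no blank samples are present, skip
#'   subtraction (fill still applied).
#' @return Named list of per-building `feature_table`s with no missing or
#'   negative values.
#' @export
blank_subtract_fill <- function(table, allow_no_blank = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  bl <- table$samples$role == "blank"
  if (!any(bl) && !allow_no_blank) stop("no blank samples present")
  blank_mean <- if (any(bl)) {
    rowMeans(table$intensities[, bl, drop = FALSE], na.rm = TRUE)
  } else {
    rep(0, nrow(table$features))
  }
  blank_mean[is.na(blank_mean)] <- 0
  per_b <- ft_split_buildings(table)
  lapply(per_b, function(t) {
    x <- sweep(t$intensities, 1, blank_mean, "-")
    for (f in seq_len(nrow(x))) {
      v <- x[f, ]
      bad <- is.na(v) | v < 0
      if (all(bad)) {
        stop("feature ", t$features$feature_id[f],
             " has no observed value in a building; fill undefined")
      }
      if (any(bad)) {
        x[f, bad] <- min(v[!bad]) / 2
      }
    }
    feature_table(t$features, t$samples, x, scale = t$scale)
  })
}

#' Cross-building intensity filter and replicate averaging
#'
#' Removes, from every building, features whose summed log2 intensity across
#' all buildings and days is not strictly greater than `min_sum_log`
#' (low-abundance features near the blank background), then averages replicate
#' samples of the same building-day into one column.
#'
#' @param tables named list of per-building `feature_table`s on log2 scale.
#' @param min_sum_log the sum threshold (default 100).
#' @return List with `tables` (filtered, replicate-averaged) and `removed`
#'   (feature ids).
#' @export
finalize_tables <- function(tables, min_sum_log = 100) {
  stopifnot(is.list(tables), length(tables) >= 1)
  sums <- Reduce(`+`, lapply(tables, function(t) {
    rowSums(t$intensities, na.rm = TRUE)
  }))
  keep <- sums > min_sum_log
  removed <- tables[[1]]$features$feature_id[!keep]
  tables <- lapply(tables, function(t) {
    t <- ft_subset(t, features = which(keep))
    average_replicates(t)
  })
  list(tables = tables, removed = removed)
}

#' Average replicate samples of the same building-day
#'
#' @param table a single-building `feature_table`.
#' @return A `feature_table` with one column per day; `replicate_index` set
#'   to 1, `run_order` to the smallest among the replicates.
#' @export
average_replicates <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  days <- as.character(table$samples$day)
  if (!anyDuplicated(days)) return(table)
  udays <- unique(days)
  idx1 <- match(udays, days)
  x <- vapply(udays, function(d) {
    rowMeans(table$intensities[, days == d, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(table$features)))
  s <- table$samples[idx1, , drop = FALSE]
  s$replicate_index <- 1L
  s$run_order <- vapply(udays, function(d) {
    min(table$samples$run_order[days == d])
  }, numeric(1))
  s$sample_id <- paste0(s$building, "_", as.character(s$day))
  feature_table(table$features, s, x, scale = table$scale)
}

#' Full preprocessing pipeline
#'
#' Fixed stage order: log2 transform, pooled-QC CV filter, run-order drift
#' correction, blank subtraction + half-minimum fill (splitting into
#' per-building tables), cross-building sum filter, replicate averaging.
#'
#' @param table a raw-scale `feature_table` with study, QC and blank samples.
#' @param params a [preprocess_params()] object.
#' @param runorder_correction set `FALSE` to skip the drift correction.
#' @return List with `tables` (named per-building list, log2 scale, one column
#'   per day, no missing values) and `log` (features removed at each step).
#' @export
preprocess <- function(table, params = preprocess_params(),
                       runorder_correction = TRUE) {
  stopifnot(inherits(table, "feature_table"),
            inherits(params, "preprocess_params"))
  log <- list()
  if (params$correction_scale == "raw" && runorder_correction) {
    table <- run_order_correct(table)
  }
  table <- log2_transform(table)
  cvf <- qc_cv_filter(table, cv_max = params$cv_max, ddof = params$ddof)
  table <- cvf$table
  log$cv_removed <- cvf$removed
  if (params$correction_scale == "log2" && runorder_correction) {
    table <- run_order_correct(table)
  }
  per_b <- blank_subtract_fill(table)
  fin <- finalize_tables(per_b, min_sum_log = params$min_sum_log)
  log$sum_removed <- fin$removed
  list(tables = fin$tables, log = log)
}
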