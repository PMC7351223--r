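#' Stability classification parameters
#'
#' Thresholds for the stable/unstable taxonomy: through-time log2 SD below 2
#' is stable; among unstable features, SD strictly above 3.5 is Class 2,
#' otherwise median log2 intensity below 14 is Class 1, and the rest Class 3.
#'
#' @param sd_stable_max SD threshold (stable strictly below; `>=` unstable).
#' @param sd_class2_min Class 2 SD threshold (strictly above).
#' @param median_class1_max Class 1 median threshold (strictly below).
#' @param kw_q_max FDR threshold for the between-building Kruskal-Wallis
#'   screen.
#' @param mw_q_max FDR threshold for weekday/weekend Mann-Whitney tests.
#' @param ddof SD convention (0 population, 1 sample).
#' @return List of class `stability_params`.
#' @export
stability_params <- function(sd_stable_max = 2.0, sd_class2_min = 3.5,
                             median_class1_max = 14.0,
                             kw_q_max = 1e-5, mw_q_max = 0.05, ddof = 0) {
  stopifnot(sd_class2_min > sd_stable_max, ddof %in% c(0, 1))
  structure(list(sd_stable_max = sd_stable_max,
                 sd_class2_min = sd_class2_min,
                 median_class1_max = median_class1_max,
                 kw_q_max = kw_q_max, mw_q_max = mw_q_max, ddof = ddof),
            class = "stability_params")
}

#' Per-feature through-time summary statistics for one building
#'
#' Mean, SD (population by default) and median of the log2 intensity across
#' the building's sampling days (replicates already averaged, one column per
#' day).
#'
#' @param table a single-building log2-scale `feature_table`.
#' @param ddof SD convention (0 population, 1 sample).
#' @return data.frame of class `stability_report`: feature_id, mz, rt,
#'   mean, sd, median (label columns added by [classify_stability()]).
#' @export
summarize_stability <- function(table, ddof = 0) {
  stopifnot(inherits(table, "feature_table"))
  m <- day_matrix(table)
  if (ncol(m) < 2) stop("need at least 2 days to summarize")
  rep <- data.frame(
    feature_id = table$features$feature_id,
    mz = table$features$mz,
    rt = table$features$rt,
    mean = rowMeans(m),
    sd = apply(m, 1, sd_ddof, ddof = ddof),
    median = apply(m, 1, stats::median)
  )
  class(rep) <- c("stability_report", "data.frame")
  rep
}

#' Assign stability labels and unstable classes
#'
#' A total, deterministic function of (SD, median): SD < 2 is stable and
#' SD >= 2 unstable; unstable features with SD > 3.5 are Class 2, the rest
#' split by median log2 intensity (< 14 Class 1, otherwise Class 3).
#'
#' @param report a [summarize_stability()] report.
#' @param params a [stability_params()].
#' @return The report with `label` ("stable"/"unstable") and
#'   `unstable_class` (1/2/3 or `NA` for stable features).
#' @export
classify_stability <- function(report, params = stability_params()) {
  stopifnot(inherits(report, "stability_report"))
  lab <- ifelse(report$sd < params$sd_stable_max, "stable", "unstable")
  cls <- rep(NA_integer_, nrow(report))
  uns <- lab == "unstable"
  cls[uns & report$sd > params$sd_class2_min] <- 2L
  rest <- uns & is.na(cls)
  cls[rest & report$median < params$median_class1_max] <- 1L
  cls[rest & report$median >= params$median_class1_max] <- 3L
  report$label <- lab
  report$unstable_class <- cls
  report
}

#' Stable/unstable overlap across buildings
#'
#' For a given label, counts features in each of the 2^B - 1 building
#' combination regions (the Venn regions of "carries this label in building
#' b"), with the fraction shared by all buildings reported over the union.
#'
#' @param reports named list of per-building classified stability reports.
#' @param label `"stable"` or `"unstable"`.
#' @return List: `regions` (data.frame of building combination and count),
#'   `union_size`, `frac_all` (fraction of the union carrying the label in
#'   every building).
#' @export
overlap_analysis <- function(reports, label = c("stable", "unstable")) {
  label <- match.arg(label)
  stopifnot(length(reports) >= 1)
  ids <- reports[[1]]$feature_id
  for (r in reports) {
    if (!identical(sort(r$feature_id), sort(ids))) {
      stop("mismatched feature sets across buildings")
    }
  }
  inset <- vapply(reports, function(r) {
    r$label[match(ids, r$feature_id)] == label
  }, logical(length(ids)))
  in_any <- rowSums(inset) > 0
  key <- apply(inset, 1, function(z) paste(names(reports)[z], collapse = "+"))
  key <- key[in_any]
  combos <- unlist(lapply(seq_along(reports), function(k) {
    utils::combn(names(reports), k, paste, collapse = "+")
  }))
  counts <- vapply(combos, function(cb) sum(key == cb), integer(1))
  all_key <- paste(names(reports), collapse = "+")
  list(
    regions = data.frame(buildings = combos, count = as.integer(counts)),
    union_size = sum(in_any),
    frac_all = if (sum(in_any)) unname(counts[all_key]) / sum(in_any) else NA_real_
  )
}

#' Kruskal-Wallis screen for between-building differences
#'
#' Per feature, a tie-corrected Kruskal-Wallis test over per-day log2
#' intensities grouped by building, followed by Benjamini-Hochberg FDR
#' correction across the screened feature set. Features constant across all
#' groups get p = 1.
#'
#' @param tables named list of per-building log2 `feature_table`s
#'   (replicates averaged).
#' @param restrict_to optional feature-id subset: BH correction and the
#'   returned records cover only these features.
#' @param q_max significance threshold on the BH Q-value.
#' @return data.frame (feature_id, statistic, p, q, significant), ordered as
#'   the screened set.
#' @export
kw_screen <- function(tables, restrict_to = NULL, q_max = 1e-5) {
  stopifnot(is.list(tables), length(tables) >= 3)
  mats <- lapply(tables, day_matrix)
  ids <- tables[[1]]$features$feature_id
  if (is.null(restrict_to)) restrict_to <- ids
  idx <- match(restrict_to, ids)
  if (anyNA(idx)) stop("restrict_to contains unknown feature ids")
  grp <- factor(rep(names(tables), vapply(mats, ncol, integer(1))))
  res <- t(vapply(idx, function(f) {
    v <- unlist(lapply(mats, function(m) m[f, ]))
    if (length(unique(v)) == 1) return(c(NA_real_, 1))
    kt <- stats::kruskal.test(v, grp)
    c(unname(kt$statistic), kt$p.value)
  }, numeric(2)))
  q <- stats::p.adjust(res[, 2], method = "BH")
  data.frame(feature_id = restrict_to, statistic = res[, 1],
             p = res[, 2], q = q, significant = q < q_max)
}

#' Weekday/weekend Mann-Whitney screen for one building
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per feature between two
#' day groups, BH-corrected across features. Two modes: Saturdays vs
#' Wednesdays only, or weekend days vs all weekdays.
#'
#' @param table a single-building log2 `feature_table`, replicates averaged.
#' @param mode `"sat_vs_wed"` or `"weekend_vs_allweekdays"`.
#' @param q_max FDR threshold.
#' @return data.frame (feature_id, statistic, p, q, significant).
#' @export
weekday_weekend_test <- function(table,
                                 mode = c("weekend_vs_allweekdays",
                                          "sat_vs_wed"),
                                 q_max = 0.05) {
  stopifnot(inherits(table, "feature_table"))
  mode <- match.arg(mode)
  m <- day_matrix(table)
  days <- as.Date(colnames(m))
  dow <- format(days, "%u")
  if (mode == "sat_vs_wed") {
    g1 <- dow == "6"
    g2 <- dow == "3"
  } else {
    g1 <- dow %in% c("6", "7")
    g2 <- !g1
  }
  if (sum(g1) < 2 || sum(g2) < 2) {
    stop("each day group needs at least 2 samples")
  }
  res <- t(apply(m, 1, function(v) {
    if (length(unique(v)) == 1) return(c(NA_real_, 1))
    wt <- suppressWarnings(stats::wilcox.test(v[g1], v[g2], exact = FALSE))
    c(unname(wt$statistic), wt$p.value)
  }))
  q <- stats::p.adjust(res[, 2], method = "BH")
  data.frame(feature_id = table$features$feature_id,
             statistic = res[, 1], p = res[, 2], q = q,
             significant = q < q_max)
}

#' Between-building regression of through-time mean intensities
#'
#' Ordinary least squares of building j's per-feature through-time means on
#' building i's, with the Pearson correlation coefficient.
#'
#' @param report_i,report_j stability reports for the two buildings (shared
#'   feature universe).
#' @return List: `slope`, `intercept`, `r`.
#' @export
between_building_regression <- function(report_i, report_j) {
  ids <- intersect(report_i$feature_id, report_j$feature_id)
  if (length(ids) < 2) stop("need at least 2 shared features")
  x <- report_i$mean[match(ids, report_i$feature_id)]
  y <- report_j$mean[match(ids, report_j$feature_id)]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in mean-intensity vector")
  }
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y))
}
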