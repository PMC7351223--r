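#' Construct a feature table
#'
#' The central container of the package: an LC-MS feature intensity matrix
#' (features as rows, samples as columns) together with per-feature m/z and
#' retention-time metadata and per-sample study metadata. Missing measurements
#' are `NA`, never zero: preprocessing treats "not observed" differently from
#' "observed at zero".
#'
#' @param features data.frame with columns `feature_id` (unique character),
#'   `mz` (Daltons, > 0) and `rt` (seconds, >= 0).
#' @param samples data.frame with columns `sample_id`, `building`, `day`
#'   (coercible to `Date`), `weekday_flag`, `replicate_index`, `run_order`,
#'   `role` (one of `"study"`, `"qc"`, `"blank"`) and optionally `batch`
#'   (defaults to 1). QC and blank samples carry no building/day semantics;
#'   their `building`/`day` entries are set to `NA`.
#' @param intensities numeric matrix, `nrow(features)` x `nrow(samples)`.
#' @param scale one of `"raw"`, `"log2"`, `"znorm"`. Raw intensities must be
#'   non-negative.
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, samples, intensities,
                          scale = c("raw", "log2", "znorm")) {
  scale <- match.arg(scale)
  features <- as.data.frame(features)
  samples <- as.data.frame(samples)

  req_f <- c("feature_id", "mz", "rt")
  if (!all(req_f %in% names(features))) {
    stop("features must have columns: ", paste(req_f, collapse = ", "))
  }
  features$feature_id <- as.character(features$feature_id)
  if (anyDuplicated(features$feature_id)) {
    stop("duplicate feature ids")
  }
  if (any(!is.finite(features$mz)) || any(features$mz <= 0)) {
    stop("feature mz must be finite and > 0")
  }
  if (any(!is.finite(features$rt)) || any(features$rt < 0)) {
    stop("feature rt must be finite and >= 0")
  }

  req_s <- c("sample_id", "building", "day", "weekday_flag",
             "replicate_index", "run_order", "role")
  if (!all(req_s %in% names(samples))) {
    stop("samples must have columns: ", paste(req_s, collapse = ", "))
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (!all(samples$role %in% c("study", "qc", "blank"))) {
    stop("sample role must be study, qc or blank")
  }
  if (is.null(samples$batch)) samples$batch <- 1L
  samples$day <- as.Date(samples$day)
  samples$building <- as.character(samples$building)
  # qc/blank samples have no building/day semantics downstream
  nb <- samples$role != "study"
  samples$building[nb] <- NA_character_
  samples$day[nb] <- as.Date(NA)
  if (any(samples$role == "study" & is.na(samples$day))) {
    stop("study samples must have a day")
  }
  # weekday flag is derivable from the date; fill where missing
  miss_wf <- is.na(samples$weekday_flag) & samples$role == "study"
  if (any(miss_wf)) {
    samples$weekday_flag[miss_wf] <- is_weekday(samples$day[miss_wf])
  }
  for (b in unique(samples$batch)) {
    ro <- samples$run_order[samples$batch == b]
    if (anyDuplicated(ro)) stop("run_order must be unique within a batch")
  }

  intensities <- as.matrix(intensities)
  if (!is.numeric(intensities)) stop("non-numeric intensity values")
  if (nrow(intensities) != nrow(features) ||
      ncol(intensities) != nrow(samples)) {
    stop("intensity matrix dimensions do not match feature/sample lists")
  }
  if (scale == "raw" && any(intensities < 0, na.rm = TRUE)) {
    stop("raw intensities must be non-negative")
  }
  dimnames(intensities) <- list(features$feature_id, samples$sample_id)

  structure(
    list(features = features, samples = samples,
         intensities = intensities, scale = scale),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples [%s scale]\n",
              nrow(x$features), nrow(x$samples), x$scale))
  tb <- table(x$samples$role)
  cat("  roles:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  bl <- unique(stats::na.omit(x$samples$building))
  if (length(bl)) cat("  buildings:", paste(sort(bl), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

is_weekday <- function(day) {
  !(format(as.Date(day), "%u") %in% c("6", "7"))
}

#' Subset a feature table
#'
#' @param table a `feature_table`.
#' @param features character vector of feature ids or logical/integer index.
#' @param samples character vector of sample ids or logical/integer index.
#' @return The subsetted `feature_table`.
#' @export
ft_subset <- function(table, features = NULL, samples = NULL) {
  stopifnot(inherits(table, "feature_table"))
  fi <- seq_len(nrow(table$features))
  si <- seq_len(nrow(table$samples))
  if (!is.null(features)) {
    fi <- if (is.character(features)) {
      match(features, table$features$feature_id)
    } else fi[features]
    if (anyNA(fi)) stop("unknown feature id(s)")
  }
  if (!is.null(samples)) {
    si <- if (is.character(samples)) {
      match(samples, table$samples$sample_id)
    } else si[samples]
    if (anyNA(si)) stop("unknown sample id(s)")
  }
  feature_table(table$features[fi, , drop = FALSE],
                table$samples[si, , drop = FALSE],
                table$intensities[fi, si, drop = FALSE],
                scale = table$scale)
}

#' Split a study table into per-building tables
#'
#' QC and blank samples are dropped; each returned table holds one building's
#' study samples.
#'
#' @param table a `feature_table`.
#' @return Named list of `feature_table`s, one per building.
#' @export
ft_split_buildings <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  st <- table$samples$role == "study"
  bs <- sort(unique(table$samples$building[st]))
  out <- lapply(bs, function(b) {
    ft_subset(table, samples = which(st & table$samples$building == b))
  })
  names(out) <- bs
  out
}

#' Read a feature table from CSV/TSV
#'
#' The matrix file has one header row of sample ids after the leading
#' `feature_id`, `mz`, `rt` columns; a companion metadata file maps sample ids
#' to study metadata. Empty cells are read as missing (`NA`), not zero.
#' Because supplementary-table layouts vary, `header_map` lets the caller remap
#' nonstandard metadata column names, e.g.
#' `c(sample_id = "Sample", building = "bldg")`.
#'
#' @param path matrix file path.
#' @param meta_path metadata file path.
#' @param format `"csv"` or `"tsv"`.
#' @param scale intensity scale of the file (default `"raw"`).
#' @param header_map optional named character vector mapping canonical
#'   metadata column names to the names used in the file.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path, meta_path, format = c("csv", "tsv"),
                               scale = "raw", header_map = NULL) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  mat <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(mat) < 4) stop("matrix file needs feature_id, mz, rt + samples")
  if (!all(c("feature_id", "mz", "rt") == names(mat)[1:3])) {
    stop("matrix file must start with columns feature_id, mz, rt")
  }
  meta <- utils::read.table(meta_path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(header_map)) {
    for (canon in names(header_map)) {
      j <- match(header_map[[canon]], names(meta))
      if (is.na(j)) stop("header_map column not found: ", header_map[[canon]])
      names(meta)[j] <- canon
    }
  }
  sample_ids <- names(mat)[-(1:3)]
  missing_meta <- setdiff(sample_ids, meta$sample_id)
  if (length(missing_meta)) {
    stop("sample id(s) in matrix but absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  ints <- as.matrix(mat[, -(1:3), drop = FALSE])
  if (!is.numeric(ints)) stop("non-numeric intensity values")
  feature_table(mat[, 1:3], meta, ints, scale = scale)
}

#' Write a feature table to CSV/TSV
#'
#' Emits the matrix and metadata in the dialect [read_feature_table()]
#' consumes. Intensities are written with 15 significant digits so a
#' write/read round trip is lossless well past 10 significant digits, and the
#' output is byte-identical for identical input.
#'
#' @param table a `feature_table`.
#' @inheritParams read_feature_table
#' @return Invisibly, `c(path, meta_path)`.
#' @export
write_feature_table <- function(table, path, meta_path,
                                format = c("csv", "tsv")) {
  stopifnot(inherits(table, "feature_table"))
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  fmt_num <- function(x) {
    out <- sprintf("%.15g", x)
    out[is.na(x)] <- ""
    out
  }
  mat <- cbind(
    data.frame(feature_id = table$features$feature_id,
               mz = fmt_num(table$features$mz),
               rt = fmt_num(table$features$rt),
               check.names = FALSE),
    as.data.frame(apply(table$intensities, 2, fmt_num),
                  check.names = FALSE)
  )
  utils::write.table(mat, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  meta <- table$samples
  meta$day <- as.character(meta$day)
  utils::write.table(meta, meta_path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(c(path, meta_path))
}

#' Restrict per-building tables to their shared sampling days
#'
#' Cross-building comparisons (clustering on a common axis, similarity,
#' one-to-one distances) require identical ordered day sets; this restricts
#' each building's table to the intersection of all buildings' days.
#' Replicates must already be averaged (one column per day).
#'
#' @param tables named list of per-building `feature_table`s.
#' @return Named list of `feature_table`s, each with the same ordered shared
#'   days. Feature sets are untouched. Idempotent.
#' @export
align_shared_days <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  day_sets <- lapply(tables, function(t) unique(as.character(t$samples$day)))
  shared <- Reduce(intersect, day_sets)
  if (!length(shared)) stop("empty intersection of sampling days")
  shared <- sort(shared)
  lapply(tables, function(t) {
    if (anyDuplicated(as.character(t$samples$day))) {
      stop("replicates must be averaged before aligning days")
    }
    idx <- match(shared, as.character(t$samples$day))
    ft_subset(t, samples = idx)
  })
}

#' Per-building day matrix
#'
#' Convenience accessor: the intensity matrix of a single-building table with
#' columns ordered by day and named by ISO date.
#'
#' @param table a single-building `feature_table`, replicates averaged.
#' @return Numeric matrix, features x days.
#' @export
day_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  days <- as.character(table$samples$day)
  if (anyDuplicated(days)) stop("replicates must be averaged first")
  ord <- order(days)
  m <- table$intensities[, ord, drop = FALSE]
  colnames(m) <- days[ord]
  m
}
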