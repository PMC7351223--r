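#' Similarity parameters
#'
#' Distance and correlation thresholds for fTD pair analysis: Euclidean
#' distance 1.5 (high stringency) and 2.82 (low stringency) on z-normalized
#' shared-day series, anticorrelation at Pearson r below -0.6, the
#' all-buildings negative screen at r below -0.2, and a minimum
#' retention-time separation of 30 s for the delta-mz/delta-rt summaries.
#'
#' @param d_high_stringency,d_low_stringency distance cutoffs.
#' @param r_anti,r_neg correlation cutoffs.
#' @param rt_min_delta minimum rt difference (seconds).
#' @return List of class `similarity_params`.
#' @export
similarity_params <- function(d_high_stringency = 1.5,
                              d_low_stringency = 2.82,
                              r_anti = -0.6, r_neg = -0.2,
                              rt_min_delta = 30) {
  stopifnot(d_high_stringency < d_low_stringency)
  structure(list(d_high_stringency = d_high_stringency,
                 d_low_stringency = d_low_stringency,
                 r_anti = r_anti, r_neg = r_neg,
                 rt_min_delta = rt_min_delta),
            class = "similarity_params")
}

z_matrix <- function(z) {
  stopifnot(inherits(z, "feature_table"), z$scale == "znorm")
  degen <- attr(z, "degenerate")
  keep <- !(z$features$feature_id %in% degen)
  list(m = z$intensities[keep, , drop = FALSE],
       features = z$features[keep, , drop = FALSE])
}

cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Pairwise fTD Euclidean distances
#'
#' Three comparison kinds: `intra_all` (all unordered distinct feature pairs
#' within one building, n(n-1)/2 records), `inter_all` (all cross pairs
#' between two buildings), `inter_one_to_one` (each feature against itself in
#' the other building). Series must be aligned on shared days; degenerate
#' features are excluded.
#'
#' @param z_a `znorm` feature table for the first building.
#' @param z_b second building's `znorm` table (ignored for `intra_all`).
#' @param kind comparison kind.
#' @return data.frame (feature_a, feature_b, distance, delta_mz, delta_rt).
#' @export
pair_distances <- function(z_a, z_b = NULL,
                           kind = c("intra_all", "inter_all",
                                    "inter_one_to_one")) {
  kind <- match.arg(kind)
  A <- z_matrix(z_a)
  if (kind == "intra_all") {
    n <- nrow(A$m)
    d <- as.vector(stats::dist(A$m))
    ii <- rep(seq_len(n - 1), times = (n - 1):1)
    jj <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
    return(data.frame(
      feature_a = A$features$feature_id[ii],
      feature_b = A$features$feature_id[jj],
      distance = d,
      delta_mz = abs(A$features$mz[ii] - A$features$mz[jj]),
      delta_rt = abs(A$features$rt[ii] - A$features$rt[jj])))
  }
  stopifnot(!is.null(z_b))
  B <- z_matrix(z_b)
  if (!identical(as.character(z_a$samples$day), as.character(z_b$samples$day))) {
    stop("day sets not aligned; use align_shared_days() first")
  }
  if (kind == "inter_one_to_one") {
    ids <- intersect(A$features$feature_id, B$features$feature_id)
    ia <- match(ids, A$features$feature_id)
    ib <- match(ids, B$features$feature_id)
    d <- sqrt(rowSums((A$m[ia, , drop = FALSE] - B$m[ib, , drop = FALSE])^2))
    return(data.frame(feature_a = ids, feature_b = ids, distance = d,
                      delta_mz = 0, delta_rt = 0))
  }
  D <- cross_dist(A$m, B$m)
  ii <- rep(seq_len(nrow(D)), times = ncol(D))
  jj <- rep(seq_len(ncol(D)), each = nrow(D))
  data.frame(
    feature_a = A$features$feature_id[ii],
    feature_b = B$features$feature_id[jj],
    distance = as.vector(D),
    delta_mz = abs(A$features$mz[ii] - B$features$mz[jj]),
    delta_rt = abs(A$features$rt[ii] - B$features$rt[jj]))
}

#' Fraction of pairs below a distance cutoff, with a delta-mz/rt histogram
#'
#' The fraction is count(distance < cutoff) / count(all records). The 2-D
#' histogram covers the sub-cutoff pairs whose rt difference exceeds
#' `rt_min_delta` (adduct/isotope pairs co-elute, so requiring a minimum rt
#' separation focuses the histogram on temporally similar but
#' chromatographically distinct pairs).
#'
#' @param records a [pair_distances()] data.frame.
#' @param d_cutoff distance cutoff.
#' @param rt_min_delta minimum rt difference (s) for histogram inclusion.
#' @param mz_breaks,rt_breaks histogram bin edges.
#' @return List: `fraction`, `n_below`, `n_total`, `histogram` (data.frame
#'   mz_bin, rt_bin, count), `bins` (the break vectors).
#' @export
threshold_summary <- function(records, d_cutoff, rt_min_delta = 30,
                              mz_breaks = seq(0, 800, by = 25),
                              rt_breaks = seq(0, 800, by = 25)) {
  if (!nrow(records)) stop("no pair records")
  below <- records$distance < d_cutoff
  hist_rec <- records[below & records$delta_rt > rt_min_delta, , drop = FALSE]
  mz_bin <- cut(pmin(hist_rec$delta_mz, max(mz_breaks) - 1e-9),
                breaks = mz_breaks, include.lowest = TRUE)
  rt_bin <- cut(pmin(hist_rec$delta_rt, max(rt_breaks) - 1e-9),
                breaks = rt_breaks, include.lowest = TRUE)
  counts <- as.data.frame(table(mz_bin = mz_bin, rt_bin = rt_bin),
                          responseName = "count")
  list(fraction = mean(below), n_below = sum(below), n_total = nrow(records),
       histogram = counts[counts$count > 0, ],
       bins = list(mz = mz_breaks, rt = rt_breaks))
}

pearson_matrix <- function(m) {
  stats::cor(t(m))
}

#' Screen for anticorrelated feature pairs within a building
#'
#' Returns unordered feature pairs whose fTD Pearson correlation is below
#' `r_cutoff`. Optionally keeps only pairs whose stationary statistical
#' properties are not significantly different: a two-sided Mann-Whitney test
#' on the two features' pre-normalization log2 day intensities, BH-corrected
#' across the tested pairs, must give Q > `q_max` (anticorrelated dynamics
#' with indistinguishable intensity distributions are invisible to
#' single-time-point sampling).
#'
#' @param z `znorm` feature table.
#' @param r_cutoff Pearson threshold (pairs strictly below are kept).
#' @param require_not_different apply the Mann-Whitney screen.
#' @param log2_table the building's log2 table (required when
#'   `require_not_different`).
#' @param q_max BH Q-value threshold (pairs with Q > `q_max` kept).
#' @return data.frame (feature_a, feature_b, r, delta_mz, delta_rt, and q
#'   when screened).
#' @export
anticorrelation_screen <- function(z, r_cutoff = -0.6,
                                   require_not_different = FALSE,
                                   log2_table = NULL, q_max = 0.05) {
  A <- z_matrix(z)
  if (ncol(A$m) < 3) stop("need at least 3 shared days")
  R <- pearson_matrix(A$m)
  sel <- which(upper.tri(R) & R < r_cutoff, arr.ind = TRUE)
  out <- data.frame(
    feature_a = A$features$feature_id[sel[, 1]],
    feature_b = A$features$feature_id[sel[, 2]],
    r = R[sel],
    delta_mz = abs(A$features$mz[sel[, 1]] - A$features$mz[sel[, 2]]),
    delta_rt = abs(A$features$rt[sel[, 1]] - A$features$rt[sel[, 2]]))
  if (require_not_different) {
    if (is.null(log2_table)) stop("log2_table required for the MW screen")
    m <- day_matrix(log2_table)
    p <- vapply(seq_len(nrow(out)), function(i) {
      a <- m[out$feature_a[i], ]
      b <- m[out$feature_b[i], ]
      if (identical(unname(a), unname(b))) return(1)
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))$p.value
    }, numeric(1))
    out$q <- stats::p.adjust(p, method = "BH")
    out <- out[out$q > q_max, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Feature pairs negatively correlated in every building
#'
#' Intersection over buildings of the unordered pairs with fTD Pearson
#' correlation below `r_neg`.
#'
#' @param z_list named list of per-building `znorm` tables over an identical
#'   feature universe (degenerate-free in all buildings).
#' @param r_neg correlation cutoff.
#' @return data.frame (feature_a, feature_b, r per building).
#' @export
triple_negative_pairs <- function(z_list, r_neg = -0.2) {
  stopifnot(length(z_list) >= 2)
  mats <- lapply(z_list, z_matrix)
  ids <- mats[[1]]$features$feature_id
  for (A in mats) {
    if (!identical(A$features$feature_id, ids)) {
      stop("mismatched feature universes across buildings")
    }
  }
  Rs <- lapply(mats, function(A) pearson_matrix(A$m))
  neg <- Reduce(`&`, lapply(Rs, function(R) R < r_neg))
  sel <- which(upper.tri(neg) & neg, arr.ind = TRUE)
  out <- data.frame(feature_a = ids[sel[, 1]], feature_b = ids[sel[, 2]])
  for (b in names(z_list)) {
    out[[paste0("r_", b)]] <- Rs[[b]][sel]
  }
  out
}

#' Cluster-center correlation matrix with Ward ordering
#'
#' Pairwise Pearson correlation between K-means cluster centers, plus the
#' leaf order of Ward hierarchical clustering on the correlation-derived
#' distance (1 - r), as used for correlation heat maps of center dynamics.
#'
#' @param model a `cluster_model` (or a centers matrix).
#' @return List: `correlation` (symmetric matrix, unit diagonal), `order`
#'   (leaf order), `hclust` (the dendrogram object).
#' @export
center_correlation <- function(model) {
  centers <- if (inherits(model, "cluster_model")) model$centers else model
  if (nrow(centers) < 2) stop("need at least 2 centers")
  if (any(apply(centers, 1, stats::sd) == 0)) {
    stop("constant center has undefined correlation")
  }
  R <- stats::cor(t(centers))
  hc <- stats::hclust(stats::as.dist(1 - R), method = "ward.D2")
  list(correlation = R, order = hc$order, hclust = hc)
}
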