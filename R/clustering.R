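#' Z-normalize feature temporal dynamics
#'
#' Per feature, subtracts the through-time mean and divides by the
#' through-time (population) SD of the day series, so every fTD is on a
#' comparable scale for clustering and distance calculations. Degenerate
#' (zero-SD) features become all-zero series and are flagged; they are
#' excluded from clustering and similarity analyses.
#'
#' @param table a single-building log2 `feature_table`, one column per day.
#' @return A `feature_table` on `znorm` scale with attribute `"degenerate"`
#'   (feature ids with zero through-time SD). Idempotent up to the degenerate
#'   flag.
#' @export
znormalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  m <- day_matrix(table)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, sd_ddof, ddof = 0)
  degen <- sdv == 0 | is.na(sdv)
  z <- (m - mu) / ifelse(degen, 1, sdv)
  z[degen, ] <- 0
  out <- feature_table(table$features,
                       table$samples[match(colnames(m),
                                           as.character(table$samples$day)), ],
                       z, scale = "znorm")
  attr(out, "degenerate") <- table$features$feature_id[degen]
  out
}

# K-means that tolerates k close to the number of distinct rows and recovers
# from empty-cluster failures of the default algorithm.
robust_kmeans <- function(m, k, nstart = 10) {
  udist <- unique(as.data.frame(m))
  if (k > nrow(udist)) stop("feature count (distinct series) below k")
  if (k == nrow(udist)) {
    key <- apply(m, 1, paste, collapse = "\r")
    ukey <- apply(udist, 1, paste, collapse = "\r")
    cl <- match(key, ukey)
    return(list(cluster = cl, centers = as.matrix(udist),
                tot.withinss = 0))
  }
  fit <- tryCatch(
    stats::kmeans(m, centers = k, nstart = nstart, iter.max = 100),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (!is.null(fit)) return(fit)
  # fall back: initialize at k distinct observed rows, MacQueen updates
  best <- NULL
  for (attempt in seq_len(50)) {
    init <- as.matrix(udist[sample.int(nrow(udist), k), , drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(m, centers = init,
                                     algorithm = "MacQueen", iter.max = 100)),
      error = function(e) NULL
    )
    if (is.null(fit) || any(fit$size == 0)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    if (attempt >= 10 && !is.null(best)) break
  }
  if (is.null(best)) stop("k-means failed to produce k non-empty clusters")
  best
}

#' Cluster feature temporal dynamics by K-means
#'
#' Euclidean K-means over z-normalized day series. Cluster ids are relabeled
#' in decreasing size order (cluster 1 is the largest) for stable reporting.
#' Degenerate (flagged zero-SD) features are excluded.
#'
#' @param z a `znorm`-scale `feature_table` from [znormalize()].
#' @param k number of clusters (default 100).
#' @param seed integer seed controlling initialization.
#' @param nstart random restarts.
#' @return List of class `cluster_model`: `k`, `assignment` (named integer
#'   vector, feature id -> cluster), `centers` (k x days matrix; each row the
#'   mean of its members' series), `sizes`, `inertia`, `member_sds` (per
#'   cluster, mean over members of the SD of member series around the
#'   center).
#' @export
cluster_ftds <- function(z, k = 100, seed = 1, nstart = 10) {
  stopifnot(inherits(z, "feature_table"), z$scale == "znorm")
  degen <- attr(z, "degenerate")
  keep <- !(z$features$feature_id %in% degen)
  m <- z$intensities[keep, , drop = FALSE]
  colnames(m) <- as.character(z$samples$day)
  if (nrow(m) < k) stop("feature count below k")
  set.seed(seed)
  fit <- robust_kmeans(m, k, nstart = nstart)
  cl <- fit$cluster
  sizes <- tabulate(cl, nbins = k)
  relabel <- order(sizes, decreasing = TRUE)
  newid <- integer(k)
  newid[relabel] <- seq_len(k)
  cl <- newid[cl]
  # recompute centers as member means under the new labels
  centers <- t(vapply(seq_len(k), function(ci) {
    colMeans(m[cl == ci, , drop = FALSE])
  }, numeric(ncol(m))))
  colnames(centers) <- colnames(m)
  member_sds <- vapply(seq_len(k), function(ci) {
    mm <- m[cl == ci, , drop = FALSE]
    mean(apply(sweep(mm, 2, centers[ci, ], "-"), 1,
               function(r) sqrt(mean(r^2))))
  }, numeric(1))
  names(cl) <- rownames(m)
  structure(list(k = k, assignment = cl, centers = centers,
                 sizes = tabulate(cl, nbins = k),
                 inertia = sum((m - centers[cl, , drop = FALSE])^2),
                 member_sds = member_sds,
                 days = colnames(m)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model: k=%d over %d features, %d days; inertia %.3f\n",
              x$k, length(x$assignment), length(x$days), x$inertia))
  cat("  largest clusters:", paste(utils::head(x$sizes, 5), collapse = ", "),
      "\n")
  invisible(x)
}

rbf_kernel <- function(t1, t2, length_scale) {
  d <- outer(t1, t2, "-")
  exp(-d^2 / (2 * length_scale^2))
}

#' Fit a Gaussian process to a cluster-center day series
#'
#' GP regression with a squared-exponential (RBF) kernel of length scale
#' 0.125 day (3 hours) and unit signal variance; the cluster's mean member SD
#' enters as homoscedastic observation noise (variance = mean member SD
#' squared) together with a small jitter `alpha`. With a 3-hour length scale
#' the correlation between days is e^-32, so the posterior reverts to the
#' prior (mean 0, SD 1 on the z scale) away from sampled days: day-to-day
#' dynamics carry no predictive information under this model.
#'
#' @param center numeric day series (z scale cluster center).
#' @param member_sds per-member SDs around the center (their mean sets the
#'   noise level); a single number is used as the noise SD directly.
#' @param times numeric observation times in days; default
#'   `seq_along(center) - 1` or, if `center` has day names, days since the
#'   first day.
#' @param length_scale RBF length scale in days.
#' @param alpha jitter added to the kernel diagonal.
#' @return Object of class `gp_fit`; use [predict.gp_fit()].
#' @export
fit_cluster_gp <- function(center, member_sds = 0, times = NULL,
                           length_scale = 0.125, alpha = 1e-4) {
  if (any(!is.finite(center))) stop("non-finite center values")
  if (length(center) < 2) stop("need at least 2 time points")
  if (is.null(times)) {
    d <- if (!is.null(names(center))) {
      tryCatch(as.Date(names(center)), error = function(e) NULL)
    } else NULL
    times <- if (!is.null(d) && !anyNA(d)) {
      as.numeric(d - d[1])
    } else {
      seq_along(center) - 1
    }
  }
  noise_sd <- mean(member_sds)
  K <- rbf_kernel(times, times, length_scale)
  Ky <- K + diag(noise_sd^2 + alpha, length(times))
  L <- chol(Ky)
  alpha_vec <- backsolve(L, forwardsolve(t(L), center))
  structure(list(times = times, y = center, L = L, alpha_vec = alpha_vec,
                 length_scale = length_scale, noise_sd = noise_sd,
                 alpha = alpha),
            class = "gp_fit")
}

#' Posterior mean and SD of a fitted cluster GP
#'
#' @param object a `gp_fit`.
#' @param newtimes numeric query times in days.
#' @param ... unused.
#' @return data.frame (time, mean, sd) of the noise-free posterior.
#' @export
predict.gp_fit <- function(object, newtimes, ...) {
  ks <- rbf_kernel(newtimes, object$times, object$length_scale)
  mu <- as.numeric(ks %*% object$alpha_vec)
  v <- forwardsolve(t(object$L), t(ks))
  var_post <- pmax(1 - colSums(v^2), 0)
  data.frame(time = newtimes, mean = mu, sd = sqrt(var_post))
}

#' Sample autocorrelation of a day series
#'
#' Standard sample ACF (lag 0 = 1) as used to show that cluster dynamics
#' carry essentially no information across a one-day lag.
#'
#' @param series numeric series.
#' @param max_lag maximum lag (must be below the series length).
#' @return Named numeric vector of ACF values for lags `0:max_lag`.
#' @export
autocorrelation <- function(series, max_lag) {
  if (length(series) <= max_lag) stop("series length must exceed max_lag")
  if (stats::sd(series) == 0) stop("constant series has undefined ACF")
  a <- stats::acf(series, lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf[, 1, 1]
  names(a) <- 0:max_lag
  a
}

#' Waste-stream mixing experiment
#'
#' For each stream count k, mixes the observed building table with k
#' simulated streams ([simulate_extra_streams()]), z-normalizes, clusters
#' with K-means, and sums the Euclidean distances between all pairs of
#' cluster centers. Shrinking of this statistic with k quantifies how quickly
#' distinctive single-day dynamics are averaged away downstream. k = 0 is the
#' unmixed study and is deterministic.
#'
#' @param table a single-building log2 `feature_table`, one column per day.
#' @param ks stream counts to test.
#' @param k_clusters number of K-means clusters.
#' @param n_reps repeats per k (SD reported over repeats).
#' @param method mixing method, see [simulate_extra_streams()].
#' @param seed master seed; per-(k, rep) seeds are derived from it.
#' @return List: `records` data.frame (k, rep, statistic) and `summary`
#'   data.frame (k, mean, sd).
#' @export
mixing_experiment <- function(table, ks = c(0, 10, 25, 50), k_clusters = 100,
                              n_reps = 10, method = "gaussian", seed = 1) {
  stopifnot(inherits(table, "feature_table"), all(ks >= 0))
  stat_one <- function(k, rep_i) {
    sub_seed <- (seed + 7919L * k + 104729L * rep_i) %% .Machine$integer.max
    mixed <- simulate_extra_streams(table, k, method = method,
                                    seed = sub_seed)
    z <- znormalize(mixed)
    cm <- cluster_ftds(z, k = k_clusters, seed = sub_seed)
    sum(stats::dist(cm$centers))
  }
  recs <- do.call(rbind, lapply(ks, function(k) {
    reps <- if (k == 0) 1L else n_reps
    data.frame(k = k, rep = seq_len(reps),
               statistic = vapply(seq_len(reps),
                                  function(r) stat_one(k, r), numeric(1)))
  }))
  summ <- do.call(rbind, lapply(split(recs, recs$k), function(d) {
    data.frame(k = d$k[1], mean = mean(d$statistic),
               sd = if (nrow(d) > 1) stats::sd(d$statistic) else 0)
  }))
  rownames(summ) <- NULL
  list(records = recs, summary = summ[order(summ$k), ])
}
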