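# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached_study <- function(seed = 7) {
  key <- paste0("study_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_study(synthetic_config(seed = seed))
  }
  .fixture_cache[[key]]
}

# Preprocessed default study: per-building log2 tables, shared-day aligned
# tables and z-normalized series.
cached_pipeline <- function(seed = 7) {
  key <- paste0("pp_", seed)
  if (is.null(.fixture_cache[[key]])) {
    g <- cached_study(seed)
    pp <- preprocess(g$table)
    al <- align_shared_days(pp$tables)
    zs <- lapply(al, znormalize)
    .fixture_cache[[key]] <- list(truth = g$truth, tables = pp$tables,
                                  log = pp$log, aligned = al, z = zs)
  }
  .fixture_cache[[key]]
}

# Minimal hand-built table: nf features x days for one building, no QC/blank.
make_building_table <- function(m, mz = NULL, rt = NULL, building = "B1",
                                days = NULL, scale = "log2") {
  nf <- nrow(m)
  nd <- ncol(m)
  if (is.null(mz)) mz <- seq(100, 100 + nf - 1)
  if (is.null(rt)) rt <- seq(60, 60 + 10 * (nf - 1), length.out = nf)
  if (is.null(days)) days <- as.Date("2017-10-02") + seq_len(nd) - 1
  feature_table(
    features = data.frame(feature_id = sprintf("T%03d", seq_len(nf)),
                          mz = mz, rt = rt),
    samples = data.frame(sample_id = paste0(building, "_", days),
                         building = building, day = days,
                         weekday_flag = NA, replicate_index = 1L,
                         run_order = seq_len(nd), role = "study"),
    intensities = m, scale = scale)
}

# Exact-formula GP posterior oracle: naive kernel construction + solve().
gp_posterior_oracle <- function(times, y, noise_sd, query,
                                length_scale = 0.125, alpha = 1e-4) {
  n <- length(times)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- exp(-(times[i] - times[j])^2 / (2 * length_scale^2))
    }
  }
  Ky <- K + diag(noise_sd^2 + alpha, n)
  Kinv <- solve(Ky)
  t(vapply(query, function(tq) {
    ks <- vapply(times, function(t) {
      exp(-(tq - t)^2 / (2 * length_scale^2))
    }, numeric(1))
    mu <- as.numeric(ks %*% Kinv %*% y)
    v <- 1 - as.numeric(ks %*% Kinv %*% ks)
    c(mean = mu, sd = sqrt(max(v, 0)))
  }, numeric(2)))
}

# Brute-force pair statistics for oracle comparisons.
brute_euclidean <- function(a, b) sqrt(sum((a - b)^2))
brute_pearson <- function(a, b) {
  am <- a - mean(a)
  bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}
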