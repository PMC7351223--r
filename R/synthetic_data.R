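#' Configuration for the synthetic multi-building study generator
#'
#' The defaults emulate the structure of a three-building, three-month
#' longitudinal wastewater study: 16 shared sampling days (dense in the first
#' three weeks, then weekly-ish, with several Saturdays), a few
#' building-specific extra days and replicate days, log2 intensities roughly
#' in 10-30, a majority of temporally stable features (through-time log2 SD
#' below 2) and three unstable classes, planted groups of features sharing a
#' latent day-effect time course, adduct pairs that share a time course and an
#' exact adduct mass relation, building marker features, weekday-elevated
#' features in building 1, multiplicative run-order drift visible in pooled-QC
#' samples over two batches, and a solvent-blank background.
#'
#' @param n_buildings number of buildings.
#' @param n_days_shared number of sampling days shared by all buildings.
#' @param n_days_extra_per_building building-specific additional days.
#' @param n_replicate_days number of shared days measured in replicate.
#' @param n_replicates replicates on those days.
#' @param n_features total number of features.
#' @param frac_stable fraction of features planted temporally stable.
#' @param class_mix length-3 fractions (summing to 1) of unstable Classes
#'   1/2/3 among unstressed unstable features.
#' @param n_dynamic_groups number of planted shared-dynamics groups.
#' @param group_size_range inclusive (min, max) group sizes.
#' @param n_adduct_pairs number of planted adduct pairs.
#' @param n_building_marker_features features with a mean shift in one
#'   building.
#' @param marker_shift marker mean shift, log2 units.
#' @param n_weekday_features features elevated on weekdays in building 1.
#' @param weekday_shift weekday elevation, log2 units.
#' @param n_cv_violators features with irreproducible pooled-QC values
#'   (planted CV-filter violators).
#' @param n_low_features features at blank-background level (planted
#'   sum-filter violators).
#' @param qc_every a QC sample every this many study injections.
#' @param drift_amplitude multiplicative run-order drift range; the drift
#'   curve runs geometrically from 1/amplitude to amplitude over each batch.
#'   1.0 means no drift.
#' @param blank_level blank background, log2 units.
#' @param noise_sd per-measurement noise, log2 units.
#' @param qc_noise_sd pooled-QC measurement noise, log2 units.
#' @param seed integer seed; all generator randomness flows from it.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_buildings = 3,
                             n_days_shared = 16,
                             n_days_extra_per_building = 4,
                             n_replicate_days = 3,
                             n_replicates = 2,
                             n_features = 300,
                             frac_stable = 0.6,
                             class_mix = c(0.35, 0.3, 0.35),
                             n_dynamic_groups = 5,
                             group_size_range = c(6, 12),
                             n_adduct_pairs = 5,
                             n_building_marker_features = 9,
                             marker_shift = 4,
                             n_weekday_features = 30,
                             weekday_shift = 1.5,
                             n_cv_violators = 5,
                             n_low_features = 10,
                             qc_every = 6,
                             drift_amplitude = 1.25,
                             blank_level = 4,
                             noise_sd = 0.5,
                             qc_noise_sd = 0.15,
                             seed = 1) {
  stopifnot(frac_stable >= 0, frac_stable <= 1,
            length(class_mix) == 3, all(class_mix >= 0),
            abs(sum(class_mix) - 1) < 1e-9,
            n_buildings >= 1, n_days_shared >= 2, n_features >= 1,
            length(group_size_range) == 2,
            group_size_range[1] <= group_size_range[2],
            group_size_range[1] >= 2,
            qc_every >= 1, drift_amplitude >= 1, noise_sd >= 0)
  structure(as.list(environment()), class = "synthetic_config")
}

# Shared sampling-day calendar: dense first ~3 weeks, then sparser, with
# Saturdays mixed in (offsets congruent to 5 mod 7 from the Monday start).
shared_day_offsets <- function(n) {
  base <- c(0, 1, 2, 4, 5, 8, 10, 12, 16, 19, 23, 30, 37, 47, 61, 75)
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, 75 + 7 * seq_len(n - length(base)))
}

candidate_extra_offsets <- function() {
  c(3, 6, 9, 11, 13, 15, 17, 18, 20, 24, 25, 26, 31, 32, 38, 39,
    44, 45, 51, 52, 58, 59, 65, 66, 72, 73)
}

# Per-day dynamics (deviation from the feature's base mean) for one
# feature-building series, by stability archetype.
archetype_series <- function(type, n_days, params) {
  switch(type,
    stable = stats::rnorm(n_days, 0, params$stable_day_sd),
    class1 = {
      # low baseline with occasional large spikes (at least 2 spike days)
      nspike <- max(2L, stats::rbinom(1, n_days, 0.15))
      spikes <- sample.int(n_days, min(nspike, n_days))
      v <- stats::rnorm(n_days, 0, 0.6)
      v[spikes] <- v[spikes] + stats::runif(length(spikes), 6, 9)
      v
    },
    class2 = stats::rnorm(n_days, 0, 4.5),
    class3 = {
      # mid-level with irregular moderate jumps
      v <- stats::rnorm(n_days, 0, 1)
      jmp <- stats::runif(n_days) < 0.3
      v[jmp] <- v[jmp] + sample(c(-1, 1), sum(jmp), TRUE) *
        stats::runif(sum(jmp), 3, 6)
      v
    },
    stop("unknown archetype ", type)
  )
}

#' Generate a synthetic multi-building longitudinal study
#'
#' Produces a raw-scale feature table (study, QC and blank samples over two
#' run-order batches, with multiplicative drift applied) plus a ground-truth
#' object from which every planted structure is recoverable by feature id.
#'
#' Planted structure, on the log2 scale: stable features with small day
#' effects; unstable Class 1 (low median, occasional spikes), Class 2
#' (high-variance day effects, SD > 3.5) and Class 3 (mid-level irregular
#' jumps); dynamic groups whose members share a per-building latent day
#' course scaled per feature; adduct pairs sharing one course with m/z values
#' related by exact adduct mass algebra; marker features shifted by
#' `marker_shift` in one building; weekday-elevated features in building 1;
#' pooled-QC CV violators; and blank-level features that fail the
#' cross-building sum filter.
#'
#' @param config a [synthetic_config()].
#' @return List with `table` (raw-scale [feature_table()]) and `truth`
#'   (ground-truth list: per-feature roles, per-building stability labels and
#'   classes, group membership, adduct pair links, markers, weekday features,
#'   planted filter violators, and the true drift curve per batch).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  buildings <- paste0("B", seq_len(cfg$n_buildings))

  # ---- feature role allocation -------------------------------------------
  group_sizes <- if (cfg$n_dynamic_groups > 0) {
    sample(seq(cfg$group_size_range[1], cfg$group_size_range[2]),
           cfg$n_dynamic_groups, replace = TRUE)
  } else integer(0)
  n_planted <- cfg$n_low_features + cfg$n_cv_violators +
    2L * cfg$n_adduct_pairs + sum(group_sizes) +
    cfg$n_building_marker_features
  if (n_planted > cfg$n_features) {
    stop("infeasible config: planted structures exceed feature count")
  }
  n_stable_target <- round(cfg$frac_stable * cfg$n_features)
  n_stable_planted <- cfg$n_low_features + cfg$n_cv_violators +
    cfg$n_building_marker_features
  n_rest <- cfg$n_features - n_planted
  n_rest_stable <- n_stable_target - n_stable_planted
  n_rest_unstable <- n_rest - n_rest_stable
  if (n_rest_stable < cfg$n_weekday_features || n_rest_unstable < 0) {
    stop("infeasible config: stable fraction incompatible with planted roles")
  }

  ids <- sprintf("F%04d", seq_len(cfg$n_features))
  role <- character(cfg$n_features)
  cursor <- 0L
  take <- function(n) {
    out <- cursor + seq_len(n)
    cursor <<- cursor + n
    out
  }
  i_low <- take(cfg$n_low_features);            role[i_low] <- "low"
  i_cv <- take(cfg$n_cv_violators);             role[i_cv] <- "cv_violator"
  i_add <- take(2L * cfg$n_adduct_pairs);       role[i_add] <- "adduct"
  i_grp <- take(sum(group_sizes));              role[i_grp] <- "group"
  i_mark <- take(cfg$n_building_marker_features); role[i_mark] <- "marker"
  i_wk <- take(cfg$n_weekday_features);         role[i_wk] <- "stable"
  i_rs <- take(n_rest_stable - cfg$n_weekday_features)
  role[i_rs] <- "stable"
  i_ru <- take(n_rest_unstable);                role[i_ru] <- "unstable"
  i_stable_like <- c(i_low, i_cv, i_mark, i_wk, i_rs)

  group_id <- rep(NA_integer_, cfg$n_features)
  group_id[i_grp] <- rep(seq_along(group_sizes), group_sizes)

  # ---- m/z, rt; adduct pairs tied to packaged compounds ------------------
  mz <- stats::runif(cfg$n_features, 80, 800)
  rt <- stats::runif(cfg$n_features, 30, 700)
  adduct_pairs <- NULL
  if (cfg$n_adduct_pairs > 0) {
    comp <- load_compound_table()
    comp <- comp[comp$monoisotopic_mass > 120 & comp$monoisotopic_mass < 700, ]
    if (nrow(comp) < cfg$n_adduct_pairs) stop("compound table too small")
    pick <- sample.int(nrow(comp), cfg$n_adduct_pairs)
    rules <- adduct_rules()
    rule_mh <- rules[rules$name == "[M-H]-", ]
    alt_names <- rep(c("[M-H-H2O]-", "[M+Cl]-"),
                     length.out = cfg$n_adduct_pairs)
    recs <- vector("list", cfg$n_adduct_pairs)
    for (p in seq_len(cfg$n_adduct_pairs)) {
      M <- comp$monoisotopic_mass[pick[p]]
      fa <- i_add[2 * p - 1]
      fb <- i_add[2 * p]
      rule_alt <- rules[rules$name == alt_names[p], ]
      mz[fa] <- M * rule_mh$multiplicity + rule_mh$mass_delta
      mz[fb] <- M * rule_alt$multiplicity + rule_alt$mass_delta
      rt[fb] <- rt[fa] + stats::runif(1, -3, 3)  # adducts co-elute
      recs[[p]] <- data.frame(
        pair_id = p, feature_a = ids[fa], feature_b = ids[fb],
        rule_a = rule_mh$name, rule_b = rule_alt$name,
        compound = comp$name[pick[p]], neutral_mass = M,
        delta_mz = abs(mz[fb] - mz[fa]))
    }
    adduct_pairs <- do.call(rbind, recs)
  }

  # ---- day calendars ------------------------------------------------------
  origin <- as.Date("2017-10-02")  # a Monday
  shared_days <- origin + shared_day_offsets(cfg$n_days_shared)
  cand <- setdiff(candidate_extra_offsets(), shared_day_offsets(cfg$n_days_shared))
  extra_days <- lapply(buildings, function(b) {
    if (cfg$n_days_extra_per_building == 0) return(as.Date(character(0)))
    origin + sort(sample(cand, cfg$n_days_extra_per_building))
  })
  names(extra_days) <- buildings
  days_by_b <- lapply(buildings, function(b) {
    sort(unique(c(shared_days, extra_days[[b]])))
  })
  names(days_by_b) <- buildings
  rep_days <- shared_days[seq_len(min(cfg$n_replicate_days,
                                      length(shared_days)))]

  # ---- feature/building parameters ---------------------------------------
  base_mean <- numeric(cfg$n_features)
  base_mean[i_stable_like] <- stats::runif(length(i_stable_like), 14, 26)
  base_mean[i_low] <- cfg$blank_level + stats::runif(length(i_low), 0.2, 1)
  stable_day_sd <- stats::runif(cfg$n_features, 0.3, 1.0)
  stable_day_sd[i_low] <- 0.2

  uclass <- rep(NA_integer_, cfg$n_features)
  if (length(i_ru)) {
    uclass[i_ru] <- sample.int(3, length(i_ru), TRUE, prob = cfg$class_mix)
  }
  base_mean[i_ru[uclass[i_ru] == 1]] <-
    stats::runif(sum(uclass[i_ru] == 1), 11, 13)
  base_mean[i_ru[uclass[i_ru] == 2]] <-
    stats::runif(sum(uclass[i_ru] == 2), 14, 22)
  # class 3 and group/adduct baselines sit clear of the median-14 class
  # boundary even after blank subtraction downstream
  base_mean[i_ru[uclass[i_ru] == 3]] <-
    stats::runif(sum(uclass[i_ru] == 3), 18.5, 24)
  base_mean[i_grp] <- stats::runif(length(i_grp), 18, 24)
  base_mean[i_add] <- stats::runif(length(i_add), 18, 24)
  uclass[c(i_grp, i_add)] <- 3L

  # building-specific instability for base unstable features: unstable in all
  # buildings about a third of the time, otherwise in a random 1-2 buildings
  unstable_in <- matrix(FALSE, cfg$n_features, cfg$n_buildings,
                        dimnames = list(ids, buildings))
  for (f in i_ru) {
    if (stats::runif(1) < 0.34 || cfg$n_buildings == 1) {
      unstable_in[f, ] <- TRUE
    } else {
      k <- sample(seq_len(max(1, cfg$n_buildings - 1)), 1)
      unstable_in[f, sample.int(cfg$n_buildings, k)] <- TRUE
    }
  }
  unstable_in[c(i_grp, i_add), ] <- TRUE

  marker_building <- rep(NA_character_, cfg$n_features)
  marker_dir <- rep(NA_real_, cfg$n_features)
  if (length(i_mark)) {
    marker_building[i_mark] <- buildings[1 + (seq_along(i_mark) - 1) %%
                                           cfg$n_buildings]
    marker_dir[i_mark] <- sample(c(-1, 1), length(i_mark), TRUE)
  }
  grp_scale <- rep(NA_real_, cfg$n_features)
  grp_scale[i_grp] <- stats::runif(length(i_grp), 0.9, 1.3)

  # ---- per-building per-day core values (log2, noiseless) ----------------
  core <- lapply(buildings, function(b) {
    matrix(NA_real_, cfg$n_features, length(days_by_b[[b]]),
           dimnames = list(ids, as.character(days_by_b[[b]])))
  })
  names(core) <- buildings
  ap_params <- list(stable_day_sd = NA)
  for (bi in seq_along(buildings)) {
    b <- buildings[bi]
    nd <- length(days_by_b[[b]])
    wk <- is_weekday(days_by_b[[b]])
    group_course <- if (cfg$n_dynamic_groups > 0) {
      matrix(stats::rnorm(cfg$n_dynamic_groups * nd, 0, 2.8),
             cfg$n_dynamic_groups, nd)
    } else NULL
    pair_course <- if (cfg$n_adduct_pairs > 0) {
      matrix(stats::rnorm(cfg$n_adduct_pairs * nd, 0, 3.2),
             cfg$n_adduct_pairs, nd)
    } else NULL
    for (f in seq_len(cfg$n_features)) {
      r <- role[f]
      v <- base_mean[f]
      if (r %in% c("low", "cv_violator", "stable", "marker")) {
        dyn <- archetype_series("stable", nd,
                                list(stable_day_sd = stable_day_sd[f]))
      } else if (r == "group") {
        dyn <- grp_scale[f] * group_course[group_id[f], ]
      } else if (r == "adduct") {
        p <- ceiling((match(f, i_add)) / 2)
        dyn <- pair_course[p, ]
      } else {  # base unstable
        if (unstable_in[f, bi]) {
          dyn <- archetype_series(paste0("class", uclass[f]), nd, ap_params)
        } else {
          dyn <- archetype_series("stable", nd,
                                  list(stable_day_sd = stable_day_sd[f]))
        }
      }
      if (!is.na(marker_building[f]) && marker_building[f] == b) {
        v <- v + marker_dir[f] * cfg$marker_shift
      }
      vals <- v + dyn
      if (f %in% i_wk && bi == 1) vals <- vals + cfg$weekday_shift * wk
      core[[b]][f, ] <- vals
    }
  }

  # planted stability labels per feature per building
  stab <- matrix("stable", cfg$n_features, cfg$n_buildings,
                 dimnames = list(ids, buildings))
  stab_class <- matrix(NA_integer_, cfg$n_features, cfg$n_buildings,
                       dimnames = list(ids, buildings))
  for (bi in seq_along(buildings)) {
    uns <- unstable_in[, bi]
    stab[uns, bi] <- "unstable"
    stab_class[uns, bi] <- uclass[uns]
  }

  # ---- assemble samples, run order, drift --------------------------------
  study <- do.call(rbind, lapply(buildings, function(b) {
    dd <- days_by_b[[b]]
    do.call(rbind, lapply(seq_along(dd), function(j) {
      nrep <- if (dd[j] %in% rep_days) cfg$n_replicates else 1L
      data.frame(building = b, day = dd[j], replicate_index = seq_len(nrep))
    }))
  }))
  study$sample_id <- paste0(study$building, "_", study$day,
                            ifelse(study$replicate_index > 1,
                                   paste0("_r", study$replicate_index), ""))
  # two batches split by calendar midpoint, injections shuffled within batch
  midpoint <- stats::median(as.numeric(shared_days))
  study$batch <- ifelse(as.numeric(study$day) <= midpoint, 1L, 2L)

  all_samples <- list()
  drift_truth <- list()
  for (batch in 1:2) {
    st <- study[study$batch == batch, , drop = FALSE]
    st <- st[sample.int(nrow(st)), , drop = FALSE]
    n_st <- nrow(st)
    n_qc <- max(2L, ceiling(n_st / cfg$qc_every) + 1L)
    # interleave: QC first, then blocks of qc_every study samples, QC between
    rows <- list()
    qi <- 0L
    add_qc <- function() {
      qi <<- qi + 1L
      data.frame(building = NA, day = as.Date(NA), replicate_index = 1L,
                 sample_id = sprintf("QC_b%d_%02d", batch, qi),
                 batch = batch, role = "qc")
    }
    rows[[length(rows) + 1L]] <- add_qc()
    for (blk in seq_len(ceiling(n_st / cfg$qc_every))) {
      lo <- (blk - 1L) * cfg$qc_every + 1L
      hi <- min(blk * cfg$qc_every, n_st)
      chunk <- st[lo:hi, , drop = FALSE]
      chunk$role <- "study"
      rows[[length(rows) + 1L]] <- chunk
      rows[[length(rows) + 1L]] <- add_qc()
    }
    bl <- data.frame(building = NA, day = as.Date(NA), replicate_index = 1L,
                     sample_id = sprintf("BLANK_b%d_%d", batch, 1:2),
                     batch = batch, role = "blank")
    seqd <- do.call(rbind, c(rows, list(bl)))
    seqd$run_order <- seq_len(nrow(seqd))
    all_samples[[batch]] <- seqd
    rng <- range(seqd$run_order)
    u <- (seqd$run_order - rng[1]) / max(1, diff(rng))
    drift_truth[[batch]] <- data.frame(
      run_order = seqd$run_order,
      multiplier = cfg$drift_amplitude^(2 * u - 1))
  }
  samples <- do.call(rbind, all_samples)
  samples$weekday_flag <- is_weekday(samples$day)
  rownames(samples) <- NULL

  # ---- intensities --------------------------------------------------------
  pooled_mean <- rowMeans(do.call(cbind, core))
  qc_sd <- rep(cfg$qc_noise_sd, cfg$n_features)
  qc_sd[i_cv] <- 12
  # adducts of one compound share the ionization source: tighter noise
  noise_sd_f <- rep(cfg$noise_sd, cfg$n_features)
  noise_sd_f[i_add] <- cfg$noise_sd / 2
  log2_vals <- matrix(NA_real_, cfg$n_features, nrow(samples),
                      dimnames = list(ids, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    sj <- samples[j, ]
    if (sj$role == "study") {
      cv <- core[[sj$building]][, as.character(sj$day)]
      log2_vals[, j] <- cv + stats::rnorm(cfg$n_features, 0, noise_sd_f)
    } else if (sj$role == "qc") {
      log2_vals[, j] <- pooled_mean + stats::rnorm(cfg$n_features, 0, qc_sd)
    } else {
      log2_vals[, j] <- stats::rnorm(cfg$n_features, cfg$blank_level, 0.3)
    }
  }
  raw <- 2^log2_vals
  for (batch in 1:2) {
    dt <- drift_truth[[batch]]
    jj <- which(samples$batch == batch & samples$role != "blank")
    mult <- dt$multiplier[match(samples$run_order[jj], dt$run_order)]
    raw[, jj] <- sweep(raw[, jj, drop = FALSE], 2, mult, "*")
  }

  features <- data.frame(feature_id = ids, mz = mz, rt = rt,
                         ionization_mode = "negative")
  table <- feature_table(features, samples, raw, scale = "raw")

  truth <- list(
    config = cfg,
    roles = data.frame(feature_id = ids, role = role,
                       group_id = group_id,
                       marker_building = marker_building,
                       marker_direction = marker_dir),
    stability = stab,
    stability_class = stab_class,
    groups = split(ids[i_grp], group_id[i_grp]),
    adduct_pairs = adduct_pairs,
    markers = data.frame(feature_id = ids[i_mark],
                         building = marker_building[i_mark],
                         shift = marker_dir[i_mark] * cfg$marker_shift),
    weekday_features = ids[i_wk],
    weekday_building = if (cfg$n_buildings >= 1) buildings[1] else NULL,
    cv_violators = ids[i_cv],
    low_features = ids[i_low],
    shared_days = shared_days,
    drift = drift_truth
  )
  list(table = table, truth = truth)
}

#' Mix a building's observed dynamics with simulated waste streams
#'
#' Emulates sampling further downstream (or over longer aggregation): the
#' observed per-day series is averaged with `k` simulated independent streams.
#' Under `"gaussian"`, each stream draws i.i.d. values matching the observed
#' per-feature marginal mean and (population) SD; under `"permute_days"`,
#' each stream is an independent day permutation of the observed series per
#' feature. `k = 0` returns the input unchanged.
#'
#' @param table a single-building log2-scale `feature_table`, one column per
#'   day.
#' @param k number of simulated streams (>= 0).
#' @param method `"gaussian"` or `"permute_days"`.
#' @param seed integer seed.
#' @return A `feature_table` holding the per-day arithmetic mean of the
#'   observed and the `k` simulated streams.
#' @export
simulate_extra_streams <- function(table, k,
                                   method = c("gaussian", "permute_days"),
                                   seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method)
  if (k < 0) stop("k must be non-negative")
  if (k == 0) return(table)
  set.seed(seed)
  x <- table$intensities
  nd <- ncol(x)
  acc <- x
  for (s in seq_len(k)) {
    sim <- if (method == "gaussian") {
      mu <- rowMeans(x)
      sdv <- apply(x, 1, sd_ddof, ddof = 0)
      matrix(stats::rnorm(length(x), mean = rep(mu, nd),
                          sd = rep(sdv, nd)), nrow(x), nd)
    } else {
      t(apply(x, 1, function(v) v[sample.int(nd)]))
    }
    acc <- acc + sim
  }
  feature_table(table$features, table$samples, acc / (k + 1),
                scale = table$scale)
}
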