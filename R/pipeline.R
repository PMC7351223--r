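#' End-to-end pipeline over a raw study table
#'
#' Runs the stages in fixed order — preprocess, stability, clustering,
#' similarity, classification, annotation, grouping — writing each stage's
#' outputs as CSV/JSON under `outdir` and a provenance log with the MD5 hash
#' of every file. Identical inputs, configuration and seed give identical
#' hashes. Stages can be toggled; later stages consume earlier stages'
#' in-memory results, never their files.
#'
#' @param table a raw-scale `feature_table` (study + QC + blank samples), or
#'   `NULL` to generate one from `synth_config`.
#' @param outdir output directory (created).
#' @param seed master seed; per-stage seeds are derived by fixed offsets.
#' @param stages character vector of stages to run.
#' @param synth_config optional [synthetic_config()] used when `table` is
#'   `NULL`.
#' @param preprocess_params,stability_params,ml_params,grouping_params
#'   stage parameter objects.
#' @param k_clusters K-means cluster count (capped at the feature count).
#' @param ppm_max annotation ppm tolerance.
#' @return List of stage results, invisibly; `provenance` holds the file
#'   hash log (also written to `provenance.json`).
#' @export
run_pipeline <- function(table = NULL, outdir, seed = 1,
                         stages = c("preprocess", "stability", "cluster",
                                    "similarity", "classify", "annotate",
                                    "group"),
                         synth_config = synthetic_config(seed = seed),
                         preprocess_params = ftdkit::preprocess_params(),
                         stability_params = ftdkit::stability_params(),
                         ml_params = ftdkit::ml_params(seed = seed + 40L),
                         grouping_params = ftdkit::grouping_params(),
                         k_clusters = 100, ppm_max = 5) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }
  res <- list()
  if (is.null(table)) {
    gen <- generate_study(synth_config)
    table <- gen$table
    res$truth <- gen$truth
  }

  if (!"preprocess" %in% stages) stop("the preprocess stage is required")
  pp <- preprocess(table, preprocess_params)
  res$tables <- pp$tables
  res$preprocess_log <- pp$log
  for (b in names(pp$tables)) {
    write_feature_table(pp$tables[[b]],
                        file.path(outdir, paste0("log2_", b, ".csv")),
                        file.path(outdir, paste0("log2_", b, "_meta.csv")))
    files <- c(files, file.path(outdir, paste0("log2_", b, ".csv")),
               file.path(outdir, paste0("log2_", b, "_meta.csv")))
  }
  buildings <- names(pp$tables)

  if ("stability" %in% stages) {
    reports <- lapply(pp$tables, function(t) {
      classify_stability(summarize_stability(t, ddof = stability_params$ddof),
                         stability_params)
    })
    res$stability <- reports
    stab_df <- Reduce(function(a, b) merge(a, b, by = c("feature_id", "mz", "rt")),
                      lapply(buildings, function(b) {
                        r <- reports[[b]][, c("feature_id", "mz", "rt",
                                              "label", "unstable_class")]
                        names(r)[4:5] <- paste0(c("label_", "class_"), b)
                        r
                      }))
    emit(stab_df, "stability.csv")
    if (length(buildings) >= 3) {
      res$kw <- kw_screen(pp$tables, q_max = stability_params$kw_q_max)
      emit(res$kw, "kw_screen.csv")
    }
  }

  aligned <- align_shared_days(pp$tables)
  zs <- lapply(aligned, znormalize)
  res$z <- zs

  if ("cluster" %in% stages) {
    kc <- min(k_clusters, min(vapply(zs, function(z) {
      nrow(z$intensities) - length(attr(z, "degenerate"))
    }, numeric(1))))
    res$clusters <- lapply(seq_along(zs), function(i) {
      cluster_ftds(zs[[i]], k = kc, seed = seed + 10L + i)
    })
    names(res$clusters) <- names(zs)
    for (b in names(res$clusters)) {
      emit(data.frame(feature_id = names(res$clusters[[b]]$assignment),
                      cluster = res$clusters[[b]]$assignment),
           paste0("clusters_", b, ".csv"))
    }
    res$gp <- lapply(res$clusters, function(cm) {
      fit_cluster_gp(cm$centers[1, ], cm$member_sds[1])
    })
  }

  if ("similarity" %in% stages) {
    res$similarity <- lapply(zs, function(z) {
      threshold_summary(pair_distances(z, kind = "intra_all"), 1.5)$fraction
    })
    sim_df <- data.frame(building = names(res$similarity),
                         frac_below_1.5 = unlist(res$similarity))
    emit(sim_df, "similarity_fractions.csv")
  }

  if ("classify" %in% stages) {
    prof <- build_day_profiles(pp$tables)
    res$classifier <- train_evaluate(prof$x, prof$y, ml_params)
    emit(res$classifier$importance, "importance.csv")
    res$important <- extract_important_features(res$classifier, ml_params)
  }

  if ("annotate" %in% stages) {
    ann <- annotate_table(ft_subset(table,
                                    features = pp$tables[[1]]$features$feature_id),
                          ppm_max = ppm_max)
    res$annotation <- ann
    if (!is.null(ann$records)) emit(ann$records, "annotations.csv")
    emit(data.frame(feature_id = names(ann$levels), level = ann$levels),
         "mrs_levels.csv")
  }

  if ("group" %in% stages && !is.null(res$important) &&
      length(res$important) > 0) {
    res$groups <- lapply(names(zs), function(b) {
      ms <- grouping_params$min_group_size
      msz <- if (b %in% names(ms)) ms[[b]] else ms[[1]]
      anchors <- intersect(res$important, zs[[b]]$features$feature_id)
      if (!length(anchors)) return(NULL)
      group_by_important(zs[[b]], anchors,
                         d_group = grouping_params$d_group, min_size = msz)
    })
    names(res$groups) <- names(zs)
    for (b in names(res$groups)) {
      if (!is.null(res$groups[[b]]) && nrow(res$groups[[b]])) {
        emit(res$groups[[b]], paste0("groups_", b, ".csv"))
      }
    }
    if (!is.null(res$clusters) && length(res$clusters) >= 2) {
      rt <- stats::setNames(pp$tables[[1]]$features$rt,
                            pp$tables[[1]]$features$feature_id)
      cc <- cross_building_cocluster(res$clusters, rt,
                                     grouping_params$cocluster_min_overlap,
                                     grouping_params$cocluster_rt_span_min)
      emit(cc, "coclusters.csv")
      res$coclusters <- cc
    }
  }

  prov <- data.frame(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  prov_path <- file.path(outdir, "provenance.json")
  jsonlite::write_json(list(seed = seed, stages = stages, files = prov),
                       prov_path, auto_unbox = TRUE, digits = NA)
  res$provenance <- prov
  invisible(res)
}
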