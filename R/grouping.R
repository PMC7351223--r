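#' Grouping parameters
#'
#' Thresholds for anchoring feature groups on important features (IFs) and
#' for cross-building co-clustering: group membership at Euclidean distance
#' below 1.5; per-building minimum group sizes of 20/20/5 (an alternative
#' 15/8/3 set is in use for figure-level reporting and can be passed
#' instead); co-cluster intersections kept when strictly larger than 5
#' features and spanning strictly more than 30 s of retention time.
#'
#' @param d_group distance cutoff for group membership.
#' @param min_group_size named per-building size thresholds (strictly
#'   greater kept).
#' @param cocluster_min_overlap minimum co-cluster intersection (strict >).
#' @param cocluster_rt_span_min minimum rt span, seconds (strict >).
#' @return List of class `grouping_params`.
#' @export
grouping_params <- function(d_group = 1.5,
                            min_group_size = c(B1 = 20, B2 = 20, B3 = 5),
                            cocluster_min_overlap = 5,
                            cocluster_rt_span_min = 30) {
  stopifnot(d_group > 0, all(min_group_size >= 0))
  structure(list(d_group = d_group, min_group_size = min_group_size,
                 cocluster_min_overlap = cocluster_min_overlap,
                 cocluster_rt_span_min = cocluster_rt_span_min),
            class = "grouping_params")
}

#' Group features around important features
#'
#' Each IF anchors the set of features within `d_group` Euclidean distance
#' of it (on z-normalized shared-day series). Features inside several IFs'
#' groups are counted toward each group's size, but are finally assigned
#' only to the largest group they belong to (size ties broken by
#' lexicographic IF id). Groups not strictly exceeding `min_size` are
#' dropped.
#'
#' @param z a `znorm` feature table.
#' @param important character vector of IF feature ids (within the table).
#' @param d_group membership distance cutoff.
#' @param min_size scalar minimum group size for this building (strict >).
#' @return data.frame (feature_id, group_if, distance) of assigned features;
#'   attribute `"group_sizes"` holds the pre-assignment multi-membership
#'   sizes.
#' @export
group_by_important <- function(z, important, d_group = 1.5, min_size = 0) {
  A <- z_matrix(z)
  if (!length(important)) stop("empty important-feature list")
  miss <- setdiff(important, A$features$feature_id)
  if (length(miss)) stop("IF(s) not in feature universe: ",
                         paste(miss, collapse = ", "))
  important <- sort(important)
  D <- cross_dist(A$m, A$m[match(important, A$features$feature_id), ,
                           drop = FALSE])
  dimnames(D) <- list(A$features$feature_id, important)
  member <- D < d_group
  sizes <- colSums(member)
  assigned <- which(rowSums(member) > 0)
  # largest group wins; ties by lexicographic IF id (columns are sorted)
  pick <- vapply(assigned, function(f) {
    cand <- which(member[f, ])
    cand[which.max(sizes[cand])]
  }, integer(1))
  out <- data.frame(feature_id = A$features$feature_id[assigned],
                    group_if = important[pick],
                    distance = D[cbind(assigned, pick)])
  keep_groups <- important[sizes > min_size]
  out <- out[out$group_if %in% keep_groups, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "group_sizes") <- sizes
  out
}

#' Metric MDS embedding of grouped features
#'
#' Classical (metric) multidimensional scaling of the Euclidean distance
#' matrix of the selected features into two dimensions, with Kruskal
#' stress-1 reported. The embedding is deterministic.
#'
#' @param z a `znorm` feature table.
#' @param features feature ids to embed (>= 3).
#' @return data.frame (feature_id, x, y) with attribute `"stress"`.
#' @export
mds_embed <- function(z, features) {
  A <- z_matrix(z)
  idx <- match(features, A$features$feature_id)
  if (anyNA(idx)) stop("unknown feature id(s)")
  if (length(idx) < 3) stop("need at least 3 features for MDS")
  m <- A$m[idx, , drop = FALSE]
  d <- stats::dist(m)
  xy <- stats::cmdscale(d, k = 2)
  dhat <- stats::dist(xy)
  stress <- sqrt(sum((as.vector(d) - as.vector(dhat))^2) /
                   sum(as.vector(d)^2))
  out <- data.frame(feature_id = features, x = xy[, 1], y = xy[, 2])
  rownames(out) <- NULL
  attr(out, "stress") <- stress
  out
}

#' Cross-building co-clustered feature sets
#'
#' For every pair and triple of K-means clusters from distinct buildings,
#' keeps the feature intersection if it holds strictly more than
#' `min_overlap` features and the members span strictly more than
#' `rt_span_min` seconds of retention time (max rt - min rt).
#'
#' @param models named list of per-building `cluster_model`s over the same
#'   feature universe.
#' @param feature_rt named numeric vector: feature id -> rt (seconds).
#' @param min_overlap intersection size threshold (strict >).
#' @param rt_span_min rt span threshold in seconds (strict >).
#' @return data.frame (buildings, clusters, n_features, rt_span, members as
#'   a comma-joined string); zero rows if nothing passes.
#' @export
cross_building_cocluster <- function(models, feature_rt,
                                     min_overlap = 5, rt_span_min = 30) {
  stopifnot(length(models) >= 2)
  ids <- names(models[[1]]$assignment)
  for (m in models) {
    if (!identical(sort(names(m$assignment)), sort(ids))) {
      stop("mismatched feature universes across buildings")
    }
  }
  combos <- unlist(lapply(2:length(models), function(k) {
    utils::combn(names(models), k, simplify = FALSE)
  }), recursive = FALSE)
  recs <- list()
  for (cmb in combos) {
    key <- vapply(cmb, function(b) {
      unname(models[[b]]$assignment[ids])
    }, integer(length(ids)))
    grp <- split(ids, apply(key, 1, paste, collapse = "/"))
    for (g in names(grp)) {
      members <- grp[[g]]
      if (length(members) <= min_overlap) next
      span <- diff(range(feature_rt[members]))
      if (!(span > rt_span_min)) next
      recs[[length(recs) + 1L]] <- data.frame(
        buildings = paste(cmb, collapse = "+"),
        clusters = g,
        n_features = length(members),
        rt_span = span,
        members = paste(sort(members), collapse = ","))
    }
  }
  if (!length(recs)) {
    return(data.frame(buildings = character(0), clusters = character(0),
                      n_features = integer(0), rt_span = numeric(0),
                      members = character(0)))
  }
  do.call(rbind, recs)
}
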