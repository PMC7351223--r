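make_grouped_z <- function() {
  # two well-separated dynamic motifs plus background noise
  set.seed(42)
  nd <- 12
  motif1 <- rnorm(nd, 0, 2)
  motif2 <- rnorm(nd, 0, 2)
  rows <- rbind(
    t(replicate(8, motif1 + rnorm(nd, 0, 0.1))),
    t(replicate(4, motif2 + rnorm(nd, 0, 0.1))),
    matrix(rnorm(6 * nd, 0, 2), 6, nd))
  tb <- make_building_table(rows + 18, days = as.Date("2017-10-02") + 1:nd)
  znormalize(tb)
}

test_that("features are assigned to the largest qualifying IF group", {
  z <- make_grouped_z()
  # IFs: one anchor in the size-8 motif, one in the size-4 motif
  out <- group_by_important(z, c("T001", "T009"), d_group = 1.5)
  sizes <- attr(out, "group_sizes")
  expect_gte(sizes[["T001"]], 8)
  expect_gte(sizes[["T009"]], 4)
  # members of motif 1 map to the larger group
  expect_true(all(out$group_if[out$feature_id %in%
                                 sprintf("T%03d", 1:8)] == "T001"))
  # background features within no IF distance are unassigned
  expect_false(any(sprintf("T%03d", 13:18) %in% out$feature_id))
  # a feature in both groups goes to the larger one; with equal sizes the
  # lexicographically first IF wins
  m <- matrix(rep(c(1, -1), 5), nrow = 5, ncol = 2, byrow = TRUE)
  tb <- make_building_table(m)
  zz <- tb; zz$scale <- "znorm"; attr(zz, "degenerate") <- character(0)
  tie <- group_by_important(zz, c("T002", "T004"), d_group = 0.5)
  expect_true(all(tie$group_if == "T002"))
  # deterministic + idempotent
  expect_identical(group_by_important(z, c("T001", "T009")),
                   group_by_important(z, c("T001", "T009")))
  expect_error(group_by_important(z, character(0)), "empty")
  expect_error(group_by_important(z, "nope"), "not in feature universe")
})

test_that("group size thresholds are strict", {
  z <- make_grouped_z()
  sizes <- attr(group_by_important(z, c("T001", "T009")), "group_sizes")
  s9 <- sizes[["T009"]]
  out <- group_by_important(z, c("T001", "T009"), min_size = s9)
  expect_false("T009" %in% out$group_if)  # size must strictly exceed
  out2 <- group_by_important(z, c("T001", "T009"), min_size = s9 - 1)
  expect_true("T009" %in% out2$group_if)
})

test_that("metric MDS preserves planted geometry", {
  # three equidistant series embed as a near-equilateral triangle
  m <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  tb <- make_building_table(m)
  z <- tb; z$scale <- "znorm"; attr(z, "degenerate") <- character(0)
  em <- mds_embed(z, c("T001", "T002", "T003"))
  d <- dist(em[, c("x", "y")])
  expect_lt(max(d) - min(d), 1e-6)
  expect_lt(attr(em, "stress"), 1e-6)

  # duplicate series land on coincident points
  m2 <- rbind(m, m[1, ])
  z2 <- make_building_table(m2); z2$scale <- "znorm"
  attr(z2, "degenerate") <- character(0)
  em2 <- mds_embed(z2, sprintf("T%03d", 1:4))
  expect_lt(sqrt(sum((em2[1, c("x", "y")] - em2[4, c("x", "y")])^2)), 1e-9)
  expect_error(mds_embed(z, c("T001", "T002")), "at least 3")

  # embedded distances track input distances; groups separate
  skip_if_not_installed("cluster")
  zg <- make_grouped_z()
  feats <- sprintf("T%03d", 1:12)
  em3 <- mds_embed(zg, feats)
  din <- as.vector(dist(zg$intensities[feats, ]))
  dout <- as.vector(dist(em3[, c("x", "y")]))
  expect_gte(cor(din, dout, method = "spearman"), 0.8)
  lab <- rep(1:2, c(8, 4))
  sil <- cluster::silhouette(lab, dist(em3[, c("x", "y")]))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("co-clustering applies strict overlap and rt-span thresholds", {
  mk_model <- function(assign) {
    structure(list(k = max(assign), assignment = assign,
                   sizes = tabulate(assign)), class = "cluster_model")
  }
  ids <- sprintf("F%02d", 1:12)
  # cluster 1 shared by both buildings holds features 1-6 (6 > 5)
  a1 <- setNames(c(rep(1L, 6), rep(2L, 6)), ids)
  a2 <- setNames(c(rep(1L, 6), rep(2L, 6)), ids)
  rt_wide <- setNames(seq(10, 400, length.out = 12), ids)
  cc <- cross_building_cocluster(list(B1 = mk_model(a1), B2 = mk_model(a2)),
                                 rt_wide)
  expect_equal(nrow(cc), 2)
  expect_true(all(cc$n_features == 6))

  # intersection of exactly 5 features is rejected
  a3 <- a2
  a3[6] <- 2L
  cc5 <- cross_building_cocluster(list(B1 = mk_model(a1), B2 = mk_model(a3)),
                                  rt_wide)
  expect_false(any(grepl("^1/1$", cc5$clusters)))

  # 29 s rt span is rejected
  rt_narrow <- rt_wide
  rt_narrow[1:6] <- seq(100, 129, length.out = 6)
  cc29 <- cross_building_cocluster(list(B1 = mk_model(a1),
                                        B2 = mk_model(a2)), rt_narrow)
  expect_false("1/1" %in% cc29$clusters)
  # every reported record satisfies both predicates post hoc
  for (i in seq_len(nrow(cc))) {
    members <- strsplit(cc$members[i], ",")[[1]]
    expect_gt(length(members), 5)
    expect_gt(diff(range(rt_wide[members])), 30)
  }
})

test_that("planted groups co-cluster across all synthetic buildings", {
  pl <- cached_pipeline()
  models <- lapply(names(pl$z), function(b) {
    cluster_ftds(pl$z[[b]], k = 25, seed = 17)
  })
  names(models) <- names(pl$z)
  rt <- setNames(pl$tables$B1$features$rt, pl$tables$B1$features$feature_id)
  cc <- cross_building_cocluster(models, rt)
  triple <- cc[cc$buildings == "B1+B2+B3", ]
  expect_gt(nrow(triple), 0)
  # at least 60% of planted groups of size > 5 appear as a triple co-cluster
  big_groups <- Filter(function(g) length(g) > 5, pl$truth$groups)
  recovered <- vapply(big_groups, function(g) {
    any(vapply(triple$members, function(ms) {
      mem <- strsplit(ms, ",")[[1]]
      length(intersect(mem, g)) > 5
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(recovered), 0.6)
})
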