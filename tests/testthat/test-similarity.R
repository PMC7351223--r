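test_that("pair distances match hand values and brute-force oracles", {
  # a = (1,-1), b = (-1,1): distance sqrt(8)
  m <- rbind(c(1, -1), c(-1, 1), c(1, -1))
  tb <- make_building_table(m)
  z <- tb; z$scale <- "znorm"
  attr(z, "degenerate") <- character(0)
  pd <- pair_distances(z, kind = "intra_all")
  expect_equal(nrow(pd), 3)
  expect_equal(pd$distance[pd$feature_a == "T001" & pd$feature_b == "T002"],
               sqrt(8))
  expect_equal(pd$distance[pd$feature_a == "T001" & pd$feature_b == "T003"],
               0)

  # brute-force double-loop oracle on a 40-feature instance
  set.seed(17)
  n <- 40
  mm <- matrix(rnorm(n * 12), n, 12)
  zt <- znormalize(make_building_table(mm,
                                       days = as.Date("2017-10-02") + 1:12))
  pd2 <- pair_distances(zt, kind = "intra_all")
  expect_equal(nrow(pd2), n * (n - 1) / 2)
  zm <- zt$intensities
  k <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- k + 1
      expect_equal(pd2$distance[k], brute_euclidean(zm[i, ], zm[j, ]),
                   tolerance = 1e-10)
    }
  }
  # z-normalized series obey d^2 = 2 n (1 - r) under the population SD
  r <- vapply(seq_len(nrow(pd2)), function(k) {
    brute_pearson(zm[match(pd2$feature_a[k], rownames(zm)), ],
                  zm[match(pd2$feature_b[k], rownames(zm)), ])
  }, numeric(1))
  expect_equal(pd2$distance^2, 2 * 12 * (1 - r), tolerance = 1e-9)
})

test_that("inter-building comparisons need aligned days and support one-to-one", {
  pl <- cached_pipeline()
  za <- pl$z$B1
  zb <- pl$z$B2
  oo <- pair_distances(za, zb, kind = "inter_one_to_one")
  expect_equal(oo$feature_a, oo$feature_b)
  # identical series across buildings give distance zero
  self <- pair_distances(za, za, kind = "inter_one_to_one")
  expect_true(all(self$distance == 0))
  xa <- pair_distances(za, zb, kind = "inter_all")
  nA <- nrow(za$intensities) - length(attr(za, "degenerate"))
  expect_equal(nrow(xa), nA^2)
  # cross-pair values agree with the brute-force oracle on a sample
  set.seed(8)
  pick <- sample(nrow(xa), 50)
  for (k in pick) {
    a <- za$intensities[xa$feature_a[k], ]
    b <- zb$intensities[xa$feature_b[k], ]
    expect_equal(xa$distance[k], brute_euclidean(a, b), tolerance = 1e-10)
  }
})

test_that("threshold summaries count sub-cutoff fractions and planted adduct pairs", {
  pl <- cached_pipeline()
  pd <- pair_distances(pl$z$B1, kind = "intra_all")
  ts <- threshold_summary(pd, 2.82)
  expect_equal(ts$fraction, mean(pd$distance < 2.82))
  expect_equal(ts$n_total, nrow(pd))
  # identical series: fraction 1 at any positive cutoff; cutoff 0 only
  # counts exact duplicates
  m <- rbind(c(1, -1), c(1, -1))
  z <- make_building_table(m); z$scale <- "znorm"
  attr(z, "degenerate") <- character(0)
  pd0 <- pair_distances(z, kind = "intra_all")
  expect_equal(threshold_summary(pd0, 0.001)$fraction, 1)
  expect_equal(threshold_summary(pd0, 0)$fraction, 0)

  # planted adduct pairs sit below the high-stringency cutoff with exact
  # adduct delta mz
  ap <- pl$truth$adduct_pairs
  hit <- merge(pd, ap, by = c("feature_a", "feature_b"))
  expect_equal(nrow(hit), nrow(ap))
  expect_true(all(hit$distance < 1.5))
  expect_equal(hit$delta_mz.x, hit$delta_mz.y, tolerance = 1e-9)
})

test_that("anticorrelation screens find mirrored pairs and honor the MW filter", {
  d <- as.Date("2017-10-02") + 0:9
  set.seed(4)
  a <- rnorm(10)
  a <- a - mean(a)   # exactly symmetric pair: equal medians up to sign
  m <- rbind(a, -a, rnorm(10))
  lt <- make_building_table(m + 15, days = d)
  z <- znormalize(lt)
  ac <- anticorrelation_screen(z, r_cutoff = -0.6)
  expect_true(any(ac$feature_a == "T001" & ac$feature_b == "T002"))
  expect_equal(ac$r[ac$feature_a == "T001" & ac$feature_b == "T002"], -1)

  # mirrored pair with equal medians survives the not-different screen
  ac2 <- anticorrelation_screen(z, r_cutoff = -0.6,
                                require_not_different = TRUE,
                                log2_table = lt)
  expect_true(any(ac2$feature_a == "T001" & ac2$feature_b == "T002"))

  # a mirrored pair with a big mean offset is excluded by the screen
  m2 <- rbind(a, -a + 10)
  lt2 <- make_building_table(m2 + 15, days = d)
  z2 <- znormalize(lt2)
  ac3 <- anticorrelation_screen(z2, r_cutoff = -0.6,
                                require_not_different = TRUE,
                                log2_table = lt2)
  expect_false(any(ac3$feature_a == "T001" & ac3$feature_b == "T002"))
})

test_that("all-building negative pairs are the intersection over buildings", {
  d <- as.Date("2017-10-02") + 0:7
  set.seed(6)
  a <- rnorm(8)
  mk <- function(third_row, b) {
    z <- znormalize(make_building_table(rbind(a, -a, third_row) + 20,
                                        building = b, days = d))
    z
  }
  zs <- list(B1 = mk(-a + rnorm(8, 0, 0.1), "B1"),
             B2 = mk(-a + rnorm(8, 0, 0.1), "B2"),
             B3 = mk(a + rnorm(8, 0, 0.1), "B3"))
  tn <- triple_negative_pairs(zs, r_neg = -0.2)
  pair12 <- tn$feature_a == "T001" & tn$feature_b == "T002"
  expect_true(any(pair12))     # mirrored everywhere
  pair13 <- tn$feature_a == "T001" & tn$feature_b == "T003"
  expect_false(any(pair13))    # correlated in B3
  # r = -1 cutoff: almost surely empty on noisy data
  expect_equal(nrow(triple_negative_pairs(zs, r_neg = -1)), 0)
})

test_that("center correlation is symmetric with Ward ordering of duplicates", {
  set.seed(2)
  base <- rnorm(10)
  centers <- rbind(base, base + rnorm(10, 0, 0.01), -base,
                   rnorm(10))
  cc <- center_correlation(centers)
  expect_equal(unname(diag(cc$correlation)), rep(1, 4))
  expect_equal(cc$correlation, t(cc$correlation))
  expect_gt(cc$correlation[1, 2], 0.99)
  expect_equal(cc$correlation[1, 3], -1, tolerance = 1e-3)
  # the two near-duplicate centers merge first -> adjacent leaves
  pos <- match(c(1, 2), cc$order)
  expect_equal(abs(diff(pos)), 1)
  expect_error(center_correlation(rbind(rep(1, 5), rnorm(5))), "constant")
})
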