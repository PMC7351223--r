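test_that("summary statistics use the population SD convention", {
  m <- rbind(rep(12, 4), c(10, 14, 10, 14))
  tb <- make_building_table(m)
  rep <- summarize_stability(tb)
  expect_equal(rep$mean, c(12, 12))
  expect_equal(rep$sd, c(0, 2))
  expect_equal(rep$median, c(12, 12))
  expect_error(summarize_stability(make_building_table(matrix(1, 2, 1))),
               "2 days")
  # sample-SD convention available
  expect_equal(summarize_stability(tb, ddof = 1)$sd[2], sd(c(10, 14, 10, 14)))
})

test_that("stability taxonomy boundaries follow the stated inequalities", {
  cases <- data.frame(
    sd = c(1.99, 2.00, 3.6, 3.5, 2.5, 2.5),
    median = c(10, 10, 25, 13.9, 13.9, 14.0),
    label = c("stable", "unstable", "unstable", "unstable", "unstable",
              "unstable"),
    class = c(NA, 1, 2, 1, 1, 3))
  rep <- data.frame(feature_id = paste0("f", seq_len(nrow(cases))),
                    mz = 100, rt = 60, mean = 15, sd = cases$sd,
                    median = cases$median)
  class(rep) <- c("stability_report", "data.frame")
  out <- classify_stability(rep)
  expect_equal(out$label, cases$label)
  expect_equal(out$unstable_class, as.integer(cases$class))
})

test_that("overlap analysis counts Venn regions with the union denominator", {
  mk <- function(labels) {
    r <- data.frame(feature_id = paste0("f", seq_along(labels)),
                    mz = 100, rt = 60, mean = 15, sd = 1, median = 15,
                    label = labels, unstable_class = NA)
    class(r) <- c("stability_report", "data.frame")
    r
  }
  all_stable <- list(B1 = mk(rep("stable", 4)), B2 = mk(rep("stable", 4)),
                     B3 = mk(rep("stable", 4)))
  ov <- overlap_analysis(all_stable, "stable")
  expect_equal(ov$frac_all, 1)
  expect_equal(ov$union_size, 4)
  expect_equal(sum(ov$regions$count), 4)

  disjoint <- list(B1 = mk(c("stable", "unstable", "unstable")),
                   B2 = mk(c("unstable", "stable", "unstable")),
                   B3 = mk(c("unstable", "unstable", "stable")))
  expect_equal(overlap_analysis(disjoint, "stable")$frac_all, 0)

  # planted building-specific instability matches ground truth
  pl <- cached_pipeline()
  reps <- lapply(pl$tables, function(t) {
    classify_stability(summarize_stability(t))
  })
  ov2 <- overlap_analysis(reps, "unstable")
  truth_uns <- pl$truth$stability[reps$B1$feature_id, ]
  truth_all3 <- sum(rowSums(truth_uns == "unstable") == 3)
  truth_any <- sum(rowSums(truth_uns == "unstable") > 0)
  expect_lt(abs(ov2$frac_all - truth_all3 / truth_any), 0.15)
  expect_equal(sum(ov2$regions$count), ov2$union_size)
})

test_that("Kruskal-Wallis screen flags planted shifts and respects the null", {
  # identical group distributions: p ~ 1
  d <- as.Date("2017-10-02") + 0:5
  mk <- function(b, m) make_building_table(m, building = b, days = d)
  base <- matrix(rep(c(10, 11, 12, 13, 14, 15), each = 2), 2, 6, byrow = TRUE)
  same <- list(B1 = mk("B1", base), B2 = mk("B2", base), B3 = mk("B3", base))
  kw0 <- kw_screen(same, q_max = 1e-5)
  expect_true(all(kw0$p > 0.9))
  expect_false(any(kw0$significant))

  # +4 log2 shift in one building is recovered
  shifted <- base
  shifted[1, ] <- shifted[1, ] + 4
  kw1 <- kw_screen(list(B1 = mk("B1", shifted), B2 = mk("B2", base),
                        B3 = mk("B3", base)), q_max = 0.05)
  expect_true(kw1$significant[1])
  expect_false(kw1$significant[2])

  # null data, many features: nothing at Q < 1e-5
  set.seed(11)
  nf <- 400
  null_tabs <- lapply(c("B1", "B2", "B3"), function(b) {
    make_building_table(matrix(rnorm(nf * 10, 15, 1), nf, 10), building = b,
                        days = as.Date("2017-10-02") + 0:9)
  })
  names(null_tabs) <- c("B1", "B2", "B3")
  expect_equal(sum(kw_screen(null_tabs, q_max = 1e-5)$significant), 0)

  # on the synthetic study, the screen recovers exactly the planted markers
  pl <- cached_pipeline()
  kw <- kw_screen(pl$tables, q_max = 1e-5)
  expect_setequal(kw$feature_id[kw$significant],
                  pl$truth$markers$feature_id)
})

test_that("weekday/weekend tests behave under planted effect and null", {
  pl <- cached_pipeline()
  b1 <- weekday_weekend_test(pl$tables$B1, mode = "weekend_vs_allweekdays")
  found <- b1$feature_id[b1$significant]
  expect_gt(length(intersect(found, pl$truth$weekday_features)), 0)
  expect_lte(length(setdiff(found, pl$truth$weekday_features)), 2)
  # no planted effect in the other buildings
  b2 <- weekday_weekend_test(pl$tables$B2, mode = "weekend_vs_allweekdays")
  expect_lte(sum(b2$significant), 2)
  # Saturday-vs-Wednesday only has too little data for any detection
  sat <- weekday_weekend_test(pl$tables$B1, mode = "sat_vs_wed")
  expect_equal(sum(sat$significant), 0)
  # identical group values give p = 1
  const <- make_building_table(matrix(15, 3, 16),
                               days = pl$truth$shared_days)
  expect_true(all(weekday_weekend_test(const)$p == 1))
})

test_that("between-building regression matches exact OLS cases", {
  mk_rep <- function(means) {
    r <- data.frame(feature_id = paste0("f", seq_along(means)),
                    mz = 100, rt = 60, mean = means, sd = 1,
                    median = means)
    class(r) <- c("stability_report", "data.frame")
    r
  }
  same <- between_building_regression(mk_rep(c(1, 2, 3)), mk_rep(c(1, 2, 3)))
  expect_equal(same$r, 1)
  expect_equal(same$slope, 1)
  expect_equal(same$intercept, 0)
  dbl <- between_building_regression(mk_rep(c(1, 2, 3)), mk_rep(c(2, 4, 6)))
  expect_equal(dbl$r, 1)
  expect_equal(dbl$slope, 2)
  rev <- between_building_regression(mk_rep(c(1, 2, 3)), mk_rep(c(3, 2, 1)))
  expect_equal(rev$r, -1)
  expect_error(between_building_regression(mk_rep(c(1, 1, 1)),
                                           mk_rep(c(1, 2, 3))),
               "zero variance")

  # synthetic buildings share most feature means: high correlation
  pl <- cached_pipeline()
  reps <- lapply(pl$tables, summarize_stability)
  fit <- between_building_regression(reps$B1, reps$B2)
  expect_gt(fit$r, 0.9)
})
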