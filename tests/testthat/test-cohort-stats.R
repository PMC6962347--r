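# Per-plaque aggregation, Wilcoxon rank-sum, correlation screens.

test_that("plaque aggregation: mean, sample SD, degenerate n = 1", {
  a <- aggregate_plaque(c(4, 6))
  expect_equal(a$mean, 5)
  expect_equal(a$sd, sqrt(2))
  expect_equal(a$n, 2)
  b <- aggregate_plaque(5.1)
  expect_equal(b$mean, 5.1)
  expect_equal(b$sd, 0)
  expect_equal(b$n, 1)
  expect_error(aggregate_plaque(numeric(0)), "no passing")
})

test_that("sampling distribution of the aggregate mean behaves", {
  set.seed(55)
  hits <- replicate(200, {
    abs(aggregate_plaque(rnorm(15, mean = 5, sd = 1))$mean - 5) < 1
  })
  expect_gte(mean(hits), 0.95)
})

test_that("exact Wilcoxon matches full enumeration", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")
  # identical samples have maximal overlap: p = 1 (ties force approx)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # cross-check the exact branch against the reference implementation
  set.seed(77)
  for (rep in 1:25) {
    m <- sample(3:6, 1)
    n <- sample(3:6, 1)
    x <- rnorm(m)
    y <- rnorm(n)
    expect_equal(
      wilcoxon_rank_sum(x, y)$p_value,
      wilcox.test(x, y, exact = TRUE)$p.value
    )
  }
})

test_that("normal approximation tracks the exact branch within 0.02", {
  set.seed(88)
  errs <- replicate(100, {
    x <- rnorm(6)
    y <- rnorm(6)
    abs(wilcoxon_rank_sum(x, y)$p_value -
      wilcoxon_rank_sum(x, y, exact_limit = 0L)$p_value)
  })
  expect_lt(max(errs), 0.02)
})

test_that("Wilcoxon p is invariant under monotone transforms", {
  set.seed(3)
  x <- rnorm(5)
  y <- rnorm(7)
  p0 <- wilcoxon_rank_sum(x, y)$p_value
  expect_equal(wilcoxon_rank_sum(exp(x), exp(y))$p_value, p0)
  expect_equal(wilcoxon_rank_sum(x^3, y^3)$p_value, p0)
})

test_that("group comparison flags require every pairwise rejection", {
  params <- default_velocity_parameters()
  # separations this wide are detected in every small-sample test
  sds <- params$sds * 0 + 0.01
  cfg <- cohort_sim_config(velocity_sds = sds, acquisition_sd = 0.01,
    components = NULL, seed = 12L)
  co <- simulate_cohort(cfg)
  res <- compare_aha_groups(co, "gv", "T")
  expect_true(all(res$p_values < 0.05))
  expect_true(res$significant_all)
  # an empty group leaves that pair undefined and the flag false
  co2 <- co[co$aha_type != "VII", ]
  res2 <- compare_aha_groups(co2, "gv", "T")
  expect_true(is.na(res2$p_values[["VII"]]))
  expect_false(res2$significant_all)
})

test_that("correlations: exact linear, hand-ranked Spearman, n gating", {
  co <- data.frame(
    plaque_id = sprintf("P%d", 1:5), subject_id = sprintf("S%d", 1:5),
    view = "L", aha_type = "III",
    gv_mean = c(1, 2, 3, 4, 5), gv_sd = 0, gv_n = 3,
    lin = 2 * c(1, 2, 3, 4, 5) + 1,
    scrambled = c(2, 1, 4, 3, 5)
  )
  class(co) <- c("cohort_table", "data.frame")
  r1 <- correlate(co, "gv", "L", "lin")
  expect_equal(r1$pearson_r, 1)
  expect_equal(r1$spearman_r, 1)
  # rank displacement d = (-1, 1, -1, 1, 0): rho = 1 - 6*4/(5*24) = 0.8,
  # confirmed against the reference rank correlation
  r2 <- correlate(co, "gv", "L", "scrambled")
  expect_equal(r2$spearman_r, 1 - 6 * 4 / (5 * 24))
  expect_equal(
    r2$spearman_r,
    cor(co$gv_mean[1:5], co$scrambled[1:5], method = "spearman")
  )
  # p-values match the reference t-approximation implementations
  set.seed(21)
  xv <- rnorm(20)
  yv <- 0.5 * xv + rnorm(20)
  co2 <- data.frame(
    plaque_id = sprintf("P%d", 1:20), subject_id = sprintf("S%d", 1:20),
    view = "L", aha_type = "III", gv_mean = xv, gv_sd = 0, gv_n = 1,
    cov = yv
  )
  class(co2) <- c("cohort_table", "data.frame")
  r3 <- correlate(co2, "gv", "L", "cov")
  ref_p <- cor.test(xv, yv)
  ref_s <- suppressWarnings(cor.test(xv, yv, method = "spearman"))
  expect_equal(r3$pearson_r, unname(ref_p$estimate))
  expect_equal(r3$pearson_p, ref_p$p.value)
  expect_equal(r3$spearman_r, unname(ref_s$estimate))
  # undefined below 3 pairwise-complete observations
  co$lin[3:5] <- NA
  r4 <- correlate(co, "gv", "L", "lin")
  expect_false(r4$defined)
  expect_false(r4$flagged)
  expect_equal(r4$n_used, 2)
})

test_that("correlation coefficients are invariant as claimed", {
  set.seed(31)
  x <- rnorm(15)
  y <- 0.6 * x + rnorm(15)
  mk <- function(xv, yv) {
    co <- data.frame(
      plaque_id = sprintf("P%d", seq_along(xv)),
      subject_id = sprintf("S%d", seq_along(xv)), view = "L",
      aha_type = "III", gv_mean = xv, gv_sd = 0, gv_n = 1, cov = yv
    )
    class(co) <- c("cohort_table", "data.frame")
    correlate(co, "gv", "L", "cov")
  }
  base <- mk(x, y)
  affine <- mk(3 * x - 2, y)
  expect_equal(affine$pearson_r, base$pearson_r)
  monotone <- mk(x, exp(y))
  expect_equal(monotone$spearman_r, base$spearman_r)
})

test_that("pairwise missing plaques are excluded per analysis", {
  comp <- data.frame(
    name = c("full", "holey"), mean = c(5, 5), sd = c(1, 1),
    anchor = c("gv_L", "gv_L"), target_r = c(0.3, 0.3),
    missing_fraction = c(0, 0.3), clip_lo = -Inf, clip_hi = Inf
  )
  co <- simulate_cohort(cohort_sim_config(components = comp, seed = 40L))
  r_full <- correlate(co, "gv", "L", "full")
  r_holey <- correlate(co, "gv", "L", "holey")
  expect_equal(r_full$n_used, 27)
  expect_equal(r_holey$n_used, sum(!is.na(co$holey[co$view == "L"])))
  expect_lt(r_holey$n_used, 27)
})

test_that("full evaluation is structurally complete and deterministic", {
  co <- simulate_cohort(cohort_sim_config(seed = 8L))
  rep1 <- run_full_evaluation(co)
  expect_equal(nrow(rep1$group_comparisons), 8) # 4 metrics x 2 views
  expect_equal(
    nrow(rep1$correlations),
    8 * nrow(default_component_table())
  )
  rep2 <- run_full_evaluation(simulate_cohort(cohort_sim_config(seed = 8L)))
  expect_identical(rep1, rep2)
  # a covariate missing for every plaque yields undefined rows
  co$iph_vol_mm3 <- NA_real_
  rep3 <- run_full_evaluation(co)
  iph_rows <- rep3$correlations[rep3$correlations$covariate == "iph_vol_mm3", ]
  expect_true(all(!iph_rows$defined))
  expect_true(all(!iph_rows$flagged))
})

test_that("malformed cohort tables name the offending column", {
  co <- simulate_cohort(cohort_sim_config(seed = 1L))
  co$gv_mean <- NULL
  expect_error(run_full_evaluation(co), "gv_mean")
})
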