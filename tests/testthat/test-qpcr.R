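test_that("standard curves recover perfect-doubling chemistry", {
  lc <- 1:6
  ct <- 40 - log2(10) * lc          # slope -3.32193 by construction
  curve <- fit_standard_curve(lc, ct)
  expect_equal(curve$slope, -log2(10), tolerance = 1e-9)
  expect_equal(curve$efficiency, 2, tolerance = 1e-9)
  expect_equal(curve$percent_efficiency, 1, tolerance = 1e-9)
  # duplicated standards with equal Ct do not change the fit
  curve2 <- fit_standard_curve(c(lc, lc), c(ct, ct))
  expect_equal(curve2$slope, curve$slope, tolerance = 1e-12)
  expect_equal(curve2$intercept, curve$intercept, tolerance = 1e-12)
  expect_error(fit_standard_curve(1:2, c(36, 33)), "at least 3")
  expect_error(fit_standard_curve(c(1, 1.5, 2), c(36, 35, 33)), "2 log10")
  expect_error(fit_standard_curve(1:4, c(10, 12, 14, 16)), "non-amplifying")
})

test_that("quantification inverts the curve and normalizes per ug and ul", {
  curve <- fit_standard_curve(1:6, 40 - log2(10) * (1:6))
  expect_equal(quantify(curve$intercept, curve)$copies, 1, tolerance = 1e-9)
  expect_equal(quantify(curve$intercept + curve$slope, curve)$copies, 10,
               tolerance = 1e-9)
  # halving template mass doubles copies/ug, leaves copies/ul unchanged
  q1 <- quantify(30, curve, template_mass_ug = 1, volume_ul = 2)
  q2 <- quantify(30, curve, template_mass_ug = 0.5, volume_ul = 2)
  expect_equal(q2$copies_per_ug, 2 * q1$copies_per_ug)
  expect_equal(q2$copies_per_ul, q1$copies_per_ul)
  expect_warning(quantify(5, curve), "extrapolation")
})

test_that("fit/quantify round trip recovers input copies to 1e-9", {
  copies <- 10^seq(2, 7, by = 1)
  ct <- 38 - 3.1 * log10(copies)
  curve <- fit_standard_curve(log10(copies), ct)
  back <- quantify(ct, curve)$copies
  expect_equal(back, copies, tolerance = 1e-9)
})

test_that("flagellin index is a per-mouse log10 ratio, scale invariant", {
  tr <- data.frame(mouse = c("m1", "m2"), copies_per_ul = c(100, 1000))
  ge <- data.frame(mouse = c("m1", "m2"), copies_per_ul = c(100, 100))
  idx <- flagellin_index(tr, ge)
  expect_equal(idx$log_ratio, c(0, 1))
  # joint rescaling of transcript and gene copies cancels
  tr2 <- transform(tr, copies_per_ul = copies_per_ul * 7.3)
  ge2 <- transform(ge, copies_per_ul = copies_per_ul * 7.3)
  expect_equal(flagellin_index(tr2, ge2)$log_ratio, idx$log_ratio)
  # unpaired mice are excluded with a warning
  tr3 <- rbind(tr, data.frame(mouse = "m9", copies_per_ul = 5))
  expect_warning(idx3 <- flagellin_index(tr3, ge), "m9")
  expect_identical(idx3$mouse, c("m1", "m2"))
})

test_that("healthy-vs-colitis flagellin groups are detectable with the power a Monte Carlo oracle predicts", {
  # oracle: unpaired t-test power for N(0.09, 0.18) vs N(-0.34, 0.31), n = 5
  reps <- 10000
  set.seed(500)
  oracle_rej <- mean(vapply(seq_len(reps), function(i) {
    t.test(rnorm(5, 0.09, 0.18), rnorm(5, -0.34, 0.31))$p.value < 0.05
  }, logical(1)))
  # the same experiment expressed through copy numbers and flagellin_index
  set.seed(501)
  reps2 <- 400
  rej <- mean(vapply(seq_len(reps2), function(i) {
    genes <- 10^rnorm(10, 5, 0.3)
    ratio <- c(rnorm(5, 0.09, 0.18), rnorm(5, -0.34, 0.31))
    idx <- flagellin_index(
      data.frame(mouse = paste0("m", 1:10), copies_per_ul = genes * 10^ratio),
      data.frame(mouse = paste0("m", 1:10), copies_per_ul = genes))
    t.test(idx$log_ratio[1:5], idx$log_ratio[6:10])$p.value < 0.05
  }, logical(1)))
  se <- sqrt(oracle_rej * (1 - oracle_rej) * (1 / reps + 1 / reps2))
  expect_gte(rej, oracle_rej - 4 * se)
})

test_that("expression ratios follow the efficiency-corrected formula", {
  mk <- function(ct) data.frame(sample = paste0("s", 1:4), ct = ct)
  ctl <- c("s1", "s2"); trt <- c("s3", "s4")
  # no change anywhere -> ratio 1
  r0 <- expression_ratio(mk(rep(25, 4)), mk(rep(20, 4)), ctl, trt)
  expect_equal(r0$ratio, 1)
  # target dCt = 1 at E = 2, reference unchanged -> ratio 2
  r1 <- expression_ratio(mk(c(26, 26, 25, 25)), mk(rep(20, 4)), ctl, trt)
  expect_equal(r1$ratio, 2)
  # reference dCt = 1 at E = 2, target unchanged -> ratio 0.5
  r2 <- expression_ratio(mk(rep(25, 4)), mk(c(21, 21, 20, 20)), ctl, trt)
  expect_equal(r2$ratio, 0.5)
  # a plate-wide Ct offset cancels exactly
  set.seed(3)
  tgt <- mk(rnorm(4, 27)); ref <- mk(rnorm(4, 19))
  ra <- expression_ratio(tgt, ref, ctl, trt)
  rb <- expression_ratio(transform(tgt, ct = ct + 3.7),
                         transform(ref, ct = ct + 3.7), ctl, trt)
  expect_equal(ra$ratio, rb$ratio, tolerance = 1e-12)
  expect_error(expression_ratio(tgt, ref, "s1", trt), "at least 2")
})

test_that("fixed reallocation test returns p = 1 for indistinguishable groups", {
  d <- data.frame(sample = paste0("s", 1:8),
                  ct = rep(c(25, 26, 24, 25.5), 2))
  hk <- data.frame(sample = paste0("s", 1:8), ct = rep(c(20, 21, 19, 20.5), 2))
  # treatment group is a copy of the control group
  r <- fixed_reallocation_test(d, hk, paste0("s", 1:4), paste0("s", 5:8),
                               n_reallocations = 500, seed = 1)
  expect_equal(r$p_value, 1)
  # fully degenerate data: p = 1 with a warning
  dd <- data.frame(sample = paste0("s", 1:8), ct = rep(25, 8))
  expect_warning(rd <- fixed_reallocation_test(dd, dd, paste0("s", 1:4),
                                               paste0("s", 5:8),
                                               n_reallocations = 200, seed = 1),
                 "identical")
  expect_equal(rd$p_value, 1)
  expect_error(fixed_reallocation_test(d, hk, paste0("s", 1:4), paste0("s", 5:8),
                                       n_reallocations = 50), ">= 100")
})

test_that("randomization p-values are reproducible and seed-sensitive", {
  d <- simulate_qpcr_dataset(log2_fold_change = 1.5, seed = 7)
  r1 <- fixed_reallocation_test(d$target, d$housekeeping, d$control_ids,
                                d$treatment_ids, n_reallocations = 2000, seed = 5)
  r2 <- fixed_reallocation_test(d$target, d$housekeeping, d$control_ids,
                                d$treatment_ids, n_reallocations = 2000, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
})

test_that("a planted 8-fold change is detected almost surely at n = 4 vs 4", {
  reps <- 500
  rej <- vapply(seq_len(reps), function(i) {
    d <- simulate_qpcr_dataset(n_control = 4, n_treatment = 4,
                               log2_fold_change = 3, ct_sd = 0.25,
                               seed = 10000 + i)
    fixed_reallocation_test(d$target, d$housekeeping, d$control_ids,
                            d$treatment_ids, n_reallocations = 2000,
                            seed = i)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)
})

test_that("two-group ANOVA coincides with the pooled t-test (F = t^2)", {
  set.seed(12)
  v <- c(rnorm(5, 0), rnorm(5, 1))
  g <- rep(c("a", "b"), each = 5)
  gt <- group_tests(v, g)
  expect_equal(gt$p, gt$t_test$p.value, tolerance = 1e-10)
  expect_equal(gt$F, unname(gt$t_test$statistic)^2, tolerance = 1e-10)
})

test_that("SNK letters separate a distant group and merge identical ones", {
  # identically distributed groups: F ~ 0, one shared letter
  v0 <- rep(c(1, 2, 3), 3)
  g0 <- rep(c("a", "b", "c"), each = 3)
  gt0 <- group_tests(v0, g0)
  expect_equal(gt0$F, 0)
  expect_identical(unname(unique(gt0$letters)), "a")
  # one group shifted far away gets a distinct letter
  v1 <- c(1.0, 1.2, 0.9, 1.1, 1.0, 0.8, 9.0, 9.3, 8.9)
  g1 <- rep(c("a", "b", "c"), each = 3)
  gt1 <- group_tests(v1, g1)
  expect_identical(unname(gt1$letters["a"]), unname(gt1$letters["b"]))
  expect_false(gt1$letters["c"] %in% gt1$letters[c("a", "b")])
  # all-constant groups are an error
  expect_error(group_tests(rep(1, 6), rep(c("a", "b"), each = 3)),
               "zero within-group variance")
})

test_that("SNK at two groups reduces to the pooled t-test decision", {
  # q = t * sqrt(2) and qtukey(., 2, df) = sqrt(2) * qt(0.975, df): the
  # stepwise procedure and the t-test must agree on significance
  set.seed(31)
  for (i in 1:20) {
    v <- c(rnorm(4, 0), rnorm(4, runif(1, 0, 2)))
    g <- rep(c("a", "b"), each = 4)
    gt <- group_tests(v, g)
    snk_sig <- length(unique(gt$letters)) == 2
    expect_identical(snk_sig, gt$t_test$p.value < 0.05)
  }
})
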