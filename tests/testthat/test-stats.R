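test_that("Pearson r, p and regression line match first principles", {
  set.seed(31)
  for (rep in 1:5) {
    x <- stats::rnorm(18, 28, 5)
    y <- 0.4 * x + stats::rnorm(18, 0, 2)
    got <- pearson_corr(x, y, names = c("bmi", "naf_knee"))
    want <- bf_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$n_used, 18)
  }

  # pairwise deletion: NAs are dropped as pairs, n reflects it
  x <- c(1, 2, 3, NA, 5, 6); y <- c(2.1, 3.9, 6.2, 8, NA, 12.5)
  got <- pearson_corr(x, y)
  want <- bf_pearson(c(1, 2, 3, 6), c(2.1, 3.9, 6.2, 12.5))
  expect_equal(got$r, want$r)
  expect_equal(got$n_used, 4)

  expect_error(pearson_corr(1:5, rep(2, 5)), "degenerate")
  expect_error(pearson_corr(c(1, 2, NA), c(1, NA, 3)), "fewer than 3")
  expect_error(pearson_corr(1:4, 1:5), "equal length")
})

test_that("correlation p-value agrees with a permutation oracle", {
  # exhaustive-ish check via Monte Carlo permutations at fixed seed: for a
  # moderate observed r, the permutation p and the t-transform p agree to
  # sampling error
  set.seed(42)
  x <- stats::rnorm(18); y <- 0.6 * x + stats::rnorm(18, 0, 0.9)
  r_obs <- bf_pearson(x, y)$r
  B <- 4000
  exceed <- 0
  for (b in 1:B) {
    rb <- bf_pearson(x, sample(y))$r
    if (abs(rb) >= abs(r_obs)) exceed <- exceed + 1
  }
  p_perm <- exceed / B
  p_t <- corr_pvalue(r_obs, 18)
  expect_lt(abs(p_perm - p_t), 3 * sqrt(p_t * (1 - p_t) / B) + 0.005)

  # monotone in |r|, symmetric in sign, exact limits
  expect_gt(corr_pvalue(0.3, 18), corr_pvalue(0.5, 18))
  expect_equal(corr_pvalue(-0.4, 18), corr_pvalue(0.4, 18))
  expect_equal(corr_pvalue(1, 18), 0)
  expect_equal(corr_pvalue(0, 18), 1)
})

test_that("paired laterality test matches the brute-force t formula", {
  set.seed(7)
  left <- stats::rnorm(18, 2, 0.5)
  right <- left + stats::rnorm(18, 0.1, 0.2)
  got <- paired_t(left, right, joint = "knee", tracer = "FDG")
  want <- bf_paired_t(left, right)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_equal(got$mean_diff, want$mean_diff)
  expect_equal(got$n, 18)

  # identical sides: no lateralization signal, not an error
  same <- paired_t(left, left)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(paired_t(left, left + 1), "zero variance")

  # missing pairs are dropped
  l2 <- left; l2[3] <- NA
  expect_equal(paired_t(l2, right)$n, 17)
})

test_that("minimal detectable correlation solves the Fisher-z relation", {
  for (n in c(10, 18, 30, 100)) {
    r <- min_detectable_r(n)
    z <- stats::qnorm(0.975) + stats::qnorm(0.8)
    # plug the solution back into the sample-size relation
    expect_equal((z / atanh(r))^2 + 3, n, tolerance = 1e-3,
                 label = sprintf("n recovered at n = %d", n))
  }
  # the study's planning value: n = 18, power 0.8, alpha 0.05
  expect_equal(round(min_detectable_r(18), 2), 0.62)
  # monotone: more subjects detect weaker correlations
  expect_lt(min_detectable_r(30), min_detectable_r(18))
  expect_lt(min_detectable_r(18, power = 0.8), min_detectable_r(18, 0.9))
  expect_error(min_detectable_r(3), "at least 4")
})

test_that("detectability threshold is confirmed by simulated power", {
  # Monte Carlo power at the computed minimal detectable r should be close
  # to the requested 80%, and clearly below it for a weaker correlation
  n <- 18
  r_min <- min_detectable_r(n)
  sim_power <- function(rho, B = 4000) {
    hits <- 0
    for (b in 1:B) {
      x <- stats::rnorm(n)
      y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
      if (corr_pvalue(bf_pearson(x, y)$r, n) < 0.05) hits <- hits + 1
    }
    hits / B
  }
  set.seed(99)
  expect_lt(abs(sim_power(r_min) - 0.80), 0.03)
  expect_lt(sim_power(0.40), 0.55)
  # null calibration: rejection rate at rho = 0 is close to alpha
  expect_lt(abs(sim_power(0) - 0.05), 0.015)
})

test_that("cohort analysis assembles per-cell statistics faithfully", {
  set.seed(11)
  n <- 18
  bmi <- stats::rnorm(n, 28, 4)
  vas <- stats::runif(n, 0, 10)
  tab <- data.frame(
    subject = sprintf("s%02d", 1:n),
    handedness = c(rep("right", 13), rep("left", 4), "ambidextrous"),
    bmi = bmi, vas = vas,
    fdg_knee = 1 + 0.05 * bmi + stats::rnorm(n, 0, 0.1),
    naf_knee_left = 2 + 0.04 * bmi + stats::rnorm(n, 0, 0.1),
    naf_knee_right = 2.1 + 0.04 * bmi + stats::rnorm(n, 0, 0.1))
  rep_ <- cohort_analysis(tab)
  cc <- rep_$correlations
  # side-averaged naf_knee is derived from the per-side columns
  expect_true(any(cc$tracer == "NaF" & cc$joint == "knee"))
  avg <- (tab$naf_knee_left + tab$naf_knee_right) / 2
  want <- bf_pearson(bmi, avg)
  row <- cc[cc$variable == "bmi" & cc$tracer == "NaF", ]
  expect_equal(row$r, want$r, tolerance = 1e-12)
  expect_equal(row$p, want$p, tolerance = 1e-10)
  # 2 uptake columns x 2 covariates
  expect_equal(nrow(cc), 4)
  expect_false("handedness" %in% cc$variable)

  # laterality test against the oracle
  lat <- rep_$laterality
  expect_equal(nrow(lat), 1)
  want_t <- bf_paired_t(tab$naf_knee_left, tab$naf_knee_right)
  expect_equal(lat$t, want_t$t, tolerance = 1e-12)

  # right-handed restriction drops 5 subjects from the paired test
  lat_rh <- cohort_analysis(tab, right_handed_only = TRUE)$laterality
  expect_equal(lat_rh$n, 13)
  want_rh <- bf_paired_t(tab$naf_knee_left[1:13], tab$naf_knee_right[1:13])
  expect_equal(lat_rh$t, want_rh$t, tolerance = 1e-12)

  # BH adjustment is applied within each joint x tracer family
  ccq <- cohort_analysis(tab, bh = TRUE)$correlations
  fam <- ccq[ccq$tracer == "FDG" & ccq$joint == "knee", ]
  expect_equal(sort(fam$q), sort(stats::p.adjust(fam$p, "BH")))

  # a degenerate covariate yields NA cells, not an error
  tab$flat <- 5
  cc2 <- cohort_analysis(tab)$correlations
  expect_true(all(is.na(cc2$r[cc2$variable == "flat"])))

  # matrix layout: one row per variable with per-tracer columns
  m <- correlation_matrix(rep_, "knee")
  expect_equal(sort(m$variable), sort(c("bmi", "vas")))
  expect_true(all(c("FDG_r", "FDG_p", "NaF_r", "NaF_p") %in% names(m)))
  expect_equal(m$NaF_r[m$variable == "bmi"], want$r, tolerance = 1e-12)
})
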