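test_that("cohort generation is deterministic and respects its schema", {
  spec <- cohort_spec(n = 18, correlations = default_correlations(),
                      sides = TRUE, seed = 7)
  a <- make_cohort(spec)
  b <- make_cohort(spec)
  expect_identical(a, b)
  expect_equal(nrow(a), 18)
  expect_true(all(c("subject", "handedness", "bmi", "height", "weight",
                    "fdg_knee", "naf_si", "naf_knee_left",
                    "naf_knee_right") %in% names(a)))
  expect_false(anyDuplicated(a$subject) > 0)
  expect_true(all(a$handedness %in% c("right", "left", "ambidextrous")))
  # a different seed gives different draws
  expect_false(identical(a$bmi, make_cohort(spec, seed = 8)$bmi))
})

test_that("marginals respect their ranges and hit the calibrated median", {
  spec <- cohort_spec(n = 4000, seed = 3)
  tab <- make_cohort(spec)
  marg <- default_marginals()
  for (k in seq_len(nrow(marg))) {
    v <- tab[[marg$variable[k]]]
    expect_true(all(v >= marg$lo[k] & v <= marg$hi[k]),
                label = paste(marg$variable[k], "within range"))
    expect_lt(abs(stats::median(v) - marg$median[k]),
              0.05 * max(1, abs(marg$median[k])))
  }
  # weight is exactly consistent with BMI and height
  expect_equal(tab$weight, tab$bmi * (tab$height / 100)^2)
})

test_that("designed correlations are realized by the copula", {
  R <- default_correlations()
  # the default matrix reproduces the reported pairwise values exactly and
  # is positive semi-definite
  published <- list(c("bmi", "fdg_knee", 0.62), c("bmi", "naf_knee", 0.50),
                    c("bmi", "naf_hip", 0.55), c("bmi", "naf_si", 0.54),
                    c("fdg_knee", "naf_knee", 0.77),
                    c("vas_ptglobal", "fdg_hip", -0.75),
                    c("vas_ptglobal", "fdg_si", -0.65),
                    c("bmi", "leptin", 0.65), c("bmi", "total_fat", 0.75))
  for (tr in published)
    expect_equal(R[tr[[1]], tr[[2]]], as.numeric(tr[[3]]), tolerance = 1e-12)
  expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)

  spec <- cohort_spec(n = 5000, correlations = R, seed = 11)
  tab <- make_cohort(spec)
  for (tr in published) {
    r_hat <- bf_pearson(tab[[tr[[1]]]], tab[[tr[[2]]]])$r
    expect_lt(abs(r_hat - as.numeric(tr[[3]])), 0.04,
              label = sprintf("corr(%s, %s)", tr[[1]], tr[[2]]))
  }
  # an implied cross-correlation is realized too
  expect_lt(abs(bf_pearson(tab$leptin, tab$fdg_knee)$r -
                  R["leptin", "fdg_knee"]), 0.04)
  # an unspecified pair stays near zero
  expect_lt(abs(bf_pearson(tab$age, tab$naf_knee)$r), 0.05)
})

test_that("side columns preserve the average and missingness is MCAR", {
  spec <- cohort_spec(n = 200, sides = TRUE, laterality_mean = 0.05,
                      missing_rates = c(leptin = 0.3), seed = 5)
  tab <- make_cohort(spec)
  for (u in c("fdg_knee", "naf_hip"))
    expect_equal((tab[[paste0(u, "_left")]] + tab[[paste0(u, "_right")]]) / 2,
                 tab[[u]], tolerance = 1e-12)
  expect_true(all(tab$naf_si_left >= 0 & tab$naf_si_right >= 0))
  miss <- mean(is.na(tab$leptin))
  expect_gt(miss, 0.15); expect_lt(miss, 0.45)
  expect_false(anyNA(tab$bmi))

  expect_error(cohort_spec(missing_rates = 0.3), "named")
  expect_error(cohort_spec(correlations = list(c("bmi", "nope", 0.5))),
               "unknown variable")
})

test_that("an infeasible correlation target is rejected as non-PSD", {
  bad <- list(c("bmi", "leptin", 0.9), c("bmi", "total_fat", 0.9),
              c("leptin", "total_fat", -0.9))
  expect_error(cohort_spec(correlations = bad),
               "positive semi-definite")
})

test_that("phantom construction is deterministic and self-consistent", {
  a <- small_phantom("hip")
  b <- small_phantom("hip")
  expect_identical(a$ct$values, b$ct$values)
  expect_identical(a$pet$values, b$pet$values)

  # the truth mask is exactly the HU rule applied to the generated CT
  expect_equal(a$truth$mask$values,
               a$ct$values >= 150 & a$ct$values <= 1500)
  # cortical bone lies inside the window; marrow and soft tissue below it
  expect_true(all(a$ct$values[a$truth$mask$values] >= 150))
  expect_true(all(a$ct$values[!a$truth$mask$values] < 150))

  # converting the generated PET recovers the designed SUV inside bone
  suv <- activity_to_suv(a$pet, a$meta)
  expect_equal(unique(round(suv$values[a$truth$bone], 9)),
               unname(a$truth$suv_mean["left"]))

  # volumes are mirror-symmetric about the midline by construction
  expect_equal(a$ct$values, a$ct$values[dim(a$ct$values)[1]:1, , ])

  # optional PET noise is seeded and changes the volume
  n1 <- small_phantom("hip", noise_sd = 50, seed = 2)
  n2 <- small_phantom("hip", noise_sd = 50, seed = 2)
  expect_identical(n1$pet$values, n2$pet$values)
  expect_false(identical(n1$pet$values, a$pet$values))

  expect_error(phantom_spec("hip", cortical_hu = 2000), "150")
  expect_error(phantom_spec("hip", bone_suv = -1), "suv|negative|>= 0")
})

test_that("phantom metadata follow the tracer-specific protocol", {
  fdg <- small_phantom("knee", tracer = "FDG")
  expect_equal(fdg$meta$uptake_min, 180)
  expect_equal(fdg$meta$injected_dose_mbq,
               0.11 * fdg$meta$body_weight_kg * 37, tolerance = 1e-9)
  naf <- small_phantom("knee", tracer = "NaF")
  expect_equal(naf$meta$uptake_min, 90)
  expect_equal(naf$meta$injected_dose_mbq,
               0.08 * naf$meta$body_weight_kg * 37, tolerance = 1e-9)
})
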