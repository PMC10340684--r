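test_that("global SUVmean is the plain arithmetic mean over the mask", {
  set.seed(13)
  d <- c(8L, 7L, 6L)
  suv <- volume(array(stats::runif(prod(d), 0, 5), d), c(2, 2, 2),
                c(0, 0, 0), "SUV", tracer = "FDG")
  sel <- array(stats::runif(prod(d)) < 0.4, d)
  u <- global_suv_mean(suv, mask(sel), subject = "s01", joint = "knee",
                       side = "left")
  # independent accumulation by explicit loop
  tot <- 0; n <- 0
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    if (sel[i, j, k]) { tot <- tot + suv$values[i, j, k]; n <- n + 1 }
  expect_equal(u$suv_mean, tot / n)
  expect_equal(u$voxel_count, n)
  expect_equal(u$tracer, "FDG")

  expect_error(global_suv_mean(suv, mask(array(FALSE, d))),
               "no voxels segmented")
  expect_error(global_suv_mean(suv, mask(array(TRUE, c(4, 4, 4)))),
               "different grids")
})

test_that("a uniform bone block is quantified exactly end-to-end", {
  # CT: one 1000 HU block in soft tissue; PET built so the designed SUV is
  # 2.4 inside the block and 0.3 outside
  d <- c(40L, 40L, 40L)
  ct_vals <- array(40, d)
  ct_vals[22:33, 22:33, 22:33] <- 1000
  ct <- volume(ct_vals, c(2, 2, 2), c(0, 0, 0), "CT")
  meta <- injection_meta(200, "MBq", "2023-01-01 08:00:00",
                         "2023-01-01 09:30:00", body_weight_kg = 70,
                         tracer = "NaF")
  dose_dec <- meta$injected_dose_mbq * 1e6 *
    2^(-meta$uptake_min / meta$half_life_min)
  suv_field <- array(0.3, d)
  suv_field[22:33, 22:33, 22:33] <- 2.4
  pet <- volume(suv_field * dose_dec / (70 * 1000), c(2, 2, 2),
                c(0, 0, 0), "PET")
  lm <- landmark_set(knee = list(left = list(
    intercondylar_eminence = c(40, 40, 40))))
  u <- quantify_joint(ct, pet, meta, lm, "knee", "left",
                      closing_radius = 2)
  expect_equal(u$suv_mean, 2.4, tolerance = 1e-12)
  expect_equal(u$voxel_count, 12L^3)

  # region growing from high-HU seeds gives the same region here
  ug <- quantify_joint(ct, pet, meta, lm, "knee", "left",
                       closing_radius = 2, grow = TRUE)
  expect_equal(ug$suv_mean, u$suv_mean)
  expect_equal(ug$voxel_count, u$voxel_count)
})

test_that("phantom bone SUV is recovered through the full pipeline", {
  # 4 mm test grids need a proportionally smaller closing element; the
  # study-condition 2 mm grids are exercised in the acceptance tests
  for (joint in c("knee", "hip")) {
    ph <- small_phantom(joint, bone_suv = 1.587)
    for (side in c("left", "right")) {
      u <- quantify_joint(ph$ct, ph$pet, ph$meta, ph$landmarks, joint,
                          side, closing_radius = 10)
      expect_lt(abs(u$suv_mean - 1.587) / 1.587, 0.05,
                label = sprintf("%s %s relative SUV error", joint, side))
    }
  }
  # the narrow SI cleft is more sensitive to the coarse 4 mm grid; hold it
  # to a looser bound here (the 2 mm grid is held to 5% in acceptance)
  ph <- small_phantom("si", bone_suv = 1.587)
  u <- quantify_joint(ph$ct, ph$pet, ph$meta, ph$landmarks, "si", "left",
                      closing_radius = 10)
  expect_lt(abs(u$suv_mean - 1.587) / 1.587, 0.10)
})

test_that("pre-closing segmentation equals the HU-rule truth inside the box", {
  ph <- small_phantom("hip")
  box <- build_roi("hip", ph$landmarks, ph$ct, "right")
  seg <- threshold_bone(ph$ct, box)
  ind <- array(FALSE, dim(ph$ct$values))
  b <- box$bounds_vox
  ind[(b[1, 1] + 1):b[2, 1], (b[1, 2] + 1):b[2, 2],
      (b[1, 3] + 1):b[2, 3]] <- TRUE
  expect_equal(seg$values, ph$truth$mask$values & ind)
})

test_that("per-side designed SUVs are recovered and averaged correctly", {
  ph <- small_phantom("knee", bone_suv = c(left = 1, right = 2))
  ul <- quantify_joint(ph$ct, ph$pet, ph$meta, ph$landmarks, "knee",
                       "left", subject = "s01", closing_radius = 10)
  ur <- quantify_joint(ph$ct, ph$pet, ph$meta, ph$landmarks, "knee",
                       "right", subject = "s01", closing_radius = 10)
  expect_lt(abs(ul$suv_mean - 1), 0.05)
  expect_lt(abs(ur$suv_mean - 2), 0.10)
  expect_equal(average_sides(ul, ur), (ul$suv_mean + ur$suv_mean) / 2)

  ur2 <- ur; ur2$subject <- "s02"
  expect_error(average_sides(ul, ur2), "mismatched subject")
  tab <- uptake_table(list(ul, ur))
  expect_equal(dim(tab), c(2L, 6L))
  expect_equal(tab$side, c("left", "right"))
})

test_that("pipeline failures are tagged with the failing stage", {
  ph <- small_phantom("knee")
  expect_error(
    quantify_joint(ph$ct, ph$pet, ph$meta, landmark_set(), "knee", "left"),
    "^\\[roi\\]")
  soft <- volume(array(40, dim(ph$ct$values)), ph$ct$spacing,
                 ph$ct$origin, "CT")
  expect_error(
    quantify_joint(soft, ph$pet, ph$meta, ph$landmarks, "knee", "left",
                   closing_radius = 2),
    "^\\[quantify\\] no voxels segmented")
  far <- volume(ph$pet$values, ph$pet$spacing, ph$pet$origin + 1e5, "PET")
  expect_error(
    quantify_joint(ph$ct, far, ph$meta, ph$landmarks, "knee", "left"),
    "^\\[suv\\]")
})
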