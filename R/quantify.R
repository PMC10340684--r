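#' Global SUVmean over a mask
#'
#' The global SUVmean is the unweighted arithmetic mean of the SUV of all
#' voxels included in the final segmented region.
#'
#' @param suv a `jsv_volume` of modality "SUV" on the CT grid.
#' @param m a non-empty `jsv_mask` on the same grid.
#' @param subject subject identifier.
#' @param joint,side,tracer labels for the result; default taken from the
#'   mask's box and the SUV volume's tracer tag.
#' @return an object of class `joint_uptake` with fields `subject`,
#'   `joint`, `side`, `tracer`, `suv_mean`, `voxel_count`, `provenance`.
#' @export
global_suv_mean <- function(suv, m, subject = "subject",
                            joint = NULL, side = NULL, tracer = NULL) {
  stopifnot(inherits(suv, "jsv_volume"), inherits(m, "jsv_mask"))
  if (!identical(dim(suv$values), dim(m$values)))
    stop("SUV volume and mask are on different grids")
  if (m$voxel_count == 0L) stop("no voxels segmented: empty mask")
  vals <- suv$values[m$values]
  if (is.null(joint)) joint <- if (!is.null(m$box)) m$box$joint else NA
  if (is.null(side)) side <- if (!is.null(m$box)) m$box$side else NA
  if (is.null(tracer)) tracer <- if (!is.null(suv$tracer)) suv$tracer else NA
  structure(
    list(subject = subject, joint = joint, side = side, tracer = tracer,
         suv_mean = mean(vals), voxel_count = m$voxel_count,
         suv_min = min(vals), suv_max = max(vals),
         provenance = m$provenance),
    class = "joint_uptake")
}

#' @export
print.joint_uptake <- function(x, ...) {
  cat(sprintf("<joint_uptake> %s %s %s %s: SUVmean %.4f over %d voxels\n",
              x$subject, x$joint, x$side, x$tracer, x$suv_mean,
              x$voxel_count))
  invisible(x)
}

#' Quantify one joint and side end-to-end
#'
#' Composes the full pipeline: ROI construction from landmarks, bone
#' segmentation on the CT (HU thresholding, or seeded region growing when
#' `grow = TRUE`), morphological closing, resampling of the PET onto the
#' CT grid, SUV conversion, and the global SUVmean.
#'
#' @param ct CT `jsv_volume` (HU).
#' @param pet PET `jsv_volume` (Bq/mL), coregistered with the CT.
#' @param meta an `injection_meta`.
#' @param landmarks a `landmark_set`.
#' @param joint "knee", "hip" or "si".
#' @param side "left" or "right".
#' @param subject subject identifier.
#' @param lower,upper HU thresholds (defaults 150 and 1500).
#' @param closing_radius element radius in voxels (default 20).
#' @param element closing element, "disk2d" or "ball3d".
#' @param grow use seeded region growing instead of plain thresholding:
#'   seeds are all in-box voxels at or above `seed_hu`, and only the
#'   connected components touching them are retained.
#' @param seed_hu HU level defining seeds for `grow = TRUE` (default 300).
#' @param connectivity growing connectivity (default 26).
#' @param decay_correct passed to [activity_to_suv()].
#' @param roi_args named list of extra arguments for the ROI builder.
#' @return a `joint_uptake`.
#' @export
quantify_joint <- function(ct, pet, meta, landmarks, joint, side,
                           subject = "subject", lower = 150, upper = 1500,
                           closing_radius = 20,
                           element = c("disk2d", "ball3d"), grow = FALSE,
                           seed_hu = 300, connectivity = 26,
                           decay_correct = TRUE, roi_args = list()) {
  element <- match.arg(element)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  box <- stage("roi", do.call(build_roi,
                              c(list(joint, landmarks, ct, side), roi_args)))
  m <- stage("segmentation", {
    if (grow) {
      thr <- threshold_bone(ct, box, lower, upper)
      seed_sel <- ct$values >= seed_hu & thr$values
      if (!any(seed_sel)) stop("no seed voxels at or above ", seed_hu, " HU")
      seeds <- which(seed_sel, arr.ind = TRUE) - 1L
      region_grow(ct, seeds, lower, upper, connectivity, box)
    } else {
      threshold_bone(ct, box, lower, upper)
    }
  })
  m <- stage("closing", morphological_close(m, closing_radius, element))
  suv <- stage("suv", {
    pet_on_ct <- resample_to_grid(pet, ct)
    activity_to_suv(pet_on_ct, meta, decay_correct = decay_correct)
  })
  stage("quantify",
        global_suv_mean(suv, m, subject = subject, joint = joint,
                        side = side, tracer = meta$tracer))
}

#' Average the left and right SUVmean of one joint
#'
#' The subject-level uptake statistic fed to the cohort correlations is
#' the unweighted mean of the left and right global SUVmean.
#'
#' @param left,right `joint_uptake` results for the same subject, joint
#'   and tracer.
#' @return the scalar side-averaged SUVmean.
#' @export
average_sides <- function(left, right) {
  stopifnot(inherits(left, "joint_uptake"), inherits(right, "joint_uptake"))
  for (f in c("subject", "joint", "tracer"))
    if (!identical(left[[f]], right[[f]]))
      stop("cannot average sides: mismatched ", f, " (",
           left[[f]], " vs ", right[[f]], ")")
  (left$suv_mean + right$suv_mean) / 2
}

#' Collect joint_uptake results into a data frame
#' @param results list of `joint_uptake` objects.
#' @return a data.frame with one row per result.
#' @export
uptake_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(subject = r$subject, joint = r$joint, side = r$side,
               tracer = r$tracer, suv_mean = r$suv_mean,
               voxel_count = r$voxel_count, stringsAsFactors = FALSE)))
}
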