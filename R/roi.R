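JOINTS <- c("knee", "hip", "si")
SIDES <- c("left", "right")

#' Per-subject anatomical landmarks
#'
#' All coordinates are mm world coordinates on the CT grid. The expected
#' structure, per joint and side:
#' * knee: `intercondylar_eminence` — length-3 point (x, y, z).
#' * hip: `head_neck_junction_x` — sagittal coordinate of the plane
#'   separating femoral head from neck; `pelvic_brim_x` — sagittal
#'   coordinate of the pelvic brim; `neck_edge_z` — length-2 (inferior,
#'   superior) z extent of the femoral-neck edge.
#' * si: `articulation_x` — sagittal coordinate of the sacrum–ilium
#'   articulation line; `articulation_z` — length-2 (inferior, superior)
#'   z extent of the articulation.
#'
#' @param knee,hip,si named lists with `left`/`right` entries as above
#'   (any subset may be supplied).
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(knee = NULL, hip = NULL, si = NULL) {
  lm <- list(knee = knee, hip = hip, si = si)
  for (j in JOINTS) {
    if (is.null(lm[[j]])) next
    bad <- setdiff(names(lm[[j]]), SIDES)
    if (length(bad)) stop("unknown side(s) for ", j, ": ",
                          paste(bad, collapse = ", "))
  }
  structure(lm, class = "landmark_set")
}

#' Read landmarks from a JSON file
#' @param path path to a landmark JSON file keyed by joint then side.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  landmark_set(knee = j$knee, hip = j$hip, si = j$si)
}

#' Write landmarks to a JSON file
#' @param landmarks a `landmark_set`.
#' @param path output path.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  jsonlite::write_json(unclass(landmarks)[!vapply(landmarks, is.null,
                                                  logical(1))],
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

get_landmark <- function(landmarks, joint, side) {
  lm <- landmarks[[joint]][[side]]
  if (is.null(lm))
    stop("missing ", joint, " landmarks for side '", side, "'")
  lm
}

#' Axis-aligned rectangular region of interest
#'
#' Converts mm bounds to half-open 0-based voxel index bounds on the CT
#' grid: a voxel belongs to the box when its center lies inside the mm
#' bounds (inclusive). Bounds are clipped to the volume extent and the
#' clipping is recorded.
#'
#' @param joint "knee", "hip" or "si".
#' @param side "left" or "right".
#' @param mm_bounds 2x3 matrix, rows `lo` and `hi`, mm bounds per axis.
#' @param ct the reference CT `jsv_volume`.
#' @return an object of class `region_box` with elements `bounds_vox`
#'   (2x3, rows lo/hi, half-open, 0-based), `bounds_mm`, and `clipped`.
#' @export
region_box <- function(joint, side, mm_bounds, ct) {
  joint <- match.arg(joint, JOINTS)
  side <- match.arg(side, SIDES)
  stopifnot(is.matrix(mm_bounds), dim(mm_bounds) == c(2, 3))
  if (any(mm_bounds[2, ] < mm_bounds[1, ]))
    stop("empty region: hi < lo in mm bounds")
  d <- dim(ct$values)
  eps <- 1e-6
  lo_idx <- ceiling((mm_bounds[1, ] - ct$origin) / ct$spacing - eps)
  hi_idx <- floor((mm_bounds[2, ] - ct$origin) / ct$spacing + eps) + 1
  clipped <- any(lo_idx < 0) || any(hi_idx > d)
  lo_idx <- pmax(lo_idx, 0)
  hi_idx <- pmin(hi_idx, d)
  if (any(hi_idx <= lo_idx))
    stop(joint, " ", side, " region is empty on the CT grid ",
         "(outside the volume or narrower than a voxel)")
  structure(
    list(joint = joint, side = side,
         bounds_vox = rbind(lo = lo_idx, hi = hi_idx),
         bounds_mm = mm_bounds, clipped = clipped,
         id = paste(joint, side, sep = "_")),
    class = "region_box")
}

#' @export
print.region_box <- function(x, ...) {
  cat(sprintf("<region_box> %s %s%s\n  vox [%s) x [%s) x [%s)\n",
              x$joint, x$side, if (x$clipped) " (clipped)" else "",
              paste(x$bounds_vox[, 1], collapse = ", "),
              paste(x$bounds_vox[, 2], collapse = ", "),
              paste(x$bounds_vox[, 3], collapse = ", ")))
  invisible(x)
}

# half-volume in-plane bounds for one side, split at the midsagittal plane;
# side is decided by which half contains x_mm
halfvolume_x <- function(ct, x_mm, midline_mm = NULL) {
  ext <- world_extent(ct)
  if (is.null(midline_mm)) midline_mm <- mean(ext[, 1])
  if (x_mm >= midline_mm) c(midline_mm, ext["hi", 1])
  else c(ext["lo", 1], midline_mm)
}

#' Build the knee region of interest
#'
#' Axial slab from 4 cm inferior to 4 cm superior of the intercondylar
#' eminence. In-plane, the box spans the half field of view on the
#' eminence's side of the midsagittal plane and the full
#' anterior-posterior extent (the axial planes are the anatomically
#' defined boundaries; the in-plane split separates left from right).
#'
#' @param landmarks a `landmark_set` with a knee `intercondylar_eminence`
#'   for `side`.
#' @param ct the CT `jsv_volume`.
#' @param side "left" or "right".
#' @param slab_halfwidth_mm half-extent of the axial slab (default 40 mm).
#' @param midline_mm x coordinate of the midsagittal plane; defaults to
#'   the volume's mid-x.
#' @return a `region_box`.
#' @export
knee_roi <- function(landmarks, ct, side, slab_halfwidth_mm = 40,
                     midline_mm = NULL) {
  lm <- get_landmark(landmarks, "knee", side)
  em <- as.numeric(lm$intercondylar_eminence)
  if (length(em) != 3L || any(!is.finite(em)))
    stop("intercondylar_eminence must be a finite mm point (x, y, z)")
  ext <- world_extent(ct)
  xr <- halfvolume_x(ct, em[1], midline_mm)
  mm <- rbind(lo = c(xr[1], ext["lo", 2], em[3] - slab_halfwidth_mm),
              hi = c(xr[2], ext["hi", 2], em[3] + slab_halfwidth_mm))
  region_box("knee", side, mm, ct)
}

#' Build the hip region of interest
#'
#' Rectangular region around the femoral head and its articulation with
#' the acetabulum, excluding the femoral neck: the lateral border is the
#' femoral head–neck junction plane, the medial border sits 2 mm lateral
#' to the pelvic brim, and the superior/inferior borders extend 10 mm
#' beyond the femoral-neck edge. The anterior-posterior extent spans the
#' volume (only lateral/medial/superior/inferior borders are anatomically
#' constrained).
#'
#' @inheritParams knee_roi
#' @param brim_margin_mm distance medial border is kept lateral of the
#'   pelvic brim (default 2 mm).
#' @param neck_margin_mm superior/inferior margin beyond the neck edge
#'   (default 10 mm).
#' @return a `region_box`.
#' @export
hip_roi <- function(landmarks, ct, side, brim_margin_mm = 2,
                    neck_margin_mm = 10) {
  lm <- get_landmark(landmarks, "hip", side)
  jx <- as.numeric(lm$head_neck_junction_x)
  bx <- as.numeric(lm$pelvic_brim_x)
  nz <- as.numeric(lm$neck_edge_z)
  if (!length(jx) || !length(bx) || length(nz) != 2L)
    stop("hip landmarks require head_neck_junction_x, pelvic_brim_x ",
         "and neck_edge_z (length 2)")
  # the medial border is pulled brim_margin_mm back toward the lateral side
  medial <- bx - brim_margin_mm * sign(bx - jx)
  if (medial == jx) stop("degenerate hip landmarks: zero-width region")
  if (sign(medial - jx) != sign(bx - jx))
    stop("inconsistent hip landmarks: medial border lies lateral ",
         "to the head-neck junction")
  ext <- world_extent(ct)
  mm <- rbind(lo = c(min(jx, medial), ext["lo", 2],
                     min(nz) - neck_margin_mm),
              hi = c(max(jx, medial), ext["hi", 2],
                     max(nz) + neck_margin_mm))
  region_box("hip", side, mm, ct)
}

#' Build the sacroiliac region of interest
#'
#' Rectangular region extending 20 mm laterally and 20 mm medially from
#' the sacrum–ilium articulation line, vertically spanning the superior
#' and inferior ends of the articulation. The anterior-posterior extent
#' spans the volume.
#'
#' @inheritParams knee_roi
#' @param lateral_margin_mm half-width either side of the articulation
#'   (default 20 mm).
#' @return a `region_box`.
#' @export
si_roi <- function(landmarks, ct, side, lateral_margin_mm = 20) {
  lm <- get_landmark(landmarks, "si", side)
  ax <- as.numeric(lm$articulation_x)
  az <- as.numeric(lm$articulation_z)
  if (!length(ax) || length(az) != 2L)
    stop("SI landmarks require articulation_x and articulation_z (length 2)")
  ext <- world_extent(ct)
  mm <- rbind(lo = c(ax - lateral_margin_mm, ext["lo", 2], min(az)),
              hi = c(ax + lateral_margin_mm, ext["hi", 2], max(az)))
  region_box("si", side, mm, ct)
}

#' Build the region of interest for any joint
#' @inheritParams knee_roi
#' @param joint "knee", "hip" or "si".
#' @param ... passed to the joint-specific builder.
#' @export
build_roi <- function(joint, landmarks, ct, side, ...) {
  joint <- match.arg(joint, JOINTS)
  switch(joint,
         knee = knee_roi(landmarks, ct, side, ...),
         hip = hip_roi(landmarks, ct, side, ...),
         si = si_roi(landmarks, ct, side, ...))
}
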