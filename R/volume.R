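#' Construct a volume
#'
#' A `jsv_volume` is a 3D scalar grid with axis-aligned geometry: CT values in
#' Hounsfield units, PET values in Bq/mL, or dimensionless SUV. World
#' coordinates follow `world = origin + index0 * spacing`, where `index0` is
#' the 0-based voxel index along each array dimension.
#'
#' @param values numeric 3D array (finite everywhere).
#' @param spacing numeric length-3, mm per axis, all positive.
#' @param origin numeric length-3, mm world coordinates of voxel (0,0,0).
#' @param modality one of "CT", "PET", "SUV", "MASK".
#' @param tracer optional tracer tag ("FDG" or "NaF") for PET/SUV volumes.
#' @return an object of class `jsv_volume`.
#' @export
volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   modality = c("CT", "PET", "SUV", "MASK"), tracer = NULL) {
  modality <- match.arg(modality)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("expected 3D volume, got ", length(dim(values)), " dimensions")
  if (any(dim(values) <= 0L)) stop("all three dimensions must be positive")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be three finite values (mm)")
  if (any(!is.finite(values)))
    stop("volume contains non-finite values (NaN/Inf)")
  if (!is.null(tracer)) tracer <- match_tracer(tracer)
  structure(
    list(values = values, spacing = spacing, origin = origin,
         modality = modality, tracer = tracer),
    class = "jsv_volume")
}

match_tracer <- function(tracer) {
  switch(toupper(tracer), FDG = "FDG", NAF = "NaF",
         stop("unknown tracer: ", tracer))
}

#' @export
print.jsv_volume <- function(x, ...) {
  cat(sprintf("<jsv_volume> %s %s  dim %s  spacing %s mm  origin %s mm\n",
              x$modality, if (is.null(x$tracer)) "" else x$tracer,
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ",")))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.jsv_volume <- function(x) dim(x$values)

#' World extent of a volume
#'
#' Returns the mm coordinates spanned by voxel centers: a 2x3 matrix with
#' rows `lo` and `hi`.
#' @param vol a `jsv_volume`.
#' @export
world_extent <- function(vol) {
  lo <- vol$origin
  hi <- vol$origin + (dim(vol$values) - 1L) * vol$spacing
  rbind(lo = lo, hi = hi)
}

#' Convert world mm coordinates to continuous 0-based voxel indices
#' @param vol a `jsv_volume`.
#' @param mm numeric length-3 point or n x 3 matrix of mm coordinates.
#' @export
world_to_voxel <- function(vol, mm) {
  if (is.matrix(mm)) sweep(sweep(mm, 2, vol$origin), 2, vol$spacing, "/")
  else (as.numeric(mm) - vol$origin) / vol$spacing
}

#' Convert 0-based voxel indices to world mm coordinates
#' @param vol a `jsv_volume`.
#' @param idx numeric length-3 index or n x 3 matrix of 0-based indices.
#' @export
voxel_to_world <- function(vol, idx) {
  if (is.matrix(idx)) sweep(sweep(idx, 2, vol$spacing, "*"), 2, vol$origin, "+")
  else vol$origin + as.numeric(idx) * vol$spacing
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Read a volume from a NIfTI file
#'
#' @param path path to a .nii or .nii.gz file holding a 3D image.
#' @param modality how to interpret the values: "CT" (HU), "PET" (Bq/mL),
#'   "SUV" (dimensionless) or "MASK".
#' @param tracer optional tracer tag for PET/SUV volumes.
#' @return a `jsv_volume` with spacing and origin taken from the header.
#' @export
read_volume <- function(path, modality = c("CT", "PET", "SUV", "MASK"),
                        tracer = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3D volume in ", path, ", got ", length(d), " dimensions")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(sp <= 0)) stop("non-positive voxel spacing in header of ", path)
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  vals <- as.array(img)
  attributes(vals) <- list(dim = d)
  volume(vals, spacing = sp, origin = origin, modality = modality,
         tracer = tracer)
}

#' Write a volume to a NIfTI file
#'
#' Masks are written as uint8 0/1, everything else as float64 so round trips
#' are lossless.
#' @param vol a `jsv_volume`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "jsv_volume"))
  vals <- vol$values
  datatype <- if (vol$modality == "MASK") "uint8" else "double"
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1)); m[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Resample a volume onto the grid of a reference volume
#'
#' Trilinear interpolation in world coordinates. Reference voxels whose
#' centers fall outside the moving volume's support are filled with
#' `fill` (default 0). Grids are axis-aligned; PET is resampled onto the CT
#' grid in the pipeline because masks are CT-derived.
#'
#' @param moving the `jsv_volume` to resample.
#' @param reference the `jsv_volume` whose grid defines the output.
#' @param fill value for voxels outside the moving support.
#' @return a `jsv_volume` on the reference grid carrying the moving
#'   volume's modality and tracer.
#' @export
resample_to_grid <- function(moving, reference, fill = 0) {
  stopifnot(inherits(moving, "jsv_volume"), inherits(reference, "jsv_volume"))
  em <- world_extent(moving); er <- world_extent(reference)
  if (any(em["hi", ] < er["lo", ]) || any(er["hi", ] < em["lo", ]))
    stop("moving and reference volumes are disjoint in world space")
  if (same_grid(moving, reference)) {
    out <- moving
    return(out)
  }
  dref <- dim(reference$values)
  # continuous 0-based index into the moving grid for each reference axis
  ax <- lapply(1:3, function(k) {
    w <- reference$origin[k] + (seq_len(dref[k]) - 1) * reference$spacing[k]
    (w - moving$origin[k]) / moving$spacing[k]
  })
  dm <- dim(moving$values)
  f1 <- clamp_floor(ax[[1]], dm[1]); f2 <- clamp_floor(ax[[2]], dm[2])
  f3 <- clamp_floor(ax[[3]], dm[3])
  # expand per-axis pieces to the full reference grid
  i0 <- array(f1$i0, dref); t1 <- array(f1$t, dref)
  j0 <- array(rep(f2$i0, each = dref[1]), dref)
  t2 <- array(rep(f2$t, each = dref[1]), dref)
  k0 <- array(rep(f3$i0, each = dref[1] * dref[2]), dref)
  t3 <- array(rep(f3$t, each = dref[1] * dref[2]), dref)
  vm <- moving$values
  idx <- function(di, dj, dk) {
    vm[(i0 + di) + dm[1] * (j0 + dj) + dm[1] * dm[2] * (k0 + dk) + 1L]
  }
  out <- (1 - t1) * (1 - t2) * (1 - t3) * idx(0L, 0L, 0L) +
    t1 * (1 - t2) * (1 - t3) * idx(1L, 0L, 0L) +
    (1 - t1) * t2 * (1 - t3) * idx(0L, 1L, 0L) +
    t1 * t2 * (1 - t3) * idx(1L, 1L, 0L) +
    (1 - t1) * (1 - t2) * t3 * idx(0L, 0L, 1L) +
    t1 * (1 - t2) * t3 * idx(1L, 0L, 1L) +
    (1 - t1) * t2 * t3 * idx(0L, 1L, 1L) +
    t1 * t2 * t3 * idx(1L, 1L, 1L)
  outside <- array(f1$out, dref) | array(rep(f2$out, each = dref[1]), dref) |
    array(rep(f3$out, each = dref[1] * dref[2]), dref)
  out[outside] <- fill
  dim(out) <- dref
  volume(out, spacing = reference$spacing, origin = reference$origin,
         modality = moving$modality, tracer = moving$tracer)
}

# floor with clamping for trilinear gather; returns 0-based lower corner,
# fraction, and an outside-support flag (tolerates tiny float overshoot)
clamp_floor <- function(x, n, tol = 1e-9) {
  out <- x < -tol | x > (n - 1) + tol
  x <- pmin(pmax(x, 0), n - 1)
  i0 <- pmin(floor(x), n - 2)
  i0 <- pmax(i0, 0)
  list(i0 = as.integer(i0), t = x - i0, out = out)
}
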