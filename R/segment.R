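#' Binary mask on the CT grid
#'
#' Carries the binary array, its voxel count, the region box it was
#' produced in (if any) and full provenance of the operators applied.
#'
#' @param values logical or 0/1 3D array.
#' @param box optional `region_box` the mask is confined to.
#' @param provenance named list of parameters (thresholds, radius, ...).
#' @return an object of class `jsv_mask`.
#' @export
mask <- function(values, box = NULL, provenance = list()) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("mask must be a 3D array")
  values <- array(as.logical(values), dim(values))
  structure(
    list(values = values, voxel_count = sum(values), box = box,
         provenance = provenance),
    class = "jsv_mask")
}

#' @export
print.jsv_mask <- function(x, ...) {
  cat(sprintf("<jsv_mask> %d voxels, dim %s%s\n", x$voxel_count,
              paste(dim(x$values), collapse = "x"),
              if (is.null(x$box)) "" else paste0(", box ", x$box$id)))
  invisible(x)
}

# logical array with TRUE inside the (half-open, 0-based) voxel bounds
box_indicator <- function(d, box) {
  b <- box$bounds_vox
  ind <- array(FALSE, d)
  ind[(b[1, 1] + 1):b[2, 1], (b[1, 2] + 1):b[2, 2],
      (b[1, 3] + 1):b[2, 3]] <- TRUE
  ind
}

#' Threshold bone inside a region of interest
#'
#' Selects voxels of the region box whose CT number lies within
#' `[lower, upper]` HU (inclusive). The defaults are the bone window used
#' throughout the pipeline: 150 to 1500 HU.
#'
#' @param ct a CT `jsv_volume`.
#' @param box a `region_box`; if `NULL` the whole volume is used.
#' @param lower,upper HU thresholds, `lower < upper`.
#' @return a `jsv_mask` confined to the box.
#' @export
threshold_bone <- function(ct, box = NULL, lower = 150, upper = 1500) {
  stopifnot(inherits(ct, "jsv_volume"))
  if (lower >= upper) stop("lower threshold must be below upper threshold")
  sel <- ct$values >= lower & ct$values <= upper
  if (!is.null(box)) sel <- sel & box_indicator(dim(ct$values), box)
  mask(sel, box = box,
       provenance = list(op = "threshold", lower_hu = lower,
                         upper_hu = upper,
                         box = if (is.null(box)) NULL else box$id))
}

# neighborhood offsets for 6/18/26 connectivity
conn_offsets <- function(connectivity) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3)
  as.matrix(g[keep, ])
}

# binary dilation by one step of the given connectivity, via array shifts
shift_dilate <- function(m, offsets) {
  d <- dim(m)
  out <- m
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    src <- lapply(1:3, function(k) {
      i <- seq_len(d[k]) - o[k]
      i[i < 1 | i > d[k]] <- NA
      i
    })
    shifted <- m[src[[1]], src[[2]], src[[3]]]
    shifted[is.na(shifted)] <- FALSE
    out <- out | shifted
  }
  out
}

#' Region growing from seed voxels
#'
#' Grows the connected component(s) of the HU-thresholded set that contain
#' the seeds, by geodesic dilation to a fixpoint under the configured
#' connectivity. The result is always a subset of the plain threshold mask
#' with the same bounds.
#'
#' @param ct a CT `jsv_volume`.
#' @param seeds integer matrix (n x 3) of 0-based voxel indices, or a
#'   length-3 vector for a single seed.
#' @param lower,upper HU thresholds.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param box optional `region_box` restricting the growth domain.
#' @return a `jsv_mask`.
#' @export
region_grow <- function(ct, seeds, lower = 150, upper = 1500,
                        connectivity = 26, box = NULL) {
  stopifnot(inherits(ct, "jsv_volume"))
  if (lower >= upper) stop("lower threshold must be below upper threshold")
  if (!is.matrix(seeds)) seeds <- matrix(seeds, nrow = 1)
  storage.mode(seeds) <- "integer"
  d <- dim(ct$values)
  if (any(seeds < 0) || any(sweep(seeds, 2, d, ">=")))
    stop("seed outside volume: ",
         paste(seeds[which(rowSums(seeds < 0 | sweep(seeds, 2, d, ">=")) >
                             0)[1], ], collapse = ","))
  domain <- ct$values >= lower & ct$values <= upper
  if (!is.null(box)) domain <- domain & box_indicator(d, box)
  lin <- seeds[, 1] + d[1] * seeds[, 2] + d[1] * d[2] * seeds[, 3] + 1L
  hu <- ct$values[lin]
  bad <- which(hu < lower | hu > upper)
  if (length(bad))
    stop("seed (", paste(seeds[bad[1], ], collapse = ","),
         ") has HU ", hu[bad[1]], " outside [", lower, ", ", upper, "]")
  if (!is.null(box) && !all(domain[lin]))
    stop("seed outside the region box")
  offsets <- conn_offsets(connectivity)
  grown <- array(FALSE, d)
  grown[lin] <- TRUE
  repeat {
    nxt <- shift_dilate(grown, offsets) & domain
    if (sum(nxt) == sum(grown)) break
    grown <- nxt
  }
  mask(grown, box = box,
       provenance = list(op = "region_grow", lower_hu = lower,
                         upper_hu = upper, connectivity = connectivity,
                         n_seeds = nrow(seeds),
                         box = if (is.null(box)) NULL else box$id))
}

# 2D disk structuring element: offsets with dx^2 + dy^2 <= r^2
disk_kernel <- function(radius) {
  s <- 2L * radius + 1L
  k <- matrix(0L, s, s)
  idx <- expand.grid(i = seq_len(s), j = seq_len(s))
  inside <- (idx$i - radius - 1)^2 + (idx$j - radius - 1)^2 <= radius^2
  k[cbind(idx$i[inside], idx$j[inside])] <- 1L
  k
}

# 3D ball structuring element as a double array (for FFT convolution)
ball_kernel <- function(radius) {
  s <- 2L * radius + 1L
  ax <- seq_len(s) - radius - 1
  d2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  array(as.numeric(d2 <= radius^2), dim = c(s, s, s))
}

# 3D convolution via FFT with zero padding; returns rounded counts
fft_conv3 <- function(a, k) {
  da <- dim(a); dk <- dim(k)
  dd <- da + dk - 1L
  pa <- array(0, dd); pa[1:da[1], 1:da[2], 1:da[3]] <- a
  pk <- array(0, dd); pk[1:dk[1], 1:dk[2], 1:dk[3]] <- k
  full <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) / prod(dd)
  r <- (dk - 1L) %/% 2L
  full[(r[1] + 1):(r[1] + da[1]), (r[2] + 1):(r[2] + da[2]),
       (r[3] + 1):(r[3] + da[3])]
}

#' Morphological closing of a bone mask
#'
#' Dilation followed by erosion. The default element is a 2D disk of the
#' given radius (in voxels) applied independently to every axial slice,
#' mirroring slice-based workstation behavior; `element = "ball3d"` uses a
#' 3D ball instead. The structuring element is clipped at volume borders
#' (outside counts as background for dilation and as foreground for
#' erosion), so closing is extensive, idempotent and monotone. Radius 0 is
#' the identity. If the mask carries a region box and `clip_to_box` is
#' TRUE, the closed mask is re-confined to the box.
#'
#' @param m a `jsv_mask`.
#' @param radius element radius in voxels (default 20).
#' @param element "disk2d" (per axial slice, default) or "ball3d".
#' @param clip_to_box confine the result to the mask's region box
#'   (default TRUE when the mask has one).
#' @return a `jsv_mask`.
#' @export
morphological_close <- function(m, radius = 20,
                                element = c("disk2d", "ball3d"),
                                clip_to_box = TRUE) {
  stopifnot(inherits(m, "jsv_mask"))
  element <- match.arg(element)
  if (!is.finite(radius) || radius < 0) stop("radius must be >= 0")
  radius <- as.integer(radius)
  vals <- m$values
  if (radius > 0 && m$voxel_count > 0) {
    if (element == "disk2d") {
      k <- disk_kernel(radius)
      d <- dim(vals)
      for (z in seq_len(d[3])) {
        sl <- matrix(as.numeric(vals[, , z]), d[1], d[2])
        if (!any(sl > 0)) next
        closed <- EBImage::erode(EBImage::dilate(sl, k), k)
        vals[, , z] <- closed > 0.5
      }
    } else {
      k <- ball_kernel(radius)
      dil <- fft_conv3(array(as.numeric(m$values), dim(m$values)), k) > 0.5
      # clipped-element erosion: keep voxels with no background in the
      # element's in-volume footprint
      ero <- fft_conv3(array(as.numeric(!dil), dim(dil)), k) < 0.5
      vals <- ero & dil
    }
  }
  if (clip_to_box && !is.null(m$box))
    vals <- vals & box_indicator(dim(vals), m$box)
  mask(vals, box = m$box,
       provenance = c(m$provenance,
                      list(closing_radius = radius,
                           closing_element = element)))
}

#' Write a mask as uint8 NIfTI with a provenance JSON sidecar
#'
#' @param m a `jsv_mask`.
#' @param path output .nii/.nii.gz path; provenance goes to
#'   `<path>.json` (with any .nii/.nii.gz extension stripped).
#' @param ct the CT `jsv_volume` providing the grid geometry.
#' @export
write_mask <- function(m, path, ct) {
  stopifnot(inherits(m, "jsv_mask"), inherits(ct, "jsv_volume"))
  vol <- volume(array(as.numeric(m$values), dim(m$values)),
                spacing = ct$spacing, origin = ct$origin, modality = "MASK")
  write_volume(vol, path)
  side <- sub("\\.nii(\\.gz)?$", "", path)
  jsonlite::write_json(
    c(m$provenance, list(voxel_count = m$voxel_count)),
    paste0(side, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
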