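#' Specification of a digital joint phantom
#'
#' Describes a paired CT/PET phantom for one joint (both sides in one
#' volume) built from geometric primitives: cylinders/spheres/slabs with a
#' cortical shell around a marrow cavity, embedded in soft tissue. HU
#' classes are chosen so the ground-truth bone mask coincides exactly with
#' the 150-1500 HU threshold rule (cortex inside the window, marrow and
#' soft tissue below it), and the marrow cavity tests subcortical capture
#' by morphological closing.
#'
#' @param joint "knee", "hip" or "si".
#' @param tracer "FDG" or "NaF"; sets the default injected dose
#'   (0.11 mCi/kg FDG, 0.08 mCi/kg NaF) and uptake time (180 min FDG,
#'   90 min NaF).
#' @param bone_suv designed SUV of bone (cortex and marrow); a scalar, or
#'   a named vector `c(left = , right = )` for side-specific uptake.
#' @param background_suv designed SUV of soft tissue (default 0.3 for FDG
#'   blood pool/muscle, 0.5 for NaF).
#' @param dims,spacing_mm,origin_mm CT grid geometry. Defaults: 2 mm
#'   isotropic, 128 x 128 in-plane, 160/128/96 slices for knee/hip/si.
#' @param cortical_hu,marrow_hu,soft_hu HU of the tissue classes
#'   (defaults 1000, 100, 40).
#' @param weight_kg body weight used for the embedded injection metadata.
#' @param noise_sd Gaussian noise added to the designed SUV field
#'   (SUV units, truncated at 0; default 0 so the design is exact).
#' @param pet_spacing_mm optional PET grid spacing; default the CT grid
#'   (coregistered acquisition).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(joint = c("knee", "hip", "si"),
                         tracer = c("NaF", "FDG"),
                         bone_suv = 1.587, background_suv = NULL,
                         dims = NULL, spacing_mm = c(2, 2, 2),
                         origin_mm = c(0, 0, 0),
                         cortical_hu = 1000, marrow_hu = 100, soft_hu = 40,
                         weight_kg = 77.7, noise_sd = 0,
                         pet_spacing_mm = NULL, seed = 1L) {
  joint <- match.arg(joint)
  tracer <- match_tracer(tracer[1])
  if (is.null(dims))
    dims <- switch(joint, knee = c(128L, 128L, 160L),
                   hip = c(128L, 128L, 128L), si = c(128L, 128L, 96L))
  if (is.null(background_suv))
    background_suv <- if (tracer == "FDG") 0.3 else 0.5
  if (length(bone_suv) == 1L && is.null(names(bone_suv)))
    bone_suv <- c(left = unname(bone_suv), right = unname(bone_suv))
  if (!all(c("left", "right") %in% names(bone_suv)))
    stop("bone_suv must be a scalar or named c(left=, right=)")
  if (any(bone_suv < 0) || background_suv < 0)
    stop("designed SUVs must be >= 0")
  if (!(cortical_hu >= 150 && cortical_hu <= 1500))
    stop("cortical HU must lie within the [150, 1500] bone window")
  if (marrow_hu >= 150 || soft_hu >= 150)
    stop("marrow and soft-tissue HU must lie below 150")
  structure(
    list(joint = joint, tracer = tracer, bone_suv = bone_suv,
         background_suv = background_suv, dims = as.integer(dims),
         spacing = spacing_mm, origin = origin_mm,
         cortical_hu = cortical_hu, marrow_hu = marrow_hu,
         soft_hu = soft_hu, weight_kg = weight_kg, noise_sd = noise_sd,
         pet_spacing = pet_spacing_mm, seed = as.integer(seed)),
    class = "phantom_spec")
}

default_meta <- function(tracer, weight_kg) {
  dose_mci_per_kg <- if (tracer == "FDG") 0.11 else 0.08
  uptake_min <- if (tracer == "FDG") 180 else 90
  t0 <- as.POSIXct("2023-01-01 09:00:00", tz = "UTC")
  injection_meta(injected_dose = dose_mci_per_kg * weight_kg,
                 dose_unit = "mCi", injection_time = t0,
                 acquisition_time = t0 + uptake_min * 60,
                 body_weight_kg = weight_kg, tracer = tracer)
}

# world-coordinate arrays for a grid (voxel centers, mm)
coord_grids <- function(dims, spacing, origin) {
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(dims[k]) - 1) * spacing[k])
  list(x = array(ax[[1]], dims),
       y = array(rep(ax[[2]], each = dims[1]), dims),
       z = array(rep(ax[[3]], each = dims[1] * dims[2]), dims))
}

shelled <- function(outer, inner) list(cortex = outer & !inner, marrow = inner)

# geometry of one joint pair on an arbitrary grid; returns tissue-class
# indicators plus landmark coordinates (mm). The volume is symmetric about
# the midsagittal plane; "left" is the +x half.
phantom_geometry <- function(joint, dims, spacing, origin) {
  g <- coord_grids(dims, spacing, origin)
  ext_hi <- origin + (dims - 1) * spacing
  mid <- (origin[1] + ext_hi[1]) / 2
  yc <- (origin[2] + ext_hi[2]) / 2
  zc <- (origin[3] + ext_hi[3]) / 2
  cortex <- array(FALSE, dims); marrow <- array(FALSE, dims)
  side_x <- c(left = mid + 48, right = mid - 48)
  lms <- list()
  sph <- function(cx, cy, cz, r)
    (g$x - cx)^2 + (g$y - cy)^2 + (g$z - cz)^2 <= r^2
  cyl_z <- function(cx, cy, r, zlo, zhi)
    (g$x - cx)^2 + (g$y - cy)^2 <= r^2 & g$z >= zlo & g$z <= zhi
  cyl_x <- function(cy, cz, r, xlo, xhi)
    (g$y - cy)^2 + (g$z - cz)^2 <= r^2 & g$x >= xlo & g$x <= xhi
  slab <- function(xlo, xhi, ylo, yhi, zlo, zhi)
    g$x >= xlo & g$x <= xhi & g$y >= ylo & g$y <= yhi &
    g$z >= zlo & g$z <= zhi
  add <- function(outer, inner) {
    cortex <<- cortex | (outer & !inner)
    marrow <<- marrow | inner
  }
  if (joint == "knee") {
    z_em <- zc  # intercondylar eminence plane
    for (s in c("left", "right")) {
      cx <- side_x[[s]]
      # femur above the joint space, tibia below; 6 mm cortical shell
      add(cyl_z(cx, yc, 24, z_em + 6, ext_hi[3] - 10),
          cyl_z(cx, yc, 18, z_em + 12, ext_hi[3] - 16))
      add(cyl_z(cx, yc, 24, origin[3] + 10, z_em - 6),
          cyl_z(cx, yc, 18, origin[3] + 16, z_em - 12))
      # patella: solid cortical sphere anterior to the distal femur
      add(sph(cx, yc - 38, z_em + 8, 10), array(FALSE, dims))
      lms$knee[[s]] <- list(intercondylar_eminence = c(cx, yc, z_em))
    }
  } else if (joint == "hip") {
    for (s in c("left", "right")) {
      lat <- if (s == "left") 1 else -1   # lateral direction along x
      hx <- mid + lat * 52
      # femoral head: 24 mm sphere, 5 mm shell
      add(sph(hx, yc, zc, 24), sph(hx, yc, zc, 19))
      # femoral neck: cylinder running laterally from the head
      xr <- sort(c(hx, hx + lat * 56))
      xri <- sort(c(hx + lat * 6, hx + lat * 56))
      add(cyl_x(yc, zc, 14, xr[1], xr[2]),
          cyl_x(yc, zc, 9, xri[1], xri[2]))
      # pelvic plate medial to the head; its lateral face is the brim
      bx <- mid + lat * 16
      pxr <- sort(c(bx, bx - lat * 8))
      add(slab(pxr[1], pxr[2], yc - 40, yc + 40, zc - 40, zc + 40),
          array(FALSE, dims))
      lms$hip[[s]] <- list(head_neck_junction_x = hx + lat * 20,
                           pelvic_brim_x = bx,
                           neck_edge_z = c(zc - 14, zc + 14))
    }
  } else {  # si
    z_art <- c(zc - 56, zc + 56)
    # sacrum: central slab, 8 mm shell
    add(slab(mid - 33, mid + 33, yc - 28, yc + 28, z_art[1], z_art[2]),
        slab(mid - 25, mid + 25, yc - 20, yc + 20,
             z_art[1] + 8, z_art[2] - 8))
    for (s in c("left", "right")) {
      lat <- if (s == "left") 1 else -1
      # ilium: lateral slab across a 2 mm joint space
      ilo <- sort(c(mid + lat * 35, mid + lat * 75))
      iin <- sort(c(mid + lat * 43, mid + lat * 67))
      add(slab(ilo[1], ilo[2], yc - 28, yc + 28, z_art[1], z_art[2]),
          slab(iin[1], iin[2], yc - 20, yc + 20,
               z_art[1] + 8, z_art[2] - 8))
      lms$si[[s]] <- list(articulation_x = mid + lat * 34,
                          articulation_z = z_art)
    }
  }
  left_half <- g$x >= mid
  list(cortex = cortex, marrow = marrow, left_half = left_half,
       landmarks = do.call(landmark_set, lms), midline = mid)
}

#' Generate a digital joint phantom
#'
#' Builds the coregistered CT and PET volumes, the per-side landmarks, the
#' injection metadata embedded in the PET, and the ground truth: the
#' HU-rule bone mask (exactly the voxels the 150-1500 HU threshold
#' selects) and the designed per-side bone SUVmean. The PET activity is
#' constructed so that [activity_to_suv()] under the embedded metadata
#' returns the designed SUV field. Deterministic for a fixed seed.
#'
#' @param spec a `phantom_spec`.
#' @return a list with `ct`, `pet`, `meta`, `landmarks` and `truth`
#'   (elements `mask` — the HU-rule `jsv_mask`; `bone` — cortex plus
#'   marrow indicator; `suv_mean` — named designed SUVmean per side;
#'   `midline`).
#' @export
make_joint_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec$joint, spec$dims, spec$spacing, spec$origin)
  if (!any(geo$cortex))
    stop("phantom geometry exceeds the grid: no bone voxels")
  hu <- array(spec$soft_hu, spec$dims)
  hu[geo$marrow] <- spec$marrow_hu
  hu[geo$cortex] <- spec$cortical_hu
  ct <- volume(hu, spec$spacing, spec$origin, modality = "CT")
  meta <- default_meta(spec$tracer, spec$weight_kg)

  pet_dims <- spec$dims; pet_spacing <- spec$spacing
  if (!is.null(spec$pet_spacing)) {
    pet_spacing <- spec$pet_spacing
    pet_dims <- as.integer(floor((spec$dims - 1) * spec$spacing /
                                   pet_spacing) + 1)
  }
  pgeo <- if (is.null(spec$pet_spacing)) geo
          else phantom_geometry(spec$joint, pet_dims, pet_spacing,
                                spec$origin)
  bone <- pgeo$cortex | pgeo$marrow
  suv_field <- array(spec$background_suv, pet_dims)
  suv_field[bone & pgeo$left_half] <- spec$bone_suv[["left"]]
  suv_field[bone & !pgeo$left_half] <- spec$bone_suv[["right"]]
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    suv_field <- pmax(suv_field +
                        stats::rnorm(length(suv_field), 0, spec$noise_sd), 0)
    dim(suv_field) <- pet_dims
  }
  dose_bq <- meta$injected_dose_mbq * 1e6 *
    2^(-meta$uptake_min / meta$half_life_min)
  activity <- suv_field * dose_bq / (meta$body_weight_kg * 1000)
  pet <- volume(activity, pet_spacing, spec$origin, modality = "PET",
                tracer = spec$tracer)

  truth_mask <- mask(ct$values >= 150 & ct$values <= 1500,
                     provenance = list(op = "phantom_truth",
                                       lower_hu = 150, upper_hu = 1500))
  list(ct = ct, pet = pet, meta = meta, landmarks = geo$landmarks,
       truth = list(mask = truth_mask, bone = geo$cortex | geo$marrow,
                    suv_mean = spec$bone_suv, midline = geo$midline))
}
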