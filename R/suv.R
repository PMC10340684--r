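F18_HALF_LIFE_MIN <- 109.77
MBQ_PER_MCI <- 37

#' Injection metadata for SUV conversion
#'
#' Captures the quantities that turn an activity-concentration PET volume
#' into body-weight SUV: injected dose, injection and acquisition times,
#' and patient weight. Doses are stored internally in MBq (1 mCi = 37 MBq).
#'
#' @param injected_dose injected activity, strictly positive.
#' @param dose_unit "MBq" (default) or "mCi".
#' @param injection_time,acquisition_time `POSIXct` timestamps or strings
#'   parseable by [as.POSIXct()]; acquisition must not precede injection.
#' @param body_weight_kg body weight in kg, strictly positive.
#' @param tracer "FDG" or "NaF".
#' @param half_life_min isotope half-life in minutes; default fluorine-18
#'   (109.77 min).
#' @return an object of class `injection_meta`.
#' @export
injection_meta <- function(injected_dose, dose_unit = c("MBq", "mCi"),
                           injection_time, acquisition_time,
                           body_weight_kg, tracer = c("FDG", "NaF"),
                           half_life_min = F18_HALF_LIFE_MIN) {
  dose_unit <- match.arg(dose_unit)
  tracer <- match_tracer(tracer[1])
  dose_mbq <- if (dose_unit == "mCi") injected_dose * MBQ_PER_MCI
              else injected_dose
  if (!is.finite(dose_mbq) || dose_mbq <= 0)
    stop("injected dose must be strictly positive")
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("body weight must be strictly positive")
  if (!is.finite(half_life_min) || half_life_min <= 0)
    stop("half-life must be strictly positive")
  it <- as.POSIXct(injection_time, tz = "UTC")
  at <- as.POSIXct(acquisition_time, tz = "UTC")
  uptake_min <- as.numeric(difftime(at, it, units = "mins"))
  if (is.na(uptake_min) || uptake_min < 0)
    stop("acquisition time precedes injection time")
  structure(
    list(injected_dose_mbq = dose_mbq, injection_time = it,
         acquisition_time = at, uptake_min = uptake_min,
         body_weight_kg = body_weight_kg, tracer = tracer,
         half_life_min = half_life_min),
    class = "injection_meta")
}

#' @export
print.injection_meta <- function(x, ...) {
  cat(sprintf("<injection_meta> %s  %.1f MBq  %.1f kg  uptake %.1f min (T1/2 %.2f min)\n",
              x$tracer, x$injected_dose_mbq, x$body_weight_kg,
              x$uptake_min, x$half_life_min))
  invisible(x)
}

#' Read injection metadata from a JSON sidecar
#'
#' Expected keys: `injected_dose`, `dose_unit`, `injection_time`,
#' `acquisition_time`, `body_weight_kg`, `tracer`, and optionally
#' `half_life_min`.
#' @param path path to the JSON file.
#' @export
read_injection_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  injection_meta(
    injected_dose = j$injected_dose,
    dose_unit = if (is.null(j$dose_unit)) "MBq" else j$dose_unit,
    injection_time = j$injection_time,
    acquisition_time = j$acquisition_time,
    body_weight_kg = j$body_weight_kg,
    tracer = j$tracer,
    half_life_min = if (is.null(j$half_life_min)) F18_HALF_LIFE_MIN
                    else j$half_life_min)
}

#' Write injection metadata to a JSON sidecar
#' @param meta an `injection_meta`.
#' @param path output path.
#' @export
write_injection_meta <- function(meta, path) {
  stopifnot(inherits(meta, "injection_meta"))
  jsonlite::write_json(
    list(injected_dose = meta$injected_dose_mbq, dose_unit = "MBq",
         injection_time = format(meta$injection_time, "%Y-%m-%d %H:%M:%S"),
         acquisition_time = format(meta$acquisition_time, "%Y-%m-%d %H:%M:%S"),
         body_weight_kg = meta$body_weight_kg, tracer = meta$tracer,
         half_life_min = meta$half_life_min),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert PET activity concentration to body-weight SUV
#'
#' SUV = C / (D(t) / W) with C the activity concentration in Bq/mL, W the
#' body weight in grams and D(t) the injected dose in Bq decay-corrected to
#' acquisition time, `D(t) = D * 2^(-uptake / half_life)`. With
#' `decay_correct = FALSE` the dose is used as injected (appropriate when
#' the scanner already decay-corrected the image to injection time).
#'
#' @param pet a `jsv_volume` with modality "PET" in Bq/mL.
#' @param meta an `injection_meta`.
#' @param decay_correct correct the dose to acquisition time (default TRUE).
#' @return a `jsv_volume` of modality "SUV" on the same grid.
#' @export
activity_to_suv <- function(pet, meta, decay_correct = TRUE) {
  stopifnot(inherits(pet, "jsv_volume"), inherits(meta, "injection_meta"))
  if (pet$modality != "PET")
    stop("activity_to_suv expects a PET volume in Bq/mL")
  dose_bq <- meta$injected_dose_mbq * 1e6
  if (decay_correct)
    dose_bq <- dose_bq * 2^(-meta$uptake_min / meta$half_life_min)
  weight_g <- meta$body_weight_kg * 1000
  suv <- pet$values / (dose_bq / weight_g)
  volume(suv, spacing = pet$spacing, origin = pet$origin,
         modality = "SUV", tracer = meta$tracer)
}
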