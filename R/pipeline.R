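#' Read and validate a run configuration
#'
#' A run configuration is a single JSON document (or an equivalent named
#' list) validated before any compute. Recognised fields: `data_dir`,
#' `out_dir`, `joints`, `tracers`, `subjects`, `lower_hu`, `upper_hu`,
#' `closing_radius`, `element`, `grow`, `seed_hu`, `connectivity`,
#' `right_handed_only`, `bh`, `plots`, `seed`.
#'
#' @param config path to a JSON file, or a named list.
#' @return a validated config list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  defaults <- list(joints = JOINTS, tracers = c("FDG", "NaF"),
                   subjects = NULL, lower_hu = 150, upper_hu = 1500,
                   closing_radius = 20, element = "disk2d", grow = FALSE,
                   seed_hu = 300, connectivity = 26,
                   right_handed_only = FALSE, bh = FALSE, plots = TRUE,
                   seed = 1L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config$joints <- match.arg(config$joints, JOINTS, several.ok = TRUE)
  config$tracers <- unname(vapply(config$tracers, match_tracer,
                                  character(1)))
  if (config$closing_radius < 0) stop("closing_radius must be >= 0")
  if (config$lower_hu >= config$upper_hu)
    stop("lower_hu must be below upper_hu")
  if (!is.null(config$data_dir) && !dir.exists(config$data_dir))
    stop("data_dir does not exist: ", config$data_dir)
  class(config) <- "run_config"
  config
}

subject_paths <- function(data_dir, subject, joint, tracer) {
  base <- file.path(data_dir, "subjects", subject)
  list(ct = file.path(base, paste0(joint, "_ct.nii.gz")),
       pet = file.path(base, sprintf("%s_%s_pet.nii.gz", joint,
                                     tolower(tracer))),
       meta = file.path(base, sprintf("%s_%s_meta.json", joint,
                                      tolower(tracer))),
       landmarks = file.path(base, paste0(joint, "_landmarks.json")))
}

#' Simulate an imaging cohort on disk
#'
#' Draws a synthetic clinical cohort, then writes per-subject digital
#' joint phantoms whose per-side designed bone SUVs are the cohort's
#' uptake values: for every subject, joint and tracer, a CT, a PET, an
#' injection-metadata sidecar and a landmark file under
#' `out_dir/subjects/<id>/`, plus `clinical.csv` (covariates only) and
#' `designed_uptake.csv` (the ground-truth SUVs) at the top level.
#'
#' @param out_dir output directory (created if needed).
#' @param cohort a cohort table from [make_cohort()] with per-side uptake
#'   columns, or `NULL` to draw one from `cohort_spec_args`.
#' @param joints,tracers which joints/tracers to materialize.
#' @param cohort_spec_args arguments for [cohort_spec()] when `cohort` is
#'   NULL (e.g. `n`, `correlations`).
#' @param phantom_args extra arguments passed to [phantom_spec()]
#'   (e.g. `spacing_mm`, `dims`, `noise_sd`).
#' @param seed RNG seed for the cohort draw.
#' @return invisibly, a list with the cohort table and the directory.
#' @export
run_simulate <- function(out_dir, cohort = NULL, joints = JOINTS,
                         tracers = c("FDG", "NaF"),
                         cohort_spec_args = list(), phantom_args = list(),
                         seed = 1L) {
  joints <- match.arg(joints, JOINTS, several.ok = TRUE)
  tracers <- unname(vapply(tracers, match_tracer, character(1)))
  if (is.null(cohort)) {
    sp_args <- utils::modifyList(
      list(correlations = default_correlations(), sides = TRUE, seed = seed),
      cohort_spec_args)
    cohort <- make_cohort(do.call(cohort_spec, sp_args))
  }
  dir.create(file.path(out_dir, "subjects"), recursive = TRUE,
             showWarnings = FALSE)
  up_cols <- grep("^(fdg|naf)_(knee|hip|si)(_left|_right)?$",
                  names(cohort), value = TRUE)
  clinical <- cohort[, setdiff(names(cohort), up_cols), drop = FALSE]
  utils::write.csv(clinical, file.path(out_dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort[, c("subject", up_cols), drop = FALSE],
                   file.path(out_dir, "designed_uptake.csv"),
                   row.names = FALSE)
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject[i]
    sdir <- file.path(out_dir, "subjects", sid)
    dir.create(sdir, showWarnings = FALSE)
    for (joint in joints) {
      ct_written <- FALSE
      for (tracer in tracers) {
        base <- paste0(tolower(tracer), "_", joint)
        suv_l <- cohort[[paste0(base, "_left")]][i]
        suv_r <- cohort[[paste0(base, "_right")]][i]
        if (is.null(suv_l) || is.null(suv_r)) {
          suv_l <- suv_r <- cohort[[base]][i]
        }
        if (is.null(suv_l) || !is.finite(suv_l) || !is.finite(suv_r)) next
        args <- utils::modifyList(
          list(joint = joint, tracer = tracer,
               bone_suv = c(left = suv_l, right = suv_r),
               weight_kg = if ("weight" %in% names(cohort) &&
                                is.finite(cohort$weight[i]))
                 cohort$weight[i] else 77.7,
               seed = seed + i),
          phantom_args)
        ph <- make_joint_phantom(do.call(phantom_spec, args))
        paths <- subject_paths(out_dir, sid, joint, tracer)
        if (!ct_written) {
          write_volume(ph$ct, paths$ct)
          write_landmarks(ph$landmarks, paths$landmarks)
          ct_written <- TRUE
        }
        write_volume(ph$pet, paths$pet)
        write_injection_meta(ph$meta, paths$meta)
      }
    }
  }
  invisible(list(cohort = cohort, dir = out_dir))
}

#' Quantify every subject, joint, side and tracer in a data directory
#'
#' Runs the full per-joint pipeline ([quantify_joint()]) over the cohort
#' laid out by [run_simulate()] (or hand-assembled in the same layout) and
#' writes `results.csv`, a provenance JSON and a structured run log under
#' `out_dir`. Per-subject failures are logged and skipped; the returned
#' `status` is nonzero when any subject failed or nothing was processed.
#'
#' @param config a `run_config`, JSON path or named list (see
#'   [read_run_config()]); must contain `data_dir` and `out_dir`.
#' @return invisibly, a list with `results` (data.frame), `failures`,
#'   `status` (0 = all processed) and output paths.
#' @export
run_quantify <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$data_dir) || is.null(cfg$out_dir))
    stop("config must set data_dir and out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "quantify_log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logline <- function(...) writeLines(paste0(...), log_con)
  logline("run_quantify joints=", paste(cfg$joints, collapse = ","),
          " tracers=", paste(cfg$tracers, collapse = ","),
          " hu=[", cfg$lower_hu, ",", cfg$upper_hu,
          "] closing_radius=", cfg$closing_radius,
          " element=", cfg$element, " grow=", cfg$grow)
  subjects <- cfg$subjects
  if (is.null(subjects)) {
    subjects <- sort(list.dirs(file.path(cfg$data_dir, "subjects"),
                               recursive = FALSE, full.names = FALSE))
  }
  results <- list(); failures <- character()
  for (sid in subjects) {
    res <- tryCatch({
      rows <- list()
      for (joint in cfg$joints) {
        paths <- subject_paths(cfg$data_dir, sid, joint, cfg$tracers[1])
        ct <- read_volume(paths$ct, "CT")
        landmarks <- read_landmarks(paths$landmarks)
        for (tracer in cfg$tracers) {
          paths <- subject_paths(cfg$data_dir, sid, joint, tracer)
          pet <- read_volume(paths$pet, "PET", tracer = tracer)
          meta <- read_injection_meta(paths$meta)
          for (side in SIDES) {
            r <- quantify_joint(ct, pet, meta, landmarks, joint, side,
                                subject = sid, lower = cfg$lower_hu,
                                upper = cfg$upper_hu,
                                closing_radius = cfg$closing_radius,
                                element = cfg$element, grow = cfg$grow,
                                seed_hu = cfg$seed_hu,
                                connectivity = cfg$connectivity)
            logline(sid, " ", joint, " ", side, " ", tracer,
                    " suv_mean=", format(r$suv_mean, digits = 8),
                    " voxels=", r$voxel_count)
            rows[[length(rows) + 1L]] <- r
          }
        }
      }
      rows
    }, error = function(e) {
      logline("FAILED ", sid, ": ", conditionMessage(e))
      warning("subject ", sid, " failed: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(res)) failures <- c(failures, sid)
    else results <- c(results, res)
  }
  res_df <- if (length(results)) uptake_table(results) else
    data.frame(subject = character(), joint = character(),
               side = character(), tracer = character(),
               suv_mean = numeric(), voxel_count = integer(),
               stringsAsFactors = FALSE)
  res_path <- file.path(cfg$out_dir, "results.csv")
  utils::write.csv(res_df, res_path, row.names = FALSE)
  prov <- list(parameters = cfg[c("joints", "tracers", "lower_hu",
                                  "upper_hu", "closing_radius", "element",
                                  "grow", "seed_hu", "connectivity")],
               n_subjects = length(subjects), n_rows = nrow(res_df),
               failures = failures)
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  status <- if (length(subjects) == 0L) 2L else
    if (length(failures)) 1L else 0L
  logline("done: ", nrow(res_df), " rows, ", length(failures),
          " failures, status ", status)
  invisible(list(results = res_df, failures = failures, status = status,
                 results_path = res_path, log_path = log_path))
}

# wide per-subject uptake table from long results: columns
# <tracer>_<joint>_left/right plus side averages
results_to_wide <- function(res_df) {
  res_df$col <- sprintf("%s_%s_%s", tolower(res_df$tracer), res_df$joint,
                        res_df$side)
  wide <- stats::reshape(
    res_df[, c("subject", "col", "suv_mean")],
    idvar = "subject", timevar = "col", direction = "wide")
  names(wide) <- sub("^suv_mean\\.", "", names(wide))
  wide
}

#' Cohort statistics over quantified results
#'
#' Joins `results.csv` with the clinical covariate table on subject id and
#' runs [cohort_analysis()]: per-joint correlation matrices, paired
#' laterality tests, and (optionally) scatter plots with least-squares
#' lines for every uptake/covariate pair. Orphan subject ids on either
#' side are reported.
#'
#' @param config a `run_config`, JSON path or named list with `out_dir`
#'   (holding `results.csv` from [run_quantify()], unless `results` is
#'   given), `clinical_csv`, and the stats options `bh`,
#'   `right_handed_only`, `plots`.
#' @param results optional long results data.frame, bypassing
#'   `results.csv`.
#' @return invisibly, a list with the `cohort_report`, the merged wide
#'   table and output paths.
#' @export
run_stats <- function(config, results = NULL) {
  cfg <- read_run_config(config)
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(results)) {
    res_path <- file.path(cfg$out_dir, "results.csv")
    if (!file.exists(res_path)) stop("results.csv not found in out_dir")
    results <- utils::read.csv(res_path, stringsAsFactors = FALSE)
  }
  if (is.null(cfg$clinical_csv) || !file.exists(cfg$clinical_csv))
    stop("config must set clinical_csv (existing file)")
  clinical <- utils::read.csv(cfg$clinical_csv, stringsAsFactors = FALSE)
  wide <- results_to_wide(results)
  orphans_res <- setdiff(wide$subject, clinical$subject)
  orphans_clin <- setdiff(clinical$subject, wide$subject)
  if (length(orphans_res) || length(orphans_clin))
    warning("subject ids without a match - results: [",
            paste(orphans_res, collapse = ", "), "]; clinical: [",
            paste(orphans_clin, collapse = ", "), "]", call. = FALSE)
  tab <- merge(clinical, wide, by = "subject")
  if (!nrow(tab)) stop("no overlapping subject ids between results ",
                       "and clinical table")
  report <- cohort_analysis(tab, bh = cfg$bh,
                            right_handed_only = cfg$right_handed_only)
  utils::write.csv(report$correlations,
                   file.path(cfg$out_dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(report$laterality,
                   file.path(cfg$out_dir, "laterality.csv"),
                   row.names = FALSE)
  for (joint in unique(report$correlations$joint))
    utils::write.csv(correlation_matrix(report, joint),
                     file.path(cfg$out_dir,
                               paste0("correlation_matrix_", joint, ".csv")),
                     row.names = FALSE)
  jsonlite::write_json(
    list(correlations = report$correlations,
         laterality = report$laterality),
    file.path(cfg$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  if (isTRUE(cfg$plots)) plot_scatter_grid(tab, report, cfg$out_dir)
  invisible(list(report = report, table = tab, out_dir = cfg$out_dir))
}

# scatter plot with least-squares line per uptake x covariate pair
plot_scatter_grid <- function(tab, report, out_dir) {
  pdir <- file.path(out_dir, "plots")
  dir.create(pdir, showWarnings = FALSE)
  cc <- report$correlations
  for (i in seq_len(nrow(cc))) {
    u <- sprintf("%s_%s", tolower(cc$tracer[i]), cc$joint[i])
    v <- cc$variable[i]
    x <- tab[[v]]; y <- tab[[u]]
    keep <- is.finite(x) & is.finite(y)
    if (sum(keep) < 3) next
    fn <- file.path(pdir, sprintf("%s_vs_%s.png", u, v))
    grDevices::png(fn, width = 600, height = 480)
    graphics::plot(x[keep], y[keep], pch = 19, xlab = v,
                   ylab = paste(cc$tracer[i], cc$joint[i], "SUVmean"),
                   main = sprintf("r = %.3f, p = %.3g, n = %d",
                                  cc$r[i], cc$p[i], cc$n[i]))
    if (is.finite(cc$slope[i]))
      graphics::abline(cc$intercept[i], cc$slope[i], col = "red3")
    grDevices::dev.off()
  }
  invisible(pdir)
}

#' Materialize a standard fixture set of phantoms and cohorts
#'
#' Writes one small phantom per joint (CT, PET, metadata, landmarks,
#' ground-truth mask) and an 18-subject cohort CSV with the default
#' designed correlation structure, for demonstrations and smoke tests.
#'
#' @param out_dir output directory.
#' @param seed RNG seed.
#' @return invisibly, `out_dir`.
#' @export
write_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (joint in JOINTS) {
    sp <- phantom_spec(joint, tracer = "NaF",
                       dims = c(64L, 64L, 64L), spacing_mm = c(4, 4, 4),
                       seed = seed)
    ph <- make_joint_phantom(sp)
    write_volume(ph$ct, file.path(out_dir, paste0(joint, "_ct.nii.gz")))
    write_volume(ph$pet, file.path(out_dir,
                                   paste0(joint, "_naf_pet.nii.gz")))
    write_injection_meta(ph$meta,
                         file.path(out_dir, paste0(joint, "_naf_meta.json")))
    write_landmarks(ph$landmarks,
                    file.path(out_dir, paste0(joint, "_landmarks.json")))
    write_mask(ph$truth$mask,
               file.path(out_dir, paste0(joint, "_truth_mask.nii.gz")),
               ph$ct)
  }
  cohort <- make_cohort(cohort_spec(n = 18,
                                    correlations = default_correlations(),
                                    sides = TRUE, seed = seed))
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
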