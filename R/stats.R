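#' Pearson correlation with regression line
#'
#' Pairwise deletion of missing values, sample Pearson r, the two-sided
#' p-value from the t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with
#' n - 2 degrees of freedom, and the least-squares slope/intercept of y on
#' x.
#'
#' @param x,y numeric vectors of equal length; NAs deleted pairwise.
#' @param names optional length-2 character vector naming the pair.
#' @return an object of class `corr_result` with `r`, `p`, `n_used`,
#'   `slope`, `intercept`, `pair`.
#' @export
pearson_corr <- function(x, y, names = c("x", "y")) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("fewer than 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate variable: zero variance in ", names[
      which(c(stats::sd(x), stats::sd(y)) == 0)[1]])
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(
    list(pair = names, r = unname(ct$estimate), p = ct$p.value,
         n_used = n, slope = unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1])),
    class = "corr_result")
}

#' @export
print.corr_result <- function(x, ...) {
  cat(sprintf("<corr_result> %s ~ %s: r = %.3f, p = %.4g, n = %d\n",
              x$pair[2], x$pair[1], x$r, x$p, x$n_used))
  invisible(x)
}

#' Two-sided p-value of a Pearson correlation
#'
#' Uses the t transform with n - 2 degrees of freedom; strictly
#' decreasing in |r| for fixed n. `|r| >= 1` returns the limit p = 0.
#'
#' @param r correlation coefficient.
#' @param n sample size (>= 3).
#' @return the two-sided p-value.
#' @export
corr_pvalue <- function(r, n) {
  if (n < 3) stop("n must be at least 3")
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Paired laterality t-test
#'
#' Classical paired t-test on (right - left), reported with the mean
#' difference and two-sided p-value. Identically zero differences yield
#' t = 0, p = 1 rather than an error.
#'
#' @param left,right numeric vectors of per-subject uptake, equal length;
#'   pairs with missing values are dropped.
#' @param joint,tracer optional labels.
#' @return an object of class `paired_t_result` with `n`, `mean_diff`
#'   (right - left), `t`, `p`.
#' @export
paired_t <- function(left, right, joint = NA, tracer = NA) {
  if (length(left) != length(right))
    stop("left and right must have equal length")
  keep <- is.finite(left) & is.finite(right)
  d <- right[keep] - left[keep]
  n <- length(d)
  if (n < 2) stop("fewer than 2 complete pairs")
  if (all(d == 0)) {
    tval <- 0; p <- 1
  } else {
    tt <- tryCatch(stats::t.test(d), error = function(e)
      stop("zero variance of nonzero differences", call. = FALSE))
    tval <- unname(tt$statistic); p <- tt$p.value
  }
  structure(
    list(joint = joint, tracer = tracer, n = n, mean_diff = mean(d),
         t = tval, p = p),
    class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat(sprintf("<paired_t> %s %s: mean(R-L) = %.4f, t = %.3f, p = %.4g, n = %d\n",
              x$joint, x$tracer, x$mean_diff, x$t, x$p, x$n))
  invisible(x)
}

#' Minimal detectable correlation for a given sample size
#'
#' Solves the Fisher-z sample-size relation
#' `n = ((z_{1-alpha/2} + z_{power}) / atanh(r))^2 + 3`
#' for r by bisection (to 1e-6): the smallest correlation detectable with
#' the requested power at a two-sided level alpha. Decreasing in n.
#'
#' @param n sample size (>= 4).
#' @param power target power in (0, 1) (default 0.8).
#' @param alpha two-sided significance level in (0, 1) (default 0.05).
#' @return the minimal detectable r.
#' @export
min_detectable_r <- function(n, power = 0.8, alpha = 0.05) {
  if (n < 4) stop("n must be at least 4")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  f <- function(r) ((z / atanh(r))^2 + 3) - n
  lo <- 1e-12; hi <- 1 - 1e-12
  if (f(hi) > 0) stop("infeasible: n too small for any r < 1")
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Cohort-level correlation and laterality report
#'
#' For every uptake column (side-averaged SUVmean per tracer and joint)
#' against every clinical covariate, computes the Pearson correlation,
#' its t-transform p-value and regression line, with pairwise deletion so
#' each cell carries its own n. When per-side columns
#' (`<tracer>_<joint>_left` / `_right`) are present, paired laterality
#' t-tests are run per joint and tracer. Cells with fewer than 3 complete
#' pairs, or with a degenerate (zero-variance) variable, are reported as
#' unavailable (NA) rather than raising an error.
#'
#' @param table a data.frame with one row per subject: a `subject` column,
#'   optionally `handedness` ("right"/"left"/"ambidextrous"), uptake
#'   columns named `<tracer>_<joint>` (tracer in fdg/naf, joint in
#'   knee/hip/si; per-side variants with `_left`/`_right` suffix), and
#'   clinical covariate columns.
#' @param clinical_cols character vector of covariate columns; default all
#'   non-uptake, non-id columns.
#' @param bh also report Benjamini-Hochberg adjusted q-values per uptake
#'   column (default FALSE; the primary report is unadjusted).
#' @param right_handed_only restrict the laterality tests to right-handed
#'   subjects (default FALSE).
#' @return a list of class `cohort_report` with `correlations` (one row
#'   per joint x tracer x variable) and `laterality` data frames.
#' @export
cohort_analysis <- function(table, clinical_cols = NULL, bh = FALSE,
                            right_handed_only = FALSE) {
  stopifnot(is.data.frame(table))
  if (anyDuplicated(table$subject))
    stop("subject ids must be unique")
  up_pat <- "^(fdg|naf)_(knee|hip|si)$"
  side_pat <- "^(fdg|naf)_(knee|hip|si)_(left|right)$"
  uptake_cols <- grep(up_pat, names(table), value = TRUE)
  side_cols <- grep(side_pat, names(table), value = TRUE)
  # derive missing side-averaged columns from per-side ones
  for (sc in side_cols) {
    base <- sub("_(left|right)$", "", sc)
    if (!base %in% names(table) &&
        all(paste0(base, c("_left", "_right")) %in% names(table))) {
      table[[base]] <- (table[[paste0(base, "_left")]] +
                          table[[paste0(base, "_right")]]) / 2
      uptake_cols <- c(uptake_cols, base)
    }
  }
  if (!length(uptake_cols)) stop("no uptake columns found")
  if (is.null(clinical_cols))
    clinical_cols <- setdiff(names(table),
                             c("subject", "handedness", uptake_cols,
                               side_cols))
  if (!length(clinical_cols)) stop("no clinical covariate columns found")

  rows <- list()
  for (u in uptake_cols) {
    tracer <- toupper(sub("_.*", "", u))
    joint <- sub("^(fdg|naf)_", "", u)
    for (v in clinical_cols) {
      res <- tryCatch(pearson_corr(table[[v]], table[[u]], names = c(v, u)),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        joint = joint, tracer = if (tracer == "NAF") "NaF" else tracer,
        variable = v,
        r = if (is.null(res)) NA_real_ else res$r,
        p = if (is.null(res)) NA_real_ else res$p,
        n = if (is.null(res)) sum(is.finite(table[[v]]) &
                                    is.finite(table[[u]])) else res$n_used,
        slope = if (is.null(res)) NA_real_ else res$slope,
        intercept = if (is.null(res)) NA_real_ else res$intercept,
        stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, rows)
  if (bh) {
    correlations$q <- NA_real_
    for (u in unique(paste(correlations$joint, correlations$tracer))) {
      sel <- paste(correlations$joint, correlations$tracer) == u
      correlations$q[sel] <- stats::p.adjust(correlations$p[sel],
                                             method = "BH")
    }
  }

  lat_tab <- table
  if (right_handed_only) {
    if (!"handedness" %in% names(table))
      stop("right_handed_only requires a handedness column")
    lat_tab <- table[table$handedness == "right", , drop = FALSE]
  }
  lat_rows <- list()
  bases <- unique(sub("_(left|right)$", "", side_cols))
  for (b in bases) {
    lcol <- paste0(b, "_left"); rcol <- paste0(b, "_right")
    if (!all(c(lcol, rcol) %in% names(lat_tab))) next
    tracer <- toupper(sub("_.*", "", b))
    joint <- sub("^(fdg|naf)_", "", b)
    res <- tryCatch(paired_t(lat_tab[[lcol]], lat_tab[[rcol]],
                             joint = joint,
                             tracer = if (tracer == "NAF") "NaF" else tracer),
                    error = function(e) NULL)
    lat_rows[[length(lat_rows) + 1L]] <- data.frame(
      joint = joint, tracer = if (tracer == "NAF") "NaF" else tracer,
      n = if (is.null(res)) sum(is.finite(lat_tab[[lcol]]) &
                                  is.finite(lat_tab[[rcol]])) else res$n,
      mean_diff = if (is.null(res)) NA_real_ else res$mean_diff,
      t = if (is.null(res)) NA_real_ else res$t,
      p = if (is.null(res)) NA_real_ else res$p,
      stringsAsFactors = FALSE)
  }
  laterality <- if (length(lat_rows)) do.call(rbind, lat_rows)
                else data.frame()
  structure(list(correlations = correlations, laterality = laterality,
                 n_subjects = nrow(table)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d subjects, %d correlation cells, %d laterality tests\n",
              x$n_subjects, nrow(x$correlations), nrow(x$laterality)))
  invisible(x)
}

#' Reshape a cohort report into a per-joint correlation matrix
#'
#' Produces the familiar table layout: one row per clinical variable,
#' columns `FDG r`, `FDG p`, `NaF r`, `NaF p` for the requested joint.
#'
#' @param report a `cohort_report`.
#' @param joint "knee", "hip" or "si".
#' @return a data.frame.
#' @export
correlation_matrix <- function(report, joint) {
  stopifnot(inherits(report, "cohort_report"))
  cc <- report$correlations[report$correlations$joint == joint, ]
  vars <- unique(cc$variable)
  out <- data.frame(variable = vars, stringsAsFactors = FALSE)
  for (tr in c("FDG", "NaF")) {
    sub <- cc[cc$tracer == tr, ]
    m <- match(vars, sub$variable)
    out[[paste0(tr, "_r")]] <- sub$r[m]
    out[[paste0(tr, "_p")]] <- sub$p[m]
    out[[paste0(tr, "_n")]] <- sub$n[m]
  }
  out
}
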