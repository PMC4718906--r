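#' Two-sample Student t score
#'
#' Absolute pooled-variance two-sample t statistic between two groups of
#' ThI values. Pooled-variance Student's t (not Welch) is the default used
#' throughout the package; a Welch variant is available for sensitivity
#' analysis.
#'
#' @param group_a,group_b numeric vectors with at least 2 values each.
#' @param welch use the Welch (unequal-variance) statistic instead.
#' @return `|t|`, dimensionless.
#' @examples
#' t_score(c(0.60, 0.62, 0.64), c(0.70, 0.74, 0.78))
#' @export
t_score <- function(group_a, group_b, welch = FALSE) {
  abs(t_stat_summary(length(group_a), mean(group_a), sd(group_a),
                     length(group_b), mean(group_b), sd(group_b),
                     welch = welch)$t)
}

# Pooled (or Welch) two-sample t from summary statistics; the workhorse
# shared by t_score() and group_compare().
t_stat_summary <- function(n1, m1, s1, n2, m2, s2, welch = FALSE) {
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 values")
  if (welch) {
    se2 <- s1^2 / n1 + s2^2 / n2
    if (se2 <= 0) stop("degenerate data: zero variance in both groups")
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    if (sp2 <= 0) stop("degenerate data: zero pooled variance")
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = t, df = df)
}

#' Select the optimal nNUF level from labelled cohorts
#'
#' For every nNUF level on a grid and each curve branch, extracts the ThI
#' at that level from every curve in both cohorts with [thi_at_nnuf()] and
#' computes the pooled Student t score between cohorts. Levels where any
#' curve lacks a crossing on a side are skipped on that side (never
#' imputed). The (level, side) with the highest t score gives the greatest
#' cohort separation; with hot lesions compressing curves towards higher
#' ThI, the right branch is expected to win.
#'
#' @param neg_curves,pos_curves lists of [nnufti()] curves (at least 2
#'   each): tumour-free and tumour-bearing cohorts.
#' @param nnuf_grid nNUF levels to scan (default 0.05 to 0.95 by 0.05).
#' @param welch passed to [t_score()].
#' @return An object of class `nnuf_scan`: a list with `scan` (data frame
#'   `level`, `side`, `t_score`; `NA` where skipped), `optimal_level`,
#'   `optimal_side`, `optimal_t`.
#' @export
scan_optimal_nnuf <- function(neg_curves, pos_curves,
                              nnuf_grid = seq(0.05, 0.95, by = 0.05),
                              welch = FALSE) {
  if (length(neg_curves) < 2 || length(pos_curves) < 2)
    stop("each cohort needs at least 2 curves")
  stopifnot(all(vapply(c(neg_curves, pos_curves), inherits, TRUE, "nnufti")))
  if (any(nnuf_grid <= 0 | nnuf_grid >= 1))
    stop("`nnuf_grid` levels must lie strictly between 0 and 1")
  sides <- c("left", "right")
  scan <- expand.grid(level = nnuf_grid, side = sides,
                      stringsAsFactors = FALSE)
  scan$t_score <- NA_real_
  extract <- function(curves, level, side) {
    vals <- vapply(curves, function(cv)
      tryCatch(thi_at_nnuf(cv, level, side), error = function(e) NA_real_),
      numeric(1))
    if (any(is.na(vals))) NULL else vals
  }
  for (i in seq_len(nrow(scan))) {
    a <- extract(neg_curves, scan$level[i], scan$side[i])
    b <- extract(pos_curves, scan$level[i], scan$side[i])
    if (is.null(a) || is.null(b)) next
    scan$t_score[i] <- tryCatch(t_score(a, b, welch = welch),
                                error = function(e) NA_real_)
  }
  if (all(is.na(scan$t_score)))
    stop("calibration failure: no nNUF level has crossings on any side in both cohorts")
  best <- which.max(scan$t_score)
  structure(list(scan = scan,
                 optimal_level = scan$level[best],
                 optimal_side = scan$side[best],
                 optimal_t = scan$t_score[best]),
            class = "nnuf_scan")
}

#' @export
print.nnuf_scan <- function(x, ...) {
  cat(sprintf("nNUF level scan: %d (level, side) cells, %d defined\n",
              nrow(x$scan), sum(!is.na(x$scan$t_score))))
  cat(sprintf("  optimal: nNUF = %.3g on the %s branch (t = %.3g)\n",
              x$optimal_level, x$optimal_side, x$optimal_t))
  invisible(x)
}

#' Fit the ThI-versus-mean-concentration correction model
#'
#' ThI at a fixed nNUF level depends on the mean activity concentration of
#' the liver (lower counts mean relatively noisier volumes and higher ThI).
#' This fits an ordinary least-squares quadratic
#' `ThI ~ c0 + c1 m + c2 m^2` to (mean concentration, ThI) pairs from a
#' tumour-free cohort, to be removed by [normalize_thi()].
#'
#' @param m mean activity concentrations, counts per voxel (>= 3 distinct
#'   values), or a two-column data frame / matrix of `(m, thi)` pairs.
#' @param thi ThI values matching `m` (omit when `m` holds pairs).
#' @param m_ref reference concentration the correction maps to (default
#'   60 counts/voxel).
#' @return An object of class `conc_model`: coefficients `(c0, c1, c2)`,
#'   `m_ref`, `r_squared` (plain, not adjusted), `n_fit`, `m_range`.
#' @examples
#' m <- seq(30, 120, length.out = 10)
#' fit_concentration_model(m, 0.8 - 0.004 * m + 1e-5 * m^2)
#' @export
fit_concentration_model <- function(m, thi = NULL, m_ref = 60) {
  if (is.null(thi)) {
    pairs <- as.data.frame(m)
    if (ncol(pairs) < 2) stop("`m` must carry (m, thi) pairs when `thi` is missing")
    thi <- pairs[[2]]
    m <- pairs[[1]]
  }
  m <- as.numeric(m); thi <- as.numeric(thi)
  if (length(m) != length(thi)) stop("`m` and `thi` lengths differ")
  if (length(m) < 3) stop("need at least 3 (m, thi) pairs")
  if (length(unique(m)) < 3)
    stop("rank-deficient design: need at least 3 distinct m values")
  fit <- lm(thi ~ m + I(m^2))
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((thi - mean(thi))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(coefficients = stats::setNames(as.numeric(coef(fit)),
                                                c("c0", "c1", "c2")),
                 m_ref = m_ref,
                 r_squared = r2,
                 n_fit = length(m),
                 m_range = range(m)),
            class = "conc_model")
}

#' @export
coef.conc_model <- function(object, ...) object$coefficients

#' @param object,newdata `predict()` evaluates the fitted quadratic at
#'   concentrations `newdata` (defaults to `m_ref`).
#' @rdname fit_concentration_model
#' @export
predict.conc_model <- function(object, newdata = object$m_ref, ...) {
  cf <- object$coefficients
  m <- as.numeric(newdata)
  cf[["c0"]] + cf[["c1"]] * m + cf[["c2"]] * m^2
}

#' @export
print.conc_model <- function(x, ...) {
  cf <- x$coefficients
  cat("Concentration correction model (quadratic OLS)\n")
  cat(sprintf("  ThI = %.6g + %.6g m + %.6g m^2   (m in counts/voxel)\n",
              cf[["c0"]], cf[["c1"]], cf[["c2"]]))
  cat(sprintf("  r^2 = %.3g on n = %d livers; reference m = %g counts/voxel\n",
              x$r_squared, x$n_fit, x$m_ref))
  invisible(x)
}

#' Correct ThI to the reference mean activity concentration
#'
#' Applies the additive correction `nThI = ThI - f(m) + f(m_ref)` with `f`
#' the fitted quadratic of a [fit_concentration_model()]: at `m = m_ref`
#' the correction is the identity, and within-cohort spread is preserved.
#' Concentrations more than a factor 2 outside the fitted range trigger an
#' extrapolation warning (the value is still returned).
#'
#' @param model a `conc_model`.
#' @param thi ThI value(s) to correct.
#' @param m mean activity concentration(s), counts per voxel, `> 0`.
#' @return nThI, same length as `thi`.
#' @export
normalize_thi <- function(model, thi, m) {
  stopifnot(inherits(model, "conc_model"))
  if (any(m <= 0)) stop("`m` must be positive")
  lo <- model$m_range[1] / 2
  hi <- model$m_range[2] * 2
  if (any(m < lo | m > hi))
    warning(sprintf(
      "concentration outside [%g, %g] counts/voxel: extrapolating the fitted quadratic",
      lo, hi))
  thi - predict(model, m) + predict(model, model$m_ref)
}

#' Persist calibration results
#'
#' `write_scan()` stores an [scan_optimal_nnuf()] result as CSV
#' (`level,side,t_score`); `write_model()`/`read_model()` store a
#' [fit_concentration_model()] as JSON (coefficients, `m_ref`,
#' `r_squared`, `n_fit`, `m_range`).
#'
#' @param scan an `nnuf_scan`; `model` a `conc_model`; `path` a file path.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "nnuf_scan"))
  write.csv(scan$scan, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param model,path see above.
#' @rdname write_scan
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "conc_model"))
  jsonlite::write_json(
    list(coefficients = as.list(model$coefficients), m_ref = model$m_ref,
         r_squared = model$r_squared, n_fit = model$n_fit,
         m_range = model$m_range),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scan
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(coefficients = unlist(x$coefficients)[c("c0", "c1", "c2")],
                 m_ref = x$m_ref, r_squared = x$r_squared,
                 n_fit = x$n_fit, m_range = x$m_range),
            class = "conc_model")
}
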