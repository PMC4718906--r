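#' Positive predictive value at an nThI threshold
#'
#' `PPV(tau) = TP / (TP + FP)` with `TP` the number of tumour-bearing
#' (positive) livers with `nThI >= tau` and `FP` the number of tumour-free
#' (negative) livers with `nThI >= tau`. Comparisons are inclusive, so when
#' `tau` is an index patient's own nThI that patient always counts as a
#' true positive.
#'
#' @param tau nThI threshold.
#' @param pos_values nThI values of the positive cohort (nonempty).
#' @param neg_values nThI values of the negative cohort (nonempty).
#' @return PPV in `[0, 1]`.
#' @examples
#' compute_ppv(0.70, pos_values = c(0.75, 0.72, 0.64), neg_values = rep(0.62, 10))
#' @export
compute_ppv <- function(tau, pos_values, neg_values) {
  if (!length(pos_values) || !length(neg_values))
    stop("both cohorts must be nonempty")
  tp <- sum(pos_values >= tau)
  fp <- sum(neg_values >= tau)
  if (tp + fp == 0)
    stop(sprintf("PPV undefined at tau = %g: no patient at or above threshold", tau))
  tp / (tp + fp)
}

#' Compare nThI between two groups (Student's t test)
#'
#' Pooled-variance two-sample t test. Either group may be given as raw
#' values or as a summary `list(n =, mean =, sd =)`, so published cohort
#' summaries can be compared against raw values. p-values are two-sided.
#'
#' @param values_a,values_b numeric vectors (n >= 2) or summary lists with
#'   elements `n`, `mean`, `sd`.
#' @param welch use the Welch statistic instead of pooled variance.
#' @return An `htest`-classed list with `statistic` (t), `parameter` (df)
#'   and `p.value`.
#' @examples
#' group_compare(list(n = 40, mean = 0.623, sd = 0.032), c(0.70, 0.66, 0.61, 0.72))
#' @export
group_compare <- function(values_a, values_b, welch = FALSE) {
  a <- summarize_group(values_a)
  b <- summarize_group(values_b)
  st <- t_stat_summary(a$n, a$mean, a$sd, b$n, b$mean, b$sd, welch = welch)
  p <- 2 * pt(-abs(st$t), df = st$df)
  structure(list(statistic = c(t = st$t),
                 parameter = c(df = st$df),
                 p.value = p,
                 estimate = c(`mean of x` = a$mean, `mean of y` = b$mean),
                 method = if (welch) "Welch two-sample t test"
                          else "Pooled-variance two-sample Student t test",
                 alternative = "two.sided",
                 data.name = "values_a and values_b"),
            class = "htest")
}

summarize_group <- function(x) {
  if (is.list(x) && !is.null(x$n)) {
    if (is.null(x$mean) || is.null(x$sd))
      stop("group summary needs `n`, `mean` and `sd`")
    list(n = x$n, mean = x$mean, sd = x$sd)
  } else {
    x <- as.numeric(x)
    if (length(x) < 2) stop("each group needs at least 2 values")
    list(n = length(x), mean = mean(x), sd = sd(x))
  }
}

#' Assign an nThI decision band
#'
#' Maps nThI to `low` (additional imaging of limited value), `indeterminate`
#' (follow-up with other modalities recommended) or `high` (strong
#' indicator of tumour burden). Defaults: below 0.64 is low, `[0.64, 0.70)`
#' is indeterminate, 0.70 and above is high.
#'
#' @param nthi finite nThI value(s).
#' @param edges lower and upper band edges, `c(low_edge, high_edge)`.
#' @return factor with levels `low`, `indeterminate`, `high`.
#' @examples
#' assign_band(c(0.62, 0.66, 0.74))
#' @export
assign_band <- function(nthi, edges = c(0.64, 0.70)) {
  if (any(!is.finite(nthi))) stop("`nthi` must be finite")
  if (length(edges) != 2 || edges[1] >= edges[2])
    stop("`edges` must be two increasing band edges")
  cut(nthi, breaks = c(-Inf, edges, Inf), right = FALSE,
      labels = c("low", "indeterminate", "high"))
}

#' Classify a patient cohort
#'
#' Completes a cohort table: computes nThI from `thi` and `mean_conc` via
#' [normalize_thi()], the decision band via [assign_band()], and — for each
#' patient in a positive group — the PPV at the patient's own nThI against
#' the tumour-free reference values via [compute_ppv()].
#'
#' @param cohort data frame with at least `patient_id`, `group`, `thi`,
#'   `mean_conc`; `group` values containing `"pos"` mark the positive
#'   cohort.
#' @param model a [fit_concentration_model()] result.
#' @param neg_reference nThI values of the tumour-free reference cohort
#'   (used as the PPV denominator pool).
#' @param edges band edges for [assign_band()].
#' @return the cohort with `nthi`, `ppv` (NA outside positive groups) and
#'   `band` filled in.
#' @export
classify_cohort <- function(cohort, model, neg_reference,
                            edges = c(0.64, 0.70)) {
  need <- c("patient_id", "group", "thi", "mean_conc")
  if (!all(need %in% names(cohort)))
    stop(sprintf("cohort needs column(s): %s",
                 paste(setdiff(need, names(cohort)), collapse = ", ")))
  if (!nrow(cohort)) stop("empty cohort")
  cohort$nthi <- normalize_thi(model, cohort$thi, cohort$mean_conc)
  pos <- grepl("pos", cohort$group)
  cohort$ppv <- NA_real_
  if (any(pos)) {
    pos_vals <- cohort$nthi[pos]
    cohort$ppv[pos] <- vapply(pos_vals, compute_ppv, numeric(1),
                              pos_values = pos_vals,
                              neg_values = neg_reference)
  }
  cohort$band <- as.character(assign_band(cohort$nthi, edges))
  cohort
}
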