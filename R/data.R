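#' Bundled reference cohort
#'
#' The published reference cohort the method's decision bands were derived
#' from: 13 livers that were scintigraphy-negative at imaging but
#' radiologically confirmed to carry tumours within a 3-year follow-up
#' ("radtech-positive"), with each patient's normalized threshold index
#' (nThI), positive predictive value (PPV) at the patient's own nThI, and
#' time of radiological diagnosis relative to imaging (years).
#'
#' @return data frame with columns `patient_id`, `time_years`, `nthi`,
#'   `ppv`.
#' @examples
#' ref <- reference_cohort()
#' mean(ref$ppv)
#' @export
reference_cohort <- function() {
  read.csv(system.file("extdata", "radtech_pos_reference.csv",
                       package = "nnufti"),
           stringsAsFactors = FALSE)
}

#' Published summary statistics of the companion reference groups
#'
#' Group-level nThI summaries reported alongside [reference_cohort()]:
#' the 40 tumour-free livers (`radtech_neg`, including the maximum nThI
#' observed in that group, 0.68) and the 10 scintigraphy-positive livers
#' (`octreotide_pos`). These summaries are accepted directly by
#' [group_compare()].
#'
#' @return named list of lists with elements `n`, `mean`, `sd` (and `max`
#'   for the tumour-free group).
#' @export
reference_summaries <- function() {
  list(radtech_neg = list(n = 40, mean = 0.623, sd = 0.032, max = 0.68),
       octreotide_pos = list(n = 10, mean = 0.84, sd = 0.088))
}
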