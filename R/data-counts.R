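#' Bundled fracture-detection contingency counts
#'
#' Per-stratum true/false positive/negative counts from a published
#' multicenter validation of automated lumbar insufficiency-fracture
#' detection on MRI (1000 vertebral bodies in 200 patients; strata: entire
#' cohort, vertebral levels L1-L5, acquiring institution, scanner vendor,
#' field strength). Useful as a worked input for [diagnostic_metrics()]
#' and [run_evaluate()]-style tabulations.
#'
#' @return data frame with columns stratum, group, n_vertebrae, tp, fp,
#'   tn, fn
#' @export
#' @examples
#' counts <- fracture_validation_counts()
#' row <- counts[counts$stratum == "entire_cohort", ]
#' diagnostic_metrics(contingency_counts(row$tp, row$fp, row$tn, row$fn))
fracture_validation_counts <- function() {
  path <- system.file("extdata", "fracture_validation_counts.csv",
                      package = "vertmorph", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
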