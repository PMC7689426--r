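#' Classifier calibration protocol on a synthetic cohort
#'
#' The standardized check that the synthetic generator and the
#' evaluation stack behave as designed: generate one cohort, extract
#' the T2w feature panel for reader 1's first segmentation, prune
#' redundant features by correlation (`|r| > 0.8`, registry order), and
#' score a pooled stratified 10-fold naive Bayes cross-validation.
#' Under the default (effect-carrying) generator settings the AUC should
#' be high; with the effect disabled (`effect_dell = 0, effect_dsd = 0`)
#' it should scatter around chance — slightly below 0.5, as pooled
#' cross-validation with a handful of events is known to be
#' pessimistic.
#'
#' @param seed cohort seed (also drives the fold seed).
#' @param spec a [cohort_spec()]; default study conditions.
#' @param classifier classifier name (default `"NaiveBayes"`).
#' @return The pooled cross-validated AUC (positive class = event).
#' @export
calibration_auc <- function(seed, spec = cohort_spec(),
                            classifier = "NaiveBayes") {
  co <- generate_cohort(spec, seed = seed)
  x <- cohort_features(co, "r1r1", sequences = "T2w")
  x <- x[, colSums(is.na(x)) == 0, drop = FALSE]
  neutral <- data.frame(feature = colnames(x), icc_inter = 1, icc_intra = 1,
                        band = "excellent", verdict = "keep",
                        partner = NA_character_, stringsAsFactors = FALSE)
  kept <- kept_features(suppressWarnings(redundancy_prune(x, neutral)))
  cv <- run_crossval(x[, kept, drop = FALSE], co$subjects$macce,
                     classifier_spec(classifier), k = 10,
                     seed = derive_seed(seed, "calibration"))
  unname(pooled_metrics(cv)["auc"])
}
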