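#' Published reference values for the wallflower proliferation study
#'
#' The headline results reported for the original wallflower (*Erysimum
#' cheiri*) MLP-NSGAII analysis that the packaged dataset comes from: model
#' fit statistics per response and partition, the recommended medium with
#' its predicted responses, the variable-sensitivity ratios with importance
#' ranks, and the wet-lab validation means. Used by
#' [compare_to_reference()] to tabulate discrepancies of a pipeline run.
#'
#' @return nested list: `fit` (R2 / RMSE / MBE, train and test, per
#'   response), `recommendation` (doses in mg/L and predicted responses),
#'   `vsr` (ratio and rank per input and response), `validation`
#'   (experimental means of the recommended medium).
#' @export
reference_values <- function() {
  list(
    fit = data.frame(
      response = c("SN", "SL", "CW"),
      r2_train = c(0.85, 0.99, 0.94),
      r2_test = c(0.84, 0.99, 0.93),
      rmse_train = c(0.62, 0.08, 0.02),
      rmse_test = c(0.68, 0.08, 0.02),
      mbe_train = c(0.0002, 0.00009, 0.0003),
      mbe_test = c(-0.005, -0.007, 0.001)),
    recommendation = c(BA = 1.41, Kin = 1.17, NAA = 0.04, GA3 = 0.14,
                       SN = 7.12, SL = 3.99, CW = 0.21),
    vsr = data.frame(
      output = rep(c("SN", "SL", "CW"), each = 4),
      input = rep(c("BA", "Kin", "NAA", "GA3"), 3),
      VSR = c(2.162, 2.067, 1.074, 1.071,
              9.189, 8.844, 1.263, 1.425,
              3.573, 3.114, 1.084, 1.010),
      rank = c(1, 2, 3, 4,
               1, 2, 4, 3,
               1, 2, 3, 4)),
    validation = c(SN = 7.1, SL = 3.67, CW = 0.19))
}
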