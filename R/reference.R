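# Reference coefficient table from the motivating nationwide claims
# analysis of regional CKD cost differences, shipped as package data so
# the contrast/projection machinery has a worked example without any
# access-restricted claims data.

#' Reference coefficient estimates of the motivating CKD cost analysis
#'
#' Loads the packaged two-component coefficient table (binary and
#' overall-mean parts of the marginalized two-part segmented model, with
#' 95% confidence limits) reported by the motivating nationwide claims
#' analysis of chronic kidney disease medical costs by regional medical
#' vulnerability in South Korea.
#'
#' Note: the reported confidence limits for the binary-part age
#' coefficient do not bracket its estimate (an apparent typographical
#' error in the source table); the estimate is taken at face value and the
#' limits are stored as reported.
#'
#' @return data.frame with component, parameter, term, estimate, lower,
#'   upper.
#' @export
reference_estimates <- function() {
  utils::read.csv(system.file("extdata", "ckd_reference_estimates.csv",
                              package = "mtpcost", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Fit object preloaded with the reference estimates
#'
#' Wraps [reference_estimates()] into an `mtp_fit` shell (standard errors
#' back-computed from the reported 95% limits as half-width / 1.96;
#' covariance diagonal, so multi-coefficient contrast SEs ignore
#' cross-coefficient covariance, which the source does not report).
#'
#' @return an `mtp_fit` usable with [mtp_contrast()],
#'   [named_slope_contrasts()], [predict_region_difference()] and
#'   [predict_trajectory()].
#' @export
mtp_reference_fit <- function() {
  ref <- reference_estimates()
  est <- stats::setNames(ref$estimate, ref$parameter)
  se <- stats::setNames((ref$upper - ref$lower) / (2 * stats::qnorm(0.975)),
                        ref$parameter)
  fit <- mtp_fit_from_estimates(
    est, se = se,
    par_names_binary = ref$parameter[ref$component == "binary"],
    par_names_mean = ref$parameter[ref$component == "overall_mean"],
    n_subjects = 7966L, converged = TRUE)
  fit
}
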