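# Post-fit machinery: delta-method linear contrasts of the fitted
# coefficients, the 3 x 3 grid of monthly log-mean slope effects by region
# and period, the cumulative region-difference projection over years since
# diagnosis, and model-implied log-mean trajectories.

#' Linear contrast of fitted coefficients
#'
#' Computes `w' theta_hat` for a named weight vector `w`, with delta-method
#' standard error `sqrt(w' V w)` from the fit's coefficient covariance and
#' a Wald confidence interval.
#'
#' @param fit an `mtp_fit`.
#' @param weights named numeric vector; names must be fitted parameter
#'   names.
#' @param level confidence level, default 0.95.
#' @return object of class `mtp_contrast` with fields `weights`,
#'   `estimate`, `se`, `ci`.
#' @export
mtp_contrast <- function(fit, weights, level = 0.95) {
  cf <- coef(fit)
  bad <- setdiff(names(weights), names(cf))
  if (length(bad))
    stop("unknown coefficient name(s): ", paste(bad, collapse = ", "),
         "; valid names: ", paste(names(cf), collapse = ", "))
  w <- stats::setNames(numeric(length(cf)), names(cf))
  w[names(weights)] <- weights
  est <- sum(w * cf)
  se <- if (!is.null(fit$vcov)) sqrt(max(0, drop(t(w) %*% fit$vcov %*% w)))
        else NA_real_
  ci <- if (is.na(se)) c(lower = NA_real_, upper = NA_real_)
        else drop(wald_ci(est, se, level))
  structure(list(weights = weights, estimate = est, se = se, ci = ci,
                 level = level, scale_note = "log"),
            class = "mtp_contrast")
}

#' @export
print.mtp_contrast <- function(x, ...) {
  cat(sprintf("contrast %s: %.4f (se %.4f, %g%% CI %.4f to %.4f)\n",
              paste(sprintf("%+g*%s", x$weights, names(x$weights)),
                    collapse = " "),
              x$estimate, x$se, 100 * x$level, x$ci[1], x$ci[2]))
  invisible(x)
}

# weight definitions for the slope-effect grid; single source of truth
slope_contrast_weights <- function() {
  list(
    nonvulnerable = list(
      before = c(beta4 = 1),
      after = c(beta4 = 1, beta6 = 1),
      after_before = c(beta6 = 1)),
    vulnerable = list(
      before = c(beta4 = 1, beta7 = 1),
      after = c(beta4 = 1, beta6 = 1, beta7 = 1, beta8 = 1),
      after_before = c(beta6 = 1, beta8 = 1)),
    difference_of_regions = list(
      before = c(beta7 = 1),
      after = c(beta7 = 1, beta8 = 1),
      after_before = c(beta8 = 1)))
}

#' Slope effects of diagnosis and region on the monthly log overall mean
#'
#' Emits the 3 x 3 grid of monthly log-mean slope contrasts implied by the
#' segmented design: the pre-diagnosis slope is `beta4` (nonvulnerable)
#' and `beta4 + beta7` (vulnerable); the post-diagnosis slope is
#' `beta4 + beta6` (nonvulnerable) and `beta4 + beta6 + beta7 + beta8`
#' (vulnerable); the after-minus-before changes are `beta6` and
#' `beta6 + beta8`; the region difference of the post-diagnosis slope is
#' `beta7 + beta8` and the region difference of the after-minus-before
#' change (the difference in differences) is `beta8`. Every cell is
#' produced by [mtp_contrast()]; there is no separately coded formula.
#'
#' @param fit an `mtp_fit` using the standard segmented design (structural
#'   coefficients `beta1`..`beta8` present).
#' @param level confidence level.
#' @return data.frame with region, period, estimate, se, lower, upper.
#' @export
named_slope_contrasts <- function(fit, level = 0.95) {
  need <- paste0("beta", 4:8)
  if (!all(need %in% names(coef(fit))))
    stop("fit does not use the standard segmented design (missing ",
         paste(setdiff(need, names(coef(fit))), collapse = ", "), ")")
  wg <- slope_contrast_weights()
  rows <- list()
  for (rg in names(wg)) for (pd in names(wg[[rg]])) {
    w <- wg[[rg]][[pd]]
    if (!length(w)) {
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, period = pd, estimate = 0, se = 0, lower = 0, upper = 0)
    } else {
      ct <- mtp_contrast(fit, w, level)
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, period = pd, estimate = ct$estimate, se = ct$se,
        lower = ct$ci[1], upper = ct$ci[2])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Projected region difference in overall mean cost over years since diagnosis
#'
#' The monthly log-mean gap between vulnerable and nonvulnerable regions
#' grows post-diagnosis at rate `beta7 + beta8` per month of after-time.
#' Following the reporting convention of the motivating analysis, the
#' cumulative difference is expressed as `100 * (beta7 + beta8) * years`
#' percent - i.e. the per-month log slope difference scaled by the number
#' of years elapsed (a small-effect approximation; note the deliberate
#' month/year unit asymmetry of this convention, which reproduces the
#' published projection). The exponential-scale variant
#' `100 * (exp((beta7 + beta8) * years) - 1)` is also available.
#'
#' @param fit an `mtp_fit`.
#' @param years non-negative scalar or vector of years since diagnosis.
#' @param scale `"linear"` (default, reporting convention) or `"exp"`.
#' @param level confidence level.
#' @return data.frame with years, difference_pct, se, lower, upper.
#' @export
predict_region_difference <- function(fit, years, scale = c("linear", "exp"),
                                      level = 0.95) {
  scale <- match.arg(scale)
  stopifnot(all(years >= 0))
  ct <- mtp_contrast(fit, c(beta7 = 1, beta8 = 1), level)
  slope <- ct$estimate
  if (scale == "linear") {
    est <- 100 * slope * years
    se <- if (is.na(ct$se)) NA_real_ else 100 * abs(years) * ct$se
  } else {
    est <- 100 * (exp(slope * years) - 1)
    se <- if (is.na(ct$se)) NA_real_
          else 100 * abs(years) * exp(slope * years) * ct$se
  }
  ci <- wald_ci(est, ifelse(is.na(se), 0, se), level)
  ci[is.na(se), ] <- NA_real_
  data.frame(years = years, difference_pct = est, se = se,
             lower = ci[, "lower"], upper = ci[, "upper"])
}

#' Model-implied log mean expenditure trajectory
#'
#' Builds the overall-mean design row for each requested month of a fixed
#' covariate profile and returns `x2' beta_hat` with delta-method pointwise
#' confidence limits: a piecewise-linear curve in time with a possible
#' level shift and slope change at the diagnosis month (time 24).
#'
#' @param fit an `mtp_fit`.
#' @param profile named list of covariate values: `region` (0/1 or the
#'   factor labels), and values for each adjustment covariate of the fit
#'   (for the default design: `age`, `sex` (0 = male, 1 = female), `cci`
#'   score).
#' @param times integer months in 0..48 (default all).
#' @param level confidence level.
#' @return data.frame with time, log_mean, se, lower, upper.
#' @export
predict_trajectory <- function(fit, profile, times = 0:48, level = 0.95) {
  if (any(times < 0 | times > 48)) stop("`times` must lie within 0..48")
  region <- profile$region %||% 0
  if (is.character(region) || is.factor(region))
    region <- as.numeric(as.character(region) == "vulnerable")
  Xs <- structural_design(times, rep(region, length(times)))
  pn <- fit$par_names_mean
  extra <- setdiff(pn, paste0("beta", seq_len(ncol(Xs))))
  Xe <- NULL
  if (length(extra)) {
    # covariate columns follow the design's covariate order; profile must
    # name each one by its design term
    terms <- fit$covariate_terms %||% c("age", "sex", "cci")
    if (length(terms) != length(extra))
      stop("profile covariates cannot be matched to the fitted design")
    miss <- setdiff(terms, names(profile))
    if (length(miss)) stop("profile is missing covariate(s): ",
                           paste(miss, collapse = ", "))
    Xe <- do.call(cbind, lapply(terms, function(v) rep(as.numeric(profile[[v]]),
                                                       length(times))))
  }
  X <- cbind(Xs, Xe)
  cf <- coef(fit)[pn]
  est <- drop(X %*% cf)
  if (!is.null(fit$vcov)) {
    V <- fit$vcov[pn, pn, drop = FALSE]
    se <- sqrt(pmax(0, rowSums((X %*% V) * X)))
  } else se <- rep(NA_real_, length(est))
  ci <- wald_ci(est, ifelse(is.na(se), 0, se), level)
  ci[is.na(se), ] <- NA_real_
  data.frame(time = times, log_mean = est, se = se,
             lower = ci[, "lower"], upper = ci[, "upper"])
}

#' Plot log-mean cost trajectories by region
#'
#' Draws the model-implied piecewise-linear log-mean curves with pointwise
#' confidence bands for both regions at a covariate profile.
#'
#' @param fit an `mtp_fit`.
#' @param profile covariate profile without `region`; defaults to a
#'   60-year-old male with comorbidity score 1.
#' @param file optional path; when given, a PNG is written there.
#' @return invisibly, the list of the two trajectory data.frames.
#' @export
plot_trajectories <- function(fit, profile = list(age = 60, sex = 0, cci = 1),
                              file = NULL) {
  tr0 <- predict_trajectory(fit, c(profile, region = 0))
  tr1 <- predict_trajectory(fit, c(profile, region = 1))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600, res = 110)
    on.exit(grDevices::dev.off())
  }
  ylim <- range(tr0$lower, tr0$upper, tr1$lower, tr1$upper,
                tr0$log_mean, tr1$log_mean, na.rm = TRUE)
  graphics::plot(tr0$time, tr0$log_mean, type = "l", lwd = 2, ylim = ylim,
                 xlab = "months since window start (diagnosis at 24)",
                 ylab = "log mean monthly expenditure",
                 main = "Model-implied expenditure trajectories")
  graphics::lines(tr1$time, tr1$log_mean, lwd = 2, lty = 2)
  if (!anyNA(tr0$lower)) {
    graphics::lines(tr0$time, tr0$lower, lty = 3)
    graphics::lines(tr0$time, tr0$upper, lty = 3)
    graphics::lines(tr1$time, tr1$lower, lty = 3)
    graphics::lines(tr1$time, tr1$upper, lty = 3)
  }
  graphics::abline(v = 24, col = "grey60")
  graphics::legend("topleft", c("nonvulnerable", "vulnerable"),
                   lty = c(1, 2), lwd = 2, bty = "n")
  invisible(list(nonvulnerable = tr0, vulnerable = tr1))
}
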