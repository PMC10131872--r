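# Parameter container for the marginalized two-part model and the
# unconstrained internal parameterization used by the optimizer.

#' Marginalized two-part model parameters
#'
#' Bundles the binary-part coefficients `alpha` (structural terms plus
#' covariate terms), the overall-mean-part coefficients `beta`, the gamma
#' shape `kappa`, and the random-intercept covariance given by standard
#' deviations `sigma_a` (binary part), `sigma_d` (mean part) and
#' cross-part correlation `rho`.
#'
#' @param alpha named numeric vector of binary-part coefficients.
#' @param beta named numeric vector of mean-part coefficients.
#' @param kappa gamma shape, > 0.
#' @param sigma_a,sigma_d random-intercept standard deviations, >= 0.
#' @param rho cross-part correlation in (-1, 1).
#' @return object of class `mtp_params`.
#' @export
mtp_params <- function(alpha, beta, kappa = 1, sigma_a = 0, sigma_d = 0,
                       rho = 0) {
  stopifnot(is.numeric(alpha), is.numeric(beta))
  if (!is.finite(kappa) || kappa <= 0) stop("`kappa` must be > 0")
  if (sigma_a < 0 || sigma_d < 0) stop("random-effect SDs must be >= 0")
  if (abs(rho) >= 1) stop("`rho` must lie in (-1, 1)")
  structure(list(alpha = alpha, beta = beta, kappa = kappa,
                 sigma_a = sigma_a, sigma_d = sigma_d, rho = rho),
            class = "mtp_params")
}

#' @export
print.mtp_params <- function(x, ...) {
  cat("<mtp_params>\n binary part:\n")
  print(round(x$alpha, 4))
  cat(" overall mean part:\n")
  print(round(x$beta, 4))
  cat(sprintf(" kappa = %.4g, sigma_a = %.4g, sigma_d = %.4g, rho = %.4g\n",
              x$kappa, x$sigma_a, x$sigma_d, x$rho))
  invisible(x)
}

re_covariance <- function(params) {
  with(params, {
    S <- matrix(c(sigma_a^2, rho * sigma_a * sigma_d,
                  rho * sigma_a * sigma_d, sigma_d^2), 2, 2)
    S
  })
}

# internal optimizer scale: (alpha, beta, log kappa, log sigma_a,
# log sigma_d, atanh rho)
params_to_internal <- function(params) {
  c(params$alpha, params$beta, log(params$kappa),
    log(max(params$sigma_a, 1e-8)), log(max(params$sigma_d, 1e-8)),
    atanh(params$rho))
}

internal_to_params <- function(theta, p1, p2, names1 = NULL, names2 = NULL) {
  alpha <- theta[seq_len(p1)]
  beta <- theta[p1 + seq_len(p2)]
  names(alpha) <- names1
  names(beta) <- names2
  rest <- theta[p1 + p2 + 1:4]
  mtp_params(alpha, beta, kappa = exp(rest[1]), sigma_a = exp(rest[2]),
             sigma_d = exp(rest[3]), rho = tanh(rest[4]))
}

# Jacobian d(natural)/d(internal): identity for coefficients, exp for the
# log-scale parameters, 1 - rho^2 for atanh(rho).
internal_jacobian <- function(theta, p1, p2) {
  rest <- theta[p1 + p2 + 1:4]
  c(rep(1, p1 + p2), exp(rest[1]), exp(rest[2]), exp(rest[3]),
    1 - tanh(rest[4])^2)
}

#' Serialize / deserialize model parameters as JSON
#'
#' Field names follow the reporting convention (`alpha1`..`alpha8`,
#' `gamma1`.., `beta1`..`beta8`, `delta1`.., `kappa`, `sigma_a`, `sigma_d`,
#' `rho`).
#'
#' @param params an [mtp_params()].
#' @param path file path.
#' @export
write_params_json <- function(params, path) {
  jsonlite::write_json(list(alpha = as.list(params$alpha),
                            beta = as.list(params$beta),
                            kappa = params$kappa, sigma_a = params$sigma_a,
                            sigma_d = params$sigma_d, rho = params$rho),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mtp_params(unlist(x$alpha), unlist(x$beta), kappa = x$kappa,
             sigma_a = x$sigma_a, sigma_d = x$sigma_d, rho = x$rho)
}
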