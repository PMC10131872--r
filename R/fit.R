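# Maximum-likelihood fitting of the marginalized two-part model and Wald
# inference. The optimizer works on an unconstrained internal scale
# (log kappa, log sigmas, atanh rho); quadrature nodes are re-centred at the
# subject posterior modes between optimizer cycles so that within a cycle
# the objective has exact analytic gradients.

#' Fit the marginalized two-part model
#'
#' Starting values come from two independence fits (logistic regression of
#' the usage indicator on the binary-part columns; gamma log-link
#' regression of the positive costs on the mean-part columns, with the
#' shape from the gamma fit's moment dispersion) plus small positive
#' random-effect SD starts. The marginal likelihood is then maximized by
#' L-BFGS-B with analytic gradients under adaptive Gauss-Hermite
#' quadrature, re-centring the quadrature between cycles until the
#' log-likelihood stabilizes. The covariance of the estimates is the
#' inverse observed information (finite differences of the analytic
#' gradient), transformed to the natural scale by the delta method; when
#' the information matrix is not positive definite an outer product of
#' per-subject gradients is used instead, with a warning.
#'
#' @param design an `mtp_design` from [build_design()].
#' @param quad a [quadrature_spec()].
#' @param control list; `max_outer` quadrature re-centring cycles (default
#'   25), `maxit` inner L-BFGS-B iterations per cycle (default 400),
#'   `rel_tol` log-likelihood convergence tolerance (default 1e-8),
#'   `grad_tol` gradient max-norm tolerance (default 1e-5), `max_polish`
#'   Newton polish steps (default 8), `start` optional [mtp_params()]
#'   override.
#' @return object of class `mtp_fit`: estimates (natural scale), vcov,
#'   log-likelihood, convergence diagnostics.
#' @export
mtp_fit <- function(design, quad = quadrature_spec(), control = list()) {
  ctl <- utils::modifyList(list(max_outer = 25L, maxit = 400L,
                                rel_tol = 1e-8, grad_tol = 1e-5,
                                factr = 1e4, pgtol = 1e-8, max_polish = 12L,
                                start = NULL), control)
  y <- design$y
  ns <- n_subjects(design)
  if (ns < 2) stop("need at least 2 subjects")
  if (!any(y > 0) || !any(y == 0))
    stop("need both zero and positive outcomes to identify the two parts")

  p1 <- ncol(design$x1); p2 <- ncol(design$x2)
  # standardize columns to unit root-mean-square for optimizer conditioning
  # (time-scaled columns span 0..48); estimates are mapped back afterwards
  s1 <- pmax(1, sqrt(colMeans(design$x1^2)))
  s2 <- pmax(1, sqrt(colMeans(design$x2^2)))
  X1 <- sweep(design$x1, 2, s1, "/")
  X2 <- sweep(design$x2, 2, s2, "/")
  qr1 <- qr(X1)
  if (qr1$rank < p1) {
    bad <- colnames(design$x1)[qr1$pivot[(qr1$rank + 1):p1]]
    stop("design is rank deficient; near-collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  start <- ctl$start %||% starting_values(design)
  theta <- c(start$alpha * s1, start$beta * s2,
             log(start$kappa), log(max(start$sigma_a, 1e-3)),
             log(max(start$sigma_d, 1e-3)), atanh(start$rho))

  lower <- c(rep(-Inf, p1 + p2), log(1e-4), log(1e-5), log(1e-5), -5)
  upper <- c(rep(Inf, p1 + p2), log(1e4), log(10), log(10), 5)
  rule <- gh_product_rule(quad$nodes_per_dim)

  # KKT-projected gradient max-norm: components pushing into an active box
  # bound are optimal there and do not count against convergence
  proj_gnorm <- function(theta, g) {
    g[theta <= lower + 1e-10 & g < 0] <- 0
    g[theta >= upper - 1e-10 & g > 0] <- 0
    max(abs(g))
  }

  theta_to_args <- function(theta) {
    list(alpha = theta[seq_len(p1)], beta = theta[p1 + seq_len(p2)],
         lk = theta[p1 + p2 + 1], lsa = theta[p1 + p2 + 2],
         lsd = theta[p1 + p2 + 3], zr = theta[p1 + p2 + 4])
  }
  eval_fixed <- function(theta, modes, want_grad) {
    a <- theta_to_args(theta)
    cpp_mtp_loglik(X1, X2, y, design$sidx, a$alpha, a$beta,
                   a$lk, a$lsa, a$lsd, a$zr, rule$nodes, rule$logw,
                   modes$modes, modes$scales, want_grad)
  }
  update_modes <- function(theta, prev) {
    a <- theta_to_args(theta)
    if (quad$adaptive) {
      cpp_mtp_modes(X1, X2, y, design$sidx, a$alpha, a$beta,
                    a$lk, a$lsa, a$lsd, a$zr,
                    if (is.null(prev)) matrix(0, 0, 2) else prev$modes)
    } else {
      S <- re_covariance(list(sigma_a = exp(a$lsa), sigma_d = exp(a$lsd),
                              rho = tanh(a$zr)))
      L <- t(chol(S))
      list(modes = matrix(0, ns, 2),
           scales = matrix(rep(c(L[1, 1], L[1, 2], L[2, 1], L[2, 2]),
                               each = ns), ns, 4))
    }
  }

  modes <- update_modes(theta, NULL)
  ll_prev <- eval_fixed(theta, modes, FALSE)$loglik
  n_inner <- 0L
  ll_stable <- FALSE
  for (cycle in seq_len(ctl$max_outer)) {
    # cache so optim's paired fn/gr calls at one point cost one evaluation
    cache <- new.env(parent = emptyenv())
    run <- function(th) {
      key <- paste(format(th, digits = 17), collapse = ",")
      if (!identical(cache$key, key)) {
        cache$res <- eval_fixed(th, modes, TRUE)
        cache$key <- key
      }
      cache$res
    }
    opt <- stats::optim(theta, fn = function(th) -run(th)$loglik,
                        gr = function(th) -run(th)$grad,
                        method = "L-BFGS-B", lower = lower, upper = upper,
                        control = list(maxit = ctl$maxit, factr = ctl$factr,
                                       pgtol = ctl$pgtol))
    theta <- opt$par
    n_inner <- n_inner + opt$counts[1]
    modes <- update_modes(theta, modes)
    ll_new <- eval_fixed(theta, modes, FALSE)$loglik
    rel <- abs(ll_new - ll_prev) / (abs(ll_new) + 0.1)
    mtp_log(sprintf("cycle %d: loglik %.6f (rel change %.2e)", cycle, ll_new,
                    rel), level = 2L)
    ll_prev <- ll_new
    if (rel < ctl$rel_tol) { ll_stable <- TRUE; break }
  }

  # Degenerate variance components: L-BFGS can leave a vanishing SD a
  # hair's breadth above its box bound on a flat likelihood; snap such
  # components onto the bound when that costs no likelihood, so the
  # KKT-projected convergence check applies
  near <- which(is.finite(lower) & theta > lower & theta < lower + 0.25)
  if (length(near)) {
    cand <- theta
    cand[near] <- lower[near]
    llc <- eval_fixed(cand, modes, FALSE)$loglik
    if (is.finite(llc) && llc >= ll_prev - 1e-8 * (abs(ll_prev) + 1)) {
      theta <- cand
      modes <- update_modes(theta, modes)
      ll_prev <- eval_fixed(theta, modes, FALSE)$loglik
    }
  }

  # Newton polish with the observed-information Hessian: quadratic
  # convergence of the gradient norm near the optimum, and the final
  # Hessian doubles as the covariance input
  H <- NULL
  h_stale <- FALSE
  g <- eval_fixed(theta, modes, TRUE)$grad
  for (np in seq_len(ctl$max_polish)) {
    if (proj_gnorm(theta, g) < ctl$grad_tol) break
    if (is.null(H)) {       # frozen across polish steps; it changes little
      H <- stats::optimHess(theta,
                            fn = function(th) -eval_fixed(th, modes, FALSE)$loglik,
                            gr = function(th) -eval_fixed(th, modes, TRUE)$grad)
      H <- (H + t(H)) / 2
      h_stale <- FALSE
    }
    step <- tryCatch(solve(H, g), error = function(e) g / max(abs(g)))
    gn <- proj_gnorm(theta, g)
    tstep <- 1
    accepted <- FALSE
    for (ls in 1:10) {
      cand <- pmin(pmax(theta + tstep * step, lower), upper)
      rc <- eval_fixed(cand, modes, TRUE)
      # near the optimum the log-likelihood sits at re-centring noise
      # level, so a shrinking gradient norm is the reliable acceptance test
      if (is.finite(rc$loglik) &&
          (proj_gnorm(cand, rc$grad) < gn ||
           rc$loglik >= ll_prev - 1e-9 * (abs(ll_prev) + 1))) {
        accepted <- TRUE
        break
      }
      tstep <- tstep / 2
    }
    if (!accepted) {
      if (h_stale) { H <- NULL; next }   # retry once with a fresh Hessian
      break
    }
    theta <- cand
    h_stale <- TRUE
    modes <- update_modes(theta, modes)
    res <- eval_fixed(theta, modes, TRUE)
    ll_prev <- res$loglik
    g <- res$grad
    mtp_log(sprintf("polish %d: loglik %.6f, grad max %.2e", np, ll_prev,
                    max(abs(g))), level = 2L)
  }
  if (h_stale) H <- NULL  # recompute the information at the final theta
  final <- eval_fixed(theta, modes, TRUE)
  gnorm <- proj_gnorm(theta, final$grad)
  converged <- ll_stable && gnorm < ctl$grad_tol
  if (!converged)
    mtp_log(sprintf("fit did not meet convergence criteria (grad max %.2e)",
                    gnorm))

  # observed information on the internal scale by finite differences of the
  # analytic gradient (fixed final quadrature nodes)
  if (is.null(H)) {
    H <- stats::optimHess(theta,
                          fn = function(th) -eval_fixed(th, modes, FALSE)$loglik,
                          gr = function(th) -eval_fixed(th, modes, TRUE)$grad)
    H <- (H + t(H)) / 2
  }
  vcov_int <- tryCatch(solve(H), error = function(e) NULL)
  used_opg <- FALSE
  if (is.null(vcov_int) || any(diag(vcov_int) <= 0) ||
      inherits(tryCatch(chol(vcov_int), error = function(e) e, warning = function(w) w),
               c("error", "warning"))) {
    warning("observed information not positive definite; ",
            "using outer-product-of-gradients covariance")
    used_opg <- TRUE
    G <- per_subject_gradients(X1, X2, y, design$sidx, theta, p1, p2, rule,
                               modes)
    vcov_int <- tryCatch(solve(crossprod(G)),
                         error = function(e) solve(crossprod(G) +
                                                     1e-8 * diag(ncol(G))))
  }
  # natural scale: undo both the column standardization and the internal
  # transform (delta method with diagonal Jacobian)
  J <- internal_jacobian(theta, p1, p2) / c(s1, s2, rep(1, 4))
  vcov_nat <- vcov_int * tcrossprod(J)

  theta_nat <- theta
  theta_nat[seq_len(p1)] <- theta[seq_len(p1)] / s1
  theta_nat[p1 + seq_len(p2)] <- theta[p1 + seq_len(p2)] / s2
  params_hat <- internal_to_params(theta_nat, p1, p2,
                                   design$par_names_binary,
                                   design$par_names_mean)
  est <- c(params_hat$alpha, params_hat$beta,
           kappa = params_hat$kappa, sigma_a = params_hat$sigma_a,
           sigma_d = params_hat$sigma_d, rho = params_hat$rho)
  names(est) <- c(design$par_names_binary, design$par_names_mean,
                  "kappa", "sigma_a", "sigma_d", "rho")
  dimnames(vcov_nat) <- dimnames(vcov_int) <- list(names(est), names(est))

  structure(list(params_hat = params_hat, coefficients = est,
                 vcov = vcov_nat, vcov_internal = vcov_int,
                 theta_internal = theta, col_scale_binary = s1,
                 col_scale_mean = s2, loglik = ll_prev,
                 n_subjects = ns, n_obs = length(y),
                 converged = converged, iterations = n_inner,
                 gradient_norm = gnorm, n_floor = final$n_floor,
                 used_opg = used_opg, start = start, quad = quad,
                 par_names_binary = design$par_names_binary,
                 par_names_mean = design$par_names_mean),
            class = "mtp_fit")
}

starting_values <- function(design) {
  z <- as.numeric(design$y > 0)
  b0 <- tryCatch(
    stats::glm.fit(design$x1, z, family = stats::binomial())$coefficients,
    error = function(e) rep(0, ncol(design$x1)))
  pos <- design$y > 0
  g <- tryCatch(
    stats::glm.fit(design$x2[pos, , drop = FALSE], design$y[pos],
                   family = stats::Gamma(link = "log")),
    error = function(e) NULL)
  if (!is.null(g) && all(is.finite(g$coefficients))) {
    beta0 <- g$coefficients
    mu <- g$fitted.values
    disp <- sum((design$y[pos] / mu - 1)^2) / max(1, g$df.residual)
    kappa0 <- max(0.05, min(100, 1 / disp))
  } else {
    beta0 <- stats::lm.fit(design$x2[pos, , drop = FALSE],
                           log(design$y[pos]))$coefficients
    kappa0 <- 1
  }
  # the independence gamma fit targets the positive mean; shift the
  # intercept toward the overall mean scale E(Y) = pi * mu
  beta0[1] <- beta0[1] + log(max(mean(z), 0.05))
  b0[!is.finite(b0)] <- 0; beta0[!is.finite(beta0)] <- 0
  mtp_params(stats::setNames(b0, design$par_names_binary),
             stats::setNames(beta0, design$par_names_mean),
             kappa = kappa0, sigma_a = 0.3, sigma_d = 0.3, rho = 0)
}

per_subject_gradients <- function(X1, X2, y, sidx, theta, p1, p2, rule,
                                  modes) {
  ns <- length(sidx) - 1L
  G <- matrix(0, ns, p1 + p2 + 4)
  a <- theta[seq_len(p1)]; b <- theta[p1 + seq_len(p2)]
  for (i in seq_len(ns)) {
    r <- (sidx[i] + 1L):sidx[i + 1L]
    res <- cpp_mtp_loglik(X1[r, , drop = FALSE], X2[r, , drop = FALSE],
                          y[r], c(0L, length(r)), a, b,
                          theta[p1 + p2 + 1], theta[p1 + p2 + 2],
                          theta[p1 + p2 + 3], theta[p1 + p2 + 4],
                          rule$nodes, rule$logw,
                          modes$modes[i, , drop = FALSE],
                          modes$scales[i, , drop = FALSE], TRUE)
    G[i, ] <- res$grad
  }
  G
}

#' Wald confidence interval
#'
#' `estimate +/- z * se` with `z` the standard-normal quantile for the
#' requested two-sided level.
#'
#' @param estimate point estimate(s).
#' @param se standard error(s), > 0.
#' @param level confidence level in (0, 1), default 0.95.
#' @return matrix with columns `lower`, `upper`.
#' @export
wald_ci <- function(estimate, se, level = 0.95) {
  stopifnot(all(se >= 0), level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  cbind(lower = estimate - z * se, upper = estimate + z * se)
}

#' @export
coef.mtp_fit <- function(object, ...) object$coefficients

#' @export
vcov.mtp_fit <- function(object, ...) object$vcov

#' @export
logLik.mtp_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_obs, class = "logLik")
}

#' @export
print.mtp_fit <- function(x, ...) {
  cat(sprintf("<mtp_fit> %d subjects, %d subject-months, logLik %.2f (%s)\n",
              x$n_subjects, x$n_obs, x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  print(summary(x), ...)
  invisible(x)
}

#' Summarize a fit in the two-component reporting layout
#'
#' @param object an `mtp_fit`.
#' @param level confidence level for Wald limits.
#' @param ... unused.
#' @return data.frame with component, parameter, term, estimate, se, lower,
#'   upper.
#' @export
summary.mtp_fit <- function(object, level = 0.95, ...) {
  est <- object$coefficients
  se <- if (!is.null(object$vcov)) sqrt(pmax(diag(object$vcov), 0))
        else rep(NA_real_, length(est))
  ci <- wald_ci(est, ifelse(is.na(se), 0, se), level)
  ci[is.na(se), ] <- NA_real_
  p1 <- length(object$par_names_binary)
  p2 <- length(object$par_names_mean)
  comp <- c(rep("binary", p1), rep("overall_mean", p2),
            rep("dispersion", length(est) - p1 - p2))
  data.frame(component = comp, parameter = names(est),
             estimate = unname(est), se = unname(se),
             lower = unname(ci[, 1]), upper = unname(ci[, 2]))
}

#' Write a fitted model as a reporting-style CSV or JSON
#'
#' The CSV mirrors the two-component coefficient table (component,
#' parameter, estimate, 95% limits); the JSON round-trips the full fit
#' (estimates, covariance, diagnostics).
#'
#' @param fit an `mtp_fit`.
#' @param path output path.
#' @param level confidence level for the CSV limits.
#' @export
write_fit_csv <- function(fit, path, level = 0.95) {
  utils::write.csv(summary(fit, level = level), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fit_csv
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    coefficients = as.list(fit$coefficients),
    vcov = if (is.null(fit$vcov)) NULL else unclass(as.data.frame(fit$vcov)),
    loglik = fit$loglik, n_subjects = fit$n_subjects, n_obs = fit$n_obs,
    converged = fit$converged, iterations = fit$iterations,
    gradient_norm = fit$gradient_norm, n_floor = fit$n_floor,
    par_names_binary = fit$par_names_binary,
    par_names_mean = fit$par_names_mean), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_csv
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- unlist(x$coefficients)
  V <- if (!is.null(x$vcov)) {
    V <- as.matrix(as.data.frame(x$vcov))
    dimnames(V) <- list(names(coefs), names(coefs))
    V
  }
  mtp_fit_from_estimates(coefs, vcov = V,
                         par_names_binary = x$par_names_binary,
                         par_names_mean = x$par_names_mean,
                         loglik = x$loglik, n_subjects = x$n_subjects,
                         n_obs = x$n_obs, converged = x$converged)
}

#' Assemble a fit object from externally given estimates
#'
#' Builds an `mtp_fit` shell around a named coefficient vector (for
#' example, published estimates), optionally with a covariance matrix or
#' per-coefficient standard errors, so the post-fit contrast and
#' projection machinery can be applied without refitting. With only
#' standard errors the covariance is diagonal; cross-coefficient
#' covariances are then unavailable and contrast SEs involving several
#' coefficients are approximations.
#'
#' @param coefficients named numeric vector.
#' @param vcov optional covariance matrix over the coefficients.
#' @param se optional named standard errors (used if `vcov` is NULL).
#' @param par_names_binary,par_names_mean coefficient-name bookkeeping;
#'   inferred from names (`alpha*`/`gamma*` vs `beta*`/`delta*`) if omitted.
#' @param loglik,n_subjects,n_obs,converged optional metadata.
#' @return an `mtp_fit`.
#' @export
mtp_fit_from_estimates <- function(coefficients, vcov = NULL, se = NULL,
                                   par_names_binary = NULL,
                                   par_names_mean = NULL, loglik = NA_real_,
                                   n_subjects = NA_integer_,
                                   n_obs = NA_integer_, converged = NA) {
  nm <- names(coefficients)
  if (is.null(nm)) stop("`coefficients` must be named")
  if (is.null(par_names_binary))
    par_names_binary <- nm[grepl("^(alpha|gamma)", nm)]
  if (is.null(par_names_mean))
    par_names_mean <- nm[grepl("^(beta|delta)", nm)]
  if (is.null(vcov) && !is.null(se)) {
    vcov <- diag(se[nm]^2, length(nm))
    dimnames(vcov) <- list(nm, nm)
    vcov[is.na(vcov)] <- 0
  }
  structure(list(params_hat = NULL, coefficients = coefficients,
                 vcov = vcov, vcov_internal = NULL, theta_internal = NULL,
                 loglik = loglik, n_subjects = n_subjects, n_obs = n_obs,
                 converged = converged, iterations = NA_integer_,
                 gradient_norm = NA_real_, n_floor = 0, used_opg = FALSE,
                 start = NULL, quad = NULL,
                 par_names_binary = par_names_binary,
                 par_names_mean = par_names_mean),
            class = "mtp_fit")
}
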