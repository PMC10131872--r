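# User-facing likelihood components of the marginalized two-part model and
# the quadrature-integrated subject/total log-likelihoods.

PI_FLOOR <- 1e-6

#' Quadrature settings for the random-effect integral
#'
#' @param nodes_per_dim Gauss-Hermite nodes per random-effect dimension
#'   (default 9; the 2-D product rule uses `nodes_per_dim^2` points).
#' @param adaptive centre and scale the nodes at each subject's posterior
#'   mode (Laplace centring)? Plain quadrature (prior-scaled, zero-centred)
#'   is kept for oracle comparisons.
#' @param mc_oracle_draws Monte-Carlo draws used only by testing oracles.
#' @return object of class `quadrature_spec`.
#' @export
quadrature_spec <- function(nodes_per_dim = 9L, adaptive = TRUE,
                            mc_oracle_draws = 1e5) {
  stopifnot(nodes_per_dim >= 1)
  structure(list(nodes_per_dim = as.integer(nodes_per_dim),
                 adaptive = isTRUE(adaptive),
                 mc_oracle_draws = mc_oracle_draws),
            class = "quadrature_spec")
}

# 2-D product Gauss-Hermite rule (weight exp(-|t|^2)); returns K x 2 node
# matrix and log product weights
gh_product_rule <- function(nodes_per_dim) {
  gh <- if (nodes_per_dim == 1L) list(x = 0, w = sqrt(pi))
        else pracma::gaussHermite(nodes_per_dim)
  grid <- expand.grid(t1 = gh$x, t2 = gh$x)
  lw <- log(gh$w)
  list(nodes = as.matrix(grid),
       logw = as.vector(outer(lw, lw, "+")[cbind(match(grid$t1, gh$x),
                                                 match(grid$t2, gh$x))]))
}

#' Probability of any medical use in a month
#'
#' Binary part of the model: `P(Y > 0 | a) = logistic(x1' alpha + a)`.
#' The binary part models *usage*; the zero-cost probability is its
#' complement (see [prob_zero_cost()]).
#'
#' @param x1 design row vector or matrix (rows = observations).
#' @param alpha binary-part coefficients.
#' @param a random intercept (scalar or per-row vector), default 0.
#' @return probabilities in (0, 1).
#' @export
zero_prob <- function(x1, alpha, a = 0) {
  x1 <- rbind(x1)
  unname(stats::plogis(drop(x1 %*% alpha) + a))
}

#' @rdname zero_prob
#' @export
prob_zero_cost <- function(x1, alpha, a = 0) 1 - zero_prob(x1, alpha, a)

#' Overall (marginal-over-zeros) mean cost given the random effects
#'
#' `nu = exp(x2' beta + d)`, the conditional expectation of the cost with
#' zeros included, so `exp(beta_k)` is the multiplicative change in the
#' overall mean per unit of covariate k.
#'
#' @param x2 design row vector or matrix.
#' @param beta mean-part coefficients.
#' @param d random intercept, default 0.
#' @return positive means.
#' @export
marginal_mean <- function(x2, beta, d = 0) {
  x2 <- rbind(x2)
  eta <- unname(drop(x2 %*% beta) + d)
  nu <- exp(eta)
  if (any(!is.finite(nu)))
    stop("overflow in marginal mean: linear predictor reached ",
         max(eta[!is.finite(nu) | eta == max(eta)]))
  nu
}

#' Mean cost among users implied by the marginalized parameterization
#'
#' Recovers the conditional-on-positive mean `mu = nu / pi`, so that
#' `pi * mu = nu` holds exactly. `pi` values at or below the floor
#' (`1e-6`) are clipped before division; the number of clipped entries is
#' attached as attribute `"n_clipped"`.
#'
#' @param nu overall mean(s), > 0.
#' @param pi usage probability(ies) in (0, 1].
#' @return positive conditional means.
#' @export
conditional_positive_mean <- function(nu, pi) {
  stopifnot(all(nu > 0), all(pi > 0), all(pi <= 1))
  clipped <- pi < PI_FLOOR
  mu <- nu / pmax(pi, PI_FLOOR)
  attr(mu, "n_clipped") <- sum(clipped)
  mu
}

#' Gamma log-density in shape/mean parameterization
#'
#' Density of the positive part: gamma with shape `kappa` and mean `mu`
#' (scale `mu / kappa`).
#'
#' @param y positive outcomes.
#' @param kappa shape, > 0.
#' @param mu mean, > 0.
#' @return log-density values.
#' @export
gamma_logpdf <- function(y, kappa, mu) {
  if (any(y <= 0)) stop("`y` must be positive; zeros belong to the binary part")
  stopifnot(kappa > 0, all(mu > 0))
  kappa * (log(kappa) - log(mu)) - lgamma(kappa) + (kappa - 1) * log(y) -
    kappa * y / mu
}

# conditional two-part log-likelihood given fixed random effects (a, d);
# also the closed form when sigma_a = sigma_d = 0
twopart_loglik_cond <- function(x1, x2, y, params, a = 0, d = 0) {
  pi <- zero_prob(x1, params$alpha, a)
  ll <- numeric(length(y))
  z <- y > 0
  if (any(!z)) ll[!z] <- log1p(-pi[!z])
  if (any(z)) {
    nu <- marginal_mean(rbind(x2)[z, , drop = FALSE], params$beta, if (length(d) > 1) d[z] else d)
    mu <- conditional_positive_mean(nu, pi[z])
    ll[z] <- log(pi[z]) + gamma_logpdf(y[z], params$kappa, mu)
  }
  sum(ll)
}

# dispatch a design-shaped chunk through the C++ quadrature core
agq_eval <- function(x1, x2, y, sidx, params, quad, want_grad = FALSE,
                     modes = NULL) {
  theta <- params_to_internal(params)
  p1 <- length(params$alpha); p2 <- length(params$beta)
  rule <- gh_product_rule(quad$nodes_per_dim)
  ns <- length(sidx) - 1L
  if (quad$adaptive) {
    if (is.null(modes)) {
      modes <- cpp_mtp_modes(x1, x2, y, sidx, params$alpha, params$beta,
                             theta[p1 + p2 + 1], theta[p1 + p2 + 2],
                             theta[p1 + p2 + 3], theta[p1 + p2 + 4],
                             matrix(0, 0, 2))
    }
  } else {
    L <- t(chol(re_covariance(params)))
    modes <- list(modes = matrix(0, ns, 2),
                  scales = matrix(rep(c(L[1, 1], L[1, 2], L[2, 1], L[2, 2]),
                                      each = ns), ns, 4))
  }
  res <- cpp_mtp_loglik(x1, x2, y, sidx, params$alpha, params$beta,
                        theta[p1 + p2 + 1], theta[p1 + p2 + 2],
                        theta[p1 + p2 + 3], theta[p1 + p2 + 4],
                        rule$nodes, rule$logw, modes$modes, modes$scales,
                        want_grad)
  res$modes <- modes
  res
}

#' Subject-level marginal log-likelihood
#'
#' Integrates the conditional two-part likelihood of one subject's rows
#' over the bivariate normal random intercepts by (adaptive) Gauss-Hermite
#' product quadrature. With both random-effect SDs equal to zero the exact
#' closed-form independent two-part log-likelihood is returned.
#'
#' @param x1,x2 design matrices for the subject's observations.
#' @param y outcome vector (non-negative costs).
#' @param params an [mtp_params()].
#' @param quad a [quadrature_spec()].
#' @return scalar log-likelihood.
#' @export
subject_loglik <- function(x1, x2, y, params, quad = quadrature_spec()) {
  x1 <- rbind(x1); x2 <- rbind(x2)
  stopifnot(length(y) == nrow(x1), nrow(x1) == nrow(x2))
  if (params$sigma_a == 0 && params$sigma_d == 0)
    return(twopart_loglik_cond(x1, x2, y, params))
  if (params$sigma_a == 0 || params$sigma_d == 0)
    return(subject_loglik_1d(x1, x2, y, params))
  res <- agq_eval(x1, x2, y, c(0L, length(y)), params, quad)
  res$loglik
}

# one random effect degenerate: exact 1-D Gauss-Hermite over the live one
subject_loglik_1d <- function(x1, x2, y, params, nodes = 40L) {
  gh <- pracma::gaussHermite(nodes)
  s <- max(params$sigma_a, params$sigma_d)
  vals <- vapply(seq_len(nodes), function(k) {
    b <- sqrt(2) * s * gh$x[k]
    if (params$sigma_a > 0)
      twopart_loglik_cond(x1, x2, y, params, a = b, d = 0)
    else twopart_loglik_cond(x1, x2, y, params, a = 0, d = b)
  }, numeric(1))
  m <- max(vals + log(gh$w))
  m + log(sum(exp(vals + log(gh$w) - m))) - 0.5 * log(pi)
}

#' Total marginal log-likelihood of a design
#'
#' Sum of [subject_loglik()] over the subjects of an `mtp_design`;
#' order-independent up to floating point. The count of positive-part
#' probability-floor clips encountered during integration is attached as
#' attribute `"n_floor"`.
#'
#' @param design an `mtp_design` from [build_design()].
#' @param params an [mtp_params()].
#' @param quad a [quadrature_spec()].
#' @return scalar log-likelihood with attribute `n_floor`.
#' @export
total_loglik <- function(design, params, quad = quadrature_spec()) {
  if (params$sigma_a == 0 && params$sigma_d == 0) {
    ll <- twopart_loglik_cond(design$x1, design$x2, design$y, params)
    return(structure(ll, n_floor = 0))
  }
  if (params$sigma_a == 0 || params$sigma_d == 0) {
    ns <- n_subjects(design)
    ll <- sum(vapply(seq_len(ns), function(i) {
      r <- (design$sidx[i] + 1L):design$sidx[i + 1L]
      subject_loglik_1d(design$x1[r, , drop = FALSE],
                        design$x2[r, , drop = FALSE], design$y[r], params)
    }, numeric(1)))
    return(structure(ll, n_floor = 0))
  }
  res <- agq_eval(design$x1, design$x2, design$y, design$sidx, params, quad)
  structure(res$loglik, n_floor = res$n_floor)
}
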