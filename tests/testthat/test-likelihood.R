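ref_params <- function(sigma_a = 0.8, sigma_d = 0.5, rho = 0.5,
                       kappa = 0.8) {
  mtp_params(alpha = c(0.3, -0.1), beta = c(2, 0.05), kappa = kappa,
             sigma_a = sigma_a, sigma_d = sigma_d, rho = rho)
}

test_that("usage probability is the logistic of the linear predictor", {
  expect_equal(zero_prob(matrix(0, 1, 1), 1), 0.5)
  # published binary intercept: logistic(-0.4169) ~ 0.3973
  expect_equal(zero_prob(1, -0.4169), plogis(-0.4169))
  expect_equal(round(zero_prob(1, -0.4169), 4), 0.3973)
  a <- seq(-2, 2, by = 0.5)
  expect_true(all(diff(zero_prob(1, 0.2, a)) > 0))
  expect_equal(prob_zero_cost(1, -0.4169), 1 - plogis(-0.4169))
})

test_that("overall mean is log-linear with multiplicative coefficients", {
  expect_equal(marginal_mean(matrix(0, 1, 1), 1), 1)
  expect_equal(marginal_mean(1, 11.1894), exp(11.1894))
  expect_equal(round(marginal_mean(1, 11.1894) / 1e4, 2), 7.24)
  # exp(beta_k) multiplies the mean per unit covariate
  x0 <- c(1, 2); x1 <- c(1, 3); beta <- c(0.5, 0.3)
  expect_equal(marginal_mean(x1, beta) / marginal_mean(x0, beta),
               exp(beta[2]))
  expect_error(marginal_mean(1, 1e4), "overflow")
})

test_that("conditional positive mean preserves pi * mu = nu", {
  expect_equal(as.numeric(conditional_positive_mean(100, 0.5)), 200)
  expect_equal(as.numeric(conditional_positive_mean(3.7, 1)), 3.7)
  set.seed(1)
  nu <- rexp(50) + 0.1; pi <- runif(50, 0.05, 1)
  mu <- conditional_positive_mean(nu, pi)
  expect_equal(pi * as.numeric(mu), nu)
  clipped <- conditional_positive_mean(1, 1e-9)
  expect_equal(attr(clipped, "n_clipped"), 1L)
  expect_equal(as.numeric(clipped), 1e6)
})

test_that("gamma log-density matches the reference implementation", {
  set.seed(2)
  y <- rexp(30) + 0.01; kappa <- 0.8; mu <- 5
  expect_equal(gamma_logpdf(y, kappa, mu),
               dgamma(y, shape = kappa, scale = mu / kappa, log = TRUE))
  # shape 1 is exponential with rate 1/mu
  expect_equal(gamma_logpdf(2, 1, 3), -log(3) - 2 / 3)
  for (pars in list(c(0.6, 2), c(2.5, 40))) {
    total <- integrate(function(z) exp(gamma_logpdf(z, pars[1], pars[2])),
                       0, Inf, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  set.seed(3)
  draws <- rgamma(2e5, shape = 0.8, scale = 5 / 0.8)
  expect_lt(abs(mean(draws) - 5), 3 * sd(draws) / sqrt(2e5))
  expect_error(gamma_logpdf(0, 1, 1), "positive")
})

test_that("degenerate random effects reduce to the closed-form two-part model", {
  x <- cbind(1, c(0, 1, 2)); y <- c(0, 3.2, 11.5)
  p0 <- ref_params(sigma_a = 0, sigma_d = 0, rho = 0)
  expect_equal(subject_loglik(x, x, y, p0),
               oracle_twopart_cond(x, x, y, p0$alpha, p0$beta, p0$kappa),
               tolerance = 1e-12)
})

test_that("quadrature subject likelihood agrees with Monte-Carlo integration", {
  set.seed(4)
  for (rep in 1:3) {
    x <- cbind(1, rnorm(3)); y <- c(0, rexp(2) * 10)
    p <- ref_params()
    agq <- subject_loglik(x, x, y, p, quadrature_spec(9))
    mc <- oracle_mc_subject_loglik(x, x, y, p, draws = 1e5)
    expect_lt(abs(agq - mc$loglik), 3 * mc$se)
  }
})

test_that("an all-zero subject reduces to a 1-D logistic integral", {
  x1 <- matrix(1, 1, 1)
  p <- mtp_params(alpha = -0.4169, beta = 2, kappa = 1, sigma_a = 0.8,
                  sigma_d = 0.5, rho = 0.4)
  direct <- log(integrate(function(a) {
    (1 - plogis(-0.4169 + a)) * dnorm(a, sd = 0.8)
  }, -Inf, Inf, rel.tol = 1e-12)$value)
  expect_equal(subject_loglik(x1, x1, 0, p, quadrature_spec(15)), direct,
               tolerance = 1e-8)
  # with rho = 0 the d-dimension integrates out exactly for a zero-only
  # subject, so the 2-D rule must match the 1-D integral as well
  p0 <- mtp_params(alpha = -0.4169, beta = 2, kappa = 1, sigma_a = 0.8,
                   sigma_d = 0.5, rho = 0)
  expect_equal(subject_loglik(x1, x1, 0, p0, quadrature_spec(15)), direct,
               tolerance = 1e-8)
})

test_that("one degenerate dimension matches direct 1-D integration", {
  x <- cbind(1, c(0, 1)); y <- c(0, 4.2)
  p <- mtp_params(alpha = c(0.3, -0.1), beta = c(1.5, 0.05), kappa = 0.9,
                  sigma_a = 0, sigma_d = 0.6, rho = 0)
  # +/- 12 SD covers the posterior; infinite limits hit dgamma(scale -> 0)
  direct <- log(integrate(Vectorize(function(d) {
    exp(oracle_twopart_cond(x, x, y, p$alpha, p$beta, p$kappa, a = 0, d = d)) *
      dnorm(d, sd = 0.6)
  }), -7.2, 7.2, rel.tol = 1e-12)$value)
  expect_equal(subject_loglik(x, x, y, p), direct, tolerance = 1e-7)
})

test_that("total log-likelihood is an order-invariant sum over subjects", {
  des <- small_design(12, seed = 71)
  p <- truth_params(default_params(n_subjects = 12))
  quad <- quadrature_spec(5)
  total <- total_loglik(des, p, quad)

  # singleton: equals subject_loglik
  r <- (des$sidx[1] + 1L):des$sidx[2]
  expect_equal(subject_loglik(des$x1[r, ], des$x2[r, ], des$y[r], p, quad),
               {
                 one <- des
                 one$x1 <- des$x1[r, , drop = FALSE]
                 one$x2 <- des$x2[r, , drop = FALSE]
                 one$y <- des$y[r]; one$sidx <- c(0L, length(r))
                 as.numeric(total_loglik(one, p, quad))
               }, tolerance = 1e-10)

  # permutation invariance
  ns <- length(des$sidx) - 1L
  perm <- sample(ns)
  blocks <- lapply(seq_len(ns), function(i) (des$sidx[i] + 1L):des$sidx[i + 1L])
  ord <- unlist(blocks[perm])
  des2 <- des
  des2$x1 <- des$x1[ord, ]; des2$x2 <- des$x2[ord, ]; des2$y <- des$y[ord]
  des2$sidx <- c(0L, cumsum(lengths(blocks[perm])))
  expect_equal(as.numeric(total_loglik(des2, p, quad)), as.numeric(total),
               tolerance = 1e-8)

  # additivity: doubling every subject doubles the total
  des3 <- des
  des3$x1 <- rbind(des$x1, des$x1); des3$x2 <- rbind(des$x2, des$x2)
  des3$y <- c(des$y, des$y)
  des3$sidx <- c(des$sidx, des$sidx[-1] + des$sidx[ns + 1L])
  expect_equal(as.numeric(total_loglik(des3, p, quad)), 2 * as.numeric(total),
               tolerance = 1e-10)
})

test_that("quadrature refinement converges monotonically", {
  des <- small_design(25, seed = 83)
  p <- truth_params(default_params(n_subjects = 25))
  ll <- vapply(c(5, 9, 15), function(nd)
    as.numeric(total_loglik(des, p, quadrature_spec(nd))), numeric(1))
  d1 <- abs(ll[2] - ll[1]); d2 <- abs(ll[3] - ll[2])
  expect_lt(d2, d1 + 1e-10)
  expect_lt(d2, 1e-4)
})

test_that("plain and adaptive quadrature agree when nodes are plentiful", {
  x <- cbind(1, c(0, 1, 2)); y <- c(0, 3.2, 11.5)
  p <- ref_params()
  adaptive <- subject_loglik(x, x, y, p, quadrature_spec(9))
  plain <- subject_loglik(x, x, y, p, quadrature_spec(31, adaptive = FALSE))
  expect_equal(adaptive, plain, tolerance = 1e-7)
})

test_that("parameter container validates and round-trips through JSON", {
  expect_error(mtp_params(1, 1, kappa = -1), "kappa")
  expect_error(mtp_params(1, 1, rho = 1), "rho")
  p <- ref_params()
  path <- withr::local_tempfile(fileext = ".json")
  write_params_json(p, path)
  back <- read_params_json(path)
  expect_equal(back$alpha, p$alpha, ignore_attr = TRUE)
  expect_equal(back$kappa, p$kappa)
  expect_equal(back$rho, p$rho)
})
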