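# Independent oracles and small fixture builders shared across tests.
# The oracles deliberately avoid the package's likelihood code paths:
# the closed form is written against stats::dgamma / plogis directly, and
# the Monte-Carlo integrator averages the conditional likelihood over raw
# normal draws.

# conditional two-part log-likelihood written independently of the package
oracle_twopart_cond <- function(x1, x2, y, alpha, beta, kappa, a = 0, d = 0) {
  eta1 <- drop(rbind(x1) %*% alpha) + a
  eta2 <- drop(rbind(x2) %*% beta) + d
  p <- plogis(eta1)
  mu <- exp(eta2) / pmax(p, 1e-6)
  sum(ifelse(y == 0, log(1 - p),
             log(p) + stats::dgamma(y, shape = kappa,
                                    scale = mu / kappa, log = TRUE)))
}

# Monte-Carlo estimate of the marginal subject log-likelihood with its
# standard error (on the log scale, delta method)
oracle_mc_subject_loglik <- function(x1, x2, y, params, draws = 1e5) {
  S <- matrix(c(params$sigma_a^2,
                params$rho * params$sigma_a * params$sigma_d,
                params$rho * params$sigma_a * params$sigma_d,
                params$sigma_d^2), 2, 2)
  L <- t(chol(S))
  z <- L %*% matrix(rnorm(2 * draws), 2)
  x1 <- rbind(x1); x2 <- rbind(x2)
  llm <- matrix(0, length(y), draws)
  for (j in seq_along(y)) {
    e1 <- drop(x1[j, ] %*% params$alpha) + z[1, ]
    p <- plogis(e1)
    if (y[j] == 0) {
      llm[j, ] <- log1p(-p)
    } else {
      e2 <- drop(x2[j, ] %*% params$beta) + z[2, ]
      mu <- exp(e2) / pmax(p, 1e-6)
      llm[j, ] <- log(p) + stats::dgamma(y[j], shape = params$kappa,
                                         scale = mu / params$kappa,
                                         log = TRUE)
    }
  }
  ll <- colSums(llm)
  m <- max(ll)
  w <- exp(ll - m)
  list(loglik = m + log(mean(w)),
       se = stats::sd(w) / (mean(w) * sqrt(draws)))
}

# small claims table: one row per (subject, month, cost, codes)
make_claims <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(subject_id = r[[1]], month = r[[2]],
               cost = as.numeric(r[[3]]), codes = r[[4]],
               stringsAsFactors = FALSE)
  }))
}

# subject attribute table with sensible defaults
make_subjects <- function(subject_id, diagnosis_month, parc_value = 0,
                          age = 60, sex = "male", income = "middle",
                          coverage = "NHI", cci = 1, death_month = NA) {
  data.frame(subject_id = subject_id, diagnosis_month = diagnosis_month,
             parc_value = parc_value, age = age, sex = sex, income = income,
             coverage = coverage, cci = cci, death_month = death_month,
             stringsAsFactors = FALSE)
}

# small simulated design for likelihood/fitting tests
small_design <- function(n_subjects = 80, seed = 301) {
  cfg <- default_params(n_subjects = n_subjects, seed = seed)
  build_design(generate_cohort(cfg))
}
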