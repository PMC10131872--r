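test_that("identical seeds give bit-identical panels, different seeds differ", {
  cfg <- default_params(n_subjects = 60, seed = 41)
  p1 <- generate_cohort(cfg)
  p2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  p3 <- generate_cohort(cfg, seed = 42)
  expect_false(identical(p1$cost, p3$cost))
})

test_that("generator configuration is validated", {
  expect_error(default_params(n_subjects = 0), "positive")
  cfg <- default_params(n_subjects = 10)
  cfg$rho <- 1.2
  expect_error(validate_gen_config(cfg), "rho")
  cfg <- default_params(n_subjects = 10)
  cfg$kappa <- -1
  expect_error(validate_gen_config(cfg), "kappa")
  expect_silent(validate_gen_config(default_params()))
})

test_that("default parameters embed the published structural estimates", {
  cfg <- default_params()
  expect_equal(unname(cfg$beta["diagnosis_region_after_time"]), -0.0152)
  expect_equal(unname(cfg$alpha["time"]), 0.0260)
  expect_equal(unname(cfg$beta["region_time"]), 0.0178)
  tp <- truth_params(cfg)
  expect_s3_class(tp, "mtp_params")
  expect_equal(unname(tp$beta["beta8"]), -0.0152)
})

test_that("zero-cost share and region share match the calibration targets", {
  panel <- generate_cohort(default_params(n_subjects = 1500, seed = 77))
  zero_share <- mean(panel$cost == 0)
  # calibrated to 0.29; subject-clustered MC error at n = 1500 is ~0.007
  expect_lt(abs(zero_share - 0.29), 0.021)
  subj <- panel[!duplicated(panel$subject_id), ]
  expect_lt(abs(mean(subj$region == "vulnerable") - 0.122), 0.026)
})

test_that("usage probability matches the random-effect-averaged analytic value", {
  cfg <- default_params(n_subjects = 3000, seed = 55)
  # degenerate covariates so each (region, time) is a pure cell
  cfg$covariate_distributions$age_bands <-
    data.frame(lo = 60, hi = 60, prob = 1)
  cfg$covariate_distributions$sex_female <- 0
  cfg$covariate_distributions$cci <- c(`0` = 0, `1` = 1, `2` = 0)
  panel <- generate_cohort(cfg)
  gh <- pracma::gaussHermite(40)
  for (tt in c(0, 24, 48)) {
    rows <- panel$time == tt & panel$region == "nonvulnerable"
    emp <- mean(panel$cost[rows] > 0)
    x1 <- c(1, as.numeric(tt >= 24), 0, tt, 0, max(0, tt - 24), 0, 0, 60, 0, 1)
    eta <- sum(x1 * cfg$alpha)
    ana <- sum(gh$w * plogis(eta + sqrt(2) * cfg$sigma_a * gh$x)) / sqrt(pi)
    se <- sqrt(ana * (1 - ana) / sum(rows))
    expect_lt(abs(emp - ana), 4 * se)
  }
})

test_that("cell mean cost matches the log-normal mixing identity", {
  cfg <- default_params(n_subjects = 4000, seed = 66)
  cfg$covariate_distributions$age_bands <-
    data.frame(lo = 60, hi = 60, prob = 1)
  cfg$covariate_distributions$sex_female <- 0
  cfg$covariate_distributions$cci <- c(`0` = 0, `1` = 1, `2` = 0)
  panel <- generate_cohort(cfg)
  for (tt in c(12, 36)) {
    rows <- panel$time == tt & panel$region == "nonvulnerable"
    x2 <- c(1, as.numeric(tt >= 24), 0, tt, 0, max(0, tt - 24), 0, 0, 60, 0, 1)
    expected <- exp(sum(x2 * cfg$beta) + cfg$sigma_d^2 / 2)
    emp <- mean(panel$cost[rows])
    se <- stats::sd(panel$cost[rows]) / sqrt(sum(rows))
    expect_lt(abs(emp - expected), 4 * se)
  }
})

test_that("with no random effects the panel is an independent two-part sample", {
  cfg <- default_params(n_subjects = 4000, seed = 88)
  cfg$sigma_a <- 0; cfg$sigma_d <- 0; cfg$rho <- 0
  cfg$covariate_distributions$age_bands <-
    data.frame(lo = 60, hi = 60, prob = 1)
  cfg$covariate_distributions$sex_female <- 0
  cfg$covariate_distributions$cci <- c(`0` = 0, `1` = 1, `2` = 0)
  panel <- generate_cohort(cfg)
  tt <- 10
  rows <- panel$time == tt & panel$region == "nonvulnerable"
  x <- c(1, 0, 0, tt, 0, 0, 0, 0, 60, 0, 1)
  p_true <- plogis(sum(x * cfg$alpha))
  nu_true <- exp(sum(x * cfg$beta))
  n <- sum(rows)
  expect_lt(abs(mean(panel$cost[rows] > 0) - p_true),
            4 * sqrt(p_true * (1 - p_true) / n))
  expect_lt(abs(mean(panel$cost[rows]) - nu_true),
            4 * stats::sd(panel$cost[rows]) / sqrt(n))
})

test_that("ground-truth manifest accompanies every written panel", {
  cfg <- default_params(n_subjects = 12, seed = 4)
  panel <- generate_cohort(cfg)
  truth <- attr(panel, "truth")
  expect_equal(truth$seed, 4L)
  expect_equal(unname(truth$params$beta["beta8"]), -0.0152)
  prefix <- file.path(withr::local_tempdir(), "sim")
  files <- write_cohort(panel, prefix)
  expect_true(all(file.exists(files)))
  manifest <- jsonlite::read_json(files[["truth"]], simplifyVector = TRUE)
  expect_equal(manifest$seed_used, 4L)
  expect_equal(manifest$kappa, cfg$kappa)
})

test_that("optional death process truncates follow-up", {
  cfg <- default_params(n_subjects = 200, seed = 13)
  cfg$death_hazard <- 0.05
  panel <- generate_cohort(cfg)
  lengths <- table(panel$subject_id)
  expect_true(any(lengths < 49))
  expect_true(all(panel$time >= 0))
  # every subject retains at least the first window month
  expect_equal(length(lengths), 200L)
})
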