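test_that("washout filter keeps incident cases and excludes edge years", {
  claims <- make_claims(
    list("A", "2003-05", 50, "N181"),   # prevalent: washout year
    list("A", "2010-01", 20, "N185"),
    list("B", "2010-07", 120, "N184;E11"),
    list("B", "2009-01", 10, "J45"),    # non-CKD claim earlier: irrelevant
    list("C", "2018-01", 80, "N18"),    # tail year
    list("D", "2012-03", 30, "I10"))    # never coded CKD
  out <- apply_washout_filter(claims)
  expect_equal(out$subject_id, "B")
  expect_equal(out$diagnosis_month, "2010-07")
})

test_that("washout filter warns on unparseable diagnosis dates", {
  claims <- make_claims(list("X", "July 2010", 10, "N18"),
                        list("Y", "2011-02", 10, "N18"))
  expect_warning(out <- apply_washout_filter(claims), "parseable")
  expect_equal(out$subject_id, "Y")
})

test_that("washout filter is idempotent", {
  claims <- make_claims(
    list("A", "2003-05", 50, "N181"), list("B", "2010-07", 120, "N184"),
    list("B", "2011-07", 10, "N184"), list("C", "2018-01", 80, "N18"))
  once <- apply_washout_filter(claims)
  again <- apply_washout_filter(claims[claims$subject_id %in% once$subject_id, ])
  expect_identical(once, again)
})

test_that("region classification uses a strict threshold and partitions [-1,1]", {
  expect_equal(as.character(classify_region(-0.50)), "vulnerable")
  expect_equal(as.character(classify_region(0)), "nonvulnerable")
  # boundary value is nonvulnerable: the rule is strictly-less-than
  expect_equal(as.character(classify_region(-0.33)), "nonvulnerable")
  expect_error(classify_region(-1.2), "\\[-1, 1\\]")
  expect_error(classify_region(1.01), "\\[-1, 1\\]")
  grid <- seq(-1, 1, by = 0.01)
  cls <- classify_region(grid)
  expect_false(anyNA(cls))
  expect_setequal(levels(cls), c("nonvulnerable", "vulnerable"))
})

test_that("cost panel aligns claims to the diagnosis-centred window", {
  subjects <- make_subjects("B", "2010-07")
  claims <- make_claims(
    list("B", "2010-05", 120, "E11"),    # 2 months before diagnosis
    list("B", "2010-05", 30, "N18"),     # same month: summed
    list("B", "2010-07", 200, "N18"),
    list("B", "2020-01", 999, "N18"))    # outside any window month
  panel <- build_cost_panel(subjects, claims)
  expect_s3_class(panel, "cost_panel")
  expect_equal(nrow(panel), 49L)
  expect_equal(panel$cost[panel$time == 22], 150)
  expect_equal(panel$cost[panel$time == 24], 200)
  # months without claims are explicit zero rows
  expect_equal(sum(panel$cost == 0), 47L)
})

test_that("panel rows stop at death and truncate at the study window", {
  subjects <- make_subjects(c("D1", "D2"), c("2010-07", "2003-12"),
                            death_month = c("2011-01", NA))
  claims <- make_claims(list("D1", "2010-07", 10, "N18"),
                        list("D2", "2004-01", 10, "N18"))
  panel <- build_cost_panel(subjects, claims)
  d1 <- panel[panel$subject_id == "D1", ]
  expect_equal(max(d1$time), 30L)   # 2011-01 is time 30; later rows absent
  expect_equal(nrow(d1), 31L)
  d2 <- panel[panel$subject_id == "D2", ]
  expect_equal(min(d2$time), 1L)    # 2001-12 precedes the study window
})

test_that("covariate coding bands ages, top-codes comorbidity, flags missing", {
  subj <- data.frame(age = c(45, 80, 79, 25, NA), sex = "male",
                     income = "low", coverage = "NHI", cci = c(0, 5, 2, 1, 1))
  out <- categorize_covariates(subj)
  expect_equal(as.character(out$age_band[1:4]),
               c("40-49", ">80", "70-79", "<30"))
  expect_equal(as.character(out$cci_category), c("0", "2+", "2+", "1", "1"))
  expect_false(out$covariates_complete[5])
  # bands partition: counts sum to the subject count
  ages <- sample(18:95, 500, replace = TRUE)
  bands <- categorize_covariates(data.frame(age = ages, sex = "male",
                                            income = "low", coverage = "NHI",
                                            cci = 0))$age_band
  expect_equal(sum(table(bands)), 500L)
})

test_that("panel region split matches the generator's configured share", {
  cfg <- default_params(n_subjects = 2000, seed = 5)
  split <- region_split(generate_cohort(cfg))
  # binomial error band: 3 * sqrt(p(1-p)/n) ~ 2.2 percentage points
  expect_lt(abs(split[["vulnerable"]] - 12.2), 2.2)
  expect_equal(sum(split), 100)
})

test_that("cost panel CSV round-trips", {
  cfg <- default_params(n_subjects = 15, seed = 9)
  panel <- generate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cost_panel(panel, path)
  back <- read_cost_panel(path)
  expect_equal(as.data.frame(back), as.data.frame(panel),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("cost panel constructor enforces its invariants", {
  df <- data.frame(subject_id = "a", time = 49L, cost = 1,
                   region = "nonvulnerable", age = 50, sex = "male",
                   income = "low", coverage = "NHI", cci = 0)
  expect_error(cost_panel(df), "0..48")
  df$time <- 10L; df$cost <- -1
  expect_error(cost_panel(df), "non-negative")
  df2 <- rbind(transform(df, cost = 1), transform(df, cost = 2))
  expect_error(cost_panel(df2), "duplicate")
})
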