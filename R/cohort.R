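# Cohort construction: washout filtering of incident cases, region
# classification from the regional healthcare-level index (PARC), covariate
# coding, and alignment of monthly costs to a 49-month diagnosis-centred
# window (24 months before, the diagnosis month, 24 months after).

AGE_BAND_BREAKS <- c(-Inf, 29, 39, 49, 59, 69, 79, Inf)
AGE_BAND_LABELS <- c("<30", "30-39", "40-49", "50-59", "60-69", "70-79", ">80")

#' Classify a region as medically vulnerable from its PARC value
#'
#' The position value for relative composite (PARC) index summarises a
#' region's healthcare level on `[-1, 1]` (1 best, 0 average, -1 worst).
#' A region is classed *vulnerable* when its PARC value is strictly below
#' the threshold (default -0.33); a value exactly at the threshold is
#' nonvulnerable.
#'
#' @param parc_value numeric vector of PARC values in `[-1, 1]`.
#' @param threshold strict cut-point, default `-0.33`.
#' @return factor with levels `"nonvulnerable"`, `"vulnerable"`.
#' @examples
#' classify_region(c(-0.5, -0.33, 0))
#' @export
classify_region <- function(parc_value, threshold = -0.33) {
  if (!is.numeric(parc_value)) stop("`parc_value` must be numeric")
  bad <- !is.na(parc_value) & (parc_value < -1 | parc_value > 1)
  if (any(bad)) {
    stop("PARC values must lie in [-1, 1]; offending value(s): ",
         paste(utils::head(parc_value[bad], 3L), collapse = ", "))
  }
  factor(ifelse(parc_value < threshold, "vulnerable", "nonvulnerable"),
         levels = c("nonvulnerable", "vulnerable"))
}

#' Read a claims table from CSV
#'
#' Expected columns: `subject_id`, `month` (ISO `"YYYY-MM"`), `cost`
#' (non-negative), and `codes` (semicolon-separated diagnosis code strings,
#' may be empty).
#'
#' @param path file path.
#' @return data.frame of claims records.
#' @export
read_claims <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  need <- c("subject_id", "month", "cost", "codes")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("claims file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$cost < 0, na.rm = TRUE)) stop("claims contain negative costs")
  df
}

code_has_prefix <- function(codes, prefix) {
  vapply(strsplit(ifelse(is.na(codes), "", codes), ";", fixed = TRUE),
         function(cs) any(startsWith(trimws(cs), prefix)), logical(1))
}

#' Select incident cases by washout filtering
#'
#' Finds, per subject, the first calendar month carrying a diagnosis code
#' with the given prefix and retains only subjects whose first such month
#' falls outside the washout years (so prevalent cases carried in from
#' before the observation window are excluded) and outside the tail years
#' (so the post-diagnosis follow-up window is observable).
#'
#' @param claims data.frame as returned by [read_claims()].
#' @param ckd_code_prefix diagnosis code prefix identifying the condition
#'   (default `"N18"`, chronic kidney disease in ICD-10).
#' @param washout_years integer years treated as washout (default 2002:2003).
#' @param tail_years integer years excluded at the end (default 2018:2019).
#' @return data.frame with columns `subject_id`, `diagnosis_month`
#'   (`"YYYY-MM"`). Subjects carrying the code only in unparseable months are
#'   rejected with a warning, never silently dropped.
#' @export
apply_washout_filter <- function(claims, ckd_code_prefix = "N18",
                                 washout_years = 2002:2003,
                                 tail_years = 2018:2019) {
  hit <- code_has_prefix(claims$codes, ckd_code_prefix)
  dx <- claims[hit, c("subject_id", "month"), drop = FALSE]
  if (!nrow(dx)) {
    return(data.frame(subject_id = character(), diagnosis_month = character(),
                      stringsAsFactors = FALSE))
  }
  dx$idx <- ym_index(dx$month)
  bad_date <- is.na(dx$idx)
  if (any(bad_date)) {
    bad_ids <- unique(dx$subject_id[bad_date])
    # reject subjects whose earliest coded month cannot be placed in time
    all_bad <- setdiff(bad_ids, unique(dx$subject_id[!bad_date]))
    if (length(all_bad)) {
      warning("rejected ", length(all_bad),
              " subject(s) with the diagnosis code but no parseable month: ",
              paste(utils::head(all_bad, 5L), collapse = ", "))
    }
    dx <- dx[!bad_date, , drop = FALSE]
  }
  if (!nrow(dx)) {
    return(data.frame(subject_id = character(), diagnosis_month = character(),
                      stringsAsFactors = FALSE))
  }
  first <- stats::aggregate(idx ~ subject_id, data = dx, FUN = min)
  yr <- ym_year(first$idx)
  keep <- !(yr %in% washout_years) & !(yr %in% tail_years)
  n_excl <- sum(!keep)
  if (n_excl) mtp_log(sprintf("washout filter excluded %d prevalent/tail subject(s)",
                              n_excl), level = 2L)
  data.frame(subject_id = first$subject_id[keep],
             diagnosis_month = ym_label(first$idx[keep]),
             stringsAsFactors = FALSE)
}

#' Code subject-level covariates into analysis categories
#'
#' Adds the 7 descriptive age bands (`<30` ... `>80`; age exactly 80 falls
#' in `>80`), keeps continuous age for modelling, top-codes the Charlson
#' comorbidity index at 2 (`0`, `1`, `2+`), and validates sex, income
#' tertile and coverage type levels.
#'
#' @param subjects data.frame with columns `age`, `sex` (`"male"`/`"female"`),
#'   `income` (`"low"`/`"middle"`/`"high"`), `coverage` (`"NHI"`/
#'   `"medical_aid"`), `cci` (non-negative integer score or category).
#' @return the input with added `age_band` and `cci_category` factors and
#'   a logical `covariates_complete` flag.
#' @export
categorize_covariates <- function(subjects) {
  subjects$age_band <- cut(subjects$age, breaks = AGE_BAND_BREAKS,
                           labels = AGE_BAND_LABELS, right = TRUE)
  subjects$cci_category <- factor(ifelse(is.na(subjects$cci), NA,
                                         ifelse(subjects$cci >= 2, "2+",
                                                as.character(subjects$cci))),
                                  levels = c("0", "1", "2+"))
  subjects$sex <- factor(as.character(subjects$sex),
                         levels = c("male", "female"))
  subjects$income <- factor(as.character(subjects$income),
                            levels = c("low", "middle", "high"))
  subjects$coverage <- factor(as.character(subjects$coverage),
                              levels = c("NHI", "medical_aid"))
  subjects$covariates_complete <-
    !(is.na(subjects$age) | is.na(subjects$sex) | is.na(subjects$income) |
        is.na(subjects$coverage) | is.na(subjects$cci_category))
  n_miss <- sum(!subjects$covariates_complete)
  if (n_miss) mtp_log(sprintf("%d subject(s) have incomplete covariates", n_miss))
  subjects
}

#' Construct a cost panel
#'
#' Low-level constructor validating the panel invariants: integer month
#' index `time` in 0..48 with diagnosis at 24, non-negative costs, at most
#' one row per subject-month, every subject present with at least one row.
#'
#' @param df data.frame with columns `subject_id`, `time`, `cost`, `region`,
#'   `age`, `sex`, `income`, `coverage`, `cci`.
#' @return the validated data.frame with class `cost_panel`.
#' @export
cost_panel <- function(df) {
  need <- c("subject_id", "time", "cost", "region", "age", "sex",
            "income", "coverage", "cci")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cost panel missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(df$time < 0 | df$time > 48)) stop("`time` must lie in 0..48")
  if (any(df$cost < 0)) stop("costs must be non-negative")
  if (anyDuplicated(df[c("subject_id", "time")]))
    stop("duplicate subject-month rows in panel")
  df <- df[order(df$subject_id, df$time), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("cost_panel", "data.frame")
  df
}

#' @export
print.cost_panel <- function(x, ...) {
  cat(sprintf("<cost_panel> %d rows, %d subjects, %.1f%% zero-cost months\n",
              nrow(x), length(unique(x$subject_id)), 100 * mean(x$cost == 0)))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Align monthly claim costs into a diagnosis-centred cost panel
#'
#' Sums every claim of a subject within each calendar month of the window
#' running from 24 months before to 24 months after the diagnosis month
#' (`time = 24 + (claim month - diagnosis month)`), inserting explicit
#' zero-cost rows for window months without claims. Months strictly after
#' the subject's death month, or falling outside the study window, are
#' absent (unbalanced panel). Subjects left with no rows are dropped with
#' a logged count.
#'
#' @param subjects data.frame with `subject_id`, `diagnosis_month`,
#'   `parc_value`, `age`, `sex`, `income`, `coverage`, `cci` and optional
#'   `death_month`; incomplete-covariate subjects are excluded with a
#'   logged count.
#' @param claims data.frame of claims records (all claims count toward the
#'   monthly totals, not only those with the index diagnosis code).
#' @param parc_threshold strict vulnerability cut-point, default -0.33.
#' @param study_start,study_end ISO year-months bounding observable claims.
#' @return a [cost_panel()].
#' @export
build_cost_panel <- function(subjects, claims, parc_threshold = -0.33,
                             study_start = "2002-01", study_end = "2019-12") {
  subjects <- categorize_covariates(subjects)
  n_incomplete <- sum(!subjects$covariates_complete)
  if (n_incomplete)
    mtp_log(sprintf("excluding %d subject(s) with missing covariates", n_incomplete))
  subjects <- subjects[subjects$covariates_complete, , drop = FALSE]

  dx_idx <- ym_index(subjects$diagnosis_month)
  if (anyNA(dx_idx)) stop("unparseable diagnosis_month for subject(s): ",
                          paste(subjects$subject_id[is.na(dx_idx)], collapse = ", "))
  death_idx <- if ("death_month" %in% names(subjects))
    ym_index(subjects$death_month) else rep(NA_integer_, nrow(subjects))
  if (any(!is.na(death_idx) & death_idx < dx_idx - 24L))
    stop("death_month precedes the observation window for some subject(s)")

  lo <- ym_index(study_start); hi <- ym_index(study_end)
  claims$midx <- ym_index(claims$month)
  agg <- stats::aggregate(cost ~ subject_id + midx, data = claims, FUN = sum)

  out <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    months <- dx_idx[i] + (-24:24)
    keep <- months >= lo & months <= hi
    if (!is.na(death_idx[i])) keep <- keep & months <= death_idx[i]
    months <- months[keep]
    if (!length(months)) next
    cost <- numeric(length(months))
    rows <- agg$subject_id == subjects$subject_id[i] & agg$midx %in% months
    if (any(rows)) {
      m <- match(agg$midx[rows], months)
      cost[m] <- agg$cost[rows]
    }
    out[[i]] <- data.frame(subject_id = subjects$subject_id[i],
                           time = months - dx_idx[i] + 24L, cost = cost,
                           stringsAsFactors = FALSE)
  }
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped) mtp_log(sprintf("dropped %d subject(s) with no observable window months",
                               dropped))
  panel <- do.call(rbind, out)
  if (is.null(panel) || !nrow(panel)) stop("no subjects left after truncation")

  j <- match(panel$subject_id, subjects$subject_id)
  panel$region <- classify_region(subjects$parc_value[j], parc_threshold)
  panel$age <- subjects$age[j]
  panel$sex <- subjects$sex[j]
  panel$income <- subjects$income[j]
  panel$coverage <- subjects$coverage[j]
  panel$cci <- pmin(subjects$cci[j], 2L)
  cost_panel(panel)
}

#' Region composition of a cost panel
#'
#' @param panel a [cost_panel()].
#' @return named numeric: percentage of subjects in each region class.
#' @export
region_split <- function(panel) {
  subj <- panel[!duplicated(panel$subject_id), c("subject_id", "region")]
  100 * prop.table(table(subj$region))
}

#' Write / read a cost panel as CSV
#'
#' @param panel a [cost_panel()].
#' @param path file path.
#' @return `write_cost_panel` returns `path` invisibly; `read_cost_panel`
#'   returns a [cost_panel()].
#' @export
write_cost_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cost_panel
#' @export
read_cost_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time", "cost", "region", "age", "sex",
            "income", "coverage", "cci")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cost panel file ", path, " is missing column(s): ",
                         paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df$region <- factor(df$region, levels = c("nonvulnerable", "vulnerable"))
  df$sex <- factor(df$sex, levels = c("male", "female"))
  df$income <- factor(df$income, levels = c("low", "middle", "high"))
  df$coverage <- factor(df$coverage, levels = c("NHI", "medical_aid"))
  cost_panel(df)
}
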