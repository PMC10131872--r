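# Segmented interrupted-time-series design matrices for the two model parts.
# Column order mirrors the reporting layout of the motivating analysis:
# intercept, diagnosis-period indicator, region, time, then the two-way
# products, the three-way product, then adjustment covariates.
#
# Identifiability note: the region slope term (column 7) multiplies TIME,
# not after-time. A region x after_time column would coincide exactly with
# diagnosis x region x after_time (after_time > 0 forces diagnosis = 1),
# leaving the two coefficients identified only through their sum; the
# region x time form is the standard controlled-ITS design and keeps the
# post-diagnosis region slope gap equal to beta7 + beta8 and the
# difference-in-differences equal to beta8.

STRUCTURAL_COLS <- c("intercept", "diagnosis", "region", "time",
                     "diagnosis_region", "diagnosis_after_time",
                     "region_time", "diagnosis_region_after_time")

# Structural design rows for given month indices (0..48) and region codes.
# after_time = max(0, time - 24); diagnosis = 1 iff time >= 24 (the
# diagnosis month itself counts as post-diagnosis, with after_time = 0).
structural_design <- function(time, region) {
  if (any(time < 0 | time > 48)) stop("`time` must lie in 0..48")
  diagnosis <- as.numeric(time >= 24)
  after <- pmax(0, time - 24)
  cbind(intercept = 1, diagnosis = diagnosis, region = region, time = time,
        diagnosis_region = diagnosis * region,
        diagnosis_after_time = diagnosis * after,
        region_time = region * time,
        diagnosis_region_after_time = diagnosis * region * after)
}

covariate_columns <- function(panel, covariate_spec) {
  known <- c("age", "sex", "cci", "income", "coverage")
  bad <- setdiff(covariate_spec, known)
  if (length(bad)) stop("unknown covariate(s) in spec: ",
                        paste(bad, collapse = ", "),
                        "; valid names: ", paste(known, collapse = ", "))
  cols <- list()
  for (v in covariate_spec) {
    cols[[v]] <- switch(v,
      age = cbind(age = as.numeric(panel$age)),
      sex = cbind(sex = as.numeric(panel$sex == "female")),
      # single-column comorbidity score 0/1/2 (2+ top-coded to 2)
      cci = cbind(cci = pmin(as.numeric(panel$cci), 2)),
      income = cbind(income_middle = as.numeric(panel$income == "middle"),
                     income_high = as.numeric(panel$income == "high")),
      coverage = cbind(coverage_medical_aid =
                         as.numeric(panel$coverage == "medical_aid")))
  }
  do.call(cbind, cols)
}

# Parameter names in the reporting convention: the 8 structural terms of the
# binary part are alpha1..alpha8 and its covariates gamma1..; the overall
# mean part mirrors them as beta1..beta8 and delta1.. .
param_names_for <- function(colnames_, part = c("binary", "mean")) {
  part <- match.arg(part)
  ns <- length(STRUCTURAL_COLS)
  nc <- length(colnames_) - ns
  if (part == "binary") c(paste0("alpha", seq_len(ns)), paste0("gamma", seq_len(nc)))
  else c(paste0("beta", seq_len(ns)), paste0("delta", seq_len(nc)))
}

#' Build the two-part segmented ITS design matrices from a cost panel
#'
#' Produces identically structured per-observation design rows for the
#' binary (usage) part and the overall-mean part: intercept, post-diagnosis
#' indicator (1 from the diagnosis month, time >= 24), region (1 =
#' vulnerable), month index `time` in 0..48, the products
#' diagnosis x region, diagnosis x after_time, region x time and
#' diagnosis x region x after_time (with after_time = max(0, time - 24)),
#' followed by the requested adjustment covariates (sex coded 1 = female,
#' comorbidity entered as the 0/1/2 category score). The region slope term
#' enters as region x time rather than region x after_time, which would
#' duplicate the three-way column exactly (see the package vignette).
#'
#' @param panel a [cost_panel()].
#' @param covariate_spec character vector of adjustment covariates; any of
#'   `"age"`, `"sex"`, `"cci"`, `"income"`, `"coverage"`. Default matches the
#'   motivating analysis (age, sex, cci).
#' @return an object of class `mtp_design`: list with matrices `x1`, `x2`,
#'   outcome `y`, `subject_id`, 0-based subject start offsets `sidx`, and
#'   the parameter names of both parts.
#' @export
build_design <- function(panel, covariate_spec = c("age", "sex", "cci")) {
  if (!inherits(panel, "cost_panel")) panel <- cost_panel(as.data.frame(panel))
  panel <- panel[order(panel$subject_id, panel$time), , drop = FALSE]
  region <- as.numeric(panel$region == "vulnerable")
  X <- cbind(structural_design(panel$time, region),
             covariate_columns(panel, covariate_spec))
  sid <- as.character(panel$subject_id)
  starts <- c(0L, cumsum(rle(sid)$lengths))
  out <- list(x1 = X, x2 = X, y = as.numeric(panel$cost),
              subject_id = sid, sidx = as.integer(starts),
              par_names_binary = param_names_for(colnames(X), "binary"),
              par_names_mean = param_names_for(colnames(X), "mean"),
              covariate_spec = covariate_spec)
  class(out) <- "mtp_design"
  out
}

#' @export
print.mtp_design <- function(x, ...) {
  cat(sprintf("<mtp_design> %d observations, %d subjects, %d columns/part\n",
              length(x$y), length(x$sidx) - 1L, ncol(x$x1)))
  cat("columns:", paste(colnames(x$x1), collapse = ", "), "\n")
  invisible(x)
}

n_subjects <- function(design) length(design$sidx) - 1L

#' Export / import a design matrix for audit
#'
#' Writes the overall-mean part rows together with the outcome and subject
#' id as CSV with a mandatory column-name header; the reader restores the
#' matrix with identical column order.
#'
#' @param design an `mtp_design`.
#' @param path file path.
#' @export
write_design_csv <- function(design, path) {
  df <- data.frame(subject_id = design$subject_id, y = design$y,
                   design$x2, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(subject_id = "character"))
  X <- as.matrix(df[, setdiff(names(df), c("subject_id", "y")), drop = FALSE])
  starts <- c(0L, cumsum(rle(df$subject_id)$lengths))
  out <- list(x1 = X, x2 = X, y = df$y, subject_id = df$subject_id,
              sidx = as.integer(starts),
              par_names_binary = param_names_for(colnames(X), "binary"),
              par_names_mean = param_names_for(colnames(X), "mean"),
              covariate_spec = NULL)
  class(out) <- "mtp_design"
  out
}
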