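# internal helpers shared across modules

#' @keywords internal
#' @importFrom Rcpp sourceCpp
#' @useDynLib mtpcost, .registration = TRUE
"_PACKAGE"

# Parse "YYYY-MM" strings into integer month indices (months since 2000-01).
# Whole-month arithmetic on these indices is exact; no Date objects needed
# because claims are keyed by calendar month only.
ym_index <- function(x) {
  x <- as.character(x)
  ok <- grepl("^[0-9]{4}-(0[1-9]|1[0-2])$", x)
  out <- rep(NA_integer_, length(x))
  if (any(ok)) {
    yr <- as.integer(substr(x[ok], 1, 4))
    mo <- as.integer(substr(x[ok], 6, 7))
    out[ok] <- (yr - 2000L) * 12L + (mo - 1L)
  }
  out
}

ym_year <- function(idx) 2000L + idx %/% 12L

ym_label <- function(idx) sprintf("%04d-%02d", ym_year(idx), idx %% 12L + 1L)

# Run code with a private RNG stream: sets the seed, restores the caller's
# .Random.seed afterwards so library calls never perturb user simulations.
with_preserved_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Timestamped stderr logging; level gate set via options(mtpcost.verbosity=)
# with 0 = quiet, 1 = normal, 2 = verbose.
mtp_log <- function(msg, level = 1L) {
  verb <- getOption("mtpcost.verbosity", 1L)
  if (level <= verb) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), msg)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
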