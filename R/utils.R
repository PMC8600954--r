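#' Molecular subgroup labels
#'
#' The four consensus medulloblastoma molecular subgroups, in canonical order.
#' @export
MB_SUBGROUPS <- c("WNT", "SHH", "Group3", "Group4")

#' Histological variant labels
#'
#' CLA classic; LCA large cell/anaplastic; DN desmoplastic/nodular; MBEN
#' medulloblastoma with extensive nodularity. Central review may additionally
#' return MBNOS (not otherwise specified) when no definitive variant can be
#' assigned.
#' @export
MB_VARIANTS <- c("CLA", "LCA", "DN", "MBEN")

#' Round half away from zero
#'
#' Reporting percentages uses commercial (half-away-from-zero) rounding rather
#' than R's banker's rounding, so 77.5 reports as 78. Raw unrounded values are
#' always retained alongside rounded ones.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage with the package-wide rounding rule
#'
#' @param num,den numerator and denominator counts.
#' @return list with `raw` (unrounded percent) and `rounded` (integer percent).
#' @export
as_percent <- function(num, den) {
  if (den == 0) {
    return(list(raw = NA_real_, rounded = NA_real_))
  }
  raw <- 100 * num / den
  list(raw = raw, rounded = round_half_up(raw))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the random-number stream seeded to `seed`, then restores
#' the caller's stream, so seeded simulation calls never disturb the session
#' RNG. Used throughout the package wherever reproducible draws are needed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Shared guard: x must be a single finite number.
assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# Format "raw% (rounded%)" for text reports.
fmt_pct <- function(num, den) {
  p <- as_percent(num, den)
  if (is.na(p$raw)) return("NA")
  sprintf("%d/%d = %.1f%% (%d%%)", num, den, p$raw, as.integer(p$rounded))
}
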