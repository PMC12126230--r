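#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map2 map_dbl map_int map_chr pmap
NULL

# Percent rounded half-away-from-zero to one decimal, the convention used in
# all direction/binding summaries (so 51.25 prints as 51.3, not 51.2).
round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage of a count pair, rounded half away from zero
#'
#' Computes `100 * k / n` rounded half-away-from-zero to one decimal place.
#' This is the rounding convention used by [summarize_direction()] and
#' [intersect_binding()] summaries.
#'
#' @param k Numerator count.
#' @param n Denominator count (> 0).
#' @return A numeric percentage on the 0--100 scale.
#' @examples
#' percent_of(460, 658) # 69.9
#' percent_of(164, 320) # 51.3
#' @export
percent_of <- function(k, n) {
  stopifnot(is.numeric(k), is.numeric(n), all(n > 0))
  round_half_away(100 * k / n, 1)
}

# Run code with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is restored afterwards so simulation substreams never perturb
# user-level randomness.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stable 31-bit hash of a character key, folded with a global seed, so every
# simulated gene/sample gets a reproducible substream independent of
# iteration order. Arithmetic stays below 2^53 so doubles are exact.
derive_seed <- function(seed, key) {
  stopifnot(length(key) == 1L, is.character(key))
  m <- 2147483629 # largest prime < 2^31
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 131 + c) %% m
  as.integer((h + (seed %% m)) %% m)
}

check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'", class = "apascan_error")
  }
  invisible(strand)
}
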