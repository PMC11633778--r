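#' @keywords internal
"_PACKAGE"

## Run expr with a local RNG seed, restoring the caller's RNG state.
## All stochastic generators in the package route their randomness through
## this so that no call mutates global state.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Well identifiers for a multiwell plate
#'
#' Builds standard well names ("A01".."P24" for 384-well geometry) from row
#' and column indices.
#'
#' @param row,col 1-based integer row/column indices.
#' @return Character vector of well ids.
#' @examples
#' well_id(2, 3) # "B03"
#' @export
well_id <- function(row, col) {
  stopifnot(all(row >= 1), all(row <= 26), all(col >= 1))
  paste0(LETTERS[row], sprintf("%02d", col))
}

## Deterministic 32-bit FNV-1a hash of a character vector; used to stamp
## output tables with the configuration they were produced under.
## 32-bit modular multiply done in 16-bit halves to stay in double precision.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    ## xor on the low 16 bits only (b < 2^16); h may exceed 2^31, so split
    lo <- h %% 65536
    hi <- h %/% 65536
    lo <- bitwXor(as.integer(lo), as.integer(b %% 65536))
    h <- hi * 65536 + lo
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## round-half-up to match printed percentages (base round() is banker's)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Percentage of a count, at printed precision
#'
#' @param k numerator count.
#' @param n denominator count.
#' @param digits decimal places to report (half-up rounding).
#' @return Numeric percentage.
#' @examples
#' fraction_pct(39, 51) # 76.5
#' @export
fraction_pct <- function(k, n, digits = 1) {
  stopifnot(n > 0, k >= 0)
  round_half_up(100 * k / n, digits)
}
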