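#' Physical constants
#'
#' Constants used throughout the package: the molar gas constant `GAS_CONSTANT`
#' (8.314 J mol^-1 K^-1) and the Faraday constant `FARADAY` (96485 C mol^-1).
#' Energies are handled internally in kJ mol^-1; `kT_kj(temperature)` returns
#' the thermal energy RT in kJ mol^-1 at a given temperature in kelvin.
#'
#' @name constants
#' @keywords internal
NULL

#' @rdname constants
#' @export
GAS_CONSTANT <- 8.314

#' @rdname constants
#' @export
FARADAY <- 96485

#' Thermal energy RT in kJ/mol
#'
#' @param temperature Temperature in kelvin (> 0).
#' @return RT in kJ mol^-1.
#' @export
kT_kj <- function(temperature) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  GAS_CONSTANT * temperature / 1000
}

# Run code with a temporary RNG state derived from `seed`, restoring the
# caller's stream afterwards so package functions never clobber user RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Half-up rounding
#'
#' Rounds half away from zero (base R's `round()` rounds half to even), the
#' convention used when reporting free energies at integer precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits to keep.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
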