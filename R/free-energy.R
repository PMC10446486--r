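#' Directed free-energy value with uncertainty
#'
#' A signed free-energy difference between two labelled states, carried with a
#' nonnegative uncertainty. Reversing the direction negates the value and
#' preserves the error.
#'
#' @param value Free-energy difference in kJ mol^-1 for moving `from` -> `to`.
#' @param error Nonnegative uncertainty in kJ mol^-1.
#' @param from,to State labels.
#' @param label Optional human-readable description.
#' @return An object of class `free_energy` with fields `value`, `error`,
#'   `from`, `to`, `label`.
#' @examples
#' dg <- free_energy(-83, 3, from = "solvent", to = "SBD")
#' reverse(dg)
#' @export
free_energy <- function(value, error = 0, from = "A", to = "B", label = "") {
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  stopifnot(is.numeric(error), length(error) == 1, is.finite(error))
  if (error < 0) stop("free-energy error must be nonnegative")
  # from == to is admitted: closed loops have a well-defined (zero) total
  structure(
    list(value = value, error = error,
         from = as.character(from), to = as.character(to),
         label = as.character(label)),
    class = "free_energy"
  )
}

#' Reverse the direction of a free-energy value
#'
#' @param x A `free_energy` object.
#' @return The same edge traversed in the opposite direction: value negated,
#'   error unchanged, endpoints swapped.
#' @export
reverse <- function(x) UseMethod("reverse")

#' @export
reverse.free_energy <- function(x) {
  free_energy(-x$value, x$error, from = x$to, to = x$from, label = x$label)
}

#' @export
print.free_energy <- function(x, ...) {
  cat(sprintf("<free_energy> %s -> %s: %+.3f +/- %.3f kJ/mol %s\n",
              x$from, x$to, x$value, x$error,
              if (nzchar(x$label)) paste0("(", x$label, ")") else ""))
  invisible(x)
}

#' Format a free-energy value at reporting precision
#'
#' Values and errors are rounded half-up to the nearest integer kJ mol^-1, the
#' precision at which transport free energies are conventionally reported;
#' raw values are never modified.
#'
#' @param x A `free_energy` object.
#' @return Character scalar like `"+23 +/- 4 kJ/mol"`.
#' @export
format_reported <- function(x) {
  stopifnot(inherits(x, "free_energy"))
  sprintf("%+d +/- %d kJ/mol",
          as.integer(round_half_up(x$value)),
          as.integer(round_half_up(x$error)))
}
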