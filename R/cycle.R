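#' Transport legs and cycle assembly
#'
#' Free-energy changes for substrate movement between compartments or binding
#' sites (e.g. SSD, membrane, solvent, SBD of an RND-family transporter) are
#' represented as directed legs and composed into end-to-end transport paths.
#' Because the component measurements are statistically independent, path
#' errors combine in quadrature.
#'
#' @name cycle_assembly
NULL

.default_sites <- c("SSD", "membrane", "solvent", "SBD", "ECD_base", "site1",
                    "site2", "bulk", "gas")

#' Construct a directed transport leg
#'
#' @param from,to Site labels. Unknown sites are rejected unless listed in
#'   `sites`.
#' @param value Free-energy change in kJ mol^-1 for `from` -> `to`.
#' @param error Nonnegative uncertainty (kJ mol^-1).
#' @param provenance Free-text origin of the value (PMF id, ABFE id,
#'   literature).
#' @param sites Character vector of admissible site labels; defaults to the
#'   built-in vocabulary, extended automatically by any label already used in
#'   `from`/`to` when `sites = NULL`.
#' @return A `transport_leg` object (also a `free_energy`).
#' @examples
#' transport_leg("membrane", "solvent", 88, 1, provenance = "PMF-3")
#' @export
transport_leg <- function(from, to, value, error = 0, provenance = "",
                          sites = .default_sites) {
  if (identical(from, to)) stop("'from' and 'to' sites must differ")
  if (!is.null(sites)) {
    unknown <- setdiff(c(from, to), sites)
    if (length(unknown))
      stop("unknown site label(s): ", paste(unknown, collapse = ", "),
           "; extend 'sites' to admit them")
  }
  fe <- free_energy(value, error, from = from, to = to, label = provenance)
  fe$provenance <- as.character(provenance)
  class(fe) <- c("transport_leg", class(fe))
  fe
}

#' @export
reverse.transport_leg <- function(x) {
  out <- transport_leg(x$to, x$from, -x$value, x$error,
                       provenance = x$provenance, sites = NULL)
  out
}

#' Combine independent errors in quadrature
#'
#' The total uncertainty of a sum of independent quantities is
#' sqrt(sum(e_i^2)).
#'
#' @param errors Numeric vector of nonnegative uncertainties.
#' @return The quadrature sum.
#' @examples
#' quadrature_error(c(3, 1, 3)) # sqrt(19)
#' @export
quadrature_error <- function(errors) {
  stopifnot(is.numeric(errors))
  if (any(!is.finite(errors)) || any(errors < 0))
    stop("errors must be finite and nonnegative")
  sqrt(sum(errors^2))
}

#' Compose transport legs into an end-to-end path
#'
#' Chains directed legs from `start` to `end`, reversing individual legs where
#' needed so the chain is contiguous. The total is the signed sum of leg
#' values; the total error is the quadrature sum of leg errors, appropriate
#' when the legs derive from independent calculations.
#'
#' @param legs List of `transport_leg` objects, in chain order.
#' @param start,end Site labels of the path endpoints.
#' @return A `transport_path` object: fields `legs` (as traversed), `total`
#'   (a [free_energy]), and `path` (the site sequence).
#' @examples
#' legs <- list(
#'   transport_leg("SSD", "membrane", 18, 3, "PMF-2"),
#'   transport_leg("membrane", "solvent", 88, 1, "PMF-3"),
#'   transport_leg("solvent", "SBD", -83, 3, "PMF-4")
#' )
#' p <- compose_path(legs, "SSD", "SBD")
#' format_reported(p$total) # "+23 +/- 4 kJ/mol"
#' @export
compose_path <- function(legs, start, end) {
  stopifnot(is.list(legs), length(legs) >= 1)
  if (!all(vapply(legs, inherits, logical(1), "free_energy")))
    stop("all legs must be transport_leg/free_energy objects")
  current <- start
  used <- vector("list", length(legs))
  for (i in seq_along(legs)) {
    leg <- legs[[i]]
    if (identical(leg$from, current)) {
      used[[i]] <- leg
    } else if (identical(leg$to, current)) {
      used[[i]] <- reverse(leg)
    } else {
      stop(sprintf("broken chain at site '%s': leg %d connects %s -> %s",
                   current, i, leg$from, leg$to))
    }
    current <- used[[i]]$to
  }
  if (!identical(current, end))
    stop(sprintf("path ends at '%s', expected '%s'", current, end))
  total_value <- sum(vapply(used, `[[`, numeric(1), "value"))
  total_error <- quadrature_error(vapply(used, `[[`, numeric(1), "error"))
  structure(
    list(legs = used,
         total = free_energy(total_value, total_error, from = start, to = end,
                             label = "composed path"),
         path = c(start, vapply(used, `[[`, character(1), "to"))),
    class = "transport_path"
  )
}

#' @export
print.transport_path <- function(x, ...) {
  cat("<transport_path>", paste(x$path, collapse = " -> "), "\n")
  for (leg in x$legs)
    cat(sprintf("  %-10s -> %-10s %+8.3f +/- %.3f  [%s]\n",
                leg$from, leg$to, leg$value, leg$error,
                if (!is.null(leg$provenance)) leg$provenance else ""))
  cat("  total:", format_reported(x$total),
      sprintf("(raw %+.4f +/- %.4f)\n", x$total$value, x$total$error))
  invisible(x)
}

#' Compare direct and indirect estimates of the same transport step
#'
#' Quantifies thermodynamic-cycle closure between two independent estimates of
#' the same free-energy change (e.g. an alchemical "direct" route versus a
#' composed PMF "indirect" route).
#'
#' @param direct,indirect `free_energy` objects describing the same endpoints
#'   in the same direction.
#' @return A list: `discrepancy` (direct - indirect, a [free_energy]),
#'   `consistent_1sigma` (does the combined 1-sigma interval contain zero?),
#'   and `same_sign` (do both estimates agree in sign?).
#' @export
cycle_closure <- function(direct, indirect) {
  stopifnot(inherits(direct, "free_energy"), inherits(indirect, "free_energy"))
  if (!identical(direct$from, indirect$from) ||
      !identical(direct$to, indirect$to))
    stop("direct and indirect estimates must share endpoints and direction")
  d <- direct$value - indirect$value
  e <- quadrature_error(c(direct$error, indirect$error))
  list(
    discrepancy = free_energy(d, e, from = direct$from, to = direct$to,
                              label = "direct - indirect"),
    consistent_1sigma = abs(d) <= e,
    same_sign = sign(direct$value) == sign(indirect$value)
  )
}
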