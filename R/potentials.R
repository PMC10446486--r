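#' Analytic one-dimensional potentials
#'
#' Closed-form test potentials used by the synthetic-data generators. Each
#' constructor returns an `analytic_potential`: a list with a vectorised
#' evaluator `fun(x)` (kJ mol^-1 as a function of position in nm), a `domain`,
#' and where available closed-form landmarks (`well_depth`, `barrier`).
#'
#' * `potential_flat()` — constant zero.
#' * `potential_harmonic(k, x0)` — 0.5 k (x - x0)^2.
#' * `potential_double_well(barrier, x1, x2)` — symmetric quartic with minima
#'   at `x1`, `x2` and a barrier of height `barrier` at the midpoint.
#' * `potential_well_plateau(depth, edge, width)` — a smooth well of given
#'   depth rising to a flat plateau at zero, emulating extraction of a lipid
#'   from a favourable environment into solvent.
#'
#' @param k Stiffness (kJ mol^-1 nm^-2).
#' @param x0 Minimum position (nm).
#' @param barrier Barrier height (kJ mol^-1) above the two minima.
#' @param x1,x2 Positions of the two minima (nm), `x1 < x2`.
#' @param depth Well depth (kJ mol^-1, > 0).
#' @param edge Position (nm) where the well shoulder sits.
#' @param width Switching width (nm) of the shoulder.
#' @param domain Length-2 numeric giving the sampled interval (nm).
#' @return An `analytic_potential` object.
#' @name analytic_potential
NULL

# dotted formals so partial matching can't capture parameters passed via ...
new_potential <- function(.kind, .fun, .domain, ...) {
  stopifnot(is.function(.fun), length(.domain) == 2, .domain[1] < .domain[2])
  structure(c(list(kind = .kind, fun = .fun, domain = .domain), list(...)),
            class = "analytic_potential")
}

#' @rdname analytic_potential
#' @export
potential_flat <- function(domain = c(0, 1)) {
  new_potential("flat", function(x) rep(0, length(x)), domain)
}

#' @rdname analytic_potential
#' @export
potential_harmonic <- function(k = 100, x0 = 0.5, domain = c(0, 1)) {
  stopifnot(k >= 0)
  new_potential("harmonic", function(x) 0.5 * k * (x - x0)^2, domain,
                k = k, x0 = x0, well_depth = 0)
}

#' @rdname analytic_potential
#' @export
potential_double_well <- function(barrier = 20, x1 = 0.25, x2 = 0.75,
                                  domain = c(0, 1)) {
  stopifnot(barrier > 0, x1 < x2)
  mid <- (x1 + x2) / 2
  half <- (x2 - x1) / 2
  fun <- function(x) {
    u <- (x - mid) / half
    barrier * (u^2 - 1)^2
  }
  new_potential("double_well", fun, domain,
                barrier = barrier, x1 = x1, x2 = x2)
}

#' @rdname analytic_potential
#' @export
potential_well_plateau <- function(depth = 83, edge = 0.6, width = 0.15,
                                   domain = c(0, 1.5)) {
  stopifnot(depth > 0, width > 0)
  # smoothstep from -depth (x << edge) to 0 (x >> edge)
  fun <- function(x) {
    t <- pmin(pmax((x - edge) / width + 0.5, 0), 1)
    s <- t * t * (3 - 2 * t)
    -depth * (1 - s)
  }
  new_potential("well_plateau", fun, domain,
                well_depth = depth, edge = edge)
}

#' @export
print.analytic_potential <- function(x, ...) {
  cat(sprintf("<analytic_potential> kind=%s domain=[%g, %g] nm\n",
              x$kind, x$domain[1], x$domain[2]))
  invisible(x)
}
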