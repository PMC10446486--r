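#' Electrochemical gradients and coupling stoichiometry
#'
#' The free energy available from moving an ion down its transmembrane
#' electrochemical gradient is
#'
#'   dG = RT * ln(c_in / c_out) + z * F * dV
#'
#' for one mole of ion moved from outside to inside, with dV = V_in - V_out.
#' With the sign convention used throughout, a negative dG means influx is
#' favourable; a physiological resting potential is negative. The number of
#' ions whose downhill movement must be harnessed to pay an uphill substrate
#' export cost is the ratio of the export free energy to the per-ion driving
#' energy, rounded up to an integer.
#'
#' @name ion_coupling
NULL

#' Ion species with a transmembrane concentration gradient
#'
#' @param name Species label, e.g. `"Na+"`.
#' @param z Signed integer charge in elementary units (nonzero).
#' @param c_in,c_out Intracellular / extracellular concentrations in mM
#'   (both > 0). Activities are approximated by concentrations.
#' @return An `ion_species` object.
#' @examples
#' ion_na() # standard cellular Na+ gradient: 12 mM in / 145 mM out
#' @export
ion_species <- function(name, z, c_in, c_out) {
  stopifnot(length(z) == 1, z == as.integer(z))
  if (z == 0) stop("ion charge must be nonzero")
  if (!is.numeric(c_in) || c_in <= 0 || !is.numeric(c_out) || c_out <= 0)
    stop("concentrations must be positive")
  structure(list(name = as.character(name), z = as.integer(z),
                 c_in = c_in, c_out = c_out),
            class = "ion_species")
}

#' @rdname ion_species
#' @export
ion_na <- function() ion_species("Na+", +1L, c_in = 12, c_out = 145)

#' @rdname ion_species
#' @export
ion_k <- function() ion_species("K+", +1L, c_in = 150, c_out = 4)

#' Membrane electrical/thermal condition
#'
#' @param delta_v Membrane potential V_in - V_out, in millivolts.
#' @param temperature Temperature in kelvin; default 310 K (physiological).
#' @return A `membrane_condition` object.
#' @export
membrane_condition <- function(delta_v, temperature = 310) {
  stopifnot(is.numeric(delta_v), is.numeric(temperature), temperature > 0)
  structure(list(delta_v = delta_v, temperature = temperature),
            class = "membrane_condition")
}

#' Electrochemical free energy of ion influx
#'
#' Free energy in kJ mol^-1 of moving one mole of the ion from outside to
#' inside the membrane: `RT ln(c_in/c_out) + zF dV`. Negative values mean
#' influx is favourable.
#'
#' @param ion An [ion_species].
#' @param cond A [membrane_condition] (its `delta_v` may be a vector).
#' @return Numeric vector of dG values (kJ mol^-1), one per `delta_v`.
#' @examples
#' electrochemical_dg(ion_na(), membrane_condition(-60)) # about -12.2
#' @export
electrochemical_dg <- function(ion, cond) {
  stopifnot(inherits(ion, "ion_species"), inherits(cond, "membrane_condition"))
  rt <- GAS_CONSTANT * cond$temperature / 1000           # kJ/mol
  chem <- rt * log(ion$c_in / ion$c_out)
  elec <- ion$z * FARADAY * (cond$delta_v / 1000) / 1000 # C/mol * V -> kJ/mol
  chem + elec
}

#' Nernst equilibrium potential
#'
#' The membrane potential (mV) at which the ion's electrochemical free energy
#' vanishes: `-(RT/zF) ln(c_in/c_out)`.
#'
#' @param ion An [ion_species].
#' @param temperature Temperature in kelvin.
#' @return Equilibrium potential in mV.
#' @examples
#' nernst_potential(ion_k()) # about -96.8 mV
#' @export
nernst_potential <- function(ion, temperature = 310) {
  stopifnot(inherits(ion, "ion_species"), temperature > 0)
  rt <- GAS_CONSTANT * temperature / 1000
  -(rt / (ion$z * FARADAY / 1000)) * log(ion$c_in / ion$c_out) * 1000
}

#' Coupling ions required to pay an export cost
#'
#' Computes the per-ion driving energy released by the stated transport
#' direction (influx or efflux) under the given condition, and the number of
#' such ions needed per substrate exported. The transport direction is always
#' explicit: Na+-coupled transporters typically harvest influx, K+-coupled
#' ones efflux.
#'
#' @param export_dg Substrate export cost in kJ mol^-1 (> 0).
#' @param ion An [ion_species].
#' @param cond A [membrane_condition]; `delta_v` may be a vector.
#' @param direction `"influx"` or `"efflux"`: the ion movement harvested.
#' @return A data.frame with columns `delta_v`, `driving` (kJ mol^-1 released
#'   per ion), `ratio` (export_dg / driving), `count` (ceiling of ratio) and
#'   `feasible` (driving > 0). Where infeasible, `ratio`/`count` are `NA`.
#' @examples
#' coupling_ions(20, ion_na(), membrane_condition(-60), "influx") # count 2
#' @export
coupling_ions <- function(export_dg, ion, cond,
                          direction = c("influx", "efflux")) {
  direction <- match.arg(direction)
  if (!is.numeric(export_dg) || length(export_dg) != 1 || export_dg <= 0)
    stop("export_dg must be a single positive value; import needs no coupling")
  dg_in <- electrochemical_dg(ion, cond)
  driving <- if (direction == "influx") -dg_in else dg_in
  feasible <- driving > 0
  ratio <- ifelse(feasible, export_dg / driving, NA_real_)
  data.frame(
    delta_v = cond$delta_v,
    driving = driving,
    ratio = ratio,
    count = ifelse(feasible, ceiling(ratio), NA_real_),
    feasible = feasible
  )
}

#' Stoichiometry curves over a membrane-potential grid
#'
#' Tabulates per-ion driving energies and coupling-ion requirements over a
#' grid of membrane potentials for one or more export costs, suitable for
#' plotting or TSV export.
#'
#' @param export_dg Numeric vector of export costs (kJ mol^-1, all > 0).
#' @param ion An [ion_species].
#' @param delta_v Numeric vector of membrane potentials (mV).
#' @param direction `"influx"` or `"efflux"`.
#' @param temperature Temperature in kelvin.
#' @return A `stoichiometry_curve` data.frame with columns `ion`, `export_dg`,
#'   `delta_v`, `driving`, `ratio`, `count`, `feasible`.
#' @examples
#' sc <- stoichiometry_curve(c(10, 20, 40), ion_na(),
#'                           delta_v = seq(-100, 0, by = 20))
#' @export
stoichiometry_curve <- function(export_dg, ion, delta_v,
                                direction = c("influx", "efflux"),
                                temperature = 310) {
  direction <- match.arg(direction)
  stopifnot(length(export_dg) >= 1, length(delta_v) >= 1)
  if (any(export_dg <= 0)) stop("all export costs must be positive")
  rows <- lapply(export_dg, function(g) {
    tab <- coupling_ions(g, ion, membrane_condition(delta_v, temperature),
                         direction)
    cbind(ion = ion$name, export_dg = g, tab)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("stoichiometry_curve", "data.frame")
  out
}
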