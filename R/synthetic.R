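#' Synthetic-data generators with known ground truth
#'
#' Every input class the analysis layer consumes can be generated here with a
#' closed-form answer attached: biased reaction-coordinate samples from
#' analytic potentials (for WHAM), lambda-coupled harmonic reduced-potential
#' matrices (for MBAR/BAR), and toy membrane-protein trajectories with planted
#' waters, ions and helix scaffolds (for the geometry probes). All generators
#' are deterministic under a fixed seed.
#'
#' @name synthetic_data
NULL

#' Umbrella-sampling window
#'
#' Biased reaction-coordinate samples from one umbrella window: a harmonic
#' bias of stiffness `force_constant` centred at `center` on top of the
#' underlying free-energy landscape.
#'
#' @param center Bias centre (nm).
#' @param force_constant Bias stiffness (kJ mol^-1 nm^-2, >= 0).
#' @param temperature Temperature (K).
#' @param samples Numeric vector of reaction-coordinate values (nm).
#' @param times Sample times (ns); defaults to sample index.
#' @param equilibration_cutoff Time before which samples are discarded by
#'   analysis routines (same units as `times`); default 0.
#' @return An `umbrella_window` object.
#' @export
umbrella_window <- function(center, force_constant, temperature, samples,
                            times = seq_along(samples),
                            equilibration_cutoff = 0) {
  stopifnot(is.numeric(samples), length(samples) >= 1,
            all(is.finite(samples)))
  if (force_constant < 0) stop("force_constant must be nonnegative")
  if (temperature <= 0) stop("temperature must be positive")
  if (length(times) != length(samples))
    stop("times and samples must have equal length")
  keep <- times > equilibration_cutoff
  if (!any(keep)) stop("no samples remain after the equilibration discard")
  structure(list(center = center, force_constant = force_constant,
                 temperature = temperature, samples = samples, times = times,
                 equilibration_cutoff = equilibration_cutoff),
            class = "umbrella_window")
}

# samples surviving the equilibration discard
window_samples <- function(w) w$samples[w$times > w$equilibration_cutoff]

#' Generate umbrella windows by Metropolis sampling of an analytic potential
#'
#' Random-walk Metropolis Monte Carlo on U(x) + 0.5 k (x - c)^2 at the given
#' temperature, one independent chain per window (chains advance in lockstep,
#' vectorised across windows). The proposal step is tuned towards ~40%
#' acceptance during a discarded burn-in; a warning is raised if the final
#' acceptance rate leaves (0.05, 0.95). Proposals outside the potential's
#' domain are rejected (hard walls).
#'
#' @param potential An [analytic_potential].
#' @param centers Bias centres (nm), inside the potential domain.
#' @param force_constant Bias stiffness (kJ mol^-1 nm^-2); default 1000, with
#'   0.05 nm window spacing the conventional umbrella set-up.
#' @param n_samples Retained samples per window.
#' @param temperature Temperature (K); default 323 (coarse-grained lipid
#'   convention).
#' @param seed Integer seed; the generator is deterministic given it.
#' @param stride Keep every `stride`-th Metropolis step (decorrelation).
#' @param burn_in Discarded tuning steps before retention starts.
#' @return List of [umbrella_window] objects with attribute `"potential"`
#'   carrying the ground truth.
#' @export
gen_umbrella_windows <- function(potential, centers, force_constant = 1000,
                                 n_samples = 5000, temperature = 323,
                                 seed = 1, stride = 5, burn_in = 1000) {
  stopifnot(inherits(potential, "analytic_potential"))
  dom <- potential$domain
  if (any(centers < dom[1] | centers > dom[2]))
    stop("all centers must lie within the potential domain")
  W <- length(centers)
  rt <- kT_kj(temperature)
  energy <- function(x) {
    potential$fun(x) + 0.5 * force_constant * (x - centers)^2
  }
  with_seed(seed, {
    x <- centers
    e <- energy(x)
    # guess a step from the bias curvature; flat bias -> domain-scaled step
    step <- rep(if (force_constant > 0) 2 * sqrt(rt / force_constant)
                else (dom[2] - dom[1]) / 4, W)
    # burn-in with step adaptation in chunks
    n_chunks <- 20
    chunk <- max(1, ceiling(burn_in / n_chunks))
    for (ch in seq_len(n_chunks)) {
      acc <- numeric(W)
      for (it in seq_len(chunk)) {
        prop <- x + stats::runif(W, -1, 1) * step
        ok <- prop >= dom[1] & prop <= dom[2]
        ep <- e
        ep[ok] <- energy(prop)[ok]
        accept <- ok & (log(stats::runif(W)) < (e - ep) / rt)
        x[accept] <- prop[accept]
        e[accept] <- ep[accept]
        acc <- acc + accept
      }
      rate <- acc / chunk
      step <- step * ifelse(rate > 0.45, 1.25, ifelse(rate < 0.35, 0.8, 1))
    }
    # production
    total <- n_samples * stride
    out <- matrix(NA_real_, nrow = n_samples, ncol = W)
    acc <- numeric(W)
    kept <- 0
    for (it in seq_len(total)) {
      prop <- x + stats::runif(W, -1, 1) * step
      ok <- prop >= dom[1] & prop <= dom[2]
      ep <- e
      ep[ok] <- energy(prop)[ok]
      accept <- ok & (log(stats::runif(W)) < (e - ep) / rt)
      x[accept] <- prop[accept]
      e[accept] <- ep[accept]
      acc <- acc + accept
      if (it %% stride == 0) {
        kept <- kept + 1
        out[kept, ] <- x
      }
    }
    rate <- acc / total
    if (any(rate <= 0.05 | rate >= 0.95))
      warning(sprintf(
        "Metropolis acceptance rate outside (0.05, 0.95) in %d window(s); ",
        sum(rate <= 0.05 | rate >= 0.95)),
        "consider adjusting the proposal step")
    windows <- lapply(seq_len(W), function(i) {
      umbrella_window(center = centers[i], force_constant = force_constant,
                      temperature = temperature, samples = out[, i])
    })
    attr(windows, "potential") <- potential
    windows
  })
}

#' Lambda schedule for an alchemical leg
#'
#' @param values Nondecreasing lambda points; must start at 0 and end at 1
#'   within each phase.
#' @param phase Optional per-point phase labels (e.g. `"mass"` vs `"vdw"`).
#' @return A `lambda_schedule` object.
#' @examples
#' # 29-window decoupling schedule: 0.05 steps to lambda = 0.6, then coarser
#' lambda_schedule(c(seq(0, 0.6, by = 0.05), seq(0.625, 1, by = 0.025)))
#' @export
lambda_schedule <- function(values, phase = NULL) {
  stopifnot(is.numeric(values), length(values) >= 2)
  if (is.null(phase)) phase <- rep("main", length(values))
  if (length(phase) != length(values)) stop("phase labels must match values")
  for (ph in unique(phase)) {
    v <- values[phase == ph]
    if (any(diff(v) < 0)) stop("lambda values must be nondecreasing")
    if (abs(v[1]) > 1e-12 || abs(v[length(v)] - 1) > 1e-12)
      stop("each phase must start at lambda = 0 and end at lambda = 1")
  }
  structure(list(values = values, phase = phase), class = "lambda_schedule")
}

#' Generate reduced potentials for a lambda-scaled harmonic system
#'
#' Each lambda state k is a 1D harmonic oscillator of stiffness `kappa(k)`
#' obtained by geometric interpolation between `kappa0` (lambda = 0) and
#' `kappa1` (lambda = 1). Samples are drawn exactly from each state's
#' Boltzmann (Gaussian) distribution and the reduced potential is evaluated at
#' every state, giving a complete MBAR input with the closed-form end-to-end
#' free energy attached: dG = (RT/2) ln(kappa1/kappa0).
#'
#' @param schedule A [lambda_schedule].
#' @param kappa0,kappa1 End-state stiffnesses (kJ mol^-1 nm^-2, > 0).
#' @param n_per_state Samples drawn from each state.
#' @param temperature Temperature (K).
#' @param seed Integer seed.
#' @return A [reduced_potential_matrix] with attributes `"analytic_dg"`
#'   (kJ mol^-1, state 1 -> state K) and `"analytic_dg_per_state"`.
#' @export
gen_reduced_potentials <- function(schedule, kappa0 = 500, kappa1 = 2000,
                                   n_per_state = 1000, temperature = 323,
                                   seed = 1) {
  stopifnot(inherits(schedule, "lambda_schedule"))
  if (kappa0 <= 0 || kappa1 <= 0)
    stop("end-state stiffnesses must be positive")
  lam <- schedule$values
  K <- length(lam)
  kap <- kappa0 * (kappa1 / kappa0)^lam
  if (any(kap <= 0)) stop("interior stiffness must stay positive")
  rt <- kT_kj(temperature)
  with_seed(seed, {
    xs <- unlist(lapply(kap, function(kk)
      stats::rnorm(n_per_state, 0, sqrt(rt / kk))))
    # u[k, n]: reduced potential of sample n at state k
    u <- outer(kap, xs^2) * (0.5 / rt)
    m <- reduced_potential_matrix(u, n_k = rep(n_per_state, K),
                                  temperature = temperature)
    attr(m, "analytic_dg") <- (rt / 2) * log(kap[K] / kap[1])
    attr(m, "analytic_dg_per_state") <- (rt / 2) * log(kap / kap[1])
    attr(m, "lambda") <- lam
    m
  })
}

#' Specification of a toy membrane-protein trajectory
#'
#' Defines a planted scene used by [gen_toy_trajectory]: a periodic box, bulk
#' waters, an ion following a parametric approach-and-bind path towards a
#' target site, and two helix scaffolds whose axial separation follows a
#' prescribed schedule (emulating ion-induced pinching of intracellular helix
#' ends).
#'
#' @param n_frames Number of frames (> 0).
#' @param box Length-3 box dimensions (nm).
#' @param n_waters Number of water oxygens placed uniformly in the box.
#' @param ion_target Length-3 binding-site position (nm).
#' @param ion_bound_frames Integer vector of frames (1-based) in which the ion
#'   sits within `ion_bind_radius` of the target; elsewhere it is placed far
#'   from it.
#' @param ion_bind_radius Displacement of the bound ion from the target (nm).
#' @param helix_sep Numeric vector (length `n_frames`) of inter-axis distances
#'   (nm) between the two helix scaffolds.
#' @param jitter Uniform placement jitter (nm) applied to waters only.
#' @return A `toy_trajectory_spec` object.
#' @export
toy_trajectory_spec <- function(n_frames = 15, box = c(10, 10, 10),
                                n_waters = 50,
                                ion_target = c(5, 5, 5),
                                ion_bound_frames = seq_len(14),
                                ion_bind_radius = 0.2,
                                helix_sep = NULL,
                                jitter = 0.02) {
  stopifnot(n_frames >= 1, n_waters >= 0, length(box) == 3, all(box > 0))
  if (is.null(helix_sep)) helix_sep <- rep(1.0, n_frames)
  if (length(helix_sep) != n_frames)
    stop("helix_sep must have one value per frame")
  if (any(ion_target < 0 | ion_target > box))
    stop("ion path must lie within the box")
  structure(list(n_frames = n_frames, box = box, n_waters = n_waters,
                 ion_target = ion_target, ion_bound_frames = ion_bound_frames,
                 ion_bind_radius = ion_bind_radius, helix_sep = helix_sep,
                 jitter = jitter),
            class = "toy_trajectory_spec")
}

#' Generate a toy trajectory with planted ground truth
#'
#' Builds a multi-frame coordinate set containing two 5-residue helix
#' scaffolds (CA atoms only, residues 1-5 and 101-105 on chains A and B), a
#' single Na+ ion on an approach-and-bind path, a binding-site probe residue
#' (ASP 50, one CA at the target site), and bulk water oxygens. Ground truth
#' sufficient to assert every geometry operation is attached.
#'
#' @param spec A [toy_trajectory_spec].
#' @param seed Integer seed.
#' @return A [trajectory] with attribute `"truth"`: a list holding the planted
#'   per-frame ion-target contact flags, expected contact fraction (%), the
#'   helix-separation schedule, and water positions.
#' @export
gen_toy_trajectory <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "toy_trajectory_spec"))
  nf <- spec$n_frames
  box <- spec$box
  with_seed(seed, {
    centre <- box / 2
    # helix scaffolds: 5 CA atoms each, axes along z, separated along x
    z_off <- seq(-0.6, 0.6, length.out = 5)
    frames <- vector("list", nf)
    bound <- seq_len(nf) %in% spec$ion_bound_frames
    waters0 <- if (spec$n_waters > 0)
      cbind(stats::runif(spec$n_waters, 0, box[1]),
            stats::runif(spec$n_waters, 0, box[2]),
            stats::runif(spec$n_waters, 0, box[3]))
    else matrix(numeric(0), ncol = 3)
    far_point <- pmin(spec$ion_target + c(3, 3, 3), box - 0.5)
    for (f in seq_len(nf)) {
      sep <- spec$helix_sep[f]
      helixA <- cbind(centre[1] - sep / 2, centre[2], centre[3] + z_off)
      helixB <- cbind(centre[1] + sep / 2, centre[2], centre[3] + z_off)
      site <- matrix(spec$ion_target, nrow = 1)
      ion <- if (bound[f]) spec$ion_target + c(spec$ion_bind_radius, 0, 0)
             else far_point
      waters <- waters0
      if (spec$n_waters > 0) {
        waters <- waters + matrix(stats::runif(3 * spec$n_waters,
                                               -spec$jitter, spec$jitter),
                                  ncol = 3)
        waters <- sweep(waters, 2, box, function(p, b) p %% b)
      }
      frames[[f]] <- rbind(helixA, helixB, site, matrix(ion, nrow = 1),
                           waters)
    }
    atoms <- data.frame(
      name = c(rep("CA", 11), "NA", rep("OW", spec$n_waters)),
      resid = c(1:5, 101:105, 50L, 200L,
                if (spec$n_waters > 0) 300L + seq_len(spec$n_waters)),
      resname = c(rep("ALA", 10), "ASP", "NA",
                  rep("SOL", spec$n_waters)),
      chain = c(rep("A", 5), rep("B", 5), "A", "I",
                rep("W", spec$n_waters)),
      element = c(rep("C", 11), "Na", rep("O", spec$n_waters)),
      stringsAsFactors = FALSE
    )
    traj <- trajectory(frames, atoms, box = box, times = seq_len(nf) - 1)
    attr(traj, "truth") <- list(
      ion_bound = bound,
      contact_fraction = 100 * mean(bound),
      helix_sep = spec$helix_sep,
      n_waters = spec$n_waters,
      ion_target = spec$ion_target
    )
    traj
  })
}
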