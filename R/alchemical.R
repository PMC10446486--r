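#' Alchemical free-energy estimation
#'
#' Free energies of alchemical legs (decoupling a ligand over a lambda
#' schedule, or perturbing one ion into another) are estimated from
#' reduced-potential sample matrices. The multistate Bennett acceptance ratio
#' (MBAR) is the primary estimator; the pairwise Bennett acceptance ratio
#' (BAR) and exponential averaging are available as cross-checks. Estimators
#' work in reduced (dimensionless) units internally and report kJ mol^-1.
#'
#' @name alchemical
NULL

#' Reduced-potential sample matrix
#'
#' Container for MBAR input: `u[k, n]` is the reduced (dimensionless)
#' potential of pooled sample n evaluated at state k. Samples are ordered by
#' origin state: the first `n_k[1]` columns were drawn from state 1, and so
#' on.
#'
#' @param u Numeric K x N matrix of reduced potentials, all finite, K >= 2.
#' @param n_k Integer vector of per-state sample counts, summing to N.
#' @param temperature Temperature (K) used to convert to kJ mol^-1.
#' @return A `reduced_potential_matrix` object.
#' @export
reduced_potential_matrix <- function(u, n_k, temperature) {
  u <- as.matrix(u)
  if (nrow(u) < 2) stop("at least two states are required")
  if (!all(is.finite(u))) stop("all reduced potentials must be finite")
  if (length(n_k) != nrow(u)) stop("n_k must have one entry per state")
  if (sum(n_k) != ncol(u))
    stop("per-state sample counts must sum to the number of samples")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(u = u, n_k = as.numeric(n_k), temperature = temperature),
            class = "reduced_potential_matrix")
}

# drop the first `fraction` of each state's own samples (equilibration)
discard_initial <- function(m, fraction) {
  if (fraction <= 0) return(m)
  if (fraction >= 1) stop("discard fraction must be < 1")
  ends <- cumsum(m$n_k)
  starts <- c(1, utils::head(ends, -1) + 1)
  keep <- unlist(lapply(seq_along(m$n_k), function(k) {
    idx <- starts[k]:ends[k]
    idx[-seq_len(floor(fraction * length(idx)))]
  }))
  reduced_potential_matrix(m$u[, keep, drop = FALSE],
                           vapply(seq_along(m$n_k), function(k)
                             m$n_k[k] - floor(fraction * m$n_k[k]),
                             numeric(1)),
                           m$temperature)
}

# column-wise log-sum-exp of (log_nk + f - u)
mbar_log_denom <- function(u, f, log_nk) {
  a <- (f + log_nk) - u               # K x N, recycled by column
  amax <- apply(a, 2, max)
  amax + log(colSums(exp(sweep(a, 2, amax))))
}

#' Estimate per-state free energies with MBAR
#'
#' Solves the self-consistent MBAR equations for the reduced free energies of
#' all states, anchored at state 1 = 0. The solution is found by quasi-Newton
#' minimisation of the MBAR objective followed by self-consistent polishing to
#' `tolerance`; asymptotic errors come from the covariance of the weight
#' matrix.
#'
#' @param matrix A [reduced_potential_matrix].
#' @param tolerance Convergence tolerance on the maximum change of the reduced
#'   free energies; default 1e-8.
#' @param max_iterations Self-consistent iteration cap.
#' @param discard_fraction Fraction of each state's initial samples discarded
#'   as equilibration before estimation (default 0; alchemical production legs
#'   conventionally discard ~4%).
#' @param overlap_warn Warn when the smallest adjacent-state overlap-matrix
#'   element falls below this value (default 0.03).
#' @return An `mbar_result`: `free_energies` and `errors` (kJ mol^-1 relative
#'   to state 1), `delta_g` (end-to-end [free_energy]), `contributions`
#'   (per-interval kJ mol^-1, summing to `delta_g$value`), `overlap` (K x K
#'   overlap matrix), `min_adjacent_overlap`, `residual`, `iterations`.
#' @export
estimate_mbar <- function(matrix, tolerance = 1e-8, max_iterations = 10000,
                          discard_fraction = 0, overlap_warn = 0.03) {
  stopifnot(inherits(matrix, "reduced_potential_matrix"))
  m <- discard_initial(matrix, discard_fraction)
  u <- m$u
  n_k <- m$n_k
  if (any(n_k <= 0)) stop("every state must contribute samples")
  K <- nrow(u); N <- ncol(u)
  log_nk <- log(n_k)
  rt <- kT_kj(m$temperature)

  obj <- function(f) {
    f <- c(0, f)
    sum(mbar_log_denom(u, f, log_nk)) - sum(n_k * f)
  }
  grad <- function(f) {
    f <- c(0, f)
    d <- mbar_log_denom(u, f, log_nk)
    # expected counts under current f
    ec <- vapply(seq_len(K), function(k)
      sum(exp(f[k] + log_nk[k] - u[k, ] - d)), numeric(1))
    (ec - n_k)[-1]
  }
  f <- numeric(K - 1)
  if (K > 1) {
    opt <- stats::optim(f, obj, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    f <- opt$par
  }
  f_full <- c(0, f)
  resid <- Inf; iter <- 0
  while (iter < max_iterations) {
    iter <- iter + 1
    d <- mbar_log_denom(u, f_full, log_nk)
    f_new <- -vapply(seq_len(K), function(k)
      logsumexp(-u[k, ] - d), numeric(1))
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f_full))
    f_full <- f_new
    if (resid < tolerance) break
  }
  if (resid >= tolerance)
    stop(sprintf("MBAR did not converge (residual %.3g after %d iterations)",
                 resid, iter))
  d <- mbar_log_denom(u, f_full, log_nk)
  W <- t(exp(sweep(-u, 2, d) + f_full))        # N x K weight matrix
  # covariance by eigendecomposition of W'W (svd-ew scheme)
  O <- crossprod(W)
  eig <- eigen(O, symmetric = TRUE)
  S <- sqrt(pmax(eig$values, 0))
  V <- eig$vectors
  inner <- diag(K) - (S * t(V)) %*% (n_k * V) %*% diag(S, K)
  inner_inv <- tryCatch(solve(inner), error = function(e) {
    sv <- svd(inner)
    keep <- sv$d > max(sv$d) * 1e-10
    sv$v[, keep, drop = FALSE] %*% diag(1 / sv$d[keep],
      sum(keep)) %*% t(sv$u[, keep, drop = FALSE])
  })
  Theta <- V %*% diag(S, K) %*% inner_inv %*% diag(S, K) %*% t(V)
  var_f <- pmax(diag(Theta) + Theta[1, 1] - 2 * Theta[1, ], 0)
  overlap <- sweep(crossprod(W), 2, n_k, `*`)
  adj <- if (K >= 2) overlap[cbind(seq_len(K - 1), 2:K)] else numeric(0)
  if (length(adj) && min(adj) < overlap_warn)
    warning(sprintf("low phase-space overlap between adjacent states (min %.3f)",
                    min(adj)))
  fe <- f_full * rt
  err <- sqrt(var_f) * rt
  var_end <- max(Theta[K, K] + Theta[1, 1] - 2 * Theta[1, K], 0)
  structure(list(
    free_energies = fe, errors = err,
    f_reduced = f_full,
    delta_g = free_energy(fe[K], sqrt(var_end) * rt,
                          from = "state1", to = paste0("state", K),
                          label = "MBAR"),
    contributions = diff(fe),
    overlap = overlap, min_adjacent_overlap =
      if (length(adj)) min(adj) else NA_real_,
    residual = resid, iterations = iter,
    temperature = m$temperature
  ), class = "mbar_result")
}

#' @export
print.mbar_result <- function(x, ...) {
  cat(sprintf("<mbar_result> %d states; dG = %+.4f +/- %.4f kJ/mol (min adjacent overlap %.3f)\n",
              length(x$free_energies), x$delta_g$value, x$delta_g$error,
              x$min_adjacent_overlap))
  invisible(x)
}

#' Bennett acceptance ratio for one adjacent state pair
#'
#' Solves the Bennett self-consistency equation for the reduced free-energy
#' difference between two states given forward work values (u_1 - u_0 on
#' samples from state 0) and reverse work values (u_0 - u_1 on samples from
#' state 1). Antisymmetric under state swap.
#'
#' @param w_forward,w_reverse Reduced work values.
#' @param temperature Temperature (K).
#' @param tolerance Root-finding tolerance (reduced units).
#' @return A `bar_result` list: `delta_g` ([free_energy], kJ mol^-1), reduced
#'   `df`, and its asymptotic `error`.
#' @export
estimate_bar <- function(w_forward, w_reverse, temperature,
                         tolerance = 1e-10) {
  stopifnot(length(w_forward) >= 1, length(w_reverse) >= 1,
            all(is.finite(w_forward)), all(is.finite(w_reverse)))
  n_f <- length(w_forward); n_r <- length(w_reverse)
  M <- log(n_f / n_r)
  fermi <- function(t) 1 / (1 + exp(t))
  g <- function(df)
    log(sum(fermi(M + w_forward - df))) - log(sum(fermi(-M + w_reverse + df)))
  # bracket from the two exponential-averaging estimates
  df_f <- -(logsumexp(-w_forward) - log(n_f))
  df_r <- (logsumexp(-w_reverse) - log(n_r))
  lo <- min(df_f, df_r) - 10
  hi <- max(df_f, df_r) + 10
  glo <- g(lo); ghi <- g(hi)
  if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0) {
    if (!is.finite(glo) || !is.finite(ghi))
      stop("BAR diverged: no overlap between the two states")
  }
  df <- stats::uniroot(g, c(lo, hi), extendInt = "yes",
                       tol = tolerance)$root
  fF <- fermi(M + w_forward - df)
  fR <- fermi(-M + w_reverse + df)
  var_df <- (mean(fF^2) / mean(fF)^2 - 1) / n_f +
            (mean(fR^2) / mean(fR)^2 - 1) / n_r
  rt <- kT_kj(temperature)
  structure(list(
    delta_g = free_energy(df * rt, sqrt(max(var_df, 0)) * rt,
                          from = "state0", to = "state1", label = "BAR"),
    df = df, error = sqrt(max(var_df, 0)) * rt), class = "bar_result")
}

#' BAR over an adjacent pair of a reduced-potential matrix
#'
#' @param matrix A [reduced_potential_matrix].
#' @param pair Length-2 integer vector of adjacent state indices (i, i+1).
#' @inheritParams estimate_bar
#' @return A `bar_result` (see [estimate_bar]).
#' @export
estimate_bar_pair <- function(matrix, pair, tolerance = 1e-10) {
  stopifnot(inherits(matrix, "reduced_potential_matrix"), length(pair) == 2)
  i <- pair[1]; j <- pair[2]
  ends <- cumsum(matrix$n_k)
  starts <- c(1, utils::head(ends, -1) + 1)
  idx_i <- starts[i]:ends[i]; idx_j <- starts[j]:ends[j]
  estimate_bar(matrix$u[j, idx_i] - matrix$u[i, idx_i],
               matrix$u[i, idx_j] - matrix$u[j, idx_j],
               matrix$temperature, tolerance)
}

#' Exponential averaging (Zwanzig) free energy
#'
#' One-sided free-energy estimate from forward reduced work values, as a
#' cross-check in the high-overlap limit.
#'
#' @param w_forward Reduced work values (u_target - u_origin on origin
#'   samples).
#' @param temperature Temperature (K).
#' @return Free energy in kJ mol^-1.
#' @export
estimate_exp <- function(w_forward, temperature) {
  stopifnot(all(is.finite(w_forward)))
  -(logsumexp(-w_forward) - log(length(w_forward))) * kT_kj(temperature)
}

fe_value <- function(x) {
  if (inherits(x, "free_energy")) return(x)
  if (inherits(x, "mbar_result")) return(x$delta_g)
  if (inherits(x, "bar_result")) return(x$delta_g)
  if (is.numeric(x) && length(x) == 1) return(free_energy(x, 0))
  if (is.list(x) && !is.null(x$value))
    return(free_energy(x$value, x$error %||% 0))
  stop("cannot interpret a free-energy value from the supplied object")
}

#' Assemble an absolute binding free-energy cycle
#'
#' Combines a site-decoupling leg, a reference (gas-phase/restraint) leg, and
#' any explicit restraint bookkeeping terms into a total binding free energy:
#' `total = site_leg - reference_leg - sum(restraint_terms)`, with all legs
#' expressed in the coupled -> decoupled direction. Errors combine in
#' quadrature. Restraint contributions are accepted only as supplied values;
#' no analytic restraint volumes are computed.
#'
#' @param site_leg,reference_leg Leg values: [free_energy], `mbar_result`,
#'   `bar_result` or numeric.
#' @param restraint_terms Numeric vector or list of leg-like values (default
#'   none).
#' @return An `abfe_cycle`: `total` ([free_energy]) plus the stored legs.
#' @export
combine_abfe <- function(site_leg, reference_leg, restraint_terms = list()) {
  if (missing(site_leg) || missing(reference_leg))
    stop("incomplete cycle: both site and reference legs are required")
  site <- fe_value(site_leg)
  ref <- fe_value(reference_leg)
  if (is.numeric(restraint_terms)) restraint_terms <- as.list(restraint_terms)
  rts <- lapply(restraint_terms, fe_value)
  value <- site$value - ref$value - sum(vapply(rts, `[[`, numeric(1), "value"))
  err <- quadrature_error(c(site$error, ref$error,
                            vapply(rts, `[[`, numeric(1), "error")))
  structure(list(site_leg = site, reference_leg = ref,
                 restraint_terms = rts,
                 total = free_energy(value, err, from = "bound",
                                     to = "unbound", label = "ABFE total")),
            class = "abfe_cycle")
}

#' Relative perturbation cycle (bound vs free legs)
#'
#' The double free-energy difference of perturbing a species in two
#' environments: `ddg = bound_leg - free_leg`, errors in quadrature.
#'
#' @param bound_leg,free_leg Leg values (see [combine_abfe] for accepted
#'   forms).
#' @return A `perturbation_cycle` with field `ddg` (a [free_energy]).
#' @export
perturbation_cycle <- function(bound_leg, free_leg) {
  b <- fe_value(bound_leg); f <- fe_value(free_leg)
  structure(list(bound_leg = b, free_leg = f,
                 ddg = free_energy(b$value - f$value,
                                   quadrature_error(c(b$error, f$error)),
                                   from = "free", to = "bound",
                                   label = "ddG")),
            class = "perturbation_cycle")
}

#' Mean and standard deviation over replicate estimates
#'
#' @param results List (or numeric vector) of at least two replicate leg
#'   values.
#' @return A [free_energy] whose value is the arithmetic mean and whose error
#'   is the sample SD between repeats; attribute `"n"` carries the replicate
#'   count.
#' @export
replicate_statistics <- function(results) {
  if (is.numeric(results)) results <- as.list(results)
  if (length(results) < 2)
    stop("at least two replicates are required for a standard deviation")
  vals <- vapply(results, function(x) fe_value(x)$value, numeric(1))
  out <- free_energy(mean(vals), stats::sd(vals), from = "state1",
                     to = "state2", label = "replicate mean")
  attr(out, "n") <- length(vals)
  out
}

#' Consistency of forward and inverse perturbations
#'
#' For a transformation run in both directions, reports |forward + reverse|
#' (which should vanish: inverse perturbations give values of the same
#' magnitude and opposite sign) and whether the discrepancy lies within the
#' combined error.
#'
#' @param forward,reverse `perturbation_cycle` objects (or [free_energy]s)
#'   describing the same transformation in opposite directions.
#' @return List with `discrepancy`, `combined_error`, and `consistent`.
#' @export
check_inverse_perturbation <- function(forward, reverse) {
  f <- if (inherits(forward, "perturbation_cycle")) forward$ddg
       else fe_value(forward)
  r <- if (inherits(reverse, "perturbation_cycle")) reverse$ddg
       else fe_value(reverse)
  disc <- abs(f$value + r$value)
  err <- quadrature_error(c(f$error, r$error))
  list(discrepancy = disc, combined_error = err,
       consistent = disc <= err)
}
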