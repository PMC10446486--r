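#' Potential-of-mean-force reconstruction by WHAM
#'
#' Umbrella-sampling windows (harmonically biased reaction-coordinate samples)
#' are unbiased into a single free-energy profile with the weighted histogram
#' analysis method: the per-window free-energy constants f_i and the unbiased
#' bin probabilities p_j are iterated to self-consistency,
#'
#'   p_j = (sum_i n_ij) / (sum_i N_i exp((f_i - w_i(x_j)) / RT))
#'   f_i = -RT log( sum_j p_j exp(-w_i(x_j) / RT) )
#'
#' where w_i(x) = 0.5 k_i (x - c_i)^2 is the bias of window i and n_ij its
#' histogram. The profile is -RT log p_j, anchored so its minimum over an
#' anchor region (default: the last 10% of the coordinate range, normally an
#' unbound plateau) is zero.
#'
#' @name umbrella_pmf
NULL

#' PMF profile container
#'
#' @param bin_centers Strictly increasing bin centres (nm).
#' @param free_energy Per-bin free energies (kJ mol^-1); `NaN` marks bins with
#'   no samples (never interpolated).
#' @param error Per-bin nonnegative errors (kJ mol^-1).
#' @param sample_counts Pooled per-bin sample counts.
#' @param anchor_region Length-2 interval over which the profile minimum is
#'   zeroed.
#' @return A `pmf_profile` object.
#' @export
pmf_profile <- function(bin_centers, free_energy, error = NULL,
                        sample_counts = NULL, anchor_region = NULL) {
  n <- length(bin_centers)
  if (is.null(error)) error <- rep(0, n)
  if (is.null(sample_counts)) sample_counts <- rep(NA_real_, n)
  stopifnot(length(free_energy) == n, length(error) == n,
            length(sample_counts) == n)
  if (any(diff(bin_centers) <= 0))
    stop("bin_centers must be strictly increasing")
  if (any(error < 0, na.rm = TRUE)) stop("errors must be nonnegative")
  structure(list(bin_centers = bin_centers, free_energy = free_energy,
                 error = error, sample_counts = sample_counts,
                 anchor_region = anchor_region),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  ok <- is.finite(x$free_energy)
  cat(sprintf(
    "<pmf_profile> %d bins over [%.3f, %.3f] nm (%d empty); range %.2f kJ/mol\n",
    length(x$bin_centers), min(x$bin_centers), max(x$bin_centers), sum(!ok),
    if (any(ok)) diff(range(x$free_energy[ok])) else NA_real_))
  invisible(x)
}

#' @export
as.data.frame.pmf_profile <- function(x, ...) {
  data.frame(bin_center = x$bin_centers, free_energy = x$free_energy,
             error = x$error, count = x$sample_counts)
}

# anchor so min over anchor_region (or global min) is zero; returns profile
anchor_profile <- function(fe, bin_centers, anchor_region) {
  ok <- is.finite(fe)
  sel <- ok
  if (!is.null(anchor_region))
    sel <- ok & bin_centers >= anchor_region[1] & bin_centers <= anchor_region[2]
  if (!any(sel)) sel <- ok
  fe - min(fe[sel])
}

# core WHAM solver on precomputed histograms.
# n_ij: W x B counts; bias_red: W x B reduced bias energies w_i(x_j)/RT;
# returns list(p, g, iterations, residual, converged)
wham_core <- function(n_ij, bias_red, rt, tolerance, max_iterations,
                      g_init = NULL) {
  W <- nrow(n_ij); B <- ncol(n_ij)
  N_i <- rowSums(n_ij)
  n_j <- colSums(n_ij)
  cmat <- exp(-bias_red)                       # W x B
  g <- if (is.null(g_init)) numeric(W) else g_init
  resid <- Inf
  iter <- 0
  while (iter < max_iterations) {
    iter <- iter + 1
    denom <- colSums((N_i * exp(g)) * cmat)    # length B
    p <- ifelse(denom > 0, n_j / denom, 0)
    s <- sum(p)
    if (s <= 0) stop("WHAM degenerate: all bins empty")
    p <- p / s
    g_new <- -log(pmax(cmat %*% p, .Machine$double.xmin))[, 1]
    g_new <- g_new - g_new[1]
    resid <- max(abs(g_new - g)) * rt          # kJ/mol
    g <- g_new
    if (resid < tolerance) break
  }
  list(p = p, g = g, iterations = iter, residual = resid,
       converged = resid < tolerance)
}

# shared set-up: histogram windows on a common grid
wham_setup <- function(windows, n_bins, range = NULL) {
  stopifnot(length(windows) >= 1)
  temps <- vapply(windows, `[[`, numeric(1), "temperature")
  if (diff(range(temps)) > 1e-9)
    stop("all windows must share a temperature")
  samples <- lapply(windows, window_samples)
  if (is.null(range)) range <- range(unlist(samples))
  if (diff(range) <= 0) stop("pooled samples must span a nonzero range")
  breaks <- seq(range[1], range[2], length.out = n_bins + 1)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  n_ij <- t(vapply(samples, function(s) {
    s <- pmin(pmax(s, range[1]), range[2])
    tabulate(findInterval(s, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = n_bins)
  }, numeric(n_bins)))
  if (sum(colSums(n_ij) > 0) < 2)
    stop("pooled samples must span more than one bin")
  rt <- kT_kj(temps[1])
  bias_red <- t(vapply(windows, function(w)
    0.5 * w$force_constant * (centers - w$center)^2 / rt,
    numeric(n_bins)))
  list(n_ij = n_ij, bias_red = bias_red, centers = centers, rt = rt,
       range = range)
}

# pairwise histogram overlap between windows adjacent in centre order
window_overlaps <- function(n_ij, centers_of_windows) {
  ord <- order(centers_of_windows)
  p <- n_ij / pmax(rowSums(n_ij), 1)
  W <- nrow(n_ij)
  if (W < 2) return(numeric(0))
  ov <- vapply(seq_len(W - 1), function(i)
    sum(pmin(p[ord[i], ], p[ord[i + 1], ])), numeric(1))
  names(ov) <- paste0(ord[-W], "-", ord[-1])
  ov
}

#' Solve WHAM for a set of umbrella windows
#'
#' @param windows List of [umbrella_window] objects sharing a temperature.
#' @param n_bins Number of histogram bins over the sampled range; default 200.
#' @param tolerance Convergence tolerance on the maximum change in window
#'   free-energy constants (kJ mol^-1); default 1e-6.
#' @param max_iterations Iteration cap; non-convergence is an error carrying
#'   the last residual.
#' @param anchor_region Length-2 interval (nm) over which the profile minimum
#'   is zeroed; default the last 10% of the sampled range.
#' @param range Optional fixed coordinate range (nm) for the bins; default the
#'   pooled sample range.
#' @param window_weights Optional nonnegative per-window weights (used by the
#'   Bayesian bootstrap); default all 1.
#' @param g_init Optional warm-start reduced window constants.
#' @return A [pmf_profile] with extra fields `iterations`, `residual`,
#'   `window_constants` (kJ mol^-1) and `overlap` (adjacent-window histogram
#'   overlap diagnostic; a warning is raised if any pair has none).
#' @export
solve_wham <- function(windows, n_bins = 200, tolerance = 1e-6,
                       max_iterations = 1e5, anchor_region = NULL,
                       range = NULL, window_weights = NULL, g_init = NULL) {
  setup <- wham_setup(windows, n_bins, range)
  n_ij <- setup$n_ij
  if (!is.null(window_weights)) {
    stopifnot(length(window_weights) == length(windows),
              all(window_weights >= 0))
    n_ij <- n_ij * window_weights
  }
  centers_w <- vapply(windows, `[[`, numeric(1), "center")
  ov <- window_overlaps(n_ij, centers_w)
  if (length(ov) && any(ov == 0))
    warning("zero histogram overlap between ", sum(ov == 0),
            " adjacent window pair(s); the profile may be disconnected")
  sol <- wham_core(n_ij, setup$bias_red, setup$rt, tolerance, max_iterations,
                   g_init)
  if (!sol$converged)
    stop(sprintf(
      "WHAM did not converge within %d iterations (last residual %.3g kJ/mol)",
      as.integer(max_iterations), sol$residual))
  counts <- colSums(n_ij)
  fe <- ifelse(counts > 0 & sol$p > 0, -setup$rt * log(sol$p), NaN)
  if (is.null(anchor_region)) {
    r <- setup$range
    anchor_region <- c(r[2] - 0.1 * diff(r), r[2])
  }
  fe <- anchor_profile(fe, setup$centers, anchor_region)
  prof <- pmf_profile(setup$centers, fe, sample_counts = counts,
                      anchor_region = anchor_region)
  prof$iterations <- sol$iterations
  prof$residual <- sol$residual
  prof$window_constants <- sol$g * setup$rt
  prof$g <- sol$g
  prof$overlap <- ov
  prof
}

#' Bayesian-bootstrap errors for a WHAM profile
#'
#' Re-solves WHAM `n_rounds` times under random re-weightings of the data and
#' reports the per-bin standard deviation of the anchored profiles. The
#' default scheme (`method = "bayesian"`) draws Dirichlet(1, ..., 1) weights
#' over complete windows, re-weighting whole histograms — the
#' complete-histogram Bayesian bootstrap. `method = "samples"` instead
#' resamples data points within each window (multinomial bootstrap of the
#' histogram counts).
#'
#' @inheritParams solve_wham
#' @param n_rounds Number of bootstrap rounds (>= 2); 2000 is the conventional
#'   choice for production profiles.
#' @param seed Integer seed; results are deterministic given it.
#' @param method `"bayesian"` (Dirichlet window weights) or `"samples"`.
#' @return Numeric vector of per-bin standard deviations (kJ mol^-1), `NaN`
#'   where the full-data profile is undefined. Attribute `"profile"` carries
#'   the full-data [pmf_profile] with its `error` field filled in.
#' @export
bootstrap_pmf <- function(windows, n_rounds = 200, seed = 1, n_bins = 200,
                          tolerance = 1e-6, max_iterations = 1e5,
                          anchor_region = NULL, range = NULL,
                          method = c("bayesian", "samples")) {
  method <- match.arg(method)
  if (n_rounds < 2) stop("n_rounds must be at least 2")
  full <- solve_wham(windows, n_bins = n_bins, tolerance = tolerance,
                     max_iterations = max_iterations,
                     anchor_region = anchor_region, range = range)
  setup <- wham_setup(windows, n_bins, range %||% range(unlist(
    lapply(windows, window_samples))))
  W <- length(windows)
  B <- n_bins
  profs <- matrix(NA_real_, nrow = n_rounds, ncol = B)
  with_seed(seed, {
    for (r in seq_len(n_rounds)) {
      if (method == "bayesian") {
        wts <- stats::rgamma(W, shape = 1)
        wts <- wts / sum(wts) * W
        n_ij <- setup$n_ij * wts
      } else {
        n_ij <- t(vapply(seq_len(W), function(i) {
          row <- setup$n_ij[i, ]
          n <- sum(row)
          if (n == 0) return(row)
          as.numeric(stats::rmultinom(1, n, prob = row / n))
        }, numeric(B)))
      }
      sol <- wham_core(n_ij, setup$bias_red, setup$rt, tolerance,
                       max_iterations, g_init = full$g)
      fe <- ifelse(colSums(n_ij) > 0 & sol$p > 0, -setup$rt * log(sol$p), NaN)
      profs[r, ] <- anchor_profile(fe, setup$centers, full$anchor_region)
    }
  })
  err <- apply(profs, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) < 2) NaN else stats::sd(col)
  })
  err[!is.finite(full$free_energy)] <- NaN
  full$error <- err
  structure(err, profile = full)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binding free energy from a PMF profile
#'
#' The free-energy difference between the deepest point of a bound region and
#' the mean level of a reference region (typically an unbound plateau), with
#' the error of the minimum bin and of the reference mean combined in
#' quadrature. Direction is reference -> bound.
#'
#' @param profile A [pmf_profile].
#' @param bound_region,reference_region Length-2 intervals (nm) that intersect
#'   the profile's bins.
#' @return A [free_energy], `from = "reference"`, `to = "bound"`.
#' @export
binding_free_energy <- function(profile, bound_region, reference_region) {
  stopifnot(inherits(profile, "pmf_profile"))
  x <- profile$bin_centers
  fe <- profile$free_energy
  in_b <- x >= bound_region[1] & x <= bound_region[2] & is.finite(fe)
  in_r <- x >= reference_region[1] & x <= reference_region[2] & is.finite(fe)
  if (!any(in_b) || !any(in_r))
    stop("region does not intersect any defined profile bin")
  i_min <- which(in_b)[which.min(fe[in_b])]
  ref_mean <- mean(fe[in_r])
  err_min <- profile$error[i_min]
  err_ref <- sqrt(sum(profile$error[in_r]^2, na.rm = TRUE)) / sum(in_r)
  if (!is.finite(err_min)) err_min <- 0
  free_energy(fe[i_min] - ref_mean,
              quadrature_error(c(err_min, err_ref)),
              from = "reference", to = "bound", label = "PMF binding")
}

#' Barrier height of a PMF profile
#'
#' Height of the highest point inside a search interval above the profile's
#' global minimum. Taking a raw max/min over bins is upward-biased by per-bin
#' noise, so each extremum is estimated by a local quadratic fit over
#' `fit_halfwidth` bins on either side of the extremal bin (set
#' `fit_halfwidth = 0` for the raw bin values).
#'
#' @param profile A [pmf_profile].
#' @param between Optional length-2 interval (nm) bounding the barrier search.
#' @param fit_halfwidth Bins on each side of an extremum used in the local
#'   quadratic fit; default 5.
#' @return Barrier height in kJ mol^-1.
#' @export
profile_barrier <- function(profile, between = NULL, fit_halfwidth = 5) {
  x <- profile$bin_centers
  fe <- profile$free_energy
  ok <- is.finite(fe)
  if (is.null(between)) between <- range(x[ok])
  sel <- ok & x >= between[1] & x <= between[2]
  if (!any(sel)) stop("no defined bins inside the search interval")
  local_extremum <- function(idx_set, which_fun) {
    i0 <- idx_set[which_fun(fe[idx_set])]
    if (fit_halfwidth == 0) return(fe[i0])
    nb <- which(ok & abs(seq_along(x) - i0) <= fit_halfwidth)
    if (length(nb) < 4) return(fe[i0])
    fit <- stats::lm(fe[nb] ~ stats::poly(x[nb], 2, raw = TRUE))
    cf <- stats::coef(fit)
    vx <- -cf[2] / (2 * cf[3])
    if (!is.finite(vx) || vx < min(x[nb]) || vx > max(x[nb])) vx <- x[i0]
    as.numeric(cf[1] + cf[2] * vx + cf[3] * vx^2)
  }
  peak <- local_extremum(which(sel), which.max)
  base <- local_extremum(which(ok), which.min)
  peak - base
}

#' Convergence of the profile over cumulative time blocks
#'
#' Recomputes the profile on cumulative time prefixes of every window
#' (1/b, 2/b, ..., b/b of each window's sampling time) on a fixed bin grid and
#' reports the maximum absolute change between the last two prefixes.
#'
#' @inheritParams solve_wham
#' @param time_blocks Number of cumulative prefixes (>= 2).
#' @return List with `profiles` (list of [pmf_profile]) and
#'   `max_delta` (kJ mol^-1 between the final two prefixes, over bins defined
#'   in both).
#' @export
convergence_series <- function(windows, time_blocks, n_bins = 200,
                               tolerance = 1e-6, max_iterations = 1e5,
                               anchor_region = NULL) {
  if (time_blocks < 2) stop("time_blocks must be at least 2")
  if (any(vapply(windows, function(w) length(window_samples(w)),
                 numeric(1)) < time_blocks))
    stop("each window needs at least as many samples as time blocks")
  full_range <- range(unlist(lapply(windows, window_samples)))
  profiles <- lapply(seq_len(time_blocks), function(b) {
    sub <- lapply(windows, function(w) {
      keep <- w$times > w$equilibration_cutoff
      t_kept <- w$times[keep]; s_kept <- w$samples[keep]
      cutoff <- min(t_kept) + (max(t_kept) - min(t_kept)) * b / time_blocks
      idx <- t_kept <= cutoff
      umbrella_window(w$center, w$force_constant, w$temperature,
                      s_kept[idx], times = t_kept[idx])
    })
    solve_wham(sub, n_bins = n_bins, tolerance = tolerance,
               max_iterations = max_iterations, anchor_region = anchor_region,
               range = full_range)
  })
  last <- profiles[[time_blocks]]$free_energy
  prev <- profiles[[time_blocks - 1]]$free_energy
  both <- is.finite(last) & is.finite(prev)
  list(profiles = profiles,
       max_delta = if (any(both)) max(abs(last[both] - prev[both])) else NaN)
}
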