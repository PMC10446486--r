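test_that("unbiased sampling of a flat potential yields a flat profile", {
  w <- gen_umbrella_windows(potential_flat(), centers = 0.5,
                            force_constant = 0, n_samples = 3000,
                            temperature = 323, seed = 3, stride = 20)
  prof <- solve_wham(w, n_bins = 20, anchor_region = c(0, 1))
  fe <- prof$free_energy[is.finite(prof$free_energy)]
  # anchored to its minimum, so the max is the full sampling-noise spread
  expect_true(length(fe) >= 15)
  expect_lt(max(fe), 1.2)
})

test_that("WHAM recovers a harmonic landscape from biased windows", {
  w <- fixture_harmonic_windows()
  prof <- solve_wham(w, range = c(0, 1))
  pot <- attr(w, "potential")
  ok <- is.finite(prof$free_energy)
  sel <- ok & prof$bin_centers >= 0.1 & prof$bin_centers <= 0.9
  ua <- pot$fun(prof$bin_centers[sel])
  resid <- prof$free_energy[sel] - ua
  rmse <- sqrt(mean((resid - mean(resid))^2))
  expect_lt(rmse, 1)
  expect_gt(prof$iterations, 1)
  expect_true(all(prof$overlap > 0))
})

test_that("re-anchoring changes the profile by a constant only", {
  w <- fixture_harmonic_windows()
  p1 <- solve_wham(w, range = c(0, 1), anchor_region = c(0.0, 0.2))
  p2 <- solve_wham(w, range = c(0, 1), anchor_region = c(0.8, 1.0))
  ok <- is.finite(p1$free_energy) & is.finite(p2$free_energy)
  d <- p1$free_energy[ok] - p2$free_energy[ok]
  expect_lt(diff(range(d)), 1e-8)
})

test_that("non-convergence and degenerate inputs raise informative errors", {
  w <- fixture_harmonic_windows()
  expect_error(solve_wham(w, max_iterations = 2), "did not converge")
  one <- umbrella_window(0.5, 1000, 323, rep(0.5, 10))
  expect_error(solve_wham(list(one)), "more than one bin|nonzero range")
  mixed <- list(umbrella_window(0.2, 1000, 300, runif(50)),
                umbrella_window(0.4, 1000, 320, runif(50)))
  expect_error(solve_wham(mixed), "share a temperature")
})

test_that("disjoint windows trigger an overlap warning", {
  w <- list(umbrella_window(0.1, 1000, 323, runif(200, 0.0, 0.2)),
            umbrella_window(0.9, 1000, 323, runif(200, 0.8, 1.0)))
  expect_warning(solve_wham(w, n_bins = 50), "overlap")
})

test_that("interior empty bins are flagged, never interpolated", {
  w <- list(umbrella_window(0.1, 1000, 323, runif(300, 0.0, 0.2)),
            umbrella_window(0.9, 1000, 323, runif(300, 0.8, 1.0)))
  prof <- suppressWarnings(solve_wham(w, n_bins = 50))
  mid <- prof$bin_centers > 0.3 & prof$bin_centers < 0.7
  expect_true(all(is.nan(prof$free_energy[mid])))
})

test_that("bootstrap errors are deterministic and vanish for duplicated windows", {
  w <- fixture_harmonic_windows()[5:7]
  e1 <- bootstrap_pmf(w, n_rounds = 10, seed = 123, n_bins = 50)
  e2 <- bootstrap_pmf(w, n_rounds = 10, seed = 123, n_bins = 50)
  expect_identical(as.numeric(e1), as.numeric(e2))
  e3 <- bootstrap_pmf(w, n_rounds = 10, seed = 124, n_bins = 50)
  expect_false(identical(as.numeric(e1), as.numeric(e3)))
  expect_error(bootstrap_pmf(w, n_rounds = 1), "at least 2")

  # identical duplicated windows: window re-weighting cannot change anything
  base <- w[[1]]
  dup <- lapply(1:4, function(i) base)
  ed <- bootstrap_pmf(dup, n_rounds = 10, seed = 5, n_bins = 30,
                      method = "bayesian")
  expect_lt(max(ed, na.rm = TRUE), 1e-8)
})

test_that("both bootstrap schemes give comparable well-sampled-bin errors", {
  w <- fixture_harmonic_windows()
  eb <- bootstrap_pmf(w, n_rounds = 40, seed = 9, n_bins = 50,
                      range = c(0, 1), method = "bayesian")
  es <- bootstrap_pmf(w, n_rounds = 40, seed = 9, n_bins = 50,
                      range = c(0, 1), method = "samples")
  prof <- attr(eb, "profile")
  sel <- is.finite(eb) & is.finite(es) &
    prof$bin_centers >= 0.15 & prof$bin_centers <= 0.85
  expect_gt(sum(sel), 20)
  ratio <- median(eb[sel] / es[sel])
  expect_gt(ratio, 1 / 4)
  expect_lt(ratio, 4)
})

test_that("binding free energy extracts well depth with quadrature error", {
  x <- seq(0, 2, by = 0.01)
  fe <- ifelse(x < 0.5, -83, 0)           # square well below a flat plateau
  prof <- pmf_profile(x, fe, error = rep(0.5, length(x)))
  b <- binding_free_energy(prof, bound_region = c(0, 0.6),
                           reference_region = c(1.5, 2))
  expect_equal(b$value, -83)
  nref <- sum(x >= 1.5 & x <= 2)
  expect_equal(b$error, sqrt(0.5^2 + (sqrt(nref * 0.25) / nref)^2))
  # identical flat regions -> 0
  flat <- pmf_profile(x, rep(2, length(x)))
  b0 <- binding_free_energy(flat, c(1, 2), c(1, 2))
  expect_equal(b0$value, 0)
  expect_error(binding_free_energy(prof, c(5, 6), c(0, 1)), "intersect")
})

test_that("convergence series shrinks on stationary data and validates input", {
  w <- fixture_harmonic_windows()
  expect_error(convergence_series(w, time_blocks = 1), "at least 2")
  cs <- convergence_series(w, time_blocks = 4, n_bins = 60)
  expect_length(cs$profiles, 4)
  # deviation between cumulative prefixes shrinks for stationary sampling
  deltas <- vapply(2:4, function(b) {
    a <- cs$profiles[[b]]$free_energy; p <- cs$profiles[[b - 1]]$free_energy
    ok <- is.finite(a) & is.finite(p)
    max(abs(a[ok] - p[ok]))
  }, numeric(1))
  expect_lt(deltas[3], deltas[1])
  expect_equal(cs$max_delta, deltas[3])
})

test_that("WHAM on two states is consistent with BAR on the same system", {
  # two overlapping umbrella windows on a flat landscape: the window
  # free-energy constants from WHAM must agree with BAR applied to the
  # bias-energy differences of the same samples
  set.seed(21)
  kbias <- 400
  tem <- 323
  rt <- kT_kj(tem)
  c1 <- 0.45; c2 <- 0.55
  s1 <- rnorm(4000, c1, sqrt(rt / kbias))
  s2 <- rnorm(4000, c2, sqrt(rt / kbias))
  w <- list(umbrella_window(c1, kbias, tem, s1),
            umbrella_window(c2, kbias, tem, s2))
  prof <- solve_wham(w, n_bins = 80)
  df_wham <- prof$window_constants[2] - prof$window_constants[1]
  bias <- function(x, c) 0.5 * kbias * (x - c)^2
  bar <- estimate_bar((bias(s1, c2) - bias(s1, c1)) / rt,
                      (bias(s2, c1) - bias(s2, c2)) / rt, tem)
  # both estimate the same free-energy difference (here 0 by symmetry)
  expect_equal(df_wham, bar$delta_g$value, tolerance = 0.15)
})

test_that("umbrella window invariants are enforced", {
  expect_error(umbrella_window(0, -1, 300, 1:3), "nonnegative")
  expect_error(umbrella_window(0, 1, -300, 1:3), "positive")
  expect_error(umbrella_window(0, 1, 300, c(1, 2), times = c(1, 2),
                               equilibration_cutoff = 5),
               "equilibration")
  w <- umbrella_window(0, 1, 300, c(1, 2, 3), times = c(1, 2, 3),
                       equilibration_cutoff = 1.5)
  expect_equal(length(window_samples(w)), 2)
})
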