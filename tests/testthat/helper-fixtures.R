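# Shared fixtures built once per test run.

# small harmonic-potential umbrella set (flat enough for fast WHAM)
fixture_harmonic_windows <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- gen_umbrella_windows(potential_harmonic(k = 50),
                                     centers = seq(0, 1, by = 0.1),
                                     force_constant = 1000,
                                     n_samples = 1500, temperature = 323,
                                     seed = 42)
    cache
  }
})

# two-state harmonic reduced-potential matrix with closed-form dG
fixture_two_state <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- gen_reduced_potentials(lambda_schedule(c(0, 1)),
                                       kappa0 = 500, kappa1 = 2000,
                                       n_per_state = 4000,
                                       temperature = 323, seed = 7)
    cache
  }
})

# planted toy trajectory (14/15-frame ion contact, converging helices)
fixture_toy_traj <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- gen_toy_trajectory(
        toy_trajectory_spec(n_frames = 15, n_waters = 40,
                            helix_sep = seq(1.4, 1.0, length.out = 15)),
        seed = 11)
    cache
  }
})

# brute-force point-in-cylinder oracle (closed boundaries)
brute_cylinder <- function(points, center, axis, half_length, radius) {
  axis <- axis / sqrt(sum(axis^2))
  apply(points, 1, function(p) {
    rel <- p - center
    ax <- sum(rel * axis)
    rad <- sqrt(max(sum(rel^2) - ax^2, 0))
    c(inside = rad <= radius && abs(ax) <= half_length, axial = ax)
  })
}

# brute-force minimum-image distance by enumerating all 27 periodic images
brute_min_image <- function(a, b, box) {
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  min(apply(shifts, 1, function(s) sqrt(sum((a - (b + s * box))^2))))
}
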