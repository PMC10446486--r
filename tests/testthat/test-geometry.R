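# a tiny trajectory from explicit coordinates
make_traj <- function(frames, names, resids, box = c(10, 10, 10),
                      resnames = NULL, chains = NULL, elements = NULL,
                      times = NULL) {
  n <- length(names)
  atoms <- data.frame(
    name = names, resid = resids,
    resname = resnames %||% rep("UNK", n),
    chain = chains %||% rep("A", n),
    element = elements %||% substr(names, 1, 1),
    stringsAsFactors = FALSE)
  transportfe:::trajectory(frames, atoms, box, times = times)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cylinder counts match a brute-force oracle, per half", {
  set.seed(8)
  pts <- cbind(runif(50, 0, 10), runif(50, 0, 10), runif(50, 0, 10))
  # include a point exactly on the radial boundary: counted (closed)
  pts[1, ] <- c(5 + 1.3, 5, 6)
  pts[2, ] <- c(5, 5, 5 + 2)          # exactly on the end cap
  traj <- make_traj(list(pts), rep("OW", 50), 1:50)
  reg <- cylinder_region(c(5, 5, 5), half_length = 2, radius = 1.3)
  oracle <- brute_cylinder(pts, c(5, 5, 5), c(0, 0, 1), 2, 1.3)
  inside <- as.logical(oracle["inside", ])
  axial <- oracle["axial", ]
  cc_both <- cylinder_counts(traj, reg, rep(TRUE, 50))
  cc_ec <- cylinder_counts(traj, reg, rep(TRUE, 50), half = "EC")
  cc_ic <- cylinder_counts(traj, reg, rep(TRUE, 50), half = "IC")
  expect_equal(cc_both$counts, sum(inside))
  expect_equal(cc_ec$counts, sum(inside & axial > 0))
  expect_equal(cc_ic$counts, sum(inside & axial <= 0))
  expect_equal(cc_ec$counts + cc_ic$counts, cc_both$counts)
  # the two planted boundary points are inside under the closed convention
  expect_true(all(inside[1:2]))
})

test_that("counting is invariant to atom permutation and rigid translation", {
  set.seed(9)
  pts <- cbind(runif(30, 2, 8), runif(30, 2, 8), runif(30, 2, 8))
  reg <- cylinder_region(c(5, 5, 5), half_length = 1.5, radius = 1.0)
  traj <- make_traj(list(pts), rep("OW", 30), 1:30)
  n0 <- cylinder_counts(traj, reg, rep(TRUE, 30))$counts
  perm <- sample(30)
  trajp <- make_traj(list(pts[perm, ]), rep("OW", 30), (1:30)[perm])
  expect_equal(cylinder_counts(trajp, reg, rep(TRUE, 30))$counts, n0)
  shift <- c(0.7, -0.4, 1.1)
  trajs <- make_traj(list(sweep(pts, 2, -shift)), rep("OW", 30), 1:30)
  regs <- cylinder_region(c(5, 5, 5) + shift, half_length = 1.5,
                          radius = 1.0)
  expect_equal(cylinder_counts(trajs, regs, rep(TRUE, 30))$counts, n0)
})

test_that("rule-based cylinder centres track the anchor CA midpoint per frame", {
  # anchor CAs move between frames; a probe sits at their midpoint
  f1 <- rbind(c(4, 5, 5), c(6, 5, 5), c(5, 5, 5))
  f2 <- rbind(c(6, 5, 5), c(8, 5, 5), c(7, 5, 5))
  traj <- make_traj(list(f1, f2), c("CA", "CA", "OW"), c(510, 1092, 2000))
  reg <- cylinder_region(ca_midpoint(510, 1092), half_length = 2,
                         radius = 1.3)
  cc <- cylinder_counts(traj, reg, function(a) a$name == "OW")
  expect_equal(cc$counts, c(1, 1))
  expect_error(
    cylinder_counts(traj, cylinder_region(ca_midpoint(510, 9999)),
                    function(a) a$name == "OW"),
    "9999")
})

test_that("trailing-window summaries use only the final frames", {
  pts_in <- rbind(c(5, 5, 5)); pts_out <- rbind(c(0.5, 0.5, 0.5))
  frames <- c(replicate(5, pts_out, simplify = FALSE),
              replicate(5, pts_in, simplify = FALSE))
  traj <- make_traj(frames, "OW", 1, times = 0:9)
  reg <- cylinder_region(c(5, 5, 5), half_length = 1, radius = 1)
  all_t <- cylinder_counts(traj, reg, rep(TRUE, 1))
  tail_t <- cylinder_counts(traj, reg, rep(TRUE, 1), tail_time = 4)
  expect_equal(all_t$mean, 0.5)
  expect_equal(tail_t$mean, 1)
  expect_equal(tail_t$sd, 0)
})

test_that("ion contact fractions reproduce planted contacts and thresholds", {
  traj <- fixture_toy_traj()
  tab <- ion_contact_fractions(traj, function(a) a$name == "NA",
                               residues = c(50, 1), cutoff = 0.3)
  expect_s3_class(tab, "contact_table")
  expect_equal(tab$fraction[tab$resid == 50], 100 * 14 / 15,
               tolerance = 1e-12)
  expect_equal(round(tab$fraction[tab$resid == 50], 1), 93.3)
  # residue 1 (helix scaffold, far away) never contacts: excluded by the
  # 1% reporting threshold
  expect_false(1 %in% tab$resid)
  expect_error(ion_contact_fractions(traj, function(a) a$name == "NA",
                                     residues = integer(0)),
               "nonempty")
})

test_that("contact fractions are invariant to frame duplication and dilute by half", {
  traj <- fixture_toy_traj()
  dup <- transportfe:::trajectory(c(traj$frames, traj$frames), traj$atoms,
                                  traj$box)
  f1 <- ion_contact_fractions(traj, function(a) a$name == "NA", 50)$fraction
  f2 <- ion_contact_fractions(dup, function(a) a$name == "NA", 50)$fraction
  expect_equal(f1, f2)
  # dilution with no-contact frames (ion far away) halves the fraction
  far <- lapply(traj$frames, function(m) {
    m[traj$atoms$name == "NA", ] <- c(0.5, 0.5, 0.5); m
  })
  dil <- transportfe:::trajectory(c(traj$frames, far), traj$atoms, traj$box)
  f3 <- ion_contact_fractions(dil, function(a) a$name == "NA", 50,
                              report_threshold = 0)$fraction
  expect_equal(f3, f1 / 2)
})

test_that("minimum-image distances match 27-image enumeration", {
  box <- c(5, 6, 7)
  set.seed(10)
  for (i in 1:20) {
    a <- runif(3, 0, box); b <- runif(3, 0, box)
    expect_equal(min_image_dist(a, b, box), brute_min_image(a, b, box),
                 tolerance = 1e-12)
  }
  # a pair straddling the boundary
  a <- c(0.1, 3, 3); b <- c(4.9, 3, 3)
  expect_equal(min_image_dist(a, b, box), 0.2, tolerance = 1e-12)
})

test_that("CA distance series handle identity, fixed separations and PBC", {
  f <- rbind(c(1, 1, 1), c(1.4, 1, 1), c(9.9, 1, 1))
  traj <- make_traj(list(f), c("CA", "CA", "CA"), c(1, 2, 3))
  expect_equal(min_ca_distance(traj, 1, 1)$distances, 0)
  expect_equal(min_ca_distance(traj, 1, 2)$distances, 0.4,
               tolerance = 1e-12)
  # across the periodic boundary: 1.2 direct, 10 - 8.9... via image
  expect_equal(min_ca_distance(traj, 1, 3)$distances,
               brute_min_image(f[1, ], f[3, ], c(10, 10, 10)),
               tolerance = 1e-12)
  expect_error(min_ca_distance(traj, 1, 42), "42")
  # the toy trajectory reproduces its planted helix-separation schedule
  toy <- fixture_toy_traj()
  d <- min_ca_distance(toy, 3, 103)
  expect_equal(d$distances, attr(toy, "truth")$helix_sep, tolerance = 1e-9)
})

test_that("positional RMSD handles static, shifted and random-walk motion", {
  p0 <- rbind(c(2, 2, 2))
  static <- make_traj(replicate(4, p0, simplify = FALSE), "NA", 1)
  expect_equal(positional_rmsd(static, rep(TRUE, 1))$rmsd, rep(0, 4))
  shifted <- make_traj(list(p0, p0 + c(0.3, 0, 0), p0 + c(0, 0.3, 0)),
                       "NA", 1)
  expect_equal(positional_rmsd(shifted, rep(TRUE, 1))$rmsd, c(0, 0.3, 0.3))
  # random walk: E[RMSD_t^2] = 3 t sigma^2
  set.seed(14)
  sigma <- 0.05; nstep <- 400
  steps <- matrix(rnorm(3 * nstep, 0, sigma), ncol = 3)
  pos <- apply(steps, 2, cumsum)
  frames <- lapply(seq_len(nstep), function(i) matrix(pos[i, ], 1))
  rw <- make_traj(frames, "NA", 1)
  r <- positional_rmsd(rw, rep(TRUE, 1),
                       reference = matrix(c(0, 0, 0), 1))
  msd_emp <- mean(r$rmsd[nstep %/% 2]^2)
  expect_lt(abs(msd_emp - 3 * (nstep %/% 2) * sigma^2),
            3 * sqrt(2 / 3) * 3 * (nstep %/% 2) * sigma^2)
})

test_that("density grids conserve mass and localise a static atom", {
  one <- make_traj(list(rbind(c(2.25, 2.25, 2.25))), "OW", 1,
                   box = c(5, 5, 5))
  g <- water_density(one, rep(TRUE, 1), spacing = 0.5)
  expect_equal(sum(g$values), 1)
  expect_equal(max(g$values), 1)      # all mass in one voxel
  traj <- fixture_toy_traj()
  g2 <- water_density(traj, function(a) a$name == "OW", spacing = 0.5)
  expect_equal(sum(g2$values), attr(traj, "truth")$n_waters,
               tolerance = 1e-12)
  expect_error(water_density(one, rep(TRUE, 1), spacing = 99), "exceeds")
  # uniform points spread roughly evenly (chi-square on coarse voxels)
  set.seed(15)
  pts <- cbind(runif(4000, 0, 5), runif(4000, 0, 5), runif(4000, 0, 5))
  u <- make_traj(list(pts), rep("OW", 4000), 1:4000, box = c(5, 5, 5))
  gu <- water_density(u, rep(TRUE, 4000), spacing = 2.5)
  counts <- as.numeric(gu$values)
  chi2 <- sum((counts - 500)^2 / 500)
  expect_lt(chi2, qchisq(0.999, df = 7))
})

test_that("z-coordinate series report only region residents", {
  traj <- fixture_toy_traj()
  reg <- cylinder_region(attr(traj, "truth")$ion_target, half_length = 1,
                         radius = 0.5)
  recs <- z_coordinate_series(traj, list(na = function(a) a$name == "NA"),
                              reg)
  # ion is inside in exactly the planted bound frames
  expect_equal(sort(recs$time), traj$times[attr(traj, "truth")$ion_bound])
  # species subsets partition the full record set
  both <- z_coordinate_series(traj, list(na = function(a) a$name == "NA",
                                         water = function(a)
                                           a$name == "OW"), reg)
  expect_equal(nrow(both[both$species == "na", ]), nrow(recs))
  # empty region yields an empty series
  far_reg <- cylinder_region(c(0.2, 0.2, 0.2), half_length = 0.05,
                             radius = 0.05)
  empty <- z_coordinate_series(traj, list(na = function(a) a$name == "NA"),
                               far_reg)
  expect_equal(nrow(empty), 0)
})

test_that("residue occupancies rank planted contacts and halve under pooling", {
  # ligand at origin-ish; residues 1-4 planted within 0.6 nm, 5-8 far
  lig <- c(5, 5, 5)
  near <- lapply(1:4, function(i) lig + c(0.3, 0, 0) + (i - 1) * 0.05)
  far <- lapply(1:4, function(i) c(1, 1, 1) + i * 0.2)
  pts <- do.call(rbind, c(list(lig), near, far))
  traj <- make_traj(list(pts, pts), c("C1", rep("CA", 8)), c(99, 1:8))
  occ <- residue_occupancy(traj, function(a) a$resid == 99, cutoff = 0.6)
  expect_setequal(occ$resid[occ$occupancy == 1], 1:4)
  expect_true(all(occ$occupancy[occ$resid %in% 5:8] == 0))
  top <- residue_occupancy(traj, function(a) a$resid == 99, cutoff = 0.6,
                           top_k = 4)
  expect_setequal(top$resid, 1:4)
  # pooling with a window whose contacts are disjoint halves occupancies
  pts2 <- pts; pts2[2:5, ] <- pts2[2:5, ] + 3   # move residues 1-4 away
  traj2 <- make_traj(list(pts2, pts2), c("C1", rep("CA", 8)), c(99, 1:8))
  pooled <- residue_occupancy(list(traj, traj2),
                              function(a) a$resid == 99, cutoff = 0.6)
  expect_equal(pooled$occupancy[pooled$resid %in% 1:4], rep(0.5, 4))
})

test_that("trajectory and region constructors enforce invariants", {
  expect_error(cylinder_region(c(0, 0, 0), radius = -1), "positive")
  expect_error(cylinder_region(c(0, 0, 0), axis = c(0, 0, 0)), "nonzero")
  expect_error(make_traj(list(rbind(c(1, 1, 1))), "CA", 1, box = c(-1, 1, 1)),
               "box")
  expect_error(
    transportfe:::trajectory(list(rbind(c(1, 1, 1)), rbind(c(1, 1, 1),
                                                           c(2, 2, 2))),
                             data.frame(name = "CA", resid = 1,
                                        resname = "ALA", chain = "A",
                                        element = "C"), c(5, 5, 5)),
    "constant atom count")
})
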