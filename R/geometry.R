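#' Geometric probes of trajectories
#'
#' Cylinder-partitioned hydration/ion counting within a transmembrane domain,
#' residue-ion contact fractions, per-residue ligand occupancies,
#' minimum-image inter-residue distances, positional RMSD and time-averaged
#' density grids. Boundary conventions are closed: a point exactly on the
#' cylinder radius or end cap is counted inside.
#'
#' @name traj_geometry
NULL

#' Cylindrical analysis region
#'
#' A cylinder of given half-length and radius. The centre is either a fixed
#' point or the rule "midpoint of the CA atoms of two residues", re-evaluated
#' per frame; the default axis is the membrane normal (z). The positive axial
#' side is the extracellular (EC) half, the nonpositive side intracellular
#' (IC).
#'
#' @param center Length-3 point (nm), or a length-2 vector of residue ids
#'   wrapped in [ca_midpoint()].
#' @param axis Axis direction (normalised internally; must be nonzero).
#' @param half_length Half the cylinder length (nm, > 0). A 4-nm-long TMD
#'   cylinder has `half_length = 2`.
#' @param radius Cylinder radius (nm, > 0).
#' @return A `cylinder_region` object.
#' @examples
#' cylinder_region(ca_midpoint(510, 1092), half_length = 2, radius = 1.3)
#' @export
cylinder_region <- function(center, axis = c(0, 0, 1), half_length = 2,
                            radius = 1.3) {
  if (radius <= 0 || half_length <= 0)
    stop("radius and half_length must be positive")
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("axis must be a nonzero vector")
  if (!inherits(center, "ca_midpoint")) {
    stopifnot(is.numeric(center), length(center) == 3)
  }
  structure(list(center = center, axis = axis / nrm,
                 half_length = half_length, radius = radius),
            class = "cylinder_region")
}

#' @rdname cylinder_region
#' @param res_a,res_b Residue ids whose CA midpoint defines the centre.
#' @export
ca_midpoint <- function(res_a, res_b) {
  structure(list(res_a = res_a, res_b = res_b), class = "ca_midpoint")
}

resolve_center <- function(region, traj, frame_xyz) {
  c0 <- region$center
  if (!inherits(c0, "ca_midpoint")) return(c0)
  a <- traj$atoms
  ia <- which(a$name == "CA" & a$resid == c0$res_a)
  ib <- which(a$name == "CA" & a$resid == c0$res_b)
  if (!length(ia) || !length(ib))
    stop(sprintf("anchor residue %s lacks a CA atom",
                 if (!length(ia)) c0$res_a else c0$res_b))
  (frame_xyz[ia[1], ] + frame_xyz[ib[1], ]) / 2
}

# axial and radial coordinates of points relative to a resolved cylinder
cylinder_coords <- function(points, center, axis) {
  rel <- sweep(points, 2, center)
  axial <- as.numeric(rel %*% axis)
  radial <- sqrt(pmax(rowSums(rel^2) - axial^2, 0))
  list(axial = axial, radial = radial)
}

#' Count selected atoms inside a cylinder, per frame
#'
#' An atom is counted when its radial distance from the axis is at most the
#' radius and its axial coordinate lies within the half-length (closed
#' boundaries). `half = "EC"` restricts to axial > 0, `"IC"` to axial <= 0.
#' Rule-based centres are re-evaluated every frame.
#'
#' @param traj A [trajectory].
#' @param cylinder A [cylinder_region].
#' @param selection Atom selection (logical/index vector or function; see
#'   [resolve_selection] conventions).
#' @param half `"both"`, `"EC"` or `"IC"`.
#' @param tail_time If given, the summary statistics are restricted to frames
#'   with time >= max(time) - tail_time (e.g. the final 10 ns).
#' @return List: `counts` (per frame), `times`, `mean`, `sd` (over the
#'   summarised frames).
#' @export
cylinder_counts <- function(traj, cylinder, selection,
                            half = c("both", "EC", "IC"), tail_time = NULL) {
  half <- match.arg(half)
  sel <- resolve_selection(traj, selection)
  if (!any(sel))                      # nothing selected: zero in every frame
    return(list(counts = rep(0, n_frames(traj)), times = traj$times,
                mean = 0, sd = 0))
  counts <- vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- traj$frames[[f]]
    ctr <- resolve_center(cylinder, traj, xyz)
    cc <- cylinder_coords(xyz[sel, , drop = FALSE], ctr, cylinder$axis)
    inside <- cc$radial <= cylinder$radius &
      abs(cc$axial) <= cylinder$half_length
    inside <- switch(half,
                     both = inside,
                     EC = inside & cc$axial > 0,
                     IC = inside & cc$axial <= 0)
    sum(inside)
  }, numeric(1))
  use <- rep(TRUE, length(counts))
  if (!is.null(tail_time))
    use <- traj$times >= max(traj$times) - tail_time
  list(counts = counts, times = traj$times,
       mean = mean(counts[use]),
       sd = if (sum(use) > 1) stats::sd(counts[use]) else NA_real_)
}

#' Fraction of frames each residue contacts an ion
#'
#' For each residue in `residues`, the percentage of frames in which the
#' minimum-image distance between the ion and any atom of the residue is at
#' most `cutoff`. Rows under `report_threshold` percent are dropped and the
#' table is sorted descending.
#'
#' @param traj A [trajectory].
#' @param ion_selection Selection resolving to exactly one atom per frame.
#' @param residues Integer vector of residue ids to tabulate.
#' @param cutoff Contact cutoff (nm); default 0.3.
#' @param report_threshold Minimum percentage reported; default 1.
#' @return A `contact_table` data.frame: `resid`, `resname`, `fraction` (%).
#' @export
ion_contact_fractions <- function(traj, ion_selection, residues,
                                  cutoff = 0.3, report_threshold = 1) {
  if (!length(residues)) stop("residue set must be nonempty")
  ion <- which(resolve_selection(traj, ion_selection))
  if (length(ion) != 1) stop("ion selection must resolve to exactly one atom")
  a <- traj$atoms
  nf <- n_frames(traj)
  fr <- vapply(residues, function(r) {
    idx <- which(a$resid == r & seq_len(nrow(a)) != ion)
    if (!length(idx)) return(0)
    hits <- vapply(seq_len(nf), function(f) {
      xyz <- traj$frames[[f]]
      d <- min_image_dist(xyz[idx, , drop = FALSE],
                          matrix(xyz[ion, ], nrow = length(idx),
                                 ncol = 3, byrow = TRUE), traj$box)
      any(d <= cutoff)
    }, logical(1))
    100 * mean(hits)
  }, numeric(1))
  resnames <- vapply(residues, function(r) {
    nm <- a$resname[a$resid == r]
    if (length(nm)) nm[1] else NA_character_
  }, character(1))
  out <- data.frame(resid = residues, resname = resnames, fraction = fr)
  out <- out[out$fraction >= report_threshold, , drop = FALSE]
  out <- out[order(-out$fraction), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contact_table", "data.frame")
  attr(out, "cutoff") <- cutoff
  attr(out, "report_threshold") <- report_threshold
  out
}

#' Per-residue ligand occupancy
#'
#' Fraction of frames in which any atom of each residue lies within `cutoff`
#' of any ligand atom (minimum image). Multiple trajectories (e.g. pooled
#' umbrella windows) are pooled frame-wise.
#'
#' @param trajs A [trajectory] or list of trajectories with identical atom
#'   tables.
#' @param ligand_selection Selection of ligand atoms (applied to the first
#'   trajectory's atom table).
#' @param cutoff Contact cutoff (nm); default 0.6.
#' @param top_k If given, return only the `top_k` highest-occupancy residues.
#' @return data.frame `resid`, `resname`, `occupancy` (fraction in [0, 1]),
#'   sorted descending.
#' @export
residue_occupancy <- function(trajs, ligand_selection, cutoff = 0.6,
                              top_k = NULL) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  traj1 <- trajs[[1]]
  lig <- which(resolve_selection(traj1, ligand_selection))
  if (!length(lig)) stop("ligand selection matches no atoms")
  a <- traj1$atoms
  lig_res <- unique(a$resid[lig])
  res_ids <- setdiff(unique(a$resid), lig_res)
  total <- 0
  hit_counts <- setNames(numeric(length(res_ids)), res_ids)
  for (traj in trajs) {
    for (f in seq_len(n_frames(traj))) {
      xyz <- traj$frames[[f]]
      lxyz <- xyz[lig, , drop = FALSE]
      for (r in res_ids) {
        idx <- which(a$resid == r)
        d <- outer(seq_along(idx), seq_len(nrow(lxyz)),
                   Vectorize(function(i, j)
                     min_image_dist(xyz[idx[i], ], lxyz[j, ], traj$box)))
        if (any(d <= cutoff))
          hit_counts[as.character(r)] <- hit_counts[as.character(r)] + 1
      }
      total <- total + 1
    }
  }
  occ <- hit_counts / total
  resnames <- vapply(res_ids, function(r) a$resname[a$resid == r][1],
                     character(1))
  out <- data.frame(resid = res_ids, resname = resnames,
                    occupancy = as.numeric(occ))
  out <- out[order(-out$occupancy), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}

#' Minimum-image CA-CA distance series
#'
#' Euclidean distance between the CA atoms of two residues under the
#' orthorhombic minimum-image convention, per frame.
#'
#' @param traj A [trajectory].
#' @param residue_a,residue_b Residue ids; each must have a CA atom.
#' @return List: `distances` (per frame, nm), `times`, `mean`, `sd`.
#' @export
min_ca_distance <- function(traj, residue_a, residue_b) {
  a <- traj$atoms
  ia <- which(a$name == "CA" & a$resid == residue_a)
  ib <- which(a$name == "CA" & a$resid == residue_b)
  if (!length(ia) || !length(ib))
    stop(sprintf("residue %s has no CA atom",
                 if (!length(ia)) residue_a else residue_b))
  d <- vapply(traj$frames, function(xyz)
    min(outer(ia, ib, Vectorize(function(i, j)
      min_image_dist(xyz[i, ], xyz[j, ], traj$box)))), numeric(1))
  list(distances = d, times = traj$times, mean = mean(d),
       sd = if (length(d) > 1) stats::sd(d) else NA_real_)
}

#' Positional RMSD relative to a reference frame
#'
#' Per-frame root-mean-square deviation of the selected atoms from their
#' reference positions (default: the first frame). No rotational fitting is
#' applied — appropriate for single ions or already-aligned trajectories;
#' optional centring removes the selection's centre-of-geometry displacement.
#'
#' @param traj A [trajectory].
#' @param selection Atom selection.
#' @param reference n_sel x 3 reference coordinates (nm); default first frame.
#' @param center Subtract the centre-of-geometry displacement first?
#' @return List: `rmsd` (per frame, nm), `mean`, `sd`.
#' @export
positional_rmsd <- function(traj, selection, reference = NULL,
                            center = FALSE) {
  sel <- resolve_selection(traj, selection)
  if (!any(sel)) stop("selection matches no atoms")
  ref <- if (is.null(reference)) traj$frames[[1]][sel, , drop = FALSE]
         else reference
  stopifnot(nrow(ref) == sum(sel))
  r <- vapply(traj$frames, function(xyz) {
    p <- xyz[sel, , drop = FALSE]
    if (center) p <- sweep(p, 2, colMeans(p) - colMeans(ref))
    sqrt(mean(rowSums((p - ref)^2)))
  }, numeric(1))
  list(rmsd = r, mean = mean(r),
       sd = if (length(r) > 1) stats::sd(r) else NA_real_)
}

#' Time-averaged occupancy density grid
#'
#' Coordinates are wrapped into the box and binned on a regular grid; voxel
#' values are frame-averaged counts, so the total grid mass equals the mean
#' number of selected atoms per frame.
#'
#' @param traj A [trajectory].
#' @param selection Atom selection (conventionally water oxygens).
#' @param spacing Voxel edge (nm); must not exceed any box edge.
#' @return A `density_grid`: `origin`, `spacing` (length-3), `dims`, `values`
#'   (3D array).
#' @export
water_density <- function(traj, selection, spacing = 0.1) {
  if (any(spacing > traj$box))
    stop("voxel spacing exceeds the box")
  sel <- resolve_selection(traj, selection)
  dims <- pmax(1, ceiling(traj$box / spacing))
  sp <- traj$box / dims
  acc <- array(0, dim = dims)
  for (f in seq_len(n_frames(traj))) {
    p <- traj$frames[[f]][sel, , drop = FALSE]
    p <- sweep(p, 2, traj$box, function(x, L) x %% L)
    ijk <- vapply(1:3, function(ax)
      pmin(pmax(floor(p[, ax] / sp[ax]) + 1, 1), dims[ax]),
      numeric(nrow(p)))
    ijk <- matrix(ijk, ncol = 3)
    for (r in seq_len(nrow(ijk)))
      acc[ijk[r, 1], ijk[r, 2], ijk[r, 3]] <-
        acc[ijk[r, 1], ijk[r, 2], ijk[r, 3]] + 1
  }
  structure(list(origin = c(0, 0, 0), spacing = sp, dims = dims,
                 values = acc / n_frames(traj)),
            class = "density_grid")
}

#' Axial coordinates of region-resident atoms over time
#'
#' Emits one record per (frame, species, atom) for atoms inside the region in
#' that frame, with the atom's axial coordinate along the region axis —
#' the classic z-coordinate hydration/ion trace of a TMD cylinder.
#'
#' @param traj A [trajectory].
#' @param selections Named list of atom selections (e.g.
#'   `list(water = ..., na = ..., cl = ...)`).
#' @param region A [cylinder_region].
#' @return data.frame `time`, `species`, `axial` (nm); zero rows if the
#'   region is always empty.
#' @export
z_coordinate_series <- function(traj, selections, region) {
  stopifnot(is.list(selections), length(names(selections)) ==
              length(selections))
  recs <- list()
  for (f in seq_len(n_frames(traj))) {
    xyz <- traj$frames[[f]]
    ctr <- resolve_center(region, traj, xyz)
    for (sp in names(selections)) {
      sel <- resolve_selection(traj, selections[[sp]])
      if (!any(sel)) next
      cc <- cylinder_coords(xyz[sel, , drop = FALSE], ctr, region$axis)
      inside <- cc$radial <= region$radius &
        abs(cc$axial) <= region$half_length
      if (any(inside))
        recs[[length(recs) + 1]] <- data.frame(
          time = traj$times[f], species = sp, axial = cc$axial[inside])
    }
  }
  if (!length(recs))
    return(data.frame(time = numeric(0), species = character(0),
                      axial = numeric(0)))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Write a density grid in OpenDX plain-text format
#'
#' @param grid A `density_grid` from [water_density].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- grid$dims
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %g 0 0", grid$spacing[1]),
    sprintf("delta 0 %g 0", grid$spacing[2]),
    sprintf("delta 0 0 %g", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # OpenDX order: z fastest
  vals <- as.numeric(aperm(grid$values, c(3, 2, 1)))
  n <- length(vals)
  idx <- seq(1, n, by = 3)
  lines <- vapply(idx, function(i)
    paste(format(vals[i:min(i + 2, n)], trim = TRUE), collapse = " "),
    character(1))
  writeLines(lines, con)
  writeLines("object \"density\" class field", con)
  invisible(path)
}
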