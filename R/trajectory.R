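#' Trajectory container
#'
#' Lightweight in-memory trajectory: a list of per-frame coordinate matrices
#' (n_atoms x 3, nm), a constant atom-metadata table, an orthorhombic box
#' (three edge lengths, nm) and frame times (ns). Only orthorhombic boxes are
#' supported; triclinic inputs are rejected.
#'
#' @param frames List of n_atoms x 3 numeric matrices (nm), one per frame,
#'   constant atom count.
#' @param atoms data.frame with columns `name`, `resid`, `resname`, `chain`,
#'   `element` (one row per atom).
#' @param box Length-3 numeric box edge lengths (nm, all > 0).
#' @param times Frame times (ns); default 0, 1, ...
#' @param source Free-text provenance.
#' @return A `trajectory` object.
#' @export
trajectory <- function(frames, atoms, box, times = NULL, source = "") {
  stopifnot(is.list(frames), length(frames) >= 1)
  n_atoms <- nrow(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || ncol(f) != 3 || nrow(f) != n_atoms)
      stop("every frame must be an n_atoms x 3 matrix with constant atom count")
    if (!all(is.finite(f))) stop("coordinates must be finite")
  }
  if (length(box) != 3 || any(box <= 0))
    stop("box must be three positive orthorhombic edge lengths")
  if (nrow(atoms) != n_atoms)
    stop("atom table must have one row per atom")
  req <- c("name", "resid", "resname", "chain", "element")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(times)) times <- seq_along(frames) - 1
  stopifnot(length(times) == length(frames))
  structure(list(frames = frames, atoms = atoms, box = as.numeric(box),
                 times = as.numeric(times), source = source),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, box %.2f x %.2f x %.2f nm\n",
              length(x$frames), nrow(x$atoms), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

#' Select atoms of a trajectory by metadata
#'
#' @param traj A [trajectory].
#' @param name,resname,resid,chain,element Optional filters; an atom matches
#'   when it satisfies all supplied filters.
#' @return Logical vector over atoms.
#' @export
select_atoms <- function(traj, name = NULL, resname = NULL, resid = NULL,
                         chain = NULL, element = NULL) {
  a <- traj$atoms
  sel <- rep(TRUE, nrow(a))
  if (!is.null(name)) sel <- sel & a$name %in% name
  if (!is.null(resname)) sel <- sel & a$resname %in% resname
  if (!is.null(resid)) sel <- sel & a$resid %in% resid
  if (!is.null(chain)) sel <- sel & a$chain %in% chain
  if (!is.null(element)) sel <- sel & a$element %in% element
  sel
}

# resolve a selection argument (logical vector, indices, or function of the
# atom table) to a logical vector
resolve_selection <- function(traj, selection) {
  n <- nrow(traj$atoms)
  if (is.function(selection)) selection <- selection(traj$atoms)
  if (is.logical(selection)) {
    stopifnot(length(selection) == n)
    return(selection)
  }
  if (is.numeric(selection)) {
    out <- rep(FALSE, n); out[selection] <- TRUE
    return(out)
  }
  stop("selection must be a logical vector, index vector or function")
}

#' Minimum-image displacement and distance (orthorhombic box)
#'
#' @param a,b Numeric length-3 points or n x 3 matrices (nm).
#' @param box Length-3 orthorhombic box (nm).
#' @return `min_image_vec`: displacement(s) a - b mapped to the nearest image;
#'   `min_image_dist`: the corresponding Euclidean distance(s).
#' @export
min_image_vec <- function(a, b, box) {
  d <- a - b
  if (is.matrix(d)) sweep(d, 2, box, function(x, L) x - L * round(x / L))
  else d - box * round(d / box)
}

#' @rdname min_image_vec
#' @export
min_image_dist <- function(a, b, box) {
  d <- min_image_vec(a, b, box)
  if (is.matrix(d)) sqrt(rowSums(d^2)) else sqrt(sum(d^2))
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are written in angstroms (nm x 10) with a CRYST1 record for the
#' orthorhombic box; one MODEL block per frame.
#'
#' @param traj A [trajectory].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  b <- traj$box * 10
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    b[1], b[2], b[3], 90, 90, 90), con)
  a <- traj$atoms
  for (f in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- traj$frames[[f]] * 10
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(a)) %% 100000,
      substr(a$name, 1, 4), substr(a$resname, 1, 3),
      substr(paste0(a$chain, " "), 1, 1), a$resid %% 10000,
      xyz[, 1], xyz[, 2], xyz[, 3], substr(a$element, 1, 2))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a (multi-model) PDB file into a trajectory
#'
#' Parsing is delegated to \code{bio3d::read.pdb}; the CRYST1 record supplies
#' the box, which must be orthorhombic (all angles 90 degrees). Coordinates
#' are converted to nm.
#'
#' @param path PDB file path.
#' @param times Optional frame times (ns).
#' @return A [trajectory].
#' @export
read_trajectory_pdb <- function(path, times = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  cryst <- grep("^CRYST1", readLines(path), value = TRUE)
  if (!length(cryst))
    stop("PDB file lacks a CRYST1 record; a periodic box is required")
  fields <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                         substr(cryst[1], 25, 33), substr(cryst[1], 34, 40),
                         substr(cryst[1], 41, 47), substr(cryst[1], 48, 54)))
  if (any(abs(fields[4:6] - 90) > 1e-3))
    stop("triclinic boxes are not supported; angles must all be 90 degrees")
  box <- fields[1:3] / 10
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  n_atoms <- ncol(xyz) / 3
  frames <- lapply(seq_len(nf), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10)
  el <- pdb$atom$elesy
  if (is.null(el) || all(!nzchar(trimws(el))))
    el <- substr(trimws(pdb$atom$elety), 1, 1)
  atoms <- data.frame(
    name = trimws(pdb$atom$elety),
    resid = as.integer(pdb$atom$resno),
    resname = trimws(pdb$atom$resid),
    chain = ifelse(is.na(pdb$atom$chain), " ", pdb$atom$chain),
    element = trimws(el),
    stringsAsFactors = FALSE
  )
  trajectory(frames, atoms, box, times = times, source = path)
}
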