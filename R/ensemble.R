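#' Conformational ensemble of a molecule
#'
#' The central container for coordinate trajectories and conformer ensembles:
#' a set of frames, each holding the same atoms, with per-atom metadata.
#' Coordinates are in Angstrom and frame times in ps.
#'
#' @param coords numeric array of dimension `n_frames x n_atoms x 3`, or a
#'   list of `n_atoms x 3` matrices (one per frame).
#' @param atom_names character vector of atom names, length `n_atoms`.
#' @param residue_ids integer vector of 1-based, non-decreasing residue
#'   numbers, length `n_atoms`.
#' @param elements character vector of element symbols; inferred from
#'   `atom_names` when `NULL`.
#' @param masses numeric atomic masses in Da; looked up from `elements`
#'   when `NULL`.
#' @param resnames character vector of 3-letter residue names (used for
#'   proline detection in amide-vector extraction); defaults to `"UNK"`.
#' @param chain_id single chain identifier.
#' @param frame_times numeric times in ps, length `n_frames`; defaults to
#'   `0:(n_frames-1)`.
#' @return an object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(coords, atom_names, residue_ids,
                               elements = NULL, masses = NULL,
                               resnames = NULL, chain_id = "A",
                               frame_times = NULL) {
  if (is.list(coords)) {
    coords <- aperm(simplify2array(coords), c(3, 1, 2))
  }
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be an n_frames x n_atoms x 3 array")
  n_frames <- dim(coords)[1]
  n_atoms <- dim(coords)[2]
  if (n_frames < 1) stop("ensemble needs at least one frame")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (length(atom_names) != n_atoms) stop("atom_names length mismatch")
  residue_ids <- as.integer(residue_ids)
  if (length(residue_ids) != n_atoms) stop("residue_ids length mismatch")
  if (any(diff(residue_ids) < 0)) stop("residue_ids must be non-decreasing")
  if (is.null(elements)) elements <- infer_elements(atom_names)
  if (is.null(masses)) masses <- element_masses(elements)
  if (any(masses <= 0)) stop("masses must be positive")
  if (is.null(resnames)) resnames <- rep("UNK", n_atoms)
  if (length(resnames) == 1) resnames <- rep(resnames, n_atoms)
  if (is.null(frame_times)) frame_times <- as.numeric(seq_len(n_frames) - 1)
  if (length(frame_times) != n_frames) stop("frame_times length mismatch")
  structure(list(coords = coords, atom_names = as.character(atom_names),
                 elements = elements, masses = as.numeric(masses),
                 residue_ids = residue_ids, resnames = as.character(resnames),
                 chain_id = chain_id, frame_times = as.numeric(frame_times)),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("conformer_ensemble:", n_frames(x), "frames,", n_atoms(x), "atoms,",
      length(unique(x$residue_ids)), "residues (coords in A, times in ps)\n")
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param ens a `conformer_ensemble`.
#' @return integer count.
#' @export
n_frames <- function(ens) dim(ens$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(ens) dim(ens$coords)[2]

#' Extract one frame as an n_atoms x 3 coordinate matrix
#' @param ens a `conformer_ensemble`.
#' @param i frame index.
#' @return numeric matrix with columns x, y, z.
#' @export
frame_coords <- function(ens, i) {
  m <- ens$coords[i, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Group of replicate trajectories
#'
#' Bundles independent repeat simulations (or per-replicate derived results)
#' so that downstream averages and standard errors of the mean (SEM) are taken
#' over replicates.
#'
#' @param replicates list of `conformer_ensemble` objects (or per-replicate
#'   results of the same shape).
#' @param label name of the system, e.g. a variant or model name.
#' @param equilibration_cutoff time in ps discarded from the start of every
#'   replicate before analysis.
#' @return an object of class `replicate_set`.
#' @export
replicate_set <- function(replicates, label = "ensemble",
                          equilibration_cutoff = 0) {
  if (!is.list(replicates) || length(replicates) < 1)
    stop("need at least one replicate")
  if (equilibration_cutoff < 0) stop("equilibration_cutoff must be >= 0")
  spans <- vapply(replicates, function(r) {
    if (inherits(r, "conformer_ensemble")) diff(range(r$frame_times)) else Inf
  }, numeric(1))
  if (equilibration_cutoff > 0 && equilibration_cutoff >= min(spans))
    stop("equilibration_cutoff must be shorter than the shortest trajectory")
  structure(list(replicates = replicates, label = label,
                 equilibration_cutoff = equilibration_cutoff),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat("replicate_set '", x$label, "': ", length(x$replicates),
      " replicates, equilibration cutoff ", x$equilibration_cutoff, " ps\n",
      sep = "")
  invisible(x)
}

# Drop frames before the equilibration cutoff of a replicate_set.
discard_equilibration <- function(ens, cutoff_ps) {
  keep <- ens$frame_times >= (ens$frame_times[1] + cutoff_ps)
  if (!any(keep)) stop("equilibration cutoff removes every frame")
  ens$coords <- ens$coords[keep, , , drop = FALSE]
  ens$frame_times <- ens$frame_times[keep]
  ens
}

#' Per-residue bond-vector time series
#'
#' Holds the unit-vector orientation of one bond (typically the backbone
#' amide N-H bond) sampled at a fixed time step.
#'
#' @param vectors numeric `n_steps x 3` matrix of unit vectors.
#' @param dt time step in ps.
#' @param residue_id residue the vector belongs to.
#' @return an object of class `vector_trajectory`.
#' @export
vector_trajectory <- function(vectors, dt, residue_id = 1L) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 3) stop("vectors must have 3 columns")
  if (dt <= 0) stop("dt must be positive")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("vectors must be unit length (max |norm-1| = ",
         format(max(abs(nrm - 1))), ")")
  structure(list(vectors = vectors, dt = as.numeric(dt),
                 residue_id = as.integer(residue_id)),
            class = "vector_trajectory")
}

#' @export
print.vector_trajectory <- function(x, ...) {
  cat("vector_trajectory: residue", x$residue_id, "-", nrow(x$vectors),
      "steps, dt =", x$dt, "ps\n")
  invisible(x)
}

#' Select atoms from an ensemble
#'
#' @param ens a `conformer_ensemble`.
#' @param selection one of `"all"`, `"backbone"` (N, CA, C, O), `"calpha"`,
#'   or `"NH-pairs"`.  The first three return a reduced
#'   `conformer_ensemble`; `"NH-pairs"` returns a list of
#'   [vector_trajectory] objects, one per residue that carries both an amide
#'   N and an amide H ("H", "HN" or "H1"), holding the normalized H-N unit
#'   vector over time.  Prolines and the N-terminal residue are skipped
#'   (they have no amide proton / a charged amine); the skipped residues are
#'   recorded in the `"skipped"` attribute of the result.
#' @return reduced ensemble or list of vector trajectories.
#' @export
select_atoms <- function(ens, selection = c("all", "backbone", "calpha",
                                            "NH-pairs")) {
  selection <- match.arg(selection)
  if (selection == "NH-pairs") return(nh_vector_trajectories(ens))
  keep <- switch(selection,
    all = rep(TRUE, n_atoms(ens)),
    backbone = ens$atom_names %in% c("N", "CA", "C", "O"),
    calpha = ens$atom_names == "CA")
  if (!any(keep)) stop("no atoms matched selection '", selection, "'")
  subset_atoms(ens, which(keep))
}

subset_atoms <- function(ens, idx) {
  conformer_ensemble(ens$coords[, idx, , drop = FALSE],
                     atom_names = ens$atom_names[idx],
                     residue_ids = ens$residue_ids[idx],
                     elements = ens$elements[idx],
                     masses = ens$masses[idx],
                     resnames = ens$resnames[idx],
                     chain_id = ens$chain_id,
                     frame_times = ens$frame_times)
}

.amide_h_names <- c("H", "HN", "H1")

nh_vector_trajectories <- function(ens) {
  res <- sort(unique(ens$residue_ids))
  nterm <- res[1]
  if (length(ens$frame_times) > 1) {
    dts <- diff(ens$frame_times)
    dt <- dts[1]
    if (any(abs(dts - dt) > 1e-6 * max(dt, 1)))
      stop("NH-pairs selection needs uniformly spaced frames")
  } else dt <- 1
  out <- list()
  skipped <- integer(0)
  for (r in res) {
    in_res <- ens$residue_ids == r
    resname <- ens$resnames[in_res][1]
    if (r == nterm || toupper(resname) == "PRO") {
      skipped <- c(skipped, r)
      next
    }
    i_n <- which(in_res & ens$atom_names == "N")
    i_h <- which(in_res & ens$atom_names %in% .amide_h_names)
    if (length(i_n) != 1 || length(i_h) < 1) {
      skipped <- c(skipped, r)
      next
    }
    i_h <- i_h[1]
    v <- ens$coords[, i_h, ] - ens$coords[, i_n, ]
    if (n_frames(ens) == 1) v <- matrix(v, nrow = 1)
    nrm <- sqrt(rowSums(v^2))
    if (any(nrm == 0)) stop("coincident N and H atoms in residue ", r)
    out[[as.character(r)]] <- vector_trajectory(v / nrm, dt = dt,
                                                residue_id = r)
  }
  if (length(out) == 0) stop("no atoms matched selection 'NH-pairs'")
  attr(out, "skipped") <- skipped
  out
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Rotates and translates `mobile` onto `reference` minimizing the
#' weight-weighted RMSD; the rotation is constrained to be proper
#' (determinant +1).
#'
#' @param mobile,reference `n_atoms x 3` coordinate matrices.
#' @param weights positive per-atom weights (typically masses in Da);
#'   uniform when `NULL`.
#' @return list with `coords` (superposed mobile), `rmsd` (weighted, in A)
#'   and `rotation` (3 x 3 matrix).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("mobile and reference must have identical dimensions")
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0))
    stop("weights must be positive, one per atom")
  w <- weights / sum(weights)
  cm_m <- colSums(mobile * w); cm_r <- colSums(reference * w)
  X <- sweep(mobile, 2, cm_m); Y <- sweep(reference, 2, cm_r)
  # degenerate geometry: rank < 2 after centering (collinear points)
  if (n < 3) stop("degenerate geometry: fewer than 3 non-collinear atoms")
  sv <- svd(X * sqrt(w))$d
  if (sv[2] < 1e-10 * max(sv[1], 1))
    stop("degenerate geometry: fewer than 3 non-collinear atoms")
  H <- t(X * w) %*% Y
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- X %*% t(R)
  fitted <- sweep(fitted, 2, cm_r, "+")
  rmsd <- sqrt(sum(w * rowSums((fitted - reference)^2)))
  list(coords = fitted, rmsd = rmsd, rotation = R)
}

#' Mass-weighted RMSD time series against a reference frame
#'
#' Superposes every frame onto the reference with [kabsch_superpose] and
#' reports the minimized mass-weighted RMSD, the standard monitor of
#' structural drift along a trajectory.
#'
#' @param ens a `conformer_ensemble`.
#' @param reference frame index used as reference (default: first frame).
#' @param selection atom selection passed to [select_atoms]
#'   (default `"backbone"`; falls back to `"all"` when no backbone atoms
#'   are present, e.g. for bead models).
#' @return numeric vector of per-frame RMSD in A.
#' @export
rmsd_series <- function(ens, reference = 1, selection = "backbone") {
  sub <- tryCatch(select_atoms(ens, selection), error = function(e) NULL)
  if (is.null(sub)) sub <- ens
  ref <- frame_coords(sub, reference)
  vapply(seq_len(n_frames(sub)), function(i) {
    kabsch_superpose(frame_coords(sub, i), ref, weights = sub$masses)$rmsd
  }, numeric(1))
}
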