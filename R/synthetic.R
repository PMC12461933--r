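# Synthetic generators with analytically known ground truth.  These stand in
# for microsecond MD trajectories and measured observable tables, so every
# downstream stage (R_G, SAXS, helicity, relaxation) can be checked against
# closed forms.

#' Brownian rotational diffusion of a unit vector
#'
#' Simulates isotropic rotational diffusion on the unit sphere with rank-2
#' correlation time `tau_c`: the diffusion coefficient is
#' `D = 1/(6 tau_c)` and each step rotates the vector by an angle
#' `sqrt(4 D dt) |N(0,1)|` about a uniformly random axis perpendicular to the
#' current orientation.  The P2 autocorrelation of the output decays as
#' `exp(-t/tau_c)`, which makes this generator the analytic oracle for the
#' correlation-function and relaxation stages.
#'
#' @param tau_c rank-2 rotational correlation time in ps.
#' @param dt time step in ps; must resolve the rotation (`dt < tau_c/10`).
#' @param n_steps number of steps (at least 1000).
#' @param seed RNG seed (generators are fully seed-deterministic).
#' @param residue_id residue label attached to the trajectory.
#' @return a [vector_trajectory] with `n_steps + 1` orientations.
#' @export
simulate_rotdiff_vectors <- function(tau_c, dt, n_steps, seed,
                                     residue_id = 1L) {
  stopifnot(tau_c > 0, dt > 0, n_steps >= 1000)
  if (dt >= tau_c / 10)
    stop("dt must be < tau_c/10 to stay in the small-angle regime")
  set.seed(seed)
  D <- 1 / (6 * tau_c)
  v <- .rotdiff_walk(c(0, 0, 1), D, dt, n_steps)
  vector_trajectory(v, dt = dt, residue_id = residue_id)
}

# Core random walk on the sphere; renormalized every step to kill drift.
# With a finite cone half-angle the polar angle is reflected at the cone
# boundary each step (wobble-in-a-cone dynamics around +z).
.rotdiff_walk <- function(v0, D, dt, n_steps, cone_theta0 = Inf) {
  ang <- sqrt(4 * D * dt) * abs(stats::rnorm(n_steps))
  ca <- cos(ang); sa <- sin(ang)
  phi <- stats::runif(n_steps, 0, 2 * pi)
  cp <- cos(phi); sp <- sin(phi)
  v <- matrix(0, n_steps + 1, 3)
  x <- v0 / sqrt(sum(v0^2))
  v[1, ] <- x
  for (i in seq_len(n_steps)) {
    if (abs(x[1]) < 0.9) e1 <- c(0, x[3], -x[2]) else e1 <- c(x[3], 0, -x[1])
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(x[2] * e1[3] - x[3] * e1[2],
            x[3] * e1[1] - x[1] * e1[3],
            x[1] * e1[2] - x[2] * e1[1])
    x <- ca[i] * x + sa[i] * (cp[i] * e1 + sp[i] * e2)
    x <- x / sqrt(sum(x^2))
    if (is.finite(cone_theta0)) {
      th <- acos(min(1, max(-1, x[3])))
      if (th > cone_theta0) {
        th2 <- max(0, 2 * cone_theta0 - th)
        s_old <- sin(th)
        if (s_old > 0) {
          sc <- sin(th2) / s_old
          x <- c(x[1] * sc, x[2] * sc, cos(th2))
        } else x <- c(0, 0, 1)
      }
    }
    v[i + 1, ] <- x
  }
  v
}

#' Two-timescale (model-free) bond-vector dynamics
#'
#' Composes slow global tumbling (correlation time `tau_slow`) with fast
#' local wobble-in-a-cone motion whose amplitude is set from the order
#' parameter: `S2 = [cos(t0) (1 + cos(t0)) / 2]^2` fixes the cone half-angle
#' `t0`.  The resulting P2 correlation is approximately
#' `S2 exp(-t/tau_slow) + (1 - S2) exp(-t/tau_eff)` with
#' `tau_eff <= 2 tau_fast`.
#'
#' @param S2 order parameter in `[0, 1]`; `S2 = 1` reduces to pure global
#'   tumbling, `S2 = 0` to unrestricted fast local motion.
#' @param tau_slow,tau_fast global and local correlation times in ps
#'   (`tau_fast < tau_slow`).
#' @param dt time step in ps.
#' @param n_steps number of steps (at least 1000).
#' @param seed RNG seed.
#' @param residue_id residue label.
#' @return a [vector_trajectory].
#' @export
simulate_lipari_szabo <- function(S2, tau_slow, tau_fast, dt, n_steps, seed,
                                  residue_id = 1L) {
  stopifnot(S2 >= 0, S2 <= 1, tau_fast > 0, tau_fast < tau_slow,
            dt > 0, n_steps >= 1000)
  if (dt >= tau_slow / 10)
    stop("dt must be < tau_slow/10 to resolve the global motion")
  set.seed(seed)
  n <- n_steps + 1
  # cone half-angle from the standard model-free correspondence
  cth0 <- (-1 + sqrt(1 + 8 * sqrt(S2))) / 2
  th0 <- acos(min(1, max(0, cth0)))

  # local wobble inside the cone (reflecting boundary in the polar angle)
  if (th0 < 1e-12) {
    vloc <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  } else {
    Dloc <- 1 / (6 * tau_fast)
    vloc <- .rotdiff_walk(c(0, 0, 1), Dloc, dt, n_steps, cone_theta0 = th0)
  }

  # global tumbling as a diffusing rotation matrix (Rodrigues increments)
  Dslow <- 1 / (6 * tau_slow)
  eps <- sqrt(6 * Dslow * dt) * stats::rnorm(n_steps)
  ax <- matrix(stats::rnorm(3 * n_steps), n_steps, 3)
  ax <- ax / sqrt(rowSums(ax^2))
  v <- matrix(0, n, 3)
  R <- diag(3)
  v[1, ] <- vloc[1, ]
  for (i in seq_len(n_steps)) {
    u <- ax[i, ]; a <- eps[i]
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    dR <- diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
    R <- dR %*% R
    v[i + 1, ] <- R %*% vloc[i + 1, ]
  }
  v <- v / sqrt(rowSums(v^2))
  vector_trajectory(v, dt = dt, residue_id = residue_id)
}

#' Gaussian-chain conformer ensemble
#'
#' Each conformer is a freely jointed random walk of `n_res` C-alpha beads
#' with fixed step length `b`; bead masses are 1 Da.  The mean squared radius
#' of gyration converges to `n_res b^2 / 6` for long chains, the classic
#' Gaussian-chain result used to check the R_G and SAXS stages.
#'
#' @param n_res number of beads (residues), at least 2.
#' @param b bond length in A (default 3.8, the C-alpha virtual bond).
#' @param n_conformers number of independent conformers.
#' @param seed RNG seed.
#' @return a [conformer_ensemble] of C-alpha beads.
#' @export
sample_gaussian_chain <- function(n_res, b = 3.8, n_conformers = 1,
                                  seed = 1) {
  stopifnot(n_res >= 2, b > 0, n_conformers >= 1)
  set.seed(seed)
  n_bond <- n_res - 1
  u <- matrix(stats::rnorm(3 * n_bond * n_conformers), ncol = 3)
  u <- b * u / sqrt(rowSums(u^2))
  coords <- array(0, c(n_conformers, n_res, 3))
  for (k in seq_len(n_conformers)) {
    idx <- ((k - 1) * n_bond + 1):(k * n_bond)
    steps <- u[idx, , drop = FALSE]
    coords[k, , ] <- rbind(0, apply(steps, 2, cumsum))
  }
  conformer_ensemble(coords, atom_names = rep("CA", n_res),
                     residue_ids = seq_len(n_res),
                     elements = rep("C", n_res),
                     masses = rep(1, n_res))
}

#' Uniform-sphere bead ensemble
#'
#' Beads drawn uniformly from a ball of radius `R`; the analytic radius of
#' gyration is `sqrt(3/5) R` and the scattering profile follows the sphere
#' form factor, making this the SAXS/Guinier oracle fixture.
#'
#' @param R ball radius in A.
#' @param n_beads beads per conformer.
#' @param n_conformers number of conformers.
#' @param seed RNG seed.
#' @return a [conformer_ensemble] of unit-mass carbon beads.
#' @export
sample_sphere_beads <- function(R, n_beads, n_conformers = 1, seed = 1) {
  stopifnot(R > 0, n_beads >= 1, n_conformers >= 1)
  set.seed(seed)
  ntot <- n_beads * n_conformers
  u <- matrix(stats::rnorm(3 * ntot), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- R * stats::runif(ntot)^(1 / 3)
  pts <- u * r
  coords <- array(0, c(n_conformers, n_beads, 3))
  for (k in seq_len(n_conformers))
    coords[k, , ] <- pts[((k - 1) * n_beads + 1):(k * n_beads), , drop = FALSE]
  conformer_ensemble(coords, atom_names = rep("CA", n_beads),
                     residue_ids = seq_len(n_beads),
                     elements = rep("C", n_beads),
                     masses = rep(1, n_beads))
}

# -- internal-coordinate backbone builder (NeRF placement) --------------------

# Place atom D given A, B, C with bond |CD|, angle B-C-D (deg) and torsion
# A-B-C-D (deg).
.place_atom <- function(A, B, C, bond, angle, torsion) {
  th <- angle * pi / 180
  ta <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(th), bond * sin(th) * cos(ta), bond * sin(th) * sin(ta))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# Standard backbone geometry (lengths in A, angles in deg).
.bb_geom <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                 n_h = 1.01, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
                 ang_c_n_ca = 121.7, ang_ca_c_o = 120.8)

#' Build a single-conformer backbone with uniform dihedrals
#'
#' Constructs an N/H/CA/C/O backbone by sequential internal-coordinate
#' placement with the given `(phi, psi)` applied to every residue and
#' trans peptide bonds (`omega = 180`).  Amide hydrogens are placed 1.01 A
#' from N, anti-parallel to the preceding residue's C=O bond (the standard
#' reconstruction convention for hydrogen-bond analysis); the first residue
#' carries no amide H.
#'
#' @param n_res number of residues (at least 2).
#' @param phi,psi backbone dihedrals in degrees; the defaults (-57, -47)
#'   are the ideal alpha-helix, giving a rise of about 1.5 A per residue
#'   and i -> i+4 hydrogen bonds.
#' @param resname residue name given to all residues (default "ALA").
#' @return a one-frame [conformer_ensemble].
#' @export
build_ideal_helix <- function(n_res, phi = -57, psi = -47, resname = "ALA") {
  stopifnot(n_res >= 2)
  g <- .bb_geom
  N <- matrix(NA_real_, n_res, 3)
  CA <- matrix(NA_real_, n_res, 3)
  C <- matrix(NA_real_, n_res, 3)
  O <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  th <- g$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_res - 1)) {
    N[i + 1, ] <- .place_atom(N[i, ], CA[i, ], C[i, ],
                              g$c_n, g$ang_ca_c_n, psi)
    CA[i + 1, ] <- .place_atom(CA[i, ], C[i, ], N[i + 1, ],
                               g$n_ca, g$ang_c_n_ca, 180)
    C[i + 1, ] <- .place_atom(C[i, ], N[i + 1, ], CA[i + 1, ],
                              g$ca_c, g$ang_n_ca_c, phi)
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ],
                          g$c_o, g$ang_ca_c_o, psi + 180)
  }
  O[n_res, ] <- .place_atom(N[n_res, ], CA[n_res, ], C[n_res, ],
                            g$c_o, g$ang_ca_c_o, psi + 180)
  # amide H: 1.01 A from N, anti-parallel to preceding C=O
  H <- matrix(NA_real_, n_res, 3)
  for (i in 2:n_res) {
    co <- O[i - 1, ] - C[i - 1, ]
    H[i, ] <- N[i, ] - g$n_h * co / sqrt(sum(co^2))
  }
  names_per_res <- c("N", "H", "CA", "C", "O")
  rows <- list()
  atom_names <- character(0); resids <- integer(0)
  for (i in seq_len(n_res)) {
    if (i == 1) {
      rows <- c(rows, list(N[i, ], CA[i, ], C[i, ], O[i, ]))
      atom_names <- c(atom_names, c("N", "CA", "C", "O"))
      resids <- c(resids, rep(i, 4))
    } else {
      rows <- c(rows, list(N[i, ], H[i, ], CA[i, ], C[i, ], O[i, ]))
      atom_names <- c(atom_names, names_per_res)
      resids <- c(resids, rep(i, 5))
    }
  }
  xyz <- do.call(rbind, rows)
  coords <- array(xyz, c(1, nrow(xyz), 3))
  coords[1, , ] <- xyz
  conformer_ensemble(coords, atom_names = atom_names, residue_ids = resids,
                     resnames = resname)
}

#' Add calibrated Gaussian noise to an observable table
#'
#' Emulates an "experimental" data table: Gaussian noise with standard
#' deviation `relative_noise * |true value|` is added to every requested
#' column, and the exact sigma used is recorded in a matching `*_err`
#' column (or `eps` for a [scattering_profile]) so that error-weighted fits
#' and overlap criteria can use the true noise level.
#'
#' @param x a data.frame of true values, or a [scattering_profile].
#' @param relative_noise relative noise level (0 reproduces the input).
#' @param seed RNG seed.
#' @param columns columns to perturb; default: all numeric columns except
#'   the first (assumed to be the independent variable / residue index).
#' @return same shape as the input, with noisy values and error columns.
#' @export
make_noisy_table <- function(x, relative_noise, seed, columns = NULL) {
  stopifnot(relative_noise >= 0)
  set.seed(seed)
  if (inherits(x, "scattering_profile")) {
    sig <- relative_noise * abs(x$I)
    x$I <- x$I + stats::rnorm(length(x$I), 0, 1) * sig
    x$eps <- sig
    return(x)
  }
  if (!is.data.frame(x)) stop("x must be a data.frame or scattering_profile")
  if (is.null(columns)) {
    num <- names(x)[vapply(x, is.numeric, logical(1))]
    columns <- setdiff(num, num[1])
    if (length(columns) == 0) columns <- num
  }
  for (cl in columns) {
    sig <- relative_noise * abs(x[[cl]])
    x[[cl]] <- x[[cl]] + stats::rnorm(nrow(x), 0, 1) * sig
    x[[paste0(cl, "_err")]] <- sig
  }
  x
}
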