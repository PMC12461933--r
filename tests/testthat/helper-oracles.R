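# Independent oracles and fixture builders shared across tests.  Everything
# here is deliberately written without calling the package's own
# implementation of the quantity it checks.

# Closed-form 15N relaxation for isotropic tumbling with correlation time
# tau_ps, using the conventional Lorentzian spectral density
# J(w) = (2/5) tau / (1 + (w tau)^2).  Constants are written out here
# independently of the package's redfield_relaxation().
oracle_redfield <- function(tau_ps, freq_MHz, rNH_A = 1.02,
                            dsig_ppm = -170,
                            gH = 2.6752218744e8, gN = -2.7126e7) {
  tau <- tau_ps * 1e-12
  J <- function(w) 0.4 * tau / (1 + (w * tau)^2)
  wH <- 2 * pi * freq_MHz * 1e6
  wN <- wH * abs(gN) / gH
  d <- 1e-7 * 1.054571817e-34 * gH * gN / (rNH_A * 1e-10)^3
  c2 <- (wN * dsig_ppm * 1e-6 / sqrt(3))^2
  R1 <- d^2 / 4 * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + c2 * J(wN)
  R2 <- d^2 / 8 * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                     6 * J(wH + wN)) +
    c2 / 6 * (4 * J(0) + 3 * J(wN))
  noe <- 1 + (gH / gN) * d^2 / 4 * (6 * J(wH + wN) - J(wH - wN)) / R1
  list(T1 = 1 / R1, T2 = 1 / R2, NOE = noe)
}

# Brute-force minimum weighted RMSD over a coarse grid of rotations
# (ZYZ Euler angles) after centering; independent check of the Kabsch
# superposition on small systems.
oracle_rmsd_grid <- function(mobile, reference, weights, n_grid = 40) {
  w <- weights / sum(weights)
  X <- sweep(mobile, 2, colSums(mobile * w))
  Y <- sweep(reference, 2, colSums(reference * w))
  rotz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                               0, 0, 1), 3, 3)
  roty <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                               sin(a), 0, cos(a)), 3, 3)
  best <- Inf
  ang1 <- seq(0, 2 * pi, length.out = n_grid)
  ang2 <- seq(0, pi, length.out = n_grid / 2)
  for (a in ang1) for (b in ang2) for (g in ang1) {
    R <- rotz(a) %*% roty(b) %*% rotz(g)
    v <- sqrt(sum(w * rowSums((X %*% t(R) - Y)^2)))
    if (v < best) best <- v
  }
  best
}

# Analytic normalized sphere form factor.
sphere_form_factor <- function(q, R) {
  x <- q * R
  ifelse(x == 0, 1, (3 * (sin(x) - x * cos(x)) / x^3)^2)
}

# Concatenate the frames of ensembles sharing one topology.
combine_frames <- function(e1, e2) {
  stopifnot(identical(e1$atom_names, e2$atom_names))
  coords <- array(0, c(n_frames(e1) + n_frames(e2), n_atoms(e1), 3))
  coords[seq_len(n_frames(e1)), , ] <- e1$coords
  coords[n_frames(e1) + seq_len(n_frames(e2)), , ] <- e2$coords
  conformer_ensemble(coords, atom_names = e1$atom_names,
                     residue_ids = e1$residue_ids, elements = e1$elements,
                     masses = e1$masses, resnames = e1$resnames)
}

# Build a conformer_ensemble directly from a frames x atoms x 3 array of
# C-alpha positions (unit masses).
ca_ensemble <- function(coords) {
  n <- dim(coords)[2]
  conformer_ensemble(coords, atom_names = rep("CA", n),
                     residue_ids = seq_len(n), elements = rep("C", n),
                     masses = rep(1, n))
}

# Single-exponential decay time fitted to the initial part of a
# correlation function (log-linear fit up to ~1.5 decay times).
fit_single_tau <- function(cf, window_ps) {
  idx <- cf$t <= window_ps & cf$C > 0.05
  stats::setNames(-1 / stats::coef(stats::lm(log(cf$C[idx]) ~ cf$t[idx]))[2],
                  NULL)
}
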