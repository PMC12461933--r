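test_that("multi-model PDB round trip preserves structure and coordinates", {
  chain <- sample_gaussian_chain(91, b = 3.8, n_conformers = 5, seed = 3)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(chain, pdb)
  back <- read_ensemble(pdb)
  expect_equal(n_frames(back), 5)
  expect_equal(n_atoms(back), 91)
  # PDB stores 3 decimals
  expect_lt(max(abs(back$coords - chain$coords)), 5.1e-4)
  expect_equal(back$residue_ids, chain$residue_ids)
})

test_that("PDB reader counts models and atoms and flags bad input", {
  pdb2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1       0.100   0.000   0.000           N",
    "ATOM      2  CA  ALA A   1       1.558   0.000   0.000           C",
    "ATOM      3  C   ALA A   1       2.100   1.400   0.000           C",
    "ENDMDL", "END"), pdb2)
  ens <- read_ensemble(pdb2)
  expect_equal(n_frames(ens), 2)
  expect_equal(n_atoms(ens), 3)
  expect_equal(ens$elements, c("N", "C", "C"))

  # single MODEL
  pdb1 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(readLines(pdb2)[1:5], pdb1)
  expect_equal(n_frames(read_ensemble(pdb1)), 1)

  # inconsistent atom counts across models
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(readLines(pdb2)[-8], bad)
  expect_error(read_ensemble(bad), "differing atom counts")

  # corrupt numeric field names the line
  corrupt <- withr::local_tempfile(fileext = ".pdb")
  ln <- readLines(pdb2)
  substr(ln[2], 32, 38) <- "  xx.xx"
  writeLines(ln, corrupt)
  expect_error(read_ensemble(corrupt), "line 2")
})

test_that("xyz-table round trip keeps frame blocks and times", {
  chain <- sample_gaussian_chain(91, n_conformers = 5, seed = 4)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_ensemble(chain, xyz, format = "xyz")
  back <- read_ensemble(xyz, format = "xyz")
  expect_equal(n_frames(back), 5)
  expect_equal(n_atoms(back), 91)
  expect_equal(back$coords, chain$coords, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$frame_times, chain$frame_times)
})

test_that("atom selections subset atoms and extract amide vectors", {
  helix <- build_ideal_helix(12)
  expect_equal(n_atoms(select_atoms(helix, "calpha")), 12)
  expect_equal(n_atoms(select_atoms(helix, "backbone")), 48)

  # constructed geometry: H exactly 1.02 A along +x from N
  n_res <- 5
  xyz <- NULL
  for (i in seq_len(n_res)) xyz <- rbind(xyz, c(3 * i, 0, 0), c(3 * i + 1.02, 0, 0))
  coords <- array(0, c(2, 2 * n_res, 3))
  coords[1, , ] <- xyz; coords[2, , ] <- xyz + 5
  ens <- conformer_ensemble(coords,
                            atom_names = rep(c("N", "H"), n_res),
                            residue_ids = rep(seq_len(n_res), each = 2))
  vlist <- select_atoms(ens, "NH-pairs")
  expect_equal(length(vlist), n_res - 1)       # N-terminus skipped
  expect_equal(attr(vlist, "skipped"), 1L)
  for (v in vlist)
    expect_equal(v$vectors, matrix(c(1, 0, 0), 2, 3, byrow = TRUE),
                 ignore_attr = TRUE)
})

test_that("prolines and the N-terminal residue are excluded from NH pairs", {
  n_res <- 91
  pro_at <- c(30, 60)
  xyz <- NULL; names_v <- c(); resid <- c(); resn <- c()
  for (i in seq_len(n_res)) {
    xyz <- rbind(xyz, c(3 * i, 0, 0))
    names_v <- c(names_v, "N"); resid <- c(resid, i)
    resn <- c(resn, if (i %in% pro_at) "PRO" else "ALA")
    if (!(i %in% pro_at)) {
      xyz <- rbind(xyz, c(3 * i + 1.02, 0, 0))
      names_v <- c(names_v, "H"); resid <- c(resid, i)
      resn <- c(resn, "ALA")
    }
  }
  coords <- array(xyz, c(1, nrow(xyz), 3)); coords[1, , ] <- xyz
  ens <- conformer_ensemble(coords, atom_names = names_v,
                            residue_ids = resid, resnames = resn)
  vlist <- select_atoms(ens, "NH-pairs")
  expect_equal(length(vlist), 91 - 2 - 1)
  expect_true(all(c(1, pro_at) %in% attr(vlist, "skipped")))
})

test_that("Kabsch superposition minimizes weighted RMSD", {
  set.seed(42)
  ref <- matrix(rnorm(12), 4, 3)
  # identical frames and pure translation both give zero
  expect_equal(kabsch_superpose(ref, ref)$rmsd, 0, tolerance = 1e-12)
  expect_equal(kabsch_superpose(ref + 5, ref)$rmsd, 0, tolerance = 1e-9)

  # displaced atom: agree with a brute-force rotation-grid search
  mob <- ref; mob[2, ] <- mob[2, ] + c(1.5, -0.5, 0.7)
  w <- c(1, 2, 3, 4)
  got <- kabsch_superpose(mob, ref, w)$rmsd
  brute <- oracle_rmsd_grid(mob, ref, w)
  expect_lte(got, brute + 1e-9)        # Kabsch is the true minimum
  expect_lt(abs(got - brute), 0.02)    # coarse grid approaches it
  expect_equal(det(kabsch_superpose(mob, ref, w)$rotation), 1,
               tolerance = 1e-9)
})

test_that("RMSD is symmetric and rigid-transform invariant", {
  set.seed(7)
  for (rep in 1:5) {
    A <- matrix(rnorm(18), 6, 3)
    B <- A + 0.3 * matrix(rnorm(18), 6, 3)
    r1 <- kabsch_superpose(A, B)$rmsd
    r2 <- kabsch_superpose(B, A)$rmsd
    expect_lt(abs(r1 - r2), 1e-9)
    # common rigid transform
    th <- runif(3, 0, 2 * pi)
    R <- matrix(c(cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1]), 0,
                  0, 0, 1), 3, 3)
    shift <- rnorm(3)
    r3 <- kabsch_superpose(sweep(A %*% t(R), 2, shift, "+"),
                           sweep(B %*% t(R), 2, shift, "+"))$rmsd
    expect_lt(abs(r1 - r3), 1e-9)
  }
})

test_that("Kabsch agrees with bio3d on an unweighted case", {
  skip_if_not_installed("bio3d")
  set.seed(11)
  ref <- matrix(rnorm(30), 10, 3)
  mob <- ref + 0.4 * matrix(rnorm(30), 10, 3)
  got <- kabsch_superpose(mob, ref)$rmsd
  fitted <- suppressWarnings(
    bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(mob))))
  ref_b <- matrix(as.vector(t(ref)), ncol = 3, byrow = TRUE)
  mob_b <- matrix(fitted, ncol = 3, byrow = TRUE)
  expect_equal(got, sqrt(mean(rowSums((mob_b - ref_b)^2))),
               tolerance = 1e-6)
})

test_that("rmsd_series tracks structural drift", {
  helix <- build_ideal_helix(10)
  coords <- array(0, c(3, n_atoms(helix), 3))
  xyz <- frame_coords(helix, 1)
  coords[1, , ] <- xyz
  coords[2, , ] <- xyz          # identical
  th <- 0.8
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  coords[3, , ] <- xyz %*% t(R) # pure rotation
  ens <- conformer_ensemble(coords, atom_names = helix$atom_names,
                            residue_ids = helix$residue_ids,
                            resnames = helix$resnames)
  r <- rmsd_series(ens)
  expect_equal(r[1], 0, tolerance = 1e-12)
  expect_equal(r[2], 0, tolerance = 1e-12)
  expect_equal(r[3], 0, tolerance = 1e-9)

  # diffusing chain: RMSD trend increases (Spearman rho > 0, p < 0.01)
  set.seed(5)
  n_fr <- 100; n_at <- 30
  coords <- array(0, c(n_fr, n_at, 3))
  coords[1, , ] <- matrix(rnorm(n_at * 3, sd = 4), n_at, 3)
  for (k in 2:n_fr)
    coords[k, , ] <- coords[k - 1, , ] + matrix(rnorm(n_at * 3, sd = 0.15),
                                                n_at, 3)
  ens <- ca_ensemble(coords)
  r <- rmsd_series(ens, selection = "all")
  ct <- suppressWarnings(cor.test(seq_along(r), r, method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("degenerate and invalid inputs raise structured errors", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "degenerate")
  lin <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(lin, lin), "degenerate")
  helix <- build_ideal_helix(5)
  expect_error(select_atoms(helix, "nope"))
  expect_error(replicate_set(list()), "at least one")
  expect_error(vector_trajectory(matrix(c(1, 1, 0), 1, 3), dt = 1),
               "unit length")
})
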