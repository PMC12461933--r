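#' Per-residue alpha-helicity by hydrogen-bond assignment
#'
#' Applies the Kabsch-Sander electrostatic hydrogen-bond criterion to every
#' frame: the bond energy between an acceptor carbonyl (C=O of residue i) and
#' a donor amide (N-H of residue j) is
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol and a
#' hydrogen bond exists when `E < -0.5` kcal/mol.  A residue is assigned the
#' alpha-helix state when it lies inside a run created by two consecutive
#' i -> i+4 hydrogen bonds (turns at i-1 and i mark residues i..i+3 helical).
#' Only the alpha-helix state is assigned; 3-10, pi and strand states are out
#' of scope.
#'
#' Amide hydrogens are taken from the coordinates when present (names "H",
#' "HN" or "H1"); otherwise they are reconstructed 1.01 A from N,
#' anti-parallel to the preceding residue's C=O bond, the standard
#' reconstruction used by hydrogen-bond analyses of MD-derived structures
#' that lack protons.  The first residue and prolines never donate.
#'
#' @param ens a [conformer_ensemble] with backbone N, CA, C, O atoms.
#' @return object of class `helicity_profile`: list with `fraction`
#'   (per-residue helical fraction in `[0, 1]`), `residue` and `n_frames`.
#' @export
assign_helicity <- function(ens) {
  res <- sort(unique(ens$residue_ids))
  nres <- length(res)
  idx_of <- function(name) {
    vapply(res, function(r) {
      i <- which(ens$residue_ids == r & ens$atom_names == name)
      if (length(i) == 0) NA_integer_ else i[1]
    }, integer(1))
  }
  iN <- idx_of("N"); iC <- idx_of("C"); iO <- idx_of("O")
  iH <- vapply(res, function(r) {
    i <- which(ens$residue_ids == r & ens$atom_names %in% .amide_h_names)
    if (length(i) == 0) NA_integer_ else i[1]
  }, integer(1))
  missing_co <- res[is.na(iC) | is.na(iO) | is.na(iN)]
  if (length(missing_co))
    stop("missing backbone N/C/O atoms for residue(s): ",
         paste(missing_co, collapse = ", "))
  is_pro <- toupper(vapply(res, function(r)
    ens$resnames[ens$residue_ids == r][1], character(1))) == "PRO"

  helical_count <- numeric(nres)
  nf <- n_frames(ens)
  for (k in seq_len(nf)) {
    xyz <- frame_coords(ens, k)
    N <- xyz[iN, , drop = FALSE]
    C <- xyz[iC, , drop = FALSE]
    O <- xyz[iO, , drop = FALSE]
    H <- matrix(NA_real_, nres, 3)
    have_h <- !is.na(iH)
    H[have_h, ] <- xyz[iH[have_h], , drop = FALSE]
    # reconstruct missing amide H (not for residue 1, not for prolines)
    need <- which(!have_h & seq_len(nres) > 1 & !is_pro)
    if (length(need)) {
      co <- C[need - 1, , drop = FALSE] - O[need - 1, , drop = FALSE]
      co <- co / sqrt(rowSums(co^2))
      H[need, ] <- N[need, , drop = FALSE] + 1.01 * co
    }
    # i -> i+4 turns via the Kabsch-Sander energy
    turn <- rep(FALSE, nres)
    if (nres >= 5) {
      i <- seq_len(nres - 4); j <- i + 4
      donor_ok <- !is_pro[j] & !is.na(H[j, 1]) & j > 1
      dist <- function(a, b) sqrt(rowSums((a - b)^2))
      r_on <- dist(O[i, , drop = FALSE], N[j, , drop = FALSE])
      r_ch <- dist(C[i, , drop = FALSE], H[j, , drop = FALSE])
      r_oh <- dist(O[i, , drop = FALSE], H[j, , drop = FALSE])
      r_cn <- dist(C[i, , drop = FALSE], N[j, , drop = FALSE])
      E <- 0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
      turn[i] <- donor_ok & !is.na(E) & E < -0.5
    }
    # two consecutive turns (i-1, i) make residues i..i+3 helical
    helical <- rep(FALSE, nres)
    two <- which(turn[-1] & turn[-nres]) + 1   # indices i with turn[i-1] & turn[i]
    for (i in two) helical[i:min(nres, i + 3)] <- TRUE
    helical_count <- helical_count + helical
  }
  structure(list(fraction = helical_count / nf, residue = res,
                 n_frames = nf),
            class = "helicity_profile")
}

#' @export
print.helicity_profile <- function(x, ...) {
  cat("helicity_profile:", length(x$residue), "residues over", x$n_frames,
      "frames; mean helicity", round(mean(x$fraction), 3), "\n")
  invisible(x)
}
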