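#' Synthetic stand-in sequences for the COR15A study system
#'
#' `cor15a_synthetic` is NOT the real COR15A sequence.  It is a synthetic
#' 91-residue stand-in constructed once to match the documented sequence
#' statistics of the mature protein: 91 residues, glycine at position 68
#' (so the G68A point mutant is well defined), a LEA-protein-like
#' composition rich in A/G/S/T/K/E, a high fraction of charged residues
#' with near-uniform charge mixing, and a formal net charge of -6 at
#' pH 7.0 under the package's fixed pKa set.  Use it wherever a concrete
#' chain of the right length and charge is needed; do not treat it as the
#' biological sequence.
#'
#' `cor15a_g68a_synthetic` is the same chain with the single substitution
#' G68A.
#'
#' @format character string of 91 one-letter amino-acid codes.
#' @export
cor15a_synthetic <- paste0(
  "MASEKTKDQAGSVKEATNAGLEKTAEGAKQASDTVKEGAEYAGKTFSEDA",
  "KNSTGEAIRKDATEQAGGDLTRKEASQTAENVKSDGATEES")

#' @rdname cor15a_synthetic
#' @export
cor15a_g68a_synthetic <- local({
  s <- strsplit(paste0(
    "MASEKTKDQAGSVKEATNAGLEKTAEGAKQASDTVKEGAEYAGKTFSEDA",
    "KNSTGEAIRKDATEQAGGDLTRKEASQTAENVKSDGATEES"), "")[[1]]
  stopifnot(s[68] == "G")
  s[68] <- "A"
  paste(s, collapse = "")
})
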