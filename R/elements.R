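# Element properties used throughout: atomic masses (Da) and electron counts.
# Coordinates are in Angstrom, times in ps, everywhere in this package.

.element_mass <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  FE = 55.845, ZN = 65.38, MG = 24.305, "NA" = 22.990, CL = 35.45,
  MN = 54.938, SE = 78.971, CA = 40.078, K = 39.098
)

.element_electrons <- c(
  H = 1, C = 6, N = 7, O = 8, S = 16, P = 15,
  FE = 26, ZN = 30, MG = 12, "NA" = 11, CL = 17,
  MN = 25, SE = 34, CA = 20, K = 19
)

# Atom names that denote a genuine two-letter element; everything else falls
# back to the first alphabetic character of the atom name (protein "CA" is a
# C-alpha carbon, not calcium, so it is deliberately absent here).
.two_letter_elements <- c("FE", "ZN", "MG", "NA", "CL", "MN", "SE", "BR")

#' Infer chemical elements from PDB-style atom names
#'
#' The first alphabetic character of the atom name is taken as the element
#' symbol, unless the full name matches a known two-letter (metal/halogen)
#' element.  This mirrors how coordinate files lacking an element column are
#' commonly interpreted for proteins, where e.g. "CA" is the alpha carbon.
#'
#' @param atom_names character vector of atom names (e.g. "N", "CA", "1HG1").
#' @return character vector of element symbols.
#' @export
infer_elements <- function(atom_names) {
  up <- toupper(trimws(atom_names))
  el <- character(length(up))
  two <- up %in% .two_letter_elements
  el[two] <- up[two]
  first_alpha <- vapply(strsplit(up[!two], ""), function(ch) {
    a <- ch[grepl("[A-Z]", ch)]
    if (length(a) == 0) stop("atom name without alphabetic character: '",
                             paste(ch, collapse = ""), "'")
    a[1]
  }, character(1))
  el[!two] <- first_alpha
  el
}

element_masses <- function(elements) {
  m <- .element_mass[toupper(elements)]
  if (anyNA(m)) {
    stop("unknown element(s): ",
         paste(unique(toupper(elements)[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

element_electrons <- function(elements) {
  f <- .element_electrons[toupper(elements)]
  if (anyNA(f)) {
    stop("unknown element(s): ",
         paste(unique(toupper(elements)[is.na(f)]), collapse = ", "))
  }
  unname(f)
}
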