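#' Read a conformational ensemble from file
#'
#' Two plain-text interchange formats are supported:
#' \describe{
#'   \item{`"pdb"`}{multi-model PDB: one frame per MODEL/ENDMDL block (a file
#'     without MODEL records is a single frame).  Elements are taken from
#'     columns 77-78 when present, otherwise inferred from atom names.}
#'   \item{`"xyz"`}{whitespace- or comma-delimited table with columns
#'     `time atom resid x y z` (time in ps, coordinates in A); lines starting
#'     with `#` are ignored; one frame per distinct time value, in order of
#'     first appearance.}
#' }
#'
#' @param path file to read.
#' @param format `"pdb"` or `"xyz"`; guessed from the file extension when
#'   missing.
#' @return a [conformer_ensemble].
#' @export
read_ensemble <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  switch(match.arg(format, c("pdb", "xyz")),
         pdb = read_ensemble_pdb(path),
         xyz = read_ensemble_xyz(path))
}

read_ensemble_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("parse error: no ATOM records in ", path)
  model_id <- cumsum(startsWith(lines, "MODEL"))
  if (max(model_id) == 0) model_id <- model_id + 1L
  model_of_atom <- model_id[is_atom]
  atom_lines <- lines[is_atom]
  atom_lineno <- which(is_atom)

  num <- function(start, stop_, what) {
    s <- substr(atom_lines, start, stop_)
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v))
    if (length(bad))
      stop("parse error at line ", atom_lineno[bad[1]], ": bad ", what,
           " field '", s[bad[1]], "'")
    v
  }
  name <- trimws(substr(atom_lines, 13, 16))
  resname <- trimws(substr(atom_lines, 18, 20))
  chain <- trimws(substr(atom_lines, 22, 22))
  resid <- as.integer(num(23, 26, "residue number"))
  x <- num(31, 38, "x"); y <- num(39, 46, "y"); z <- num(47, 54, "z")
  elem <- trimws(substr(atom_lines, 77, 78))

  frames <- unique(model_of_atom)
  counts <- tabulate(match(model_of_atom, frames))
  if (length(unique(counts)) != 1)
    stop("structural error: models contain differing atom counts (",
         paste(unique(counts), collapse = ", "), ")")
  n_at <- counts[1]
  first <- model_of_atom == frames[1]
  coords <- array(NA_real_, c(length(frames), n_at, 3))
  for (k in seq_along(frames)) {
    sel <- model_of_atom == frames[k]
    coords[k, , ] <- cbind(x[sel], y[sel], z[sel])
  }
  el <- elem[first]
  if (any(el == "")) el <- NULL
  conformer_ensemble(coords,
                     atom_names = name[first],
                     residue_ids = resid[first],
                     elements = el,
                     resnames = resname[first],
                     chain_id = if (chain[1] == "") "A" else chain[1])
}

read_ensemble_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("parse error: no data rows in ", path)
  rows <- strsplit(trimws(gsub(",", " ", lines[keep])), "\\s+")
  lineno <- which(keep)
  nfield <- lengths(rows)
  if (any(nfield != 6))
    stop("parse error at line ", lineno[which(nfield != 6)[1]],
         ": expected 6 fields (time atom resid x y z)")
  m <- do.call(rbind, rows)
  tm <- suppressWarnings(as.numeric(m[, 1]))
  xyz <- suppressWarnings(matrix(as.numeric(m[, 4:6]), ncol = 3))
  resid <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(tm) | is.na(resid) | rowSums(is.na(xyz)) > 0)
  if (length(bad))
    stop("parse error at line ", lineno[bad[1]], ": non-numeric field")
  frames <- unique(tm)
  counts <- tabulate(match(tm, frames))
  if (length(unique(counts)) != 1)
    stop("structural error: time blocks contain differing atom counts")
  n_at <- counts[1]
  coords <- array(NA_real_, c(length(frames), n_at, 3))
  for (k in seq_along(frames)) coords[k, , ] <- xyz[tm == frames[k], ]
  first <- tm == frames[1]
  conformer_ensemble(coords,
                     atom_names = m[first, 2],
                     residue_ids = resid[first],
                     frame_times = frames)
}

#' Write a conformational ensemble to file
#'
#' Writers emit a leading comment/REMARK line naming the units
#' (A for coordinates, ps for times).
#'
#' @param ens a [conformer_ensemble].
#' @param path output file.
#' @param format `"pdb"` (multi-model) or `"xyz"` (delimited table);
#'   guessed from the extension when missing.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ens, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  format <- match.arg(format, c("pdb", "xyz"))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    writeLines("REMARK   coordinates in Angstrom", con)
    pad_name <- ifelse(nchar(ens$atom_names) < 4,
                       sprintf(" %-3s", ens$atom_names), ens$atom_names)
    for (k in seq_len(n_frames(ens))) {
      writeLines(sprintf("MODEL     %4d", k), con)
      xyz <- frame_coords(ens, k)
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        seq_len(n_atoms(ens)) %% 100000, pad_name, ens$resnames,
        ens$chain_id, ens$residue_ids, xyz[, 1], xyz[, 2], xyz[, 3],
        1, 0, ens$elements), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    writeLines("# time_ps atom resid x_A y_A z_A", con)
    for (k in seq_len(n_frames(ens))) {
      xyz <- frame_coords(ens, k)
      writeLines(sprintf("%.6g %s %d %.6f %.6f %.6f",
                         ens$frame_times[k], ens$atom_names,
                         ens$residue_ids, xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
  }
  invisible(path)
}
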