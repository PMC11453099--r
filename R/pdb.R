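#' @keywords internal
"_PACKAGE"

# Standard residue tables ------------------------------------------------

#' Three-letter to one-letter amino-acid code map
#' @noRd
.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

.STANDARD_AA <- names(.AA3TO1)

#' Parse an antigen structure from a PDB file
#'
#' Reads ATOM records of the selected chains from a PDB-format file and
#' returns the standard amino-acid residues with their heavy-atom
#' coordinates and per-residue geometric centers.  Waters, HETATM ligands,
#' hydrogens and non-standard residues are removed; for alternate
#' locations only the first conformer of each atom is kept; only the first
#' NMR model is read.  Residue order follows file order.
#'
#' @param path Path to a PDB-format file.
#' @param chains Character vector of chain identifiers to keep, or `NULL`
#'   for all chains.
#' @return An object of class `antigen_structure`: a list with
#'   \describe{
#'     \item{residues}{data.frame with columns `chain`, `seqnum`, `icode`,
#'       `resname` (one row per residue, file order).}
#'     \item{coords}{list of per-residue heavy-atom coordinate matrices
#'       (Angstrom).}
#'     \item{centers}{n x 3 matrix of per-residue geometric centers.}
#'     \item{source}{list with the file name and chain selection.}
#'   }
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
#'   "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
#'   "END"), pdb)
#' s <- parse_structure(pdb)
#' s$residues
#' @export
parse_structure <- function(path, chains = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  # honour only the first model of multi-model (NMR) entries
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1)]

  atom <- lines[startsWith(lines, "ATOM  ")]
  if (length(atom) == 0) stop("no ATOM records in ", path)

  fw <- function(x, from, to) trimws(substr(x, from, to))
  rec <- data.frame(
    name    = fw(atom, 13, 16),
    altloc  = fw(atom, 17, 17),
    resname = fw(atom, 18, 20),
    chain   = fw(atom, 22, 22),
    seqnum  = as.integer(fw(atom, 23, 26)),
    icode   = fw(atom, 27, 27),
    x       = as.numeric(fw(atom, 31, 38)),
    y       = as.numeric(fw(atom, 39, 46)),
    z       = as.numeric(fw(atom, 47, 54)),
    element = toupper(fw(atom, 77, 78)),
    stringsAsFactors = FALSE
  )
  # element column may be absent in minimal files: fall back to atom name
  noel <- rec$element == ""
  rec$element[noel] <- substr(gsub("[0-9]", "", rec$name[noel]), 1, 1)

  if (!is.null(chains)) {
    if (!any(rec$chain %in% chains))
      stop("none of the requested chains (", paste(chains, collapse = ","),
           ") present in ", path)
    rec <- rec[rec$chain %in% chains, , drop = FALSE]
  }

  rec <- rec[!(rec$element %in% c("H", "D")), , drop = FALSE]

  nonstd <- setdiff(unique(rec$resname), .STANDARD_AA)
  if (length(nonstd) > 0) {
    warning("dropping non-standard residues: ", paste(nonstd, collapse = ", "))
    rec <- rec[rec$resname %in% .STANDARD_AA, , drop = FALSE]
  }

  # first alternate location per (residue, atom name)
  akey <- paste(rec$chain, rec$seqnum, rec$icode, rec$name, sep = "|")
  rec <- rec[!duplicated(akey), , drop = FALSE]

  if (nrow(rec) == 0) stop("no standard amino-acid residues after filtering")

  rkey <- paste(rec$chain, rec$seqnum, rec$icode, sep = "|")
  ridx <- match(rkey, unique(rkey))        # file order preserved
  first <- !duplicated(rkey)

  residues <- data.frame(
    chain   = rec$chain[first],
    seqnum  = rec$seqnum[first],
    icode   = rec$icode[first],
    resname = rec$resname[first],
    stringsAsFactors = FALSE
  )
  coords <- lapply(seq_len(nrow(residues)), function(i) {
    m <- as.matrix(rec[ridx == i, c("x", "y", "z")])
    dimnames(m) <- list(rec$name[ridx == i], c("x", "y", "z"))
    m
  })
  elements <- lapply(seq_len(nrow(residues)),
                     function(i) rec$element[ridx == i])
  centers <- t(vapply(coords, geometric_center, numeric(3)))
  colnames(centers) <- c("x", "y", "z")

  structure(list(
    residues = residues,
    coords   = coords,
    elements = elements,
    centers  = centers,
    source   = list(path = path, chains = chains %||% unique(residues$chain))
  ), class = "antigen_structure")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric center of a residue
#'
#' Unweighted arithmetic mean of heavy-atom coordinates.
#'
#' @param coords Numeric matrix with one row per atom and columns x, y, z.
#' @return Numeric 3-vector (Angstrom).
#' @export
geometric_center <- function(coords) {
  coords <- rbind(coords)
  if (nrow(coords) == 0) stop("geometric_center: empty atom list")
  colMeans(coords[, 1:3, drop = FALSE])
}

#' Residue identifier keys "chain|seqnum|icode"
#' @noRd
residue_keys <- function(residues) {
  paste(residues$chain, residues$seqnum, residues$icode, sep = "|")
}

#' Number of residues in a structure
#' @param x An `antigen_structure`.
#' @param ... Ignored.
#' @export
length.antigen_structure <- function(x) nrow(x$residues)

#' @export
print.antigen_structure <- function(x, ...) {
  cat("antigen_structure:", nrow(x$residues), "residues,",
      sum(vapply(x$coords, nrow, integer(1))), "heavy atoms\n")
  cat("  chains:", paste(unique(x$residues$chain), collapse = ", "), "\n")
  cat("  source:", x$source$path, "\n")
  invisible(x)
}

#' @export
as.data.frame.antigen_structure <- function(x, ...) {
  cbind(x$residues, as.data.frame(x$centers))
}

#' One-letter sequence of a structure's residue list
#'
#' @param structure An `antigen_structure`.
#' @return Single character string (residues in file order).
#' @export
structure_sequence <- function(structure) {
  paste(.AA3TO1[structure$residues$resname], collapse = "")
}

#' Write the per-residue surface/center profile as TSV
#'
#' Columns: chain, seqnum, icode, resname, rsa, is_surface, cx, cy, cz.
#'
#' @param structure An `antigen_structure`.
#' @param profile A `surface_profile` for the same structure.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_residue_profile <- function(structure, profile, path) {
  stopifnot(length(profile$rsa) == nrow(structure$residues))
  out <- cbind(structure$residues,
               rsa = round(profile$rsa, 4),
               is_surface = profile$is_surface,
               cx = round(structure$centers[, 1], 3),
               cy = round(structure$centers[, 2], 3),
               cz = round(structure$centers[, 3], 3))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a structure as a minimal PDB file
#'
#' Serializes heavy atoms back to fixed-width ATOM records; used by the
#' synthetic-fixture generator and for round-trip testing.
#'
#' @param structure An `antigen_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(structure$residues))) {
    r <- structure$residues[i, ]
    xyz <- structure$coords[[i]]
    el <- structure$elements[[i]]
    for (a in seq_len(nrow(xyz))) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, substr(rownames(xyz)[a], 1, 4), " ", r$resname, r$chain,
        r$seqnum, ifelse(r$icode == "", " ", r$icode),
        xyz[a, 1], xyz[a, 2], xyz[a, 3], 1, 0, el[a]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
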