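# Ground-truth epitope annotation from antibody-antigen complexes,
# transfer onto unbound structures, and dataset-curation filters.

#' Extract the epitope of an antibody-antigen complex by atomic distance
#'
#' An antigen residue is epitopal when any of its heavy atoms lies within
#' `cutoff` Angstrom of any antibody heavy atom.  This implements the
#' distance component of contact-analysis annotation; contact-type
#' legitimacy classification is deliberately not modelled.
#'
#' @param complex_structure An `antigen_structure` parsed from the complex
#'   with both chain groups retained.
#' @param antigen_chains Character vector of antigen chain ids.
#' @param antibody_chains Character vector of antibody chain ids
#'   (e.g. heavy + light).
#' @param cutoff Contact distance cutoff in Angstrom (default 4.0).
#' @return An `epitope_annotation`: data.frame (chain, seqnum, icode,
#'   resname) of epitopal antigen residues, with attributes `antigen_id`
#'   and `source = "contact"`.
#' @export
extract_epitope <- function(complex_structure, antigen_chains,
                            antibody_chains, cutoff = 4.0) {
  if (length(antigen_chains) == 0 || length(antibody_chains) == 0)
    stop("both chain groups must be non-empty")
  if (length(intersect(antigen_chains, antibody_chains)) > 0)
    stop("antigen and antibody chain groups overlap")

  res <- complex_structure$residues
  ag <- which(res$chain %in% antigen_chains)
  ab <- which(res$chain %in% antibody_chains)
  if (length(ag) == 0) stop("no antigen residues for chains ",
                            paste(antigen_chains, collapse = ","))
  if (length(ab) == 0) stop("no antibody residues for chains ",
                            paste(antibody_chains, collapse = ","))

  abxyz <- do.call(rbind, complex_structure$coords[ab])
  hit <- vapply(ag, function(i) {
    min_cross_dist(complex_structure$coords[[i]], abxyz) <= cutoff
  }, logical(1))

  ann <- res[ag[hit], , drop = FALSE]
  rownames(ann) <- NULL
  if (nrow(ann) == 0)
    warning("no antigen-antibody contacts within ", cutoff,
            " A; check the chain assignment")
  new_annotation(ann,
                 antigen_id = basename(complex_structure$source$path),
                 source = "contact")
}

# minimum Euclidean distance between two point sets
min_cross_dist <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  d2min <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- (b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2 + (b[, 3] - a[i, 3])^2
    m <- min(d2)
    if (m < d2min) d2min <- m
  }
  sqrt(d2min)
}

new_annotation <- function(df, antigen_id = NA_character_, source = "file") {
  stopifnot(all(c("chain", "seqnum", "icode") %in% names(df)))
  attr(df, "antigen_id") <- antigen_id
  attr(df, "source") <- source
  class(df) <- c("epitope_annotation", "data.frame")
  df
}

#' Global pairwise alignment of two protein sequences
#'
#' BLOSUM62, gap open 11, gap extend 1; returns the aligned strings, the
#' per-column position maps and the fractional identity over alignment
#' columns excluding terminal gaps.
#'
#' @param seq_a,seq_b Character strings (one-letter amino-acid codes).
#' @return List with `aligned_a`, `aligned_b`, `map_ab` (integer vector:
#'   for each position of `seq_a`, the aligned position in `seq_b` or NA),
#'   and `identity` in [0, 1].
#' @export
align_sequences <- function(seq_a, seq_b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

  pa <- cumsum(a != "-"); pa[a == "-"] <- NA
  pb <- cumsum(b != "-"); pb[b == "-"] <- NA

  map_ab <- rep(NA_integer_, nchar(seq_a))
  both <- !is.na(pa) & !is.na(pb)
  map_ab[pa[both]] <- pb[both]

  # identity over columns excluding end gaps
  inner <- seq(min(which(a != "-" & b != "-")), max(which(a != "-" & b != "-")))
  identity <- sum(a[inner] == b[inner] & a[inner] != "-") / length(inner)

  list(aligned_a = paste(a, collapse = ""),
       aligned_b = paste(b, collapse = ""),
       map_ab = map_ab, identity = identity)
}

#' Transfer an epitope annotation onto an unbound structure
#'
#' Aligns the bound antigen sequence to the unbound one and maps each
#' epitopal position across the alignment.  Positions that align to a gap
#' in the unbound sequence are dropped with a warning; sequence pairs
#' below the identity threshold are refused.
#'
#' @param annotation An `epitope_annotation` on `bound` residues.
#' @param bound,unbound `antigen_structure` objects.
#' @param min_identity Minimum fractional sequence identity (default 0.95,
#'   the bound/unbound pairing criterion).
#' @return An `epitope_annotation` on `unbound` residues with
#'   `source = "transferred"`.
#' @export
transfer_annotation <- function(annotation, bound, unbound,
                                min_identity = 0.95) {
  keys_b <- residue_keys(bound$residues)
  idx <- match(residue_keys(annotation), keys_b)
  if (anyNA(idx))
    stop("annotation contains residues absent from the bound structure")

  aln <- align_sequences(structure_sequence(bound),
                         structure_sequence(unbound))
  if (aln$identity < min_identity)
    stop(sprintf(
      "bound/unbound sequence identity %.3f below the %.2f threshold",
      aln$identity, min_identity))

  mapped <- aln$map_ab[idx]
  if (anyNA(mapped)) {
    warning(sum(is.na(mapped)),
            " epitopal position(s) align to gaps and were dropped")
  }
  out <- unbound$residues[mapped[!is.na(mapped)], , drop = FALSE]
  rownames(out) <- NULL
  new_annotation(out,
                 antigen_id = basename(unbound$source$path),
                 source = "transferred")
}

#' Residue overlap between two epitope annotations
#'
#' Percentage of identical residues, Jaccard-style by default:
#' 100 * |a intersect b| / |a union b|.  The `"min"` denominator
#' (smaller set size) is available as an alternative; the 0% and 100%
#' endpoints are invariant to the choice.
#'
#' @param a,b `epitope_annotation` objects (or data.frames with chain,
#'   seqnum, icode) on the same antigen residue space.
#' @param denominator `"union"` (default) or `"min"`.
#' @return List with `percent_overlap` in [0, 100] and `shared`
#'   (character vector of shared residue keys).
#' @export
epitope_overlap <- function(a, b, denominator = c("union", "min")) {
  denominator <- match.arg(denominator)
  ka <- unique(residue_keys(a))
  kb <- unique(residue_keys(b))
  if (length(ka) == 0 && length(kb) == 0) {
    warning("both annotations are empty; overlap reported as 0")
    return(list(percent_overlap = 0, shared = character(0)))
  }
  shared <- intersect(ka, kb)
  den <- switch(denominator,
                union = length(union(ka, kb)),
                min = max(min(length(ka), length(kb)), 1L))
  list(percent_overlap = 100 * length(shared) / den, shared = shared)
}

#' Greedy redundancy filter on sequence identity
#'
#' Processes sequences longest-first; a sequence joins the first existing
#' representative with global-alignment identity above the threshold,
#' otherwise it founds a new cluster.  Representatives are returned.
#'
#' @param sequences Named character vector of protein sequences.
#' @param identity_threshold Maximum allowed pairwise identity between
#'   retained sequences (default 0.30, i.e. a 30% redundancy cut).
#' @return Character vector: names of the representative sequences.
#' @export
redundancy_filter <- function(sequences, identity_threshold = 0.30) {
  stopifnot(length(sequences) >= 1)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  ord <- order(-nchar(sequences))
  reps <- character(0)
  for (i in ord) {
    redundant <- FALSE
    for (r in reps) {
      if (align_sequences(sequences[[i]], sequences[[r]])$identity >
          identity_threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) reps <- c(reps, names(sequences)[i])
  }
  reps
}

#' Dataset-curation filter on complex metadata
#'
#' Keeps a complex when its resolution is strictly below `max_resolution`
#' and its antigen length falls inside the closed size window.  Default
#' bounds (resolution < 3 Angstrom, 100-450 residues) follow the unbound
#' dataset curation; set `min_length = 61, max_length = Inf` for the
#' looser ">60 residues" bound-complex variant.
#'
#' @param resolution Crystallographic resolution in Angstrom.
#' @param length Antigen length in residues.
#' @param max_resolution Strict upper bound on resolution (default 3.0).
#' @param min_length,max_length Inclusive length bounds (default 100, 450).
#' @return Logical scalar; `FALSE` with a warning when metadata is missing.
#' @export
complex_filter <- function(resolution, length, max_resolution = 3.0,
                           min_length = 100, max_length = 450) {
  if (is.null(resolution) || is.null(length) ||
      is.na(resolution) || is.na(length)) {
    warning("missing metadata; complex rejected")
    return(FALSE)
  }
  resolution < max_resolution && length >= min_length && length <= max_length
}

#' Read / write epitope annotation TSV files
#'
#' Format: tab-separated columns `antigen_id`, `chain`, `seqnum`, `icode`,
#' one residue per line (icode empty for none).
#'
#' @param path File path.
#' @return For the reader, an `epitope_annotation`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "integer", "character"),
                          na.strings = NULL)
  df$icode[is.na(df$icode)] <- ""
  new_annotation(df[, c("chain", "seqnum", "icode"), drop = FALSE],
                 antigen_id = df$antigen_id[1], source = "file")
}

#' @rdname read_annotation
#' @param annotation An `epitope_annotation`.
#' @export
write_annotation <- function(annotation, path) {
  out <- data.frame(antigen_id = attr(annotation, "antigen_id"),
                    chain = annotation$chain,
                    seqnum = annotation$seqnum,
                    icode = annotation$icode)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
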