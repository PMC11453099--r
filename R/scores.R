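# Per-residue score tables from base interface classifiers.

#' Read a per-classifier score TSV
#'
#' Format: tab-separated columns `chain`, `seqnum`, `icode`, `score`.
#'
#' @param path File path.
#' @return data.frame with those columns.
#' @export
read_score_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer",
                                         "character", "numeric"),
                          na.strings = NULL)
  df$icode[is.na(df$icode)] <- ""
  df
}

#' @rdname read_score_tsv
#' @param scores data.frame with chain, seqnum, icode, score.
#' @export
write_score_tsv <- function(scores, path) {
  utils::write.table(scores[, c("chain", "seqnum", "icode", "score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a per-residue score table aligned to a structure
#'
#' Joins one score file per base classifier onto the structure's residue
#' list (exact match on chain, author residue number and insertion code).
#' Residues missing from a file are imputed 0 — absence of interface
#' evidence — with a warning.
#'
#' @param paths Named character vector of score-file paths; names become
#'   classifier column names (unnamed: file base names).
#' @param structure An `antigen_structure`.
#' @param antigen_id Identifier stored in the table (default: structure
#'   source file name).
#' @return A `score_table`: data.frame with columns `antigen_id`, `chain`,
#'   `seqnum`, `icode`, then one numeric column per classifier, attribute
#'   `classifiers` listing them.
#' @export
load_scores <- function(paths, structure,
                        antigen_id = basename(structure$source$path)) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    names(paths) <- tools::file_path_sans_ext(basename(paths))
  keys <- residue_keys(structure$residues)
  tab <- data.frame(antigen_id = antigen_id,
                    structure$residues[, c("chain", "seqnum", "icode")],
                    stringsAsFactors = FALSE)
  for (cl in names(paths)) {
    sc <- read_score_tsv(paths[[cl]])
    idx <- match(keys, paste(sc$chain, sc$seqnum, sc$icode, sep = "|"))
    if (all(is.na(idx)))
      stop("score file ", paths[[cl]], " shares no residues with the structure")
    v <- sc$score[idx]
    if (anyNA(v)) {
      warning(sum(is.na(v)), " residue(s) missing from classifier '", cl,
              "'; imputed score 0")
      v[is.na(v)] <- 0
    }
    tab[[cl]] <- v
  }
  new_score_table(tab, classifiers = names(paths))
}

new_score_table <- function(df, classifiers) {
  attr(df, "classifiers") <- classifiers
  class(df) <- c("score_table", "data.frame")
  df
}

#' Classifier column names of a score table
#' @param table A `score_table`.
#' @export
score_classifiers <- function(table) {
  cl <- attr(table, "classifiers")
  if (is.null(cl))
    cl <- setdiff(names(table),
                  c("antigen_id", "chain", "seqnum", "icode", "label"))
  cl
}

#' Min-max normalise classifier scores per antigen
#'
#' Rescales each classifier column to [0, 1] independently within each
#' antigen (base classifiers' score scales vary by query).  A constant
#' column maps to all zeros with a warning.  Idempotent.
#'
#' @param table A `score_table` (may hold several antigens).
#' @param per_antigen Normalise within each antigen (default) or globally.
#' @return The normalised `score_table`.
#' @export
normalize_scores <- function(table, per_antigen = TRUE) {
  cls <- score_classifiers(table)
  groups <- if (per_antigen) split(seq_len(nrow(table)), table$antigen_id)
            else list(seq_len(nrow(table)))
  for (cl in cls) {
    for (idx in groups) {
      v <- table[[cl]][idx]
      rng <- range(v)
      if (diff(rng) == 0) {
        if (rng[1] != 0)
          warning("constant score column '", cl, "' mapped to zeros")
        table[[cl]][idx] <- 0
      } else {
        table[[cl]][idx] <- (v - rng[1]) / diff(rng)
      }
    }
  }
  table
}
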