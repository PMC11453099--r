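# Synthetic antigens with planted spatial epitope patches and simulated
# base-classifier score tracks, so the entire pipeline runs offline.

#' Specification for a synthetic antigen fixture
#'
#' The generator states a realistic world once: antigens of 100-450
#' residues (the curated size window), 2-3 spatial epitope patches of ~14
#' residues (observed epitopes span 6-29 residues, mean 15), patch
#' centroids at least 25 Angstrom apart, and three partially informative
#' classifiers with sensitivity 0.6 over Gaussian noise (sd 0.12) on a
#' base score of 0.15.
#'
#' @param n_residues Number of residues (default 150).
#' @param n_patches Number of planted epitope patches (default 2).
#' @param patch_size Residues per patch (default 14).
#' @param patch_separation Minimum centroid separation in Angstrom
#'   (default 25).
#' @param sensitivity Per-classifier score lift on covered patch residues
#'   (default three classifiers at 0.6).
#' @param coverage List (one element per classifier) of patch indices the
#'   classifier "sees"; `NULL` draws random coverage (each classifier
#'   covers each patch with probability 0.7, every patch covered by at
#'   least one classifier).
#' @param base Baseline score level (default 0.15).
#' @param noise_sd Gaussian score noise (default 0.12).
#' @param seed Integer seed; generation is a pure function of it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_residues = 150, n_patches = 2, patch_size = 14,
                         patch_separation = 25,
                         sensitivity = c(sppider_like = 0.6,
                                         ispred_like = 0.6,
                                         dockpred_like = 0.6),
                         coverage = NULL, base = 0.15, noise_sd = 0.12,
                         seed = 1) {
  stopifnot(n_patches * patch_size <= n_residues, patch_separation > 0)
  if (is.null(names(sensitivity)))
    names(sensitivity) <- paste0("clf", seq_along(sensitivity))
  structure(list(n_residues = n_residues, n_patches = n_patches,
                 patch_size = patch_size,
                 patch_separation = patch_separation,
                 sensitivity = sensitivity, coverage = coverage,
                 base = base, noise_sd = noise_sd, seed = seed),
            class = "fixture_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# self-avoiding 3D random walk with 3.8 A steps (CA-like backbone trace)
random_walk <- function(n, step = 3.8, min_sep = 3.6, max_tries = 50) {
  pos <- matrix(NA_real_, n, 3)
  pos[1, ] <- 0
  i <- 2
  stalls <- 0
  while (i <= n) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      u <- stats::rnorm(3)
      cand <- pos[i - 1, ] + step * u / sqrt(sum(u^2))
      d2 <- (pos[seq_len(i - 2), 1, drop = TRUE] - cand[1])^2 +
        (pos[seq_len(i - 2), 2, drop = TRUE] - cand[2])^2 +
        (pos[seq_len(i - 2), 3, drop = TRUE] - cand[3])^2
      if (i == 2 || all(d2 >= min_sep^2)) {
        pos[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (placed) {
      i <- i + 1
    } else {
      # back off a few steps and retry
      i <- max(2, i - 5)
      stalls <- stalls + 1
      if (stalls > 200) stop("self-avoiding walk failed; loosen geometry")
    }
  }
  pos
}

#' Generate a synthetic antigen with planted epitope patches
#'
#' Residues are single pseudo-atoms along a self-avoiding 3D random walk;
#' each patch is a spatially contiguous ball of residues around a seed
#' residue, and patch centroids are at least `patch_separation` apart.
#' Deterministic under the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @param antigen_id Identifier used in file names and tables.
#' @return List with `structure` (an `antigen_structure`), `patches`
#'   (list of per-patch `epitope_annotation`s), `annotation` (their
#'   union) and `spec`.
#' @export
make_synthetic_antigen <- function(spec, antigen_id = "synthetic") {
  with_seed(spec$seed, {
    xyz <- random_walk(spec$n_residues)
    patches <- plant_patches(xyz, spec)
  })

  residues <- data.frame(chain = "A", seqnum = seq_len(spec$n_residues),
                         icode = "", resname = "ALA",
                         stringsAsFactors = FALSE)
  coords <- lapply(seq_len(spec$n_residues), function(i) {
    m <- xyz[i, , drop = FALSE]
    dimnames(m) <- list("CA", c("x", "y", "z"))
    m
  })
  st <- structure(list(
    residues = residues, coords = coords,
    elements = rep(list("C"), spec$n_residues),
    centers = `colnames<-`(xyz, c("x", "y", "z")),
    source = list(path = antigen_id, chains = "A")
  ), class = "antigen_structure")

  anns <- lapply(seq_along(patches), function(p) {
    new_annotation(residues[patches[[p]], c("chain", "seqnum", "icode",
                                            "resname")],
                   antigen_id = antigen_id, source = "contact")
  })
  all_idx <- sort(unique(unlist(patches)))
  list(structure = st,
       patches = anns,
       patch_idx = patches,
       annotation = new_annotation(
         residues[all_idx, c("chain", "seqnum", "icode", "resname")],
         antigen_id = antigen_id, source = "contact"),
       spec = spec)
}

# choose patch seed residues with separated centroids; patch = the
# patch_size nearest unused residues to each seed
plant_patches <- function(xyz, spec) {
  if (spec$n_patches == 0) return(list())
  n <- nrow(xyz)
  for (attempt in 1:60) {
    buffer <- if (attempt <= 30) 5 else 0   # relax the seed spacing late
    cand <- sample(n)
    seeds <- cand[1]
    for (s in cand[-1]) {
      if (length(seeds) == spec$n_patches) break
      if (all(sqrt(colSums((t(xyz[seeds, , drop = FALSE]) - xyz[s, ])^2)) >=
              spec$patch_separation + buffer))
        seeds <- c(seeds, s)
    }
    if (length(seeds) < spec$n_patches) next

    used <- integer(0)
    patches <- list()
    for (s in seeds) {
      d <- sqrt(rowSums(sweep(xyz, 2, xyz[s, ])^2))
      d[used] <- Inf
      members <- order(d)[seq_len(spec$patch_size)]
      patches <- c(patches, list(sort(members)))
      used <- c(used, members)
    }
    centroids <- t(vapply(patches, function(p) colMeans(xyz[p, , drop = FALSE]),
                          numeric(3)))
    ok <- TRUE
    if (spec$n_patches > 1) {
      dd <- as.matrix(stats::dist(centroids))
      ok <- min(dd[upper.tri(dd)]) >= spec$patch_separation
    }
    if (ok) return(patches)
  }
  stop("could not place ", spec$n_patches, " patches ",
       spec$patch_separation, " A apart; loosen the spec")
}

#' Simulate base-classifier score tracks for a synthetic antigen
#'
#' Classifier c scores residue i as
#' `clip(base + sensitivity_c * [i in a patch covered by c] +
#' N(0, noise_sd), 0, 1)`.  Coverage defaults to the spec's, drawn once
#' per antigen.
#'
#' @param antigen Result of [make_synthetic_antigen()].
#' @param dir Optional directory: writes one score TSV per classifier.
#' @param label Add the true per-residue epitope label column
#'   (default TRUE).
#' @return A `score_table` with one column per classifier (and `label`),
#'   attribute `coverage` recording which patches each classifier saw.
#'   When `dir` is given, attribute `paths` holds the written files.
#' @export
simulate_scores <- function(antigen, dir = NULL, label = TRUE) {
  spec <- antigen$spec
  n <- spec$n_residues
  n_clf <- length(spec$sensitivity)
  in_patch <- lapply(antigen$patch_idx, function(p) seq_len(n) %in% p)

  tab <- with_seed(spec$seed + 1L, {
    coverage <- spec$coverage
    if (is.null(coverage) && spec$n_patches > 0) {
      repeat {
        coverage <- lapply(seq_len(n_clf), function(c)
          which(stats::runif(spec$n_patches) < 0.7))
        covered <- sort(unique(unlist(coverage)))
        if (identical(covered, seq_len(spec$n_patches))) break
      }
    } else if (is.null(coverage)) {
      coverage <- rep(list(integer(0)), n_clf)
    }
    tab <- data.frame(antigen_id = antigen$structure$source$path,
                      antigen$structure$residues[, c("chain", "seqnum",
                                                     "icode")],
                      stringsAsFactors = FALSE)
    for (c in seq_len(n_clf)) {
      seen <- Reduce(`|`, in_patch[coverage[[c]]], rep(FALSE, n))
      s <- spec$base + spec$sensitivity[c] * seen +
        stats::rnorm(n, 0, spec$noise_sd)
      tab[[names(spec$sensitivity)[c]]] <- pmin(pmax(s, 0), 1)
    }
    attr(tab, "coverage") <- coverage
    tab
  })
  coverage <- attr(tab, "coverage")
  if (label) {
    all_idx <- sort(unique(unlist(antigen$patch_idx)))
    tab$label <- seq_len(n) %in% all_idx
  }
  tab <- new_score_table(tab, classifiers = names(spec$sensitivity))
  attr(tab, "coverage") <- coverage

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(names(spec$sensitivity), function(cl) {
      p <- file.path(dir, paste0(cl, ".tsv"))
      write_score_tsv(data.frame(tab[, c("chain", "seqnum", "icode")],
                                 score = tab[[cl]]), p)
      p
    }, character(1))
    attr(tab, "paths") <- paths
  }
  tab
}

#' Generate a reproducible benchmark corpus of synthetic antigens
#'
#' Antigen sizes are drawn uniformly from `size_range` (default the
#' 100-450 curated window); patch counts are 2 for ~90% of antigens and 3
#' otherwise, matching the observed prevalence of two- vs three-epitope
#' calls.
#'
#' @param n_antigens Number of antigens (>= 4).
#' @param size_range Length bounds in residues.
#' @param seed Corpus seed; antigen i uses `seed * 1000 + i`.
#' @param dir Optional directory: writes PDB, annotation and score files
#'   per antigen.
#' @param ... Further arguments passed to [fixture_spec()] (noise,
#'   sensitivity, ...).
#' @return A `benchmark_set`: list with `antigens` (per-antigen lists as
#'   from [make_synthetic_antigen()], plus `$scores`), `table` (stacked
#'   labelled `score_table` over all antigens) and `sizes`.
#' @export
make_benchmark_set <- function(n_antigens = 12, size_range = c(100, 450),
                               seed = 42, dir = NULL, ...) {
  stopifnot(n_antigens >= 4)
  sizes <- with_seed(seed, {
    s <- sample(seq(size_range[1], size_range[2]), n_antigens,
                replace = TRUE)
    np <- sample(c(2L, 3L), n_antigens, replace = TRUE,
                 prob = c(0.9, 0.1))
    list(s = s, np = np)
  })
  antigens <- lapply(seq_len(n_antigens), function(i) {
    id <- sprintf("ag%03d", i)
    spec <- fixture_spec(n_residues = sizes$s[i], n_patches = sizes$np[i],
                         seed = seed * 1000L + i, ...)
    ag <- make_synthetic_antigen(spec, antigen_id = id)
    ag$scores <- simulate_scores(
      ag, dir = if (is.null(dir)) NULL else file.path(dir, id))
    if (!is.null(dir)) {
      write_pdb(ag$structure, file.path(dir, id, paste0(id, ".pdb")))
      write_annotation(ag$annotation,
                       file.path(dir, id, paste0(id, "_epitope.tsv")))
    }
    ag
  })
  names(antigens) <- vapply(antigens,
                            function(a) a$structure$source$path,
                            character(1))
  table <- do.call(rbind, lapply(antigens, function(a) a$scores))
  rownames(table) <- NULL
  table <- new_score_table(table,
                           classifiers = score_classifiers(antigens[[1]]$scores))
  structure(list(antigens = antigens, table = table,
                 sizes = stats::setNames(sizes$s, names(antigens))),
            class = "benchmark_set")
}

#' @export
print.benchmark_set <- function(x, ...) {
  cat("benchmark_set:", length(x$antigens), "synthetic antigens,",
      nrow(x$table), "residues,",
      sum(x$table$label), "epitopal\n")
  invisible(x)
}
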