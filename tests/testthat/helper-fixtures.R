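# Shared fixtures and independent test oracles.

# --- minimal PDB text ---------------------------------------------------

pdb_atom_line <- function(serial, name, resname, chain, seqnum, x, y, z,
                          element = substr(name, 1, 1), icode = " ",
                          record = "ATOM  ") {
  sprintf("%s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, " ", resname, chain, seqnum, icode,
          x, y, z, 1, 0, element)
}

# three-alanine toy chain; returns the path
write_toy_pdb <- function(path = tempfile(fileext = ".pdb"),
                          extra_lines = character(0)) {
  lines <- c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 0.0, 0.0, 0.0, "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.5, 0.0, 0.0, "C"),
    pdb_atom_line(3, "N",  "ALA", "A", 2, 3.0, 1.0, 0.0, "N"),
    pdb_atom_line(4, "CA", "ALA", "A", 2, 4.5, 1.0, 0.0, "C"),
    pdb_atom_line(5, "N",  "ALA", "A", 3, 6.0, 2.0, 0.0, "N"),
    pdb_atom_line(6, "CA", "ALA", "A", 3, 7.5, 2.0, 0.0, "C"),
    extra_lines,
    "END")
  writeLines(lines, path)
  path
}

# a synthetic two-chain "complex": antigen chain A (two residues) and an
# antibody chain H placed at an exact minimum distance `gap` from residue 1
write_complex_pdb <- function(gap, path = tempfile(fileext = ".pdb")) {
  lines <- c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 0, 20, 0, "C"),
    pdb_atom_line(3, "CA", "GLY", "H", 1, gap, 0, 0, "C"),
    pdb_atom_line(4, "CA", "GLY", "H", 2, gap + 10, 0, 0, "C"),
    "END")
  writeLines(lines, path)
  path
}

# structure built directly from a coordinate matrix (one CA per residue)
structure_from_xyz <- function(xyz, chain = "A", resname = "ALA",
                               id = "toy") {
  n <- nrow(xyz)
  residues <- data.frame(chain = chain, seqnum = seq_len(n), icode = "",
                         resname = resname, stringsAsFactors = FALSE)
  coords <- lapply(seq_len(n), function(i) {
    m <- xyz[i, , drop = FALSE]
    dimnames(m) <- list("CA", c("x", "y", "z"))
    m
  })
  structure(list(residues = residues, coords = coords,
                 elements = rep(list("C"), n),
                 centers = `colnames<-`(xyz, c("x", "y", "z")),
                 source = list(path = id, chains = chain)),
            class = "antigen_structure")
}

res_keys <- function(df) paste(df$chain, df$seqnum, df$icode, sep = "|")

# --- independent oracles ------------------------------------------------

# Ward linkage by the Lance-Williams recursion on squared Euclidean
# distances (heights reported as sqrt, the "two singletons merge at their
# distance" convention).  Returns the sorted merge heights and the list of
# partitions (one per k).
ward_oracle <- function(xyz) {
  n <- nrow(xyz)
  d2 <- as.matrix(dist(xyz))^2
  size <- rep(1, n)
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  partitions[[n]] <- members
  cost <- d2 / 2  # ward merge cost for singletons: d^2/2; heights = sqrt(2*cost)
  while (length(active) > 1) {
    m <- length(active)
    best <- c(Inf, NA, NA)
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      i <- active[a]; j <- active[b]
      if (d2[i, j] < best[1]) best <- c(d2[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, sqrt(d2[i, j]))
    ni <- size[i]; nj <- size[j]
    # Lance-Williams update of squared ward distances to every other cluster
    for (k in setdiff(active, c(i, j))) {
      nk <- size[k]
      d2[i, k] <- d2[k, i] <-
        ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    members[[i]] <- c(members[[i]], members[[j]])
    active <- setdiff(active, j)
    partitions[[length(active)]] <- members[active]
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition (list of index vectors) for comparison
canon_partition <- function(p) {
  s <- lapply(unname(p), function(x) sort(unname(x)))
  s[order(vapply(s, min, numeric(1)))]
}

# maximum-gap cluster count by sweeping cut heights over the dendrogram
gap_sweep_oracle <- function(heights, k_max = 8) {
  n <- length(heights) + 1
  bp <- c(0, heights)
  # cutting at any height inside (bp[m], bp[m+1]) crosses n - (m - 1)
  # branches; the line can travel that interval's span without hitting a merge
  best_k <- NA; best_span <- -Inf
  for (m in seq_len(n - 1)) {
    k <- n - (m - 1)                   # clusters cutting just below merge m
    span <- bp[m + 1] - bp[m]
    if (k < 2 || k > min(k_max, n - 1)) next
    if (span > best_span + 1e-12 ||
        (abs(span - best_span) <= 1e-12 && k < best_k)) {
      best_span <- span; best_k <- k
    }
  }
  best_k
}

# ROC-AUC as the brute-force fraction of concordant positive-negative
# pairs (ties count one half)
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
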