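# Solvent accessibility: rolling-probe (Shrake-Rupley) surface area.

# van der Waals radii (Angstrom) by element; generic fallback 1.80
.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)
.VDW_DEFAULT <- 1.80

# Theoretical maximum accessible surface areas (Angstrom^2) per residue
# type (Tien et al. 2013), used to normalise ASA into relative solvent
# accessibility.
.MAX_ASA <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
)
.MAX_ASA_GENERIC <- 200.0

# quasi-uniform points on the unit sphere (golden-spiral lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area per atom
#'
#' Rolls a spherical probe over the structure: each atom is expanded by
#' the probe radius and sampled with a fixed spherical point lattice; the
#' accessible fraction is the share of points not buried inside any
#' neighbouring expanded sphere.
#'
#' @param xyz n x 3 matrix of heavy-atom coordinates (Angstrom).
#' @param elements Character vector of element symbols, length n.
#' @param probe Probe radius in Angstrom (water, default 1.4).
#' @param n_points Number of lattice points per atom (default 92).
#' @return Numeric vector of per-atom ASA in Angstrom^2.
#' @export
shrake_rupley <- function(xyz, elements, probe = 1.4, n_points = 92) {
  xyz <- rbind(xyz)
  n <- nrow(xyz)
  stopifnot(length(elements) == n)
  rad <- .VDW[elements]
  rad[is.na(rad)] <- .VDW_DEFAULT
  rr <- rad + probe
  pts <- sphere_points(n_points)
  asa <- numeric(n)
  maxrr <- max(rr)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nbr <- which(d2 < (rr[i] + maxrr)^2 & d2 > 1e-12)
    nbr <- nbr[d2[nbr] < (rr[i] + rr[nbr])^2]
    p <- pts * rr[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    if (length(nbr) == 0) {
      acc <- n_points
    } else {
      buried <- rep(FALSE, n_points)
      for (j in nbr) {
        if (all(buried)) break
        dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        buried <- buried | dj2 < rr[j]^2
      }
      acc <- sum(!buried)
    }
    asa[i] <- 4 * pi * rr[i]^2 * acc / n_points
  }
  asa
}

#' Surface profile of an antigen structure
#'
#' Computes per-residue relative solvent accessibility (RSA) by the
#' Shrake-Rupley method and flags surface-exposed residues.  RSA is the
#' residue's summed heavy-atom ASA divided by its residue-type theoretical
#' maximum; a residue is surface-exposed when RSA is at or above
#' `rsa_threshold`.  The count of surface residues, `R`, feeds the dynamic
#' epitope-calling threshold [dynamic_threshold()].
#'
#' @param structure An `antigen_structure`.
#' @param rsa_threshold Surface cutoff on RSA (default 0.05, i.e. 5%).
#' @param probe Probe radius (Angstrom).
#' @param n_points Sphere lattice size per atom.
#' @return An object of class `surface_profile`: list with `asa`, `rsa`,
#'   `is_surface` (per residue, structure order), `R` (surface count) and
#'   `rsa_threshold`.
#' @export
surface_profile <- function(structure, rsa_threshold = 0.05,
                            probe = 1.4, n_points = 92) {
  if (nrow(structure$residues) == 0) stop("empty structure")
  xyz <- do.call(rbind, structure$coords)
  elements <- unlist(structure$elements)
  natoms <- vapply(structure$coords, nrow, integer(1))
  asa_atom <- shrake_rupley(xyz, elements, probe = probe, n_points = n_points)
  asa <- as.numeric(tapply(asa_atom, rep(seq_along(natoms), natoms), sum))

  maxasa <- .MAX_ASA[structure$residues$resname]
  if (anyNA(maxasa)) {
    warning("unknown residue type(s) for RSA normalisation; using generic ",
            "maximum of ", .MAX_ASA_GENERIC, " A^2")
    maxasa[is.na(maxasa)] <- .MAX_ASA_GENERIC
  }
  rsa <- asa / maxasa
  is_surface <- rsa >= rsa_threshold
  structure(list(asa = asa, rsa = rsa, is_surface = is_surface,
                 R = sum(is_surface), rsa_threshold = rsa_threshold),
            class = "surface_profile")
}

#' @export
print.surface_profile <- function(x, ...) {
  cat("surface_profile:", length(x$rsa), "residues,",
      x$R, "surface-exposed (RSA >=", x$rsa_threshold, ")\n")
  invisible(x)
}
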