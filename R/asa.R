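# Shrake-Rupley solvent-accessible surface area and relative accessibility.
# No R package in the stack computes SASA directly, so the rolling-probe
# approximation is implemented here: each atom's sphere (vdW radius + probe)
# is sampled with a deterministic golden-section spiral and the accessible
# fraction is the share of sample points outside every neighbouring sphere.

# van der Waals radii by element (Angstrom); generic fallback 1.70
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

# Theoretical maximum whole-residue ASA (Angstrom^2), Tien et al. (2013)
# theoretical values, used to normalise to relative ASA.
MAX_ASA_TIEN <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167, E = 223, Q = 225, G = 104,
  H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
  T = 172, W = 285, Y = 263, V = 174)

AA_3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# deterministic unit sphere sampling (golden-section spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area per atom
#'
#' @param xyz Numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param elements Character vector of element symbols (used for van der
#'   Waals radii; unknown elements fall back to carbon's 1.70 A).
#' @param probe Probe radius in Angstrom (water: 1.4).
#' @param n_points Sphere sample points per atom (>= 960 recommended).
#' @return Numeric vector of per-atom accessible areas in Angstrom^2.
#' @export
shrake_rupley <- function(xyz, elements, probe = 1.4, n_points = 960) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(elements))
  radii <- .VDW_RADII[toupper(elements)]
  radii[is.na(radii)] <- 1.70
  rs <- radii + probe
  sp <- .sphere_points(n_points)
  n <- nrow(xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    # neighbours whose expanded spheres can intersect atom i's
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rs[i] + rs)^2 & seq_len(n) != i)
    pts <- sweep(sp * rs[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- rowSums(sweep(pts[acc, , drop = FALSE], 2, xyz[j, ])^2)
      acc[acc] <- dj >= rs[j]^2
    }
    area[i] <- 4 * pi * rs[i]^2 * mean(acc)
  }
  area
}

#' Relative solvent accessibility of a residue
#'
#' Whole-residue Shrake-Rupley area in the context of the full structure,
#' divided by the residue's theoretical maximum area ([MAX_ASA_TIEN]), as a
#' percentage.  Deterministic for fixed probe and point count.
#'
#' @param structure A `bio3d` pdb object (from [bio3d::read.pdb()]) or a path
#'   to a PDB file.
#' @param chain Chain id.
#' @param residue Residue number.
#' @param probe Probe radius in Angstrom.
#' @param n_points Sphere sample points per atom.
#' @return Relative ASA in percent, with attribute `incomplete = TRUE` (plus
#'   a warning) when backbone atoms are missing and the value was computed on
#'   the atoms present.
#' @export
relative_asa <- function(structure, chain, residue, probe = 1.4,
                         n_points = 960) {
  pdb <- if (is.character(structure)) bio3d::read.pdb(structure) else structure
  at <- pdb$atom
  at <- at[at$type == "ATOM" & (is.na(at$alt) | at$alt %in% c("", "A")), ]
  sel <- at$chain == chain & at$resno == residue
  if (!any(sel)) stop("residue ", chain, ":", residue, " not found")
  aa3 <- unique(at$resid[sel])[1]
  aa1 <- AA_3TO1[aa3]
  if (is.na(aa1)) stop("non-standard residue ", aa3)
  elements <- if (!is.null(at$elesy) && any(nzchar(trimws(at$elesy)))) {
    trimws(at$elesy)
  } else {
    substr(trimws(at$elety), 1, 1)
  }
  heavy <- !elements %in% "H"
  xyz <- cbind(at$x, at$y, at$z)[heavy, , drop = FALSE]
  area <- shrake_rupley(xyz, elements[heavy], probe = probe,
                        n_points = n_points)
  res_area <- sum(area[sel[heavy]])
  out <- 100 * res_area / MAX_ASA_TIEN[[aa1]]
  have <- trimws(at$elety[sel])
  if (!all(c("N", "CA", "C", "O") %in% have)) {
    warning("residue ", chain, ":", residue,
            " is missing backbone atoms; ASA computed on atoms present")
    attr(out, "incomplete") <- TRUE
  }
  out
}
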