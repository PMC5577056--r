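# Bound-form distance-distribution analysis: extract Calpha distance series
# from multi-model snapshot ensembles and compare their distributions between
# wild type and mutant with a rank-sum test.

#' Build a snapshot ensemble
#'
#' @param atoms Data frame with one row per atom: columns `chain`, `residue`,
#'   `atom` (PDB atom name, e.g. `"CA"`), `aa` (3-letter residue name).
#' @param coords Numeric array `n_atoms x 3 x n_frames`; every frame shares
#'   the same atom roster and at least 2 frames are required.
#' @return An object of class `snapshot_ensemble`.
#' @export
snapshot_ensemble <- function(atoms, coords) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "residue", "atom", "aa") %in% names(atoms)))
  coords <- as.array(coords)
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1] != nrow(atoms))
    stop("coords and atoms disagree on atom count")
  if (dim(coords)[3] < 2) stop("need >= 2 frames")
  structure(list(atoms = atoms, coords = coords),
            class = "snapshot_ensemble")
}

#' @export
print.snapshot_ensemble <- function(x, ...) {
  cat(sprintf("<snapshot_ensemble> %d atoms, %d frames, chains %s\n",
              nrow(x$atoms), dim(x$coords)[3],
              paste(unique(x$atoms$chain), collapse = "/")))
  invisible(x)
}

#' Read a multi-model PDB file as a snapshot ensemble
#'
#' One frame per MODEL record; alternate locations other than blank/"A" are
#' dropped.
#'
#' @param path PDB file path.
#' @return A [snapshot_ensemble()].
#' @export
read_snapshot_ensemble <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  keep <- at$type == "ATOM" & (is.na(at$alt) | at$alt %in% c("", "A"))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  n_atoms <- sum(keep)
  ix <- which(keep)
  coords <- array(NA_real_, c(n_atoms, 3, n_frames))
  for (f in seq_len(n_frames)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    coords[, , f] <- m[ix, , drop = FALSE]
  }
  atoms <- data.frame(chain = at$chain[keep], residue = at$resno[keep],
                      atom = trimws(at$elety[keep]),
                      aa = at$resid[keep], stringsAsFactors = FALSE)
  snapshot_ensemble(atoms, coords)
}

# parse "H:29" / list(chain=, residue=) residue references
.parse_res <- function(x) {
  if (is.list(x)) return(list(chain = x$chain, residue = as.integer(x$residue)))
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("residue reference must look like 'H:29'")
  num <- as.integer(gsub("[^0-9]", "", parts[2]))
  list(chain = parts[1], residue = num)
}

#' Per-frame Calpha-Calpha distance series
#'
#' Euclidean distance between the Calpha atoms of two residues in every
#' frame, in frame order.
#'
#' @param ensemble A [snapshot_ensemble()].
#' @param res_a,res_b Residue references, `"H:29"` style or
#'   `list(chain=, residue=)`.
#' @return Numeric vector of distances in Angstrom, one per frame.
#' @export
ca_distance_series <- function(ensemble, res_a, res_b) {
  stopifnot(inherits(ensemble, "snapshot_ensemble"))
  find_ca <- function(ref) {
    r <- .parse_res(ref)
    i <- which(ensemble$atoms$chain == r$chain &
               ensemble$atoms$residue == r$residue &
               ensemble$atoms$atom == "CA")
    if (!length(i))
      stop("missing CA atom for ", r$chain, ":", r$residue,
           " (all frames share the atom roster)")
    i[1]
  }
  ia <- find_ca(res_a)
  ib <- find_ca(res_b)
  d <- sqrt(colSums((ensemble$coords[ia, , ] - ensemble$coords[ib, , ])^2))
  bad <- which(!is.finite(d))
  if (length(bad))
    stop("missing coordinates in frame ", bad[1])
  as.numeric(d)
}

#' Compare two distance distributions
#'
#' Median shift `median(a) - median(b)` plus a two-sided Mann-Whitney
#' (Wilcoxon rank-sum) test: exact enumeration when both samples have at
#' most 8 untied values, otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param series_a,series_b Numeric distance series (each >= 5 values).
#' @return An object of class `distance_comparison` with `median_shift`
#'   (Angstrom), `u_statistic` and `p_value`.
#' @export
compare_distance_distributions <- function(series_a, series_b) {
  if (length(series_a) < 5 || length(series_b) < 5)
    stop("both series need >= 5 values")
  ties <- any(duplicated(c(series_a, series_b)))
  exact <- length(series_a) <= 8 && length(series_b) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(series_a, series_b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  structure(list(series_a = series_a, series_b = series_b,
                 median_shift = stats::median(series_a) -
                   stats::median(series_b),
                 u_statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 exact = exact),
            class = "distance_comparison")
}

#' @export
print.distance_comparison <- function(x, ...) {
  cat(sprintf(
    "Distance-distribution comparison: median shift %.3f A, U = %g, p = %.3g%s\n",
    x$median_shift, x$u_statistic, x$p_value,
    if (x$exact) " (exact)" else ""))
  invisible(x)
}

#' Write a snapshot ensemble as a multi-model PDB file
#'
#' @param ensemble A [snapshot_ensemble()].
#' @param path Output path.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "snapshot_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  at <- ensemble$atoms
  n_frames <- dim(ensemble$coords)[3]
  for (f in seq_len(n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ensemble$coords[, , f]
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(at)),
      ifelse(nchar(at$atom) < 4, paste0(" ", at$atom), at$atom),
      at$aa, at$chain, at$residue, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      substr(at$atom, 1, 1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
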