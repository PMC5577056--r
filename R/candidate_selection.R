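# The fluctuation-editing selection filter: a residue is a mutation candidate
# iff it (1) displays relaxation dispersion, (2) lies outside the CDR,
# (3) has a large side chain (not A/G/S/T/V) and (4) has relative solvent
# accessibility above a threshold (default 20%).

SMALL_RESIDUES <- c("A", "G", "S", "T", "V")
AA1 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

#' Composite amide chemical-shift perturbation
#'
#' `sqrt(dH^2 + (alpha * dN)^2)` with the conventional 15N weight
#' `alpha = 0.14`.
#'
#' @param delta_h 1H shift change in ppm (vectorised).
#' @param delta_n 15N shift change in ppm.
#' @param alpha Nitrogen weight.
#' @return Composite shift change in ppm (non-negative; zero iff both inputs
#'   are zero).
#' @examples
#' composite_csp(0.10, 0.50)  # 0.1221 ppm
#' @export
composite_csp <- function(delta_h, delta_n, alpha = 0.14) {
  sqrt(delta_h^2 + (alpha * delta_n)^2)
}

#' Flag residues by chemical-shift-perturbation thresholds
#'
#' Classifies each residue's composite CSP against the mean and the mean plus
#' one (population) standard deviation of all residues with data, mirroring
#' the usual two-line annotation of CSP bar plots.
#'
#' @param csp Numeric vector of composite CSP values (>= 2 non-NA values).
#' @return Factor with levels `none`, `above_mean`, `above_mean_plus_sd`
#'   (the latter is a subset of values flagged `above_mean`); comparisons are
#'   strict, so identical values all map to `none`.
#' @export
csp_flags <- function(csp) {
  ok <- is.finite(csp)
  if (sum(ok) < 2) stop("need >= 2 residues with CSP data")
  m <- mean(csp[ok])
  s <- sqrt(mean((csp[ok] - m)^2))  # population SD
  out <- rep(NA_character_, length(csp))
  out[ok] <- "none"
  out[ok & csp > m] <- "above_mean"
  out[ok & csp > m + s] <- "above_mean_plus_sd"
  factor(out, levels = c("none", "above_mean", "above_mean_plus_sd"))
}

#' Is this a large residue?
#'
#' The size criterion of the selection filter: residues other than Ala, Gly,
#' Ser, Thr and Val count as large (worth mutating to Ala).
#'
#' @param amino_acid One-letter amino-acid code(s).
#' @return Logical vector.
#' @examples
#' is_large_residue(c("R", "G", "W"))  # TRUE FALSE TRUE
#' @export
is_large_residue <- function(amino_acid) {
  aa <- toupper(amino_acid)
  bad <- !aa %in% AA1
  if (any(bad))
    stop("unknown amino-acid code(s): ",
         paste(unique(amino_acid[bad]), collapse = ", "))
  !aa %in% SMALL_RESIDUES
}

#' Define CDR boundaries
#'
#' @param ranges Named list, one element per chain (`H`, `L`), each a
#'   data.frame with columns `start` and `end` (inclusive residue numbers).
#' @param scheme_name Label for the numbering scheme.
#' @return An object of class `cdr_definition`.
#' @seealso [kabat_cdr()] for the shipped default scheme.
#' @export
cdr_definition <- function(ranges, scheme_name = "custom") {
  stopifnot(is.list(ranges), length(names(ranges)) == length(ranges))
  for (ch in names(ranges)) {
    r <- ranges[[ch]]
    stopifnot(all(c("start", "end") %in% names(r)))
    if (any(r$start > r$end)) stop("CDR range with start > end in chain ", ch)
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)]))
      stop("overlapping CDR ranges in chain ", ch)
    ranges[[ch]] <- r
  }
  structure(list(scheme_name = scheme_name, ranges = ranges),
            class = "cdr_definition")
}

#' Kabat CDR definition for an Fv fragment
#'
#' The default scheme: heavy-chain CDRs 31-35, 50-65, 95-102 and light-chain
#' CDRs 24-34, 50-56, 89-97 (Kabat numbering).
#' @return A `cdr_definition`.
#' @export
kabat_cdr <- function() {
  cdr_definition(list(
    H = data.frame(start = c(31, 50, 95), end = c(35, 65, 102)),
    L = data.frame(start = c(24, 50, 89), end = c(34, 56, 97))),
    scheme_name = "kabat")
}

#' Is a residue inside the CDR?
#'
#' @param chain Chain id(s) (`"H"`/`"L"`).
#' @param residue Residue number(s).
#' @param cdr A [cdr_definition].
#' @return Logical vector.
#' @export
in_cdr <- function(chain, residue, cdr = kabat_cdr()) {
  stopifnot(inherits(cdr, "cdr_definition"))
  mapply(function(ch, num) {
    r <- cdr$ranges[[ch]]
    if (is.null(r)) return(FALSE)
    any(num >= r$start & num <= r$end)
  }, as.character(chain), as.numeric(residue), USE.NAMES = FALSE)
}

#' Build a residue-annotation table
#'
#' One record per residue with everything the selection filter needs.
#'
#' @param chain,residue,aa Residue identity (chain letter, number, one-letter
#'   code).
#' @param has_dispersion Did the residue survive the flat-curve exclusion and
#'   fit (i.e. does it fluctuate)?
#' @param rex Dispersion amplitude in 1/s (0 if none).
#' @param in_cdr Is the residue inside a CDR?
#' @param relative_asa Relative solvent accessibility in percent (may exceed
#'   100 for distorted conformers; capped validity range 0-150).
#' @param csp Optional composite chemical-shift perturbation in ppm.
#' @return A data.frame of class `residue_annotation`.
#' @export
residue_annotation <- function(chain, residue, aa, has_dispersion, rex,
                               in_cdr, relative_asa, csp = NA_real_) {
  stopifnot(all(rex >= 0))
  if (any(relative_asa < 0 | relative_asa > 150))
    stop("relative_asa must lie in [0, 150]")
  is_large_residue(aa)  # validates codes
  out <- data.frame(
    residue_id = sprintf("%s:%s%d", chain, toupper(aa), as.integer(residue)),
    chain = as.character(chain), residue = as.integer(residue),
    aa = toupper(aa), has_dispersion = as.logical(has_dispersion),
    rex = rex, in_cdr = as.logical(in_cdr), relative_asa = relative_asa,
    csp = csp, row.names = NULL)
  class(out) <- c("residue_annotation", "data.frame")
  out
}

#' Select alanine-mutation candidates
#'
#' Applies the four-criteria fluctuation-editing filter to an annotation
#' table: selected iff `has_dispersion & !in_cdr & is_large_residue(aa) &
#' relative_asa > asa_threshold` (strict `>`).  Rejected residues carry the
#' first failed criterion (checked in that order) as the reason.  Selection
#' is a pure function of the annotations; no ordering effects.
#'
#' @param annotations A `residue_annotation` data.frame (or compatible).
#' @param cdr Optional [cdr_definition]; if supplied, the `in_cdr` column is
#'   recomputed from it, otherwise the column is used as-is.
#' @param asa_threshold Relative ASA threshold in percent (default 20).
#' @return A list of class `candidate_selection` with data.frames `selected`
#'   and `rejected` (the latter with a `reason` column) and the threshold
#'   used.
#' @export
select_candidates <- function(annotations, cdr = NULL, asa_threshold = 20) {
  need <- c("residue_id", "aa", "has_dispersion", "in_cdr", "relative_asa")
  miss <- setdiff(need, names(annotations))
  if (length(miss)) stop("annotations lack columns: ",
                         paste(miss, collapse = ", "))
  ann <- as.data.frame(annotations)
  if (!is.null(cdr)) ann$in_cdr <- in_cdr(ann$chain, ann$residue, cdr)
  reason <- rep(NA_character_, nrow(ann))
  reason[is.na(reason) & !ann$has_dispersion] <- "no_dispersion"
  reason[is.na(reason) & ann$in_cdr] <- "in_cdr"
  reason[is.na(reason) & !is_large_residue(ann$aa)] <- "small_residue"
  reason[is.na(reason) & !(ann$relative_asa > asa_threshold)] <- "low_asa"
  sel <- is.na(reason)
  rejected <- ann[!sel, , drop = FALSE]
  rejected$reason <- reason[!sel]
  structure(list(selected = ann[sel, , drop = FALSE],
                 rejected = rejected,
                 asa_threshold = asa_threshold),
            class = "candidate_selection")
}

#' @export
print.candidate_selection <- function(x, ...) {
  cat(sprintf("Fluctuation-editing selection: %d candidate(s), %d rejected (ASA > %g%%)\n",
              nrow(x$selected), nrow(x$rejected), x$asa_threshold))
  if (nrow(x$selected))
    cat("  selected:", paste(x$selected$residue_id, collapse = ", "), "\n")
  if (nrow(x$rejected)) {
    cat("  rejections by reason:\n")
    print(table(x$rejected$reason))
  }
  invisible(x)
}
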