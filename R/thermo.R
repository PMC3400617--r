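# Duplex end-stability scoring for RISC strand selection. The strand whose 5'
# end is less tightly paired has lower internal stability and is loaded into
# RISC more efficiently; we compare nearest-neighbor free-energy sums over the
# terminal base-pair window at each 5' end of the guide/passenger duplex.

# Watson-Crick RNA nearest-neighbor stack free energies, dG37 in kcal/mol
# (Xia et al. 1998, Biochemistry 37:14719, Table 4). Keyed by the top-strand
# dinucleotide 5'->3'; the 180-degree-rotated stack is the same parameter
# (e.g. AG == CU). Helix-initiation and terminal-AU terms are omitted: only
# differences between the two end windows are interpreted, so constants shared
# by both ends would cancel.
NN_DG37 <- c(
  AA = -0.93, UU = -0.93,
  AU = -1.10,
  UA = -1.33,
  CU = -2.08, AG = -2.08,
  CA = -2.11, UG = -2.11,
  GU = -2.24, AC = -2.24,
  GA = -2.35, UC = -2.35,
  CG = -2.36,
  GG = -3.26, CC = -3.26,
  GC = -3.42
)

is_wc_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
  (a == "G" & b == "C") | (a == "C" & b == "G")
}

# dG37 of the `window_bp` terminal pairs at the 5' end of `strand`, paired
# antiparallel with `partner` (strand position i <-> partner position L-i+1).
# A stack contributes only when both flanking pairs are Watson-Crick;
# mismatched positions (e.g. from seed mutations) and G:U contribute 0.
end_dG <- function(strand, partner, window_bp) {
  s <- seq_chars(strand)
  p <- seq_chars(partner)
  L <- length(p)
  if (length(s) != L) {
    stop("guide and passenger must have equal length to form the designed duplex",
         call. = FALSE)
  }
  if (window_bp < 2L || window_bp > L) {
    stop(sprintf("window of %d bp out of range for a %d-bp duplex", window_bp, L),
         call. = FALSE)
  }
  paired <- vapply(seq_len(window_bp),
                   function(i) is_wc_pair(s[i], p[L - i + 1L]), logical(1L))
  total <- 0
  for (i in seq_len(window_bp - 1L)) {
    if (paired[i] && paired[i + 1L]) {
      total <- total + NN_DG37[[paste0(s[i], s[i + 1L])]]
    }
  }
  total
}

duplex_asymmetry <- function(guide, passenger, window_bp = 4L) {
  end_dG(guide, passenger, window_bp) - end_dG(passenger, guide, window_bp)
}

#' Nearest-neighbor free energy of a duplex end window
#'
#' Sums Watson-Crick RNA nearest-neighbor stack free energies (dG37,
#' kcal/mol) over the terminal `window_bp` base pairs at the requested 5' end
#' of the guide/passenger duplex. Less negative means less stable. Stacks
#' flanked by a non-Watson-Crick position (seed-mutation mismatches, G:U)
#' contribute 0, a deliberately conservative simplification.
#'
#' @param guide,passenger equal-length RNA sequences forming the designed
#'   duplex (antiparallel; guide position i pairs passenger position L-i+1).
#' @param end `"guide_5p"` or `"passenger_5p"`.
#' @param window_bp terminal window width in base pairs (default 4).
#' @return Free energy in kcal/mol (<= 0).
#' @examples
#' d <- assemble_hairpin(paper_mirnas()[["hsa-miR-127-3p"]])
#' end_window_dG(d$guide$sequence, d$passenger, "guide_5p")
#' @export
end_window_dG <- function(guide, passenger, end = c("guide_5p", "passenger_5p"),
                          window_bp = 4L) {
  end <- match.arg(end)
  g <- as_nt_seq(guide, "RNA")
  p <- as_nt_seq(passenger, "RNA")
  if (end == "guide_5p") end_dG(g, p, window_bp) else end_dG(p, g, window_bp)
}

#' Predict which strand of a designed duplex is loaded into RISC
#'
#' Computes the end-stability asymmetry `guide_5p_dG - passenger_5p_dG`. A
#' positive asymmetry (guide 5' end less stable) predicts guide loading; a
#' negative one predicts passenger loading; values within `tolerance` of zero
#' are ambiguous. The prediction is advisory: a warning is emitted when the
#' preferred strand is not the guide.
#'
#' @param design a [assemble_hairpin()] result (or a list with `guide` and
#'   `passenger`).
#' @param window_bp terminal window width in base pairs (default 4).
#' @param tolerance kcal/mol band treated as ambiguous (default 0.5).
#' @return Object of class `duplex_end_stability` with fields `guide_5p_dG`,
#'   `passenger_5p_dG`, `window_bp`, `asymmetry`, `predicted_loaded`.
#' @examples
#' predict_loaded_strand(assemble_hairpin(paper_mirnas()[["hsa-miR-127-3p"]]))
#' @export
predict_loaded_strand <- function(design, window_bp = 4L, tolerance = 0.5) {
  g <- as_nt_seq(design$guide, "RNA")
  p <- as_nt_seq(design$passenger, "RNA")
  g5 <- end_dG(g, p, window_bp)
  p5 <- end_dG(p, g, window_bp)
  asym <- g5 - p5
  predicted <- if (asym > tolerance) "guide"
               else if (asym < -tolerance) "passenger"
               else "ambiguous"
  if (predicted != "guide") {
    warning(sprintf(
      "predicted loaded strand is '%s' (asymmetry %.2f kcal/mol); consider ",
      predicted, asym),
      "destabilize_passenger_3prime() to favor guide loading", call. = FALSE)
  }
  structure(list(
    guide_5p_dG = g5, passenger_5p_dG = p5, window_bp = as.integer(window_bp),
    asymmetry = asym, predicted_loaded = predicted,
    parameter_table = "Xia-Turner WC RNA NN dG37"
  ), class = "duplex_end_stability")
}

#' @export
print.duplex_end_stability <- function(x, ...) {
  cat(sprintf(
    "<duplex_end_stability> %d-bp windows (%s)\n  guide 5' dG %.2f | passenger 5' dG %.2f | asymmetry %.2f kcal/mol -> %s\n",
    x$window_bp, x$parameter_table, x$guide_5p_dG, x$passenger_5p_dG,
    x$asymmetry, x$predicted_loaded))
  invisible(x)
}
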