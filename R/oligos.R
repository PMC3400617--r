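# Synthesis-ready top/bottom DNA oligos with vector-specific flanks and
# restriction overhangs.

revcomp_dna <- function(x) as.character(reverse_complement(nt_seq(x, "DNA")))

new_oligo_pair <- function(name, top, bottom, profile, warnings = character(0)) {
  structure(list(
    name = name,
    top = top,
    bottom = bottom,
    profile = profile$name,
    enzymes = profile$enzymes,
    overhangs = list(
      top_5p = profile$top_prefix,       # single-stranded after annealing
      bottom_5p = profile$bottom_prefix,
      bottom_3p = profile$bottom_suffix
    ),
    warnings = warnings
  ), class = "oligo_pair")
}

#' @export
print.oligo_pair <- function(x, ...) {
  cat(sprintf("<oligo_pair> %s (%s; %s)\n", x$name, x$profile,
              paste(x$enzymes, collapse = "/")))
  cat(sprintf("  top    5'-%s-3' (%d nt)\n", x$top, nchar(x$top)))
  cat(sprintf("  bottom 5'-%s-3' (%d nt)\n", x$bottom, nchar(x$bottom)))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# Shared emission rule: core DNA -> annealed duplex per profile.
emit_pair <- function(name, core_dna, profile, warnings = character(0)) {
  body <- paste0(profile$core_prefix, core_dna, profile$core_suffix)
  top <- paste0(profile$top_prefix, body)
  bottom <- paste0(profile$bottom_prefix, revcomp_dna(body),
                   profile$bottom_suffix)
  new_oligo_pair(name, top, bottom, profile, warnings)
}

#' Emit cloning oligos for a hairpin design
#'
#' Converts the precursor to DNA and wraps it in the profile's flanks:
#' for `plvx-shRNA2`, `top = GATC + CCC + passenger + loop + guide + TTTTTA`
#' and `bottom = AATT + revcomp(CCC + core + TTTTTA)` (strict mode: the bottom
#' strand is the exact reverse complement of the double-stranded region). An
#' internal T run of >= 4 inside the core (which would terminate Pol III
#' early; the 3' TTTTTA flank is the intended terminator) is reported as a
#' warning, not an error.
#'
#' @param design a [assemble_hairpin()] result.
#' @param profile profile name or [vector_profile()] (default `plvx-shRNA2`).
#' @return [`oligo_pair`][emit_overexpression_oligos] object with fields
#'   `top`, `bottom` (both 5'->3' DNA), `overhangs`, `warnings`.
#' @examples
#' emit_overexpression_oligos(assemble_hairpin(paper_mirnas()[["hsa-miR-127-3p"]]))
#' @export
emit_overexpression_oligos <- function(design, profile = "plvx-shRNA2") {
  stopifnot(inherits(design, "hairpin_design"))
  profile <- vector_profile(profile)
  core <- as.character(reverse_transcribe(design$precursor))
  warnings <- character(0)
  if (grepl("TTTT", core, fixed = TRUE)) {
    warnings <- c(warnings,
                  "internal T-run >= 4 inside the hairpin core may terminate Pol III early")
    warning(warnings[length(warnings)], call. = FALSE)
  }
  nm <- paste0("plvx-", sub("^hsa-miR-", "hs-", design$guide$name))
  emit_pair(nm, core, profile, warnings)
}

#' Verify complementarity of an annealed oligo pair
#'
#' Aligns the two strands as implied by the overhang annotations (the top
#' minus its 5' overhang against the bottom minus its 5' overhang and 3'
#' extension) and reports every non-complementary position. Strict-mode
#' emission always yields zero mismatches; the verbatim printed
#' plvx-hs-146b-3p bottom strand reports mismatches at the seed-mutated
#' positions in both arms.
#'
#' @param pair an `oligo_pair`.
#' @return Object of class `duplex_report`: `ok`, `n_mismatches`,
#'   `mismatch_positions` (1-based on the full top strand), `annealed_length`,
#'   `overhangs`.
#' @export
verify_duplex <- function(pair) {
  stopifnot(inherits(pair, "oligo_pair"))
  oh <- pair$overhangs
  top_ann <- substring(pair$top, nchar(oh$top_5p) + 1L)
  bot_len <- nchar(pair$bottom)
  bot_ann <- substr(pair$bottom, nchar(oh$bottom_5p) + 1L,
                    bot_len - nchar(oh$bottom_3p))
  if (nchar(top_ann) != nchar(bot_ann)) {
    return(structure(list(
      ok = FALSE, n_mismatches = NA_integer_, mismatch_positions = integer(0),
      annealed_length = NA_integer_, overhangs = oh,
      note = sprintf("annealed regions differ in length (%d vs %d)",
                     nchar(top_ann), nchar(bot_ann))
    ), class = "duplex_report"))
  }
  expected <- seq_chars(nt_seq(revcomp_dna(top_ann), "DNA"))
  observed <- seq_chars(nt_seq(bot_ann, "DNA"))
  mm_bottom <- which(expected != observed)
  # report in top-strand coordinates (full oligo, 1-based from its 5' end)
  mm_top <- sort(nchar(top_ann) - mm_bottom + 1L + nchar(oh$top_5p))
  structure(list(
    ok = length(mm_top) == 0L,
    n_mismatches = length(mm_top),
    mismatch_positions = mm_top,
    annealed_length = nchar(top_ann),
    overhangs = oh,
    note = ""
  ), class = "duplex_report")
}

#' @export
print.duplex_report <- function(x, ...) {
  if (isTRUE(x$ok)) {
    cat(sprintf("<duplex_report> OK: %d annealed bp, 0 mismatches\n",
                x$annealed_length))
  } else if (nzchar(x$note)) {
    cat("<duplex_report> FAILED:", x$note, "\n")
  } else {
    cat(sprintf("<duplex_report> %d mismatch(es) at top-strand position(s) %s\n",
                x$n_mismatches, paste(x$mismatch_positions, collapse = ", ")))
  }
  invisible(x)
}

ANNEALING_PROTOCOL_NOTE <-
  "anneal equimolar oligos: 95C 2 min, then -1C every 90 s down to 25C"

#' Write an ordering sheet for synthesized oligos
#'
#' One row per strand: construct name, strand, 5'->3' sequence, length,
#' enzymes, and the annealing protocol note. With `path`, writes a TSV that
#' round-trips through [utils::read.delim()].
#'
#' @param pairs list of `oligo_pair` objects (may be empty).
#' @param path optional TSV output path.
#' @return The sheet as a data.frame (invisibly when `path` is given).
#' @export
emit_ordering_sheet <- function(pairs, path = NULL) {
  if (inherits(pairs, "oligo_pair")) pairs <- list(pairs)
  rows <- lapply(pairs, function(p) {
    data.frame(
      name = p$name,
      strand = c("top", "bottom"),
      sequence = c(p$top, p$bottom),
      length = c(nchar(p$top), nchar(p$bottom)),
      enzymes = paste(p$enzymes, collapse = "/"),
      protocol = ANNEALING_PROTOCOL_NOTE
    )
  })
  sheet <- if (length(rows)) do.call(rbind, rows) else data.frame(
    name = character(0), strand = character(0), sequence = character(0),
    length = integer(0), enzymes = character(0), protocol = character(0))
  rownames(sheet) <- NULL
  if (!is.null(path)) {
    utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(sheet))
  }
  sheet
}
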