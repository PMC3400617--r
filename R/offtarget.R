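# Screens the engineered passenger strand for unintended miRNA-like (seed
# match) or siRNA-like (full-length match) activity against a user-supplied
# sequence set (typically 3'UTRs). Only the supplied sense strand is scanned,
# matching how miRNA targeting works.

to_dna_string <- function(x) {
  s <- toupper(as.character(x))
  chartr("U", "T", s)
}

#' Scan targets for passenger seed matches
#'
#' Counts, per target, occurrences of the DNA reverse complement of the
#' passenger's seed window (default positions 2-8, the canonical 7-mer) in the
#' supplied sense-strand sequences. Overlapping occurrences are all counted.
#' Full-length perfect reverse-complement matches (siRNA-like cleavage sites)
#' are tallied separately. Targets may be DNA or RNA; counts are invariant to
#' the representation. Malformed records are skipped with a warning.
#'
#' @param passenger RNA sequence (the engineered 5'-arm strand).
#' @param targets named character vector (or list) of target sequences, e.g.
#'   from [read_target_fasta()]. Empty is allowed and yields zero counts.
#' @param seed_window 1-based positions on the passenger (default `2:8`).
#' @return Object of class `offtarget_report` with fields `seed_used` (RNA),
#'   `probe` (DNA searched for), `per_target` (data.frame target/count),
#'   `total_hits`, `perfect_match_hits`, `skipped_records`.
#' @examples
#' p <- build_passenger(paper_mirnas()[["hsa-miR-127-3p"]])
#' scan_seed_matches(p, c(utr1 = "ACGTACGT"))
#' @export
scan_seed_matches <- function(passenger, targets = character(0),
                              seed_window = 2:8) {
  p <- as_nt_seq(passenger, "RNA")
  seed_window <- as.integer(seed_window)
  if (min(seed_window) < 1L || max(seed_window) > nchar(p)) {
    stop("seed window out of range for the passenger", call. = FALSE)
  }
  seed_rna <- paste(seq_chars(p)[seed_window], collapse = "")
  probe <- as.character(reverse_complement(nt_seq(chartr("U", "T", seed_rna), "DNA")))
  full_probe <- as.character(reverse_complement(
    nt_seq(to_dna_string(p), "DNA")))

  targets <- unlist(lapply(targets, as.character))
  nms <- names(targets)
  if (is.null(nms)) nms <- paste0("target_", seq_along(targets))

  counts <- integer(0)
  perfect <- 0L
  skipped <- 0L
  kept <- character(0)
  for (i in seq_along(targets)) {
    s <- to_dna_string(targets[[i]])
    if (grepl("[^ACGT]", s)) {
      warning(sprintf("skipping malformed target record '%s'", nms[i]),
              call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    subject <- Biostrings::DNAString(s)
    n <- if (nchar(s) >= nchar(probe)) {
      Biostrings::countPattern(probe, subject)
    } else 0L
    counts <- c(counts, n)
    kept <- c(kept, nms[i])
    if (nchar(s) >= nchar(full_probe)) {
      perfect <- perfect + Biostrings::countPattern(full_probe, subject)
    }
  }
  structure(list(
    seed_used = seed_rna,
    probe = probe,
    per_target = data.frame(target = kept, count = counts),
    total_hits = sum(counts),
    perfect_match_hits = perfect,
    skipped_records = skipped
  ), class = "offtarget_report")
}

#' @export
print.offtarget_report <- function(x, ...) {
  cat(sprintf(
    "<offtarget_report> seed %s (probe %s): %d seed hit(s) across %d target(s); %d full-length match(es)%s\n",
    x$seed_used, x$probe, x$total_hits, nrow(x$per_target),
    x$perfect_match_hits,
    if (x$skipped_records) sprintf("; %d record(s) skipped", x$skipped_records) else ""))
  if (nrow(x$per_target)) print(utils::head(x$per_target, 10L))
  invisible(x)
}

#' Check that the passenger's seed is not an existing miRNA seed
#'
#' Compares the passenger's seed window (exact string equality) against the
#' same window of each known miRNA; a non-empty result means the engineered
#' strand would mimic an existing miRNA's targeting.
#'
#' @param passenger RNA sequence.
#' @param known_mirnas list of [mature_mirna()] objects or named character
#'   vector of RNA sequences (e.g. miRBase mature set).
#' @param window 1-based positions compared on both strands (default `2:8`).
#' @return Character vector of miRNA names whose seed equals the passenger's
#'   (empty means the seed is novel).
#' @export
check_seed_novelty <- function(passenger, known_mirnas, window = 2:8) {
  p <- as_nt_seq(passenger, "RNA")
  window <- as.integer(window)
  if (max(window) > nchar(p)) stop("window out of range", call. = FALSE)
  pseed <- paste(seq_chars(p)[window], collapse = "")
  nms <- names(known_mirnas)
  hits <- character(0)
  for (i in seq_along(known_mirnas)) {
    m <- known_mirnas[[i]]
    nm <- if (inherits(m, "mature_mirna") && nzchar(m$name)) m$name
          else if (!is.null(nms) && nzchar(nms[i])) nms[i] else paste0("mirna_", i)
    s <- as_nt_seq(m, "RNA")
    if (nchar(s) < max(window)) next
    if (paste(seq_chars(s)[window], collapse = "") == pseed) hits <- c(hits, nm)
  }
  hits
}
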