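# FASTA input. miRBase mature.fa headers look like
# ">hsa-miR-146b-3p MIMAT0004766 Homo sapiens miR-146b-3p"; only the first
# whitespace-delimited token is kept as the record name.

#' Read mature miRNAs from a FASTA file
#'
#' Tolerates miRBase `mature.fa` dialect headers (the name is the first
#' whitespace-delimited header token) and uppercases residues. Records are
#' validated as RNA; records that fail validation (e.g. contain `T` or
#' ambiguity codes) are skipped with a warning.
#'
#' @param path path to a FASTA file of mature miRNA sequences (RNA alphabet).
#' @return Named list of [mature_mirna()] objects. The number of skipped
#'   records is attached as attribute `skipped`.
#' @export
read_mirna_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  nms <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1L), 1L)
  out <- list()
  skipped <- 0L
  for (i in seq_along(set)) {
    rec <- tryCatch(
      mature_mirna(as.character(set[[i]]), name = nms[i],
                   source = basename(path)),
      error = function(e) {
        warning(sprintf("skipping FASTA record '%s': %s", nms[i],
                        conditionMessage(e)), call. = FALSE)
        NULL
      }
    )
    if (is.null(rec)) skipped <- skipped + 1L else out[[nms[i]]] <- rec
  }
  attr(out, "skipped") <- skipped
  out
}

#' Read target sequences (e.g. 3'UTRs) from a FASTA file
#'
#' Accepts DNA or RNA records; all are uppercased and converted to DNA for
#' scanning. Malformed records are skipped with a warning and tallied.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of DNA sequences, with attribute `skipped`.
#' @export
read_target_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  nms <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1L), 1L)
  out <- character(0)
  skipped <- 0L
  for (i in seq_along(set)) {
    s <- toupper(as.character(set[[i]]))
    s <- chartr("U", "T", s)
    if (grepl("[^ACGT]", s)) {
      warning(sprintf("skipping malformed target record '%s'", nms[i]),
              call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    out[nms[i]] <- s
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector (or list of `nt_seq`) of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- vapply(seqs, as.character, character(1L))
  lines <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  writeLines(lines, path)
  invisible(path)
}
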