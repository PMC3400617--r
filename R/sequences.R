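# Alphabet-safe sequence primitives. Positions are 1-based from the 5' end of
# the strand under discussion, everywhere in the toolkit.

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")

#' Create a nucleotide sequence with a declared alphabet
#'
#' Sequences are stored as uppercase character scalars with an `alphabet`
#' attribute. Mixed case is uppercased on ingest. `T` in an RNA context and `U`
#' in a DNA context are rejected rather than silently converted (use
#' [transcribe()] / [reverse_transcribe()]), as are IUPAC ambiguity codes.
#'
#' @param x character scalar; the residues (may be empty).
#' @param alphabet `"RNA"` or `"DNA"`.
#' @param name optional free-text label.
#' @return An object of class `nt_seq`.
#' @examples
#' nt_seq("uucaagaga", "RNA")
#' @export
nt_seq <- function(x, alphabet = c("RNA", "DNA"), name = "") {
  alphabet <- match.arg(alphabet)
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("sequence must be a single character string", call. = FALSE)
  }
  x <- toupper(x)
  allowed <- if (alphabet == "RNA") RNA_BASES else DNA_BASES
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% allowed)
  if (length(bad)) {
    stop(sprintf(
      "invalid %s symbol '%s' at position %d (allowed: %s)",
      alphabet, chars[bad[1L]], bad[1L], paste(allowed, collapse = "")
    ), call. = FALSE)
  }
  structure(x, class = "nt_seq", alphabet = alphabet, name = name)
}

#' @export
print.nt_seq <- function(x, ...) {
  nm <- attr(x, "name")
  cat(sprintf("<nt_seq %s, %d nt%s> %s\n", attr(x, "alphabet"), nchar(x),
              if (nzchar(nm)) paste0(", ", nm) else "", unclass(x)))
  invisible(x)
}

seq_alphabet <- function(x) {
  a <- attr(x, "alphabet")
  if (is.null(a)) stop("not an nt_seq: missing alphabet", call. = FALSE)
  a
}

# Coerce a plain string to nt_seq under a declared alphabet; pass nt_seq through
# (checking the alphabet if one is required).
as_nt_seq <- function(x, alphabet, name = "") {
  if (inherits(x, "mature_mirna")) x <- x$sequence
  if (inherits(x, "nt_seq")) {
    if (!missing(alphabet) && seq_alphabet(x) != alphabet) {
      stop(sprintf("expected a %s sequence, got %s", alphabet, seq_alphabet(x)),
           call. = FALSE)
    }
    return(x)
  }
  nt_seq(x, alphabet = alphabet, name = name)
}

seq_chars <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1L]]

#' Mature miRNA input
#'
#' Wraps an RNA sequence with its arm of origin (`"5p"`, `"3p"`, or
#' `"unknown"`, inferred from the name suffix when possible). Lengths outside
#' 18--26 nt are an error; outside 20--24 nt a warning (typical mature miRNAs
#' are ~22 nt).
#'
#' @param sequence RNA string or `nt_seq`.
#' @param name record name, e.g. `"hsa-miR-146b-3p"`.
#' @param arm `"5p"`, `"3p"`, or `"unknown"`.
#' @param source free text describing where the sequence came from.
#' @return An object of class `mature_mirna` (a list with elements `sequence`,
#'   `name`, `arm`, `source`).
#' @examples
#' mature_mirna("UGCCCUGUGGACUCAGUUCUGG", "hsa-miR-146b-3p")
#' @export
mature_mirna <- function(sequence, name = "", arm = NULL, source = "user") {
  sequence <- as_nt_seq(sequence, "RNA", name = name)
  n <- nchar(sequence)
  if (n < 18L || n > 26L) {
    stop(sprintf("mature miRNA '%s' has length %d; expected 18-26 nt", name, n),
         call. = FALSE)
  }
  if (n < 20L || n > 24L) {
    warning(sprintf("mature miRNA '%s' has unusual length %d nt", name, n),
            call. = FALSE)
  }
  if (is.null(arm)) {
    arm <- if (grepl("-5p$", name)) "5p" else if (grepl("-3p$", name)) "3p" else "unknown"
  }
  arm <- match.arg(arm, c("5p", "3p", "unknown"))
  structure(list(sequence = sequence, name = name, arm = arm, source = source),
            class = "mature_mirna")
}

#' @export
print.mature_mirna <- function(x, ...) {
  cat(sprintf("<mature_mirna> %s (%s arm, %d nt)\n  %s\n",
              x$name, x$arm, nchar(x$sequence), as.character(x$sequence)))
  invisible(x)
}

#' Watson-Crick reverse complement
#'
#' Alphabet-preserving reverse complement (RNA in, RNA out; DNA in, DNA out),
#' delegated to Biostrings.
#'
#' @param seq an `nt_seq`, `mature_mirna`, or plain string (plus `alphabet`).
#' @param alphabet required when `seq` is a plain string.
#' @return `nt_seq` of the same alphabet and length.
#' @examples
#' reverse_complement(nt_seq("TCGGATCCGTCTGAGCTTGGCT", "DNA"))
#' @export
reverse_complement <- function(seq, alphabet) {
  seq <- as_nt_seq(seq, alphabet)
  a <- seq_alphabet(seq)
  if (nchar(seq) == 0L) return(seq)
  xs <- if (a == "RNA") Biostrings::RNAString(as.character(seq))
        else Biostrings::DNAString(as.character(seq))
  nt_seq(as.character(Biostrings::reverseComplement(xs)), alphabet = a,
         name = attr(seq, "name"))
}

#' Transcribe DNA to RNA / reverse transcribe RNA to DNA
#'
#' A pure T<->U swap (no strand change); the round trip is the identity.
#'
#' @param seq DNA (`transcribe`) or RNA (`reverse_transcribe`) sequence.
#' @return `nt_seq` in the other alphabet.
#' @examples
#' transcribe(nt_seq("TTCAAGAGA", "DNA"))
#' @export
transcribe <- function(seq) {
  seq <- as_nt_seq(seq, "DNA")
  nt_seq(chartr("T", "U", as.character(seq)), "RNA", name = attr(seq, "name"))
}

#' @rdname transcribe
#' @export
reverse_transcribe <- function(seq) {
  seq <- as_nt_seq(seq, "RNA")
  nt_seq(chartr("U", "T", as.character(seq)), "DNA", name = attr(seq, "name"))
}

#' Count identical positions inside a window
#'
#' Compares two same-alphabet sequences position by position over a 1-based
#' window (e.g. `3:8`, the seed-collision window) and returns the number of
#' identical positions.
#'
#' @param a,b sequences of the same alphabet.
#' @param window integer vector of 1-based positions, within both lengths.
#' @return Integer in `[0, length(window)]`.
#' @examples
#' positional_identity(nt_seq("AGAACU", "RNA"), nt_seq("AGAACU", "RNA"), 1:6)
#' @export
positional_identity <- function(a, b, window) {
  a <- if (inherits(a, "mature_mirna")) a$sequence else a
  b <- if (inherits(b, "mature_mirna")) b$sequence else b
  if (!inherits(a, "nt_seq") || !inherits(b, "nt_seq")) {
    stop("positional_identity() needs nt_seq (or mature_mirna) inputs",
         call. = FALSE)
  }
  if (seq_alphabet(a) != seq_alphabet(b)) {
    stop("sequences must share an alphabet", call. = FALSE)
  }
  window <- as.integer(window)
  if (length(window) == 0L) return(0L)
  if (min(window) < 1L || max(window) > min(nchar(a), nchar(b))) {
    stop(sprintf("window [%d, %d] out of range for lengths %d and %d",
                 min(window), max(window), nchar(a), nchar(b)), call. = FALSE)
  }
  sum(seq_chars(a)[window] == seq_chars(b)[window])
}
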