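# Built-in worked-example inputs and a synthetic duplex-pair generator used by
# the property tests.

# Mature sequences recoverable verbatim from the printed cloning primers.
PAPER_MIRNA_SEQS <- c(
  "hsa-miR-146b-3p" = "UGCCCUGUGGACUCAGUUCUGG",
  "hsa-miR-146b-5p" = "UGAGAACUGAAUUCCAUAGGCU",
  "hsa-miR-127-3p"  = "UCGGAUCCGUCUGAGCUUGGCU",
  "hsa-miR-142-3p"  = "UGUAGUGUUUCCUACUUUAUGGA"
)

#' Built-in worked-example mature miRNAs
#'
#' The four mature sequences used by the worked examples (hsa-miR-146b-3p,
#' hsa-miR-146b-5p, hsa-miR-127-3p, hsa-miR-142-3p), as a named list of
#' [mature_mirna()] objects.
#'
#' @param names optional subset of names to return.
#' @return Named list of `mature_mirna` objects.
#' @examples
#' paper_mirnas()[["hsa-miR-146b-3p"]]
#' @export
paper_mirnas <- function(names = NULL) {
  seqs <- PAPER_MIRNA_SEQS
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(seqs))
    if (length(missing)) {
      stop("unknown fixture miRNA(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    seqs <- seqs[names]
  }
  out <- lapply(base::names(seqs), function(n) {
    mature_mirna(seqs[[n]], name = n, source = "fixture")
  })
  stats::setNames(out, base::names(seqs))
}

# Printed synthesis oligos, whitespace-stripped (typesetting spaces removed).
# The plvx-hs-146b-3p bottom strand is preserved verbatim: it repeats the
# forward arm sequences instead of exact complements, so strict-mode emission
# intentionally differs from it at the four mutated positions.
PAPER_OLIGO_FIXTURES <- list(
  "plvx-hs-146b-3p" = c(
    top    = "GATCCCCCCAGGATTGAGTCCACAGGGCATTCAAGAGATGCCCTGTGGACTCAGTTCTGGTTTTTA",
    bottom = "AATTTAAAAACCAGGATTGAGTCCACAGGGCATCTCTTGAATGCCCTGTGGACTCAGTTCTGGGGG"
  ),
  "plvx-hs-127-3p" = c(
    top    = "GATCCCCAGCCAAGCTCAGACGGATCCGATTCAAGAGATCGGATCCGTCTGAGCTTGGCTTTTTTA",
    bottom = "AATTTAAAAAAGCCAAGCTCAGACGGATCCGATCTCTTGAATCGGATCCGTCTGAGCTTGGCTGGG"
  ),
  "plvx-hs-142-3p" = c(
    top    = "GATCCCCTCCATAAAGTAGGAAACACTACATTCAAGAGATGTAGTGTTTCCTACTTTATGGATTTTTA",
    bottom = "AATTTAAAAATCCATAAAGTAGGAAACACTACATCTCTTGAATGTAGTGTTTCCTACTTTATGGAGGG"
  ),
  "psicheck-hs-146b-3p" = c(
    top    = "TCGACACCCCAGAACTGAGTCCACAGGGCAGGTCAACAATCACCCCAGAACTGAGTCCACAGGGCAGGC",
    bottom = "GGCCGCCTGCCCTGTGGACTCAGTTCTGGGGTGATTGTTGACCTGCCCTGTGGACTCAGTTCTGGGGTG"
  ),
  "psicheck-hs-146b-5p" = c(
    top    = "TCGACACCAGCCTATGGAATTCAGTTCTCAGGTCAACAATCACCAGCCTATGGAATTCAGTTCTCAGGC",
    bottom = "GGCCGCCTGAGAACTGAATTCCATAGGCTGGTGATTGTTGACCTGAGAACTGAATTCCATAGGCTGGTG"
  ),
  "pMIR-hs-146b-3p" = c(
    top    = "CACCCCAGAACTGACAGCACAGGGCAGGTCAACAATCACCCCAGAACTGACAGCACAGGGCAGGC",
    bottom = "CGCGGCCTGCCCTGTGCTGTCAGTTCTGGGGTGATTGTTGACCTGCCCTGTGCTGTCAGTTCTGGGGTGAGCT"
  ),
  "pMIR-hs-146b-3p-mut" = c(
    top    = "CACCCCAGAACTGACAGCAGACGGGAGGTCAACAATCACCCCAGAACTGACAGCAGACGGGAGGC",
    bottom = "CGCGGCCTCCCGTCTGCTGTCAGTTCTGGGGTGATTGTTGACCTCCCGTCTGCTGTCAGTTCTGGGGTGAGCT"
  )
)

#' Built-in worked-example synthesis oligos
#'
#' The printed cloning-oligo pairs for the worked-example constructs
#' (overexpression inserts and luciferase sensor inserts), keyed by construct
#' name, whitespace-stripped. Used as regression fixtures: strict-mode emission
#' reproduces every strand byte-for-byte except the plvx-hs-146b-3p bottom
#' strand, which is kept verbatim (see [verify_duplex()]).
#'
#' @param construct optional single construct name.
#' @return A named list of `c(top=, bottom=)` character pairs, or one such pair.
#' @export
paper_oligo_fixtures <- function(construct = NULL) {
  if (is.null(construct)) return(PAPER_OLIGO_FIXTURES)
  if (!construct %in% names(PAPER_OLIGO_FIXTURES)) {
    stop("unknown fixture construct: ", construct, call. = FALSE)
  }
  PAPER_OLIGO_FIXTURES[[construct]]
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

random_rna <- function(n) paste(sample(RNA_BASES, n, replace = TRUE), collapse = "")

#' Generate synthetic guide/counterpart duplex pairs with controlled seed overlap
#'
#' Test-support generator: draws random guide miRNAs, derives the engineered
#' passenger (reverse complement of the guide), and constructs a counterpart
#' miRNA whose collision window shares exactly `seed_overlap` identical
#' positions with the passenger's window. Reproducible given `seed`.
#'
#' @param n number of pairs.
#' @param seed_overlap integer in `0:length(window)`; exact number of identical
#'   window positions between passenger and counterpart.
#' @param seed integer RNG seed (required for reproducibility).
#' @param length guide length in nt (default 22, a typical mature miRNA).
#' @param window collision window on both strands (default `3:8`).
#' @return data.frame with columns `guide`, `counterpart`, `overlap`.
#' @examples
#' generate_fixtures(3, seed_overlap = 6, seed = 1)
#' @export
generate_fixtures <- function(n, seed_overlap, seed = NULL, length = 22L,
                              window = 3:8) {
  stopifnot(n >= 0, seed_overlap >= 0, seed_overlap <= length(window))
  with_seed(seed, {
    guide <- character(n)
    counterpart <- character(n)
    for (i in seq_len(n)) {
      g <- random_rna(length)
      p <- seq_chars(reverse_complement(nt_seq(g, "RNA")))
      cp <- strsplit(random_rna(length), "", fixed = TRUE)[[1L]]
      keep <- sort(sample(window, seed_overlap))
      cp[keep] <- p[keep]
      for (w in setdiff(window, keep)) {
        cp[w] <- sample(setdiff(RNA_BASES, p[w]), 1L)
      }
      guide[i] <- g
      counterpart[i] <- paste(cp, collapse = "")
    }
    data.frame(guide = guide, counterpart = counterpart,
               overlap = rep(as.integer(seed_overlap), n))
  })
}
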