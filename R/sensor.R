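# Luciferase 3'UTR sensor inserts: two tandem copies of a target site behind
# Renilla/firefly luciferase. Site kinds: perfect (exact reverse complement of
# the miRNA; slicing-competent), bulged (non-complementary at the miRNA's
# central positions; miRNA-like repression only), and seed-mutant (bulged site
# additionally broken opposite the seed; the specificity control).

SENSOR_SITE_PREFIX <- "ACC"        # layout constants taken verbatim from the
SENSOR_LINKER <- "GGTCAACAATC"     # worked-example inserts; treated as fixed
SENSOR_TERMINAL <- "GGC"           # spacers with no claimed function

# Site position p pairs miRNA position L - p + 1 (antiparallel).
site_pos_for_mirna_pos <- function(m, L) L - m + 1L

dna_complement <- function(ch) chartr("ACGT", "TGCA", ch)

new_sensor_site <- function(kind, sequence, edits, mirna) {
  structure(list(kind = kind, sequence = sequence, edits = edits,
                 mirna = mirna$name), class = "sensor_site")
}

#' @export
print.sensor_site <- function(x, ...) {
  cat(sprintf("<sensor_site> %s site for %s\n  5'-%s-3'\n", x$kind, x$mirna,
              x$sequence))
  if (nrow(x$edits)) {
    cat("  edits:", paste(sprintf("%d:%s>%s", x$edits$position, x$edits$from,
                                  x$edits$to), collapse = ", "), "\n")
  }
  invisible(x)
}

no_edits <- function() {
  data.frame(position = integer(0), from = character(0), to = character(0))
}

# Substitute the site base at the positions opposite the given miRNA positions
# with its own Watson-Crick complement. Because the starting base pairs the
# miRNA, its complement equals the opposing miRNA base (in DNA) and can never
# re-pair: the substitution is guaranteed non-complementary, and deterministic.
edit_opposite <- function(site_chars, mirna_positions, L) {
  pos <- sort(vapply(mirna_positions, site_pos_for_mirna_pos, integer(1L), L))
  edits <- data.frame(position = pos, from = site_chars[pos],
                      to = dna_complement(site_chars[pos]))
  site_chars[pos] <- edits$to
  list(chars = site_chars, edits = edits)
}

#' Perfect sensor site for a mature miRNA
#'
#' The DNA reverse complement of the mature sequence: a fully paired,
#' slicing-competent target site.
#'
#' @param mirna [mature_mirna()] or RNA sequence.
#' @return `sensor_site` of kind `"perfect"` (no edits).
#' @examples
#' make_perfect_site(paper_mirnas()[["hsa-miR-146b-3p"]])
#' @export
make_perfect_site <- function(mirna) {
  if (!inherits(mirna, "mature_mirna")) mirna <- mature_mirna(mirna)
  site <- as.character(reverse_complement(reverse_transcribe(mirna$sequence)))
  new_sensor_site("perfect", site, no_edits(), mirna)
}

#' Centrally bulged sensor site
#'
#' Starts from the perfect site and makes the positions opposite the miRNA's
#' central positions (default 10-12, the slicing register) non-complementary,
#' so repression must go through miRNA-like (non-slicing) pairing. Each edited
#' base is replaced by its own Watson-Crick complement, a deterministic rule
#' that reproduces the worked-example site.
#'
#' @param mirna [mature_mirna()] or RNA sequence.
#' @param bulge_positions miRNA positions to unpair (default `10:12`); must
#'   not overlap the seed (positions 2-8).
#' @return `sensor_site` of kind `"bulged"`; `edits` are relative to the
#'   perfect site.
#' @examples
#' make_bulged_site(paper_mirnas()[["hsa-miR-146b-3p"]])
#' @export
make_bulged_site <- function(mirna, bulge_positions = 10:12) {
  if (!inherits(mirna, "mature_mirna")) mirna <- mature_mirna(mirna)
  L <- nchar(mirna$sequence)
  bulge_positions <- as.integer(bulge_positions)
  if (min(bulge_positions) < 1L || max(bulge_positions) > L) {
    stop("bulge positions out of range for the miRNA", call. = FALSE)
  }
  if (any(bulge_positions %in% 2:8)) {
    stop("bulge positions overlap the seed (miRNA positions 2-8); a bulged ",
         "site must keep seed pairing intact", call. = FALSE)
  }
  perfect <- make_perfect_site(mirna)
  res <- edit_opposite(seq_chars(nt_seq(perfect$sequence, "DNA")),
                       bulge_positions, L)
  new_sensor_site("bulged", paste(res$chars, collapse = ""), res$edits, mirna)
}

#' Seed-mutant sensor site (negative control)
#'
#' Takes a bulged parent site and additionally breaks pairing opposite the
#' miRNA seed, at the first, central (ceiling of the median), and last
#' positions of the seed window -- three spaced substitutions, the pattern
#' recovered from the worked-example mutant site. Each edited base is replaced
#' by its own Watson-Crick complement.
#'
#' @param parent a `sensor_site` of kind `"bulged"`.
#' @param mirna the same miRNA the parent was built for.
#' @param seed_positions miRNA seed window to disrupt (default `2:7`).
#' @return `sensor_site` of kind `"seed_mutant"`; `edits` are relative to the
#'   parent site.
#' @examples
#' m <- paper_mirnas()[["hsa-miR-146b-3p"]]
#' make_seed_mutant_site(make_bulged_site(m), m)
#' @export
make_seed_mutant_site <- function(parent, mirna, seed_positions = 2:7) {
  stopifnot(inherits(parent, "sensor_site"))
  if (parent$kind != "bulged") {
    stop("seed-mutant sites are derived from a bulged parent", call. = FALSE)
  }
  if (!inherits(mirna, "mature_mirna")) mirna <- mature_mirna(mirna)
  L <- nchar(mirna$sequence)
  seed_positions <- sort(as.integer(seed_positions))
  targets <- unique(c(seed_positions[1L],
                      as.integer(ceiling(stats::median(seed_positions))),
                      seed_positions[length(seed_positions)]))
  res <- edit_opposite(seq_chars(nt_seq(parent$sequence, "DNA")), targets, L)
  new_sensor_site("seed_mutant", paste(res$chars, collapse = ""), res$edits,
                  mirna)
}

#' Assemble a two-site sensor insert with cloning oligos
#'
#' Builds the insert body `ACC + site + GGTCAACAATC + ACC + site + GGC` (two
#' identical tandem sites with fixed spacers) and emits the annealed oligo
#' pair for the sensor backbone: psiCHECK (XhoI/NotI, Renilla 3'UTR) or
#' pMIR-Report (MluI/SacI).
#'
#' @param site a `sensor_site`.
#' @param profile `"psicheck"` or `"pmir-report"` (or a [vector_profile()]).
#' @return Object of class `sensor_insert`: `sites` (list of 2), `body`,
#'   `oligos` (an `oligo_pair`), `profile`.
#' @examples
#' assemble_sensor_insert(make_perfect_site(paper_mirnas()[["hsa-miR-146b-3p"]]))
#' @export
assemble_sensor_insert <- function(site, profile = "psicheck") {
  stopifnot(inherits(site, "sensor_site"))
  profile <- vector_profile(profile)
  if (!identical(profile$kind, "sensor")) {
    stop(sprintf("profile '%s' is not a sensor backbone", profile$name),
         call. = FALSE)
  }
  body <- paste0(SENSOR_SITE_PREFIX, site$sequence, SENSOR_LINKER,
                 SENSOR_SITE_PREFIX, site$sequence, SENSOR_TERMINAL)
  nm <- paste0(if (profile$name == "psicheck") "psicheck-" else "pMIR-",
               sub("^hsa-miR-", "hs-", site$mirna),
               if (site$kind == "seed_mutant") "-mut" else "")
  pair <- emit_pair(nm, body, profile)
  structure(list(
    sites = list(site, site),
    body = body,
    layout = c(prefix = SENSOR_SITE_PREFIX, linker = SENSOR_LINKER,
               terminal = SENSOR_TERMINAL),
    profile = profile$name,
    oligos = pair
  ), class = "sensor_insert")
}

#' @export
print.sensor_insert <- function(x, ...) {
  cat(sprintf("<sensor_insert> 2x %s site for %s on %s\n", x$sites[[1L]]$kind,
              x$sites[[1L]]$mirna, x$profile))
  print(x$oligos)
  invisible(x)
}
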