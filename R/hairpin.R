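# The artificial miRNA* precursor: passenger (modified full complement of the
# guide) in the 5' arm, a short loop, and the guide (the miRNA* to express) in
# the 3' arm. Seed collisions between the passenger and the natural counterpart
# miRNA are detected over a 1-based window (default sites 3-8) and destroyed by
# deterministic substitutions.

DEFAULT_LOOP <- "UUCAAGAGA"  # widely used 9-nt shRNA loop
DEFAULT_COLLISION_WINDOW <- 3:8

#' Build the unmutated passenger strand for a guide miRNA*
#'
#' The engineered 5'-arm strand is the full Watson-Crick reverse complement of
#' the guide (unlike natural precursors, which carry mismatches and internal
#' loops).
#'
#' @param guide [mature_mirna()] or RNA sequence: the miRNA* to overexpress.
#' @return RNA `nt_seq`, the unmutated anti-miRNA* strand.
#' @examples
#' build_passenger(mature_mirna("UCGGAUCCGUCUGAGCUUGGCU", "hsa-miR-127-3p"))
#' @export
build_passenger <- function(guide) {
  g <- as_nt_seq(guide, "RNA")
  nm <- if (inherits(guide, "mature_mirna")) guide$name else attr(g, "name")
  out <- reverse_complement(g)
  attr(out, "name") <- if (nzchar(nm)) paste0("anti-", sub("^hsa-miR-", "", nm)) else ""
  out
}

#' Detect a seed collision between passenger and counterpart miRNA
#'
#' Compares the engineered passenger and the natural counterpart miRNA position
#' by position over the collision window (default sites 3-8, counted from each
#' strand's 5' end). Under the default policy a collision is an all-identical
#' window; a softer threshold (minimum identical count) can be supplied.
#'
#' @param passenger RNA sequence (engineered 5'-arm strand).
#' @param counterpart [mature_mirna()]: the abundant miRNA from the same
#'   natural precursor. `NULL` is a configuration error (run without a
#'   counterpart only if you accept an unscreened passenger).
#' @param window 1-based positions compared on both strands (default `3:8`).
#' @param threshold identical-position count at or above which a collision is
#'   declared; default `length(window)` (all identical).
#' @return Object of class `seed_collision` with fields `window`,
#'   `identical_count`, `collision`, `passenger_window_bases`,
#'   `counterpart_window_bases`, `threshold`.
#' @examples
#' p <- build_passenger(paper_mirnas()[["hsa-miR-146b-3p"]])
#' detect_seed_collision(p, paper_mirnas()[["hsa-miR-146b-5p"]])
#' @export
detect_seed_collision <- function(passenger, counterpart,
                                  window = DEFAULT_COLLISION_WINDOW,
                                  threshold = length(window)) {
  if (is.null(counterpart)) {
    stop("no counterpart miRNA supplied; pass one, or design without a ",
         "collision check (counterpart = NULL is not accepted silently)",
         call. = FALSE)
  }
  p <- as_nt_seq(passenger, "RNA")
  cp <- as_nt_seq(counterpart, "RNA")
  window <- as.integer(window)
  ident <- positional_identity(p, cp, window)
  structure(list(
    window = window,
    identical_count = ident,
    collision = ident >= threshold,
    passenger_window_bases = paste(seq_chars(p)[window], collapse = ""),
    counterpart_window_bases = paste(seq_chars(cp)[window], collapse = ""),
    threshold = as.integer(threshold)
  ), class = "seed_collision")
}

#' @export
print.seed_collision <- function(x, ...) {
  cat(sprintf(
    "<seed_collision> sites %d-%d: %d/%d identical (%s vs %s) -> %s\n",
    min(x$window), max(x$window), x$identical_count, length(x$window),
    x$passenger_window_bases, x$counterpart_window_bases,
    if (x$collision) "COLLISION" else "no collision"))
  invisible(x)
}

# Length of the maximal run of `base` containing position `idx` of `chars`.
run_length_at <- function(chars, idx, base = "T") {
  if (chars[idx] != base) return(0L)
  lo <- idx
  while (lo > 1L && chars[lo - 1L] == base) lo <- lo - 1L
  hi <- idx
  while (hi < length(chars) && chars[hi + 1L] == base) hi <- hi + 1L
  hi - lo + 1L
}

# Would substituting U at passenger position `pos` sit inside a T run of >=
# `run` on the encoded DNA top strand (5'CCC + passenger + loop)? Used as the
# Pol III guard during mutation selection: only a substitution *to* U can
# create a new terminator-like run. The 3' TTTTTA flank is excluded on
# purpose: it is the Pol III terminator itself.
mutation_creates_t_run <- function(passenger, loop, pos, run = 4L) {
  core <- strsplit(paste0("CCC", chartr("U", "T", paste0(as.character(passenger),
                                                         as.character(loop)))),
                   "", fixed = TRUE)[[1L]]
  run_length_at(core, pos + 3L) >= run
}

apply_mutations <- function(passenger, mutations) {
  ch <- seq_chars(passenger)
  if (NROW(mutations)) {
    for (k in seq_len(nrow(mutations))) {
      pos <- mutations$position[k]
      if (ch[pos] != mutations$from[k]) {
        stop(sprintf("mutation %d: from-base %s does not match passenger base %s",
                     pos, mutations$from[k], ch[pos]), call. = FALSE)
      }
      ch[pos] <- mutations$to[k]
    }
  }
  nt_seq(paste(ch, collapse = ""), "RNA", name = attr(passenger, "name"))
}

empty_mutations <- function() {
  data.frame(position = integer(0), from = character(0), to = character(0))
}

#' Propose seed-disrupting substitutions on the passenger strand
#'
#' When the passenger's collision window is identical to the counterpart
#' miRNA's seed, this engine chooses deterministic substitutions that destroy
#' the similarity. Under the `"paper"` policy, candidate positions are those
#' whose substitution leaves a G:U wobble in the hairpin stem (passenger A->G
#' opposite guide U; passenger C->U opposite guide G), scanned from the 3' end
#' of the window toward the 5' end, skipping positions adjacent to one already
#' chosen, until two substitutions are placed. Fallback tiers (other
#' transitions, then transversions) cover inputs with too few wobble-capable
#' positions. Every substitution must (a) differ from the counterpart base at
#' that position, (b) not create a run of >= 4 T in the encoded DNA top strand
#' (Pol III terminator guard), and (c) if `reference_seeds` is supplied, not
#' leave the mutated window equal to any reference seed.
#'
#' @param passenger RNA sequence (unmutated anti-miRNA* strand).
#' @param counterpart [mature_mirna()] (the natural counterpart miRNA).
#' @param window collision window (default `3:8`).
#' @param threshold collision threshold passed to [detect_seed_collision()].
#' @param n_mutations number of substitutions to place (default 2).
#' @param loop loop RNA used for the T-run guard context (default UUCAAGAGA).
#' @param reference_seeds optional character vector of window-length RNA
#'   strings the mutated window must not equal.
#' @return data.frame of substitutions with columns `position` (1-based from
#'   the passenger 5' end), `from`, `to`; zero rows when there is no collision.
#' @examples
#' p <- build_passenger(paper_mirnas()[["hsa-miR-146b-3p"]])
#' propose_seed_mutations(p, paper_mirnas()[["hsa-miR-146b-5p"]])
#' @export
propose_seed_mutations <- function(passenger, counterpart,
                                   window = DEFAULT_COLLISION_WINDOW,
                                   threshold = length(window),
                                   n_mutations = 2L,
                                   loop = DEFAULT_LOOP,
                                   reference_seeds = NULL) {
  p <- as_nt_seq(passenger, "RNA")
  report <- detect_seed_collision(p, counterpart, window, threshold)
  if (!report$collision) return(empty_mutations())

  cp <- seq_chars(as_nt_seq(counterpart, "RNA"))
  pch <- seq_chars(p)
  window <- sort(as.integer(window), decreasing = TRUE)  # scan 3' -> 5'

  # Preference tiers per position: wobble-preserving transitions first (the
  # stem keeps a G:U pair), then the remaining transitions, then transversions.
  candidate_bases <- function(base) {
    wobble <- switch(base, A = "G", C = "U", character(0))
    other_transition <- switch(base, G = "A", U = "C", character(0))
    transversions <- setdiff(RNA_BASES, c(base, wobble, other_transition))
    list(wobble, other_transition, transversions)
  }

  chosen <- empty_mutations()
  violated <- character(0)
  for (tier in 1:3) {
    for (pos in window) {
      if (nrow(chosen) >= n_mutations) break
      if (pos %in% chosen$position) next
      if (any(abs(pos - chosen$position) == 1L)) next  # skip adjacent
      for (to in candidate_bases(pch[pos])[[tier]]) {
        if (to == cp[pos]) {
          violated <- c(violated, sprintf("pos %d %s->%s equals counterpart base", pos, pch[pos], to))
          next
        }
        trial <- chosen
        trial[nrow(trial) + 1L, ] <- list(pos, pch[pos], to)
        mutated <- apply_mutations(p, trial)
        if (to == "U" && mutation_creates_t_run(mutated, loop, pos)) {
          violated <- c(violated, sprintf("pos %d %s->%s creates T-run >= 4", pos, pch[pos], to))
          next
        }
        if (!is.null(reference_seeds)) {
          win <- paste(seq_chars(mutated)[sort(window)], collapse = "")
          if (win %in% toupper(reference_seeds)) {
            violated <- c(violated, sprintf("pos %d %s->%s matches a reference seed", pos, pch[pos], to))
            next
          }
        }
        chosen <- trial
        break
      }
    }
    if (nrow(chosen) >= n_mutations) break
  }

  if (nrow(chosen) < n_mutations) {
    stop("no satisfying mutation set within the policy budget; constraints ",
         "violated: ", paste(unique(violated), collapse = "; "), call. = FALSE)
  }
  chosen <- chosen[order(chosen$position), , drop = FALSE]
  rownames(chosen) <- NULL

  post <- detect_seed_collision(apply_mutations(p, chosen), counterpart,
                                sort(window), threshold)
  if (post$collision) {
    stop("mutation set failed to eliminate the seed collision", call. = FALSE)
  }
  chosen
}

#' Assemble the hairpin design object
#'
#' Concatenates passenger (with mutations applied), loop, and guide in
#' 5'->3' order into the precursor.
#'
#' @param guide [mature_mirna()]: the miRNA* to overexpress (3' arm).
#' @param mutations data.frame as returned by [propose_seed_mutations()]
#'   (may have zero rows).
#' @param loop loop RNA (default UUCAAGAGA; must be at least 4 nt so the
#'   hairpin can close).
#' @param counterpart optional [mature_mirna()] recorded on the design.
#' @return Object of class `hairpin_design` with fields `guide`, `passenger`
#'   (mutated), `passenger_unmutated`, `loop`, `mutations`, `counterpart`,
#'   `precursor`.
#' @examples
#' assemble_hairpin(paper_mirnas()[["hsa-miR-127-3p"]])
#' @export
assemble_hairpin <- function(guide, mutations = empty_mutations(),
                             loop = DEFAULT_LOOP, counterpart = NULL) {
  if (!inherits(guide, "mature_mirna")) guide <- mature_mirna(guide)
  loop <- as_nt_seq(loop, "RNA")
  if (nchar(loop) < 4L) {
    stop("loop must be at least 4 nt for the hairpin to close", call. = FALSE)
  }
  unmut <- build_passenger(guide)
  passenger <- apply_mutations(unmut, mutations)
  precursor <- nt_seq(paste0(as.character(passenger), as.character(loop),
                             as.character(guide$sequence)), "RNA",
                      name = paste0(guide$name, " precursor"))
  structure(list(
    guide = guide,
    passenger = passenger,
    passenger_unmutated = unmut,
    loop = loop,
    mutations = mutations,
    counterpart = counterpart,
    precursor = precursor
  ), class = "hairpin_design")
}

#' @export
print.hairpin_design <- function(x, ...) {
  cat(sprintf("<hairpin_design> %s (%d nt precursor)\n", x$guide$name,
              nchar(x$precursor)))
  cat(sprintf("  5' arm (passenger): %s\n", as.character(x$passenger)))
  cat(sprintf("  loop              : %s\n", as.character(x$loop)))
  cat(sprintf("  3' arm (guide)    : %s\n", as.character(x$guide$sequence)))
  if (nrow(x$mutations)) {
    cat("  passenger mutations:",
        paste(sprintf("%d:%s>%s", x$mutations$position, x$mutations$from,
                      x$mutations$to), collapse = ", "), "\n")
  } else {
    cat("  passenger mutations: none (exact complement)\n")
  }
  invisible(x)
}

#' Destabilize the passenger 3' end to favor guide loading
#'
#' Optional enhancement pass: searches substitutions in the passenger's
#' 3'-terminal 4 positions (the region paired with the guide's 5' end) and
#' keeps up to `n_mutations` that strictly increase the duplex end-stability
#' asymmetry in favor of guide loading (see [predict_loaded_strand()]). If no
#' strictly improving substitution exists the design is returned unchanged
#' with a warning.
#'
#' @param design a [assemble_hairpin()] result.
#' @param n_mutations maximum substitutions to add (default 1).
#' @param window_bp end-window width in base pairs for the stability score.
#' @return A `hairpin_design` with any accepted substitutions appended to
#'   `mutations` and applied to `passenger`.
#' @export
destabilize_passenger_3prime <- function(design, n_mutations = 1L,
                                         window_bp = 4L) {
  stopifnot(inherits(design, "hairpin_design"))
  L <- nchar(design$passenger)
  tail_pos <- seq(max(1L, L - 3L), L)
  for (k in seq_len(n_mutations)) {
    current <- duplex_asymmetry(design$guide$sequence, design$passenger,
                                window_bp)
    best <- NULL
    for (pos in tail_pos) {
      if (pos %in% design$mutations$position) next
      from <- seq_chars(design$passenger)[pos]
      for (to in setdiff(RNA_BASES, from)) {
        trial <- design$mutations
        trial[nrow(trial) + 1L, ] <- list(pos, from, to)
        mutated <- apply_mutations(design$passenger_unmutated, trial)
        score <- duplex_asymmetry(design$guide$sequence, mutated, window_bp)
        if (score > current + 1e-12 && (is.null(best) || score > best$score)) {
          best <- list(mutations = trial, score = score)
        }
      }
    }
    if (is.null(best)) {
      if (k == 1L) {
        warning("no substitution in the passenger 3'-terminal 4 positions ",
                "improves the loading asymmetry; design unchanged",
                call. = FALSE)
      }
      break
    }
    design$mutations <- best$mutations
    design$passenger <- apply_mutations(design$passenger_unmutated,
                                        best$mutations)
  }
  design$mutations <- design$mutations[order(design$mutations$position), ,
                                       drop = FALSE]
  rownames(design$mutations) <- NULL
  design$precursor <- nt_seq(paste0(as.character(design$passenger),
                                    as.character(design$loop),
                                    as.character(design$guide$sequence)),
                             "RNA", name = attr(design$precursor, "name"))
  design
}
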