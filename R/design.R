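# End-to-end wrappers binding the modules into single calls, plus design
# report output (JSON bundle, TSV ordering sheet, FASTA of inserts).

#' Design a star-strand overexpression construct end to end
#'
#' Builds the passenger (reverse complement of the guide), screens it against
#' the counterpart miRNA's seed (collision window sites 3-8 by default),
#' applies the mutation engine when a collision is found, assembles the
#' hairpin, scores strand-loading asymmetry, and emits the cloning oligos.
#' Without a counterpart the pure complement is emitted with a warning, as for
#' guides whose natural precursor partner carries no seed similarity.
#'
#' @param guide [mature_mirna()] (or RNA string): the miRNA* to overexpress.
#' @param counterpart optional [mature_mirna()]: the abundant miRNA from the
#'   same natural precursor, screened for seed collisions.
#' @param vector profile name or [vector_profile()] (default `plvx-shRNA2`).
#' @param loop loop RNA (default UUCAAGAGA).
#' @param collision_window seed-collision window (default `3:8`).
#' @param collision_threshold identical-count threshold (default all-identical).
#' @param destabilize number of passenger 3'-end substitutions to attempt via
#'   [destabilize_passenger_3prime()] (default 0 = off).
#' @param reference_seeds optional RNA strings forbidden as the mutated window.
#' @return Object of class `star_design`: `design` (`hairpin_design`),
#'   `collision_pre`, `collision_post` (`seed_collision` or `NULL`),
#'   `stability` (`duplex_end_stability`), `oligos` (`oligo_pair`),
#'   `warnings`.
#' @examples
#' fx <- paper_mirnas()
#' design_star_construct(fx[["hsa-miR-146b-3p"]], fx[["hsa-miR-146b-5p"]])
#' @export
design_star_construct <- function(guide, counterpart = NULL,
                                  vector = "plvx-shRNA2",
                                  loop = DEFAULT_LOOP,
                                  collision_window = DEFAULT_COLLISION_WINDOW,
                                  collision_threshold = length(collision_window),
                                  destabilize = 0L,
                                  reference_seeds = NULL) {
  if (!inherits(guide, "mature_mirna")) guide <- mature_mirna(guide)
  passenger <- build_passenger(guide)
  warnings <- character(0)
  collision_pre <- NULL
  collision_post <- NULL
  mutations <- empty_mutations()
  if (is.null(counterpart)) {
    msg <- "no counterpart miRNA supplied; emitting the pure complement without a seed-collision check"
    warnings <- c(warnings, msg)
    warning(msg, call. = FALSE)
  } else {
    if (!inherits(counterpart, "mature_mirna")) {
      counterpart <- mature_mirna(counterpart)
    }
    collision_pre <- detect_seed_collision(passenger, counterpart,
                                           collision_window,
                                           collision_threshold)
    if (collision_pre$collision) {
      mutations <- propose_seed_mutations(passenger, counterpart,
                                          collision_window,
                                          collision_threshold,
                                          loop = loop,
                                          reference_seeds = reference_seeds)
    }
  }
  design <- assemble_hairpin(guide, mutations, loop, counterpart)
  if (!is.null(counterpart)) {
    collision_post <- detect_seed_collision(design$passenger, counterpart,
                                            collision_window,
                                            collision_threshold)
  }
  if (destabilize > 0L) {
    design <- destabilize_passenger_3prime(design, destabilize)
  }
  stability <- withCallingHandlers(
    predict_loaded_strand(design),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  oligos <- withCallingHandlers(
    emit_overexpression_oligos(design, vector),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  structure(list(
    design = design,
    collision_pre = collision_pre,
    collision_post = collision_post,
    stability = stability,
    oligos = oligos,
    warnings = warnings
  ), class = "star_design")
}

#' @export
print.star_design <- function(x, ...) {
  cat("== star-strand overexpression design ==\n")
  print(x$design)
  if (!is.null(x$collision_pre)) {
    cat("  pre-mutation : "); print(x$collision_pre)
    cat("  post-mutation: "); print(x$collision_post)
  }
  print(x$stability)
  print(x$oligos)
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Design a luciferase sensor construct end to end
#'
#' @param mirna [mature_mirna()] (or RNA string) the sensor reports on.
#' @param kind `"perfect"` (default; psiCHECK-style slicing sensor),
#'   `"bulged"` (miRNA-like repression sensor), or `"seed_mutant"`
#'   (negative-control variant of the bulged sensor).
#' @param vector sensor backbone (default `"psicheck"` for perfect sites,
#'   `"pmir-report"` otherwise).
#' @param bulge_positions,seed_positions passed to [make_bulged_site()] /
#'   [make_seed_mutant_site()].
#' @return A `sensor_insert` (see [assemble_sensor_insert()]).
#' @examples
#' design_sensor_construct(paper_mirnas()[["hsa-miR-146b-5p"]])
#' @export
design_sensor_construct <- function(mirna,
                                    kind = c("perfect", "bulged", "seed_mutant"),
                                    vector = NULL,
                                    bulge_positions = 10:12,
                                    seed_positions = 2:7) {
  kind <- match.arg(kind)
  if (!inherits(mirna, "mature_mirna")) mirna <- mature_mirna(mirna)
  if (is.null(vector)) {
    vector <- if (kind == "perfect") "psicheck" else "pmir-report"
  }
  site <- switch(kind,
    perfect = make_perfect_site(mirna),
    bulged = make_bulged_site(mirna, bulge_positions),
    seed_mutant = make_seed_mutant_site(make_bulged_site(mirna, bulge_positions),
                                        mirna, seed_positions)
  )
  assemble_sensor_insert(site, vector)
}

#' Summarize a star design as a report list / write it to files
#'
#' `design_report()` returns a plain list (JSON-ready); `write_design_report()`
#' writes the JSON bundle and, optionally, the TSV ordering sheet and a FASTA
#' of the insert strands.
#'
#' @param x a `star_design`.
#' @return Named list with guide, passenger, loop, mutation table, collision
#'   reports, stability scores, oligos, and warnings.
#' @export
design_report <- function(x) {
  stopifnot(inherits(x, "star_design"))
  collision <- function(cr) {
    if (is.null(cr)) return(NULL)
    list(window = range(cr$window), identical_count = cr$identical_count,
         collision = cr$collision,
         passenger_window_bases = cr$passenger_window_bases,
         counterpart_window_bases = cr$counterpart_window_bases)
  }
  list(
    guide = list(name = x$design$guide$name,
                 sequence = as.character(x$design$guide$sequence),
                 arm = x$design$guide$arm),
    passenger = as.character(x$design$passenger),
    loop = as.character(x$design$loop),
    precursor = as.character(x$design$precursor),
    mutations = x$design$mutations,
    collision_pre = collision(x$collision_pre),
    collision_post = collision(x$collision_post),
    stability = list(
      guide_5p_dG = x$stability$guide_5p_dG,
      passenger_5p_dG = x$stability$passenger_5p_dG,
      asymmetry = x$stability$asymmetry,
      window_bp = x$stability$window_bp,
      predicted_loaded = x$stability$predicted_loaded,
      parameter_table = x$stability$parameter_table),
    oligos = list(name = x$oligos$name, top = x$oligos$top,
                  bottom = x$oligos$bottom, profile = x$oligos$profile),
    warnings = x$warnings
  )
}

#' @rdname design_report
#' @param json_path output path for the JSON bundle.
#' @param sheet_path optional output path for the TSV ordering sheet.
#' @param fasta_path optional output path for a FASTA of both insert strands.
#' @export
write_design_report <- function(x, json_path, sheet_path = NULL,
                                fasta_path = NULL) {
  rep <- design_report(x)
  jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(sheet_path)) emit_ordering_sheet(list(x$oligos), sheet_path)
  if (!is.null(fasta_path)) {
    write_fasta(stats::setNames(c(x$oligos$top, x$oligos$bottom),
                                paste0(x$oligos$name, c("_top", "_bottom"))),
                fasta_path)
  }
  invisible(json_path)
}
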