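test_that("build_passenger yields the exact complement arm of the printed primers", {
  cases <- list(
    c("hsa-miR-127-3p", "AGCCAAGCUCAGACGGAUCCGA"),
    c("hsa-miR-142-3p", "UCCAUAAAGUAGGAAACACUACA"),
    c("hsa-miR-146b-3p", "CCAGAACUGAGUCCACAGGGCA")
  )
  for (cs in cases) {
    expect_equal(as.character(build_passenger(fx[[cs[1]]])), cs[2])
  }
})

test_that("seed collision on the 146b pair is 6/6 before and 4/6 after mutation", {
  anti <- build_passenger(fx[["hsa-miR-146b-3p"]])
  pre <- detect_seed_collision(anti, fx[["hsa-miR-146b-5p"]])
  expect_true(pre$collision)
  expect_equal(pre$identical_count, 6L)
  expect_equal(pre$passenger_window_bases, "AGAACU")

  post <- detect_seed_collision(nt_seq("CCAGGAUUGAGUCCACAGGGCA", "RNA"),
                                fx[["hsa-miR-146b-5p"]])
  expect_false(post$collision)
  expect_equal(post$identical_count, 4L)

  none <- detect_seed_collision(nt_seq("AAAAAAAAAA", "RNA"),
                                mature_mirna("CCCCCCCCCCCCCCCCCCCCCC", "all-c"))
  expect_equal(none$identical_count, 0L)
  expect_false(none$collision)

  expect_error(detect_seed_collision(anti, NULL), "counterpart")
})

test_that("mutation engine reproduces the worked-example substitutions (5 A>G, 7 C>U)", {
  anti <- build_passenger(fx[["hsa-miR-146b-3p"]])
  muts <- propose_seed_mutations(anti, fx[["hsa-miR-146b-5p"]])
  expect_equal(muts$position, c(5L, 7L))
  expect_equal(muts$from, c("A", "C"))
  expect_equal(muts$to, c("G", "U"))
})

test_that("mutation engine returns no mutations without a collision", {
  anti <- build_passenger(fx[["hsa-miR-127-3p"]])
  # hsa-miR-127's counterpart seed does not collide: use a disjoint stand-in
  muts <- propose_seed_mutations(anti, mature_mirna("GGGGGGGGGGGGGGGGGGGGGG", "decoy"))
  expect_equal(nrow(muts), 0L)
})

test_that("mutation engine eliminates collisions and never leaves a T-run (generated pairs)", {
  pairs <- generate_fixtures(120, seed_overlap = 6, seed = 401)
  for (i in seq_len(nrow(pairs))) {
    guide <- mature_mirna(pairs$guide[i], sprintf("synth-%d", i))
    cp <- mature_mirna(pairs$counterpart[i], sprintf("synth-cp-%d", i))
    anti <- build_passenger(guide)
    muts <- propose_seed_mutations(anti, cp)
    expect_gte(nrow(muts), 2L)
    expect_true(all(muts$position %in% 3:8))
    mutated <- nt_seq(paste(replace(strsplit(as.character(anti), "")[[1]],
                                    muts$position, muts$to), collapse = ""), "RNA")
    expect_false(detect_seed_collision(mutated, cp)$collision)
    # no substitution may sit inside a T-run >= 4 on the encoded top strand
    core <- strsplit(chartr("U", "T", paste0("CCC", as.character(mutated),
                                             "UUCAAGAGA")), "")[[1]]
    for (k in seq_len(nrow(muts))) {
      pos <- muts$position[k] + 3L
      if (core[pos] != "T") next
      lo <- pos; while (lo > 1 && core[lo - 1] == "T") lo <- lo - 1
      hi <- pos; while (hi < length(core) && core[hi + 1] == "T") hi <- hi + 1
      expect_lt(hi - lo + 1, 4)
    }
  }
})

test_that("mutation engine is deterministic and honors reference seeds", {
  anti <- build_passenger(fx[["hsa-miR-146b-3p"]])
  a <- propose_seed_mutations(anti, fx[["hsa-miR-146b-5p"]])
  b <- propose_seed_mutations(anti, fx[["hsa-miR-146b-5p"]])
  expect_identical(a, b)
  # forbid the window the paper policy would produce; engine must pick another
  forbidden <- "AGGAUU"
  alt <- propose_seed_mutations(anti, fx[["hsa-miR-146b-5p"]],
                                reference_seeds = forbidden)
  mutated <- replace(strsplit(as.character(anti), "")[[1]], alt$position, alt$to)
  expect_false(paste(mutated[3:8], collapse = "") == forbidden)
})

test_that("assemble_hairpin builds passenger+loop+guide and checks its invariants", {
  muts <- data.frame(position = c(5L, 7L), from = c("A", "C"), to = c("G", "U"))
  d <- assemble_hairpin(fx[["hsa-miR-146b-3p"]], muts)
  expect_equal(as.character(d$precursor),
               paste0("CCAGGAUUGAGUCCACAGGGCA", "UUCAAGAGA", "UGCCCUGUGGACUCAGUUCUGG"))
  expect_equal(nchar(d$precursor), 53L)
  expect_equal(nchar(d$loop), 9L)

  d127 <- assemble_hairpin(fx[["hsa-miR-127-3p"]])
  expect_equal(nrow(d127$mutations), 0L)
  expect_equal(as.character(d127$passenger),
               as.character(reverse_complement(fx[["hsa-miR-127-3p"]]$sequence)))

  # reverting mutations reproduces the exact complement
  reverted <- replace(strsplit(as.character(d$passenger), "")[[1]],
                      d$mutations$position, d$mutations$from)
  expect_equal(paste(reverted, collapse = ""),
               as.character(reverse_complement(fx[["hsa-miR-146b-3p"]]$sequence)))

  expect_error(assemble_hairpin(fx[["hsa-miR-127-3p"]], loop = "UUC"),
               "at least 4 nt")
  badmut <- data.frame(position = 1L, from = "G", to = "A")
  expect_error(assemble_hairpin(fx[["hsa-miR-127-3p"]], badmut),
               "does not match")
})

test_that("destabilize_passenger_3prime strictly improves asymmetry or leaves design alone", {
  muts <- data.frame(position = c(5L, 7L), from = c("A", "C"), to = c("G", "U"))
  d <- assemble_hairpin(fx[["hsa-miR-146b-3p"]], muts)
  before <- end_window_dG(d$guide$sequence, d$passenger, "guide_5p") -
            end_window_dG(d$guide$sequence, d$passenger, "passenger_5p")
  d2 <- destabilize_passenger_3prime(d, 1)
  added <- d2$mutations[!(d2$mutations$position %in% muts$position), ]
  expect_equal(nrow(added), 1L)
  expect_true(added$position %in% 19:22)
  after <- end_window_dG(d2$guide$sequence, d2$passenger, "guide_5p") -
           end_window_dG(d2$guide$sequence, d2$passenger, "passenger_5p")
  expect_gt(after, before)

  # exhaustive search agrees: the greedy pick attains the best single-substitution score
  best <- -Inf
  pch <- strsplit(as.character(d$passenger), "")[[1]]
  for (pos in 19:22) for (to in setdiff(c("A", "C", "G", "U"), pch[pos])) {
    trial <- pch; trial[pos] <- to
    tp <- paste(trial, collapse = "")
    sc <- oracle_end_dG(as.character(d$guide$sequence), tp) -
          oracle_end_dG(tp, as.character(d$guide$sequence))
    best <- max(best, sc)
  }
  expect_equal(after, best)

  # monotonicity on random unmutated designs
  set.seed(77)
  for (i in 1:15) {
    g <- mature_mirna(random_rna_str(22), sprintf("rand-%d", i))
    dd <- assemble_hairpin(g)
    pre <- suppressWarnings(predict_loaded_strand(dd))$asymmetry
    d3 <- suppressWarnings(destabilize_passenger_3prime(dd, 2))
    post <- suppressWarnings(predict_loaded_strand(d3))$asymmetry
    expect_gte(post, pre)
  }
})
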