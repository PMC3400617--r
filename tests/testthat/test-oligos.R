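printed <- paper_oligo_fixtures()

star_for <- function(name) {
  if (name == "hsa-miR-146b-3p") {
    design_star_construct(fx[[name]], fx[["hsa-miR-146b-5p"]])
  } else {
    suppressWarnings(design_star_construct(fx[[name]]))
  }
}

test_that("strict-mode emission reproduces the printed overexpression oligos", {
  # all three top strands byte-for-byte
  for (nm in c("hsa-miR-146b-3p", "hsa-miR-127-3p", "hsa-miR-142-3p")) {
    res <- star_for(nm)
    key <- paste0("plvx-", sub("hsa-miR-", "hs-", nm))
    expect_equal(res$oligos$top, printed[[key]][["top"]], label = key)
    expect_equal(res$oligos$name, key)
  }
  # unmutated designs reproduce both printed strands
  for (nm in c("hsa-miR-127-3p", "hsa-miR-142-3p")) {
    res <- star_for(nm)
    key <- paste0("plvx-", sub("hsa-miR-", "hs-", nm))
    expect_equal(res$oligos$bottom, printed[[key]][["bottom"]], label = key)
  }
})

test_that("emitted top strands end in the profile terminator and carry BamHI/EcoRI overhangs", {
  for (nm in c("hsa-miR-146b-3p", "hsa-miR-127-3p", "hsa-miR-142-3p")) {
    res <- star_for(nm)
    expect_match(res$oligos$top, "TTTTTA$")
    expect_match(res$oligos$top, "^GATC")
    expect_match(res$oligos$bottom, "^AATT")
  }
})

test_that("verify_duplex reports zero mismatches for every strict-mode pair", {
  designs <- c("hsa-miR-146b-3p", "hsa-miR-127-3p", "hsa-miR-142-3p")
  for (nm in designs) {
    rep <- verify_duplex(star_for(nm)$oligos)
    expect_true(rep$ok)
    expect_equal(rep$n_mismatches, 0L)
  }
  set.seed(31)
  for (i in 1:10) {
    d <- assemble_hairpin(mature_mirna(random_rna_str(22), sprintf("r%d", i)))
    pair <- suppressWarnings(emit_overexpression_oligos(d))
    expect_equal(verify_duplex(pair)$n_mismatches, 0L)
  }
})

test_that("the printed 146b-3p bottom strand mismatches at the mutated positions in both arms", {
  res <- star_for("hsa-miR-146b-3p")
  verbatim <- res$oligos
  verbatim$bottom <- printed[["plvx-hs-146b-3p"]][["bottom"]]
  rep <- verify_duplex(verbatim)
  expect_false(rep$ok)
  # top-strand coordinates: passenger arm starts at 8 (GATC+CCC), so the seed
  # mutations at passenger 5 and 7 sit at 12 and 14; the guide arm starts at
  # 39, and its bases opposite those mutations sit at 39+16-1=54 and 39+18-1=56
  expect_equal(rep$mismatch_positions, c(12L, 14L, 54L, 56L))
})

test_that("ordering sheets list both strands with true lengths and round-trip", {
  pairs <- lapply(c("hsa-miR-146b-3p", "hsa-miR-127-3p", "hsa-miR-142-3p"),
                  function(nm) star_for(nm)$oligos)
  sheet <- emit_ordering_sheet(pairs)
  expect_equal(nrow(sheet), 6L)
  expect_equal(sheet$length, nchar(sheet$sequence))
  expect_true(all(grepl("95C", sheet$protocol)))

  path <- withr::local_tempfile(fileext = ".tsv")
  emit_ordering_sheet(pairs, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$sequence, sheet$sequence)
  expect_equal(back$name, sheet$name)

  empty <- withr::local_tempfile(fileext = ".tsv")
  emit_ordering_sheet(list(), empty)
  expect_equal(nrow(read.delim(empty)), 0L)
})

test_that("T-runs inside the core are a warning, not an error", {
  g <- mature_mirna("GCAAAAGCGCGCGCGCGCGCUG", "synthetic-a-run")
  d <- assemble_hairpin(g)   # passenger contains UUUU opposite the A run
  expect_warning(pair <- emit_overexpression_oligos(d), "T-run")
  expect_true(length(pair$warnings) > 0)
  expect_equal(verify_duplex(pair)$n_mismatches, 0L)
})

test_that("unknown or incomplete profiles are configuration errors", {
  d <- assemble_hairpin(fx[["hsa-miR-127-3p"]])
  expect_error(emit_overexpression_oligos(d, "no-such-vector"), "unknown vector profile")
  expect_error(vector_profile(list(name = "custom", top_prefix = "GATC")),
               "missing required field")
})
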