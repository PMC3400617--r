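printed <- paper_oligo_fixtures()

test_that("perfect sites are the DNA reverse complement of the mature miRNA", {
  expect_equal(make_perfect_site(fx[["hsa-miR-146b-3p"]])$sequence,
               "CCAGAACTGAGTCCACAGGGCA")
  expect_equal(make_perfect_site(fx[["hsa-miR-146b-5p"]])$sequence,
               "AGCCTATGGAATTCAGTTCTCA")
  for (nm in names(fx)) {
    site <- make_perfect_site(fx[[nm]])
    expect_equal(as.character(transcribe(reverse_complement(nt_seq(site$sequence, "DNA")))),
                 as.character(fx[[nm]]$sequence), label = nm)
    expect_equal(nrow(site$edits), 0L)
  }
})

test_that("bulged sites unpair the miRNA central positions with recorded edits", {
  site <- make_bulged_site(fx[["hsa-miR-146b-3p"]])
  expect_equal(site$sequence, "CCAGAACTGACAGCACAGGGCA")
  expect_equal(site$edits$position, c(11L, 12L, 13L))
  expect_equal(site$edits$from, c("G", "T", "C"))
  expect_equal(site$edits$to, c("C", "A", "G"))

  # at every edited site position the base opposes (site p <-> miRNA L-p+1)
  # a non-complementary miRNA base
  mir <- strsplit(as.character(fx[["hsa-miR-146b-3p"]]$sequence), "")[[1]]
  pairs <- c(A = "U", C = "G", G = "C", T = "A")
  sch <- strsplit(site$sequence, "")[[1]]
  for (p in site$edits$position) {
    expect_false(pairs[[sch[p]]] == mir[22 - p + 1])
  }
  expect_error(make_bulged_site(fx[["hsa-miR-146b-3p"]], bulge_positions = 6:8),
               "overlap the seed")
})

test_that("seed-mutant sites break spaced seed pairing with recorded edits", {
  m <- fx[["hsa-miR-146b-3p"]]
  parent <- make_bulged_site(m)
  mut <- make_seed_mutant_site(parent, m)
  expect_equal(mut$sequence, "CCAGAACTGACAGCAGACGGGA")
  expect_equal(mut$edits$position, c(16L, 18L, 21L))
  expect_equal(mut$edits$from, c("C", "G", "C"))
  expect_equal(mut$edits$to, c("G", "C", "G"))

  # complementarity opposite the miRNA seed (positions 2-8): the mutant keeps
  # 4 of 7 paired (frozen from a position-by-position count), fewer than the
  # bulged parent's 7
  comp_count <- function(site) {
    mir <- strsplit(as.character(m$sequence), "")[[1]]
    pairs <- c(A = "U", C = "G", G = "C", T = "A")
    sch <- strsplit(site, "")[[1]]
    sum(sapply(2:8, function(i) pairs[[sch[22 - i + 1]]] == mir[i]))
  }
  expect_equal(comp_count(mut$sequence), 4L)
  expect_equal(comp_count(parent$sequence), 7L)

  expect_error(make_seed_mutant_site(make_perfect_site(m), m), "bulged parent")
})

test_that("assembled sensor inserts reproduce all four printed oligo pairs", {
  cases <- list(
    list("hsa-miR-146b-3p", "perfect", NULL, "psicheck-hs-146b-3p"),
    list("hsa-miR-146b-5p", "perfect", NULL, "psicheck-hs-146b-5p"),
    list("hsa-miR-146b-3p", "bulged", "pmir-report", "pMIR-hs-146b-3p"),
    list("hsa-miR-146b-3p", "seed_mutant", "pmir-report", "pMIR-hs-146b-3p-mut")
  )
  for (cs in cases) {
    ins <- design_sensor_construct(fx[[cs[[1]]]], kind = cs[[2]], vector = cs[[3]])
    expect_equal(ins$oligos$name, cs[[4]])
    expect_equal(ins$oligos$top, printed[[cs[[4]]]][["top"]], label = cs[[4]])
    expect_equal(ins$oligos$bottom, printed[[cs[[4]]]][["bottom"]], label = cs[[4]])
    expect_true(verify_duplex(ins$oligos)$ok)
  }
})

test_that("every insert contains exactly two copies of its site", {
  for (kind in c("perfect", "bulged", "seed_mutant")) {
    ins <- design_sensor_construct(fx[["hsa-miR-146b-3p"]], kind = kind)
    site <- ins$sites[[1]]$sequence
    hits <- gregexpr(site, ins$oligos$top, fixed = TRUE)[[1]]
    expect_length(hits[hits > 0], 2L)
    expect_equal(ins$body,
                 paste0("ACC", site, "GGTCAACAATC", "ACC", site, "GGC"))
  }
})

test_that("sensor profiles reject overexpression backbones and vice versa", {
  site <- make_perfect_site(fx[["hsa-miR-127-3p"]])
  expect_error(assemble_sensor_insert(site, "plvx-shRNA2"), "not a sensor")
})
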