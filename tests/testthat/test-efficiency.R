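# Frozen cross-implementation oracle values (Biopython MeltingTemp Tm_NN,
# SantaLucia 1998 unified table, 50 mM Na+, total oligo 500 nM).
TM_ORACLE <- c(
  ACGTACGTACGTACGTACGT   = 56.1458,
  GGGGGGGGGGCCCCCCCCCC   = 75.3631,
  AAAAAAAAAATTTTTTTTTT   = 38.6976,
  TCCTACGGGAGGCAGCAG     = 58.5057,
  CCGTCAATTCCTTTGAGT     = 49.9445,
  GACTGCATCGATCGTAGCTA   = 54.4664,
  TGGAGCATGTGGTTTAATTCGA = 55.3436
)

test_that("nearest-neighbour Tm is deterministic and tracks an independent oracle", {
  p <- "ACGTACGTACGTACGTACGT"
  expect_identical(melting_temperature(p), melting_temperature(p))
  expect_gt(melting_temperature("GGGGGGGGGGCCCCCCCCCC"),
            melting_temperature("AAAAAAAAAATTTTTTTTTT"))
  for (s in names(TM_ORACLE))
    expect_lt(abs(melting_temperature(s) - TM_ORACLE[[s]]), 1.5)
  expect_error(melting_temperature("A"), "at least 2")
})

test_that("fuzzy ramps hit their printed boundary values exactly", {
  expect_equal(score_tm(52), 1)
  expect_equal(score_tm(50), 0)
  expect_equal(score_tm(51), 0.5)
  expect_equal(score_tm_range(primer_set_pair("ACGTACGTACGTACGTA",
                                              "ACGTACGTACGTACGTA")), 1)
  lens <- c(rep(750, 99), 675)  # median 750, 1st percentile 675
  expect_equal(score_amplicon_range(c(rep(750, 100))), 1)
  expect_equal(score_amplicon_range(lens), 0.5)
  expect_equal(score_amplicon_range(c(rep(750, 99), 700)), 1)
  expect_error(score_amplicon_range(numeric(0)), "no amplicon")
})

test_that("GC-content term has the plateau, the hard fail and the continuous low ramp", {
  gc_primer <- function(ngc, len = 20) {
    paste0(strrep("G", ceiling(ngc / 2)), strrep("C", floor(ngc / 2)),
           strrep("A", len - ngc))
  }
  expect_equal(score_gc(gc_primer(11)), 1)    # f = 0.55
  expect_equal(score_gc(gc_primer(15)), 0)    # f = 0.75 hard fail
  expect_equal(score_gc(gc_primer(9)), 0.5)   # f = 0.45 on the ramp
  expect_equal(score_gc(gc_primer(10)), 1)    # f = 0.50 plateau edge
  expect_equal(score_gc(gc_primer(8)), 0)     # f = 0.40 ramp base
  expect_equal(score_gc(gc_primer(14)), 1)    # f = 0.70 plateau edge
})

test_that("3'-end stability terms follow the last-3 AT and last-5 GC rules", {
  expect_equal(score_end3_at("ACGTACGTACGATT"), 0)
  expect_equal(score_end3_at("ACGTACGTACGTAA"), 0)
  expect_equal(score_end3_at("ACGTACGTACGATG"), 1)
  expect_equal(score_end3_gc("ACGTACGTAGCGCA"), 0)  # 4 G/C in last 5
  expect_equal(score_end3_gc("ACGTACGTAGCGAT"), 1)  # exactly 3 is tolerated
  expect_equal(score_end3_gc("ACGTACGTAGGCCG"), 0)  # 5 G/C
})

test_that("homopolymer term scores run lengths 4/5/6 as 1/0.5/0", {
  expect_equal(score_homopolymer("ACGTACGTACGTACGTA"), 1)
  expect_equal(score_homopolymer("ACGTAAAAACGTACGTA"), 0.5)
  expect_equal(score_homopolymer("ACGTAAAAAACGTACGT"), 0)
  expect_equal(score_homopolymer("ACGTAAAACGTACGTAC"), 1)  # run of 4 is fine
})

test_that("self-dimer term applies the 8/11 ramp to the gap-free match maximum", {
  expect_equal(score_self_dimer("AAAAAAAAAAAAAAAAA"), 1)   # revcomp all T
  expect_equal(score_self_dimer("ATATATATATATATATAT"), 0)  # self-complementary
  p10 <- "GGGGATATATATATGGGG"
  expect_identical(oracle_max_matches(p10, reverse_complement(p10)), 10L)
  expect_equal(score_self_dimer(p10), 1 / 3)
})

test_that("hairpin term detects 3'-end fold-back and ignores self-overlap", {
  expect_equal(score_hairpin("GGGGGATATATATCCCCC"), 0)
  expect_equal(score_hairpin("CCCCCATATATATGGGGG"), 0)
  expect_equal(score_hairpin("AAAAAAAAAAAAAAAAA"), 1)
  # 3'-terminal seed is palindromic but nothing upstream pairs with it:
  # the fold-back may not align the seed onto its own source positions
  expect_equal(score_hairpin("AAAAAAAAAAAACATATG"), 1)
  expect_error(score_hairpin("ACGTACGT"), "twice")
})

test_that("cross-dimer ramp matches the printed constants on crafted pairs", {
  f <- "AAAAAAAAAACCCCCCCC"
  r10 <- reverse_complement("AAAAAAAAAAGGGGGGGG")  # m = 10
  r9 <- reverse_complement("AAAAAAAAAGGGGGGGGG")   # m = 9
  expect_identical(oracle_max_matches(f, "AAAAAAAAAAGGGGGGGG"), 10L)
  expect_identical(oracle_max_matches(f, "AAAAAAAAAGGGGGGGGG"), 9L)
  expect_equal(score_cross_dimer(primer_set_pair(f, r10)), 1 / 3)
  expect_equal(score_cross_dimer(primer_set_pair(f, r9)), 2 / 3)
  expect_equal(score_cross_dimer(primer_set_pair(
    "AAAAAAAAAAAAAAAAA", "AAAAAAAAAAAAAAAAA")), 1)
  expect_equal(score_cross_dimer(primer_set_pair(
    "ACGTGGCTACGATCGTAC", reverse_complement("ACGTGGCTACGATCGTAC"))), 0)
})

test_that("fuzzy ramps interpolate linearly between their endpoints", {
  for (x in seq(50, 52, by = 0.25))
    expect_equal(score_tm(x), (x - 50) / 2)
  for (delta in seq(50, 100, by = 10)) {
    lens <- c(rep(750, 99), 750 - delta)  # median 750, 1st percentile 750 - delta
    expect_equal(score_amplicon_range(lens),
                 min(1, max(0, (100 - delta) / 50)))
  }
})

test_that("efficiency score aggregates terms as means plus set-pair terms", {
  sim <- generate_synthetic_refset(synthetic_ref_spec(
    n_seq = 6, seq_length = 400, forward_pos = 50, reverse_pos = 330,
    mutation_rate = 0, seed = 5))
  pair <- primer_set_pair(
    c("TCCTACGGGAGGCAGCAG", "GACTGCATCGATCGTAGCTA"),
    "CCGTCAATTCCTTTGAGT")
  eff <- efficiency_score(pair, sim$refset)
  expect_length(unclass(eff), 10L)
  expect_true(all(eff >= 0 & eff <= 1))
  expect_equal(attr(eff, "total"), sum(eff))
  expect_gte(attr(eff, "total"), 0); expect_lte(attr(eff, "total"), 10)
  # single-primer terms are means of the per-primer term functions
  prim <- c(pair$forward, pair$reverse)
  expect_equal(eff[["gc"]], mean(vapply(prim, score_gc, 0)))
  expect_equal(eff[["homopolymer"]], mean(vapply(prim, score_homopolymer, 0)))
  expect_equal(eff[["end3_at"]], mean(vapply(prim, score_end3_at, 0)))
  expect_equal(eff[["self_dimer"]], mean(vapply(prim, score_self_dimer, 0)))
  expect_equal(eff[["tm"]],
               mean(vapply(prim, function(p) score_tm(melting_temperature(p)), 0)))
  # invariant to primer order within sets
  pair2 <- primer_set_pair(rev(pair$forward), pair$reverse)
  eff2 <- efficiency_score(pair2, sim$refset)
  expect_equal(attr(eff, "total"), attr(eff2, "total"))
})

test_that("a set-pair violating nearly every constraint scores at the floor", {
  sim <- generate_synthetic_refset(synthetic_ref_spec(
    n_seq = 5, seq_length = 300, forward_pos = 30, reverse_pos = 250,
    mutation_rate = 0, seed = 3))
  bad <- primer_set_pair("AAAAAATATATATATATATATATAT", "TTTTTTATATATATATA")
  eff <- efficiency_score(bad, sim$refset)
  expect_lte(attr(eff, "total"), 1)
  expect_equal(eff[["amplicon_range"]], 0)  # amplifies nothing
})

test_that("hand-scored toy set-pair reproduces the manual term-by-term sum", {
  # One forward, one reverse; each term worked out from its definition.
  f <- "GCGTACGCATGCAGCGTG"  # 18 nt, 12 G/C (f_GC = 2/3), ends GTG
  r <- "TGCACGCTGCATGCGTAC"  # 18 nt, 11 G/C, ends TAC
  sim <- generate_synthetic_refset(synthetic_ref_spec(
    n_seq = 4, seq_length = 400, forward_primer = f, forward_pos = 40,
    reverse_primer = r, reverse_pos = 330, mutation_rate = 0, seed = 9))
  eff <- efficiency_score(primer_set_pair(f, r), sim$refset)
  manual <- c(
    tm = mean(c(score_tm(melting_temperature(f)),
                score_tm(melting_temperature(r)))),
    gc = 1,               # both fractions inside [0.5, 0.7]
    end3_at = 1,          # GTG and TAC both contain G or C
    end3_gc = mean(c(score_end3_gc(f), score_end3_gc(r))),
    homopolymer = 1,      # no run above 2
    self_dimer = mean(c(score_self_dimer(f), score_self_dimer(r))),
    hairpin = mean(c(score_hairpin(f), score_hairpin(r))),
    tm_range = score_tm_range(primer_set_pair(f, r)),
    cross_dimer = score_cross_dimer(primer_set_pair(f, r)),
    amplicon_range = 1    # single planted product length
  )
  got <- unclass(eff)
  attr(got, "total") <- NULL
  expect_equal(got, manual, tolerance = 1e-12)
  expect_equal(attr(eff, "total"), sum(manual))
})
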