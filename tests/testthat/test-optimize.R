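test_that("dominance follows the strict Pareto definition on (E, C, M)", {
  expect_true(dominates(c(10, 0.9, 0.2), c(9, 0.8, 0.3)))
  expect_false(dominates(c(9, 0.8, 0.3), c(9, 0.8, 0.3)))  # equal vectors
  expect_false(dominates(c(10, 0.7, 0.2), c(9, 0.9, 0.3)))  # incomparable
  expect_false(dominates(c(9, 0.9, 0.3), c(10, 0.7, 0.2)))
  # equal in two objectives, better in one, still dominates
  expect_true(dominates(c(9, 0.8, 0.2), c(9, 0.8, 0.3)))
})

test_that("dominance is irreflexive and transitive on random score triples", {
  set.seed(53)
  for (i in 1:400) {
    v <- lapply(1:3, function(k)
      c(sample(0:10, 1), sample(seq(0, 1, 0.1), 1), sample(seq(0, 1, 0.1), 1)))
    expect_false(dominates(v[[1]], v[[1]]))
    if (dominates(v[[1]], v[[2]]) && dominates(v[[2]], v[[3]]))
      expect_true(dominates(v[[1]], v[[3]]))
  }
})

test_that("pareto_front equals the all-pairs oracle and is idempotent", {
  expect_error(pareto_front(toy_archive(numeric(0), numeric(0), numeric(0))),
               "empty")
  single <- toy_archive(5, 0.5, 0.5)
  expect_length(pareto_front(single), 1L)
  # dominance chain collapses to its maximum
  chain <- toy_archive(c(1, 2, 3), c(0.1, 0.2, 0.3), c(0.9, 0.5, 0.1))
  expect_equal(pareto_front(chain)[[1]]$E, 3)
  expect_length(pareto_front(chain), 1L)
  set.seed(59)
  for (i in 1:60) {
    n <- sample(3:120, 1)
    E <- sample(seq(0, 10, 0.5), n, replace = TRUE)
    C <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    M <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    arch <- toy_archive(E, C, M)
    front <- pareto_front(arch)
    keep <- oracle_front_keep(E, C, M)
    expect_equal(vapply(front, `[[`, 0, "E"), E[keep])
    expect_equal(vapply(front, `[[`, 0, "C"), C[keep])
    expect_equal(vapply(front, `[[`, 0, "M"), M[keep])
    expect_length(pareto_front(front), length(front))  # idempotent
    # no front entry is dominated by anything in the archive
    for (e in front)
      for (j in seq_len(n))
        expect_false(dominates(c(E[j], C[j], M[j]), c(e$E, e$C, e$M)))
  }
})

test_that("simplex weights are valid, uniform in expectation, and seed-reproducible", {
  set.seed(61)
  draws <- t(replicate(10000, sample_weights()))
  expect_true(all(draws >= 0))
  expect_true(all(abs(rowSums(draws) - 1) < 1e-12))
  expect_true(all(abs(colMeans(draws) - 1 / 3) < 0.02))
  set.seed(101); a <- replicate(5, sample_weights())
  set.seed(101); b <- replicate(5, sample_weights())
  expect_identical(a, b)
})

test_that("weighted score is the stated normalized linear combination", {
  sv <- structure(list(E = 9, C = 0.6, C_count = 6L, M = 0.25),
                  class = "score_vector")
  alpha <- c(E = 1 / 3, C = 1 / 3, M = 1 / 3)
  expect_equal(primeropt:::scalarize(sv, alpha), (0.9 + 0.6 + 0.75) / 3)
  expect_equal(primeropt:::scalarize(
    structure(list(E = 10, C = 0, M = 5), class = "score_vector"),
    c(E = 1, C = 0, M = 0)), 1)
  expect_equal(primeropt:::scalarize(
    structure(list(E = 0, C = 0, M = 0), class = "score_vector"),
    c(E = 0, C = 0, M = 1)), 1)
  expect_equal(primeropt:::scalarize(
    structure(list(E = 0, C = 0, M = 1.7), class = "score_vector"),
    c(E = 0, C = 0, M = 1)), 0)  # bias clamp
  expect_error(weighted_score(primer_set_pair("ACGTACGTACGTACGTA", "ACGTACGTACGTACGTA"),
                              c(0.5, 0.5, 0.5),
                              ref_set(c(x = strrep("A", 50)))),
               "sum to 1")
})

test_that("the single-edit neighbourhood has the right size, bounds and content", {
  p18 <- "ACGTGGCTACGATCGTAG"
  pair <- primer_set_pair(p18, "TGCCATGCATCGAATGCA")
  nb <- neighborhood(pair, 1, search_config(move_len_min = 15, move_len_max = 25))
  expect_length(nb, 3 * 18 + 8 + 2)
  # every neighbour differs from the input in exactly the addressed primer,
  # by exactly one edit
  for (x in nb) {
    expect_identical(x$reverse, pair$reverse)
    q <- x$forward
    expect_true(abs(nchar(q) - 18) <= 1)
    expect_false(identical(q, p18))
  }
  expect_false(anyDuplicated(vapply(nb, function(x) x$forward, "")) > 0)
  # at the lower length bound removals are excluded
  p15 <- "ACGTGGCTACGATCG"
  nb15 <- neighborhood(primer_set_pair(p15, "TGCCATGCATCGAATGCA"), 1,
                       search_config(move_len_min = 15, move_len_max = 25))
  expect_length(nb15, 3 * 15 + 8)
  # at the upper bound additions are excluded
  p25 <- strrep("ACGTG", 5)
  nb25 <- neighborhood(primer_set_pair(p25, "TGCCATGCATCGAATGCA"), 1,
                       search_config(move_len_min = 15, move_len_max = 25))
  expect_length(nb25, 3 * 25 + 2)
  # neighbours duplicating an existing primer of the same set are dropped
  twin <- primer_set_pair(c("ACGTGGCTACGATCGTAG", "ACGTGGCTACGATCGTAC"),
                          "TGCCATGCATCGAATGCA")
  nb_tw <- neighborhood(twin, 1)
  expect_false(any(vapply(nb_tw, function(x) anyDuplicated(x$forward) > 0, TRUE)))
  expect_length(nb_tw, 3 * 18 + 8 + 2 - 1)  # one substitution recreates the twin
  expect_error(neighborhood(pair, 5), "index")
})

test_that("local search fixes a planted seed-region defect and verifies local optimality", {
  p <- "TCCTACGGGAGGCAGCAG"
  pv <- strsplit(p, "")[[1]]
  alt <- pv; alt[1] <- "G"; alt[2] <- "A"          # variant planted in half the set
  start <- alt; start[3] <- "G"                     # one further edit: covers only half
  refset <- two_variant_refset(p, paste(alt, collapse = ""),
                               "CCGTCAATTCCTTTGAGT", n_half = 4, seed = 67)
  start_pair <- primer_set_pair(paste(start, collapse = ""), "CCGTCAATTCCTTTGAGT")
  expect_equal(score_vector(start_pair, refset)$C, 0.5)
  alpha <- c(E = 0.1, C = 0.8, M = 0.1)
  got <- local_search(start_pair, alpha, refset)
  sv <- attr(got, "score_vector")
  expect_equal(sv$C, 1)
  expect_gte(attr(got, "weighted_score"),
             weighted_score(start_pair, alpha, refset))
  # exhaustive re-scan: no single-edit neighbour of any primer improves it
  best <- attr(got, "weighted_score")
  for (i in 1:2) {
    for (nbr in neighborhood(got, i))
      expect_lte(weighted_score(nbr, alpha, refset), best)
  }
})

test_that("accepted local-search moves strictly increase the scalarized score", {
  sim <- generate_synthetic_refset(synthetic_ref_spec(
    n_seq = 10, seq_length = 500, forward_pos = 60, reverse_pos = 420,
    mutation_rate = 0.05, seed = 71))
  start <- primer_set_pair("TCCTACGGGAGGCAGTAG", "CCGTCAATTCCTTTGACT")
  alpha <- c(E = 0.5, C = 0.4, M = 0.1)
  s0 <- weighted_score(start, alpha, sim$refset)
  got <- local_search(start, alpha, sim$refset)
  expect_gte(attr(got, "weighted_score"), s0)
  # a local optimum is returned unchanged
  again <- local_search(got, alpha, sim$refset)
  expect_identical(again$forward, got$forward)
  expect_identical(again$reverse, got$reverse)
})

test_that("candidate selection applies the length, domain and amplicon filters", {
  sim <- generate_synthetic_refset(synthetic_ref_spec(
    n_seq = 6, seq_length = 1200, forward_pos = 200, reverse_pos = 880,
    mutation_rate = 0, seed = 73))
  cands <- data.frame(
    id = c("ok_meta", "short16", "archaeal", "outrange", "degen", "computed"),
    forward = c("TCCTACGGGAGGCAGCAG", "TCCTACGGGAGGCAGC", "TCCTACGGGAGGCAGCAG",
                "TCCTACGGGAGGCAGCAG", "TCCTACGGGAGGCAGCAH", "TCCTACGGGAGGCAGCAG"),
    reverse = c("CCGTCAATTCCTTTGAGT", "CCGTCAATTCCTTTGAGT", "CCGTCAATTCCTTTGAGT",
                "CCGTCAATTCCTTTGAGT", "CCGTCAATTCCTTTGAGT", "CCGTCAATTCCTTTGAGT"),
    domain = c("Bacteria", "Universal", "Archaea", "Bacteria", NA, NA),
    amplicon_length = c(700, 700, 700, 1500, 700, NA)
  )
  scfg <- search_config(amplicon_min = 650, amplicon_max = 750)
  arch <- select_initial(cands, sim$refset, search = scfg)
  kept <- vapply(arch, `[[`, "", "id")
  expect_setequal(kept, c("ok_meta", "degen", "computed"))
  degen <- arch[[which(kept == "degen")]]
  expect_length(degen$pair$forward, 3L)  # H expands to three primers
  expect_error(select_initial(cands[2, , drop = FALSE], sim$refset,
                              search = scfg),
               "widen")
})

test_that("multi-objective search is seed-deterministic and respects the restart budget", {
  sim <- generate_synthetic_refset(synthetic_ref_spec(
    n_seq = 12, seq_length = 500, forward_pos = 60, reverse_pos = 420,
    mutation_rate = 0.08, seed = 79))
  init <- list(primer_set_pair("TCCTACGGGAGGCAGTAG", "CCGTCAATTCCTTTGACT"))
  scfg0 <- search_config(restarts = 0, seed = 5)
  arch0 <- multi_objective_search(sim$refset, init, search = scfg0)
  expect_length(arch0, 1L)  # zero restarts: the initial archive
  scfg <- search_config(restarts = 3, seed = 5)
  a1 <- multi_objective_search(sim$refset, init, search = scfg)
  a2 <- multi_objective_search(sim$refset, init, search = scfg)
  expect_length(a1, 1L + 3L)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  expect_equal(vapply(a1, `[[`, "", "provenance"),
               c("initial", rep("local-search", 3)))
})

test_that("archive Jaccard compares solution lists as sets of set-pairs", {
  x <- primer_set_pair("ACGTGGCTACGATCGTAG", "TGCCATGCATCGAATGCA")
  y <- primer_set_pair("ACGTGGCTACGATCGTAC", "TGCCATGCATCGAATGCA")
  z <- primer_set_pair("ACGTGGCTACGATCGTAT", "TGCCATGCATCGAATGCA")
  expect_equal(archive_jaccard(list(x, y), list(x, y)), 1)
  expect_equal(archive_jaccard(list(x), list(y, z)), 0)
  expect_equal(archive_jaccard(list(x, y), list(y, z)), 1 / 3)
  expect_equal(archive_jaccard(list(), list()), 1)
  # order within primer sets does not affect identity
  x2 <- primer_set_pair(rev(x$forward), x$reverse)
  expect_equal(archive_jaccard(list(x), list(x2)), 1)
})
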