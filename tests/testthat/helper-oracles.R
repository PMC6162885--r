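# Independent brute-force oracles used across the suite. These are written
# from the definitions, not from the package internals.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(len, bases = BASES) {
  paste(sample(bases, len, replace = TRUE), collapse = "")
}

# Maximum matches over all gap-free alignments, enumerated offset by offset.
oracle_max_matches <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- 0L
  for (off in (-(nb - 1L)):(na - 1L)) {
    ia <- max(1L, off + 1L):min(na, off + nb)
    ib <- ia - off
    best <- max(best, sum(av[ia] == bv[ib]))
  }
  best
}

# Naive per-window matcher: 3' seed exact, at most max_mm mismatches in the
# remainder. Returns data.frame(start, mismatches).
oracle_find_sites <- function(primer, seq, seed_len = 5L, max_mm = 2L) {
  pv <- strsplit(primer, "")[[1]]; sv <- strsplit(seq, "")[[1]]
  m <- length(pv); L <- length(sv)
  starts <- integer(0); mms <- integer(0)
  if (L >= m) {
    seed_idx <- (m - seed_len + 1L):m
    for (s in 1L:(L - m + 1L)) {
      w <- sv[s:(s + m - 1L)]
      if (any(pv[seed_idx] != w[seed_idx])) next
      mm <- sum(pv[-seed_idx] != w[-seed_idx])
      if (mm <= max_mm) { starts <- c(starts, s); mms <- c(mms, mm) }
    }
  }
  data.frame(start = starts, mismatches = mms)
}

# All-pairs Pareto oracle: plain double loop over the dominance definition
# (E, C maximized, M minimized, vectors must differ).
oracle_front_keep <- function(E, C, M) {
  n <- length(E)
  keep <- rep(TRUE, n)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i == j) next
      differ <- E[i] != E[j] || C[i] != C[j] || M[i] != M[j]
      if (differ && E[i] >= E[j] && C[i] >= C[j] && M[i] <= M[j]) {
        keep[j] <- FALSE
        break
      }
    }
  }
  keep & !duplicated(paste(E, C, M))
}

# Minimal archive builder for optimizer tests: entries carry scores only.
toy_archive <- function(E, C, M) {
  dummy <- primeropt::primer_set_pair("ACGTACGTACGTACGTA", "TGCATGCATGCATGCAT")
  entries <- lapply(seq_along(E), function(i)
    list(pair = dummy, E = E[i], C = C[i], C_count = 0L, M = M[i],
         provenance = "initial", restart = NA_integer_))
  structure(entries, class = "primer_archive")
}

# Two-variant planted refset: half the sequences carry the primer `p`, half
# carry `p` with substitutions at `alt_pos` replaced by `alt_base`; the
# reverse site is planted everywhere. Ground truth coverage is known by
# construction.
two_variant_refset <- function(p, p_alt, rev_primer, n_half = 5,
                               seq_length = 400, fwd_pos = 60,
                               rev_pos = 330, seed = 1) {
  set.seed(seed)
  plant <- function(primer_f) {
    s <- sample(BASES, seq_length, replace = TRUE)
    s[fwd_pos:(fwd_pos + nchar(primer_f) - 1L)] <- strsplit(primer_f, "")[[1]]
    rc <- primeropt::reverse_complement(rev_primer)
    s[rev_pos:(rev_pos + nchar(rev_primer) - 1L)] <- strsplit(rc, "")[[1]]
    paste(s, collapse = "")
  }
  seqs <- c(vapply(seq_len(n_half), function(i) plant(p), ""),
            vapply(seq_len(n_half), function(i) plant(p_alt), ""))
  primeropt::ref_set(seqs, sprintf("tv%02d", seq_along(seqs)))
}
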