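# Synthetic 16S-like reference sets with known ground truth: random
# background emulating variable regions, with planted conserved primer
# binding sites whose presence and per-base substitutions are recorded, so
# that the exact expected coverage and matching-bias are known by
# construction.

#' Specification of a synthetic reference set
#'
#' Each generated sequence is a uniform-random A/C/G/T background of fixed
#' length. A forward primer binding site (the primer sequence itself) and a
#' reverse primer binding site (the reverse complement of the reverse
#' primer) are planted at fixed positions, mimicking conserved blocks
#' flanking variable regions. Each site is present in a sequence
#' independently with its carrier fraction and, when present, each of its
#' bases is substituted independently with the per-site mutation rate.
#'
#' The defaults emulate the canonical bacterial 16S layout: 1500 nt
#' sequences, a forward site at the conserved block upstream of V3 and a
#' reverse site downstream of V6, yielding a ~719 nt product.
#'
#' @param n_seq Number of sequences.
#' @param seq_length Sequence length (nt).
#' @param forward_primer,reverse_primer Planted primers (non-degenerate).
#' @param forward_pos,reverse_pos 1-based start positions of the planted
#'   forward site and of the reverse-binding site on the sense strand.
#' @param forward_fraction,reverse_fraction Fraction of sequences carrying
#'   each site.
#' @param mutation_rate Per-base substitution probability within planted
#'   sites (0.05 by default, a conserved-block level of variation).
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `synthetic_ref_spec`.
#' @export
synthetic_ref_spec <- function(n_seq = 50, seq_length = 1500,
                               forward_primer = "TCCTACGGGAGGCAGCAG",
                               forward_pos = 340,
                               reverse_primer = "CCGTCAATTCCTTTGAGT",
                               reverse_pos = 1041,
                               forward_fraction = 1, reverse_fraction = 1,
                               mutation_rate = 0.05, seed = 1) {
  check_primer(forward_primer, "forward_primer")
  check_primer(reverse_primer, "reverse_primer")
  f_end <- forward_pos + nchar(forward_primer) - 1L
  r_end <- reverse_pos + nchar(reverse_primer) - 1L
  if (forward_pos < 1 || r_end > seq_length)
    po_stop("planted sites must fit within the sequence length")
  if (f_end >= reverse_pos)
    po_stop("planted sites overlap or touch; the forward site must end ",
            "strictly before the reverse site starts")
  for (fr in c(forward_fraction, reverse_fraction, mutation_rate))
    if (fr < 0 || fr > 1) po_stop("fractions and rates must be in [0, 1]")
  structure(list(n_seq = as.integer(n_seq), seq_length = as.integer(seq_length),
                 forward_primer = toupper(forward_primer),
                 forward_pos = as.integer(forward_pos),
                 reverse_primer = toupper(reverse_primer),
                 reverse_pos = as.integer(reverse_pos),
                 forward_fraction = forward_fraction,
                 reverse_fraction = reverse_fraction,
                 mutation_rate = mutation_rate, seed = as.integer(seed)),
            class = "synthetic_ref_spec")
}

mutate_site <- function(primer, rate) {
  chars <- strsplit(primer, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(chars)) < rate)
  for (k in hit) chars[k] <- sample(setdiff(c("A", "C", "G", "T"), chars[k]), 1L)
  list(seq = paste(chars, collapse = ""), mutated = hit)
}

#' Generate a synthetic reference set with ground truth
#'
#' @param spec A [synthetic_ref_spec()].
#' @return A list with elements `refset` (a [ref_set()]), `truth` (a data
#'   frame with one row per sequence: site presence, mutation counts inside
#'   and outside the 3' seed of each planted site, and `covered`, whether
#'   the planted pair is expected to cover the sequence under the
#'   seed-exact / at-most-2-mismatch rule) and `amplicon_length` (the
#'   planted product length).
#' @export
generate_synthetic_refset <- function(spec) {
  if (!inherits(spec, "synthetic_ref_spec"))
    po_stop("spec must be a synthetic_ref_spec")
  set.seed(spec$seed)
  bases <- c("A", "C", "G", "T")
  seed_len <- 5L
  m_f <- nchar(spec$forward_primer)
  m_r <- nchar(spec$reverse_primer)
  n <- spec$n_seq
  seqs <- character(n)
  truth <- data.frame(
    id = sprintf("synth%03d", seq_len(n)),
    forward_present = logical(n), reverse_present = logical(n),
    forward_mut_seed = integer(n), forward_mut_other = integer(n),
    reverse_mut_seed = integer(n), reverse_mut_other = integer(n)
  )
  for (i in seq_len(n)) {
    s <- sample(bases, spec$seq_length, replace = TRUE)
    if (runif(1L) < spec$forward_fraction) {
      truth$forward_present[i] <- TRUE
      site <- mutate_site(spec$forward_primer, spec$mutation_rate)
      truth$forward_mut_seed[i] <- sum(site$mutated > m_f - seed_len)
      truth$forward_mut_other[i] <- length(site$mutated) - truth$forward_mut_seed[i]
      s[spec$forward_pos:(spec$forward_pos + m_f - 1L)] <-
        strsplit(site$seq, "", fixed = TRUE)[[1L]]
    }
    if (runif(1L) < spec$reverse_fraction) {
      truth$reverse_present[i] <- TRUE
      site <- mutate_site(spec$reverse_primer, spec$mutation_rate)
      truth$reverse_mut_seed[i] <- sum(site$mutated > m_r - seed_len)
      truth$reverse_mut_other[i] <- length(site$mutated) - truth$reverse_mut_seed[i]
      s[spec$reverse_pos:(spec$reverse_pos + m_r - 1L)] <-
        strsplit(reverse_complement(site$seq), "", fixed = TRUE)[[1L]]
    }
    seqs[i] <- paste(s, collapse = "")
  }
  truth$covered <- truth$forward_present & truth$reverse_present &
    truth$forward_mut_seed == 0L & truth$forward_mut_other <= 2L &
    truth$reverse_mut_seed == 0L & truth$reverse_mut_other <= 2L
  list(refset = ref_set(seqs, truth$id), truth = truth,
       amplicon_length = spec$reverse_pos + m_r - 1L - spec$forward_pos + 1L)
}
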