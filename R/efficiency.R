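# Ten-term fuzzy efficiency score of a primer-set-pair: seven single-primer
# terms averaged across all primers plus three set-pair terms, total in
# [0, 10].

# Nearest-neighbour thermodynamic parameters. dh in kcal/mol, ds in
# cal/(mol K), dinucleotides read 5'->3' on the top strand. The unified
# parameter set includes terminal initiation terms per first/last base and a
# symmetry entropy correction for self-complementary oligos.
NN_TABLES <- list(
  santalucia1998 = list(
    dh = c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0, TT = -7.9, TG = -8.5,
           AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0),
    ds = c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9),
    init_dh = c(A = 2.3, T = 2.3, G = 0.1, C = 0.1),
    init_ds = c(A = 4.1, T = 4.1, G = -2.8, C = -2.8),
    sym_ds = -1.4
  )
)

GAS_CONSTANT <- 1.987  # cal / (mol K)

#' Melting temperature of a primer (nearest-neighbour model)
#'
#' Duplex melting temperature from nearest-neighbour enthalpy/entropy sums
#' with terminal initiation terms, an entropic monovalent-salt correction of
#' 0.368 (n - 1) ln\[Na+\] and the two-state formula
#' Tm = dH / (dS + R ln x) with x = CT/4 (CT/2 with a symmetry correction for
#' self-complementary oligos). Defaults: unified parameters, 50 mM Na+,
#' 500 nM total oligonucleotide.
#'
#' @param p Non-degenerate primer, at least 2 nt.
#' @param config A [po_config()] (fields `nn_table`, `na_conc`, `oligo_conc`).
#' @return Temperature in degrees Celsius.
#' @export
melting_temperature <- function(p, config = po_config()) {
  config <- as_po_config(config)
  p <- toupper(p)
  chars <- check_primer(p, min_len = 2L)
  n <- length(chars)
  tab <- NN_TABLES[[config$nn_table]]
  nn <- paste0(chars[-n], chars[-1L])
  dh <- sum(tab$dh[nn]) + tab$init_dh[[chars[1L]]] + tab$init_dh[[chars[n]]]
  ds <- sum(tab$ds[nn]) + tab$init_ds[[chars[1L]]] + tab$init_ds[[chars[n]]]
  selfcomp <- identical(p, reverse_complement(p))
  x <- if (selfcomp) config$oligo_conc / 2 else config$oligo_conc / 4
  if (selfcomp) ds <- ds + tab$sym_ds
  ds <- ds + 0.368 * (n - 1L) * log(config$na_conc)
  1000 * dh / (ds + GAS_CONSTANT * log(x)) - 273.15
}

#' Fuzzy efficiency terms
#'
#' Each term maps a primer property onto \[0, 1\]: 1 when the constraint is
#' met with margin, 0 when clearly violated, linear in between. Thresholds
#' come from [po_config()]; the defaults are the standard primer-design
#' rules (Tm at least 52 C, GC fraction 0.5-0.7, no AT-only or GC-heavy
#' 3' ends, homopolymers at most 4 nt, dimer matches at most 8, no 3'-end
#' hairpin, Tm range at most 3 C, amplicon-length spread at most 50 nt).
#'
#' @param tm Melting temperature (degrees C).
#' @param p A non-degenerate primer string.
#' @param pairs A [primer_set_pair()].
#' @param lengths Numeric vector of amplicon lengths (nt) across all
#'   forward x reverse combinations and reference sequences.
#' @param config A [po_config()].
#' @return A score in \[0, 1\].
#' @name efficiency_terms
NULL

#' @rdname efficiency_terms
#' @export
score_tm <- function(tm, config = po_config()) {
  config <- as_po_config(config)
  fuzzy_ramp(tm, config$tm_zero, config$tm_one)
}

#' @rdname efficiency_terms
#' @export
score_gc <- function(p, config = po_config()) {
  config <- as_po_config(config)
  chars <- check_primer(toupper(p))
  f <- mean(chars %in% c("G", "C"))
  if (f > config$gc_plateau_hi) return(0)
  if (f >= config$gc_plateau_lo) return(1)
  fuzzy_ramp(f, config$gc_ramp_zero, config$gc_plateau_lo)
}

#' @rdname efficiency_terms
#' @export
score_end3_at <- function(p) {
  chars <- check_primer(toupper(p), min_len = 3L)
  last3 <- chars[(length(chars) - 2L):length(chars)]
  if (all(last3 %in% c("A", "T"))) 0 else 1
}

#' @rdname efficiency_terms
#' @export
score_end3_gc <- function(p) {
  chars <- check_primer(toupper(p), min_len = 5L)
  last5 <- chars[(length(chars) - 4L):length(chars)]
  if (sum(last5 %in% c("G", "C")) > 3L) 0 else 1
}

#' @rdname efficiency_terms
#' @export
score_homopolymer <- function(p, config = po_config()) {
  config <- as_po_config(config)
  run <- max(rle(check_primer(toupper(p)))$lengths)
  if (run >= config$homopolymer_zero) return(0)
  if (run >= config$homopolymer_half) return(0.5)
  1
}

#' @rdname efficiency_terms
#' @export
score_self_dimer <- function(p, config = po_config()) {
  config <- as_po_config(config)
  p <- toupper(p)
  m <- max_gapfree_matches(p, reverse_complement(p))
  fuzzy_ramp(m, config$self_dimer_zero, config$self_dimer_one)
}

#' @rdname efficiency_terms
#' @export
score_hairpin <- function(p, config = po_config()) {
  config <- as_po_config(config)
  p <- toupper(p)
  chars <- check_primer(p)
  if (length(chars) < 2L * config$hairpin_seed)
    po_stop("primer shorter than twice the hairpin seed length")
  if (cpp_hairpin_hit(p, config$hairpin_seed, config$hairpin_min_match)) 0 else 1
}

#' @rdname efficiency_terms
#' @export
score_tm_range <- function(pairs, config = po_config()) {
  config <- as_po_config(config)
  tms <- vapply(all_primers(pairs), melting_temperature, 0, config = config)
  fuzzy_ramp(max(tms) - min(tms), config$tm_range_zero, config$tm_range_one)
}

#' @rdname efficiency_terms
#' @export
score_cross_dimer <- function(pairs, config = po_config()) {
  config <- as_po_config(config)
  m <- 0L
  for (f in pairs$forward) {
    for (r in pairs$reverse) {
      m <- max(m, max_gapfree_matches(f, reverse_complement(r)))
    }
  }
  fuzzy_ramp(m, config$cross_dimer_zero, config$cross_dimer_one)
}

# Nearest-rank order statistics: the q-th percentile is the ceil(q n)-th
# order statistic; the median of an even-sized sample is the mean of the two
# central order statistics.
nearest_rank_percentile <- function(x, q) {
  x <- sort(x)
  x[max(1L, ceiling(q * length(x)))]
}

nearest_rank_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2L == 1L) x[(n + 1L) %/% 2L] else (x[n %/% 2L] + x[n %/% 2L + 1L]) / 2
}

#' @rdname efficiency_terms
#' @export
score_amplicon_range <- function(lengths, config = po_config()) {
  config <- as_po_config(config)
  if (length(lengths) == 0L) po_stop("no amplicon lengths supplied")
  delta <- nearest_rank_median(lengths) - nearest_rank_percentile(lengths, 0.01)
  fuzzy_ramp(delta, config$amplicon_range_zero, config$amplicon_range_one)
}

SINGLE_TERMS <- c("tm", "gc", "end3_at", "end3_gc", "homopolymer",
                  "self_dimer", "hairpin")
PAIR_TERMS <- c("tm_range", "cross_dimer", "amplicon_range")

# The 7 single-primer fuzzy terms of one primer, plus its Tm (needed for the
# set-pair Tm-range term). Hot path of the local search; cached per primer in
# the reference index.
single_primer_terms <- function(p, config) {
  tm <- melting_temperature(p, config)
  c(tm = score_tm(tm, config),
    gc = score_gc(p, config),
    end3_at = score_end3_at(p),
    end3_gc = score_end3_gc(p),
    homopolymer = score_homopolymer(p, config),
    self_dimer = score_self_dimer(p, config),
    hairpin = score_hairpin(p, config),
    tm_value = tm)
}

#' Efficiency score of a primer-set-pair
#'
#' The seven single-primer terms are arithmetic means over all primers in
#' the forward and reverse sets; the melting-temperature range, cross-dimer
#' and amplicon-length-range terms are computed on the set-pair as a whole.
#' The total is the sum of the ten terms and ranges from 0 (minimal
#' efficiency) to 10 (maximal efficiency). The amplicon-length term needs
#' the amplicon length distribution on a reference set; a set-pair that
#' produces no amplicon at all scores 0 on that term.
#'
#' @param pairs A [primer_set_pair()].
#' @param refset A reference set (see [read_fasta()]) or reference index;
#'   may be `NULL` when `profile` is given.
#' @param config A [po_config()].
#' @param profile Optional precomputed [build_profile()] result for `pairs`
#'   on `refset`, to avoid recomputation.
#' @return An `efficiency_breakdown`: named numeric vector of the ten terms
#'   with attribute `total` (also the sum of the vector).
#' @export
efficiency_score <- function(pairs, refset = NULL, config = po_config(),
                             profile = NULL) {
  config <- as_po_config(config)
  index <- if (!is.null(refset)) ensure_index(refset, config) else NULL
  if (is.null(profile)) {
    if (is.null(index))
      po_stop("either a reference set or a match profile is required")
    profile <- build_profile(pairs, index, config)
  }
  efficiency_from_parts(pairs, profile, config, index)
}

# Internal: efficiency with optional per-primer term caching via the index.
efficiency_from_parts <- function(pairs, profile, config, index = NULL) {
  primers <- all_primers(pairs)
  terms <- vapply(primers, function(p) {
    if (!is.null(index)) index_terms(index, p) else single_primer_terms(p, config)
  }, numeric(8L))
  singles <- rowMeans(terms[SINGLE_TERMS, , drop = FALSE])
  tms <- terms["tm_value", ]
  tm_range <- fuzzy_ramp(max(tms) - min(tms),
                         config$tm_range_zero, config$tm_range_one)
  cross <- score_cross_dimer(pairs, config)
  lens <- profile$lengths[!is.na(profile$lengths)]
  amp <- if (length(lens)) score_amplicon_range(lens, config) else 0
  out <- c(singles,
           tm_range = unname(tm_range), cross_dimer = unname(cross),
           amplicon_range = unname(amp))
  structure(out, total = sum(out), class = "efficiency_breakdown")
}

#' @export
print.efficiency_breakdown <- function(x, digits = 3, ...) {
  cat("efficiency breakdown (0-1 per term):\n")
  print(round(unclass(x), digits))
  cat("total:", round(attr(x, "total"), digits), "of 10\n")
  invisible(x)
}
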