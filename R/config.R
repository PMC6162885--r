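# Scoring configuration: every fuzzy threshold, ramp endpoint, matching rule
# and thermodynamic condition, as one flat key/value object so that a flat
# YAML config file (and CLI overrides) can mirror it one-to-one.

#' Scoring configuration
#'
#' All tunable thresholds of the three objective scores. Each fuzzy term is a
#' linear ramp clamped to \[0, 1\] between a `*_zero` endpoint (score 0) and a
#' `*_one` endpoint (score 1); between the endpoints the score interpolates
#' linearly, so the direction of the ramp is implied by their ordering.
#'
#' @param tm_zero,tm_one Melting-temperature ramp (degrees C): score 0 at or
#'   below `tm_zero`, 1 at or above `tm_one`.
#' @param gc_ramp_zero,gc_plateau_lo,gc_plateau_hi GC-content fraction: score
#'   1 on `[gc_plateau_lo, gc_plateau_hi]`, 0 below `gc_ramp_zero` or above
#'   `gc_plateau_hi`, linear in between on the low side.
#' @param self_dimer_zero,self_dimer_one Gap-free match counts for the
#'   self-dimer screen: 1 at or below `self_dimer_one` matches, 0 at or above
#'   `self_dimer_zero`.
#' @param cross_dimer_zero,cross_dimer_one Same ramp for forward x reverse
#'   dimers.
#' @param hairpin_seed Length (nt) of the 3'-terminal fragment folded back in
#'   the hairpin screen.
#' @param hairpin_min_match Minimum number of the `hairpin_seed - 1` bases
#'   preceding the terminal base that must pair for a hairpin call.
#' @param homopolymer_half,homopolymer_zero Homopolymer run lengths (nt)
#'   scoring 0.5 and 0.
#' @param tm_range_zero,tm_range_one Melting-temperature range ramp
#'   (degrees C) across all primers of a set-pair.
#' @param amplicon_range_zero,amplicon_range_one Ramp (nt) on the difference
#'   between the median and the first percentile of amplicon lengths.
#' @param seed_len Length (nt) of the 3' seed that must match the template
#'   exactly.
#' @param max_mismatches Mismatches tolerated outside the seed.
#' @param length_tolerance Half-width (nt) of the window around the target
#'   amplicon length within which a sequence counts as covered.
#' @param bias_sentinel Matching-bias value reported when no sequence is
#'   covered, so that such solutions are dominated.
#' @param nn_table Nearest-neighbour parameter table for the melting
#'   temperature; currently `"santalucia1998"` (unified parameters).
#' @param na_conc Monovalent cation concentration (mol/L).
#' @param oligo_conc Total oligonucleotide concentration (mol/L).
#' @return An object of class `po_config` (named list).
#' @export
po_config <- function(tm_zero = 50, tm_one = 52,
                      gc_ramp_zero = 0.4, gc_plateau_lo = 0.5,
                      gc_plateau_hi = 0.7,
                      self_dimer_zero = 11, self_dimer_one = 8,
                      cross_dimer_zero = 11, cross_dimer_one = 8,
                      hairpin_seed = 5, hairpin_min_match = 3,
                      homopolymer_half = 5, homopolymer_zero = 6,
                      tm_range_zero = 5, tm_range_one = 3,
                      amplicon_range_zero = 100, amplicon_range_one = 50,
                      seed_len = 5, max_mismatches = 2,
                      length_tolerance = 100, bias_sentinel = 1e6,
                      nn_table = "santalucia1998",
                      na_conc = 0.05, oligo_conc = 5e-7) {
  cfg <- list(
    tm_zero = tm_zero, tm_one = tm_one,
    gc_ramp_zero = gc_ramp_zero, gc_plateau_lo = gc_plateau_lo,
    gc_plateau_hi = gc_plateau_hi,
    self_dimer_zero = self_dimer_zero, self_dimer_one = self_dimer_one,
    cross_dimer_zero = cross_dimer_zero, cross_dimer_one = cross_dimer_one,
    hairpin_seed = hairpin_seed, hairpin_min_match = hairpin_min_match,
    homopolymer_half = homopolymer_half, homopolymer_zero = homopolymer_zero,
    tm_range_zero = tm_range_zero, tm_range_one = tm_range_one,
    amplicon_range_zero = amplicon_range_zero,
    amplicon_range_one = amplicon_range_one,
    seed_len = seed_len, max_mismatches = max_mismatches,
    length_tolerance = length_tolerance, bias_sentinel = bias_sentinel,
    nn_table = nn_table, na_conc = na_conc, oligo_conc = oligo_conc
  )
  ramps <- list(c("tm_zero", "tm_one"), c("self_dimer_zero", "self_dimer_one"),
                c("cross_dimer_zero", "cross_dimer_one"),
                c("tm_range_zero", "tm_range_one"),
                c("amplicon_range_zero", "amplicon_range_one"),
                c("gc_ramp_zero", "gc_plateau_lo"))
  for (r in ramps)
    if (cfg[[r[1L]]] == cfg[[r[2L]]])
      po_stop("degenerate ramp: ", r[1L], " equals ", r[2L])
  if (na_conc <= 0 || oligo_conc <= 0)
    po_stop("concentrations must be positive")
  if (seed_len < 1 || max_mismatches < 0 || length_tolerance < 0)
    po_stop("matching thresholds must be positive")
  if (!nn_table %in% names(NN_TABLES))
    po_stop("unknown nearest-neighbour table '", nn_table, "'")
  structure(cfg, class = "po_config")
}

as_po_config <- function(cfg) {
  if (is.null(cfg)) return(po_config())
  if (inherits(cfg, "po_config")) return(cfg)
  if (is.list(cfg)) return(do.call(po_config, cfg))
  po_stop("config must be a po_config object or a named list")
}

# Clamped linear ramp between zero_at (score 0) and one_at (score 1);
# direction implied by the ordering of the two endpoints.
fuzzy_ramp <- function(x, zero_at, one_at) {
  v <- (x - zero_at) / (one_at - zero_at)
  pmin(1, pmax(0, v))
}

#' Read a flat YAML scoring configuration
#'
#' The file holds flat `key: value` pairs whose names are exactly the
#' arguments of [po_config()]; unknown keys are an error (they are almost
#' always typos), missing keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `po_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) po_stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(po_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    po_stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(po_config, vals)
}

#' Search configuration
#'
#' Parameters of candidate selection and of the multi-objective local search.
#'
#' @param amplicon_min,amplicon_max Desired amplicon length range (nt) used
#'   when filtering initial candidate pairs.
#' @param init_len_min,init_len_max Primer length bounds (nt) applied to
#'   every expanded primer of an initial candidate pair.
#' @param move_len_min,move_len_max Primer length bounds (nt) for local
#'   search moves; base additions/removals never leave this interval.
#' @param restarts Number of restarts of each search run.
#' @param runs Number of independent runs (sequential, with derived seeds);
#'   archives are merged before the final front.
#' @param seed Integer random seed governing every stochastic choice.
#' @return An object of class `po_search_config`.
#' @export
search_config <- function(amplicon_min = 700, amplicon_max = 800,
                          init_len_min = 17, init_len_max = 21,
                          move_len_min = 15, move_len_max = 25,
                          restarts = 20, runs = 1, seed = 1) {
  if (amplicon_min >= amplicon_max) po_stop("amplicon_min must be < amplicon_max")
  if (move_len_min < 6) po_stop("move_len_min must be at least 6 (seed + 1)")
  if (move_len_min > move_len_max || init_len_min > init_len_max)
    po_stop("length bounds must be ordered")
  if (restarts < 0 || runs < 1) po_stop("restarts must be >= 0 and runs >= 1")
  structure(list(amplicon_min = amplicon_min, amplicon_max = amplicon_max,
                 init_len_min = init_len_min, init_len_max = init_len_max,
                 move_len_min = move_len_min, move_len_max = move_len_max,
                 restarts = restarts, runs = runs, seed = as.integer(seed)),
            class = "po_search_config")
}

as_search_config <- function(x) {
  if (is.null(x)) return(search_config())
  if (inherits(x, "po_search_config")) return(x)
  if (is.list(x)) return(do.call(search_config, x))
  po_stop("search config must be a po_search_config object or a named list")
}
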