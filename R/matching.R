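# Seed-anchored primer matching against a reference set; amplicon lengths,
# coverage and matching-bias.

#' Construct a reference set
#'
#' An ordered collection of 16S (or any) reference sequences on the sense
#' strand. Sequences may contain IUPAC ambiguity codes; at match time any
#' non-ACGT reference letter counts as a mismatch.
#'
#' @param sequences Character vector of IUPAC nucleotide strings, 5'->3'.
#' @param ids Unique sequence identifiers (defaults to names of `sequences`).
#' @return An object of class `ref_set` with elements `ids` and `sequences`.
#' @export
ref_set <- function(sequences, ids = names(sequences)) {
  if (length(sequences) == 0L) po_stop("reference set is empty")
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  if (length(ids) != length(sequences)) po_stop("ids and sequences differ in length")
  if (anyDuplicated(ids)) po_stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  sequences <- toupper(unname(sequences))
  for (i in seq_along(sequences)) check_iupac(sequences[i], paste0("sequence '", ids[i], "'"))
  structure(list(ids = as.character(ids), sequences = sequences), class = "ref_set")
}

#' @export
print.ref_set <- function(x, ...) {
  cat("reference set:", length(x$ids), "sequences, lengths",
      min(nchar(x$sequences)), "-", max(nchar(x$sequences)), "nt\n")
  invisible(x)
}

#' Build a reference index
#'
#' Precomputes reverse complements and caches per-primer match sites and
#' per-primer efficiency terms, so that repeated scoring during local search
#' only pays for the primer that changed. The index is bound to the scoring
#' configuration it was built with; passing a different configuration to a
#' scoring function triggers a fresh index.
#'
#' @param refset A [ref_set()].
#' @param config A [po_config()].
#' @return An object of class `ref_index`.
#' @export
ref_index <- function(refset, config = po_config()) {
  if (inherits(refset, "ref_index")) refset <- refset$refset
  if (!inherits(refset, "ref_set")) po_stop("refset must be a ref_set")
  config <- as_po_config(config)
  idx <- new.env(parent = emptyenv())
  idx$refset <- refset
  idx$ids <- refset$ids
  idx$seqs <- refset$sequences
  idx$rc <- vapply(refset$sequences, reverse_complement, "", USE.NAMES = FALSE)
  idx$lens <- nchar(refset$sequences)
  idx$n <- length(refset$ids)
  idx$config <- config
  idx$sites <- new.env(parent = emptyenv())
  idx$terms <- new.env(parent = emptyenv())
  class(idx) <- "ref_index"
  idx
}

#' @export
print.ref_index <- function(x, ...) {
  cat("reference index over", x$n, "sequences;",
      length(ls(x$sites)), "cached primer site lists\n")
  invisible(x)
}

ensure_index <- function(refset, config) {
  if (inherits(refset, "ref_index")) {
    if (identical(unclass(refset$config), unclass(as_po_config(config))))
      return(refset)
    return(ref_index(refset$refset, config))
  }
  ref_index(refset, config)
}

# Sense-strand start positions of match sites for one primer over all
# sequences of the index, cached per (orientation, primer).
index_sites <- function(index, primer, orientation) {
  key <- paste0(orientation, ":", primer)
  hit <- index$sites[[key]]
  if (!is.null(hit)) return(hit)
  cfg <- index$config
  m <- nchar(primer)
  if (orientation == "forward") {
    batch <- cpp_find_sites_batch(primer, index$seqs, cfg$seed_len, cfg$max_mismatches)
    starts <- lapply(batch, function(s) s[, 1L])
  } else {
    batch <- cpp_find_sites_batch(primer, index$rc, cfg$seed_len, cfg$max_mismatches)
    starts <- lapply(seq_along(batch), function(i) {
      j <- batch[[i]][, 1L]
      sort(index$lens[i] - j - m + 2L)
    })
  }
  index$sites[[key]] <- starts
  starts
}

index_terms <- function(index, primer) {
  hit <- index$terms[[primer]]
  if (!is.null(hit)) return(hit)
  v <- single_primer_terms(primer, index$config)
  index$terms[[primer]] <- v
  v
}

#' Find match sites of a primer on one reference sequence
#'
#' A window matches when the primer's 3'-terminal seed (default 5 nt) matches
#' the template exactly and the remaining 5' positions carry at most
#' `max_mismatches` (default 2) mismatches. In reverse orientation the primer
#' is matched against the reverse complement of the sequence and sites are
#' reported in sense-strand coordinates. Reference letters outside A/C/G/T
#' count as mismatches and break the seed.
#'
#' @param primer Non-degenerate primer, at least `seed_len + 1` nt.
#' @param sequence A single reference sequence (IUPAC string).
#' @param orientation `"forward"` (sense-strand binding) or `"reverse"`.
#' @param config A [po_config()].
#' @return A data frame with columns `start`, `end` (1-based, inclusive,
#'   sense strand), `strand` and `mismatches`, one row per site.
#' @export
find_matches <- function(primer, sequence,
                         orientation = c("forward", "reverse"),
                         config = po_config()) {
  orientation <- match.arg(orientation)
  config <- as_po_config(config)
  primer <- toupper(primer)
  check_primer(primer, min_len = config$seed_len + 1L)
  sequence <- toupper(sequence)
  check_iupac(sequence)
  m <- nchar(primer)
  L <- nchar(sequence)
  if (orientation == "forward") {
    sites <- cpp_find_sites(primer, sequence, config$seed_len, config$max_mismatches)
    start <- sites[, 1L]
  } else {
    sites <- cpp_find_sites(primer, reverse_complement(sequence),
                            config$seed_len, config$max_mismatches)
    start <- L - sites[, 1L] - m + 2L
  }
  ord <- order(start)
  data.frame(start = start[ord], end = start[ord] + m - 1L,
             strand = rep(if (orientation == "forward") "forward-binding"
                          else "reverse-binding", length(start)),
             mismatches = sites[ord, 2L])
}

#' Amplicon length for one forward/reverse primer combination
#'
#' Over all pairings of a forward-binding site of `f` with a reverse-binding
#' site of `r` starting strictly downstream of the forward site's end, the
#' amplicon spans both primer footprints (forward start through reverse
#' end). The shortest such product is returned, since PCR kinetics favour
#' the shortest template; `NA` when no valid pairing exists.
#'
#' @param f,r Forward and reverse primers.
#' @param sequence A single reference sequence.
#' @param config A [po_config()].
#' @return Amplicon length in nt, or `NA`.
#' @export
amplicon_for_combination <- function(f, r, sequence, config = po_config()) {
  config <- as_po_config(config)
  fs <- find_matches(f, sequence, "forward", config)
  rs <- find_matches(r, sequence, "reverse", config)
  cpp_shortest_amplicons(list(fs$start), nchar(f), list(rs$start), nchar(r))[1L]
}

#' Match profile of a primer-set-pair on a reference set
#'
#' Computes the shortest amplicon for every (forward primer, reverse primer,
#' sequence) triple, the target amplicon length (nearest-rank median of all
#' amplicon lengths), and the per-sequence combination count: the number of
#' forward x reverse combinations whose amplicon lies within
#' `length_tolerance` (default 100 nt) of the target.
#'
#' @param pairs A [primer_set_pair()].
#' @param refset A [ref_set()] or [ref_index()].
#' @param config A [po_config()].
#' @return An object of class `match_profile` with elements `lengths`
#'   (matrix, one row per combination, one column per sequence, `NA` =
#'   no amplicon), `target_length`, `counts` (named integer vector) and
#'   `n_amplicons`.
#' @export
build_profile <- function(pairs, refset, config = po_config()) {
  config <- as_po_config(config)
  index <- ensure_index(refset, config)
  nf <- length(pairs$forward); nr <- length(pairs$reverse)
  L <- matrix(NA_real_, nrow = nf * nr, ncol = index$n,
              dimnames = list(NULL, index$ids))
  combos <- character(nf * nr)
  k <- 0L
  for (f in pairs$forward) {
    fsites <- index_sites(index, f, "forward")
    flen <- nchar(f)
    for (r in pairs$reverse) {
      rsites <- index_sites(index, r, "reverse")
      k <- k + 1L
      L[k, ] <- cpp_shortest_amplicons(fsites, flen, rsites, nchar(r))
      combos[k] <- paste(f, r, sep = "|")
    }
  }
  rownames(L) <- combos
  lens <- L[!is.na(L)]
  target <- if (length(lens)) nearest_rank_median(lens) else NA_real_
  counts <- if (length(lens)) {
    colSums(!is.na(L) & abs(L - target) <= config$length_tolerance)
  } else {
    stats::setNames(rep(0L, index$n), index$ids)
  }
  structure(list(lengths = L, target_length = target,
                 counts = as.integer(counts),
                 ids = index$ids, n_amplicons = length(lens)),
            class = "match_profile")
}

#' @export
print.match_profile <- function(x, ...) {
  cat("match profile:", nrow(x$lengths), "combinations x",
      ncol(x$lengths), "sequences;", x$n_amplicons, "amplicons, target length",
      x$target_length, "nt\n")
  invisible(x)
}

#' Coverage of a reference set by a primer-set-pair
#'
#' A sequence is covered when at least one forward and one reverse primer
#' match it with an amplicon within the length tolerance of the target
#' length, i.e. when its combination count is at least 1.
#'
#' @param profile A [build_profile()] result.
#' @return List with `count` (covered sequences) and `fraction`.
#' @export
coverage <- function(profile) {
  covered <- sum(profile$counts >= 1L)
  list(count = covered, fraction = covered / length(profile$counts))
}

#' Matching-bias of a primer-set-pair
#'
#' The coefficient of variation (population standard deviation over mean) of
#' the number of forward x reverse combinations matching each covered
#' sequence. Uncovered sequences are already penalized by coverage and do
#' not enter the statistic. When no sequence is covered the configured
#' sentinel is returned so that such solutions are dominated.
#'
#' @param profile A [build_profile()] result.
#' @param config A [po_config()].
#' @return Non-negative coefficient of variation.
#' @export
matching_bias <- function(profile, config = po_config()) {
  config <- as_po_config(config)
  x <- profile$counts[profile$counts >= 1L]
  if (length(x) == 0L) return(config$bias_sentinel)
  mu <- mean(x)
  sqrt(mean((x - mu)^2)) / mu
}

#' Objective score vector of a primer-set-pair
#'
#' Evaluates the three competing objectives on a reference set: efficiency E
#' (0-10, maximized), coverage C (fraction, maximized) and matching-bias M
#' (coefficient of variation, minimized).
#'
#' @param pairs A [primer_set_pair()].
#' @param refset A [ref_set()] or [ref_index()].
#' @param config A [po_config()].
#' @return A list of class `score_vector` with elements `E`, `C`, `C_count`,
#'   `M` and `breakdown` (the efficiency term breakdown).
#' @export
score_vector <- function(pairs, refset, config = po_config()) {
  config <- as_po_config(config)
  index <- ensure_index(refset, config)
  profile <- build_profile(pairs, index, config)
  eff <- efficiency_from_parts(pairs, profile, config, index)
  cov <- coverage(profile)
  structure(list(E = attr(eff, "total"), C = cov$fraction,
                 C_count = cov$count, M = matching_bias(profile, config),
                 breakdown = eff),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, digits = 4, ...) {
  cat(sprintf("E = %.*f, C = %.*f (%d seqs), M = %.*f\n",
              digits, x$E, digits, x$C, x$C_count, digits, x$M))
  invisible(x)
}
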