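# Pareto dominance, front maintenance, scalarization, best-improvement local
# search and the restart-driven multi-objective search.

score_triple <- function(x) {
  if (inherits(x, "score_vector") || (is.list(x) && all(c("E", "C", "M") %in% names(x))))
    return(c(E = x$E, C = x$C, M = x$M))
  if (is.numeric(x) && length(x) == 3L) {
    if (is.null(names(x))) names(x) <- c("E", "C", "M")
    return(x[c("E", "C", "M")])
  }
  po_stop("expected a score vector (E, C, M)", class = "po_internal_error")
}

#' Pareto dominance of objective vectors
#'
#' `a` dominates `b` when the two vectors differ, efficiency and coverage of
#' `a` are at least those of `b`, and matching-bias of `a` is at most that of
#' `b` (E and C are maximized, M minimized). Identical vectors do not
#' dominate each other; the relation is a strict partial order.
#'
#' @param a,b Score vectors: [score_vector()] results, lists with `E`, `C`,
#'   `M`, or numeric length-3 vectors (E, C, M).
#' @return Logical.
#' @export
dominates <- function(a, b) {
  a <- score_triple(a); b <- score_triple(b)
  if (all(a == b)) return(FALSE)
  a["E"] >= b["E"] && a["C"] >= b["C"] && a["M"] <= b["M"]
}

archive_entry <- function(pair, sv, provenance, restart = NA_integer_,
                          run = NA_integer_, id = NA_character_) {
  list(pair = pair, E = sv$E, C = sv$C, C_count = sv$C_count, M = sv$M,
       provenance = provenance, restart = restart, run = run, id = id)
}

new_archive <- function(entries = list()) {
  structure(entries, class = "primer_archive")
}

#' @export
print.primer_archive <- function(x, ...) {
  cat("archive of", length(x), "primer-set-pairs\n")
  invisible(x)
}

#' Convert an archive to a data frame
#'
#' One row per entry: comma-joined primer sets (sorted within each set),
#' objective scores and provenance.
#'
#' @param x A `primer_archive` (e.g. from [multi_objective_search()]).
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.primer_archive <- function(x, ...) {
  if (length(x) == 0L)
    return(data.frame(forward = character(), reverse = character(),
                      E = numeric(), C_fraction = numeric(),
                      C_count = integer(), M = numeric(),
                      provenance = character(), restart = integer()))
  data.frame(
    forward = vapply(x, function(e) paste(sort(e$pair$forward), collapse = ","), ""),
    reverse = vapply(x, function(e) paste(sort(e$pair$reverse), collapse = ","), ""),
    E = vapply(x, function(e) e$E, 0),
    C_fraction = vapply(x, function(e) e$C, 0),
    C_count = vapply(x, function(e) as.integer(e$C_count), 0L),
    M = vapply(x, function(e) e$M, 0),
    provenance = vapply(x, function(e) e$provenance, ""),
    restart = vapply(x, function(e) as.integer(e$restart), 0L)
  )
}

#' Pareto front of an archive
#'
#' Entries not dominated by any other entry; among entries with identical
#' score vectors only the first occurrence is retained.
#'
#' @param archive A `primer_archive` (non-empty).
#' @return A `primer_archive` holding the front.
#' @export
pareto_front <- function(archive) {
  if (length(archive) == 0L) po_stop("archive is empty")
  E <- vapply(archive, function(e) e$E, 0)
  C <- vapply(archive, function(e) e$C, 0)
  M <- vapply(archive, function(e) e$M, 0)
  ge_E <- outer(E, E, ">="); ge_C <- outer(C, C, ">="); le_M <- outer(M, M, "<=")
  eq <- outer(E, E, "==") & outer(C, C, "==") & outer(M, M, "==")
  dom <- ge_E & ge_C & le_M & !eq  # dom[i, j]: i dominates j
  nondom <- colSums(dom) == 0L
  keep <- nondom & !duplicated(paste(E, C, M))
  new_archive(archive[keep])
}

#' Sample scalarization weights from the unit simplex
#'
#' Weights for (E, C, M) drawn uniformly at random from the 2-simplex via
#' the exponential-spacings construction; deterministic under a set seed.
#'
#' @return Named numeric vector (`E`, `C`, `M`), non-negative, summing to 1.
#' @export
sample_weights <- function() {
  w <- -log(runif(3L))
  stats::setNames(w / sum(w), c("E", "C", "M"))
}

# Scalarized score of an already-evaluated solution: objectives normalized
# to [0, 1] (E/10, C as a fraction, matching-bias remapped to
# max(0, 1 - M) so it is maximized like the others).
scalarize <- function(sv, alpha) {
  unname(alpha[["E"]] * sv$E / 10 + alpha[["C"]] * sv$C +
         alpha[["M"]] * max(0, 1 - sv$M))
}

#' Scalarized (weighted) score of a primer-set-pair
#'
#' Linear combination of the normalized objectives with weights `alpha`:
#' `alpha_E * E/10 + alpha_C * C + alpha_M * max(0, 1 - M)`.
#'
#' @param pairs A [primer_set_pair()].
#' @param alpha Weights from [sample_weights()] (or any non-negative triple
#'   summing to 1, named E/C/M).
#' @param refset A [ref_set()] or [ref_index()].
#' @param config A [po_config()].
#' @return Scalar in \[0, 1\].
#' @export
weighted_score <- function(pairs, alpha, refset, config = po_config()) {
  alpha <- check_weights(alpha)
  scalarize(score_vector(pairs, refset, config), alpha)
}

check_weights <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 3L)
    po_stop("alpha must be three weights")
  if (is.null(names(alpha))) names(alpha) <- c("E", "C", "M")
  if (any(alpha < 0) || abs(sum(alpha) - 1) > 1e-12)
    po_stop("weights must be non-negative and sum to 1")
  alpha[c("E", "C", "M")]
}

#' Single-edit neighbourhood of one primer
#'
#' All set-pairs obtained by replacing the addressed primer with every
#' single-base substitution (3 per position), every single-base addition at
#' either extremity (4 bases x 2 ends) and the removal of the first or last
#' base, subject to the move length bounds. Neighbours whose edited primer
#' duplicates a primer already in the same set are excluded. Enumeration
#' order (positions ascending, bases A/C/G/T, substitutions before additions
#' before removals) fixes the tie-break of the local search.
#'
#' @param pairs A [primer_set_pair()].
#' @param i Index of the primer in `c(forward, reverse)`.
#' @param search A [search_config()] (fields `move_len_min`, `move_len_max`).
#' @return List of `primer_set_pair` objects.
#' @export
neighborhood <- function(pairs, i, search = search_config()) {
  search <- as_search_config(search)
  nf <- length(pairs$forward)
  n_tot <- nf + length(pairs$reverse)
  if (!is.numeric(i) || length(i) != 1L || i < 1L || i > n_tot)
    po_stop("primer index out of range")
  side <- if (i <= nf) "forward" else "reverse"
  j <- if (i <= nf) i else i - nf
  p <- pairs[[side]][j]
  chars <- strsplit(p, "", fixed = TRUE)[[1L]]
  m <- length(chars)
  bases <- c("A", "C", "G", "T")
  variants <- character(0L)
  for (pos in seq_len(m)) {
    for (b in bases[bases != chars[pos]]) {
      v <- chars; v[pos] <- b
      variants <- c(variants, paste(v, collapse = ""))
    }
  }
  if (m + 1L <= search$move_len_max)
    variants <- c(variants, paste0(bases, p), paste0(p, bases))
  if (m - 1L >= search$move_len_min)
    variants <- c(variants, substr(p, 2L, m), substr(p, 1L, m - 1L))
  out <- list()
  for (v in variants) {
    set <- pairs[[side]]
    if (v %in% set[-j]) next
    set[j] <- v
    out[[length(out) + 1L]] <- if (side == "forward")
      primer_set_pair(set, pairs$reverse) else primer_set_pair(pairs$forward, set)
  }
  out
}

#' Best-improvement local search of a scalarization
#'
#' Cycles over the primers of the set-pair; for each primer the full
#' single-edit neighbourhood is evaluated and the search moves to the best
#' strictly-improving neighbour, repeatedly, until that primer admits no
#' improving edit; the cycle restarts until a full pass over all primers is
#' quiescent. The returned set-pair is a verified local optimum of the
#' scalarized objective and its weighted score never falls below the
#' start's.
#'
#' @param start A [primer_set_pair()].
#' @param alpha Scalarization weights (see [sample_weights()]).
#' @param refset A [ref_set()] or [ref_index()].
#' @param config A [po_config()].
#' @param search A [search_config()].
#' @return The locally optimal `primer_set_pair`, with attributes
#'   `score_vector` and `weighted_score`.
#' @export
local_search <- function(start, alpha, refset, config = po_config(),
                         search = search_config()) {
  alpha <- check_weights(alpha)
  config <- as_po_config(config)
  search <- as_search_config(search)
  index <- ensure_index(refset, config)
  curr <- start
  curr_sv <- score_vector(curr, index, config)
  curr_score <- scalarize(curr_sv, alpha)
  n_primers <- length(all_primers(curr))
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(n_primers)) {
      repeat {
        nbrs <- neighborhood(curr, i, search)
        if (length(nbrs) == 0L) break
        best_k <- 0L; best_score <- curr_score; best_sv <- NULL
        for (k in seq_along(nbrs)) {
          sv <- score_vector(nbrs[[k]], index, config)
          s <- scalarize(sv, alpha)
          if (s > best_score) { best_k <- k; best_score <- s; best_sv <- sv }
        }
        if (best_k == 0L) break
        curr <- nbrs[[best_k]]
        curr_sv <- best_sv
        curr_score <- best_score
        improved <- TRUE
      }
    }
  }
  attr(curr, "score_vector") <- curr_sv
  attr(curr, "weighted_score") <- curr_score
  curr
}

#' Select and score initial candidate primer pairs
#'
#' Filters a candidate list of (possibly degenerate) primer pairs the way
#' published 16S primer collections are screened before optimization: the
#' expected amplicon length (metadata if present, otherwise the median
#' amplicon length computed on the reference set) must lie in the desired
#' range; every expanded primer must be within the initial length bounds
#' (default 17-21 nt); and the target domain, when annotated, must be
#' Bacteria or Universal (unannotated candidates are kept). Survivors are
#' expanded to primer-set-pairs and scored.
#'
#' @param candidates Data frame from [read_candidates()] (columns `id`,
#'   `forward`, `reverse`, optional `domain`, `amplicon_length`).
#' @param refset A [ref_set()] or [ref_index()].
#' @param config A [po_config()].
#' @param search A [search_config()].
#' @return A `primer_archive` of scored initial solutions.
#' @export
select_initial <- function(candidates, refset, config = po_config(),
                           search = search_config()) {
  config <- as_po_config(config)
  search <- as_search_config(search)
  index <- ensure_index(refset, config)
  entries <- list()
  for (row in seq_len(nrow(candidates))) {
    cand <- candidates[row, ]
    pair <- expand_pair(cand$forward, cand$reverse)
    lens <- nchar(all_primers(pair))
    if (any(lens < search$init_len_min | lens > search$init_len_max)) next
    dom <- if ("domain" %in% names(cand)) cand$domain else NA_character_
    if (!is.na(dom) && !dom %in% c("Bacteria", "Universal")) next
    amp <- if ("amplicon_length" %in% names(cand)) cand$amplicon_length else NA_real_
    profile <- NULL
    if (is.na(amp)) {
      profile <- build_profile(pair, index, config)
      amp <- profile$target_length
    }
    if (is.na(amp) || amp < search$amplicon_min || amp > search$amplicon_max) next
    sv <- score_vector(pair, index, config)
    entries[[length(entries) + 1L]] <-
      archive_entry(pair, sv, "initial", id = as.character(cand$id))
  }
  if (length(entries) == 0L)
    po_stop("no candidate primer pair survived the filters; ",
            "widen the amplicon range or the primer length bounds")
  new_archive(entries)
}

#' Multi-objective search for optimal primer-set-pairs
#'
#' Restart-driven approximation of the Pareto front: starting from an
#' archive of initial solutions, each restart recomputes the front, samples
#' a front member uniformly at random and a weight vector uniformly from the
#' unit simplex, runs best-improvement local search on that scalarization,
#' and appends the local optimum to the archive. Fully deterministic given
#' the seed.
#'
#' @param refset A [ref_set()] or [ref_index()].
#' @param init A non-empty `primer_archive` of initial solutions (from
#'   [select_initial()]) or a list of [primer_set_pair()] objects.
#' @param config A [po_config()].
#' @param search A [search_config()] (`restarts`, `seed`, move bounds).
#' @param verbose Emit one structured line per restart (restart index,
#'   weights, start and end scalarized score) via [message()].
#' @return A `primer_archive` containing the initial entries plus one local
#'   optimum per restart.
#' @export
multi_objective_search <- function(refset, init, config = po_config(),
                                   search = search_config(), verbose = FALSE) {
  config <- as_po_config(config)
  search <- as_search_config(search)
  index <- ensure_index(refset, config)
  archive <- as_initial_archive(init, index, config)
  if (length(archive) == 0L) po_stop("initial archive is empty")
  set.seed(search$seed)
  for (r in seq_len(search$restarts)) {
    front <- pareto_front(archive)
    start <- front[[sample.int(length(front), 1L)]]$pair
    alpha <- sample_weights()
    if (verbose) {
      s0 <- scalarize(score_vector(start, index, config), alpha)
    }
    res <- local_search(start, alpha, index, config, search)
    sv <- attr(res, "score_vector")
    if (verbose)
      message(sprintf(
        "restart=%d alpha=(%.3f,%.3f,%.3f) start_score=%.4f end_score=%.4f",
        r, alpha[["E"]], alpha[["C"]], alpha[["M"]], s0,
        attr(res, "weighted_score")))
    attributes(res)[c("score_vector", "weighted_score")] <- NULL
    archive[[length(archive) + 1L]] <- archive_entry(res, sv, "local-search",
                                                     restart = r)
  }
  new_archive(archive)
}

as_initial_archive <- function(init, index, config) {
  if (inherits(init, "primer_archive")) return(init)
  if (inherits(init, "primer_set_pair")) init <- list(init)
  if (is.list(init) && all(vapply(init, inherits, TRUE, "primer_set_pair"))) {
    return(new_archive(lapply(init, function(p)
      archive_entry(p, score_vector(p, index, config), "initial"))))
  }
  po_stop("init must be a primer_archive or primer_set_pair(s)")
}

#' Jaccard index between two solution lists
#'
#' Solutions are primer-set-pairs; two are equal when their forward and
#' reverse sets are identical (order within a set is irrelevant). Used to
#' quantify heterogeneity between the fronts of independent runs. Two empty
#' lists have index 1.
#'
#' @param a,b Lists of [primer_set_pair()] objects (or `primer_archive`s).
#' @return Jaccard index in \[0, 1\].
#' @export
archive_jaccard <- function(a, b) {
  keys <- function(x) {
    unique(vapply(x, function(e) {
      if (inherits(e, "primer_set_pair")) setpair_key(e) else setpair_key(e$pair)
    }, ""))
  }
  ka <- keys(a); kb <- keys(b)
  if (length(ka) == 0L && length(kb) == 0L) return(1)
  length(intersect(ka, kb)) / length(union(ka, kb))
}
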