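# Top-level entry point and the primer_search result class.

#' Optimize primer-set-pairs on a reference set
#'
#' Runs one or more independent multi-objective searches (sequentially, with
#' per-run seeds derived from `search$seed`), merges their archives and
#' computes the final Pareto front. This is the programmatic equivalent of
#' the command-line tool shipped in `inst/cli/`.
#'
#' @param refset A [ref_set()] (e.g. from [read_fasta()]) or [ref_index()].
#' @param init Initial solutions: a `primer_archive` from [select_initial()],
#'   a list of [primer_set_pair()] objects, or a single set-pair.
#' @param config A [po_config()].
#' @param search A [search_config()] (`runs`, `restarts`, `seed`, bounds).
#' @param verbose Emit one structured line per restart (see
#'   [multi_objective_search()]).
#' @return An object of class `primer_search`: list with `archive` (all
#'   evaluated solutions across runs, with per-run provenance), `front`
#'   (the merged Pareto front), `run_fronts` (per-run fronts, for
#'   heterogeneity statistics), `config` and `search`.
#' @examples
#' sim <- generate_synthetic_refset(synthetic_ref_spec(n_seq = 8,
#'   seq_length = 400, forward_pos = 50, reverse_pos = 330,
#'   mutation_rate = 0, seed = 1))
#' pair <- primer_set_pair("TCCTACGGGAGGCAGCAG", "CCGTCAATTCCTTTGAGT")
#' res <- optimize_primers(sim$refset, list(pair),
#'   search = search_config(restarts = 2, seed = 1))
#' summary(res)
#' @export
optimize_primers <- function(refset, init, config = po_config(),
                             search = search_config(), verbose = FALSE) {
  config <- as_po_config(config)
  search <- as_search_config(search)
  index <- ensure_index(refset, config)
  init_archive <- as_initial_archive(init, index, config)
  merged <- list()
  run_fronts <- vector("list", search$runs)
  for (run in seq_len(search$runs)) {
    run_search <- search
    run_search$seed <- (search$seed + run - 1L) %% .Machine$integer.max
    arch <- multi_objective_search(index, init_archive, config, run_search,
                                   verbose = verbose)
    for (k in seq_along(arch)) arch[[k]]$run <- run
    run_fronts[[run]] <- pareto_front(arch)
    merged <- c(merged, unclass(arch)[
      if (run == 1L) seq_along(arch) else -seq_along(init_archive)])
  }
  archive <- new_archive(merged)
  structure(list(archive = archive, front = pareto_front(archive),
                 run_fronts = run_fronts, config = config, search = search),
            class = "primer_search")
}

#' @export
print.primer_search <- function(x, ...) {
  cat("multi-objective primer search:", x$search$runs, "run(s) x",
      x$search$restarts, "restart(s), seed", x$search$seed, "\n")
  cat("archive:", length(x$archive), "solutions; Pareto front:",
      length(x$front), "\n")
  invisible(x)
}

#' @export
summary.primer_search <- function(object, ...) {
  df <- archive_table(object$front)
  cat("Pareto front (", nrow(df), " of ", length(object$archive),
      " archived solutions):\n", sep = "")
  show <- df
  show$E <- round(show$E, 3)
  show$C_fraction <- round(show$C_fraction, 3)
  show$M <- round(show$M, 3)
  print(show, row.names = FALSE)
  if (length(object$run_fronts) > 1L) {
    jac <- run_heterogeneity(object)
    cat(sprintf("mean pairwise Jaccard index between run fronts: %.3f\n", jac))
  }
  invisible(df)
}

#' Mean pairwise Jaccard index between run fronts
#'
#' Heterogeneity of the solution lists returned by the independent runs of a
#' search: the mean, over all pairs of runs, of the Jaccard index between
#' their Pareto fronts (solutions identified by their primer sets). Values
#' near 0 indicate that runs explore different parts of the search space.
#'
#' @param x A `primer_search` with at least two runs.
#' @return Mean Jaccard index in \[0, 1\].
#' @export
run_heterogeneity <- function(x) {
  fronts <- x$run_fronts
  if (length(fronts) < 2L) po_stop("need at least two runs")
  pairs <- utils::combn(length(fronts), 2L)
  mean(apply(pairs, 2L, function(ij)
    archive_jaccard(fronts[[ij[1L]]], fronts[[ij[2L]]])))
}

#' Plot a primer search result
#'
#' Coverage against efficiency for all archived solutions, with the Pareto
#' front highlighted and points shaded by matching-bias (darker = more
#' biased).
#'
#' @param x A `primer_search`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.primer_search <- function(x, ...) {
  df <- as.data.frame(x$archive)
  fr <- as.data.frame(x$front)
  mrange <- range(df$M[df$M < 1e5], 0, 1)
  shade <- function(m) {
    m <- pmin(pmax(m, mrange[1L]), mrange[2L])
    grey(0.8 * (1 - (m - mrange[1L]) / max(mrange[2L] - mrange[1L], 1e-9)))
  }
  graphics::plot(df$C_fraction, df$E, pch = 21, bg = shade(df$M),
                 xlab = "coverage (fraction)", ylab = "efficiency (0-10)",
                 main = "primer-set-pair archive", ...)
  graphics::points(fr$C_fraction, fr$E, pch = 21, bg = shade(fr$M),
                   cex = 1.6, lwd = 2, col = "firebrick")
  graphics::legend("bottomleft", pch = c(21, 21), pt.cex = c(1, 1.6),
                   col = c("black", "firebrick"),
                   legend = c("archived", "Pareto front"), bty = "n")
  invisible(x)
}

#' @importFrom grDevices grey
NULL
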