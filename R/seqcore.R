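# Sequence primitives: IUPAC alphabet, reverse complement, degenerate
# expansion and gap-free match counting.

# Per-code base options; the 15 IUPAC nucleotide codes ('-' and gaps excluded).
IUPAC_OPTIONS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

check_iupac <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    po_stop(what, " must be a single non-empty string")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(IUPAC_COMPLEMENT))
  if (length(bad))
    po_stop("non-IUPAC character '", chars[bad[1L]], "' at position ",
            bad[1L], " in ", what)
  invisible(chars)
}

check_primer <- function(p, what = "primer", min_len = 5L) {
  chars <- check_iupac(p, what)
  if (any(!chars %in% c("A", "C", "G", "T")))
    po_stop(what, " must be non-degenerate (A/C/G/T only): ", p)
  if (length(chars) < min_len)
    po_stop(what, " must be at least ", min_len, " nt, got ", length(chars))
  invisible(chars)
}

#' Reverse complement of a nucleotide sequence
#'
#' Degenerate IUPAC codes map to their complement codes (R to Y, B to V, ...).
#'
#' @param seq Single nucleotide string over the IUPAC alphabet, read 5'->3'.
#' @return The reverse complement, 5'->3'.
#' @examples
#' reverse_complement("ACGTR")  # "YACGT"
#' @export
reverse_complement <- function(seq) {
  chars <- check_iupac(toupper(seq))
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Expand a degenerate primer into its non-degenerate primers
#'
#' Returns the Cartesian product of the per-position base options, i.e. every
#' oligonucleotide present in the synthesized mixture. The result size equals
#' the degeneracy (product of per-position option counts).
#'
#' @param p Degenerate primer (IUPAC string), 5'->3'.
#' @return Character vector of non-degenerate primers.
#' @examples
#' expand_degenerate("ACGTHACGT")  # 3 primers
#' @export
expand_degenerate <- function(p) {
  chars <- check_iupac(toupper(p), "degenerate primer")
  opts <- IUPAC_OPTIONS[chars]
  out <- ""
  for (o in opts) out <- as.vector(outer(out, o, paste0))
  out
}

#' Construct a primer-set-pair
#'
#' A primer-set-pair is a non-empty set of forward and a non-empty set of
#' reverse non-degenerate primers used together in one reaction; it is the
#' search state of the optimizer and the natural expansion of a degenerate
#' primer pair.
#'
#' @param forward,reverse Character vectors of non-degenerate primers
#'   (A/C/G/T, each at least 5 nt), 5'->3'. Duplicates within a set are not
#'   allowed.
#' @return An object of class `primer_set_pair` with elements `forward` and
#'   `reverse`.
#' @export
primer_set_pair <- function(forward, reverse) {
  for (side in list(forward = forward, reverse = reverse)) {
    if (length(side) == 0L)
      po_stop("both primer sets must be non-empty")
  }
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (p in forward) check_primer(p, "forward primer")
  for (p in reverse) check_primer(p, "reverse primer")
  if (anyDuplicated(forward)) po_stop("duplicate sequences in forward set")
  if (anyDuplicated(reverse)) po_stop("duplicate sequences in reverse set")
  structure(list(forward = forward, reverse = reverse),
            class = "primer_set_pair")
}

#' @export
print.primer_set_pair <- function(x, ...) {
  cat("primer-set-pair:", length(x$forward), "forward x",
      length(x$reverse), "reverse primers\n")
  cat("  forward:", paste(x$forward, collapse = ", "), "\n")
  cat("  reverse:", paste(x$reverse, collapse = ", "), "\n")
  invisible(x)
}

#' Expand a degenerate primer pair into a primer-set-pair
#'
#' @param fwd,rev Degenerate primers (IUPAC strings), 5'->3'.
#' @return A [primer_set_pair()] whose forward and reverse sets are the full
#'   degenerate expansions.
#' @export
expand_pair <- function(fwd, rev) {
  primer_set_pair(expand_degenerate(fwd), expand_degenerate(rev))
}

all_primers <- function(pairs) c(pairs$forward, pairs$reverse)

# Canonical identity of a set-pair: order within a set is irrelevant.
setpair_key <- function(pairs) {
  paste(paste(sort(pairs$forward), collapse = ","),
        paste(sort(pairs$reverse), collapse = ","), sep = "|")
}

#' Maximum matches in a gap-free alignment
#'
#' Slides `b` along `a` over every relative offset with at least one
#' overlapping position (no gaps, no end-anchoring) and returns the maximum
#' count of positions carrying the same letter. This is the match statistic
#' used by the self-dimer and cross-dimer screens, where `b` is the reverse
#' complement of the partner primer.
#'
#' @param a,b Non-empty nucleotide strings.
#' @return Integer, at most `min(nchar(a), nchar(b))`.
#' @export
max_gapfree_matches <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) po_stop("empty sequence")
  cpp_max_gapfree_matches(toupper(a), toupper(b))
}
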