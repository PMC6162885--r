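# Readers and writers: FASTA reference sets, candidate primer TSVs, archive
# and match-profile exports.

#' Read a reference set from FASTA
#'
#' Accepts multi-record FASTA with wrapped or unwrapped sequence lines,
#' mixed case (uppercased on read) and CRLF line endings. The record id is
#' the first whitespace-delimited token of the header. Validation is strict:
#' duplicate ids, empty files and non-IUPAC characters (named by record and
#' position) are errors rather than silent coercions.
#'
#' @param path Path to a FASTA file.
#' @return A [ref_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) po_stop("file not found: ", path)
  lines <- gsub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) po_stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) po_stop("not a FASTA file (no leading '>'): ", path)
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    po_stop("duplicate record id '", ids[duplicated(ids)][1L], "' in ", path)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 paste, "", collapse = "")
  if (length(seqs) != length(ids) || any(!nzchar(seqs)))
    po_stop("record without sequence in ", path)
  seqs <- toupper(unname(seqs))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% names(IUPAC_COMPLEMENT))
    if (length(bad))
      po_stop("non-IUPAC character '", chars[bad[1L]], "' at position ",
              bad[1L], " of record '", ids[i], "'")
  }
  ref_set(seqs, ids)
}

#' Write a reference set to FASTA
#'
#' @param refset A [ref_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(refset, path) {
  if (!inherits(refset, "ref_set")) po_stop("refset must be a ref_set")
  x <- Biostrings::DNAStringSet(refset$sequences)
  names(x) <- refset$ids
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read candidate primer pairs from TSV
#'
#' Tab-separated file with a header; mandatory columns `id`, `forward`,
#' `reverse` (IUPAC, possibly degenerate), optional columns `domain`
#' (Bacteria / Universal / Archaea / other) and `amplicon_length` (nt, the
#' expected product length on a reference gene). Blank optional fields
#' become `NA`.
#'
#' @param path Path to the TSV file.
#' @return A data frame, one row per candidate pair.
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) po_stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(c("id", "forward", "reverse"), names(df))
  if (length(missing))
    po_stop("candidate file is missing column(s): ",
            paste(missing, collapse = ", "))
  if (nrow(df) == 0L) po_stop("candidate file has no rows: ", path)
  for (row in seq_len(nrow(df))) {
    check_iupac(toupper(df$forward[row]), paste0("forward primer in row ", row))
    check_iupac(toupper(df$reverse[row]), paste0("reverse primer in row ", row))
  }
  df$forward <- toupper(df$forward)
  df$reverse <- toupper(df$reverse)
  if ("domain" %in% names(df)) {
    df$domain[!nzchar(trimws(df$domain))] <- NA_character_
  }
  if ("amplicon_length" %in% names(df)) {
    raw <- trimws(df$amplicon_length)
    raw[!nzchar(raw)] <- NA_character_
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      po_stop("malformed amplicon_length '", raw[bad[1L]], "' in row ", bad[1L])
    if (any(num <= 0, na.rm = TRUE))
      po_stop("amplicon_length must be positive")
    df$amplicon_length <- num
  }
  df
}

#' Read primer-set-pairs from TSV
#'
#' Tab-separated file with header columns `id`, `forward`, `reverse`, where
#' the primer sets are comma-joined non-degenerate primers.
#'
#' @param path Path to the TSV file.
#' @return Named list of [primer_set_pair()] objects.
#' @export
read_setpairs <- function(path) {
  if (!file.exists(path)) po_stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(c("id", "forward", "reverse"), names(df))
  if (length(missing))
    po_stop("set-pair file is missing column(s): ",
            paste(missing, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(row) {
    primer_set_pair(strsplit(df$forward[row], ",", fixed = TRUE)[[1L]],
                    strsplit(df$reverse[row], ",", fixed = TRUE)[[1L]])
  })
  stats::setNames(out, df$id)
}

archive_table <- function(archive) {
  df <- as.data.frame(archive)
  ord <- order(-df$E, -df$C_fraction, df$M, df$forward, df$reverse)
  df[ord, , drop = FALSE]
}

#' Write archive and Pareto front to TSV
#'
#' Writes `<prefix>.archive.tsv` and `<prefix>.front.tsv`, deterministically
#' ordered by descending efficiency, then descending coverage, then
#' ascending matching-bias, then lexicographic primer sets. Scores are
#' written at full double precision so that reading the files back
#' reproduces identical score vectors.
#'
#' @param result A `primer_search` (see [optimize_primers()]) or a
#'   `primer_archive`.
#' @param prefix Output path prefix.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_results <- function(result, prefix) {
  if (inherits(result, "primer_search")) {
    archive <- result$archive
    front <- result$front
  } else if (inherits(result, "primer_archive")) {
    archive <- result
    front <- pareto_front(result)
  } else po_stop("result must be a primer_search or primer_archive")
  paths <- c(archive = paste0(prefix, ".archive.tsv"),
             front = paste0(prefix, ".front.tsv"))
  for (nm in names(paths)) {
    df <- archive_table(if (nm == "archive") archive else front)
    for (col in c("E", "C_fraction", "M"))
      df[[col]] <- sprintf("%.17g", df[[col]])
    ok <- tryCatch({
      write.table(df, paths[[nm]], sep = "\t", quote = FALSE,
                  row.names = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) po_stop("cannot write ", paths[[nm]])
  }
  invisible(paths)
}

#' Read an archive TSV back into a data frame
#'
#' @param path A file written by [write_results()].
#' @return Data frame with numeric score columns.
#' @export
read_archive <- function(path) {
  if (!file.exists(path)) po_stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in c("E", "C_fraction", "M")) df[[col]] <- as.numeric(df[[col]])
  df$C_count <- as.integer(df$C_count)
  df$restart <- suppressWarnings(as.integer(df$restart))
  df
}

#' Export a match profile to TSV
#'
#' One row per reference sequence: id, combination count (after the target
#' length filter) and the shortest amplicon length over all combinations
#' (NA when the set-pair forms no product on that sequence).
#'
#' @param profile A [build_profile()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  best <- suppressWarnings(apply(profile$lengths, 2L, min, na.rm = TRUE))
  best[!is.finite(best)] <- NA_real_
  df <- data.frame(id = profile$ids,
                   combination_count = profile$counts,
                   best_amplicon_length = best)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
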