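#' @keywords internal
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    cache <<- e$BLOSUM62
    cache
  }
})

#' Global Needleman-Wunsch alignment with BLOSUM62
#'
#' Optimal global alignment under the BLOSUM62 substitution matrix with
#' affine gap penalties (a gap of length L costs `gap_open + L *
#' gap_extend`).  The identity fraction uses the full alignment length,
#' including gap columns, as denominator.
#'
#' @param a,b protein sequences (one-letter strings, standard alphabet).
#' @param gap_open,gap_extend affine gap penalties.
#' @return List with `score`, `identity` (fraction), `aligned_a`,
#'   `aligned_b`.
#' @export
global_align <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  check_protein_letters(a, "a")
  check_protein_letters(b, "b")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62_matrix(),
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  ident <- sum(pa == pb & pa != "-") / length(pa)
  list(score = Biostrings::score(al), identity = ident,
       aligned_a = paste(pa, collapse = ""),
       aligned_b = paste(pb, collapse = ""))
}

check_protein_letters <- function(s, label) {
  if (!is.character(s) || length(s) != 1L || nchar(s) == 0L) {
    abort(paste0("sequence ", label, " must be a non-empty string"))
  }
  chars <- strsplit(toupper(s), "")[[1]]
  bad <- which(!chars %in% unname(AA1))
  if (length(bad) > 0L) {
    abort(paste0("non-standard letter '", chars[bad[1]], "' at position ",
                 bad[1], " of sequence ", label))
  }
}

#' Pairwise identity matrix of entry sequences
#'
#' @param entries tibble with `entry_id` and `sequence` columns (see
#'   [make_entries()]), or a named character vector of sequences.
#' @param ... passed to [global_align()].
#' @return Symmetric matrix of identity fractions with unit diagonal.
#' @export
identity_matrix <- function(entries, ...) {
  if (is.character(entries)) {
    seqs <- entries
    ids <- names(entries)
    if (is.null(ids)) ids <- paste0("seq", seq_along(entries))
  } else {
    seqs <- entries$sequence
    ids <- entries$entry_id
  }
  n <- length(seqs)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        m[i, j] <- m[j, i] <- global_align(seqs[i], seqs[j], ...)$identity
      }
    }
  }
  m
}

#' Greedy maximum-identity culling
#'
#' Entries are scanned in alphanumeric order of their identifiers; an entry
#' is kept iff its identity with every previously kept entry is strictly
#' below `X` percent.  The result therefore satisfies the pairwise bound by
#' construction and is deterministic given the ordering.
#'
#' @param entries tibble with `entry_id` (and any other columns), or a
#'   character vector of ids.
#' @param identities identity matrix from [identity_matrix()] (fractions).
#' @param X identity level in percent, in (0, 100].
#' @return The kept subset of `entries`, same type as the input.
#' @export
cull_by_identity <- function(entries, identities, X) {
  stopifnot(X > 0, X <= 100)
  ids <- if (is.character(entries)) entries else entries$entry_id
  ord <- order(ids)
  kept <- character(0)
  for (k in ord) {
    id <- ids[k]
    if (length(kept) == 0L ||
        all(identities[id, kept] < X / 100)) {
      kept <- c(kept, id)
    }
  }
  if (is.character(entries)) {
    entries[entries %in% kept]
  } else {
    entries[entries$entry_id %in% kept, , drop = FALSE]
  }
}
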