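#' Build an idealized B-DNA duplex
#'
#' Places the packaged per-nucleotide strand-frame template (fiber-style
#' geometry: twist 36 degrees and rise 3.38 Angstrom per step; the
#' complementary strand is the image under a two-fold rotation about the
#' frame x-axis) along a helical axis for an arbitrary sequence.  All
#' standard heavy atoms are present; the 5'-terminal residue of each strand
#' lacks its phosphate group.
#'
#' @param sequence base-letter string (A/C/G/T), written 5' to 3' for the
#'   first strand.
#' @param chain_ids two chain identifiers for the duplex strands.
#' @return Object of class `bdna_duplex`: a list with `sequence` and `atoms`
#'   (tibble: chain, resno, resid, pair_pos, atom, element, x, y, z in
#'   Angstrom).
#' @examples
#' dup <- build_bdna_duplex("ACGT")
#' nrow(unique(dup$atoms[, c("chain", "resno")]))  # 8 nucleotides
#' @export
build_bdna_duplex <- function(sequence, chain_ids = c("X", "Y")) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  letters_vec <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!letters_vec %in% c("A", "C", "G", "T"))
  if (length(letters_vec) < 1L) abort("sequence must have length >= 1")
  if (length(bad) > 0L) {
    abort(paste0("non-ACGT character '", letters_vec[bad[1]],
                 "' at position ", bad[1]))
  }
  L <- length(letters_vec)
  res_I <- paste0("D", letters_vec)
  frame <- bdna_frame()

  twist <- -36 * pi / 180
  rise <- 3.38
  helical <- function(xyz, k) {
    co <- cos(k * twist)
    si <- sin(k * twist)
    R <- matrix(c(co, si, 0, -si, co, 0, 0, 0, 1), 3, 3)
    sweep(xyz %*% t(R), 2, c(0, 0, k * rise), "+")
  }

  rows <- list()
  for (i in seq_len(L)) {
    k <- L - i
    b1 <- res_I[i]
    t1 <- frame[frame$base == b1, , drop = FALSE]
    xyz1 <- helical(as.matrix(t1[, c("x", "y", "z")]), k)
    rows[[length(rows) + 1L]] <- tibble(
      chain = chain_ids[1], resno = i, resid = b1, pair_pos = i,
      atom = t1$atom, element = t1$element,
      x = xyz1[, 1], y = xyz1[, 2], z = xyz1[, 3]
    )
    b2 <- unname(DNA_COMP[b1])
    t2 <- frame[frame$base == b2, , drop = FALSE]
    m <- as.matrix(t2[, c("x", "y", "z")])
    m[, 2] <- -m[, 2]
    m[, 3] <- -m[, 3]
    xyz2 <- helical(m, k)
    rows[[length(rows) + 1L]] <- tibble(
      chain = chain_ids[2], resno = L - i + 1L, resid = b2, pair_pos = i,
      atom = t2$atom, element = t2$element,
      x = xyz2[, 1], y = xyz2[, 2], z = xyz2[, 3]
    )
  }
  atoms <- bind_rows(rows)
  # 5'-terminal residues lack the phosphate group
  atoms <- atoms[!(atoms$resno == 1L &
                     atoms$atom %in% c("P", "OP1", "OP2")), , drop = FALSE]
  atoms <- arrange(atoms, .data$chain, .data$resno)
  structure(list(sequence = paste(letters_vec, collapse = ""), atoms = atoms,
                 chain_ids = chain_ids),
            class = "bdna_duplex")
}

#' @export
print.bdna_duplex <- function(x, ...) {
  cat("<bdna_duplex> ", nchar(x$sequence), " bp, sequence ", x$sequence,
      "\n", sep = "")
  invisible(x)
}

#' Coordinates of one nucleotide instance in a duplex
#' @keywords internal
duplex_residue <- function(duplex, chain, resno) {
  a <- duplex$atoms
  a[a$chain == chain & a$resno == resno, , drop = FALSE]
}
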