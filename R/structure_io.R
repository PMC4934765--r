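#' Parse a PDB document into a structure record
#'
#' Reads ATOM/HETATM coordinates through bio3d and scans the header for the
#' REMARK 2 resolution and REMARK 3 R-factor records.  Chains are classified
#' as protein or DNA from their residue-name vocabulary.
#'
#' @param document PDB text (single string or character vector of lines) or
#'   a path to a PDB file.
#' @param id identifier stored in the record; defaults to the file stem or
#'   `"structure"`.
#' @return Object of class `structure_record`: list with `id`, `atoms`
#'   (tibble: chain, resno, resid, atom, element, x, y, z), `chains` (tibble:
#'   chain, type, sequence), `resolution`, `r_factor` (either may be `NA`).
#' @export
parse_structure <- function(document, id = NULL) {
  if (length(document) == 1L && !grepl("\n", document) &&
      file.exists(document)) {
    lines <- readLines(document)
    if (is.null(id)) id <- sub("\\.pdb$", "", basename(document))
  } else {
    lines <- if (length(document) == 1L) strsplit(document, "\n")[[1]]
    else document
  }
  if (length(lines) == 0L || !any(nzchar(lines))) {
    abort("parse_structure(): empty document")
  }
  if (is.null(id)) id <- "structure"

  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  bad <- which(is_atom & nchar(lines) < 54)
  if (length(bad) > 0L) {
    abort(paste0("malformed fixed-width coordinate record at line ", bad[1]))
  }
  coords <- substr(lines[is_atom], 31, 54)
  if (any(is.na(suppressWarnings(as.numeric(substr(coords, 1, 8)))))) {
    off <- which(is.na(suppressWarnings(
      as.numeric(substr(coords, 1, 8)))))[1]
    abort(paste0("malformed coordinate field at line ",
                 which(is_atom)[off]))
  }

  resolution <- NA_real_
  r_factor <- NA_real_
  r2 <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
  if (length(r2) > 0L) {
    rest <- sub("^.*RESOLUTION\\.", "", r2[1])
    m <- regmatches(rest, regexpr("[0-9]+\\.?[0-9]*", rest))
    if (length(m) > 0L) resolution <- as.numeric(m)
  }
  r3 <- grep("^REMARK   3.*R VALUE", lines, value = TRUE)
  if (length(r3) > 0L) {
    m <- regmatches(r3[1], regexpr("[0-9]*\\.[0-9]+\\s*$", r3[1]))
    if (length(m) > 0L) r_factor <- as.numeric(m)
  }

  if (!any(is_atom)) {
    return(structure(list(id = id, atoms = tibble(), chains = tibble(),
                          resolution = resolution, r_factor = r_factor),
                     class = "structure_record"))
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, verbose = FALSE)
  a <- pdb$atom
  elem <- trimws(a$elesy)
  guess <- toupper(substr(trimws(a$elety), 1, 1))
  elem[!nzchar(elem)] <- guess[!nzchar(elem)]
  atoms <- tibble(chain = a$chain, resno = a$resno, resid = trimws(a$resid),
                  atom = trimws(a$elety), element = elem,
                  x = a$x, y = a$y, z = a$z)
  if (any(!is.finite(atoms$x + atoms$y + atoms$z))) {
    abort("non-finite coordinates in document")
  }

  chains <- atoms |>
    group_by(chain) |>
    summarise(type = chain_type(.data$resid), sequence = {
      res <- .data$resid[!duplicated(.data$resno)]
      if (chain_type(.data$resid) == "protein") {
        paste(ifelse(res %in% names(AA1), AA1[res], "X"), collapse = "")
      } else NA_character_
    }, .groups = "drop")

  structure(list(id = id, atoms = atoms, chains = chains,
                 resolution = resolution, r_factor = r_factor),
            class = "structure_record")
}

chain_type <- function(resid) {
  res <- unique(resid)
  if (mean(res %in% DNA_RES) > 0.5) return("dna")
  if (mean(res %in% AA3) > 0.5) return("protein")
  "other"
}

#' @export
print.structure_record <- function(x, ...) {
  cat("<structure_record> ", x$id, ": ", nrow(x$chains), " chain(s), ",
      nrow(x$atoms), " atoms; resolution ",
      ifelse(is.na(x$resolution), "absent", x$resolution),
      " A, R-factor ", ifelse(is.na(x$r_factor), "absent", x$r_factor),
      "\n", sep = "")
  invisible(x)
}

#' Crystallographic quality filter
#'
#' Keeps structures solved to a resolution strictly better than
#' `max_resolution` with an R-factor no worse than `max_rfactor`.  Records
#' missing either metadatum are excluded with a warning (conservative
#' reading of the filter).
#'
#' @param records list of `structure_record`s.
#' @param max_resolution resolution bound in Angstrom (strict `<`).
#' @param max_rfactor R-factor bound (`<=`).
#' @return The kept sublist, with attribute `"excluded"` naming the dropped
#'   records.
#' @export
filter_structures <- function(records, max_resolution = 2.5,
                              max_rfactor = 0.25) {
  stopifnot(max_resolution > 0, max_rfactor > 0)
  if (inherits(records, "structure_record")) records <- list(records)
  ok <- vapply(records, function(r) {
    if (is.na(r$resolution) || is.na(r$r_factor)) {
      warn(paste0(r$id, ": missing resolution or R-factor; excluded"))
      return(FALSE)
    }
    r$resolution < max_resolution && r$r_factor <= max_rfactor
  }, logical(1))
  out <- records[ok]
  attr(out, "excluded") <- vapply(records[!ok], function(r) r$id, character(1))
  out
}

#' Detect double-stranded DNA regions
#'
#' Finds Watson-Crick paired regions between antiparallel DNA chains: a base
#' pair requires complementary residue letters, a purine N1 to pyrimidine N3
#' distance below 3.5 Angstrom and antiparallel local C1' strand directions;
#' regions shorter than `min_bp` consecutive pairs are dropped.
#'
#' @param record a `structure_record`.
#' @param min_bp minimum number of consecutive base pairs.
#' @return Tibble with one row per region: chain1, chain2, start1, end1,
#'   n_bp, plus a `pairs` list-column of the residue pairing.
#' @export
detect_duplexes <- function(record, min_bp = 4) {
  stopifnot(inherits(record, "structure_record"))
  dch <- record$chains$chain[record$chains$type == "dna"]
  if (length(dch) < 2L) return(tibble())
  a <- record$atoms
  out <- list()
  for (i in seq_along(dch)) {
    for (j in seq_along(dch)) {
      if (i == j) next
      p <- pair_chains(a, dch[i], dch[j])
      if (is.null(p)) next
      # split into runs of consecutive pairs (resno1 ascending by 1,
      # resno2 descending by 1)
      runs <- split_runs(p)
      for (r in runs) {
        if (nrow(r) >= min_bp && i < j) {
          out[[length(out) + 1L]] <- tibble(
            chain1 = dch[i], chain2 = dch[j],
            start1 = min(r$resno1), end1 = max(r$resno1), n_bp = nrow(r),
            pairs = list(r))
        }
      }
    }
  }
  if (length(out) == 0L) return(tibble())
  bind_rows(out)
}

pair_chains <- function(atoms, ch1, ch2) {
  n1 <- atoms[atoms$chain == ch1 & ((atoms$resid %in% PURINES &
                                       atoms$atom == "N1") |
                                      (!atoms$resid %in% PURINES &
                                         atoms$atom == "N3")), ]
  n2 <- atoms[atoms$chain == ch2 & ((atoms$resid %in% PURINES &
                                       atoms$atom == "N1") |
                                      (!atoms$resid %in% PURINES &
                                         atoms$atom == "N3")), ]
  if (nrow(n1) == 0L || nrow(n2) == 0L) return(NULL)
  d <- proxy_dist(as.matrix(n1[, c("x", "y", "z")]),
                  as.matrix(n2[, c("x", "y", "z")]))
  hits <- which(d < 3.5, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(NULL)
  comp <- unname(DNA_COMP[n1$resid[hits[, 1]]]) == n2$resid[hits[, 2]]
  hits <- hits[comp, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  p <- tibble(resno1 = n1$resno[hits[, 1]], resno2 = n2$resno[hits[, 2]],
              resid1 = n1$resid[hits[, 1]], resid2 = n2$resid[hits[, 2]])
  p <- p[!duplicated(p$resno1) & !duplicated(p$resno2), , drop = FALSE]
  p <- arrange(p, .data$resno1)
  # antiparallel check: each strand's C1' path in its own ascending residue
  # order must run opposite to the partner's
  if (nrow(p) >= 2L) {
    c1a <- chain_c1(atoms, ch1, sort(p$resno1))
    c1b <- chain_c1(atoms, ch2, sort(p$resno2))
    if (!is.null(c1a) && !is.null(c1b)) {
      va <- c1a[nrow(c1a), ] - c1a[1, ]
      vb <- c1b[nrow(c1b), ] - c1b[1, ]
      if (sum(va * vb) >= 0) return(NULL)
    }
  }
  p
}

chain_c1 <- function(atoms, ch, resnos) {
  sel <- atoms[atoms$chain == ch & atoms$atom == "C1'" &
                 atoms$resno %in% resnos, ]
  sel <- sel[match(resnos, sel$resno), , drop = FALSE]
  if (anyNA(sel$resno)) return(NULL)
  as.matrix(sel[, c("x", "y", "z")])
}

split_runs <- function(p) {
  if (nrow(p) == 0L) return(list())
  brk <- c(FALSE, diff(p$resno1) != 1L | diff(p$resno2) != -1L)
  split(p, cumsum(brk))
}

#' Split a structure into single-protein-chain analysis entries
#'
#' Protein chains with identical sequences (homomultimers) collapse to the
#' alphabetically first chain; each remaining distinct chain becomes one
#' independent entry paired with the recognised DNA duplex chains.
#'
#' @param record a `structure_record` that passed the filters.
#' @param duplexes optional result of [detect_duplexes()]; computed when
#'   missing.
#' @return Tibble with one row per entry: entry_id, structure_id, chain,
#'   sequence, dna_chains (list-column).
#' @export
make_entries <- function(record, duplexes = NULL) {
  stopifnot(inherits(record, "structure_record"))
  if (is.null(duplexes)) duplexes <- detect_duplexes(record)
  if (nrow(duplexes) == 0L) return(tibble())
  pch <- record$chains[record$chains$type == "protein", , drop = FALSE]
  if (nrow(pch) == 0L) return(tibble())
  pch <- arrange(pch, .data$chain)
  pch <- pch[!duplicated(pch$sequence), , drop = FALSE]
  dna_chains <- unique(c(duplexes$chain1, duplexes$chain2))
  tibble(entry_id = paste0(record$id, "_", pch$chain),
         structure_id = record$id, chain = pch$chain,
         sequence = pch$sequence,
         dna_chains = replicate(nrow(pch), dna_chains, simplify = FALSE))
}
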