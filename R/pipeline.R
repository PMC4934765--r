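#' Run the full base-readout discovery pipeline
#'
#' End-to-end driver: parse PDB documents, apply the crystallographic
#' filters, split structures into single-protein-chain entries, extract
#' contact dimers, flag the base-directed subset (optionally stripping the
#' nucleotides to bare bases), superpose each amino-acid x base distribution
#' into the common base frame, run the greedy RMSD clustering, score every
#' dimer with the supermolecular interaction energy in each requested
#' medium, classify contacted edges, and grade all combinations against the
#' four criteria of specificity.
#'
#' @param documents character vector of PDB file paths or PDB texts.
#' @param media relative permittivities to evaluate (each becomes a
#'   [medium()]).
#' @param set `"stripped"` scores amino acid-base dimers (backbone removed),
#'   `"dnmp"` scores full amino acid-dNMP dimers; both use only
#'   base-directed contacts.
#' @param apply_filters run [filter_structures()] first.
#' @param identity_cull optional identity level in percent; when given,
#'   entries are culled with [cull_by_identity()] before extraction.
#' @param contact_margin van der Waals contact margin, Angstrom.
#' @param cluster_threshold,max_clusters,min_size greedy clustering
#'   controls.
#' @param overlap_threshold,margin specificity thresholds, see
#'   [evaluate_specificity()].
#' @param verbose print progress.
#' @return Object of class `readout_study`: list with `entries`,
#'   `dimer_table` (tibble), `clusters`, `profiles`, `verdicts` (tibble)
#'   and `params`.
#' @export
run_readout_pipeline <- function(documents, media = c(4, 80),
                                 set = c("stripped", "dnmp"),
                                 apply_filters = TRUE, identity_cull = NULL,
                                 contact_margin = 1.0,
                                 cluster_threshold = 1.5, max_clusters = 6,
                                 min_size = 4, overlap_threshold = 0.3,
                                 margin = 4, verbose = FALSE) {
  set <- match.arg(set)
  say <- function(...) if (verbose) message(...)

  records <- lapply(seq_along(documents), function(i) {
    parse_structure(documents[i], id = sprintf("fx%03d", i))
  })
  if (apply_filters) records <- filter_structures(records)
  say(length(records), " structure(s) after filtering")

  entries <- bind_rows(lapply(records, make_entries))
  if (nrow(entries) == 0L) abort("no analysis entries survive the filters")
  if (!is.null(identity_cull)) {
    ids <- identity_matrix(entries)
    entries <- cull_by_identity(entries, ids, identity_cull)
  }
  say(nrow(entries), " analysis entr(ies)")

  rec_by_id <- stats::setNames(records,
                               vapply(records, function(r) r$id,
                                      character(1)))
  dimers <- list()
  for (r in seq_len(nrow(entries))) {
    entry <- entries[r, , drop = FALSE]
    found <- find_contacts(rec_by_id[[entry$structure_id]], entry,
                           margin = contact_margin)
    dimers <- c(dimers, lapply(found, flag_base_directed,
                               margin = contact_margin))
  }
  say(length(dimers), " contact dimer(s)")
  dimers <- Filter(function(d) isTRUE(d$base_directed), dimers)
  say(length(dimers), " base-directed dimer(s)")
  if (length(dimers) == 0L) abort("no base-directed dimers found")

  edges <- vapply(dimers, classify_edge, character(1),
                  margin = contact_margin)
  scored <- if (set == "stripped") lapply(dimers, strip_to_base) else dimers

  keys <- paste(vapply(scored, function(d) d$aa_type, character(1)),
                vapply(scored, function(d) d$nuc_type, character(1)))
  cluster_id <- rep(NA_integer_, length(scored))
  clusters_out <- list()
  for (key in unique(keys)) {
    idx <- which(keys == key)
    dist <- build_distribution(scored[idx])
    cls <- greedy_cluster(dist, threshold = cluster_threshold,
                          max_clusters = max_clusters, min_size = min_size)
    for (ci in seq_along(cls)) {
      cluster_id[idx[cls[[ci]]$members]] <- ci
    }
    clusters_out[[key]] <- cls
    # scored poses are now in the common frame; keep them for plots
    scored[idx] <- dist$dimers
  }

  rows <- list()
  for (eps in media) {
    med <- medium(eps)
    for (k in seq_along(scored)) {
      d <- scored[[k]]
      ie <- interaction_energy(prepare_dimer(d), med)
      rows[[length(rows) + 1L]] <- tibble(
        structure_id = d$structure_id, chain = d$chain,
        aa_resno = d$aa_resno, aa = d$aa_type,
        base = d$nuc_type, edge = edges[k], cluster = cluster_id[k],
        energy = ie$e_int, eps_r = eps)
    }
    say("energies done for eps_r = ", eps)
  }
  dimer_table <- bind_rows(rows)

  profiles <- list()
  for (eps in media) {
    for (key in unique(keys)) {
      sel <- dimer_table$eps_r == eps &
        paste(dimer_table$aa, dimer_table$base) == key
      en <- dimer_table$energy[sel]
      if (length(en) >= 4L) {
        cl <- dimer_table$cluster[sel]
        members <- lapply(sort(unique(cl[!is.na(cl)])),
                          function(ci) which(!is.na(cl) & cl == ci))
        profiles[[paste0(key, " eps", eps)]] <-
          build_profile(en, members, eps_r = eps)
      }
    }
  }

  verdicts <- evaluate_specificity(dimer_table,
                                   overlap_threshold = overlap_threshold,
                                   margin = margin)
  structure(list(entries = entries, dimer_table = dimer_table,
                 clusters = clusters_out, profiles = profiles,
                 verdicts = verdicts,
                 params = list(set = set, media = media,
                               contact_margin = contact_margin,
                               cluster_threshold = cluster_threshold,
                               max_clusters = max_clusters,
                               min_size = min_size,
                               overlap_threshold = overlap_threshold,
                               margin = margin)),
            class = "readout_study")
}

#' @export
print.readout_study <- function(x, ...) {
  cat("<readout_study> ", nrow(x$entries), " entr(ies), ",
      nrow(x$dimer_table), " dimer-energy rows, media: ",
      paste(x$params$media, collapse = ", "), "\n", sep = "")
  flagged <- x$verdicts[x$verdicts$grade != "none", , drop = FALSE]
  if (nrow(flagged) > 0L) {
    cat("flagged combinations:\n")
    print(as.data.frame(flagged[, c("aa", "base", "edge", "eps_r",
                                    "grade")]))
  } else {
    cat("no combination meets the criteria of specificity\n")
  }
  invisible(x)
}
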