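#' Freedman-Diaconis histogram bin edges
#'
#' Bin width `h = 2 * IQR * n^(-1/3)` with midpoint linear-interpolation
#' quartiles (type 5); `ceiling(range/h)` bins spanning the data from its
#' minimum.  Degenerate inputs fall back gracefully: constant data gets a
#' single unit-width bin, zero IQR with nonzero range uses the Sturges bin
#' count.
#'
#' @param values numeric vector, length >= 4.
#' @return Numeric vector of bin edges.
#' @export
freedman_diaconis_bins <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 4L) abort("freedman_diaconis_bins(): need at least 4 values")
  rng <- max(values) - min(values)
  if (rng == 0) {
    return(c(values[1] - 0.5, values[1] + 0.5))
  }
  iqr <- unname(diff(quantile(values, c(0.25, 0.75), type = 5)))
  h <- 2 * iqr * n^(-1 / 3)
  if (h == 0) {
    h <- rng / ceiling(log2(n) + 1)
  }
  nbins <- max(1L, ceiling(rng / h))
  seq(min(values), by = h, length.out = nbins + 1L)
}

bin_counts <- function(values, edges) {
  idx <- findInterval(values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  tabulate(idx, nbins = length(edges) - 1L)
}

#' Interaction-energy profile of a distribution
#'
#' Histograms the full distribution with Freedman-Diaconis bin edges,
#' selects the cluster whose members provide on average the lowest (most
#' stabilising) interaction energies, and histograms that cluster on the
#' same bin edges so the two can be overlaid.
#'
#' @param energies interaction energies of all dimers in the distribution,
#'   kJ/mol.
#' @param clusters list of integer vectors indexing `energies` (cluster
#'   memberships), or the output of [greedy_cluster()].
#' @param eps_r relative permittivity the energies were computed in.
#' @return Object of class `energy_profile`.
#' @export
build_profile <- function(energies, clusters, eps_r = NA_real_) {
  members <- lapply(clusters, function(cl) {
    if (is.list(cl) && !is.null(cl$members)) cl$members else as.integer(cl)
  })
  edges <- freedman_diaconis_bins(energies)
  dist_counts <- bin_counts(energies, edges)
  if (length(members) == 0L) {
    best <- NA_integer_
    cl_counts <- rep(0L, length(edges) - 1L)
    cl_energies <- numeric(0)
  } else {
    means <- vapply(members, function(m) mean(energies[m]), numeric(1))
    best <- which.min(means)
    cl_energies <- energies[members[[best]]]
    cl_counts <- bin_counts(cl_energies, edges)
  }
  structure(list(edges = edges, dist_counts = dist_counts,
                 cluster_counts = cl_counts, cluster_index = best,
                 cluster_energies = cl_energies, energies = energies,
                 eps_r = eps_r),
            class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat("<energy_profile> ", length(x$energies), " dimers, ",
      length(x$edges) - 1L, " bins",
      if (!is.na(x$cluster_index))
        paste0(", lowest cluster n = ", length(x$cluster_energies)) else "",
      if (!is.na(x$eps_r)) paste0(", eps_r = ", x$eps_r) else "",
      "\n", sep = "")
  invisible(x)
}

# base-edge atom sets; C6/C4-substituent atoms are shared between the
# Watson-Crick and Hoogsteen sets, ties break toward the set holding N7
# (purines) / N3 (pyrimidines)
EDGE_SETS <- list(
  DA = list(watson_crick = c("N1", "N6"), hoogsteen = c("N7", "N6"),
            sugar = c("N3", "C2")),
  DG = list(watson_crick = c("N1", "O6", "N2"), hoogsteen = c("N7", "O6"),
            sugar = c("N3", "N2")),
  DC = list(watson_crick = c("N3", "O2", "N4"),
            hoogsteen = c("N4", "C5"), sugar = c("O2")),
  DT = list(watson_crick = c("N3", "O2", "O4"),
            hoogsteen = c("O4", "C5", "C7"), sugar = c("O2"))
)

#' Classify which nucleotide edge a dimer contacts
#'
#' The label is the edge whose atom set contains the plurality of the
#' base-side contact atoms; `"phosphate"` when only sugar-phosphate
#' backbone atoms are contacted; `"stacking"` when the base is contacted
#' but no donor-acceptor heavy-atom pair lies within hydrogen-bond distance
#' (3.5 Angstrom) and the contact centroid sits at least 2.5 Angstrom out
#' of the base least-squares plane.
#'
#' @param dimer a `contact_dimer` (stripped or not).
#' @param margin contact margin in Angstrom.
#' @return One of `"hoogsteen"`, `"watson_crick"`, `"sugar"`,
#'   `"phosphate"`, `"stacking"`.
#' @export
classify_edge <- function(dimer, margin = 1.0) {
  stopifnot(inherits(dimer, "contact_dimer"))
  base_names <- BASE_HEAVY[[dimer$nuc_type]]
  nuc <- dimer$nuc_atoms
  aa_xyz <- as.matrix(dimer$aa_atoms[, c("x", "y", "z")])
  aa_rad <- vdw_radius(dimer$aa_atoms$element)
  nuc_xyz <- as.matrix(nuc[, c("x", "y", "z")])
  gaps <- proxy_dist(aa_xyz, nuc_xyz) -
    outer(aa_rad, vdw_radius(nuc$element), "+")
  contacted <- which(apply(gaps, 2, min) < margin)
  if (length(contacted) == 0L) {
    abort("classify_edge(): no qualifying contact atoms")
  }
  cont_names <- nuc$atom[contacted]
  base_contacts <- intersect(cont_names, base_names)
  if (length(base_contacts) == 0L) {
    return("phosphate")
  }
  # stacking test: donor/acceptor proximity and out-of-plane centroid
  don_acc_aa <- dimer$aa_atoms$element %in% c("N", "O")
  don_acc_nuc <- nuc$element %in% c("N", "O") & nuc$atom %in% base_names
  hb <- FALSE
  if (any(don_acc_aa) && any(don_acc_nuc)) {
    hb <- min(proxy_dist(aa_xyz[don_acc_aa, , drop = FALSE],
                         nuc_xyz[don_acc_nuc, , drop = FALSE])) < 3.5
  }
  if (!hb) {
    ring <- nuc_xyz[nuc$atom %in% base_ring_atoms(dimer$nuc_type), ,
                    drop = FALSE]
    ctr <- colMeans(ring)
    sv <- svd(sweep(ring, 2, ctr))
    normal <- sv$v[, 3]
    # centroid of the amino-acid atoms in contact with the base
    in_contact_aa <- which(apply(
      gaps[, contacted[cont_names %in% base_names], drop = FALSE], 1, min) <
        margin)
    cen <- colMeans(aa_xyz[in_contact_aa, , drop = FALSE])
    if (abs(sum((cen - ctr) * normal)) >= 2.5) {
      return("stacking")
    }
  }
  sets <- EDGE_SETS[[dimer$nuc_type]]
  votes <- vapply(sets, function(s) length(intersect(base_contacts, s)),
                  integer(1))
  if (all(votes == 0L)) {
    # base contacted outside the named edge atoms: fall back to nearest edge
    votes <- vapply(sets, function(s) {
      -min(proxy_dist(aa_xyz,
                      nuc_xyz[nuc$atom %in% s, , drop = FALSE]))
    }, numeric(1))
  }
  top <- which(votes == max(votes))
  if (length(top) > 1L) {
    pref <- if (dimer$nuc_type %in% PURINES) "hoogsteen" else "watson_crick"
    if (pref %in% names(sets)[top]) return(pref)
  }
  names(sets)[top[1]]
}

#' Evaluate the four criteria of specificity
#'
#' For every (amino acid, base, edge, medium) combination present in the
#' dimer table: (1) a geometrical cluster must exist at that edge; (2) the
#' lowest-mean cluster must be attractive (mean below zero) and be the most
#' stabilising cluster of the base's distribution; (3) little to nothing
#' besides that cluster may populate its interaction-energy span (overlap
#' fraction at most `overlap_threshold`); (4) the cluster mean must be
#' lower (signed) than the energy of any contact of the same amino acid
#' with any other base at the same edge -- by at least `margin` kJ/mol for
#' a strong verdict.
#'
#' @param dimer_table tibble with columns `aa`, `base`, `edge`, `energy`,
#'   `cluster` (cluster id within the (aa, base) distribution, `NA` when
#'   unclustered) and `eps_r`.
#' @param overlap_threshold criterion-3 bound on the overlap fraction.
#' @param margin criterion-4 cross-base margin, kJ/mol.
#' @return Tibble of verdicts: one row per (aa, base, edge, eps_r) with the
#'   four criterion flags, supporting numbers and a grade
#'   (`strong`/`ambiguous`/`none`).
#' @export
evaluate_specificity <- function(dimer_table, overlap_threshold = 0.3,
                                 margin = 4) {
  need <- c("aa", "base", "edge", "energy", "cluster", "eps_r")
  if (!all(need %in% colnames(dimer_table))) {
    abort(paste0("dimer_table must have columns: ",
                 paste(need, collapse = ", ")))
  }
  out <- list()
  for (eps in unique(dimer_table$eps_r)) {
    sub_eps <- dimer_table[dimer_table$eps_r == eps, , drop = FALSE]
    for (aa in unique(sub_eps$aa)) {
      tab_aa <- sub_eps[sub_eps$aa == aa, , drop = FALSE]
      for (base in unique(tab_aa$base)) {
        tab <- tab_aa[tab_aa$base == base, , drop = FALSE]
        cl_means <- tapply(tab$energy[!is.na(tab$cluster)],
                           tab$cluster[!is.na(tab$cluster)], mean)
        for (edge in unique(tab$edge)) {
          # clusters assigned to this edge by member majority
          cl_edges <- tapply(tab$edge[!is.na(tab$cluster)],
                             tab$cluster[!is.na(tab$cluster)],
                             function(e) names(sort(table(e),
                                                    decreasing = TRUE))[1])
          edge_cl <- names(cl_edges)[cl_edges == edge]
          c1 <- length(edge_cl) > 0L
          cluster_mean <- NA_real_
          overlap <- NA_real_
          cross_margin <- NA_real_
          c2 <- FALSE
          c3 <- FALSE
          c4 <- NA
          n_cluster <- 0L
          if (c1) {
            best <- edge_cl[which.min(cl_means[edge_cl])]
            cluster_mean <- cl_means[[best]]
            in_cl <- !is.na(tab$cluster) & tab$cluster == as.integer(best)
            n_cluster <- sum(in_cl)
            c2 <- cluster_mean < 0 &&
              abs(cluster_mean - min(cl_means)) < 1e-9
            span <- range(tab$energy[in_cl])
            others <- tab$energy[!in_cl]
            n_in_span <- sum(others >= span[1] & others <= span[2])
            overlap <- n_in_span / (n_in_span + n_cluster)
            c3 <- overlap <= overlap_threshold
            rivals <- sub_eps[sub_eps$aa == aa & sub_eps$base != base &
                                sub_eps$edge == edge, , drop = FALSE]
            if (nrow(rivals) > 0L) {
              cross_margin <- min(rivals$energy) - cluster_mean
              c4 <- cross_margin > 0
            } else {
              c4 <- NA  # verdict withheld: no rival profile at this edge
            }
          }
          grade <- if (isTRUE(c1) && isTRUE(c2) && isTRUE(c3) &&
                       isTRUE(c4)) {
            if (cross_margin >= margin) "strong" else "ambiguous"
          } else "none"
          out[[length(out) + 1L]] <- tibble(
            aa = aa, base = base, edge = edge, eps_r = eps,
            c1 = c1, c2 = c2, c3 = c3, c4 = c4, grade = grade,
            cluster_mean = cluster_mean, cluster_size = n_cluster,
            overlap = overlap, cross_base_margin = cross_margin)
        }
      }
    }
  }
  bind_rows(out)
}
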