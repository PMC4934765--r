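test_that("Freedman-Diaconis binning matches its defining formula", {
  edges <- freedman_diaconis_bins(1:8)
  # IQR (midpoint quartiles) = 4, n^(1/3) = 2 -> width 4, two bins
  expect_equal(diff(edges)[1], 4)
  expect_length(edges, 3L)
  expect_equal(edges[1], 1)

  # homogeneity: scaling the data scales the width
  set.seed(61)
  v <- rnorm(50)
  e1 <- freedman_diaconis_bins(v)
  e2 <- freedman_diaconis_bins(10 * v)
  expect_equal(diff(e2)[1], 10 * diff(e1)[1], tolerance = 1e-12)

  expect_length(freedman_diaconis_bins(rep(3, 10)), 2L)  # single bin
  expect_error(freedman_diaconis_bins(1:3), "at least 4")
})

test_that("profiles overlay the lowest-mean cluster on shared bins", {
  en <- c(-40, -41, -39, -20, -21, -19, -5, -4, -6, -3)
  prof <- build_profile(en, list(1:3, 4:6), eps_r = 4)
  expect_equal(prof$cluster_index, 1L)  # mean -40 beats mean -20
  expect_equal(sum(prof$dist_counts), length(en))
  expect_equal(sum(prof$cluster_counts), 3L)
  expect_true(all(prof$cluster_counts <= prof$dist_counts))

  # a single cluster equal to the whole distribution: identical histograms
  prof2 <- build_profile(en, list(seq_along(en)))
  expect_equal(prof2$cluster_counts, prof2$dist_counts)

  # planted low-lying cluster is fully left of the background bins
  set.seed(62)
  en3 <- c(rnorm(30, -40, 1), runif(100, -20, 0))
  prof3 <- build_profile(en3, list(1:30))
  occupied <- which(prof3$cluster_counts > 0)
  bg_occupied <- which(prof3$dist_counts - prof3$cluster_counts > 0)
  expect_lt(max(occupied), min(bg_occupied))
  # no clusters -> empty overlay
  prof4 <- build_profile(en, list())
  expect_true(all(prof4$cluster_counts == 0))
})

test_that("edge classification distinguishes the base faces", {
  rec <- motif_fixture_record(seq = "GCGAGCGC", position = 4, sd = 0,
                              seed = 63)
  ent <- make_entries(rec)
  ad <- Filter(function(d) d$nuc_type == "DA",
               find_contacts(rec, ent[1, ]))[[1]]
  expect_equal(classify_edge(ad), "hoogsteen")

  # side chain moved onto the phosphate only
  d2 <- ad
  op <- as.numeric(d2$nuc_atoms[d2$nuc_atoms$atom == "OP1",
                                c("x", "y", "z")])
  ctr <- colMeans(as.matrix(d2$nuc_atoms[
    d2$nuc_atoms$atom %in% basereadout:::BASE_HEAVY[["DA"]],
    c("x", "y", "z")]))
  dir <- (op - ctr) / sqrt(sum((op - ctr)^2))
  sc <- as.matrix(d2$aa_atoms[, c("x", "y", "z")])
  shift <- op + dir * 3.0 - sc[which(d2$aa_atoms$atom == "ND2"), ]
  d2$aa_atoms[, c("x", "y", "z")] <- sweep(sc, 2, shift, "+")
  expect_equal(classify_edge(d2), "phosphate")

  # apolar side chain stacked above the ring plane
  ring <- as.matrix(ad$nuc_atoms[
    ad$nuc_atoms$atom %in% basereadout:::base_ring_atoms("DA"),
    c("x", "y", "z")])
  rc <- colMeans(ring)
  sv <- svd(sweep(ring, 2, rc))
  normal <- sv$v[, 3]
  ile <- tibble::tibble(
    atom = c("CB", "CG1", "CG2", "CD1"), element = "C",
    x = rc[1] + normal[1] * 3.6 + c(0, 1.5, -0.8, 2.6),
    y = rc[2] + normal[2] * 3.6 + c(0, 0.4, 1.1, 0.6),
    z = rc[3] + normal[3] * 3.6 + c(0, 0.3, -0.5, 0.8))
  d3 <- basereadout:::new_contact_dimer("syn", "A", 1L, "ILE", ile,
                                        ad$nuc_chain, ad$nuc_resno, "DA",
                                        ad$nuc_atoms)
  expect_equal(classify_edge(d3), "stacking")

  # every base-contacting dimer gets exactly one valid label
  labs <- c("hoogsteen", "watson_crick", "sugar", "phosphate", "stacking")
  for (d in find_contacts(rec, ent[1, ])) {
    expect_true(classify_edge(d) %in% labs)
  }
})

make_verdict_table <- function(cluster_energies, background, rivals,
                               eps_r = 4) {
  tibble::tibble(
    aa = "ASN",
    base = c(rep("DA", length(cluster_energies) + length(background)),
             rep(c("DG", "DC", "DT"), length.out = length(rivals))),
    edge = "hoogsteen",
    energy = c(cluster_energies, background, rivals),
    cluster = c(rep(1L, length(cluster_energies)),
                rep(NA_integer_, length(background) + length(rivals))),
    eps_r = eps_r)
}

test_that("the four criteria grade constructed distributions correctly", {
  tab <- make_verdict_table(cluster_energies = c(-40, -41, -39, -40.5),
                            background = c(-10, -8, -5, -2),
                            rivals = c(-25, -20, -15, -24, -18))
  v <- evaluate_specificity(tab)
  va <- v[v$base == "DA", ]
  expect_true(all(unlist(va[, c("c1", "c2", "c3", "c4")])))
  expect_equal(va$grade, "strong")

  # overlapping background in the cluster span kills criterion 3
  tab2 <- make_verdict_table(cluster_energies = c(-40, -41, -39, -40.5),
                             background = c(-40.2, -39.5, -40.8, -39.2),
                             rivals = c(-25, -20, -15))
  v2 <- evaluate_specificity(tab2)
  expect_false(v2$c3[v2$base == "DA"])
  expect_equal(v2$grade[v2$base == "DA"], "none")

  # a rival contact below the cluster mean kills criterion 4
  tab3 <- make_verdict_table(cluster_energies = c(-30, -31, -29, -30),
                             background = c(-5, -4),
                             rivals = c(-45, -20))
  v3 <- evaluate_specificity(tab3)
  expect_false(v3$c4[v3$base == "DA"])

  # margin decides strong vs ambiguous
  tab4 <- make_verdict_table(cluster_energies = c(-30, -31, -29, -30),
                             background = c(-5, -4),
                             rivals = c(-28, -20))
  v4 <- evaluate_specificity(tab4, margin = 4)
  expect_equal(v4$grade[v4$base == "DA"], "ambiguous")
})

test_that("verdicts are monotone in the overlap threshold", {
  tab <- make_verdict_table(cluster_energies = c(-40, -41, -39, -40.5),
                            background = c(-40.2, -10, -8),
                            rivals = c(-25, -20))
  grades <- vapply(c(0.05, 0.2, 0.5, 0.9), function(thr) {
    evaluate_specificity(tab, overlap_threshold = thr)$grade[1]
  }, character(1))
  rank <- c(none = 0, ambiguous = 1, strong = 2)
  expect_true(all(diff(rank[grades]) >= 0))
})

test_that("removing the planted cluster removes the verdict", {
  tab <- make_verdict_table(cluster_energies = c(-40, -41, -39, -40.5),
                            background = c(-10, -8),
                            rivals = c(-25, -20))
  v <- evaluate_specificity(tab)
  expect_equal(v$grade[v$base == "DA"], "strong")
  tab2 <- tab[is.na(tab$cluster), ]
  v2 <- evaluate_specificity(tab2)
  expect_true(all(v2$grade[v2$base == "DA"] == "none"))
})
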