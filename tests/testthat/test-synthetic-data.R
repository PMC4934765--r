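test_that("idealized duplex has complementary antiparallel strands", {
  dup <- build_bdna_duplex("ACGT")
  res <- unique(dup$atoms[, c("chain", "resno", "resid")])
  expect_equal(nrow(res), 8L)  # 4 bp -> 8 nucleotides
  s1 <- res$resid[res$chain == "X"][order(res$resno[res$chain == "X"])]
  s2 <- res$resid[res$chain == "Y"][order(res$resno[res$chain == "Y"])]
  expect_equal(unname(basereadout:::DNA_COMP[rev(s1)]), s2)

  one <- build_bdna_duplex("A")
  expect_equal(nrow(unique(one$atoms[, c("chain", "resno")])), 2L)
  expect_error(build_bdna_duplex("ACXT"), "position 3")
})

test_that("duplex geometry matches the packaged fiber template", {
  dup <- build_bdna_duplex("ACGTACGT")
  for (ch in c("X", "Y")) {
    p <- dup$atoms[dup$atoms$chain == ch & dup$atoms$atom == "P", ]
    p <- p[order(p$resno), ]
    steps <- sqrt(rowSums(diff(as.matrix(p[, c("x", "y", "z")]))^2))
    expect_true(all(steps > 6.6 & steps < 7.0))
  }
})

test_that("5'-terminal residues lack the phosphate group", {
  dup <- build_bdna_duplex("ACGTAC")
  for (ch in c("X", "Y")) {
    first <- dup$atoms[dup$atoms$chain == ch & dup$atoms$resno == 1, ]
    expect_false(any(c("P", "OP1", "OP2") %in% first$atom))
    second <- dup$atoms[dup$atoms$chain == ch & dup$atoms$resno == 2, ]
    expect_true(all(c("P", "OP1", "OP2") %in% second$atom))
  }
})

test_that("fixtures are seed-deterministic with seed-dependent coordinates", {
  spec <- fixture_spec("GCGAGCGC",
                       planted_motifs = list(list(motif = "asn_ade_hoogsteen",
                                                  position = 4, sd = 0.2)),
                       background_poses = 2, seed = 42)
  t1 <- generate_complex_fixture(spec)
  t2 <- generate_complex_fixture(spec)
  expect_identical(as.character(t1), as.character(t2))

  spec2 <- spec
  spec2$seed <- 43L
  t3 <- generate_complex_fixture(spec2)
  expect_false(identical(as.character(t1), as.character(t3)))
  # same topology: identical atom/residue naming columns
  strip_xyz <- function(x) {
    l <- strsplit(x, "\n")[[1]]
    l <- l[startsWith(l, "ATOM")]
    substr(l, 1, 30)
  }
  expect_identical(strip_xyz(as.character(t1)), strip_xyz(as.character(t3)))
})

test_that("planted motif count matches recovered target-base dimers at sd 0", {
  rec <- motif_fixture_record(seq = "GCGAGCGC", position = 4, sd = 0,
                              background = 0, seed = 9)
  entries <- make_entries(rec)
  dimers <- find_contacts(rec, entries[1, ])
  dimers <- lapply(dimers, flag_base_directed)
  asn_ade <- Filter(function(d) {
    d$aa_type == "ASN" && d$nuc_type == "DA" && isTRUE(d$base_directed)
  }, dimers)
  expect_length(asn_ade, 1L)
  gt <- attr(generate_complex_fixture(
    fixture_spec("GCGAGCGC",
                 planted_motifs = list(list(motif = "asn_ade_hoogsteen",
                                            position = 4, sd = 0)),
                 seed = 9)), "ground_truth")
  expect_equal(asn_ade[[1]]$nuc_resno, gt$nuc_resno[1])
})

test_that("motif target position errors are caught", {
  spec <- fixture_spec("GCGAGCGC",
                       planted_motifs = list(list(motif = "asn_ade_hoogsteen",
                                                  position = 40, sd = 0)))
  expect_error(generate_complex_fixture(spec), "outside")
  spec2 <- fixture_spec("GCGAGCGC",
                        planted_motifs = list(list(motif = "asn_ade_hoogsteen",
                                                   position = 2, sd = 0)))
  expect_error(generate_complex_fixture(spec2), "neither")
})

test_that("pose distributions honour counts, spread and the cluster cap", {
  ctr <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 1.5, 0), 3, 3, byrow = TRUE)
  centers <- list(ctr, ctr + 10, ctr + 20)
  poses <- generate_pose_distribution(centers, c(10, 6, 4), spread = 0.5,
                                      background = 4, seed = 2)
  expect_length(poses, 24L)
  grp <- attr(poses, "group")
  for (g in 1:3) {
    for (k in which(grp == g)) {
      expect_lte(rmsd_fixed(poses[[k]], centers[[g]]), 0.5)
    }
  }
  bg <- which(grp == 0)
  for (k in bg) {
    for (ctr2 in centers) expect_gte(rmsd_fixed(poses[[k]], ctr2), 3)
    for (k2 in setdiff(bg, k)) {
      expect_gte(rmsd_fixed(poses[[k]], poses[[k2]]), 3)
    }
  }

  zero <- generate_pose_distribution(centers[1], 5, spread = 0, seed = 3)
  for (p in zero) expect_equal(p, centers[[1]])

  eight <- lapply(0:7, function(k) ctr + 8 * k)
  many <- generate_pose_distribution(eight, rep(10, 8), spread = 0.3,
                                     seed = 4)
  expect_length(greedy_cluster(many, threshold = 1.5, max_clusters = 6,
                               min_size = 4), 6L)
})

test_that("homolog families reach their target identities", {
  base <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 100,
                       replace = TRUE), collapse = "")
  fam <- generate_homolog_family(
    homolog_family_spec(base, c(1.0, 0.8, 0.5), seed = 7))
  expect_equal(fam$identity[1], 1)
  expect_identical(fam$sequence[1], base)
  expect_lte(abs(fam$identity[2] - 0.8), 0.02)
  expect_lte(abs(fam$identity[3] - 0.5), 0.02)
  expect_error(generate_homolog_family(
    homolog_family_spec(base, 0.0, seed = 1)), "unreachable")
  expect_error(homolog_family_spec("ACDEF", 0.5), "length")
})
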