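full_residue_atoms <- function(res, seed = 1) {
  # a residue instance taken from a planted fixture would do, but for
  # bookkeeping tests the ideal motif coordinates are enough
  tab <- basereadout:::motif_table()
  tab <- tab[tab$residue == res, ]
  tibble::tibble(atom = tab$atom, element = tab$element,
                 x = tab$x, y = tab$y, z = tab$z)
}

test_that("C-alpha fragments keep the right heavy atoms", {
  asn <- make_calpha_fragment(full_residue_atoms("ASN"), "ASN")
  expect_setequal(asn$atom, c("CA", "CB", "CG", "OD1", "ND2"))
  arg <- make_calpha_fragment(full_residue_atoms("ARG"), "ARG")
  expect_setequal(arg$atom,
                  c("CA", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"))
  expect_error(make_calpha_fragment(asn, "XYZ"), "nonstandard")
  # glycine reduces to a single carbon, proline keeps its ring
  gly_sp <- basereadout:::species_atoms("frag_GLY")
  expect_equal(sum(gly_sp$element != "H"), 1L)
  pro_sp <- basereadout:::species_atoms("frag_PRO")
  heavies <- pro_sp$element[pro_sp$element != "H"]
  expect_equal(sort(table(heavies), decreasing = TRUE),
               sort(table(c(rep("C", 4), "N")), decreasing = TRUE),
               ignore_attr = TRUE)
  expect_true("N" %in% pro_sp$atom)
})

test_that("O3' reconstruction reproduces the analytic construction", {
  o3 <- reconstruct_o3prime(c(0, 0, 0.3), c(1, 0, 0),
                            c(-0.5, 0.866, 0), c(-0.5, -0.866, 0))
  expect_equal(o3, c(0, 0, 1.910), tolerance = 1e-9)
  # equivariance under a random rotation
  set.seed(41)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  rot <- function(v) as.numeric(R %*% v)
  o3r <- reconstruct_o3prime(rot(c(0, 0, 0.3)), rot(c(1, 0, 0)),
                             rot(c(-0.5, 0.866, 0)),
                             rot(c(-0.5, -0.866, 0)))
  expect_equal(o3r, rot(c(0, 0, 1.910)), tolerance = 1e-9)
  expect_error(reconstruct_o3prime(c(0, 0, 0), c(1, 0, 0),
                                   c(-0.5, 0.866, 0), c(-0.5, -0.866, 0)),
               "plane")
})

test_that("O3' reconstruction keeps length and orthogonality on random inputs", {
  set.seed(42)
  for (k in 1:50) {
    P <- rnorm(3)
    OP1 <- P + rnorm(3)
    OP2 <- P + rnorm(3)
    O5 <- P + rnorm(3)
    n <- basereadout:::cross3(OP2 - OP1, O5 - OP1)
    if (sqrt(sum(n^2)) < 1e-3) next
    if (abs(sum((P - OP1) * n / sqrt(sum(n^2)))) < 1e-3) next
    o3 <- reconstruct_o3prime(P, OP1, OP2, O5)
    expect_equal(sqrt(sum((o3 - P)^2)), 1.610, tolerance = 1e-9)
    expect_lt(abs(sum((o3 - P) * (OP2 - OP1))) / sqrt(sum((OP2 - OP1)^2)),
              1e-6)
    expect_lt(abs(sum((o3 - P) * (O5 - OP1))) / sqrt(sum((O5 - OP1)^2)),
              1e-6)
    # same side of the plane as the phosphorus
    nn <- n / sqrt(sum(n^2))
    expect_gt(sum((o3 - OP1) * nn) * sum((P - OP1) * nn), 0)
  }
})

test_that("hydrogen addition follows the protonation rules", {
  # stripped adenine gains exactly 5 hydrogens, including H9
  dup <- build_bdna_duplex("GCGAGC")
  ade <- dup$atoms[dup$atoms$chain == "X" & dup$atoms$resno == 4,
                   c("atom", "element", "x", "y", "z")]
  ade <- ade[ade$atom %in% basereadout:::BASE_HEAVY[["DA"]], ]
  prot <- add_hydrogens(ade, "DA", "base")
  hs <- prot$atom[prot$element == "H"]
  expect_setequal(hs, c("H2", "H8", "H9", "H61", "H62"))
  # placed hydrogens sit at bonded distance from their parents
  n9 <- as.numeric(prot[prot$atom == "N9", c("x", "y", "z")])
  h9 <- as.numeric(prot[prot$atom == "H9", c("x", "y", "z")])
  expect_equal(sqrt(sum((n9 - h9)^2)), 1.01, tolerance = 0.05)
  # idempotent
  expect_equal(nrow(add_hydrogens(prot, "DA", "base")), nrow(prot))

  # histidine is N-epsilon protonated
  his_sp <- basereadout:::species_atoms("frag_HIS")
  expect_true("HE2" %in% his_sp$atom)
  expect_false("HD1" %in% his_sp$atom)
  # guanine keeps its N1 imino hydrogen (keto form), never N3
  gua_sp <- basereadout:::species_atoms("base_DG")
  expect_true("H1" %in% gua_sp$atom)
  expect_false("H3" %in% gua_sp$atom)
  expect_true("O6" %in% gua_sp$atom)
})

test_that("prepared monomer charges are exactly integral", {
  # worked examples: dNMP -1, basic fragment +1, stripped base 0
  rec <- motif_fixture_record(seq = "GCGAGCGC", position = 4, sd = 0,
                              seed = 43)
  ent <- make_entries(rec)
  ad <- Filter(function(d) d$nuc_type == "DA",
               find_contacts(rec, ent[1, ]))[[1]]
  nuc <- prepare_monomer(ad, "nuc")           # full dAMP
  expect_equal(sum(nuc$atoms$charge), -1, tolerance = 1e-9)
  expect_true("O3T" %in% nuc$atoms$atom)
  expect_true("HO3T" %in% nuc$atoms$atom)
  base <- prepare_monomer(strip_to_base(ad), "nuc")
  expect_equal(sum(base$atoms$charge), 0, tolerance = 1e-9)
  aa <- prepare_monomer(ad, "aa")
  expect_equal(sum(aa$atoms$charge), 0, tolerance = 1e-9)

  # every packaged species balances to its target total after preparation
  for (sp in unique(basereadout:::species_atoms()$species)) {
    res <- sub("^[a-z]+_", "", sp)
    kind <- unname(c(frag = "fragment", nuc = "dnmp", base = "base")[
      sub("_.*", "", sp)])
    tab <- basereadout:::species_atoms(sp)
    heavy <- tibble::tibble(atom = tab$atom, element = tab$element,
                            x = tab$x, y = tab$y, z = tab$z)[
                              tab$element != "H", ]
    prot <- add_hydrogens(heavy, res, kind)
    sys <- assign_parameters(prot, res, kind)
    target <- basereadout:::target_total_charge(res, kind)
    expect_equal(sum(sys$atoms$charge), target, tolerance = 1e-9)
  }
})

test_that("preparation only ever adds atoms", {
  rec <- motif_fixture_record(seq = "GCGAGCGC", position = 4, sd = 0,
                              seed = 44)
  ent <- make_entries(rec)
  ad <- Filter(function(d) d$nuc_type == "DA",
               find_contacts(rec, ent[1, ]))[[1]]
  ps <- prepare_dimer(strip_to_base(ad))
  for (nm in ad$aa_atoms$atom) {
    if (!nm %in% ps$atoms$atom) next
    before <- as.numeric(ad$aa_atoms[ad$aa_atoms$atom == nm,
                                     c("x", "y", "z")])
    after <- as.numeric(ps$atoms[ps$atoms$monomer == "A" &
                                   ps$atoms$atom == nm,
                                 c("x", "y", "z")])
    expect_equal(before, after)
  }
})
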