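test_that("closed-form nonbonded values are reproduced", {
  # two unit charges at 0.1 nm: Coulomb with the stated constant
  e <- engine_terms(two_atom_system(0.1, q = c(1, 1)))
  expect_equal(unname(e["coulomb"]), 1389.35485, tolerance = 1e-8)
  # Lennard-Jones minimum at 2^(1/6) sigma is exactly -eps
  sig <- 0.3
  e2 <- engine_terms(two_atom_system(2^(1 / 6) * sig,
                                     sigma = c(sig, sig),
                                     eps = c(0.5, 0.5)))
  expect_equal(unname(e2["lj"]), -0.5, tolerance = 1e-12)
  # Born ion: single charge, no descreening partner
  s <- two_atom_system(5, q = c(1, 0), eps_out = 80, gb = TRUE)
  s$gb_radius <- c(0.2 + 0.009, 0.15)  # intrinsic radius 0.2 after offset
  s$charge <- c(1, 0)
  e3 <- engine_terms(s)
  born <- -0.5 * (1 - 1 / 80) * 138.935485 / 0.2
  # the partner atom slightly descreens; compare against the oracle instead
  expect_equal(unname(e3["gb"]), unname(brute_energy(s)["gb"]),
               tolerance = 1e-12)
  s$xyz[2, ] <- c(500, 0, 0)  # partner far away: pure Born ion
  e4 <- engine_terms(s)
  expect_equal(unname(e4["gb"]), born, tolerance = 1e-6)
})

test_that("engine matches the brute-force evaluator on random systems", {
  for (seed in 1:8) {
    n <- sample(20:80, 1)
    s <- random_packed_system(n, seed = 1000 + seed, gb = seed %% 2 == 0)
    a <- engine_terms(s)
    b <- brute_energy(s)
    expect_equal(unname(a), unname(b), tolerance = 1e-11)
  }
})

test_that("energies are invariant under rigid motion and GB off equals vacuum", {
  s <- random_packed_system(40, seed = 77, gb = TRUE)
  e1 <- engine_terms(s)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  s2 <- s
  s2$xyz <- s$xyz %*% t(R) + rep(c(1, -2, 3), each = nrow(s$xyz))
  e2 <- engine_terms(s2)
  expect_equal(unname(e1), unname(e2), tolerance = 1e-6)

  s$gb <- FALSE
  s$sa <- FALSE
  vac <- engine_terms(s)
  expect_equal(unname(vac[c("bond", "angle", "dihedral", "lj", "coulomb")]),
               unname(e1[c("bond", "angle", "dihedral", "lj", "coulomb")]))
  expect_equal(unname(vac["gb"]) + unname(vac["sa"]), 0)
  # medium with eps_r = 1 disables GB and SA by construction
  expect_false(medium(1)$gb)
  expect_false(medium(1)$sa)
})

prepared_test_dimer <- function(seed = 51, sd = 0) {
  rec <- motif_fixture_record(seq = "GCGAGCGC", position = 4, sd = sd,
                              seed = seed)
  ent <- make_entries(rec)
  ad <- Filter(function(d) d$nuc_type == "DA",
               find_contacts(rec, ent[1, ]))[[1]]
  prepare_dimer(strip_to_base(flag_base_directed(ad)))
}

test_that("hydrogen minimisation descends and freezes heavy atoms", {
  ps <- prepared_test_dimer()
  e0 <- potential_energy(ps)$total
  m <- minimize_hydrogens(ps, medium(1))
  info <- attr(m, "minimization")
  expect_lte(info$energy, e0)
  heavy <- !ps$atoms$is_h
  expect_identical(as.matrix(ps$atoms[heavy, c("x", "y", "z")]),
                   as.matrix(m$atoms[heavy, c("x", "y", "z")]))
  # already minimised: coordinates essentially unchanged
  m2 <- minimize_hydrogens(m, medium(1))
  shift <- max(abs(as.matrix(m$atoms[, c("x", "y", "z")]) -
                     as.matrix(m2$atoms[, c("x", "y", "z")])))
  expect_lt(shift, 0.05)
})

test_that("a displaced hydrogen is restored to its equilibrium bond length", {
  ps <- prepared_test_dimer()
  h <- which(ps$atoms$is_h)[1]
  bnd <- ps$bonds[ps$bonds$i == h | ps$bonds$j == h, ][1, ]
  parent <- if (bnd$i == h) bnd$j else bnd$i
  dir <- as.numeric(ps$atoms[h, c("x", "y", "z")]) -
    as.numeric(ps$atoms[parent, c("x", "y", "z")])
  dir <- dir / sqrt(sum(dir^2))
  moved <- as.numeric(ps$atoms[h, c("x", "y", "z")]) + 0.2 * dir
  ps$atoms$x[h] <- moved[1]
  ps$atoms$y[h] <- moved[2]
  ps$atoms$z[h] <- moved[3]
  m <- minimize_hydrogens(ps, medium(1))
  d <- sqrt(sum((as.numeric(m$atoms[h, c("x", "y", "z")]) -
                   as.numeric(m$atoms[parent, c("x", "y", "z")]))^2))
  expect_equal(d / 10, bnd$r0, tolerance = 0.01)
})

test_that("interaction energy obeys its algebraic identity and limits", {
  ps <- prepared_test_dimer(seed = 52)
  ie <- interaction_energy(ps, medium(4))
  expect_equal(ie$e_int,
               ie$e_dimer_opt - ie$e_a_selfopt - ie$e_b_selfopt,
               tolerance = 1e-6)
  expect_equal(ie$e_int,
               ie$e_dimer_opt - (ie$e_a_dimerconf + ie$e_b_dimerconf) +
                 ie$deformation_a + ie$deformation_b,
               tolerance = 1e-9)
  # monomer labelling order does not matter
  ps2 <- ps
  ps2$atoms$monomer <- chartr("AB", "BA", ps2$atoms$monomer)
  ie2 <- interaction_energy(ps2, medium(4))
  expect_equal(ie2$e_int, ie$e_int, tolerance = 1e-6)

  # neutral monomers 500 Angstrom apart do not interact in vacuum
  far <- ps
  b_idx <- far$atoms$monomer == "B"
  far$atoms$x[b_idx] <- far$atoms$x[b_idx] + 500
  ie_far <- interaction_energy(far, medium(1))
  expect_equal(ie_far$e_int, 0, tolerance = 1e-3)

  # planted bidentate motif is attractive in a dielectric of 4
  expect_lt(ie$e_int, 0)
})
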