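test_that("fixture metadata and chains round-trip through parsing", {
  spec <- fixture_spec("GCGAGCGC",
                       planted_motifs = list(list(motif = "asn_ade_hoogsteen",
                                                  position = 4, sd = 0)),
                       resolution = 2.4, r_factor = 0.24, seed = 5)
  rec <- parse_structure(generate_complex_fixture(spec), id = "fx")
  expect_equal(rec$resolution, 2.4)
  expect_equal(rec$r_factor, 0.24)
  expect_setequal(rec$chains$type, c("protein", "dna"))
  expect_equal(sum(rec$chains$type == "dna"), 2L)
})

test_that("degenerate and malformed documents are handled", {
  hdr <- parse_structure("HEADER    EMPTY STRUCTURE", id = "h")
  expect_equal(nrow(hdr$chains), 0L)
  expect_true(is.na(hdr$resolution))
  expect_error(parse_structure(c("HEADER    X", "ATOM      1  CA")),
               "line 2")
  expect_error(parse_structure(""), "empty")
})

test_that("crystallographic filter applies strict and non-strict bounds", {
  mk <- function(res, rf) {
    structure(list(id = paste0("s", res, rf), atoms = tibble::tibble(),
                   chains = tibble::tibble(), resolution = res,
                   r_factor = rf),
              class = "structure_record")
  }
  kept <- filter_structures(list(mk(2.4, 0.24), mk(2.6, 0.20),
                                 mk(2.5, 0.20), mk(2.4, 0.26)))
  expect_equal(vapply(kept, function(r) r$id, character(1)), "s2.40.24")
  expect_warning(filter_structures(list(mk(NA, 0.2))), "missing")

  # order-independence and idempotence
  set <- list(mk(2.0, 0.1), mk(2.49, 0.25), mk(3.0, 0.1), mk(1.2, 0.3))
  ids <- function(l) sort(vapply(l, function(r) r$id, character(1)))
  expect_equal(ids(filter_structures(set)), ids(filter_structures(rev(set))))
  once <- filter_structures(set)
  expect_equal(ids(filter_structures(once)), ids(once))
})

test_that("duplex detection matches generator ground truth", {
  for (L in c(4, 7, 12, 20)) {
    set.seed(L)
    sq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                collapse = "")
    rec <- parse_structure(
      generate_complex_fixture(fixture_spec(sq, seed = L)), id = "d")
    dpx <- detect_duplexes(rec)
    expect_equal(nrow(dpx), 1L)
    expect_equal(dpx$n_bp, L)
  }
  rec3 <- parse_structure(
    generate_complex_fixture(fixture_spec("ACG", seed = 1)), id = "d3")
  expect_equal(nrow(detect_duplexes(rec3)), 0L)
})

test_that("single-stranded DNA yields no duplex", {
  rec <- parse_structure(
    generate_complex_fixture(fixture_spec("ACGTAC", seed = 2)), id = "ss")
  rec$atoms <- rec$atoms[rec$atoms$chain != "Y", ]
  rec$chains <- rec$chains[rec$chains$chain != "Y", ]
  expect_equal(nrow(detect_duplexes(rec)), 0L)
})

test_that("entries collapse homomultimers and split heteromers", {
  rec <- parse_structure(
    generate_complex_fixture(fixture_spec("GCGAGCGC", seed = 3)), id = "e")
  base <- rec
  # homodimer: duplicate protein chain A as chain B with identical sequence
  prot <- base$atoms[base$atoms$chain == "A", ]
  prot$chain <- "B"
  prot$x <- prot$x + 40
  rec_homo <- base
  rec_homo$atoms <- rbind(base$atoms, prot)
  rec_homo$chains <- rbind(base$chains,
                           tibble::tibble(chain = "B", type = "protein",
                                          sequence = base$chains$sequence[
                                            base$chains$chain == "A"]))
  ents <- make_entries(rec_homo)
  expect_equal(nrow(ents), 1L)
  expect_equal(ents$chain, "A")

  # heterodimer: chain B with a different sequence
  rec_het <- rec_homo
  rec_het$chains$sequence[rec_het$chains$chain == "B"] <- "AAAA"
  ents2 <- make_entries(rec_het)
  expect_equal(nrow(ents2), 2L)
  expect_setequal(ents2$chain, c("A", "B"))

  # DNA-only structure
  rec_dna <- base
  rec_dna$atoms <- base$atoms[base$atoms$chain != "A", ]
  rec_dna$chains <- base$chains[base$chains$chain != "A", ]
  expect_equal(nrow(make_entries(rec_dna)), 0L)
})
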