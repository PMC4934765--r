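random_rot_oracle <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

test_that("superposition recovers rigid motions exactly", {
  set.seed(11)
  pts <- matrix(rnorm(15), 5, 3)
  same <- superpose(pts, pts)
  expect_equal(same$rmsd, 0, tolerance = 1e-10)

  for (k in 1:5) {
    R <- random_rot_oracle()
    moved <- pts %*% t(R) + rep(rnorm(3, sd = 5), each = 5)
    fit <- superpose(moved, pts)
    expect_lt(fit$rmsd, 1e-6)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_equal(fit$apply(moved), pts, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line), "collinear")
})

test_that("superposition matches a local rotation-grid search", {
  set.seed(12)
  pts <- matrix(rnorm(15, sd = 2), 5, 3)
  noisy <- pts + matrix(rnorm(15, sd = 0.12), 5, 3)
  fit <- superpose(noisy, pts)
  oracle <- grid_superpose_rmsd(noisy, pts, span_deg = 10, step_deg = 1)
  expect_lte(fit$rmsd, oracle + 1e-3)
  expect_lt(abs(fit$rmsd - oracle), 0.02)
  # fitted RMSD never exceeds the unfitted RMSD
  expect_lte(fit$rmsd, rmsd_fixed(noisy, pts))
})

test_that("distributions share the packaged base frame", {
  rec1 <- motif_fixture_record(seq = "GCGAGCGC", position = 4, sd = 0,
                               seed = 31)
  rec2 <- motif_fixture_record(seq = "TTGACGTC", position = 4, sd = 0,
                               seed = 32)
  dimers <- c(
    Filter(function(d) d$nuc_type == "DA",
           find_contacts(rec1, make_entries(rec1)[1, ])),
    Filter(function(d) d$nuc_type == "DA",
           find_contacts(rec2, make_entries(rec2)[1, ])))
  dimers <- lapply(lapply(dimers, flag_base_directed), strip_to_base)
  dist <- build_distribution(dimers)
  expect_s3_class(dist, "dimer_distribution")
  for (d in dist$dimers) {
    expect_lt(d$base_fit_rmsd, 0.5)
    idx <- match(rownames(dist$template), d$nuc_atoms$atom)
    expect_lt(rmsd_fixed(as.matrix(d$nuc_atoms[idx, c("x", "y", "z")]),
                         dist$template), 0.5)
  }
  # identical sd = 0 poses land on identical side-chain coordinates
  two <- build_distribution(list(dimers[[1]], dimers[[1]]))
  expect_equal(two$dimers[[1]]$aa_atoms, two$dimers[[2]]$aa_atoms)
  expect_error(build_distribution(list()), "no dimers")
})

test_that("greedy clustering recovers planted structure", {
  ctr <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 1.5, 0), 3, 3, byrow = TRUE)
  poses <- generate_pose_distribution(list(ctr, ctr + 12), c(10, 6),
                                      spread = 0.5, background = 4,
                                      seed = 13)
  cls <- greedy_cluster(poses, threshold = 1.5, max_clusters = 6,
                        min_size = 4)
  expect_equal(vapply(cls, function(cl) length(cl$members), integer(1)),
               c(10L, 6L))
  # representative is a member; member RMSDs are below the threshold
  for (cl in cls) {
    expect_true(cl$representative %in% cl$members)
    expect_true(all(cl$rmsd < 1.5))
  }
  # all poses pairwise apart -> no clusters at min_size 2
  apart <- generate_pose_distribution(
    lapply(0:5, function(k) ctr + 6 * k), rep(1, 6), spread = 0,
    seed = 14)
  expect_length(greedy_cluster(apart, min_size = 2), 0L)
})

test_that("clustering agrees with the brute-force oracle on random inputs", {
  ctr <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 1.5, 0), 3, 3, byrow = TRUE)
  for (seed in 15:19) {
    set.seed(seed)
    ng <- sample(1:7, 1)
    pops <- sample(4:12, ng, replace = TRUE)
    centers <- lapply(seq_len(ng), function(k) ctr + 7 * k)
    poses <- generate_pose_distribution(centers, pops, spread = 0.45,
                                        background = sample(0:4, 1),
                                        seed = seed)
    cls <- greedy_cluster(poses)
    sizes <- vapply(cls, function(cl) length(cl$members), integer(1))
    expect_equal(sizes, brute_greedy_cluster(poses))
    # sizes non-increasing; clusters pairwise disjoint
    expect_true(all(diff(sizes) <= 0))
    all_members <- unlist(lapply(cls, function(cl) cl$members))
    expect_equal(anyDuplicated(all_members), 0L)
    expect_lte(length(all_members), length(poses))
  }
})
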