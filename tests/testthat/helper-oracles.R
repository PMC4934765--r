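# Independent oracles used across the test suite.  These are deliberately
# naive re-implementations (scalar loops, enumeration, closed forms) kept
# separate from the package's own code paths.

KE_ORACLE <- 138.935485

cross_oracle <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ---- brute-force molecular-mechanics energy (packed-system format) -------
brute_energy <- function(s) {
  xyz <- s$xyz
  n <- nrow(xyz)
  dd <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  e_bond <- 0
  if (nrow(s$bonds) > 0) {
    for (r in seq_len(nrow(s$bonds))) {
      e_bond <- e_bond + 0.5 * s$bond_par[r, 2] *
        (dd(s$bonds[r, 1], s$bonds[r, 2]) - s$bond_par[r, 1])^2
    }
  }
  e_ang <- 0
  if (nrow(s$angles) > 0) {
    for (r in seq_len(nrow(s$angles))) {
      i <- s$angles[r, 1]; j <- s$angles[r, 2]; k <- s$angles[r, 3]
      v1 <- xyz[i, ] - xyz[j, ]
      v2 <- xyz[k, ] - xyz[j, ]
      cosv <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      cosv <- min(1, max(-1, cosv))
      e_ang <- e_ang + 0.5 * s$angle_par[r, 2] *
        (acos(cosv) - s$angle_par[r, 1])^2
    }
  }
  e_dih <- 0
  if (nrow(s$dihedrals) > 0) {
    for (r in seq_len(nrow(s$dihedrals))) {
      i <- s$dihedrals[r, 1]; j <- s$dihedrals[r, 2]
      k <- s$dihedrals[r, 3]; l <- s$dihedrals[r, 4]
      b1 <- xyz[j, ] - xyz[i, ]
      b2 <- xyz[k, ] - xyz[j, ]
      b3 <- xyz[l, ] - xyz[k, ]
      n1 <- cross_oracle(b1, b2)
      n2 <- cross_oracle(b2, b3)
      phi <- atan2(sum(cross_oracle(n1, n2) * b2 / sqrt(sum(b2^2))),
                   sum(n1 * n2))
      e_dih <- e_dih + s$dihedral_par[r, 1] *
        (1 + cos(s$dihedral_par[r, 2] * phi - s$dihedral_par[r, 3]))
    }
  }
  cls <- matrix(0L, n, n)
  if (nrow(s$excl) > 0) {
    for (r in seq_len(nrow(s$excl))) {
      cls[s$excl[r, 1], s$excl[r, 2]] <- 1L
      cls[s$excl[r, 2], s$excl[r, 1]] <- 1L
    }
  }
  if (nrow(s$pairs14) > 0) {
    for (r in seq_len(nrow(s$pairs14))) {
      cls[s$pairs14[r, 1], s$pairs14[r, 2]] <- 2L
      cls[s$pairs14[r, 2], s$pairs14[r, 1]] <- 2L
    }
  }
  e_lj <- 0
  e_coul <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (cls[i, j] == 1L) next
      r <- dd(i, j)
      qq <- KE_ORACLE * s$charge[i] * s$charge[j] / r
      sij <- (s$sigma[i] + s$sigma[j]) / 2
      eij <- sqrt(s$eps[i] * s$eps[j])
      lj <- 0
      if (eij > 0 && sij > 0) {
        sr6 <- (sij / r)^6
        lj <- 4 * eij * (sr6^2 - sr6)
      }
      if (cls[i, j] == 2L) {
        qq <- qq / 1.2
        lj <- lj / 2
      }
      e_coul <- e_coul + qq
      e_lj <- e_lj + lj
    }
  }
  e_gb <- 0
  e_sa <- 0
  if (isTRUE(s$gb)) {
    rho <- s$gb_radius - 0.009
    Rb <- numeric(n)
    for (i in seq_len(n)) {
      inv <- 1 / rho[i]
      for (j in seq_len(n)) {
        if (j == i) next
        sj <- s$gb_screen[j] * rho[j]
        r <- dd(i, j)
        if (rho[i] >= r + sj) next
        U <- r + sj
        L <- max(rho[i], abs(r - sj))
        term <- 0.5 * (1 / L - 1 / U +
                         0.25 * (r - sj^2 / r) * (1 / U^2 - 1 / L^2) +
                         0.5 / r * log(L / U))
        if (rho[i] < sj - r) term <- term + (1 / rho[i] - 1 / L)
        inv <- inv - term
      }
      Rb[i] <- 1 / inv
    }
    pref <- -0.5 * KE_ORACLE * (1 - 1 / s$eps_out)
    for (i in seq_len(n)) {
      e_gb <- e_gb + pref * s$charge[i]^2 / Rb[i]
      if (i < n) {
        for (j in seq(i + 1, n)) {
          r <- dd(i, j)
          f <- sqrt(r^2 + Rb[i] * Rb[j] * exp(-r^2 / (4 * Rb[i] * Rb[j])))
          e_gb <- e_gb + 2 * pref * s$charge[i] * s$charge[j] / f
        }
      }
    }
    if (isTRUE(s$sa)) {
      for (i in seq_len(n)) {
        e_sa <- e_sa + s$sa_gamma * 4 * pi *
          (s$gb_radius[i] + 0.14)^2 * (s$gb_radius[i] / Rb[i])^6
      }
    }
  }
  c(bond = e_bond, angle = e_ang, dihedral = e_dih, lj = e_lj,
    coulomb = e_coul, gb = e_gb, sa = e_sa)
}

# random packed system with sane geometry (coordinates on a jittered grid)
random_packed_system <- function(n, seed, gb = FALSE, charged = TRUE) {
  set.seed(seed)
  side <- ceiling(n^(1 / 3))
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                z = seq_len(side)))[seq_len(n), ] * 0.25
  xyz <- grid + matrix(runif(3 * n, -0.05, 0.05), ncol = 3)
  nb <- sample(0:min(2 * n, 40), 1)
  bonds <- if (nb > 0) {
    t(replicate(nb, sample(n, 2)))
  } else matrix(integer(), 0, 2)
  na <- sample(0:20, 1)
  angles <- if (na > 0 && n >= 3) {
    t(replicate(na, sample(n, 3)))
  } else matrix(integer(), 0, 3)
  nd <- sample(0:20, 1)
  dihedrals <- if (nd > 0 && n >= 4) {
    t(replicate(nd, sample(n, 4)))
  } else matrix(integer(), 0, 4)
  pr <- t(combn(n, 2))
  take <- sample(nrow(pr), min(nrow(pr), 30))
  excl <- pr[take[seq_len(15)], , drop = FALSE]
  p14 <- pr[take[16:min(30, length(take))], , drop = FALSE]
  p14 <- p14[!(paste(p14[, 1], p14[, 2]) %in% paste(excl[, 1], excl[, 2])), ,
             drop = FALSE]
  list(xyz = xyz,
       charge = if (charged) runif(n, -0.9, 0.9) else rep(0, n),
       sigma = runif(n, 0.1, 0.35), eps = runif(n, 0.01, 1),
       gb_radius = runif(n, 0.1, 0.2), gb_screen = runif(n, 0.7, 1),
       bonds = storage_int2(bonds),
       bond_par = cbind(runif(max(nrow(bonds), 0), 0.1, 0.2),
                        runif(max(nrow(bonds), 0), 1e4, 4e5)),
       angles = storage_int2(angles),
       angle_par = cbind(runif(nrow(angles), 0.5, pi - 0.5),
                         runif(nrow(angles), 100, 600)),
       dihedrals = storage_int2(dihedrals),
       dihedral_par = cbind(runif(nrow(dihedrals), 0, 30),
                            sample(1:4, nrow(dihedrals), replace = TRUE),
                            runif(nrow(dihedrals), 0, 2 * pi)),
       excl = storage_int2(excl), pairs14 = storage_int2(p14),
       eps_out = sample(c(4, 16, 80), 1), gb = gb, sa = gb,
       sa_gamma = 2.05)
}

storage_int2 <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  m
}

engine_terms <- function(packed) {
  basereadout:::energy_terms_cpp(packed)
}

# ---- global-alignment score oracles --------------------------------------
# memoised recursion over (i, j, last-move): mathematically the maximum over
# every global alignment with affine gap cost open + L * extend
enum_align_score <- function(a, b, gap_open = 10, gap_extend = 0.5,
                             mat = NULL) {
  if (is.null(mat)) mat <- basereadout:::blosum62_matrix()
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    if (i > n && j > m) return(0)
    key <- paste(i, j, state)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, mat[A[i], B[j]] + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= n) {
      pen <- gap_extend + if (state != 1L) gap_open else 0
      best <- max(best, -pen + rec(i + 1L, j, 1L))
    }
    if (j <= m) {
      pen <- gap_extend + if (state != 2L) gap_open else 0
      best <- max(best, -pen + rec(i, j + 1L, 2L))
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, 0L)
}

# literal enumeration of every alignment of two tiny strings, scored by an
# independent alignment-string scorer; validates enum_align_score itself
score_alignment_strings <- function(ra, rb, gap_open = 10, gap_extend = 0.5,
                                    mat = NULL) {
  if (is.null(mat)) mat <- basereadout:::blosum62_matrix()
  ca <- strsplit(ra, "")[[1]]
  cb <- strsplit(rb, "")[[1]]
  sc <- 0
  for (k in seq_along(ca)) {
    if (ca[k] != "-" && cb[k] != "-") sc <- sc + mat[ca[k], cb[k]]
  }
  gap_cost <- function(row) {
    r <- rle(row == "-")
    runs <- r$lengths[r$values]
    sum(gap_open + runs * gap_extend)
  }
  sc - gap_cost(ca) - gap_cost(cb)
}

all_alignments_best <- function(a, b, ...) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, ra, rb) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, score_alignment_strings(paste(ra, collapse = ""),
                                                 paste(rb, collapse = ""),
                                                 ...))
      return(invisible())
    }
    if (i <= length(A) && j <= length(B)) {
      rec(i + 1L, j + 1L, c(ra, A[i]), c(rb, B[j]))
    }
    if (i <= length(A)) rec(i + 1L, j, c(ra, A[i]), c(rb, "-"))
    if (j <= length(B)) rec(i, j + 1L, c(ra, "-"), c(rb, B[j]))
    invisible()
  }
  rec(1L, 1L, character(0), character(0))
  best
}

# ---- rotation-grid superposition oracle ----------------------------------
# local exhaustive Euler-angle grid around the identity with analytic
# centroid alignment; valid when the optimal rotation is a small one
grid_superpose_rmsd <- function(mobile, reference, span_deg = 15,
                                step_deg = 1) {
  angs <- seq(-span_deg, span_deg, by = step_deg) * pi / 180
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  best <- Inf
  rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  for (a1 in angs) {
    R1 <- rz(a1)
    for (a2 in angs) {
      R2 <- ry(a2) %*% R1
      for (a3 in angs) {
        R <- rx(a3) %*% R2
        v <- sqrt(mean(rowSums((A %*% t(R) - B)^2)))
        if (v < best) best <- v
      }
    }
  }
  best
}

# ---- brute-force greedy clustering ---------------------------------------
brute_greedy_cluster <- function(poses, threshold = 1.5, max_clusters = 6,
                                 min_size = 4) {
  n <- length(poses)
  prmsd <- function(p, q) sqrt(mean(rowSums((p - q)^2)))
  active <- rep(TRUE, n)
  sizes <- integer(0)
  repeat {
    if (length(sizes) >= max_clusters || !any(active)) break
    counts <- integer(n)
    for (i in which(active)) {
      for (j in which(active)) {
        if (prmsd(poses[[i]], poses[[j]]) < threshold) {
          counts[i] <- counts[i] + 1L
        }
      }
    }
    rep_i <- which.max(counts)
    members <- which(active)
    members <- members[vapply(members, function(j)
      prmsd(poses[[rep_i]], poses[[j]]) < threshold, logical(1))]
    if (length(members) < min_size) break
    sizes <- c(sizes, length(members))
    active[members] <- FALSE
  }
  sizes
}

# ---- shared fixtures ------------------------------------------------------
motif_fixture_record <- function(seq = "GCGAGCGC", motif = "asn_ade_hoogsteen",
                                 position = 4, sd = 0, background = 0,
                                 seed = 5, ...) {
  spec <- fixture_spec(seq,
                       planted_motifs = list(list(motif = motif,
                                                  position = position,
                                                  sd = sd)),
                       background_poses = background, seed = seed, ...)
  parse_structure(generate_complex_fixture(spec), id = paste0("fix", seed))
}

# minimal two-atom packed system for closed-form checks
two_atom_system <- function(r_nm, q = c(0, 0), sigma = c(0, 0),
                            eps = c(0, 0), eps_out = 1, gb = FALSE) {
  list(xyz = rbind(c(0, 0, 0), c(r_nm, 0, 0)), charge = q, sigma = sigma,
       eps = eps, gb_radius = c(0.15, 0.15), gb_screen = c(0.8, 0.8),
       bonds = storage_int2(matrix(integer(), 0, 2)),
       bond_par = matrix(numeric(), 0, 2),
       angles = storage_int2(matrix(integer(), 0, 3)),
       angle_par = matrix(numeric(), 0, 2),
       dihedrals = storage_int2(matrix(integer(), 0, 4)),
       dihedral_par = matrix(numeric(), 0, 3),
       excl = storage_int2(matrix(integer(), 0, 2)),
       pairs14 = storage_int2(matrix(integer(), 0, 2)),
       eps_out = eps_out, gb = gb, sa = FALSE, sa_gamma = 2.05)
}

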