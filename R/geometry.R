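#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' matched coordinate sets, using the SVD construction with a determinant
#' guard so that a reflection is never returned.
#'
#' @param mobile n x 3 matrix moved onto `reference`.
#' @param reference n x 3 matrix, same row order as `mobile`.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `x %*% t(rotation) + translation`), `rmsd` after the fit,
#'   and `apply`, a function transforming any m x 3 matrix.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L) {
    abort("superpose() needs two equally sized n x 3 coordinate matrices")
  }
  if (nrow(mobile) < 3L) {
    abort("superpose() needs at least 3 matched atoms")
  }
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  # collinearity check: rank of the point cloud
  if (min(svd(A)$d[2], svd(B)$d[2]) < 1e-8) {
    abort("superpose(): degenerate (collinear) point set")
  }
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- cr - as.numeric(R %*% cm)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  apply_fun <- function(x) {
    sweep(as.matrix(x), 2, cm) %*% t(R) + rep(cr, each = nrow(as.matrix(x)))
  }
  list(rotation = R, translation = tr, rmsd = rmsd, apply = apply_fun)
}

#' Root-mean-square deviation without refitting
#' @param a,b matched n x 3 coordinate matrices.
#' @return RMSD in the input units.
#' @export
rmsd_fixed <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  sqrt(mean(rowSums((a - b)^2)))
}

#' Superpose all dimers of one type into the common base frame
#'
#' Every dimer's DNA base heavy atoms are least-squares fitted onto the
#' packaged base template of the respective type and the amino-acid atoms are
#' carried along rigidly, giving the three-dimensional distribution of the
#' side chains around the (fixed) nucleotide.
#'
#' @param dimers list of contact dimers of a single amino-acid x base type
#'   (see [find_contacts()]).
#' @return An object of class `dimer_distribution`.
#' @export
build_distribution <- function(dimers) {
  if (length(dimers) == 0L) abort("build_distribution(): no dimers supplied")
  aa <- unique(vapply(dimers, function(d) d$aa_type, character(1)))
  base <- unique(vapply(dimers, function(d) d$nuc_type, character(1)))
  if (length(aa) != 1L || length(base) != 1L) {
    abort("build_distribution(): dimers must share one amino-acid and one base type")
  }
  tmpl <- species_atoms(paste0("base_", base))
  tmpl <- tmpl[tmpl$element != "H", , drop = FALSE]
  tmpl_xyz <- as.matrix(tmpl[, c("x", "y", "z")])
  rownames(tmpl_xyz) <- tmpl$atom

  kept <- list()
  dropped <- 0L
  for (d in dimers) {
    nuc <- d$nuc_atoms
    idx <- match(rownames(tmpl_xyz), nuc$atom)
    if (anyNA(idx)) {
      dropped <- dropped + 1L
      next
    }
    fit <- superpose(as.matrix(nuc[idx, c("x", "y", "z")]), tmpl_xyz)
    d2 <- d
    d2$nuc_atoms[, c("x", "y", "z")] <- fit$apply(as.matrix(nuc[, c("x", "y", "z")]))
    d2$aa_atoms[, c("x", "y", "z")] <- fit$apply(as.matrix(d$aa_atoms[, c("x", "y", "z")]))
    d2$base_fit_rmsd <- fit$rmsd
    kept[[length(kept) + 1L]] <- d2
  }
  if (dropped > 0L) {
    warn(paste0(dropped, " dimer(s) dropped: missing base heavy atoms"))
  }
  structure(
    list(aa_type = aa, base_type = base,
         set = if (isTRUE(dimers[[1]]$stripped)) "stripped" else
           if (isTRUE(dimers[[1]]$base_directed)) "base-directed" else "all",
         dimers = kept, template = tmpl_xyz),
    class = "dimer_distribution"
  )
}

#' @export
print.dimer_distribution <- function(x, ...) {
  cat("<dimer_distribution> ", x$aa_type, " x ", x$base_type,
      " (", x$set, "), ", length(x$dimers), " dimers\n", sep = "")
  invisible(x)
}

#' Reference-atom coordinates of each pose in a distribution
#' @keywords internal
pose_ref_coords <- function(distribution) {
  refs <- reference_atoms(distribution$aa_type)
  lapply(distribution$dimers, function(d) {
    idx <- match(refs, d$aa_atoms$atom)
    if (anyNA(idx)) return(NULL)
    as.matrix(d$aa_atoms[idx, c("x", "y", "z")])
  })
}

#' Greedy RMSD clustering of superposed side-chain poses
#'
#' The pose distance is the RMSD over the amino acid's three reference atoms
#' without re-superposition (the poses already share the base frame).  The
#' pose with the most neighbours within `threshold` becomes a cluster
#' representative and is removed together with its neighbours; this repeats
#' until `max_clusters` clusters have been found or the next cluster would be
#' smaller than `min_size`.  Ties in neighbour count go to the lowest pose
#' index for determinism.
#'
#' @param distribution a `dimer_distribution` (or a list of 3 x 3
#'   reference-atom coordinate matrices).
#' @param threshold neighbour RMSD threshold in Angstrom.
#' @param max_clusters cap on the number of clusters.
#' @param min_size smallest cluster size still considered significant.
#' @return List of clusters, each with `representative` (pose index),
#'   `members` (pose indices) and `rmsd` (member RMSD to the representative).
#' @export
greedy_cluster <- function(distribution, threshold = 1.5, max_clusters = 6,
                           min_size = 4) {
  poses <- if (inherits(distribution, "dimer_distribution")) {
    pose_ref_coords(distribution)
  } else {
    distribution
  }
  keep <- !vapply(poses, is.null, logical(1))
  idx_all <- which(keep)
  n <- length(idx_all)
  if (n == 0L) return(list())
  flat <- t(vapply(poses[idx_all], function(m) as.numeric(t(m)),
                   numeric(length(as.numeric(t(poses[[idx_all[1]]]))))))
  npts <- ncol(flat) / 3
  d2 <- as.matrix(stats::dist(flat))^2 / npts   # squared ref-atom RMSD
  rms <- sqrt(d2)

  active <- rep(TRUE, n)
  clusters <- list()
  while (length(clusters) < max_clusters && any(active)) {
    counts <- rowSums(rms[, active, drop = FALSE] < threshold) * active
    # rowSums over active columns counts self once for active rows
    best <- which.max(counts)             # ties -> lowest index
    members <- which(active & rms[best, ] < threshold)
    if (length(members) < min_size) break
    clusters[[length(clusters) + 1L]] <- list(
      representative = idx_all[best],
      members = idx_all[members],
      rmsd = setNames(rms[best, members], idx_all[members])
    )
    active[members] <- FALSE
  }
  clusters
}
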