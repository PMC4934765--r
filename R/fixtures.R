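#' Specification of a synthetic protein-DNA complex fixture
#'
#' Describes a PDB fixture with an idealized duplex, side chains planted in
#' canonical binding-motif geometries (optionally perturbed by rigid-body
#' noise), and background side-chain poses in random non-repeating
#' orientations near the DNA.
#'
#' @param dna_sequence base-letter string for the first strand, 5' to 3'.
#' @param planted_motifs list of motif entries, each a list with `motif` (a
#'   packaged template name, see [motif_templates()]), `position` (base-pair
#'   position along the duplex), `sd` (pose-noise standard deviation in
#'   Angstrom) and optionally `chain` (protein chain letter).
#' @param background_poses number of random non-clustering side-chain
#'   placements near the DNA.
#' @param background_residue residue type used for background poses (one of
#'   the packaged motif residues).
#' @param background_positions base-pair positions eligible for background
#'   poses (default: all non-terminal).
#' @param n_protein_chains number of protein chains.
#' @param n_flank far-away stub residues appended per protein chain; their
#'   random ALA/GLY pattern gives every chain a distinct sequence.
#' @param resolution,r_factor crystallographic metadata written to the
#'   REMARK records.
#' @param seed integer; fully determines the output.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(dna_sequence, planted_motifs = list(),
                         background_poses = 0L,
                         background_residue = "ASN",
                         background_positions = NULL,
                         n_protein_chains = 1L, n_flank = 6L,
                         resolution = 2.0, r_factor = 0.20, seed = 1L) {
  stopifnot(nchar(dna_sequence) >= 1L, n_protein_chains >= 1L,
            n_protein_chains <= 8L, background_poses >= 0L)
  for (m in planted_motifs) {
    if (is.null(m$motif) || is.null(m$position)) {
      abort("each planted motif needs fields 'motif' and 'position'")
    }
    if (!is.null(m$sd) && m$sd < 0) abort("pose-noise sd must be >= 0")
  }
  structure(list(dna_sequence = toupper(dna_sequence),
                 planted_motifs = planted_motifs,
                 background_poses = as.integer(background_poses),
                 background_residue = toupper(background_residue),
                 background_positions = background_positions,
                 n_protein_chains = as.integer(n_protein_chains),
                 n_flank = as.integer(n_flank),
                 resolution = resolution, r_factor = r_factor,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix, determinant fixed
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Rigid-body pose noise
#'
#' Perturbs every atom with isotropic Gaussian noise and refits the original
#' internal geometry rigidly onto the noisy cloud, so the chemistry stays
#' valid while the pose moves.
#'
#' @param coords n x 3 matrix (Angstrom).
#' @param sd noise standard deviation in Angstrom.
#' @return Perturbed n x 3 matrix.
#' @export
perturb_pose <- function(coords, sd) {
  if (sd == 0) return(coords)
  noisy <- coords + matrix(rnorm(length(coords), sd = sd), ncol = 3)
  superpose(coords, noisy)$apply(coords)
}

motif_for_residue <- function(residue) {
  tab <- motif_table()
  hit <- unique(tab$motif[tab$residue == residue])
  if (length(hit) == 0L) {
    abort(paste0("no packaged motif template uses residue ", residue))
  }
  hit[1]
}

# stub backbone used for the far-away flanking residues
flank_stub <- function(resid) {
  base <- rbind(N = c(0, 0, 0), CA = c(1.45, 0, 0), C = c(2.39, 1.10, 0),
                O = c(2.00, 2.23, 0.15))
  el <- c("N", "C", "C", "O")
  if (resid == "ALA") {
    base <- rbind(base, CB = c(1.95, -0.90, 1.15))
    el <- c(el, "C")
  }
  tibble(atom = rownames(base), element = el,
         x = base[, 1], y = base[, 2], z = base[, 3])
}

#' Generate a synthetic protein-DNA complex as PDB text
#'
#' Builds the duplex for `spec$dna_sequence`, plants each requested motif by
#' superposing the packaged template onto the target base (then applying
#' rigid pose noise), adds background side chains in random non-repeating
#' orientations in contact with randomly chosen non-terminal nucleotides,
#' appends far-away stub residues so every protein chain has a distinct
#' sequence, and serialises everything as a legal PDB document with REMARK 2
#' resolution and REMARK 3 R-factor records.
#'
#' @param spec a [fixture_spec()].
#' @param file optional path; when given the document is also written there.
#' @return PDB text as a single string; the planted ground truth is attached
#'   as attribute `"ground_truth"` (a tibble).
#' @export
generate_complex_fixture <- function(spec, file = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    dup <- build_bdna_duplex(spec$dna_sequence)
    L <- nchar(spec$dna_sequence)
    s1 <- strsplit(spec$dna_sequence, "")[[1]]

    chains <- LETTERS[seq_len(spec$n_protein_chains)]
    placed <- stats::setNames(vector("list", length(chains)), chains)
    truth <- list()

    locate_base <- function(position, base_letter) {
      if (position < 1L || position > L) {
        abort(paste0("motif target position ", position,
                     " outside the ", L, "-bp duplex"))
      }
      if (s1[position] == base_letter) {
        list(chain = dup$chain_ids[1], resno = position)
      } else if (unname(DNA_COMP[paste0("D", s1[position])]) ==
                 paste0("D", base_letter)) {
        list(chain = dup$chain_ids[2], resno = L - position + 1L)
      } else {
        abort(paste0("position ", position, " provides neither ",
                     base_letter, " nor its complement"))
      }
    }

    plant_motif <- function(motif_id, position, sd) {
      tab <- motif_table(motif_id)
      base_sp <- tab$base_species[1]
      base_letter <- substr(base_sp, 6, 7)
      loc <- locate_base(position, substr(base_letter, 2, 2))
      if (loc$resno == 1L) {
        abort("motif target is a 5'-terminal nucleotide; pick another position")
      }
      target <- duplex_residue(dup, loc$chain, loc$resno)
      tmpl <- species_atoms(base_sp)
      tmpl <- tmpl[tmpl$element != "H", , drop = FALSE]
      idx <- match(tmpl$atom, target$atom)
      fit <- superpose(as.matrix(tmpl[, c("x", "y", "z")]),
                       as.matrix(target[idx, c("x", "y", "z")]))
      xyz <- fit$apply(as.matrix(tab[, c("x", "y", "z")]))
      xyz <- perturb_pose(xyz, sd)
      list(res = tibble(atom = tab$atom, element = tab$element,
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
           resid = tab$residue[1], nuc_chain = loc$chain,
           nuc_resno = loc$resno)
    }

    # planted motifs, round-robin over chains unless a chain is given
    for (k in seq_along(spec$planted_motifs)) {
      m <- spec$planted_motifs[[k]]
      ch <- if (!is.null(m$chain)) m$chain else
        chains[(k - 1L) %% length(chains) + 1L]
      p <- plant_motif(m$motif, m$position, if (is.null(m$sd)) 0 else m$sd)
      placed[[ch]] <- c(placed[[ch]], list(list(res = p$res, resid = p$resid)))
      truth[[length(truth) + 1L]] <- tibble(
        kind = "motif", motif = m$motif, chain = ch, residue = p$resid,
        nuc_chain = p$nuc_chain, nuc_resno = p$nuc_resno)
    }

    # background poses: random orientations in contact with random bases
    if (spec$background_poses > 0L) {
      res_type <- spec$background_residue
      mtab <- motif_table(motif_for_residue(res_type))
      tmpl_xyz <- as.matrix(mtab[, c("x", "y", "z")])
      refs <- reference_atoms(res_type)
      ref_idx <- match(refs, mtab$atom)
      dna_xyz <- as.matrix(dup$atoms[, c("x", "y", "z")])
      dna_rad <- vdw_radius(dup$atoms$element)
      eligible <- spec$background_positions
      if (is.null(eligible)) eligible <- seq(2L, max(2L, L - 1L))
      prev_refs <- list()
      n_done <- 0L
      tries <- 0L
      while (n_done < spec$background_poses) {
        tries <- tries + 1L
        if (tries > 500L * spec$background_poses) {
          abort("infeasible background packing: retry budget exhausted")
        }
        pos <- sample(eligible, 1L)
        strand <- sample(1:2, 1L)
        ch <- dup$chain_ids[strand]
        resno <- if (strand == 1L) pos else L - pos + 1L
        if (resno == 1L) next
        nuc <- duplex_residue(dup, ch, resno)
        bh <- nuc[nuc$atom %in% BASE_HEAVY[[nuc$resid[1]]], , drop = FALSE]
        anchor <- bh[sample(nrow(bh), 1L), ]
        ctr <- colMeans(as.matrix(bh[, c("x", "y", "z")]))
        dir <- as.numeric(c(anchor$x, anchor$y, anchor$z)) - ctr
        dir <- dir / sqrt(sum(dir^2)) + rnorm(3, sd = 0.45)
        dir <- dir / sqrt(sum(dir^2))
        R <- random_rotation()
        xyz <- tmpl_xyz %*% t(R)
        shift <- as.numeric(c(anchor$x, anchor$y, anchor$z)) +
          dir * runif(1, 3.4, 4.2) - xyz[ref_idx[1], ]
        xyz <- sweep(xyz, 2, shift, "+")
        # no steric clash with the DNA
        dmin <- min(proxy_dist(xyz, dna_xyz))
        if (dmin < 2.9) next
        # the residue must still be in contact (vdW + 1.0 rule)
        refs_xyz <- xyz[ref_idx, , drop = FALSE]
        nuc_xyz <- as.matrix(nuc[, c("x", "y", "z")])
        gaps <- proxy_dist(refs_xyz, nuc_xyz) -
          outer(vdw_radius(mtab$element[ref_idx]), vdw_radius(nuc$element), "+")
        if (min(gaps) >= 1.0) next
        # non-repeating orientations
        ok <- TRUE
        for (pr in prev_refs) {
          if (rmsd_fixed(refs_xyz, pr) < 1.6) { ok <- FALSE; break }
        }
        if (!ok) next
        prev_refs[[length(prev_refs) + 1L]] <- refs_xyz
        ch_p <- chains[(n_done %% length(chains)) + 1L]
        placed[[ch_p]] <- c(placed[[ch_p]], list(list(
          res = tibble(atom = mtab$atom, element = mtab$element,
                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
          resid = res_type)))
        truth[[length(truth) + 1L]] <- tibble(
          kind = "background", motif = NA_character_, chain = ch_p,
          residue = res_type, nuc_chain = ch, nuc_resno = resno)
        n_done <- n_done + 1L
      }
    }

    # far-away stub residues give each chain a distinct random sequence
    rows <- list()
    for (ci in seq_along(chains)) {
      ch <- chains[ci]
      resno <- 0L
      for (r in placed[[ch]]) {
        resno <- resno + 1L
        rows[[length(rows) + 1L]] <- mutate(r$res, chain = ch, resno = resno,
                                            resid = r$resid)
      }
      for (j in seq_len(spec$n_flank)) {
        resno <- resno + 1L
        # deterministic pattern: topology depends on the spec, not the seed
        resid <- if ((ci + j) %% 2L == 0L) "ALA" else "GLY"
        stub <- flank_stub(resid)
        off <- c(28 + 5 * ci, -12 + 4 * j, 6 * ci)
        rows[[length(rows) + 1L]] <- mutate(
          stub, x = .data$x + off[1], y = .data$y + off[2],
          z = .data$z + off[3], chain = ch, resno = resno, resid = resid)
      }
    }
    prot <- bind_rows(rows)
    dna <- mutate(select(dup$atoms, -"pair_pos"), kind = "dna")
    prot$kind <- "protein"
    all_atoms <- bind_rows(prot[, colnames(dna)], dna)

    text <- format_pdb(all_atoms, spec$resolution, spec$r_factor)
    if (!is.null(file)) writeLines(text, file)
    structure(paste(text, collapse = "\n"),
              ground_truth = bind_rows(truth))
  })
}

proxy_dist <- function(a, b) {
  # plain distance matrix between two coordinate sets
  sqrt(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b))
}

format_pdb <- function(atoms, resolution, r_factor) {
  out <- c(
    "HEADER    SYNTHETIC PROTEIN-DNA COMPLEX FIXTURE",
    sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", resolution),
    sprintf("REMARK   3   R VALUE            (WORKING SET) : %6.3f", r_factor)
  )
  serial <- 0L
  for (ch in unique(atoms$chain)) {
    sub <- atoms[atoms$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      nm <- sub$atom[i]
      # PDB atom-name column convention
      nm_fmt <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
      out <- c(out, sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm_fmt, sub$resid[i], ch, sub$resno[i],
        sub$x[i], sub$y[i], sub$z[i], 1.00, 0.00, sub$element[i]))
    }
    serial <- serial + 1L
    out <- c(out, sprintf("TER   %5d      %3s %1s%4d",
                          serial, sub$resid[nrow(sub)], ch,
                          sub$resno[nrow(sub)]))
  }
  c(out, "END")
}

#' Specification of a controlled-identity protein sequence family
#'
#' @param base_sequence amino-acid string (one-letter), length >= 10.
#' @param target_identities fractions in (0, 1]; one mutated copy is produced
#'   per value, with global-alignment identity to the base within two
#'   percentage points of the target.
#' @param seed integer seed.
#' @return A `homolog_family_spec` list.
#' @export
homolog_family_spec <- function(base_sequence, target_identities, seed = 1L) {
  if (nchar(base_sequence) < 10L) {
    abort("base_sequence must have length >= 10")
  }
  if (any(target_identities < 0 | target_identities > 1)) {
    abort("target identities must lie in [0, 1]")
  }
  structure(list(base_sequence = toupper(base_sequence),
                 target_identities = target_identities,
                 seed = as.integer(seed)),
            class = "homolog_family_spec")
}

#' Generate a family of homologous sequences with controlled identity
#'
#' Substitution-only mutation model: positions are sampled uniformly and
#' replaced with letters scoring non-positively against the original under
#' BLOSUM62, so the measured global-alignment identity tracks the fraction
#' of untouched positions.  The mutation count is re-tuned against the
#' measured identity until the target is met within two percentage points.
#'
#' @param spec a [homolog_family_spec()].
#' @return Tibble with `target`, `sequence`, `identity` (measured).
#' @export
generate_homolog_family <- function(spec) {
  stopifnot(inherits(spec, "homolog_family_spec"))
  base <- spec$base_sequence
  L <- nchar(base)
  aa_letters <- unname(AA1)
  blo <- blosum62_matrix()
  with_seed(spec$seed, {
    out <- lapply(spec$target_identities, function(t) {
      if (t < 0.05) {
        abort(paste0("target identity ", t,
                     " unreachable under a substitution-only model"))
      }
      if (t >= 1) {
        return(tibble(target = t, sequence = base, identity = 1))
      }
      m <- round((1 - t) * L)
      for (attempt in 1:25) {
        chars <- strsplit(base, "")[[1]]
        pos <- sample(L, min(m, L))
        for (p in pos) {
          opts <- aa_letters[blo[chars[p], aa_letters] <= 0 &
                               aa_letters != chars[p]]
          chars[p] <- sample(opts, 1L)
        }
        cand <- paste(chars, collapse = "")
        id <- global_align(base, cand)$identity
        if (abs(id - t) <= 0.02) {
          return(tibble(target = t, sequence = cand, identity = id))
        }
        m <- max(1L, m + round((id - t) * L))
      }
      abort(paste0("could not reach target identity ", t))
    })
    bind_rows(out)
  })
}

#' Generate a synthetic side-chain pose distribution
#'
#' Test input for the clustering stage: planted dense groups of poses around
#' given centres plus isolated background poses.  Poses are 3 x 3
#' reference-atom coordinate matrices in the common base frame.
#'
#' @param centers list of 3 x 3 matrices (or a single matrix recycled).
#' @param populations integer count per centre.
#' @param spread maximum reference-atom RMSD of a member to its centre, in
#'   Angstrom.
#' @param background number of isolated poses, pairwise >= 3 Angstrom RMSD
#'   apart and >= 3 Angstrom from every centre.
#' @param seed integer seed.
#' @return List of poses; the planted group of each pose (0 = background) is
#'   attached as attribute `"group"`.
#' @export
generate_pose_distribution <- function(centers, populations, spread = 0.5,
                                       background = 0L, seed = 1L) {
  if (is.matrix(centers)) centers <- list(centers)
  if (length(centers) != length(populations)) {
    abort("centers and populations must have equal length")
  }
  if (spread < 0) abort("spread must be >= 0")
  with_seed(seed, {
    poses <- list()
    group <- integer(0)
    for (g in seq_along(centers)) {
      ctr <- centers[[g]]
      for (j in seq_len(populations[g])) {
        pose <- ctr
        if (spread > 0) {
          for (k in 1:20) {
            cand <- perturb_pose(ctr, sd = spread * 0.6)
            if (rmsd_fixed(cand, ctr) <= spread) { pose <- cand; break }
          }
        }
        poses[[length(poses) + 1L]] <- pose
        group <- c(group, g)
      }
    }
    tries <- 0L
    placed_bg <- 0L
    while (placed_bg < background) {
      tries <- tries + 1L
      if (tries > 500L * max(1L, background)) {
        abort("infeasible background packing: retry budget exhausted")
      }
      base <- centers[[sample(length(centers), 1L)]]
      shift <- rnorm(3, sd = 8)
      cand <- sweep(base %*% t(random_rotation()), 2, shift, "+")
      far <- all(vapply(centers, function(ctr)
        rmsd_fixed(cand, ctr) >= 3, logical(1)))
      if (!far) next
      bg_idx <- which(group == 0L)
      ok <- all(vapply(poses[bg_idx], function(p)
        rmsd_fixed(cand, p) >= 3, logical(1)))
      if (!ok) next
      poses[[length(poses) + 1L]] <- cand
      group <- c(group, 0L)
      placed_bg <- placed_bg + 1L
    }
    attr(poses, "group") <- group
    poses
  })
}
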