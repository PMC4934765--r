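#' Reduce an amino-acid residue to its C-alpha fragment
#'
#' Removes the peptide-bond carbonyl and amide groups; the C-alpha carbon is
#' later capped as a methyl group by hydrogen addition.  Proline keeps its
#' five-membered ring (only the carboxyl group is removed, giving a neutral
#' tetrahydropyrrole after protonation) and glycine reduces to methane.
#'
#' @param atoms tibble of residue heavy atoms (atom, element, x, y, z).
#' @param residue three-letter residue name.
#' @return Tibble of fragment heavy atoms.
#' @export
make_calpha_fragment <- function(atoms, residue) {
  residue <- toupper(residue)
  if (!residue %in% AA3) abort(paste0("nonstandard residue: ", residue))
  sp <- species_atoms(paste0("frag_", residue))
  heavy <- sp$atom[sp$element != "H"]
  out <- atoms[atoms$atom %in% heavy, , drop = FALSE]
  missing <- setdiff(heavy, out$atom)
  if (length(missing) > 0L) {
    abort(paste0(residue, " fragment incomplete; missing atom(s): ",
                 paste(missing, collapse = ", ")))
  }
  out
}

#' Complete a phosphate group with its bridging O3' oxygen
#'
#' The extracted 5'-phosphate lacks the bridging oxygen contributed by the
#' preceding residue's sugar.  It is restored at the end of a 1.610 Angstrom
#' vector from the phosphorus, perpendicular to the OP1/OP2/O5' plane, on
#' the side of the plane where the phosphorus lies (tetrahedral completion).
#'
#' @param P,OP1,OP2,O5p length-3 coordinate vectors in Angstrom.
#' @return Length-3 coordinate vector of the reconstructed oxygen.
#' @export
reconstruct_o3prime <- function(P, OP1, OP2, O5p) {
  P <- as.numeric(P); OP1 <- as.numeric(OP1)
  OP2 <- as.numeric(OP2); O5p <- as.numeric(O5p)
  n <- cross3(OP2 - OP1, O5p - OP1)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) abort("reconstruct_o3prime(): degenerate oxygen plane")
  n <- n / nn
  side <- sum((P - OP1) * n)
  if (abs(side) < 1e-6) {
    abort("reconstruct_o3prime(): phosphorus lies in the OP1/OP2/O5' plane")
  }
  if (side < 0) n <- -n
  P + 1.610 * n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

species_for <- function(residue, kind) {
  switch(kind,
         fragment = paste0("frag_", toupper(residue)),
         dnmp = paste0("nuc_", toupper(residue)),
         base = paste0("base_", toupper(residue)),
         abort(paste0("unknown species kind: ", kind)))
}

species_graph <- function(sid) {
  b <- species_bonds(sid)
  split(c(b$atom2, b$atom1), c(b$atom1, b$atom2))
}

#' Add hydrogen atoms from the ideal species templates
#'
#' Every hydrogen of the packaged species template is transferred onto the
#' actual heavy-atom geometry by superposing the template's local frame (the
#' parent heavy atom plus its bonded heavy neighbours, extended through the
#' neighbour shell when fewer than three frame atoms exist).  Protonation
#' states follow the fixed rules of the preparation protocol: histidine is
#' N-epsilon protonated, guanine N1 (not N3) carries the imino hydrogen,
#' G/C are keto and A/T amino tautomers, stripped bases gain H9/H1 at the
#' glycosidic nitrogen and the completed phosphate oxygen gains a single
#' hydrogen.  Already present hydrogens are left untouched (idempotent).
#'
#' @param atoms tibble of heavy atoms (atom, element, x, y, z); for a dNMP
#'   this must already include the reconstructed `O3T` oxygen.
#' @param residue residue name (three-letter amino acid or DA/DC/DG/DT).
#' @param kind `"fragment"`, `"dnmp"` or `"base"`.
#' @return Tibble with hydrogens appended.
#' @export
add_hydrogens <- function(atoms, residue, kind) {
  sid <- species_for(residue, kind)
  sp <- species_atoms(sid)
  graph <- species_graph(sid)
  tmpl_xyz <- as.matrix(sp[, c("x", "y", "z")])
  rownames(tmpl_xyz) <- sp$atom
  is_h <- sp$element == "H"
  heavy_names <- sp$atom[!is_h]

  missing <- setdiff(heavy_names, atoms$atom)
  if (length(missing) > 0L) {
    abort(paste0(sid, ": cannot protonate; missing heavy atom(s): ",
                 paste(missing, collapse = ", ")))
  }
  act_xyz <- as.matrix(atoms[match(heavy_names, atoms$atom),
                             c("x", "y", "z")])
  rownames(act_xyz) <- heavy_names

  out <- atoms
  for (h in sp$atom[is_h]) {
    if (h %in% out$atom) next
    parent <- intersect(graph[[h]], heavy_names)[1]
    frame <- local_frame(parent, graph, heavy_names)
    if (length(frame) >= 3L) {
      fit <- superpose(tmpl_xyz[frame, , drop = FALSE],
                       act_xyz[frame, , drop = FALSE])
      pos <- fit$apply(tmpl_xyz[h, , drop = FALSE])
    } else {
      # isolated heavy atom (methane): translate the template
      pos <- tmpl_xyz[h, , drop = FALSE] - tmpl_xyz[parent, , drop = FALSE] +
        act_xyz[parent, , drop = FALSE]
    }
    out <- bind_rows(out, tibble(atom = h, element = "H",
                                 x = pos[1], y = pos[2], z = pos[3]))
  }
  out
}

local_frame <- function(parent, graph, heavy_names) {
  nb <- intersect(graph[[parent]], heavy_names)
  frame <- c(parent, nb)
  if (length(frame) < 3L) {
    for (x in nb) {
      frame <- union(frame, intersect(graph[[x]], heavy_names))
      if (length(frame) >= 3L) break
    }
  }
  utils::head(frame, 4L)
}

TARGET_CHARGE <- c(ARG = 1, LYS = 1, ASP = -1, GLU = -1)

target_total_charge <- function(residue, kind) {
  switch(kind,
         fragment = unname(TARGET_CHARGE[toupper(residue)] %|0|% 0),
         dnmp = -1,
         base = 0)
}

`%|0|%` <- function(x, d) if (length(x) == 0L || is.na(x)) d else x

#' Assign force-field parameters to a protonated monomer
#'
#' Joins the packaged Amber-form parameter set: per-atom partial charges,
#' Lennard-Jones class constants and generalized-Born radii/screening
#' factors, plus harmonic bond/angle terms whose equilibrium values come
#' from the ideal template geometry.  Charges of the specially added
#' hydrogens (C-alpha cap, proline H1, glycosidic H9/H1, phosphate O3' cap)
#' absorb the residual so the monomer total is exactly integral: +1 e for
#' arginine and lysine fragments, -1 e for aspartate, glutamate and dNMPs,
#' 0 e otherwise, split symmetrically when several hydrogens are added.
#'
#' @param atoms tibble from [add_hydrogens()].
#' @param residue residue name.
#' @param kind `"fragment"`, `"dnmp"` or `"base"`.
#' @param monomer monomer label stored on the atoms.
#' @return Object of class `prepared_system`.
#' @export
assign_parameters <- function(atoms, residue, kind, monomer = "A") {
  sid <- species_for(residue, kind)
  sp <- species_atoms(sid)
  idx <- match(atoms$atom, sp$atom)
  if (anyNA(idx)) {
    abort(paste0(sid, ": atoms not in the parameter set: ",
                 paste(atoms$atom[is.na(idx)], collapse = ", ")))
  }
  if (nrow(atoms) != nrow(sp)) {
    abort(paste0(sid, ": species atom(s) missing: ",
                 paste(setdiff(sp$atom, atoms$atom), collapse = ", ")))
  }
  lj <- lj_table()
  gb <- gb_table()
  lj_idx <- match(sp$lj[idx], lj$lj)
  gb_idx <- match(sp$element[idx], gb$element)

  charge <- sp$charge[idx]
  added <- sp$added[idx] == 1L
  target <- target_total_charge(residue, kind)
  resid_q <- target - sum(charge)
  if (any(added)) {
    charge[added] <- charge[added] + resid_q / sum(added)
  } else if (abs(resid_q) > 1e-6) {
    abort(paste0(sid, ": cannot balance charge; no designated added atoms"))
  }

  at <- tibble(atom = atoms$atom, element = atoms$element, monomer = monomer,
               x = atoms$x, y = atoms$y, z = atoms$z, charge = charge,
               sigma = lj$sigma_nm[lj_idx], eps = lj$eps_kj[lj_idx],
               gb_radius = gb$radius_nm[gb_idx],
               gb_screen = gb$screen[gb_idx],
               is_h = atoms$element == "H")

  b <- species_bonds(sid)
  i <- match(b$atom1, at$atom)
  j <- match(b$atom2, at$atom)
  tmpl <- as.matrix(sp[, c("x", "y", "z")])
  rownames(tmpl) <- sp$atom
  r0 <- unname(sqrt(rowSums((tmpl[b$atom1, , drop = FALSE] -
                               tmpl[b$atom2, , drop = FALSE])^2))) / 10  # nm
  kb <- ifelse(at$is_h[i] | at$is_h[j], 350000, 250000)  # kJ/mol/nm^2
  bonds <- tibble(i = i, j = j, r0 = r0, k = kb)

  angles <- enumerate_angles(bonds, nrow(at))
  if (nrow(angles) > 0L) {
    v1 <- tmpl[at$atom[angles$i], , drop = FALSE] -
      tmpl[at$atom[angles$j], , drop = FALSE]
    v2 <- tmpl[at$atom[angles$k], , drop = FALSE] -
      tmpl[at$atom[angles$j], , drop = FALSE]
    cosang <- rowSums(v1 * v2) /
      (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
    angles$th0 <- acos(pmin(1, pmax(-1, cosang)))
    angles$kth <- 418.4  # kJ/mol/rad^2
  }

  dtab <- species_dihedrals(sid)
  dihedrals <- tibble(i = match(dtab$atom1, at$atom),
                      j = match(dtab$atom2, at$atom),
                      k = match(dtab$atom3, at$atom),
                      l = match(dtab$atom4, at$atom),
                      kphi = dtab$k_kj, n = as.integer(dtab$n),
                      gamma = dtab$gamma_deg * pi / 180)
  new_prepared_system(at, bonds, angles, dihedrals)
}

enumerate_angles <- function(bonds, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], bonds$j[r])
    adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], bonds$i[r])
  }
  out <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2L) {
      cmb <- utils::combn(nb, 2)
      out[[length(out) + 1L]] <- tibble(i = cmb[1, ], j = j, k = cmb[2, ])
    }
  }
  if (length(out) == 0L) {
    return(tibble(i = integer(), j = integer(), k = integer(),
                  th0 = numeric(), kth = numeric()))
  }
  bind_rows(out)
}

#' @keywords internal
new_prepared_system <- function(atoms, bonds, angles, dihedrals) {
  ex <- exclusion_pairs(bonds, nrow(atoms))
  structure(list(atoms = atoms, bonds = bonds, angles = angles,
                 dihedrals = dihedrals, excl = ex$excl,
                 pairs14 = ex$pairs14),
            class = "prepared_system")
}

# graph distances 1-2/1-3 -> excluded; exactly 1-4 -> scaled pairs
exclusion_pairs <- function(bonds, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], bonds$j[r])
    adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], bonds$i[r])
  }
  excl <- list()
  p14 <- list()
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    for (d in 1:3) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
      if (length(frontier) == 0L) break
    }
    tgt <- which(dist %in% c(1L, 2L) & seq_len(n) > s)
    if (length(tgt)) excl[[length(excl) + 1L]] <- cbind(s, tgt)
    tgt4 <- which(dist == 3L & seq_len(n) > s)
    if (length(tgt4)) p14[[length(p14) + 1L]] <- cbind(s, tgt4)
  }
  list(excl = if (length(excl)) do.call(rbind, excl) else
    matrix(integer(), 0, 2),
    pairs14 = if (length(p14)) do.call(rbind, p14) else
      matrix(integer(), 0, 2))
}

#' @export
print.prepared_system <- function(x, ...) {
  cat("<prepared_system> ", nrow(x$atoms), " atoms (",
      sum(x$atoms$is_h), " H), ", nrow(x$bonds), " bonds, total charge ",
      sprintf("%+.3f", sum(x$atoms$charge)), " e\n", sep = "")
  invisible(x)
}

#' Prepare one monomer of a contact dimer
#'
#' Runs the full preparation chain for either side of a dimer: backbone
#' stripping (amino acid) or O3' completion (dNMP), hydrogen addition and
#' parameter assignment.
#'
#' @param dimer a `contact_dimer`.
#' @param side `"aa"` or `"nuc"`.
#' @param monomer monomer label.
#' @return A `prepared_system`.
#' @export
prepare_monomer <- function(dimer, side = c("aa", "nuc"), monomer = "A") {
  side <- match.arg(side)
  if (side == "aa") {
    frag <- make_calpha_fragment(dimer$aa_atoms, dimer$aa_type)
    prot <- add_hydrogens(frag, dimer$aa_type, "fragment")
    return(assign_parameters(prot, dimer$aa_type, "fragment", monomer))
  }
  kind <- if (isTRUE(dimer$stripped)) "base" else "dnmp"
  atoms <- dimer$nuc_atoms
  if (kind == "dnmp" && !"O3T" %in% atoms$atom) {
    need <- c("P", "OP1", "OP2", "O5'")
    idx <- match(need, atoms$atom)
    if (anyNA(idx)) {
      abort("cannot reconstruct O3': phosphate atoms missing")
    }
    xyz <- as.matrix(atoms[idx, c("x", "y", "z")])
    o3t <- reconstruct_o3prime(xyz[1, ], xyz[2, ], xyz[3, ], xyz[4, ])
    atoms <- bind_rows(atoms, tibble(atom = "O3T", element = "O",
                                     x = o3t[1], y = o3t[2], z = o3t[3]))
  }
  prot <- add_hydrogens(atoms, dimer$nuc_type, kind)
  assign_parameters(prot, dimer$nuc_type, kind, monomer)
}

#' Prepare a full two-monomer dimer system
#'
#' @param dimer a `contact_dimer`.
#' @return A `prepared_system` with monomer labels `"A"` (amino-acid
#'   fragment) and `"B"` (nucleotide or stripped base).
#' @export
prepare_dimer <- function(dimer) {
  a <- prepare_monomer(dimer, "aa", "A")
  b <- prepare_monomer(dimer, "nuc", "B")
  combine_systems(a, b)
}

#' @keywords internal
combine_systems <- function(a, b) {
  off <- nrow(a$atoms)
  atoms <- bind_rows(a$atoms, b$atoms)
  shift <- function(tb, cols) {
    for (cc in cols) tb[[cc]] <- tb[[cc]] + off
    tb
  }
  bonds <- bind_rows(a$bonds, shift(b$bonds, c("i", "j")))
  angles <- bind_rows(a$angles, shift(b$angles, c("i", "j", "k")))
  dihedrals <- bind_rows(a$dihedrals, shift(b$dihedrals,
                                            c("i", "j", "k", "l")))
  excl <- rbind(a$excl, b$excl + off)
  p14 <- rbind(a$pairs14, b$pairs14 + off)
  structure(list(atoms = atoms, bonds = bonds, angles = angles,
                 dihedrals = dihedrals, excl = excl, pairs14 = p14),
            class = "prepared_system")
}

#' Extract one monomer of a prepared dimer as its own system
#' @param system a two-monomer `prepared_system`.
#' @param monomer monomer label to keep.
#' @return A `prepared_system`.
#' @export
split_system <- function(system, monomer) {
  keep <- which(system$atoms$monomer == monomer)
  if (length(keep) == 0L) abort(paste0("no monomer labelled ", monomer))
  remap <- rep(NA_integer_, nrow(system$atoms))
  remap[keep] <- seq_along(keep)
  sub_idx <- function(tb, cols) {
    inkeep <- matrix(unlist(lapply(cols, function(cc) tb[[cc]] %in% keep)),
                     nrow = nrow(tb))
    all_in <- rowSums(inkeep) == length(cols)
    any_in <- rowSums(inkeep) > 0
    if (any(any_in & !all_in)) {
      abort("monomer split crosses a bonded term")
    }
    tb <- tb[all_in, , drop = FALSE]
    for (cc in cols) tb[[cc]] <- remap[tb[[cc]]]
    tb
  }
  sub_mat <- function(m) {
    ok <- m[, 1] %in% keep & m[, 2] %in% keep
    out <- m[ok, , drop = FALSE]
    out[] <- remap[out]
    out
  }
  structure(list(atoms = system$atoms[keep, , drop = FALSE],
                 bonds = sub_idx(system$bonds, c("i", "j")),
                 angles = sub_idx(system$angles, c("i", "j", "k")),
                 dihedrals = sub_idx(system$dihedrals, c("i", "j", "k", "l")),
                 excl = sub_mat(system$excl),
                 pairs14 = sub_mat(system$pairs14)),
            class = "prepared_system")
}
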