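#' Contact predicate of the interface definition
#'
#' Two atoms are in contact when their distance is smaller than the sum of
#' their van der Waals radii plus `margin`.
#'
#' @param distance interatomic distance(s), Angstrom.
#' @param r1,r2 van der Waals radii, Angstrom.
#' @param margin contact margin, Angstrom (1.0 in the interface definition).
#' @return Logical.
#' @export
is_contact <- function(distance, r1, r2, margin = 1.0) {
  distance - r1 - r2 < margin
}

new_contact_dimer <- function(structure_id, chain, aa_resno, aa_type,
                              aa_atoms, nuc_chain, nuc_resno, nuc_type,
                              nuc_atoms, base_directed = NA,
                              five_prime = FALSE, stripped = FALSE) {
  structure(list(structure_id = structure_id, chain = chain,
                 aa_resno = aa_resno, aa_type = aa_type, aa_atoms = aa_atoms,
                 nuc_chain = nuc_chain, nuc_resno = nuc_resno,
                 nuc_type = nuc_type, nuc_atoms = nuc_atoms,
                 base_directed = base_directed, five_prime = five_prime,
                 stripped = stripped),
            class = "contact_dimer")
}

#' @export
print.contact_dimer <- function(x, ...) {
  cat("<contact_dimer> ", x$structure_id, " ", x$chain, ":", x$aa_type,
      x$aa_resno, " - ", x$nuc_chain, ":", x$nuc_type, x$nuc_resno,
      if (isTRUE(x$stripped)) " [stripped]" else "",
      if (isTRUE(x$base_directed)) " [base-directed]" else "", "\n", sep = "")
  invisible(x)
}

#' Extract interacting amino acid-dNMP dimers from an analysis entry
#'
#' A dimer is emitted for every (amino acid, nucleotide) residue pair whose
#' minimum gap over (amino-acid reference atom, DNA heavy atom) pairs --
#' distance minus the two van der Waals radii -- is below `margin`.
#' Nucleotides at the 5' end of a strand (no phosphate group) are discarded.
#' At most one dimer per residue pair is produced.
#'
#' @param record the parsed `structure_record`.
#' @param entry one row of [make_entries()] output.
#' @param margin contact margin in Angstrom.
#' @return List of `contact_dimer` objects.
#' @export
find_contacts <- function(record, entry, margin = 1.0) {
  a <- record$atoms
  prot <- a[a$chain == entry$chain, , drop = FALSE]
  dna_chains <- entry$dna_chains[[1]]
  dimers <- list()
  for (dch in dna_chains) {
    dna <- a[a$chain == dch, , drop = FALSE]
    for (rn in unique(dna$resno)) {
      nuc <- dna[dna$resno == rn, , drop = FALSE]
      ntype <- nuc$resid[1]
      if (!ntype %in% DNA_RES) next
      five_prime <- !"P" %in% nuc$atom
      if (five_prime) next
      nuc_xyz <- as.matrix(nuc[, c("x", "y", "z")])
      nuc_rad <- vdw_radius(nuc$element)
      for (pr in unique(prot$resno)) {
        res <- prot[prot$resno == pr, , drop = FALSE]
        rtype <- res$resid[1]
        if (!rtype %in% AA3) next
        refs <- reference_atoms(rtype)
        idx <- match(refs, res$atom)
        if (anyNA(idx)) {
          warn(paste0(record$id, " ", entry$chain, ":", rtype, pr,
                      ": reference atom(s) missing; residue skipped"))
          next
        }
        ref_xyz <- as.matrix(res[idx, c("x", "y", "z")])
        gaps <- proxy_dist(ref_xyz, nuc_xyz) -
          outer(vdw_radius(res$element[idx]), nuc_rad, "+")
        if (min(gaps) < margin) {
          dimers[[length(dimers) + 1L]] <- new_contact_dimer(
            record$id, entry$chain, pr, rtype,
            res[, c("atom", "element", "x", "y", "z")],
            dch, rn, ntype, nuc[, c("atom", "element", "x", "y", "z")])
        }
      }
    }
  }
  dimers
}

#' Flag dimers whose amino acid touches the DNA base moiety
#'
#' The base-directed test uses every amino-acid atom (not only the reference
#' atoms) against the base-moiety atoms of the nucleotide, with the same van
#' der Waals margin rule as the contact definition.
#'
#' @param dimer a `contact_dimer` (not stripped).
#' @param margin contact margin in Angstrom.
#' @return The dimer with `base_directed` set.
#' @export
flag_base_directed <- function(dimer, margin = 1.0) {
  stopifnot(inherits(dimer, "contact_dimer"))
  if (isTRUE(dimer$stripped)) {
    abort("flag_base_directed(): dimer is already stripped to the base")
  }
  base_atoms <- dimer$nuc_atoms[dimer$nuc_atoms$atom %in%
                                  BASE_HEAVY[[dimer$nuc_type]], , drop = FALSE]
  aa_xyz <- as.matrix(dimer$aa_atoms[, c("x", "y", "z")])
  gaps <- proxy_dist(aa_xyz, as.matrix(base_atoms[, c("x", "y", "z")])) -
    outer(vdw_radius(dimer$aa_atoms$element), vdw_radius(base_atoms$element),
          "+")
  dimer$base_directed <- min(gaps) < margin
  dimer
}

#' Strip a dimer's nucleotide to its base moiety
#'
#' Removes the sugar and phosphate atoms, leaving only base heavy atoms; a
#' hydrogen is later added at N9 (purines) or N1 (pyrimidines) during system
#' preparation.  Idempotent on already stripped dimers.
#'
#' @param dimer a `contact_dimer` containing a full dNMP.
#' @return The stripped dimer.
#' @export
strip_to_base <- function(dimer) {
  stopifnot(inherits(dimer, "contact_dimer"))
  if (isTRUE(dimer$stripped)) return(dimer)
  if (!dimer$nuc_type %in% DNA_RES) {
    abort(paste0("unknown base type: ", dimer$nuc_type))
  }
  keep <- dimer$nuc_atoms$atom %in% BASE_HEAVY[[dimer$nuc_type]]
  dimer$nuc_atoms <- dimer$nuc_atoms[keep, , drop = FALSE]
  dimer$stripped <- TRUE
  dimer
}
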