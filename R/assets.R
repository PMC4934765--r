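#' Packaged parameter and geometry assets
#'
#' The package ships a compact, self-contained parameter set in the Amber
#' functional form as plain-text tables under `inst/extdata/`:
#' per-species atom templates (ideal coordinates, partial charges,
#' Lennard-Jones classes), bond graphs, Lennard-Jones class constants,
#' generalized-Born intrinsic radii and screening factors, van der Waals
#' contact radii, the three reference atoms per amino acid, the idealized
#' duplex strand frame and the canonical docked motif poses.
#'
#' @param name file stem, e.g. `"species_atoms"`.
#' @return A data frame (cached after first read).
#' @keywords internal
read_asset <- function(name) {
  cache <- asset_env()
  if (!is.null(cache[[name]])) {
    return(cache[[name]])
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "basereadout")
  if (!nzchar(path)) {
    abort(paste0("packaged asset not found: ", name))
  }
  out <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cache[[name]] <- out
  out
}

asset_env <- local({
  e <- new.env(parent = emptyenv())
  function() e
})

#' @keywords internal
species_atoms <- function(species = NULL) {
  tab <- read_asset("species_atoms")
  if (!is.null(species)) {
    tab <- tab[tab$species == species, , drop = FALSE]
    if (nrow(tab) == 0L) abort(paste0("unknown species: ", species))
  }
  tab
}

#' @keywords internal
species_bonds <- function(species) {
  tab <- read_asset("species_bonds")
  tab[tab$species == species, c("atom1", "atom2"), drop = FALSE]
}

#' @keywords internal
species_dihedrals <- function(species) {
  tab <- read_asset("species_dihedrals")
  tab[tab$species == species, , drop = FALSE]
}

#' Three reference atoms of an amino-acid type
#'
#' Reference atoms are the residue's characteristic side-chain atoms used by
#' the contact criterion and by the pose distance of the clustering stage.
#' Glycine and alanine fall back to C-alpha-centred triplets.
#'
#' @param residue three-letter residue name (e.g. `"ASN"`).
#' @return Character vector of three atom names.
#' @export
reference_atoms <- function(residue) {
  tab <- read_asset("reference_atoms")
  row <- tab[tab$residue == toupper(residue), , drop = FALSE]
  if (nrow(row) == 0L) abort(paste0("no reference atoms for residue: ", residue))
  unname(unlist(row[1, c("ref1", "ref2", "ref3")]))
}

#' Van der Waals radius of an element
#'
#' Radii used by the contact criterion (contact when the interatomic
#' distance is less than the radius sum plus a 1.0 Angstrom margin).
#'
#' @param element element symbol(s).
#' @return Numeric radius/radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  tab <- read_asset("vdw_radii")
  idx <- match(toupper(element), tab$element)
  if (anyNA(idx)) {
    abort(paste0("no van der Waals radius for element(s): ",
                 paste(unique(element[is.na(idx)]), collapse = ", ")))
  }
  tab$radius_A[idx]
}

#' @keywords internal
lj_table <- function() read_asset("lj_classes")

#' @keywords internal
gb_table <- function() read_asset("gb_params")

#' @keywords internal
bdna_frame <- function() read_asset("bdna_frame")

#' @keywords internal
motif_table <- function(motif = NULL) {
  tab <- read_asset("motifs")
  if (!is.null(motif)) {
    tab <- tab[tab$motif == motif, , drop = FALSE]
    if (nrow(tab) == 0L) abort(paste0("unknown motif template: ", motif))
  }
  tab
}

#' Names of the packaged motif geometry templates
#' @return Character vector of motif identifiers.
#' @export
motif_templates <- function() unique(read_asset("motifs")$motif)

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")
DNA_RES <- c("DA", "DC", "DG", "DT")
DNA_COMP <- c(DA = "DT", DT = "DA", DG = "DC", DC = "DG")
PURINES <- c("DA", "DG")

# base heavy atoms per residue type (the clustering frame and the
# base-directed contact test operate on these)
BASE_HEAVY <- list(
  DA = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  DG = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  DC = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  DT = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6")
)

SUGAR_PHOSPHATE <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                     "O3'", "C2'", "C1'", "O3T")

#' @keywords internal
base_ring_atoms <- function(base) {
  if (base %in% PURINES) c("N9", "C8", "N7", "C5", "C4")
  else c("N1", "C2", "N3", "C4", "C5", "C6")
}
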