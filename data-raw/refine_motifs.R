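# Refine the geometrically docked motif templates to the packaged force
# field's own rigid-body energy optimum, so that planted poses sit at an
# energy minimum rather than on a repulsive wall.
# Run from the repository root: Rscript data-raw/refine_motifs.R
suppressMessages(devtools::load_all(".", quiet = TRUE))

path <- "inst/extdata/motifs.csv"
tab <- read.csv(path, stringsAsFactors = FALSE)

rigid <- function(xyz, par) {
  # small-angle rotation about the centroid + translation
  cen <- colMeans(xyz)
  a <- par[1:3]
  th <- sqrt(sum(a^2))
  R <- diag(3)
  if (th > 1e-12) {
    k <- a / th
    K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  sweep(sweep(xyz, 2, cen) %*% t(R), 2, cen + par[4:6], "+")
}

for (mid in unique(tab$motif)) {
  rows <- which(tab$motif == mid)
  sub <- tab[rows, ]
  res <- sub$residue[1]
  bsid <- sub$base_species[1]
  bsp <- basereadout:::species_atoms(bsid)
  bsp <- bsp[bsp$element != "H", ]
  base_atoms <- tibble::tibble(atom = bsp$atom, element = bsp$element,
                               x = bsp$x, y = bsp$y, z = bsp$z)
  aa0 <- as.matrix(sub[, c("x", "y", "z")])

  make_dimer <- function(xyz) {
    basereadout:::new_contact_dimer(
      "tmpl", "A", 1L, res,
      tibble::tibble(atom = sub$atom, element = sub$element,
                     x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
      "X", 2L, sub("base_", "", bsid), base_atoms, base_directed = TRUE,
      stripped = TRUE)
  }
  obj <- function(par) {
    xyz <- rigid(aa0, par)
    ps <- try(prepare_dimer(make_dimer(xyz)), silent = TRUE)
    if (inherits(ps, "try-error")) return(1e6)
    m <- minimize_hydrogens(ps, medium(1), max_steps = 150)
    attr(m, "minimization")$energy
  }
  e0 <- obj(rep(0, 6))
  opt <- optim(rep(0, 6), obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-8))
  xyz <- rigid(aa0, opt$par)
  ie <- interaction_energy(prepare_dimer(make_dimer(xyz)), medium(1))
  cat(sprintf("%s: dimer E %8.2f -> %8.2f ; refined vacuum E_int %8.2f\n",
              mid, e0, opt$value, ie$e_int))
  tab[rows, c("x", "y", "z")] <- round(xyz, 3)
}
write.csv(tab, path, row.names = FALSE, quote = FALSE)
cat("motif templates refined\n")
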