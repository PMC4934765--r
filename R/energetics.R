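#' Dielectric environment for the energy model
#'
#' In vacuum (`eps_r = 1`) the generalized-Born and surface-area terms are
#' switched off and the plain Coulomb term is never scaled.  For `eps_r > 1`
#' the relative permittivity enters only as the solvent dielectric of the
#' generalized-Born term (solute dielectric 1), combined with an ACE-type
#' nonpolar surface-area term.
#'
#' @param eps_r relative permittivity (1, 4, 16 and 80 are the standard
#'   choices).
#' @param sa_gamma surface-tension coefficient, kJ/mol/nm^2.
#' @return A `medium` object.
#' @export
medium <- function(eps_r = 1, sa_gamma = 2.05) {
  stopifnot(eps_r >= 1)
  structure(list(eps_r = eps_r, gb = eps_r > 1, sa = eps_r > 1,
                 sa_gamma = sa_gamma),
            class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat("<medium> eps_r = ", x$eps_r,
      if (x$gb) " (GB/SA implicit solvent)" else " (vacuum)", "\n", sep = "")
  invisible(x)
}

# pack a prepared_system + medium into the flat list the engine expects;
# coordinates converted Angstrom -> nm
pack_system <- function(system, medium) {
  at <- system$atoms
  list(xyz = as.matrix(at[, c("x", "y", "z")]) / 10,
       charge = at$charge, sigma = at$sigma, eps = at$eps,
       gb_radius = at$gb_radius, gb_screen = at$gb_screen,
       bonds = as.matrix(system$bonds[, c("i", "j")]),
       bond_par = as.matrix(system$bonds[, c("r0", "k")]),
       angles = as.matrix(system$angles[, c("i", "j", "k")]),
       angle_par = as.matrix(system$angles[, c("th0", "kth")]),
       dihedrals = as.matrix(system$dihedrals[, c("i", "j", "k", "l")]),
       dihedral_par = as.matrix(system$dihedrals[, c("kphi", "n", "gamma")]),
       excl = storage_int(system$excl), pairs14 = storage_int(system$pairs14),
       eps_out = medium$eps_r, gb = medium$gb, sa = medium$sa,
       sa_gamma = medium$sa_gamma)
}

storage_int <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (ncol(m) != 2L) m <- matrix(integer(), 0, 2)
  m
}

#' Single-point potential energy
#'
#' Evaluates the Amber-form terms -- harmonic bonds and angles, periodic
#' dihedrals, 12-6 Lennard-Jones and Coulomb (electrostatic constant
#' 138.935485 kJ mol-1 nm e-2; 1-4 pairs scaled by 1/1.2 for Coulomb and
#' 1/2 for Lennard-Jones; no cutoff) -- plus, when the medium requests it,
#' the Hawkins-Cramer-Truhlar generalized-Born polar term and an ACE-type
#' surface-area term.
#'
#' @param system a `prepared_system`.
#' @param medium a [medium()].
#' @return Tibble with one row: bond, angle, dihedral, lj, coulomb, gb, sa
#'   and total, in kJ/mol.
#' @export
potential_energy <- function(system, medium = basereadout::medium(1)) {
  stopifnot(inherits(system, "prepared_system"), inherits(medium, "medium"))
  if (medium$gb && anyNA(system$atoms$gb_radius)) {
    abort("GB requested but generalized-Born parameters are missing")
  }
  e <- energy_terms_cpp(pack_system(system, medium))
  out <- as_tibble(as.list(e))
  out$total <- sum(e)
  out
}

#' Conjugate-gradient relaxation of hydrogen positions
#'
#' Minimises the potential energy over hydrogen coordinates only; heavy
#' atoms stay exactly at their input positions.  Polak-Ribiere conjugate
#' gradients with backtracking line search; terminates when the largest
#' force component on a hydrogen drops below `force_tol` or after
#' `max_steps` iterations.
#'
#' @param system a `prepared_system` with hydrogens present.
#' @param medium a [medium()].
#' @param force_tol force tolerance, kJ/mol/nm.
#' @param max_steps iteration cap.
#' @return The system with relaxed hydrogen coordinates; the final energy
#'   and convergence data are attached as attribute `"minimization"`.
#' @export
minimize_hydrogens <- function(system, medium = basereadout::medium(1),
                               force_tol = 10, max_steps = 400) {
  stopifnot(inherits(system, "prepared_system"))
  hidx <- which(system$atoms$is_h)
  if (length(hidx) == 0L) abort("no hydrogens to minimise")
  packed <- pack_system(system, medium)
  xyz <- packed$xyz

  eval_eg <- function(coords_h) {
    packed$xyz[hidx, ] <- matrix(coords_h, ncol = 3, byrow = TRUE)
    energy_grad_cpp(packed, as.integer(hidx))
  }
  p <- as.numeric(t(xyz[hidx, , drop = FALSE]))
  eg <- eval_eg(p)
  if (!is.finite(eg$energy)) abort("divergent energy at step 0")
  g <- eg$grad
  d <- -g
  energy <- eg$energy
  step <- 1e-5
  converged <- max(abs(g)) < force_tol
  iter <- 0L
  while (!converged && iter < max_steps) {
    iter <- iter + 1L
    # backtracking line search along d
    gd <- sum(g * d)
    if (gd >= 0) { d <- -g; gd <- sum(g * d) }
    alpha <- step
    ok <- FALSE
    for (t in 1:30) {
      cand <- p + alpha * d
      e2 <- eval_eg(cand)
      if (is.finite(e2$energy) && e2$energy <= energy + 1e-4 * alpha * gd) {
        ok <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!ok) break
    if (!is.finite(e2$energy)) {
      abort(paste0("divergent energy at step ", iter))
    }
    g_new <- e2$grad
    beta <- max(0, sum(g_new * (g_new - g)) / sum(g * g))
    d <- -g_new + beta * d
    p <- cand
    g <- g_new
    energy <- e2$energy
    step <- max(alpha * 2, 1e-7)
    converged <- max(abs(g)) < force_tol
  }
  out <- system
  out$atoms[hidx, c("x", "y", "z")] <-
    matrix(p, ncol = 3, byrow = TRUE) * 10
  attr(out, "minimization") <- list(energy = energy, iterations = iter,
                                    max_force = max(abs(g)),
                                    converged = converged)
  out
}

#' Supermolecular interaction energy with deformation terms
#'
#' Protocol: relax the dimer's hydrogens; take the single-point energy of
#' the relaxed dimer; split it into its monomers and take their single-point
#' energies in the dimer conformation; relax each monomer's hydrogens alone
#' and take the relaxed single-point energies.  The deformation energy of a
#' monomer is its dimer-conformation energy minus its self-relaxed energy,
#' and the interaction energy is the dimer energy minus the two
#' dimer-conformation monomer energies plus both deformation energies --
#' algebraically the dimer energy minus the two self-relaxed monomer
#' energies.
#'
#' @param system a two-monomer `prepared_system` (labels `"A"`, `"B"`).
#' @param medium a [medium()].
#' @param ... passed to [minimize_hydrogens()].
#' @return Tibble with one row: e_int, e_dimer_opt, e_a_dimerconf,
#'   e_b_dimerconf, deformation_a, deformation_b, e_a_selfopt, e_b_selfopt,
#'   eps_r.
#' @export
interaction_energy <- function(system, medium = basereadout::medium(1), ...) {
  labs <- unique(system$atoms$monomer)
  if (length(labs) != 2L) {
    abort("interaction_energy() needs exactly two monomer labels")
  }
  dimer_opt <- minimize_hydrogens(system, medium, ...)
  e_dimer <- potential_energy(dimer_opt, medium)$total
  monA <- split_system(dimer_opt, labs[1])
  monB <- split_system(dimer_opt, labs[2])
  e_a_dc <- potential_energy(monA, medium)$total
  e_b_dc <- potential_energy(monB, medium)$total
  e_a_self <- potential_energy(minimize_hydrogens(monA, medium, ...),
                               medium)$total
  e_b_self <- potential_energy(minimize_hydrogens(monB, medium, ...),
                               medium)$total
  d_a <- e_a_dc - e_a_self
  d_b <- e_b_dc - e_b_self
  tibble(e_int = e_dimer - (e_a_dc + e_b_dc) + d_a + d_b,
         e_dimer_opt = e_dimer, e_a_dimerconf = e_a_dc,
         e_b_dimerconf = e_b_dc, deformation_a = d_a, deformation_b = d_b,
         e_a_selfopt = e_a_self, e_b_selfopt = e_b_self,
         eps_r = medium$eps_r)
}
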