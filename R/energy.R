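## Nonbonded energetics: Lennard-Jones with plain 14 A truncation and
## vacuum Coulomb. Solvent screening is not folded into a distance-dependent
## dielectric; it lives entirely in the continuum desolvation term.

#' Energy-engine configuration
#'
#' Defaults follow the LIECE protocol: 14 A vdW cutoff, interior dielectric
#' 1.0, exterior 78.5, Poisson grid focusing from 1.0 to 0.4 A, and a
#' minimization schedule of 500 steepest-descent plus 1000 conjugate-gradient
#' steps stopping at a gradient RMS of 0.001 kcal/mol/A.
#'
#' @param vdw_cutoff A; LJ pairs beyond this contribute exactly 0.
#' @param coulomb_constant kcal A mol^-1 e^-2.
#' @param eps_interior,eps_exterior solute and solvent dielectric constants.
#' @param grid_spacing_coarse,grid_spacing_fine A; focusing levels.
#' @param grid_margin A beyond the solute extent at the coarse level.
#' @param fine_margin A beyond the solute extent at the fine level.
#' @param sd_steps,cg_steps minimizer step budgets.
#' @param grad_rms_tol kcal/mol/A convergence threshold.
#' @param restraint_k kcal/mol/A^2, harmonic positional restraints to the
#'   input coordinates (stand-in for bonded terms).
#' @param solver_tol relative residual for the Poisson solve.
#' @param solver_max_iter iteration cap for the Poisson solve.
#' @return list of class `liece_energy_config`.
#' @export
energy_config <- function(vdw_cutoff = 14, coulomb_constant = COULOMB_KCAL,
                          eps_interior = 1.0, eps_exterior = 78.5,
                          grid_spacing_coarse = 1.0, grid_spacing_fine = 0.4,
                          grid_margin = 10, fine_margin = 4,
                          sd_steps = 500, cg_steps = 1000,
                          grad_rms_tol = 0.001, restraint_k = 10,
                          solver_tol = 1e-6, solver_max_iter = 10000) {
  stopifnot(vdw_cutoff > 0, eps_exterior >= eps_interior, eps_interior >= 1,
            grid_spacing_fine < grid_spacing_coarse,
            grad_rms_tol > 0, solver_tol > 0, restraint_k >= 0)
  structure(list(
    vdw_cutoff = vdw_cutoff, coulomb_constant = coulomb_constant,
    eps_interior = eps_interior, eps_exterior = eps_exterior,
    grid_spacing_coarse = grid_spacing_coarse,
    grid_spacing_fine = grid_spacing_fine,
    grid_margin = grid_margin, fine_margin = fine_margin,
    sd_steps = sd_steps, cg_steps = cg_steps,
    grad_rms_tol = grad_rms_tol, restraint_k = restraint_k,
    solver_tol = solver_tol, solver_max_iter = solver_max_iter
  ), class = "liece_energy_config")
}

.check_param <- function(x) {
  if (!is_parameterized(x))
    stop("structure has unparameterized atoms (run assign_parameters) ",
         "or missing charges")
}

.pair_indices <- function(x, group_a, group_b) {
  n <- n_atoms(x)
  if (is.null(group_a)) group_a <- seq_len(n)
  if (is.null(group_b)) group_b <- seq_len(n)
  identical_groups <- length(group_a) == length(group_b) &&
    all(sort(group_a) == sort(group_b))
  if (!identical_groups && length(intersect(group_a, group_b)))
    stop("groups must be disjoint or identical")
  list(a = group_a, b = group_b, internal = identical_groups)
}

.pair_dist <- function(x, ia, ib) {
  xyz <- coords(x)
  dx <- outer(xyz[ia, 1], xyz[ib, 1], "-")
  dy <- outer(xyz[ia, 2], xyz[ib, 2], "-")
  dz <- outer(xyz[ia, 3], xyz[ib, 3], "-")
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Lennard-Jones energy between (or within) atom groups
#'
#' `sum over pairs with r <= cutoff of eps_ij [ (rmin_ij/r)^12 -
#' 2 (rmin_ij/r)^6 ]` with Lorentz-Berthelot combination
#' (`eps_ij = sqrt(eps_i eps_j)`, `rmin_ij = (rmin_i + rmin_j)/2`).
#' Truncation is plain: pairs beyond the cutoff contribute exactly 0, no
#' switching or shifting. Identical groups give the total internal energy
#' over all unique pairs; disjoint groups the inter-group energy.
#'
#' @param x parameterized `liece_structure`.
#' @param group_a,group_b integer atom indices (row indices, not serials);
#'   `NULL` means all atoms.
#' @param config [energy_config()].
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(x, group_a = NULL, group_b = NULL,
                      config = energy_config()) {
  .check_param(x)
  g <- .pair_indices(x, group_a, group_b)
  r <- .pair_dist(x, g$a, g$b)
  if (g$internal) r[lower.tri(r, diag = TRUE)] <- Inf
  if (any(r == 0)) stop("coincident atoms (r = 0) in LJ evaluation")
  a <- x$atoms
  epsij <- sqrt(outer(a$eps[g$a], a$eps[g$b]))
  rminij <- outer(a$rmin[g$a], a$rmin[g$b], "+") / 2
  mask <- r <= config$vdw_cutoff
  if (!any(mask)) return(0)
  sr6 <- (rminij[mask] / r[mask])^6
  sum(epsij[mask] * (sr6^2 - 2 * sr6))
}

#' Coulomb energy between (or within) atom groups
#'
#' `sum over pairs of k_e q_i q_j / r`, no cutoff, vacuum dielectric.
#'
#' @inheritParams lj_energy
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(x, group_a = NULL, group_b = NULL,
                           config = energy_config()) {
  .check_param(x)
  g <- .pair_indices(x, group_a, group_b)
  r <- .pair_dist(x, g$a, g$b)
  if (g$internal) r[lower.tri(r, diag = TRUE)] <- Inf
  if (any(r == 0)) stop("coincident atoms (r = 0) in Coulomb evaluation")
  q <- x$atoms$charge
  qq <- outer(q[g$a], q[g$b])
  sum(config$coulomb_constant * qq / r)
}
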