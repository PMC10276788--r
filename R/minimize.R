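## Cartesian energy minimization. Objective = internal LJ (truncated) +
## internal Coulomb + harmonic positional restraints to the input
## coordinates; bonded force-field terms are deliberately absent, the
## restraints take their place (strain relief without a full force field).

.objective <- function(xyz, a, mobile, ref, config) {
  n <- nrow(xyz)
  dx <- outer(xyz[, 1], xyz[, 1], "-")
  dy <- outer(xyz[, 2], xyz[, 2], "-")
  dz <- outer(xyz[, 3], xyz[, 3], "-")
  r2 <- dx^2 + dy^2 + dz^2
  up <- upper.tri(r2)
  if (any(r2[up] == 0)) return(list(E = Inf, G = NULL))
  r <- sqrt(r2)
  epsij <- sqrt(outer(a$eps, a$eps))
  rminij <- outer(a$rmin, a$rmin, "+") / 2
  qq <- config$coulomb_constant * outer(a$charge, a$charge)

  mask <- up & r <= config$vdw_cutoff
  sr6 <- matrix(0, n, n)
  sr6[mask] <- (rminij[mask] / r[mask])^6
  E_lj <- sum(epsij[mask] * (sr6[mask]^2 - 2 * sr6[mask]))
  E_cl <- sum(qq[up] / r[up])
  dref <- xyz - ref
  E_rs <- 0.5 * config$restraint_k * sum(dref^2)

  ## dV/dr / r, symmetric pair matrix
  fr <- matrix(0, n, n)
  m2 <- r <= config$vdw_cutoff & r > 0
  diag(m2) <- FALSE
  sr6f <- matrix(0, n, n)
  sr6f[m2] <- (rminij[m2] / r[m2])^6
  fr[m2] <- -12 * epsij[m2] * (sr6f[m2]^2 - sr6f[m2]) / r2[m2]
  rpos <- r > 0
  fr[rpos] <- fr[rpos] - qq[rpos] / (r2[rpos] * r[rpos])
  diag(fr) <- 0
  gx <- rowSums(fr * dx)
  gy <- rowSums(fr * dy)
  gz <- rowSums(fr * dz)
  G <- cbind(gx, gy, gz) + config$restraint_k * dref
  G[!mobile, ] <- 0
  list(E = E_lj + E_cl + E_rs, G = G)
}

#' Minimize a structure by steepest descent then conjugate gradient
#'
#' Runs up to `sd_steps` steepest-descent iterations followed by up to
#' `cg_steps` Polak-Ribiere conjugate-gradient iterations, each with an
#' Armijo backtracking line search, stopping early once the gradient RMS
#' over mobile coordinates drops to `grad_rms_tol` (kcal/mol/A). The energy
#' never increases across accepted steps; immobile atoms do not move.
#'
#' @param x parameterized `liece_structure`.
#' @param config [energy_config()]; `restraint_k = 0` turns restraints off.
#' @param mobile integer atom indices free to move (default: all).
#' @return list with elements `structure`, `converged`, `final_grad_rms`,
#'   `energy` (kcal/mol) and `n_steps`.
#' @export
minimize_structure <- function(x, config = energy_config(), mobile = NULL) {
  .check_param(x)
  a <- x$atoms
  n <- n_atoms(x)
  mob <- rep(FALSE, n)
  mob[if (is.null(mobile)) seq_len(n) else mobile] <- TRUE
  xyz <- coords(x)
  ref <- xyz
  ob <- .objective(xyz, a, mob, ref, config)
  if (!is.finite(ob$E)) stop("non-finite energy at input coordinates")

  nmob <- 3 * sum(mob)
  grms <- function(G) sqrt(sum(G^2) / nmob)
  budget <- c(rep("sd", config$sd_steps), rep("cg", config$cg_steps))
  converged <- FALSE
  steps <- 0L
  alpha <- 1e-3
  d <- -ob$G
  g_old <- ob$G
  for (phase in budget) {
    if (grms(ob$G) <= config$grad_rms_tol) { converged <- TRUE; break }
    if (phase == "sd") {
      d <- -ob$G
    } else {
      beta <- sum(ob$G * (ob$G - g_old)) / max(sum(g_old^2), 1e-300)
      beta <- max(0, beta)
      d <- -ob$G + beta * d
      if (sum(d * ob$G) >= 0) d <- -ob$G  # restart on non-descent
    }
    g_old <- ob$G
    slope <- sum(d * ob$G)
    ## Armijo backtracking
    step <- alpha
    accepted <- FALSE
    for (ls in 1:40) {
      trial <- xyz + step * d
      obt <- .objective(trial, a, mob, ref, config)
      if (is.finite(obt$E) && obt$E <= ob$E + 1e-4 * step * slope) {
        xyz <- trial; ob <- obt; alpha <- step * 2; accepted <- TRUE
        break
      }
      step <- step / 2
    }
    steps <- steps + 1L
    if (!accepted) { # stuck at line-search resolution
      if (grms(ob$G) <= config$grad_rms_tol) converged <- TRUE
      break
    }
  }
  if (!converged && length(budget) > 0 && grms(ob$G) <= config$grad_rms_tol)
    converged <- TRUE
  list(structure = set_coords(x, xyz), converged = converged,
       final_grad_rms = grms(ob$G), energy = ob$E, n_steps = steps)
}
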