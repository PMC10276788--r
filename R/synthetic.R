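## Synthetic-data layer: energy-affinity tables with known linear
## structure, toy charged pocket-ligand complexes with brute-force
## checkable energies, and decoy poses that violate the filter
## constraints. All generators are pure functions of their spec (seed
## included): the RNG is Mersenne-Twister with inversion normals, seeded
## explicitly, and the caller's RNG state is left untouched.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Specification for a synthetic energy-affinity table
#'
#' Defaults emulate the statistical structure of the fitted models on real
#' series: the vdW term dominates (its coefficient is several-fold larger
#' than the electrostatic ones), vdW and Coulomb interaction terms are
#' negative (favorable), desolvation is a positive penalty, and the
#' resulting dG_exp spans a few kcal/mol with measurement-scale noise.
#'
#' @param alpha,beta,gamma,delta generating coefficients (delta kcal/mol).
#' @param n number of ligands.
#' @param term_ranges named list of `c(low, high)` (kcal/mol) for
#'   `dE_vdw`, `dE_coul`, `dG_solv`; terms are drawn uniformly.
#' @param noise_sd Gaussian noise on dg_exp, kcal/mol.
#' @param seed integer RNG seed.
#' @param dataset_label,docking_program,receptor_model grouping labels.
#' @return list of class `liece_table_spec`.
#' @export
table_spec <- function(alpha = 0.18, beta = 0.018, gamma = 0.06,
                       delta = 0, n = 50,
                       term_ranges = list(dE_vdw = c(-60, -25),
                                          dE_coul = c(-20, -5),
                                          dG_solv = c(8, 25)),
                       noise_sd = 0.5, seed = 1,
                       dataset_label = "synthetic",
                       docking_program = "simulated",
                       receptor_model = "toy") {
  stopifnot(n >= 1, noise_sd >= 0,
            all(vapply(term_ranges, function(r)
              length(r) == 2 && all(is.finite(r)) && r[1] < r[2],
              logical(1))))
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 n = as.integer(n), term_ranges = term_ranges,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 dataset_label = dataset_label,
                 docking_program = docking_program,
                 receptor_model = receptor_model),
            class = "liece_table_spec")
}

#' Generate a synthetic energy-affinity table
#'
#' Energy terms are uniform draws from `spec$term_ranges`;
#' `dg_exp = alpha dE_vdw + beta dE_coul + gamma dG_solv + delta +
#' N(0, noise_sd)`. Identical specs (seed included) give identical tables.
#'
#' @param spec a [table_spec()].
#' @return an energy table (`liece_energy_table` data.frame).
#' @export
gen_energy_table <- function(spec = table_spec()) {
  stopifnot(inherits(spec, "liece_table_spec"))
  .with_seed(spec$seed, {
    tr <- spec$term_ranges
    d <- data.frame(
      ligand_id = sprintf("L%03d", seq_len(spec$n)),
      dE_vdw = stats::runif(spec$n, tr$dE_vdw[1], tr$dE_vdw[2]),
      dE_coul = stats::runif(spec$n, tr$dE_coul[1], tr$dE_coul[2]),
      dG_solv = stats::runif(spec$n, tr$dG_solv[1], tr$dG_solv[2]),
      stringsAsFactors = FALSE
    )
    d$dg_exp <- spec$alpha * d$dE_vdw + spec$beta * d$dE_coul +
      spec$gamma * d$dG_solv + spec$delta +
      stats::rnorm(spec$n, 0, spec$noise_sd)
    d$dataset_label <- spec$dataset_label
    d$docking_program <- spec$docking_program
    d$receptor_model <- spec$receptor_model
    class(d) <- c("liece_energy_table", "data.frame")
    d
  })
}

#' Default nonbonded parameter table for toy systems
#'
#' Element-keyed LJ well depths, pair-minimum contributions and Born radii
#' of magnitudes typical for biomolecular force fields.
#'
#' @return a `liece_parameters` table with entries for H, C, N, O.
#' @export
default_parameter_table <- function() {
  parameter_table(list(
    H = c(0.030, 1.60, 1.20),
    C = c(0.100, 4.00, 1.90),
    N = c(0.170, 3.70, 1.70),
    O = c(0.120, 3.40, 1.60)
  ))
}

#' Specification for a toy pocket-ligand complex
#'
#' @param pocket_atoms carbon atoms forming the spherical pocket cage.
#' @param pocket_charge total charge (e) on the anchor carboxylate-like
#'   oxygen pair at the pocket bottom.
#' @param ligand_atoms ligand size: one cationic nitrogen, a chain of
#'   carbons toward the pocket mouth, and one terminal polar oxygen.
#' @param ligand_charge charge (e) on the cationic amine-like nitrogen.
#' @param pocket_radius cage radius, A.
#' @param jitter amplitude of the deterministic coordinate jitter, A.
#' @param seed integer RNG seed.
#' @return list of class `liece_complex_spec`.
#' @export
complex_spec <- function(pocket_atoms = 48, pocket_charge = -1,
                         ligand_atoms = 5, ligand_charge = 1,
                         pocket_radius = 5.0, jitter = 0.04, seed = 1) {
  stopifnot(pocket_atoms >= 1, ligand_atoms >= 2, pocket_radius > 3)
  structure(list(pocket_atoms = as.integer(pocket_atoms),
                 pocket_charge = pocket_charge,
                 ligand_atoms = as.integer(ligand_atoms),
                 ligand_charge = ligand_charge,
                 pocket_radius = pocket_radius,
                 jitter = jitter, seed = as.integer(seed)),
            class = "liece_complex_spec")
}

## deterministic toy geometry, pocket axis = +z, mouth opens toward +z
.toy_geometry <- function(spec, seed) {
  R <- spec$pocket_radius
  .with_seed(seed, {
    ## cage: spherical Fibonacci lattice, mouth cone (half-angle 62 deg)
    ## removed, sites colliding with the anchor pair removed
    anchor <- rbind(OD1 = c(-1.1, 0, -R + 0.8), OD2 = c(1.1, 0, -R + 0.8))
    m <- ceiling(spec$pocket_atoms / 0.7)
    repeat {
      pts <- .sphere_points(m) * R
      keep <- pts[, 3] <= R * cos(62 * pi / 180)
      pts <- pts[keep, , drop = FALSE]
      da <- pmin(sqrt(colSums((t(pts) - anchor[1, ])^2)),
                 sqrt(colSums((t(pts) - anchor[2, ])^2)))
      pts <- pts[da > 2.2, , drop = FALSE]
      if (nrow(pts) >= spec$pocket_atoms) break
      m <- m + 4L
    }
    ## thin to the requested count with an even stride so the whole cup
    ## (bottom to rim) stays covered
    pts <- pts[order(pts[, 3]), , drop = FALSE]
    pts <- pts[unique(round(seq(1, nrow(pts),
                                length.out = spec$pocket_atoms))), ,
               drop = FALSE]

    nlig <- spec$ligand_atoms
    n_carbon <- nlig - 2L
    lig <- rbind(N1 = c(0, 0, -1.1))
    if (n_carbon > 0)
      lig <- rbind(lig, matrix(
        c(rep(0, 2 * n_carbon), seq(0.5, by = 1.55, length.out = n_carbon)),
        ncol = 3, dimnames = list(paste0("C", seq_len(n_carbon)), NULL)))
    top_z <- if (n_carbon > 0) 0.5 + 1.55 * (n_carbon - 1) else 0.5
    lig <- rbind(lig, O1 = c(1.5, 0, min(top_z, R - 1.2) + 0.4))

    jit <- function(x) x + matrix(stats::runif(length(x), -spec$jitter,
                                               spec$jitter), ncol = 3)
    list(cage = jit(pts), anchor = anchor, ligand = jit(lig),
         frame = list(axis = c(0, 0, 1),
                      anchor_center = colMeans(anchor),
                      bury_site = c(0, 1.9, -0.4)))
  })
}

#' Generate a toy charged pocket-ligand complex
#'
#' A rigid spherical cage of carbon atoms with an open mouth along +z and
#' an anionic carboxylate-like oxygen pair (residue ASP 155) at the bottom
#' forms the pocket; the ligand is a cationic nitrogen placed 3-4 A from
#' the anchor pair with a short carbon chain toward the mouth and a
#' solvent-facing polar oxygen. All atoms are parameterized from
#' [default_parameter_table()]. Specs whose jitter produces an atom
#' overlap (< 1.5 A) are regenerated with an incremented seed
#' (deterministically), up to 100 attempts.
#'
#' @param spec a [complex_spec()].
#' @return list with `complex_structure`, `protein`, `ligand`
#'   (parameterized structures; the ligand carries the pocket frame as
#'   `attr(, "frame")`) and `spec`.
#' @export
gen_toy_complex <- function(spec = complex_spec()) {
  stopifnot(inherits(spec, "liece_complex_spec"))
  params <- default_parameter_table()
  for (attempt in 0:99) {
    g <- .toy_geometry(spec, spec$seed + attempt)
    all_xyz <- rbind(g$cage, g$anchor, g$ligand)
    if (min(stats::dist(all_xyz)) >= 1.5) {
      nc <- nrow(g$cage)
      prot_atoms <- data.frame(
        serial = seq_len(nc + 2L),
        name = c(sprintf("C%d", seq_len(nc)), "OD1", "OD2"),
        element = c(rep("C", nc), "O", "O"),
        x = c(g$cage[, 1], g$anchor[, 1]),
        y = c(g$cage[, 2], g$anchor[, 2]),
        z = c(g$cage[, 3], g$anchor[, 3]),
        charge = c(rep(0, nc), rep(spec$pocket_charge / 2, 2)),
        resname = c(rep("PCK", nc), "ASP", "ASP"),
        resno = c(rep(1L, nc), 155L, 155L),
        chain = "A", stringsAsFactors = FALSE
      )
      protein <- assign_parameters(
        molecular_structure(prot_atoms, "toy_pocket", "receptor"), params)
      nl <- nrow(g$ligand)
      lig_atoms <- data.frame(
        serial = seq_len(nl),
        name = rownames(g$ligand),
        element = substr(rownames(g$ligand), 1, 1),
        x = g$ligand[, 1], y = g$ligand[, 2], z = g$ligand[, 3],
        charge = c(spec$ligand_charge, rep(0, nl - 1)),
        resname = "LIG", resno = 1L, chain = "B",
        stringsAsFactors = FALSE
      )
      ligand <- assign_parameters(
        molecular_structure(lig_atoms, "toy_ligand", "ligand"), params)
      attr(ligand, "frame") <- g$frame
      return(list(
        complex_structure = combine_structures(protein, ligand,
                                               "toy_complex"),
        protein = protein, ligand = ligand, spec = spec
      ))
    }
  }
  stop("could not generate an overlap-free toy complex in 100 attempts")
}

#' Generate a decoy pose violating a named filter constraint
#'
#' Modes: `"flip"` rotates the pose 180 degrees about an axis through its
#' centroid perpendicular to the pocket axis, pointing the cationic center
#' away from the anchor (an involution: flipping twice restores the pose);
#' `"strand_donor"` relocates the pose's solvent-facing polar oxygen to a
#' buried site with no hydrogen-bond partner; `"expose_apolar"` slides the
#' apolar chain (every atom but the cationic nitrogen) out of the pocket
#' mouth along the pocket axis.
#'
#' @param pose a toy ligand pose carrying `attr(, "frame")` (from
#'   [gen_toy_complex()]), or supply `frame` explicitly.
#' @param mode `"flip"`, `"strand_donor"` or `"expose_apolar"`.
#' @param frame pocket frame (list with `axis`, `anchor_center`,
#'   `bury_site`).
#' @return the transformed pose (frame attribute preserved).
#' @export
gen_decoy_pose <- function(pose, mode = c("flip", "strand_donor",
                                          "expose_apolar"),
                           frame = attr(pose, "frame")) {
  mode <- match.arg(mode)
  if (is.null(frame))
    stop("pose carries no pocket frame; supply `frame`")
  out <- switch(mode,
    flip = {
      ## axis perpendicular to the pocket axis through the centroid
      perp <- if (abs(frame$axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      perp <- perp - sum(perp * frame$axis) * frame$axis
      transform_structure(pose, rotation_matrix(perp, 180))
    },
    strand_donor = {
      a <- pose$atoms
      cand <- which(a$element %in% c("N", "O") &
                      !(a$element == "N" & !is.na(a$charge) &
                          a$charge >= 0.5))
      if (!length(cand))
        stop("strand_donor not achievable: pose has no non-cationic ",
             "polar atom")
      p <- pose
      p$atoms[cand[1], c("x", "y", "z")] <- as.list(frame$bury_site)
      p
    },
    expose_apolar = {
      a <- pose$atoms
      keep <- which(a$element == "N" & !is.na(a$charge) & a$charge >= 0.5)
      if (length(keep) == nrow(a))
        stop("expose_apolar not achievable: no apolar atoms")
      p <- pose
      mov <- setdiff(seq_len(nrow(a)), keep)
      shift <- 5 * frame$axis
      p$atoms$x[mov] <- p$atoms$x[mov] + shift[1]
      p$atoms$y[mov] <- p$atoms$y[mov] + shift[2]
      p$atoms$z[mov] <- p$atoms$z[mov] + shift[3]
      p
    }
  )
  attr(out, "frame") <- frame
  out
}
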