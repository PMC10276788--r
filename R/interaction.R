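## Assembly of the three LIECE interaction terms. Every Delta term is the
## complex - protein - ligand difference of component energies computed
## under one configuration.

#' LIECE interaction terms for a protein-ligand complex
#'
#' Computes `dE_vdw`, `dE_coul` and `dG_solv`, each as
#' `E(complex) - E(protein) - E(ligand)`. With `minimize_first = TRUE` each
#' component is relaxed with [minimize_structure()] (restrained Cartesian
#' minimization) before the single-point evaluation: the complex is
#' minimized as a whole and split at the minimized coordinates, while the
#' free protein and ligand are minimized separately from their input
#' coordinates. Without minimization, components are evaluated at identical
#' coordinates, so the vdW and Coulomb differences reduce exactly to the
#' protein-ligand inter-group sums.
#'
#' @param complex_structure,protein,ligand parameterized structures; the
#'   complex must contain the protein's atoms followed by the ligand's.
#' @param config [energy_config()].
#' @param minimize_first relax components before evaluation?
#' @param terms which terms to compute (`"vdw"`, `"coul"`, `"solv"`);
#'   vdW-only models do not need the Poisson solves, and widely separated
#'   components make the solvation grid needlessly large.
#' @return list with `terms` (named vector `dE_vdw`, `dE_coul`, `dG_solv`,
#'   kcal/mol), `components` (3 x 3 data.frame of per-component energies)
#'   and, when minimized, the relaxed structures and convergence flags.
#' @export
interaction_terms <- function(complex_structure, protein, ligand,
                              config = energy_config(),
                              minimize_first = FALSE,
                              terms = c("vdw", "coul", "solv")) {
  terms <- match.arg(terms, several.ok = TRUE)
  np <- n_atoms(protein); nl <- n_atoms(ligand)
  if (n_atoms(complex_structure) != np + nl)
    stop("complex atom count (", n_atoms(complex_structure),
         ") != protein + ligand (", np + nl, ")")
  for (s in list(complex_structure, protein, ligand)) .check_param(s)

  minimized <- NULL
  if (minimize_first) {
    mc <- minimize_structure(complex_structure, config)
    mp <- minimize_structure(protein, config)
    ml <- minimize_structure(ligand, config)
    complex_structure <- mc$structure
    ## free forms relaxed separately; bound forms taken from the relaxed
    ## complex would double-count strain, so protein/ligand components are
    ## the separately minimized free forms
    protein <- mp$structure
    ligand <- ml$structure
    minimized <- list(complex = mc, protein = mp, ligand = ml)
  }

  comp <- function(s) c(
    E_vdw = if ("vdw" %in% terms) lj_energy(s, config = config) else NA,
    E_coul = if ("coul" %in% terms) coulomb_energy(s, config = config)
             else NA,
    G_solv = if ("solv" %in% terms) solvation_energy(s, config) else NA
  )
  ec <- comp(complex_structure); ep <- comp(protein); el <- comp(ligand)
  delta <- c(dE_vdw = ec[["E_vdw"]] - ep[["E_vdw"]] - el[["E_vdw"]],
             dE_coul = ec[["E_coul"]] - ep[["E_coul"]] - el[["E_coul"]],
             dG_solv = ec[["G_solv"]] - ep[["G_solv"]] - el[["G_solv"]])
  components <- data.frame(rbind(complex = ec, protein = ep, ligand = el))
  out <- list(terms = delta, components = components)
  if (!is.null(minimized)) out$minimized <- minimized
  out
}
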