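# Nonbonded terms against closed forms and brute-force double loops;
# minimizer against the analytic LJ minimum.

test_that("LJ pair energy reproduces the pair-minimum identity and cutoff", {
  tbl <- parameter_table(list(C = c(0.5, 4.0, 1.9)))
  dimer_at <- function(r) make_structure(rbind(c(0, 0, 0), c(r, 0, 0)),
                                         params = tbl)
  # at r = rmin the energy is exactly -eps
  expect_equal(lj_energy(dimer_at(4.0)), -0.5)
  # beyond the cutoff: exactly zero (plain truncation)
  expect_identical(lj_energy(dimer_at(15)), 0)
  expect_identical(lj_energy(dimer_at(14.001)), 0)
  expect_lt(lj_energy(dimer_at(13.999)), 0)
  # coincident atoms are a geometry error
  expect_error(lj_energy(dimer_at(0)), "r = 0")
})

test_that("Coulomb energy matches its defining constant", {
  s <- make_structure(rbind(c(0, 0, 0), c(COULOMB_KCAL, 0, 0)), charge = 1)
  expect_equal(coulomb_energy(s), 1.0)
  s0 <- make_structure(rbind(c(0, 0, 0), c(3, 0, 0)), charge = 0)
  expect_equal(coulomb_energy(s0), 0)
  spm <- make_structure(rbind(c(0, 0, 0), c(3, 0, 0)), charge = c(1, -1))
  expect_equal(coulomb_energy(spm), -110.69, tolerance = 1e-4)
})

test_that("group energies equal brute-force double-loop sums", {
  for (seed in 1:4) {
    s <- random_cluster(8, seed)
    expect_equal(lj_energy(s), brute_lj(s, 1:8, 1:8), tolerance = 1e-12)
    expect_equal(coulomb_energy(s), brute_coulomb(s, 1:8, 1:8),
                 tolerance = 1e-12)
    ga <- 1:3; gb <- 4:8
    expect_equal(lj_energy(s, ga, gb), brute_lj(s, ga, gb),
                 tolerance = 1e-12)
    expect_equal(coulomb_energy(s, ga, gb), brute_coulomb(s, ga, gb),
                 tolerance = 1e-12)
  }
  s <- random_cluster(8, 9)
  expect_error(lj_energy(s, 1:4, 3:8), "disjoint")
})

test_that("unparameterized atoms are rejected, not zeroed", {
  atoms <- data.frame(serial = 1:2, name = c("C1", "C2"), element = "C",
                      x = c(0, 4), y = 0, z = 0, charge = 0)
  s <- molecular_structure(atoms)
  expect_error(lj_energy(s), "unparameterized")
  expect_error(coulomb_energy(s), "unparameterized")
})

test_that("minimization finds the analytic LJ dimer minimum", {
  tbl <- parameter_table(list(C = c(0.5, 4.0, 1.9)))
  s <- make_structure(rbind(c(0, 0, 0), c(1.3 * 4.0, 0, 0)), params = tbl)
  cfg <- energy_config(restraint_k = 0)
  res <- minimize_structure(s, cfg)
  sep <- abs(diff(coords(res$structure)[, 1]))
  expect_lt(abs(sep - 4.0), 1e-3)
  expect_true(res$converged)
  expect_equal(res$energy, -0.5, tolerance = 1e-6)
  expect_lte(res$final_grad_rms, res$n_steps * 0 + Inf)  # finite
  # energy never increased relative to the start
  expect_lte(res$energy,
             lj_energy(s, config = cfg) + coulomb_energy(s, config = cfg))
})

test_that("minimizer respects convergence, budgets and immobile atoms", {
  tbl <- parameter_table(list(C = c(0.5, 4.0, 1.9)))
  at_min <- make_structure(rbind(c(0, 0, 0), c(4.0, 0, 0)), params = tbl)
  cfg <- energy_config(restraint_k = 0)
  res <- minimize_structure(at_min, cfg)
  expect_true(res$converged)
  expect_lt(max(abs(coords(res$structure) - coords(at_min))), 1e-6)

  s <- make_structure(rbind(c(0, 0, 0), c(5.2, 0, 0)), params = tbl)
  zero <- minimize_structure(s, energy_config(sd_steps = 0, cg_steps = 0,
                                              restraint_k = 0))
  expect_identical(coords(zero$structure), coords(s))
  expect_false(zero$converged)

  fixed <- minimize_structure(s, cfg, mobile = 2)
  expect_equal(coords(fixed$structure)[1, ], coords(s)[1, ])
  expect_false(isTRUE(all.equal(coords(fixed$structure)[2, ],
                                coords(s)[2, ])))
})

test_that("restraints hold atoms near their input positions", {
  tbl <- parameter_table(list(C = c(0.5, 4.0, 1.9)))
  s <- make_structure(rbind(c(0, 0, 0), c(5.2, 0, 0)), params = tbl)
  free <- minimize_structure(s, energy_config(restraint_k = 0))
  held <- minimize_structure(s, energy_config(restraint_k = 10))
  drift_free <- max(abs(coords(free$structure) - coords(s)))
  drift_held <- max(abs(coords(held$structure) - coords(s)))
  expect_lt(drift_held, drift_free)
})

test_that("interaction terms reduce to inter-group sums at fixed coordinates", {
  toy <- gen_toy_complex()
  it <- interaction_terms(toy$complex_structure, toy$protein, toy$ligand,
                          terms = c("vdw", "coul"))
  np <- n_atoms(toy$protein)
  nc <- n_atoms(toy$complex_structure)
  expect_equal(it$terms[["dE_vdw"]],
               lj_energy(toy$complex_structure, 1:np, (np + 1):nc),
               tolerance = 1e-9)
  expect_equal(it$terms[["dE_coul"]],
               coulomb_energy(toy$complex_structure, 1:np, (np + 1):nc),
               tolerance = 1e-9)
  # additivity: differences of independently computed components
  expect_equal(it$terms[["dE_vdw"]],
               it$components["complex", "E_vdw"] -
               it$components["protein", "E_vdw"] -
               it$components["ligand", "E_vdw"], tolerance = 1e-9)
})

test_that("widely separated components give zero vdW and analytic Coulomb", {
  toy <- gen_toy_complex()
  far <- transform_structure(toy$ligand, shift = c(0, 0, 100))
  cx <- combine_structures(toy$protein, far)
  it <- interaction_terms(cx, toy$protein, far, terms = c("vdw", "coul"))
  expect_identical(it$terms[["dE_vdw"]], 0)
  np <- n_atoms(toy$protein)
  expect_equal(it$terms[["dE_coul"]],
               brute_coulomb(cx, 1:np, (np + 1):n_atoms(cx)),
               tolerance = 1e-10)
  expect_error(interaction_terms(cx, toy$protein, toy$protein,
                                 terms = "vdw"), "atom count")
})

test_that("a cationic ligand in an anionic pocket binds electrostatically but pays desolvation", {
  toy <- gen_toy_complex()
  it <- interaction_terms(toy$complex_structure, toy$protein, toy$ligand)
  expect_lt(it$terms[["dE_coul"]], 0)
  expect_gt(it$terms[["dG_solv"]], 0)
})

test_that("rigid motion leaves the energy terms unchanged", {
  toy <- gen_toy_complex()
  Rm <- rotation_matrix(c(1, 1, 0), 30)
  move <- function(s) transform_structure(s, Rm, shift = c(3.1, -2.2, 5.7),
                                          center = c(0, 0, 0))
  cx <- toy$complex_structure
  expect_lt(abs(lj_energy(move(cx)) - lj_energy(cx)), 1e-6)
  expect_lt(abs(coulomb_energy(move(cx)) - coulomb_energy(cx)), 1e-6)
  g1 <- solvation_energy(toy$ligand)
  g2 <- solvation_energy(move(toy$ligand))
  expect_lt(abs(g2 - g1) / abs(g1), 0.005)
  # pure translation re-centers the grid: equality to solver tolerance
  g3 <- solvation_energy(transform_structure(toy$ligand,
                                             shift = c(17.3, -4.9, 8.1)))
  expect_lt(abs(g3 - g1) / abs(g1), 1e-4)
})

test_that("minimize_first relaxes strain before the single-point evaluation", {
  # ligand slightly compressed against the pair-minimum distance
  tbl <- parameter_table(list(C = c(0.3, 4.0, 1.9), N = c(0.2, 3.7, 1.7)))
  prot <- make_structure(rbind(c(0, 0, 0)), params = tbl)
  lig <- make_structure(rbind(c(3.4, 0, 0)), element = "N", params = tbl)
  cx <- combine_structures(prot, lig)
  cfg <- energy_config(restraint_k = 0.5)
  raw <- interaction_terms(cx, prot, lig, cfg, terms = "vdw")
  rel <- interaction_terms(cx, prot, lig, cfg, minimize_first = TRUE,
                           terms = "vdw")
  expect_lt(rel$terms[["dE_vdw"]], raw$terms[["dE_vdw"]])
  expect_true(rel$minimized$complex$converged)
})
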