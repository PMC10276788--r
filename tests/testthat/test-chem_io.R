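test_that("PDB fixtures round-trip through write and read", {
  pdb <- write_lines_tmp(c(
    "ATOM      1  N   ASP A 155      10.000  11.500  12.250  1.00  0.00           N",
    "ATOM      2  CA  ASP A 155      11.000  11.500  12.250  1.00  0.00           C",
    "ATOM      3  OD1 ASP A 155      12.125  10.750  13.500  1.00  0.00           O",
    "END"), ".pdb")
  s <- read_structure(pdb, kind = "receptor")
  expect_equal(n_atoms(s), 3)
  expect_equal(s$atoms$name, c("N", "CA", "OD1"))
  expect_equal(coords(s)[1, ], c(x = 10, y = 11.5, z = 12.25))
  expect_equal(s$atoms$resno, rep(155L, 3))

  out <- tempfile(fileext = ".pdb")
  write_structure(s, out)
  s2 <- read_structure(out)
  expect_equal(coords(s2), coords(s))
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(s2$atoms$element, s$atoms$element)
})

test_that("mol2 charges are preserved exactly", {
  mol2 <- write_lines_tmp(c(
    "@<TRIPOS>MOLECULE", "toy", " 2 1 0 0 0", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    "      1 N1          0.0000    0.0000    0.0000 N.4       1 LIG         0.5000",
    "      2 C1          1.5000    0.0000    0.0000 C.3       1 LIG        -0.5000",
    "@<TRIPOS>BOND",
    "     1    1    2 1"), ".mol2")
  s <- read_structure(mol2, kind = "ligand")
  expect_equal(s$atoms$charge, c(0.5, -0.5))
  expect_equal(s$atoms$element, c("N", "C"))

  out <- tempfile(fileext = ".mol2")
  write_structure(s, out)
  s2 <- read_structure(out)
  expect_equal(s2$atoms$charge, s$atoms$charge)
  expect_equal(coords(s2), coords(s))
})

test_that("SDF input is parsed with coordinates", {
  sdf <- write_lines_tmp(c(
    "toymol", "  fixture", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0",
    "M  END", "$$$$"), ".sdf")
  s <- read_structure(sdf, kind = "ligand")
  expect_equal(n_atoms(s), 2)
  expect_equal(s$atoms$element, c("N", "C"))
  expect_equal(coords(s)[2, 1], 1.5, ignore_attr = TRUE)
})

test_that("malformed structures are rejected with informative errors", {
  dup <- write_lines_tmp(c(
    "ATOM      7  N   ASP A 155      10.000  11.500  12.250  1.00  0.00           N",
    "ATOM      7  CA  ASP A 155      11.000  11.500  12.250  1.00  0.00           C",
    "END"), ".pdb")
  expect_error(read_structure(dup), "7")

  bad <- write_lines_tmp(c(
    "ATOM  xxxxx  N   ASP A 155      10.000  11.500  12.250  1.00  0.00           N",
    "END"), ".pdb")
  expect_error(read_structure(bad), "line 1")

  atoms <- data.frame(serial = 1, name = "Q1", element = "Qq",
                      x = 0, y = 0, z = 0)
  expect_error(molecular_structure(atoms), "Q1")
})

test_that("parameter assignment covers all atoms or fails whole", {
  tbl <- parameter_table(list(C = c(0.1, 4.0, 1.9)))
  s <- make_structure(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
                      params = tbl)
  expect_equal(s$atoms$eps, rep(0.1, 3))
  expect_equal(s$atoms$rmin, rep(4.0, 3))
  expect_equal(s$atoms$born_radius, rep(1.9, 3))

  atoms <- data.frame(serial = 1:2, name = c("C1", "N1"),
                      element = c("C", "N"), x = c(0, 3), y = 0, z = 0,
                      charge = 0)
  sN <- molecular_structure(atoms)
  expect_error(assign_parameters(sN, tbl), "N")
  # failed assignment leaves nothing partially set
  expect_true(all(is.na(sN$atoms$eps)))

  tbl2 <- parameter_table(list(C = c(0.1, 4.0, 1.9),
                               CSP = c(0.2, 3.0, 1.5)))
  s2 <- assign_parameters(
    molecular_structure(data.frame(serial = 1:2, name = c("C1", "C2"),
                                   element = "C", x = c(0, 3), y = 0,
                                   z = 0, charge = 0)),
    tbl2, overrides = c(C2 = "CSP"))
  expect_equal(s2$atoms$eps, c(0.1, 0.2))
  expect_equal(s2$atoms$rmin, c(4.0, 3.0))
})

test_that("affinity tables convert Ki to dG on the molar standard state", {
  csv <- write_lines_tmp(c("ligand_id,ki_molar", "L1,1.0", "L2,1e-9"), ".csv")
  aff <- read_affinity_table(csv)
  expect_equal(aff$dg_exp[1], 0.0)
  expect_lt(aff$dg_exp[2], 0)

  nmol <- write_lines_tmp(c("ligand_id,ki_nM", "L1,1"), ".csv")
  expect_equal(read_affinity_table(nmol)$dg_exp, aff$dg_exp[2])

  pki <- write_lines_tmp(c("ligand_id,pki", "L1,8.27"), ".csv")
  expect_equal(read_affinity_table(pki)$dg_exp, -11.27, tolerance = 0.01)

  expect_error(read_affinity_table(
    write_lines_tmp(c("ligand_id,ki_molar", "L1,-2"), ".csv")), "row")
  expect_error(read_affinity_table(
    write_lines_tmp(c("ligand_id,ki_molar", "L1,1", "L1,2"), ".csv")),
    "L1")
  expect_error(read_affinity_table(
    write_lines_tmp(c("ligand_id,ki_molar,pki", "L1,1,8"), ".csv")),
    "exactly one")
})

test_that("affinity conversion is monotone in Ki", {
  set.seed(11)
  ki <- sort(10^runif(25, -12, 0))
  expect_true(all(diff(ki_to_dg(ki)) > 0))
})

test_that("energy tables honor column maps, filters and validation", {
  csv <- write_lines_tmp(c(
    "ligand_id,dE_vdw,dE_coul,dG_solv,dg_exp,dataset_label,docking_program,receptor_model",
    "L1,-40.5,-10.25,12.125,-9.5,2Cdrugs,HYBRID,inactRisp",
    "L2,-35.0,-8.0,10.0,-8.75,NBPhe,DOCK3.7,inactRisp"), ".csv")
  rows <- read_energy_table(csv)
  expect_equal(nrow(rows), 2)
  expect_equal(rows$dE_vdw, c(-40.5, -35.0))
  sub <- subset_energy_table(rows, dataset_label = "2Cdrugs")
  expect_equal(sub$ligand_id, "L1")

  renamed <- write_lines_tmp(c(
    "id,dEvdw,dEcoul,dGsolv,dGexp",
    "L1,-40.5,-10.25,12.125,-9.5"), ".csv")
  rows2 <- read_energy_table(renamed, column_map = c(
    ligand_id = "id", dE_vdw = "dEvdw", dE_coul = "dEcoul",
    dG_solv = "dGsolv", dg_exp = "dGexp"))
  expect_equal(rows2$dE_vdw, rows$dE_vdw[1])
  expect_equal(rows2$dG_solv, rows$dG_solv[1])

  expect_error(read_energy_table(renamed), "column_map")
  badnum <- write_lines_tmp(c(
    "ligand_id,dE_vdw,dE_coul,dG_solv,dg_exp",
    "L1,oops,-8,10,-9"), ".csv")
  expect_error(read_energy_table(badnum), "row 1")
})

test_that("energy tables round-trip through the canonical writer", {
  tab <- gen_energy_table(table_spec(n = 8, seed = 5))
  f <- tempfile(fileext = ".csv")
  write_energy_table(tab, f, comments = "fixture")
  back <- read_energy_table(f)
  for (col in c("dE_vdw", "dE_coul", "dG_solv", "dg_exp"))
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-12)
})
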