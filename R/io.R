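## File I/O: molecular structures (PDB via bio3d, mol2 via bio3d, SDF via
## ChemmineR), nonbonded parameter tables, affinity tables and energy-term
## tables (CSV, UTF-8, header row; lines starting with '#' are provenance
## comments and skipped).

#' Read a molecular structure from PDB, mol2 or SDF
#'
#' PDB files carry no partial charges; supply them through `charges`, a CSV
#' with columns `serial,charge` (elementary charge units). mol2 TRIPOS
#' charges and SDF `M  CHG`/property-block charges are honored.
#'
#' @param path input file.
#' @param format `"pdb"`, `"mol2"` or `"sdf"`; default guessed from the
#'   file extension.
#' @param kind structure kind stored on the result (`"receptor"`,
#'   `"ligand"`, `"complex"`, `"other"`).
#' @param charges optional path to a sidecar charge CSV (PDB only).
#' @return a [molecular_structure()].
#' @export
read_structure <- function(path, format = NULL, kind = "other",
                           charges = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("pdb", "mol2", "sdf"))
  x <- switch(format,
    pdb = .read_pdb(path, charges),
    mol2 = .read_mol2(path),
    sdf = .read_sdf(path)
  )
  x$kind <- kind
  x
}

.read_pdb <- function(path, charges = NULL) {
  ## pre-check duplicate serials so the error names the serial, not a
  ## downstream symptom
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  serials <- suppressWarnings(as.integer(substr(lines[rec], 7, 11)))
  if (anyNA(serials))
    stop("malformed ATOM/HETATM record at line ",
         which(rec)[which(is.na(serials))[1]], " of ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  a <- pdb$atom
  atoms <- data.frame(
    serial = a$eleno, name = a$elety, element = a$elesy,
    x = a$x, y = a$y, z = a$z,
    resname = a$resid, resno = a$resno,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    stringsAsFactors = FALSE
  )
  if (!is.null(charges)) {
    q <- utils::read.csv(charges, comment.char = "#")
    if (!all(c("serial", "charge") %in% names(q)))
      stop("charge sidecar must have columns serial,charge")
    idx <- match(atoms$serial, q$serial)
    if (anyNA(idx))
      stop("charge sidecar lacks serial(s): ",
           paste(atoms$serial[is.na(idx)], collapse = ", "))
    atoms$charge <- q$charge[idx]
  }
  molecular_structure(atoms, title = basename(path))
}

.read_mol2 <- function(path) {
  m <- suppressWarnings(bio3d::read.mol2(path))
  a <- m$atom
  atoms <- data.frame(
    serial = a$eleno, name = a$elena,
    element = sub("\\..*$", "", a$elety),
    x = a$x, y = a$y, z = a$z, charge = a$charge,
    resname = a$resid, resno = a$resno,
    stringsAsFactors = FALSE
  )
  molecular_structure(atoms, title = if (length(m$name)) m$name[1]
                      else basename(path))
}

.read_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("SDF input requires the ChemmineR package")
  sdfs <- ChemmineR::read.SDFset(path)
  sdf <- sdfs[[1]]
  ab <- ChemmineR::atomblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  ## formal charges from the atom block's charge column (V3 field, already
  ## decoded by ChemmineR where present), else 0
  q <- if ("charge" %in% colnames(ab)) ab[, "charge"] else rep(0, n)
  atoms <- data.frame(
    serial = seq_len(n),
    name = paste0(el, seq_len(n)),
    element = el,
    x = ab[, 1], y = ab[, 2], z = ab[, 3],
    charge = as.numeric(q),
    stringsAsFactors = FALSE
  )
  molecular_structure(atoms, title = ChemmineR::sdfid(sdfs)[1])
}

#' Write a molecular structure to PDB or mol2
#'
#' Coordinates are written with 3 (PDB) or 4 (mol2) decimals and charges
#' with 4 decimals, matching what [read_structure()] parses back, so values
#' expressed at that precision round-trip exactly.
#'
#' @param x a `liece_structure`.
#' @param path output file.
#' @param format `"pdb"` or `"mol2"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("pdb", "mol2"))
  a <- x$atoms
  if (format == "pdb") {
    el <- ifelse(nchar(a$element) == 1, paste0(" ", a$element), a$element)
    nm <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
                 sprintf("%-4s", a$name))
    lines <- sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$serial, nm, substr(a$resname, 1, 3), substr(a$chain, 1, 1),
      a$resno, a$x, a$y, a$z, 1, 0, el
    )
    writeLines(c(lines, "END"), path)
  } else {
    hdr <- c("@<TRIPOS>MOLECULE",
             if (nzchar(x$title)) x$title else "untitled",
             sprintf("%5d %5d %5d %5d %5d", nrow(a), 0L, 0L, 0L, 0L),
             "SMALL", "USER_CHARGES", "@<TRIPOS>ATOM")
    body <- sprintf("%7d %-8s %10.4f %10.4f %10.4f %-8s %4d %-8s %10.4f",
                    a$serial, a$name, a$x, a$y, a$z,
                    ifelse(is.na(a$element), "Du", a$element),
                    a$resno, a$resname,
                    ifelse(is.na(a$charge), 0, a$charge))
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

#' Read a nonbonded parameter table
#'
#' CSV with columns `type,eps,rmin,born_radius`: LJ well depth (kcal/mol),
#' LJ pair-minimum contribution (Angstrom) and Born radius (Angstrom) per
#' atom-type key.
#'
#' @param path CSV file.
#' @return a named list mapping type key to `c(eps, rmin, born_radius)`,
#'   of class `liece_parameters`.
#' @export
read_parameter_table <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("type", "eps", "rmin", "born_radius")
  if (!all(need %in% names(d)))
    stop("parameter table must have columns ", paste(need, collapse = ","))
  parameter_table(stats::setNames(
    lapply(seq_len(nrow(d)),
           function(i) c(eps = d$eps[i], rmin = d$rmin[i],
                         born_radius = d$born_radius[i])),
    d$type
  ))
}

#' Construct a parameter table from a named list
#'
#' @param entries named list; each element `c(eps, rmin, born_radius)`.
#' @return object of class `liece_parameters`.
#' @export
parameter_table <- function(entries) {
  if (anyDuplicated(names(entries)))
    stop("duplicate type keys in parameter table")
  for (k in names(entries)) {
    v <- entries[[k]]
    if (length(v) != 3 || any(!is.finite(v)))
      stop("parameter entry '", k, "' must be 3 finite numbers")
    if (v[1] < 0 || v[2] <= 0 || v[3] <= 0)
      stop("parameter entry '", k,
           "' violates eps >= 0, rmin > 0, born_radius > 0")
    entries[[k]] <- stats::setNames(as.numeric(v),
                                    c("eps", "rmin", "born_radius"))
  }
  structure(entries, class = "liece_parameters")
}

#' Attach nonbonded parameters to every atom
#'
#' The type key defaults to the element symbol; `overrides` maps individual
#' atom names (or serials given as `"serial:<n>"`) to other keys. Missing
#' keys abort with a list of every unmapped type; no partial assignment is
#' performed.
#'
#' @param x a `liece_structure`.
#' @param table a `liece_parameters` table.
#' @param overrides named character vector, `atom name -> type key`.
#' @return the structure with `eps`, `rmin`, `born_radius` set.
#' @export
assign_parameters <- function(x, table, overrides = NULL) {
  stopifnot(inherits(table, "liece_parameters"))
  a <- x$atoms
  keys <- a$element
  if (!is.null(overrides)) {
    hit <- match(a$name, names(overrides))
    keys[!is.na(hit)] <- overrides[hit[!is.na(hit)]]
    sid <- match(paste0("serial:", a$serial), names(overrides))
    keys[!is.na(sid)] <- overrides[sid[!is.na(sid)]]
  }
  missing <- sort(unique(keys[!(keys %in% names(table))]))
  if (length(missing))
    stop("no nonbonded parameters for type(s): ",
         paste(missing, collapse = ", "))
  p <- do.call(rbind, table[keys])
  x$atoms$eps <- p[, "eps"]
  x$atoms$rmin <- p[, "rmin"]
  x$atoms$born_radius <- p[, "born_radius"]
  validate_structure(x)
  x
}

#' Convert an inhibition constant to a binding free energy
#'
#' `dG_exp = R T ln(Ki)` with Ki on the 1 M standard state,
#' R = 1.9872e-3 kcal mol^-1 K^-1 and T = 298 K by default.
#'
#' @param ki_molar inhibition constant in mol/L (> 0); vectorized.
#' @param temperature Kelvin.
#' @return free energy in kcal/mol.
#' @export
ki_to_dg <- function(ki_molar, temperature = 298) {
  if (any(!is.finite(ki_molar)) || any(ki_molar <= 0))
    stop("Ki must be positive and finite")
  GAS_CONSTANT_KCAL * temperature * log(ki_molar)
}

#' Read an affinity table
#'
#' CSV with a `ligand_id` column and exactly one of `ki_molar`, `ki_nM` or
#' `pki`. Each row's experimental free energy `dg_exp` (kcal/mol) is
#' computed with [ki_to_dg()] at 298 K. Optional columns `dataset_label`
#' and `assay_note` are carried through.
#'
#' @param path CSV file.
#' @return data.frame with columns `ligand_id`, `ki_molar`, `pki`,
#'   `dg_exp`, `dataset_label`, `assay_note`, in file row order.
#' @export
read_affinity_table <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"ligand_id" %in% names(d)) stop("affinity table needs ligand_id")
  dup <- d$ligand_id[duplicated(d$ligand_id)]
  if (length(dup))
    stop("duplicate ligand_id: ", paste(unique(dup), collapse = ", "))
  kcols <- intersect(c("ki_molar", "ki_nM", "pki"), names(d))
  if (length(kcols) != 1)
    stop("affinity table must have exactly one of ki_molar, ki_nM, pki; ",
         "found: ", if (length(kcols)) paste(kcols, collapse = ", ")
         else "none")
  ki <- switch(kcols,
    ki_molar = d$ki_molar,
    ki_nM = d$ki_nM * 1e-9,
    pki = 10^(-d$pki)
  )
  if (any(!is.finite(ki) | ki <= 0))
    stop("nonpositive or missing Ki in row(s): ",
         paste(which(!is.finite(ki) | ki <= 0), collapse = ", "))
  data.frame(
    ligand_id = as.character(d$ligand_id),
    ki_molar = ki,
    pki = -log10(ki),
    dg_exp = ki_to_dg(ki),
    dataset_label = if ("dataset_label" %in% names(d)) d$dataset_label
                    else "other",
    assay_note = if ("assay_note" %in% names(d)) d$assay_note else "",
    stringsAsFactors = FALSE
  )
}

.ENERGY_COLS <- c("ligand_id", "dE_vdw", "dE_coul", "dG_solv", "dg_exp",
                  "dataset_label", "docking_program", "receptor_model")

#' Read an energy-term table
#'
#' Canonical header: `ligand_id,dE_vdw,dE_coul,dG_solv,dg_exp,
#' dataset_label,docking_program,receptor_model`. Foreign schemas are
#' accommodated through `column_map`, a named character vector mapping
#' canonical names to the file's column names. Numeric parsing is
#' locale-independent ('.' decimal separator).
#'
#' @param path CSV file.
#' @param column_map named character vector (canonical -> file column).
#' @return data.frame of energy rows (class `liece_energy_table`).
#' @export
read_energy_table <- function(path, column_map = NULL) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                       check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(d))
        stop("mapped column '", src, "' (for ", canon, ") not in file")
      names(d)[names(d) == src] <- canon
    }
  }
  grouping_defaults <- c(dataset_label = "other",
                         docking_program = "unknown",
                         receptor_model = "unknown")
  for (g in names(grouping_defaults))
    if (!g %in% names(d)) d[[g]] <- grouping_defaults[[g]]
  miss <- setdiff(setdiff(.ENERGY_COLS, names(grouping_defaults)), names(d))
  if (length(miss))
    stop("energy table lacks column(s): ", paste(miss, collapse = ", "),
         " (use column_map to rename)")
  for (col in c("dE_vdw", "dE_coul", "dG_solv", "dg_exp")) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    if (anyNA(v))
      stop("non-numeric value in column ", col, " at row ",
           which(is.na(v))[1])
    d[[col]] <- v
  }
  d <- d[, .ENERGY_COLS]
  key <- paste(d$ligand_id, d$docking_program, d$receptor_model, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (ligand_id, docking_program, receptor_model): ",
         key[duplicated(key)][1])
  class(d) <- c("liece_energy_table", "data.frame")
  d
}

#' Write an energy-term table with the canonical header
#'
#' @param rows energy table data.frame.
#' @param path output CSV.
#' @param comments optional character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(rows, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.csv(as.data.frame(rows)[, .ENERGY_COLS], con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset an energy table by grouping columns
#'
#' @param rows energy table.
#' @param dataset_label,docking_program,receptor_model optional values to
#'   match; `NULL` keeps all.
#' @return the matching rows.
#' @export
subset_energy_table <- function(rows, dataset_label = NULL,
                                docking_program = NULL,
                                receptor_model = NULL) {
  keep <- rep(TRUE, nrow(rows))
  if (!is.null(dataset_label)) keep <- keep & rows$dataset_label %in% dataset_label
  if (!is.null(docking_program)) keep <- keep & rows$docking_program %in% docking_program
  if (!is.null(receptor_model)) keep <- keep & rows$receptor_model %in% receptor_model
  rows[keep, , drop = FALSE]
}
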