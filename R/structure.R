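## MolecularStructure container: an ordered atom table plus metadata.
## Atoms carry coordinates, partial charges and (once assigned) nonbonded
## parameters: LJ well depth (eps, kcal/mol), LJ pair-minimum contribution
## (rmin, A; rmin_ij = (rmin_i + rmin_j)/2) and a Born radius (A) defining
## the dielectric boundary. Unparameterized atoms hold NA, never 0.

.ELEMENTS <- c(
  "H", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE", "NA", "MG", "AL",
  "SI", "P", "S", "CL", "AR", "K", "CA", "MN", "FE", "CO", "NI", "CU",
  "ZN", "SE", "BR", "I"
)

.ATOM_COLS <- c(
  "serial", "name", "element", "x", "y", "z", "charge",
  "eps", "rmin", "born_radius", "resname", "resno", "chain"
)

#' Construct a molecular structure
#'
#' Builds the atom-table container used throughout the package. `atoms` must
#' contain columns `serial`, `name`, `element`, `x`, `y`, `z`; optional
#' columns `charge`, `eps`, `rmin`, `born_radius`, `resname`, `resno`,
#' `chain` are filled with defaults (`NA` for parameters, 0 for charge when
#' absent is *not* assumed: a missing charge column is stored as `NA`).
#'
#' @param atoms data.frame of atoms.
#' @param title character title.
#' @param kind one of `"receptor"`, `"ligand"`, `"complex"`, `"other"`.
#' @return An object of class `liece_structure`.
#' @export
molecular_structure <- function(atoms, title = "", kind = "other") {
  kind <- match.arg(kind, c("receptor", "ligand", "complex", "other"))
  req <- c("serial", "name", "element", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atom table lacks required column(s): ", paste(miss, collapse = ", "))
  for (col in setdiff(.ATOM_COLS, names(atoms))) {
    atoms[[col]] <- switch(col,
      charge = NA_real_, eps = NA_real_, rmin = NA_real_,
      born_radius = NA_real_, resname = "LIG", chain = "A",
      resno = 1L, NA
    )
  }
  atoms <- atoms[, .ATOM_COLS]
  atoms$serial <- as.integer(atoms$serial)
  atoms$resno <- as.integer(atoms$resno)
  atoms$element <- toupper(as.character(atoms$element))
  for (col in c("x", "y", "z", "charge", "eps", "rmin", "born_radius"))
    atoms[[col]] <- as.numeric(atoms[[col]])
  rownames(atoms) <- NULL
  x <- structure(list(atoms = atoms, title = title, kind = kind),
                 class = "liece_structure")
  validate_structure(x)
  x
}

#' Validate a molecular structure
#'
#' Checks serial uniqueness, finite coordinates, recognized element symbols
#' and, where parameters are assigned, their sign constraints
#' (`eps >= 0`, `rmin > 0`, `born_radius > 0`).
#'
#' @param x a `liece_structure`.
#' @return `x`, invisibly. Errors describe the offending atoms.
#' @export
validate_structure <- function(x) {
  stopifnot(inherits(x, "liece_structure"))
  a <- x$atoms
  dup <- a$serial[duplicated(a$serial)]
  if (length(dup))
    stop("duplicated atom serial(s): ", paste(unique(dup), collapse = ", "))
  bad <- !is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)
  if (any(bad))
    stop("non-finite coordinates for atom serial(s): ",
         paste(a$serial[bad], collapse = ", "))
  unk <- !(a$element %in% .ELEMENTS)
  if (any(unk))
    stop("unknown element for atom(s): ",
         paste(sprintf("%d (%s, '%s')", a$serial[unk], a$name[unk],
                       a$element[unk]), collapse = ", "))
  chg <- !is.na(a$charge) & !is.finite(a$charge)
  if (any(chg))
    stop("non-finite partial charge for serial(s): ",
         paste(a$serial[chg], collapse = ", "))
  has_par <- !is.na(a$eps) | !is.na(a$rmin) | !is.na(a$born_radius)
  if (any(has_par)) {
    p <- a[has_par, ]
    if (any(is.na(p$eps) | is.na(p$rmin) | is.na(p$born_radius)))
      stop("partially parameterized atoms present")
    if (any(p$eps < 0)) stop("negative LJ well depth")
    if (any(p$rmin <= 0)) stop("non-positive LJ rmin")
    if (any(p$born_radius <= 0)) stop("non-positive Born radius")
  }
  invisible(x)
}

#' @export
print.liece_structure <- function(x, ...) {
  cat(sprintf("<liece_structure> %s (%s): %d atoms, net charge %s\n",
              if (nzchar(x$title)) x$title else "(untitled)", x$kind,
              nrow(x$atoms),
              if (all(is.na(x$atoms$charge))) "unset"
              else sprintf("%+.3f e", sum(x$atoms$charge, na.rm = TRUE))))
  invisible(x)
}

#' Number of atoms in a structure
#' @param x a `liece_structure`.
#' @return integer count.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Coordinates as an n x 3 matrix
#' @param x a `liece_structure`.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
coords <- function(x) as.matrix(x$atoms[, c("x", "y", "z")])

#' Replace coordinates
#' @param x a `liece_structure`.
#' @param xyz n x 3 numeric matrix.
#' @return the modified structure.
#' @export
set_coords <- function(x, xyz) {
  stopifnot(nrow(xyz) == n_atoms(x), ncol(xyz) == 3)
  x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
  x
}

#' Are all atoms parameterized?
#' @param x a `liece_structure`.
#' @return logical scalar.
#' @export
is_parameterized <- function(x) {
  a <- x$atoms
  !any(is.na(a$eps) | is.na(a$rmin) | is.na(a$born_radius) | is.na(a$charge))
}

#' Combine receptor and ligand into a complex
#'
#' Atom order is receptor first, then ligand. Ligand serials are renumbered
#' past the receptor's largest serial when they collide.
#'
#' @param receptor,ligand `liece_structure` objects.
#' @param title title for the complex.
#' @return a `liece_structure` of kind `"complex"`.
#' @export
combine_structures <- function(receptor, ligand, title = "complex") {
  a <- receptor$atoms
  b <- ligand$atoms
  if (any(b$serial %in% a$serial))
    b$serial <- max(a$serial) + seq_len(nrow(b))
  molecular_structure(rbind(a, b), title = title, kind = "complex")
}

#' Rigid-body transform of a structure
#'
#' Applies `x -> R (x - center) + center + shift` to every atom.
#'
#' @param x a `liece_structure`.
#' @param rotation 3 x 3 rotation matrix (default identity).
#' @param shift length-3 translation vector (Angstrom).
#' @param center length-3 rotation center (default: centroid of `x`).
#' @return the transformed structure.
#' @export
transform_structure <- function(x, rotation = diag(3), shift = c(0, 0, 0),
                                center = NULL) {
  xyz <- coords(x)
  if (is.null(center)) center <- colMeans(xyz)
  out <- sweep(xyz, 2, center) %*% t(rotation)
  out <- sweep(out, 2, center + shift, "+")
  set_coords(x, out)
}

#' Rotation matrix about an axis
#'
#' @param axis length-3 axis vector (normalized internally).
#' @param angle rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  c_ <- cos(th); s <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  c_ * diag(3) + s * ux + (1 - c_) * tcrossprod(u)
}
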