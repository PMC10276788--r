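## Geometric pose-acceptance filters: a deterministic surrogate for visual
## pose inspection. A pose is acceptable when it forms the conserved salt
## bridge to the binding-pocket anchor residue (the D3.32 aspartate in
## aminergic GPCRs), leaves no buried polar atom without a hydrogen-bond or
## ionic partner, and does not leave too much hydrophobic surface exposed
## to solvent.

#' Pose-filter rules
#'
#' The thresholds are conventions of structural-biology practice, not
#' fitted quantities; all are configurable.
#'
#' @param anchor_resno residue number of the anchor residue (e.g. the
#'   conserved aspartate; numbering is the structure's own).
#' @param anchor_resname expected residue name (checked when present).
#' @param ionic_max_dist A, maximum N(+)...O(-) distance for a salt bridge.
#' @param hbond_max_dist A, maximum donor-acceptor heavy-atom distance.
#' @param hbond_min_angle degrees, minimum D-H...A angle (used when
#'   hydrogens are present).
#' @param burial_threshold fractional exposure below which a polar atom
#'   counts as buried.
#' @param exposed_apolar_max maximum allowed exposed apolar fraction.
#' @param probe_radius A, solvent probe for the numeric surface.
#' @return list of class `liece_filter_rules`.
#' @export
filter_rules <- function(anchor_resno = 155, anchor_resname = "ASP",
                         ionic_max_dist = 4.0, hbond_max_dist = 3.5,
                         hbond_min_angle = 120, burial_threshold = 0.1,
                         exposed_apolar_max = 0.5, probe_radius = 1.4) {
  stopifnot(ionic_max_dist > 0, hbond_max_dist > 0,
            hbond_min_angle > 0, hbond_min_angle <= 180,
            burial_threshold > 0, exposed_apolar_max > 0)
  structure(list(
    anchor_resno = anchor_resno, anchor_resname = anchor_resname,
    ionic_max_dist = ionic_max_dist, hbond_max_dist = hbond_max_dist,
    hbond_min_angle = hbond_min_angle,
    burial_threshold = burial_threshold,
    exposed_apolar_max = exposed_apolar_max, probe_radius = probe_radius
  ), class = "liece_filter_rules")
}

## fixed, seedless 92-point unit sphere (spherical Fibonacci lattice)
.SPHERE_N <- 92L
.sphere_points <- function(n = .SPHERE_N) {
  k <- seq_len(n) - 1
  z <- 1 - (2 * k + 1) / n
  phi <- k * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Per-atom solvent exposure (Shrake-Rupley style)
#'
#' Each atom's sphere of radius `born_radius + probe` is sampled at a fixed
#' 92-point lattice; a point is accessible when it lies outside every other
#' atom's probe-expanded sphere. Deterministic: no random sampling.
#'
#' @param x parameterized `liece_structure` (Born radii set).
#' @param probe probe radius in A.
#' @return data.frame with `serial`, `exposure` (fraction of accessible
#'   points, in `[0, 1]`) and `area` (accessible area, A^2).
#' @export
atom_exposure <- function(x, probe = 1.4) {
  .check_param(x)
  xyz <- coords(x)
  rad <- x$atoms$born_radius + probe
  n <- nrow(xyz)
  sp <- .sphere_points()
  exposure <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    pts <- sweep(sp * rad[i], 2, xyz[i, ], "+")
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    if (!length(nb)) { exposure[i] <- 1; next }
    acc <- rep(TRUE, nrow(pts))
    for (j in nb) {
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
             (pts[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > rad[j]^2
      if (!any(acc)) break
    }
    exposure[i] <- mean(acc)
  }
  data.frame(serial = x$atoms$serial, exposure = exposure,
             area = exposure * 4 * pi * rad^2)
}

.anchor_atoms <- function(receptor, rules) {
  a <- receptor$atoms
  sel <- a$resno == rules$anchor_resno
  if (!is.null(rules$anchor_resname) && any(sel))
    sel <- sel & a$resname == rules$anchor_resname
  if (!any(sel))
    stop("anchor residue ", rules$anchor_resname, " ",
         rules$anchor_resno, " not found in receptor")
  which(sel & a$element == "O")
}

.cationic_centers <- function(ligand, threshold = 0.5) {
  a <- ligand$atoms
  which(a$element == "N" & !is.na(a$charge) & a$charge >= threshold)
}

#' Find ionic contacts between ligand cationic centers and the anchor residue
#'
#' Cationic centers are ligand nitrogens with partial charge >= +0.5;
#' anionic centers are the (carboxylate) oxygens of the anchor residue. One
#' contact is reported per (center, residue) pair, at the minimum N-O
#' distance, when that distance is within `rules$ionic_max_dist`.
#'
#' @param ligand,receptor parameterized structures.
#' @param rules [filter_rules()].
#' @return data.frame `ligand_serial`, `residue`, `receptor_serial`,
#'   `distance` (A); zero rows when no contact qualifies.
#' @export
find_ionic_contacts <- function(ligand, receptor, rules = filter_rules()) {
  oidx <- .anchor_atoms(receptor, rules)
  nidx <- .cationic_centers(ligand)
  out <- data.frame(ligand_serial = integer(), residue = character(),
                    receptor_serial = integer(), distance = numeric())
  if (!length(nidx) || !length(oidx)) return(out)
  lxyz <- coords(ligand); rxyz <- coords(receptor)
  for (i in nidx) {
    d <- sqrt(colSums((t(rxyz[oidx, , drop = FALSE]) - lxyz[i, ])^2))
    jmin <- which.min(d)
    if (d[jmin] <= rules$ionic_max_dist)
      out <- rbind(out, data.frame(
        ligand_serial = ligand$atoms$serial[i],
        residue = paste0(receptor$atoms$resname[oidx[jmin]],
                         receptor$atoms$resno[oidx[jmin]]),
        receptor_serial = receptor$atoms$serial[oidx[jmin]],
        distance = d[jmin]))
  }
  out
}

## polar heavy atoms with attached hydrogens (bond inferred from distance)
.attached_h <- function(x, heavy_idx) {
  a <- x$atoms
  hidx <- which(a$element == "H")
  if (!length(hidx)) return(list())
  xyz <- coords(x)
  lapply(heavy_idx, function(i) {
    d <- sqrt(colSums((t(xyz[hidx, , drop = FALSE]) - xyz[i, ])^2))
    hidx[d <= 1.25]
  })
}

#' Find hydrogen bonds between a ligand and a receptor
#'
#' Donors are N/O atoms bearing a hydrogen; acceptors are any N/O. A pair
#' qualifies when the heavy-atom distance is within `hbond_max_dist` and
#' some D-H...A angle is at least `hbond_min_angle`. In structures without
#' hydrogen coordinates every N/O is treated as a potential donor and the
#' distance criterion alone applies.
#'
#' @param ligand,receptor parameterized structures.
#' @param rules [filter_rules()].
#' @return data.frame `donor_serial`, `acceptor_serial`, `donor_side`
#'   (`"ligand"` or `"receptor"`), `distance` (A), `angle` (degrees, `NA`
#'   without hydrogens).
#' @export
find_hbonds <- function(ligand, receptor, rules = filter_rules()) {
  out <- data.frame(donor_serial = integer(), acceptor_serial = integer(),
                    donor_side = character(), distance = numeric(),
                    angle = numeric())
  sides <- list(list(don = ligand, acc = receptor, side = "ligand"),
                list(don = receptor, acc = ligand, side = "receptor"))
  for (s in sides) {
    don <- s$don; acc <- s$acc
    didx <- which(don$atoms$element %in% c("N", "O"))
    aidx <- which(acc$atoms$element %in% c("N", "O"))
    if (!length(didx) || !length(aidx)) next
    has_h <- any(don$atoms$element == "H")
    hs <- if (has_h) .attached_h(don, didx) else NULL
    dxyz <- coords(don); axyz <- coords(acc)
    for (m in seq_along(didx)) {
      i <- didx[m]
      hset <- if (has_h) hs[[m]] else integer()
      if (has_h && !length(hset)) next  # polar atom without H: not a donor
      d <- sqrt(colSums((t(axyz[aidx, , drop = FALSE]) - dxyz[i, ])^2))
      for (m2 in which(d <= rules$hbond_max_dist)) {
        j <- aidx[m2]
        ang <- NA_real_
        ok <- TRUE
        if (has_h) {
          angs <- vapply(hset, function(h) {
            v1 <- dxyz[i, ] - coords(don)[h, ]
            v2 <- axyz[j, ] - coords(don)[h, ]
            acos(pmin(1, pmax(-1, sum(v1 * v2) /
              sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          }, numeric(1))
          ang <- max(angs)
          ok <- ang >= rules$hbond_min_angle
        }
        if (ok)
          out <- rbind(out, data.frame(
            donor_serial = don$atoms$serial[i],
            acceptor_serial = acc$atoms$serial[j],
            donor_side = s$side, distance = d[m2], angle = ang))
      }
    }
  }
  out
}

#' Full interaction report for one pose
#'
#' Combines ionic contacts, hydrogen bonds, stranded polar atoms (buried
#' ligand N/O with no hydrogen-bond or ionic partner) and the exposed
#' apolar fraction (accessible area of the ligand's carbon atoms in the
#' complex, relative to the free ligand).
#'
#' @param ligand,receptor parameterized structures.
#' @param rules [filter_rules()].
#' @return list with `ionic_contacts`, `hbonds`, `stranded_polar` (ligand
#'   serials) and `exposed_apolar_fraction`.
#' @export
interaction_report <- function(ligand, receptor, rules = filter_rules()) {
  ionic <- find_ionic_contacts(ligand, receptor, rules)
  hb <- find_hbonds(ligand, receptor, rules)
  cx <- combine_structures(receptor, ligand)
  expo <- atom_exposure(cx, rules$probe_radius)
  nr <- n_atoms(receptor)
  lig_expo <- expo$exposure[(nr + 1):(nr + n_atoms(ligand))]

  a <- ligand$atoms
  polar <- which(a$element %in% c("N", "O"))
  partnered <- a$serial %in% c(
    ionic$ligand_serial,
    hb$donor_serial[hb$donor_side == "ligand"],
    hb$acceptor_serial[hb$donor_side == "receptor"]
  )
  stranded <- a$serial[polar[
    lig_expo[polar] < rules$burial_threshold & !partnered[polar]
  ]]

  apolar <- which(a$element == "C")
  if (length(apolar)) {
    free_expo <- atom_exposure(ligand, rules$probe_radius)
    free_area <- sum(free_expo$area[apolar])
    cx_area <- sum(expo$area[nr + apolar])
    frac <- if (free_area > 0) min(1, cx_area / free_area) else 0
  } else frac <- 0

  list(ionic_contacts = ionic, hbonds = hb, stranded_polar = stranded,
       exposed_apolar_fraction = frac)
}

#' Accept or reject docking poses on the interaction constraints
#'
#' A pose is accepted iff it has at least one ionic contact to the anchor
#' residue, no stranded polar atom, and an exposed apolar fraction within
#' the allowed maximum. Rejections carry every violated constraint as a
#' reason code (`NO_ANCHOR_CONTACT`, `STRANDED_POLAR`, `EXPOSED_APOLAR`),
#' not just the first.
#'
#' @param poses list of ligand-pose structures (or a single structure).
#' @param receptor parameterized receptor structure.
#' @param rules [filter_rules()].
#' @return list with `accepted` (list of poses), `rejected` (list of
#'   `list(pose, reasons)`) and `decisions`, a data.frame with one row per
#'   pose (`pose_id`, `accepted`, `reasons`, `n_ionic`,
#'   `exposed_apolar_fraction`).
#' @export
filter_poses <- function(poses, receptor, rules = filter_rules()) {
  if (inherits(poses, "liece_structure")) poses <- list(poses)
  decisions <- data.frame(pose_id = character(), accepted = logical(),
                          reasons = character(), n_ionic = integer(),
                          exposed_apolar_fraction = numeric())
  accepted <- list(); rejected <- list()
  for (p in seq_along(poses)) {
    pose <- poses[[p]]
    rep_ <- interaction_report(pose, receptor, rules)
    reasons <- character()
    if (nrow(rep_$ionic_contacts) == 0) reasons <- c(reasons, "NO_ANCHOR_CONTACT")
    if (length(rep_$stranded_polar)) reasons <- c(reasons, "STRANDED_POLAR")
    if (rep_$exposed_apolar_fraction > rules$exposed_apolar_max)
      reasons <- c(reasons, "EXPOSED_APOLAR")
    ok <- length(reasons) == 0
    id <- if (nzchar(pose$title)) pose$title else paste0("pose", p)
    decisions <- rbind(decisions, data.frame(
      pose_id = id, accepted = ok,
      reasons = paste(reasons, collapse = ";"),
      n_ionic = nrow(rep_$ionic_contacts),
      exposed_apolar_fraction = rep_$exposed_apolar_fraction))
    if (ok) accepted <- c(accepted, list(pose))
    else rejected <- c(rejected, list(list(pose = pose, reasons = reasons)))
  }
  list(accepted = accepted, rejected = rejected, decisions = decisions)
}
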