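# Fixtures are built in code; nothing is read from disk that a test did
# not itself write.

# bare structure from a coordinate matrix, all parameterized
make_structure <- function(xyz, element = "C", charge = 0, name = NULL,
                           resname = "LIG", resno = 1L, kind = "other",
                           params = default_parameter_table()) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  element <- rep_len(element, n)
  atoms <- data.frame(
    serial = seq_len(n),
    name = if (is.null(name)) paste0(element, seq_len(n)) else name,
    element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = rep_len(charge, n),
    resname = rep_len(resname, n), resno = rep_len(resno, n),
    chain = "A", stringsAsFactors = FALSE
  )
  assign_parameters(molecular_structure(atoms, "fixture", kind), params)
}

# random parameterized cluster with minimum separation (rejection sampling
# under a fixed seed)
random_cluster <- function(n, seed, box = 8, min_sep = 2.2,
                           element = "C", charge_sd = 0.3) {
  set.seed(seed)
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < n) {
    p <- runif(3, -box / 2, box / 2)
    if (nrow(pts) == 0 || min(sqrt(colSums((t(pts) - p)^2))) >= min_sep)
      pts <- rbind(pts, p)
  }
  q <- round(rnorm(n, 0, charge_sd), 3)
  make_structure(pts, element = element, charge = q)
}

# independent brute-force oracles (straight double loops, no vectorized
# shortcuts shared with the implementation)
brute_lj <- function(s, ia, ib, cutoff = 14) {
  a <- s$atoms
  E <- 0
  for (i in ia) for (j in ib) {
    if (i >= j && setequal(ia, ib)) next
    r <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
              (a$z[i] - a$z[j])^2)
    if (r > cutoff) next
    eps <- sqrt(a$eps[i] * a$eps[j])
    rmin <- (a$rmin[i] + a$rmin[j]) / 2
    E <- E + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }
  E
}

brute_coulomb <- function(s, ia, ib, k = COULOMB_KCAL) {
  a <- s$atoms
  E <- 0
  for (i in ia) for (j in ib) {
    if (i >= j && setequal(ia, ib)) next
    r <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
              (a$z[i] - a$z[j])^2)
    E <- E + k * a$charge[i] * a$charge[j] / r
  }
  E
}

# exhaustive donor/acceptor pair enumeration under the same geometric
# predicate (no-hydrogen convention: every N/O can donate)
brute_hbonds <- function(ligand, receptor, max_dist = 3.5) {
  pairs <- 0L
  for (don in list(ligand, receptor)) {
    acc <- if (identical(don, ligand)) receptor else ligand
    di <- which(don$atoms$element %in% c("N", "O"))
    ai <- which(acc$atoms$element %in% c("N", "O"))
    for (i in di) for (j in ai) {
      r <- sqrt((don$atoms$x[i] - acc$atoms$x[j])^2 +
                (don$atoms$y[i] - acc$atoms$y[j])^2 +
                (don$atoms$z[i] - acc$atoms$z[j])^2)
      if (r <= max_dist) pairs <- pairs + 1L
    }
  }
  pairs
}

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
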