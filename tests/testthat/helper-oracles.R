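# Independent oracles used to cross-check the package implementation.
# Deliberately naive: plain loops and textbook formulas, no shared code with
# the functions they verify.

# O(n^2) double-loop native-contact enumeration over heavy atoms
bf_contacts <- function(structure, cutoff = 4.5, min_separation = 3) {
  at <- structure$atoms[!structure$atoms$is_hydrogen, ]
  n <- nrow(at)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(at$residue_index[i] - at$residue_index[j]) <= min_separation) next
      d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                  (at$z[i] - at$z[j])^2)
      if (d < cutoff) {
        a <- if (at$serial[i] < at$serial[j]) c(i, j) else c(j, i)
        rows[[length(rows) + 1]] <- data.frame(
          serial_i = at$serial[a[1]], serial_j = at$serial[a[2]], r0 = d)
      }
    }
  }
  if (length(rows) == 0) return(data.frame(serial_i = integer(),
                                           serial_j = integer(),
                                           r0 = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$serial_i, out$serial_j), , drop = FALSE]
}

# naive per-pair loop evaluation of the soft Q sum
bf_soft_q <- function(xyz, pairs, beta = 5, lam = 1.8) {
  total <- 0
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$atom_i[k]; j <- pairs$atom_j[k]
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    total <- total + 1 / (1 + exp(beta * (r - lam * pairs$r0[k])))
  }
  total / nrow(pairs)
}

# Horn quaternion superposition: minimal RMSD of mobile onto ref
quaternion_rmsd <- function(ref, mobile) {
  p <- sweep(ref, 2, colMeans(ref))
  q <- sweep(mobile, 2, colMeans(mobile))
  s <- t(q) %*% p
  k <- matrix(c(
    s[1,1]+s[2,2]+s[3,3], s[2,3]-s[3,2],       s[3,1]-s[1,3],       s[1,2]-s[2,1],
    s[2,3]-s[3,2],       s[1,1]-s[2,2]-s[3,3], s[1,2]+s[2,1],       s[3,1]+s[1,3],
    s[3,1]-s[1,3],       s[1,2]+s[2,1],       -s[1,1]+s[2,2]-s[3,3], s[2,3]+s[3,2],
    s[1,2]-s[2,1],       s[3,1]+s[1,3],        s[2,3]+s[3,2],       -s[1,1]-s[2,2]+s[3,3]
  ), nrow = 4, byrow = TRUE)
  lam <- max(eigen(k, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(p^2) + sum(q^2) - 2 * lam) / nrow(ref)
  sqrt(max(msd, 0))
}

# random proper rotation matrix
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  r <- qr.Q(qr_d)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# random cloud of heavy atoms spread over a handful of residues
random_toy_structure <- function(n_atoms = 50, n_residues = 10,
                                 box = 12) {
  res <- sort(sample(0:(n_residues - 1), n_atoms, replace = TRUE))
  res <- res - min(res)
  res <- match(res, sort(unique(res))) - 1L
  nres <- max(res) + 1L
  names20 <- names(qstab::residue_group_scheme())
  res_names <- sample(names20, nres, replace = TRUE)
  atoms <- tibble::tibble(
    serial = seq_len(n_atoms),
    name = rep("CA", n_atoms),
    element = "C",
    is_hydrogen = FALSE,
    residue_index = res,
    residue_name = res_names[res + 1L],
    chain_id = "A",
    author_seq_id = res + 1L,
    ins_code = "",
    x = runif(n_atoms, 0, box),
    y = runif(n_atoms, 0, box),
    z = runif(n_atoms, 0, box),
    is_cap_atom = FALSE
  )
  residues <- tibble::tibble(
    residue_index = 0:(nres - 1L),
    residue_name = res_names,
    chain_id = "A",
    author_seq_id = 1:nres,
    ins_code = "",
    in_cdr = NA_integer_
  )
  structure(list(atoms = atoms, residues = residues, cdr_ranges = NULL,
                 source_id = "random_toy"),
            class = "structure_model")
}

# structure with atoms at explicitly chosen positions/residues
manual_structure <- function(xyz, residue_index,
                             residue_name = NULL, name = NULL) {
  n <- nrow(xyz)
  if (is.null(residue_name)) residue_name <- rep("ALA", n)
  if (is.null(name)) name <- rep("CA", n)
  nres <- max(residue_index) + 1L
  rn_per_res <- character(nres)
  rn_per_res[residue_index + 1L] <- residue_name
  atoms <- tibble::tibble(
    serial = seq_len(n), name = name, element = "C", is_hydrogen = FALSE,
    residue_index = as.integer(residue_index),
    residue_name = residue_name, chain_id = "A",
    author_seq_id = as.integer(residue_index + 1L), ins_code = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], is_cap_atom = FALSE
  )
  residues <- tibble::tibble(
    residue_index = 0:(nres - 1L), residue_name = rn_per_res,
    chain_id = "A", author_seq_id = 1:nres, ins_code = "",
    in_cdr = NA_integer_
  )
  structure(list(atoms = atoms, residues = residues, cdr_ranges = NULL,
                 source_id = "manual"),
            class = "structure_model")
}

# single-replica ensemble from a list of coordinate matrices
frames_ensemble <- function(frames, times = NULL, system_id = "test") {
  n <- nrow(frames[[1]])
  coords <- array(unlist(frames), dim = c(n, 3, length(frames)))
  if (is.null(times)) times <- seq_along(frames)
  trajectory_ensemble(list(list(replica_id = 1L, times = times,
                                coords = coords)),
                      system_id = system_id)
}

# three-residue PDB text fixture (tri-alanine-like, with one hydrogen)
toy_pdb_text <- function() {
  c("MODEL     1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.300   2.400   0.100  1.00  0.00           O",
    "ATOM      5  HA  ALA A   1       1.800  -0.500   0.900  1.00  0.00           H",
    "ATOM      6  N   GLY A   2       3.300   1.500   0.100  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       4.000   2.800   0.100  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       5.500   2.600   0.200  1.00  0.00           C",
    "ATOM      9  O   GLY A   2       6.000   1.500   0.300  1.00  0.00           O",
    "ATOM     10  N   ASP A   3       6.300   3.700   0.200  1.00  0.00           N",
    "ATOM     11  CA  ASP A   3       7.700   3.600   0.300  1.00  0.00           C",
    "ATOM     12  C   ASP A   3       8.400   4.900   0.400  1.00  0.00           C",
    "ATOM     13  O   ASP A   3       7.800   6.000   0.400  1.00  0.00           O",
    "ENDMDL",
    "END")
}

write_toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(toy_pdb_text(), path)
  path
}
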