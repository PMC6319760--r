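#' Specification of a synthetic test system
#'
#' Bundles the parameters of the toy-structure generator and the trajectory
#' simulator. The defaults emulate, at desk scale, the ensemble design used
#' for stability estimation of single-domain antibodies: a compact,
#' mostly-stable fold; ten replica trajectories differing only in
#' seed-derived randomness; a minority of residues that coherently lose
#' their native contacts partway through the run; optional rigid-body drift
#' of the whole molecule. 200 frames spanning 100 ns stand in for a 10-ps
#' save interval at reduced temporal resolution.
#'
#' @param n_residues Number of residues (>= 10, default 60).
#' @param atoms_per_residue Heavy atoms per residue (default 5: N, CA, C, O,
#'   CB).
#' @param spacing Lattice spacing of residue centres in Angstrom (default
#'   3.9, chosen so that at default contact parameters the large majority of
#'   residues carry at least 30 native contacts while a minority near chain
#'   termini and lattice turns fall below — exercising the excluded-residue
#'   rule).
#' @param n_replicas Replica trajectories per system (default 10).
#' @param n_frames Frames per replica (default 200).
#' @param total_time_ns Simulated span in ns (default 100; frame spacing is
#'   `total_time_ns / n_frames`).
#' @param unstable_residues 0-based indices of residues designed to unfold.
#' @param amplitude Terminal displacement scale s in Angstrom for each
#'   unstable residue (recycled; default 20).
#' @param onset Onset fraction tau in `[0, 1]` at which each unstable
#'   residue starts moving (recycled; default 0.5).
#' @param base_noise Global per-atom thermal jitter SD sigma0 in Angstrom
#'   (default 0.3).
#' @param rigid_body Superimpose a slow random rigid-body rotation +
#'   translation drift on every frame (default `FALSE`).
#' @param seed Master seed for the structure (and, unless `traj_seed` is
#'   given, the trajectories).
#' @param traj_seed Separate seed for trajectory randomness; defaults to
#'   `seed + 1`, so the reference structure can be held fixed while replica
#'   ensembles are varied.
#' @return A list of class `toy_system_spec`.
#' @export
toy_system_spec <- function(n_residues = 60, atoms_per_residue = 5,
                            spacing = 3.9, n_replicas = 10, n_frames = 200,
                            total_time_ns = 100,
                            unstable_residues = integer(),
                            amplitude = 20, onset = 0.5, base_noise = 0.3,
                            rigid_body = FALSE, seed = 1,
                            traj_seed = NULL) {
  if (n_residues < 10) stop("n_residues must be >= 10", call. = FALSE)
  if (atoms_per_residue < 4) {
    stop("need >= 4 atoms per residue (N, CA, C, O backbone)",
         call. = FALSE)
  }
  if (base_noise < 0) stop("base_noise must be >= 0", call. = FALSE)
  k <- length(unstable_residues)
  if (k > 0) {
    if (any(unstable_residues < 0 | unstable_residues >= n_residues)) {
      stop("unstable_residues out of range", call. = FALSE)
    }
    amplitude <- rep_len(amplitude, k)
    onset <- rep_len(onset, k)
    if (any(amplitude < 0) || any(!is.finite(amplitude))) {
      stop("amplitudes must be finite and >= 0", call. = FALSE)
    }
    if (any(onset < 0 | onset > 1)) {
      stop("onset fractions must be in [0, 1]", call. = FALSE)
    }
  }
  if (is.null(traj_seed)) traj_seed <- seed + 1L
  structure(
    list(n_residues = as.integer(n_residues),
         atoms_per_residue = as.integer(atoms_per_residue),
         spacing = spacing, n_replicas = as.integer(n_replicas),
         n_frames = as.integer(n_frames), total_time_ns = total_time_ns,
         unstable_residues = as.integer(unstable_residues),
         amplitude = amplitude, onset = onset, base_noise = base_noise,
         rigid_body = isTRUE(rigid_body), seed = as.integer(seed),
         traj_seed = as.integer(traj_seed)),
    class = "toy_system_spec"
  )
}

# boustrophedon path through a compact dx x dy x dz lattice
.snake_lattice <- function(n) {
  dx <- ceiling(n^(1 / 3) - 1e-9)
  dy <- ceiling(sqrt(n / dx) - 1e-9)
  dz <- ceiling(n / (dx * dy))
  layer <- matrix(NA_integer_, nrow = dx * dy, ncol = 2)
  i <- 1L
  for (yy in 0:(dy - 1)) {
    xs <- if (yy %% 2 == 0) 0:(dx - 1) else (dx - 1):0
    for (xx in xs) { layer[i, ] <- c(xx, yy); i <- i + 1L }
  }
  cells <- matrix(NA_integer_, nrow = n, ncol = 3)
  for (i in 0:(n - 1)) {
    z <- i %/% (dx * dy)
    r <- i %% (dx * dy) + 1L
    rc <- if (z %% 2 == 0) layer[r, ] else layer[dx * dy - r + 1L, ]
    cells[i + 1L, ] <- c(rc[1], rc[2], z)
  }
  cells
}

# fixed local heavy-atom geometry; CB-like extras cycle three directions
.ATOM_TEMPLATE <- list(
  N  = c(-1.20, -0.80,  0.00),
  CA = c( 0.00,  0.00,  0.00),
  C  = c( 1.20,  0.80,  0.00),
  O  = c( 1.30,  1.00,  1.20),
  CB = c( 0.00,  1.30, -1.20),
  CG = c(-0.60,  0.40,  1.40),
  CD = c( 0.60, -1.30,  0.90)
)

#' Generate a toy reference structure
#'
#' Residues are laid out along a space-filling snake through a compact 3-D
#' lattice — a stand-in for a packed beta-sandwich core — with a fixed
#' heavy-atom geometry per residue plus a small seeded jitter. Residue names
#' are drawn from the 20 standard amino acids with all three physicochemical
#' groups guaranteed present. At the default 60 residues and contact
#' parameters, interior residues carry well over 30 native contacts while
#' chain termini fall below 30, so the excluded-residue rule is exercised.
#' Generation is deterministic given `spec$seed`; a steric clash (any
#' heavy-atom pair closer than 1 Angstrom) triggers regeneration with fresh
#' jitter, failing after 10 attempts.
#'
#' @param spec A [toy_system_spec()].
#' @return A `structure_model` (chain A, author numbering 1..n).
#' @export
make_toy_structure <- function(spec) {
  stopifnot(inherits(spec, "toy_system_spec"))
  n <- spec$n_residues
  m <- spec$atoms_per_residue
  cells <- .snake_lattice(n)
  centers <- cells * spec$spacing
  atom_names <- names(.ATOM_TEMPLATE)[((seq_len(m) - 1L) %%
                                         length(.ATOM_TEMPLATE)) + 1L]
  offsets <- do.call(rbind, .ATOM_TEMPLATE[atom_names])

  set.seed(spec$seed)
  scheme <- residue_group_scheme()
  res_names <- sample(names(scheme), n, replace = TRUE)
  gl <- group_labels(scheme)
  for (gi in seq_along(gl)) {   # guarantee all three groups appear
    if (!any(scheme[res_names] == gl[gi])) {
      res_names[n - gi + 1L] <- names(scheme)[scheme == gl[gi]][1]
    }
  }

  for (attempt in 1:10) {
    jitter <- matrix(stats::runif(n * m * 3, -0.15, 0.15), ncol = 3)
    xyz <- centers[rep(seq_len(n), each = m), ] +
      offsets[rep(seq_len(m), times = n), ] + jitter
    dimnames(xyz) <- NULL
    if (min(stats::dist(xyz)) >= 1.0) break
    if (attempt == 10) stop("steric collapse in toy structure generation",
                            call. = FALSE)
  }

  element <- substr(atom_names, 1, 1)
  atoms <- tibble::tibble(
    serial = seq_len(n * m),
    name = rep(atom_names, times = n),
    element = rep(element, times = n),
    is_hydrogen = FALSE,
    residue_index = rep(0:(n - 1), each = m),
    residue_name = rep(res_names, each = m),
    chain_id = "A",
    author_seq_id = rep(1:n, each = m),
    ins_code = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    is_cap_atom = FALSE
  )
  residues <- tibble::tibble(
    residue_index = 0:(n - 1), residue_name = res_names, chain_id = "A",
    author_seq_id = 1:n, ins_code = "", in_cdr = NA_integer_
  )
  structure(list(atoms = atoms, residues = residues, cdr_ranges = NULL,
                 source_id = sprintf("toy%03d_seed%d", n, spec$seed)),
            class = "structure_model")
}

# smoothstep ramp on [0,1]
.smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

#' Simulate a replica trajectory ensemble with designed instability
#'
#' Every frame is the native structure plus (i) isotropic Gaussian jitter of
#' SD `base_noise` on each atom, (ii) for each designed unstable residue, a
#' coherent displacement of all its atoms along a random per-replica
#' direction, smoothly ramping from zero at onset fraction tau to the full
#' amplitude s at the end of the run, and (iii) optionally a slow rigid-body
#' rotation/translation drift of the whole molecule. Replicas differ only in
#' seed-derived randomness (independent substreams of `spec$traj_seed`), so
#' the ensemble is bitwise reproducible.
#'
#' @param structure The reference `structure_model` (from
#'   [make_toy_structure()] or a file).
#' @param spec A [toy_system_spec()].
#' @param system_id System identifier (default: the structure's source id).
#' @return A `trajectory_ensemble` with `spec$n_replicas` replicas of
#'   `spec$n_frames` frames each.
#' @export
simulate_ensemble <- function(structure, spec,
                              system_id = structure$source_id) {
  stopifnot(inherits(structure, "structure_model"),
            inherits(spec, "toy_system_spec"))
  x0 <- structure_xyz(structure)
  n_atoms <- nrow(x0)
  res_of_atom <- structure$atoms$residue_index
  times <- seq_len(spec$n_frames) * spec$total_time_ns / spec$n_frames
  centroid <- colMeans(x0)

  set.seed(spec$traj_seed)
  replica_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_replicas)

  unstable <- spec$unstable_residues
  atom_sets <- lapply(unstable, function(k) which(res_of_atom == k))

  replicas <- vector("list", spec$n_replicas)
  for (r in seq_len(spec$n_replicas)) {
    set.seed(replica_seeds[r])
    dirs <- NULL
    if (length(unstable) > 0) {
      dirs <- matrix(stats::rnorm(3 * length(unstable)), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
    }
    if (spec$rigid_body) {
      axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
      total_angle <- stats::runif(1, pi / 4, pi)
      trans_vel <- stats::rnorm(3, sd = 5)
    }
    coords <- array(NA_real_, dim = c(n_atoms, 3, spec$n_frames))
    for (f in seq_len(spec$n_frames)) {
      frac <- f / spec$n_frames
      x <- x0 + matrix(stats::rnorm(n_atoms * 3, sd = spec$base_noise),
                       ncol = 3)
      for (u in seq_along(unstable)) {
        tau <- spec$onset[u]
        if (frac >= tau && spec$amplitude[u] > 0) {
          ramp <- if (tau >= 1) 1 else (frac - tau) / (1 - tau)
          d <- spec$amplitude[u] * .smoothstep(ramp)
          idx <- atom_sets[[u]]
          x[idx, ] <- x[idx, ] + rep(dirs[u, ], each = length(idx)) * d
        }
      }
      if (spec$rigid_body) {
        ang <- frac * total_angle
        rot <- .axis_angle_matrix(axis, ang)
        x <- sweep(x, 2, centroid) %*% t(rot)
        x <- sweep(x, 2, centroid + frac * trans_vel, "+")
      }
      coords[, , f] <- x
    }
    replicas[[r]] <- list(replica_id = r, times = times, coords = coords)
  }
  trajectory_ensemble(replicas, system_id = system_id, n_atoms = n_atoms)
}

.axis_angle_matrix <- function(axis, theta) {
  k <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
               nrow = 3, byrow = TRUE)
  diag(3) + sin(theta) * kx + (1 - cos(theta)) * (kx %*% kx)
}

#' Build a multi-system synthetic stability benchmark
#'
#' Emulates a panel of single-domain antibodies with a wide melting-
#' temperature range: each system is assigned a pseudo-Tm (default spread
#' 46.75-85 degrees C, matching the span typical of engineered VHH panels)
#' and a designed instability that strictly decreases as pseudo-Tm
#' increases — less stable systems carry more unfolding residues. Running
#' the analysis pipeline over the suite should therefore recover a strong
#' positive correlation between final-window all-all Q and pseudo-Tm.
#'
#' @param n_systems Number of systems (default 7).
#' @param seed Master seed; system structure/trajectory seeds and unstable-
#'   residue draws derive from it.
#' @param pseudo_tm Optional increasing vector of pseudo melting
#'   temperatures (length `n_systems`).
#' @param n_unstable Optional strictly decreasing integer vector: designed
#'   unstable-residue count per system (default spans 9 down to 1).
#' @param ... Further arguments passed to [toy_system_spec()] (e.g.
#'   `n_frames`, `n_replicas`).
#' @return Tibble: `system_id`, `pseudo_tm`, `n_unstable`, `spec`
#'   (list-column of [toy_system_spec()]s).
#' @export
make_benchmark_suite <- function(n_systems = 7, seed = 1, pseudo_tm = NULL,
                                 n_unstable = NULL, ...) {
  if (is.null(pseudo_tm)) {
    pseudo_tm <- if (n_systems == 7) {
      c(46.75, 58, 60, 69, 70.7, 79, 85)
    } else {
      seq(47, 85, length.out = n_systems)
    }
  }
  stopifnot(length(pseudo_tm) == n_systems, all(diff(pseudo_tm) > 0))
  if (is.null(n_unstable)) {
    n_unstable <- round(seq(9, 1, length.out = n_systems))
  }
  stopifnot(length(n_unstable) == n_systems, all(diff(n_unstable) < 0))

  set.seed(seed)
  sys_seeds <- sample.int(2^30, n_systems)
  specs <- vector("list", n_systems)
  for (i in seq_len(n_systems)) {
    base <- toy_system_spec(seed = sys_seeds[i], ...)
    # draw designed unfolding residues from the chain interior, spaced out
    pool <- seq(5L, base$n_residues - 6L, by = 3L)
    set.seed(sys_seeds[i] + 7L)
    unstable <- sort(sample(pool, n_unstable[i]))
    specs[[i]] <- toy_system_spec(seed = sys_seeds[i],
                                  unstable_residues = unstable, ...)
  }
  tibble::tibble(
    system_id = sprintf("synth%02d", seq_len(n_systems)),
    pseudo_tm = pseudo_tm,
    n_unstable = as.integer(n_unstable),
    spec = specs
  )
}
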