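#' Default parameters of the soft Q kernel
#'
#' The soft fraction of native contacts of a frame is
#' \deqn{Q = \frac{1}{N}\sum_{(i,j)} \frac{1}{1 + \exp[\beta\,(r_{ij} - \lambda r^0_{ij})]}}
#' over the N native pairs, with \eqn{r_{ij}} the instantaneous distance and
#' \eqn{r^0_{ij}} the native distance. `beta` (Angstrom^-1) sets the
#' sharpness of the switching function and `lambda >= 1` the tolerated
#' fluctuation of the native distance. Defaults (5 Angstrom^-1, 1.8) are the
#' published values of the soft-Q order parameter; both are recorded in every
#' report.
#'
#' @param beta Smoothing parameter in 1/Angstrom (> 0, default 5).
#' @param lam Tolerance factor (>= 1, default 1.8).
#' @return A named list of class `q_parameters`.
#' @export
q_parameters <- function(beta = 5.0, lam = 1.8) {
  if (beta <= 0) stop("beta must be positive", call. = FALSE)
  if (lam < 1) stop("lam must be >= 1", call. = FALSE)
  structure(list(beta = beta, lam = lam), class = "q_parameters")
}

#' Soft fraction of native contacts of a single frame
#'
#' Evaluates the logistic-weighted Q over a contact selection. The logistic
#' is evaluated in a numerically safe form (via [stats::plogis()]), so fully
#' unfolded frames give a contribution that underflows cleanly to 0 instead
#' of overflowing.
#'
#' @param xyz `n_atoms x 3` coordinate matrix (Angstrom) in the reference
#'   atom ordering, or a `structure_model`.
#' @param contacts A `native_contacts` object or subset.
#' @param params A [q_parameters()] list.
#' @return Q in (0, 1).
#' @examples
#' # a single contact at exactly lambda * r0 sits at the logistic midpoint
#' s <- make_toy_structure(toy_system_spec(n_residues = 12, seed = 1))
#' nc <- build_native_contacts(s)
#' soft_q(structure_xyz(s), nc)
#' @export
soft_q <- function(xyz, contacts, params = q_parameters()) {
  stopifnot(inherits(contacts, "native_contacts"))
  if (inherits(xyz, "structure_model")) xyz <- structure_xyz(xyz)
  p <- contacts$pairs
  if (nrow(p) == 0) {
    stop("empty contact selection: Q undefined", call. = FALSE)
  }
  if (nrow(xyz) != contacts$n_atoms) {
    stop("frame has ", nrow(xyz), " atoms; contact set expects ",
         contacts$n_atoms, call. = FALSE)
  }
  d <- sqrt((xyz[p$atom_i, 1] - xyz[p$atom_j, 1])^2 +
              (xyz[p$atom_i, 2] - xyz[p$atom_j, 2])^2 +
              (xyz[p$atom_i, 3] - xyz[p$atom_j, 3])^2)
  mean(stats::plogis(-params$beta * (d - params$lam * p$r0)))
}

# per-pair logistic contributions for one replica: n_frames x n_pairs matrix
.pair_contributions <- function(coords, contacts, params) {
  p <- contacts$pairs
  nf <- dim(coords)[3]
  out <- matrix(NA_real_, nrow = nf, ncol = nrow(p))
  thr <- params$lam * p$r0
  for (f in seq_len(nf)) {
    m <- coords[, , f]
    d <- sqrt((m[p$atom_i, 1] - m[p$atom_j, 1])^2 +
                (m[p$atom_i, 2] - m[p$atom_j, 2])^2 +
                (m[p$atom_i, 3] - m[p$atom_j, 3])^2)
    out[f, ] <- stats::plogis(-params$beta * (d - thr))
  }
  out
}

#' Q time series over an ensemble
#'
#' One Q value per frame per replica for an arbitrary contact selection.
#'
#' @param ensemble A `trajectory_ensemble` whose frames follow the reference
#'   atom ordering.
#' @param contacts A `native_contacts` object or subset (non-empty).
#' @param params A [q_parameters()] list.
#' @param selection Label stored in the output (default: the contact set's
#'   own selection label).
#' @return Tidy tibble: `system_id`, `replica_id`, `frame`, `time_ns`,
#'   `selection`, `q`.
#' @export
q_series <- function(ensemble, contacts, params = q_parameters(),
                     selection = NULL) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"),
            inherits(contacts, "native_contacts"))
  if (nrow(contacts$pairs) == 0) {
    stop("empty contact selection: Q undefined", call. = FALSE)
  }
  if (ensemble$n_atoms != contacts$n_atoms) {
    stop("ensemble atom count does not match contact set", call. = FALSE)
  }
  if (is.null(selection)) selection <- contacts$selection
  purrr::map_dfr(ensemble$replicas, function(r) {
    contrib <- .pair_contributions(r$coords, contacts, params)
    tibble::tibble(system_id = ensemble$system_id,
                   replica_id = r$replica_id,
                   frame = seq_len(nrow(contrib)), time_ns = r$times,
                   selection = selection, q = rowMeans(contrib))
  })
}

#' Q time series for a residue-group pair
#'
#' Composition of [mask_by_groups()] and [q_series()]. An empty group-pair
#' selection yields a zero-row tibble with a warning (so the pair is dropped
#' from downstream correlation rather than aborting a whole run).
#'
#' @inheritParams q_series
#' @param group_a,group_b Group labels or `"all"`.
#' @param scheme A `residue_group_scheme`.
#' @return Tibble as [q_series()], with selection `"<group_a>-<group_b>"`.
#' @export
group_pair_q_series <- function(ensemble, contacts, group_a, group_b,
                                scheme = residue_group_scheme(),
                                params = q_parameters()) {
  sub <- mask_by_groups(contacts, group_a, group_b, scheme,
                        allow_empty = TRUE)
  if (nrow(sub$pairs) == 0) {
    warning("group pair ", group_a, "-", group_b,
            " has no native contacts; series undefined", call. = FALSE)
    return(tibble::tibble(system_id = character(), replica_id = integer(),
                          frame = integer(), time_ns = numeric(),
                          selection = character(), q = numeric()))
  }
  q_series(ensemble, sub, params)
}

#' Per-residue Q time series
#'
#' The Q of each residue with respect to all its native-contact partners,
#' computed for every frame. Pair contributions are evaluated once and
#' aggregated per residue (each pair contributes to both of its residues).
#' Residues without native contacts are omitted (their Q is undefined).
#'
#' @inheritParams q_series
#' @param residues 0-based residue indices to compute (default: all residues
#'   having at least one contact).
#' @return Tidy tibble: `system_id`, `replica_id`, `residue_index`, `frame`,
#'   `time_ns`, `q`.
#' @export
per_residue_q_series <- function(ensemble, contacts, residues = NULL,
                                 params = q_parameters()) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"),
            inherits(contacts, "native_contacts"))
  if (ensemble$n_atoms != contacts$n_atoms) {
    stop("ensemble atom count does not match contact set", call. = FALSE)
  }
  pr <- contacts$per_residue
  with_contacts <- pr$residue_index[pr$n_contacts > 0]
  if (is.null(residues)) {
    residues <- with_contacts
  } else if (!all(residues %in% pr$residue_index)) {
    stop("unknown residue index", call. = FALSE)
  } else if (!all(residues %in% with_contacts)) {
    stop("residue(s) without native contacts: per-residue Q undefined",
         call. = FALSE)
  }
  p <- contacts$pairs
  cols <- lapply(residues, function(k) which(p$res_i == k | p$res_j == k))
  purrr::map_dfr(ensemble$replicas, function(r) {
    contrib <- .pair_contributions(r$coords, contacts, params)
    nf <- nrow(contrib)
    purrr::map_dfr(seq_along(residues), function(ri) {
      tibble::tibble(system_id = ensemble$system_id,
                     replica_id = r$replica_id,
                     residue_index = residues[ri],
                     frame = seq_len(nf), time_ns = r$times,
                     q = rowMeans(contrib[, cols[[ri]], drop = FALSE]))
    })
  })
}
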