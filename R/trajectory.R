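#' Construct a trajectory ensemble from in-memory coordinates
#'
#' An ensemble is one system's set of independent replica trajectories, all
#' sharing the reference structure's atom ordering. Coordinates are stored in
#' Angstrom as one `n_atoms x 3 x n_frames` array per replica.
#'
#' @param replicas List of replicas; each a list with `coords`
#'   (`n_atoms x 3 x n_frames` array, Angstrom), `times` (ns, strictly
#'   increasing) and optionally `replica_id`.
#' @param system_id System identifier.
#' @param n_atoms Expected atom count (taken from the first replica when
#'   omitted).
#' @return A `trajectory_ensemble` object.
#' @export
trajectory_ensemble <- function(replicas, system_id = "system",
                                n_atoms = NULL) {
  if (length(replicas) < 1) stop("need at least one replica", call. = FALSE)
  for (k in seq_along(replicas)) {
    r <- replicas[[k]]
    if (is.null(r$replica_id)) replicas[[k]]$replica_id <- k
    r <- replicas[[k]]
    if (length(dim(r$coords)) != 3 || dim(r$coords)[2] != 3) {
      stop("replica ", k, ": coords must be an n_atoms x 3 x n_frames array",
           call. = FALSE)
    }
    if (dim(r$coords)[3] != length(r$times)) {
      stop("replica ", k, ": times length does not match frame count",
           call. = FALSE)
    }
    if (length(r$times) > 1 && any(diff(r$times) <= 0)) {
      stop("replica ", k, ": times must be strictly increasing",
           call. = FALSE)
    }
  }
  na <- vapply(replicas, function(r) dim(r$coords)[1], integer(1))
  if (is.null(n_atoms)) n_atoms <- na[1]
  if (any(na != n_atoms)) {
    stop("replica atom counts differ from reference (", n_atoms, ")",
         call. = FALSE)
  }
  structure(list(system_id = system_id, replicas = replicas,
                 n_atoms = as.integer(n_atoms)),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  nf <- vapply(x$replicas, function(r) dim(r$coords)[3], integer(1))
  cat("<trajectory_ensemble> ", x$system_id, ": ", length(x$replicas),
      " replica(s), ", x$n_atoms, " atoms, ",
      paste(range(nf), collapse = "-"), " frames\n", sep = "")
  invisible(x)
}

#' Read replica trajectories against a reference structure
#'
#' Reads one trajectory file per replica. Multi-model PDB is always
#' supported; DCD is accepted as a binary format (coordinates assumed to be
#' in Angstrom, the DCD convention). Frames must contain exactly the
#' reference's atoms in the reference order; frame times are assigned as
#' `frame * dt_ns` since neither format stores physical time reliably.
#'
#' @param paths Character vector of trajectory files, one replica each.
#' @param reference The reference `structure_model` (the topology).
#' @param dt_ns Time between saved frames in ns (default 0.5).
#' @param system_id System identifier (default: reference `source_id`).
#' @return A `trajectory_ensemble`.
#' @export
read_trajectory <- function(paths, reference, dt_ns = 0.5,
                            system_id = NULL) {
  stopifnot(inherits(reference, "structure_model"))
  if (is.null(system_id)) system_id <- reference$source_id
  n_atoms <- nrow(reference$atoms)
  replicas <- purrr::imap(paths, function(p, k) {
    if (!file.exists(p)) stop("trajectory file not found: ", p, call. = FALSE)
    xyz <- if (grepl("\\.dcd$", p, ignore.case = TRUE)) {
      bio3d::read.dcd(p, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.pdb(p, multi = TRUE, verbose = FALSE))$xyz
    }
    xyz <- unclass(xyz)
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
    if (ncol(xyz) != 3 * n_atoms) {
      stop("trajectory '", p, "' has ", ncol(xyz) / 3,
           " atoms; reference has ", n_atoms, call. = FALSE)
    }
    nf <- nrow(xyz)
    coords <- aperm(array(t(xyz), dim = c(3, n_atoms, nf)), c(2, 1, 3))
    list(replica_id = k, times = seq_len(nf) * dt_ns, coords = coords)
  })
  trajectory_ensemble(replicas, system_id = system_id, n_atoms = n_atoms)
}

#' Write an ensemble as multi-model PDB trajectories
#'
#' One file per replica, frames as MODEL/ENDMDL blocks, coordinates at PDB
#' precision (3 decimals).
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param reference The matching `structure_model` (atom records).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default: system id).
#' @return Character vector of written paths, invisibly.
#' @export
write_trajectory_pdb <- function(ensemble, reference, dir,
                                 prefix = ensemble$system_id) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"),
            inherits(reference, "structure_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- reference$atoms
  paths <- character(length(ensemble$replicas))
  for (k in seq_along(ensemble$replicas)) {
    r <- ensemble$replicas[[k]]
    nf <- dim(r$coords)[3]
    path <- file.path(dir, sprintf("%s_rep%02d.pdb", prefix, r$replica_id))
    con <- file(path, open = "wt")
    for (f in seq_len(nf)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      writeLines(sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        a$serial, .pdb_atom_name(a$name), a$residue_name, a$chain_id,
        a$author_seq_id, r$coords[, 1, f], r$coords[, 2, f],
        r$coords[, 3, f], 1, 0, a$element), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
    close(con)
    paths[k] <- path
  }
  invisible(paths)
}

# PDB atom-name column convention: names shorter than 4 chars start in col 14
.pdb_atom_name <- function(name) {
  ifelse(nchar(name) >= 4, substr(name, 1, 4), paste0(" ", name))
}

.BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Backbone RMSD time series against the reference
#'
#' For every frame the backbone (N, CA, C, O by default) is superposed onto
#' the reference by the optimal least-squares rigid transformation and the
#' root-mean-square deviation over the backbone atoms is reported, in nm.
#'
#' @param ensemble A `trajectory_ensemble`.
#' @param reference The reference `structure_model`.
#' @param backbone Atom names treated as backbone (default N, CA, C, O).
#' @return Tibble: `system_id`, `replica_id`, `frame`, `time_ns`, `rmsd_nm`.
#' @export
backbone_rmsd_series <- function(ensemble, reference,
                                 backbone = .BACKBONE_NAMES) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"),
            inherits(reference, "structure_model"))
  a <- reference$atoms
  bb <- which(a$name %in% backbone & !a$is_hydrogen)
  if (length(bb) < 3) {
    stop("backbone atoms (", paste(backbone, collapse = ","),
         ") missing from reference", call. = FALSE)
  }
  ref_xyz <- as.numeric(t(cbind(a$x, a$y, a$z)))
  bb_xyz_ind <- as.numeric(vapply(bb, function(i) (3 * (i - 1)) + 1:3,
                                  numeric(3)))
  ref_bb <- ref_xyz[bb_xyz_ind]
  purrr::map_dfr(ensemble$replicas, function(r) {
    nf <- dim(r$coords)[3]
    mob <- t(apply(r$coords, 3, function(m) as.numeric(t(m))))
    if (nf == 1) mob <- matrix(mob, nrow = 1)
    # least-squares (Kabsch) superposition; RMS computed at full precision
    fitted <- bio3d::fit.xyz(ref_xyz, mob, fixed.inds = bb_xyz_ind,
                             mobile.inds = bb_xyz_ind)
    if (nf == 1) fitted <- matrix(fitted, nrow = 1)
    dev2 <- (fitted[, bb_xyz_ind, drop = FALSE] -
               matrix(ref_bb, nrow = nf, ncol = length(ref_bb),
                      byrow = TRUE))^2
    rms <- sqrt(rowSums(dev2) / length(bb))
    tibble::tibble(system_id = ensemble$system_id, replica_id = r$replica_id,
                   frame = seq_len(nf), time_ns = r$times,
                   rmsd_nm = rms / 10)
  })
}

#' Final-window summary of a time series
#'
#' Implements the analysis-window rule: within each replica, frames with
#' `time >= (1 - window_fraction) * t_end` are kept (the final 30% by
#' default, matching a final-30-ns window of a 100 ns run); the headline mean
#' and standard deviation are computed over the selected frames pooled across
#' replicas, and per-replica means are retained for alternative summaries.
#' Alternatively an absolute window length can be given via `window_ns`.
#'
#' @param series Tibble with at least `replica_id`, a time column and a value
#'   column (as produced by [q_series()] or [backbone_rmsd_series()]).
#' @param value Name of the value column (default `"q"`, falling back to
#'   `"rmsd_nm"` when absent).
#' @param window_fraction Fraction of each replica's final time kept
#'   (default 0.3).
#' @param window_ns Absolute window length in ns; overrides
#'   `window_fraction` when given.
#' @param time Name of the time column (default `"time_ns"`).
#' @return A `window_stats` object: list with `mean`, `sd` (sample SD over
#'   pooled frames), `n_frames`, `window` (`c(t_start, t_end)` of the first
#'   replica), and `per_replica` (tibble of per-replica means and frame
#'   counts).
#' @export
final_window_stats <- function(series, value = NULL, window_fraction = 0.3,
                               window_ns = NULL, time = "time_ns") {
  if (nrow(series) == 0) stop("empty series", call. = FALSE)
  if (is.null(value)) {
    value <- if ("q" %in% names(series)) "q" else "rmsd_nm"
  }
  stopifnot(value %in% names(series), time %in% names(series))
  win <- .window_frames(series, window_fraction, window_ns, time)
  if (nrow(win) == 0) stop("analysis window selects zero frames",
                           call. = FALSE)
  v <- win[[value]]
  per_rep <- win |>
    dplyr::group_by(.data$replica_id) |>
    dplyr::summarise(mean = mean(.data[[value]]), n_frames = dplyr::n(),
                     .groups = "drop")
  t_end <- max(series[[time]][series$replica_id == series$replica_id[1]])
  t_start <- if (is.null(window_ns)) (1 - window_fraction) * t_end
             else t_end - window_ns
  structure(
    list(mean = mean(v), sd = stats::sd(v), n_frames = length(v),
         window = c(t_start = t_start, t_end = t_end),
         per_replica = per_rep),
    class = "window_stats"
  )
}

.window_frames <- function(series, window_fraction, window_ns, time) {
  series |>
    dplyr::group_by(.data$replica_id) |>
    dplyr::filter(
      .data[[time]] >= if (is.null(window_ns)) {
        (1 - window_fraction) * max(.data[[time]])
      } else {
        max(.data[[time]]) - window_ns
      }
    ) |>
    dplyr::ungroup()
}

#' @export
print.window_stats <- function(x, ...) {
  cat(sprintf("<window_stats> mean %.4f sd %.4f (%d frames, window %.3g-%.3g ns)\n",
              x$mean, x$sd, x$n_frames, x$window[1], x$window[2]))
  invisible(x)
}

#' Per-group final-window means
#'
#' Grouped version of [final_window_stats()]: computes the final-window mean
#' per combination of grouping columns (e.g. per residue and replica), which
#' is the input to [detect_unstable_residues()].
#'
#' @param series Tidy series tibble containing `replica_id`, the time column
#'   and the value column.
#' @param ... Grouping columns (tidy-select, e.g. `residue_index,
#'   replica_id`).
#' @inheritParams final_window_stats
#' @return Tibble with the grouping columns plus `mean_q` and `n_frames`.
#' @export
final_window_means <- function(series, ..., value = "q",
                               window_fraction = 0.3, window_ns = NULL,
                               time = "time_ns") {
  win <- .window_frames(series, window_fraction, window_ns, time)
  win |>
    dplyr::group_by(...) |>
    dplyr::summarise(mean_q = mean(.data[[value]]), n_frames = dplyr::n(),
                     .groups = "drop")
}
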