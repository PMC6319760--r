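#' Build the native contact set of a reference structure
#'
#' A native contact is an unordered pair of heavy atoms within `cutoff`
#' Angstrom in the reference structure whose residues are separated by more
#' than `min_separation` positions in sequence (internal contiguous
#' numbering). The native distance r0 of every pair is stored at full
#' precision; it parameterises the soft Q kernel ([soft_q()]). The cutoff
#' comparison is strict (`r0 < cutoff`), so a pair at exactly the cutoff is
#' excluded.
#'
#' The numeric defaults (4.5 Angstrom, sequence separation > 3, heavy atoms
#' only) are the conventional ones for the soft fraction-of-native-contacts
#' order parameter; they are configurable and are echoed into every report
#' for provenance.
#'
#' @param structure A `structure_model`.
#' @param cutoff Contact distance cutoff in Angstrom (default 4.5).
#' @param min_separation Residues must satisfy `|i - j| > min_separation`
#'   (default 3).
#' @param heavy_only Restrict to non-hydrogen atoms (default `TRUE`).
#' @return A `native_contacts` object: list with `pairs` (tibble: `atom_i`,
#'   `atom_j` row indices into the structure's atom table with
#'   `serial_i < serial_j`, serials, residue indices and names, `r0`),
#'   `per_residue` (tibble: `residue_index`, `n_contacts` for every residue),
#'   `params`, `n_atoms`, `source_id` and a `selection` label (`"all-all"`
#'   for the full set).
#' @export
build_native_contacts <- function(structure, cutoff = 4.5,
                                  min_separation = 3, heavy_only = TRUE) {
  stopifnot(inherits(structure, "structure_model"))
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (min_separation < 0) stop("min_separation must be >= 0", call. = FALSE)

  at <- structure$atoms
  sel <- if (heavy_only) which(!at$is_hydrogen) else seq_len(nrow(at))
  if (length(sel) < 2) stop("fewer than two atoms available", call. = FALSE)
  xyz <- cbind(at$x[sel], at$y[sel], at$z[sel])
  res <- at$residue_index[sel]

  d <- as.matrix(stats::dist(xyz))
  sep_ok <- abs(outer(res, res, "-")) > min_separation
  hit <- which(upper.tri(d) & d < cutoff & sep_ok, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    stop("empty native contact set: Q is undefined for this structure/",
         "parameters", call. = FALSE)
  }
  ai <- sel[hit[, 1]]; aj <- sel[hit[, 2]]
  # orient each pair by increasing serial, then sort the list
  swap <- at$serial[ai] > at$serial[aj]
  tmp <- ai[swap]; ai[swap] <- aj[swap]; aj[swap] <- tmp
  ord <- order(at$serial[ai], at$serial[aj])
  ai <- ai[ord]; aj <- aj[ord]

  pairs <- tibble::tibble(
    atom_i = ai, atom_j = aj,
    serial_i = at$serial[ai], serial_j = at$serial[aj],
    res_i = at$residue_index[ai], res_j = at$residue_index[aj],
    res_name_i = at$residue_name[ai], res_name_j = at$residue_name[aj],
    r0 = sqrt((at$x[ai] - at$x[aj])^2 + (at$y[ai] - at$y[aj])^2 +
                (at$z[ai] - at$z[aj])^2)
  )
  .new_native_contacts(pairs, structure,
                       params = list(cutoff = cutoff,
                                     min_separation = min_separation,
                                     heavy_atoms_only = heavy_only),
                       selection = "all-all")
}

.new_native_contacts <- function(pairs, structure, params, selection) {
  counts <- tabulate(c(pairs$res_i, pairs$res_j) + 1L,
                     nbins = nrow(structure$residues))
  per_residue <- tibble::tibble(
    residue_index = structure$residues$residue_index,
    n_contacts = as.integer(counts)
  )
  structure(
    list(pairs = pairs, per_residue = per_residue, params = params,
         n_atoms = nrow(structure$atoms), source_id = structure$source_id,
         selection = selection),
    class = "native_contacts"
  )
}

#' @export
print.native_contacts <- function(x, ...) {
  cat("<native_contacts> ", x$source_id, " [", x$selection, "]\n", sep = "")
  cat("  ", nrow(x$pairs), " pairs; cutoff ", x$params$cutoff,
      " A, |dres| > ", x$params$min_separation, "\n", sep = "")
  invisible(x)
}

# subset pairs while keeping bookkeeping consistent
.subset_contacts <- function(contacts, keep, selection) {
  out <- contacts
  out$pairs <- contacts$pairs[keep, , drop = FALSE]
  counts <- tabulate(c(out$pairs$res_i, out$pairs$res_j) + 1L,
                     nbins = nrow(contacts$per_residue))
  out$per_residue <- tibble::tibble(
    residue_index = contacts$per_residue$residue_index,
    n_contacts = as.integer(counts)
  )
  out$selection <- selection
  out
}

#' Restrict a contact set to a residue-group pair
#'
#' A pair is selected iff one member belongs to `group_a` and the other to
#' `group_b`, in either order; `"all"` matches any group. `("all", "all")`
#' returns the full set. The six unordered pairings of the three groups
#' partition the full set.
#'
#' @param contacts A `native_contacts` object.
#' @param group_a,group_b Group label (see [group_labels()]) or `"all"`.
#' @param scheme A `residue_group_scheme`.
#' @param allow_empty Return an empty subset instead of raising when no pair
#'   matches (default `FALSE`).
#' @return A `native_contacts` subset with `selection` set to
#'   `"<group_a>-<group_b>"`.
#' @export
mask_by_groups <- function(contacts, group_a, group_b,
                           scheme = residue_group_scheme(),
                           allow_empty = FALSE) {
  stopifnot(inherits(contacts, "native_contacts"))
  valid <- c(group_labels(scheme), "all")
  if (!group_a %in% valid || !group_b %in% valid) {
    stop("unknown group label; expected one of: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  p <- contacts$pairs
  gi <- classify_residue(p$res_name_i, scheme)
  gj <- classify_residue(p$res_name_j, scheme)
  match_one <- function(g, side) if (g == "all") rep(TRUE, nrow(p)) else side == g
  keep <- (match_one(group_a, gi) & match_one(group_b, gj)) |
    (match_one(group_a, gj) & match_one(group_b, gi))
  if (!any(keep) && !allow_empty) {
    stop("empty selection for group pair ", group_a, "-", group_b,
         call. = FALSE)
  }
  .subset_contacts(contacts, keep, paste0(group_a, "-", group_b))
}

#' Restrict a contact set to one residue
#'
#' Selects every pair with at least one atom in the residue; the basis of the
#' per-residue Q used for unstable-residue detection.
#'
#' @param contacts A `native_contacts` object.
#' @param residue_index 0-based internal residue index.
#' @return A `native_contacts` subset (possibly empty) with selection
#'   `"residue:<index>"`.
#' @export
mask_by_residue <- function(contacts, residue_index) {
  stopifnot(inherits(contacts, "native_contacts"))
  if (!residue_index %in% contacts$per_residue$residue_index) {
    stop("residue index ", residue_index, " not in structure", call. = FALSE)
  }
  keep <- contacts$pairs$res_i == residue_index |
    contacts$pairs$res_j == residue_index
  .subset_contacts(contacts, keep, paste0("residue:", residue_index))
}

#' Residues with too few native contacts for a reliable Q
#'
#' Residues with fewer than `min_contacts` native atomic contacts (strict
#' `<`) have unreliable per-residue Q values; they are reported separately
#' and never flagged as unstable.
#'
#' @param contacts A `native_contacts` object (the full set).
#' @param min_contacts Threshold (default 30).
#' @return Integer vector of excluded 0-based residue indices.
#' @export
excluded_residues <- function(contacts, min_contacts = 30) {
  stopifnot(inherits(contacts, "native_contacts"))
  pr <- contacts$per_residue
  pr$residue_index[pr$n_contacts < min_contacts]
}

#' Export a contact set to CSV
#'
#' Writes atom serials, residue indices/names and native distances for
#' inspection or as a plain-text fixture.
#'
#' @param contacts A `native_contacts` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contacts_csv <- function(contacts, path) {
  stopifnot(inherits(contacts, "native_contacts"))
  readr::write_csv(contacts$pairs, path)
  invisible(path)
}

#' Import a contact set from CSV
#'
#' Inverse of [write_contacts_csv()]; the structure provides the residue
#' bookkeeping and atom count.
#'
#' @param path CSV path written by [write_contacts_csv()].
#' @param structure The `structure_model` the contacts refer to.
#' @param params Contact parameters to record (list with `cutoff`,
#'   `min_separation`, `heavy_atoms_only`).
#' @return A `native_contacts` object.
#' @export
read_contacts_csv <- function(path, structure,
                              params = list(cutoff = NA_real_,
                                            min_separation = NA_integer_,
                                            heavy_atoms_only = NA)) {
  pairs <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             res_name_i = readr::col_character(),
                             res_name_j = readr::col_character()
                           ))
  .new_native_contacts(tibble::as_tibble(pairs), structure, params,
                       selection = "all-all")
}
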