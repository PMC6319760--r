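#' Detect unstable residues from per-residue final-window means
#'
#' A residue is flagged unstable in a replica when its per-residue Q,
#' averaged over the final analysis window of that replica, falls strictly
#' below `q_threshold` (default 0.6). Residues with fewer than
#' `min_contacts` native atomic contacts (default 30) have unreliable Q
#' values: they are listed as excluded and are never flagged, whatever their
#' mean Q.
#'
#' @param window_means Tibble with `residue_index`, `replica_id`, `mean_q`
#'   (as produced by [final_window_means()] on a [per_residue_q_series()]).
#' @param contacts The full `native_contacts` set (supplies per-residue
#'   contact counts).
#' @param structure Optional `structure_model` used to attach author-
#'   numbered labels and CDR flags.
#' @param q_threshold Flagging threshold on the final-window mean Q (strict
#'   `<`; default 0.6).
#' @param min_contacts Minimum native contacts for a reliable per-residue Q
#'   (strict `<` defines exclusion; default 30).
#' @return List with `flagged` (tibble: one row per flagged
#'   (residue, replica): `residue_index`, `residue` label, `replica_id`,
#'   `mean_q`, `n_contacts`, `in_cdr`), `per_residue` (tibble aggregated per
#'   flagged residue with `n_replicas_affected`) and `excluded` (tibble of
#'   excluded residues with their contact counts).
#' @export
detect_unstable_residues <- function(window_means, contacts,
                                     structure = NULL, q_threshold = 0.6,
                                     min_contacts = 30) {
  stopifnot(inherits(contacts, "native_contacts"),
            all(c("residue_index", "replica_id", "mean_q") %in%
                  names(window_means)))
  excl <- excluded_residues(contacts, min_contacts)
  counts <- contacts$per_residue

  lab <- function(idx) {
    if (!is.null(structure)) residue_label(structure, idx)
    else as.character(idx)
  }
  cdr <- function(idx) {
    if (!is.null(structure)) in_cdr(structure, idx) else rep(NA, length(idx))
  }

  flagged <- window_means |>
    dplyr::filter(.data$mean_q < q_threshold,
                  !.data$residue_index %in% excl) |>
    dplyr::left_join(counts, by = "residue_index") |>
    dplyr::arrange(.data$residue_index, .data$replica_id)
  flagged <- flagged |>
    dplyr::mutate(residue = lab(.data$residue_index),
                  in_cdr = cdr(.data$residue_index)) |>
    dplyr::select("residue_index", "residue", "replica_id", "mean_q",
                  "n_contacts", "in_cdr")

  per_residue <- flagged |>
    dplyr::group_by(.data$residue_index, .data$residue, .data$n_contacts,
                    .data$in_cdr) |>
    dplyr::summarise(n_replicas_affected = dplyr::n(),
                     mean_q = mean(.data$mean_q), .groups = "drop")

  excluded <- counts |>
    dplyr::filter(.data$residue_index %in% excl) |>
    dplyr::mutate(residue = lab(.data$residue_index)) |>
    dplyr::select("residue_index", "residue", "n_contacts")

  list(flagged = flagged, per_residue = per_residue, excluded = excluded)
}

#' Group composition of the unstable residues
#'
#' Percentage of unstable residues belonging to each physicochemical group,
#' weighted by the number of trajectories affected per residue: for group g,
#' `100 * sum over flagged residues in g of replicas_affected / total
#' replicas_affected over all flagged residues`.
#'
#' @param detection Result of [detect_unstable_residues()], or its
#'   `per_residue` tibble; requires a `residue_name` available either via a
#'   `structure` or a `residue_name` column.
#' @param structure `structure_model` supplying residue names (optional if
#'   the tibble already carries `residue_name`).
#' @param scheme A `residue_group_scheme`.
#' @return Tibble: `group`, `weight` (replicas affected), `percent`. All
#'   three groups are present (0 where unaffected); percentages sum to 100.
#'   With no flagged residues the percentages are `NA` (undefined).
#' @export
composition_stats <- function(detection, structure = NULL,
                              scheme = residue_group_scheme()) {
  pr <- if (is.data.frame(detection)) detection else detection$per_residue
  gl <- group_labels(scheme)
  if (!"residue_name" %in% names(pr)) {
    if (is.null(structure)) {
      stop("need `structure` (or a residue_name column) to classify ",
           "flagged residues", call. = FALSE)
    }
    i <- match(pr$residue_index, structure$residues$residue_index)
    pr$residue_name <- structure$residues$residue_name[i]
  }
  if (nrow(pr) == 0) {
    return(tibble::tibble(group = gl, weight = 0,
                          percent = NA_real_))
  }
  pr$group <- classify_residue(pr$residue_name, scheme)
  agg <- pr |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(weight = sum(.data$n_replicas_affected),
                     .groups = "drop")
  out <- tibble::tibble(group = gl) |>
    dplyr::left_join(agg, by = "group") |>
    dplyr::mutate(weight = dplyr::coalesce(.data$weight, 0L))
  out$percent <- 100 * out$weight / sum(out$weight)
  out
}

#' Stable fraction of a residue group
#'
#' Percentage of a group's (residue, replica) slots that stayed stable:
#' `100 * (1 - replicas_affected_in_group / (n_group_residues_after_exclusion
#' * n_replicas))`. Excluded residues are ignored in both numerator and
#' denominator.
#'
#' @param detection Result of [detect_unstable_residues()].
#' @param contacts The full `native_contacts` set.
#' @param structure `structure_model` supplying residue names.
#' @param group Group label (see [group_labels()]).
#' @param n_replicas Number of replicas analysed.
#' @param scheme A `residue_group_scheme`.
#' @param min_contacts Exclusion threshold, matching the detection call
#'   (default 30).
#' @return Percentage in `[0, 100]`.
#' @export
group_stability_fraction <- function(detection, contacts, structure, group,
                                     n_replicas,
                                     scheme = residue_group_scheme(),
                                     min_contacts = 30) {
  stopifnot(group %in% group_labels(scheme))
  excl <- excluded_residues(contacts, min_contacts)
  res <- structure$residues
  grp <- classify_residue(res$residue_name, scheme)
  members <- res$residue_index[grp == group &
                                 !res$residue_index %in% excl]
  if (length(members) == 0) {
    stop("group '", group, "' is empty after exclusions", call. = FALSE)
  }
  pr <- detection$per_residue
  affected <- sum(pr$n_replicas_affected[pr$residue_index %in% members])
  100 * (1 - affected / (length(members) * n_replicas))
}

#' Pearson product-moment correlation
#'
#' Thin, guarded wrapper around [stats::cor()]: requires equal lengths of at
#' least 3 and nonzero variance in both vectors (a degenerate input is an
#' error, never a silent `NA`).
#'
#' @param x,y Numeric vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: Pearson r undefined", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Correlate per-system Q averages with melting temperatures
#'
#' For every Q selection, the Pearson correlation between the per-system
#' final-window mean Q and the experimental (or pseudo) Tm. Systems missing
#' a selection are dropped pairwise with a warning; selections with fewer
#' than 3 usable systems or zero variance are reported with `r = NA` and a
#' note rather than an error.
#'
#' @param system_summaries Tibble with `system_id`, `selection`, `mean`
#'   (one row per system x selection; see [tidy.stability_report()]).
#' @param tm Tibble with `system_id`, `tm_celsius` (one row per system).
#' @param selections Selections to correlate (default: all present).
#' @return Tibble: `selection`, `r`, `n`, `note`.
#' @export
correlation_table <- function(system_summaries, tm, selections = NULL) {
  stopifnot(all(c("system_id", "selection", "mean") %in%
                  names(system_summaries)),
            all(c("system_id", "tm_celsius") %in% names(tm)))
  if (anyDuplicated(tm$system_id)) {
    stop("duplicate system_id in Tm table", call. = FALSE)
  }
  if (is.null(selections)) selections <- unique(system_summaries$selection)
  joined <- dplyr::inner_join(system_summaries, tm, by = "system_id")
  n_sys <- dplyr::n_distinct(joined$system_id)
  if (n_sys < 3) {
    stop("fewer than 3 systems with both Q and Tm", call. = FALSE)
  }
  purrr::map_dfr(selections, function(s) {
    d <- joined[joined$selection == s, ]
    if (nrow(d) < n_sys) {
      warning("selection '", s, "' missing for ",
              n_sys - nrow(d), " system(s); dropped pairwise",
              call. = FALSE)
    }
    if (nrow(d) < 3) {
      return(tibble::tibble(selection = s, r = NA_real_, n = nrow(d),
                            note = "insufficient systems (<3)"))
    }
    if (stats::sd(d$mean) == 0 || stats::sd(d$tm_celsius) == 0) {
      return(tibble::tibble(selection = s, r = NA_real_, n = nrow(d),
                            note = "zero variance"))
    }
    tibble::tibble(selection = s, r = pearson_r(d$mean, d$tm_celsius),
                   n = nrow(d), note = "")
  })
}

# the ten standard Q selections: all-all, each group vs all, and the six
# disjoint unordered group pairs
.standard_selections <- function(scheme = residue_group_scheme()) {
  gl <- group_labels(scheme)
  pairs <- list(c("all", "all"))
  for (g in gl) pairs <- c(pairs, list(c(g, "all")))
  for (i in seq_along(gl)) {
    for (j in i:length(gl)) pairs <- c(pairs, list(c(gl[i], gl[j])))
  }
  pairs
}

#' Full stability analysis of one system
#'
#' Runs the complete per-system pipeline: backbone RMSD, all-all Q, the
#' three group-vs-all and six disjoint group-pair Q series, per-residue Q,
#' final-window statistics for each, unstable-residue detection, composition
#' and per-group stability percentages. All parameters are echoed into the
#' report for provenance.
#'
#' @param structure Reference `structure_model` (annotate CDRs first if CDR
#'   flags are wanted in the unstable-residue table).
#' @param ensemble A `trajectory_ensemble` for the system.
#' @param contacts Optional prebuilt `native_contacts`; built from
#'   `structure` with `cutoff`/`min_separation` when omitted.
#' @param cutoff,min_separation Contact definition (Angstrom; sequence
#'   separation), see [build_native_contacts()].
#' @param params A [q_parameters()] list.
#' @param scheme A `residue_group_scheme`.
#' @param window_fraction Final-window fraction (default 0.3).
#' @param q_threshold Unstable-residue threshold (default 0.6).
#' @param min_contacts Exclusion threshold (default 30).
#' @param keep_series Keep the full Q/RMSD time series in the report
#'   (default `TRUE`; set `FALSE` to save memory on large runs).
#' @return A `stability_report` object; see [tidy.stability_report()] and
#'   [glance.stability_report()].
#' @export
analyze_system <- function(structure, ensemble, contacts = NULL,
                           cutoff = 4.5, min_separation = 3,
                           params = q_parameters(),
                           scheme = residue_group_scheme(),
                           window_fraction = 0.3, q_threshold = 0.6,
                           min_contacts = 30, keep_series = TRUE) {
  stopifnot(inherits(structure, "structure_model"),
            inherits(ensemble, "trajectory_ensemble"))
  if (is.null(contacts)) {
    contacts <- build_native_contacts(structure, cutoff = cutoff,
                                      min_separation = min_separation)
  }

  rmsd <- backbone_rmsd_series(ensemble, structure)
  rmsd_stats <- final_window_stats(rmsd, value = "rmsd_nm",
                                   window_fraction = window_fraction)

  sel_series <- purrr::map_dfr(.standard_selections(scheme), function(gp) {
    group_pair_q_series(ensemble, contacts, gp[1], gp[2], scheme, params)
  })
  selections <- sel_series |>
    dplyr::group_by(.data$selection) |>
    dplyr::group_modify(function(d, key) {
      ws <- final_window_stats(dplyr::mutate(d, replica_id = d$replica_id),
                               value = "q",
                               window_fraction = window_fraction)
      tibble::tibble(mean = ws$mean, sd = ws$sd, n_frames = ws$n_frames)
    }) |>
    dplyr::ungroup()

  resq <- per_residue_q_series(ensemble, contacts, params = params)
  res_means <- final_window_means(resq, .data$residue_index,
                                  .data$replica_id,
                                  window_fraction = window_fraction)
  detection <- detect_unstable_residues(res_means, contacts, structure,
                                        q_threshold = q_threshold,
                                        min_contacts = min_contacts)
  composition <- composition_stats(detection, structure, scheme)
  n_rep <- length(ensemble$replicas)
  stability <- purrr::map_dfr(group_labels(scheme), function(g) {
    pct <- tryCatch(
      group_stability_fraction(detection, contacts, structure, g, n_rep,
                               scheme, min_contacts),
      error = function(e) NA_real_
    )
    tibble::tibble(group = g, percent_stable = pct)
  })

  report <- structure(
    list(system_id = ensemble$system_id,
         n_replicas = n_rep,
         rmsd = rmsd_stats,
         selections = selections,
         per_residue_means = res_means,
         detection = detection,
         composition = composition,
         group_stability = stability,
         params = list(
           contact = contacts$params,
           q = unclass(params),
           window_fraction = window_fraction,
           q_threshold = q_threshold,
           min_contacts = min_contacts,
           scheme = attr(scheme, "name"),
           backbone = .BACKBONE_NAMES
         ),
         n_contacts = nrow(contacts$pairs)),
    class = "stability_report"
  )
  if (keep_series) {
    report$series <- list(rmsd = rmsd, q = sel_series)
  }
  report
}

#' @export
print.stability_report <- function(x, ...) {
  qa <- x$selections[x$selections$selection == "all-all", ]
  cat("<stability_report> ", x$system_id, " (", x$n_replicas,
      " replicas)\n", sep = "")
  cat(sprintf("  all-all Q %.3f (%.3f); backbone RMSD %.3f nm (%.3f)\n",
              qa$mean, qa$sd, x$rmsd$mean, x$rmsd$sd))
  cat("  ", nrow(x$detection$per_residue), " unstable residue(s); ",
      nrow(x$detection$excluded), " excluded (<",
      x$params$min_contacts, " contacts)\n", sep = "")
  invisible(x)
}

#' Tidy a stability report
#'
#' One row per Q selection with the final-window mean/SD, in the style of
#' broom's `tidy()` verbs.
#'
#' @param x A `stability_report`.
#' @param ... Unused.
#' @return Tibble: `system_id`, `selection`, `mean`, `sd`, `n_frames`.
#' @export
tidy.stability_report <- function(x, ...) {
  dplyr::mutate(x$selections, system_id = x$system_id, .before = 1)
}

#' One-row summary of a stability report
#'
#' @param x A `stability_report`.
#' @param ... Unused.
#' @return One-row tibble: headline Q and RMSD, unstable/excluded counts.
#' @export
glance.stability_report <- function(x, ...) {
  qa <- x$selections[x$selections$selection == "all-all", ]
  tibble::tibble(
    system_id = x$system_id,
    q_all_mean = qa$mean, q_all_sd = qa$sd,
    rmsd_mean_nm = x$rmsd$mean, rmsd_sd_nm = x$rmsd$sd,
    n_unstable_residues = nrow(x$detection$per_residue),
    n_excluded_residues = nrow(x$detection$excluded),
    n_replicas = x$n_replicas,
    n_native_contacts = x$n_contacts
  )
}

#' Turn an object into a tidy tibble
#'
#' Broom-style generic; the package provides methods for its result types.
#'
#' @param x An object.
#' @param ... Method arguments.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model/result summary
#'
#' Broom-style generic; the package provides methods for its result types.
#'
#' @param x An object.
#' @param ... Method arguments.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Compare variant systems against a wild type
#'
#' Side-by-side means (SD) of backbone RMSD and the three headline Q
#' selections (hydrophilic-all, all-all, hydrophobic-small), with deltas
#' relative to the wild type. Reports computed with differing contact/Q/
#' window parameters are refused: they are not comparable.
#'
#' @param wt `stability_report` of the wild type.
#' @param ... `stability_report`s of the variants (named arguments become
#'   row labels).
#' @return Tibble: `system`, `rmsd_nm`, `rmsd_sd`, one mean/sd pair per Q
#'   selection, and `delta_q_*` columns vs the wild type.
#' @export
compare_variants <- function(wt, ...) {
  variants <- list(...)
  if (length(variants) == 1 && is.list(variants[[1]]) &&
      !inherits(variants[[1]], "stability_report")) {
    variants <- variants[[1]]
  }
  all_rep <- c(list(wt), variants)
  stopifnot(all(vapply(all_rep, inherits, logical(1), "stability_report")))
  ref_par <- wt$params
  for (r in all_rep[-1]) {
    if (!identical(r$params, ref_par)) {
      stop("reports were computed with different parameters; ",
           "not comparable", call. = FALSE)
    }
  }
  cols <- c("hydrophilic-all", "all-all", "hydrophobic-small")
  row_of <- function(rep) {
    s <- rep$selections
    out <- tibble::tibble(system = rep$system_id,
                          rmsd_nm = rep$rmsd$mean, rmsd_sd = rep$rmsd$sd)
    for (cl in cols) {
      i <- which(s$selection == cl)
      nm <- gsub("-", "_", cl)
      out[[paste0("q_", nm)]] <- if (length(i)) s$mean[i] else NA_real_
      out[[paste0("q_", nm, "_sd")]] <- if (length(i)) s$sd[i] else NA_real_
    }
    out
  }
  tab <- purrr::map_dfr(all_rep, row_of)
  for (cl in cols) {
    nm <- paste0("q_", gsub("-", "_", cl))
    tab[[paste0("delta_", nm)]] <- tab[[nm]] - tab[[nm]][1]
  }
  tab$delta_rmsd_nm <- tab$rmsd_nm - tab$rmsd_nm[1]
  tab
}

#' Run the synthetic stability benchmark end to end
#'
#' Generates every system of a [make_benchmark_suite()] table, analyses it
#' with [analyze_system()], and correlates the per-system final-window Q
#' averages with the pseudo melting temperatures.
#'
#' @param suite Tibble from [make_benchmark_suite()].
#' @param ... Passed on to [analyze_system()] (e.g. `params`,
#'   `window_fraction`).
#' @return List with `reports` (named list of `stability_report`s),
#'   `summaries` (tibble of per-system selection means), `glances`
#'   (one-row-per-system tibble) and `correlations`
#'   ([correlation_table()] output against `pseudo_tm`).
#' @export
run_benchmark <- function(suite, ...) {
  reports <- purrr::map(seq_len(nrow(suite)), function(i) {
    spec <- suite$spec[[i]]
    s <- make_toy_structure(spec)
    ens <- simulate_ensemble(s, spec, system_id = suite$system_id[i])
    analyze_system(s, ens, keep_series = FALSE, ...)
  })
  names(reports) <- suite$system_id
  summaries <- purrr::map_dfr(reports, tidy)
  tm <- tibble::tibble(system_id = suite$system_id,
                       tm_celsius = suite$pseudo_tm)
  list(reports = reports, summaries = summaries,
       glances = purrr::map_dfr(reports, glance),
       correlations = correlation_table(summaries, tm))
}
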