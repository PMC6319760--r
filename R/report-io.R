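#' Read a run configuration file
#'
#' The configuration is a YAML file naming the systems (id, reference
#' structure, trajectory files, optional CDR spans and Tm) and the analysis
#' parameters; missing parameters take the package defaults. The parsed
#' configuration is echoed verbatim into every report for provenance.
#'
#' @param path YAML file path.
#' @return A `run_config` list with `parameters` (complete) and `systems`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  as_run_config(raw, dir = dirname(path))
}

#' Build a run configuration from a list
#'
#' @param x List with `systems` and optionally `parameters` and `seed`.
#' @param dir Directory relative paths in `x` are resolved against.
#' @return A `run_config` list.
#' @export
as_run_config <- function(x, dir = ".") {
  defaults <- list(cutoff = 4.5, min_separation = 3, beta = 5.0,
                   lambda = 1.8, window_fraction = 0.3, q_threshold = 0.6,
                   min_contacts = 30, dt_ns = 0.5)
  par <- utils::modifyList(defaults, x$parameters %||% list())
  systems <- x$systems
  if (is.null(systems) || length(systems) == 0) {
    stop("config declares no systems", call. = FALSE)
  }
  resolve <- function(p) {
    ifelse(file.exists(p) | grepl("^/", p), p, file.path(dir, p))
  }
  for (k in seq_along(systems)) {
    s <- systems[[k]]
    if (is.null(s$id) || is.null(s$structure) || is.null(s$trajectories)) {
      stop("system ", k, ": needs id, structure and trajectories",
           call. = FALSE)
    }
    systems[[k]]$structure <- resolve(s$structure)
    systems[[k]]$trajectories <- resolve(unlist(s$trajectories))
  }
  structure(list(parameters = par, systems = systems,
                 seed = x$seed %||% 1L),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write one system's stability report to disk
#'
#' Emits the report as plain-text tables: a JSON summary (headline numbers,
#' composition, group stability and the full parameter block) plus CSVs for
#' the Q selections, the per-residue final-window means, the unstable-
#' residue table (CDR membership marked with a star, as stability reports
#' conventionally print it) and the excluded residues. Output is
#' deterministic: identical reports produce byte-identical files.
#'
#' @param report A `stability_report`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default: system id).
#' @return Character vector of written paths, invisibly.
#' @export
write_stability_report <- function(report, dir,
                                   prefix = report$system_id) {
  stopifnot(inherits(report, "stability_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(dir, paste0(prefix, "_", name, ".csv"))
    readr::write_csv(df, p)
    paths <<- c(paths, p)
  }
  w(tidy(report), "selections")
  w(report$per_residue_means, "per_residue")
  unst <- report$detection$flagged |>
    dplyr::mutate(cdr_star = ifelse(!is.na(.data$in_cdr) & .data$in_cdr,
                                    "*", ""))
  w(unst, "unstable")
  w(report$detection$excluded, "excluded")
  w(report$composition, "composition")
  w(report$group_stability, "group_stability")
  if (!is.null(report$series)) {
    w(report$series$q, "q_timeseries")
    w(report$series$rmsd, "rmsd_timeseries")
  }
  js <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(
    list(system_id = report$system_id,
         glance = glance(report),
         rmsd = list(mean_nm = report$rmsd$mean, sd_nm = report$rmsd$sd,
                     n_frames = report$rmsd$n_frames,
                     window_ns = as.list(report$rmsd$window)),
         composition = report$composition,
         group_stability = report$group_stability,
         parameters = report$params),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, js))
}

#' Run the full analysis workflow from a configuration
#'
#' Reads every system's structure and trajectories, runs
#' [analyze_system()], writes per-system report files, and — when at least
#' three systems carry a Tm — a correlation table of each Q selection
#' against Tm. With fewer than three such systems the correlation file
#' records that the section is undefined instead of failing.
#'
#' @param config A `run_config` (see [read_run_config()]) or path to one.
#' @param out_dir Output directory.
#' @return List with `reports`, `summaries`, `correlations` (or `NULL`),
#'   and `files`; also written to `out_dir`.
#' @export
run_analysis <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  par <- config$parameters
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  reports <- list()
  files <- character(0)
  for (s in config$systems) {
    st <- read_structure(s$structure, source_id = s$id)
    if (!is.null(s$cdr1) || !is.null(s$cdr2) || !is.null(s$cdr3)) {
      st <- annotate_cdrs(st, cdr1 = s$cdr1, cdr2 = s$cdr2, cdr3 = s$cdr3)
    }
    ens <- read_trajectory(s$trajectories, st, dt_ns = par$dt_ns,
                           system_id = s$id)
    rep <- analyze_system(
      st, ens,
      cutoff = par$cutoff, min_separation = par$min_separation,
      params = q_parameters(beta = par$beta, lam = par$lambda),
      window_fraction = par$window_fraction,
      q_threshold = par$q_threshold, min_contacts = par$min_contacts
    )
    reports[[s$id]] <- rep
    files <- c(files, write_stability_report(rep, out_dir))
  }
  summaries <- purrr::map_dfr(reports, tidy)

  tm <- purrr::map_dfr(config$systems, function(s) {
    tibble::tibble(system_id = s$id,
                   tm_celsius = s$tm_celsius %||% NA_real_)
  })
  tm <- tm[!is.na(tm$tm_celsius), ]
  corr <- NULL
  corr_path <- file.path(out_dir, "correlations.csv")
  if (nrow(tm) >= 3) {
    corr <- correlation_table(summaries, tm)
    readr::write_csv(corr, corr_path)
  } else {
    readr::write_csv(
      tibble::tibble(note = sprintf(
        "correlation undefined: insufficient systems with Tm (<3); have %d",
        nrow(tm))),
      corr_path)
  }
  files <- c(files, corr_path)

  jsonlite::write_json(
    list(parameters = par,
         systems = purrr::map_chr(config$systems, "id"),
         glances = purrr::map_dfr(reports, glance)),
    file.path(out_dir, "run_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, file.path(out_dir, "run_summary.json"))

  list(reports = reports, summaries = summaries, correlations = corr,
       files = files)
}

#' Write a synthetic system to disk
#'
#' Generates the toy reference structure and replica ensemble of a
#' [toy_system_spec()] and writes them as a reference PDB, one multi-model
#' PDB per replica, and a YAML echo of the generating spec for provenance.
#'
#' @param spec A [toy_system_spec()].
#' @param dir Output directory.
#' @param system_id System identifier (default: derived from the spec seed).
#' @return List with `structure_path`, `trajectory_paths`, `spec_path` and
#'   the in-memory `structure`/`ensemble`.
#' @export
simulate_to_files <- function(spec, dir, system_id = NULL) {
  stopifnot(inherits(spec, "toy_system_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  st <- make_toy_structure(spec)
  if (!is.null(system_id)) st$source_id <- system_id
  ens <- simulate_ensemble(st, spec, system_id = st$source_id)
  sp <- file.path(dir, paste0(st$source_id, "_ref.pdb"))
  write_structure(st, sp)
  tp <- write_trajectory_pdb(ens, st, dir)
  yp <- file.path(dir, paste0(st$source_id, "_spec.yaml"))
  yaml::write_yaml(unclass(spec), yp)
  list(structure_path = sp, trajectory_paths = tp, spec_path = yp,
       structure = st, ensemble = ens)
}
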