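#' Read a reference structure from a PDB file
#'
#' Parses one MODEL of a PDB file into a `structure_model`: an atom table with
#' contiguous 0-based internal residue indices plus the author residue
#' numbering retained for report readability (e.g. `"Trp47"`). Alternate
#' locations are resolved to the highest-occupancy conformer (ties keep the
#' first encountered). Waters, ions and other heteroatoms are dropped unless
#' `keep_hetero = TRUE`; N-terminal/C-terminal capping groups (ACE, NME) are
#' folded into the adjacent protein residue so that their atoms count for
#' contact definitions without appearing as separate residues in reports.
#'
#' @param path Path to a PDB file.
#' @param model 1-based MODEL index to read (default 1; files without MODEL
#'   records have a single model).
#' @param keep_hetero Retain HETATM records (waters, ions, ligands)? Default
#'   `FALSE`: the analysis operates on the protein only.
#' @param source_id Identifier stored on the model; defaults to the file name
#'   without extension.
#' @return A `structure_model` object: a list with `atoms` (tibble: `serial`,
#'   `name`, `element`, `is_hydrogen`, `residue_index`, `residue_name`,
#'   `chain_id`, `author_seq_id`, `ins_code`, `x`, `y`, `z`; coordinates in
#'   Angstrom), `residues` (one row per residue with author numbering and CDR
#'   flag), `cdr_ranges` (`NULL` until [annotate_cdrs()] is called) and
#'   `source_id`.
#' @seealso [annotate_cdrs()], [build_native_contacts()], [write_structure()]
#' @export
read_structure <- function(path, model = 1, keep_hetero = FALSE,
                           source_id = NULL) {
  if (!file.exists(path)) {
    stop("structure file not found: ", path, call. = FALSE)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  n_models <- max(1L, nrow(pdb$xyz))
  if (model < 1 || model > n_models) {
    stop("model index ", model, " out of range: file has ", n_models,
         " model(s)", call. = FALSE)
  }
  at <- pdb$atom
  # overwrite coordinates with the requested model
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  if (!keep_hetero) {
    cap <- at$type == "HETATM" & at$resid %in% c("ACE", "NME", "NMA")
    at <- at[at$type == "ATOM" | cap, , drop = FALSE]
  }
  if (nrow(at) == 0) stop("no protein atoms in model ", model, call. = FALSE)

  at <- .resolve_altloc(at)
  if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  .new_structure_model(at, source_id)
}

# keep, per (chain, resno, insert, elety), the highest-occupancy altloc
# (ties -> first record); preserves original atom order otherwise
.resolve_altloc <- function(at) {
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(at)
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  keep <- rep(TRUE, nrow(at))
  for (k in unique(key[alt != ""])) {
    idx <- which(key == k)
    if (length(idx) > 1) {
      best <- idx[which.max(occ[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  at[keep, , drop = FALSE]
}

.CAP_RESIDUES <- c("ACE", "NME", "NMA")

.new_structure_model <- function(at, source_id) {
  ins <- at$insert
  ins[is.na(ins)] <- ""
  resname <- toupper(at$resid)
  rid_key <- paste(at$chain, at$resno, ins, resname, sep = "\r")
  # residue blocks in file order
  block <- match(rid_key, unique(rid_key))

  is_cap <- resname %in% .CAP_RESIDUES
  # fold caps into the adjacent protein residue: ACE -> following, NME -> preceding
  uniq <- unique(rid_key)
  cap_of_block <- resname[match(uniq, rid_key)] %in% .CAP_RESIDUES
  block_map <- seq_along(uniq)
  for (b in which(cap_of_block)) {
    nm <- resname[match(uniq[b], rid_key)]
    target <- if (nm == "ACE") b + 1L else b - 1L
    if (target >= 1L && target <= length(uniq) && !cap_of_block[target]) {
      block_map[b] <- target
    }
  }
  merged <- block_map[block]
  residue_index <- match(merged, sort(unique(merged))) - 1L

  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) {
    elem[bad] <- vapply(at$elety[bad], .element_from_name, character(1))
  }
  elem <- toupper(trimws(elem))

  # residue bookkeeping from the non-cap member of each merged block
  atoms <- tibble::tibble(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = elem,
    is_hydrogen = elem %in% c("H", "D"),
    residue_index = residue_index,
    residue_name = resname,
    chain_id = as.character(at$chain),
    author_seq_id = as.integer(at$resno),
    ins_code = ins,
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    is_cap_atom = is_cap
  )
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("non-finite coordinates in structure", call. = FALSE)
  }
  res <- atoms |>
    dplyr::filter(!.data$is_cap_atom) |>
    dplyr::distinct(.data$residue_index, .keep_all = TRUE) |>
    dplyr::select("residue_index", "residue_name", "chain_id",
                  "author_seq_id", "ins_code")
  # blocks that are caps with no neighbor to fold into would be missing here
  orphan <- setdiff(unique(atoms$residue_index), res$residue_index)
  if (length(orphan) > 0) {
    extra <- atoms |>
      dplyr::filter(.data$residue_index %in% orphan) |>
      dplyr::distinct(.data$residue_index, .keep_all = TRUE) |>
      dplyr::select("residue_index", "residue_name", "chain_id",
                    "author_seq_id", "ins_code")
    res <- dplyr::bind_rows(res, extra)
  }
  res <- dplyr::arrange(res, .data$residue_index)
  # propagate merged residue identity onto cap atoms
  atoms$residue_name <- res$residue_name[atoms$residue_index + 1L]
  res$in_cdr <- NA_integer_

  structure(
    list(atoms = atoms, residues = res, cdr_ranges = NULL,
         source_id = source_id),
    class = "structure_model"
  )
}

.element_from_name <- function(name) {
  nm <- gsub("[0-9'\"]", "", trimws(name))
  if (nchar(nm) == 0) return("X")
  first <- substr(nm, 1, 1)
  if (first %in% c("H", "C", "N", "O", "S", "P")) first else toupper(first)
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", x$source_id, "\n", sep = "")
  cat("  ", nrow(x$atoms), " atoms (",
      sum(!x$atoms$is_hydrogen), " heavy), ",
      nrow(x$residues), " residues\n", sep = "")
  if (!is.null(x$cdr_ranges)) {
    cat("  CDR spans: ",
        paste(sprintf("%d-%d", x$cdr_ranges$start, x$cdr_ranges$end),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Heavy atoms of a structure
#'
#' @param structure A `structure_model`.
#' @return Tibble of non-hydrogen atom rows.
#' @export
heavy_atoms <- function(structure) {
  stopifnot(inherits(structure, "structure_model"))
  dplyr::filter(structure$atoms, !.data$is_hydrogen)
}

#' Coordinate matrix of a structure
#'
#' @param structure A `structure_model`.
#' @return Numeric matrix, one row per atom (file order), columns x/y/z in
#'   Angstrom.
#' @export
structure_xyz <- function(structure) {
  stopifnot(inherits(structure, "structure_model"))
  unname(cbind(structure$atoms$x, structure$atoms$y, structure$atoms$z))
}

#' Write a structure back to PDB
#'
#' Coordinates are written at the PDB fixed precision (3 decimals, Angstrom).
#'
#' @param structure A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "structure_model"))
  a <- structure$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(cbind(a$x, a$y, a$z))),
    type = rep("ATOM", nrow(a)),
    eleno = a$serial,
    elety = a$name,
    resid = a$residue_name,
    chain = a$chain_id,
    resno = a$author_seq_id,
    insert = ifelse(a$ins_code == "", NA, a$ins_code),
    elesy = a$element
  )
  invisible(path)
}

#' Residue label in author numbering
#'
#' Formats residues the way stability reports print them, e.g. `"Trp47"`.
#'
#' @param structure A `structure_model`.
#' @param residue_index Internal 0-based residue indices.
#' @return Character vector of labels.
#' @export
residue_label <- function(structure, residue_index) {
  res <- structure$residues
  i <- match(residue_index, res$residue_index)
  if (anyNA(i)) stop("unknown residue index", call. = FALSE)
  nm <- res$residue_name[i]
  nm3 <- paste0(substr(nm, 1, 1), tolower(substr(nm, 2, 3)))
  paste0(nm3, res$author_seq_id[i], res$ins_code[i])
}

#' Annotate CDR loops on a structure
#'
#' Attaches the three complementarity-determining-region (CDR) spans, given in
#' author residue numbering, and flags every residue falling inside one.
#' Framework residues stay unflagged. Spans must exist in the structure and
#' must not overlap.
#'
#' @param structure A `structure_model`.
#' @param cdr1,cdr2,cdr3 Length-2 numeric vectors `c(start, end)` in author
#'   numbering, or `NULL` to leave a loop unset.
#' @param chain Chain the spans refer to (default: the structure's first
#'   chain).
#' @return The structure with `cdr_ranges` set and `residues$in_cdr` holding
#'   the CDR number (1, 2 or 3) or `NA` outside the loops.
#' @export
annotate_cdrs <- function(structure, cdr1 = NULL, cdr2 = NULL, cdr3 = NULL,
                          chain = NULL) {
  stopifnot(inherits(structure, "structure_model"))
  spans <- list(cdr1, cdr2, cdr3)
  present <- !vapply(spans, is.null, logical(1))
  res <- structure$residues
  res$in_cdr <- NA_integer_
  if (!any(present)) {
    structure$cdr_ranges <- tibble::tibble(cdr = integer(), start = integer(),
                                           end = integer())
    structure$residues <- res
    return(structure)
  }
  if (is.null(chain)) chain <- res$chain_id[1]
  rng <- tibble::tibble(
    cdr = which(present),
    start = vapply(spans[present], function(s) as.integer(s[1]), integer(1)),
    end = vapply(spans[present], function(s) as.integer(s[2]), integer(1))
  )
  if (any(rng$end < rng$start)) {
    stop("CDR span end precedes start", call. = FALSE)
  }
  rng_s <- rng[order(rng$start), ]
  if (nrow(rng_s) > 1 &&
      any(rng_s$start[-1] <= rng_s$end[-nrow(rng_s)])) {
    stop("CDR spans overlap", call. = FALSE)
  }
  on_chain <- res$chain_id == chain
  for (k in seq_len(nrow(rng))) {
    if (!any(on_chain & res$author_seq_id == rng$start[k]) ||
        !any(on_chain & res$author_seq_id == rng$end[k])) {
      stop("CDR", rng$cdr[k], " span ", rng$start[k], "-", rng$end[k],
           " not found in structure (chain ", chain, ")", call. = FALSE)
    }
    inside <- on_chain & res$author_seq_id >= rng$start[k] &
      res$author_seq_id <= rng$end[k]
    res$in_cdr[inside] <- rng$cdr[k]
  }
  structure$cdr_ranges <- rng
  structure$residues <- res
  structure
}

#' Is a residue inside a CDR loop?
#'
#' @param structure An annotated `structure_model` (see [annotate_cdrs()]).
#' @param residue_index 0-based internal residue indices.
#' @return Logical vector; `FALSE` everywhere when no annotation is attached.
#' @export
in_cdr <- function(structure, residue_index) {
  res <- structure$residues
  i <- match(residue_index, res$residue_index)
  if (anyNA(i)) stop("unknown residue index", call. = FALSE)
  !is.na(res$in_cdr[i])
}
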