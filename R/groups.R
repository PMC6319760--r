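#' Physicochemical residue grouping
#'
#' The three-group partition of the 20 standard amino acids used throughout
#' the Q-value decomposition: hydrophilic (Asp, Glu, Gln, Asn, Arg, Lys, His),
#' hydrophobic (Phe, Tyr, Trp, Leu, Val, Ile, Met, Cys, Pro) and small
#' (Gly, Ala, Ser, Thr). The groups are disjoint and exhaustive over the
#' standard residues.
#'
#' @param name Scheme name recorded in reports.
#' @return A `residue_group_scheme`: a named character vector mapping 3-letter
#'   residue codes to group labels, with a `name` attribute.
#' @examples
#' scheme <- residue_group_scheme()
#' classify_residue("ASP", scheme)
#' @export
residue_group_scheme <- function(name = "hydrophilic/hydrophobic/small") {
  mapping <- c(
    ASP = "hydrophilic", GLU = "hydrophilic", GLN = "hydrophilic",
    ASN = "hydrophilic", ARG = "hydrophilic", LYS = "hydrophilic",
    HIS = "hydrophilic",
    PHE = "hydrophobic", TYR = "hydrophobic", TRP = "hydrophobic",
    LEU = "hydrophobic", VAL = "hydrophobic", ILE = "hydrophobic",
    MET = "hydrophobic", CYS = "hydrophobic", PRO = "hydrophobic",
    GLY = "small", ALA = "small", SER = "small", THR = "small"
  )
  structure(mapping, name = name, class = "residue_group_scheme")
}

#' Group labels of a scheme
#' @param scheme A `residue_group_scheme`.
#' @return Character vector of distinct group labels, in first-appearance
#'   order.
#' @export
group_labels <- function(scheme = residue_group_scheme()) {
  unique(unname(scheme))
}

#' Classify residues into physicochemical groups
#'
#' @param residue_name Character vector of 3-letter residue codes (any case).
#' @param scheme A `residue_group_scheme`.
#' @return Character vector of group labels. A residue name absent from the
#'   scheme is an error, never a silent default.
#' @export
classify_residue <- function(residue_name, scheme = residue_group_scheme()) {
  key <- toupper(residue_name)
  out <- unname(scheme[key])
  if (anyNA(out)) {
    stop("residue name(s) not covered by group scheme: ",
         paste(unique(key[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}
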