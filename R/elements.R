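#' Element reference data
#'
#' Van der Waals radii (Angstrom) and atomic numbers for the elements that
#' occur in deposited ribosome models. Radii follow the widely used Bondi
#' set for the organic elements (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80).
#' Metals and halides common as bound ions are included so that full
#' deposited assemblies pass validation.
#'
#' @format A tibble with columns `element`, `vdw_radius` (Angstrom) and
#'   `atomic_number`.
#' @export
element_data <- function() {
  tibble::tribble(
    ~element, ~vdw_radius, ~atomic_number,
    "H",  1.20,  1,
    "C",  1.70,  6,
    "N",  1.55,  7,
    "O",  1.52,  8,
    "F",  1.47,  9,
    "NA", 2.27, 11,
    "MG", 1.73, 12,
    "P",  1.80, 15,
    "S",  1.80, 16,
    "CL", 1.75, 17,
    "K",  2.75, 19,
    "CA", 2.31, 20,
    "MN", 2.05, 25,
    "FE", 2.04, 26,
    "CO", 2.00, 27,
    "NI", 1.97, 28,
    "CU", 1.96, 29,
    "ZN", 2.01, 30,
    "SE", 1.90, 34,
    "BR", 1.85, 35,
    "MO", 2.10, 42,
    "I",  1.98, 53
  )
}

# fast lookups keyed by upper-case element symbol
.element_env <- new.env(parent = emptyenv())

.element_table <- function() {
  if (is.null(.element_env$tab)) .element_env$tab <- element_data()
  .element_env$tab
}

#' Look up van der Waals radii for element symbols
#'
#' @param element character vector of element symbols (case-insensitive).
#' @param radius_set optional named numeric vector overriding the default
#'   radius table, e.g. `c(C = 1.7, N = 1.55)`.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element, radius_set = NULL) {
  el <- toupper(element)
  tab <- .element_table()
  r <- tab$vdw_radius[match(el, tab$element)]
  if (!is.null(radius_set)) {
    idx <- match(el, toupper(names(radius_set)))
    r[!is.na(idx)] <- unname(radius_set[idx[!is.na(idx)]])
  }
  if (anyNA(r)) {
    stop("no van der Waals radius defined for element(s): ",
         paste(unique(el[is.na(r)]), collapse = ", "), call. = FALSE)
  }
  r
}

#' Look up atomic numbers for element symbols
#'
#' @inheritParams vdw_radius
#' @return integer vector of atomic numbers.
#' @export
atomic_number <- function(element) {
  el <- toupper(element)
  tab <- .element_table()
  z <- tab$atomic_number[match(el, tab$element)]
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(el[is.na(z)]), collapse = ", "), call. = FALSE)
  }
  as.integer(z)
}

# residue-name classification -------------------------------------------

.protein_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL"
)

.nucleic_residues <- c(
  "A", "U", "G", "C", "I",
  "DA", "DT", "DG", "DC", "DI"
)

#' Classify residue names into polymer classes
#'
#' @param resname character vector of residue names.
#' @return character vector: `"protein"`, `"nucleic"` or `"other"`.
#' @export
polymer_class <- function(resname) {
  rn <- toupper(resname)
  out <- rep("other", length(rn))
  out[rn %in% .protein_residues] <- "protein"
  out[rn %in% .nucleic_residues] <- "nucleic"
  out
}
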