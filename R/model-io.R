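#' Atomic model tables
#'
#' An atomic model is a tibble with one row per atom and columns
#' `serial`, `name`, `element`, `resname`, `chain`, `resnum`, `inscode`,
#' `alt`, `x`, `y`, `z`, `occupancy`, `bfactor`, `hetero`. Row order is the
#' record order of the source file. The attributes `identifier` and
#' `source_format` record provenance. All user-facing functions take this
#' tibble as their first argument, so analyses chain with the pipe.
#'
#' @name atomic_model
NULL

new_atomic_model <- function(atoms, identifier = "", source_format = "memory") {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(c("serial", "name", "element", "resname", "chain", "resnum",
                  "inscode", "alt", "x", "y", "z", "occupancy", "bfactor",
                  "hetero") %in% names(atoms)))
  if (nrow(atoms) > 0) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
      stop("non-finite atom coordinates", call. = FALSE)
    }
    occ <- atoms$occupancy
    if (any(!is.na(occ) & (occ < 0 | occ > 1))) {
      stop("occupancy outside [0, 1]", call. = FALSE)
    }
    vdw_radius(atoms$element) # errors on unrecognized elements
  }
  attr(atoms, "identifier") <- identifier
  attr(atoms, "source_format") <- source_format
  class(atoms) <- unique(c("atomic_model", class(atoms)))
  atoms
}

#' Read an atomic model from a PDB or mmCIF file
#'
#' Reads all ATOM/HETATM records of the first model, keeping hydrogens and
#' alternate locations as found. Elements missing from the file are inferred
#' from atom names.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return an atomic model tibble (see [atomic_model]).
#' @export
read_model <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") {
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
    } else {
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom
  element <- toupper(trimws(at$elesy))
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) {
    element[missing_el] <- toupper(bio3d::atom2ele(at$elety[missing_el]))
  }
  atoms <- tibble::tibble(
    serial    = as.integer(at$eleno),
    name      = trimws(at$elety),
    element   = element,
    resname   = trimws(at$resid),
    chain     = as.character(at$chain),
    resnum    = as.integer(at$resno),
    inscode   = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    alt       = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    x         = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    bfactor   = ifelse(is.na(at$b), 0, at$b),
    hetero    = at$type == "HETATM"
  )
  new_atomic_model(atoms, identifier = basename(path),
                   source_format = toupper(format))
}

#' Write an atomic model to a PDB or mmCIF file
#'
#' PDB coordinates are written with 3 decimals (format precision); mmCIF
#' with 4.
#'
#' @param model an atomic model tibble.
#' @param path output path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (nrow(model) == 0) stop("refusing to write an empty model", call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  if (format == "pdb") {
    bio3d::write.pdb(
      file = path,
      type = ifelse(model$hetero, "HETATM", "ATOM"),
      eleno = model$serial, elety = model$name,
      alt = ifelse(model$alt == "", "", model$alt),
      resid = model$resname, chain = model$chain,
      resno = model$resnum,
      insert = ifelse(model$inscode == "", "", model$inscode),
      xyz = as.vector(t(as.matrix(model[, c("x", "y", "z")]))),
      o = model$occupancy, b = model$bfactor,
      elesy = model$element
    )
  } else {
    write_cif_atoms(model, path)
  }
  invisible(path)
}

# minimal mmCIF atom_site writer (bio3d reads mmCIF but does not write it)
write_cif_atoms <- function(model, path) {
  hdr <- c(
    "data_model",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  q <- function(s) ifelse(s == "", ".", s)
  rows <- sprintf(
    "%s %d %s %s %s %s %s 1 %d %s %.4f %.4f %.4f %.2f %.2f %d %s %s %s 1",
    ifelse(model$hetero, "HETATM", "ATOM"),
    model$serial, model$element, model$name, q(model$alt), model$resname,
    model$chain, model$resnum, q(model$inscode),
    model$x, model$y, model$z, model$occupancy, model$bfactor,
    model$resnum, model$resname, model$chain, model$name
  )
  writeLines(c(hdr, rows, "#"), path)
}

#' Select atoms from a model
#'
#' Constraints combine as a conjunction; a `NULL` constraint matches
#' everything on that axis. Residue ranges are inclusive on both ends and
#' use author numbering, matching how structural papers cite helix spans.
#'
#' @param model an atomic model tibble.
#' @param chains character vector of chain identifiers.
#' @param residues residue constraint: an integer vector of residue numbers,
#'   a length-2 vector `c(start, end)`, or a list of such ranges (their
#'   union is taken).
#' @param atoms character vector of atom names (e.g. `"P"` for an rRNA
#'   backbone trace, `"CA"` for protein).
#' @param elements character vector of element symbols.
#' @param polymer `"any"`, `"protein"` or `"nucleic"`.
#' @return the matching sub-model, original order preserved.
#' @export
select_atoms <- function(model, chains = NULL, residues = NULL, atoms = NULL,
                         elements = NULL, polymer = c("any", "protein", "nucleic")) {
  polymer <- match.arg(polymer)
  keep <- rep(TRUE, nrow(model))
  if (!is.null(chains)) keep <- keep & model$chain %in% chains
  if (!is.null(residues)) {
    if (is.list(residues)) {
      in_range <- rep(FALSE, nrow(model))
      for (rg in residues) {
        stopifnot(length(rg) == 2)
        in_range <- in_range | (model$resnum >= rg[1] & model$resnum <= rg[2])
      }
    } else if (length(residues) == 2 && residues[2] >= residues[1]) {
      in_range <- model$resnum >= residues[1] & model$resnum <= residues[2]
    } else {
      in_range <- model$resnum %in% residues
    }
    keep <- keep & in_range
  }
  if (!is.null(atoms)) keep <- keep & model$name %in% atoms
  if (!is.null(elements)) keep <- keep & model$element %in% toupper(elements)
  if (polymer != "any") keep <- keep & polymer_class(model$resname) == polymer
  out <- model[keep, , drop = FALSE]
  attr(out, "identifier") <- attr(model, "identifier")
  attr(out, "source_format") <- attr(model, "source_format")
  class(out) <- class(model)
  out
}

#' Reduce a model to one conformer per atom for geometry
#'
#' Keeps, per (chain, residue, insertion code, atom name), the record with
#' the highest occupancy, preferring blank/'A' alternate-location codes on
#' ties, and drops hydrogens. Deposited cryo-EM models are heavy-atom only;
#' all geometry and surface-area computations use this view while file I/O
#' preserves every record.
#'
#' @param model an atomic model tibble.
#' @return an atomic model tibble with hydrogens removed and alternate
#'   locations collapsed.
#' @export
canonical_conformer <- function(model) {
  m <- model[model$element != "H" & model$element != "D", , drop = FALSE]
  if (nrow(m) == 0) return(m)
  ord <- order(m$chain, m$resnum, m$inscode, m$name,
               -m$occupancy, m$alt != "", m$alt)
  m2 <- m[ord, , drop = FALSE]
  key <- paste(m2$chain, m2$resnum, m2$inscode, m2$name, sep = "\r")
  m2 <- m2[!duplicated(key), , drop = FALSE]
  out <- m2[order(m2$serial), , drop = FALSE]
  attr(out, "identifier") <- attr(model, "identifier")
  class(out) <- class(model)
  out
}

coords_matrix <- function(model) {
  as.matrix(model[, c("x", "y", "z")])
}

set_coords <- function(model, xyz) {
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

#' Apply a rigid transform to a model's coordinates
#'
#' @param model an atomic model tibble.
#' @param rotation 3x3 rotation matrix (applied first).
#' @param translation length-3 numeric vector, Angstrom.
#' @param about optional length-3 center: rotate about this point rather
#'   than the lab origin.
#' @return the transformed model.
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0),
                            about = NULL) {
  xyz <- coords_matrix(model)
  if (!is.null(about)) {
    xyz <- sweep(xyz, 2, about)
    xyz <- xyz %*% t(rotation)
    xyz <- sweep(xyz, 2, about + translation, `+`)
  } else {
    xyz <- xyz %*% t(rotation)
    xyz <- sweep(xyz, 2, translation, `+`)
  }
  set_coords(model, xyz)
}
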