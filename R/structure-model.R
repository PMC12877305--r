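#' Atom-table columns of a structure model
#'
#' @keywords internal
#' @noRd
.atom_cols <- c("serial", "name", "element", "alt_loc", "residue_name",
                "chain_id", "residue_number", "insertion_code",
                "x", "y", "z", "occupancy", "b_factor", "record")

#' Construct a structure model
#'
#' A `structure_model` is the coordinate container used by all geometry,
#' superposition and surface routines: a flat atom table (one row per
#' ATOM/HETATM record, alternate locations retained) ordered as in the
#' source, plus an identifier and the source format. Residues within a
#' chain are ordered by residue number, with insertion-coded residues
#' following the same number without a code.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `alt_loc`, `residue_name`, `chain_id`, `residue_number`,
#'   `insertion_code`, `x`, `y`, `z` (Angstrom), `occupancy`, `b_factor`,
#'   `record` ("ATOM" or "HETATM").
#' @param identifier character scalar naming the model.
#' @param source_format one of "pdb", "mmcif", "synthetic".
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, identifier = "model",
                            source_format = c("synthetic", "pdb", "mmcif")) {
  source_format <- match.arg(source_format)
  stopifnot(is.data.frame(atoms))
  missing_cols <- setdiff(.atom_cols, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, .atom_cols]
  atoms$name <- trimws(as.character(atoms$name))
  if (any(!nzchar(atoms$name))) stop("atom names must be non-empty")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom table")
  occ <- atoms$occupancy
  if (any(is.na(occ) | occ < 0 | occ > 1))
    stop("occupancies must lie in [0, 1]")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$insertion_code,
               atoms$name, atoms$alt_loc, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate atomic site: ", key[anyDuplicated(key)])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, identifier = identifier,
                 source_format = source_format),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("<structure_model> ", x$identifier, " (", x$source_format, ")\n",
      sep = "")
  ch <- unique(a$chain_id)
  cat("  ", nrow(a), " atoms, ", length(ch), " chain(s): ",
      paste(ch, collapse = ", "), "\n", sep = "")
  for (c_id in ch) {
    ca <- a[a$chain_id == c_id, ]
    rn <- unique(paste(ca$residue_number, ca$insertion_code))
    cat("    chain ", c_id, ": ", length(rn), " residues, residue numbers ",
        min(ca$residue_number), "-", max(ca$residue_number), "\n", sep = "")
  }
  invisible(x)
}

#' Coordinate matrix of a model (or atom table)
#'
#' @param x a `structure_model` or an atom data.frame.
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(x) {
  a <- if (inherits(x, "structure_model")) x$atoms else x
  m <- as.matrix(a[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Apply a rigid transform to every atom of a model
#'
#' Coordinates are mapped as `x -> R x + t`.
#'
#' @param model a `structure_model`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @return The transformed `structure_model`.
#' @export
transform_model <- function(model, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- coords(model) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  model$atoms[, c("x", "y", "z")] <- xyz
  model
}

# residue-level split key, insertion codes ordered after the bare number
.site_key <- function(atoms)
  paste(atoms$chain_id, atoms$residue_number, atoms$insertion_code,
        atoms$name, sep = "|")

.residue_key <- function(atoms)
  paste(atoms$chain_id, atoms$residue_number, atoms$insertion_code, sep = "|")
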