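#' Read a macromolecular structure
#'
#' Reads PDB (fixed-width ATOM/HETATM records) or mmCIF (atom_site loop)
#' coordinate files into a [structure_model()]. Both ATOM and HETATM
#' records enter one hierarchy (noncanonical residues and carbohydrate
#' ligands are frequently deposited as HETATM groups); alternate-location
#' duplicates are retained and resolved only at selection time.
#' Coordinates are kept exactly as printed (Angstrom).
#'
#' @param path path to the coordinate file.
#' @param format "auto" (default; by file extension), "pdb" or "mmcif".
#' @param identifier model identifier; defaults to the file base name.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           identifier = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, pdb = , ent = "pdb", cif = , mmcif = "mmcif",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format = \"pdb\" or \"mmcif\""))
  }
  if (format == "pdb") .validate_pdb_records(path)
  parsed <- if (format == "pdb")
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE))
  else
    suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
  a <- parsed$atom
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    element = trimws(ifelse(is.na(a$elesy) | !nzchar(trimws(a$elesy)),
                            .element_from_name(a$elety), a$elesy)),
    alt_loc = ifelse(is.na(a$alt), "", a$alt),
    residue_name = trimws(a$resid),
    chain_id = ifelse(is.na(a$chain), "", a$chain),
    residue_number = as.integer(a$resno),
    insertion_code = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b_factor = ifelse(is.na(a$b), 0, a$b),
    record = a$type,
    stringsAsFactors = FALSE)
  structure_model(atoms,
                  identifier = identifier %||%
                    tools::file_path_sans_ext(basename(path)),
                  source_format = if (format == "pdb") "pdb" else "mmcif")
}

# fixed-width sanity scan so malformed records fail with a line number
.validate_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) return(invisible(TRUE))
  idx <- which(rec)
  for (field in list(c(31, 38), c(39, 46), c(47, 54))) {
    vals <- suppressWarnings(
      as.numeric(substr(lines[idx], field[1], field[2])))
    bad <- which(is.na(vals))
    if (length(bad))
      stop("malformed coordinate field in PDB record at line ", idx[bad[1]],
           ": '", lines[idx[bad[1]]], "'")
  }
  invisible(TRUE)
}

.element_from_name <- function(name) {
  n <- gsub("[0-9']", "", trimws(name))
  two <- toupper(substr(n, 1, 2))
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "SE"),
         two, substr(n, 1, 1))
}

#' Write a model as a PDB file
#'
#' Output is re-readable by [read_structure()] with coordinates
#' round-tripping at the 3-decimal precision of the PDB fixed-width
#' fields. All alternate-location records present in the model are
#' emitted. An empty model yields a file containing only END.
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  if (nrow(a) == 0) {
    writeLines("END", path)
    return(invisible(path))
  }
  if (any(nchar(a$name) > 4))
    stop("atom names longer than 4 characters cannot be written to PDB")
  xyz <- coords(a)
  if (any(abs(xyz) >= 10000))
    stop("coordinate overflow: |value| must be < 10000 Angstrom ",
         "for the fixed-width PDB field")
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(xyz)),
                   type = a$record,
                   eleno = a$serial,
                   elety = a$name,
                   alt = ifelse(nzchar(a$alt_loc), a$alt_loc, NA),
                   resid = a$residue_name,
                   chain = a$chain_id,
                   resno = a$residue_number,
                   insert = ifelse(nzchar(a$insertion_code),
                                   a$insertion_code, NA),
                   o = a$occupancy,
                   b = a$b_factor,
                   elesy = a$element,
                   verbose = FALSE)
  invisible(path)
}
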