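#' End-to-end geometric analysis of a switch/host complex
#'
#' Runs the full descriptor + surface + hydrogen-bond pipeline on one
#' structure: the azobenzene torsion/interplanar descriptor set of the
#' guest residue, the three-context side-chain accessible-surface
#' report, and the protein-host hydrogen-bond table.
#'
#' @param model a `structure_model`, or a path to a coordinate file.
#' @param guest selector (object or string) for the switch-bearing
#'   residue.
#' @param host selector for the host ligand atoms; NULL skips the
#'   surface and hydrogen-bond stages.
#' @param ring1,ring2 [ring_spec()]s of the two phenyl rings (defaults:
#'   the synthetic generator's nomenclature).
#' @param azo_atoms azo nitrogen names, ring1-side first.
#' @param protein selector for the protein side of the hydrogen-bond
#'   search (default: everything that is not the host).
#' @param params a [sasa_params()] object.
#' @param hbond_max_distance,hbond_min_angle hydrogen-bond criteria
#'   passed to [hydrogen_bonds()].
#' @return Object of class `azo_report`: `descriptor` (an
#'   `azo_geometry`), `surface` (a `surface_report` or NULL), `hbonds`
#'   (an `hbond_table` or NULL).
#' @export
analyze_complex <- function(model, guest, host = NULL,
                            ring1 = azo_ring1(), ring2 = azo_ring2(),
                            azo_atoms = azo_nitrogens(),
                            protein = NULL,
                            params = sasa_params(),
                            hbond_max_distance = 3.5,
                            hbond_min_angle = 90) {
  if (is.character(model)) model <- read_structure(model)
  desc <- azo_descriptor(model, guest, ring1, azo_atoms, ring2)
  surface <- hbonds <- NULL
  if (!is.null(host)) {
    surface <- sidechain_asa_contexts(model, guest, host, params)
    if (is.null(protein)) {
      hsel <- if (is.character(host)) parse_selector(host) else host
      hkey <- .site_key(select_atoms(model, hsel))
      prot_tab <- model$atoms[!.site_key(model$atoms) %in% hkey &
                                !model$atoms$residue_name %in%
                                  .water_names, , drop = FALSE]
      hbonds <- hydrogen_bonds(model,
                               set_a = selector(),
                               set_b = hsel,
                               max_distance = hbond_max_distance,
                               min_antecedent_angle = hbond_min_angle,
                               category = "protein-host")
      keep <- paste(hbonds$donor_chain, hbonds$donor_resno,
                    hbonds$donor_atom) %in%
        paste(prot_tab$chain_id, prot_tab$residue_number, prot_tab$name)
      hbonds <- hbonds[keep, , drop = FALSE]
      class(hbonds) <- c("hbond_table", "data.frame")
    } else {
      hbonds <- hydrogen_bonds(model, protein, host,
                               max_distance = hbond_max_distance,
                               min_antecedent_angle = hbond_min_angle,
                               category = "protein-host")
    }
  }
  structure(list(descriptor = desc, surface = surface, hbonds = hbonds,
                 identifier = model$identifier),
            class = "azo_report")
}

#' @export
print.azo_report <- function(x, ...) {
  cat("== azo_report:", x$identifier, "==\n")
  print(x$descriptor)
  if (!is.null(x$surface)) print(x$surface)
  if (!is.null(x$hbonds)) print(x$hbonds)
  invisible(x)
}

#' Flatten an analysis report to a one-row table
#'
#' @param x an `azo_report`.
#' @param ... unused.
#' @return One-row data.frame with the descriptor angles, the three ASA
#'   contexts, the burial fraction and the hydrogen-bond count.
#' @export
as.data.frame.azo_report <- function(x, ...) {
  row <- as.data.frame(x$descriptor)
  row$asa_isolated <- if (is.null(x$surface)) NA else x$surface$asa_isolated
  row$asa_in_protein <- if (is.null(x$surface)) NA else
    x$surface$asa_in_protein
  row$asa_in_complex <- if (is.null(x$surface)) NA else
    x$surface$asa_in_complex
  row$burial_fraction <- if (is.null(x$surface)) NA else
    x$surface$burial_fraction
  row$n_hbonds <- if (is.null(x$hbonds)) NA_integer_ else nrow(x$hbonds)
  row
}

#' Write an analysis report as TSV or JSON
#'
#' JSON output is schema-stable: fields `identifier`, `descriptor`,
#' `surface`, `hbonds`.
#'
#' @param x an `azo_report`.
#' @param path output file.
#' @param format "tsv" (the flattened row plus an hbond table block) or
#'   "json".
#' @return Invisibly, `path`.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      identifier = x$identifier,
      descriptor = as.data.frame(x$descriptor),
      surface = if (is.null(x$surface)) NULL else
        x$surface[c("asa_isolated", "asa_in_protein", "asa_in_complex",
                    "burial_fraction")],
      hbonds = if (is.null(x$hbonds)) NULL else
        as.data.frame(unclass(x$hbonds), stringsAsFactors = FALSE))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    utils::write.table(as.data.frame(x), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (!is.null(x$hbonds) && nrow(x$hbonds)) {
      cat("\n", file = path, append = TRUE)
      suppressWarnings(utils::write.table(
        as.data.frame(unclass(x$hbonds)), path, sep = "\t",
        row.names = FALSE, quote = FALSE, append = TRUE))
    }
  }
  invisible(path)
}
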