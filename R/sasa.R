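#' SASA parameters
#'
#' Parameters of the Shrake-Rupley-style accessible-surface computation:
#' a probe sphere of `probe_radius` rolls over the van der Waals spheres
#' of the heavy atoms; each atom's accessible area is the exposed
#' fraction of a deterministic golden-section (Fibonacci) point lattice
#' on its solvent-extended sphere times `4 pi (r + probe)^2`.
#'
#' Default radii (Angstrom) are common NACCESS-like values: C 1.70,
#' N 1.55, O 1.52, S 1.80, H 1.09, P 1.80. Elements absent from the
#' table fall back to `fallback_radius` with a warning.
#'
#' @param probe_radius probe sphere radius, Angstrom (default 1.4, a
#'   water-sized probe).
#' @param n_sphere_points number of lattice points per atom (default
#'   960; must be >= 96). More points reduce quadrature error.
#' @param radii named numeric vector mapping element symbols to van der
#'   Waals radii, Angstrom.
#' @param fallback_radius radius used for unlisted elements.
#' @return Object of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960,
                        radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                                  H = 1.09, P = 1.80),
                        fallback_radius = 1.70) {
  stopifnot(probe_radius > 0, n_sphere_points >= 96)
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 radii = radii, fallback_radius = fallback_radius),
            class = "sasa_params")
}

# deterministic golden-section lattice on the unit sphere
.fibonacci_sphere <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

.atom_radii <- function(elements, params) {
  r <- unname(params$radii[elements])
  miss <- is.na(r)
  if (any(miss)) {
    warning("no van der Waals radius for element(s) ",
            paste(unique(elements[miss]), collapse = ", "),
            "; using fallback ", params$fallback_radius, " A")
    r[miss] <- params$fallback_radius
  }
  r
}

.water_names <- c("HOH", "WAT", "DOD", "H2O")

#' Solvent-accessible surface area per atom
#'
#' Deterministic Shrake-Rupley accessible surface: for every heavy atom,
#' the fraction of golden-section lattice points on its solvent-extended
#' sphere (radius `r_atom + probe`) not buried inside any neighbour's
#' extended sphere, times the sphere area. No randomness is involved, so
#' repeated runs are identical.
#'
#' @param model a `structure_model`, or an atom data.frame.
#' @param params a [sasa_params()] object.
#' @param heavy_only drop hydrogens before the computation (default
#'   TRUE; crystal structures at typical resolution carry no hydrogens,
#'   and accessible areas are conventionally heavy-atom areas).
#' @param exclude_water drop water molecules (default TRUE).
#' @return Numeric vector of per-atom areas (Angstrom^2), one entry per
#'   retained atom, with the retained atom table attached as attribute
#'   `"atoms"`.
#' @export
sasa <- function(model, params = sasa_params(), heavy_only = TRUE,
                 exclude_water = TRUE) {
  a <- if (inherits(model, "structure_model")) model$atoms else model
  if (heavy_only) a <- a[a$element != "H" & a$element != "D", , drop = FALSE]
  if (exclude_water) a <- a[!a$residue_name %in% .water_names, , drop = FALSE]
  n <- nrow(a)
  if (n == 0) return(structure(numeric(0), atoms = a))
  xyz <- coords(a)
  rad <- .atom_radii(a$element, params) + params$probe_radius
  pts <- .fibonacci_sphere(params$n_sphere_points)
  areas <- numeric(n)
  # cell-free neighbour search: pairwise distances once (models here are
  # a few thousand atoms at most)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rad + rad[i])^2 & d2 > 0)
    sphere <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      exposed <- rep(TRUE, nrow(sphere))
      for (j in nb) {
        if (!any(exposed)) break
        dj <- sweep(sphere[exposed, , drop = FALSE], 2, xyz[j, ])
        exposed[exposed] <- rowSums(dj^2) >= rad[j]^2
      }
      frac <- mean(exposed)
    } else frac <- 1
    areas[i] <- frac * 4 * pi * rad[i]^2
  }
  structure(areas, atoms = a)
}

#' Three-context accessible-surface report for a guest side chain
#'
#' Computes the accessible surface area summed over a guest residue's
#' side-chain atoms (every residue atom except the backbone N, CA, C, O)
#' in three contexts, all at the identical conformation: (i) the guest
#' residue extracted in place, isolated; (ii) the full model with the
#' host ligand removed; (iii) the full model. The burial fraction is
#' `1 - asa_in_complex / asa_isolated`.
#'
#' @param model a `structure_model` containing guest and host.
#' @param guest selector resolving to exactly one residue (the
#'   switch-bearing residue).
#' @param host selector matching the host ligand atoms (e.g. the
#'   cyclodextrin residues).
#' @param params a [sasa_params()] object.
#' @param isolated_whole_residue include the backbone atoms of the guest
#'   in the isolated-context model (default TRUE: the isolated reference
#'   is the whole free amino acid; the areas summed are always
#'   side-chain areas).
#' @return Object of class `surface_report`: `asa_isolated`,
#'   `asa_in_protein`, `asa_in_complex` (Angstrom^2), `burial_fraction`.
#' @export
sidechain_asa_contexts <- function(model, guest, host,
                                   params = sasa_params(),
                                   isolated_whole_residue = TRUE) {
  ga <- select_atoms(model, guest)
  if (nrow(ga) == 0) stop("guest selector matched no atoms")
  if (length(unique(.residue_key(ga))) != 1)
    stop("guest selector must resolve to exactly one residue")
  backbone <- c("N", "CA", "C", "O", "OXT")
  sc_names <- setdiff(ga$name, backbone)
  ha <- select_atoms(model, host)
  all_atoms <- model$atoms
  guest_id <- rownames(ga) # not stable; match by site key instead
  gkey <- .site_key(ga)
  hkey <- .site_key(ha)
  akey <- .site_key(all_atoms)
  sum_sc <- function(atom_tab) {
    ar <- sasa(structure(list(atoms = atom_tab, identifier = "ctx",
                              source_format = "synthetic"),
                         class = "structure_model"), params)
    kept <- attr(ar, "atoms")
    sum(ar[.site_key(kept) %in% gkey & kept$name %in% sc_names])
  }
  iso_tab <- all_atoms[akey %in% gkey, , drop = FALSE]
  if (!isolated_whole_residue)
    iso_tab <- iso_tab[iso_tab$name %in% sc_names, , drop = FALSE]
  asa_isolated <- sum_sc(iso_tab)
  asa_in_protein <- sum_sc(all_atoms[!akey %in% hkey, , drop = FALSE])
  asa_in_complex <- sum_sc(all_atoms)
  structure(list(asa_isolated = asa_isolated,
                 asa_in_protein = asa_in_protein,
                 asa_in_complex = asa_in_complex,
                 burial_fraction = 1 - asa_in_complex / asa_isolated),
            class = "surface_report")
}

#' @export
print.surface_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<surface_report> side-chain ASA: isolated %.1f, in protein %.1f, ",
    "in complex %.1f A^2 (burial %.1f%%)\n"),
    x$asa_isolated, x$asa_in_protein, x$asa_in_complex,
    100 * x$burial_fraction))
  invisible(x)
}
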