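## Synthetic-structure generator: azobenzene residues with exactly
## planted torsions, a toroidal pseudo-sugar host, and a helical
## scaffold. Idealized bond geometry (C-C aromatic 1.39, C-N 1.42,
## N=N 1.25 Angstrom, 120-degree ring angles) is fixed; the generator is
## the exact inverse of the descriptor measurement.

.unit <- function(v) v / sqrt(sum(v^2))

# Rodrigues rotation of (row) vectors about a unit axis through origin
.rotate_about <- function(xyz, axis, deg) {
  axis <- .unit(axis)
  th <- deg * pi / 180
  one <- if (is.matrix(xyz)) xyz else matrix(xyz, ncol = 3)
  k <- matrix(axis, nrow(one), 3, byrow = TRUE)
  rot <- one * cos(th) +
    t(apply(one, 1, function(v) .cross3(axis, v))) * sin(th) +
    k * rowSums(one * k) * (1 - cos(th))
  if (is.matrix(xyz)) rot else rot[1, ]
}

# NeRF internal-coordinate placement: position d bonded to c with
# |d-c| = bond, angle(b,c,d) = angle_deg, dihedral(a,b,c,d) = torsion_deg
.place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- -torsion_deg * pi / 180  # sign matches dihedral_angle()
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + cbind(bc, m, n) %*% d2
}

.mk_atoms <- function(names, xyz, residue_name, chain_id, residue_number,
                      serial_start = 1L, record = "ATOM") {
  data.frame(
    serial = seq_along(names) + serial_start - 1L,
    name = names,
    element = substr(gsub("[0-9']", "", names), 1, 1),
    alt_loc = "",
    residue_name = residue_name,
    chain_id = chain_id,
    residue_number = as.integer(residue_number),
    insertion_code = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, b_factor = 0, record = record,
    stringsAsFactors = FALSE)
}

#' Ring specs and azo-nitrogen names of the synthetic azobenzene residue
#'
#' The generator names the first (backbone-proximal) phenyl ring
#' C1...C6 with C1 the azo-attached ipso carbon, the azo nitrogens
#' N1 (bonded to C1) and N2, and the second ring C7...C12 with C7 the
#' ipso carbon bonded to N2.
#'
#' @return `azo_ring1()`/`azo_ring2()`: a [ring_spec()];
#'   `azo_nitrogens()`: character 2-vector.
#' @export
azo_ring1 <- function() ring_spec(paste0("C", 1:6))

#' @rdname azo_ring1
#' @export
azo_ring2 <- function() ring_spec(paste0("C", 7:12))

#' @rdname azo_ring1
#' @export
azo_nitrogens <- function() c("N1", "N2")

#' Build an azobenzene amino-acid residue with planted torsions
#'
#' Constructs an idealized p-(phenylazo)-phenylalanine-like residue:
#' two exactly planar phenyl rings (regular hexagons, side 1.39
#' Angstrom), the azo bridge (C-N 1.42, N=N 1.25 Angstrom, 113-degree
#' C-N=N angles) and backbone stubs N, CA, C, O, CB attached at the
#' para carbon of the first ring. The three azo torsions are realized
#' exactly as given, so [azo_descriptor()] on the built residue
#' recovers them to machine precision whenever `|chi_pre|` and
#' `|chi_post|` are at most 90 degrees (values beyond 90 are measured
#' relative to the other ortho carbon and come back shifted by 180).
#'
#' @param chi_pre,chi_azo,chi_post planted torsions, degrees in
#'   (-180, 180].
#' @param chi1,chi2 side-chain attachment torsions (N-CA-CB-Cipso and
#'   CA-CB-Cpara-Cortho), degrees; default 180.
#' @param residue_name,chain_id,residue_number placement of the residue
#'   in the model.
#' @return A `structure_model` with one 19-atom residue.
#' @export
build_azobenzene_residue <- function(chi_pre = 0, chi_azo = 180,
                                     chi_post = 0, chi1 = 180, chi2 = 180,
                                     residue_name = "PAP", chain_id = "A",
                                     residue_number = 1L) {
  cc <- 1.39; cn <- 1.42; nn <- 1.25
  # ring1: regular hexagon in the xy-plane, centered at the origin,
  # C1 (ipso) on +x; exocyclic bonds radial
  th <- (0:5) * 60 * pi / 180
  ring1 <- cbind(cc * cos(th), cc * sin(th), 0)
  c1 <- ring1[1, ]; c2 <- ring1[2, ]; c3 <- ring1[3, ]; c4 <- ring1[4, ]
  n1 <- c1 + c(cn, 0, 0)
  n2 <- as.vector(.place_atom(c2, c1, n1, nn, 113, chi_pre))
  c7 <- as.vector(.place_atom(c1, n1, n2, cn, 113, chi_azo))
  c8 <- as.vector(.place_atom(n1, n2, c7, cc, 120, chi_post))
  # remaining ring2 vertices: regular hexagon through C7 and C8 whose
  # plane contains the exocyclic N2-C7 bond
  center2 <- c7 + cc * .unit(c7 - n2)
  v0 <- c7 - center2
  n2ax <- .unit(.cross3(v0, c8 - center2))
  cand <- center2 + .rotate_about(v0, n2ax, 60)
  step <- if (sum((cand - c8)^2) < 1e-12) 60 else -60
  ring2 <- t(vapply(0:5, function(k)
    center2 + .rotate_about(v0, n2ax, step * k), numeric(3)))
  # backbone stubs off the para carbon C4
  cb <- c4 + 1.51 * .unit(c4)
  ca <- as.vector(.place_atom(c3, c4, cb, 1.53, 114, chi2))
  nb <- as.vector(.place_atom(c4, cb, ca, 1.47, 110, chi1))
  cco <- as.vector(.place_atom(c4, cb, ca, 1.53, 110,
                               ((chi1 + 120 + 180) %% 360) - 180))
  ob <- as.vector(.place_atom(nb, ca, cco, 1.23, 121, 0))
  names_all <- c("N", "CA", "C", "O", "CB",
                 paste0("C", 1:6), "N1", "N2", paste0("C", 7:12))
  xyz <- rbind(nb, ca, cco, ob, cb, ring1, n1, n2, ring2)
  atoms <- .mk_atoms(names_all, xyz, residue_name, chain_id,
                     residue_number, record = "HETATM")
  structure_model(atoms, identifier = "azobenzene_residue",
                  source_format = "synthetic")
}

#' Build a synthetic host-guest toy complex
#'
#' Assembles the guest-through-torus topology of a cyclodextrin
#' inclusion complex from purely geometric parts: a poly-Ala helical
#' scaffold, an azobenzene residue whose long axis is aligned with +x
#' and centered at the origin, `host_units` pseudo-sugar units arranged
#' with n-fold symmetry about that axis at `host_radius`, and one
#' planted hydrogen-bond site per host unit (a serine-like side-chain
#' oxygen placed exactly 2.7 Angstrom from the unit's narrow-rim
#' hydroxyl oxygen). The pseudo-sugars are geometric occluders (a 3x3
#' carbon grid plus three hydroxyl-like oxygens each), not chemical
#' models.
#'
#' The planted hydrogen-bond pairs and the guest residue number are
#' attached as attribute `"manifest"`.
#'
#' @param host_units number of host units (>= 3, default 6, the
#'   six-glucose torus of an alpha-cyclodextrin).
#' @param host_radius axis-to-unit-center distance, Angstrom (default
#'   5.5; at 15 or more the torus no longer occludes the guest).
#' @param scaffold_length number of scaffold residues (default 20).
#' @param noise_sigma per-coordinate Gaussian displacement, Angstrom
#'   (default 0).
#' @param seed RNG seed used when `noise_sigma > 0`.
#' @param chi planted `(chi_pre, chi_azo, chi_post)` of the guest;
#'   defaults to the twisted trans conformation observed for a
#'   protein-displayed azobenzene side chain.
#' @return A `structure_model` (chains A = scaffold + guest + planted
#'   serines, H = host) with attribute `"manifest"`.
#' @export
build_toy_complex <- function(host_units = 6, host_radius = 5.5,
                              scaffold_length = 20, noise_sigma = 0,
                              seed = 1L,
                              chi = c(62.9, -179.1, -28.2)) {
  stopifnot(host_units >= 3, noise_sigma >= 0)
  guest <- build_azobenzene_residue(chi[1], chi[2], chi[3],
                                    residue_number = scaffold_length + 1L)
  # align the azo long axis (ring1 centroid -> ring2 centroid) with +x,
  # azo midpoint at the origin
  ga <- guest$atoms
  r1c <- colMeans(coords(ga[ga$name %in% paste0("C", 1:6), ]))
  r2c <- colMeans(coords(ga[ga$name %in% paste0("C", 7:12), ]))
  mid <- colMeans(coords(ga[ga$name %in% c("N1", "N2"), ]))
  ax <- .unit(r2c - r1c)
  rot_axis <- .cross3(ax, c(1, 0, 0))
  ang <- acos(max(-1, min(1, ax[1]))) * 180 / pi
  xyz <- sweep(coords(ga), 2, mid)
  if (sqrt(sum(rot_axis^2)) > 1e-12)
    xyz <- .rotate_about(xyz, rot_axis, ang)
  ga[, c("x", "y", "z")] <- xyz
  guest_tab <- ga

  # helical scaffold along -x, clear of guest and host
  x0 <- min(guest_tab$x) - 3
  idx <- seq_len(scaffold_length)
  helix <- function(t, radius = 2.3)
    cbind(x0 - 1.5 * t, radius * cos(t * 100 * pi / 180),
          radius * sin(t * 100 * pi / 180))
  sc <- do.call(rbind, lapply(idx, function(i) {
    pos <- rbind(helix(i - 0.33), helix(i), helix(i + 0.33),
                 helix(i + 0.33, radius = 3.3), helix(i, radius = 3.6))
    .mk_atoms(c("N", "CA", "C", "O", "CB"), pos, "ALA", "A", i)
  }))

  # host torus: n-fold symmetric pseudo-sugar units about the x axis
  host <- list(); planted <- list()
  for (k in seq_len(host_units)) {
    theta <- 360 * (k - 1) / host_units
    rhat <- c(0, cos(theta * pi / 180), sin(theta * pi / 180))
    that <- c(0, -sin(theta * pi / 180), cos(theta * pi / 180))
    ck <- host_radius * rhat
    grid <- expand.grid(dx = c(-1.2, 0, 1.2), dt = c(-1.6, 0, 1.6))
    cpos <- t(apply(grid, 1, function(g)
      ck + g[["dx"]] * c(1, 0, 0) + g[["dt"]] * that))
    o2 <- ck + 1.2 * c(1, 0, 0) + 1.2 * rhat + 0.8 * that
    o3 <- ck + 1.2 * c(1, 0, 0) + 1.2 * rhat - 0.8 * that
    o6 <- ck - (1.2 + 1.43) * c(1, 0, 0)
    host[[k]] <- .mk_atoms(c(paste0("C", 1:9), "O2", "O3", "O6"),
                           rbind(cpos, o2, o3, o6), "SUG", "H", k,
                           record = "HETATM")
    og <- o6 - c(2.7, 0, 0)
    cbog <- og - c(1.43, 0, 0)
    planted[[k]] <- .mk_atoms(c("CB", "OG"), rbind(cbog, og), "SER", "A",
                              scaffold_length + 1L + k)
  }
  atoms <- rbind(sc, guest_tab, do.call(rbind, planted),
                 do.call(rbind, host))
  atoms$serial <- seq_len(nrow(atoms))
  model <- structure_model(atoms, identifier = "toy_complex",
                           source_format = "synthetic")
  if (noise_sigma > 0) model <- perturb_model(model, noise_sigma, seed)
  manifest <- list(
    guest_residue = scaffold_length + 1L,
    guest_chain = "A",
    host_chain = "H",
    planted_hbonds = data.frame(
      donor_resno = scaffold_length + 1L + seq_len(host_units),
      donor_atom = "OG",
      acceptor_resno = seq_len(host_units),
      acceptor_atom = "O6",
      distance = 2.7),
    chi = chi)
  attr(model, "manifest") <- manifest
  model
}

#' Add seeded Gaussian coordinate noise to a model
#'
#' i.i.d. normal displacement of every coordinate; the global RNG state
#' is left untouched, so the same seed always yields the same output.
#'
#' @param model a `structure_model`.
#' @param sigma standard deviation, Angstrom (>= 0; 0 is the identity).
#' @param seed integer RNG seed.
#' @return The perturbed `structure_model`.
#' @export
perturb_model <- function(model, sigma, seed = 1L) {
  stopifnot(inherits(model, "structure_model"))
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(model)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  n <- nrow(model$atoms)
  model$atoms[, c("x", "y", "z")] <-
    coords(model) + matrix(stats::rnorm(3 * n, sd = sigma), n, 3)
  model
}
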