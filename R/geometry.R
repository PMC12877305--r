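#' Least-squares plane through a set of points
#'
#' Fits the plane minimising the mean squared point-plane distance (via
#' SVD of the centered coordinates; the normal is the singular direction
#' of minimal variance). The normal's sign follows the right-hand rule
#' over the ordered traversal of the points: `normal . sum_k (p_k - c) x
#' (p_{k+1} - c) > 0`, so a counter-clockwise hexagon in the xy-plane has
#' normal +z.
#'
#' @param xyz numeric matrix (>= 3 rows) of positions, Angstrom.
#' @return Object of class `plane`: `normal` (unit 3-vector), `centroid`,
#'   `rms_deviation` (Angstrom, root-mean-square out-of-plane distance).
#' @export
fit_plane <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3) stop("plane fit requires at least 3 points")
  ctr <- colMeans(xyz)
  cen <- sweep(xyz, 2, ctr)
  sv <- svd(cen)
  # collinear (or coincident) points: the two smallest singular values
  # both vanish relative to the largest
  if (sv$d[2] <= max(sv$d[1], 1) * 1e-9)
    stop("degenerate geometry: points are collinear")
  normal <- sv$v[, 3]
  n <- nrow(cen)
  s <- c(0, 0, 0)
  for (k in seq_len(n)) {
    s <- s + .cross3(cen[k, ], cen[if (k == n) 1 else k + 1, ])
  }
  if (sum(normal * s) < 0) normal <- -normal
  structure(list(normal = normal / sqrt(sum(normal^2)), centroid = ctr,
                 rms_deviation = sqrt(mean((cen %*% normal)^2))),
            class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("<plane> normal = (%.4f, %.4f, %.4f), rms dev = %.4f A\n",
              x$normal[1], x$normal[2], x$normal[3], x$rms_deviation))
  invisible(x)
}

.cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Signed torsion angle of four points
#'
#' Standard right-hand torsion convention: looking down the p2->p3 bond,
#' the angle from the p1 side to the p4 side, in degrees in (-180, 180].
#' A trans-planar arrangement gives 180, an eclipsed cis one gives 0, and
#' reversing the atom order (p4, p3, p2, p1) leaves the value unchanged.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return Torsion angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b2^2)) < 1e-12) stop("degenerate geometry: p2 == p3")
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("degenerate geometry: collinear atom triple in torsion")
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Angle between two planes
#'
#' `alpha_raw` is the angle between the two normals (arccos of their dot
#' product, clamped to \[-1, 1\]), in \[0, 180\] degrees; it depends on the
#' orientation each normal happened to receive. `alpha_folded = min(raw,
#' 180 - raw)` in \[0, 90\] is orientation-free and is the angle reported
#' for interplanar comparisons between aromatic rings.
#'
#' @param a,b objects of class `plane` (or unit 3-vectors).
#' @return list with `alpha_raw` and `alpha_folded`, degrees.
#' @export
interplanar_angle <- function(a, b) {
  na <- if (inherits(a, "plane")) a$normal else a / sqrt(sum(a^2))
  nb <- if (inherits(b, "plane")) b$normal else b / sqrt(sum(b^2))
  d <- max(-1, min(1, sum(na * nb)))
  raw <- acos(d) * 180 / pi
  list(alpha_raw = raw, alpha_folded = min(raw, 180 - raw))
}

#' Ring specification
#'
#' Six atom names in bonded order around a phenyl ring, beginning at the
#' ipso carbon (the ring atom bonded to the azo nitrogen).
#'
#' @param atom_names character vector of exactly 6 unique atom names.
#' @return Object of class `ring_spec`.
#' @export
ring_spec <- function(atom_names) {
  atom_names <- as.character(atom_names)
  if (length(atom_names) != 6 || anyDuplicated(atom_names))
    stop("a ring spec is exactly 6 unique atom names in bonded order")
  structure(list(atom_names = atom_names), class = "ring_spec")
}

.resolve_named_atoms <- function(res_atoms, names_wanted) {
  idx <- match(names_wanted, res_atoms$name)
  if (anyNA(idx))
    stop("named atom(s) not found in residue: ",
         paste(names_wanted[is.na(idx)], collapse = ", "))
  coords(res_atoms[idx, , drop = FALSE])
}

#' Azobenzene conformational descriptors
#'
#' Computes the descriptor tuple of an azobenzene moiety: the three
#' torsions about the ring1-N, N=N and N-ring2 bonds and the interplanar
#' angle between the two phenyl ring planes (fitted to the six ring
#' carbons of each ring only).
#'
#' * `chi_azo  = dihedral(ipso1, N1, N2, ipso2)`
#' * `chi_pre  = dihedral(ortho1, ipso1, N1, N2)`
#' * `chi_post = dihedral(N1, N2, ipso2, ortho2)`
#'
#' Each ring's ipso carbon has two ring neighbours; the ortho carbon
#' entering the torsion is the one yielding `|chi| <= 90` (the two
#' choices differ by 180 degrees), with an exact 90-degree tie broken by
#' the lexicographically lower atom name. `alpha_folded` (in \[0, 90\]) is
#' the orientation-free interplanar angle; `alpha_raw` (in \[0, 180\])
#' retains the normal orientations induced by the ring traversal order.
#'
#' @param model a `structure_model`.
#' @param residue an `atom_selector` (or selector string) resolving to
#'   the azobenzene-bearing residue.
#' @param ring1 [ring_spec()] of the first (inner) phenyl ring, starting
#'   at the carbon bonded to the first azo nitrogen.
#' @param azo_atoms character 2-vector: the azo nitrogen bonded to ring1,
#'   then the one bonded to ring2.
#' @param ring2 [ring_spec()] of the second (outer) phenyl ring.
#' @return Object of class `azo_geometry` with fields `chi_pre`,
#'   `chi_azo`, `chi_post`, `alpha_raw`, `alpha_folded` (degrees) and the
#'   fitted `plane1`, `plane2`.
#' @export
azo_descriptor <- function(model, residue, ring1, azo_atoms, ring2) {
  stopifnot(inherits(ring1, "ring_spec"), inherits(ring2, "ring_spec"),
            length(azo_atoms) == 2)
  res <- select_atoms(model, residue, require_nonempty = TRUE)
  r1 <- .resolve_named_atoms(res, ring1$atom_names)
  r2 <- .resolve_named_atoms(res, ring2$atom_names)
  nn <- .resolve_named_atoms(res, azo_atoms)
  ipso1 <- r1[1, ]; ipso2 <- r2[1, ]
  n1 <- nn[1, ]; n2 <- nn[2, ]
  chi_azo <- dihedral_angle(ipso1, n1, n2, ipso2)
  pick_ortho <- function(ring_xyz, ring_names, torsion_of) {
    # ring neighbours of the ipso carbon are positions 2 and 6
    cand <- list(c(2L, ring_names[2]), c(6L, ring_names[6]))
    vals <- c(torsion_of(ring_xyz[2, ]), torsion_of(ring_xyz[6, ]))
    ok <- abs(vals) <= 90
    if (sum(ok) == 1) return(vals[ok])
    # both at exactly 90 (or numeric tie): lower atom name wins
    sel <- order(ring_names[c(2L, 6L)])[1]
    vals[sel]
  }
  chi_pre <- pick_ortho(r1, ring1$atom_names,
                        function(o) dihedral_angle(o, ipso1, n1, n2))
  chi_post <- pick_ortho(r2, ring2$atom_names,
                         function(o) dihedral_angle(n1, n2, ipso2, o))
  p1 <- fit_plane(r1); p2 <- fit_plane(r2)
  ang <- interplanar_angle(p1, p2)
  structure(list(chi_pre = chi_pre, chi_azo = chi_azo, chi_post = chi_post,
                 alpha_raw = ang$alpha_raw, alpha_folded = ang$alpha_folded,
                 plane1 = p1, plane2 = p2),
            class = "azo_geometry")
}

#' @export
print.azo_geometry <- function(x, digits = 1, ...) {
  cat(sprintf(
    "<azo_geometry> chi_pre %.*f  chi_azo %.*f  chi_post %.*f  alpha %.*f (raw %.*f) deg\n",
    digits, x$chi_pre, digits, x$chi_azo, digits, x$chi_post,
    digits, x$alpha_folded, digits, x$alpha_raw))
  invisible(x)
}

#' @export
as.data.frame.azo_geometry <- function(x, ...) {
  data.frame(chi_pre = x$chi_pre, chi_azo = x$chi_azo,
             chi_post = x$chi_post, alpha_raw = x$alpha_raw,
             alpha_folded = x$alpha_folded)
}
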