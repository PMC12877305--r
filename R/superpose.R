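#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' of `R a + t` against `b` over all paired points, by SVD of the
#' covariance of the centered coordinates with the usual determinant
#' correction that excludes reflections. The returned RMSD is the global
#' minimum over all proper rigid motions.
#'
#' @param coords_a,coords_b numeric matrices of equal dimension (>= 3
#'   rows, 3 columns): mobile and reference coordinates, paired row by
#'   row, Angstrom.
#' @return Object of class `superposition`: `rotation` (3x3, det +1),
#'   `translation` (3-vector), `rmsd` (Angstrom), `n_pairs`.
#' @export
kabsch <- function(coords_a, coords_b) {
  a <- as.matrix(coords_a); b <- as.matrix(coords_b)
  if (nrow(a) != nrow(b)) stop("pairing error: coordinate sets differ in length")
  if (nrow(a) < 3) stop("underdetermined: need at least 3 paired points")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  if (max(abs(a0)) < 1e-12 && max(abs(b0)) < 1e-12 && nrow(a) >= 3)
    stop("degenerate geometry: all points coincident")
  h <- crossprod(a0, b0)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- a0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b0)^2)))
  structure(list(rotation = rot,
                 translation = as.vector(cb - rot %*% ca),
                 rmsd = rmsd, n_pairs = nrow(a)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.3f A over %d pairs\n",
              x$rmsd, x$n_pairs))
  invisible(x)
}

#' C-alpha RMSD between two chains over residue ranges
#'
#' Pairs C-alpha atoms of two chains by identical author residue number
#' over a multi-interval range (e.g. positions 3-74 and 79-227), drops
#' residues missing from either chain (unmodeled stretches are common in
#' crystal structures), and reports the Kabsch RMSD of the surviving
#' pairs. `n_pairs` reports the survivors; the count of dropped residues
#' is attached as attribute `"n_dropped"`.
#'
#' @param model_a,model_b `structure_model` objects.
#' @param chain_a,chain_b chain identifiers.
#' @param ranges list of inclusive `c(start, end)` residue-number pairs.
#' @param atom_name atom paired per residue (default "CA").
#' @return A `superposition` (see [kabsch()]).
#' @export
rmsd_ca_ranges <- function(model_a, model_b, chain_a, chain_b, ranges,
                           atom_name = "CA") {
  sa <- select_atoms(model_a,
                     selector(chain = chain_a, ranges = ranges,
                              atom_names = atom_name))
  sb <- select_atoms(model_b,
                     selector(chain = chain_b, ranges = ranges,
                              atom_names = atom_name))
  key_a <- paste(sa$residue_number, sa$insertion_code)
  key_b <- paste(sb$residue_number, sb$insertion_code)
  common <- intersect(key_a, key_b)
  if (length(common) < 3)
    stop("underdetermined: fewer than 3 paired residues survive")
  res <- kabsch(coords(sa[match(common, key_a), ]),
                coords(sb[match(common, key_b), ]))
  attr(res, "n_dropped") <- length(union(key_a, key_b)) - length(common)
  res
}

#' Superpose a model on anchor-atom pairs
#'
#' Fits the rigid transform from a small set of anchor atoms (each given
#' as a selector pair resolving to exactly one atom on each model) and
#' applies it to every atom of the mobile model. This is the
#' substructure-anchored overlay used to compare azobenzene conformers
#' on the first phenyl ring plus the first azo nitrogen. Pairing is by
#' selector pair, so permuting the list of pairs leaves the transform
#' unchanged.
#'
#' @param mobile,reference `structure_model` objects.
#' @param atom_pairs list of `list(mobile = sel, reference = sel)` pairs
#'   (selectors or selector strings), each resolving to exactly one atom.
#' @return list with `model` (the transformed mobile model) and `result`
#'   (the anchor-only `superposition`).
#' @export
superpose_on_substructure <- function(mobile, reference, atom_pairs) {
  if (length(atom_pairs) < 3)
    stop("underdetermined: need at least 3 anchor pairs")
  one <- function(model, sel, side) {
    hit <- select_atoms(model, sel)
    if (nrow(hit) != 1)
      stop("selection-cardinality error: ", side,
           " anchor selector resolves to ", nrow(hit), " atoms")
    coords(hit)[1, ]
  }
  am <- t(vapply(atom_pairs, function(p) one(mobile, p$mobile, "mobile"),
                 numeric(3)))
  ar <- t(vapply(atom_pairs, function(p) one(reference, p$reference,
                                             "reference"), numeric(3)))
  fit <- kabsch(am, ar)
  list(model = transform_model(mobile, fit$rotation, fit$translation),
       result = fit)
}
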