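#' Infer azobenzene ring and azo-nitrogen atom names from geometry
#'
#' Deposited azobenzene-bearing residues carry deposition-specific atom
#' nomenclature. This utility derives the descriptor topology from the
#' coordinates alone: heavy-atom bonds are taken as pairs closer than
#' `bond_cutoff`; the azo pair is the unique N-N bonded nitrogen pair;
#' each nitrogen's bonded carbon is an ipso carbon; each ring is the
#' 6-cycle of carbons through its ipso atom, ordered by traversal. Ring 1
#' is the ring whose centroid lies closer to the backbone CA (or, when
#' no CA exists, to the residue centroid of non-ring atoms).
#'
#' @param model a `structure_model`.
#' @param residue selector for the azobenzene-bearing residue.
#' @param bond_cutoff heavy-atom bond distance cutoff, Angstrom
#'   (default 1.75).
#' @return list with `ring1`, `ring2` ([ring_spec()]s, ipso first) and
#'   `azo_atoms` (character 2-vector, ring1-side nitrogen first).
#' @export
infer_azo_topology <- function(model, residue, bond_cutoff = 1.75) {
  res <- select_atoms(model, residue, require_nonempty = TRUE)
  res <- res[res$element != "H", , drop = FALSE]
  xyz <- coords(res)
  n <- nrow(res)
  d <- as.matrix(stats::dist(xyz))
  bonded <- d > 0.4 & d < bond_cutoff
  nb <- lapply(seq_len(n), function(i) which(bonded[i, ]))
  is_n <- res$element == "N"
  nn <- which(vapply(seq_len(n), function(i)
    is_n[i] && any(is_n[nb[[i]]]), logical(1)))
  pair <- NULL
  for (i in nn) for (j in nb[[i]]) if (j > i && is_n[j]) pair <- c(i, j)
  if (is.null(pair)) stop("no azo N=N pair found in residue")
  ipso_of <- function(ni) {
    cc <- nb[[ni]][res$element[nb[[ni]]] == "C"]
    if (length(cc) != 1)
      stop("azo nitrogen is not bonded to exactly one carbon")
    cc
  }
  ring_from <- function(start) {
    # depth-limited search for the 6-cycle of carbons through start
    path_search <- function(path) {
      last <- path[length(path)]
      if (length(path) == 6)
        return(if (start %in% nb[[last]]) path else NULL)
      for (nxt in nb[[last]]) {
        if (res$element[nxt] != "C" || nxt %in% path) next
        hit <- path_search(c(path, nxt))
        if (!is.null(hit)) return(hit)
      }
      NULL
    }
    ring <- path_search(start)
    if (is.null(ring)) stop("no 6-carbon ring found at inferred ipso atom")
    ring
  }
  i1 <- ipso_of(pair[1]); i2 <- ipso_of(pair[2])
  r1 <- ring_from(i1); r2 <- ring_from(i2)
  anchor <- if ("CA" %in% res$name) xyz[match("CA", res$name), ]
  else colMeans(xyz[-c(r1, r2, pair), , drop = FALSE])
  d1 <- sum((colMeans(xyz[r1, , drop = FALSE]) - anchor)^2)
  d2 <- sum((colMeans(xyz[r2, , drop = FALSE]) - anchor)^2)
  if (d2 < d1) {
    tmp <- r1; r1 <- r2; r2 <- tmp
    pair <- rev(pair)
  }
  list(ring1 = ring_spec(res$name[r1]),
       ring2 = ring_spec(res$name[r2]),
       azo_atoms = res$name[pair])
}
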