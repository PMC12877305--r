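#' Enumerate hydrogen bonds between two atom sets
#'
#' Distance-based donor/acceptor enumeration between the N/O heavy atoms
#' of two selections, as used to describe the circular hydrogen-bond
#' network between host hydroxyl groups and the protein residues
#' surrounding a switch. With no hydrogens in the model (the usual case
#' for crystal structures at ~2 Angstrom), the criterion is a heavy-atom
#' distance cutoff plus an antecedent-angle screen: for each atom of a
#' candidate pair, the angle antecedent-atom-partner must be at least
#' `min_antecedent_angle` for every covalently bonded heavy neighbour,
#' which excludes through-bond contacts and clashes.
#'
#' @param model a `structure_model`.
#' @param set_a,set_b atom selectors (or selector strings) for the two
#'   sides; they may overlap when intra-set bonds are wanted.
#' @param max_distance donor-acceptor heavy-atom cutoff, Angstrom
#'   (default 3.5).
#' @param min_antecedent_angle degrees (default 90).
#' @param category label stored on each bond (default inferred:
#'   "a-b" cross bonds).
#' @return data.frame of class `hbond_table`, sorted by distance:
#'   donor/acceptor identification columns, `distance` (Angstrom),
#'   `angle_evidence` (the smallest antecedent angle observed, degrees,
#'   NA when neither atom has a bonded neighbour) and `category`.
#' @export
hydrogen_bonds <- function(model, set_a, set_b, max_distance = 3.5,
                           min_antecedent_angle = 90,
                           category = "a-b") {
  stopifnot(inherits(model, "structure_model"))
  aa <- select_atoms(model, set_a)
  ab <- select_atoms(model, set_b)
  polar <- function(t) t[t$element %in% c("N", "O"), , drop = FALSE]
  aa <- polar(aa); ab <- polar(ab)
  empty <- data.frame(
    donor_chain = character(), donor_resno = integer(),
    donor_resname = character(), donor_atom = character(),
    acceptor_chain = character(), acceptor_resno = integer(),
    acceptor_resname = character(), acceptor_atom = character(),
    distance = numeric(), angle_evidence = numeric(),
    category = character(), stringsAsFactors = FALSE)
  class(empty) <- c("hbond_table", "data.frame")
  if (nrow(aa) == 0 || nrow(ab) == 0) return(empty)
  xa <- coords(aa); xb <- coords(ab)
  key_a <- .site_key(aa); key_b <- .site_key(ab)
  heavy <- model$atoms[model$atoms$element != "H", , drop = FALSE]
  xh <- coords(heavy)
  res_h <- .residue_key(heavy)
  antecedents <- function(tab, i, xyz_i) {
    # bonded heavy neighbours: same or adjacent residue, 0.4-1.9 A
    cand <- which(res_h == .residue_key(tab[i, , drop = FALSE]) |
                    (heavy$chain_id == tab$chain_id[i] &
                       abs(heavy$residue_number - tab$residue_number[i]) == 1))
    d2 <- rowSums(sweep(xh[cand, , drop = FALSE], 2, xyz_i)^2)
    xh[cand[d2 > 0.16 & d2 < 1.9^2], , drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(aa))) {
    d <- sqrt(rowSums(sweep(xb, 2, xa[i, ])^2))
    hits <- which(d <= max_distance & d > 0.1 & key_b[] != key_a[i])
    for (j in hits) {
      angs <- numeric(0)
      for (side in list(list(tab = aa, k = i, self = xa[i, ], other = xb[j, ]),
                        list(tab = ab, k = j, self = xb[j, ], other = xa[i, ]))) {
        ants <- antecedents(side$tab, side$k, side$self)
        if (nrow(ants)) {
          v1 <- sweep(ants, 2, side$self)
          v2 <- side$other - side$self
          cosang <- (v1 %*% v2) /
            (sqrt(rowSums(v1^2)) * sqrt(sum(v2^2)))
          angs <- c(angs, acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
        }
      }
      if (length(angs) && min(angs) < min_antecedent_angle) next
      rows[[length(rows) + 1L]] <- data.frame(
        donor_chain = aa$chain_id[i], donor_resno = aa$residue_number[i],
        donor_resname = aa$residue_name[i], donor_atom = aa$name[i],
        acceptor_chain = ab$chain_id[j], acceptor_resno = ab$residue_number[j],
        acceptor_resname = ab$residue_name[j], acceptor_atom = ab$name[j],
        distance = d[j],
        angle_evidence = if (length(angs)) min(angs) else NA_real_,
        category = category, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  # de-duplicate symmetric pairs when the two sets overlap
  pk <- apply(cbind(paste(out$donor_chain, out$donor_resno, out$donor_atom),
                    paste(out$acceptor_chain, out$acceptor_resno,
                          out$acceptor_atom)), 1,
              function(r) paste(sort(r), collapse = "<->"))
  out <- out[!duplicated(pk), , drop = FALSE]
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hbond_table", "data.frame")
  out
}

#' @export
print.hbond_table <- function(x, ...) {
  cat("<hbond_table> ", nrow(x), " hydrogen bond(s)\n", sep = "")
  if (nrow(x)) {
    df <- data.frame(
      donor = paste0(x$donor_chain, "/", x$donor_resname, x$donor_resno,
                     "/", x$donor_atom),
      acceptor = paste0(x$acceptor_chain, "/", x$acceptor_resname,
                        x$acceptor_resno, "/", x$acceptor_atom),
      dist = round(x$distance, 2),
      angle = round(x$angle_evidence, 1))
    print.data.frame(df, row.names = FALSE)
  }
  invisible(x)
}
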