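#' Build an atom selector
#'
#' Selectors express the multi-interval residue-range selections used for
#' RMSD comparisons (e.g. C-alpha positions 3-74 and 79-227 of one chain)
#' as well as residue-name and atom-name filters. Ranges are normalized:
#' sorted, merged when overlapping or adjacent.
#'
#' @param chain chain identifier, or NULL for any chain.
#' @param ranges list of inclusive `c(start, end)` integer pairs (or a
#'   single pair), or NULL for all residue numbers.
#' @param residue_name 3-letter residue name(s), or NULL.
#' @param atom_names character vector of atom names, or NULL.
#' @param alt_loc policy for alternate locations: `"highest_occupancy"`
#'   (default; ties broken by alphabetical alt-loc id), `"first"`, or
#'   `"specific"` with `alt_id` given. Blank alt-loc atoms are always kept.
#' @param alt_id specific alternate-location id when `alt_loc = "specific"`.
#' @return An object of class `atom_selector`.
#' @export
selector <- function(chain = NULL, ranges = NULL, residue_name = NULL,
                     atom_names = NULL,
                     alt_loc = c("highest_occupancy", "first", "specific"),
                     alt_id = NULL) {
  alt_loc <- match.arg(alt_loc)
  if (alt_loc == "specific" && is.null(alt_id))
    stop("alt_loc = \"specific\" requires alt_id")
  if (!is.null(ranges)) {
    if (is.numeric(ranges)) ranges <- list(ranges)
    ranges <- lapply(ranges, function(r) {
      if (length(r) != 2 || r[1] > r[2])
        stop("each range must be c(start, end) with start <= end")
      as.integer(r)
    })
    ranges <- ranges[order(vapply(ranges, `[`, integer(1), 1))]
    merged <- list(ranges[[1]])
    for (r in ranges[-1]) {
      last <- merged[[length(merged)]]
      if (r[1] <= last[2] + 1L)
        merged[[length(merged)]] <- c(last[1], max(last[2], r[2]))
      else merged <- c(merged, list(r))
    }
    ranges <- merged
  }
  structure(list(chain = chain, ranges = ranges,
                 residue_name = residue_name, atom_names = atom_names,
                 alt_loc = alt_loc, alt_id = alt_id),
            class = "atom_selector")
}

#' @export
print.atom_selector <- function(x, ...) {
  rng <- if (is.null(x$ranges)) "*" else
    paste(vapply(x$ranges, function(r)
      if (r[1] == r[2]) as.character(r[1]) else paste0(r[1], "-", r[2]),
      character(1)), collapse = ",")
  cat("<atom_selector> chain=", x$chain %||% "*", " residues=", rng,
      " resname=", paste(x$residue_name %||% "*", collapse = "|"),
      " atoms=", paste(x$atom_names %||% "*", collapse = ","),
      " alt_loc=", x$alt_loc, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse the selector mini-grammar
#'
#' Grammar: `"CHAIN:RES[-RES][,RES[-RES]...][/NAME[,NAME...]]"`, e.g.
#' `"A:3-74,79-227/CA"`. The chain part may be omitted (`":10-20"`), the
#' range part may be `*` for all residues.
#'
#' @param text selector string.
#' @param ... further arguments passed to [selector()] (e.g. alt-loc
#'   policy, residue_name).
#' @return An `atom_selector`.
#' @export
parse_selector <- function(text, ...) {
  stopifnot(is.character(text), length(text) == 1)
  main <- strsplit(text, "/", fixed = TRUE)[[1]]
  if (length(main) > 2) stop("malformed selector: ", text)
  atom_names <- if (length(main) == 2)
    strsplit(main[2], ",", fixed = TRUE)[[1]] else NULL
  cr <- strsplit(main[1], ":", fixed = TRUE)[[1]]
  if (length(cr) == 1) { chain <- cr; rng_txt <- "*" }
  else { chain <- if (nzchar(cr[1])) cr[1] else NULL; rng_txt <- cr[2] }
  ranges <- NULL
  if (!identical(rng_txt, "*") && nzchar(rng_txt)) {
    ranges <- lapply(strsplit(rng_txt, ",", fixed = TRUE)[[1]], function(tok) {
      ends <- suppressWarnings(as.integer(strsplit(tok, "-", fixed = TRUE)[[1]]))
      if (any(is.na(ends)) || !length(ends) %in% 1:2)
        stop("malformed residue range: ", tok)
      c(ends[1], ends[length(ends)])
    })
  }
  selector(chain = chain, ranges = ranges, atom_names = atom_names, ...)
}

#' Select atoms from a model
#'
#' Applies chain, residue-range, residue-name and atom-name filters, then
#' resolves alternate locations exactly once per atomic site according to
#' the selector's policy. Atoms are returned in model order; selection is
#' idempotent and a multi-interval range equals the union of the
#' per-interval selections.
#'
#' @param model a `structure_model`.
#' @param sel an `atom_selector` (or a selector string, parsed via
#'   [parse_selector()]).
#' @param require_nonempty error if nothing matches (default FALSE).
#' @return data.frame of atoms (possibly zero rows), in model order.
#' @export
select_atoms <- function(model, sel, require_nonempty = FALSE) {
  stopifnot(inherits(model, "structure_model"))
  if (is.character(sel)) sel <- parse_selector(sel)
  stopifnot(inherits(sel, "atom_selector"))
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain)) keep <- keep & a$chain_id == sel$chain
  if (!is.null(sel$ranges)) {
    in_rng <- rep(FALSE, nrow(a))
    for (r in sel$ranges)
      in_rng <- in_rng | (a$residue_number >= r[1] & a$residue_number <= r[2])
    keep <- keep & in_rng
  }
  if (!is.null(sel$residue_name))
    keep <- keep & a$residue_name %in% sel$residue_name
  if (!is.null(sel$atom_names)) keep <- keep & a$name %in% sel$atom_names
  a <- a[keep, , drop = FALSE]
  if (nrow(a) > 1) a <- .resolve_alt_locs(a, sel$alt_loc, sel$alt_id)
  if (require_nonempty && nrow(a) == 0)
    stop("selection matched no atoms")
  rownames(a) <- NULL
  a
}

# one record per atomic site (chain, resno, icode, name)
.resolve_alt_locs <- function(a, policy, alt_id) {
  key <- .site_key(a)
  if (!anyDuplicated(key)) return(a)
  keep <- vapply(split(seq_len(nrow(a)), key)[unique(key)], function(idx) {
    if (length(idx) == 1) return(idx)
    sub <- a[idx, ]
    blank <- !nzchar(sub$alt_loc)
    if (any(blank)) return(idx[which(blank)[1]])
    pick <- switch(policy,
      first = 1L,
      highest_occupancy =
        order(-sub$occupancy, sub$alt_loc)[1],
      specific = {
        hit <- which(sub$alt_loc == alt_id)
        if (!length(hit)) return(NA_integer_)
        hit[1]
      })
    idx[pick]
  }, integer(1))
  keep <- sort(keep[!is.na(keep)])
  a[keep, , drop = FALSE]
}
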