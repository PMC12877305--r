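#' Standard average atomic weights (IUPAC), Da
#' @keywords internal
#' @noRd
.atomic_weights <- c(H = 1.00794, C = 12.0107, N = 14.0067, O = 15.9994,
                     S = 32.065, P = 30.973762, Se = 78.96)

#' Average mass of an elemental formula
#'
#' @param formula Hill-style formula string, e.g. `"C15H15N3O2"`.
#' @return Average mass in Da.
#' @examples
#' formula_mass("H2O")   # 18.015
#' @export
formula_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!nzchar(formula) || paste(toks, collapse = "") != formula)
    stop("cannot parse elemental formula: ", formula)
  total <- 0
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    count <- sub("^[A-Za-z]+", "", tok)
    count <- if (nzchar(count)) as.integer(count) else 1L
    w <- .atomic_weights[el]
    if (is.na(w)) stop("unknown element in formula: ", el)
    total <- total + w * count
  }
  unname(total)
}

# residue (= free amino acid minus H2O) elemental formulas
.residue_formulas <- c(
  G = "C2H3NO",   A = "C3H5NO",    S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",   T = "C4H7NO2",   C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO",  N = "C4H6N2O2",  D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3",   M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",   R = "C6H12N4O",  Y = "C9H9NO2",  W = "C11H10N2O")

.water_mass <- function() formula_mass("H2O")

#' Net mass change of GFP-type chromophore maturation, Da
#'
#' Autocatalytic backbone cyclization of the chromophore tripeptide
#' loses one water; the subsequent oxidation loses H2. Net average
#' delta: -(H2O + H2) = -20.031 Da.
#' @return Negative delta in Da.
#' @export
chromophore_maturation_delta <- function()
  -(formula_mass("H2O") + formula_mass("H2"))

#' Build a modified protein sequence for mass calculation
#'
#' Represents a biosynthetic protein chain: one-letter residue codes
#' (the 20 canonical ones plus registered extension codes for
#' noncanonical residues) and a list of mass-affecting modifications.
#'
#' @param sequence character scalar of one-letter codes, or a character
#'   vector of codes. Whitespace and digits are dropped.
#' @param ncaa named character vector registering extension codes as
#'   *free amino acid* elemental formulas, e.g.
#'   `c(X = "C15H15N3O2")` for p-(phenylazo)-L-phenylalanine; the
#'   residue composition used is that formula minus H2O.
#' @param remove_initiator_met subtract one Met residue mass
#'   (post-translational processing of the start Met); requires the
#'   sequence to begin with M.
#' @param mature_chromophore apply the GFP chromophore maturation delta,
#'   [chromophore_maturation_delta()].
#' @param custom_deltas numeric vector of additional mass deltas, Da.
#' @return Object of class `modified_sequence`.
#' @export
modified_sequence <- function(sequence, ncaa = character(),
                              remove_initiator_met = FALSE,
                              mature_chromophore = FALSE,
                              custom_deltas = numeric()) {
  if (length(sequence) == 1)
    sequence <- strsplit(gsub("[0-9*[:space:]]", "", sequence), "")[[1]]
  sequence <- toupper(sequence)
  known <- c(names(.residue_formulas), names(ncaa))
  bad <- setdiff(unique(sequence), known)
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "),
         " (register noncanonical codes via ncaa = c(CODE = formula))")
  mods <- list()
  if (remove_initiator_met) {
    if (sequence[1] != "M")
      stop("remove_initiator_met requires the sequence to start with M")
    mods <- c(mods, list(list(kind = "n_terminal_met_removed", site = 1L,
                              delta = -formula_mass(.residue_formulas["M"]))))
  }
  if (mature_chromophore)
    mods <- c(mods, list(list(kind = "chromophore_maturation", site = NA,
                              delta = chromophore_maturation_delta())))
  for (d in custom_deltas)
    mods <- c(mods, list(list(kind = "custom_delta", site = NA, delta = d)))
  structure(list(residues = sequence, ncaa = ncaa, modifications = mods),
            class = "modified_sequence")
}

#' Average molecular mass of a (modified) protein sequence
#'
#' Sum of residue average masses plus one water for the chain termini,
#' plus all modification deltas. Average (not monoisotopic) masses at
#' standard IUPAC atomic weights, matching the scale of ESI
#' deconvolution results.
#'
#' @param seq a [modified_sequence()], or a plain sequence passed on to
#'   `modified_sequence(...)` together with `...`.
#' @param ... arguments forwarded to [modified_sequence()] when `seq` is
#'   not already one.
#' @return Average mass in Da.
#' @examples
#' average_mass("G")                      # free glycine, 75.07
#' @export
average_mass <- function(seq, ...) {
  if (!inherits(seq, "modified_sequence"))
    seq <- modified_sequence(seq, ...)
  res_mass <- function(code) {
    if (code %in% names(.residue_formulas))
      formula_mass(.residue_formulas[code])
    else formula_mass(seq$ncaa[code]) - .water_mass()
  }
  codes <- unique(seq$residues)
  per <- vapply(codes, res_mass, numeric(1))
  total <- sum(per[match(seq$residues, codes)]) + .water_mass()
  total + sum(vapply(seq$modifications, `[[`, numeric(1), "delta"))
}

#' @export
print.modified_sequence <- function(x, ...) {
  cat("<modified_sequence> ", length(x$residues), " residues",
      if (length(x$ncaa)) paste0(", ncAA codes: ",
                                 paste(names(x$ncaa), collapse = ",")),
      "\n", sep = "")
  for (m in x$modifications)
    cat(sprintf("  %s: %+0.3f Da\n", m$kind, m$delta))
  invisible(x)
}

#' Read a one-record FASTA (or plain text) sequence
#'
#' @param path FASTA or plain-text sequence file. Placeholder characters
#'   (e.g. `X` for a noncanonical residue) are kept as-is.
#' @return character scalar sequence.
#' @export
read_sequence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1, warn = FALSE)
  if (startsWith(first, ">")) {
    seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                               seqonly = TRUE)
    toupper(seqs[[1]])
  } else {
    toupper(gsub("[[:space:]]", "", paste(readLines(path, warn = FALSE),
                                          collapse = "")))
  }
}
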