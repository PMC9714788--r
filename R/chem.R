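# Exact-mass chemistry: elemental formulas, negative-mode adducts, glycan
# fragment compositions.

# IUPAC 2021 monoisotopic masses of the most abundant isotope, in Da.
.ATOMIC_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  K  = 38.96370668,
  Na = 22.9897692809,
  Cl = 34.96885268
)

.ELECTRON_MASS <- 0.00054857990907

#' Parse an elemental formula into element counts
#'
#' Accepts Hill-style formulas over the element set C, H, N, O, P, S, K, Na,
#' Cl (the elements occurring in small endogenous metabolites and the
#' negative-mode adducts used here). No parentheses, charges or isotope
#' labels.
#'
#' @param formula A single formula string, e.g. `"C6H12O6"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("H2O")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("formula must be a single non-empty string")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("cannot parse formula: '", formula, "'")
  }
  el <- sub("[0-9]*$", "", toks)
  n <- sub("^[A-Za-z]+", "", toks)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  unknown <- setdiff(el, names(.ATOMIC_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  counts <- integer(length(.ATOMIC_MASS))
  names(counts) <- names(.ATOMIC_MASS)
  for (i in seq_along(el)) counts[[el[i]]] <- counts[[el[i]]] + n[i]
  counts
}

#' Monoisotopic neutral mass of an elemental formula
#'
#' @param formula Formula string (see [parse_formula()]).
#' @return Monoisotopic mass in Da.
#' @examples
#' neutral_mass("H2O") # 18.010565
#' @export
neutral_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(counts * .ATOMIC_MASS[names(counts)])
}

# Element deltas of the five negative-mode adducts. Charge is -1 for all;
# "M-H2O" is the deprotonated water-loss ion [M-H2O-H]-.
.ADDUCT_DELTA <- list(
  "M-H"     = c(H = -1L),
  "M-H2O"   = c(H = -3L, O = -1L),
  "M+K-2H"  = c(K = 1L, H = -2L),
  "M+Na-2H" = c(Na = 1L, H = -2L),
  "M+Cl"    = c(Cl = 1L)
)

#' The five negative-mode adduct rules
#'
#' @return Data frame with columns `label`, `mass_delta` (Da, sum of the atom
#'   deltas) and `charge` (-1 throughout).
#' @export
adduct_rules <- function() {
  data.frame(
    label = names(.ADDUCT_DELTA),
    mass_delta = vapply(.ADDUCT_DELTA, function(d) {
      sum(d * .ATOMIC_MASS[names(d)])
    }, numeric(1)),
    charge = -1L,
    row.names = NULL
  )
}

#' m/z of a singly charged negative adduct ion
#'
#' Adds the adduct's atom delta to the neutral monoisotopic mass and accounts
#' for the electron gained by the (-1)-charged ion.
#'
#' @param neutral Neutral monoisotopic mass in Da (> 0).
#' @param label Adduct label, one of `"M-H"`, `"M-H2O"`, `"M+K-2H"`,
#'   `"M+Na-2H"`, `"M+Cl"`.
#' @return Ion m/z in Da (charge 1).
#' @examples
#' adduct_mz(neutral_mass("C13H10N2"), "M-H") # 9-AA matrix ion, 193.0771
#' @export
adduct_mz <- function(neutral, label) {
  if (!is.numeric(neutral) || any(neutral <= 0)) {
    stop("neutral mass must be positive")
  }
  if (!label %in% names(.ADDUCT_DELTA)) {
    stop("unknown adduct label: '", label, "'")
  }
  d <- .ADDUCT_DELTA[[label]]
  mz <- neutral + sum(d * .ATOMIC_MASS[names(d)]) + .ELECTRON_MASS
  if (any(mz <= 0)) {
    stop("adduct '", label, "' yields non-positive m/z for neutral mass ",
         format(neutral))
  }
  mz
}

# Glycan residues are dehydrated monosaccharides (monosaccharide - H2O);
# modifications are mass additions. Formulas carried alongside so that a
# composition can be expanded to a full elemental formula.
.GLYCAN_RESIDUE_FORMULA <- c(
  Hex    = "C6H10O5",
  HexNAc = "C8H13NO5",
  HexA   = "C6H8O6",
  HexN   = "C6H11NO4",
  dHex   = "C6H10O4",
  NeuAc  = "C11H17NO8",
  NeuGc  = "C11H17NO9",
  Pen    = "C5H8O4"
)

.GLYCAN_MOD_FORMULA <- c(
  S  = "SO3",    # sulfation
  P  = "HPO3",   # phosphorylation
  Ac = "C2H2O"   # acetylation
)

#' Construct a glycan fragment composition
#'
#' A composition counts monosaccharide residues (`Hex`, `HexNAc`, `HexA`,
#' `HexN`, `dHex`, `NeuAc`, `NeuGc`, `Pen`) and modifications (`S` sulfate,
#' `P` phosphate, `Ac` acetyl). Residues are dehydrated; a free reducing end
#' adds back one water.
#'
#' @param residues Named integer vector of residue counts.
#' @param mods Named integer vector of modification counts (may be empty).
#' @param reducing_end Logical; add one H2O for a free reducing end.
#' @return Object of class `glycan_composition`.
#' @export
glycan_composition <- function(residues, mods = integer(0),
                               reducing_end = TRUE) {
  res <- integer(length(.GLYCAN_RESIDUE_FORMULA))
  names(res) <- names(.GLYCAN_RESIDUE_FORMULA)
  if (length(residues)) {
    bad <- setdiff(names(residues), names(res))
    if (length(bad)) stop("unknown residue(s): ", paste(bad, collapse = ", "))
    res[names(residues)] <- as.integer(residues)
  }
  md <- integer(length(.GLYCAN_MOD_FORMULA))
  names(md) <- names(.GLYCAN_MOD_FORMULA)
  if (length(mods)) {
    bad <- setdiff(names(mods), names(md))
    if (length(bad)) stop("unknown modification(s): ", paste(bad, collapse = ", "))
    md[names(mods)] <- as.integer(mods)
  }
  if (any(res < 0) || any(md < 0)) stop("counts must be non-negative")
  if (sum(res) == 0L) stop("composition must contain at least one residue")
  structure(list(residues = res, mods = md,
                 reducing_end = isTRUE(reducing_end)),
            class = "glycan_composition")
}

#' Neutral monoisotopic mass of a glycan fragment composition
#'
#' Sum of dehydrated-residue masses plus modification deltas, plus one H2O
#' when the reducing end is free.
#'
#' @param comp A [glycan_composition()].
#' @return Neutral mass in Da.
#' @examples
#' glycan_fragment_mass(glycan_composition(c(Hex = 1))) # glucose, 180.063388
#' @export
glycan_fragment_mass <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  neutral_mass(glycan_formula(comp))
}

#' Expand a glycan composition to its elemental formula
#'
#' @param comp A [glycan_composition()].
#' @return Formula string in element order C, H, N, O, P, S.
#' @export
glycan_formula <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  counts <- integer(length(.ATOMIC_MASS))
  names(counts) <- names(.ATOMIC_MASS)
  add <- function(formula, times) {
    if (times > 0) counts <<- counts + parse_formula(formula) * times
  }
  for (r in names(comp$residues)) add(.GLYCAN_RESIDUE_FORMULA[[r]], comp$residues[[r]])
  for (m in names(comp$mods)) add(.GLYCAN_MOD_FORMULA[[m]], comp$mods[[m]])
  if (comp$reducing_end) add("H2O", 1L)
  ord <- c("C", "H", "N", "O", "P", "S", "K", "Na", "Cl")
  parts <- vapply(ord, function(e) {
    n <- counts[[e]]
    if (n == 0L) "" else if (n == 1L) e else paste0(e, n)
  }, character(1))
  paste(parts, collapse = "")
}

#' Render a glycan composition label
#'
#' Compositional nomenclature: residues in the fixed order Hex, HexA,
#' HexNAc, HexN, dHex, NeuAc, NeuGc, Pen followed by modifications S, P,
#' Ac, each with its count (e.g. `"HexNAc1S1"`, `"HexA1HexNAc1S1"`).
#'
#' @param comp A [glycan_composition()].
#' @return Label string.
#' @export
glycan_label <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  display <- c("Hex", "HexA", "HexNAc", "HexN", "dHex", "NeuAc", "NeuGc",
               "Pen")
  parts <- c(
    vapply(display, function(r) {
      n <- comp$residues[[r]]
      if (n == 0L) "" else paste0(r, n)
    }, character(1)),
    vapply(names(comp$mods), function(m) {
      n <- comp$mods[[m]]
      if (n == 0L) "" else paste0(m, n)
    }, character(1))
  )
  paste(parts[nzchar(parts)], collapse = "")
}
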