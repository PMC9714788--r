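# Accurate-mass annotation of picked peaks: metabolite records expanded by
# the five negative-mode adducts, matched within a ppm tolerance, plus
# compositional glycan-fragment annotation and exogenous filtering.

#' Signed parts-per-million mass error
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z (> 0).
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0")
  (observed - theoretical) / theoretical * 1e6
}

.empty_annotations <- function() {
  data.frame(peak_mz = numeric(0), id = character(0), name = character(0),
             adduct = character(0), theo_mz = numeric(0), ppm = numeric(0),
             class = character(0), endogenous = logical(0),
             pathways = character(0), source = character(0),
             stringsAsFactors = FALSE)
}

.sort_annotations <- function(out) {
  out <- out[order(out$peak_mz, abs(out$ppm), out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate peaks against the metabolite reference table
#'
#' Every (peak, record, adduct) combination whose theoretical m/z lies
#' within `tol_ppm` of the peak center is emitted; peaks may carry several
#' candidates, ranked by absolute ppm error. Output order is deterministic
#' (peak m/z, |ppm|, id) and independent of table row order.
#'
#' @param peaks `peak_list` or data frame with an `mz` column.
#' @param db Metabolite table from [load_metabolite_db()].
#' @param tol_ppm Tolerance in ppm (default 4).
#' @param adducts Adduct labels to consider (default all five).
#' @return Annotation data frame with columns `peak_mz`, `id`, `name`,
#'   `adduct`, `theo_mz`, `ppm`, `class`, `endogenous`, `pathways`
#'   (semicolon-joined), `source`.
#' @export
annotate_peaks <- function(peaks, db, tol_ppm = 4,
                           adducts = adduct_rules()$label) {
  if (nrow(db) == 0L) return(.empty_annotations())
  cand <- adduct_table(db, adducts)
  out <- lapply(peaks$mz, function(p) {
    lo <- p / (1 + tol_ppm * 1e-6)
    hi <- p / (1 - tol_ppm * 1e-6)
    sel <- which(cand$mz >= lo & cand$mz <= hi)
    sel <- sel[abs(ppm_error(p, cand$mz[sel])) <= tol_ppm]
    if (!length(sel)) return(NULL)
    data.frame(peak_mz = p, id = cand$id[sel], name = cand$name[sel],
               adduct = cand$adduct[sel], theo_mz = cand$mz[sel],
               ppm = ppm_error(p, cand$mz[sel]), class = cand$class[sel],
               endogenous = cand$endogenous[sel],
               pathways = vapply(cand$pathways[sel], paste, character(1),
                                 collapse = ";"),
               source = "metabolite", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(.empty_annotations())
  .sort_annotations(out)
}

#' Drop annotations of exogenous records
#'
#' Keeps only records flagged endogenous, mirroring the exclusion of
#' irrelevant annotations such as drugs, pesticides and the MALDI matrix.
#'
#' @param annos Annotation data frame (with an `endogenous` column).
#' @return Filtered annotation data frame.
#' @export
filter_exogenous <- function(annos) {
  out <- annos[annos$endogenous, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate glycan fragment compositions and annotate peaks
#'
#' Enumerates compositions within per-residue and per-modification bounds,
#' computes the deprotonated `[M-H]-` m/z of each, and matches peaks within
#' `tol_ppm`. Composition labels use the compositional nomenclature of
#' [glycan_label()].
#'
#' @param peaks `peak_list` or data frame with an `mz` column.
#' @param max_residues Named vector of maximal residue counts (defaults to 2
#'   for Hex/HexNAc/HexA and 1 for the rest).
#' @param max_mods Named vector of maximal modification counts (default S 2,
#'   P 2, Ac 1).
#' @param tol_ppm Tolerance in ppm.
#' @param mz_range Neutral-mass window retained (defaults to the acquired
#'   m/z 75-1100 range).
#' @param max_total_residues Cap on the summed residue count.
#' @param max_compositions Enumeration cap; exceeding it truncates with a
#'   warning.
#' @param reducing_end Free reducing end (adds H2O).
#' @return Annotation data frame (`source = "glycan"`, `id` = composition
#'   label), same columns as [annotate_peaks()].
#' @export
annotate_glycans <- function(peaks,
                             max_residues = c(Hex = 2, HexNAc = 2, HexA = 2,
                                              HexN = 1, dHex = 1, NeuAc = 1,
                                              NeuGc = 1, Pen = 1),
                             max_mods = c(S = 2, P = 2, Ac = 1),
                             tol_ppm = 4, mz_range = c(75, 1100),
                             max_total_residues = 4,
                             max_compositions = 2e5,
                             reducing_end = TRUE) {
  res_names <- names(.GLYCAN_RESIDUE_FORMULA)
  mod_names <- names(.GLYCAN_MOD_FORMULA)
  rmax <- stats::setNames(rep(0L, length(res_names)), res_names)
  rmax[names(max_residues)] <- as.integer(max_residues)
  mmax <- stats::setNames(rep(0L, length(mod_names)), mod_names)
  mmax[names(max_mods)] <- as.integer(max_mods)
  if (any(rmax < 0) || any(mmax < 0)) stop("bounds must be non-negative")

  n_comb <- prod(rmax + 1) * prod(mmax + 1)
  if (n_comb > max_compositions) {
    warning("glycan enumeration capped at ", max_compositions,
            " of ", n_comb, " compositions")
  }
  # mixed-radix enumeration of the first min(n_comb, cap) compositions,
  # never materializing the full grid
  n_enum <- min(n_comb, max_compositions)
  radix <- c(rmax, mmax) + 1
  idx <- seq_len(n_enum) - 1
  grid <- as.data.frame(lapply(stats::setNames(seq_along(radix),
                                               names(radix)), function(j) {
    place <- if (j == 1) 1 else prod(radix[seq_len(j - 1)])
    (idx %/% place) %% radix[j]
  }))
  total_res <- rowSums(grid[, res_names, drop = FALSE])
  grid <- grid[total_res > 0 & total_res <= max_total_residues, ,
               drop = FALSE]
  if (nrow(grid) == 0L) return(.empty_annotations())

  res_mass <- vapply(.GLYCAN_RESIDUE_FORMULA, neutral_mass, numeric(1))
  mod_mass <- vapply(.GLYCAN_MOD_FORMULA, neutral_mass, numeric(1))
  neutral <- as.matrix(grid[, res_names, drop = FALSE]) %*% res_mass +
    as.matrix(grid[, mod_names, drop = FALSE]) %*% mod_mass +
    if (reducing_end) neutral_mass("H2O") else 0
  mz <- adduct_mz(as.numeric(neutral), "M-H")
  keep <- mz >= mz_range[1] & mz <= mz_range[2]
  grid <- grid[keep, , drop = FALSE]
  mz <- mz[keep]
  if (!length(mz)) return(.empty_annotations())

  labels <- vapply(seq_len(nrow(grid)), function(i) {
    row <- unlist(grid[i, ])
    comp <- glycan_composition(row[res_names][row[res_names] > 0],
                               row[mod_names][row[mod_names] > 0],
                               reducing_end = reducing_end)
    glycan_label(comp)
  }, character(1))

  out <- lapply(peaks$mz, function(p) {
    ppm <- ppm_error(p, mz)
    sel <- which(abs(ppm) <= tol_ppm)
    if (!length(sel)) return(NULL)
    data.frame(peak_mz = p, id = labels[sel], name = labels[sel],
               adduct = "M-H", theo_mz = mz[sel], ppm = ppm[sel],
               class = "Glycan fragment", endogenous = TRUE,
               pathways = "", source = "glycan", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(.empty_annotations())
  .sort_annotations(out)
}

#' Reduce annotations to the single best candidate per peak
#'
#' Candidates are ranked by absolute ppm error with the record id as a
#' deterministic tie-break. Used where downstream reporting needs one name
#' per peak; statistics always operate per peak regardless of annotation
#' multiplicity.
#'
#' @param annos Annotation data frame.
#' @return One row per annotated `peak_mz`.
#' @export
best_annotation <- function(annos) {
  if (nrow(annos) == 0L) return(annos)
  annos <- .sort_annotations(annos)
  out <- annos[!duplicated(annos$peak_mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}
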