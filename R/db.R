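# Bundled reference tables: metabolites, pathways, glycan building blocks.
# The metabolite table is a synthetic desk-scale stand-in for KEGG/HMDB
# records (curated endogenous metabolites plus flagged exogenous decoys).

#' Load the bundled metabolite reference table
#'
#' Columns: `id`, `name`, `formula`, `mass` (monoisotopic, Da), `pathways`
#' (list column of pathway IDs), `class` (chemical taxonomy label),
#' `endogenous` (logical). Every stored mass is recomputable from its formula
#' to within 1e-6 Da.
#'
#' @param path Optional path to an alternative TSV with the same columns
#'   (pathways semicolon-joined, endogenous coded 0/1).
#' @return Data frame of metabolite records.
#' @export
load_metabolite_db <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "metabolites.tsv", package = "osteomsi",
                        mustWork = TRUE)
  }
  db <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(mass = "numeric"))
  need <- c("id", "name", "formula", "mass", "pathways", "class", "endogenous")
  missing <- setdiff(need, names(db))
  if (length(missing)) {
    stop("metabolite table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(db$id)) stop("metabolite ids are not unique")
  db$pathways <- strsplit(ifelse(is.na(db$pathways), "", db$pathways), ";",
                          fixed = TRUE)
  db$endogenous <- db$endogenous == 1
  db
}

#' Load the bundled pathway name table
#'
#' @param path Optional alternative TSV (columns `pathway`, `name`).
#' @return Data frame mapping pathway IDs to display names.
#' @export
load_pathway_names <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pathways.tsv", package = "osteomsi",
                        mustWork = TRUE)
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Load the glycan building-block table
#'
#' Residue labels with the elemental formula of the dehydrated residue
#' (monosaccharide minus water).
#'
#' @param path Optional alternative TSV (columns `residue`, `formula`).
#' @return Data frame with columns `residue`, `formula`, `mass`.
#' @export
load_glycan_residues <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "glycan_residues.tsv", package = "osteomsi",
                        mustWork = TRUE)
  }
  res <- utils::read.delim(path, stringsAsFactors = FALSE)
  res$mass <- vapply(res$formula, neutral_mass, numeric(1))
  res
}

#' All theoretical adduct m/z values for a metabolite table
#'
#' Expands every record by the five negative-mode adducts.
#'
#' @param db Metabolite table from [load_metabolite_db()].
#' @param adducts Character vector of adduct labels (default all five).
#' @return Data frame with columns `id`, `name`, `adduct`, `mz`, plus the
#'   record's `class`, `endogenous` flag and `pathways`.
#' @export
adduct_table <- function(db, adducts = adduct_rules()$label) {
  out <- do.call(rbind, lapply(adducts, function(a) {
    data.frame(id = db$id, name = db$name, adduct = a,
               mz = adduct_mz(db$mass, a), class = db$class,
               endogenous = db$endogenous, stringsAsFactors = FALSE)
  }))
  out$pathways <- rep(db$pathways, times = length(adducts))
  out[order(out$mz), , drop = FALSE]
}
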