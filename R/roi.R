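# ROI label masks over the pixel grid. A mask is a label image (integer
# matrix indexing a label vocabulary) plus a per-section group tag, the way
# annotated bone sections carry mineralized cortical bone, osteoid, bone
# marrow and background regions.

#' Default bone compartment vocabulary
#'
#' Background first, then the three tissue compartments.
#' @return Character vector of labels.
#' @export
bone_vocabulary <- function() {
  c("background", "mineralized_bone", "osteoid", "bone_marrow")
}

#' Construct an ROI mask
#'
#' @param grid Integer matrix (rows = y, cols = x) of 1-based indices into
#'   `vocabulary`.
#' @param vocabulary Character vector of region labels; the first entry is
#'   the off-tissue/background label.
#' @param group Group tag of the section (e.g. `"WT"`, `"Hyp"`).
#' @param section_id Section identifier.
#' @return Object of class `roi_mask`.
#' @export
roi_mask <- function(grid, vocabulary = bone_vocabulary(), group = NA_character_,
                     section_id = NA_character_) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "integer"
  if (any(is.na(grid)) || any(grid < 1L) || any(grid > length(vocabulary))) {
    stop("mask grid contains indices outside the label vocabulary")
  }
  structure(list(grid = grid, vocabulary = vocabulary, group = group,
                 section_id = section_id),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  tab <- table(factor(x$vocabulary[x$grid], levels = x$vocabulary))
  cat(sprintf("<roi_mask> %d x %d, section %s, group %s\n",
              nrow(x$grid), ncol(x$grid), x$section_id, x$group))
  print(tab)
  invisible(x)
}

#' Per-pixel labels of a mask aligned to a dataset's pixel list
#'
#' @param mask An [roi_mask()].
#' @param coords Data frame of 0-based `x`, `y` pixel coordinates.
#' @return Character vector of labels, one per coordinate row.
#' @export
mask_labels <- function(mask, coords) {
  stopifnot(inherits(mask, "roi_mask"))
  idx <- cbind(coords$y + 1L, coords$x + 1L)
  if (any(idx[, 1] > nrow(mask$grid)) || any(idx[, 2] > ncol(mask$grid))) {
    stop("coordinates outside the mask grid")
  }
  mask$vocabulary[mask$grid[idx]]
}

.validate_mask_against <- function(mask, ds) {
  ny <- max(ds$coords$y) + 1L
  nx <- max(ds$coords$x) + 1L
  if (nrow(mask$grid) > ny || ncol(mask$grid) > nx) {
    stop(sprintf("mask grid (%d x %d) larger than dataset extent (%d x %d)",
                 nrow(mask$grid), ncol(mask$grid), ny, nx))
  }
  labelled <- which(mask$grid != 1L, arr.ind = TRUE)
  if (nrow(labelled)) {
    key <- paste(labelled[, 2] - 1L, labelled[, 1] - 1L)
    have <- paste(ds$coords$x, ds$coords$y)
    missing <- setdiff(key, have)
    if (length(missing)) {
      stop("mask labels ", length(missing),
           " pixel(s) absent from the dataset, first: (",
           missing[1], ")")
    }
  }
  invisible(mask)
}

#' Read an ROI mask from TSV or PNG
#'
#' Two dialects are accepted: a TSV with columns `x`, `y`, `label` (0-based
#' coordinates; unlisted pixels default to the background label), or a
#' grayscale PNG whose rounded 8-bit value indexes the vocabulary (0 =
#' background).
#'
#' @param path File path (`.tsv`/`.txt` or `.png`).
#' @param ds Dataset the mask must be congruent with.
#' @param vocabulary Allowed labels, background first.
#' @param group,section_id Metadata tags stored on the mask.
#' @return A validated [roi_mask()].
#' @export
read_roi_mask <- function(path, ds, vocabulary = bone_vocabulary(),
                          group = NA_character_, section_id = NA_character_) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  ny <- max(ds$coords$y) + 1L
  nx <- max(ds$coords$x) + 1L
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    grid <- matrix(as.integer(round(img * 255)) + 1L, nrow = nrow(img))
    if (any(grid > length(vocabulary))) {
      stop("PNG mask contains label index outside the vocabulary")
    }
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("x", "y", "label") %in% names(tab))) {
      stop("mask TSV needs columns x, y, label")
    }
    bad <- setdiff(unique(tab$label), vocabulary)
    if (length(bad)) {
      stop("mask label(s) outside vocabulary: ", paste(bad, collapse = ", "))
    }
    if (nrow(tab) && (max(tab$y) + 1L > ny || max(tab$x) + 1L > nx)) {
      stop(sprintf("mask grid (%d x %d) larger than dataset extent (%d x %d)",
                   max(tab$y) + 1L, max(tab$x) + 1L, ny, nx))
    }
    grid <- matrix(1L, nrow = ny, ncol = nx)
    if (nrow(tab)) {
      grid[cbind(tab$y + 1L, tab$x + 1L)] <- match(tab$label, vocabulary)
    }
  }
  mask <- roi_mask(grid, vocabulary, group, section_id)
  .validate_mask_against(mask, ds)
  mask
}

#' Write an ROI mask to TSV or PNG
#'
#' @param mask An [roi_mask()].
#' @param path Output path; format chosen by extension (`.png` or TSV
#'   otherwise). The TSV lists only non-background pixels.
#' @return Invisibly, `path`.
#' @export
write_roi_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG((mask$grid - 1L) / 255, path)
  } else {
    labelled <- which(mask$grid != 1L, arr.ind = TRUE)
    tab <- data.frame(x = labelled[, 2] - 1L, y = labelled[, 1] - 1L,
                      label = mask$vocabulary[mask$grid[labelled]])
    tab <- tab[order(tab$y, tab$x), , drop = FALSE]
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
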