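# imzML input/output.
#
# imzML stores MSI spectra as an mzML-derived XML index (.imzML) plus a raw
# binary file (.ibd) holding the m/z and intensity arrays. In continuous mode
# all pixels share one m/z axis; in processed mode each pixel carries its
# own. Pixel indices are 1-based in the file and 0-based inside this package.

#' Construct an MSI dataset
#'
#' @param coords Data frame with integer columns `x`, `y` (0-based pixel
#'   column/row indices, no duplicates).
#' @param mz Continuous mode: one strictly increasing numeric m/z axis.
#'   Processed mode: list of per-pixel axes.
#' @param intensity Continuous mode: numeric matrix, pixels in rows (aligned
#'   with `coords`), axis points in columns. Processed mode: list of
#'   per-pixel intensity vectors.
#' @param mode `"continuous"` or `"processed"`.
#' @return Object of class `msi_dataset`.
#' @export
msi_dataset <- function(coords, mz, intensity,
                        mode = c("continuous", "processed")) {
  mode <- match.arg(mode)
  coords <- data.frame(x = as.integer(coords$x), y = as.integer(coords$y))
  if (anyDuplicated(coords)) stop("duplicate pixel coordinates")
  if (any(coords$x < 0) || any(coords$y < 0)) stop("coordinates must be >= 0")
  n <- nrow(coords)
  if (n == 0L) stop("dataset has no pixels")
  check_axis <- function(x, where) {
    if (length(x) == 0L) stop("empty m/z axis ", where)
    if (any(diff(x) <= 0)) stop("m/z axis not strictly increasing ", where)
  }
  if (mode == "continuous") {
    mz <- as.numeric(mz)
    check_axis(mz, "(shared axis)")
    intensity <- as.matrix(intensity)
    if (nrow(intensity) != n || ncol(intensity) != length(mz)) {
      stop("intensity matrix must be n_pixels x n_axis")
    }
    if (any(intensity < 0)) stop("negative intensities")
  } else {
    if (!is.list(mz) || !is.list(intensity) || length(mz) != n ||
        length(intensity) != n) {
      stop("processed mode needs per-pixel m/z and intensity lists")
    }
    for (i in seq_len(n)) {
      check_axis(mz[[i]], sprintf("(pixel %d)", i))
      if (length(intensity[[i]]) != length(mz[[i]])) {
        stop("intensity length mismatch at pixel ", i)
      }
      if (any(intensity[[i]] < 0)) stop("negative intensities at pixel ", i)
    }
  }
  structure(list(coords = coords, mz = mz, intensity = intensity,
                 mode = mode),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> %d pixels, %s mode, grid %d x %d\n",
              nrow(x$coords), x$mode, max(x$coords$x) + 1L,
              max(x$coords$y) + 1L))
  invisible(x)
}

#' Number of pixels in an MSI dataset
#' @param ds An `msi_dataset`.
#' @return Integer pixel count.
#' @export
n_pixels <- function(ds) nrow(ds$coords)

# Canonical (y, x) pixel order so that datasets compare independently of
# on-disk spectrum order.
sort_pixels <- function(ds) {
  ord <- order(ds$coords$y, ds$coords$x)
  ds$coords <- ds$coords[ord, , drop = FALSE]
  rownames(ds$coords) <- NULL
  if (ds$mode == "continuous") {
    ds$intensity <- ds$intensity[ord, , drop = FALSE]
  } else {
    ds$mz <- ds$mz[ord]
    ds$intensity <- ds$intensity[ord]
  }
  ds
}

.imzml_paths <- function(path) {
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  list(xml = paste0(base, ".imzML"), ibd = paste0(base, ".ibd"))
}

# Deterministic pseudo-UUID derived from dataset shape and content so that
# identical datasets produce byte-identical files.
.dataset_uuid <- function(ds) {
  key <- paste(ds$mode, nrow(ds$coords),
               paste(ds$coords$x, ds$coords$y, collapse = ","),
               if (ds$mode == "continuous") {
                 paste(format(range(ds$mz), digits = 17),
                       format(sum(ds$intensity), digits = 17))
               } else {
                 paste(format(sum(unlist(ds$intensity)), digits = 17),
                       format(sum(unlist(ds$mz)), digits = 17))
               })
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(key, tmp)
  unname(tools::md5sum(tmp))
}

#' Write an MSI dataset as imzML
#'
#' Produces a standard-conformant `.imzML`/`.ibd` pair (64-bit float arrays,
#' no compression, external binary data). Internal 0-based coordinates are
#' written 1-based as the format requires. Identical datasets yield
#' byte-identical files.
#'
#' @param ds An [msi_dataset()].
#' @param path Output path; the `.imzML`/`.ibd` extensions are added or
#'   replaced as needed.
#' @return Invisibly, the two file paths.
#' @export
write_imzml <- function(ds, path) {
  stopifnot(inherits(ds, "msi_dataset"))
  p <- .imzml_paths(path)
  n <- nrow(ds$coords)
  uuid <- .dataset_uuid(ds)
  continuous <- ds$mode == "continuous"

  ibd <- file(p$ibd, "wb")
  ok <- FALSE
  on.exit(if (!ok) {close(ibd); unlink(c(p$ibd, p$xml))}, add = TRUE)
  writeBin(as.raw(strtoi(substring(uuid, seq(1, 31, 2), seq(2, 32, 2)),
                         16L)), ibd)
  offset <- 16
  if (continuous) {
    nax <- length(ds$mz)
    writeBin(ds$mz, ibd, size = 8, endian = "little")
    mz_offsets <- rep(offset, n)
    mz_lengths <- rep(nax, n)
    offset <- offset + 8 * nax
    int_offsets <- offset + 8 * nax * (seq_len(n) - 1)
    int_lengths <- rep(nax, n)
    for (i in seq_len(n)) {
      writeBin(as.numeric(ds$intensity[i, ]), ibd, size = 8,
               endian = "little")
    }
  } else {
    mz_offsets <- int_offsets <- numeric(n)
    mz_lengths <- int_lengths <- integer(n)
    for (i in seq_len(n)) {
      mz_offsets[i] <- offset
      mz_lengths[i] <- length(ds$mz[[i]])
      writeBin(as.numeric(ds$mz[[i]]), ibd, size = 8, endian = "little")
      offset <- offset + 8 * mz_lengths[i]
      int_offsets[i] <- offset
      int_lengths[i] <- length(ds$intensity[[i]])
      writeBin(as.numeric(ds$intensity[[i]]), ibd, size = 8,
               endian = "little")
      offset <- offset + 8 * int_lengths[i]
    }
  }
  close(ibd)
  ok <- TRUE
  ibd_md5 <- unname(tools::md5sum(p$ibd))

  mode_cv <- if (continuous) {
    '<cvParam cvRef="IMS" accession="IMS:1000030" name="continuous" value=""/>'
  } else {
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed" value=""/>'
  }
  head <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '  <cvList count="3">',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '    <cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '    <cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '  </cvList>',
    '  <fileDescription>',
    '    <fileContent>',
    '      <cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum" value=""/>',
    paste0('      ', mode_cv),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>', uuid),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000090" name="ibd MD5" value="%s"/>', toupper(ibd_md5)),
    '    </fileContent>',
    '  </fileDescription>',
    '  <referenceableParamGroupList count="2">',
    '    <referenceableParamGroup id="mzArray">',
    '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '    </referenceableParamGroup>',
    '    <referenceableParamGroup id="intensityArray">',
    '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '    </referenceableParamGroup>',
    '  </referenceableParamGroupList>',
    '  <softwareList count="1">',
    '    <software id="osteomsi" version="0.1.0">',
    '      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="osteomsi"/>',
    '    </software>',
    '  </softwareList>',
    '  <scanSettingsList count="1">',
    '    <scanSettings id="scanSettings1">',
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>', max(ds$coords$x) + 1L),
    sprintf('      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>', max(ds$coords$y) + 1L),
    '    </scanSettings>',
    '  </scanSettingsList>',
    '  <instrumentConfigurationList count="1">',
    '    <instrumentConfiguration id="IC1"/>',
    '  </instrumentConfigurationList>',
    '  <dataProcessingList count="1">',
    '    <dataProcessing id="export">',
    '      <processingMethod order="1" softwareRef="osteomsi">',
    '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '      </processingMethod>',
    '    </dataProcessing>',
    '  </dataProcessingList>',
    '  <run defaultInstrumentConfigurationRef="IC1" id="run1">',
    sprintf('    <spectrumList count="%d" defaultDataProcessingRef="export">', n)
  )
  spec_block <- sprintf(paste0(
    '      <spectrum index="%d" id="spectrum=%d" defaultArrayLength="0">\n',
    '        <scanList count="1">\n',
    '          <cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>\n',
    '          <scan>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n',
    '          </scan>\n',
    '        </scanList>\n',
    '        <binaryDataArrayList count="2">\n',
    '          <binaryDataArray encodedLength="0">\n',
    '            <referenceableParamGroupRef ref="mzArray"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
    '            <binary/>\n',
    '          </binaryDataArray>\n',
    '          <binaryDataArray encodedLength="0">\n',
    '            <referenceableParamGroupRef ref="intensityArray"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>\n',
    '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
    '            <binary/>\n',
    '          </binaryDataArray>\n',
    '        </binaryDataArrayList>\n',
    '      </spectrum>'),
    seq_len(n) - 1L, seq_len(n), ds$coords$x + 1L, ds$coords$y + 1L,
    mz_lengths, 8 * mz_lengths, mz_offsets,
    int_lengths, 8 * int_lengths, int_offsets)
  tail <- c('    </spectrumList>', '  </run>', '</mzML>')
  con <- file(p$xml, "wb")
  writeLines(c(head, spec_block, tail), con, useBytes = TRUE)
  close(con)
  invisible(p)
}

# Namespace-agnostic XPath (imzML files may or may not declare the mzML
# default namespace); avoids the cost of stripping namespaces node by node.
.xp <- function(doc, path) {
  path <- gsub("/(?=[A-Za-z])", "/*[local-name()='", path, perl = TRUE)
  path <- gsub("(\\w)(/|\\[@|$)", "\\1']\\2", path, perl = TRUE)
  xml2::xml_find_all(doc, path)
}

#' Read an imzML dataset
#'
#' Supports continuous and processed mode, 32- and 64-bit float arrays,
#' uncompressed external binary data. Pixel coordinates are converted from
#' the format's 1-based convention to 0-based and spectra are returned in
#' canonical (y, x) order regardless of on-disk order.
#'
#' @param path Path to the `.imzML` file (the `.ibd` must sit next to it).
#' @return An [msi_dataset()].
#' @export
read_imzml <- function(path) {
  p <- .imzml_paths(path)
  if (!file.exists(p$xml)) stop("imzML file not found: ", p$xml)
  if (!file.exists(p$ibd)) stop("binary ibd file not found: ", p$ibd)
  doc <- xml2::read_xml(p$xml)

  mode <- if (length(.xp(doc, "//fileContent/cvParam[@accession='IMS:1000030']"))) {
    "continuous"
  } else if (length(.xp(doc, "//fileContent/cvParam[@accession='IMS:1000031']"))) {
    "processed"
  } else {
    stop("imzML lacks a continuous/processed mode declaration")
  }

  # Byte width of each array type from its referenceable param group.
  width_of <- function(group_id) {
    g <- .xp(doc, sprintf("//referenceableParamGroup[@id='%s']", group_id))
    if (length(.xp(g[[1]], ".//cvParam[@accession='MS:1000523']"))) 8L
    else if (length(.xp(g[[1]], ".//cvParam[@accession='MS:1000521']"))) 4L
    else stop("unsupported binary data type in group ", group_id)
  }
  widths <- c(mzArray = width_of("mzArray"),
              intensityArray = width_of("intensityArray"))

  num_attr <- function(path) {
    as.numeric(xml2::xml_attr(.xp(doc, path), "value"))
  }
  px <- num_attr("//spectrum/scanList/scan/cvParam[@accession='IMS:1000050']")
  py <- num_attr("//spectrum/scanList/scan/cvParam[@accession='IMS:1000051']")
  n <- length(px)
  if (n == 0L) stop("imzML contains no spectra")

  refs <- xml2::xml_attr(
    .xp(doc, "//binaryDataArray/referenceableParamGroupRef"), "ref")
  offs <- num_attr("//binaryDataArray/cvParam[@accession='IMS:1000102']")
  lens <- num_attr("//binaryDataArray/cvParam[@accession='IMS:1000103']")
  if (length(refs) != 2L * n || length(offs) != 2L * n ||
      length(lens) != 2L * n) {
    stop("malformed imzML: binary array metadata incomplete")
  }
  is_mz <- refs == "mzArray"
  mz_off <- offs[is_mz]; mz_len <- lens[is_mz]
  int_off <- offs[!is_mz]; int_len <- lens[!is_mz]

  ibd_size <- file.size(p$ibd)
  need <- max(c(mz_off + mz_len * widths[["mzArray"]],
                int_off + int_len * widths[["intensityArray"]]))
  if (ibd_size < need) {
    stop(sprintf("ibd file truncated: need %d bytes, have %d (first missing byte offset %d)",
                 as.integer(need), as.integer(ibd_size),
                 as.integer(ibd_size)))
  }

  con <- file(p$ibd, "rb")
  on.exit(close(con))
  read_arr <- function(off, len, width) {
    seek(con, where = off, origin = "start")
    readBin(con, what = "numeric", n = len, size = width, endian = "little")
  }

  coords <- data.frame(x = as.integer(px) - 1L, y = as.integer(py) - 1L)
  if (mode == "continuous") {
    mz <- read_arr(mz_off[1], mz_len[1], widths[["mzArray"]])
    if (any(diff(mz) <= 0)) stop("format error: m/z axis not strictly increasing")
    intensity <- matrix(0, nrow = n, ncol = mz_len[1])
    for (i in seq_len(n)) {
      intensity[i, ] <- read_arr(int_off[i], int_len[i],
                                 widths[["intensityArray"]])
    }
    ds <- msi_dataset(coords, mz, intensity, mode = "continuous")
  } else {
    mzl <- vector("list", n)
    il <- vector("list", n)
    for (i in seq_len(n)) {
      mzl[[i]] <- read_arr(mz_off[i], mz_len[i], widths[["mzArray"]])
      if (any(diff(mzl[[i]]) <= 0)) {
        stop("format error: m/z axis not strictly increasing at pixel ", i)
      }
      il[[i]] <- read_arr(int_off[i], int_len[i], widths[["intensityArray"]])
    }
    ds <- msi_dataset(coords, mzl, il, mode = "processed")
  }
  sort_pixels(ds)
}
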