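# imzML and ROI mask input/output.

test_that("imzML write/read round-trips are bit-exact in 64-bit", {
  for (make in list(tiny_continuous, tiny_processed)) {
    ds <- make()
    path <- tempfile()
    write_imzml(ds, path)
    back <- read_imzml(paste0(path, ".imzML"))
    expect_identical(back$mode, ds$mode)
    expect_equal(back$coords, ds$coords)
    if (ds$mode == "continuous") {
      expect_identical(back$mz, as.numeric(ds$mz))
      expect_identical(unname(back$intensity), unname(ds$intensity))
    } else {
      expect_identical(back$mz, lapply(ds$mz, as.numeric))
      expect_identical(back$intensity, lapply(ds$intensity, as.numeric))
    }
  }
})

test_that("1-based file coordinates become 0-based internal coordinates", {
  ds <- msi_dataset(data.frame(x = 0L, y = 0L), mz = c(1, 2),
                    intensity = matrix(c(5, 6), 1), mode = "continuous")
  path <- tempfile()
  write_imzml(ds, path)
  xml <- readLines(paste0(path, ".imzML"))
  expect_true(any(grepl('IMS:1000050" name="position x" value="1"', xml)))
  back <- read_imzml(paste0(path, ".imzML"))
  expect_equal(back$coords, data.frame(x = 0L, y = 0L))
})

test_that("reading is independent of on-disk pixel order", {
  ds <- tiny_continuous()
  shuffled <- ds
  ord <- c(5, 3, 9, 1, 7, 2, 8, 4, 6)
  shuffled$coords <- ds$coords[ord, ]
  shuffled$intensity <- ds$intensity[ord, ]
  p1 <- tempfile(); p2 <- tempfile()
  write_imzml(ds, p1)
  write_imzml(shuffled, p2)
  a <- read_imzml(paste0(p1, ".imzML"))
  b <- read_imzml(paste0(p2, ".imzML"))
  expect_equal(a$coords, b$coords)
  expect_equal(a$intensity, b$intensity)
})

test_that("a truncated ibd is rejected with the missing byte offset named", {
  ds <- tiny_continuous()
  path <- tempfile()
  p <- write_imzml(ds, path)
  size <- file.size(p$ibd)
  raw <- readBin(p$ibd, "raw", size)
  writeBin(raw[1:(size - 100)], p$ibd)
  expect_error(read_imzml(p$xml), "truncated.*offset")
})

test_that("invalid datasets and missing files are rejected", {
  expect_error(msi_dataset(data.frame(x = c(0L, 0L), y = c(0L, 0L)),
                           mz = c(1, 2),
                           intensity = matrix(1, 2, 2),
                           mode = "continuous"),
               "duplicate")
  expect_error(msi_dataset(data.frame(x = 0L, y = 0L), mz = c(2, 1),
                           intensity = matrix(1, 1, 2),
                           mode = "continuous"),
               "increasing")
  expect_error(msi_dataset(data.frame(x = integer(0), y = integer(0)),
                           mz = c(1, 2), intensity = matrix(0, 0, 2),
                           mode = "continuous"),
               "no pixels")
  expect_error(read_imzml(tempfile(fileext = ".imzML")), "not found")
})

test_that("pyimzML (independent reader) parses our continuous files", {
  man <- small_manifest()
  py <- sprintf("
import sys
from pyimzml.ImzMLParser import ImzMLParser
p = ImzMLParser(%s)
mz, ii = p.getspectrum(0)
print(len(p.coordinates), len(mz), '%%.6f' %% mz[0], '%%.6f' %% sum(ii[:5]))
", shQuote(man$imzml[1]))
  out <- tryCatch(system2("python", c("-c", shQuote(py)), stdout = TRUE,
                          stderr = FALSE),
                  warning = function(w) character(0),
                  error = function(e) character(0))
  # if python/pyimzML is unavailable the check is vacuous, not a failure
  if (length(out) == 1) {
    ds <- read_imzml(man$imzml[1])
    parts <- strsplit(out, " ")[[1]]
    expect_equal(as.integer(parts[1]), n_pixels(ds))
    expect_equal(as.integer(parts[2]), length(ds$mz))
    expect_equal(as.numeric(parts[3]), ds$mz[1], tolerance = 1e-6)
  } else {
    succeed("pyimzML not available for the cross-check")
  }
})

test_that("ROI masks round-trip through TSV and PNG to the same mask", {
  man <- small_manifest()
  ds <- read_imzml(man$imzml[1])
  m_tsv <- read_roi_mask(man$mask_tsv[1], ds)
  m_png <- read_roi_mask(man$mask_png[1], ds)
  expect_identical(m_tsv$grid, m_png$grid)
  expect_identical(mask_labels(m_tsv, ds$coords),
                   mask_labels(m_png, ds$coords))
})

test_that("mask validation catches bad labels and oversize grids", {
  ds <- tiny_continuous()
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(x = 0L, y = 0L, label = "cartilage"), tsv,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_roi_mask(tsv, ds), "outside vocabulary")
  write.table(data.frame(x = 10L, y = 10L, label = "osteoid"), tsv,
              sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_roi_mask(tsv, ds), "larger than")
  # all-background mask: no labelled pixels, still valid
  write.table(data.frame(x = integer(0), y = integer(0),
                         label = character(0)), tsv,
              sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_roi_mask(tsv, ds)
  expect_true(all(mask_labels(m, ds$coords) == "background"))
})
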