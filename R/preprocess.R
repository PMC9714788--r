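# Spectrum preprocessing: RMS normalization, mean spectra, robust noise
# estimation, peak picking on the overall mean spectrum, and construction of
# the pixels x peaks data cube.

#' Root-mean-square normalize every spectrum
#'
#' Divides each pixel's intensity vector by its root-mean-square value so
#' that every output spectrum has RMS 1. All-zero spectra are left unchanged
#' with a warning.
#'
#' @param ds An [msi_dataset()].
#' @return Normalized dataset.
#' @export
rms_normalize <- function(ds) {
  stopifnot(inherits(ds, "msi_dataset"))
  if (ds$mode == "continuous") {
    rms <- sqrt(rowMeans(ds$intensity^2))
    zero <- rms == 0
    if (any(zero)) {
      warning(sum(zero), " all-zero spectrum/spectra left unnormalized")
      rms[zero] <- 1
    }
    ds$intensity <- ds$intensity / rms
  } else {
    zero <- 0L
    ds$intensity <- lapply(ds$intensity, function(v) {
      rms <- sqrt(mean(v^2))
      if (rms == 0) {
        zero <<- zero + 1L
        v
      } else {
        v / rms
      }
    })
    if (zero > 0L) {
      warning(zero, " all-zero spectrum/spectra left unnormalized")
    }
  }
  ds
}

.select_pixels <- function(ds, mask, labels) {
  if (is.null(mask)) return(seq_len(nrow(ds$coords)))
  lab <- mask_labels(mask, ds$coords)
  if (is.null(labels)) labels <- setdiff(mask$vocabulary, mask$vocabulary[1])
  which(lab %in% labels)
}

#' Mean spectrum over selected pixels
#'
#' Arithmetic mean of the spectra of all pixels selected by the optional ROI
#' mask. Processed-mode spectra are first resampled to a common axis by
#' linear interpolation at a fixed bin width.
#'
#' @param ds An [msi_dataset()].
#' @param mask Optional [roi_mask()]; with no mask all pixels are used.
#' @param labels Labels selecting pixels from the mask (default: every
#'   non-background label).
#' @param bin_width Resampling bin width in Da for processed mode.
#' @return List with `mz` and `intensity` vectors.
#' @export
mean_spectrum <- function(ds, mask = NULL, labels = NULL, bin_width = 0.01) {
  stopifnot(inherits(ds, "msi_dataset"))
  sel <- .select_pixels(ds, mask, labels)
  if (length(sel) == 0L) stop("no pixels selected (empty ROI)")
  if (ds$mode == "continuous") {
    list(mz = ds$mz,
         intensity = colMeans(ds$intensity[sel, , drop = FALSE]))
  } else {
    lo <- min(vapply(ds$mz[sel], min, numeric(1)))
    hi <- max(vapply(ds$mz[sel], max, numeric(1)))
    axis <- seq(lo, hi, by = bin_width)
    acc <- numeric(length(axis))
    for (i in sel) {
      acc <- acc + stats::approx(ds$mz[[i]], ds$intensity[[i]], xout = axis,
                                 yleft = 0, yright = 0)$y
    }
    list(mz = axis, intensity = acc / length(sel))
  }
}

#' Robust per-bin noise level of a spectrum
#'
#' Sliding-window median absolute deviation about the local median, scaled
#' by 1.4826 for consistency with the Gaussian standard deviation. Robust to
#' isolated peaks in the window.
#'
#' @param mz Ascending m/z axis.
#' @param intensity Intensity vector.
#' @param window Window width in Da (> 0; must exceed the local bin spacing).
#' @return Numeric vector of noise levels, one per bin.
#' @export
estimate_noise <- function(mz, intensity, window = 1) {
  if (window <= 0) stop("window must be > 0")
  n <- length(mz)
  stopifnot(length(intensity) == n)
  if (n > 1L && window < min(diff(mz))) {
    stop("window smaller than the bin spacing")
  }
  half <- window / 2
  lo <- findInterval(mz - half, mz, left.open = TRUE) + 1L
  hi <- findInterval(mz + half, mz)
  vapply(seq_len(n), function(i) {
    w <- intensity[lo[i]:hi[i]]
    med <- stats::median(w)
    1.4826 * stats::median(abs(w - med))
  }, numeric(1))
}

# Local median companion to estimate_noise (baseline level per bin).
.local_median <- function(mz, intensity, window = 1) {
  half <- window / 2
  lo <- findInterval(mz - half, mz, left.open = TRUE) + 1L
  hi <- findInterval(mz + half, mz)
  vapply(seq_along(mz), function(i) {
    stats::median(intensity[lo[i]:hi[i]])
  }, numeric(1))
}

#' Pick peaks from a mean spectrum
#'
#' Local maxima whose baseline-subtracted apex exceeds `snr_threshold` times
#' the local noise level. Noise is the windowed MAD of [estimate_noise()];
#' baseline is the local median over the same window. The peak center is the
#' apex m/z (no centroid fitting).
#'
#' @param mean_spec List with `mz` and `intensity` (see [mean_spectrum()]).
#' @param snr_threshold Minimal signal-to-noise ratio (default 3).
#' @param window Noise/baseline window in Da.
#' @return Data frame (class `peak_list`) with columns `mz`, `snr`,
#'   `intensity`, ordered by m/z; may be empty.
#' @export
pick_peaks <- function(mean_spec, snr_threshold = 3, window = 1) {
  mz <- mean_spec$mz
  y <- mean_spec$intensity
  n <- length(y)
  if (n < 3L) {
    return(structure(data.frame(mz = numeric(0), snr = numeric(0),
                                intensity = numeric(0)),
                     class = c("peak_list", "data.frame")))
  }
  apex <- which(y[-c(1L, n)] > y[-c(n - 1L, n)] &
                  y[-c(1L, n)] > y[-c(1L, 2L)]) + 1L
  if (length(apex) == 0L) {
    return(structure(data.frame(mz = numeric(0), snr = numeric(0),
                                intensity = numeric(0)),
                     class = c("peak_list", "data.frame")))
  }
  noise <- estimate_noise(mz, y, window)
  base <- .local_median(mz, y, window)
  excess <- y[apex] - base[apex]
  nz <- noise[apex]
  snr <- ifelse(nz > 0, excess / nz, ifelse(excess > 0, Inf, 0))
  keep <- snr >= snr_threshold
  out <- data.frame(mz = mz[apex][keep], snr = snr[keep],
                    intensity = y[apex][keep])
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("peak_list", "data.frame"))
}

# Per-pixel local medians of the spectra around each peak center
# (pixels x peaks). The same window serves every pixel in continuous mode.
.window_medians <- function(axis, rows, centers, window) {
  half <- window / 2
  lo <- findInterval(centers - half, axis, left.open = TRUE) + 1L
  hi <- findInterval(centers + half, axis)
  out <- matrix(0, nrow(rows), length(centers))
  for (j in seq_along(centers)) {
    if (hi[j] >= lo[j]) {
      out[, j] <- matrixStats::rowMedians(rows, cols = lo[j]:hi[j])
    }
  }
  out
}

# Assign every axis point to the nearest peak center, kept only inside the
# center's half-open ppm window [c(1-tol), c(1+tol)). Overlaps resolve to
# the nearest center.
.axis_peak_assignment <- function(axis, centers, tol_ppm) {
  k <- length(centers)
  # findInterval gives the left neighbor; choose the nearer of left/right.
  left <- pmax(findInterval(axis, centers), 1L)
  right <- pmin(left + 1L, k)
  nearest <- ifelse(abs(axis - centers[left]) <= abs(axis - centers[right]),
                    left, right)
  lo <- centers[nearest] * (1 - tol_ppm * 1e-6)
  hi <- centers[nearest] * (1 + tol_ppm * 1e-6)
  inside <- axis >= lo & axis < hi
  list(peak = ifelse(inside, nearest, NA_integer_), inside = inside)
}

#' Build the pixels x peaks data cube
#'
#' Each entry is the aggregate (sum by default, optionally max) of a pixel's
#' intensities within the peak's +-`tol_ppm` window, half-open at the upper
#' edge. Axis points falling into two overlapping windows are assigned to
#' the nearest center (a message reports how many).
#'
#' @param ds An [msi_dataset()].
#' @param peaks A `peak_list` from [pick_peaks()] (or any data frame with an
#'   `mz` column of strictly increasing centers).
#' @param tol_ppm Extraction half-window in ppm (default 4, matching the
#'   annotation tolerance).
#' @param agg `"sum"` (default) or `"max"`.
#' @param baseline `"none"` (default: raw windowed aggregate) or `"median"`:
#'   subtract, per pixel and peak, the local median of the spectrum within
#'   `baseline_window` around the center before aggregating (floored at
#'   zero). Median subtraction removes additive chemical baseline without
#'   disturbing between-group intensity ratios.
#' @param baseline_window Window (Da) of the local-median baseline.
#' @return Object of class `msi_datacube`: list with `intensity`
#'   (n_pixels x n_peaks matrix), `coords`, `peak_mz`.
#' @export
build_datacube <- function(ds, peaks, tol_ppm = 4, agg = c("sum", "max"),
                           baseline = c("none", "median"),
                           baseline_window = 1) {
  stopifnot(inherits(ds, "msi_dataset"))
  agg <- match.arg(agg)
  baseline <- match.arg(baseline)
  if (tol_ppm <= 0) stop("tol_ppm must be > 0")
  centers <- peaks$mz
  if (length(centers) == 0L) stop("empty peak list")
  if (any(diff(centers) <= 0)) stop("peak centers must be strictly increasing")
  k <- length(centers)

  cube_for <- function(axis, rows) {
    asn <- .axis_peak_assignment(axis, centers, tol_ppm)
    # overlap diagnostic: points also inside the neighboring center's window
    if (k > 1L) {
      other <- ifelse(axis > centers[pmax(asn$peak, 1L)],
                      asn$peak + 1L, asn$peak - 1L)
      valid <- asn$inside & !is.na(other) & other >= 1L & other <= k
      oc <- centers[pmin(pmax(other, 1L), k)]
      amb <- sum(valid & abs(axis - oc) < oc * tol_ppm * 1e-6)
      if (amb > 0) {
        message(amb, " axis point(s) in overlapping windows assigned to nearest center")
      }
    }
    sel <- which(asn$inside)
    if (agg == "sum") {
      s <- Matrix::sparseMatrix(i = sel, j = asn$peak[sel],
                                x = 1, dims = c(length(axis), k))
      as.matrix(rows %*% s)
    } else {
      out <- matrix(0, nrow(rows), k)
      for (j in seq_len(k)) {
        cols <- sel[asn$peak[sel] == j]
        if (length(cols)) {
          out[, j] <- apply(rows[, cols, drop = FALSE], 1, max)
        }
      }
      out
    }
  }

  if (ds$mode == "continuous") {
    cube <- cube_for(ds$mz, ds$intensity)
    if (baseline == "median") {
      cube <- pmax(cube - .window_medians(ds$mz, ds$intensity, centers,
                                          baseline_window), 0)
    }
  } else {
    cube <- matrix(0, nrow(ds$coords), k)
    for (i in seq_len(nrow(ds$coords))) {
      row <- cube_for(ds$mz[[i]], matrix(ds$intensity[[i]], nrow = 1))
      if (baseline == "median") {
        row <- pmax(row - .window_medians(ds$mz[[i]],
                                          matrix(ds$intensity[[i]],
                                                 nrow = 1),
                                          centers, baseline_window), 0)
      }
      cube[i, ] <- row
    }
  }
  structure(list(intensity = cube, coords = ds$coords, peak_mz = centers),
            class = "msi_datacube")
}

#' @export
print.msi_datacube <- function(x, ...) {
  cat(sprintf("<msi_datacube> %d pixels x %d peaks\n",
              nrow(x$intensity), ncol(x$intensity)))
  invisible(x)
}

#' Extract one ion image from a data cube
#'
#' @param cube An `msi_datacube`.
#' @param peak Peak index.
#' @return Numeric matrix (rows = y, cols = x) with NA off-grid.
#' @export
ion_image <- function(cube, peak) {
  img <- matrix(NA_real_, max(cube$coords$y) + 1L, max(cube$coords$x) + 1L)
  img[cbind(cube$coords$y + 1L, cube$coords$x + 1L)] <- cube$intensity[, peak]
  img
}
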