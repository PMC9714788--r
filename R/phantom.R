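# Ground-truthed synthetic bone-phantom MSI generator.
#
# The phantom emulates a femoral cross-section on a 2-D pixel grid (50 um
# notional spacing): a mineralized cortical ring, an inner osteoid seam, a
# bone marrow core and off-tissue background, imaged over m/z 75-1100 in
# negative mode. Two genotype-like groups of sections carry planted
# multiplicative effects on selected peaks; pixel noise is multiplicative
# log-normal; spectra are synthesized as Gaussian peaks at exact adduct m/z
# (with a small calibration jitter) over a sparse axis plus rectified
# baseline noise.

# Deterministic sub-seed so that standalone and pipeline calls agree.
.substream <- function(seed, tag) {
  (as.numeric(seed) * 69091 + tag) %% 2147483647
}

#' Specify a synthetic bone phantom
#'
#' Defaults define the package's reference scenario: 64 x 64 pixels, ~300
#' planted metabolite peaks, 2 groups x 5 sections, log-normal pixel noise
#' with 20% CV, 20 planted up- and 15 down-regulated peaks at |log2FC| = 3.
#'
#' Base intensities cycle through `base_cycle`, spanning two orders of
#' magnitude the way real MSI spectra are dominated by a stable tier of
#' strong ions; planted-effect peaks sit at the fixed mid-range
#' `effect_base` so the normalization backbone is carried by unaffected
#' peaks. Off-tissue pixels carry strong matrix-cluster ions (plus the
#' 9-aminoacridine matrix peak at m/z 193.0771), as MALDI background
#' spectra do. The additive baseline combines a per-section chemical-noise
#' pattern shared by the section's pixels (so mean spectra keep realistic
#' roughness) with per-pixel white noise, both rectified at zero.
#'
#' @param nrow,ncol Grid size in pixels.
#' @param outer_radius Outer radius of the mineralized cortical ring (px).
#' @param ring_width Width of the mineralized ring (px).
#' @param seam_width Width of the osteoid seam (px, >= 1).
#' @param n_per_group Sections per group.
#' @param groups Two group tags (first = reference, e.g. wild-type-like).
#' @param n_peaks Number of metabolite-derived peaks to plant.
#' @param base_cycle Home-compartment base intensities (a.u.) cycled over
#'   the planted peaks.
#' @param effect_base Home base intensity of the planted-effect peaks.
#' @param off_ratio,bg_ratio Intensity of a peak outside its home
#'   compartment / on background pixels, as a fraction of its home base.
#' @param matrix_base Background base intensity of the 9-AA matrix ion.
#' @param cluster_bases Base intensities cycled over the matrix-cluster
#'   ions (background-home pseudo-peaks).
#' @param n_clusters Number of matrix-cluster ions.
#' @param matrix_tissue_ratio Fraction of a matrix ion's base seen on
#'   tissue pixels (matrix suppression).
#' @param cv Per-pixel multiplicative log-normal noise CV (>= 0).
#' @param n_up,n_down Planted up-/down-regulated peak counts.
#' @param effect_log2 Planted |log2 fold change| (group 2 vs group 1).
#' @param sigma_ppm Gaussian peak width sigma in ppm of the center m/z.
#' @param jitter_ppm Calibration jitter bound (<= 1 ppm; one draw per peak).
#' @param baseline_sd Chemical-noise baseline sigma (shared pattern).
#' @param white_sd Per-pixel white baseline noise sigma.
#' @param axis_step Baseline m/z grid step (Da).
#' @param mz_range Acquired m/z range.
#' @param min_peak_spacing Minimal spacing between planted peak centers (Da).
#' @param seed Master seed; everything the generator draws derives from it.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(nrow = 64, ncol = 64, outer_radius = 28,
                         ring_width = 6, seam_width = 3, n_per_group = 5,
                         groups = c("WT", "Hyp"), n_peaks = 300,
                         base_cycle = c(3, 5, 8, 12, 20, 40, 80, 150, 300, 500),
                         effect_base = 20, off_ratio = 0.3,
                         bg_ratio = 0.005, matrix_base = 800,
                         cluster_bases = c(150, 300, 600, 1000),
                         n_clusters = 12, matrix_tissue_ratio = 0.2,
                         cv = 0.2, n_up = 20, n_down = 15, effect_log2 = 3,
                         sigma_ppm = 8, jitter_ppm = 0.5, baseline_sd = 0.3,
                         white_sd = 0.1, axis_step = 0.5,
                         mz_range = c(75, 1100),
                         min_peak_spacing = 0.5, seed = 1L) {
  if (seam_width < 1) stop("seam width must be >= 1")
  if (ring_width < 1) stop("ring width must be >= 1")
  if (cv < 0) stop("noise CV must be >= 0")
  if (!is.finite(effect_log2)) stop("effects must be finite")
  if (outer_radius >= min(nrow, ncol) / 2) {
    stop("geometry overflow: outer radius does not fit the grid")
  }
  if (outer_radius - ring_width - seam_width <= 1) {
    stop("geometry overflow: no room for the marrow core")
  }
  if (length(groups) != 2L) stop("exactly two groups")
  if (jitter_ppm > 1) stop("calibration jitter must be <= 1 ppm")
  structure(as.list(environment()), class = "phantom_spec")
}

.disc_labels <- function(spec, cx, cy, r_outer, r_seam, r_marrow) {
  xs <- matrix(rep(seq_len(spec$ncol) - 1L, each = spec$nrow),
               spec$nrow, spec$ncol)
  ys <- matrix(rep(seq_len(spec$nrow) - 1L, times = spec$ncol),
               spec$nrow, spec$ncol)
  d <- sqrt((xs - cx)^2 + (ys - cy)^2)
  grid <- matrix(1L, spec$nrow, spec$ncol)          # background
  grid[d < r_outer] <- 2L                           # mineralized ring
  grid[d < r_seam] <- 3L                            # osteoid seam
  grid[d < r_marrow] <- 4L                          # marrow core
  grid
}

#' Generate the per-section compartment masks of a phantom
#'
#' Concentric geometry (mineralized ring, osteoid seam, marrow core,
#' background outside) with a small seeded per-section perturbation of the
#' center and radii, emulating section-to-section variation.
#'
#' @param spec A [phantom_spec()].
#' @return List of [roi_mask()], one per section, in group order (all group
#'   1 sections first).
#' @export
generate_phantom_masks <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_sections <- 2L * spec$n_per_group
  lapply(seq_len(n_sections), function(i) {
    set.seed(.substream(spec$seed, i))
    cx <- (spec$ncol - 1) / 2 + stats::runif(1, -1, 1)
    cy <- (spec$nrow - 1) / 2 + stats::runif(1, -1, 1)
    dr <- stats::runif(1, -0.5, 0.5)
    r_outer <- spec$outer_radius + dr
    r_seam <- r_outer - spec$ring_width
    r_marrow <- r_seam - spec$seam_width
    grid <- .disc_labels(spec, cx, cy, r_outer, r_seam, r_marrow)
    grp <- if (i <= spec$n_per_group) spec$groups[1] else spec$groups[2]
    k <- if (i <= spec$n_per_group) i else i - spec$n_per_group
    roi_mask(grid, bone_vocabulary(), group = grp,
             section_id = sprintf("%s_%d", grp, k))
  })
}

#' Select the planted peaks of a phantom from the reference table
#'
#' Expands endogenous records by the five adducts, keeps candidates inside
#' the m/z range with a margin, and greedily selects `n_peaks` centers at
#' least `min_peak_spacing` apart (also clear of the matrix ion). Home
#' compartments cycle through mineralized bone, osteoid and marrow, home
#' base intensities cycle through `spec$base_cycle`; the first `n_up`
#' cortical-home peaks get the planted up effect and the next `n_down` the
#' down effect (their base is pinned to `spec$effect_base`). The
#' 9-aminoacridine matrix ion and `n_clusters` matrix-cluster ions are
#' appended as background-home peaks with no effect.
#'
#' @param spec A [phantom_spec()].
#' @param db Metabolite table from [load_metabolite_db()].
#' @return Data frame: `id`, `name`, `adduct`, `mz`, `home`, `base`,
#'   `effect_log2`.
#' @export
build_phantom_peaks <- function(spec, db) {
  cand <- adduct_table(db[db$endogenous, , drop = FALSE])
  lo <- spec$mz_range[1] + 2
  hi <- spec$mz_range[2] - 5
  cand <- cand[cand$mz >= lo & cand$mz <= hi, , drop = FALSE]
  matrix_mz <- adduct_mz(neutral_mass("C13H10N2"), "M-H")
  keep <- abs(cand$mz - matrix_mz) > spec$min_peak_spacing
  cand <- cand[keep, , drop = FALSE]
  sel <- integer(0)
  last <- -Inf
  for (i in seq_len(nrow(cand))) {
    if (cand$mz[i] - last >= spec$min_peak_spacing) {
      sel <- c(sel, i)
      last <- cand$mz[i]
      if (length(sel) == spec$n_peaks) break
    }
  }
  if (length(sel) < spec$n_peaks) {
    stop("reference table yields only ", length(sel),
         " separable peaks of the requested ", spec$n_peaks)
  }
  peaks <- cand[sel, c("id", "name", "adduct", "mz")]
  homes <- c("mineralized_bone", "osteoid", "bone_marrow")
  peaks$home <- rep_len(homes, nrow(peaks))
  peaks$base <- rep_len(spec$base_cycle, nrow(peaks))
  peaks$effect_log2 <- 0
  cortical <- which(peaks$home %in% c("mineralized_bone", "osteoid"))
  if (length(cortical) < spec$n_up + spec$n_down) {
    stop("not enough cortical-home peaks for the planted effects")
  }
  eff <- cortical[seq_len(spec$n_up + spec$n_down)]
  peaks$effect_log2[eff] <- rep(c(spec$effect_log2, -spec$effect_log2),
                                c(spec$n_up, spec$n_down))
  peaks$base[eff] <- spec$effect_base

  # Matrix ion + matrix-cluster ions, background-home, kept clear of every
  # database adduct m/z.
  all_theo <- adduct_table(db)$mz
  cl_mz <- seq(spec$mz_range[1] + 45, spec$mz_range[2] - 50,
               length.out = spec$n_clusters) + 0.1337
  for (j in seq_along(cl_mz)) {
    while (min(abs(cl_mz[j] - all_theo)) < 0.1 ||
           min(abs(cl_mz[j] - peaks$mz)) < spec$min_peak_spacing) {
      cl_mz[j] <- cl_mz[j] + 0.11
    }
  }
  bg_rows <- data.frame(
    id = c("MATRIX_9AA", sprintf("MATRIX_CLUSTER_%02d",
                                 seq_len(spec$n_clusters))),
    name = c("9-aminoacridine", sprintf("matrix cluster %02d",
                                        seq_len(spec$n_clusters))),
    adduct = "M-H",
    mz = c(matrix_mz, cl_mz),
    home = "background",
    base = c(spec$matrix_base, rep_len(spec$cluster_bases,
                                       spec$n_clusters)),
    effect_log2 = 0)
  peaks <- rbind(peaks, bg_rows)
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

# Base intensity matrix: compartments (vocabulary order) x peaks. Tissue
# peaks show off_ratio of their home base in the other tissue compartments
# and bg_ratio on background; matrix ions show matrix_tissue_ratio of their
# background base on tissue.
.phantom_base <- function(spec, peaks) {
  vocab <- bone_vocabulary()
  tissue <- setdiff(vocab, "background")
  B <- matrix(0, nrow = length(vocab), ncol = nrow(peaks),
              dimnames = list(vocab, NULL))
  is_bg <- peaks$home == "background"
  for (v in tissue) {
    B[v, ] <- ifelse(is_bg, peaks$base * spec$matrix_tissue_ratio,
                     ifelse(peaks$home == v, peaks$base,
                            peaks$base * spec$off_ratio))
  }
  B["background", ] <- ifelse(is_bg, peaks$base,
                              peaks$base * spec$bg_ratio)
  B
}

#' Generate the peak-level ground-truth intensity cubes of a phantom
#'
#' The peak-space ground truth underlying [generate_dataset()]: for every
#' section, a pixels x peaks matrix of expected compartment intensities
#' multiplied by the group effect and per-pixel log-normal noise
#' (mean-one, CV = `spec$cv`). No spectra are synthesized.
#'
#' @param spec A [phantom_spec()].
#' @param db Metabolite table.
#' @return List (`phantom_truth`): `cubes` (list of `msi_datacube`),
#'   `masks`, `peaks`, `groups`, `base` (compartment x peak matrix),
#'   `coords`.
#' @export
generate_intensity_cubes <- function(spec, db) {
  stopifnot(inherits(spec, "phantom_spec"))
  peaks <- build_phantom_peaks(spec, db)
  masks <- generate_phantom_masks(spec)
  B <- .phantom_base(spec, peaks)
  vocab <- bone_vocabulary()
  coords <- data.frame(
    x = rep(seq_len(spec$ncol) - 1L, times = spec$nrow),
    y = rep(seq_len(spec$nrow) - 1L, each = spec$ncol))
  sdlog <- sqrt(log1p(spec$cv^2))
  effect_mult <- 2^peaks$effect_log2
  n_sections <- 2L * spec$n_per_group
  groups <- rep(spec$groups, each = spec$n_per_group)
  cubes <- lapply(seq_len(n_sections), function(i) {
    comp <- match(mask_labels(masks[[i]], coords), vocab)
    mean_mat <- B[comp, , drop = FALSE]
    if (groups[i] == spec$groups[2]) {
      mean_mat <- sweep(mean_mat, 2, effect_mult, "*")
    }
    set.seed(.substream(spec$seed, 100000 + i))
    noise <- matrix(
      stats::rlnorm(length(mean_mat), meanlog = -sdlog^2 / 2, sdlog = sdlog),
      nrow = nrow(mean_mat))
    structure(list(intensity = mean_mat * noise, coords = coords,
                   peak_mz = peaks$mz),
              class = "msi_datacube")
  })
  structure(list(cubes = cubes, masks = masks, peaks = peaks,
                 groups = groups, base = B, coords = coords, spec = spec),
            class = "phantom_truth")
}

# Sparse peak-shape matrix (peaks x axis) for Gaussian peaks sampled at
# sigma offsets -3..3 around the jittered centers.
.phantom_axis <- function(spec, centers) {
  offsets <- -3:3
  sigma <- centers * spec$sigma_ppm * 1e-6
  pts <- as.vector(outer(sigma, offsets) + centers)
  axis <- sort(unique(c(seq(spec$mz_range[1], spec$mz_range[2],
                            by = spec$axis_step), pts)))
  ij <- lapply(seq_along(centers), function(k) {
    cols <- findInterval(centers[k] + offsets * sigma[k], axis)
    vals <- exp(-((axis[cols] - centers[k])^2) / (2 * sigma[k]^2))
    cbind(k, cols, vals)
  })
  ij <- do.call(rbind, ij)
  shapes <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = ij[, 3],
                                 dims = c(length(centers), length(axis)))
  list(axis = axis, shapes = shapes)
}

#' Generate a full synthetic phantom dataset as imzML
#'
#' Synthesizes per-pixel spectra (Gaussian peaks at the planted adduct m/z
#' plus rectified baseline noise on a sparse common axis) from the
#' peak-level ground truth and writes one continuous-mode imzML pair per
#' section, plus mask TSV/PNG files and ground-truth tables. Outputs are
#' byte-identical for identical spec + seed.
#'
#' @param spec A [phantom_spec()].
#' @param db Metabolite table.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a manifest list: `imzml` (paths), `mask_tsv`,
#'   `mask_png`, `groups`, `section_ids`, `truth` (the
#'   [generate_intensity_cubes()] object), `peaks_path`.
#' @export
generate_dataset <- function(spec, db, dir) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_intensity_cubes(spec, db)
  peaks <- truth$peaks

  set.seed(.substream(spec$seed, 900001))
  jitter <- stats::runif(nrow(peaks), -spec$jitter_ppm, spec$jitter_ppm)
  centers <- peaks$mz * (1 + jitter * 1e-6)
  ax <- .phantom_axis(spec, centers)

  n_sections <- length(truth$cubes)
  paths <- character(n_sections)
  mask_tsv <- character(n_sections)
  mask_png <- character(n_sections)
  section_ids <- vapply(truth$masks, function(m) m$section_id, character(1))
  for (i in seq_len(n_sections)) {
    signal <- as.matrix(truth$cubes[[i]]$intensity %*% ax$shapes)
    set.seed(.substream(spec$seed, 200000 + i))
    # Per-section chemical-noise baseline pattern (shared by the section's
    # pixels, independent across sections) plus per-pixel white noise.
    chem <- abs(stats::rnorm(length(ax$axis), 0, spec$baseline_sd))
    white <- abs(matrix(stats::rnorm(length(signal), 0, spec$white_sd),
                        nrow = nrow(signal)))
    ds <- msi_dataset(truth$coords, ax$axis,
                      sweep(signal + white, 2, chem, "+"),
                      mode = "continuous")
    base <- file.path(dir, sprintf("phantom_%s", section_ids[i]))
    write_imzml(ds, base)
    paths[i] <- paste0(base, ".imzML")
    mask_tsv[i] <- paste0(base, "_mask.tsv")
    mask_png[i] <- paste0(base, "_mask.png")
    write_roi_mask(truth$masks[[i]], mask_tsv[i])
    write_roi_mask(truth$masks[[i]], mask_png[i])
  }
  peaks_out <- peaks
  peaks_out$mz_jittered <- centers
  peaks_path <- file.path(dir, "ground_truth_peaks.tsv")
  utils::write.table(peaks_out, peaks_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(imzml = paths, mask_tsv = mask_tsv, mask_png = mask_png,
                 groups = truth$groups, section_ids = section_ids,
                 truth = truth, peaks_path = peaks_path))
}

#' Match picked peaks to the phantom's planted peaks
#'
#' @param picked `peak_list` (picked centers).
#' @param truth_peaks Ground-truth peak table.
#' @param tol_ppm Matching tolerance (default 4 ppm).
#' @return Integer vector, for each truth peak the index of the matching
#'   picked peak (NA if missed).
#' @export
match_planted_peaks <- function(picked, truth_peaks, tol_ppm = 4) {
  vapply(truth_peaks$mz, function(m) {
    d <- abs(ppm_error(picked$mz, m))
    j <- which.min(d)
    if (length(j) && d[j] <= tol_ppm) j else NA_integer_
  }, integer(1))
}
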