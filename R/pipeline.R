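# Config-driven orchestration of the full analysis: imzML input -> RMS
# normalization -> mean-spectrum peak picking -> data cubes -> pLSA/PCA
# segmentation -> annotation -> ROI statistics -> enrichment -> spatial
# correlation network, with logged provenance and deterministic outputs.

#' Assemble and validate a pipeline configuration
#'
#' @param imzml Character vector of section imzML paths.
#' @param masks Character vector of mask paths (TSV or PNG), aligned with
#'   `imzml`.
#' @param groups Group tag per section (two levels; first level is the
#'   reference).
#' @param out_dir Output directory.
#' @param db_path Optional metabolite table path (default: bundled table).
#' @param snr Peak-picking S/N threshold (default 3).
#' @param tol_ppm Annotation/extraction tolerance in ppm (default 4).
#' @param fc_cut Volcano |log2FC| cutoff (default 1).
#' @param alpha Significance level (default 0.05).
#' @param n_components pLSA components incl. background (default 4).
#' @param baseline_window Local-median baseline window (Da) used when
#'   extracting ion images; should span several peak widths but stay below
#'   the typical peak spacing (default 0.3).
#' @param plsa_restarts Seeded EM restarts for the pLSA fits (best final
#'   log-likelihood wins).
#' @param plsa_tol,plsa_max_iter EM convergence tolerance (relative
#'   log-likelihood change) and iteration cap for the pLSA fits. The
#'   pipeline uses a stricter tolerance than the [fit_plsa()] default:
#'   with many pixels the log-likelihood is large and a loose relative
#'   criterion can stop EM before weakly separated components resolve.
#' @param seed RNG seed for the pLSA initialization.
#' @param roi_labels ROI labels for the group statistics (cortical bone).
#' @param vocabulary Mask label vocabulary, background first.
#' @param plsa_section Index of the section segmented with pLSA/PCA
#'   (default: first section of the second group).
#' @return Validated `pipeline_config` list.
#' @export
pipeline_config <- function(imzml, masks, groups, out_dir,
                            db_path = NULL, snr = 3, tol_ppm = 4,
                            fc_cut = 1, alpha = 0.05, n_components = 4,
                            baseline_window = 0.3, plsa_tol = 1e-8,
                            plsa_max_iter = 1000L, plsa_restarts = 5L,
                            seed = 1L,
                            roi_labels = c("mineralized_bone", "osteoid"),
                            vocabulary = bone_vocabulary(),
                            plsa_section = NULL) {
  cfg_err <- function(...) stop("config error: ", ..., call. = FALSE)
  if (length(imzml) < 1L) cfg_err("no imzML inputs")
  if (length(masks) != length(imzml)) cfg_err("one mask per imzML required")
  if (length(groups) != length(imzml)) cfg_err("one group tag per section")
  for (f in imzml) {
    p <- .imzml_paths(f)
    if (!file.exists(p$xml)) cfg_err("missing imzML file: ", p$xml)
    if (!file.exists(p$ibd)) cfg_err("missing ibd file: ", p$ibd)
  }
  for (f in masks) if (!file.exists(f)) cfg_err("missing mask file: ", f)
  if (!is.null(db_path) && !file.exists(db_path)) {
    cfg_err("missing metabolite table: ", db_path)
  }
  if (snr <= 0) cfg_err("snr must be > 0")
  if (tol_ppm <= 0) cfg_err("tol_ppm must be > 0")
  if (fc_cut < 0) cfg_err("fc_cut must be >= 0")
  if (alpha <= 0 || alpha >= 1) cfg_err("alpha must lie in (0, 1)")
  if (n_components < 2) cfg_err("n_components must be >= 2")
  if (baseline_window <= 0) cfg_err("baseline_window must be > 0")
  if (plsa_tol <= 0) cfg_err("plsa_tol must be > 0")
  if (length(unique(groups)) != 2L) cfg_err("exactly two groups required")
  if (is.null(plsa_section)) {
    plsa_section <- which(groups == unique(groups)[2])[1]
  }
  structure(list(imzml = imzml, masks = masks, groups = groups,
                 out_dir = out_dir, db_path = db_path, snr = snr,
                 tol_ppm = tol_ppm, fc_cut = fc_cut, alpha = alpha,
                 n_components = n_components,
                 baseline_window = baseline_window, plsa_tol = plsa_tol,
                 plsa_max_iter = as.integer(plsa_max_iter),
                 plsa_restarts = as.integer(plsa_restarts),
                 seed = as.integer(seed),
                 roi_labels = roi_labels, vocabulary = vocabulary,
                 plsa_section = plsa_section),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return Validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(unclass(config)), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

# Every exported table carries a header row and the config hash in a
# comment line.
.write_table <- function(df, path, hash) {
  con <- file(path, "wb")
  writeLines(sprintf("# osteomsi config %s", hash), con, useBytes = TRUE)
  close(con)
  suppressWarnings(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) read + RMS-normalize all sections and accumulate the overall
#' mean spectrum; (2) pick peaks (S/N threshold) on the mean spectrum; (3)
#' build per-section data cubes at the ppm tolerance; (4) pLSA segmentation
#' of one section (background identified from its mask, peaks assigned to
#' components) plus PCA, and a group-level pLSA on per-section ROI mean
#' intensities; (5) adduct-aware metabolite and glycan annotation with
#' exogenous filtering; (6) ROI group statistics, volcano classification,
#' class composition and pathway over-representation; (7) spatial
#' correlation network within the ROI of the segmented section. All
#' artifacts are written under `config$out_dir`; a run log echoes the
#' parameters; outputs are deterministic given the seed.
#'
#' @param config A [pipeline_config()].
#' @return List with the main in-memory results (`peaks`, `cubes`, `masks`,
#'   `plsa`, `segmentation`, `peak_assignment`, `pca`, `group_plsa`,
#'   `annotations`, `stat_table`, `volcano_counts`, `classes`,
#'   `enrichment`, `network`, `paths`, `config_hash`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) {
               stop("stage '", name, "' failed: ", conditionMessage(e),
                    call. = FALSE)
             })
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  paths <- list()
  log_lines <- c(sprintf("osteomsi %s",
                         as.character(utils::packageVersion("osteomsi"))),
                 sprintf("config hash %s", hash),
                 sprintf("sections %d", length(config$imzml)),
                 sprintf("parameters: snr=%g tol_ppm=%g fc_cut=%g alpha=%g n_components=%d seed=%d",
                         config$snr, config$tol_ppm, config$fc_cut,
                         config$alpha, config$n_components, config$seed))

  db <- stage("load_db", load_metabolite_db(config$db_path))
  n_sec <- length(config$imzml)

  # Pass 1: masks + overall mean spectrum of the normalized sections.
  masks <- vector("list", n_sec)
  acc <- NULL
  axis <- NULL
  total_px <- 0L
  stage("mean_spectrum", {
    for (i in seq_len(n_sec)) {
      ds <- rms_normalize(read_imzml(config$imzml[i]))
      masks[[i]] <- read_roi_mask(config$masks[i], ds,
                                   vocabulary = config$vocabulary,
                                   group = config$groups[i],
                                   section_id = sprintf("section_%d", i))
      # Tissue-restricted mean: off-tissue pixels would dilute thin
      # compartments (the osteoid seam) and carry matrix-cluster signal.
      ms <- mean_spectrum(ds, masks[[i]])
      lab <- mask_labels(masks[[i]], ds$coords)
      n_sel <- sum(lab != config$vocabulary[1])
      if (is.null(axis)) {
        axis <- ms$mz
        acc <- ms$intensity * n_sel
      } else {
        if (length(ms$mz) != length(axis) || any(ms$mz != axis)) {
          ms$intensity <- stats::approx(ms$mz, ms$intensity, xout = axis,
                                        yleft = 0, yright = 0)$y
        }
        acc <- acc + ms$intensity * n_sel
      }
      total_px <- total_px + n_sel
    }
  })
  overall_mean <- list(mz = axis, intensity = acc / total_px)

  peaks <- stage("pick_peaks", pick_peaks(overall_mean, config$snr))
  if (nrow(peaks) == 0L) stop("stage 'pick_peaks' failed: no peaks at S/N ",
                              config$snr, call. = FALSE)
  paths$peaklist <- .write_table(as.data.frame(peaks),
                                 file.path(config$out_dir, "peaklist.tsv"),
                                 hash)
  log_lines <- c(log_lines, sprintf("picked peaks %d", nrow(peaks)))

  # Pass 2: per-section data cubes.
  cubes <- stage("datacube", lapply(seq_len(n_sec), function(i) {
    ds <- rms_normalize(read_imzml(config$imzml[i]))
    build_datacube(ds, peaks, tol_ppm = config$tol_ppm,
                   baseline = "median",
                   baseline_window = config$baseline_window)
  }))

  # Segmentation of the designated section.
  si <- config$plsa_section
  model <- stage("plsa", {
    m <- fit_plsa(cubes[[si]], config$n_components, seed = config$seed,
                  max_iter = config$plsa_max_iter, tol = config$plsa_tol,
                  nstart = config$plsa_restarts)
    identify_background(m, masks[[si]])
  })
  seg <- segment_pixels(model)
  assign <- assign_peaks(model)
  pca <- stage("pca", fit_pca(cubes[[si]],
                              min(config$n_components,
                                  min(dim(cubes[[si]]$intensity)) - 1L)))
  paths$segmentation <- .write_table(
    data.frame(cubes[[si]]$coords, component = seg$component),
    file.path(config$out_dir, "segmentation.tsv"), hash)
  paths$peak_components <- .write_table(
    assign, file.path(config$out_dir, "peak_components.tsv"), hash)
  counts <- attr(assign, "counts")
  log_lines <- c(log_lines,
                 sprintf("pLSA section %d: background component %s; peaks per component: %s",
                         si, model$background,
                         paste(sprintf("%s=%d", names(counts), counts),
                               collapse = " ")))

  # Group-level pLSA on per-section ROI mean intensities.
  group_plsa <- stage("group_plsa", {
    roi_means <- t(vapply(seq_len(n_sec), function(i) {
      lab <- mask_labels(masks[[i]], cubes[[i]]$coords)
      colMeans(cubes[[i]]$intensity[lab %in% config$roi_labels, ,
                                    drop = FALSE])
    }, numeric(ncol(cubes[[1]]$intensity))))
    gm <- fit_plsa(roi_means, 2L, seed = config$seed,
                   max_iter = config$plsa_max_iter, tol = config$plsa_tol,
                   nstart = config$plsa_restarts)
    list(model = gm, scores = sweep(gm$p_pixel, 2, gm$prior, "*") /
           rowSums(sweep(gm$p_pixel, 2, gm$prior, "*")),
         groups = config$groups)
  })

  annos <- stage("annotation", {
    a <- annotate_peaks(peaks, db, tol_ppm = config$tol_ppm)
    endo <- filter_exogenous(a)
    gly <- annotate_glycans(peaks, tol_ppm = config$tol_ppm)
    list(all = a, endogenous = endo, glycan = gly)
  })
  paths$annotations <- .write_table(
    rbind(annos$all, annos$glycan),
    file.path(config$out_dir, "annotations.tsv"), hash)
  log_lines <- c(log_lines,
                 sprintf("annotated peaks %d (endogenous %d, glycan-matched %d)",
                         length(unique(annos$all$peak_mz)),
                         length(unique(annos$endogenous$peak_mz)),
                         length(unique(annos$glycan$peak_mz))))

  stat_table <- stage("roi_stats", {
    st <- roi_stat_table(cubes, masks, config$groups,
                         roi_labels = config$roi_labels)
    volcano_classify(st, fc_cut = config$fc_cut, alpha = config$alpha)
  })
  paths$stats <- .write_table(stat_table,
                              file.path(config$out_dir, "stat_table.tsv"),
                              hash)
  vc <- attr(stat_table, "counts")
  log_lines <- c(log_lines,
                 sprintf("volcano: %d changed (%d up, %d down)",
                         vc["total_changed"], vc["up"], vc["down"]))

  classes <- class_composition(annos$endogenous, stat_table)
  paths$classes <- .write_table(classes,
                                file.path(config$out_dir,
                                          "class_composition.tsv"), hash)

  enrichment <- stage("enrichment", {
    best <- best_annotation(annos$endogenous)
    background <- unique(best$id)
    changed_mz <- stat_table$peak_mz[stat_table$direction != "ns"]
    hits <- unique(best$id[best$peak_mz %in% changed_mz])
    sets <- lapply(
      stats::setNames(nm = unique(unlist(
        strsplit(best$pathways, ";", fixed = TRUE)))),
      function(pw) {
        best$id[vapply(strsplit(best$pathways, ";", fixed = TRUE),
                       function(p) pw %in% p, logical(1))]
      })
    sets <- sets[nzchar(names(sets))]
    if (length(hits) && length(sets)) {
      ora_enrichment(hits, sets, background)
    } else {
      data.frame(pathway = character(0), hits = integer(0),
                 size = integer(0), ratio = numeric(0), p = numeric(0),
                 p_adj = numeric(0))
    }
  })
  paths$enrichment <- .write_table(
    enrichment, file.path(config$out_dir, "enrichment.tsv"), hash)

  net <- stage("network", build_network(
    annos$endogenous, stat_table, cubes[[si]], masks[[si]],
    alpha = config$alpha, roi_labels = config$roi_labels,
    label_fc = config$fc_cut))
  paths$network <- file.path(config$out_dir, "network.graphml")
  export_graph(net, paths$network)
  log_lines <- c(log_lines,
                 sprintf("network: %d nodes, %d edges",
                         igraph::vcount(net), igraph::ecount(net)))

  paths$log <- file.path(config$out_dir, "run_log.txt")
  con <- file(paths$log, "wb")
  writeLines(log_lines, con, useBytes = TRUE)
  close(con)

  list(peaks = peaks, cubes = cubes, masks = masks,
       overall_mean = overall_mean, plsa = model, segmentation = seg,
       peak_assignment = assign, pca = pca, group_plsa = group_plsa,
       annotations = annos, stat_table = stat_table, volcano_counts = vc,
       classes = classes, enrichment = enrichment, network = net,
       paths = paths, config_hash = hash)
}
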