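# Differential statistics over ROIs and compartments: Mann-Whitney,
# Kruskal-Wallis with Dunn's post hoc test, Benjamini-Hochberg adjustment,
# per-section log2 fold changes, volcano classification, chemical-class
# composition and hypergeometric pathway over-representation.

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum U with midrank ties. The p-value is exact (by enumeration of
#' labelings) when the pooled sample size is at most 12 and there are no
#' ties, otherwise a normal approximation with tie and continuity
#' correction is used.
#'
#' @param a,b Numeric samples (both nonempty).
#' @return List with `U` (statistic of sample `a`) and `p` (two-sided).
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  pooled <- c(a, b)
  if (max(pooled) == min(pooled)) {
    return(list(U = length(a) * length(b) / 2, p = 1))
  }
  use_exact <- (length(a) + length(b) <= 12) && !anyDuplicated(pooled)
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)
  )
  p <- unname(wt$p.value)
  if (!is.finite(p)) p <- 1
  list(U = unname(wt$statistic), p = min(p, 1))
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Kruskal-Wallis H with tie correction and a chi-square p-value
#' (df = k - 1), followed by Dunn's z-tests on the pooled midranks for every
#' pair of groups, with Benjamini-Hochberg adjustment across the pairs.
#'
#' @param groups Named list of >= 3 nonempty numeric samples.
#' @return List with `H`, `p`, and `dunn` (data frame: `group1`, `group2`,
#'   `z`, `p`, `p_adj`).
#' @export
kruskal_dunn <- function(groups) {
  if (length(groups) < 3L) {
    stop("need >= 3 groups; use mann_whitney() for two")
  }
  if (any(!vapply(groups, length, integer(1)))) {
    stop("all groups must be nonempty")
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (max(x) == min(x)) {
    pairs <- utils::combn(names(groups), 2)
    return(list(H = 0, p = 1,
                dunn = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                                  z = 0, p = 1, p_adj = 1)))
  }
  kw <- stats::kruskal.test(x, g)
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  pairs <- utils::combn(names(groups), 2)
  z <- vapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i1]] + 1 / n[[i2]]))
    (rbar[[i1]] - rbar[[i2]]) / se
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(z))
  list(H = unname(kw$statistic), p = unname(kw$p.value),
       dunn = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         z = z, p = p, p_adj = bh_adjust(p)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @return Adjusted p-values, original order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Log2 fold change from per-section ROI means
#'
#' `log2(mean(b_means) / mean(a_means))`, where each element is one
#' section's ROI mean intensity. Group A is the reference; a non-positive
#' reference mean yields NA (flagged by a warning).
#'
#' @param a_means,b_means Per-section ROI mean intensities (>= 1 each).
#' @return Log2 fold change (B vs A).
#' @export
log2_fold_change <- function(a_means, b_means) {
  if (!length(a_means) || !length(b_means)) {
    stop("need at least one section per group")
  }
  ref <- mean(a_means)
  if (!is.finite(ref) || ref <= 0) {
    warning("non-positive reference mean; fold change undefined")
    return(NA_real_)
  }
  log2(mean(b_means) / ref)
}

#' Per-peak group statistics over an ROI
#'
#' For every peak: per-section ROI mean intensities, log2 fold change
#' (group B vs reference group A, from the per-section means), the primary
#' pixel-wise two-sided Mann-Whitney p (pixels pooled within group, as in
#' the figure legends' pixel-wise intensity distributions) and a
#' pseudoreplication-safe per-section-mean Mann-Whitney p.
#'
#' @param cubes List of `msi_datacube`, one per section, sharing peaks.
#' @param masks List of [roi_mask()] aligned with `cubes`.
#' @param groups Factor/character of section group tags (2 levels; first
#'   level is the reference A).
#' @param roi_labels Mask labels forming the ROI (default: mineralized bone
#'   + osteoid, i.e. cortical bone).
#' @return `stat_table` data frame: `peak`, `peak_mz`, `log2fc`, `U`, `p`
#'   (primary, pixel-wise), `p_pixel`, `p_section`, `mean_a`, `mean_b`.
#' @export
roi_stat_table <- function(cubes, masks, groups,
                           roi_labels = c("mineralized_bone", "osteoid")) {
  stopifnot(length(cubes) == length(masks), length(groups) == length(cubes))
  groups <- factor(groups, levels = unique(as.character(groups)))
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  sel <- lapply(seq_along(cubes), function(i) {
    lab <- mask_labels(masks[[i]], cubes[[i]]$coords)
    which(lab %in% roi_labels)
  })
  if (any(!lengths(sel))) stop("ROI empty in at least one section")
  k <- ncol(cubes[[1]]$intensity)
  ga <- which(groups == levels(groups)[1])
  gb <- which(groups == levels(groups)[2])

  res <- lapply(seq_len(k), function(j) {
    vals <- lapply(seq_along(cubes), function(i) {
      cubes[[i]]$intensity[sel[[i]], j]
    })
    sec_means <- vapply(vals, mean, numeric(1))
    pa <- unlist(vals[ga]); pb <- unlist(vals[gb])
    mw_px <- mann_whitney(pa, pb)
    mw_sec <- mann_whitney(sec_means[ga], sec_means[gb])
    data.frame(peak = j, peak_mz = cubes[[1]]$peak_mz[j],
               log2fc = suppressWarnings(
                 log2_fold_change(sec_means[ga], sec_means[gb])),
               U = mw_px$U, p = mw_px$p, p_pixel = mw_px$p,
               p_section = mw_sec$p,
               mean_a = mean(sec_means[ga]), mean_b = mean(sec_means[gb]))
  })
  out <- do.call(rbind, res)
  class(out) <- c("stat_table", "data.frame")
  out
}

#' Volcano classification of a stat table
#'
#' `up` when log2FC >= `fc_cut` and p < `alpha`; `down` when
#' log2FC <= -`fc_cut` and p < `alpha`; otherwise `ns`.
#'
#' @param stat_table Data frame with `log2fc` and `p` columns.
#' @param fc_cut Absolute log2 fold-change cutoff (default 1).
#' @param alpha Significance level (default 0.05).
#' @return The table with a `direction` column; attribute `"counts"` holds
#'   `total_changed`, `up`, `down`.
#' @export
volcano_classify <- function(stat_table, fc_cut = 1, alpha = 0.05) {
  fc <- stat_table$log2fc
  p <- stat_table$p
  dir <- rep("ns", nrow(stat_table))
  dir[!is.na(fc) & fc >= fc_cut & p < alpha] <- "up"
  dir[!is.na(fc) & fc <= -fc_cut & p < alpha] <- "down"
  stat_table$direction <- dir
  attr(stat_table, "counts") <- c(total_changed = sum(dir != "ns"),
                                  up = sum(dir == "up"),
                                  down = sum(dir == "down"))
  stat_table
}

#' Chemical-class composition of changed peaks
#'
#' Percentages of metabolite classes among the peaks classified up and
#' down, using each peak's best annotation. Unannotated peaks are omitted.
#'
#' @param annos Annotation data frame (deduplicated internally per peak).
#' @param stat_table Volcano-classified table (with `peak_mz`, `direction`).
#' @return Data frame `direction`, `class`, `n`, `percent`; percentages sum
#'   to 100 within each direction.
#' @export
class_composition <- function(annos, stat_table) {
  best <- best_annotation(annos)
  out <- lapply(c("up", "down"), function(d) {
    mz <- stat_table$peak_mz[stat_table$direction == d]
    cls <- best$class[best$peak_mz %in% mz]
    if (!length(cls)) return(NULL)
    tab <- table(cls)
    data.frame(direction = d, class = names(tab), n = as.integer(tab),
               percent = 100 * as.numeric(tab) / sum(tab))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(direction = character(0), class = character(0),
                      n = integer(0), percent = numeric(0))
  }
  out
}

#' Hypergeometric pathway over-representation
#'
#' Upper-tail hypergeometric p of observing at least the seen number of hit
#' metabolites in each pathway, against a background of all detected
#' annotated metabolites. Enrichment ratio is observed / expected hits.
#'
#' @param hits Character vector of hit metabolite ids (subset of
#'   `background`).
#' @param pathway_sets Named list of pathway member id vectors.
#' @param background Character vector of background ids.
#' @return Data frame `pathway`, `hits`, `size`, `ratio`, `p`, `p_adj`.
#' @export
ora_enrichment <- function(hits, pathway_sets, background) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  hits <- unique(hits)
  if (!all(hits %in% background)) stop("hits must be a subset of background")
  nbg <- length(background)
  nhit <- length(hits)
  out <- lapply(names(pathway_sets), function(pw) {
    members <- intersect(unique(pathway_sets[[pw]]), background)
    size <- length(members)
    if (size == 0L) return(NULL)
    obs <- length(intersect(members, hits))
    expected <- size * nhit / nbg
    data.frame(pathway = pw, hits = obs, size = size,
               ratio = if (expected > 0) obs / expected else NA_real_,
               p = stats::phyper(obs - 1, size, nbg - size, nhit,
                                 lower.tail = FALSE))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(pathway = character(0), hits = integer(0),
                      size = integer(0), ratio = numeric(0), p = numeric(0),
                      p_adj = numeric(0)))
  }
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare one peak's intensity across compartments and groups
#'
#' Per-section, per-compartment pixel-intensity summaries (median, min,
#' max, n) plus: a group test within each compartment (pixel-wise
#' Mann-Whitney, two groups) and a compartment test within each group
#' (Mann-Whitney for two labels, Kruskal-Wallis + Dunn for more).
#' Compartments absent from a section are omitted with a warning.
#'
#' @param cubes List of `msi_datacube` (one per section).
#' @param masks List of [roi_mask()] aligned with `cubes`.
#' @param groups Section group tags.
#' @param peak Peak index.
#' @param labels Compartment labels to compare (>= 2 present overall).
#' @return List with `summaries` (data frame), `group_tests` (per label),
#'   `compartment_tests` (per group).
#' @export
compartment_compare <- function(cubes, masks, groups, peak,
                                labels = c("mineralized_bone", "osteoid",
                                           "bone_marrow")) {
  groups <- as.factor(groups)
  pix <- list()
  sums <- list()
  for (i in seq_along(cubes)) {
    lab <- mask_labels(masks[[i]], cubes[[i]]$coords)
    for (l in labels) {
      v <- cubes[[i]]$intensity[lab == l, peak]
      if (!length(v)) {
        warning("label '", l, "' absent in section ", i, "; omitted")
        next
      }
      sums[[length(sums) + 1L]] <- data.frame(
        section = i, group = as.character(groups[i]), label = l,
        n = length(v), median = stats::median(v), min = min(v), max = max(v))
      pix[[paste(i, l)]] <- list(group = as.character(groups[i]), label = l,
                                 values = v)
    }
  }
  summaries <- do.call(rbind, sums)
  present <- unique(summaries$label)
  if (length(present) < 2L) stop("fewer than 2 compartments present")

  pool <- function(keep) {
    unlist(lapply(pix[keep], `[[`, "values"), use.names = FALSE)
  }
  glev <- levels(droplevels(groups))
  group_tests <- if (length(glev) == 2L) {
    do.call(rbind, lapply(present, function(l) {
      keep_a <- vapply(pix, function(e) e$label == l && e$group == glev[1],
                       logical(1))
      keep_b <- vapply(pix, function(e) e$label == l && e$group == glev[2],
                       logical(1))
      if (!any(keep_a) || !any(keep_b)) return(NULL)
      mw <- mann_whitney(pool(keep_a), pool(keep_b))
      data.frame(label = l, U = mw$U, p = mw$p)
    }))
  } else NULL

  compartment_tests <- lapply(stats::setNames(glev, glev), function(g) {
    samples <- lapply(stats::setNames(present, present), function(l) {
      keep <- vapply(pix, function(e) e$label == l && e$group == g,
                     logical(1))
      pool(keep)
    })
    samples <- samples[lengths(samples) > 0]
    if (length(samples) < 2L) return(NULL)
    if (length(samples) == 2L) {
      mw <- mann_whitney(samples[[1]], samples[[2]])
      list(test = "mann_whitney",
           pair = names(samples), U = mw$U, p = mw$p)
    } else {
      c(list(test = "kruskal_dunn"), kruskal_dunn(samples))
    }
  })

  list(summaries = summaries, group_tests = group_tests,
       compartment_tests = compartment_tests)
}
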