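#!/usr/bin/env Rscript
# Stage 3: score the pLSA segmentation against the phantom's ground truth.
#
# Pixel-label accuracy on tissue pixels after permutation matching of the
# arbitrary component order, the background-component identification, and
# the fraction of planted peaks associated with their home compartment.

library(osteomsi)

res <- readRDS("scratch/analysis/pipeline_result.rds")
truth_peaks <- read.delim("results/analysis/ground_truth_peaks.tsv")
manifest <- read.delim("results/analysis/manifest.tsv")
spec <- phantom_spec(seed = 3)
masks <- generate_phantom_masks(spec)

si <- which(manifest$group == "Hyp")[1]
lab <- mask_labels(masks[[si]], res$cubes[[si]]$coords)
tissue <- lab != "background"
acc <- best_label_accuracy(res$segmentation$component[tissue],
                           lab[tissue], res$plsa$n_components)

mt <- match_planted_peaks(res$peaks, truth_peaks)
okp <- !is.na(mt) & truth_peaks$home != "background"
assoc <- mean(acc$assignment[truth_peaks$home[okp]] ==
                res$peak_assignment$component[mt[okp]])
counts <- attr(res$peak_assignment, "counts")

eval_tab <- data.frame(
  metric = c("plsa_pixel_accuracy", "peak_association_accuracy",
             "background_component", "pca_pc1_variance"),
  value = c(acc$accuracy, assoc, res$plsa$background,
            res$pca$explained_variance[1]))
write.table(eval_tab, "results/analysis/segmentation_eval.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("pLSA pixel accuracy (tissue, permutation-matched): %.1f%% of %d pixels.\n",
            100 * acc$accuracy, sum(tissue)))
cat(sprintf("Background component: %d (of %d).\n",
            res$plsa$background, res$plsa$n_components))
cat(sprintf("Peaks per component: %s.\n",
            paste(sprintf("%s=%d", names(counts), counts), collapse = " ")))
cat(sprintf("Peak-compartment association: %.1f%% of %d recovered planted peaks.\n",
            100 * assoc, sum(okp)))
cat(sprintf("PCA: PC1 explains %.1f%% of the variance.\n",
            100 * res$pca$explained_variance[1]))
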