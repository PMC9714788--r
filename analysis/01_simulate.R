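#!/usr/bin/env Rscript
# Stage 1: generate the reference bone phantom.
#
# Ten sections (5 wild-type-like, 5 Hyp-like) of a 64 x 64 femoral
# cross-section phantom with ~300 planted metabolite peaks, written as
# continuous-mode imzML plus compartment masks. Raw data land in
# scratch/analysis/phantom (large, regenerable); the ground-truth peak
# table is copied to results/analysis for the later evaluation stages.

library(osteomsi)

dir.create("results/analysis", showWarnings = FALSE, recursive = TRUE)
raw_dir <- "scratch/analysis/phantom"

spec <- phantom_spec(seed = 3)
db <- load_metabolite_db()
man <- generate_dataset(spec, db, raw_dir)

invisible(file.copy(man$peaks_path,
                    "results/analysis/ground_truth_peaks.tsv",
                    overwrite = TRUE))
manifest <- data.frame(imzml = man$imzml, mask = man$mask_tsv,
                       group = man$groups, section = man$section_ids)
write.table(manifest, "results/analysis/manifest.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

tp <- man$truth$peaks
cat(sprintf("Simulated %d sections (%s).\n", nrow(manifest),
            paste(table(manifest$group), collapse = " + ")))
cat(sprintf("Planted %d peaks (%d tissue-derived, %d matrix ions): %d up, %d down at |log2FC| = %g.\n",
            nrow(tp), sum(tp$home != "background"),
            sum(tp$home == "background"),
            sum(tp$effect_log2 > 0), sum(tp$effect_log2 < 0),
            spec$effect_log2))
cat("Raw imzML under", raw_dir, "- tables under results/analysis.\n")
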