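#!/usr/bin/env Rscript
# Stage 4: score the differential analysis against the planted effects.
#
# Volcano recovery of the planted up/down sets, false positives among the
# null peaks, the log2 fold-change error distribution, and annotation
# recovery of the planted identities at 4 ppm.

library(osteomsi)

res <- readRDS("scratch/analysis/pipeline_result.rds")
tp <- read.delim("results/analysis/ground_truth_peaks.tsv")
db <- load_metabolite_db()

mt <- match_planted_peaks(res$peaks, tp)
up_true <- which(tp$effect_log2 > 0)
dn_true <- which(tp$effect_log2 < 0)
dir_of <- res$stat_table$direction[mt]
fp <- setdiff(which(res$stat_table$direction != "ns"),
              mt[c(up_true, dn_true)])
err <- res$stat_table$log2fc[mt[c(up_true, dn_true)]] -
  tp$effect_log2[c(up_true, dn_true)]

planted <- tp[tp$home != "background", ]
set.seed(99)
obs <- data.frame(mz = planted$mz * (1 + runif(nrow(planted), -9e-7, 9e-7)))
annos <- annotate_peaks(obs, db, tol_ppm = 4)
hit <- vapply(seq_len(nrow(planted)), function(i) {
  any(abs(annos$peak_mz - obs$mz[i]) < 1e-9 &
        annos$id == planted$id[i] & annos$adduct == planted$adduct[i])
}, logical(1))

eval_tab <- data.frame(
  metric = c("planted_matched", "up_recovered", "down_recovered",
             "false_positives", "log2fc_max_abs_error",
             "log2fc_mean_abs_error", "annotation_recovery"),
  value = c(sum(!is.na(mt)), sum(dir_of[up_true] == "up", na.rm = TRUE),
            sum(dir_of[dn_true] == "down", na.rm = TRUE), length(fp),
            max(abs(err), na.rm = TRUE), mean(abs(err), na.rm = TRUE),
            mean(hit)))
write.table(eval_tab, "results/analysis/recovery_eval.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Planted peaks matched to picked peaks: %d of %d.\n",
            sum(!is.na(mt)), nrow(tp)))
cat(sprintf("Volcano recovery: %d/%d up, %d/%d down, %d false positives.\n",
            sum(dir_of[up_true] == "up", na.rm = TRUE), length(up_true),
            sum(dir_of[dn_true] == "down", na.rm = TRUE), length(dn_true),
            length(fp)))
cat(sprintf("log2FC error over planted effects: max %.3f, mean %.3f.\n",
            max(abs(err), na.rm = TRUE), mean(abs(err), na.rm = TRUE)))
cat(sprintf("Annotation recovery of planted identities at 4 ppm: %.1f%%.\n",
            100 * mean(hit)))
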