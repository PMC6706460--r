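#!/usr/bin/env Rscript
# Step 2 — read-depth CNV calling on the simulated case.
#
# Normalizes window counts to copy ratios, scans with a 50-kb sliding
# window in 5-kb increments, refines breakpoints by coverage-step
# maximization, screens rarity against a 30-sample reference panel
# (rank-sum, p < 1e-4), quantifies mosaicism, and emits ISCN-style
# nomenclature. Writes results/cnv_calls.tsv.

suppressPackageStartupMessages(library(ntgs))
if (!file.exists("results/sim/case01.windows.tsv"))
  stop("run analysis/01_simulate_inputs.R first")

genome <- default_genome()
cfg <- sim_config()
prof <- read_windows("results/sim/case01.windows.tsv",
                     sample_id = "case01", sex = "male")
panel <- reference_panel(simulate_panel(genome, cfg, seed = 20260101L, n = 30))

calls <- call_cnvs(prof, panel)
calls$iscn <- vapply(seq_len(nrow(calls)), function(i) {
  if (calls$level[i] == "chromosome" && calls$chrom[i] == "chrY")
    return(iscn_string(list(type = "mosaic_sex_loss")))
  op <- c("het-del" = "del", "hom-del" = "del", dup = "dup", trp = "trp")
  iscn_string(list(type = op[[calls$type[i]]], chrom = calls$chrom[i],
                   start = calls$start[i], end = calls$end[i],
                   de_novo = TRUE), genome)
}, character(1))

dir.create("results", showWarnings = FALSE)
write_cnv_calls(calls, "results/cnv_calls.tsv")

cat("CNV calls (kept after rarity screen):\n")
kept <- calls[calls$keep, ]
for (i in seq_len(nrow(kept)))
  cat(sprintf("  %-5s %9.0f-%9.0f  %-7s %7.1f kb  ratio %.2f  mosaic %s\n    %s\n",
              kept$chrom[i], kept$start[i], kept$end[i], kept$type[i],
              kept$size_kb[i], kept$mean_ratio[i],
              ifelse(is.na(kept$mosaic_fraction[i]), "-",
                     sprintf("%.0f%%", 100 * kept$mosaic_fraction[i])),
              kept$iscn[i]))
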