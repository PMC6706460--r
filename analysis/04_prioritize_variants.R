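#!/usr/bin/env Rscript
# Step 4 — small-variant prioritization, trio phasing, classification.
#
# Applies the retention cascade (known pathogenic OR: MAF <= 5%, coding /
# junction, >= 2 damaging predictor calls, OMIM disease gene), resolves
# inheritance from the trio, phases candidate compound heterozygotes in
# recessive genes, and assigns the five-tier classification. Writes
# results/variant_report.tsv.

suppressPackageStartupMessages(library(ntgs))
if (!file.exists("results/sim/case01.variants.tsv"))
  stop("run analysis/01_simulate_inputs.R first")

v <- read.delim("results/sim/case01.variants.tsv")
trio <- read.delim("results/sim/case01.trio.tsv")

retained <- prioritize(v)
retained$origin_called <- vapply(retained$variant_id, function(id) {
  r <- trio[trio$variant_id == id, ]
  determine_inheritance(r$gt_proband, r$gt_father, r$gt_mother)
}, character(1))

# phase recessive genes with more than one retained heterozygous variant
retained$biallelic <- NA_character_
for (g in unique(retained$gene[retained$omim_mode %in% c("AR", "XLR")])) {
  idx <- retained$gene == g
  retained$biallelic[idx] <- phase_compound_het(retained$origin_called[idx])
}

cls <- lapply(seq_len(nrow(retained)), function(i)
  classify_variant(retained[i, ], retained$origin_called[i],
                   isTRUE(retained$phenotype_consistent[i]),
                   biallelic = retained$biallelic[i]))
retained$tier <- vapply(cls, `[[`, character(1), "tier")
retained$note <- vapply(cls, `[[`, character(1), "note")

dir.create("results", showWarnings = FALSE)
write.table(retained, "results/variant_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("retained %d of %d variants:\n", nrow(retained), nrow(v)))
for (i in seq_len(nrow(retained)))
  cat(sprintf("  %-6s %s:%s (%s)  %-9s %-10s -> %s\n",
              retained$gene[i], retained$transcript[i], retained$chgvs[i],
              retained$consequence[i], retained$origin_called[i],
              ifelse(is.na(retained$biallelic[i]), "", retained$biallelic[i]),
              retained$tier[i]))
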