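#!/usr/bin/env Rscript
# Step 1 — generate the study inputs with known truth.
#
# Produces, under results/sim/:
#   * a male ~30x windowed-coverage profile carrying (a) a heterozygous
#     deletion with the size of the refined 16p11.2 event (751,905 bp) and
#     (b) a 40% mosaic loss of chromosome Y (the mosaic Turner analog);
#   * case/control chimeric read-pair tables carrying a reciprocal
#     translocation, an inversion, and a 150.1-kb insertion, plus random
#     noise and shared systematic artifacts;
#   * an annotated small-variant table with trio genotypes (four true
#     variants among 30 decoys);
#   * a qPCR plate encoding a one-copy deletion;
#   * the reduced genome's cytoband map.
# The reference panel used downstream is regenerated from its seed
# (recorded here) rather than written: it is 30 genome-wide profiles.

suppressPackageStartupMessages(library(ntgs))
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

SEED_CASE <- 42L; SEED_PAIRS <- 11L; SEED_VAR <- 9L; SEED_QPCR <- 5L
PANEL_SEED <- 20260101L; PANEL_N <- 30L

genome <- default_genome()
cfg <- sim_config()         # 1500 reads / 5-kb window at CN 2, male, NB noise
write_cytoband_map(genome, "results/sim/cytobands.txt")

truth_cnv <- truth_set(cnvs = data.frame(
  chrom = c("chr1", "chrY"),
  start = c(20000001, 1), end = c(20751905, genome$lengths[["chrY"]]),
  type = "het-del", mosaic = c(1, 0.40)))
prof <- simulate_coverage(genome, truth_cnv, cfg, seed = SEED_CASE,
                          sample_id = "case01")
write_windows(prof, "results/sim/case01.windows.tsv")

truth_sv <- truth_set(svs = list(
  list(type = "translocation", chromA = "chr1", posA = 15e6,
       chromB = "chr3", posB = 22e6, n_pairs = 10),
  list(type = "inversion", chrom = "chr2", start = 5e6, end = 9e6,
       n_pairs = 8),
  list(type = "insertion", receptor_chrom = "chr2", receptor_pos = 40e6,
       source_chrom = "chr3", source_start = 30000000,
       source_end = 30150050, n_pairs = 8)))
pp <- simulate_chimeric_pairs(genome, truth_sv, cfg, seed = SEED_PAIRS)
write_bedpe(pp$case, "results/sim/case01.pairs.bedpe")
write_bedpe(pp$control, "results/sim/control.pairs.bedpe")

truth_var <- data.frame(
  gene = c("BRAF", "KMT2D", "ARMC4", "ARMC4"),
  transcript = c("NM_004333", "NM_003482", "NM_018076", "NM_018076"),
  chgvs = c("c.G1411T", "c.16474delG", "c.1614_1615del", "c.C2306A"),
  phgvs = c("p.V471F", "p.D5492fs", "p.P538fs", "p.P769H"),
  consequence = c("missense", "frameshift", "frameshift", "missense"),
  known_status = c("ClinVar-P/LP", "none", "none", "none"),
  omim_mode = c("AD", "AD", "AR", "AR"),
  origin = c("de novo", "de novo", "pat", "mat"),
  phenotype_consistent = TRUE)
vt <- simulate_variant_table(truth_var, n_decoys = 30, seed = SEED_VAR)
write.table(vt$variants, "results/sim/case01.variants.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(vt$trio, "results/sim/case01.trio.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

plate <- simulate_qpcr_cts(copies_case = 1, copies_control = 2,
                           noise_sd = 0.05, seed = SEED_QPCR)
write.csv(plate, "results/sim/case01.qpcr.csv", row.names = FALSE)

cat("Simulated inputs written to results/sim/\n")
cat(sprintf("  coverage: %d windows, truth = 751.9-kb het del + 40%% mosaic Y loss\n",
            nrow(prof$windows)))
cat(sprintf("  pairs: %d case / %d control (3 true SVs + noise + artifacts)\n",
            nrow(pp$case), nrow(pp$control)))
cat(sprintf("  variants: %d rows (4 truth, 30 decoys)\n", nrow(vt$variants)))
cat(sprintf("  reference panel: regenerate with simulate_panel(seed = %d, n = %d)\n",
            PANEL_SEED, PANEL_N))
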