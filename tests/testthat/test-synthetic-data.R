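test_that("coverage simulation is deterministic and respects the count model", {
  g <- fx_genome(); cfg <- fx_cfg()
  tr <- truth_set(cnvs = data.frame(chrom = "chr1", start = 1e6 + 1,
                                    end = 2e6, type = "dup", mosaic = 1))
  a <- simulate_coverage(g, tr, cfg, seed = 7)
  b <- simulate_coverage(g, tr, cfg, seed = 7)
  expect_identical(a, b)
  c_ <- simulate_coverage(g, tr, cfg, seed = 8)
  expect_false(identical(a$windows$count, c_$windows$count))
  expect_true(all(a$windows$count >= 0))
  expect_true(all(a$windows$count == floor(a$windows$count)))
})

test_that("flat truth gives window means at the configured depth", {
  g <- fx_genome(); cfg <- fx_cfg()
  p <- simulate_coverage(g, NULL, cfg, seed = 3)
  auto <- !(p$windows$chrom %in% c("chrX", "chrY"))
  x <- p$windows$count[auto]
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - cfg$mean_count), 3 * se)
})

test_that("window expectation scales linearly with local copy number", {
  g <- fx_genome()
  cfg <- sim_config(count_model = "expected")  # noise off
  tr <- truth_set(cnvs = data.frame(
    chrom = "chr1",
    start = c(1e6, 5e6, 9e6, 13e6) + 1, end = c(2e6, 6e6, 10e6, 14e6),
    type = c("het-del", "hom-del", "dup", "trp"), mosaic = 1))
  p <- simulate_coverage(g, tr, cfg, seed = 1)
  w <- p$windows[p$windows$chrom == "chr1", ]
  mid <- (w$start + w$end) / 2
  cn <- rep(2, nrow(w))
  cnmap <- c("het-del" = 1, "hom-del" = 0, "dup" = 3, "trp" = 4)
  for (i in seq_len(nrow(tr$cnvs)))
    cn[mid >= tr$cnvs$start[i] & mid <= tr$cnvs$end[i]] <- cnmap[[tr$cnvs$type[i]]]
  fit <- stats::lm(w$count ~ cn)
  expect_lt(abs(stats::coef(fit)[["cn"]] / (cfg$mean_count / 2) - 1), 0.02)
  expect_lt(abs(stats::coef(fit)[["(Intercept)"]]), cfg$mean_count * 0.02)
})

test_that("embedded events shift regional means as the ploidy mixture predicts", {
  g <- fx_genome(); cfg <- fx_cfg()
  tr <- truth_set(cnvs = data.frame(
    chrom = c("chr2", "chrY"), start = c(10e6 + 1, 1), end = c(10.75e6, 10e6),
    type = c("het-del", "het-del"), mosaic = c(1, 0.4)))
  p <- simulate_coverage(g, tr, cfg, seed = 11)
  w <- p$windows
  mid <- (w$start + w$end) / 2
  indel <- w$chrom == "chr2" & mid >= 10e6 + 1 & mid <= 10.75e6
  base <- mean(w$count[w$chrom == "chr2" & !indel])
  # 150-window heterozygous deletion sits at half the diploid baseline
  expect_lt(abs(mean(w$count[indel]) / base - 0.5), 0.02)
  # 40% mosaic chrY loss leaves 60% of the male single-copy baseline
  y <- mean(w$count[w$chrom == "chrY"])
  expect_lt(abs(y / (cfg$mean_count / 2) - 0.6), 0.02)
})

test_that("chimeric-pair generation is deterministic, coherent, and plants shared artifacts", {
  g <- fx_genome(); cfg <- fx_cfg()
  tr <- truth_set(svs = list(list(type = "translocation", chromA = "chr1",
                                  posA = 15e6, chromB = "chr3", posB = 22e6,
                                  n_pairs = 10)))
  a <- simulate_chimeric_pairs(g, tr, cfg, seed = 5)
  b <- simulate_chimeric_pairs(g, tr, cfg, seed = 5)
  expect_identical(a, b)

  # artifacts appear at byte-identical coordinates in case and control
  art_case <- a$case[grepl("^artifact", a$case$origin), 1:8]
  art_ctrl <- a$control[grepl("^artifact", a$control$origin), 1:8]
  rownames(art_case) <- rownames(art_ctrl) <- NULL
  expect_identical(art_case, art_ctrl)

  # no truth, no noise, no artifacts -> empty case table
  cfg0 <- sim_config(noise_pairs = 0,
                     artifact_sites = default_artifact_sites()[0, ])
  e <- simulate_chimeric_pairs(g, NULL, cfg0, seed = 1)
  expect_equal(nrow(e$case), 0)

  # one translocation with 10 pairs -> exactly two coherent interchromosomal
  # clusters of 10 (one per reciprocal junction)
  t1 <- simulate_chimeric_pairs(g, tr, cfg0, seed = 2)
  cl <- cluster_pairs(extract_chimeric_pairs(t1$case))
  expect_equal(nrow(cl), 2)
  expect_equal(cl$n_support, c(10L, 10L))
  expect_true(all(cl$chrom1 == "chr1" & cl$chrom2 == "chr3"))
  expect_true(all(cl$strand_consistency == 1))
})

test_that("insertion truth links the receptor site to both source-fragment ends", {
  g <- fx_genome()
  cfg0 <- sim_config(noise_pairs = 0,
                     artifact_sites = default_artifact_sites()[0, ])
  tr <- truth_set(svs = list(list(type = "insertion",
                                  receptor_chrom = "chr2", receptor_pos = 40e6,
                                  source_chrom = "chr3",
                                  source_start = 30e6, source_end = 30150050,
                                  n_pairs = 8)))
  pp <- simulate_chimeric_pairs(g, tr, cfg0, seed = 3)
  cl <- cluster_pairs(extract_chimeric_pairs(pp$case))
  expect_equal(nrow(cl), 2)
  expect_true(all(cl$chrom1 == "chr2" & cl$chrom2 == "chr3"))
  # receptor footprints co-locate; source footprints flank the interval
  expect_lt(diff(range(cl$bp1)), 1500)
  expect_gt(diff(range(cl$bp2)), 1e5)
})

test_that("variant-table generator emits truth with stated fields and decoys that each fail one criterion", {
  tv <- data.frame(gene = c("BRAF", "ARMC4", "ARMC4"),
                   consequence = c("missense", "frameshift", "missense"),
                   known_status = c("ClinVar-P/LP", "none", "none"),
                   omim_mode = c("AD", "AR", "AR"),
                   origin = c("de novo", "pat", "mat"))
  st <- simulate_variant_table(tv, n_decoys = 25, seed = 4)
  v <- st$variants
  braf <- v[v$gene == "BRAF", ]
  expect_equal(braf$known_status, "ClinVar-P/LP")
  expect_equal(braf$omim_mode, "AD")
  arm <- v[v$gene == "ARMC4", ]
  expect_setequal(arm$origin, c("pat", "mat"))
  # trio genotypes encode the origins
  tri <- merge(st$trio, v[, c("variant_id", "gene", "origin")])
  pat <- tri[tri$origin == "pat", ]
  expect_true(all(pat$gt_father == "het" & pat$gt_mother == "ref"))
  # every decoy violates at least one retention criterion
  d <- v[!v$is_truth, ]
  viol <- d$maf > 0.05 | !(d$region %in% c("coding", "junction")) |
    d$damaging_calls < 2 | d$omim_mode == "none"
  expect_true(all(viol & d$known_status == "none"))
})

test_that("cohort generator reproduces requested marginals exactly", {
  coh <- integrate_cohort(simulate_cohort(seed = 1))
  expect_equal(table(coh$group)[["isolated"]], 34)
  expect_equal(table(coh$group)[["syndromic"]], 16)
  expect_equal(sum(coh$gs_diagnostic), 16)
  expect_equal(sum(coh$cma_diagnostic), 8)
  expect_true(all(coh$nt_mm >= 3.5))
  expect_equal(sum(coh$gs_finding_type == "snv", na.rm = TRUE), 7)

  expect_equal(nrow(simulate_cohort(group_sizes = c(isolated = 0, syndromic = 0),
                                    gs_positives = c(0, 0), cma_positives = c(0, 0),
                                    gs_finding_types = c(snv = 0, cnv = 0,
                                                         mosaic_aneuploidy = 0))), 0)
  expect_error(simulate_cohort(group_sizes = c(isolated = 3, syndromic = 2),
                               gs_positives = c(5, 0)), "positives")

  # brute-force recount over random consistent marginals
  set.seed(99)
  for (i in 1:200) {
    n <- sample(1:25, 2)
    gs <- c(sample(0:n[1], 1), sample(0:n[2], 1))
    cma <- c(sample(0:gs[1], 1), sample(0:gs[2], 1))
    extra <- sum(gs) - sum(cma)
    mos <- if (extra > 0) sample(0:min(1, extra), 1) else 0
    coh <- integrate_cohort(simulate_cohort(
      group_sizes = c(isolated = n[1], syndromic = n[2]),
      gs_positives = gs, cma_positives = cma,
      gs_finding_types = c(snv = extra - mos, cnv = sum(cma),
                           mosaic_aneuploidy = mos),
      n_vous = sample(0:5, 1), seed = i))
    got_gs <- tapply(coh$gs_diagnostic, factor(coh$group, c("isolated", "syndromic")), sum)
    got_cma <- tapply(coh$cma_diagnostic, factor(coh$group, c("isolated", "syndromic")), sum)
    expect_equal(as.numeric(ifelse(is.na(got_gs), 0, got_gs)), as.numeric(gs))
    expect_equal(as.numeric(ifelse(is.na(got_cma), 0, got_cma)), as.numeric(cma))
  }
})

test_that("qPCR plate generator encodes copy number in Ct as the efficiency model predicts", {
  # one- vs two-copy target, noiseless: exactly one cycle between samples
  pl <- simulate_qpcr_cts(1, 2, efficiency = 1, noise_sd = 0, seed = 1)
  tgt <- function(s) mean(pl$ct[pl$sample == s & pl$amplicon == "target"])
  expect_equal(tgt("case") - tgt("control"), 1)
  # equal copies: delta-delta-Ct zero
  pl2 <- simulate_qpcr_cts(2, 2, noise_sd = 0, seed = 1)
  expect_equal(ddct_copy_ratio(pl2)$ddct, c(0, 0))
  expect_error(simulate_qpcr_cts(1, 2, replicates = 0), "replicates")

  # Monte-Carlo: noisy plates still centre the downstream ratio on 0.5
  ratios <- vapply(1:500, function(s)
    mean(ddct_copy_ratio(simulate_qpcr_cts(1, 2, noise_sd = 0.1,
                                           seed = s))$ratio), numeric(1))
  expect_lt(abs(mean(ratios) - 0.5), 0.01)
})
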