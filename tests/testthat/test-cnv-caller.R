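make_profile <- function(counts_by_chrom, window_bp = 5000) {
  w <- do.call(rbind, lapply(names(counts_by_chrom), function(ch) {
    n <- length(counts_by_chrom[[ch]])
    data.frame(chrom = ch, start = seq(1, by = window_bp, length.out = n),
               end = seq(window_bp, by = window_bp, length.out = n),
               count = counts_by_chrom[[ch]], gc = 0.5, ratio = NA_real_)
  }))
  structure(list(sample_id = "t", sex = "female", windows = w),
            class = "window_profile")
}

test_that("normalization fixes the autosomal median at 1 and keeps zero windows", {
  p <- normalize_windows(make_profile(list(chr1 = rep(100, 50), chr2 = rep(100, 50))))
  expect_true(all(p$windows$ratio == 1))

  p2 <- normalize_windows(make_profile(list(chr1 = rep(100, 60), chr2 = rep(50, 40))))
  expect_equal(unique(p2$windows$ratio[p2$windows$chrom == "chr1"]), 1)
  expect_equal(unique(p2$windows$ratio[p2$windows$chrom == "chr2"]), 0.5)

  z <- make_profile(list(chr1 = c(rep(100, 50), 0), chr2 = rep(100, 50)))
  expect_equal(min(normalize_windows(z)$windows$ratio), 0)
  expect_error(normalize_windows(structure(list(windows = NULL),
                                           class = "window_profile")), "empty")
})

test_that("GC correction removes a planted quadratic GC bias", {
  g <- fx_genome()
  w <- make_windows(g, gc = "wave")
  cfg <- sim_config(gc_coef = c(1.2, -2))
  p <- simulate_coverage(g, NULL, cfg, seed = 6, windows = w)
  auto <- !(w$chrom %in% c("chrX", "chrY"))   # sex chromosomes sit at 0.5
  raw <- normalize_windows(p)
  fit0 <- stats::lm(raw$windows$ratio[auto] ~ raw$windows$gc[auto])
  corr <- normalize_windows(p, gc_correct = TRUE)
  fit1 <- stats::lm(corr$windows$ratio[auto] ~ corr$windows$gc[auto])
  expect_gt(abs(stats::coef(fit0)[2]), 0.3)      # bias visible before
  expect_lt(abs(stats::coef(fit1)[2]), 0.03)     # flat after
})

test_that("candidate scan finds embedded deletions, reports whole-chromosome shifts, stays quiet on flat profiles", {
  g <- fx_genome(); cfg <- fx_cfg()
  flat <- normalize_windows(simulate_coverage(g, NULL, cfg, seed = 2))
  expect_equal(nrow(scan_candidates(flat)), 0)
  expect_error(scan_candidates(flat, scan_bp = 50000, step_bp = 7000), "divide")

  # deletion with the size/coordinates of the study's refined 16p11.2 event
  tr <- truth_set(cnvs = data.frame(chrom = "chr1", start = 29538256,
                                    end = 30290160, type = "het-del", mosaic = 1))
  p <- normalize_windows(simulate_coverage(g, tr, cfg, seed = 13))
  cands <- scan_candidates(p)
  seg <- cands[cands$level == "segment" & cands$chrom == "chr1", ]
  expect_equal(nrow(seg), 1)
  ov <- min(seg$end, 30290160) - max(seg$start, 29538256) + 1
  expect_gt(ov / (30290160 - 29538256 + 1), 0.95)

  # 40% mosaic chrY loss in a male -> chromosome-level candidate
  trY <- truth_set(cnvs = data.frame(chrom = "chrY", start = 1, end = 10e6,
                                     type = "het-del", mosaic = 0.4))
  pY <- normalize_windows(simulate_coverage(g, trY, cfg, seed = 14))
  cY <- scan_candidates(pY)
  expect_true(any(cY$chrom == "chrY" & cY$level == "chromosome"))
})

test_that("breakpoint refinement is exact on noise-free grid-aligned events and window-accurate under noise", {
  g <- fx_genome()
  cfg0 <- sim_config(count_model = "expected")
  tr <- truth_set(cnvs = data.frame(chrom = "chr2", start = 10000001,
                                    end = 10500000, type = "het-del", mosaic = 1))
  p <- normalize_windows(simulate_coverage(g, tr, cfg0, seed = 1))
  call <- refine_breakpoints(p, scan_candidates(p)[1, ])
  expect_equal(call$start, 10000001)
  expect_equal(call$end, 10500000)
  expect_equal(call$type, "het-del")
  expect_equal(call$size_kb, 500.0)

  # off-grid truth at the 16p11.2 coordinates: edges land within one window
  tr2 <- truth_set(cnvs = data.frame(chrom = "chr1", start = 29538256,
                                     end = 30290160, type = "het-del", mosaic = 1))
  p2 <- normalize_windows(simulate_coverage(g, tr2, fx_cfg(), seed = 23))
  call2 <- refine_breakpoints(p2, scan_candidates(p2)[1, ])
  expect_lte(abs(call2$start - 29538256), 5000)
  expect_lte(abs(call2$end - 30290160), 5000)
  expect_lt(abs(call2$size_kb - 751.9), 10)

  short <- scan_candidates(p)[1, ]; short$end_idx <- short$start_idx
  expect_error(refine_breakpoints(p, short), "2 windows")
})

test_that("own rank-sum test matches wilcox.test exactly and a permutation oracle under ties", {
  set.seed(42)
  for (i in 1:40) {   # tie-free instances, exact path
    n1 <- sample(2:8, 1); n2 <- sample(2:10, 1)
    x <- stats::rnorm(n1); y <- stats::rnorm(n2, 0.8)
    ours <- ranksum_test(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
  for (i in 1:8) {    # tied instances vs Monte-Carlo permutation
    x <- sample(c(0.5, 1), 6, replace = TRUE)
    y <- sample(c(0.5, 1), 7, replace = TRUE)
    expect_lt(abs(ranksum_test(x, y)$p - ranksum_mc_p(x, y, seed = i)), 0.03)
  }
  # large-sample normal path agrees with wilcox.test's corrected approximation
  x <- stats::rnorm(30); y <- stats::rnorm(35, 0.5)
  expect_equal(ranksum_test(x, y)$p,
               stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
})

test_that("rarity screen keeps true rare CNVs, drops panel-shared polymorphisms and flat regions", {
  g <- fx_genome(); cfg <- fx_cfg(); panel <- fx_panel()
  tr <- truth_set(cnvs = data.frame(chrom = "chr1", start = 20000001,
                                    end = 20750000, type = "het-del", mosaic = 1))
  p <- normalize_windows(simulate_coverage(g, tr, cfg, seed = 31))
  rare <- rare_cnv_test(p, panel, "chr1", 20000001, 20750000)
  expect_lt(rare$p, 1e-4)
  expect_true(rare$keep)

  flatreg <- rare_cnv_test(p, panel, "chr2", 20000001, 20750000)
  expect_gt(flatreg$p, 1e-4)
  expect_false(flatreg$keep)

  # polymorphic deletion carried by half the panel: not rare
  carrier <- truth_set(cnvs = tr$cnvs)
  poly <- lapply(1:10, function(i) if (i <= 5) carrier else NULL)
  panel_poly <- reference_panel(simulate_panel(g, cfg, seed = 77, n = 10,
                                               polymorphic = poly))
  rp <- rare_cnv_test(p, panel_poly, "chr1", 20000001, 20750000)
  expect_gt(rp$p, 1e-4)
  expect_false(rp$keep)

  expect_error(rare_cnv_test(p, panel, "chr9", 1, 1e6), "panel grid")

  # p decreases monotonically with region size at fixed effect
  ps <- vapply(c(10, 20, 40, 80), function(nw) {
    prof <- make_profile(list(chr1 = rep(50, nw), chr2 = rep(100, nw + 200)))
    prof <- normalize_windows(prof)
    pan <- reference_panel(list(
      make_profile(list(chr1 = rep(100, nw) + rep(c(0, 1), length.out = nw),
                        chr2 = rep(100, nw + 200))),
      make_profile(list(chr1 = rep(100, nw) - rep(c(0, 1), length.out = nw),
                        chr2 = rep(100, nw + 200)))))
    rare_cnv_test(prof, pan, "chr1", 1, nw * 5000)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("rarity screen agrees with brute-force enumeration on small instances", {
  set.seed(7)
  for (i in 1:25) {
    nw <- sample(2:8, 1)                 # region windows
    np <- sample(2:3, 1)                 # panel samples
    case_counts <- round(stats::runif(nw, 40, 110))
    prof <- normalize_windows(make_profile(list(
      chr1 = c(case_counts, rep(100, 30)), chr2 = rep(100, 30))))
    pans <- lapply(seq_len(np), function(j) normalize_windows(make_profile(list(
      chr1 = c(round(stats::runif(nw, 80, 120)), rep(100, 30)),
      chr2 = rep(100, 30)))))
    pan <- structure(list(windows = pans[[1]]$windows[, c("chrom", "start", "end")],
                          ratios = vapply(pans, function(p) p$windows$ratio,
                                          numeric(nrow(pans[[1]]$windows))),
                          mean_ratio = NA, sd_ratio = NA),
                     class = "reference_panel")
    got <- rare_cnv_test(prof, pan, "chr1", 1, nw * 5000)$p
    x <- prof$windows$ratio[seq_len(nw)]
    oracle <- max(vapply(seq_len(np), function(j)
      ranksum_mc_p(x, pan$ratios[seq_len(nw), j], B = 40000, seed = i),
      numeric(1)))
    expect_lt(abs(got - oracle), 0.03)
  }
})

test_that("mosaic-fraction algebra matches its closed form and clamps", {
  expect_equal(estimate_mosaic_fraction(0.3, 0.5, 0), 0.4)   # chrY male loss
  expect_equal(estimate_mosaic_fraction(0.5, 0.5, 0), 0)
  expect_equal(estimate_mosaic_fraction(0.75, 1, 0.5), 0.5)  # autosomal het del
  expect_equal(estimate_mosaic_fraction(-0.2, 1, 0), 1)      # clamped
  expect_error(estimate_mosaic_fraction(0.5, 1, 1), "undefined")
})

test_that("whole-chromosome mosaic fractions are recovered within 5 points across the detectable range", {
  g <- fx_genome(); cfg <- fx_cfg()
  for (f in c(0.2, 0.4, 0.6, 0.8)) {
    est <- vapply(1:10, function(s) {
      tr <- truth_set(cnvs = data.frame(chrom = "chrY", start = 1, end = 10e6,
                                        type = "het-del", mosaic = f))
      calls <- call_cnvs(simulate_coverage(g, tr, cfg, seed = 1000 * f + s))
      calls$mosaic_fraction[calls$chrom == "chrY" & calls$level == "chromosome"][1]
    }, numeric(1))
    expect_true(all(abs(est - f) < 0.05))
  }
})

test_that("CNV sizes reproduce the reported kb values exactly", {
  expect_identical(cnv_size_kb(29538256, 30290160), 751.9)
  expect_identical(cnv_size_kb(29832358, 30091372), 259.0)
  expect_identical(cnv_size_kb(122757221, 122907271), 150.1)
  expect_identical(cnv_size_kb(100, 100), 0.0)
  expect_error(cnv_size_kb(10, 5), "end < start")
})
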