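# shared fixtures, built once per test run

.fx <- new.env()

fx_genome <- function() {
  if (is.null(.fx$genome)) .fx$genome <- default_genome()
  .fx$genome
}

fx_cfg <- function() sim_config()

# 30-sample reference panel at default noise, cached
fx_panel <- function() {
  if (is.null(.fx$panel))
    .fx$panel <- reference_panel(simulate_panel(fx_genome(), fx_cfg(),
                                                seed = 20260101, n = 30))
  .fx$panel
}

# genome-sequencing nomenclature strings of the study's reported CNVs
table2_iscn_strings <- c(
  "seq[hg19] del(16)(p11.2)dn chr16:g.29538256_30290160del",
  "seq[hg19] del(20)(p13p12.3) chr20:g.4937184_8674795del",
  "seq[hg19] del(8)(p23.3p23.2) chr8:g.10134_5523520del",
  "seq[hg19] dup(8)(q22.1q24.3) chr8:g.98620704_146298884dup",
  "seq[hg19] del(1)(q23.1q25.2)dn chr1:g.157878750_176611630del",
  "seq[hg19] trp(2)(q11.2q21.1)dn chr2:g.98070117_131452568trp",
  "seq[hg19] del(7)(q21.3q22.3)dn chr7:g.96777381_107062981del",
  "seq[hg19] del(22)(q11.21) chr22:g.18912476_21471029del",
  "seq[hg19] del(22)(q11.21)dn chr22:g.18912979_21443877del",
  "(X)x1,(Y)x0∼1"
)

# independent two-sided Fisher oracle: exhaustive hypergeometric enumeration
fisher_enum_p <- function(x1, n1, x2, n2) {
  k <- x1 + x2
  j <- max(0, k - n2):min(n1, k)
  pr <- stats::dhyper(j, n1, n2, k)
  obs <- stats::dhyper(x1, n1, n2, k)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# independent Monte-Carlo permutation oracle for the rank-sum two-sided p
ranksum_mc_p <- function(x, y, B = 20000, seed = 1) {
  set.seed(seed)
  n1 <- length(x); v <- c(x, y)
  r <- rank(v)
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (length(v) + 1) / 2
  w_perm <- replicate(B, sum(rank(v)[sample(length(v), n1)]))
  lo <- mean(w_perm <= w_obs); hi <- mean(w_perm >= w_obs)
  min(1, 2 * min(lo, hi))
}

# truth set of 20 well-separated mixed SVs on the reduced genome
fx_sv_truth <- function(n_pairs = 8) {
  svs <- list()
  add <- function(x) svs[[length(svs) + 1]] <<- c(x, list(n_pairs = n_pairs))
  # 8 translocations across chromosome pairs
  tpairs <- list(c("chr1", "chr2"), c("chr1", "chr3"), c("chr2", "chr3"),
                 c("chr1", "chrX"), c("chr2", "chrX"), c("chr3", "chrX"),
                 c("chr1", "chrY"), c("chr2", "chrY"))
  for (i in seq_along(tpairs)) {
    posB <- if (tpairs[[i]][2] == "chrY") 1e6 + i * 0.8e6 else 2e6 + i * 1.7e6
    add(list(type = "translocation", chromA = tpairs[[i]][1],
             posA = 3e6 + i * 2.5e6, chromB = tpairs[[i]][2], posB = posB))
  }
  # 6 inversions
  for (i in 1:6)
    add(list(type = "inversion", chrom = c("chr1", "chr2", "chr3")[(i %% 3) + 1],
             start = 24e6 + i * 2.1e6, end = 24e6 + i * 2.1e6 + 3e5 + i * 5e4))
  # 6 insertions
  for (i in 1:6)
    add(list(type = "insertion",
             receptor_chrom = c("chr1", "chr2")[(i %% 2) + 1],
             receptor_pos = 44e6 - i * 2.2e6,
             source_chrom = "chr3",
             source_start = 1e6 + i * 4e6,
             source_end = 1e6 + i * 4e6 + 1.2e5 + i * 1e4))
  truth_set(svs = svs)
}

# did a called event recover a true SV? (type + breakpoints within tol)
sv_matches <- function(ev, sv, tol = 5000) {
  near <- function(a, b) abs(a - b) <= tol
  if (sv$type == "translocation")
    ev$type == "translocation" &
      ((ev$chromA == sv$chromA & near(ev$bpA, sv$posA) &
          ev$chromB == sv$chromB & near(ev$bpB, sv$posB)) |
         (ev$chromA == sv$chromB & near(ev$bpA, sv$posB) &
            ev$chromB == sv$chromA & near(ev$bpB, sv$posA)))
  else if (sv$type == "inversion")
    ev$type == "inversion" & ev$chromA == sv$chrom &
      near(ev$bpA, sv$start) & near(ev$bpB, sv$end)
  else
    ev$type == "insertion" &
      !is.na(ev$receptor_chrom) & ev$receptor_chrom == sv$receptor_chrom &
      near(ev$receptor_pos, sv$receptor_pos) &
      near(ev$source_start, sv$source_start) &
      near(ev$source_end, sv$source_end)
}

# recall + false-event count of the SV cascade for one seed
sv_cascade_eval <- function(seed, truth = fx_sv_truth()) {
  pp <- simulate_chimeric_pairs(fx_genome(), truth, fx_cfg(), seed)
  ev <- call_svs(pp$case, pp$control)
  hit <- vapply(truth$svs, function(sv)
    any(vapply(seq_len(nrow(ev)), function(i) sv_matches(ev[i, ], sv),
               logical(1))), logical(1))
  matched_ev <- vapply(seq_len(nrow(ev)), function(i)
    any(vapply(truth$svs, function(sv) sv_matches(ev[i, ], sv), logical(1))),
    logical(1))
  list(recall = mean(hit), false_events = sum(!matched_ev))
}
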