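#' Simulate a cohort case table with fixed diagnostic marginals
#'
#' Builds a per-case table whose group sizes and per-method positive
#' counts exactly match the requested marginals, with per-case finding
#' lists (type and pathogenicity tier) attached so the integration and
#' yield machinery can be run end to end. Defaults reproduce the study
#' cohort: 34 isolated + 16 syndromic fetuses with nuchal translucency
#' >= 3.5 mm; genome sequencing diagnosed 10 + 6 cases (one mosaic
#' whole-chromosome loss, eight CNVs, seven small variants) while
#' CMA/karyotyping diagnosed the 5 + 3 CNV cases.
#'
#' @param group_sizes named integer vector c(isolated=, syndromic=)
#' @param gs_positives genome-sequencing positives per group
#' @param cma_positives CMA/karyotype positives per group (a subset of the
#'   GS positives: every array-detectable CNV is also seen by sequencing)
#' @param gs_finding_types named totals of GS finding types across groups;
#'   must sum to `sum(gs_positives)` with `cnv == sum(cma_positives)`
#' @param n_vous number of additional non-diagnostic VOUS findings
#'   scattered over the cohort
#' @param seed integer seed (governs NT values, sample types, VOUS spread)
#' @return data.frame with one row per case: case_id, group, nt_mm,
#'   sample_type, gs_finding_type, plus list-columns findings_gs /
#'   findings_cma of per-case finding tables (type, tier)
#' @export
simulate_cohort <- function(group_sizes = c(isolated = 34, syndromic = 16),
                            gs_positives = c(10, 6),
                            cma_positives = c(5, 3),
                            gs_finding_types = c(snv = 7, cnv = 8,
                                                 mosaic_aneuploidy = 1),
                            n_vous = 10, seed = 1L) {
  if (any(gs_positives > group_sizes) || any(cma_positives > group_sizes))
    stop_input("positives > group size")
  if (any(cma_positives > gs_positives))
    stop_input("CMA positives must be a subset of GS positives")
  n <- sum(group_sizes)
  if (n == 0) {
    return(data.frame(case_id = character(), group = character(),
                      nt_mm = numeric(), sample_type = character(),
                      gs_finding_type = character()))
  }
  if (sum(gs_finding_types) != sum(gs_positives))
    stop_input("finding-type totals must sum to total GS positives")
  if (gs_finding_types[["cnv"]] != sum(cma_positives))
    stop_input("cnv finding count must equal total CMA positives")
  set.seed(as.integer(seed))

  groups <- rep(names(group_sizes), group_sizes)
  d <- data.frame(case_id = sprintf("case%03d", seq_len(n)), group = groups,
                  nt_mm = round(3.5 + stats::rexp(n, 1 / 2.2), 1),
                  sample_type = sample(c("CVS", "AF"), n, TRUE, prob = c(.74, .26)),
                  gs_finding_type = NA_character_, stringsAsFactors = FALSE)

  # deterministic allocation: within each group the first cma_positives
  # cases carry the array-detectable CNVs; the remaining GS-only positives
  # draw from the mosaic-aneuploidy then small-variant pools
  pool <- c(rep("mosaic_aneuploidy", gs_finding_types[["mosaic_aneuploidy"]]),
            rep("snv", gs_finding_types[["snv"]]))
  k <- 0L
  off <- 0L
  for (g in seq_along(group_sizes)) {
    idx <- off + seq_len(group_sizes[g])
    ncma <- cma_positives[g]
    ngs <- gs_positives[g]
    d$gs_finding_type[idx[seq_len(ncma)]] <- "cnv"
    extra <- ngs - ncma
    if (extra > 0) {
      d$gs_finding_type[idx[ncma + seq_len(extra)]] <- pool[k + seq_len(extra)]
      k <- k + extra
    }
    off <- off + group_sizes[g]
  }

  tier_for <- function(type) if (is.na(type)) NULL else
    data.frame(type = type,
               tier = sample(c("pathogenic", "likely pathogenic"), 1))
  d$findings_gs <- lapply(d$gs_finding_type, tier_for)
  d$findings_cma <- lapply(seq_len(n), function(i)
    if (!is.na(d$gs_finding_type[i]) && d$gs_finding_type[i] == "cnv")
      d$findings_gs[[i]] else NULL)
  if (n_vous > 0) {
    vi <- sample(n, min(n_vous, n))
    for (i in vi)
      d$findings_gs[[i]] <- rbind(d$findings_gs[[i]],
                                  data.frame(type = "cnv", tier = "VOUS"))
  }
  d
}

#' Simulate a qPCR Ct plate for copy-number validation
#'
#' Models the standard relative-quantification design: a target amplicon
#' inside the candidate CNV and a copy-number-neutral reference amplicon,
#' each measured in both the case and a normal control, in >= 3
#' replicates. At 100% PCR efficiency each copy-number doubling shifts Ct
#' by exactly one cycle: `Ct = base - log(copies/2) / log(1 + E)`.
#'
#' @param copies_case,copies_control target-locus copy number in case and
#'   control (>= 0; the reference locus is 2 copies in both)
#' @param efficiency PCR efficiency E in the validated 0.95-1.05 band
#' @param replicates wells per sample x amplicon x primer pair (>= 1)
#' @param noise_sd per-well Ct noise SD (cycles)
#' @param seed integer seed
#' @param primer_pairs number of independent primer pairs (the validation
#'   protocol uses two)
#' @return a `qpcr_plate` data.frame: primer_pair, sample, amplicon, ct
#' @export
simulate_qpcr_cts <- function(copies_case, copies_control = 2,
                              efficiency = 1, replicates = 3,
                              noise_sd = 0.1, seed = 1L, primer_pairs = 2) {
  if (copies_case < 0 || copies_control < 0) stop_input("copies must be >= 0")
  if (efficiency < 0.95 || efficiency > 1.05)
    stop_input("PCR efficiency outside the validated 0.95-1.05 band")
  if (replicates < 1) stop_input("replicates must be >= 1")
  set.seed(as.integer(seed))
  base_t <- 28; base_r <- 25
  ct_of <- function(base, copies) {
    if (copies == 0) return(base + 12)  # beyond-range amplification failure
    base - log(copies / 2) / log(1 + efficiency)
  }
  grid <- expand.grid(primer_pair = paste0("pp", seq_len(primer_pairs)),
                      sample = c("case", "control"),
                      amplicon = c("target", "reference"),
                      rep = seq_len(replicates), stringsAsFactors = FALSE)
  mu <- mapply(function(s, a) {
    copies <- if (a == "reference") 2 else if (s == "case") copies_case else copies_control
    ct_of(if (a == "reference") base_r else base_t, copies)
  }, grid$sample, grid$amplicon)
  grid$ct <- mu + stats::rnorm(nrow(grid), 0, noise_sd)
  grid[, c("primer_pair", "sample", "amplicon", "ct")]
}
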