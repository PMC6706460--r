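#' Classify a structural rearrangement
#'
#' No clinical guideline covers balanced rearrangements, so the rule used
#' for interpretation is: a breakpoint disrupting the body of an OMIM
#' disease gene makes the event potentially pathogenic; disruption of a
#' regulatory element or topologically associating domain (TAD) boundary
#' alone yields a variant of uncertain significance; neither, a
#' polymorphism.
#'
#' @param event one event row from [classify_events()]
#' @param breakpoint_genes data.frame of genes overlapping any breakpoint
#'   (columns gene, omim_mode; zero rows = no gene hit). NULL means the
#'   annotation track is missing and classification is deferred.
#' @param tad_disrupted logical: a TAD boundary or regulatory element is
#'   disrupted
#' @return list: classification ("potentially pathogenic", "VOUS",
#'   "polymorphism", or "deferred"), gene, mode
#' @export
classify_sv <- function(event, breakpoint_genes = NULL, tad_disrupted = FALSE) {
  if (is.null(breakpoint_genes)) {
    warning("missing annotation track: SV classification deferred")
    return(list(classification = "deferred", gene = NA, mode = NA))
  }
  omim <- breakpoint_genes[!is.na(breakpoint_genes$omim_mode) &
                             breakpoint_genes$omim_mode != "none", , drop = FALSE]
  if (nrow(omim) > 0)
    return(list(classification = "potentially pathogenic",
                gene = omim$gene[1], mode = omim$omim_mode[1]))
  if (isTRUE(tad_disrupted))
    return(list(classification = "VOUS", gene = NA, mode = NA))
  list(classification = "polymorphism", gene = NA, mode = NA)
}

#' Emit ISCN-style nomenclature for a finding
#'
#' Renders deletions/duplications/triplications as
#' `seq[hg19] <op>(<chrom>)(<bands>)[dn] chr<chrom>:g.<start>_<end><op>`
#' and mosaic sex-chromosome loss as `(X)x1,(Y)x0~1`-style counts. The
#' supported dialect is deliberately constrained to the operations the
#' pipeline reports; [parse_iscn()] inverts it.
#'
#' @param finding list with `type` ("del", "dup", "trp", or
#'   "mosaic_sex_loss"), `chrom`, `start`, `end`, optional `de_novo`
#'   flag, optional `bands` (looked up in `genome` when absent)
#' @param genome a [genome_spec()] for band lookup (optional if `bands`
#'   given)
#' @param assembly assembly tag in the string
#' @return nomenclature string
#' @export
iscn_string <- function(finding, genome = NULL, assembly = "hg19") {
  if (finding$type == "mosaic_sex_loss")
    return("(X)x1,(Y)x0∼1")
  if (!finding$type %in% c("del", "dup", "trp"))
    stop_input("unsupported ISCN operation: ", finding$type)
  bands <- finding$bands %||% {
    if (is.null(genome)) stop_input("bands or genome required")
    b1 <- band_at(genome, finding$chrom, finding$start)
    b2 <- band_at(genome, finding$chrom, finding$end)
    if (b1 == b2) b1 else paste0(b1, b2)
  }
  ch <- sub("^chr", "", finding$chrom)
  dn <- if (isTRUE(finding$de_novo)) "dn" else ""
  sprintf("seq[%s] %s(%s)(%s)%s chr%s:g.%d_%d%s",
          assembly, finding$type, ch, bands, dn, ch,
          as.integer(finding$start), as.integer(finding$end), finding$type)
}

#' Parse an ISCN-style nomenclature string of the supported dialect
#'
#' @param s nomenclature string from [iscn_string()]
#' @return finding list (type, chrom, start, end, bands, de_novo,
#'   assembly)
#' @export
parse_iscn <- function(s) {
  if (grepl("^\\(X\\)x1,\\(Y\\)x0[~∼]1$", s))
    return(list(type = "mosaic_sex_loss", chrom = "chrY"))
  m <- regmatches(s, regexec(
    "^seq\\[([^]]+)\\] (del|dup|trp)\\((\\w+)\\)\\(([^)]+)\\)(dn)? chr(\\w+):g\\.(\\d+)_(\\d+)(del|dup|trp)$",
    s))[[1]]
  if (!length(m)) stop_input("cannot parse ISCN string: ", s)
  if (m[3] != m[10]) stop_input("inconsistent operations in: ", s)
  list(type = m[3], chrom = paste0("chr", m[4]), bands = m[5],
       de_novo = m[6] == "dn", start = as.numeric(m[8]), end = as.numeric(m[9]),
       assembly = m[2])
}

tier_rank <- function(tier) {
  match(tier, c("pathogenic", "likely pathogenic", "potentially pathogenic",
                "VOUS", "likely benign", "benign", "polymorphism"))
}

#' Integrate a case's findings into a ranked report
#'
#' @param findings data.frame with at least `tier` (and optionally
#'   `size_kb`, `chrom`, `start` used for deterministic ordering); NULL
#'   or zero rows means no findings
#' @return list: diagnostic (TRUE iff any pathogenic / likely pathogenic
#'   finding), findings (ranked, P/LP first, then by size then position)
#' @export
integrate_case <- function(findings) {
  if (is.null(findings) || nrow(findings) == 0)
    return(list(diagnostic = FALSE, findings = findings))
  o <- order(tier_rank(findings$tier),
             -(findings$size_kb %||% rep(0, nrow(findings))),
             findings$chrom %||% rep("", nrow(findings)),
             findings$start %||% rep(0, nrow(findings)))
  ranked <- findings[o, , drop = FALSE]
  rownames(ranked) <- NULL
  list(diagnostic = any(findings$tier %in% c("pathogenic", "likely pathogenic")),
       findings = ranked)
}

#' Apply finding integration across a cohort table
#'
#' Adds `<method>_diagnostic` flags by running [integrate_case()] on each
#' case's finding list.
#'
#' @param cohort cohort table from [simulate_cohort()] (list-columns
#'   findings_gs / findings_cma)
#' @return cohort with logical columns gs_diagnostic, cma_diagnostic
#' @export
integrate_cohort <- function(cohort) {
  cohort$gs_diagnostic <- vapply(cohort$findings_gs,
                                 function(f) integrate_case(f)$diagnostic, logical(1))
  cohort$cma_diagnostic <- vapply(cohort$findings_cma,
                                  function(f) integrate_case(f)$diagnostic, logical(1))
  cohort
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' @param x successes
#' @param n trials
#' @param conf confidence level
#' @return c(lower, upper) as proportions
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

#' Diagnostic yield with exact confidence intervals
#'
#' Computes, per clinical group and overall, the diagnostic proportion of
#' a method with its 95% Clopper-Pearson interval, reported in percent to
#' one decimal (half up).
#'
#' @param cohort cohort table with a `group` column and a
#'   `<method>_diagnostic` logical column (see [integrate_cohort()])
#' @param method method label, e.g. "gs" or "cma"
#' @return data.frame: group, n, positives, yield_pct, ci_lo, ci_hi
#' @export
diagnostic_yield <- function(cohort, method = "gs") {
  if (nrow(cohort) == 0) stop_input("empty cohort")
  flag <- cohort[[paste0(method, "_diagnostic")]]
  if (is.null(flag)) stop_input("no diagnostic flag for method ", method)
  groups <- c(as.list(split(flag, cohort$group)), list(overall = flag))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    f <- groups[[g]]
    x <- sum(f); n <- length(f)
    ci <- clopper_pearson(x, n)
    data.frame(group = g, n = n, positives = x,
               yield_pct = round_half_up(100 * x / n, 1),
               ci_lo = round_half_up(100 * ci[1], 1),
               ci_hi = round_half_up(100 * ci[2], 1))
  }))
  rownames(out) <- NULL
  out
}

#' Compare two diagnostic yields
#'
#' Chi-square test without continuity correction when all four expected
#' counts of the 2x2 table reach 5, otherwise Fisher's exact test
#' (two-sided).
#'
#' @param a_pos,a_n positives and total of group A
#' @param b_pos,b_n positives and total of group B
#' @return list: statistic (chi-square statistic or odds ratio), p,
#'   method
#' @export
compare_yields <- function(a_pos, a_n, b_pos, b_n) {
  if (a_n <= 0 || b_n <= 0) stop_input("totals must be > 0")
  tab <- matrix(c(a_pos, a_n - a_pos, b_pos, b_n - b_pos), nrow = 2,
                byrow = TRUE)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expd >= 5)) {
    t <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(t$statistic), p = t$p.value,
         method = "chi-square")
  } else {
    t <- stats::fisher.test(tab)
    list(statistic = unname(t$estimate), p = t$p.value, method = "fisher")
  }
}

#' Relative copy ratio from a qPCR plate by the delta-delta-Ct method
#'
#' For each primer pair: `dCt = mean(Ct_target) - mean(Ct_reference)`
#' within sample, `ddCt = dCt_case - dCt_control`, copy ratio
#' `2^-ddCt`. Replicate SDs are propagated to an SD of the ratio by the
#' delta method. Invariant to any constant shift of all Ct values.
#'
#' @param plate `qpcr_plate` data.frame (primer_pair, sample, amplicon,
#'   ct) with >= 3 replicates per well group
#' @return data.frame: primer_pair, ddct, ratio, ratio_sd
#' @export
ddct_copy_ratio <- function(plate) {
  need <- expand.grid(sample = c("case", "control"),
                      amplicon = c("target", "reference"))
  out <- do.call(rbind, lapply(unique(plate$primer_pair), function(pp) {
    p <- plate[plate$primer_pair == pp, ]
    grp <- function(s, a) p$ct[p$sample == s & p$amplicon == a]
    for (i in seq_len(nrow(need)))
      if (length(grp(need$sample[i], need$amplicon[i])) < 3)
        stop_input("missing or under-replicated well group (", pp, ")")
    sem2 <- function(x) stats::var(x) / length(x)
    dct_case <- mean(grp("case", "target")) - mean(grp("case", "reference"))
    dct_ctrl <- mean(grp("control", "target")) - mean(grp("control", "reference"))
    ddct <- dct_case - dct_ctrl
    sd_ddct <- sqrt(sem2(grp("case", "target")) + sem2(grp("case", "reference")) +
                      sem2(grp("control", "target")) + sem2(grp("control", "reference")))
    ratio <- 2^(-ddct)
    data.frame(primer_pair = pp, ddct = ddct, ratio = ratio,
               ratio_sd = ratio * log(2) * sd_ddct)
  }))
  rownames(out) <- NULL
  out
}
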