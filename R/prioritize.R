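#' Default prioritization and classification rule set
#'
#' The retention cascade keeps a variant if it is already reported
#' pathogenic (ClinVar P/LP or HGMD DM), or if it jointly satisfies the
#' novel-variant criteria: population minor allele frequency <= 5%,
#' located in coding sequence or an exon-intron junction, called damaging
#' by at least `damaging_min` of the five in-silico predictors (SIFT,
#' PolyPhen-2, MutationTaster, Human Splicing Finder, MaxEntScan), and
#' located in an OMIM disease gene. "Multiple algorithms" is interpreted
#' as >= 2 of 5; missing annotation fails the criterion it belongs to.
#'
#' @param maf_max MAF retention threshold
#' @param damaging_min predictor consensus threshold
#' @return list of rule parameters, editable and passed to
#'   [prioritize()] / [classify_variant()]
#' @export
default_rules <- function(maf_max = 0.05, damaging_min = 2) {
  list(maf_max = maf_max, damaging_min = damaging_min,
       regions = c("coding", "junction"),
       known = c("ClinVar-P/LP", "HGMD-DM"),
       truncating = c("frameshift", "nonsense", "splice-site"))
}

#' Prioritize annotated small variants
#'
#' Applies the retention cascade and records, per retained variant, which
#' criteria fired. Idempotent and order-invariant.
#'
#' @param variants annotated variant table (columns gene, consequence,
#'   zygosity, maf, damaging_calls, known_status, omim_mode, region;
#'   missing fields are treated as failing their criterion)
#' @param rules a [default_rules()] list
#' @return the retained rows with logical trace columns crit_known,
#'   crit_maf, crit_region, crit_predictors, crit_omim and a
#'   `criteria` summary string
#' @export
prioritize <- function(variants, rules = default_rules()) {
  v <- variants
  if (nrow(v) == 0) return(cbind(v, criteria = character(0)))
  get <- function(col, default) if (is.null(v[[col]])) rep(default, nrow(v)) else v[[col]]
  known <- get("known_status", "none") %in% rules$known
  maf_ok <- !is.na(get("maf", NA_real_)) & get("maf", NA_real_) <= rules$maf_max
  region_ok <- get("region", "other") %in% rules$regions
  pred_ok <- !is.na(get("damaging_calls", NA_integer_)) &
    get("damaging_calls", NA_integer_) >= rules$damaging_min
  omim_ok <- get("omim_mode", "none") %in% c("AD", "AR", "XLD", "XLR")
  novel_path <- maf_ok & region_ok & pred_ok & omim_ok
  keep <- known | novel_path
  out <- v[keep, , drop = FALSE]
  out$crit_known <- known[keep]
  out$crit_maf <- maf_ok[keep]
  out$crit_region <- region_ok[keep]
  out$crit_predictors <- pred_ok[keep]
  out$crit_omim <- omim_ok[keep]
  out$criteria <- apply(cbind(known = known[keep], novel = novel_path[keep]), 1,
                        function(x) paste(names(x)[x], collapse = "+"))
  rownames(out) <- NULL
  out
}

#' Determine inheritance from trio genotypes
#'
#' @param gt_proband,gt_father,gt_mother genotypes in
#'   \{"ref","het","hom","missing"\} (NA treated as missing)
#' @return one of "de novo", "paternal", "maternal", "biparental",
#'   "unknown"
#' @export
determine_inheritance <- function(gt_proband, gt_father, gt_mother) {
  carries <- function(g) !is.na(g) & g %in% c("het", "hom", "hemi")
  if (!carries(gt_proband)) stop_input("proband does not carry the variant")
  f <- gt_father; m <- gt_mother
  if (is.na(f) || f == "missing" || is.na(m) || m == "missing") return("unknown")
  cf <- carries(f); cm <- carries(m)
  if (cf && cm) "biparental"
  else if (cf) "paternal"
  else if (cm) "maternal"
  else "de novo"
}

#' Phase candidate compound heterozygotes in one recessive gene
#'
#' @param origins character vector of per-variant parental origins
#'   ("paternal", "maternal", "de novo", "biparental", "unknown") for the
#'   heterozygous variants found in one AR/XLR gene
#' @return verdict: "confirmed-trans" (origins on different parents),
#'   "cis" (all on the same parent), "suspected" (>= 2 variants, phase
#'   unresolved), or "single-carrier"
#' @export
phase_compound_het <- function(origins) {
  if (length(origins) < 2) return("single-carrier")
  pat <- "paternal" %in% origins
  mat <- "maternal" %in% origins
  if (pat && mat) "confirmed-trans"
  else if ((pat || mat) && !any(origins %in% c("unknown", "de novo", "biparental")))
    "cis"
  else "suspected"
}

#' Classify a prioritized variant into the five-tier scheme
#'
#' Deterministic rule table over \{known status, consequence class,
#' inheritance mode of the gene, variant origin, phenotype match,
#' biallelic state\}:
#' known P/LP with phenotype match is pathogenic (without the match,
#' likely pathogenic); a novel truncating variant in a dominant gene is
#' likely pathogenic when de novo or phenotype-consistent; a novel
#' missense in a dominant gene needs both; recessive genes require a
#' biallelic state (homozygous or confirmed-trans compound het) before
#' any P/LP call; everything else is a variant of uncertain significance.
#'
#' @param variant one-row variant (needs known_status, consequence,
#'   omim_mode, zygosity)
#' @param origin inheritance from [determine_inheritance()]
#' @param phenotype_consistent logical expert flag supplied per case
#' @param biallelic verdict from [phase_compound_het()] for AR/XLR genes
#'   (or NA for dominant genes)
#' @param rules a [default_rules()] list
#' @return list: tier (one of "pathogenic", "likely pathogenic", "VOUS",
#'   "likely benign", "benign"), note
#' @export
classify_variant <- function(variant, origin = "unknown",
                             phenotype_consistent = FALSE, biallelic = NA,
                             rules = default_rules()) {
  known <- (variant$known_status %||% "none") %in% rules$known
  mode <- variant$omim_mode %||% "none"
  trunc <- variant$consequence %in% rules$truncating
  recessive <- mode %in% c("AR", "XLR")
  dominant <- mode %in% c("AD", "XLD")
  hom <- variant$zygosity %in% c("hom", "hemi")
  bial <- recessive && (hom || identical(biallelic, "confirmed-trans"))

  if (recessive && !bial) {
    return(list(tier = "VOUS",
                note = "recessive gene without biallelic variant"))
  }
  if (known) {
    if (phenotype_consistent)
      return(list(tier = "pathogenic", note = "known variant, phenotype match"))
    return(list(tier = "likely pathogenic", note = "known variant"))
  }
  if (mode == "none")
    return(list(tier = "VOUS", note = "no established disease gene/mode"))
  if (dominant) {
    if (trunc && (origin == "de novo" || phenotype_consistent))
      return(list(tier = "likely pathogenic",
                  note = "novel truncating, dominant gene"))
    if (!trunc && origin == "de novo" && phenotype_consistent)
      return(list(tier = "likely pathogenic",
                  note = "novel de novo missense, dominant gene, phenotype match"))
    return(list(tier = "VOUS", note = "dominant gene, insufficient evidence"))
  }
  # recessive, biallelic
  if (trunc || phenotype_consistent)
    return(list(tier = "likely pathogenic", note = "biallelic, recessive gene"))
  list(tier = "VOUS", note = "biallelic but unsupported")
}
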