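#' Simulate an annotated small-variant table with trio genotypes
#'
#' Emits every field the prioritization cascade consumes. Truth variants
#' pass the retention rules by construction and carry the stated zygosity
#' and parental origin; each decoy violates exactly one retention
#' criterion (population frequency, region, predictor consensus, or OMIM
#' gene status) while satisfying the rest, so a correct prioritizer
#' retains exactly the truth set.
#'
#' @param truth data.frame of true variants with columns gene, transcript,
#'   chgvs, phgvs, consequence, zygosity, maf, damaging_calls,
#'   known_status, omim_mode, region, origin ("de novo", "pat", "mat",
#'   "biparental"), phenotype_consistent; missing annotation columns are
#'   filled with passing defaults
#' @param n_decoys number of decoy variants to add
#' @param seed integer seed
#' @return list with `variants` (proband annotation table, one row per
#'   variant, column `variant_id`) and `trio` (variant_id, gt_proband,
#'   gt_father, gt_mother)
#' @export
simulate_variant_table <- function(truth = NULL, n_decoys = 20, seed = 1L) {
  set.seed(as.integer(seed))
  defaults <- list(transcript = "NM_000000", chgvs = "c.1A>G", phgvs = "p.?",
                   consequence = "missense", zygosity = "het", maf = 0,
                   damaging_calls = 4L, known_status = "none",
                   omim_mode = "AD", region = "coding", origin = "de novo",
                   phenotype_consistent = TRUE)
  tv <- if (is.null(truth) || nrow(truth) == 0) NULL else {
    for (nm in names(defaults))
      if (is.null(truth[[nm]])) truth[[nm]] <- rep(defaults[[nm]], nrow(truth))
    truth$is_truth <- TRUE
    truth
  }

  dk <- if (n_decoys > 0) {
    genes <- paste0("DEC", seq_len(n_decoys))
    violation <- sample(c("maf", "region", "predictors", "omim"),
                        n_decoys, replace = TRUE)
    d <- data.frame(
      gene = genes, transcript = paste0("NM_9", sprintf("%05d", seq_len(n_decoys))),
      chgvs = "c.100A>G", phgvs = "p.K34R",
      consequence = "missense", zygosity = "het",
      maf = round(stats::runif(n_decoys, 0, 0.04), 4),
      damaging_calls = sample(2:5, n_decoys, replace = TRUE),
      known_status = "none", omim_mode = sample(c("AD", "AR"), n_decoys, TRUE),
      region = "coding", origin = sample(c("pat", "mat"), n_decoys, TRUE),
      phenotype_consistent = FALSE, is_truth = FALSE)
    d$maf[violation == "maf"] <- round(stats::runif(sum(violation == "maf"), 0.051, 0.4), 3)
    d$region[violation == "region"] <- "other"
    d$consequence[violation == "region"] <- "intronic"
    d$damaging_calls[violation == "predictors"] <- sample(0:1, sum(violation == "predictors"), TRUE)
    d$omim_mode[violation == "omim"] <- "none"
    d
  } else NULL

  v <- rbind(tv, dk)
  if (is.null(v)) v <- data.frame()
  if (nrow(v)) {
    v$variant_id <- sprintf("v%03d", seq_len(nrow(v)))
    v <- v[, c("variant_id", setdiff(names(v), "variant_id"))]
  }
  trio <- if (nrow(v)) {
    gt_par <- function(origin, zyg) {
      f <- rep("ref", length(origin)); m <- rep("ref", length(origin))
      f[origin %in% c("pat", "biparental")] <- "het"
      m[origin %in% c("mat", "biparental")] <- "het"
      f[origin == "biparental" & zyg == "hom"] <- "het"
      list(f = f, m = m)
    }
    p <- gt_par(v$origin, v$zygosity)
    data.frame(variant_id = v$variant_id, gt_proband = v$zygosity,
               gt_father = p$f, gt_mother = p$m)
  } else data.frame(variant_id = character(), gt_proband = character(),
                    gt_father = character(), gt_mother = character())
  list(variants = v, trio = trio)
}
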