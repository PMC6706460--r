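#' Construct a truth set for simulation
#'
#' Holds the ground truth every generator embeds and every
#' parameter-recovery test compares against: true CNVs (with optional
#' mosaic fraction), true structural rearrangements, and true small
#' variants with parental origin.
#'
#' @param cnvs data.frame with columns chrom, start, end,
#'   type (one of "het-del", "hom-del", "dup", "trp"), mosaic
#'   (fraction of cells carrying the event, in `[0,1]`; 1 = constitutional)
#' @param svs list of SV descriptors; each a list with `type` one of
#'   "translocation", "inversion", "insertion" plus coordinates
#'   (`chromA`,`posA`,`chromB`,`posB` for translocations;
#'   `chrom`,`start`,`end` for inversions; `receptor_chrom`,`receptor_pos`,
#'   `source_chrom`,`source_start`,`source_end` for insertions, optionally a
#'   `fragments` data.frame for complex insertions) and `n_pairs`
#'   (supporting read pairs, >= 1)
#' @param variants data.frame of true small variants (see
#'   [simulate_variant_table()])
#' @return object of class `truth_set`
#' @export
truth_set <- function(cnvs = NULL, svs = NULL, variants = NULL) {
  if (!is.null(cnvs)) {
    stopifnot(all(c("chrom", "start", "end", "type") %in% names(cnvs)))
    if (is.null(cnvs$mosaic)) cnvs$mosaic <- 1
    if (any(cnvs$mosaic < 0 | cnvs$mosaic > 1))
      stop_input("mosaic fraction must be in [0,1]")
    if (!all(cnvs$type %in% c("het-del", "hom-del", "dup", "trp")))
      stop_input("unknown CNV type")
    if (any(cnvs$end < cnvs$start)) stop_input("CNV end < start")
  }
  if (!is.null(svs)) {
    for (sv in svs) {
      if (is.null(sv$type)) stop_input("SV without type")
      if (is.null(sv$n_pairs) || sv$n_pairs < 1)
        stop_input("each true SV needs a supporting-pair count >= 1")
    }
  }
  structure(list(cnvs = cnvs, svs = svs, variants = variants),
            class = "truth_set")
}

#' Simulation configuration
#'
#' Defaults encode the study conditions: ~30-fold genome sequencing of
#' 300-500 bp fragments with 100-bp paired-end reads gives approximately
#' `30 * 5000 / 100 = 1500` reads per 5-kb window at copy number 2, which
#' is the diploid baseline `mean_count`. Counts are negative binomial
#' (dispersion `size` parameter; larger = closer to Poisson); the paper's
#' data fix no empirical dispersion, so a moderate default is used and
#' exposed. Insert sizes are normal(350, 50) bp inside the stated
#' 300-500 bp band.
#'
#' @param mean_count expected read count per 5-kb window at copy number 2
#' @param dispersion negative-binomial size parameter; `Inf` gives Poisson
#' @param count_model "nbinom", "poisson", or "expected" (deterministic
#'   rounded expectations, the noise-free setting)
#' @param gc_coef length-2 numeric: linear and quadratic GC-bias
#'   coefficients on the window mean, as multiplier
#'   `1 + c1*(gc-0.5) + c2*(gc-0.5)^2`; off (0,0) by default
#' @param sex sample sex, "male" or "female" (sets X/Y baseline ploidy)
#' @param noise_pairs expected number of random chimeric noise pairs per
#'   genome (Poisson)
#' @param artifact_sites data.frame of systematic-artifact junctions shared
#'   between case and control (chromA, posA, sideA, chromB, posB, sideB,
#'   n_pairs); `default_artifact_sites()` if NULL
#' @param panel_n reference-panel size (>= 2)
#' @param insert_mean,insert_sd insert-size model (bp)
#' @param read_len read length (bp)
#' @return object of class `sim_config`
#' @export
sim_config <- function(mean_count = 1500, dispersion = 100,
                       count_model = c("nbinom", "poisson", "expected"),
                       gc_coef = c(0, 0), sex = c("male", "female"),
                       noise_pairs = 2000, artifact_sites = NULL,
                       panel_n = 30, insert_mean = 350, insert_sd = 50,
                       read_len = 100) {
  count_model <- match.arg(count_model)
  sex <- match.arg(sex)
  if (mean_count < 0 || noise_pairs < 0 || insert_sd < 0)
    stop_input("rates must be >= 0")
  if (panel_n < 2) stop_input("panel size must be >= 2")
  structure(list(mean_count = mean_count, dispersion = dispersion,
                 count_model = count_model, gc_coef = gc_coef, sex = sex,
                 noise_pairs = noise_pairs,
                 artifact_sites = artifact_sites %||% default_artifact_sites(),
                 panel_n = panel_n, insert_mean = insert_mean,
                 insert_sd = insert_sd, read_len = read_len),
            class = "sim_config")
}

#' Default systematic-artifact junction sites
#'
#' Recurrent mapping artifacts produce chimeric-pair clusters at identical
#' coordinates in every sample; the systematic filter removes them by
#' comparison against a control set. These fixed sites are planted in both
#' the case and the control tables.
#'
#' @return data.frame of artifact junctions
#' @export
default_artifact_sites <- function() {
  data.frame(
    chromA = c("chr1", "chr1", "chr2", "chr3"),
    posA   = c(12.4e6, 41.05e6, 8.77e6, 22.3e6),
    sideA  = c("D", "U", "D", "D"),
    chromB = c("chr2", "chr3", "chr3", "chrX"),
    posB   = c(33.1e6, 5.6e6, 31.02e6, 9.4e6),
    sideB  = c("U", "D", "U", "U"),
    n_pairs = c(8L, 6L, 12L, 5L)
  )
}

# expected copy number of a window given sex and chromosome
base_copy_number <- function(chrom, sex) {
  ifelse(chrom %in% c("chrX", "chrY"),
         ifelse(sex == "male", 1, ifelse(chrom == "chrX", 2, 0)),
         2)
}

# copy number after applying a CNV of given type to base cn
event_copy_number <- function(base, type) {
  switch(type,
         "het-del" = pmax(base - 1, 0),
         "hom-del" = 0,
         "dup"     = base + 1,
         "trp"     = base + 2,
         stop_input("unknown CNV type ", type))
}
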