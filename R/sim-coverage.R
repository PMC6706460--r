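#' Simulate windowed read-depth coverage with embedded CNVs
#'
#' Generates the per-5-kb-window read counts a ~30-fold genome-sequencing
#' run would produce, with true CNVs (including mosaic events) embedded by
#' scaling the window expectation linearly with local copy number. A window
#' belongs to an event when its midpoint falls inside the event interval.
#' Mosaic events mix the normal and event ploidies:
#' `cn_eff = f * cn_event + (1 - f) * cn_base`.
#'
#' @param genome a [genome_spec()]
#' @param truth a [truth_set()] (its `cnvs` are embedded; may be NULL)
#' @param cfg a [sim_config()]
#' @param seed integer seed; identical seed and config give identical output
#' @param windows optional precomputed window grid from [make_windows()]
#' @return a `window_profile`: list with `sample_id`, `sex`, and `windows`
#'   (data.frame chrom, start, end, count, gc, ratio = NA until
#'   [normalize_windows()])
#' @export
simulate_coverage <- function(genome, truth = NULL, cfg = sim_config(),
                              seed = 1L, windows = NULL,
                              sample_id = "sample") {
  set.seed(as.integer(seed))
  w <- windows %||% make_windows(genome)
  cn <- base_copy_number(w$chrom, cfg$sex)
  cnvs <- if (!is.null(truth)) truth$cnvs else NULL
  if (!is.null(cnvs)) {
    for (i in seq_len(nrow(cnvs))) {
      ev <- cnvs[i, ]
      if (!ev$chrom %in% genome$chroms ||
          ev$start < 1 || ev$end > genome$lengths[[ev$chrom]])
        stop_input("truth CNV outside genome: ", ev$chrom, ":", ev$start, "-", ev$end)
      mid <- (w$start + w$end) / 2
      hit <- w$chrom == ev$chrom & mid >= ev$start & mid <= ev$end
      cn_ev <- event_copy_number(cn[hit], ev$type)
      cn[hit] <- ev$mosaic * cn_ev + (1 - ev$mosaic) * cn[hit]
    }
  }
  gcm <- 1 + cfg$gc_coef[1] * (w$gc - 0.5) + cfg$gc_coef[2] * (w$gc - 0.5)^2
  mu <- cfg$mean_count * (cn / 2) * pmax(gcm, 0) * (w$end - w$start + 1) / 5000
  if (cfg$mean_count < 0) stop_input("negative depth")
  w$count <- switch(cfg$count_model,
    expected = round(mu),
    poisson  = stats::rpois(length(mu), mu),
    nbinom   = if (is.infinite(cfg$dispersion)) stats::rpois(length(mu), mu)
               else stats::rnbinom(length(mu), size = cfg$dispersion, mu = mu))
  w$count <- pmax(w$count, 0L)
  w$ratio <- NA_real_
  structure(list(sample_id = sample_id, sex = cfg$sex, windows = w),
            class = "window_profile")
}

#' Simulate a reference panel of control coverage profiles
#'
#' Each control sample is an independent draw with no embedded events
#' unless `polymorphic` truth sets are supplied per sample (used to model
#' population-polymorphic CNVs segregating in the panel).
#'
#' @param genome a [genome_spec()]
#' @param cfg a [sim_config()]
#' @param seed master seed; per-sample sub-seeds are derived from it
#' @param n panel size (default `cfg$panel_n`)
#' @param polymorphic optional list (length `n`) of [truth_set()]s or NULL
#'   entries giving events carried by individual panel members
#' @return list of `window_profile`s
#' @export
simulate_panel <- function(genome, cfg = sim_config(), seed = 1L,
                           n = cfg$panel_n, polymorphic = NULL) {
  seeds <- derive_seeds(seed, n)
  windows <- make_windows(genome)
  lapply(seq_len(n), function(i) {
    tr <- if (!is.null(polymorphic)) polymorphic[[i]] else NULL
    simulate_coverage(genome, tr, cfg, seeds[i], windows = windows,
                      sample_id = paste0("control", i))
  })
}
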