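#' Normalize window counts to copy ratios
#'
#' Converts raw per-window counts to copy ratios on the convention that
#' the autosomal median ratio is exactly 1.0 (copy number 2). Optionally
#' divides by a reference panel's per-window mean ratio (flattening
#' recurrent coverage structure) and/or removes GC bias by dividing out a
#' quadratic ratio-vs-GC fit estimated on autosomal windows. Zero-count
#' windows are retained with ratio 0.
#'
#' @param profile a `window_profile`
#' @param panel optional [reference_panel()]
#' @param gc_correct logical, apply quadratic GC correction
#' @return the profile with `windows$ratio` populated
#' @export
normalize_windows <- function(profile, panel = NULL, gc_correct = FALSE) {
  w <- profile$windows
  if (is.null(w) || nrow(w) == 0) stop_input("empty profile")
  auto <- !(w$chrom %in% c("chrX", "chrY"))
  med <- stats::median(w$count[auto])
  if (med <= 0) stop_input("autosomal median count is zero")
  r <- w$count / med
  if (gc_correct) {
    fit <- stats::lm(r[auto] ~ w$gc[auto] + I(w$gc[auto]^2))
    pred <- cbind(1, w$gc, w$gc^2) %*% stats::coef(fit)
    pred <- pmax(as.numeric(pred), 0.1)
    r <- r / (pred / stats::median(pred[auto]))
  }
  if (!is.null(panel)) {
    # flatten recurrent window-level structure but preserve each
    # chromosome's baseline (a sex-matched panel must not erase the
    # X/Y single-copy level, nor a mosaic shift)
    ref <- panel$mean_ratio
    for (ch in unique(w$chrom)) {
      i <- w$chrom == ch
      m <- stats::median(ref[i])
      ref[i] <- if (m > 0.05) ref[i] / m else 1
    }
    r <- r / pmax(ref, 0.05)
  }
  r <- r / stats::median(r[auto])
  w$ratio <- r
  profile$windows <- w
  profile
}

#' Build a reference panel from control profiles
#'
#' @param profiles list of `window_profile`s on the same window grid
#' @return object of class `reference_panel`: windows grid, per-window
#'   ratio matrix (windows x samples), per-window mean and SD
#' @export
reference_panel <- function(profiles) {
  if (length(profiles) < 2) stop_input("panel needs >= 2 samples")
  norm <- lapply(profiles, normalize_windows)
  grid <- norm[[1]]$windows[, c("chrom", "start", "end")]
  for (p in norm[-1])
    if (!identical(p$windows$start, grid$start) ||
        !identical(p$windows$chrom, grid$chrom))
      stop_input("panel profiles are not on the same window grid")
  m <- vapply(norm, function(p) p$windows$ratio, numeric(nrow(grid)))
  structure(list(windows = grid, ratios = m,
                 mean_ratio = rowMeans(m),
                 sd_ratio = apply(m, 1, stats::sd)),
            class = "reference_panel")
}

# expected copy ratio per chromosome given sex (autosomal baseline 1.0,
# single-copy sex chromosomes in males 0.5)
expected_ratio <- function(chrom, sex) base_copy_number(chrom, sex) / 2

# infer sex from the chrX median ratio of a normalized profile
infer_sex <- function(profile) {
  w <- profile$windows
  x <- w$ratio[w$chrom == "chrX"]
  if (!length(x)) return("female")
  if (stats::median(x) < 0.75) "male" else "female"
}

#' Scan a normalized profile for CNV candidate regions
#'
#' Slides a `scan_bp` window in `step_bp` increments (the default 50 kb /
#' 5 kb gives a 10-window mean stepping one window at a time) and flags a
#' candidate where the sliding mean ratio deviates from the chromosome's
#' expected ratio by more than `threshold`, sustained over at least
#' `min_run` consecutive sliding positions. Overlapping hits are merged
#' into maximal runs. A chromosome whose overall median deviates beyond
#' the threshold is reported as a single chromosome-level candidate (the
#' mosaic-aneuploidy path) and not re-scanned segment-wise.
#'
#' @param profile a normalized `window_profile`
#' @param scan_bp sliding-window size (bp); must be a multiple of `step_bp`
#' @param step_bp increment (bp); must equal the profile's window size
#' @param threshold deviation from expected relative ratio for candidacy
#' @param min_run minimum consecutive deviating sliding windows
#' @param chrom_threshold deviation of the chromosome median that flags a
#'   chromosome-level candidate; default 0.08, just under the relative
#'   shift of a 20% mosaic autosomal monosomy (0.1), the lowest mosaic
#'   level the pipeline aims to quantify
#' @param sex "male", "female" or "auto" (inferred from chrX)
#' @return data.frame of candidates: chrom, start_idx, end_idx (indices
#'   into the chromosome's windows), start, end (bp), mean_ratio,
#'   expected, level ("segment" or "chromosome")
#' @export
scan_candidates <- function(profile, scan_bp = 50000, step_bp = 5000,
                            threshold = 0.2, min_run = 3,
                            chrom_threshold = 0.08,
                            sex = c("auto", "male", "female")) {
  sex <- match.arg(sex)
  if (scan_bp %% step_bp != 0) stop_input("step must divide scan window")
  w <- profile$windows
  if (all(is.na(w$ratio))) stop_input("profile not normalized")
  if (sex == "auto") sex <- profile$sex %||% infer_sex(profile)
  k <- scan_bp %/% step_bp
  out <- list()
  for (ch in unique(w$chrom)) {
    wi <- which(w$chrom == ch)
    e <- expected_ratio(ch, sex)
    if (e == 0) next  # chrY in a female profile carries no signal
    rel <- w$ratio[wi] / e
    if (abs(stats::median(rel) - 1) > chrom_threshold) {
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start_idx = 1L, end_idx = length(wi),
        start = w$start[wi[1]], end = w$end[wi[length(wi)]],
        mean_ratio = mean(w$ratio[wi]), expected = e, level = "chromosome")
      next
    }
    if (length(wi) < k) next
    roll <- as.numeric(stats::filter(rel, rep(1 / k, k), sides = 1))
    roll <- roll[!is.na(roll)]            # roll[i] = mean of windows i-k+1 .. i
    hit <- abs(roll - 1) > threshold
    rl <- rle(hit)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    segs <- NULL
    for (j in which(rl$values & rl$lengths >= min_run)) {
      # trimmed sliding index i covers original windows i .. i+k-1
      a <- starts[j]; b <- min(ends[j] + k - 1, length(wi))
      segs <- rbind(segs, c(a, b))
    }
    if (is.null(segs)) next
    # merge overlapping / adjacent runs into maximal candidates
    segs <- segs[order(segs[, 1]), , drop = FALSE]
    merged <- segs[1, , drop = FALSE]
    for (j in seq_len(nrow(segs))[-1]) {
      last <- nrow(merged)
      if (segs[j, 1] <= merged[last, 2] + 1)
        merged[last, 2] <- max(merged[last, 2], segs[j, 2])
      else merged <- rbind(merged, segs[j, ])
    }
    for (j in seq_len(nrow(merged))) {
      a <- merged[j, 1]; b <- merged[j, 2]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start_idx = a, end_idx = b,
        start = w$start[wi[a]], end = w$end[wi[b]],
        mean_ratio = mean(w$ratio[wi[a:b]]), expected = e,
        level = "segment")
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start_idx = integer(),
                      end_idx = integer(), start = numeric(), end = numeric(),
                      mean_ratio = numeric(), expected = numeric(),
                      level = character()))
  do.call(rbind, out)
}

#' Refine candidate breakpoints by coverage-step maximization
#'
#' Places each breakpoint at the 5-kb window edge maximizing the
#' mean-ratio step between the `flank_k` windows inside and outside the
#' edge (the coverage increment-rate statistic). The search spans
#' `flank_k` windows either side of the candidate edge. Chromosome-level
#' candidates pass through with the chromosome ends as breakpoints.
#'
#' @param profile a normalized `window_profile`
#' @param cand one row of [scan_candidates()] output
#' @param flank_k flanking span in windows for the step statistic
#' @param sex "male", "female" or "auto"
#' @return a one-row data.frame CNV call: chrom, start, end, type,
#'   mean_ratio, mosaic_fraction (NA if constitutional), size_kb, level
#' @export
refine_breakpoints <- function(profile, cand, flank_k = 10,
                               sex = c("auto", "male", "female")) {
  sex <- match.arg(sex)
  if (sex == "auto") sex <- profile$sex %||% infer_sex(profile)
  w <- profile$windows
  wi <- which(w$chrom == cand$chrom)
  e <- cand$expected %||% expected_ratio(cand$chrom, sex)
  if (cand$level == "chromosome")
    return(finish_call(cand$chrom, w$start[wi[1]], w$end[wi[length(wi)]],
                       mean(w$ratio[wi]), e, "chromosome"))
  if (cand$end_idx - cand$start_idx + 1 < 2)
    stop_input("candidate shorter than 2 windows: rejected")
  r <- w$ratio[wi]
  direction <- sign(cand$mean_ratio / e - 1)
  score_edge <- function(j, edge) {
    # "first": j is the first window inside; "last": j is the last inside
    if (edge == "first") { ins <- j:min(j + flank_k - 1, length(r))
                           outs <- max(1, j - flank_k):(j - 1) }
    else { ins <- max(1, j - flank_k + 1):j
           outs <- (j + 1):min(j + flank_k, length(r)) }
    if (j == 1 && edge == "first") return(-Inf)
    if (j == length(r) && edge == "last") return(-Inf)
    (mean(r[ins]) - mean(r[outs])) * direction
  }
  srange <- max(2, cand$start_idx - flank_k):min(length(r), cand$start_idx + flank_k)
  erange <- max(1, cand$end_idx - flank_k):min(length(r) - 1, cand$end_idx + flank_k)
  s <- srange[which.max(vapply(srange, score_edge, numeric(1), edge = "first"))]
  en <- erange[which.max(vapply(erange, score_edge, numeric(1), edge = "last"))]
  if (en < s) { s2 <- min(s, en); en <- max(s, en); s <- s2 }
  finish_call(cand$chrom, w$start[wi[s]], w$end[wi[en]],
              mean(r[s:en]), e, "segment")
}

# type the event from its relative mean ratio and estimate mosaicism;
# single-copy steps in ratio units are 0.5 (one copy at diploid scaling)
finish_call <- function(chrom, start, end, mean_ratio, expected, level) {
  loss <- mean_ratio < expected
  ev1 <- if (loss) max(expected - 0.5, 0) else expected + 0.5   # one-copy step
  ev2 <- if (loss) max(expected - 1, 0) else expected + 1       # two-copy step
  f1 <- (expected - mean_ratio) / (expected - ev1)
  two_step <- abs(f1) > 1.1 && ev2 != ev1
  ev <- if (two_step) ev2 else ev1
  f <- estimate_mosaic_fraction(mean_ratio, expected, ev)
  type <- if (loss) {
    if (two_step) "hom-del" else "het-del"  # on single-copy chromosomes the
  } else {                                  # one-copy loss IS the total loss
    if (two_step) "trp" else "dup"
  }
  data.frame(chrom = chrom, start = start, end = end, type = type,
             mean_ratio = mean_ratio,
             mosaic_fraction = if (f >= 0.1 && f <= 0.9) f else NA_real_,
             size_kb = cnv_size_kb(start, end), level = level,
             stringsAsFactors = FALSE)
}

#' Estimate the mosaic fraction from copy ratios
#'
#' For a cell population where a fraction f carries an event with copy
#' ratio `event` and the rest sit at `expected`, the observed mean ratio
#' is the mixture `f*event + (1-f)*expected`, so
#' `f = (expected - observed) / (expected - event)`, clamped to `[0,1]`.
#' For whole-chromosome Y loss in a male, `expected` is the single-copy
#' baseline (0.5) and `event` is 0.
#'
#' @param observed observed mean copy ratio
#' @param expected copy ratio of the unaffected cell population
#' @param event copy ratio of the aberrant cell population
#' @return fraction in `[0,1]`
#' @export
estimate_mosaic_fraction <- function(observed, expected, event) {
  if (expected == event) stop_input("expected == event: fraction undefined")
  min(1, max(0, (expected - observed) / (expected - event)))
}

#' Rarity test of a CNV region against a reference panel
#'
#' Two-sided rank-sum comparison of the case's per-window copy ratios in
#' the region against each panel sample's ratios over the same windows;
#' the reported p is the maximum over panel samples, so an event is "rare"
#' only if its copy-ratio signature differs from every panel member. A
#' population-polymorphic CNV segregating in the panel therefore fails the
#' screen (large p), which is the behavior the interpretation step relies
#' on. `mode = "pooled"` instead pools all panel windows into one
#' comparison sample.
#'
#' @param profile normalized case `window_profile`
#' @param panel a [reference_panel()] on the same grid
#' @param chrom,start,end region (1-based inclusive; must span >= 2 windows)
#' @param alpha rarity threshold (fixed screen, default 1e-4)
#' @param mode "per-sample-max" (default) or "pooled"
#' @return list: p, keep (p < alpha), n_windows, method
#' @export
rare_cnv_test <- function(profile, panel, chrom, start, end, alpha = 1e-4,
                          mode = c("per-sample-max", "pooled")) {
  mode <- match.arg(mode)
  w <- profile$windows
  idx <- which(w$chrom == chrom & w$start >= start & w$end <= end)
  pidx <- which(panel$windows$chrom == chrom & panel$windows$start >= start &
                  panel$windows$end <= end)
  if (!length(pidx)) stop_input("region absent from panel grid")
  if (length(idx) < 2) stop_input("region must span >= 2 windows")
  x <- w$ratio[idx]
  if (mode == "pooled") {
    res <- ranksum_test(x, as.numeric(panel$ratios[pidx, ]))
    return(list(p = res$p, keep = res$p < alpha, n_windows = length(idx),
                method = res$method))
  }
  ps <- apply(panel$ratios[pidx, , drop = FALSE], 2,
              function(y) ranksum_test(x, y)$p)
  list(p = max(ps), keep = max(ps) < alpha, n_windows = length(idx),
       method = "per-sample-max rank-sum")
}

#' Report a CNV size in kb to one decimal
#'
#' Coordinates are 1-based inclusive, so the span is `end - start + 1` bp.
#'
#' @param start,end breakpoint coordinates (bp, 1-based inclusive)
#' @return size in kb, one decimal (half up)
#' @export
cnv_size_kb <- function(start, end) {
  if (any(end < start)) stop_input("end < start")
  round_half_up((end - start + 1) / 1000, 1)
}

#' Full read-depth CNV calling cascade
#'
#' normalize -> sliding-window scan -> breakpoint refinement -> panel
#' rarity screen, returning one row per surviving call.
#'
#' @param profile a `window_profile` (normalized automatically if needed)
#' @param panel optional [reference_panel()]; when given it is used both
#'   for normalization and for the rarity screen
#' @param min_size_kb minimum reportable size (default 25 kb = 5 windows)
#' @param alpha rarity threshold
#' @param ... passed to [scan_candidates()]
#' @return data.frame of CNV calls with rarity p-values and keep flags
#' @export
call_cnvs <- function(profile, panel = NULL, min_size_kb = 25,
                      alpha = 1e-4, gc_correct = FALSE, ...) {
  if (all(is.na(profile$windows$ratio)))
    profile <- normalize_windows(profile, panel, gc_correct = gc_correct)
  cands <- scan_candidates(profile, ...)
  calls <- list()
  for (i in seq_len(nrow(cands))) {
    call <- tryCatch(refine_breakpoints(profile, cands[i, ]),
                     error = function(e) NULL)
    if (is.null(call) || call$size_kb < min_size_kb) next
    if (!is.null(panel) && call$level == "segment") {
      rt <- rare_cnv_test(profile, panel, call$chrom, call$start, call$end,
                          alpha = alpha)
      call$p_rare <- rt$p; call$keep <- rt$keep
    } else {
      call$p_rare <- NA_real_; call$keep <- TRUE
    }
    calls[[length(calls) + 1]] <- call
  }
  if (!length(calls))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      type = character(), mean_ratio = numeric(),
                      mosaic_fraction = numeric(), size_kb = numeric(),
                      level = character(), p_rare = numeric(),
                      keep = logical()))
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
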