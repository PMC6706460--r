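# chromosome ordering used to canonicalize pair ends (numeric, then X, Y)
chrom_rank <- function(chrom) {
  s <- sub("^chr", "", chrom)
  n <- suppressWarnings(as.numeric(s))
  n[s == "X"] <- 1e3; n[s == "Y"] <- 1e3 + 1
  n[is.na(n)] <- 2e3 + as.integer(factor(s[is.na(n)]))
  n
}

# joining side encoded from the read strand: a "+" read's joined side lies
# downstream of its position ("D"), a "-" read's upstream ("U")
strand_side <- function(strand) ifelse(strand == "+", "D", "U")

#' Extract chimeric read pairs from a pair table
#'
#' Keeps interchromosomal pairs and same-chromosome pairs separated by
#' strictly more than `distance_cutoff` bp (default 10 kb, beyond any
#' plausible insert), dropping pairs where either read is below the
#' mapping-quality floor. Ends are canonicalized so the lower
#' chromosome/coordinate side comes first; strands travel with their
#' reads.
#'
#' @param pairs pair table (chrom1, pos1, strand1, mapq1, chrom2, pos2,
#'   strand2, mapq2, ...)
#' @param distance_cutoff same-chromosome separation cutoff in bp (> 0)
#' @param min_mapq minimum per-read mapping quality
#' @return filtered, canonicalized pair table with a `type` column
#'   (two-letter joining type, e.g. "DU")
#' @export
extract_chimeric_pairs <- function(pairs, distance_cutoff = 10000,
                                   min_mapq = 30) {
  if (distance_cutoff <= 0) stop_input("cutoff must be > 0")
  need <- c("chrom1", "pos1", "strand1", "mapq1",
            "chrom2", "pos2", "strand2", "mapq2")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop_input("malformed pair table, missing: ",
                               paste(miss, collapse = ", "))
  bad <- which(!pairs$strand1 %in% c("+", "-") | !pairs$strand2 %in% c("+", "-") |
                 is.na(pairs$pos1) | is.na(pairs$pos2))
  if (length(bad))
    stop_input("malformed pair record at line ", bad[1])
  keep <- (pairs$mapq1 >= min_mapq & pairs$mapq2 >= min_mapq) &
    (pairs$chrom1 != pairs$chrom2 |
       abs(pairs$pos1 - pairs$pos2) > distance_cutoff)
  p <- pairs[keep, , drop = FALSE]
  swap <- chrom_rank(p$chrom1) > chrom_rank(p$chrom2) |
    (p$chrom1 == p$chrom2 & p$pos1 > p$pos2)
  if (any(swap)) {
    tmp <- p[swap, ]
    p[swap, c("chrom1", "pos1", "strand1", "mapq1")] <-
      tmp[, c("chrom2", "pos2", "strand2", "mapq2")]
    p[swap, c("chrom2", "pos2", "strand2", "mapq2")] <-
      tmp[, c("chrom1", "pos1", "strand1", "mapq1")]
  }
  p$type <- paste0(strand_side(p$strand1), strand_side(p$strand2))
  rownames(p) <- NULL
  p
}

#' Cluster chimeric pairs by sorted coordinates
#'
#' Single pass over pairs sorted by (chromosome pair, joining type,
#' coordinates): a pair joins an open cluster iff it shares the
#' chromosome pair and joining type and extends both footprints by at
#' most `window` bp. Output is independent of input order (sorting is
#' internal).
#'
#' @param pairs canonicalized pairs from [extract_chimeric_pairs()]
#' @param window clustering window in bp (default 1000, about twice the
#'   insert-size spread)
#' @param read_len read length, used for breakpoint estimates
#' @return data.frame of clusters: chrom1, foot1_min, foot1_max, bp1,
#'   chrom2, foot2_min, foot2_max, bp2, type, n_support, span1, span2,
#'   strand_consistency, median_mapq, members (list of pair row indices
#'   in the sorted order)
#' @export
cluster_pairs <- function(pairs, window = 1000, read_len = 100) {
  if (nrow(pairs) == 0) return(empty_cluster_table())
  if (is.null(pairs$type))
    pairs$type <- paste0(strand_side(pairs$strand1), strand_side(pairs$strand2))
  o <- order(chrom_rank(pairs$chrom1), chrom_rank(pairs$chrom2),
             pairs$type, pairs$pos1, pairs$pos2)
  p <- pairs[o, , drop = FALSE]
  key <- paste(p$chrom1, p$chrom2, p$type)
  open <- list()   # open clusters for the current key
  done <- list()
  cur_key <- ""
  flush <- function() { done[seq_along(open) + length(done)] <<- open; open <<- list() }
  for (i in seq_len(nrow(p))) {
    if (key[i] != cur_key) { flush(); cur_key <- key[i] }
    placed <- FALSE
    drop <- logical(length(open))
    for (ci in seq_along(open)) {
      cl <- open[[ci]]
      if (p$pos1[i] - cl$max1 > window) { drop[ci] <- TRUE; next }
      ext2 <- max(0, p$pos2[i] - cl$max2, cl$min2 - p$pos2[i])
      if (!placed && p$pos1[i] - cl$max1 <= window && ext2 <= window) {
        cl$max1 <- max(cl$max1, p$pos1[i]); cl$min1 <- min(cl$min1, p$pos1[i])
        cl$max2 <- max(cl$max2, p$pos2[i]); cl$min2 <- min(cl$min2, p$pos2[i])
        cl$members <- c(cl$members, i)
        open[[ci]] <- cl
        placed <- TRUE
      }
    }
    if (any(drop)) { done[seq_len(sum(drop)) + length(done)] <- open[drop]; open <- open[!drop] }
    if (!placed)
      open[[length(open) + 1]] <- list(chrom1 = p$chrom1[i], chrom2 = p$chrom2[i],
                                       type = p$type[i],
                                       min1 = p$pos1[i], max1 = p$pos1[i],
                                       min2 = p$pos2[i], max2 = p$pos2[i],
                                       members = i)
  }
  flush()
  rows <- lapply(done, function(cl) {
    m <- cl$members
    side1 <- substr(cl$type, 1, 1); side2 <- substr(cl$type, 2, 2)
    bp_est <- function(side, mn, mx) if (side == "D") mx + read_len else mn
    sc <- max(table(paste(p$strand1[m], p$strand2[m]))) / length(m)
    data.frame(chrom1 = cl$chrom1, foot1_min = cl$min1, foot1_max = cl$max1,
               bp1 = bp_est(side1, cl$min1, cl$max1),
               chrom2 = cl$chrom2, foot2_min = cl$min2, foot2_max = cl$max2,
               bp2 = bp_est(side2, cl$min2, cl$max2),
               type = cl$type, n_support = length(m),
               span1 = cl$max1 - cl$min1 + 1, span2 = cl$max2 - cl$min2 + 1,
               strand_consistency = sc,
               median_mapq = stats::median(c(p$mapq1[m], p$mapq2[m])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- I(lapply(done, function(cl) p$pair_id[cl$members]))
  o2 <- order(chrom_rank(out$chrom1), out$foot1_min,
              chrom_rank(out$chrom2), out$foot2_min, out$type)
  out <- out[o2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_cluster_table <- function() {
  data.frame(chrom1 = character(), foot1_min = numeric(), foot1_max = numeric(),
             bp1 = numeric(), chrom2 = character(), foot2_min = numeric(),
             foot2_max = numeric(), bp2 = numeric(), type = character(),
             n_support = integer(), span1 = numeric(), span2 = numeric(),
             strand_consistency = numeric(), median_mapq = numeric())
}

# reciprocal overlap fraction of two closed intervals, relative to each
reciprocal_overlap <- function(a1, a2, b1, b2) {
  ov <- max(0, min(a2, b2) - max(a1, b1) + 1)
  c(ov / (a2 - a1 + 1), ov / (b2 - b1 + 1))
}

#' Systematic-error filter: drop clusters shared with a control set
#'
#' A cluster is a systematic artifact if a control cluster with the same
#' chromosome pair and joining type reciprocally overlaps both of its
#' footprints by at least `min_overlap` in both directions.
#'
#' @param clusters case clusters from [cluster_pairs()]
#' @param control control clusters built with the same parameters
#' @param min_overlap reciprocal-overlap fraction (default 0.5)
#' @param read_len footprint padding on the joined side
#' @return surviving clusters (a subset of the input)
#' @export
filter_systematic <- function(clusters, control, min_overlap = 0.5,
                              read_len = 100) {
  if (nrow(clusters) == 0 || is.null(control) || nrow(control) == 0)
    return(clusters)
  pad <- function(df, i, side) {
    mn <- df[[paste0("foot", side, "_min")]][i]
    mx <- df[[paste0("foot", side, "_max")]][i] + read_len
    c(mn, mx)
  }
  sys <- vapply(seq_len(nrow(clusters)), function(i) {
    cand <- which(control$chrom1 == clusters$chrom1[i] &
                    control$chrom2 == clusters$chrom2[i] &
                    control$type == clusters$type[i])
    for (j in cand) {
      o1 <- reciprocal_overlap(pad(clusters, i, 1)[1], pad(clusters, i, 1)[2],
                               pad(control, j, 1)[1], pad(control, j, 1)[2])
      o2 <- reciprocal_overlap(pad(clusters, i, 2)[1], pad(clusters, i, 2)[2],
                               pad(control, j, 2)[1], pad(control, j, 2)[2])
      if (all(c(o1, o2) >= min_overlap)) return(TRUE)
    }
    FALSE
  }, logical(1))
  clusters[!sys, , drop = FALSE]
}

#' Random-error filter: threshold the cluster property matrix
#'
#' Keeps a cluster iff every property passes: supporting-pair count,
#' footprint spans, strand consistency, and median mapping quality.
#' Monotone in each threshold; survivors are a subset of the input.
#'
#' @param clusters clusters from [cluster_pairs()]
#' @param min_support minimum supporting pairs (default 4)
#' @param max_span maximum footprint span in bp (default 1500)
#' @param min_strand_consistency minimum modal-strand fraction (default 1)
#' @param min_mapq minimum median mapping quality (default 30)
#' @return surviving clusters
#' @export
filter_random <- function(clusters, min_support = 4, max_span = 1500,
                          min_strand_consistency = 1, min_mapq = 30) {
  if (min_support <= 0 || max_span <= 0) stop_input("thresholds must be positive")
  if (nrow(clusters) == 0) return(clusters)
  keep <- clusters$n_support >= min_support &
    clusters$span1 <= max_span & clusters$span2 <= max_span &
    clusters$strand_consistency >= min_strand_consistency &
    clusters$median_mapq >= min_mapq
  clusters[keep, , drop = FALSE]
}

flip_type <- function(type) chartr("DU", "UD", type)

#' Type structural events from filtered clusters (joining-type step)
#'
#' The orientation step of the cascade: clusters are grouped by locus and
#' interpreted through their joining types. Two same-chromosome clusters
#' with the complementary "DD" and "UU" types and matching footprints are
#' an inversion; two interchromosomal clusters with complementary types
#' and co-located footprints on both sides are a reciprocal
#' translocation; two or more interchromosomal clusters sharing a narrow
#' receptor footprint on one chromosome and flanking an interval on the
#' other are an insertion (the receptor side is the co-located one, the
#' source interval spans the outer junction estimates). Anything else is
#' reported complex/unresolved with a reason.
#'
#' @param clusters filtered clusters
#' @param match_tol breakpoint co-location tolerance in bp for pairing
#'   junctions (default 2000, about insert scale)
#' @return data.frame of events: type, chromA, bpA, chromB, bpB,
#'   receptor_chrom, receptor_pos, source_chrom, source_start,
#'   source_end, size_kb, n_support, reason
#' @export
classify_events <- function(clusters, match_tol = 2000) {
  ev <- list()
  emit <- function(...) ev[[length(ev) + 1]] <<- event_row(...)
  cl <- clusters
  used <- rep(FALSE, nrow(cl))

  # same-chromosome: complementary DD/UU pairs -> inversion
  same <- which(cl$chrom1 == cl$chrom2)
  for (i in same) {
    if (used[i]) next
    j <- same[!used[same] & same != i &
                cl$type[same] == flip_type(cl$type[i]) &
                cl$type[same] %in% c("DD", "UU") & cl$type[i] %in% c("DD", "UU") &
                abs(cl$bp1[same] - cl$bp1[i]) <= match_tol &
                abs(cl$bp2[same] - cl$bp2[i]) <= match_tol]
    if (length(j)) {
      j <- j[1]; used[c(i, j)] <- TRUE
      emit(type = "inversion", chromA = cl$chrom1[i],
           bpA = round(mean(cl$bp1[c(i, j)])), chromB = cl$chrom2[i],
           bpB = round(mean(cl$bp2[c(i, j)])),
           n_support = sum(cl$n_support[c(i, j)]))
    }
  }

  # interchromosomal clusters: group into locus components (two clusters
  # are linked when their footprints co-locate on at least one side), so
  # independent events sharing a chromosome pair stay separate
  inter <- which(cl$chrom1 != cl$chrom2 & !used)
  if (length(inter)) {
    comp <- seq_along(inter)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (a in seq_along(inter)) for (b in seq_len(a - 1L)) {
      i <- inter[a]; j <- inter[b]
      if (cl$chrom1[i] != cl$chrom1[j] || cl$chrom2[i] != cl$chrom2[j]) next
      if (abs(cl$bp1[i] - cl$bp1[j]) <= match_tol ||
          abs(cl$bp2[i] - cl$bp2[j]) <= match_tol)
        comp[find(a)] <- find(b)
    }
    roots <- vapply(seq_along(inter), find, integer(1))
    for (rt in unique(roots)) {
      g <- inter[roots == rt]
      if (length(g) >= 2) {
        co1 <- diff(range(cl$bp1[g])) <= match_tol
        co2 <- diff(range(cl$bp2[g])) <= match_tol
        if (co1 && co2 && length(g) == 2 &&
            cl$type[g[1]] == flip_type(cl$type[g[2]])) {
          used[g] <- TRUE
          emit(type = "translocation", chromA = cl$chrom1[g[1]],
               bpA = round(mean(cl$bp1[g])), chromB = cl$chrom2[g[1]],
               bpB = round(mean(cl$bp2[g])), n_support = sum(cl$n_support[g]))
          next
        }
        if (xor(co1, co2)) {
          rec_side <- if (co1) 1 else 2
          src_side <- 3 - rec_side
          src_bp <- cl[[paste0("bp", src_side)]][g]
          # joining consistency: receptor needs both its sides (D and U)
          rec_types <- substr(cl$type[g], rec_side, rec_side)
          if (all(c("D", "U") %in% rec_types)) {
            used[g] <- TRUE
            emit(type = "insertion",
                 chromA = cl[[paste0("chrom", rec_side)]][g[1]],
                 bpA = round(mean(cl[[paste0("bp", rec_side)]][g])),
                 chromB = cl[[paste0("chrom", src_side)]][g[1]],
                 bpB = round(min(src_bp)),
                 receptor_chrom = cl[[paste0("chrom", rec_side)]][g[1]],
                 receptor_pos = round(mean(cl[[paste0("bp", rec_side)]][g])),
                 source_chrom = cl[[paste0("chrom", src_side)]][g[1]],
                 source_start = round(min(src_bp)),
                 source_end = round(max(src_bp)),
                 n_support = sum(cl$n_support[g]))
            next
          }
        }
      }
    }
  }

  # leftovers are unresolved
  for (i in which(!used)) {
    emit(type = "complex", chromA = cl$chrom1[i], bpA = cl$bp1[i],
         chromB = cl$chrom2[i], bpB = cl$bp2[i], n_support = cl$n_support[i],
         reason = if (cl$chrom1[i] == cl$chrom2[i])
           "unpaired intrachromosomal junction" else "single interchromosomal cluster")
  }
  if (!length(ev)) return(empty_event_table())
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

event_row <- function(type, chromA, bpA, chromB, bpB, n_support,
                      receptor_chrom = NA_character_, receptor_pos = NA_real_,
                      source_chrom = NA_character_, source_start = NA_real_,
                      source_end = NA_real_, reason = NA_character_) {
  data.frame(type = type, chromA = chromA, bpA = bpA, chromB = chromB,
             bpB = bpB, receptor_chrom = receptor_chrom,
             receptor_pos = receptor_pos, source_chrom = source_chrom,
             source_start = source_start, source_end = source_end,
             size_kb = if (!is.na(source_start)) cnv_size_kb(source_start, source_end)
                       else NA_real_,
             n_support = n_support, reason = reason, stringsAsFactors = FALSE)
}

empty_event_table <- function() {
  data.frame(type = character(), chromA = character(), bpA = numeric(),
             chromB = character(), bpB = numeric(),
             receptor_chrom = character(), receptor_pos = numeric(),
             source_chrom = character(), source_start = numeric(),
             source_end = numeric(), size_kb = numeric(),
             n_support = integer(), reason = character())
}

#' Full chimeric-pair SV calling cascade
#'
#' extraction -> clustering -> systematic filter -> random filter ->
#' joining-type classification, in that fixed order.
#'
#' @param case_pairs,control_pairs raw pair tables
#' @param distance_cutoff,min_mapq see [extract_chimeric_pairs()]
#' @param window clustering window (bp)
#' @param ... thresholds passed to [filter_random()]
#' @return event table from [classify_events()]
#' @export
call_svs <- function(case_pairs, control_pairs = NULL,
                     distance_cutoff = 10000, min_mapq = 30,
                     window = 1000, ...) {
  cc <- cluster_pairs(extract_chimeric_pairs(case_pairs, distance_cutoff,
                                             min_mapq), window)
  ctrl <- if (!is.null(control_pairs))
    cluster_pairs(extract_chimeric_pairs(control_pairs, distance_cutoff,
                                         min_mapq), window)
  cc <- filter_systematic(cc, ctrl)
  cc <- filter_random(cc, ...)
  classify_events(cc)
}

#' Characterize a breakpoint junction sequence
#'
#' Aligns the junction against the two reference flanks: the longest
#' junction prefix matching a suffix of flank A and the longest junction
#' suffix matching a prefix of flank B. A gap between the two anchors is
#' a non-templated insertion; an overlap is microhomology (mutually
#' exclusive).
#'
#' @param junction junction sequence (uppercase ACGT)
#' @param flank_a reference sequence ending at breakpoint A (>= 20 bases)
#' @param flank_b reference sequence starting at breakpoint B (>= 20 bases)
#' @param min_anchor minimum matched bases per flank to accept alignment
#' @return list: insert_len, insert_seq, microhomology
#' @export
characterize_junction <- function(junction, flank_a, flank_b,
                                  min_anchor = 10) {
  up <- function(s) toupper(s)
  junction <- up(junction); flank_a <- up(flank_a); flank_b <- up(flank_b)
  if (nchar(flank_a) < 20 || nchar(flank_b) < 20)
    stop_input("flanks must each be >= 20 bases")
  nj <- nchar(junction)
  pre <- 0
  for (k in seq_len(min(nj, nchar(flank_a)))) {
    if (substr(junction, 1, k) ==
        substr(flank_a, nchar(flank_a) - k + 1, nchar(flank_a))) pre <- k
  }
  suf <- 0
  for (k in seq_len(min(nj, nchar(flank_b)))) {
    if (substr(junction, nj - k + 1, nj) == substr(flank_b, 1, k)) suf <- k
  }
  if (pre < min_anchor || suf < min_anchor)
    stop_input("junction matches neither flank: alignment error")
  if (pre + suf < nj) {
    list(insert_len = nj - pre - suf,
         insert_seq = substr(junction, pre + 1, nj - suf),
         microhomology = 0L)
  } else {
    list(insert_len = 0L, insert_seq = "",
         microhomology = pre + suf - nj)
  }
}

#' Lost source segments of a complex insertion
#'
#' A complex insertion can shatter its source interval into fragments,
#' some of which are lost on insertion. Given the source interval and the
#' retained fragment list, returns the uncovered sub-intervals.
#'
#' @param source_start,source_end source interval (1-based inclusive)
#' @param fragments data.frame with columns start, end of retained
#'   fragments (any order, may touch)
#' @return data.frame of lost segments (start, end); zero rows if fully
#'   covered
#' @export
lost_segments <- function(source_start, source_end, fragments) {
  f <- fragments[order(fragments$start), , drop = FALSE]
  lost <- list()
  cursor <- source_start
  for (i in seq_len(nrow(f))) {
    if (f$start[i] > cursor)
      lost[[length(lost) + 1]] <- c(cursor, f$start[i] - 1)
    cursor <- max(cursor, f$end[i] + 1)
  }
  if (cursor <= source_end)
    lost[[length(lost) + 1]] <- c(cursor, source_end)
  if (!length(lost)) return(data.frame(start = numeric(), end = numeric()))
  out <- do.call(rbind, lost)
  data.frame(start = out[, 1], end = out[, 2])
}
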