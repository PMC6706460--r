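#' Simulate chimeric read-pair tables for a case and a control
#'
#' Every true SV in the truth set contributes one coherent read-pair
#' cluster per junction: pair coordinates fall within an insert-size
#' window of the breakpoints and strands follow the event's joining type
#' (read strand "+" means the joined side lies downstream of the read,
#' "-" upstream). Random noise pairs are uniform over the genome with
#' random strands; systematic-artifact clusters are planted at identical
#' coordinates in BOTH the case and the control table, which is what the
#' systematic filter exploits.
#'
#' @param genome a [genome_spec()]
#' @param truth a [truth_set()] whose `svs` are planted in the case table
#' @param cfg a [sim_config()]
#' @param seed integer seed
#' @return list with elements `case` and `control`, each a BEDPE-like
#'   data.frame (chrom1, pos1, strand1, mapq1, chrom2, pos2, strand2,
#'   mapq2, pair_id, origin)
#' @export
simulate_chimeric_pairs <- function(genome, truth = NULL, cfg = sim_config(),
                                    seed = 1L) {
  seeds <- derive_seeds(seed, 3)
  svs <- if (!is.null(truth)) truth$svs else NULL

  set.seed(seeds[1])
  sv_pairs <- do.call(rbind, lapply(seq_along(svs %||% list()), function(i) {
    sv <- svs[[i]]
    js <- sv_junctions(sv)
    do.call(rbind, lapply(seq_along(js), function(k) {
      j <- js[[k]]
      junction_pairs(j, sv$n_pairs, cfg,
                     origin = paste0("sv", i, "_j", k))
    }))
  }))

  # artifacts are generated from per-site seeds so coordinates are
  # byte-identical between case and control
  art <- cfg$artifact_sites
  art_seeds <- derive_seeds(97L, nrow(art) %||% 0L)
  art_pairs <- do.call(rbind, lapply(seq_len(nrow(art) %||% 0L), function(i) {
    set.seed(art_seeds[i])
    j <- list(chromA = art$chromA[i], posA = art$posA[i], sideA = art$sideA[i],
              chromB = art$chromB[i], posB = art$posB[i], sideB = art$sideB[i])
    junction_pairs(j, art$n_pairs[i], cfg, origin = paste0("artifact", i))
  }))

  case <- rbind(sv_pairs, art_pairs, noise_pairs_tbl(genome, cfg, seeds[2]))
  ctrl <- rbind(art_pairs, noise_pairs_tbl(genome, cfg, seeds[3]))
  finalize_pairs <- function(p) {
    if (is.null(p)) p <- empty_pair_table()
    if (nrow(p)) p$pair_id <- sprintf("p%06d", seq_len(nrow(p)))
    rownames(p) <- NULL
    p
  }
  list(case = finalize_pairs(case), control = finalize_pairs(ctrl))
}

empty_pair_table <- function() {
  data.frame(chrom1 = character(), pos1 = numeric(), strand1 = character(),
             mapq1 = integer(), chrom2 = character(), pos2 = numeric(),
             strand2 = character(), mapq2 = integer(),
             pair_id = character(), origin = character())
}

# junction list for one SV: each junction joins sideA of (chromA, posA)
# to sideB of (chromB, posB). "D" = downstream of the breakpoint is joined
# (supporting reads map "+" before it), "U" = upstream ("-" after it).
sv_junctions <- function(sv) {
  switch(sv$type,
    translocation = list(
      list(chromA = sv$chromA, posA = sv$posA, sideA = "D",
           chromB = sv$chromB, posB = sv$posB, sideB = "U"),
      list(chromA = sv$chromA, posA = sv$posA, sideA = "U",
           chromB = sv$chromB, posB = sv$posB, sideB = "D")),
    inversion = list(
      list(chromA = sv$chrom, posA = sv$start, sideA = "D",
           chromB = sv$chrom, posB = sv$end, sideB = "D"),
      list(chromA = sv$chrom, posA = sv$start, sideA = "U",
           chromB = sv$chrom, posB = sv$end, sideB = "U")),
    insertion = list(
      list(chromA = sv$receptor_chrom, posA = sv$receptor_pos, sideA = "D",
           chromB = sv$source_chrom, posB = sv$source_start, sideB = "U"),
      list(chromA = sv$receptor_chrom, posA = sv$receptor_pos, sideA = "U",
           chromB = sv$source_chrom, posB = sv$source_end, sideB = "D")),
    stop_input("SV with undefined joining type/kind: ", sv$type)
  )
}

# place n read pairs around one junction; the read on side "D" maps "+"
# at pos = breakpoint - d (its end stays <= breakpoint), on side "U" maps
# "-" starting just after the breakpoint
junction_pairs <- function(j, n, cfg, origin) {
  L <- pmax(round(stats::rnorm(n, cfg$insert_mean, cfg$insert_sd)),
            2 * cfg$read_len + 10)
  u <- floor(stats::runif(n, cfg$read_len, L - cfg$read_len + 1))
  place <- function(chrom, pos, side, d) {
    if (side == "D") list(chrom = chrom, pos = round(pos - d), strand = "+")
    else list(chrom = chrom, pos = round(pos + d - cfg$read_len), strand = "-")
  }
  a <- place(j$chromA, j$posA, j$sideA, u)
  b <- place(j$chromB, j$posB, j$sideB, L - u)
  data.frame(chrom1 = a$chrom, pos1 = a$pos, strand1 = a$strand, mapq1 = 60L,
             chrom2 = b$chrom, pos2 = b$pos, strand2 = b$strand, mapq2 = 60L,
             pair_id = NA_character_, origin = origin)
}

noise_pairs_tbl <- function(genome, cfg, seed) {
  set.seed(seed)
  n <- stats::rpois(1, cfg$noise_pairs)
  if (n == 0) return(NULL)
  pick <- function(k) {
    ch <- sample(genome$chroms, k, replace = TRUE,
                 prob = genome$lengths / sum(genome$lengths))
    pos <- floor(stats::runif(k, 1, genome$lengths[ch]))
    list(chrom = ch, pos = pos)
  }
  a <- pick(n); b <- pick(n)
  data.frame(chrom1 = a$chrom, pos1 = a$pos,
             strand1 = sample(c("+", "-"), n, replace = TRUE),
             mapq1 = sample(0:60, n, replace = TRUE),
             chrom2 = b$chrom, pos2 = b$pos,
             strand2 = sample(c("+", "-"), n, replace = TRUE),
             mapq2 = sample(0:60, n, replace = TRUE),
             pair_id = NA_character_, origin = "noise")
}

#' Write / read a pair table as BEDPE
#'
#' BEDPE is 0-based half-open; the in-memory representation is 1-based
#' read-start positions, converted on the way out and back in.
#'
#' @param pairs pair table as from [simulate_chimeric_pairs()]
#' @param path file path
#' @param read_len read length used to form the end coordinates
#' @export
write_bedpe <- function(pairs, path, read_len = 100) {
  out <- data.frame(chrom1 = pairs$chrom1, start1 = pairs$pos1 - 1L,
                    end1 = pairs$pos1 - 1L + read_len,
                    chrom2 = pairs$chrom2, start2 = pairs$pos2 - 1L,
                    end2 = pairs$pos2 - 1L + read_len,
                    name = pairs$pair_id,
                    score = pmin(pairs$mapq1, pairs$mapq2),
                    strand1 = pairs$strand1, strand2 = pairs$strand2,
                    mapq1 = pairs$mapq1, mapq2 = pairs$mapq2)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' @rdname write_bedpe
#' @export
read_bedpe <- function(path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "score", "strand1", "strand2", "mapq1", "mapq2")
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) < 10) stop_input("malformed BEDPE: expected >= 10 columns")
  names(x)[seq_len(min(ncol(x), 12))] <- cols[seq_len(min(ncol(x), 12))]
  if (is.null(x$mapq1)) { x$mapq1 <- x$score; x$mapq2 <- x$score }
  data.frame(chrom1 = x$chrom1, pos1 = x$start1 + 1L, strand1 = x$strand1,
             mapq1 = x$mapq1, chrom2 = x$chrom2, pos2 = x$start2 + 1L,
             strand2 = x$strand2, mapq2 = x$mapq2, pair_id = x$name,
             origin = NA_character_)
}
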