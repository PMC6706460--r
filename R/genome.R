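#' Construct a genome specification
#'
#' A `genome_spec` holds the coordinate frame every other module works in:
#' chromosome names and lengths, the p/q arm boundary, and a cytoband map
#' used for ISCN band lookup. Coordinates are 1-based inclusive throughout
#' the package (the convention of ISCN `g.start_end` notation); BED-dialect
#' files are converted on read.
#'
#' @param chroms character vector of chromosome names (e.g. "chr1")
#' @param lengths integer vector of chromosome lengths in bp
#' @param centromeres integer vector, p/q boundary per chromosome
#' @param cytobands data.frame with columns chrom, start, end, band, stain
#'   (1-based inclusive). Bands must tile each chromosome without overlap.
#' @return object of class `genome_spec`
#' @export
genome_spec <- function(chroms, lengths, centromeres, cytobands) {
  if (any(lengths <= 0)) stop_input("chromosome lengths must be > 0")
  if (length(chroms) != length(lengths) || length(chroms) != length(centromeres))
    stop_input("chroms, lengths, centromeres must have equal length")
  names(lengths) <- chroms
  names(centromeres) <- chroms
  for (ch in chroms) {
    b <- cytobands[cytobands$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) == 0) stop_input("no cytobands for ", ch)
    if (b$start[1] != 1 || b$end[nrow(b)] != lengths[[ch]] ||
        (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)] + 1)))
      stop_input("cytobands do not tile ", ch)
  }
  structure(list(chroms = chroms, lengths = lengths,
                 centromeres = centromeres, cytobands = cytobands),
            class = "genome_spec")
}

#' Reduced default genome fixture
#'
#' A five-chromosome genome (three autosomes plus X and Y, 10-60 Mb each)
#' at desk scale. Bands are 5-Mb tiles labelled outward from the centromere
#' (p11, p12, ... towards pter; q11, q12, ... towards qter), so band lookup
#' and ISCN emission behave like they would on a full cytoband file. Full
#' genome specifications load through [read_cytoband_map()].
#'
#' @return a [genome_spec()]
#' @export
default_genome <- function() {
  def <- data.frame(
    chrom = c("chr1", "chr2", "chr3", "chrX", "chrY"),
    len = c(60e6, 50e6, 40e6, 30e6, 10e6),
    cen = c(30e6, 20e6, 15e6, 12e6, 4e6)
  )
  bands <- do.call(rbind, lapply(seq_len(nrow(def)), function(i) {
    with(def[i, ], {
      pb <- rev(seq(1, cen, by = 5e6))          # band starts, pter <- cen
      p <- data.frame(start = rev(pb), end = c(rev(pb)[-1] - 1, cen))
      p$band <- paste0("p", 10 + rev(seq_len(nrow(p))))
      qb <- seq(cen + 1, len, by = 5e6)
      q <- data.frame(start = qb, end = c(qb[-1] - 1, len))
      q$band <- paste0("q", 10 + seq_len(nrow(q)))
      out <- rbind(p, q)
      data.frame(chrom = chrom, start = out$start, end = out$end,
                 band = out$band, stain = "gneg")
    })
  }))
  genome_spec(def$chrom, def$len, def$cen, bands)
}

#' Look up the cytoband containing a position
#'
#' @param genome a [genome_spec()]
#' @param chrom chromosome name
#' @param pos 1-based position
#' @return band label (e.g. "p11.2")
#' @export
band_at <- function(genome, chrom, pos) {
  b <- genome$cytobands
  hit <- b$chrom == chrom & b$start <= pos & b$end >= pos
  if (!any(hit)) stop_input("no cytoband at ", chrom, ":", pos)
  b$band[which(hit)[1]]
}

#' Read a UCSC-style cytoband file into a genome_spec
#'
#' Expects the cytoBand.txt dialect (chrom, start, end, band, stain;
#' 0-based half-open), converted to 1-based inclusive on read. Chromosome
#' lengths come from the last band; the centromere is placed at the
#' p/q band transition (acen midpoint when stains are present).
#'
#' @param path cytoband TSV path
#' @return a [genome_spec()]
#' @export
read_cytoband_map <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "band", "stain"),
                         stringsAsFactors = FALSE)
  b$start <- b$start + 1L  # BED dialect -> 1-based inclusive
  chroms <- unique(b$chrom)
  lengths <- vapply(chroms, function(ch) max(b$end[b$chrom == ch]), numeric(1))
  cens <- vapply(chroms, function(ch) {
    bb <- b[b$chrom == ch, ]
    q1 <- bb[grepl("^q", bb$band), ]
    if (nrow(q1) == 0) max(bb$end) else min(q1$start) - 1
  }, numeric(1))
  genome_spec(chroms, lengths, cens, b)
}

#' Write a genome_spec's cytobands as a UCSC-style cytoband file
#'
#' @param genome a [genome_spec()]
#' @param path output TSV path (0-based half-open, cytoBand.txt dialect)
#' @export
write_cytoband_map <- function(genome, path) {
  b <- genome$cytobands
  b$start <- b$start - 1L
  utils::write.table(b, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Build the 5-kb window grid over a genome
#'
#' @param genome a [genome_spec()]
#' @param window_bp window size in bp (default 5000, the breakpoint-precision
#'   grid). The final window of each chromosome absorbs the tail.
#' @param gc per-window GC model: "flat" fixes 0.5 everywhere; "wave" adds a
#'   smooth sinusoidal profile in (0.35, 0.65) used to exercise GC correction.
#' @return data.frame (chrom, start, end, gc), 1-based inclusive
#' @export
make_windows <- function(genome, window_bp = 5000, gc = c("flat", "wave")) {
  gc <- match.arg(gc)
  out <- do.call(rbind, lapply(genome$chroms, function(ch) {
    len <- genome$lengths[[ch]]
    starts <- seq(1, len, by = window_bp)
    ends <- pmin(starts + window_bp - 1, len)
    # drop a trailing sliver shorter than half a window into the previous one
    if (length(starts) > 1 && (ends[length(ends)] - starts[length(starts)] + 1) < window_bp / 2) {
      ends[length(ends) - 1] <- ends[length(ends)]
      starts <- starts[-length(starts)]; ends <- ends[-length(ends)]
    }
    data.frame(chrom = ch, start = starts, end = ends)
  }))
  out$gc <- if (gc == "flat") 0.5 else 0.5 + 0.15 * sin(out$start / 7.3e5)
  rownames(out) <- NULL
  out
}
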