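#' Read / write a window profile as 6-column TSV
#'
#' The on-disk dialect is BED-like (0-based half-open starts) with
#' columns chrom, start, end, count, gc, ratio; in memory coordinates are
#' 1-based inclusive.
#'
#' @param profile a `window_profile`
#' @param path TSV path
#' @export
write_windows <- function(profile, path) {
  w <- profile$windows
  out <- data.frame(chrom = w$chrom, start = w$start - 1L, end = w$end,
                    count = w$count, gc = w$gc, ratio = w$ratio)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_windows
#' @param sample_id sample id for the returned profile
#' @param sex sample sex ("male"/"female") if known
#' @export
read_windows <- function(path, sample_id = basename(path), sex = NULL) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "count")
  if (!all(need %in% names(x))) stop_input("window TSV needs columns: ",
                                           paste(need, collapse = ", "))
  w <- data.frame(chrom = x$chrom, start = x$start + 1L, end = x$end,
                  count = x$count, gc = x$gc %||% 0.5,
                  ratio = x$ratio %||% NA_real_)
  structure(list(sample_id = sample_id, sex = sex, windows = w),
            class = "window_profile")
}

#' Write CNV calls as TSV
#'
#' @param calls call table from [call_cnvs()]
#' @param path TSV path
#' @export
write_cnv_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write typed SV events as TSV (list columns dropped)
#'
#' @param events event table from [classify_events()]
#' @param path TSV path
#' @export
write_sv_events <- function(events, path) {
  flat <- events[, !vapply(events, is.list, logical(1)), drop = FALSE]
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
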