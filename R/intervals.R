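#' Genomic intervals (1-based, inclusive)
#'
#' All coordinates inside the package are 1-based and inclusive, matching
#' the `samtools depth` convention: an interval (101629, 102226) spans
#' 102226 - 101629 + 1 = 598 bp. Conversion to BED's 0-based half-open
#' convention happens only in [write_bed()] / [read_bed()].
#'
#' @param contig contig/scaffold name (scalar character)
#' @param start,end 1-based inclusive coordinates, `1 <= start <= end`
#' @return `genomic_interval()`: a one-row data.frame with columns
#'   `contig`, `start`, `end` of class `"genomic_interval"`.
#' @examples
#' iv <- genomic_interval("scaffold195", 101629, 102226)
#' interval_length(iv)  # 598
#' @export
genomic_interval <- function(contig, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(contig) == 1L, length(start) == 1L, length(end) == 1L)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    stop("invalid interval: need 1 <= start <= end, got [", start, ", ", end, "]")
  structure(data.frame(contig = as.character(contig), start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("genomic_interval", "data.frame"))
}

#' @rdname genomic_interval
#' @param x a `genomic_interval` (or any data.frame with `start`/`end`)
#' @export
interval_length <- function(x) {
  as.integer(x$end - x$start + 1L)
}

#' Reciprocal overlap of two intervals
#'
#' The overlap length divided by the length of the *longer* interval, so
#' that a value of 1 means the intervals coincide and a value >= f implies
#' each interval covers at least a fraction f of the other. Intervals on
#' different contigs have overlap 0.
#'
#' @param a,b `genomic_interval` objects
#' @return a number in \[0, 1\]
#' @export
reciprocal_overlap <- function(a, b) {
  if (a$contig != b$contig) return(0)
  ov <- min(a$end, b$end) - max(a$start, b$start) + 1L
  if (ov <= 0L) return(0)
  ov / max(interval_length(a), interval_length(b))
}
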