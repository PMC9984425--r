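#' Genomic interval (1-based, inclusive)
#'
#' Internal coordinate convention for all region arithmetic: 1-based
#' start/end, both ends included, so that a single base has
#' `start == end` and length 1.  BED input/output converts to and from
#' the 0-based half-open convention at the boundary (see
#' [read_bed()] / [write_bed()]).
#'
#' @param chrom Chromosome label (e.g. `"chr7"`).
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return An object of class `genomic_interval`.
#' @examples
#' iv <- genomic_interval("chr7", 128573817, 128574098)
#' interval_length(iv)  # 282
#' @export
genomic_interval <- function(chrom, start, end) {
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("'chrom' must be a single non-empty label")
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start < 1)
    stop("'start' and 'end' must be finite 1-based coordinates")
  if (start > end)
    stop("invalid interval: start (", start, ") > end (", end, ")")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' Length of a genomic interval in base pairs
#'
#' @param iv A [genomic_interval()].
#' @return Integer width `end - start + 1`.
#' @export
interval_length <- function(iv) {
  stopifnot(inherits(iv, "genomic_interval"))
  as.integer(iv$end - iv$start + 1)
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%d bp, 1-based inclusive)\n",
              x$chrom, format(x$start, big.mark = ","),
              format(x$end, big.mark = ","), interval_length(x)))
  invisible(x)
}

#' Test whether a position falls inside an interval
#'
#' @param iv A [genomic_interval()].
#' @param chrom,pos Query coordinate (1-based).
#' @return Logical.
#' @export
interval_contains <- function(iv, chrom, pos) {
  stopifnot(inherits(iv, "genomic_interval"))
  identical(chrom, iv$chrom) && pos >= iv$start && pos <= iv$end
}
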