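#' Assembly summary statistics
#'
#' Computes contig count, mean length, N50, total bases and a length
#' histogram for a contig set. The N50 is the length of the contig at
#' which the cumulative sum over contigs sorted by decreasing length
#' first reaches at least half the total assembly length.
#'
#' @param contigs data frame with a `length` column (nt); if absent,
#'   lengths are taken from `nchar(sequence)`.
#' @param bin_width histogram bin width in nt; bins are right-open
#'   `[k*w, (k+1)*w)`.
#' @return object of class `assembly_summary` with fields `n_contigs`,
#'   `mean_length` (rounded to nearest integer), `mean_length_raw`,
#'   `n50`, `total_bases`, `length_histogram`, `bin_width`.
#' @export
summarize_assembly <- function(contigs, bin_width = 100L) {
  len <- contig_lengths(contigs)
  if (!length(len)) stop("no contigs to summarize")
  stopifnot(bin_width >= 1)
  total <- sum(len)
  s <- sort(len, decreasing = TRUE)
  n50 <- s[[which(cumsum(s) >= total / 2)[[1L]]]]
  lo <- floor(min(len) / bin_width) * bin_width
  hi <- floor(max(len) / bin_width) * bin_width
  starts <- seq(lo, hi, by = bin_width)
  idx <- floor(len / bin_width) * bin_width
  hist <- setNames(integer(length(starts)),
                   paste0("[", starts, ",", starts + bin_width, ")"))
  tab <- table(idx)
  hist[match(as.numeric(names(tab)), starts)] <- as.integer(tab)
  structure(
    list(n_contigs = length(len),
         mean_length = round(total / length(len)),
         mean_length_raw = total / length(len),
         n50 = n50, total_bases = total,
         length_histogram = hist, bin_width = bin_width),
    class = "assembly_summary")
}

contig_lengths <- function(contigs) {
  if (!is.null(contigs$length)) as.numeric(contigs$length)
  else if (!is.null(contigs$sequence)) nchar(contigs$sequence)
  else stop("contigs need a `length` or `sequence` column")
}

#' Filter contigs by average coverage
#'
#' Contigs with an average coverage of less than `min_avg` are
#' dropped; a contig at exactly the threshold is retained. Input order
#' is preserved. This is the filter that defines the final annotation
#' dataset of a low-coverage de novo assembly.
#'
#' @param contigs data frame with an `avg_coverage` column.
#' @param min_avg coverage threshold (fold).
#' @return the retained subset of `contigs`.
#' @export
filter_by_coverage <- function(contigs, min_avg = 5) {
  stopifnot(!is.null(contigs$avg_coverage))
  out <- contigs[contigs$avg_coverage >= min_avg, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat("Assembly summary:\n")
  cat("  contigs:     ", x$n_contigs, "\n")
  cat("  total bases: ", x$total_bases, "\n")
  cat("  mean length: ", x$mean_length, "nt\n")
  cat("  N50:         ", x$n50, "nt\n")
  nz <- x$length_histogram[x$length_histogram > 0]
  cat("  length histogram (bin width ", x$bin_width, " nt, ",
      length(nz), " occupied bins)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.assembly_summary <- function(x, ...) {
  data.frame(statistic = c("n_contigs", "mean_length", "n50",
                           "total_bases"),
             value = c(x$n_contigs, x$mean_length, x$n50,
                       x$total_bases))
}
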