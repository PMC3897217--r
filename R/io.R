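#' Read sequences from FASTA/FASTQ into a read table
#'
#' Reads are represented throughout the package as a data frame with
#' columns `id` and `sequence` (IUPAC nucleotide strings). FASTQ input
#' is accepted; qualities are dropped, since no sanitization stage
#' consumes them.
#'
#' @param path path to a FASTA or FASTQ file.
#' @param format `"fasta"` or `"fastq"`; guessed from the file
#'   extension when `NULL`.
#' @return data frame with columns `id`, `sequence`.
#' @export
read_sequences <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  ss <- Biostrings::readDNAStringSet(path, format = format)
  data.frame(
    id = sub("\\s.*$", "", names(ss)),
    sequence = as.character(ss),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a read/contig table to FASTA
#'
#' @param x data frame with columns `id` and `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path) {
  stopifnot(all(c("id", "sequence") %in% names(x)))
  ss <- Biostrings::DNAStringSet(x$sequence)
  names(ss) <- x$id
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Read a taxonomic homology hit table
#'
#' BLAST-tabular-style TSV. With a header line, the columns `query_id`,
#' `subject_taxid`, `e_value` and `bitscore` are taken by name; without
#' one, an outfmt-6-like layout is assumed where column 1 is the query,
#' the e-value and bit score are the last two columns and the subject
#' taxid is the column named by `taxid_col` (default: column 2).
#'
#' @param path TSV path.
#' @param header whether the file has a header line.
#' @param taxid_col column index of the subject taxid for headerless
#'   input.
#' @return data frame with columns `query_id`, `subject_taxid`,
#'   `e_value`, `bitscore`.
#' @export
read_hit_table <- function(path, header = TRUE, taxid_col = 2L) {
  x <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (header) {
    stopifnot(all(c("query_id", "subject_taxid", "e_value", "bitscore")
                  %in% names(x)))
    x[, c("query_id", "subject_taxid", "e_value", "bitscore")]
  } else {
    nc <- ncol(x)
    data.frame(
      query_id = as.character(x[[1L]]),
      subject_taxid = as.integer(x[[taxid_col]]),
      e_value = as.numeric(x[[nc - 1L]]),
      bitscore = as.numeric(x[[nc]]),
      stringsAsFactors = FALSE
    )
  }
}

#' Read a child-to-parent taxonomy table
#'
#' Two-column TSV (`child`, `parent`), a nodes.dmp-compatible subset.
#' Lines may carry additional columns (ignored).
#'
#' @param path TSV path.
#' @param header whether the file has a header line.
#' @return data frame with integer columns `child`, `parent`.
#' @export
read_taxonomy <- function(path, header = TRUE) {
  x <- read.delim(path, header = header, stringsAsFactors = FALSE)
  data.frame(child = as.integer(x[[1L]]), parent = as.integer(x[[2L]]))
}

#' Read a per-contig GO annotation table
#'
#' Accepts either a TSV with header columns `est_id`, `go_id` (and
#' optionally `source`, `e_value`) or a GAF 2.x file (comment lines
#' starting with `!`; column 2 is the object id, column 5 the GO id,
#' column 15 the assigning source).
#'
#' @param path file path.
#' @return data frame with columns `est_id`, `go_id`, `source` and,
#'   when present in the input, `e_value`.
#' @export
read_annotation_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "!") || !grepl("est_id", first, fixed = TRUE)) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    data.frame(
      est_id = vapply(fields, `[`, "", 2L),
      go_id = vapply(fields, `[`, "", 5L),
      source = vapply(fields, function(f)
        if (length(f) >= 15L) f[[15L]] else NA_character_, ""),
      stringsAsFactors = FALSE
    )
  } else {
    x <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    stopifnot(all(c("est_id", "go_id") %in% names(x)))
    if (is.null(x$source)) x$source <- NA_character_
    keep <- c("est_id", "go_id", "source",
              if ("e_value" %in% names(x)) "e_value")
    x[, keep]
  }
}

#' Read a per-contig coverage table
#'
#' @param path two-column TSV (`id`, `avg_coverage`) with header.
#' @return data frame with columns `id`, `avg_coverage`.
#' @export
read_coverage_table <- function(path) {
  x <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  data.frame(id = as.character(x[[1L]]), avg_coverage = as.numeric(x[[2L]]))
}

#' Write a term profile to TSV
#'
#' Columns: `go_id`, `name`, `level`, `count`, `percent`.
#'
#' @param profile a [term_profile()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "term_profile"))
  write.table(as.data.frame(profile), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a term profile written by [write_profile()]
#'
#' @param path TSV path.
#' @param namespace,species optional metadata to attach; the level is
#'   taken from the table.
#' @return a `term_profile` object.
#' @export
read_profile <- function(path, namespace = NA_character_,
                         species = NA_character_) {
  x <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("go_id", "level", "count", "percent") %in% names(x)))
  if (is.null(x$name)) x$name <- x$go_id
  new_term_profile(x[, c("go_id", "name", "level", "count", "percent")],
                   namespace = namespace,
                   level = if (nrow(x)) x$level[[1L]] else NA_integer_,
                   denominator = sum(x$count),
                   denom_mode = "assignments",
                   species = species)
}

#' Read an interval table of transmembrane-domain annotations
#'
#' @param path TSV with header columns `contig_id`, `tm_start`,
#'   `tm_end` (nucleotide coordinates on the contig, 1-based
#'   inclusive).
#' @return data frame with those columns.
#' @export
read_tm_table <- function(path) {
  x <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("contig_id", "tm_start", "tm_end") %in% names(x)))
  x
}

#' Read a gene-to-category map for immune tabulation
#'
#' @param path TSV with header columns `category`, `gene`; row order
#'   fixes the display order of the category table.
#' @return data frame with columns `category`, `gene`.
#' @export
read_category_map <- function(path) {
  x <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("category", "gene") %in% names(x)))
  x[, c("category", "gene")]
}
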