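#' Linker specification for read splitting
#'
#' @param sequence the linker nucleotide sequence.
#' @param max_mismatches maximum Hamming mismatches for an occurrence
#'   to count as a linker.
#' @param min_fragment_length fragments shorter than this after
#'   excision are dropped and not counted as parts.
#' @return object of class `linker_spec`.
#' @export
linker_spec <- function(sequence, max_mismatches = 2L,
                        min_fragment_length = 50L) {
  stopifnot(nchar(sequence) >= 1, min_fragment_length >= 1,
            max_mismatches >= 0)
  structure(list(sequence = toupper(sequence),
                 max_mismatches = as.integer(max_mismatches),
                 min_fragment_length = as.integer(min_fragment_length)),
            class = "linker_spec")
}

#' Split reads on internal linker sequences
#'
#' Long-read library construction can concatenate two inserts around a
#' linker; such reads must be split before assembly. Every occurrence
#' of the linker (within `max_mismatches` Hamming mismatches,
#' scanning left to right, non-overlapping) is excised; the flanking
#' fragments become reads named `<parent>/p1`, `/p2`, ... Fragments
#' shorter than `min_fragment_length` are dropped and not counted as
#' parts. Reads without a linker pass through unchanged.
#'
#' @param reads data frame with columns `id`, `sequence`.
#' @param spec a [linker_spec()].
#' @return list with `reads` (the sanitized read table) and `stats`, a
#'   `split_stats` object: `counts` (named vector, reads split into k
#'   parts for k >= 2), `n_unsplit`, `n_total_in`, `n_total_out`.
#' @export
split_reads_on_linker <- function(reads, spec) {
  stopifnot(inherits(spec, "linker_spec"))
  n_in <- nrow(reads)
  if (!n_in) {
    return(list(reads = reads,
                stats = new_split_stats(integer(0), 0L, 0L, 0L)))
  }
  subj <- Biostrings::DNAStringSet(reads$sequence)
  hits <- Biostrings::vmatchPattern(
    Biostrings::DNAString(spec$sequence), subj,
    max.mismatch = spec$max_mismatches, fixed = TRUE)

  out_id <- vector("list", n_in)
  out_seq <- vector("list", n_in)
  parts <- integer(n_in)      # retained fragments per read with a linker hit
  had_hit <- logical(n_in)
  for (i in seq_len(n_in)) {
    m <- hits[[i]]
    if (!length(m)) {
      out_id[[i]] <- reads$id[[i]]
      out_seq[[i]] <- reads$sequence[[i]]
      next
    }
    ## greedy non-overlapping occurrences, left to right
    o <- order(IRanges::start(m))
    st <- IRanges::start(m)[o]; en <- IRanges::end(m)[o]
    keep_st <- integer(0); keep_en <- integer(0); last_end <- 0L
    for (j in seq_along(st)) {
      if (st[[j]] > last_end) {
        keep_st <- c(keep_st, st[[j]])
        keep_en <- c(keep_en, en[[j]])
        last_end <- en[[j]]
      }
    }
    had_hit[[i]] <- TRUE
    seq_i <- reads$sequence[[i]]
    frag_st <- c(1L, keep_en + 1L)
    frag_en <- c(keep_st - 1L, nchar(seq_i))
    ok <- (frag_en - frag_st + 1L) >= spec$min_fragment_length
    frags <- if (any(ok)) substring(seq_i, frag_st[ok], frag_en[ok])
    else character(0)
    k <- length(frags)
    parts[[i]] <- k
    if (k) {
      out_id[[i]] <- paste0(reads$id[[i]], "/p", seq_len(k))
      out_seq[[i]] <- frags
    } else {
      out_id[[i]] <- character(0)
      out_seq[[i]] <- character(0)
    }
  }
  split_k <- parts[had_hit & parts >= 2L]
  counts <- if (length(split_k)) {
    tab <- table(split_k)
    setNames(as.integer(tab), names(tab))
  } else setNames(integer(0), character(0))
  n_unsplit <- sum(!had_hit) + sum(had_hit & parts == 1L)
  out <- data.frame(id = unlist(out_id, use.names = FALSE),
                    sequence = unlist(out_seq, use.names = FALSE),
                    stringsAsFactors = FALSE)
  list(reads = out,
       stats = new_split_stats(counts, n_unsplit, n_in, nrow(out)))
}

new_split_stats <- function(counts, n_unsplit, n_in, n_out) {
  structure(list(counts = counts, n_unsplit = n_unsplit,
                 n_total_in = n_in, n_total_out = n_out),
            class = "split_stats")
}

#' @export
print.split_stats <- function(x, ...) {
  cat("Linker split:", x$n_total_in, "reads in,", x$n_total_out,
      "reads out,", x$n_unsplit, "unsplit\n")
  for (k in names(x$counts))
    cat("  split into", k, "parts:", x$counts[[k]], "\n")
  invisible(x)
}

#' Define the contaminant taxon groups
#'
#' @param groups data frame with columns `name`, `root_taxid`, in the
#'   order removal counts should be reported.
#' @param taxonomy data frame with integer columns `child`, `parent`
#'   (a child-to-parent map; the overall root may map to itself).
#' @return object of class `taxon_group_set`.
#' @export
taxon_group_set <- function(groups, taxonomy) {
  stopifnot(all(c("name", "root_taxid") %in% names(groups)),
            all(c("child", "parent") %in% names(taxonomy)))
  known <- unique(c(taxonomy$child, taxonomy$parent))
  if (!all(groups$root_taxid %in% known))
    stop("group root taxid(s) absent from taxonomy: ",
         paste(setdiff(groups$root_taxid, known), collapse = ", "))
  structure(list(groups = groups,
                 parent = setNames(as.integer(taxonomy$parent),
                                   taxonomy$child)),
            class = "taxon_group_set")
}

## nearest group root on the child->parent walk (most specific group);
## NA when the lineage meets no group root
group_of_taxid <- function(taxid, groups) {
  roots <- groups$groups$root_taxid
  parent <- groups$parent
  cur <- taxid
  for (step in seq_len(1000L)) {
    hit <- match(cur, roots)
    if (!is.na(hit)) return(groups$groups$name[[hit]])
    nxt <- parent[as.character(cur)]
    if (is.na(nxt) || nxt == cur) return(NA_character_)
    cur <- unname(nxt)
  }
  NA_character_
}

#' Screen reads for taxonomic contaminants
#'
#' A query is removed iff it has at least one hit with
#' `e_value < e_cutoff` (strict) whose subject taxid's lineage
#' (child-to-parent walk) contains one of the group roots. Removal is
#' attributed to the group of the best qualifying hit (lowest
#' e-value, then highest bit score, then first group in configured
#' order); a hit under nested roots is attributed to the most specific
#' one. Hits whose taxid is absent from the taxonomy are ignored with
#' a warning.
#'
#' @param query_ids character vector of read/contig ids to screen.
#' @param hits data frame with columns `query_id`, `subject_taxid`,
#'   `e_value`, `bitscore`; every `query_id` must be in `query_ids`.
#' @param groups a [taxon_group_set()].
#' @param e_cutoff strict e-value cutoff.
#' @return list with `clean_ids` (input order preserved) and `report`,
#'   a `contaminant_report`: `removed_per_group` (named, configured
#'   order, zeros kept), `n_remaining`, `n_input`, `e_cutoff`.
#' @export
screen_contaminants <- function(query_ids, hits, groups,
                                e_cutoff = 1e-20) {
  stopifnot(inherits(groups, "taxon_group_set"))
  if (!all(hits$query_id %in% query_ids))
    stop("hit table contains query ids not in `query_ids`")
  known <- hits$subject_taxid %in% names(groups$parent) |
    hits$subject_taxid %in% groups$parent
  if (any(!known)) {
    warning(sum(!known), " hit(s) with taxids absent from the taxonomy",
            " were ignored")
    hits <- hits[known, , drop = FALSE]
  }
  utax <- unique(hits$subject_taxid)
  grp_of <- setNames(
    vapply(utax, group_of_taxid, "", groups = groups), utax)
  hits$group <- unname(grp_of[as.character(hits$subject_taxid)])
  qual <- hits[!is.na(hits$group) & hits$e_value < e_cutoff, ,
               drop = FALSE]
  removed_group <- character(0)
  if (nrow(qual)) {
    grp_rank <- match(qual$group, groups$groups$name)
    o <- order(qual$e_value, -qual$bitscore, grp_rank)
    best <- qual[o, ][!duplicated(qual$query_id[o]), ]
    removed_group <- setNames(best$group, best$query_id)
  }
  removed <- names(removed_group)
  clean <- query_ids[!(query_ids %in% removed)]
  per_group <- setNames(integer(nrow(groups$groups)),
                        groups$groups$name)
  tab <- table(removed_group)
  per_group[names(tab)] <- as.integer(tab)
  report <- structure(
    list(removed_per_group = per_group,
         removed_ids = removed_group,
         n_remaining = length(clean),
         n_input = length(query_ids),
         e_cutoff = e_cutoff),
    class = "contaminant_report")
  list(clean_ids = clean, report = report)
}

#' @export
print.contaminant_report <- function(x, ...) {
  cat("Contaminant screen (E <", format(x$e_cutoff), "):\n")
  for (g in names(x$removed_per_group))
    cat(sprintf("  %-24s %d\n", g, x$removed_per_group[[g]]))
  cat(sprintf("  %-24s %d of %d\n", "Remaining reads",
              x$n_remaining, x$n_input))
  invisible(x)
}
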