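#' Collect gene-family candidates from a hit table
#'
#' A contig becomes a candidate for a family iff it has at least one
#' hit to that family with `e_value <= cutoff[method]` (inclusive, as
#' conventional for reported search cutoffs). One candidate is kept
#' per (contig, family); its best hit is the one with the lowest
#' e-value, ties broken by the longest query span.
#'
#' @param hits data frame with columns `query_id`, `family`,
#'   `reference_id`, `method`, `e_value`, `frame`, `span_start`,
#'   `span_end`.
#' @param cutoffs named e-value cutoffs, one per method present in
#'   `hits` (default: homology 1e-1, HMM-profile 1e-3).
#' @return a `candidate_set`: data frame with one row per candidate
#'   (`contig_id`, `family`, best-hit fields, and quality-flag
#'   columns initialised to `NA` until [apply_ir_quality_filter()]).
#' @export
collect_candidates <- function(hits,
                               cutoffs = c(homology = 1e-1,
                                           hmm = 1e-3)) {
  unknown <- setdiff(unique(hits$method), names(cutoffs))
  if (length(unknown))
    stop("no cutoff defined for method(s): ",
         paste(unknown, collapse = ", "))
  pass <- hits[hits$e_value <= cutoffs[hits$method], , drop = FALSE]
  if (nrow(pass)) {
    span <- pass$span_end - pass$span_start + 1L
    o <- order(pass$query_id, pass$family, pass$e_value, -span)
    pass <- pass[o, , drop = FALSE]
    key <- paste(pass$query_id, pass$family, sep = "\r")
    best <- pass[!duplicated(key), , drop = FALSE]
  } else {
    best <- pass
  }
  out <- data.frame(
    contig_id = best$query_id, family = best$family,
    reference_id = best$reference_id, method = best$method,
    e_value = best$e_value, frame = best$frame,
    span_start = best$span_start, span_end = best$span_end,
    n_tm_spanned = rep(NA_integer_, nrow(best)),
    has_internal_stop = rep(NA, nrow(best)),
    has_ambiguity = rep(NA, nrow(best)),
    dendrogram_ready = rep(NA, nrow(best)),
    assigned_name = rep(NA_character_, nrow(best)),
    stringsAsFactors = FALSE)
  row.names(out) <- NULL
  class(out) <- c("candidate_set", "data.frame")
  out
}

## codons of the best-hit reading frame fully inside [start, end];
## returns a character vector of codons (possibly length 0)
span_codons <- function(sequence, frame, start, end) {
  if (frame < 0) {
    comp <- chartr("ACGTN", "TGCAN", sequence)
    sequence <- paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]),
                      collapse = "")
    n <- nchar(sequence)
    new_start <- n - end + 1L
    end <- n - start + 1L
    start <- new_start
    frame <- -frame
  }
  ## codon starts on the contig for this frame
  first <- frame + 3L * ceiling((start - frame) / 3)
  if (first < start) first <- first + 3L
  starts <- seq.int(first, end - 2L, by = 3L)
  starts <- starts[starts + 2L <= end]
  if (!length(starts)) return(character(0))
  substring(sequence, starts, starts + 2L)
}

#' Apply the ionotropic-receptor dendrogram-readiness filter
#'
#' Dendrogram construction over receptor candidates is only reliable
#' for contigs covering enough of the conserved structure; the filter
#' requires a candidate's translated span to fully contain at least
#' two of the three annotated transmembrane domains, with no in-frame
#' stop codon strictly inside the span (a stop in the terminal codon
#' is tolerated) and no ambiguity character (non-ACGT base) in the
#' span.
#'
#' @param candidates a `candidate_set` from [collect_candidates()].
#' @param tm data frame of transmembrane intervals (`contig_id`,
#'   `tm_start`, `tm_end`, nucleotide coordinates on the contig);
#'   contigs without annotation get `n_tm_spanned = 0` (retained, but
#'   not dendrogram-ready).
#' @param sequences data frame with columns `id`, `sequence`.
#' @return the candidate set with `n_tm_spanned`,
#'   `has_internal_stop`, `has_ambiguity` and `dendrogram_ready`
#'   filled in.
#' @export
apply_ir_quality_filter <- function(candidates, tm, sequences) {
  seq_of <- setNames(sequences$sequence, sequences$id)
  for (i in seq_len(nrow(candidates))) {
    cid <- candidates$contig_id[[i]]
    s <- seq_of[[cid]]
    if (is.null(s)) stop("no sequence for contig ", cid)
    a <- candidates$span_start[[i]]
    b <- candidates$span_end[[i]]
    iv <- tm[tm$contig_id == cid, , drop = FALSE]
    candidates$n_tm_spanned[[i]] <-
      sum(iv$tm_start >= a & iv$tm_end <= b)
    cod <- span_codons(s, candidates$frame[[i]], a, b)
    internal <- head(cod, -1L)
    candidates$has_internal_stop[[i]] <-
      any(internal %in% c("TAA", "TAG", "TGA"))
    region <- substring(s, a, b)
    candidates$has_ambiguity[[i]] <-
      grepl("[^ACGT]", region)
  }
  candidates$dendrogram_ready <- candidates$n_tm_spanned >= 2L &
    !candidates$has_internal_stop & !candidates$has_ambiguity
  candidates
}

#' Assign species-prefixed names to candidates
#'
#' Candidates whose best-hit reference is a configured clear homolog
#' keep the homolog's name prefixed by the species code (e.g.
#' `CclyIR25a`); the remaining candidates of each family are numbered
#' with ascending arabic numerals starting at 1, ordered by ascending
#' best-hit e-value then contig id for determinism.
#'
#' @param candidates a `candidate_set`.
#' @param species_code non-empty species prefix (e.g. `"Ccly"`).
#' @param homolog_map named character vector mapping `reference_id`
#'   values to canonical gene names.
#' @return the candidate set with `assigned_name` filled in.
#' @export
name_candidates <- function(candidates, species_code,
                            homolog_map = default_homolog_map()) {
  stopifnot(is.character(species_code), nzchar(species_code))
  nm <- rep(NA_character_, nrow(candidates))
  is_hom <- candidates$reference_id %in% names(homolog_map)
  nm[is_hom] <- paste0(species_code,
                       homolog_map[candidates$reference_id[is_hom]])
  for (fam in unique(candidates$family)) {
    idx <- which(!is_hom & candidates$family == fam)
    if (!length(idx)) next
    o <- idx[order(candidates$e_value[idx],
                   candidates$contig_id[idx])]
    nm[o] <- paste0(species_code, gsub(" ", "", fam),
                    seq_along(o))
  }
  candidates$assigned_name <- nm
  candidates
}

#' Tabulate immune gene-family candidates by category
#'
#' Counts distinct candidate contigs per (category, gene, species),
#' with rows ordered by the configured category map. Gene labels
#' missing from the map are collected under `"uncategorized"` with a
#' warning.
#'
#' @param candidates_a,candidates_b candidate sets for the two
#'   species (their `family` column holds the gene label).
#' @param category_map data frame with columns `category`, `gene`;
#'   row order fixes the output order.
#' @param species character vector of the two species labels.
#' @return a `category_table`: data frame `category`, `gene`, and one
#'   count column per species.
#' @export
tabulate_categories <- function(candidates_a, candidates_b,
                                category_map,
                                species = c("species_a", "species_b")) {
  stopifnot(all(c("category", "gene") %in% names(category_map)))
  genes_seen <- unique(c(candidates_a$family, candidates_b$family))
  unmapped <- setdiff(genes_seen, category_map$gene)
  if (length(unmapped)) {
    warning("gene label(s) not in category map, collected under ",
            "'uncategorized': ", paste(unmapped, collapse = ", "))
    category_map <- rbind(
      category_map[, c("category", "gene")],
      data.frame(category = "uncategorized", gene = unmapped,
                 stringsAsFactors = FALSE))
  }
  count_for <- function(cands, gene)
    length(unique(cands$contig_id[cands$family == gene]))
  out <- data.frame(
    category = category_map$category, gene = category_map$gene,
    stringsAsFactors = FALSE)
  out[[species[[1L]]]] <- vapply(category_map$gene, count_for,
                                 0L, cands = candidates_a)
  out[[species[[2L]]]] <- vapply(category_map$gene, count_for,
                                 0L, cands = candidates_b)
  row.names(out) <- NULL
  class(out) <- c("category_table", "data.frame")
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate set:", nrow(x), "candidates,",
      length(unique(x$family)), "families\n")
  if (!all(is.na(x$dendrogram_ready)))
    cat("  dendrogram-ready:", sum(x$dendrogram_ready), "\n")
  print.data.frame(head(as.data.frame(x), 10L), digits = 3)
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more\n")
  invisible(x)
}
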