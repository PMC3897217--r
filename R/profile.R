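#' Propagate annotations up the DAG (true-path rule)
#'
#' An EST annotated to a term is counted as annotated to that term and
#' to every `is_a` ancestor of it; each EST is a member of a term's
#' set at most once, however many of the term's descendants it was
#' annotated to.
#'
#' @param annotations data frame with columns `est_id`, `go_id`
#'   (alternative ids are resolved; unresolvable ids are skipped with
#'   a warning).
#' @param dag a `go_dag`.
#' @return named list mapping each touched `go_id` to the character
#'   vector of distinct EST ids assigned to it.
#' @export
propagate_annotations <- function(annotations, dag) {
  go <- resolve_go_ids(dag, annotations$go_id)
  bad <- is.na(go)
  if (any(bad)) {
    warning(sum(bad), " annotation(s) with unresolvable GO ids were skipped")
    annotations <- annotations[!bad, , drop = FALSE]
    go <- go[!bad]
  }
  if (!nrow(annotations)) return(structure(list(), names = character(0)))
  ## closure per distinct annotated term, then expand
  uterms <- unique(go)
  closure <- lapply(uterms, go_ancestors, dag = dag)
  names(closure) <- uterms
  reps <- lengths(closure[go])
  long_term <- unlist(closure[go], use.names = FALSE)
  long_est <- rep(annotations$est_id, reps)
  lapply(split(long_est, long_term), unique)
}

new_term_profile <- function(df, namespace, level, denominator,
                             denom_mode, species = NA_character_) {
  structure(df, class = c("term_profile", "data.frame"),
            namespace = namespace, level = level,
            denominator = denominator, denom_mode = denom_mode,
            species = species)
}

#' Level-wise GO term profile
#'
#' Counts, for every term at the requested level of one namespace, the
#' ESTs assigned to it after true-path propagation, then converts
#' counts to percentages as
#' `count(term) * 100 / (total assignments at the level)`.
#' With the default denominator an EST annotated to m terms of the
#' level contributes m assignments, so the percentages sum to 100;
#' `denominator = "distinct"` divides by the number of distinct ESTs
#' at the level instead.
#'
#' Manual overrides mirror curation of automatic annotation: each
#' override adds a non-negative EST count to a term (creating the row
#' if the term is absent) and grows the denominator accordingly.
#'
#' @param annotations data frame (`est_id`, `go_id`), or a
#'   pre-computed propagation from [propagate_annotations()] (named
#'   list of EST sets).
#' @param dag a `go_dag`.
#' @param namespace one of the DAG's namespaces.
#' @param level integer >= 2 (the root is not profiled).
#' @param overrides optional data frame with columns `go_id`, `delta`
#'   (deltas >= 0).
#' @param denominator `"assignments"` (default) or `"distinct"`.
#' @param species optional species label carried as metadata.
#' @return a `term_profile`: data frame (`go_id`, `name`, `level`,
#'   `count`, `percent`) with metadata attributes, rows ordered by
#'   decreasing count then id.
#' @export
term_profile <- function(annotations, dag, namespace, level,
                         overrides = NULL,
                         denominator = c("assignments", "distinct"),
                         species = NA_character_) {
  denominator <- match.arg(denominator)
  stopifnot(level >= 2L)
  if (!namespace %in% names(dag$roots))
    stop("unknown namespace: ", namespace)
  prop <- if (is.data.frame(annotations))
    propagate_annotations(annotations, dag) else annotations

  lv_ids <- names(dag$level)[dag$level == level]
  ns_of <- dag$terms$namespace[match(lv_ids, dag$terms$go_id)]
  lv_ids <- lv_ids[ns_of == namespace]
  if (!length(lv_ids))
    warning("no terms at level ", level, " in ", namespace,
            "; empty profile with denominator 0")

  sets <- prop[intersect(lv_ids, names(prop))]
  counts <- setNames(as.numeric(lengths(sets)), names(sets))
  counts <- counts[counts > 0]

  if (!is.null(overrides) && nrow(overrides)) {
    stopifnot(all(c("go_id", "delta") %in% names(overrides)),
              all(overrides$delta >= 0))
    for (i in seq_len(nrow(overrides))) {
      g <- overrides$go_id[[i]]
      counts[g] <- (if (g %in% names(counts)) counts[[g]] else 0) +
        overrides$delta[[i]]
    }
  }

  denom <- if (denominator == "assignments") sum(counts)
  else length(unique(unlist(sets, use.names = FALSE))) +
    sum(overrides$delta %||% 0)
  pct <- if (denom > 0) counts * 100 / denom else counts * NA_real_

  nm <- dag$terms$name[match(names(counts), dag$terms$go_id)]
  nm[is.na(nm)] <- names(counts)[is.na(nm)]
  df <- data.frame(go_id = names(counts), name = nm,
                   level = rep(as.integer(level), length(counts)),
                   count = as.numeric(counts), percent = as.numeric(pct),
                   stringsAsFactors = FALSE, row.names = NULL)
  df <- df[order(-df$count, df$go_id), , drop = FALSE]
  row.names(df) <- NULL
  new_term_profile(df, namespace, as.integer(level), denom,
                   denominator, species)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.term_profile <- function(x, n = 10L, ...) {
  cat("Term profile", if (!is.na(attr(x, "species")))
    paste0("[", attr(x, "species"), "]") else "",
    ": ", attr(x, "namespace"), " level ", attr(x, "level"),
    ", ", nrow(x), " terms, denominator ", attr(x, "denominator"),
    " (", attr(x, "denom_mode"), ")\n", sep = "")
  print.data.frame(head(as.data.frame(x), n), digits = 4)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more terms\n")
  invisible(x)
}
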