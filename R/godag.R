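#' Construct a GO DAG object
#'
#' Internal constructor shared by [load_obo()] and the synthetic DAG
#' generator. Levels are assigned immediately via [assign_levels()].
#'
#' @param terms data frame with columns `go_id`, `name`, `namespace`,
#'   `obsolete`.
#' @param parents named list mapping each non-obsolete `go_id` to a
#'   character vector of `is_a` parent ids.
#' @param alt named character vector mapping alternative ids to
#'   primary ids.
#' @param level_mode `"min"` (default) or `"max"` path length from the
#'   namespace root.
#' @return an object of class `go_dag` with elements `terms`,
#'   `parents`, `alt`, `roots`, `level`, `level_mode`.
#' @keywords internal
new_go_dag <- function(terms, parents, alt = character(0),
                       level_mode = "min") {
  dag <- structure(
    list(terms = terms, parents = parents, alt = alt,
         roots = character(0), level = integer(0),
         level_mode = level_mode),
    class = "go_dag")
  lv <- assign_levels(dag, mode = level_mode)
  dag$level <- lv$level
  dag$roots <- lv$roots
  dag
}

#' Parse a Gene Ontology OBO file
#'
#' Minimal OBO 1.2/1.4 reader covering the fields needed for level-wise
#' profiling: `id`, `name`, `namespace`, `is_a`, `alt_id`,
#' `is_obsolete` and (optionally) `relationship: part_of`. Obsolete
#' terms are dropped, alternative ids are mapped to their primary
#' terms, and levels are assigned from the namespace roots.
#'
#' @param path path to an OBO file (or a connection of OBO lines).
#' @param use_part_of whether `part_of` relationships also define
#'   parenthood for level assignment and propagation; the default uses
#'   `is_a` edges only.
#' @param level_mode `"min"` (default) or `"max"`: whether a term's
#'   level is one plus the shortest or the longest path to its
#'   namespace root.
#' @return a `go_dag` object.
#' @export
load_obo <- function(path, use_part_of = FALSE, level_mode = "min") {
  lines <- if (inherits(path, "connection")) readLines(path) else readLines(path)
  term_starts <- which(lines == "[Term]")
  stanza_starts <- which(startsWith(lines, "["))
  ids <- character(0); nms <- character(0); nss <- character(0)
  obs <- logical(0); parents <- list(); alt <- character(0)
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[(s + 1L):end]
    block <- block[nzchar(block)]
    field <- function(key) {
      pref <- paste0(key, ": ")
      sub("\\s*(!.*)?$", "", substring(block[startsWith(block, pref)],
                                       nchar(pref) + 1L))
    }
    id <- field("id")
    if (length(id) != 1L) next
    ns <- field("namespace")
    if (length(ns) != 1L) ns <- NA_character_
    pa <- sub(" .*$", "", field("is_a"))
    if (use_part_of) {
      rel <- field("relationship")
      po <- rel[startsWith(rel, "part_of ")]
      pa <- c(pa, sub("^part_of ([^ ]+).*$", "\\1", po))
    }
    ids <- c(ids, id)
    nm <- field("name")
    nms <- c(nms, if (length(nm)) nm[[1L]] else id)
    nss <- c(nss, ns)
    obs <- c(obs, identical(field("is_obsolete"), "true"))
    parents[[id]] <- unique(pa)
    a <- field("alt_id")
    if (length(a)) alt[a] <- id
  }
  bad_ns <- is.na(nss) & !obs
  if (any(bad_ns)) {
    warning(sum(bad_ns), " term(s) without a namespace were skipped")
    keep <- !bad_ns
    parents <- parents[ids[keep]]
    ids <- ids[keep]; nms <- nms[keep]; nss <- nss[keep]; obs <- obs[keep]
  }
  terms <- data.frame(go_id = ids, name = nms, namespace = nss,
                      obsolete = obs, stringsAsFactors = FALSE)
  live <- ids[!obs]
  parents <- lapply(parents[live], function(p) p[p %in% live])
  alt <- alt[alt %in% live]
  new_go_dag(terms, parents, alt, level_mode = level_mode)
}

#' Assign levels to GO DAG terms
#'
#' The level of a namespace root is 1; every other term's level is one
#' plus the minimum (default) or maximum of its parents' levels,
#' i.e. one plus the shortest (longest) `is_a` path to the root.
#' Non-root terms that cannot reach a root are excluded with a
#' warning. A cyclic graph is a hard error.
#'
#' @param dag a `go_dag` object (its stored levels are ignored).
#' @param mode `"min"` or `"max"`.
#' @return list with `level` (named integer vector over reachable,
#'   non-obsolete terms) and `roots` (named by namespace).
#' @export
assign_levels <- function(dag, mode = c("min", "max")) {
  mode <- match.arg(mode)
  parents <- dag$parents
  ids <- names(parents)
  n_parents <- lengths(parents)

  ## roots: parentless terms; if a namespace has several, prefer the
  ## one named after the namespace (GO root convention), the others
  ## are treated as orphans
  parentless <- ids[n_parents == 0L]
  ti <- dag$terms[match(ids, dag$terms$go_id), ]
  roots <- character(0)
  for (ns in unique(ti$namespace[match(parentless, ids)])) {
    cand <- parentless[ti$namespace[match(parentless, ids)] == ns]
    if (length(cand) > 1L) {
      named <- cand[ti$name[match(cand, ids)] == ns]
      root <- if (length(named)) named[[1L]] else cand[[1L]]
    } else root <- cand
    roots[ns] <- root
  }
  orphans <- setdiff(parentless, roots)

  ## children adjacency
  children <- split(rep(ids, n_parents), unlist(parents, use.names = FALSE))

  ## cycle check: Kahn's algorithm over the full graph
  indeg <- n_parents
  names(indeg) <- ids
  queue <- parentless
  n_done <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    n_done <- n_done + 1L
    ch <- children[[v]]
    if (!is.null(ch)) {
      indeg[ch] <- indeg[ch] - 1L
      queue <- c(queue, ch[indeg[ch] == 0L])
    }
  }
  if (n_done < length(ids)) stop("cycle detected in is_a graph")

  level <- setNames(rep(NA_integer_, length(ids)), ids)
  level[roots] <- 1L
  if (mode == "min") {
    ## multi-source BFS from the roots over parent->child edges
    frontier <- unname(roots)
    l <- 1L
    while (length(frontier)) {
      ch <- unique(unlist(children[frontier], use.names = FALSE))
      ch <- ch[!is.na(match(ch, ids))]
      ch <- ch[is.na(level[ch])]
      l <- l + 1L
      level[ch] <- l
      frontier <- ch
    }
  } else {
    ## longest path: process in topological order
    topo <- character(length(ids)); k <- 0L
    indeg <- n_parents; names(indeg) <- ids
    queue <- parentless
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      k <- k + 1L; topo[k] <- v
      ch <- children[[v]]
      if (!is.null(ch)) {
        indeg[ch] <- indeg[ch] - 1L
        queue <- c(queue, ch[indeg[ch] == 0L])
      }
    }
    for (v in topo) {
      if (v %in% roots) next
      pl <- level[parents[[v]]]
      pl <- pl[!is.na(pl)]
      if (length(pl)) level[v] <- 1L + max(pl)
    }
  }
  unreachable <- union(orphans, ids[is.na(level)])
  unreachable <- setdiff(unreachable, roots)
  if (length(unreachable)) {
    warning(length(unreachable),
            " non-root term(s) unreachable from a namespace root were excluded")
    level <- level[setdiff(ids, unreachable)]
  }
  level <- level[!is.na(level)]
  list(level = level, roots = roots)
}

#' Resolve GO ids through the alternative-id map
#'
#' @param dag a `go_dag`.
#' @param go_ids character vector of GO accessions.
#' @return character vector of primary ids; ids unknown to the DAG are
#'   returned as `NA`.
#' @export
resolve_go_ids <- function(dag, go_ids) {
  out <- go_ids
  is_alt <- out %in% names(dag$alt)
  out[is_alt] <- dag$alt[out[is_alt]]
  out[!(out %in% names(dag$level))] <- NA_character_
  out
}

#' Ancestor closure of a term (including the term itself)
#'
#' @param dag a `go_dag`.
#' @param go_id a primary GO accession present in the DAG.
#' @return character vector of the term and all its `is_a` ancestors.
#' @export
go_ancestors <- function(dag, go_id) {
  seen <- character(0)
  frontier <- go_id
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(
      unique(unlist(dag$parents[frontier], use.names = FALSE)), seen)
  }
  unique(seen)
}

#' @export
print.go_dag <- function(x, ...) {
  cat("GO DAG:", sum(!x$terms$obsolete), "terms (",
      sum(x$terms$obsolete), "obsolete dropped ),",
      length(x$alt), "alt ids\n")
  for (ns in names(x$roots)) {
    in_ns <- names(x$level)[x$terms$namespace[
      match(names(x$level), x$terms$go_id)] == ns]
    cat("  ", ns, ": root ", x$roots[[ns]], ", ",
        length(in_ns), " leveled terms, max level ",
        max(x$level[in_ns]), "\n", sep = "")
  }
  cat("  level mode:", x$level_mode, "\n")
  invisible(x)
}

#' Write a GO DAG as a minimal OBO file
#'
#' Emits id/name/namespace/is_a stanzas sufficient to round-trip
#' through [load_obo()]; used to materialise synthetic ontologies.
#'
#' @param dag a `go_dag`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    t <- dag$terms[i, ]
    lines <- c("[Term]",
               paste0("id: ", t$go_id),
               paste0("name: ", t$name),
               paste0("namespace: ", t$namespace))
    if (t$obsolete) {
      lines <- c(lines, "is_obsolete: true")
    } else {
      for (p in dag$parents[[t$go_id]])
        lines <- c(lines, paste0("is_a: ", p))
    }
    alts <- names(dag$alt)[dag$alt == t$go_id]
    for (a in alts) lines <- c(lines, paste0("alt_id: ", a))
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}
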