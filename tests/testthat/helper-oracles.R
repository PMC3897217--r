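## Independent brute-force oracles used to cross-check the package's
## implementations; deliberately written with the most literal
## algorithm available.

## N50: walk the sorted lengths, accumulating until half the total
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  acc <- 0
  for (l in s) {
    acc <- acc + l
    if (acc >= total / 2) return(l)
  }
  stop("unreachable")
}

## Pearson correlation from the textbook definition
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

## term levels = 1 + shortest path from a root, by explicit BFS over
## parent->child edges derived from a parents list
oracle_levels <- function(parents, roots) {
  lev <- setNames(rep(NA_integer_, length(parents)), names(parents))
  lev[roots] <- 1L
  frontier <- roots
  while (length(frontier)) {
    nxt <- character(0)
    for (id in names(parents)) {
      if (!is.na(lev[[id]])) next
      if (any(parents[[id]] %in% frontier))
        nxt <- c(nxt, id)
    }
    for (id in nxt)
      lev[[id]] <- 1L + min(lev[unlist(parents[[id]])], na.rm = TRUE)
    frontier <- nxt
  }
  lev[!is.na(lev)]
}

## ancestor closure by naive recursion
oracle_ancestors <- function(parents, id) {
  out <- id
  for (p in parents[[id]])
    out <- union(out, oracle_ancestors(parents, p))
  out
}

## full propagation by iterating every (est, term) pair independently
oracle_propagate <- function(annotations, parents) {
  res <- list()
  for (i in seq_len(nrow(annotations))) {
    for (t in oracle_ancestors(parents, annotations$go_id[[i]])) {
      res[[t]] <- union(res[[t]], annotations$est_id[[i]])
    }
  }
  res
}

## fabricate a term_profile directly from counts (percent = share)
mk_profile <- function(counts, namespace = "biological_process",
                       level = 3L, species = NA_character_) {
  df <- data.frame(go_id = names(counts), name = names(counts),
                   level = as.integer(level),
                   count = as.numeric(counts),
                   percent = 100 * counts / sum(counts),
                   stringsAsFactors = FALSE)
  antcomp:::new_term_profile(df, namespace, as.integer(level),
                             sum(counts), "assignments", species)
}

## small OBO document from lines, returned as a temp file path
obo_file <- function(...) {
  path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", ...), path)
  path
}

obo_term <- function(id, name = id, ns = "biological_process",
                     is_a = character(0), alt_id = character(0),
                     obsolete = FALSE, extra = character(0)) {
  c("[Term]", paste0("id: ", id), paste0("name: ", name),
    paste0("namespace: ", ns),
    paste0("is_a: ", is_a), paste0("alt_id: ", alt_id),
    if (obsolete) "is_obsolete: true", extra, "")
}
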