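align_profiles <- function(a, b, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "term_profile"), inherits(b, "term_profile"))
  if (!identical(attr(a, "namespace"), attr(b, "namespace")) ||
      !identical(attr(a, "level"), attr(b, "level")))
    stop("profiles must share namespace and level")
  ids <- if (mode == "union") union(a$go_id, b$go_id)
  else intersect(a$go_id, b$go_id)
  pa <- setNames(rep(0, length(ids)), ids)
  pb <- pa
  pa[a$go_id[a$go_id %in% ids]] <- a$percent[a$go_id %in% ids]
  pb[b$go_id[b$go_id %in% ids]] <- b$percent[b$go_id %in% ids]
  list(ids = ids, pct_a = pa, pct_b = pb)
}

#' Pearson similarity of two term profiles
#'
#' Product-moment correlation of the paired percentage vectors indexed
#' by the union of the two term sets, a term absent from one species
#' contributing 0%. Used as an overall similarity measure between two
#' species' annotation at one (namespace, level).
#'
#' @param a,b `term_profile` objects at the same namespace and level,
#'   with at least 2 terms in the union.
#' @param mode `"union"` (default, absent terms as 0) or
#'   `"intersection"` (shared terms only).
#' @return the correlation coefficient.
#' @export
pearson_similarity <- function(a, b, mode = c("union", "intersection")) {
  al <- align_profiles(a, b, mode)
  if (length(al$ids) < 2L) stop("need at least 2 terms to correlate")
  if (stats::sd(al$pct_a) == 0 || stats::sd(al$pct_b) == 0)
    stop("zero variance in a percentage vector; correlation undefined")
  cor(al$pct_a, al$pct_b)
}

#' Term overlap between two profiles
#'
#' A term is present in a species iff its profile count is > 0 (after
#' any overrides). Partitions the union of the two term sets into
#' shared and species-unique terms.
#'
#' @param a,b `term_profile` objects at the same namespace and level.
#' @return list with `n_shared`, `n_unique_a`, `n_unique_b` and the
#'   corresponding id listings `shared`, `unique_a`, `unique_b`.
#' @export
term_overlap <- function(a, b) {
  align_profiles(a, b)  # namespace/level check
  ta <- a$go_id[a$count > 0]
  tb <- b$go_id[b$count > 0]
  shared <- intersect(ta, tb)
  ua <- setdiff(ta, tb)
  ub <- setdiff(tb, ta)
  list(n_shared = length(shared), n_unique_a = length(ua),
       n_unique_b = length(ub), shared = shared,
       unique_a = ua, unique_b = ub)
}

bin_labels <- function(edges) {
  c(paste0("<", edges[[1L]], "%"),
    paste0(edges[[1L]], "-", edges[[2L]], "%"),
    paste0(">", edges[[2L]], "%"))
}

#' Bin per-term percentage differences between two profiles
#'
#' For every term in the union (absent terms contributing 0%), the
#' absolute percentage difference d = |pct_a - pct_b| is assigned to
#' one of three bins; with the default edges (0.5, 1.0):
#' d in [0, 0.5) -> "<0.5%", d in [0.5, 1.0] -> "0.5-1%",
#' d > 1.0 -> ">1%". Both edges fall in the middle bin; differences
#' are binned unrounded.
#'
#' @param a,b `term_profile` objects at the same namespace and level.
#' @param edges two increasing bin edges in percent.
#' @return list with `bin_counts` (named integer vector over the three
#'   bins) and `per_term` (data frame `go_id`, `diff`, `bin`).
#' @export
bin_differences <- function(a, b, edges = c(0.5, 1.0)) {
  stopifnot(length(edges) == 2L, edges[[1L]] < edges[[2L]])
  al <- align_profiles(a, b)
  d <- abs(al$pct_a - al$pct_b)
  labs <- bin_labels(edges)
  bin <- ifelse(d < edges[[1L]], labs[[1L]],
                ifelse(d <= edges[[2L]], labs[[2L]], labs[[3L]]))
  per_term <- data.frame(go_id = al$ids, diff = unname(d), bin = bin,
                         stringsAsFactors = FALSE)
  counts <- setNames(integer(3L), labs)
  tab <- table(bin)
  counts[names(tab)] <- as.integer(tab)
  list(bin_counts = counts, per_term = per_term)
}

#' Full comparison of two species' term profiles
#'
#' Bundles [pearson_similarity()], [term_overlap()] and
#' [bin_differences()] into one report, the per-(namespace, level)
#' unit of a cross-species GO comparison.
#'
#' @inheritParams bin_differences
#' @return object of class `profile_comparison` with fields
#'   `pearson_r`, `n_shared`, `n_unique_a`, `n_unique_b`,
#'   `per_term_diff`, `bin_counts`, `bin_edges`, `namespace`, `level`,
#'   `species`.
#' @export
compare_profiles <- function(a, b, edges = c(0.5, 1.0)) {
  ov <- term_overlap(a, b)
  bins <- bin_differences(a, b, edges)
  structure(
    list(pearson_r = pearson_similarity(a, b),
         n_shared = ov$n_shared, n_unique_a = ov$n_unique_a,
         n_unique_b = ov$n_unique_b,
         shared = ov$shared, unique_a = ov$unique_a,
         unique_b = ov$unique_b,
         per_term_diff = bins$per_term, bin_counts = bins$bin_counts,
         bin_edges = edges,
         namespace = attr(a, "namespace"), level = attr(a, "level"),
         species = c(attr(a, "species"), attr(b, "species"))),
    class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  sp <- x$species
  sp[is.na(sp)] <- c("A", "B")[is.na(sp)]
  cat("Profile comparison: ", x$namespace, " level ", x$level,
      " (", sp[[1L]], " vs ", sp[[2L]], ")\n", sep = "")
  cat(sprintf("  Pearson r: %.3f\n", x$pearson_r))
  cat("  terms: ", x$n_shared, " shared, ", x$n_unique_a,
      " unique to ", sp[[1L]], ", ", x$n_unique_b, " unique to ",
      sp[[2L]], "\n", sep = "")
  cat("  |difference| bins:",
      paste(names(x$bin_counts), x$bin_counts, sep = ": ",
            collapse = ", "), "\n")
  invisible(x)
}

#' Scatter plot of one profile against another
#'
#' Mirrors the per-level correlation panels of a cross-species GO
#' comparison: each point is a term of the union, axes are the two
#' species' percentages, with the identity line.
#'
#' @param x a `profile_comparison`.
#' @param a,b the two profiles that produced `x`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_comparison <- function(x, a, b, ...) {
  al <- align_profiles(a, b)
  graphics::plot(al$pct_a, al$pct_b,
                 xlab = "percent (species A)",
                 ylab = "percent (species B)",
                 main = sprintf("%s level %d, r = %.3f",
                                x$namespace, x$level, x$pearson_r), ...)
  graphics::abline(0, 1, col = "grey50", lty = 2)
  invisible(x)
}
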