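test_that("identical profiles give r = 1, no unique terms, all small bins", {
  p <- mk_profile(c(t1 = 40, t2 = 35, t3 = 25))
  cmp <- compare_profiles(p, p)
  expect_equal(cmp$pearson_r, 1)
  expect_equal(cmp$n_shared, 3L)
  expect_equal(cmp$n_unique_a + cmp$n_unique_b, 0L)
  expect_equal(unname(cmp$bin_counts), c(3L, 0L, 0L))
})

test_that("mirror-image two-term profiles are perfectly anti-correlated", {
  a <- mk_profile(c(t1 = 90, t2 = 10))
  b <- mk_profile(c(t1 = 10, t2 = 90))
  expect_equal(pearson_similarity(a, b), -1)
})

test_that("pearson_similarity equals the direct-formula oracle on random profiles", {
  for (seed in 1:20) {
    set.seed(seed)
    cnt_a <- setNames(rexp(30) * 100 + 1,
                      sprintf("GO:%07d", 1:30))
    cnt_b <- setNames(rexp(30) * 100 + 1, names(cnt_a))
    a <- mk_profile(cnt_a)
    b <- mk_profile(cnt_b)
    expect_equal(pearson_similarity(a, b),
                 oracle_pearson(100 * cnt_a / sum(cnt_a),
                                100 * cnt_b / sum(cnt_b)),
                 tolerance = 1e-12)
  }
})

test_that("absent terms enter the correlation as 0%", {
  a <- mk_profile(c(t1 = 50, t2 = 50))
  b <- mk_profile(c(t1 = 50, t3 = 50))
  expect_equal(pearson_similarity(a, b),
               oracle_pearson(c(50, 50, 0), c(50, 0, 50)))
})

test_that("zero-variance percentage vectors are an explicit error", {
  a <- mk_profile(c(t1 = 50, t2 = 50))
  b <- mk_profile(c(t1 = 80, t2 = 20))
  expect_error(pearson_similarity(a, b), "variance")
  expect_error(pearson_similarity(mk_profile(c(t1 = 100)),
                                  mk_profile(c(t1 = 100))),
               "2 terms")
})

test_that("term overlap partitions the union", {
  a <- mk_profile(c(t1 = 10, t2 = 10, t3 = 10))
  b <- mk_profile(c(t2 = 10, t3 = 10, t4 = 10))
  ov <- term_overlap(a, b)
  expect_equal(ov$n_shared, 2L)
  expect_equal(ov$n_unique_a, 1L)
  expect_equal(ov$n_unique_b, 1L)
  expect_setequal(c(ov$shared, ov$unique_a, ov$unique_b),
                  union(a$go_id, b$go_id))
  ## swap symmetry
  ov2 <- term_overlap(b, a)
  expect_equal(ov2$n_unique_a, ov$n_unique_b)
  expect_equal(ov2$n_unique_b, ov$n_unique_a)
  ## disjoint sets share nothing
  d <- term_overlap(mk_profile(c(x = 1)), mk_profile(c(y = 1)))
  expect_equal(d$n_shared, 0L)
})

test_that("a 33.5% vs 29.6% term lands in the >1% difference bin", {
  a <- mk_profile(c("cell part" = 33.5, other = 66.5))
  b <- mk_profile(c("cell part" = 29.6, other = 70.4))
  bd <- bin_differences(a, b)
  expect_equal(bd$per_term$bin[bd$per_term$go_id == "cell part"],
               ">1%")
  expect_equal(bd$per_term$diff[bd$per_term$go_id == "cell part"],
               3.9, tolerance = 1e-9)
})

test_that("differences exactly at the edges fall in the middle bin", {
  a <- mk_profile(c(t1 = 25.5, t2 = 26, t3 = 24.2, t4 = 24.3))
  b <- mk_profile(c(t1 = 25, t2 = 25, t3 = 24.2, t4 = 25.8))
  ## both sum to 100, so percents equal counts;
  ## diffs: 0.5, 1.0, 0.0, 1.5
  bd <- bin_differences(a, b)
  expect_equal(bd$per_term$bin[match(c("t1", "t2", "t3", "t4"),
                                     bd$per_term$go_id)],
               c("0.5-1%", "0.5-1%", "<0.5%", ">1%"))
  expect_equal(sum(bd$bin_counts), 4L)
})

test_that("bin counts always sum to the union size", {
  for (seed in 1:10) {
    set.seed(seed)
    ids <- sprintf("t%02d", 1:15)
    a <- mk_profile(setNames(rexp(12) + 0.01, sample(ids, 12)))
    b <- mk_profile(setNames(rexp(12) + 0.01, sample(ids, 12)))
    bd <- bin_differences(a, b)
    expect_equal(sum(bd$bin_counts),
                 length(union(a$go_id, b$go_id)))
  }
})

test_that("Pearson r is symmetric and invariant to the counts/percent scale", {
  set.seed(99)
  cnt_a <- setNames(rpois(20, 50) + 1, sprintf("t%02d", 1:20))
  cnt_b <- setNames(rpois(20, 50) + 1, names(cnt_a))
  a <- mk_profile(cnt_a); b <- mk_profile(cnt_b)
  expect_equal(pearson_similarity(a, b), pearson_similarity(b, a))
  ## equal denominators: correlation on raw counts matches
  expect_equal(pearson_similarity(a, b),
               oracle_pearson(unname(cnt_a), unname(cnt_b)) *
                 (sum(cnt_a) / sum(cnt_a)),
               tolerance = 1e-12)
})

test_that("profiles at different levels or namespaces refuse to compare", {
  a <- mk_profile(c(t1 = 1, t2 = 1), level = 2L)
  b <- mk_profile(c(t1 = 1, t2 = 1), level = 3L)
  expect_error(pearson_similarity(a, b), "namespace and level")
  c2 <- mk_profile(c(t1 = 1, t2 = 1), namespace = "molecular_function")
  expect_error(term_overlap(a, c2), "namespace and level")
})

test_that("compare() bundles the three analyses consistently", {
  set.seed(5)
  dag <- gen_go_dag(n_terms_per_level = 20L, seed = 5)
  cfg <- sim_config(seed = 5, n_ests_per_species = 4000L,
                    n_terms_per_level = 20L, n_unique_b = 3L,
                    target_profile_correlation = 0.9)
  tabs <- gen_annotation_tables(dag, cfg)
  pa <- term_profile(tabs$table_a, dag, "biological_process", 3L)
  pb <- term_profile(tabs$table_b, dag, "biological_process", 3L)
  cmp <- compare_profiles(pa, pb)
  expect_equal(cmp$pearson_r, pearson_similarity(pa, pb))
  ov <- term_overlap(pa, pb)
  expect_equal(cmp$n_shared, ov$n_shared)
  expect_equal(cmp$n_unique_b, 3L)   # planted unique terms recovered
  expect_equal(cmp$n_unique_a, 0L)
  expect_equal(sum(cmp$bin_counts),
               cmp$n_shared + cmp$n_unique_a + cmp$n_unique_b)
})
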