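hit_row <- function(query, family = "IR", method = "homology",
                    e = 1e-5, ref = "RefX", frame = 1L,
                    span = c(151L, 750L)) {
  data.frame(query_id = query, family = family, reference_id = ref,
             method = method, e_value = e, frame = frame,
             span_start = span[[1L]], span_end = span[[2L]],
             stringsAsFactors = FALSE)
}

test_that("method-specific cutoffs are inclusive and method-checked", {
  hits <- rbind(hit_row("c1", e = 0.05),
                hit_row("c2", method = "hmm", e = 0.01),
                hit_row("c3", method = "hmm", e = 1e-3))
  cands <- collect_candidates(hits)
  expect_setequal(cands$contig_id, c("c1", "c3"))
  expect_error(collect_candidates(hit_row("c4", method = "psiblast")),
               "psiblast")
})

test_that("the best hit has lowest e-value, ties broken by span length", {
  hits <- rbind(
    hit_row("c1", e = 1e-4, ref = "worse"),
    hit_row("c1", e = 1e-6, ref = "better"),
    hit_row("c2", e = 1e-6, ref = "short", span = c(301L, 500L)),
    hit_row("c2", e = 1e-6, ref = "long", span = c(151L, 750L)))
  cands <- collect_candidates(hits)
  expect_equal(cands$reference_id[cands$contig_id == "c1"], "better")
  expect_equal(cands$reference_id[cands$contig_id == "c2"], "long")
  ## one candidate per (contig, family)
  expect_equal(nrow(cands), 2L)
})

test_that("relaxing a cutoff never removes a candidate", {
  g <- gen_candidates(sim_config(seed = 21))
  strict <- collect_candidates(g$hits,
                               c(homology = 1e-3, hmm = 1e-5))
  lax <- collect_candidates(g$hits, c(homology = 1e-1, hmm = 1e-3))
  key <- function(x) paste(x$contig_id, x$family)
  expect_true(all(key(strict) %in% key(lax)))
})

## one clean in-frame candidate sequence: 300 sense codons
clean_seq <- function(seed) {
  set.seed(seed)
  codons <- antcomp:::sense_codons()
  paste(sample(codons, 300, replace = TRUE), collapse = "")
}

test_that("the IR quality filter flags stops, ambiguities, and TM spans", {
  s <- clean_seq(1)
  seqs <- data.frame(id = "c1", sequence = s)
  tm2 <- data.frame(contig_id = "c1",
                    tm_start = c(181L, 361L, 781L),
                    tm_end = c(240L, 420L, 840L))
  cands <- collect_candidates(hit_row("c1"))
  out <- apply_ir_quality_filter(cands, tm2, seqs)
  expect_equal(out$n_tm_spanned, 2L)
  expect_false(out$has_internal_stop)
  expect_false(out$has_ambiguity)
  expect_true(out$dendrogram_ready)

  ## in-frame internal TAA kills readiness
  s_stop <- s; substr(s_stop, 451, 453) <- "TAA"
  out2 <- apply_ir_quality_filter(
    cands, tm2, data.frame(id = "c1", sequence = s_stop))
  expect_true(out2$has_internal_stop)
  expect_false(out2$dendrogram_ready)

  ## a stop in the terminal codon of the span is tolerated
  s_term <- s; substr(s_term, 748, 750) <- "TGA"
  out3 <- apply_ir_quality_filter(
    cands, tm2, data.frame(id = "c1", sequence = s_term))
  expect_false(out3$has_internal_stop)

  ## an out-of-frame TAA is not an in-frame stop
  s_oof <- s; substr(s_oof, 452, 454) <- "TAA"
  out4 <- apply_ir_quality_filter(
    cands, tm2, data.frame(id = "c1", sequence = s_oof))
  ## shifting by one base may create an accidental in-frame stop at
  ## the junctions, so recheck against a brute-force frame scan
  cods <- substring(s_oof, seq(151, 748, 3), seq(153, 750, 3))
  expect_equal(out4$has_internal_stop,
               any(head(cods, -1) %in% c("TAA", "TAG", "TGA")))

  ## one N in the span kills readiness
  s_amb <- s; substr(s_amb, 500, 500) <- "N"
  out5 <- apply_ir_quality_filter(
    cands, tm2, data.frame(id = "c1", sequence = s_amb))
  expect_true(out5$has_ambiguity)
  expect_false(out5$dendrogram_ready)
  ## an N outside the span does not
  s_out <- s; substr(s_out, 10, 10) <- "N"
  out6 <- apply_ir_quality_filter(
    cands, tm2, data.frame(id = "c1", sequence = s_out))
  expect_false(out6$has_ambiguity)
})

test_that("missing TM annotation leaves a retained, not-ready candidate", {
  seqs <- data.frame(id = "c1", sequence = clean_seq(2))
  cands <- collect_candidates(hit_row("c1"))
  out <- apply_ir_quality_filter(
    cands, data.frame(contig_id = character(0),
                      tm_start = integer(0), tm_end = integer(0)),
    seqs)
  expect_equal(nrow(out), 1L)
  expect_equal(out$n_tm_spanned, 0L)
  expect_false(out$dendrogram_ready)
})

test_that("partial TM overlap does not count as spanning", {
  seqs <- data.frame(id = "c1", sequence = clean_seq(3))
  tm <- data.frame(contig_id = "c1",
                   tm_start = c(120L, 181L, 361L),
                   tm_end = c(200L, 240L, 420L))  # first straddles 151
  out <- apply_ir_quality_filter(collect_candidates(hit_row("c1")),
                                 tm, seqs)
  expect_equal(out$n_tm_spanned, 2L)
})

test_that("naming uses homolog names, then deterministic numerals", {
  hits <- rbind(hit_row("c1", e = 1e-8, ref = "RefIR25a"),
                hit_row("c2", e = 1e-6, ref = "RefA"),
                hit_row("c3", e = 1e-4, ref = "RefB"))
  cands <- collect_candidates(hits)
  named <- name_candidates(cands, "Ccly")
  expect_equal(named$assigned_name[named$contig_id == "c1"],
               "CclyIR25a")
  expect_equal(named$assigned_name[named$contig_id == "c2"],
               "CclyIR1")   # lower e-value gets the lower numeral
  expect_equal(named$assigned_name[named$contig_id == "c3"],
               "CclyIR2")
  ## idempotent and injective
  again <- name_candidates(named, "Ccly")
  expect_equal(again$assigned_name, named$assigned_name)
  expect_equal(anyDuplicated(named$assigned_name), 0L)
  expect_error(name_candidates(cands, ""), "nzchar")
})

test_that("the screen recovers the planted pass/fail partition exactly", {
  g <- gen_candidates(sim_config(seed = 42))
  cands <- collect_candidates(g$hits)
  cands <- apply_ir_quality_filter(cands, g$tm, g$sequences)
  truth <- g$truth
  expect_setequal(cands$contig_id,
                  truth$contig_id[truth$is_candidate])
  m <- match(cands$contig_id, truth$contig_id)
  expect_equal(cands$n_tm_spanned, truth$n_tm[m])
  expect_equal(cands$has_internal_stop, truth$has_internal_stop[m])
  expect_equal(cands$has_ambiguity, truth$has_ambiguity[m])
  expect_equal(cands$dendrogram_ready, truth$dendrogram_ready[m])
})

test_that("category tabulation counts distinct contigs per gene", {
  cmap <- data.frame(
    category = c("ANTIMICROBIAL", "ANTIMICROBIAL", "RNAi"),
    gene = c("Crustin", "C-type Lectin", "Armitage"))
  empty <- collect_candidates(hit_row("x")[0, ])
  tab0 <- tabulate_categories(empty, empty, cmap,
                              species = c("Pber", "Ccly"))
  expect_equal(tab0$Pber, rep(0L, 3))
  expect_equal(tab0$Ccly, rep(0L, 3))

  a <- collect_candidates(rbind(
    hit_row("c1", family = "Crustin"),
    hit_row("c2", family = "Crustin"),
    hit_row("c1", family = "C-type Lectin")))
  b <- collect_candidates(hit_row("c9", family = "Armitage"))
  tab <- tabulate_categories(a, b, cmap, species = c("Pber", "Ccly"))
  expect_equal(tab$Pber[tab$gene == "Crustin"], 2L)
  ## one contig hit by two genes increments both rows
  expect_equal(tab$Pber[tab$gene == "C-type Lectin"], 1L)
  expect_equal(tab$Ccly[tab$gene == "Armitage"], 1L)
  expect_equal(tab$category, cmap$category)

  expect_warning(
    tab2 <- tabulate_categories(
      collect_candidates(hit_row("c5", family = "Mystery")), b,
      cmap, species = c("Pber", "Ccly")),
    "uncategorized")
  expect_equal(tab2$Pber[tab2$gene == "Mystery"], 1L)
  expect_equal(tab2$category[tab2$gene == "Mystery"],
               "uncategorized")
})
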