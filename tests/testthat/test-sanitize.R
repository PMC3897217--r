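LNK <- "GTTGGAACCGAAAGGGTTTGAATTCAAACCCTTTCGGTTCCAAC"

rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
        collapse = "")
}

test_that("a single internal linker splits a read into two counted parts", {
  left <- rand_seq(80, 1); right <- rand_seq(70, 2)
  reads <- data.frame(id = "r1",
                      sequence = paste0(left, LNK, right))
  res <- split_reads_on_linker(reads, linker_spec(LNK))
  expect_equal(res$reads$sequence, c(left, right))
  expect_equal(res$reads$id, c("r1/p1", "r1/p2"))
  expect_equal(res$stats$counts, c("2" = 1L))
  expect_equal(res$stats$n_total_out, 2L)
  expect_equal(res$stats$n_unsplit, 0L)
})

test_that("reads without a linker pass through unchanged", {
  reads <- data.frame(id = c("r1", "r2"),
                      sequence = c(rand_seq(120, 3), rand_seq(90, 4)))
  res <- split_reads_on_linker(reads, linker_spec(LNK))
  expect_identical(res$reads, reads)
  expect_equal(res$stats$n_unsplit, 2L)
  expect_equal(length(res$stats$counts), 0L)
})

test_that("empty input and a linker longer than the read are handled", {
  empty <- data.frame(id = character(0), sequence = character(0))
  res <- split_reads_on_linker(empty, linker_spec(LNK))
  expect_equal(nrow(res$reads), 0L)
  expect_equal(res$stats$n_total_in, 0L)
  short <- data.frame(id = "s", sequence = "ACGTACGT")
  res2 <- split_reads_on_linker(short, linker_spec(LNK))
  expect_identical(res2$reads, short)
})

test_that("linker occurrences within the mismatch budget are excised", {
  mut <- LNK
  substr(mut, 5, 5) <- if (substr(mut, 5, 5) == "A") "C" else "A"
  reads <- data.frame(
    id = "r1", sequence = paste0(rand_seq(70, 5), mut, rand_seq(70, 6)))
  strict <- split_reads_on_linker(reads, linker_spec(LNK, 0))
  expect_equal(strict$stats$n_unsplit, 1L)
  lax <- split_reads_on_linker(reads, linker_spec(LNK, 2))
  expect_equal(lax$stats$counts, c("2" = 1L))
})

test_that("short flanking fragments are dropped and not counted as parts", {
  ## left fragment below the 50 nt floor: one retained fragment, so
  ## the read counts as unsplit, not as a 2-part split
  reads <- data.frame(
    id = "r1", sequence = paste0(rand_seq(20, 7), LNK, rand_seq(80, 8)))
  res <- split_reads_on_linker(reads, linker_spec(LNK))
  expect_equal(nrow(res$reads), 1L)
  expect_equal(nchar(res$reads$sequence), 80L)
  expect_equal(length(res$stats$counts), 0L)
  expect_equal(res$stats$n_unsplit, 1L)
  ## both fragments too short: the read disappears entirely
  gone <- data.frame(
    id = "r2", sequence = paste0(rand_seq(20, 9), LNK, rand_seq(30, 10)))
  res2 <- split_reads_on_linker(gone, linker_spec(LNK))
  expect_equal(nrow(res2$reads), 0L)
  expect_equal(res2$stats$n_total_out, 0L)
})

test_that("splitting is idempotent and conserves non-excised bases", {
  cfg <- sim_config(seed = 11, n_reads = 500L)
  g <- gen_reads(cfg)
  spec <- linker_spec(cfg$linker_sequence)
  res <- split_reads_on_linker(g$reads, spec)
  again <- split_reads_on_linker(res$reads, spec)
  expect_equal(again$reads$sequence, res$reads$sequence)
  expect_equal(again$stats$n_unsplit, nrow(res$reads))
  ## base conservation: planted fragments are all >= the floor, so
  ## retained bases = input bases - excised linker bases
  n_linkers <- sum(g$truth$n_parts - 1L)
  expect_equal(sum(nchar(res$reads$sequence)),
               sum(nchar(g$reads$sequence)) -
                 n_linkers * nchar(cfg$linker_sequence))
})

test_that("the split histogram recovers the planted part counts", {
  cfg <- sim_config(seed = 23, n_reads = 1500L)
  g <- gen_reads(cfg)
  res <- split_reads_on_linker(g$reads, linker_spec(cfg$linker_sequence))
  planted <- table(g$truth$n_parts[g$truth$n_parts >= 2])
  expect_equal(res$stats$counts[names(planted)],
               setNames(as.integer(planted), names(planted)))
  expect_equal(res$stats$n_unsplit, sum(g$truth$n_parts == 1L))
})

mini_groups <- function() {
  taxo <- data.frame(child  = c(1L, 10L, 11L, 12L, 20L, 21L, 30L),
                     parent = c(1L, 1L, 10L, 11L, 1L, 20L, 1L))
  taxon_group_set(
    data.frame(name = c("Fungi", "Bacteria"),
               root_taxid = c(10L, 20L)), taxo)
}

test_that("the contaminant cutoff is a strict less-than", {
  gr <- mini_groups()
  hits <- data.frame(query_id = c("q1", "q2"),
                     subject_taxid = c(12L, 12L),
                     e_value = c(1e-21, 1e-19),
                     bitscore = c(100, 100))
  res <- screen_contaminants(c("q1", "q2"), hits, gr)
  expect_equal(res$clean_ids, "q2")
  expect_equal(res$report$removed_per_group,
               c(Fungi = 1L, Bacteria = 0L))
  ## exactly at the cutoff is retained
  at <- screen_contaminants(
    "q1", data.frame(query_id = "q1", subject_taxid = 12L,
                     e_value = 1e-20, bitscore = 50), gr)
  expect_equal(at$clean_ids, "q1")
})

test_that("removal is attributed to the best qualifying hit's group", {
  gr <- mini_groups()
  hits <- data.frame(query_id = rep("q1", 2),
                     subject_taxid = c(12L, 21L),
                     e_value = c(1e-30, 1e-25),
                     bitscore = c(100, 500))
  res <- screen_contaminants("q1", hits, gr)
  expect_equal(unname(res$report$removed_ids["q1"]), "Fungi")
  ## equal e-values: higher bitscore wins
  hits2 <- data.frame(query_id = rep("q1", 2),
                      subject_taxid = c(12L, 21L),
                      e_value = c(1e-30, 1e-30),
                      bitscore = c(100, 500))
  res2 <- screen_contaminants("q1", hits2, gr)
  expect_equal(unname(res2$report$removed_ids["q1"]), "Bacteria")
})

test_that("hits with unknown taxids are ignored with a warning", {
  gr <- mini_groups()
  hits <- data.frame(query_id = "q1", subject_taxid = 999L,
                     e_value = 1e-40, bitscore = 100)
  expect_warning(res <- screen_contaminants("q1", hits, gr),
                 "absent from the taxonomy")
  expect_equal(res$clean_ids, "q1")
  expect_error(
    screen_contaminants("q1",
                        data.frame(query_id = "zz",
                                   subject_taxid = 12L,
                                   e_value = 1e-40, bitscore = 1),
                        gr),
    "not in")
})

test_that("the screen recovers planted contaminant groups exactly", {
  cfg <- sim_config(seed = 31, n_reads = 3000L)
  g <- gen_reads(cfg)
  res <- screen_contaminants(g$reads$id, g$hits, g$groups)
  planted <- table(g$truth$taxon_group)
  for (grp in names(res$report$removed_per_group)) {
    expect_equal(res$report$removed_per_group[[grp]],
                 if (grp %in% names(planted))
                   as.integer(planted[[grp]]) else 0L)
  }
  ## partition invariant
  expect_equal(sum(res$report$removed_per_group) +
                 res$report$n_remaining,
               res$report$n_input)
  expect_setequal(res$clean_ids,
                  g$truth$id[g$truth$taxon_group == "none"])
})
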