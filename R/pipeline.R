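#' Pipeline configuration
#'
#' Collects every stage parameter with the conventional defaults of a
#' two-species antennal transcriptome comparison: contaminant cutoff
#' E < 1e-20 (strict), coverage filter at 5-fold (contigs below 5 are
#' ignored), profiling at levels 2 and 3, difference bins at
#' (0.5, 1.0) percent, homology screen cutoff 1e-1, HMM screen cutoff
#' 1e-3, and an annotation-ingestion e-value filter of 1e-6.
#'
#' @param out_dir output directory (created if missing).
#' @param species two species labels (species A, species B).
#' @param seed integer seed driving all synthetic inputs.
#' @param sim a [sim_config()]; defaults to `sim_config(seed = seed)`.
#'   Used for any input not supplied in `inputs`.
#' @param inputs optional named list of file paths overriding
#'   simulation: `reads` (FASTA/FASTQ), `hits` (taxonomic hit TSV),
#'   `taxonomy` (child-parent TSV), `obo`, `annotations_a`,
#'   `annotations_b`, `contigs_a`, `contigs_b` (coverage TSVs),
#'   `family_hits` (search-hit TSV), `tm` (TM interval TSV),
#'   `sequences` (candidate FASTA), `category_map`.
#' @param linker a [linker_spec()]; defaults to the simulated linker.
#' @param e_contaminant strict contaminant-screen cutoff.
#' @param min_coverage coverage filter threshold.
#' @param levels GO levels to profile.
#' @param bin_edges difference bin edges (percent).
#' @param screen_cutoffs named per-method candidate cutoffs.
#' @param annotation_min_e ingestion e-value filter for annotation
#'   records carrying an `e_value` column.
#' @param split_first whether linker splitting precedes contaminant
#'   screening (the default; the reverse order is supported).
#' @param denominator percentage denominator mode for profiles.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            species = c("Ccly", "Pber"),
                            seed = 1L,
                            sim = sim_config(seed = seed),
                            inputs = list(),
                            linker = linker_spec(sim$linker_sequence),
                            e_contaminant = 1e-20,
                            min_coverage = 5,
                            levels = c(2L, 3L),
                            bin_edges = c(0.5, 1.0),
                            screen_cutoffs = c(homology = 1e-1,
                                               hmm = 1e-3),
                            annotation_min_e = 1e-6,
                            split_first = TRUE,
                            denominator = "assignments") {
  stopifnot(length(species) == 2L, all(levels >= 2L))
  structure(list(out_dir = out_dir, species = species,
                 seed = as.integer(seed), sim = sim, inputs = inputs,
                 linker = linker, e_contaminant = e_contaminant,
                 min_coverage = min_coverage,
                 levels = as.integer(levels), bin_edges = bin_edges,
                 screen_cutoffs = screen_cutoffs,
                 annotation_min_e = annotation_min_e,
                 split_first = split_first,
                 denominator = denominator),
            class = "pipeline_config")
}

#' Filter annotation records by source e-value
#'
#' Ingestion filter for annotation tables that carry the e-value of
#' the hit the annotation was based on: records with
#' `e_value > min_e` are dropped; records lacking an e-value pass
#' with a warning.
#'
#' @param records annotation data frame, optionally with an `e_value`
#'   column.
#' @param min_e inclusive e-value threshold.
#' @return the retained records.
#' @export
filter_annotations <- function(records, min_e = 1e-6) {
  if (is.null(records$e_value)) {
    warning("annotation records lack an e_value column; ",
            "all records pass the ingestion filter")
    return(records)
  }
  missing_e <- is.na(records$e_value)
  if (any(missing_e))
    warning(sum(missing_e),
            " record(s) without e_value pass the ingestion filter")
  out <- records[missing_e | records$e_value <= min_e, , drop = FALSE]
  row.names(out) <- NULL
  out
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full comparison pipeline
#'
#' Executes the stages in order - sanitize (linker split + contaminant
#' screen), assembly statistics and coverage filter, per-species
#' level-wise GO profiling, per-level cross-species comparison, and
#' the gene-family candidate screen - writing every artifact as TSV
#' (plus one JSON summary) under `config$out_dir`, together with a
#' manifest of md5 checksums and a log of every parameter used.
#' Inputs not supplied as files in `config$inputs` are generated by
#' the synthetic-data module from `config$sim`, so a bare config runs
#' end to end. Output files contain no timestamps: two runs with the
#' same config and seed are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a `pipeline_result` list: `status` (0 on
#'   success), `manifest`, and the in-memory stage results. Any stage
#'   failure raises an error naming the stage.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[antcomp] ", ...)
  art <- character(0)
  log_lines <- c("antcomp pipeline log",
                 paste0("seed: ", config$seed),
                 paste0("species: ",
                        paste(config$species, collapse = ", ")),
                 paste0("contaminant cutoff (strict <): ",
                        format(config$e_contaminant)),
                 paste0("min coverage: ", config$min_coverage),
                 paste0("levels: ",
                        paste(config$levels, collapse = ",")),
                 paste0("bin edges: ",
                        paste(config$bin_edges, collapse = ",")),
                 paste0("screen cutoffs: ",
                        paste(names(config$screen_cutoffs),
                              config$screen_cutoffs,
                              sep = "=", collapse = ", ")),
                 paste0("annotation ingestion filter: ",
                        format(config$annotation_min_e)),
                 paste0("order: ",
                        if (config$split_first)
                          "split-then-screen" else "screen-then-split"),
                 paste0("denominator: ", config$denominator))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }
  res <- list()
  out <- function(name) file.path(config$out_dir, name)

  ## --- sanitize ----------------------------------------------------
  say("stage sanitize")
  res$sanitize <- stage("sanitize", {
    if (!is.null(config$inputs$reads)) {
      reads <- read_sequences(config$inputs$reads)
      hits <- read_hit_table(config$inputs$hits)
      taxo <- read_taxonomy(config$inputs$taxonomy)
      gset <- taxon_group_set(default_taxon_groups(), taxo)
    } else {
      g <- gen_reads(config$sim)
      reads <- g$reads; hits <- g$hits; gset <- g$groups
    }
    if (config$split_first) {
      sp <- split_reads_on_linker(reads, config$linker)
      parent <- sub("/p[0-9]+$", "", sp$reads$id)
      keep_hits <- hits[hits$query_id %in% parent, , drop = FALSE]
      ## screen fragments via their parent read's hits
      scr <- screen_contaminants(
        unique(parent), keep_hits, gset, config$e_contaminant)
      clean <- sp$reads[parent %in% scr$clean_ids, , drop = FALSE]
    } else {
      scr <- screen_contaminants(reads$id, hits, gset,
                                 config$e_contaminant)
      retained <- reads[reads$id %in% scr$clean_ids, , drop = FALSE]
      sp <- split_reads_on_linker(retained, config$linker)
      clean <- sp$reads
    }
    write_sequences(clean, out("clean_reads.fasta"))
    write_tsv(data.frame(k_parts = names(sp$stats$counts),
                         n_reads = as.integer(sp$stats$counts)),
              out("split_stats.tsv"))
    rep <- scr$report
    write_tsv(data.frame(
      group = c(names(rep$removed_per_group), "Remaining reads"),
      count = c(as.integer(rep$removed_per_group), rep$n_remaining)),
      out("contaminant_report.tsv"))
    art <- c(art, "clean_reads.fasta", "split_stats.tsv",
              "contaminant_report.tsv")
    list(split_stats = sp$stats, report = scr$report, reads = clean)
  })

  ## --- assembly stats ----------------------------------------------
  say("stage stats")
  res$stats <- stage("stats", {
    per_species <- list()
    for (i in 1:2) {
      sp_lab <- config$species[[i]]
      key <- c("contigs_a", "contigs_b")[[i]]
      contigs <- if (!is.null(config$inputs[[key]])) {
        x <- read.delim(config$inputs[[key]], header = TRUE,
                        stringsAsFactors = FALSE)
        stopifnot(all(c("id", "length", "avg_coverage") %in% names(x)))
        x[, c("id", "length", "avg_coverage")]
      } else {
        cfg_i <- config$sim
        cfg_i$seed <- cfg_i$seed + (i - 1L)
        gen_contigs(cfg_i)
      }
      filt <- filter_by_coverage(contigs, config$min_coverage)
      s_all <- summarize_assembly(contigs)
      s_filt <- summarize_assembly(filt)
      df <- rbind(cbind(dataset = "all",
                        as.data.frame(s_all)),
                  cbind(dataset = "coverage_filtered",
                        as.data.frame(s_filt)))
      write_tsv(df, out(paste0("assembly_summary_", sp_lab, ".tsv")))
      art <- c(art, paste0("assembly_summary_", sp_lab, ".tsv"))
      per_species[[sp_lab]] <-
        list(all = s_all, filtered = s_filt,
             n_filtered = nrow(filt))
    }
    per_species
  })

  ## --- profiles ----------------------------------------------------
  say("stage profile")
  res$profile <- stage("profile", {
    if (!is.null(config$inputs$obo)) {
      dag <- load_obo(config$inputs$obo)
      ann_a <- read_annotation_table(config$inputs$annotations_a)
      ann_b <- read_annotation_table(config$inputs$annotations_b)
      ns <- names(dag$roots)[[1L]]
    } else {
      dag <- gen_go_dag(
        n_levels = max(config$levels),
        n_terms_per_level = config$sim$n_terms_per_level,
        namespace = config$sim$profile_namespace,
        seed = config$sim$seed)
      tabs <- gen_annotation_tables(dag, config$sim)
      ann_a <- tabs$table_a; ann_b <- tabs$table_b
      ns <- config$sim$profile_namespace
    }
    if (!is.null(ann_a$e_value))
      ann_a <- filter_annotations(ann_a, config$annotation_min_e)
    if (!is.null(ann_b$e_value))
      ann_b <- filter_annotations(ann_b, config$annotation_min_e)
    profiles <- list()
    for (lv in config$levels) {
      if (!lv %in% unname(dag$level)) next
      pa <- term_profile(ann_a, dag, ns, lv,
                         denominator = config$denominator,
                         species = config$species[[1L]])
      pb <- term_profile(ann_b, dag, ns, lv,
                         denominator = config$denominator,
                         species = config$species[[2L]])
      fa <- sprintf("profile_%s_%s_L%d.tsv", config$species[[1L]],
                    ns, lv)
      fb <- sprintf("profile_%s_%s_L%d.tsv", config$species[[2L]],
                    ns, lv)
      write_profile(pa, out(fa)); write_profile(pb, out(fb))
      art <- c(art, fa, fb)
      profiles[[as.character(lv)]] <- list(a = pa, b = pb)
    }
    list(dag = dag, namespace = ns, profiles = profiles)
  })

  ## --- compare -----------------------------------------------------
  say("stage compare")
  res$compare <- stage("compare", {
    comps <- list()
    for (lv in names(res$profile$profiles)) {
      pr <- res$profile$profiles[[lv]]
      cmp <- compare_profiles(pr$a, pr$b, config$bin_edges)
      fn <- sprintf("comparison_%s_L%s.tsv",
                    res$profile$namespace, lv)
      write_tsv(cmp$per_term_diff, out(fn))
      art <- c(art, fn)
      comps[[lv]] <- cmp
    }
    comps
  })

  ## --- screen ------------------------------------------------------
  say("stage screen")
  res$screen <- stage("screen", {
    if (!is.null(config$inputs$family_hits)) {
      fh <- read.delim(config$inputs$family_hits,
                       stringsAsFactors = FALSE)
      tm <- read_tm_table(config$inputs$tm)
      seqs <- read_sequences(config$inputs$sequences)
      hom <- default_homolog_map()
    } else {
      gc <- gen_candidates(config$sim, config$screen_cutoffs)
      fh <- gc$hits; tm <- gc$tm; seqs <- gc$sequences
      hom <- gc$homolog_map
    }
    cands <- collect_candidates(fh, config$screen_cutoffs)
    cands <- apply_ir_quality_filter(cands, tm, seqs)
    cands <- name_candidates(cands, config$species[[1L]], hom)
    write_tsv(as.data.frame(cands), out("candidates.tsv"))
    cmap <- if (!is.null(config$inputs$category_map))
      read_category_map(config$inputs$category_map)
    else read_category_map(system.file("extdata",
                                       "immune_categories.tsv",
                                       package = "antcomp"))
    immune <- cands[cands$family %in% cmap$gene, , drop = FALSE]
    tab <- suppressWarnings(tabulate_categories(
      immune, immune[0, , drop = FALSE], cmap,
      species = config$species))
    write_tsv(as.data.frame(tab), out("immune_categories.tsv"))
    art <- c(art, "candidates.tsv", "immune_categories.tsv")
    list(candidates = cands, categories = tab)
  })

  ## --- summary, log, manifest --------------------------------------
  summary <- list(
    seed = config$seed,
    split_counts = as.list(res$sanitize$split_stats$counts),
    contaminants_removed =
      as.list(res$sanitize$report$removed_per_group),
    reads_remaining = res$sanitize$report$n_remaining,
    assembly = lapply(res$stats, function(s)
      list(n_contigs = s$all$n_contigs, n50 = s$all$n50,
           mean_length = s$all$mean_length,
           n_after_coverage_filter = s$n_filtered)),
    comparisons = lapply(res$compare, function(cmp)
      list(pearson_r = cmp$pearson_r, n_shared = cmp$n_shared,
           n_unique_a = cmp$n_unique_a,
           n_unique_b = cmp$n_unique_b,
           bins = as.list(cmp$bin_counts))),
    n_candidates = nrow(res$screen$candidates),
    n_dendrogram_ready =
      sum(res$screen$candidates$dendrogram_ready, na.rm = TRUE))
  jsonlite::write_json(summary, out("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, out("pipeline_log.txt"))
  art <- c(art, "summary.json", "pipeline_log.txt")
  manifest <- data.frame(
    file = art,
    md5 = unname(md5sum(file.path(config$out_dir, art))),
    stringsAsFactors = FALSE)
  write_tsv(manifest, out("manifest.tsv"))
  say("done: ", length(art), " artifacts in ", config$out_dir)
  invisible(structure(
    list(status = 0L, manifest = manifest, results = res,
         summary = summary, config = config),
    class = "pipeline_result"))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("antcomp pipeline run: status", x$status, "\n")
  cat("  artifacts:", nrow(x$manifest), "files in",
      x$config$out_dir, "\n")
  for (lv in names(x$results$compare))
    cat(sprintf("  level %s: r = %.3f, %d shared terms\n", lv,
                x$results$compare[[lv]]$pearson_r,
                x$results$compare[[lv]]$n_shared))
  invisible(x)
}
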