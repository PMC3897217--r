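#' Simulation configuration for the synthetic-data generators
#'
#' Bundles and validates every parameter of the fixture generators.
#' Defaults emulate the input conditions of a two-species hermit-crab
#' antennal transcriptome study: 454-style reads with internal
#' linkers, environmental contaminant fractions as observed in marine
#' sample screening, and annotation tables whose level-wise profiles
#' are highly correlated between species.
#'
#' @param seed integer seed; fully determines all generator output.
#' @param n_reads number of reads for [gen_reads()].
#' @param read_length_range nt interval (uniform read lengths).
#' @param linker_sequence the internal linker planted between
#'   concatenated inserts (default: the 454 FLX paired-end linker).
#' @param linker_insertion_probs named numeric vector mapping the
#'   number of parts k (as names `"2"`, `"3"`, ...) to the probability
#'   that a read carries k-1 internal linkers; must sum to <= 1.
#' @param contaminant_fractions named numeric vector mapping taxon
#'   group names (must match `default_taxon_groups()` names or the
#'   `groups` passed to the screen) to the fraction of reads planted
#'   as contaminants; must sum to <= 1.
#' @param n_contigs,contig_length_meanlog,contig_length_sdlog,
#'   coverage_meanlog,coverage_sdlog contig-set generator parameters:
#'   lengths and average coverages are log-normal, floored at 100 nt.
#' @param n_ests_per_species number of annotation assignments
#'   generated per species.
#' @param target_profile_correlation target Pearson correlation of the
#'   two species' level-wise percentage profiles, in [-1, 1].
#' @param n_terms_per_level number of terms per DAG level used when
#'   profiling.
#' @param n_unique_a,n_unique_b number of profiled terms planted as
#'   present in only one species.
#' @param profile_namespace,profile_level the (namespace, level) at
#'   which annotation tables are profiled.
#' @param candidate_plan data frame of planted candidate descriptors
#'   (see [default_candidate_plan()]).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_reads = 2000L,
                       read_length_range = c(100L, 400L),
                       linker_sequence = "GTTGGAACCGAAAGGGTTTGAATTCAAACCCTTTCGGTTCCAAC",
                       linker_insertion_probs = c("2" = 0.068,
                                                  "3" = 0.0012,
                                                  "4" = 0.00001),
                       contaminant_fractions = c(
                         "Bacteria" = 0.0043,
                         "Archaea" = 0.0008,
                         "Verrucomicrobium spinosum" = 0.0068,
                         "Chlorophyta" = 0.0081,
                         "Fungi" = 0.0497,
                         "Stramenopiles" = 0.0010,
                         "Glaucocystophyceae" = 0.0350,
                         "Amoebozoa" = 0.0037),
                       n_contigs = 1000L,
                       contig_length_meanlog = log(400),
                       contig_length_sdlog = 0.6,
                       coverage_meanlog = log(6),
                       coverage_sdlog = 1,
                       n_ests_per_species = 10000L,
                       target_profile_correlation = 0.99,
                       n_terms_per_level = 30L,
                       n_unique_a = 0L,
                       n_unique_b = 0L,
                       profile_namespace = "biological_process",
                       profile_level = 3L,
                       candidate_plan = default_candidate_plan()) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_reads >= 0,
            length(read_length_range) == 2L,
            read_length_range[[1L]] >= 1,
            read_length_range[[1L]] <= read_length_range[[2L]],
            nchar(linker_sequence) >= 1,
            all(linker_insertion_probs >= 0),
            sum(linker_insertion_probs) <= 1,
            all(as.integer(names(linker_insertion_probs)) >= 2L),
            all(contaminant_fractions >= 0),
            sum(contaminant_fractions) <= 1,
            n_ests_per_species >= 1,
            target_profile_correlation >= -1,
            target_profile_correlation <= 1,
            n_terms_per_level >= 3,
            n_unique_a >= 0, n_unique_b >= 0,
            profile_level >= 2)
  structure(list(
    seed = as.integer(seed), n_reads = as.integer(n_reads),
    read_length_range = as.integer(read_length_range),
    linker_sequence = toupper(linker_sequence),
    linker_insertion_probs = linker_insertion_probs,
    contaminant_fractions = contaminant_fractions,
    n_contigs = as.integer(n_contigs),
    contig_length_meanlog = contig_length_meanlog,
    contig_length_sdlog = contig_length_sdlog,
    coverage_meanlog = coverage_meanlog,
    coverage_sdlog = coverage_sdlog,
    n_ests_per_species = as.integer(n_ests_per_species),
    target_profile_correlation = target_profile_correlation,
    n_terms_per_level = as.integer(n_terms_per_level),
    n_unique_a = as.integer(n_unique_a),
    n_unique_b = as.integer(n_unique_b),
    profile_namespace = profile_namespace,
    profile_level = as.integer(profile_level),
    candidate_plan = candidate_plan), class = "sim_config")
}

random_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE),
        collapse = "")
}

#' Contaminant taxon groups of a marine 454 screening
#'
#' The taxon groups (name, NCBI root taxid) conventionally screened
#' out of marine invertebrate 454 data: bacteria, archaea, a
#' verrucomicrobial symbiont, green algae, fungi, stramenopiles,
#' glaucophytes and amoebae.
#'
#' @return data frame with columns `name`, `root_taxid` in reporting
#'   order.
#' @export
default_taxon_groups <- function() {
  data.frame(
    name = c("Bacteria", "Archaea", "Verrucomicrobium spinosum",
             "Chlorophyta", "Fungi", "Stramenopiles",
             "Glaucocystophyceae", "Amoebozoa"),
    root_taxid = c(2L, 2157L, 2736L, 3041L, 4751L, 33634L, 38254L,
                   554915L),
    stringsAsFactors = FALSE)
}

#' Minimal bundled taxonomy (synthetic subset)
#'
#' A down-sampled child-to-parent taxonomy covering the default
#' contaminant group roots, one or two leaf taxids under each, and a
#' decapod host lineage that belongs to no contaminant group. Real
#' NCBI taxids are used where convenient, but the table is a synthetic
#' stand-in for a full nodes.dmp, sufficient for lineage walks in
#' tests and fixtures.
#'
#' @return data frame with integer columns `child`, `parent`.
#' @export
default_taxonomy <- function() {
  edges <- rbind(
    c(1L, 1L),            # root
    c(131567L, 1L),       # cellular organisms
    c(2L, 131567L),       # Bacteria
    c(2157L, 131567L),    # Archaea
    c(2759L, 131567L),    # Eukaryota
    c(562L, 2L),          # bacterial leaf
    c(2287L, 2157L),      # archaeal leaf
    c(74201L, 2L),        # Verrucomicrobia (nested under Bacteria)
    c(2735L, 74201L),     # Verrucomicrobium
    c(2736L, 2735L),      # V. spinosum
    c(33090L, 2759L),     # Viridiplantae
    c(3041L, 33090L),     # Chlorophyta
    c(3052L, 3041L),      # chlorophyte genus
    c(3055L, 3052L),      # chlorophyte leaf
    c(33154L, 2759L),     # Opisthokonta
    c(4751L, 33154L),     # Fungi
    c(4890L, 4751L),      # Ascomycota
    c(4932L, 4890L),      # fungal leaf
    c(33634L, 2759L),     # Stramenopiles
    c(2836L, 33634L),     # stramenopile leaf
    c(38254L, 2759L),     # Glaucocystophyceae
    c(2762L, 38254L),     # glaucophyte leaf
    c(554915L, 2759L),    # Amoebozoa
    c(44689L, 554915L),   # amoebozoan leaf
    c(33208L, 33154L),    # Metazoa
    c(6656L, 33208L),     # Arthropoda
    c(6657L, 6656L),      # Crustacea
    c(6683L, 6657L),      # Decapoda
    c(215396L, 6683L))    # hermit crab host leaf
  data.frame(child = edges[, 1L], parent = edges[, 2L])
}

## leaf taxids used when planting contaminant hits, keyed by group
contaminant_leaves <- function() {
  list("Bacteria" = 562L, "Archaea" = 2287L,
       "Verrucomicrobium spinosum" = 2736L, "Chlorophyta" = 3055L,
       "Fungi" = 4932L, "Stramenopiles" = 2836L,
       "Glaucocystophyceae" = 2762L, "Amoebozoa" = 44689L)
}

#' Generate a synthetic read set with planted linkers and contaminants
#'
#' Reads are random DNA of uniform length within
#' `read_length_range`. A configured fraction carries k-1 internal
#' copies of the linker (so the sanitizer should split them into k
#' parts); every planted fragment is at least 60 nt, above the
#' default `min_fragment_length`. An independent configured fraction
#' is planted as contaminants: such reads receive homology hits (with
#' e-values far below the screening cutoff) to leaf taxids inside
#' their group's lineage, while a tenth of the clean reads receive
#' decoy hits - either above the cutoff or to the host lineage - that
#' a correct screen must ignore. Contaminant reads carry no linkers,
#' keeping the two ground truths independent.
#'
#' @param config a [sim_config()].
#' @return list with `reads` (id, sequence), `hits` (a taxonomic hit
#'   table), `groups` (a [taxon_group_set()]), `taxonomy`, and `truth`
#'   (per read: `id`, `taxon_group` (`"none"` for clean reads),
#'   `n_parts` planted).
#' @export
gen_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 11L)
  n <- config$n_reads
  groups_df <- default_taxon_groups()
  groups_df <- groups_df[groups_df$name %in%
                           names(config$contaminant_fractions), ,
                         drop = FALSE]
  missing_grp <- setdiff(names(config$contaminant_fractions),
                         groups_df$name)
  if (length(missing_grp))
    stop("no taxids known for contaminant group(s): ",
         paste(missing_grp, collapse = ", "))
  gset <- taxon_group_set(default_taxon_groups(), default_taxonomy())

  frac <- config$contaminant_fractions
  grp_lab <- if (n) sample(c(names(frac), "none"), n, replace = TRUE,
                           prob = c(frac, 1 - sum(frac)))
  else character(0)

  probs <- config$linker_insertion_probs
  ks <- as.integer(names(probs))
  n_parts <- rep(1L, n)
  clean <- which(grp_lab == "none")
  if (length(clean) && length(ks))
    n_parts[clean] <- sample(c(ks, 1L), length(clean), replace = TRUE,
                             prob = c(probs, 1 - sum(probs)))

  lo <- config$read_length_range[[1L]]
  hi <- config$read_length_range[[2L]]
  frag_lo <- max(60L, lo)
  frag_hi <- max(frag_lo, hi)
  seqs <- character(n)
  for (i in seq_len(n)) {
    k <- n_parts[[i]]
    if (k == 1L) {
      seqs[[i]] <- random_dna(sample(lo:hi, 1L))
    } else {
      frags <- vapply(seq_len(k), function(j)
        random_dna(sample(frag_lo:frag_hi, 1L)), "")
      seqs[[i]] <- paste(frags, collapse = config$linker_sequence)
    }
  }
  ids <- sprintf("read%06d", seq_len(n))

  leaves <- contaminant_leaves()
  hit_rows <- list()
  contam <- which(grp_lab != "none")
  for (i in contam) {
    nh <- sample(1:2, 1L)
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      query_id = rep(ids[[i]], nh),
      subject_taxid = rep(leaves[[grp_lab[[i]]]], nh),
      e_value = 10^runif(nh, -40, -21),
      bitscore = runif(nh, 80, 300),
      stringsAsFactors = FALSE)
  }
  decoys <- clean[rbinom(length(clean), 1L, 0.1) == 1L]
  for (i in decoys) {
    to_host <- runif(1) < 0.5
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      query_id = ids[[i]],
      subject_taxid = if (to_host) 215396L
      else leaves[[sample(names(leaves), 1L)]],
      e_value = if (to_host) 10^runif(1, -40, -21)
      else 10^runif(1, -19, -3),
      bitscore = runif(1, 40, 120),
      stringsAsFactors = FALSE)
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows)
  else data.frame(query_id = character(0),
                  subject_taxid = integer(0),
                  e_value = numeric(0), bitscore = numeric(0))
  list(reads = data.frame(id = ids, sequence = seqs,
                          stringsAsFactors = FALSE),
       hits = hits, groups = gset, taxonomy = default_taxonomy(),
       truth = data.frame(id = ids, taxon_group = grp_lab,
                          n_parts = n_parts,
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic contig set with known length and coverage
#'
#' Contig lengths and average coverages are drawn log-normally
#' (lengths floored at 100 nt), emulating the long right tail of a
#' hybrid 454/Illumina de novo assembly. Both drawn values are the
#' ground truth.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `id`, `length`, `avg_coverage`.
#' @export
gen_contigs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 17L)
  n <- config$n_contigs
  len <- pmax(100L, as.integer(round(stats::rlnorm(
    n, config$contig_length_meanlog, config$contig_length_sdlog))))
  cov <- stats::rlnorm(n, config$coverage_meanlog,
                       config$coverage_sdlog)
  data.frame(id = sprintf("contig%05d", seq_len(n)),
             length = len, avg_coverage = cov,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic GO DAG
#'
#' Builds a layered ontology for one namespace: a root (level 1) and
#' `n_terms_per_level` terms per level below it. Each term has one
#' parent in the layer directly above; with probability
#' `p_extra_parent` it gains an extra parent, drawn from the directly
#' preceding layer (`extra_parents = "previous"`, keeping every term's
#' min-path level equal to its layer) or from any earlier layer
#' (`extra_parents = "any"`, producing the level heterogeneity useful
#' for oracle tests).
#'
#' @param n_levels number of levels including the root.
#' @param n_terms_per_level terms per level below the root.
#' @param namespace namespace string.
#' @param seed integer seed.
#' @param p_extra_parent probability of a second parent.
#' @param extra_parents `"previous"` or `"any"`.
#' @param id_offset numeric offset for the synthetic GO accessions,
#'   letting several generated DAGs coexist.
#' @return a `go_dag` object.
#' @export
gen_go_dag <- function(n_levels = 3L, n_terms_per_level = 30L,
                       namespace = "biological_process", seed = 1L,
                       p_extra_parent = 0.2,
                       extra_parents = c("previous", "any"),
                       id_offset = 0L) {
  extra_parents <- match.arg(extra_parents)
  stopifnot(n_levels >= 2L, n_terms_per_level >= 1L)
  set.seed(seed + 29L)
  mk_id <- function(i) sprintf("GO:%07d", 9000000L + id_offset + i)
  root <- mk_id(0L)
  ids <- root
  nms <- namespace
  parents <- list()
  parents[[root]] <- character(0)
  layers <- list(root)
  counter <- 0L
  for (l in 2:n_levels) {
    layer <- character(n_terms_per_level)
    for (j in seq_len(n_terms_per_level)) {
      counter <- counter + 1L
      id <- mk_id(counter)
      layer[[j]] <- id
      pa <- sample(layers[[l - 1L]], 1L)
      if (l > 2L && runif(1) < p_extra_parent) {
        pool <- if (extra_parents == "previous") layers[[l - 1L]]
        else unlist(layers[2:(l - 1L)], use.names = FALSE)
        extra <- sample(setdiff(pool, pa), 1L)
        pa <- c(pa, extra)
      }
      parents[[id]] <- pa
      ids <- c(ids, id)
      nms <- c(nms, sprintf("%s term L%d.%d", namespace, l, j))
    }
    layers[[l]] <- layer
  }
  terms <- data.frame(go_id = ids, name = nms,
                      namespace = namespace,
                      obsolete = FALSE, stringsAsFactors = FALSE)
  new_go_dag(terms, parents)
}

#' Generate two species' annotation tables with a target profile
#' correlation
#'
#' Species A's latent term weights at the profiled level are drawn
#' exponentially. Species B's weights are a mixture of A's weights
#' and independent noise: the noise is orthogonalised against A's
#' realised weight vector and combined so that the latent weight
#' vectors correlate exactly at the target; multinomial sampling of
#' the actual assignments then adds realistic dispersion, so the
#' measured profile correlation is centred on (slightly attenuated
#' from) the target. Terms can be planted as unique to one species
#' via `n_unique_a` / `n_unique_b`; every term with positive weight
#' receives one guaranteed assignment so planted presence is exact,
#' with the remaining assignments multinomial.
#'
#' @param dag a `go_dag` with at least `n_terms_per_level` terms at
#'   the profiled level (e.g. from [gen_go_dag()]).
#' @param config a [sim_config()].
#' @return list with `table_a`, `table_b` (annotation tables:
#'   `est_id`, `go_id`, `source`), and `truth` (per species and term:
#'   latent `weight` and realised `count`).
#' @export
gen_annotation_tables <- function(dag, config) {
  stopifnot(inherits(config, "sim_config"), inherits(dag, "go_dag"))
  set.seed(config$seed + 23L)
  ns <- config$profile_namespace
  lvl <- config$profile_level
  r <- config$target_profile_correlation

  ids <- names(dag$level)[dag$level == lvl]
  ids <- ids[dag$terms$namespace[match(ids, dag$terms$go_id)] == ns]
  if (length(ids) < config$n_terms_per_level)
    stop("DAG has only ", length(ids), " terms at level ", lvl,
         " in ", ns, "; need ", config$n_terms_per_level)
  terms <- sort(ids)[seq_len(config$n_terms_per_level)]
  n_t <- length(terms)
  nu_a <- config$n_unique_a
  nu_b <- config$n_unique_b
  if (nu_a + nu_b >= n_t - 2L)
    stop("too many unique terms; fewer than 3 shared terms remain")
  uniq_a <- if (nu_a) terms[seq_len(nu_a)] else character(0)
  uniq_b <- if (nu_b) terms[nu_a + seq_len(nu_b)] else character(0)
  shared <- setdiff(terms, c(uniq_a, uniq_b))
  n_s <- length(shared)
  if (abs(r) < 1 && n_s < 3L)
    stop("target correlation unreachable with fewer than 3 shared terms")

  w_a_shared <- rexp(n_s)
  if (r == 1) {
    w_b_shared <- w_a_shared
  } else {
    z <- rexp(n_s)
    ac <- w_a_shared - mean(w_a_shared)
    zc <- z - mean(z)
    zp <- zc - sum(ac * zc) / sum(ac^2) * ac
    if (sqrt(sum(zp^2)) < 1e-12)
      stop("degenerate noise draw; target correlation unreachable")
    b <- r * ac / sqrt(sum(ac^2)) +
      sqrt(1 - r^2) * zp / sqrt(sum(zp^2))
    ## affine shift to positive weights preserves the correlation
    w_b_shared <- b - min(b) + 0.05 * (max(b) - min(b) + 1e-9)
  }
  w_a <- setNames(numeric(n_t), terms)
  w_b <- setNames(numeric(n_t), terms)
  w_a[shared] <- w_a_shared
  w_b[shared] <- w_b_shared
  if (nu_a) w_a[uniq_a] <- rexp(nu_a) * mean(w_a_shared) * 0.2
  if (nu_b) w_b[uniq_b] <- rexp(nu_b) * mean(w_b_shared) * 0.2

  sample_counts <- function(w) {
    present <- which(w > 0)
    n_rest <- config$n_ests_per_species - length(present)
    stopifnot(n_rest >= 0)
    cnt <- setNames(integer(n_t), terms)
    cnt[present] <- 1L
    cnt <- cnt + as.integer(rmultinom(1L, n_rest, w / sum(w)))
    cnt
  }
  make_table <- function(cnt, prefix) {
    n_recs <- sum(cnt)
    data.frame(
      est_id = sprintf("%s_est%06d", prefix, seq_len(n_recs)),
      go_id = rep(names(cnt), cnt),
      source = "synthetic", stringsAsFactors = FALSE)
  }
  cnt_a <- sample_counts(w_a)
  cnt_b <- sample_counts(w_b)
  truth <- rbind(
    data.frame(species = "A", go_id = terms, weight = unname(w_a),
               count = unname(cnt_a), stringsAsFactors = FALSE),
    data.frame(species = "B", go_id = terms, weight = unname(w_b),
               count = unname(cnt_b), stringsAsFactors = FALSE))
  list(table_a = make_table(cnt_a, "spA"),
       table_b = make_table(cnt_b, "spB"),
       truth = truth)
}

#' Default planted candidate plan
#'
#' A mixed plan exercising every branch of the gene-family screen:
#' ionotropic receptor (IR) candidates with 0-3 planted transmembrane
#' domains, planted in-frame stops and ambiguity characters, hits on
#' both sides of both method cutoffs, conserved coreceptor homologs
#' (IR25a, IR93a), an absent family (OR), and immune gene-family
#' candidates for category tabulation.
#'
#' @return data frame with columns `family`, `method`, `n_tm`,
#'   `has_internal_stop`, `has_ambiguity`, `above_cutoff`, `homolog`.
#' @export
default_candidate_plan <- function() {
  plan <- function(family, method = "homology", n_tm = 0L,
                   stop = FALSE, amb = FALSE, above = FALSE,
                   homolog = NA_character_)
    data.frame(family = family, method = method, n_tm = n_tm,
               has_internal_stop = stop, has_ambiguity = amb,
               above_cutoff = above, homolog = homolog,
               stringsAsFactors = FALSE)
  rbind(
    plan("IR", n_tm = 3L, homolog = "IR25a"),
    plan("IR", n_tm = 2L, homolog = "IR93a"),
    plan("IR", n_tm = 3L),
    plan("IR", n_tm = 2L),
    plan("IR", n_tm = 2L, stop = TRUE),
    plan("IR", n_tm = 2L, amb = TRUE),
    plan("IR", n_tm = 1L),
    plan("IR", n_tm = 0L),
    plan("IR", above = TRUE),
    plan("IR", method = "hmm", n_tm = 2L),
    plan("IR", method = "hmm", above = TRUE),
    plan("OR", above = TRUE),
    plan("C-type Lectin"), plan("C-type Lectin"),
    plan("Crustin"),
    plan("Serine protease inhibitor"))
}

#' Default homolog naming map for conserved IR coreceptors
#'
#' @return named character vector mapping reference ids to canonical
#'   receptor names.
#' @export
default_homolog_map <- function() {
  c(RefIR25a = "IR25a", RefIR93a = "IR93a")
}

## 61 sense codons (standard code): everything but TAA, TAG, TGA
sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

#' Generate planted gene-family candidate sequences and hit tables
#'
#' Each plan entry yields one contig built from sense codons (no
#' accidental in-frame stops), a hit whose e-value lies on the side of
#' the method cutoff requested by the plan, transmembrane-domain
#' interval annotations with the planned number of domains inside the
#' hit span, and optionally a planted in-frame stop codon or an
#' ambiguity base inside the span. Below-cutoff entries also get a
#' second, strictly worse hit so best-hit selection is exercised.
#'
#' @param config a [sim_config()] (its `candidate_plan` is used).
#' @param cutoffs named e-value cutoffs per method.
#' @return list with `sequences` (contig table with coverage), `hits`
#'   (a [collect_candidates()]-ready hit table), `tm` (interval
#'   table), `homolog_map`, and `truth` (planted flags per contig,
#'   including `is_candidate` and `dendrogram_ready`).
#' @export
gen_candidates <- function(config,
                           cutoffs = c(homology = 1e-1, hmm = 1e-3)) {
  stopifnot(inherits(config, "sim_config"))
  plan <- config$candidate_plan
  stopifnot(nrow(plan) >= 1L)
  set.seed(config$seed + 37L)
  codons <- sense_codons()
  n <- nrow(plan)
  span_start <- 151L; span_end <- 750L   # frame 1, 200 codons
  tm_inside <- list(c(181L, 240L), c(361L, 420L), c(541L, 600L))
  tm_outside <- list(c(1L, 60L), c(61L, 120L), c(781L, 840L))

  seq_rows <- vector("list", n)
  hit_rows <- list()
  tm_rows <- list()
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- plan[i, ]
    id <- sprintf("cand%03d", i)
    s <- paste(sample(codons, 300L, replace = TRUE), collapse = "")
    if (p$has_internal_stop)
      substr(s, 451L, 453L) <- "TAA"
    if (p$has_ambiguity)
      substr(s, 500L, 500L) <- "N"
    cutoff <- cutoffs[[p$method]]
    ev <- if (p$above_cutoff) cutoff * 10^runif(1, 0.7, 3)
    else cutoff * 10^-runif(1, 1, 8)
    ref <- if (!is.na(p$homolog)) paste0("Ref", p$homolog)
    else sprintf("Ref%s_%02d", gsub(" ", "_", p$family), i)
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      query_id = id, family = p$family, reference_id = ref,
      method = p$method, e_value = ev, frame = 1L,
      span_start = span_start, span_end = span_end,
      stringsAsFactors = FALSE)
    if (!p$above_cutoff)
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        query_id = id, family = p$family,
        reference_id = paste0(ref, "_alt"),
        method = p$method, e_value = min(ev * 100, cutoff),
        frame = 1L, span_start = 301L, span_end = 540L,
        stringsAsFactors = FALSE)
    k <- p$n_tm
    iv <- c(tm_inside[seq_len(k)],
            if (k < 3L) tm_outside[seq_len(3L - k)])
    iv <- iv[order(vapply(iv, `[`, 0L, 1L))]
    for (v in iv)
      tm_rows[[length(tm_rows) + 1L]] <- data.frame(
        contig_id = id, tm_start = v[[1L]], tm_end = v[[2L]])
    seq_rows[[i]] <- data.frame(
      id = id, sequence = s, length = nchar(s),
      avg_coverage = round(runif(1, 6, 40), 1),
      stringsAsFactors = FALSE)
    truth_rows[[i]] <- data.frame(
      contig_id = id, family = p$family, method = p$method,
      is_candidate = !p$above_cutoff, n_tm = p$n_tm,
      has_internal_stop = p$has_internal_stop,
      has_ambiguity = p$has_ambiguity,
      dendrogram_ready = !p$above_cutoff & p$n_tm >= 2L &
        !p$has_internal_stop & !p$has_ambiguity,
      stringsAsFactors = FALSE)
  }
  list(sequences = do.call(rbind, seq_rows),
       hits = do.call(rbind, hit_rows),
       tm = do.call(rbind, tm_rows),
       homolog_map = default_homolog_map(),
       truth = do.call(rbind, truth_rows))
}
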