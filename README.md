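# antcomp

Comparative analysis of de novo antennal transcriptomes in R.

When the olfactory organs of two non-model arthropods — say a
terrestrial and a marine hermit crab — are sequenced with mixed
454/Illumina chemistry and assembled de novo, the question "how
similar are these two transcriptomes?" has to be answered without a
reference genome. The established route is: sanitize the raw reads,
summarize the assembly, annotate contigs with Gene Ontology (GO)
terms, and compare the two species' term profiles level by level,
before screening directly for the gene families of interest
(chemoreceptors, immune effectors). `antcomp` implements that route
as reusable, tested components, together with a synthetic-data
generator that produces every input with known ground truth.

## What it computes

**Read sanitization.** 454 library construction can concatenate two
inserts around a linker; `split_reads_on_linker()` excises every
linker occurrence (Hamming mismatches allowed) and reports how many
reads split into k parts. `screen_contaminants()` removes reads whose
homology hits fall below a strict e-value cutoff (default E < 1e-20)
inside configured contaminant lineages (bacteria, fungi, algae, ...),
walking a child-to-parent taxonomy from each hit's subject taxid.

**Assembly statistics.** `summarize_assembly()` computes contig
counts, mean length, a length histogram, and the N50 — the length L
such that contigs of length ≥ L, taken longest-first, cover at least
half the assembly. `filter_by_coverage()` applies the usual "ignore
contigs under 5-fold average coverage" rule that defines the final
annotation dataset.

**Level-wise GO profiling.** `load_obo()` parses the ontology;
levels are assigned as 1 + the shortest `is_a` path from the
namespace root (root = level 1; longest-path mode available).
Annotations propagate to all ancestors (true-path rule), and
`term_profile()` converts per-term EST counts at one level into
percentages:

    percent(t) = 100 * n(t) / sum over terms s at the level of n(s)

so each profile sums to 100%. Manual curation is supported through
additive count overrides.

**Cross-species comparison.** `compare_profiles()` bundles the
Pearson correlation of the paired percentage vectors (absent terms
as 0%), the shared/unique term partition, and per-term absolute
percentage differences binned as `<0.5%`, `0.5–1%`, `>1%`.

**Gene-family screen.** `collect_candidates()` applies per-method
e-value cutoffs (homology ≤ 1e-1, HMM ≤ 1e-3) to a search-hit table;
`apply_ir_quality_filter()` marks ionotropic-receptor candidates
dendrogram-ready iff their hit span fully contains at least two of
three annotated transmembrane domains with no internal in-frame stop
and no ambiguity base; `name_candidates()` assigns species-prefixed
names (conserved homologs like IR25a keep their name, the rest get
ascending numerals); `tabulate_categories()` produces the immune
category table.

`run_pipeline()` chains all stages, writing TSV artifacts, a JSON
summary, a parameter log and an md5 manifest; runs with the same seed
are byte-identical. A thin command-line dispatcher with
subcommands (`simulate`, `sanitize`, `stats`, `profile`, `compare`,
`screen`, `run-all`) is installed at `inst/scripts/pipeline.R`.

## Worked example

```r
library(antcomp)

cfg  <- sim_config(seed = 42, target_profile_correlation = 0.99)
dag  <- gen_go_dag(n_terms_per_level = 30, seed = 42)
tabs <- gen_annotation_tables(dag, cfg)

ccly <- term_profile(tabs$table_a, dag, "biological_process", 3, species = "Ccly")
pber <- term_profile(tabs$table_b, dag, "biological_process", 3, species = "Pber")
compare_profiles(ccly, pber)
#> Profile comparison: biological_process level 3 (Ccly vs Pber)
#>   Pearson r: 0.980
#>   terms: 30 shared, 0 unique to Ccly, 0 unique to Pber
#>   |difference| bins: <0.5%: 17, 0.5-1%: 8, >1%: 5
```

The measured r (0.980) sits just below the generation target (0.99):
the two profiles are built from latent term weights correlating at
exactly 0.99, and multinomial sampling of the 10,000 assignments per
species attenuates the realised correlation slightly — the same
dispersion real replicate profiles show. Sanitization on the same
synthetic read set:

```r
g   <- gen_reads(cfg)
res <- split_reads_on_linker(g$reads, linker_spec(cfg$linker_sequence))
res$stats
#> Linker split: 2000 reads in, 2147 reads out, 1857 unsplit
#>   split into 2 parts: 139
#>   split into 3 parts: 4
scr <- screen_contaminants(unique(sub("/p[0-9]+$", "", res$reads$id)),
                           g$hits, g$groups)
scr$report
#> Contaminant screen (E < 1e-20 ):
#>   Bacteria                 14
#>   ...
#>   Fungi                    98
#>   ...
#>   Remaining reads          1779 of 2000
```

Both the split histogram and the per-group removal counts equal the
generator's planted truth exactly (that equality is what the test
suite asserts).

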