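---
title: "Methods: comparative GO profiling of two antennal transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative GO profiling of two antennal transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antcomp)
```

# The analysis problem

Two de novo assembled transcriptomes of homologous olfactory tissue
— one per species, no reference genome — are to be compared at the
abstraction level of Gene Ontology annotation, and screened for
specific gene families. `antcomp` implements the five stages of that
comparison (sanitize, summarize, profile, compare, screen) and a
synthetic-data generator that emulates every input with known ground
truth, so each stage is testable without the original sequencing
archives or external search tools. External computations (assembly,
BLAST/HMM searches, TM-domain prediction) are consumed as tabular
inputs, never re-run.

# Read sanitization

**Linker splitting.** 454 libraries concatenate two cDNA inserts
around a fixed linker; a read containing k−1 internal linker copies
represents k independent inserts. Matching is a Hamming scan: every
non-overlapping occurrence of the linker within `max_mismatches`
substitutions (default 2, on a 44 nt linker), taken left to right,
is excised. No indel alignment is attempted — for a fixed-length
linker at 454 error rates substitutions dominate, and a Hamming scan
is deterministic and cheap (`Biostrings::vmatchPattern` underneath).
Fragments shorter than `min_fragment_length` (default 50 nt, below
which a 454-era fragment contributes nothing to assembly) are
dropped and not counted as parts; a read whose excision leaves a
single retained fragment counts as unsplit. Splitting is idempotent:
fragments contain no complete linker.

**Contaminant screening.** A read is removed iff it has at least one
homology hit with e-value strictly below the cutoff (default 1e-20;
the strictness of the inequality follows the conventional "E <
cutoff" reading) whose subject taxid's lineage — a child-to-parent
walk through the supplied taxonomy — meets one of the configured
group roots. Removal is attributed to the group of the best
qualifying hit: lowest e-value, then highest bit score, then first
group in configured order. Two further conventions matter:

* *Nested groups.* Screening panels can nest (a verrucomicrobial
  symbiont inside Bacteria). A hit is attributed to the most
  specific group root on its lineage walk, so nested rows are
  counted separately rather than absorbed by the outer group.
* *Order of operations.* Whether splitting precedes screening is not
  dictated by the method; the pipeline default is split-then-screen
  (fragments inherit the parent read's hits), and the reverse order
  is a configuration switch.

Hits whose taxid is absent from the taxonomy are ignored with a
warning rather than failing the run, since public hit tables
routinely contain retired taxids.

# Assembly statistics

N50 is the length of the contig at which the cumulative sum over
contigs sorted by decreasing length first reaches half the total
assembly length — the common convention, asserted against a
brute-force oracle in the tests. The mean length is reported both
raw and rounded to the nearest nt, and is computed before and after
coverage filtering, since summary figures in the field are sometimes
quoted either way. The coverage filter implements "contigs with an
average coverage of less than 5 are ignored" literally: a contig at
exactly 5.0 is retained. The length histogram uses right-open 100 nt
bins by default; the bin width only affects display, not statistics.

# Level-wise GO profiling

**Levels.** GO is a DAG, so "level" is ambiguous. The default is
1 + the minimum `is_a` path length to the namespace root (root =
level 1) — the convention of the common annotation-chart tools —
with the maximum-path alternative available (`level_mode = "max"`).
Only `is_a` edges define levels and propagation; `part_of` edges can
be opted in. Obsolete terms are dropped, alternative ids resolve to
their primary term, cyclic graphs are a hard error, and non-root
terms that cannot reach a root are excluded with a warning.

**Propagation.** The true-path rule: an annotation to a term is an
annotation to all its ancestors, with set semantics (an EST counts
at most once per term however many descendants it was annotated to).

**Percentages.** For the set of terms at one (namespace, level),

$$\mathrm{pct}(t) = \frac{100 \cdot n(t)}{\sum_{s \in \mathrm{level}} n(s)}$$

where n(t) is the propagated EST count. The denominator is the *sum
of assignments* at the level, so an EST reaching m terms contributes
m times and the percentages sum to exactly 100 — which is what makes
multi-term bar charts comparable across species. The alternative
reading ("number of distinct ESTs at the level") is available as
`denominator = "distinct"`; its percentages can exceed 100 in sum.
Manual curation of automatic annotation is modelled as additive-only
overrides: each adds a non-negative EST count to a term (creating
the row if absent) and grows the denominator accordingly.

# Cross-species comparison

The Pearson coefficient is computed over the paired percentage
vectors indexed by the *union* of the two term sets, absent terms
contributing 0%. A correlation needs a common index, and
zero-imputation is the choice that penalises presence/absence
differences; intersection-only mode exists for sensitivity checks.
Zero variance in either vector is an explicit error, not an NA.
Because each profile's percentages are its counts rescaled by one
scalar, the correlation is identical on counts and percentages when
computed over the same index — a property the tests exploit.

Term overlap calls a term present iff its count is positive after
overrides. Percentage differences d = |pct_a − pct_b| are binned
with edges (0.5, 1.0): the published labels "<0.5%", "0.5–1%",
">1%" leave the edges ambiguous, so the convention here is
[0, 0.5), [0.5, 1.0], (1.0, ∞) — both edges in the middle bin —
applied to unrounded differences.

# Gene-family screen

Candidate collection is inclusive at the cutoff (e ≤ 1e-1 for
homology search, e ≤ 1e-3 for HMM-profile search), one candidate per
(contig, family), best hit by lowest e-value then longest span.
The ionotropic-receptor quality filter marks a candidate
dendrogram-ready iff (i) its hit span fully contains at least two of
the three annotated TM domains — partial overlap does not count, and
a missing TM annotation yields zero spanned domains but keeps the
candidate in the report; (ii) no stop codon lies strictly inside the
best hit's reading frame within the span (the terminal codon is
exempt); (iii) no non-ACGT base occurs in the span. TM intervals are
an input annotation in contig nucleotide coordinates; predicting
them is an external-tool concern. Naming is deterministic:
configured homolog references (IR25a, IR93a) keep their names behind
the species prefix, the rest are numbered by ascending best-hit
e-value then contig id. Families screened but never passing appear
as zero-candidate families rather than as a special "absent" result.
The immune category table counts distinct contigs per (category,
gene, species) in configured row order, with unmapped gene labels
collected under "uncategorized".

# The synthetic-data generator

The generator is the package's test bed and defines the conditions
under which correctness is demonstrated:

* **Reads** are uniform-length random DNA (default 100–400 nt, 2,000
  reads). Linker-insertion probabilities default to the proportions
  observed in a terrestrial hermit-crab 454 dataset (6.8% two-part,
  0.12% three-part, 1e-5 four-part); contaminant fractions default
  to the per-group proportions of a marine hermit-crab screening
  (fungi ≈ 5%, glaucophytes ≈ 3.5%, six smaller groups). Planted
  fragments are ≥ 60 nt so the split histogram equals the plant
  exactly under the default 50 nt floor. Contaminant reads carry
  pre-made hit tables (the screen consumes hit tables, so fixtures
  live at that interface) with e-values well below the cutoff, and a
  tenth of clean reads get decoy hits — above-cutoff or host-lineage
  — that a correct screen must ignore. Contaminant reads carry no
  linkers, keeping the two ground truths independent.
* **Annotation tables** target a profile correlation: species A's
  latent term weights are exponential draws; species B's are a
  mixture of A's weights and independent noise, with the noise
  orthogonalised against the realised A vector so the *latent*
  weight vectors correlate exactly at the target (an affine shift
  keeps them positive without changing the correlation). A scheme
  that only targets the correlation in expectation leaves the
  across-seed standard deviation of a 30-term sample correlation
  near 0.14 at mid-range targets — too coarse to verify ±0.02
  recovery over 20 seeds — whereas with the exact-latent
  construction the only dispersion is multinomial sampling of the
  assignments, which both mimics replicate noise and slightly
  attenuates the measured r (≈ 0.005 at r* = 0.99 with 10,000
  assignments over 30 terms). Negative targets are supported;
  fewer than 3 shared terms is an error (unreachable target). Every
  positive-weight term receives one guaranteed assignment so planted
  presence/absence structure (`n_unique_a`, `n_unique_b`) is exact.
* **Contigs** draw lengths and coverages log-normally (medians 400
  nt and 6-fold, floored at 100 nt), giving the long right tail of a
  hybrid assembly.
* **Candidates** are built from sense codons only, so stops and
  ambiguities exist exactly where planted; hits are drawn on the
  side of each method cutoff the plan requests, and below-cutoff
  entries get a second, strictly worse hit to exercise best-hit
  selection.

What the generator does *not* emulate: sequencing error models,
quality scores, assembly graphs, homology-search score
distributions, or annotation bias between ontology branches.
Passing tests therefore demonstrate the correctness of the
*computations* on well-formed inputs, not robustness to pathological
real-world annotation artifacts.

# Numerical and testing choices

All randomness flows from integer seeds; every generator is
byte-deterministic under (seed, config). Profile normalisation is
asserted to 1e-9; correlation oracles to 1e-10. Test problem sizes
are chosen to exercise the mathematics while keeping the default
suite fast: oracle equivalence (N50, Pearson, level assignment,
propagation) runs on 100 random instances each; correlation recovery
uses 30 terms, 10,000 assignments per species, 20 seeds per target
(targets 0, 0.5, 0.9, 0.99, mean within ±0.02); sanitization
ground-truth recovery uses 1,500–3,000 reads. The acceptance script
scales the read set to 20,000 and the contig set to 5,000.

# Known limitations

* The OBO reader covers the term fields needed here (id, name,
  namespace, `is_a`, `alt_id`, obsolescence, `part_of`); typedefs,
  intersections and cross-products are ignored.
* Qualities are read but not used; no quality trimming is performed.
* The contaminant screen trusts the supplied taxonomy; it does not
  fetch or merge NCBI dumps.
* Three-way species comparisons are supported only pairwise.
* The immune tabulation counts candidate contigs; it does not
  attempt isoform collapsing.
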