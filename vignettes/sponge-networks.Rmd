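---
title: "Inferring circRNA–miRNA–mRNA sponge networks from consensus circRNA calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring circRNA–miRNA–mRNA sponge networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The analysis problem

Circular RNAs (circRNAs) are covalently closed transcripts produced by
back-splicing. Because they lack free ends they escape exonucleolytic decay,
accumulate to high levels, and — when their sequence carries complementary
sites for a microRNA's seed region — can act as *sponges*: they sequester the
miRNA and thereby derepress the miRNA's mRNA targets (the
competing-endogenous-RNA, or ceRNA, hypothesis). In a case/control bulk
RNA-seq cohort this motivates a chained analysis:

1. call back-spliced junctions (BSJs) with two independent callers and keep
   the junctions both report (consensus calling controls the high
   false-positive rate of single-caller circRNA detection);
2. test consensus circRNAs, and genes, for differential expression (DE)
   between conditions, per tissue;
3. scan the sequences of significantly DE circRNAs for miRNA seed sites,
   treating the sequence as circular so sites can span the BSJ;
4. select miRNAs with broad site support among DE circRNAs, rank them by
   site frequency in *upregulated* circRNAs, and intersect their predicted
   mRNA targets with upregulated DE genes;
5. assemble the tripartite circRNA → miRNA → mRNA network and test the
   affected gene set for gene-set over-representation.

`circsponge` implements this chain as composable tibble-in/tibble-out
functions plus a driver, `run_pipeline()`. Because the patient data this
kind of study uses are access-restricted, the package ships a
synthetic-study generator (`generate_study()`) whose outputs carry a planted
ground-truth manifest; every stage of the pipeline can therefore be verified
by recovery, not just smoke-tested.

## Consensus circRNA calling

The two supported caller dialects differ only in coordinate bookkeeping: the
CIRI2-style table uses 1-based inclusive coordinates and carries a
`chr:start|end` ID; the CIRCexplorer2-style table is BED-derived, 0-based
half-open. Both are converted to the canonical 1-based inclusive key
`chrom:start|end` on read.

Three decisions here were genuinely open and are fixed as follows:

* **Strand is excluded from junction identity.** Callers disagree on strand
  for a fraction of events, the canonical ID format omits it, and excluding
  it maximises inter-caller agreement. Strand is retained on records for
  reporting.
* **Only the CIRCexplorer2-style caller's records are support-filtered**
  (`filter_bsj_support()`, default ≥ 2 junction-spanning reads); the other
  caller's list is taken as published. This mirrors how the two callers'
  outputs are typically post-processed.
* **Intersection is on the pooled candidate lists**, not per sample: a
  junction is consensus if each caller reports it in at least one sample.
  Per-sample intersection would conflate detection sensitivity with
  junction identity; the pooled reading is the permissive one consistent
  with the large detection counts such studies report. Consensus *counts*
  are then per-sample arithmetic means of the two callers' junction reads,
  kept fractional, with a junction absent from one caller in a given sample
  contributing 0 — membership is decided at the junction level, so a
  missing per-sample observation is evidence of zero support, not missing
  data.

"Detected in a condition" (for the detection summary) means present, after
all filters, in at least one sample of that condition.

## Differential expression

The DE machinery is deliberately self-contained and matches the standard
log-CPM / empirical-Bayes pipeline:

* **Filtering**: a feature is kept iff its CPM is at least `min_cpm`
  (default 10) in at least `min_samples` samples (default 9; an `"auto"`
  rule `ceiling(0.7 × smallest tissue size)` is available — the fixed
  default is primary because the 70% rule and a fixed "nine samples" are
  not mutually consistent for every cohort layout).
* **TMM normalization** (`tmm_factors()`): the reference sample is the one
  whose 75th-percentile CPM is closest to the mean of those percentiles;
  per sample, log-ratios M and average log-abundances A are computed over
  features nonzero in both sample and reference, doubly trimmed (30% on M,
  5% on A, two-sided), and averaged with inverse asymptotic-variance
  weights `1/v`, `v = (N−x)/(Nx)` summed over sample and reference. Factors
  are rescaled to geometric mean exactly 1. The implementation is checked
  in the test suite against an independent step-by-step recomputation and
  against `edgeR::calcNormFactors`.
* **log-CPM**: `log2((x + 0.5) / (lib × factor + 1) × 1e6)`, finite at zero
  counts.
* **Moderated t** (`moderated_de()`): per-feature OLS of log-CPM on the
  condition contrast (control is the reference level), residual variance
  `s²` on `d` df; a scaled-inverse-chi-square prior `(d0, s0²)` is fitted
  by matching the first two moments of `log s²` through digamma/trigamma
  identities (the trigamma equation is solved by a Newton iteration; if it
  has no positive solution the limit `d0 = ∞`, `s0² = mean(s²)` is used);
  the posterior variance `(d0 s0² + d s²)/(d0 + d)` replaces `s²` in the t
  statistic, referred to `d0 + d` df. `prior_df = 0` recovers the ordinary
  equal-variance t exactly. The suite cross-checks t, p and the prior
  against `limma::eBayes`; neither edgeR nor limma is called by package
  code.
* **Multiple testing**: Benjamini–Hochberg step-up (`bh_adjust()`), the
  default of the standard DE toolchain. The choice matters — significant
  counts depend on it — so it is stated here explicitly.
* **Per tissue, never pooled**: DE is computed independently within each
  tissue; cross-tissue claims are made only through the nonredundant union
  of significant IDs.

**Covariate assessment** (`variance_explained()`): per feature, the
fixed-effects model `log-expression ~ RIN + PMI + sex + group` is
decomposed into per-covariate R² fractions by sequential sums of squares
averaged over all covariate orderings (the LMG scheme), which removes the
order dependence of a single sequential ANOVA; fractions plus residual sum
to 1. This is a deliberate simplification of a mixed-model variance
partition on variance-stabilised counts: it preserves the decision rule
(covariates whose median fraction is small — the conventional screen is
< 4.5% — are dropped from the DE design) without the heavy machinery.
Correlated covariates share their joint variance across the correlated
set; exact single-covariate attribution is only expected for orthogonal
designs. RIN and PMI are excluded from the default DE design, matching the
outcome of that screen; they can be passed via `covariates =`.

## Seed-site scanning

A site is an occurrence, on the circRNA scanned 5'→3', of the reverse
complement of the miRNA *seed* (nucleotides 2–7). The canonical site
classes are assigned from two flanking features:

| class    | nt-8 pairing immediately 5' | A immediately 3' |
|----------|-----------------------------|-------------------|
| 8mer     | yes                         | yes               |
| 7mer-m8  | yes                         | no                |
| 7mer-A1  | no                          | yes               |
| 6mer     | no                          | no                |

Each start position is reported once with its best class (an 8mer is never
double-reported as a 7mer/6mer). In circular mode the sequence is closed:
the scan extends across the back-spliced junction and such sites are
flagged `wraps_junction`. Linear-mode sites are always a subset of
circular-mode sites *by start position*; a site flagged as wrapping may
upgrade its class relative to the linear scan when the extra flanking
nucleotide only exists on the circle. Overlapping sites at distinct starts
are all counted (no merging): the fractional per-circRNA site averages
this kind of analysis reports imply raw occurrence counting. All four
classes are counted by default (`site_classes =` restricts this; whether
6mers should count is genuinely ambiguous in the literature, so it is a
parameter, not a hard-coded choice). The scanner is verified against a
brute-force doubled-sequence oracle at every start position.

## miRNA selection, target integration, network

Selection is two-staged (`select_mirnas()`): stage 1 keeps miRNAs with a
nonzero site count in at least `min_circ` (default 10) distinct DE
circRNAs, assessed per tissue (a miRNA qualifies if any tissue reaches the
cutoff); stage 2 ranks survivors by total site count over the union of
per-tissue *upregulated* DE circRNAs, descending, ties broken
lexicographically by miRNA ID for determinism, returning the top `top_k`
(default 12). "Across both tissues" is implemented as the union of
per-tissue upregulated sets; in cohorts where no circRNA is DE in two
tissues this equals concatenation.

`integrate_targets()` intersects the selected miRNAs' predicted targets
with genes significantly *upregulated* (`adj_p < alpha`, `log2fc > 0`) in
at least one tissue. Context-style score filtering is off by default (no
published cutoff exists for this step); `max_context_score =` enables it.
Two stages of the gene list are exposed: the post-intersection affected
set (`run$affected`) and the network's mRNA layer; under the default rules
every affected gene has at least one selected-miRNA edge, so the two
coincide — they can diverge only if score filtering prunes edges after
intersection.

`build_network()` assembles the tripartite graph: circRNA → miRNA edges
where an upregulated DE circRNA carries ≥ 1 site for a selected miRNA,
miRNA → mRNA edges where the gene is affected and a predicted target. Node
size is `log2(degree)`, the display convention for these figures; only
nodes with at least one edge are kept. `write_network()` emits an
edge-list TSV pair or a minimal GraphML-style XML.

**Enrichment** (`hypergeom_enrich()`): upper-tail hypergeometric
over-representation of the affected set against a user-supplied GMT
collection, BH-adjusted across terms (both raw and adjusted p are
reported, since conventions differ). The universe is the set of genes in
the filtered count matrix — standard over-representation practice — not
the whole annotation.

## The synthetic-study generator

`generate_study()` writes every input the pipeline consumes — two caller
tables in their respective dialects, circRNA and miRNA FASTA, circRNA and
gene count matrices, sample metadata, a miRNA→gene target table with
context-style scores, a GMT collection — plus a JSON truth manifest. What
it emulates, and what it does not:

* **Cohort structure.** Three spinal-cord tissues (cervical/thoracic/
  lumbar) with 18/7, 16/6 and 16/6 case/control samples — the sample
  layout of the motivating cohort. RIN is drawn higher in cases than
  controls and PMI lower, mimicking the quality imbalance such autopsy
  cohorts show.
* **Counts** are negative binomial with a single common dispersion
  (default 0.1) around per-feature log-normal baselines (mean log2
  expression 5, SD 1.5): the simplest model under which TMM plus a
  moderated t is well-behaved. DE features receive a ±`lfc_magnitude`
  log2 shift in case samples of their tissue only; DE sets are disjoint
  across tissues (these studies find essentially no cross-tissue overlap)
  and up-biased ~70:30, matching the reported direction imbalance.
  Covariates enter as linear terms on the log2 mean with configurable
  variance fractions and a *random per-feature sign* — a common-sign
  effect would be absorbed into library size and erased by CPM
  normalization, making the variance-partition stage untestable.
* **Planted DE fractions.** `frac_de_circ = 0.15` yields ~15 DE circRNAs
  per tissue at the default `n_circ = 300` — a desk-scale stand-in for
  the tens of DE circRNAs per tissue real cohorts report, and comfortably
  above the `min_circ = 10` selection cutoff so the planted truth does not
  sit on a decision boundary.
* **Caller tables** share exactly `round(caller_overlap × n_circ)`
  junctions; each caller additionally reports its own non-consensus
  junctions. Read counts for the same junction differ between callers by
  independent ±20% multiplicative jitter, exercising the count-averaging
  rule.
* **Sequences.** Background circRNA sequences are made *seed-free* for the
  whole miRNA panel: accidental seed-match windows (junction-aware) are
  eliminated by resampling one nucleotide inside each offending window
  until none remain — rejection sampling at the window level; rejecting
  whole sequences has vanishing acceptance probability at realistic panel
  sizes. The miRNA panel is drawn so that no miRNA's seed match hides
  inside another miRNA's planted motif. Planted sites (8mers by default)
  are written verbatim at recorded positions, one of them spanning the
  junction, and a final scrub pass removes any match created at a
  plant/background boundary. The result: scanning the generated sequences
  recovers the planted manifest with precision = recall = 1, which is what
  makes the end-to-end network-recovery test meaningful.
* **Targets and gene sets.** Planted sponge miRNAs target the planted
  affected genes (a sample of the upregulated DE genes, default 37) plus
  background targets drawn from planted *downregulated* genes — genes
  that cannot be called significantly up, so the affected-set truth is
  exact under any realized false-positive rate among null genes.
  Non-sponge miRNAs target non-upregulated genes. One GMT term is a
  subset of the affected genes; background terms avoid them.

What the generator does **not** emulate: read-level data (no FASTQ or
alignment simulation), per-feature dispersion heterogeneity, GC/length
biases, isoform structure, correlated features, batch effects, or
sequence composition realism in the seed-free backgrounds. Passing the
recovery tests therefore demonstrates that the pipeline's logic is
correct under its own statistical assumptions — not that those
assumptions hold for any particular real dataset.

## Numerical and reporting choices

* Averaged consensus counts stay fractional; downstream log-CPM does not
  require integers.
* `detection_summary()` works on ID sets, so inclusion–exclusion
  identities (`unique = detected − common`) hold exactly by construction.
* Percentages in `summarize_de()` are rounded to the nearest integer,
  half away from zero; "nonredundant" is the union of significant feature
  IDs across tissues.
* Significant features with `log2fc` exactly 0 (possible only in
  degenerate input) count as neither up nor down, with a warning.
* Ties: miRNA ranking and enrichment ordering break ties
  lexicographically by ID, so all outputs are deterministic.
* Degenerate inputs error early with informative messages: empty
  universe, a group with < 2 samples, zero library sizes, overlapping
  planted sites, invalid simulation configs (all offending fields listed).

## Problem sizes and verification scale

The shipped defaults (300 circRNAs per caller, 1 200 genes, 40-miRNA
panel, 69 samples across three tissues) run the complete pipeline in well
under a minute on a single core; the test suite verifies the scanner
against its brute-force oracle on 1 000 random sequence/miRNA pairs,
type-I error on 2 000 null features, and FDR/sensitivity on 20
replicate simulations of 2 000 features at 10 samples per group. These
sizes were chosen so that the statistical checks have enough resolution
to fail if the implementation is wrong, while the whole suite stays
interactive.

## Known limitations

* No thermodynamic or duplex-folding model of miRNA binding; seed
  matching only, with no conservation or context-score computation
  (scores are consumed as input).
* The variance partition is fixed-effects; repeated samples from the same
  donor are not modelled.
* No exact NB tests or quasi-likelihood F tests; inference is the plain
  moderated t on log-CPM, without precision weights.
* The enrichment test ignores gene-set redundancy and GO graph topology.
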