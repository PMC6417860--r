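---
title: "Methods: classifying and characterizing H3K9me3-dependent endo-siRNA targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying and characterizing H3K9me3-dependent endo-siRNA targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical procedures it
implements, the assumptions behind them, and the design choices made where
the methods literature leaves the details open.

## The scientific setting

Nematode germlines produce 22G endogenous small interfering RNAs
(endo-siRNAs) that silence complementary transcripts. A subset of these
endo-siRNAs depends on H3K9 tri-methyltransferases: in a methyltransferase
mutant, the small RNAs targeting particular genes are lost (or, for other
genes, gained). The genes that lose their targeting endo-siRNAs tend to be
*newly evolved* — without orthologs in related species — carry high
H3K9me3 around their transcription start sites, and have modestly lower
densities of periodic A/T clusters (PATC), the sequence signature that
protects germline genes from piRNA silencing. The package provides the
building blocks of that genome-wide characterization: target
classification from count tables, gene-set enrichment against a
permutation null, conservation classification from homology evidence, TSS
metagene chromatin profiles with random-set controls, and rank-sum feature
comparisons — plus a synthetic-data generator that emulates the structure
of such a study so the entire pipeline is testable offline.

## Target classification

Counts are normalized to reads per million (RPM): `RPM(g) = count(g) * 1e6
/ sum(counts)` per sample, so each sample's RPM sums to one million
exactly. With a single biological sample per condition, no variance can be
estimated, and calls are made by a plain fold-change rule:

\[
\mathrm{fold}(g) = \frac{\mathrm{RPM}_{mut}(g) + c}{\mathrm{RPM}_{wt}(g) + c},
\]

with a gene called *down* when fold < 0.5 and *up* when fold > 2 (strict
inequalities, following the rule's wording). Design choices the rule
itself does not fix:

* **Pseudocount** `c = 1` RPM in numerator and denominator. The ratio is
  undefined at zero denominators; 1 RPM is the smallest expressible unit
  at typical library depths (about one read per million), so it perturbs
  well-expressed genes negligibly while regularizing the zeros.
* **Noise floor**: genes with both samples below 1 RPM are excluded from
  classification (their fold is numerically near 1 anyway, but reporting
  them as "unchanged" would overstate what the data can say); the count of
  excluded genes is reported.
* Both thresholds, the pseudocount and the floor are fields of
  `classifier_config()`.

When a replicated design is available, `load_external_de()` ingests the
result table of a proper differential-expression fit (gene, log2 fold
change, adjusted p) and splits significant genes (adjusted p strictly
below 0.1 by default) by fold-change sign; the fit itself is out of this
package's scope.

The single-replicate rule has a substantial false-positive rate whenever
count noise is overdispersed — two independent negative-binomial draws
with dispersion 0.1 around a mean of 50 differ by 2-fold about 9% of the
time on each side. The acceptance script measures and reports this rate
rather than hiding it; interpreting a called set therefore always goes
through the enrichment machinery below, which asks whether a *property* of
the called set exceeds what same-size random sets show.

## Gene-set enrichment and its permutation null

For a target list \(T\), a gene set \(S\) and the annotation universe
\(U\) (all protein-coding genes), the enrichment statistic is

\[
E = \frac{\mathrm{Observed}}{\mathrm{Expected}}
  = \frac{|T \cap S| / |T|}{|S \cap U| / |U|}.
\]

\(S\) is intersected with \(U\) before anything else — set sizes are
whatever survives the intersection of the data sources. Significance comes
from drawing `n` random subsets of \(U\) of size \(|T|\) uniformly without
replacement, computing their enrichment values, and ranking:

* **p-value** `p = (r + 1) / (n + 1)`, where `r` counts random sets whose
  enrichment is at least as extreme as the observed one, *ties included*.
  This is the standard valid permutation p: it can never be zero, its
  floor is `1/(n + 1)` (9.999e-5 at the default `n = 10000`), and under
  the null `P(p <= a) <= a` in a fixed direction.
* **Direction**: one-sided in the observed direction — *enriched* when the
  observed fold exceeds 1, *depleted* otherwise — with the direction
  reported alongside. Enrichments and depletions are distinct findings
  (e.g. a depletion of licensing-pathway targets means something different
  from an enrichment of silencing-pathway targets), so a two-sided p would
  obscure the result. Because the direction is chosen by the data, the
  *combined* null rejection rate at level \(a\) can exceed \(a\) (it is at
  most \(2a\), and much less for the discrete overlap distributions of
  realistic set sizes); the acceptance suite measures it at study-scaled
  sizes (15-gene targets, 148-gene set, 2,000-gene universe) where it sits
  far below the nominal level.
* Since every random set has the same expected fraction, ranking folds is
  ranking overlap counts; the implementation compares integer overlaps.
* `enrichment_screen()` runs one test per set of a collection, deriving
  each set's permutation seed from the master seed and the *set name*, so
  results are independent of collection order and a failed set (e.g. one
  disjoint from the universe) is flagged without aborting the screen. Raw
  per-set p-values are reported without multiple-testing correction,
  matching the per-set asterisk convention of this analysis style; a
  screen-wide correction can be applied downstream if desired.
* `exclusion_enrichment()` re-runs the test on \(T\) minus the union of
  other pathways' target sets, the standard control for "is this
  enrichment just a general preference of endo-siRNA pathways".

The hypergeometric tail would be the closed-form shortcut for this null;
it is kept as an independent cross-check in the tests, never as the
implementation, because the permutation route generalizes to statistics
without closed forms and is the procedure actually specified.

## Conservation classification

From a homology table (per gene: species with at least one ortholog;
same-species paralogs), genes are classified as:

* `unique_to_focal` ("newly evolved"): no ortholog in any surveyed
  species;
* `genus_only`: at least one ortholog among the congeners (defaults:
  *C. brenneri*, *C. briggsae*, *C. remanei*, *C. japonica*) and none in
  the outgroup;
* `conserved_among_nematodes`: at least one congener ortholog and at least
  one outgroup ortholog (defaults: *B. malayi*, *O. volvulus*,
  *P. pacificus*, *S. ratti*).

Orthogonally, a gene is `duplicated` when it has a same-species paralog
(paralogy is treated as symmetric: either end of a paralog row is
duplicated). Two rules the three definitions leave open:

* A gene with outgroup orthologs but *no* congener ortholog is not covered
  by the definitions. It is assigned `conserved_among_nematodes` with a
  warning: presence in an outgroup implies the gene predates the genus,
  and calling it newly evolved or genus-only would be strictly wrong.
* A gene absent from the homology table has no homology evidence and is
  classified `unique_to_focal`; absence of evidence is what "no known
  ortholog" means operationally.

Ortholog multiplicity within a species is deliberately ignored — one
ortholog or ten, the species counts once.

## TSS metagene profiles

All internal coordinates are 0-based half-open; GFF3's 1-based inclusive
coordinates are converted exactly once, in the reader. The TSS is the gene
start on the `+` strand and the gene end on the `-` strand.

For a base at genomic position \(p\) and a gene with TSS \(t\), the
relative offset is \(d = p - t\) on the `+` strand and \(d = t - p\) on
the `-` strand; relative bin \(i\) collects offsets in
\([-W + ib, -W + (i+1)b)\) (window \(W\) = 1000 bp, bin \(b\) = 10 bp by
default; positions are labelled by bin centers, symmetric around 0). A
bin's value is the coverage-weighted mean of the binned track over the
corresponding genomic interval, computed from per-chromosome prefix
integrals so extraction is two `findInterval` lookups per bin edge.

* **Missing data stay missing.** Positions outside track coverage
  (chromosome edges, unmappable regions) are NA, and position-wise means
  ignore them; zero-filling would fabricate signal depletion at edges.
  Positions with no data in *any* gene of a set are flagged with a
  warning.
* **Control band**: `n_controls` (default 1,000) random gene sets of the
  same size drawn from the universe, each profiled identically;
  `control_mean/low/high` are the position-wise mean and (0.025, 0.975)
  quantiles. The band answers "what would a random gene set of this size
  show", the same null as the enrichment machinery.
* The bin width (10 bp) matches how processed chromatin tracks are
  typically distributed; window, bin, quantiles and control count are all
  parameters.
* When several replicate tracks exist, they are averaged into one track
  before per-gene extraction (the alternative — extracting per replicate
  and averaging profiles — differs only at positions covered in some
  replicates and not others).

## Feature comparisons

`compare_feature()` is the Wilcoxon rank-sum test: exact when both samples
are small (`min(n) <= 8`) and tie-free, the tie-corrected normal
approximation with continuity correction otherwise (the classical switch;
at combined n = 10 the one-sided approximation stays within 0.01 of the
exact tail). Two-sided by default — the analyses report significance
without a pre-registered direction — with one-sided alternatives
available. The log2(x+1) transform is *display only*: rank tests are
invariant under strictly monotone transforms, so the p-value is computed
on raw values while medians and means are reported on the transform scale
(the scale on which density distributions are conventionally shown and
quoted). Intron numbers of multi-transcript genes enter as the arithmetic
mean of per-transcript intron counts. Degenerate input (both samples one
shared constant) returns p = 1, not NaN.

`feature_report()` compares each target set against *all* protein-coding
genes (not the complement): that is the reference the analysis style uses,
and the overlap between a target set and its superset reference can only
make the test conservative under the null.

The corrected total cell fluorescence utility implements
`CTCF = integrated_density - area * mean_background`, normalized to the
mean CTCF of control animals.

## The synthetic study generator

`simulate_study()` writes every input the pipeline reads — GFF3 gene
models, wild-type/mutant count tables, homology and feature tables, a
binned H3K9me3 bedGraph, a 15-set GMT collection, and a ready-to-run YAML
config. A `universe_spec()`/`plant_spec()` pair plus one integer seed
fully determines every byte (Mersenne-Twister with pinned normal/sample
kinds; every stage derives its own seed from the master seed and a stage
label, so regeneration is order-independent).

What the generator emulates, and the defaults that define the simulated
study conditions:

* **Universe**: 20,000 protein-coding genes on six chromosomes, uniform
  strands, gene lengths 0.6–2.4 kb, 1–3 transcripts per gene with
  Poisson intron counts (mean 4.5 per transcript; genome-scale medians of
  about 4).
* **Conservation background**: 9% newly evolved, 16% genus-only, the rest
  nematode-conserved; 33% duplicated. The 9% matches the background rate
  the conservation enrichment is read against; genus-only and duplicated
  fractions are round values of the right order for a nematode genome.
* **Counts**: per-gene expected counts log-normal across genes (meanlog
  log 30, sdlog 1, scaled to a 1e6-read library — a dynamic range of
  roughly 2^0–2^12 RPM like real endo-siRNA scatter), with independent
  negative-binomial noise per sample (`mu`/dispersion parameterization;
  dispersion 0 degenerates to Poisson, which the tests exploit as an
  oracle). Default dispersion 0.02: with two independent libraries the
  null spread of single-replicate fold changes is about
  `1.44 * sqrt(2*d + 2/mu)` log2 units, and 0.02 keeps the 2-fold rule's
  null call rate below about a percent per side, so called sets land at
  the hundreds-of-genes scale such studies report. Dispersion 0.1 is the
  stress condition used by the recovery tests.
* **Planted depletion**: 151 target genes, 35 of them newly evolved
  (matching the structure 35/151 over a 9% background, which forces a
  conservation-class enrichment fold of about 2.57 by construction);
  mutant means divided by 5. Targets are drawn only among genes with at
  least 16 RPM expected wild-type expression: target sets are by
  definition genes with *detected* endo-siRNAs — below about 5/3 RPM a
  depletion cannot cross the 0.5 threshold even in expectation, so
  planting it would specify an unobservable effect, and the observed
  dynamic range of changed genes in such data starts around 2^4 RPM.
* **PATC density**: log-normal background (meanlog 2, sdlog 1). Newly
  evolved genes and planted target genes draw from a distribution whose
  *log2(x+1)-scale median* is 10% lower (`patc_newly_evolved_factor =
  0.9`, linear factor about 0.78 at the default background median) — the
  scale on which such medians are quoted; a 10% reduction of the linear
  median would be statistically invisible at realistic set sizes, which
  would defeat the planted signal's purpose.
* **Chromatin signal**: constant baseline 1.0 with optional AR(1) noise
  (marginal sd 0.2, lag-1 correlation 0.7 — smooth like real coverage),
  10-bp bins; newly-evolved genes get `h3k9me3_elevation`-fold signal
  (default 3) within ±250 bp of the TSS, so the elevation is visible
  across the ±200 bp region the tests interrogate.
* **Gene sets**: a 15-set collection shaped like the published one
  (tissue-expression sets and small-RNA-pathway target sets, sizes scaled
  to the universe); silencing-pathway sets absorb planted targets
  (enrichment), the licensing-pathway set avoids them (depletion), tissue
  sets are random.

What it deliberately does **not** emulate: read-level artifacts
(alignment, multimapping, adapter chemistry), the extreme zero-inflation
of real 22G count distributions, correlated biological noise between
conditions, piRNA sequence targeting, fragment-level ChIP signal, or
inter-chromosomal heterogeneity. Passing tests on this generator therefore
demonstrates that the *statistical machinery* is correct and calibrated —
not that any particular biological dataset will show the planted effect
sizes.

## Numerical and reproducibility choices

* Permutation p is `(r+1)/(n+1)` with tie-inclusive counting (valid,
  never zero); the floor at `n = 10000` is 9.999e-5.
* Exact rank-sum enumeration below `min(n) = 8` without ties; continuity-
  corrected normal approximation otherwise.
* Seeds: one master seed; every stage, library, permutation screen and
  control band derives `derive_seed(master, label)` (a multiplicative
  string hash modulo 2^31 - 1), so any stage can be re-run in isolation
  with identical results and report regeneration is byte-identical.
* Test problem sizes are chosen to make each property measurable quickly:
  exhaustive-null comparisons on universes of up to 12 genes at 200,000
  permutations; calibration with 2,000 replicates on a 2,000-gene
  universe; classifier recovery at full study scale (20,000 genes, 200
  libraries); metagene oracles on exhaustively-checked 300–400 bp tracks.
* Writers emit deterministic column and line order (sorted by gene id or
  coordinate); `summary.json` contains no timestamps.

## Known limitations

* The single-replicate fold-change rule is a detection heuristic, not a
  test; its false-positive rate under overdispersion is measured and
  reported, and called sets are always interpreted through the
  random-set enrichment null.
* The direction-adaptive one-sided permutation p is not a calibrated
  two-sided test; its combined null rejection rate is bounded by twice
  the nominal level and measured in the acceptance suite.
* The outgroup-only conservation case follows a declared default rather
  than a published rule, and is warned about whenever it fires.
* The normal approximation to the rank-sum null is inaccurate for very
  unbalanced tiny samples (e.g. 1 vs 9); the implementation uses the
  exact path there, and the approximation only ever applies beyond the
  exact regime.
* bigWig input is not supported; binned signal arrives as bedGraph.
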