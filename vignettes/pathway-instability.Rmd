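---
title: "Pathway instability scoring: model, design choices and validation"
author: "PathwayInstability package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway instability scoring: model, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PathwayInstability)
```

## The model

Somatic mutation data enters as a long table of records — one row per
mutation call, carrying a sample identifier, a gene symbol, the
tumor's primary localization, a mutation class label, a mutation
identifier and the gene's coding-sequence (CDS) length. Three
statistics are derived:

* **MR** (mutation rate) of gene $n$ in sample group $g$:
  $\mathrm{MR}_n = N_{mut}(n,g) / N_{samples}(g)$. The numerator is a
  count of *records*, not of mutated samples, so recurrent hits in one
  sample all count — the score measures burden, not prevalence.
* **nMR** (normalized mutation rate):
  $\mathrm{nMR}_n = 1000 \cdot \mathrm{MR}_n / L_{CDS}(n)$, i.e. the
  rate per kilobase of coding sequence. Under a null in which
  mutations land uniformly per coding base, $E[\mathrm{MR}_n] \propto
  L_{CDS}(n)$ while $E[\mathrm{nMR}_n]$ is constant, which is the
  entire point of the normalization.
* **PI** (pathway instability) of pathway $p$:
  $\mathrm{PI}_p = \sum_n \mathrm{nMR}_n \, PG_{p,n} / N_p$, the mean
  nMR over all $N_p$ member genes, with members that were never
  mutated in the cohort contributing zero. The denominator is always
  the pathway's full membership, so a pathway is not rewarded for
  having only a few — heavily mutated — members observed. PI carries
  no per-gene activator/repressor coefficients and no log transform:
  mutation consequences are mostly uncharacterized, so every member is
  weighted equally, and burdens only accumulate (there is no "reference
  tissue" below which a score could sensibly be log-compressed).

Key modeling assumptions: one localization per sample (violations are
rejected at construction); $N_p$ counts distinct gene symbols, not
transcripts or isoforms; and the gene universe is the set of genes
observed mutated in the cohort — pathway members never observed simply
contribute zero rather than shrinking $N_p$.

## Granularity

The score definitions are group-level, but ROC screening needs one
score per sample. Per-sample matrices therefore use singleton groups
($N_{samples} = 1$, so MR reduces to the raw record count), while
cohort-level summaries (the CDS-length correlation analysis, the mean
PI used for universal-pathway selection) use the all-samples group.
Both views are exposed (`geneCounts`/`computeMR`/`computeNMR` versus
`sampleNmrMatrix`/`piMatrix`).

## Screening

Each feature (gene nMR or pathway PI) is tested with the Mann–Whitney
AUC, computed from rank sums and exactly equal to the fraction of
(positive, negative) sample pairs ordered correctly with ties counting
one half. Two comparison designs are run: one localization versus all
others pooled, and every unordered pair of localizations. Because a
feature can be informative by being *low* in a tumor type, screening is
two-sided: the **effective AUC** is $\max(\mathrm{AUC}, 1 -
\mathrm{AUC})$ with a direction flag ("high"/"low"); both raw and
effective values are retained so either convention can be audited. A
high-quality biomarker is a record with effective AUC **strictly**
above the threshold (default 0.75); the universal-pathway selection
uses a **strict** "below 0.7 in every type" cap. No multiple-testing
correction is applied — the screen is descriptive, ranking features by
discriminative strength rather than testing a family-wise null.

Universal pathways (mutated everywhere but discriminating nowhere) are
the intersection of the everywhere-quiet set with the top
$\lfloor 0.10 \cdot P \rfloor$ pathways by cohort-mean PI; the floor
and a name tie-break at the boundary make the cutoff deterministic.
The most-informative ranking counts, per pathway, the localizations it
marks at the threshold, sorting ties by name.

## Distances, trees, ordination

The pairwise biomarker count is used **verbatim** as the dissimilarity
between two localizations — no square-root or other variance transform
— because the count itself is the natural scale: zero biomarkers means
the two mutation landscapes are operationally indistinguishable.
Ward's criterion in its D2 form is then the appropriate agglomeration
on untransformed dissimilarities (the Lance–Williams update squares
and re-roots internally, and merge heights come out on the original
count scale). Pairs with zero biomarkers are maximally close by
construction; this is a convention, and with several all-zero pairs
the early merges are tie-heavy — which is why the implementation
breaks ties deterministically by the lexicographically smallest pair
of cluster representative labels, making dendrograms reproducible
bit-for-bit and invariant under input permutation. `stats::hclust`
with `ward.D2` produces the same heights on tie-free inputs but
resolves ties by input order, so it is used as a cross-check in the
tests, not as the implementation.

PCA is column-centered but *not* variance-scaled (covariance PCA):
nMR/PI scores share a unit, and scaling would inflate near-constant
features that carry no burden signal. Variance-explained fractions are
reported per component.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `minSamples` | 100 | smallest localization kept; below ~100 samples per class the per-type AUC estimates get too noisy for a 0.75 cut |
| `minSize` | 10 genes | smallest pathway scored; tiny sets make PI collapse onto single-gene behavior |
| `threshold` | 0.75 | effective-AUC bar for a high-quality biomarker (strict) |
| `aucCap` | 0.7 | effective-AUC cap for "discriminates nowhere" (strict) |
| `topFrac` | 0.10 | mean-PI fraction intersected in universal-pathway selection |
| `missingLength` | `"strict"` | error on scored genes without CDS length; `"drop"` excludes them with a logged list |
| `dedupe` | on | collapse transcript-level duplicate rows by (sample, mutation id) |

Deduplication matters for COSMIC-style exports, which emit one row per
transcript annotation of the same event; with it off, mutation totals
are inflated by the transcript multiplicity. Whether a given upstream
pipeline already collapsed transcripts is often undocumented, so both
modes are supported and the removed-row tally is logged. CDS lengths
are resolved per gene as the maximum seen across records (transcript
annotations disagree; the maximum is a deterministic, order-independent
choice), or supplied as a standalone table. The truncating-mutation
subset (exact, case-insensitive match to the four loss-of-function
labels Deletion-Frameshift, Insertion-Frameshift, Complex-frameshift,
Substitution-Nonsense) drops samples left with no records but does
**not** re-apply the localization size filter — the subset is meant to
be comparable with the full-cohort analysis over the same
localizations.

## The synthetic cohort generator

`simulateCohort` emulates the statistical structure the method
assumes, with known ground truth. Per sample of type $t$ and gene $g$,
the mutation count is Poisson with rate
$\lambda_{g,t} = \mathrm{burden}_t \cdot L_g / \sum_G L \cdot
\mathrm{fold}(g,t)$, where $\mathrm{fold}(g,t) > 1$ only for genes in
a pathway with a planted enrichment for that type. Counts (not
presence/absence) exercise the record-count semantics of MR; each
record is labeled truncating i.i.d. Defaults describe a mid-sized
pan-cancer exome cohort: 3 localizations × 200 samples, 5,000 genes,
log-normal CDS lengths with median 1.5 kb (sdlog 0.6), ~390 mutations
per sample and a 7% truncating fraction — per-sample burden and
truncating share chosen to match what large uniformly-processed tumor
exome collections report on average — and 50 pathways of 10–50 genes
drawing ~20% of members from a shared hub pool so that sets overlap,
as real collections do.

What the generator does *not* emulate: trinucleotide mutational
signatures, driver/passenger selection, hypermutator subpopulations,
copy-number events, and inter-gene rate heterogeneity beyond CDS
length. Passing tests therefore demonstrate that the scoring and
screening machinery behaves correctly under the model's own
assumptions — length-proportional burden with pathway-level
enrichments — not that the biological conclusions transfer to any
particular real cohort.

One subtlety is load-bearing for planted-effect experiments. A
multiplicative fold gives each member gene an *absolute* rate
increment proportional to its CDS length, so a single very long member
can become an individually detectable gene-level marker instead of a
diffuse pathway signal. When the intent is an effect spread over many
small per-gene increments, `plantablePathway` selects the largest
pathway whose members all have CDS ≤ 3 kb (about twice the median
gene, keeping each member's baseline rate — and hence its enriched
rate — individually weak); `simLayout` exposes the seed-determined
pathway collection so this choice can be made before the cohort is
drawn, without disturbing the random stream.

## Numerical and degenerate-input choices

* PI and AUC are plain sums/rank statistics; the only tolerance-bearing
  comparisons are in the tests (1e-12 against enumeration oracles).
* Ward.D2 ties: resolved lexicographically (see above); merge heights
  are monotone non-decreasing by construction of the criterion.
* Empty results are legal where they are meaningful (a min-size filter
  that removes everything warns; an informative ranking with no hits
  returns an empty table) and errors where they are not (an empty
  cohort, an empty class in an AUC).
* Score TSVs round-trip at 15 significant digits; Newick labels with
  metacharacters are single-quoted.

## Validation strategy and problem sizes

The test suite checks every scoring formula against brute-force
enumeration (explicit sum-over-members PI, explicit pair-count AUC,
naive $O(n^3)$ Lance–Williams agglomeration), property-style
invariants (AUC invariance under monotone transforms, label-swap
symmetry, PI linearity and mean bounds, permutation invariances,
dendrogram monotonicity), and planted-truth recovery on simulated
cohorts. The acceptance script re-runs the largest of these from
scratch: a 5,000-gene null cohort for the length-decorrelation
contrast (Spearman of MR vs CDS length high, nMR vs length near zero)
and a 3 × 200-sample cohort with one fold-5 planted pathway for
recovery (sensitivity, false-call rate, pathway- vs gene-level
biomarker counts). These sizes give stable statistics while keeping a
full run in the tens of seconds; they are study conditions of the
validation design, fixed once.

## Known limitations

* PI weights all members equally; mutation-impact coefficients are a
  natural extension once functional annotations are reliable enough.
* The screen reports discriminative strength without p-values or FDR;
  treat biomarker lists as rankings, not significance claims.
* Biomarker-count distances are not metric (the triangle inequality
  can fail), which Ward-style agglomeration tolerates but embedding
  methods would not.
* COSMIC-dialect parsing covers the GenomeScreens export; MAF/VCF
  inputs would enter as additional column dialects, not new parsers.
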