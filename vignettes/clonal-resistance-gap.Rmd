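---
title: "Quantifying clonal resistance from ctDNA: models and design choices"
author: "clonalgap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying clonal resistance from ctDNA: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalgap)
```

## The problem

When a colorectal tumor progresses on anti-EGFR antibody therapy, resistance
driver mutations (most often hotspots in *KRAS*, *NRAS*, *BRAF*, *MAP2K1*,
*EGFR*) expand in one or more subclones. Ultra-deep circulating tumor DNA
(ctDNA) sequencing samples the whole cancer cell population at once, so it can
answer a question a single biopsy cannot: *what fraction of the cancer cells
carry any identified resistance driver?* The complement of that fraction is
the **resistance gap** — cancer cells that progressed with no detectable
resistance mechanism. `clonalgap` implements the copy-number-aware clonality
algebra behind that statistic, along with the surrounding inference layer:
assay-specific variant retention filters, ploidy and amplification calling,
transcriptomic subtype assignment with switch detection, immune infiltrate
scoring, and neoantigen enumeration. Everything is exercisable on synthetic
cohorts with known ground truth; no patient data are required or included.

## The CCF model

For a mutation with local total copy number $C_{tot}$, of which $C_{mut}$
copies carry the mutation, in a sample where a fraction CCF of cells (or of
ctDNA fragments' cells of origin) carry it, the expected variant allele
fraction is

$$VAF = \frac{CCF \cdot C_{mut}}{CCF \cdot C_{tot} + 2 (1 - CCF)},$$

where the $2(1-CCF)$ term is the two copies contributed by cells without the
mutation. Inverting for CCF:

$$CCF = \frac{2 \cdot VAF}{C_{mut} + 2 \cdot VAF - VAF \cdot C_{tot}}.$$

`estimateCcf()` and `expectedClonalVaf()` implement this pair; they are exact
algebraic inverses, which the test suite verifies to $10^{-12}$ over a dense
grid of $(VAF, C_{mut}, C_{tot})$ with $C_{mut} \le C_{tot} \le 8$.

Two practical consequences of applying the formula literally:

* **Values above 1 are capped and flagged** (`ccfCapped()`): binomial sampling
  noise can push the raw estimate past 1, and downstream fractions must stay
  in $[0, 1]$.
* **The denominator always assumes two normal copies at the locus.** Under
  TP53 loss of heterozygosity with $C_{mut} = C_{tot} = 1$, a fully clonal
  mutation in 100% pure ctDNA has expected VAF $1/2$... and the inverse
  formula applied at VAF 0.5 returns $2/3$, not 1. We keep the literal
  formula rather than re-deriving a variant, because the whole downstream
  algebra (purity, expected clonal VAF, driver fractions) uses the same
  convention and the ratios it produces are internally consistent.

### ctDNA purity and the resistance gap

`estimateCtdnaPurity()` anchors the fraction of cell-free DNA of cancer
origin on the truncal TP53 mutation, whose copy state is taken from the
matched biopsy ($C_{mut} = C_{tot}$ under LOH). A tumor with two TP53
mutations from distinct events is handled by summing the VAFs and using the
summed chromosome-17p copies, flagged `combined`.

`driverFraction()` then divides each resistance driver's observed VAF by the
VAF expected if it were 100% clonal at the sample's purity, with
$C_{mut} = 1$: resistance drivers act dominantly, and assuming one mutated
copy *maximizes* the estimated driver-bearing fraction, making the gap
conservative. `resistanceGap()` sums the per-driver fractions (capped at 1;
per-driver values are also capped before summing) and reports
$gap = 1 - total$. We cap the sum because overlapping subclones cannot
jointly exceed the whole population; the uncapped sum is available through
the per-driver fractions.

```{r}
pur <- estimateCtdnaPurity(0.4, copiesMutated = 1, copiesTotal = 1)
purity(pur)
fr <- driverFraction(0.05, pur, copiesTotal = 2)
gap(resistanceGap(fr))
```

`estimateCancerCellContent()` implements the biopsy-side 2×VAF approximation
with the 10% exclusion rule. How the approximation should aggregate across a
sample's mutations is a design choice; we use the median of the VAFs: robust
against the subclonal
tail, which would drag a mean down. `assignClonalStatus()` deliberately
replaces phylogenetic CCF-clustering machinery with a transparent criterion —
clonal iff the exact binomial 95% CI of the CCF (Clopper–Pearson on the VAF,
mapped through the monotone CCF transform) includes 1 — which is adequate for
deep targeted data and for validation against simulated truth.

## Variant retention rules

Three assays, three rule sets, all applied to caller output (we never
re-call reads):

| rule | assay | retention condition |
|---|---|---|
| SNV | exome | VAF ≥ 5%, tumor depth ≥ 20, normal alt reads ≤ 2 |
| indel | exome | no disqualifying FILTER flag, normal 0/0, normal depth ≥ 10, tumor depth ≥ 20, tumor alt ≥ 5 |
| panel of normals | exome | flagged when alt/depth ≥ 2% in a normal; rejected when ≥ 5% of cohort normals flag |
| amplicon | deep amplicon | VAF ≥ 0.5% and ≥ 3 supporting reads |
| hotspot | ctDNA | ≥ 2 independent reads at a catalogued hotspot encoding a recurrent amino-acid change |

All "≥"-phrased thresholds are inclusive, applied literally (so exactly 2.0%
flags, exactly 5% of normals rejects). Filters annotate rather than drop:
every record keeps a `retained` flag and a `reject_reason`, so each decision
is auditable. A cohort normal with no counts at a locus counts as *not
flagging* — missing evidence is not evidence of an artifact.

## Ploidy and amplification calling

Ploidy is the segment-length-weighted mean of unrounded absolute copy number.
Amplification means integer CN at or above `round(3 * ploidy)`; homozygous
deletion is CN = 0; "substantial loss" mirrors the amplification rule as CN
at or below `round(ploidy / 3)`. The mirrored division is our reading of a
"3-fold decrease" and is isolated in one function so an alternative
arithmetic is a one-line change. Rounding of thresholds is half-to-even —
the tie behavior had to be fixed somehow, and half-to-even is deterministic
and standard in R.

Gene-level copy number is the length-weighted mode of overlapping segments
(genes straddle breakpoints); genes with no covering segment are *uncallable*,
never silently neutral. `harmonizeGenomeDoubling()` doubles the lower profile
of a biopsy pair when the ploidy ratio falls in [1.8, 2.2] and the doubled
profile correlates at ≥ 0.9 (length-weighted, over shared disjoint bins) with
the higher one; zero-variance profiles fall back to the exact-agreement
fraction because correlation is undefined there.

## Subtype assignment

Two classifiers with the published decision rules:

* **Centroid correlation**: Pearson correlation against subtype centroids on
  shared genes (≥ 50% of centroid genes required; the threshold is
  configurable since published signatures vary in platform coverage). Low
  confidence when best r < 0.15 or the lead over the runner-up is < 0.06.
  Correlation is affine-invariant, so any positive linear rescaling of a
  sample leaves calls unchanged; ties break toward the lexicographically
  smallest label, for determinism.
* **Nearest template**: cosine distance to marker-set indicator templates
  over the union of template genes; the permutation q-value is the empirical
  tail probability $(1+b)/(1+n)$ of the winning distance under gene-label
  shuffling; low confidence at q > 0.01. We use the raw permutation tail
  probability (an FDR-like quantity, as in nearest-template prediction
  tools) rather than a BH adjustment across 4–5 subtypes, which would be
  meaninglessly coarse at that dimension.

Preprocessing follows the conventional recipe (`normalizeAndCenter()`):
quantile normalization of `log2(x + 0.25)` and then row median centering.
The low-count filter retains genes at cpm ≥ 10/L (L = smallest library in
millions) in all samples by default; the per-sample criterion is
configurable because the "in how many samples" clause is a cohort-design
choice.

## Immune scores

CYT is `sqrt((GZMA + 1) * (PRF1 + 1))` on normalized expression. Signature
scores are plain means over present genes with coverage reported. The ssGSEA
implementation is the single-sample Barbie running sum: genes ranked by
decreasing expression, in-set steps weighted by rank value to the power
0.25, enrichment = the running-sum total; no cohort-wide rescaling (scores
are genuinely single-sample). Note that with decreasing weights this
statistic has a small positive null mean on random sets — about a tenth of
an extreme set's score in our tests — which is inherent to the weighted
running sum, not a bug; comparisons between samples are unaffected because
the bias is common. The paired reporting utilities wrap the paired t-test
and Mann–Whitney + Benjamini–Hochberg (significance at q ≤ 0.1), with
zero-variance inputs flagged instead of crashing.

## Neoantigen enumeration

The tumor-versus-germline protocol: retain germline variants (PASS, GQ ≥ 10,
genotype ≠ 0/0, coverage ≥ 10, ≥ 1 alt read, highest-AF alt per
multi-allelic site, segmental-duplication exclusion); treat all variants as
in-phase; resolve overlapping footprints (somatic beats germline, then
leftmost — a fixed, logged priority, since some rule is required and somatic
variants are the object of study); build the germline CDS ($T_{germ}$,
germline variants only) and tumor CDS ($T_{tum}$, germline + somatic),
applying variants right-to-left so indels do not invalidate coordinates;
translate to the first in-frame stop, or to the last complete codon when a
frameshift or stop-loss removes the stop; enumerate all 8–11-mers of
$S_{tum}$ not present among the 8–11-mers of $S_{germ}$. A reference
mismatch at a variant position raises an error naming the transcript —
annotation inconsistencies surface, they are not silently dropped.

Binder counting is predictor-agnostic: any `function(peptide, hla)`
returning an interaction core and a percentage rank works.
`toyRankPredictor()` is a deterministic hash-based stand-in (it also
shortens ~10% of cores to exercise that path); `tsvRankPredictor()` ingests
real predictor output from a table. Per distinct core, only the best
(lowest) rank across HLA contexts is kept; binders are cores with rank
< 0.5 that do not match any germline protein window (shortened cores can be
wild-type peptides, and those are excluded from the burden).

## The synthetic cohort generators

The generators define the validation conditions, and their defaults are the
study conditions the inference layer is meant for:

* **Read counts**: variant reads are Binomial(depth, expected VAF) with the
  admixture expectation
  $E[VAF] = purity \cdot CCF \cdot C_{mut} / (purity \cdot C_{tot} + 2(1 - purity))$.
  Depth is fixed per assay (we use 1,048× for ctDNA validation, matching
  deep liquid-biopsy panels; exome-like and amplicon-like depths can be set
  by argument). Noise is purely binomial — no overdispersion — the simplest
  model consistent with depth-driven sensitivity; an overdispersed extension
  would only widen recovery intervals. Germline het sites are drawn at
  expected VAF 0.5 regardless of purity.
* **Expression**: sample = assigned centroid + i.i.d. Gaussian noise. We
  validate label recovery at noise SD 0.5 against unit-variance centroids
  (≥ 95% required; in practice recovery is essentially complete at that
  noise, and the margin covers correlated-noise degradation real data would
  add).
* **Toy transcriptomes**: random CDS (start codon, non-stop interior codons,
  terminal stop) with one planted somatic variant per transcript cycling
  through the eight consequence classes, plus optional germline missense
  SNVs. The reference is adjusted before variants are recorded, so planted
  `ref` alleles always match.

What the generators do *not* emulate: sequencing error profiles, alignment
artifacts (beyond planted recurrent positions for the panel-of-normals
test), overdispersed counts, correlated gene-gene expression structure,
fragment-size effects in ctDNA. Passing the validation suite therefore
demonstrates correctness of the inference algebra under its own sampling
model, not robustness to every artifact of real data.

All generators draw from per-component streams derived deterministically
from one global integer seed, so every simulated object is bit-reproducible
and different components never share an RNG stream.

## Parameter-recovery validation

The central validation simulates the conditions the gap statistic is used
under: ctDNA at 1,048×, purity 0.57, a truncal TP53 anchor under LOH, and
two diploid drivers at cancer-cell fractions 0.10 and 0.20 (true gap 0.70).
Over 500 seeded replicates the recovered gap must fall inside the truth's
95% sampling interval — obtained by pushing raw binomial draws through the
estimator's closed form, independently of the simulator code path — in at
least 94% of replicates. Problem sizes throughout the suite (500 replicates,
20,000 oracle draws, 200 random transcripts, 500 null FDR simulations,
786-gene centroids, 1,000 permutations) were chosen as the smallest sizes at
which the Monte Carlo error of each check is comfortably below its decision
margin.

## Orchestration

`runPipeline()` drives an end-to-end synthetic cohort — readcounts → purity
→ gap; expression → subtype calls → switches; immune scores → paired tests;
toy transcriptome → neoantigen burden; burden and enrichment reporting —
writing TSV stage outputs and a JSON report with provenance (config hash,
seed, package version). The run is bit-reproducible under a fixed seed, and
every headline number in the report traces to a stage output file. The
manifest (sample, patient, BL/PD timepoint, response group) is validated
before any stage runs; an orphan PD sample aborts the run. The package's
interface is the R functions themselves; `scripts/acceptance.R` shows how a
shell-level reproduction of the headline quantities is assembled from them.

## Known limitations

* The CCF algebra fixes the normal contribution at two copies per locus;
  sex chromosomes and germline CNVs at driver loci are out of model.
* `assignClonalStatus()` is a single-variant binomial criterion, not a
  clustering of variants into clones.
* The nearest-template classifier is a generic re-specification, not a
  reimplementation of any published tool's exact gene lists or FDR
  machinery; published decision thresholds (shortest distance, q ≤ 0.01)
  are what is honored.
* Segmentation, purity/ploidy search, HLA typing and binding prediction are
  consumed as inputs, never computed.
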