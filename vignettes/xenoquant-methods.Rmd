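---
title: "Methods: models, parameters and design choices in xenoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in xenoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenoquant)
```

xenoquant reimplements, as one tested pipeline, the quantification stack of a
tumor-xenograft study of combined COX-2 inhibition (a celecoxib analog,
SC236) and VEGF blockade (bevacizumab): cohort outcome statistics, geNorm
qPCR normalization, gene-set enrichment with a leading-edge odds-ratio
filter, and fluorescence vessel morphometry. No raw data from such studies
are assumed to be available; every stage is instead exercised on synthetic
inputs with known ground truth, so the package's tests measure whether each
estimator recovers what was planted. This vignette documents the models,
their assumptions, the tunable parameters, the numerical choices made where
the published operator chains are underspecified, and what the synthetic
experiments do and do not demonstrate.

## Cohort outcome statistics

A cohort table holds one row per animal: treatment arm, tumor weight
(grams), and a binary lung-metastasis outcome. The analyses are

* **Metastasis incidence**: per-arm counts and percentages, rounded half-up
  to whole percent (`incidence_summary()`), and pairwise arm contrasts by
  Fisher's exact test (`fisher_exact_2x2()`).
* **Tumor weights**: tie-corrected Kruskal–Wallis H with a chi-square
  reference on $k-1$ degrees of freedom (`kruskal_wallis()`), and per-arm
  means expressed as percent of the control mean (`percent_of_control()`).
* **Repeated assays** (e.g. ELISA run in duplicate twice): summary mean of
  the per-assay means with standard error $\sqrt{\mathrm{Var}}$ of those
  means — the interassay variance rule (`repeated_assay_summary()`).
* **Per-gene qPCR contrasts**: two-sided pooled-variance t-test
  (`two_sample_t()`).

Two conventions deserve note. The two-sided Fisher p-value uses the
point-probability method — the sum of the probabilities of all tables with
the observed margins whose point probability does not exceed that of the
observed table — which is the dominant convention (and the one
`stats::fisher.test` uses). Published four-arm reports of this design do not
state sidedness; recomputing from the printed counts shows the reported
pairwise p-values (0.011 and 0.046) equal the one-sided hypergeometric tail,
while the printed control-versus-combination value (0.0001) matches the
two-sided test at 4-decimal rounding. Both alternatives are therefore
exposed and every report records which was used; neither is guessed as "the"
intent. Degenerate t-tests (zero pooled variance) return $p = 1$ when the
means agree and a flagged infinite statistic when they do not, so pipelines
on zero-noise synthetic data never crash.

## geNorm reference-gene stability

Quantification cycles are converted gene-wise to relative quantities
$RQ = E^{\,\min(C_q) - C_q}$ with amplification efficiency $E$ (default 2.0,
perfect doubling; per-gene overrides supported — efficiencies are rarely
published, and 2.0 is the conventional assumption). The stability value of
candidate reference $j$ is

$$M_j = \frac{1}{n-1}\sum_{k \ne j} \mathrm{SD}_{\text{samples}}
  \left[\log_2 (RQ_j / RQ_k)\right],$$

with the $n-1$ SD denominator and base-2 logarithms throughout (the geNorm
convention). `rank_reference_genes()` repeatedly removes the gene with the
largest M and recomputes until two remain; ties in the maximal M are broken
by excluding the gene that appears later in the input row order, making the
ranking deterministic. The pairwise variation
$V(n, n{+}1) = \mathrm{SD}[\log_2(NF_n / NF_{n+1})]$ is reported for every
step, where $NF_n$ is the geometric mean of the $n$ most stable references
per sample, but the default normalization factor uses **all six**
housekeeping genes (ACTB, HMBS, UBC, GAPD, HPRT, PPIA), matching the
emulated study's choice; `n_select` restricts to the V-selected optimum when
wanted. Target genes (the seven-gene lung-metastasis signature: COL6A1,
CSF2RA, CXCR4, KRT81, MATN2, SPARC, TNC) are divided by NF per sample and
group-compared by pooled t-tests on $\log_2$ normalized quantities — the
geNorm route rather than ΔΔCq; with $E = 2$ and stable references the two
are equivalent up to the normalizer, and the geNorm route is the one the
emulated protocol names.

## Gene-set enrichment with a gene-permutation null

Genes are ranked by a two-class metric — default signal-to-noise
$(\mu_1 - \mu_2)/(\sigma_1 + \sigma_2)$ with each class SD floored at
$0.2\,|\mu|$ (0.2 when $\mu = 0$), the usual guard against tiny-variance
artifacts at 3–4 samples per class. Scores are oriented so that a positive
score means higher expression in the *treatment* class; sets repressed under
treatment therefore accrue negative enrichment, matching the reporting
convention of the emulated analysis. Ties are broken lexicographically by
gene identifier.

The enrichment score is the classic weighted running sum: walking down the
ranked list, hits increment by $|s_i|^p / \sum_{\text{hits}} |s|^p$ (default
$p = 1$) and misses decrement by $1/(N - N_h)$; ES is the signed extremum of
the walk. An exact tie between the positive and negative extremum (which
occurs with positive probability on small universes, where both candidate
extrema can be position-determined) resolves to the positive side, with a
$10^{-12}$ tolerance so floating-point summation order cannot flip the
choice. The implementation evaluates only the $2k$ candidate extrema around
the hit positions, which is exact because the walk is linear between hits.

With 3 and 4 samples per class, phenotype permutation is degenerate (35
distinct relabelings), so the null is **gene permutation**: each of the
`n_perm` (default 5000) permutations draws a uniform random gene set of
matched size and records its ES. NES divides ES by the mean magnitude of
same-sign null scores; the nominal p is the same-sign tail fraction (a
nominal p of 0 simply means "beyond all permutations" and is printed as
0.0000 in reports). FDR q follows the standard GSEA construction — the ratio
of null to observed tail fractions at each NES, pooled within sign, capped
at 1 and then monotonized step-up so a more extreme |NES| never has a larger
q — and FWER compares each NES with the per-permutation extreme NES across
all sets.

**Leading edge and odds ratio.** The leading edge is the stretch of the list
between its relevant end and the ES extremum; hits and misses are partitioned
at that boundary and

$$\mathrm{OR} = \frac{\text{hits}_{\text{before}} / \text{misses}_{\text{before}}}
                     {\text{hits}_{\text{after}} / \text{misses}_{\text{after}}},$$

the post-hoc filter applied at OR > 2 because the nominal p is uninformative
under a gene-permutation null and NES is biased toward larger sets. Zero
cells make the raw OR infinite or zero; such results carry a degeneracy flag
and a Haldane-corrected companion (0.5 added to every cell) is always
reported, since the source formula is silent on zero denominators.

**A caution on the OR filter for null sets.** Because the boundary is chosen
at the extremum of the set's own running sum, the filter statistic is
selection-biased upward even for a purely random set: the extremum tends to
sit just after a local excess of hits, so small `hits_before` counts
produce OR > 2 with roughly 20–25% probability per null set. In a collection
with many true-null sets, *some* positively enriched null set will
essentially always exceed OR 2. An empirical report that no positively
enriched set passed the filter therefore reflects that few sets were
positively enriched at all in that dataset (broad repression), not a
reproducible null property; the filter is only meaningful jointly with an
enrichment-significance criterion, and the acceptance script reports both
the marginal and the significance-restricted versions so the distinction is
visible in numbers.

## Vessel morphometry

Two operator chains mirror the published image-analysis recipes:

* **Radius chain** (mural-cell stains): dark-level subtraction, Gaussian
  blur, linear auto-levels, common threshold, gap-closing dilation,
  small-object rejection, hole filling, then per-object inscribed radii from
  the Euclidean distance transform.
* **Density/architecture chain** (perfusion stains): the same preprocessing
  and threshold, positive-pixel fraction (MVD), then erosion,
  skeletonization, and branch/endpoint/length metrics.

Choices where the published chain names tools but not parameters:

* *AutoLevelDark* is not a documented algorithm; it is implemented as
  subtraction of the 1st-percentile intensity with clipping at zero
  (percentile configurable). *Auto Levels* maps the 1st/99th percentiles to
  the full range. The blur radius is 1.0 pixel ($\sigma = 1$), as stated.
* The published *Invert* step reflects the display-polarity convention of
  the original software; here polarity is normalized once (vessels are
  foreground) and no literal inversion is applied.
* The **common threshold** defaults to 0.5 of the rescaled range: a
  symmetrically blurred edge crosses its intensity midpoint at the true
  object boundary, so this choice makes recovered geometry (radii, areas)
  unbiased; it is one fixed value applied across experimental groups, as the
  recipe requires. Otsu thresholding is deliberately not the default (it is
  per-image, hence not "common").
* *Dilate* uses a 1-pixel disc (gap closing), *Reject Features* removes
  components under 50 px, erosion before skeletonization uses a 1-pixel
  disc; none of these values are published and all are configuration with
  provenance logging. MVD is computed from the **undilated** thresholded
  mask: the density chain contains no gap-closing dilation, and dilating
  first would bias the positive-pixel fraction upward by one boundary ring.
* The inscribed radius of a connected component is the maximum of the
  distance-to-background transform, times the pixel size; a 1-pixel object
  has distance 1 (radius = pixel size) by convention. "Average inscribed
  radius" means the mean over connected objects.
* Skeletonization uses Guo–Hall thinning (implemented in the package;
  two-subiteration peeling that preserves 8-topology). Zhang–Suen thinning
  was evaluated first and rejected: on noisy masks it leaves two-pixel
  diagonal staircases that masquerade as branch points. Skeleton pixels with
  one 8-neighbor are endpoints; pixels with three or more are branch pixels,
  and branch pixels within one pixel of each other merge into a single
  junction (so a thick X crossing counts one junction, not two nearby Ys).
  Total length sums 1 pixel per orthogonal step and $\sqrt 2$ per diagonal
  step, skipping diagonals that merely shortcut two orthogonal steps; the
  uncorrected convention is available as an option.
* Group comparison of radii dichotomizes at 10 μm (the published cutoff for
  "dilated" vessels) and applies Fisher's exact test to the above/below
  counts.

## Synthetic data: what it emulates and what it does not

All generators are seeded and bit-reproducible; identical spec + seed gives
identical output.

* `gen_cohort()` draws Bernoulli metastasis outcomes at per-arm
  probabilities and log-normal tumor weights (weights are positive and
  right-skewed; only percent-of-control means are typically published, so
  the within-arm coefficient of variation is a free parameter, default 0.3 —
  a typical spread for xenograft end weights). The default design is the
  emulated 4-arm cohort: 13/17/17/15 animals, metastasis probabilities
  12/13, 11/17, 8/17, 2/15, weight scales 1.00/0.61/0.24/0.26.
* `gen_expression()` builds a log-scale matrix of unit-variance Gaussian
  noise for 3 + 4 samples, shifts the member genes of each planted set by a
  constant in the treatment class, and adds decoy sets drawn from the
  unshifted genes so decoys are exact nulls. Planted sets are disjoint so
  truth rankings are unambiguous. The default collection size is 67 sets,
  the size of the emulated inflammation-pathway matrix. It does **not**
  emulate probe-level microarray structure, gene–gene correlation, or
  heteroscedastic noise — so passing recovery tests show estimator
  correctness under the stated model, not robustness to correlated real
  transcriptomes (under correlation the gene-permutation null is known to be
  anti-conservative).
* `gen_qpcr()` models Cq as gene baseline + shared per-sample loading factor
  + gene-specific jitter whose SD controls stability; the ground truth is
  the ascending-jitter stability order. An optional planted log2 fold change
  shifts target genes one cycle per doubling.
* `gen_vessel_image()` renders vessel trees as exact capsule unions (every
  pixel center within the segment radius), blurs first and adds background
  and Gaussian sensor noise second (optics precede the sensor), and records
  the exact topology (junctions = points where ≥ 3 segment ends meet),
  centerline length, radii, and noiseless positive-pixel fraction. Trees are
  2-D, as are the emulated micrographs; there is no out-of-focus light,
  uneven illumination, or stain heterogeneity, so segmentation results on
  real micrographs will be noisier than these tests suggest.

## Problem sizes and runtime choices

The bundled demonstration (`demo_config()`) uses 2000 genes, 67 sets with
two planted repressed sets, 500 permutations, an 8-sample qPCR plate and two
16-vessel fields, and runs in seconds. The package's own verification
experiments use the full emulated scale where it matters — 10 000 genes,
3 + 4 samples, 67 sets, 5000 permutations for single runs — and reduce
permutations to 1000 for multi-seed sweeps, which leaves permutation
standard errors far below the effect sizes being detected. Exhaustive
checks (all 2×2 tables to N = 40; all same-size gene sets on ≤ 12-gene
universes) are exact, not sampled.

## Known limitations

* The published bar values for vessel metrics and the full enrichment table
  are not reproducible without the raw images and expression data, which
  were never deposited; those stages are validated as recovery properties on
  synthetic ground truth instead.
* The gene-permutation null treats genes as exchangeable; on correlated
  expression data its nominal p and FDR are optimistic. This matches the
  emulated analysis (which chose gene permutation for its tiny sample size)
  but is a property users should keep in mind.
* The OR filter should not be interpreted marginally on large null
  collections (see the caution above).
* geNorm's M is undefined for fewer than three references, and the final
  stable pair is inherently unordered.
* Skeleton length is a digital estimate; expect a few percent of bias on
  strongly curved or very thin (≤ 2 px) structures.
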