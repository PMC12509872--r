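---
title: "Windowed principal component scans: models, conventions and design notes"
author: "pcscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed principal component scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
models, the conventions that had to be fixed where several were defensible,
the numerical choices, and what the simulation-based tests do and do not
demonstrate about real data.

## 1. Why windowed PCA

A genome-wide PCA summarizes average relatedness, but the genomic
landscape is heterogeneous: inversions, introgressed haplotypes and
regions of unusual recombination produce *local* structure that global
population labels can hide. Computing a PCA independently in rolling
windows, and following each sample's score along the chromosome, turns
these signals into readable tracks at single-sample resolution. The
classic example is a polymorphic inversion: because recombination is
suppressed between orientations, variants inside it behave like one giant
locus, and window PCAs there stratify samples into the two inversion
homozygote classes with heterozygotes exactly intermediate — a tripartite
band pattern.

## 2. Windowing conventions

Windows are 1-based, fully closed intervals, matching VCF coordinates;
a variant belongs to window `[start, end]` iff `start <= pos <= end`.
Successive windows advance by `stepSize` from an anchor at position 1, and
only full-length windows (`start + windowSize - 1 <= span`) are emitted,
so a span of `S` yields `floor((S - windowSize)/stepSize) + 1` windows.
For the GRCh38 chromosome 1 length of 248,956,422 bp with a 1 Mbp window
and 100 kb step this gives 2,480 windows. `span` defaults to the last
variant position and can be overridden with an explicit chromosome length
(`--chrom-length`). Whether windows should be anchored at position 1 or at
the first variant is genuinely underdetermined (both give the same count
on dense data, and identical counts on the human-chr1 arithmetic above);
we default to position anchoring and expose `anchor = "variant"` as an
option. A span shorter than a single window is handled by emitting one
truncated window `[1, span]` rather than failing, so short scaffolds still
produce a (clearly reduced) result.

Defaults follow scan practice on dense whole-genome data: `windowSize` 1
Mbp, PCs 1–2 (any of PC1–PC10 can be requested), `minVariants` 20 —
windows with fewer usable variants yield `NA` rows instead of being
dropped, which keeps tracks rectangular so that polarization and plotting
retain positional continuity.

## 3. The hard-call path

Per window, missing dosages are mean-imputed per variant (the alternative,
discarding any variant with a missing call, throws away most sites in
large cohorts). Variants that end up constant are uninformative and are
dropped. The matrix is then standardized; the default scaler is
Patterson's `sqrt(p(1-p))` binomial unit, the convention of genetic
eigenanalysis, with `center` and `none` available. Scores come from the
full symmetric eigendecomposition of the samples × samples covariance
`X Xᵀ` — with N samples and V ≫ N variants per window this is the cheap
orientation, and a dense deterministic decomposition means bit-identical
results across runs with no solver seed. Scores are `u_k sqrt(lambda_k)`,
identical (up to sign) to SVD scores of `X`; per-PC variance explained is
`lambda_k / sum(lambda)`. Each window's eigenvector sign is canonicalized
(the sample with the largest absolute score is made positive, lowest index
on ties) purely for reproducibility; signs across windows remain
arbitrary until polarization.

## 4. The genotype-likelihood path

Low-coverage data are better represented by genotype likelihoods than by
hard calls. Likelihood triplets are read from VCF `GL`/`PL` fields or
BEAGLE files and normalized; `PL` is decoded as `10^(-PL/10)`. For `GL`
both log10-scaled and plain-probability dialects exist in the wild, so a
triplet whose values are all ≤ 0 is treated as log10 and anything else as
plain probabilities. Flat triplets carry no information and play the role
of missing data.

The window PCA then iterates expected genotypes with individual allele
frequencies:

1. initialize per-variant frequencies `f_j` from posterior mean dosages
   under a flat prior;
2. E-step: posterior mean dosage per sample and variant under a
   Hardy–Weinberg prior at the current individual frequency `pi_ij`;
3. eigendecompose the standardized expected-genotype matrix;
4. reconstruct `pi_ij` from the rank-`max(pcs)` fit, clamped to
   `[1/(2N), 1 - 1/(2N)]` to avoid degenerate priors;
5. repeat 2–4 until the root-mean-square change in expected genotypes
   falls below `tol` (default 1e-4) or `maxIter` (default 100) is reached;
   non-convergence is reported as a flag on the window, not an error.

Defaults (`maxIter` 100, `tol` 1e-4, reconstruction rank = largest
requested PC) are desk-scale choices for windows of 10²–10³ variants and
up to a few hundred samples. The final scoring standardizes the converged
expected-genotype matrix with `p = colMeans(E)/2` through the same code
path as the hard-call PCA; this makes the certain-likelihood limit
*exactly* equal to the hard-call result, at the cost of not reusing the
clamped iterated frequencies for the last standardization (they differ
only at near-monomorphic sites, where the clamp binds).

## 5. Polarization

PCA signs are arbitrary per window, so raw tracks zigzag. The sequential
rule: leave the first valid window; for each later valid window, take the
sample with the largest absolute score in that window (adaptive mode) or
the summed scores of user-chosen guide samples (guided mode), compute the
average sign of that reference over up to `nPrev = 5` preceding valid,
already-polarized windows, and negate the window if the current sign
disagrees. Choices the rule's phrasing leaves open, fixed here: signs are
averaged unweighted (±1 per window); a zero sign average keeps the current
orientation; shorter-than-`nPrev` histories use whatever is available; `NA`
history terms are excluded; ties in "largest absolute score" go to the
lowest sample index. The rule is greedy and local by design — a global
polarity optimization (e.g. dynamic programming over the whole track) is
out of scope. Consequences worth knowing: a sign flip in the *first*
window is unrecoverable by any sequential rule (that is what
whole-chromosome `flipChromosome` is for), and a run of more than `nPrev`
consecutive wrong windows can lock in; isolated flips separated by more
than `nPrev` windows are always corrected. Polarization is idempotent and
recomputed from stored signs, so re-polarizing written output is safe.
Interval flips select windows by midpoint within closed intervals, with
set semantics (overlapping intervals never double-flip).

## 6. Visualization

One figure description — per-sample traces over window midpoints (the
midpoint is the unbiased within-window x coordinate), per-sample colors
and hover text, chromosome panel boundaries — feeds every output format,
so HTML and static renderings cannot drift apart. `NA` windows split a
trace into separate segments, never an interpolated line. The HTML output
is a deliberately lightweight, dependency-free self-contained page: SVG
polylines with native browser tooltips (sample id plus all metadata
columns) and a small script for click-to-toggle legend groups. Static
PDF/SVG/PNG formats are rendered from the same description with ggplot2
at a default 1400 × 500 px per chromosome row. Categorical metadata maps
groups onto a fixed 12-color colorblind-safe cycle (recycled with a
warning beyond 12); a numeric column is min–max scaled and mapped through
a continuous viridis spectrum. Genome-wide plots lay chromosomes
left-to-right in input order on a shared score axis (a shared scale keeps
amplitudes comparable across chromosomes; per-panel scaling would
exaggerate low-variance chromosomes). Samples are drawn by group order
(user-controllable), then input order, so group order controls
z-stacking. Plotting never mutates track files.

## 7. The simulator

`simulateCohort()` exists so every stage is testable end to end without
external downloads, and its defaults *are* the package's reference study
conditions: 2 populations × 50 samples, 5 Mbp chromosome, 1 variant per
kb, Balding–Nichols divergence F = 0.1 (moderate, typical of
between-population structure at which PCA separation is unambiguous),
an inversion planted across the middle fifth-to-three-fifths of the
chromosome (2–3 Mbp) at haplotype frequency 0.5 with a 5× divergence
multiplier, no missingness, mean depth 8, and a 1% per-base error rate.
Ancestral frequencies are Uniform(0.05, 0.95); population frequencies are
Beta-distributed around them with variance `F·p(1−p)`. The inversion is
encoded as allele-frequency divergence between inverted and standard
haplotypes — not as a coordinate reversal — because PCA sees only
genotype correlation, which is exactly how real inversions manifest in PC
space; each sample's inversion genotype is drawn once at frequency `q`
and its variant alleles inside the interval are drawn per haplotype.
Likelihoods are generated by Poisson read sampling and binomial alt-read
counts, i.e. the standard shotgun model. One global RNG stream is seeded
once, and all three file formats are emitted from the same genotype draw,
so cross-format comparisons compare like with like.

What the simulator does **not** emulate: linkage disequilibrium within
windows (variants are drawn independently), recombination maps,
coalescent genealogies, multi-chromosome linkage, reference bias, or
structured (non-uniform) missingness. Passing tests therefore demonstrate
the correctness of the machinery — parsing, windowing, eigenanalysis,
polarization, format handling — under a clean generative model, not
performance on the confounders of real callsets (batch effects, allele
balance artifacts, misassembly).

## 8. Problem sizes and numerical notes

The test and acceptance runs use desk-scale problem sizes chosen so the
whole suite completes in a couple of minutes while still exercising every
claim at meaningful resolution: 50 random matrices up to 12 × 40 for the
eigendecomposition oracle (agreement within 1e-8 up to sign), 100
eighty-window tracks for polarization recovery, a 100-sample / 5 Mbp /
depth-30 cohort (41 windows) for likelihood–hard-call consistency
(mean per-window |PC1 correlation| > 0.99), and a 60-sample / 2 Mbp
cohort for the 10%-missingness robustness check.

Degenerate inputs are handled explicitly rather than by accident: fewer
than two samples is a fatal error; all-missing variant columns are
dropped and counted; monomorphic columns are dropped before Patterson
scaling (0/0 guard); windows below `minVariants` are invalid-but-present;
eigenvalues are floored at zero before square roots; half-calls (`./1`)
are missing; haploid calls are doubled with a warning; BEAGLE triplets
summing to zero become flat. Output files round floating point to 6
significant digits, encode missing scores as literal `NA`, and are
gzipped TSV throughout.

## 9. Known limitations

* Readers load one chromosome (or requested region) into memory and
  windows are materialized lazily by index lookup; this bounds memory at
  the window level for processing but not at the record level for
  parsing. For cohorts of thousands of samples × millions of variants a
  streaming record parser would be the next step.
* The GL path is a compact re-derivation of iterative
  individual-allele-frequency PCA, not a feature-complete port of any
  published implementation; options beyond the core iteration (e.g.
  alternative convergence criteria, admixture-aware extensions) are out
  of scope.
* Polarity is resolved greedily per chromosome; no global optimization,
  and no automated classification of the divergence patterns the plots
  reveal — interpretation stays with the analyst.
* Imputation by the per-variant mean is the pragmatic default for
  moderate missingness; for heavily missing low-coverage data the
  likelihood path (or upstream imputation) is the better tool.
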