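---
title: "Methods: staged decomposition of ChIP-seq signal into non-binding components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged decomposition of ChIP-seq signal into non-binding components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipdecomp)
```

## The problem

A windowed ChIP-seq read count is a mixture.  Beyond the binding (or
chromatin-mark) signal the assay targets, it carries contributions from read
mappability (unmappable stretches can hold no reads), base composition
(GC-dependent amplification and fragmentation), chromatin accessibility
(open chromatin shears and immunoprecipitates more readily — the
"hyper-ChIPability" effect), and the generic pull-down background that
input-DNA and IgG control experiments measure.  `chipdecomp` quantifies each
contribution, removes the combined background from peak scores, and audits
downstream signal-expression associations for confounding by accessibility.

## The staged regression model

The genome (minus excluded chromosomes, chrY by default) is tiled into
consecutive non-overlapping windows of odd width $N$ (default
$N = 2^7 + 1 = 129$ bp; odd so each window is symmetric about a central
base; trailing partial windows are dropped so all windows are comparable).
For each window we record:

* $y$ — deduplicated ChIP read count (5′ ends; at most $2N$ per window,
  one per strand per position);
* mappability and GC fractions — exact fractions of 1-bases in the two
  binarized per-base tracks;
* DNaseI hypersensitivity, input-DNA and IgG deduplicated read counts.

An ordinary-least-squares model with intercept is grown in stages, adding
predictors in the fixed order **mappability, GC, DNase, input DNA, IgG**
(least to most experiment-specific) and refitting all coefficients at each
stage.  With $\mathrm{MSE}_i = \mathrm{RSS}_i/(n-1)$ and stage 0 the
intercept-only model (so $\mathrm{MSE}_0 = \widehat{\mathrm{var}}(y)$), the
percentage of variance explained by the predictor added at stage $i$ is

$$ \mathrm{POV}_i \;=\; 100\,\frac{\mathrm{MSE}_{i-1} - \mathrm{MSE}_i}
   {\widehat{\mathrm{var}}(y)} . $$

Because every quantity shares the $(n-1)$ denominator, the POVs telescope:
$\sum_i \mathrm{POV}_i = 100\,R^2$ of the full model, which is reported as
the total POV.  Defining stage 0 as the intercept-only model is what makes
the first predictor's solo contribution well defined and the total equal to
$100 R^2$; every stage keeps the intercept so that stage-1 POV equals the
squared correlation with the first predictor.

Numerical choices:

* The solver is a rank-tolerant economy-SVD least squares
  (singular values below $\max(n,p)\,\varepsilon\,d_1$ treated as zero,
  minimum-norm solution).  A predictor collinear with earlier ones
  therefore cannot reduce the RSS and receives POV exactly 0 rather than
  crashing the fit.
* Adding a column can never increase the RSS, so each POV is non-negative
  up to floating-point error; values in $(-10^{-8}, 0)$ are clipped to 0
  and anything more negative raises an internal-consistency error.
* Control and DNase counts are used raw.  POV is invariant to affine
  rescaling of any predictor column (a span property of OLS), so
  depth normalization would change coefficients but not one POV value.
* `var(y) = 0` (a constant regressand) is refused as degenerate.

The multiscale driver repeats the whole procedure at widths $2^k+1$
(default $k = 7..20$), re-tiling and re-counting from base-pair level at
each width — grids at different scales do not nest, so no aggregation
shortcut is valid.

## Peak purification

Peak calls are asymmetric and of uneven width, so each peak is redefined as
the symmetric window summit $\pm h$ (default $h = 64$, i.e. 129 bp,
matching the model's training scale).  Windows that would cross a
chromosome edge are excluded, not truncated, so every feature vector has
the same width as the training windows.  For each peak window the model
features are recomputed on the exact window and the purified binding
estimate is

$$ B = R - \hat y, $$

raw count minus predicted background (never clamped; $B$ can be negative).
Competing scores are $R$ itself and the ingested peak-caller score $S$
(opaque, "larger is better": the summit-BED score column or narrowPeak
column 7 — any monotone choice gives identical rank-based evaluations).
Evaluation follows the motif logic: stronger true binding should co-occur
with more DNA-binding-motif matches, so each score is Pearson-correlated
against the per-peak motif count $M$ (occurrences counted only when fully
contained in the peak window — the strictest unambiguous rule; either
strand counts).  Across datasets the winner tally is tested with the exact
upper-tail binomial "ratio test": $P(X \ge \text{wins})$,
$X \sim \mathrm{Bin}(\text{datasets}, 1/3)$ under the no-difference null.
Ties everywhere break by stable sort with genomic coordinate as the final
key, for reproducibility.

## Expression-association audit

Expression is measured as the raw CAGE 5′-tag count in TSS $\pm h$ windows
(no log transform; duplicated TSS positions are collapsed with ids
concatenated).  Tenfold cross-validation assigns TSSs to folds uniformly at
random under a caller-supplied seed; an OLS model is trained on nine folds
and predicts the tenth.  The headline number is the pooled out-of-fold
Pearson correlation (lower variance than the fold average, which is also
reported with a $t$-based 95% interval across folds).  The correlation gain
of a candidate TF/HM signal is the pooled PCC of core predictors plus the
candidate minus that of the cores alone, on identical fold assignments;
it may be slightly negative through CV noise.  A signal whose association
with expression is entirely mediated by accessibility shows a high
standalone PCC but a near-zero gain — the confounding signature the audit
is designed to expose.  The same operations accept arbitrary intervals
(e.g. gene bodies) and any expression read set.

## What the synthetic generator emulates

The generator mirrors the composition model the decomposition assumes, with
every parameter planted and recorded:

* **Mappability** — alternating geometric runs, defaults 400 bp mappable /
  25 bp unmappable (~94% mappable, comparable to genome-wide unique
  mappability for 36-mers).
* **GC** — i.i.d. Bernoulli(0.41) bases, the human genome-wide fraction.
* **Accessibility** — Gaussian bumps (60 per Mb, exponential amplitudes of
  mean 1, widths 300–1500 bp) on a 0.1 baseline, saturating at 2:
  overlapping regulatory elements saturate physically, and the cap keeps
  the log-linear expression link within realistic tag counts.
* **Reads** — per-window Poisson counts: DNase rate linear in
  accessibility; input-DNA and IgG rates linear in mappability and GC;
  ChIP rate $\max(0,\beta^{*\top}x)$ in the realized features (planted
  $\beta^* = (1.0, 2.0, 1.5, 0.6, 0.3, 0.2)$, giving a few background
  reads per 129-bp window, an ENCODE-like depth) plus per-peak gamma
  enrichment (mean 15) in planted peak windows.  The linear-rate emission
  makes the fitted linear model correctly specified, so coefficient
  recovery is exact in expectation; the clamp at 0 is the one deliberate
  mis-specification knob.  Reads are placed as *distinct* stranded
  positions uniform over the mappable bases of their window, so the
  realized count equals the Poisson draw, deduplication is a no-op, and
  the $2N$ bound holds by construction.  (Real data contain PCR
  duplicates; this idealization is intentional — duplicate collapse is
  exercised by dedicated unit fixtures instead.)
* **Peaks and motifs** — summits at centres of well-mappable windows;
  per-peak motif counts Poisson in the true enrichment (an increasing
  link), emitted as FIMO-format TSV.
* **Expression** — CAGE counts Poisson with mean
  $\exp(0.5 + 4 \cdot \mathrm{accessibility})$, log-linear to reproduce
  the heavy right skew of real promoter tag counts.  A "specific TF" read
  set depends on accessibility only (slope 4, roughly 1–2 reads per
  window, a realistic TF library): conditionally independent of expression
  given accessibility *by construction*.  That slope is the calibration of
  the confounder construction: the TF must look predictive on its own yet
  carry almost no accessibility information beyond the much deeper DNase
  proxy (slope 20), so its cross-validated gain over the core predictors
  stays below the 0.02 threshold the audit uses.  An optional "general
  factor" additionally receives `coupling` reads per realized CAGE tag,
  giving it genuine information beyond accessibility.

What the generator does **not** emulate: fragment-length/shift structure,
PCR duplication, sequencing error, copy-number variation, cell-line genome
divergence, and spatial autocorrelation of GC beyond window level.  Tests
passing on these fixtures therefore validate the estimators' arithmetic
and their behaviour under the assumed composition model — not robustness
to every artefact of real libraries.

## Problem sizes

The test and acceptance fixtures use genomes of 0.4–6.5 Mb: a 1 Mb
two-chromosome genome (7,751 windows of 129 bp, 300 peaks, 2,000 TSSs) for
the end-to-end fixtures, 6.5 Mb (50,000+ windows, 20 replicate genomes)
for coefficient recovery, and a 0.4 Mb smooth-rate genome for the
multiscale scan at widths $2^3+1$ to $2^9+1$.  These sizes give standard
errors small enough that every planted-parameter check is sharp while a
full run stays in the low minutes on a single core.

## Known limitations

* The staged attribution is order-dependent by design (only the *total*
  POV is order-invariant); the fixed predictor order encodes the intended
  causal priority and should be kept in mind when comparing per-predictor
  POVs across studies.
* OLS on counts is heteroskedastic; reported classical standard errors are
  complemented by HC1 robust ones, but the POV itself is a descriptive
  variance decomposition, not an efficient estimator.
* BAM ingestion is out of scope: convert once with
  `bedtools bamtobed -i reads.bam > reads.bed` and feed the BED.
* Peak calling and motif scanning are consumed (MACS-style summit
  BED/narrowPeak, FIMO TSV), never recomputed.
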