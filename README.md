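# chipdecomp

Decomposition of genome-wide ChIP-seq signal into quantified non-binding
components — mappability, GC content, chromatin accessibility (DNaseI
hypersensitivity), input-DNA and IgG controls — with background
subtraction for peak scoring and a confounding audit for
signal-expression associations at TSSs.

## What it computes

A windowed ChIP-seq read count mixes true binding with several
non-binding influences.  `chipdecomp` tiles the genome into windows of
odd width *N* (default 129 bp), counts deduplicated 5′ read ends per
window, and grows an ordinary-least-squares model one predictor at a
time in the fixed order *mappability, GC, DNase, input DNA, IgG*.  With
MSE<sub>i</sub> = RSS<sub>i</sub>/(n−1) and stage 0 the intercept-only
model, the percentage of variance explained by the predictor added at
stage *i* is

    POV_i = 100 * (MSE_{i-1} - MSE_i) / var(y)

and the POVs telescope to the full model's 100 R².  The same model runs
across a ladder of widths 2^k + 1 (multiscale scan), predicts the
non-binding background in summit-centred peak windows to give the
purified binding estimate **B = R − predicted** (evaluated against motif
occurrence counts **M**, versus raw counts **R** and peak-caller scores
**S**), and measures the cross-validated gain in predicting CAGE
expression when a TF/HM signal is added to the core background
predictors (ΔPCC), which exposes signals whose apparent association with
expression is mediated entirely by accessibility.

A fully parameterised synthetic-data generator (genome, tracks, biased
reads, planted peaks with motifs, accessibility-confounded expression)
with known planted coefficients backs the test suite; no external
downloads are needed.

## Worked example

```r
library(chipdecomp)

cfg <- sim_config(seed = 1)              # 1 Mb synthetic genome
sim <- simulate_chipseq(cfg)

grid  <- sim$grid
y     <- count_reads(sim$chip, grid)
preds <- list(mappability = sim$map_frac, gc = sim$gc_frac,
              dnase = count_reads(sim$dnase, grid),
              idna  = count_reads(sim$idna, grid),
              igg   = count_reads(sim$igg, grid))
staged_decompose(y, preds, width = grid$width)
#> Staged decomposition: n = 7751 windows of 129 bp
#>    predictor   POV
#>  mappability  0.40
#>           gc  0.01
#>        dnase 47.16
#>         idna  0.31
#>          igg  0.11
#> total POV = 48.00% (var(y) = 42.44)
```

Accessibility dominates the explainable background (the generator plants
most of its structured variance there); the five POV rows sum to the
total, the share of windowed signal that is predictable without any
binding information.  Scoring the planted peaks with the fitted model
and correlating against motif counts:

```r
tab <- score_peaks(peaks, sim$chip, fit,
                   list(mappability = sim$map_track, gc = sim$gc_track),
                   list(dnase = sim$dnase, idna = sim$idna, igg = sim$igg))
tab <- add_motif_counts(tab, read_fimo_tsv(fimo_path))
correlate_estimates(tab)
#>   estimate       pcc      p_value defined
#> 1        B 0.6419017 3.076280e-36    TRUE
#> 2        R 0.6170171 7.312318e-33    TRUE
#> 3        S 0.6790777 6.606903e-42    TRUE
```

The purified estimate B tracks motif counts better than the raw count R
(S here is the oracle true enrichment, an upper bound no real peak
caller attains).  Background subtraction also recovers the planted
enrichment scale: mean planted enrichment 15.62 versus mean B 15.13.
The confounding audit at TSSs shows the signature pattern for a TF whose
reads are driven by accessibility alone:

```r
cv_predict(y_tss, data.frame(fake_tf = x_tf), seed = 2)
#> cv_result [fake_tf]: pooled PCC = 0.5948 (fold mean 0.5880, 95% CI 0.5301..0.6459)
delta_pcc(y_tss, core_features, x_tf, seed = 2, extra_label = "fake_tf")
#> delta_pcc [fake_tf]: core 0.7449 -> 0.7471 (increase +0.0023)
```

Standalone the fake TF looks strongly predictive (PCC 0.59), but adding
it to the core background predictors improves the cross-validated
correlation by only 0.002 — its association with expression is entirely
mediated by accessibility.

A command-line wrapper over the same functions is installed as
`exec/chipdecomp` with subcommands `simulate`, `decompose`,
`multiscale`, `purify` and `expression`; see the methods vignette
(`vignettes/chipdecomp-methods.Rmd`) for the model details and design
choices.

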