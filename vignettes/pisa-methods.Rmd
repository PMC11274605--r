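---
title: "Methods: models, statistics and design choices in pisar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, statistics and design choices in pisar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pisar)
```

## The measurement model

PISA (Proteome Integral Solubility Alteration) experiments heat aliquots of
the same cell suspension along a temperature gradient, pellet the
aggregates, and pool equal volumes of the soluble supernatants into a
single multiplexed channel. What the mass spectrometer quantifies for each
protein is therefore not a melting curve but its *integral* over the
gradient. `pisar` models the underlying per-proteoform melting behaviour as
a two-state sigmoid,

$$f(t) = p + \frac{1 - p}{1 + e^{k (t - T_m^{\mathrm{eff}})}},
\qquad T_m^{\mathrm{eff}} = T_m + \Delta T_m \cdot \mathbb{1}[\text{treated}],$$

and the pooled readout as the unheated abundance times the unweighted mean
of $f$ over the eight gradient temperatures (equal 20 µL volumes make the
pool an exact arithmetic mean). Two-state melting is the standard
assumption in thermal proteome profiling; nothing in a PISA design can
distinguish it from multi-state behaviour because only the integral is
observed, so the simulator treats it as exact and the analysis never fits
curves.

Numerical notes: the sigmoid is evaluated directly and is well behaved at
extreme slopes (`exp` overflow saturates to the plateau or to 1 without
producing `NaN`); the step-function limit at slope 50 /°C reproduces the
below-midpoint count over 8 to better than $10^{-3}$. The printed gradient
is *non-uniformly* spaced (gaps 2.0–4.4 °C), so the equal-volume pool is a
biased estimate of the continuous average of $f$ over [39.4, 61.4] °C — up
to ≈ 0.048 in absolute soluble fraction at slope 0.3. This is a property
of the assay design, not of the implementation; the test suite checks
agreement with fine quadrature at 0.05.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| gradient | 39.4 … 61.4 (8 points) | °C | the printed assay design |
| slope `k` | 0.3 | 1/°C | typical melt-curve steepness (transition width ~15 °C) |
| plateau `p` | 0.02 | fraction | small residual soluble pool |
| `Tm` | uniform(45, 57) | °C | gradient interior, matching published human meltome ranges |
| `|ΔTm|` | uniform(1.5, 5) | °C | ligand/PTM-scale shifts |
| `|log2 FC|` | uniform(0.5, 2) | log2 | moderate-to-strong abundance effects |
| channel CV | 0.1 | — | multiplicative lognormal reporter-ion noise |
| replicates | 4 | — | the study design (16-plex: 2 conditions × 2 assays × 4) |
| pseudocount | 0.1 | abundance | applied after normalization, before logs |
| alpha | 0.05 | — | raw-p threshold (protein, thermal); BH-adjusted threshold (RNA) |
| RNA |log2 FC| cutoff | 1 | log2 | transcript calls need both significance and magnitude |

## What the simulator emulates — and what it does not

`simulate_experiment()` draws exact effect sets (their sizes default to the
motivating study design: 3585 of 4890 proteins passing the identification
filter; 534 up / 458 down abundance effects; 91 stabilized / 44
destabilized; 2092 / 2611 transcript effects among 19051 genes, 3551 of
them shared with the proteome; 278 methyl-lysine sites on 247 parents with
16 / 24 occupancy effects, 2 / 3 proteoform-specific midpoint shifts), then
generates every channel as
`truth × 2^(effect if treated) × lognormal noise`, with PISA channels
additionally passed through the pooled melting model. Baselines are drawn
log-uniform over four orders of magnitude so normalization is exercised by
realistic dynamic range.

Transcript effects are coupled to protein effects through
$e_t = \rho\, e_p + \sqrt{1-\rho^2}\, \eta$ with $\eta$ drawn from the same
signed-uniform marginal as the protein effects; because $\eta$ is
independent with matched variance, the population correlation between
$e_t$ and $e_p$ over coupled genes is exactly $\rho$ regardless of the
effect-size distribution. Remaining transcript up/down quotas are filled
with independent effects on other genes, so truth-set sizes stay exact.
Methyl-peptide channels are `protein abundance × occupancy × peptide
ionization factor × noise`; modified proteoforms default to their parent's
midpoint shift but can carry their own (that is how a stabilized methylated
proteoform on an otherwise unshifted protein is constructed). One to three
peptides per site exercise the aggregation step; the simulator emulates the
*quantified* site layer only — peptide detection, spectra, FDR machinery
and antibody enrichment are outside its scope. Noise is independent per
channel; replicate-level batch factors, missing values, and count-based
(negative-binomial) transcript sampling are not modelled. Passing tests on
these simulations therefore demonstrates correctness of the statistics
under the stated noise model, not robustness to batch structure or
missingness in real data.

## Statistical conventions

All two-group tests are Welch t-tests on log2-transformed values:
abundances are approximately lognormal, and Welch is robust to unequal
variances; the fold change is reported on the linear scale as
mean(treated)/mean(control). Degenerate rows follow a fixed convention:
zero variance in both groups with equal means gives p = 1 (call
`unchanged`); zero variance with different means gives p = 0 — a noiseless
difference. This convention is what makes noise-free simulations behave
predictably, and it is why `stats::t.test` (which errors on constant data)
is used as a cross-check oracle rather than as the row-wise implementation.

The thermal layer divides each PISA channel by the global channel of the
same condition and replicate. The pairing is a design decision (the assay
description does not fix it): each PISA sample physically derives from the
same cells as its global sample, so replicate-matched ratios cancel both
the abundance effect and any shared sample-handling factor exactly. The
methyl-site stability layer uses the same replicate-matched convention.

The protein and thermal layers use *raw* p < 0.05 with no fold-change
floor, while the transcript layer uses BH-adjusted p < 0.05 plus
|log2 FC| > 1 — an asymmetry inherited deliberately from the workflow the
package reproduces. Users who want multiplicity control on the protein
layers can apply `p.adjust` to the exported p-values; the volcano export
retains `log2fc` for magnitude filtering.

Chi-square enrichment uses the Pearson statistic without continuity
correction (exposed as a flag), over the *quantified* background — all
filter-passing proteins, never the whole genome. Odds ratios use the
Haldane correction when a cell is zero; empty-margin tables report p = 1
with a `degenerate` flag. "Significant at the transcript or protein level"
is the union of the RNA-called and protein-called sets; "solely explained
by protein abundance" is interpreted as thermal ∧ protein ∧ ¬RNA — an
interpretation, recorded here, that reproduces the published overlap
arithmetic (94/135 = 70%, 66/135 = 49%, 41 thermal-only).

## Normalization placement

Protein tables are normalized so every sample column sums to the mean of
the original column sums (equal loading, no scaling), then the 0.1
pseudocount is added, in that order. Two consequences are worth knowing.
First, with unbalanced true effects the treated column totals genuinely
differ from control, so equal-total normalization shifts *null* features —
the familiar composition bias of total-intensity normalization; in
noise-free simulations this makes null features formally significant (any
nonzero difference with zero variance), so exactness tests assert complete
recovery of true effect sets rather than equality of call totals. Second,
because the normalization target is data-dependent and the pseudocount is
fixed, rescaling one sample changes every p-value by a small amount
(≲ 2% relative); categorical calls are invariant.

The methyl-peptide table is *not* normalized against its own column
totals: a 278-row PTM-focused table is dominated by a handful of
high-abundance sites whose genuine occupancy changes would rescale every
other site (measured in development: a coherent ~0.3 log2 bias producing
dozens of false calls). Instead the per-column factors estimated from the
bulk protein tables — the stand-in for total peptide amount — are applied
to the methyl-peptide columns, and they then cancel exactly in the
site-to-parent-protein ratio. Sites whose parent failed the protein filter
are still analyzed for stability (the peptide-internal PISA/global ratio
needs no parent) but are excluded from the occupancy sub-layer.

## Known limitations

- **Power at the design noise level.** With per-channel CV 0.1 the log2
  PISA/global ratio has sd ≈ 0.204, so the 4 vs 4 Welch test's standard
  error is ≈ 0.144 at ~6 df. A 3 °C midpoint shift moves the log2
  solubility integral by only ≈ 0.34 at `Tm` = 50 °C (less at higher
  midpoints), giving per-protein power around 0.5 — the simulator's
  recovery of 3 °C shifts is therefore ≈ 50–60%, with direction essentially
  always correct. Detecting small shifts at this noise level needs more
  replicates, lower CV, or midpoints in the steep low-temperature region.
- Composition bias of equal-total normalization, as above.
- The transcript test is a simplified two-sample test on log intensities
  with BH control, not a count-model (negative binomial) analysis.
- Gene-set enrichment is generic (user-supplied sets, chi-square with
  random-set controls); no ontology structure or term redundancy handling.

## Problem sizes used by the test suite

Unit tests run on scaled-down simulations (hundreds of features); the
calibration, confound, recovery and correlation checks use 2000–3585
proteins and 3551-gene transcriptomes at 4 replicates — the sizes at which
the rates they measure have standard errors comfortably inside the asserted
bounds. The acceptance script re-runs all of them from a single seed in a
few seconds.
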