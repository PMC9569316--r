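---
title: "Models and methods behind secshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind secshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secshift)
```

`secshift` analyses two complementary proteome-wide readouts of
interactome rewiring across growth-phase transitions — size-exclusion
co-fractionation (CF-MS) and single-temperature thermal shift assays
(iTSA) — and ships a synthetic-data generator with programmed ground truth
so that every statistical claim the pipeline makes can be checked against
a known answer. This vignette documents the models, the tunable
parameters, the numerical choices, and what a passing test does and does
not establish.

## The measurement models

### SEC co-fractionation

Native lysate is fractionated on a size-exclusion column into
`n_fractions` (default 60) fractions ordered by decreasing molecular size;
the first `protein_fraction_count` (default 40) contain protein, spanning
the calibrated range of roughly 5 MDa at fraction 1 down to 20 kDa at
fraction 40. The map from fraction index \(f\) to apparent mass is
log-linear,

\[ \log_{10} M(f) = a + b f, \qquad b < 0 , \]

fit by least squares to reference standards (`fit_mw_calibration`). A
protein in oligomeric state \(s\) with assembly mass \(M_s\) elutes as an
approximately Gaussian band centred at the fraction implied by the
calibration; a multi-state protein is a mixture of such bands weighted by
its mixing fractions. Metabolites partition into a *bound* pool that
co-elutes under the partner protein's bands (fractions 1–40) and a *free*
pool forming a low-molecular-weight band in fractions 41–60; the bound
fraction \(\beta \in [0,1]\) is the programmed quantity the bound/free
ratio \(\beta/(1-\beta)\) recovers.

### iTSA

Soluble intensity after heating to temperature \(T\) follows a logistic
melting curve

\[ I(T) = A \cdot \frac{1}{1 + e^{k (T - T_m)}} \cdot \varepsilon , \]

with abundance \(A\), midpoint \(T_m\), slope \(k > 0\) and multiplicative
noise \(\varepsilon\). Room temperature (internally 22 °C, rendered "RT"
in files) is measured without thermal loss, \(I_{RT} = A \varepsilon\), so
the stability ratio at the midpoint is exactly 0.5. The assay is a
single-temperature shift design: full melting-curve (Tm) fitting is
deliberately out of scope.

## Statistical machinery

**Median normalization.** Every sample is rescaled so its median intensity
(over positive values; zeros are treated as missing) equals the global
median, defined as the median of the per-sample medians. A published
formulation of this step multiplies by sample-median over global-median,
which would amplify rather than remove loading differences; `secshift`
divides by the sample median so that post-normalization medians equalize
exactly, which is the stated purpose of the step.

**Differential testing.** All differential calls (abundance, stability,
metabolite totals) share one engine: two-sided two-sample t-test (Student
pooled-variance by default, Welch behind `var_equal = FALSE`) on log2
intensities, Benjamini–Hochberg FDR across all testable features, fold
change from the ratio of linear phase means, and a call when
\(q < \alpha_{FDR}\) **and** \(|\log_2 FC| > \log_2 2\). Zeros are treated
as missing; features with fewer than two usable replicates per group are
flagged untestable and excluded from the FDR adjustment. The t statistic
is computed vectorized from the closed-form formula; equivalence with
`stats::t.test` is asserted in the unit suite.

**Thermal stability.** Within each temperature group the samples (phase ×
replicate) are median-equalized as above; stability is the normalized
intensity divided by the normalized RT intensity of the same
protein/phase/replicate, making RT stability identically 1. Differential
thermal stability is called independently at each elevated temperature and
reported as the union across temperatures (default FDR 0.01; an
alternative 0.05 convention circulates for this assay, so the threshold is
an argument, not a constant).

**Differential fractionation.** Profiles are *processed* —
replicate-aggregated, normalized to maximum, rescaled to unit sum — so the
Manhattan distance (MD) between two phases lies in \([0, 2]\) and is
scale-free. Within one pairwise comparison, a molecule is differential
when its MD exceeds 1.5 × the median MD of all molecules compared; the
median is computed per comparison, not globally. Molecules detected in
only one phase are routed to presence/absence and excluded from the
median. For replicated profiles a permutation *dis-elution surrogate* is
provided: the score is the MD between replicate-mean processed profiles,
and the p-value is the add-one-smoothed fraction of replicate-label
reassignments scoring at least as high (exhaustive when the number of
splits fits the permutation budget, seeded sampling otherwise). It is a
surrogate: the published tool it stands in for is not reimplemented, and
outputs are labelled accordingly.

**Peak deconvolution.** Local maxima are detected on the raw profile
(optional 3-point smoothing is off by default because the upstream method
does not state smoothing), with plateau ties resolved to the leftmost
fraction; maxima closer than `min_separation` (default 2) fractions to a
retained higher maximum are suppressed to kill single-point jitter;
retained maxima must reach `min_rel_height` (default 10 %) of the main
maximum; boundaries sit at the deepest minimum between adjacent apexes,
with the boundary fraction assigned to the left peak so subprofiles
partition the retained signal.

**Networks.** Pearson correlations are computed between peak
*subprofiles* over the union of the two peaks' fraction ranges — peaks,
not whole profiles, carry the co-elution signal of individual oligomeric
states. Edges are kept at PCC ≥ 0.7 ("greater than 0.7" and "0.7 or
higher" both circulate; ≥ is implemented). Louvain community detection
runs on the thresholded graph with PCC weights, seeded and with node order
canonicalized so partitions are reproducible; isolated peaks become
singleton communities. The interaction rate between a dipeptide group and
a pathway is \(100 \cdot n_{\text{interactions}} /
(n_{\text{dipeptide peaks}} \cdot n_{\text{protein peaks}})\); proteins in
several pathways contribute their peaks to each pathway's denominator
independently. Dipeptide grouping consumes a user-supplied chemical
distance matrix (Ward's minimum-variance method, `ward.D2`, cut at height
1.6 by default); computing chemical fingerprints is out of scope.

## The synthetic world

The generator programs a world and the simulators render it with noise:

| parameter | default | why |
|---|---|---|
| `n_fractions` / `protein_fraction_count` | 60 / 40 | the SEC geometry of the assayed separation |
| phases | glucose, ethanol, early_stationary | the diauxic-shift time course |
| temperatures | RT, 48, 52, 56 °C | the iTSA design |
| replicates | metabolite 3, protein profile 1, iTSA 5, abundance 5 | the stated experimental replicate structure |
| `noise_sigma` | 0.1 | log-scale SD of multiplicative log-normal noise; MS intensity noise is scale-dependent, and 0.1 is the level at which the recovery criteria are posed |
| `peak_width_fractions` | 1.5 | SEC bands are approximately Gaussian with a few-fraction footprint |
| `free_peak_width` | 2.5 | the free-pool band is broader than a protein band |
| melting midpoints | N(52, 2) truncated to [46, 58] | centred in the assayed 48–56 °C window |
| bound/free odds centres | 0.02 / 0.026 / 0.147 per phase | the observed phase medians of the bound/free ratio, treated as the world's state |
| abundances / totals | log-normal, sdlog 1 | typical MS dynamic range |

Rewiring is programmed per protein, independently for fractionation
(complex disassembles to its monomer in the last phase) and stability
(+4 °C midpoint shift in the last phase), each with probability
`rewire_rate`. With zero noise the simulators conserve programmed amounts
exactly (profile sums equal totals to 1e-9), place apexes exactly at the
calibrated fractions, and halve the RT ratio exactly at the midpoint —
these identities anchor the oracle tests.

**What the generator does not emulate:** peptide-level quantification,
isotope patterns, chromatographic tailing, correlated noise between
adjacent fractions, missingness beyond a hard detection limit, partial
complex occupancy, or metabolites with several partners. A green recovery
test therefore establishes that the statistics recover the programmed
structure under idealized Gaussian-band, log-normal-noise conditions — not
that they would perform identically on real chromatograms.

## Numerical choices and degenerate inputs

* All-zero profiles raise a degenerate-profile error rather than returning
  NaN; presence/absence is the intended route for undetected molecules.
* A metabolite with zero free pool but positive bound pool gets a
  pseudo-denominator (the smallest positive free sum in the dataset) and
  an explicit flag; dropping such metabolites would bias ratio medians.
* Constant peak subprofiles are skipped in correlation (zero variance) and
  counted in an attribute.
* Identical-phase Wilcoxon comparisons return p = 1 by convention (the
  test statistic is undefined when all paired differences are zero).
* Seeds: every stochastic step (generation, simulation, permutation,
  Louvain) takes an explicit integer seed; derived seeds stay below
  \(2^{31}\).

## Design decisions that were genuinely open

* **Aggregation before the 10 % rule.** Whether peak filtering applies per
  replicate or to replicate-aggregated profiles is unstated upstream;
  `secshift` deconvolves aggregated (processed) profiles, which is less
  noise-sensitive.
* **Manhattan vs dis-elution for proteins.** Single-replicate protein
  profiles cannot support a permutation p-value, so proteins are called by
  the MD criterion and the permutation surrogate is reserved for
  replicated (metabolite) profiles; both are exposed.
* **Config documents are JSON**, not YAML: no YAML parser is available in
  the target environment, and `jsonlite` round-trips the configuration
  losslessly.

## Known limitations

* **Median equalization under broad change.** Equalizing per-temperature
  sample medians assumes most proteins are unchanged. When a large share
  of the proteome genuinely shifts stability (as in the simulated worlds
  with `rewire_rate = 0.2` and strong sigmoid effects, or in a real
  transition where half the proteome moves), the equalization rescales
  *every* protein in the affected phase and differential-stability calls
  spread far beyond the truly shifted set. This is a property of the
  normalization itself, reproduced faithfully; interpret union-set sizes
  accordingly.
* **Permutation floor at triplicates.** With 3 vs 3 replicates there are
  only \(\binom{6}{3} = 20\) label splits and the observed split plus its
  mirror always score at least the observed score, so the smoothed
  dis-elution p-value can never fall below \(3/21 \approx 0.14\).
  Sub-0.05 significance requires at least 4 replicates per phase; with
  triplicates the score ranking, not the p-value, is the informative
  output.
* The dis-elution surrogate is not numerically interchangeable with the
  published tool it stands in for.
* Ward grouping expects a meaningful chemical distance matrix from the
  caller; no fingerprinting is performed.
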