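---
title: "Methods: Poisson partition quantification of BCR/ABL1 MRD by ddPCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Poisson partition quantification of BCR/ABL1 MRD by ddPCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmrd)
```

## The measurement model

Droplet digital PCR partitions a reaction into on the order of 20,000
nanolitre droplets and amplifies each independently. Template molecules land
in droplets at random, so the copy number per droplet is Poisson with mean
$\lambda = C \, V_d$, where $C$ is the reaction concentration in copies/µl
and $V_d$ the droplet volume in µl. A droplet is positive when it received at
least one copy, hence the positive fraction estimates $1 - e^{-\lambda}$ and,
with $k$ positive of $n$ accepted droplets,

$$\hat\lambda = -\ln(1 - k/n), \qquad \hat C = \hat\lambda / V_d .$$

Assumptions worth stating: droplet volumes are equal and known; partitioning
is independent of template identity; a single copy always amplifies to a
detectable endpoint signal. Violations (volume dispersion, partial
amplification) bias $\hat C$ multiplicatively and cancel in the MRD ratio to
the extent they affect target and control alike.

MRD is the ratio $(C_\text{target}/C_\text{control}) \times 100$, with ABL1
as the control gene. A cDNA predilution common to both genes cancels in the
ratio; the pipeline records the factor (`dilution_factor`) but deliberately
never multiplies it back in, since diagnostic-scale tables are conventionally
reported on the measured scale of the diluted material.

## Confidence intervals and degenerate inputs

The 95% interval on $\hat C$ comes from the exact Clopper–Pearson binomial
interval on $p = k/n$, transformed through the monotone link
$\lambda = -\ln(1-p)$. MRD samples live at $k$ of 0–10, exactly where Wald
and score intervals undercover; the exact interval is conservative but never
anti-conservative, which is the right failure mode for a clinical
interpretation. At $k = 0$ the lower bound is exactly zero. At $k = n$ the
model saturates: no finite estimate exists, the result is flagged
(`saturated = TRUE`) with an infinite point estimate and upper bound rather
than clipped to some large number — saturation is a design problem (dilute
the input), not a numerical one. `k > n` and `n = 0` are rejected as
validation errors naming the offending well.

Monte-Carlo behaviour (recomputed by the test suite and
`scripts/acceptance.R`): merged-triplicate estimates at 0.1–100 copies/µl are
unbiased well within 2% at $C \ge 1$, and pooled interval coverage sits in
the 95–97% range typical of exact intervals. Problem sizes — 500 merged
triplicates per concentration, 2,000 replicates per limit-of-detection point
— were chosen as the smallest runs whose binomial 3-SD bands are tight enough
to be informative.

## Replicate merging

Replicate wells of one sample and target are merged by **pooling
partitions**: $k_\text{merged} = \sum k_i$, $n_\text{merged} = \sum n_i$.
This is equivalent to treating the replicates as one large well and is
strictly preferable to averaging per-well estimates at trace level, where
individual wells frequently contain zero positives and the mean of per-well
estimates is biased toward zero with higher variance (the test suite checks
the RMSE ordering by simulation). Merging first is canonical: all
classification is defined on merged counts, which makes calls invariant to
how the same droplets were split across wells.

## Quality control and thresholding

* Wells with fewer than 9000 accepted droplets are rejected (boundary
  inclusive: 9000 passes). The bound is a manufacturer-style acceptability
  floor; `min_droplets` is configurable.
* Amplitude thresholding (`call_droplets()`, when per-droplet fluorescence is
  available) replaces manual curation with a reproducible rule: the
  background mode is located by a twice-iterated median/MAD estimate and the
  threshold set `k_sigma` (default 5) robust SDs above its centre. The
  threshold is returned for audit. The default assumes separable clusters;
  heavy rain between clusters will inflate calls and should be inspected.
  Fewer than 100 droplets is refused — the background spread cannot be
  estimated.
* Run validity requires every background well (NTC, healthy-donor pool,
  Ph-negative sample) clean — at most `max_background_positive` positive
  droplets in total, default 0 — and every plasmid-standard well positive.
  Background subtraction is not performed; tolerating background positivity
  (`max_background_positive > 0`) warns that classification thresholds would
  need re-derivation.

## POS / PNQ / NEG interpretation

Classification follows parameterised EuroMRD-style rules on merged counts:
NEG below `min_positive_droplets_detected` (default 1), PNQ when detected but
below `min_positive_droplets_quantifiable` (default 3) or when the control
gene is under `min_control_copies`, POS otherwise. The three-positive-droplet
quantifiability default mirrors common digital-PCR practice of requiring at
least three positive partitions; every threshold is a config knob
(`read_rules()` reads them from YAML) because consortium guidance is
versioned and laboratories calibrate locally. A sample whose control gene is
inadequate is never silently NEG: it carries `evaluable = FALSE` (and at best
PNQ when the target is detected), avoiding false reassurance.

The class order NEG < PNQ < POS is monotone in the merged positive count for
any fixed control and rules — a property the test suite enforces.

## Limit of detection, specificity, reproducibility

The LOD design escalates replicates down a dilution ladder: 2, 6, 8, 12 and
14 replicates at nominal dilutions $10^{-4}$, $5\times10^{-5}$, $10^{-5}$,
$5\times10^{-6}$, $10^{-6}$ of a plasmid standard. A replicate is positive at
one or more positive droplets. **Maximum sensitivity** is the most dilute
point such that it and every less-dilute point have ≥75% positive replicates
— the rule is cumulative from the top, so an isolated deep positive point
does not qualify. On the packaged reference outcomes (2/2, 6/6, 6/8, 2/12,
2/14) this returns $10^{-5}$; the two positive replicates at each deeper
point are reported as-is, and "reached sensitivity" beyond the 75% label is
left to the user's interpretation, since no sharper criterion distinguishes
those points.

Two copies-per-well labelings of the ladder ship with the design: the stated
copy counts (10, 5, 2, 1, 0.5) and a proportional mapping (10, 5, 1, 0.5,
0.1) that follows the dilution-label arithmetic relative to the 10-copy
standard point. The two disagree below $5\times10^{-5}$ and the source
material does not resolve which was pipetted; the proportional mapping is the
simulator default because it is self-consistent with the labels, and both are
carried in the fixture so either can be selected.

Specificity counts background replicates with any positive droplet over the
dedicated panel (32 NTC + 4×16 donor-pool replicates). Reproducibility of
paired estimates uses the strict one-logarithm rule
$|\log_{10} a - \log_{10} b| < 1$ rather than same-integer-decade, which
would absurdly call (9.9, 10.1) irreproducible; (0, 0) pairs are
reproducible, and (0, >0) pairs form a separate *discordant detection*
category since no log distance exists.

## Paired-method comparison

`mrd_crosstab()` builds the 3×3 POS/PNQ/NEG table (rows ddPCR, columns
Q-RT-PCR). Overall concordance is the diagonal percentage; quantifiability
recovery is the share of comparator-PNQ-or-NEG samples that ddPCR quantifies.
Percentages are reported both at one decimal (half-away-from-zero) and
nearest-integer, because both conventions appear in published tables (13/24
is 54.2% at one decimal and 54.1666…% exactly — the package reports the exact
fraction and both roundings rather than choosing one).

The significance of the quantifiability gain is tested by an **exact paired
(McNemar-type) test**: collapse to quantifiable-vs-not, take discordant
counts $b$ (ddPCR-only) and $c$ (comparator-only), and compute the two-sided
exact binomial $p = \min(1,\, 2\,P(X \le \min(b,c)))$,
$X \sim \mathrm{Bin}(b+c, 1/2)$; $b+c=0$ gives $p=1$. The paired exact test
is the defensible choice for 88 paired measurements; a continuity-corrected
chi-square variant is provided as a secondary option and both reject far
below $10^{-4}$ on the reference table. For the Pearson correlation of
diagnostic values the default pairing gives a dual-transcript sample one pair
per transcript (11 pairs from 10 samples); summing its transcripts into a
single pair is available (`pairing = "aggregate"`) and documented as the
minority reading.

## The synthetic-data generator

The generator produces droplet-level data with exactly the structure the
analysis assumes: accepted-droplet counts as a rounded Gaussian truncated at
1 (20,000 ± 1,500 by default — real runs are only bounded below, via QC);
droplets positive independently with probability $1 - e^{-C V_d}$; optional
false-positive *rain* as an independent per-droplet flip (default 0, matching
the observed clean backgrounds); two well-separated Gaussian amplitude
clusters. LOD experiments draw Poisson($m$) molecules per replicate, of which
Binomial($\cdot$, ρ) land in read droplets — ρ, the partitioned fraction
(default 0.8), reflects that droplet generation and reading never capture the
whole reaction; with ρ = 1 the replicate-positivity law is exactly
$1 - e^{-m}$, the closed form the validation tests check against. Cohort
simulation draws true MRD ratios from a four-level mixture (high 1–100%, low
0.01–1%, trace 0.0005–0.01%, zero) with log-normal ABL1 concentrations
(median 200 copies/µl), and generates the comparator call from a simple
threshold model: quantifiable at or above the quantification limit (0.01% by
default), otherwise detected — hence PNQ — with probability
$1 - e^{-\text{copies sampled}}$. The mixture defaults were chosen once to
put most samples in the PNQ-relevant trace/low range, mirroring a follow-up
cohort rather than a diagnostic one.

What the generator does **not** emulate: fluorescence drift and rain
continua between clusters, droplet coalescence or volume dispersion, chip
failure modes, inhibition, and any real generative model of Q-RT-PCR (the
comparator model is an artifact construct — no such model is published for
the assay). Passing tests therefore demonstrate the pipeline's correctness
under the Poisson partition model and its robustness rules, not performance
on instrument quirks outside that model.

All generators take explicit seeds (per config or per call), restore the
caller's RNG state, and are bit-reproducible from the seed.

## Known limitations

* $V_d$ is a global constant per run (0.85 nL default); no per-well
  volumetric correction.
* No probit/logistic LOD95 curve fitting — the LOD here is the rule-based
  replicate-positivity criterion, by design.
* Transcript targets only (p190/p210 vs ABL1); IG/TR rearrangement MRD is
  out of scope.
* The classifier defaults stand in for consortium supporting documentation
  that is not reproduced here; laboratories should set `classification_rules()`
  to their accredited thresholds.
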