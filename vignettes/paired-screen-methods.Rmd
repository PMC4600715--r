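---
title: "Methods: paired isogenic siRNA screen analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired isogenic siRNA screen analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedscreen)
```

## The problem

A genome-wide RNAi viability screen run in a *pair* of isogenic cell lines —
a patient-derived mutant line and the same line functionally corrected by
cDNA complementation — asks one question per gene: does knocking the gene
down kill the mutant line more than the corrected line? Genes that do are
synthetic-lethal partners of the mutation and candidate therapeutic targets.
The assay readout is a fluorescence viability signal (resazurin reduction)
per 384-well plate well, with one siRNA pool per gene per well, several
replicate screens per cell line, and a set of non-targeting control wells on
every plate.

Three nuisance structures stand between the raw fluorescence and that
question: plate-to-plate offsets (different library plates are read at
different times with different cell input), screen-to-screen offsets (whole
replicate screens differ in overall signal), and well-level noise. The
package removes the first two, models the third, and propagates the result
through hit calling, deconvolution confirmation, and a drug-panel
comparison.

## Normalization model

Raw intensities are log2-transformed and fitted with the additive two-factor
model

$$y_{psw} = \mu + \alpha_p + \beta_s + \varepsilon_{psw},$$

where $p$ indexes the library plate, $s$ the screen, and $w$ the well;
$\sum_p \alpha_p = \sum_s \beta_s = 0$. Estimation is ordinary least squares
(`fit_plate_screen_model()`), solved exactly through the
$(p+s-1)$-dimensional normal equations, so genome-scale data cost no more
than the cross-tabulation of plate-by-screen cell counts.

The normalized value is $\hat y = y - \hat\alpha_p - \hat\beta_s$ (the grand
mean is retained). Because the correction for a physical plate is the single
constant $\hat\alpha_p + \hat\beta_s$, every well of that plate shifts
identically: within-plate contrasts — including the mutant-versus-corrected
contrast of any siRNA, since the library layout is shared across screens —
are preserved bit-for-bit. No plate-by-screen interaction is fitted: an
interaction term would absorb genuine per-plate biology into the
normalization.

Choices a user can change, and why the defaults are what they are:

* **Fit wells** (`fit_wells`, default `"sample"`): positive-control wells
  are near-zero-viability outliers by design; including them would bias the
  offsets of the plates that carry them. Controls are still *shifted* by the
  fitted offsets.
* **Log base** (fixed at 2): the base cancels in every downstream ratio and
  test statistic, but it must be pinned down for reproducible effect sizes;
  log2 makes one unit one doubling.
* **No spatial correction**: no row/column/edge polish (B-score, loess) is
  applied or offered. Offering one silently would change hit lists; the
  analysis this package implements uses plate and screen main effects only.
* **Control-relative viability** (`normalize_to_controls()`): percent of the
  mean of the same-plate non-targeting controls, computed on the linear
  scale. Whether the input is raw or normalized intensities is a switch
  (`scale`), defaulting to raw.

One known attenuation is worth stating precisely: the screen offsets absorb
the *library-average* differential signal, so a planted differential effect
$\delta$ present in a fraction $f$ of genes is recovered as
$\delta(1-f)$ in expectation. At realistic scale ($f \le$ a few tenths of a
percent) this is negligible; the bias test in the suite runs at $f = 0.25\%$
where the attenuation (0.003 log2 units) is far below Monte-Carlo
resolution.

## Differential testing

With only two or three replicate screens per cell line, per-siRNA variance
estimates on 3–4 degrees of freedom are unusable directly; the package uses
the standard empirical-Bayes remedy: borrow strength across the ~20,000
siRNAs through a scaled inverse-chi-square prior on the true residual
variances.

* **Prior estimation** (`estimate_prior()`): moment matching on
  $z_g = \log s^2_g$. The prior degrees of freedom solve
  $\psi'(d_0/2) = \mathrm{var}(z) - \overline{\psi'(d_g/2)}$ by monotone
  root finding (trigamma is strictly decreasing), and the prior variance
  follows from the digamma mean relation. If the observed scatter of $z$
  does not exceed the expected chi-square scatter, $d_0 = \infty$ and all
  variances shrink completely to the bias-corrected geometric mean. The
  estimator agrees with `limma::fitFDist` to numerical precision, which the
  test suite uses as an independent cross-check; the implementation here is
  self-contained.
* **Moderated statistic** (`moderated_test()`):
  $\tilde s^2_g = (d_0 s_0^2 + d_g s^2_g)/(d_0 + d_g)$,
  $\tilde t_g = \Delta_g / \sqrt{\tilde s^2_g (1/n_- + 1/n_+)}$, referred to
  $t_{d_0 + d_g}$ (standard normal at $d_0 = \infty$). The effect
  $\Delta_g$ is the corrected-line mean minus the mutant-line mean of the
  normalized log2 values, so positive means more lethal in the mutant.
  Unbalanced designs (2 v 3 screens) use the pooled form; no Welch
  correction, matching the linear-model framework the moderated t comes
  from.
* **Two-sided p, directional selection**: p-values are two-sided;
  `select_hits()` applies the direction filter afterwards
  (`mutant_lethal` keeps $\Delta_g > 0$), reporting wrong-direction
  exclusions separately. This mirrors how such screens are actually
  curated — significance both ways is computed, then the uninteresting
  direction is dropped with an audit count.
* **FDR**: Benjamini–Hochberg step-up via `stats::p.adjust`, gated
  *inclusively* at $q \le 0.10$ (a q-value of exactly 0.10 is selected).
  Manual curation steps — annotation-based exclusions, near-threshold
  cherry-picks — are user-supplied label sets applied by `curate_hits()`,
  never computed.

Degenerate inputs: siRNAs with zero sample variance are excluded from prior
*estimation* (log 0 is undefined) but still shrink toward $s_0^2$; siRNAs
missing from one cell line are excluded from testing with a logged count
rather than silently dropped.

## Deconvolution confirmation

Pooled-siRNA hits are retested with the four constituent siRNAs
individually. Per siRNA, mean control-relative viabilities across the
replicate experiments give the differential ratio
$R = v_+ / v_-$ and the toxicity $T = 100 - v_+$ (percent death in the
*corrected* line — deliberately not $100 - \min(v)$, since $T$ exists to
flag generic toxicity, which the corrected line measures). A siRNA passes at
$R > 2$ and $T < 50$, both strict as printed in the criterion this
implements; a gene is confirmed when at least 2 of its 4 siRNAs pass
(`confirm_genes()`, thresholds configurable). Means are taken *before*
forming $R$ and $T$; per-experiment values are retained for audit. A
mutant-line viability of exactly zero yields an infinite ratio with a flag,
not an error — biologically it is total kill in the mutant only.

## Drug-panel comparison

For a panel of lines with known cohesion status, sensitivity to a drug is
expressed per division: $n_{div} = \log_2(v_{untr}/v_{t0})$ from the
untreated arm, $GI = 100(1 - v_{tr}/v_{untr})$, and the division-corrected
sensitivity is $GI / n_{div}$. The quotient form is the simplest reading of
"corrected for the number of divisions" that makes fast- and slow-growing
lines comparable; it is the package's own definitional choice, surfaced in
the documentation and swappable in principle without touching the group
test. Lines with $n_{div} \le 0$ have no defined per-division sensitivity
and are excluded from group tests with a warning. Groups are compared with
the Wilcoxon rank-sum test: exact by full enumeration when the combined
sample is at most 12 with no ties, mid-ranks plus the tie-corrected normal
approximation otherwise, with the path reported.

## The synthetic-data generator

`simulate_screen()` inverts the analysis model: log2 intensity is
$\mu + \alpha_p + \beta_s + \gamma_g - \delta_g\,1[\text{mutant}] +
\varepsilon$, emitted on the linear scale. Structure (which genes are
lethal, which are synthetic-lethal, the planted offsets) is drawn under
`truth_seed`; well noise under the `seed` argument — so truth tables are
stable across noise replicates and paired power curves are possible.

Default conditions, chosen once to mirror the emulated study design and
held fixed:

* 384-well plates, 8 non-targeting and 2 strong positive-control wells per
  plate, 20,000 genes (54 plates), 3 screens per line (2 v 3 available as an
  override);
* $\mu = 14$ (≈16,000 RFU), $\sigma_{plate} = 0.5$,
  $\sigma_{screen} = 0.25$, $\sigma_{well} = 0.3$ log2 units — a ~23%
  well-level CV, typical of resazurin viability screens;
* 5% of genes lethal in both lines (half-normal magnitudes around 1 log2
  unit), 50 synthetic-lethal genes at $\delta = 3\sigma_{well} = 0.9$;
* the deconvolution generator (`simulate_deconvolution()`) draws per-siRNA
  knockdown efficiencies $\kappa \sim U(0.3, 1)$, half-normal off-target
  kill (sd 0.25 log2), multiplicative measurement noise of 0.1 log2 per
  reading, and defaults to a differential effect of 2.0 log2 units for true
  genes — the 4-fold differential killing a validated strong hit shows.
  This is deliberately larger than the primary screen's marginal planted
  effect: rescreens retest *selected* hits, and the confirmation rule
  ($R > 2$) cannot mathematically be met below $\kappa\delta = 1$.

What the generator does **not** emulate: spatial edge/gradient artifacts,
well-to-well crosstalk, off-target seed-sequence structure, cell-cycle or
mitotic-fate dynamics, and any non-multiplicative (additive-on-linear)
noise. Passing tests therefore certify the statistical pipeline under its
own model assumptions, not robustness to those artifacts on real plates.

### What detection power these conditions imply

With one well per siRNA per screen and 3 v 3 replicates, the standard error
of the group contrast is $\sigma_{well}\sqrt{2/3} \approx 0.82\,\sigma_{well}$,
so a planted $\delta = 3\sigma_{well}$ sits at a noncentrality of ~3.7.
Against the BH-adaptive two-sided threshold at $q \le 0.10$ with tens of
discoveries among 20,000 tests (an effective $|z|$ cut near 3.7–3.8), the
expected recovery of such genes is roughly 30–50%, not near-complete
recovery; near-complete recovery at this design requires $\delta \gtrsim
4\sigma_{well}$ or more replicates. The acceptance suite measures this
recovery rate honestly at the default conditions; the deconvolution stage,
operating at confirmed-hit effect sizes with efficient siRNAs, is where
near-complete recovery is expected and observed.

## Numerical choices

* Offsets are estimated by exact OLS on the reduced normal equations;
  sum-to-zero holds to the accumulation error of the solve (tested at
  1e-9).
* The applied per-plate correction $\hat\alpha_p + \hat\beta_s$ is
  quantized to a multiple of $2^{-40}$ (≈9e-13 log2 units) before
  subtraction. Subtracting a full-precision constant rounds differently
  from well to well (1-ulp wobble), which would break the exact
  contrast-preservation guarantee; on the coarser grid the subtraction is
  exact in IEEE arithmetic for all realistic log2 intensities, so
  within-plate differences are preserved bit-for-bit. The quantization
  error is ten orders of magnitude below the well noise.
* Prior root finding brackets $d_0/2$ in $[10^{-8}, 10^{10}]$ on the log
  scale; uniroot tolerance `.Machine$double.eps^0.5`.
* Ties in p-values receive identical q (BH is rank-based with stable
  ordering); written tables sort ascending by q then p with lexicographic
  tie-break, so output is byte-deterministic.
* On-disk numeric round trips use 17 significant digits ("%.17g"), lossless
  for IEEE doubles.
* $p = $ exactly 2 or $T = $ exactly 50 in the confirmation rule fail, as
  the strict printed inequalities require.

## Problem sizes used in the checks

The packaged checks run the genome-scale configuration (20,000 genes, six
384-well screens) where the property is about scale — FDR calibration over
200 null screens, prior recovery over 20,000 variances — and desk-scale
configurations (hundreds of genes) elsewhere; these sizes are the package's
own validation design.

## Limitations

* The normalization assumes main effects only; confounding of plate effects
  with biology (e.g. functionally clustered library plates) is not
  detectable from within the model.
* The moderated test assumes a common variance per siRNA across cell lines
  (pooled form); strongly heteroscedastic pairs are not Welch-corrected.
* The deconvolution confirmation rule is a fixed-threshold decision, not an
  error-controlled test; its specificity at the default noise is measured
  by simulation, not guaranteed.
* Curation (`curate_hits()`) is bookkeeping for human decisions; the
  package does not reproduce annotation-based exclusions computationally.
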