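---
title: "Melting-curve models and stability calling in crowdTPP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melting-curve models and stability calling in crowdTPP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdTPP)
```

# The measurement and the model

Thermal proteome profiling heats aliquots of a lysate to a gradient of
temperatures (ten points, 30–70 °C, in the design this package targets),
removes aggregated protein, and quantifies what remains soluble with TMT
reporter ions. For each protein and condition the quantity modelled is
the fold change FC(T) = I(T)/I(T~ref~) against the lowest (reference)
temperature, produced by `normalizeToReference()`. The reference fold
change is 1 by construction; a protein whose reference intensity is
missing or non-positive cannot be normalized and is carried through with
reason code `no_reference` rather than dropped silently.

Fold-change curves are described by a three-parameter sigmoid,

$$ f(T) = \frac{1 - p}{1 + e^{\,b - a/T}} + p, $$

with $T$ in degrees Celsius, shape parameter $a > 0$ (degree-scaled),
offset $b > 0$, and post-transition plateau $p \in [0, 0.5)$ — the
residual soluble fraction at high temperature. The curve is strictly
decreasing for $a > 0$ and bounded in $(p, 1)$. Two closed forms follow:

* melting point: $T_m = a / (b + \ln(1 - 2p))$, the temperature at which
  half the protein remains soluble (`meltingPoint()`), defined only when
  $p < 0.5$ and $b + \ln(1-2p) > 0$;
* slope: the analytic $df/dT$ at $T_m$ (`meltSlope()`), always negative,
  equal to $-a/(4 T_m^2)$ when $p = 0$.

Two conventions are open in this model family and were fixed as follows.
Temperatures enter in °C, not Kelvin, for parity with established TPP
curve fitting. "Slope" is defined at $T = T_m$ rather than at the true
inflection of $f$ in $T$; the two are close for these curves and the
$T_m$ convention gives a closed form that pairs naturally with the QC
threshold.

The model describes *irreversible* thermal aggregation as captured by a
filtration assay. No reversible two-state thermodynamics (van 't Hoff
enthalpies, $\Delta G$ of unfolding) is attempted: the assay does not
measure them.

# Fitting and numerical choices

`fitMeltCurve()` estimates $(a, b, p)$ by bounded Levenberg–Marquardt
least squares (via `minpack.lm`), with bounds $a, b > 0$ and
$p \in [0, 0.49]$, relative convergence tolerance $10^{-8}$ and at most
5000 function evaluations. Initialization is deterministic: $p_0$ from
the smallest observed fold change (clipped to $[0, 0.3]$), $T_{m,0}$
from the temperature whose fold change is nearest 0.5 (falling back to
the median temperature), $b_0 = 10$, $a_0 = b_0 T_{m,0}$.

A single start is not reliable for steep transitions: curves whose true
$b$ is large (25–40, i.e. transitions a few degrees wide) have a local
least-squares optimum near $b \approx 10$ in which the optimizer reports
success while misplacing $T_m$ by over a degree. The fitter therefore
re-runs from a deterministic multistart grid
($b_0 \in \{5, 10, 15, 25, 40\}$, $p_0 \in \{0, 0.1, 0.2\}$, keeping the
lowest residual sum of squares) whenever the first attempt either fails
to converge or leaves more than 2% of the curve variance unexplained.
Fewer than five finite points, or inputs the optimizer cannot handle,
yield a non-converged NaN fit instead of an exception, so proteome-wide
loops never abort. Goodness of fit is $R^2 = 1 - SS_{res}/SS_{tot}$ on
the fold changes.

Quality control mirrors the highest-stringency conventions of
established TPP analysis and is applied pairwise (`passesQC()`): both
the control and treatment fits must reach $R^2 \ge 0.8$, the control
plateau must stay below 0.3, and both slopes must be at most $-0.06$ per
°C. All three thresholds are configuration knobs (`qcCriteria()`), and
every failed criterion is named in the reason codes rather than
collapsed into a single flag.

# Stability calling

For each treatment, $\Delta T_m = T_m^{treat} - T_m^{ctrl}$ is computed
over QC-passing pairs (positive = stabilized by the crowder) and
standardized *within that treatment*: $z = (\Delta T_m - \bar x)/s$ with
the sample ($n-1$) standard deviation. The reference population is all
proteins with QC-passing control and treatment fits in that treatment —
the natural per-column standardization for a treatment-by-protein
z-score map. Calls use inclusive boundaries: $z \ge 1.96$ stabilized,
$z \le -1.96$ destabilized, otherwise null. The threshold corresponds to
a two-sided normal $\alpha$ of 0.05; no multiple-testing correction is
applied by default, matching the z-threshold convention this rule
implements (a Benjamini–Hochberg option exists in
`keywordEnrichment()` for the annotation analyses, where it belongs).

Because z-scores are location-invariant, adding a constant to every
$\Delta T_m$ of a treatment changes no call: the method detects
*relative* outliers within a treatment, not absolute shifts. Degenerate
inputs (fewer than three finite $\Delta T_m$, or zero variance) raise an
error rather than fabricating calls.

`concordanceSummary()` reduces calls across crowders to per-protein
counts and direction profiles; a protein significant in both directions
across different crowders is labelled `mixed`.

# Dataset-level QC analytics

* `spearmanMatrix()` — pairwise rank correlations with average ranks for
  ties and pairwise-complete observations; pairs sharing fewer than
  three finite values return `NA` with a warning.
* `pcaVariance()` — PCA with samples as observations (proteins as
  variables) by default, complete-case rows, and a fixed sign convention
  (largest-magnitude loading positive) so results are deterministic
  across BLAS implementations. Variance fractions always sum to 1;
  rank-deficient data simply produce trailing zero-variance components.
* `compareParamDistributions()` — Mann–Whitney U, exact for both sizes
  ≤ 8 without ties, tie-corrected normal approximation otherwise.
* `aggregatedFractionProfile()` — per-temperature mean aggregated
  fraction $1 - FC$ with per-entry clipping to $[0,1]$; apparent
  over-recovery ($FC > 1$) contributes zero to the clipped mean and is
  visible in the raw mean reported alongside.

# Mechanism regressions

`stabilitySummaryPerCrowder()` reduces QC-passing fits to one scalar per
crowder — mean $T_m$ (default), mean $\Delta T_m$, or median
$\Delta T_m$ — always over the intersection of proteins passing QC in
every condition, so crowders are compared on identical support. Which
summary the mechanism question "melting temperature vs reagent
properties" should use is genuinely open; all three modes are exported
side by side and `mechanismAnalysis()` reports each. Ordinary least
squares against each numeric reagent descriptor yields slope and $R^2$
(identically the squared Pearson correlation, hence invariant to affine
changes of descriptor units). With six crowders every regression carries
a `small_sample` flag; these are descriptive contrasts between the
crowding/viscosity account (molecular weight, mass concentration,
intrinsic viscosity) and the preferential-exclusion account (polar atom
fraction, hydrophobicity index), not hypothesis tests. Descriptor values
are user-supplied through `readCrowderProperties()`; the package invents
no defaults for reagent chemistry.

# Sequence features and enrichment

`gravy()` implements the Kyte–Doolittle grand average of hydropathy;
`proteinMw()` sums average (or monoisotopic) residue masses plus one
water. Unknown residues are skipped with a warning (GRAVY) or are an
error unless explicitly skipped (mass). `keywordEnrichment()` replaces
hosted annotation-enrichment services with a self-contained Fisher exact
test per keyword (two-sided by default) and Benjamini–Hochberg q-values;
the background universe should be the QC-analyzable protein set, not the
whole proteome, so the contrast is "affected vs measurable". Aromaticity
and the aliphatic index are provided as optional negative-control
properties; the instability index is not implemented.

# The synthetic experiment generator

`simulateTppExperiment()` emulates the targeted study design: 300
proteins (default), the ten-temperature gradient, one control plus six
crowders, and per-protein sigmoid melting with multiplicative
log-normal reporter noise (CV 5% default). Control curves draw
$T_m \sim N(52, 5^2)$ °C (kept inside the gradient), plateau
$\sim U(0, 0.25)$, and slope $\sim U(-0.12, -0.07)$ per °C — transition
steepnesses typical of well-behaved melting curves that satisfy the
stringency QC, since QC-passing proteins are the analysis substrate the
generator is meant to exercise. Per protein–crowder pair a true class is
drawn (3% stabilized, 3% destabilized by default; an optional
`leftSkewBias` adds excess destabilization to mimic the slight downward
skew of crowded-lysate melting points), and a true shift magnitude from
$N(5, 1^2)$ °C truncated below at `shiftMin = 3` °C. Truncation keeps
the truth labels meaningful: a labelled shift must be large enough to be
separable, in principle, from the null $\Delta T_m$ population by the
$z \ge 1.96$ rule, otherwise "class" and "magnitude" would contradict
each other in the ground truth itself.

Shifts are injected exactly: the treatment curve keeps $a$ and $p$ and
re-solves $b' = a/T_m' - \ln(1-2p)$, so the true $\Delta T_m$ is
analytic, not approximate. Two further constraints keep truth
identifiable through ratio normalization. Because normalization forces
$FC(T_{ref}) = 1$, the normalized noiseless curve equals the model curve
only when the protein is fully folded at the reference temperature; the
generator therefore steepens low-melting proteins just enough that
$e^{b - a/T_{ref}} \le 10^{-6}$ for the lowest melting point the protein
can reach. Real data contain proteins already partly melted at 30 °C;
the generator deliberately does not emulate them, and this is the main
sense in which passing end-to-end tests do not certify behaviour on
every real curve. The generator also does not model peptide-level
effects, TMT ratio compression, co-isolation interference, or
between-run batch structure. Missingness, when enabled, is uniform
rather than intensity-dependent.

All randomness flows from the single `seed` slot; generation is
byte-identical across runs and restores the caller's RNG state.

# Problem sizes and what the tests establish

The test suite exercises: closed-form $T_m$ against an independent
bisection oracle over 1000+ random parameter sets; a noiseless
end-to-end identity (150 proteins, 7 conditions) in which every melting
point is recovered to $10^{-4}$ °C and every truth class exactly;
recovery under the default noise model (300 proteins, CV 5%) with median
$|T_m|$ error ≤ 0.5 °C and sign accuracy ≥ 0.9 on truly shifted pairs —
tolerances fixed from seeded calibration runs and then frozen; and
oracle equivalence of the statistical primitives (Fisher exact vs
hypergeometric enumeration, Mann–Whitney vs full permutation
enumeration, hand-computed Spearman and least-squares examples).
`scripts/acceptance.R` re-runs the 300-protein design end to end and
reports the same metrics as JSON.

# Known limitations

* $T_m$ here is an operational aggregation midpoint, sensitive to
  heating protocol and buffer; only *differences* between matched
  conditions are interpreted.
* The z-score rule finds within-treatment outliers; a global shift
  affecting all proteins equally is invisible to it by design.
* Mechanism regressions rest on six points; they rank explanations
  rather than establish them.
* Published-experiment counts can only be recomputed from the deposited
  tables (`reproducePublishedCounts()`); the package ships no copy of
  them.
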