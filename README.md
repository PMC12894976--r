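# crowdTPP

Thermal proteome profiling (TPP) analysis of macromolecular crowding
effects on proteome-wide protein stability.

TPP measures, for thousands of proteins at once, the soluble fraction
remaining after aliquots of a lysate are heated across a temperature
gradient (here ten points, 30–70 °C), quantified by TMT reporter ions.
`crowdTPP` implements the full downstream analysis for experiments that
compare a control lysate against lysates supplemented with crowding
reagents (Ficoll, dextran, PEG at two molecular-weight variants each):

1. **Normalization** — reporter intensities are converted to fold changes
   FC(T) = I(T)/I(T_ref) against the lowest temperature.
2. **Melting model** — each protein–condition curve is fitted with the
   three-parameter sigmoid

   f(T) = (1 − p) / (1 + exp(b − a/T)) + p

   (T in °C; p the post-transition plateau). The melting temperature is
   the closed form T_m = a / (b + ln(1 − 2p)), the temperature at which
   half the protein remains soluble; the slope is the analytic df/dT at
   T_m. Fitting is bounded Levenberg–Marquardt least squares with a
   deterministic multistart policy.
3. **Stringency QC** — a control/treatment fit pair is analyzable iff both
   R² ≥ 0.8, the control plateau is < 0.3 and both slopes are ≤ −0.06
   (all configurable), with reason codes for every failure.
4. **Stability calling** — ΔT_m = T_m(treatment) − T_m(control) is
   standardized per treatment (z = (ΔT_m − mean)/sd, sample sd) and
   classified: z ≥ 1.96 stabilized, z ≤ −1.96 destabilized, otherwise
   null (boundaries inclusive, α = 0.05 two-sided).
5. **Concordance** — per-protein counts of significant crowders and
   direction profiles (all-stabilized / all-destabilized / mixed).
6. **Dataset QC** — pairwise Spearman matrices, PCA variance
   decomposition, Mann–Whitney comparisons of parameter distributions,
   aggregated-fraction profiles.
7. **Mechanism** — per-crowder stability summaries regressed on reagent
   physico-chemical descriptors (molecular weight, intrinsic viscosity,
   polar atom fraction, hydrophobicity index), contrasting
   crowding/viscosity against preferential-exclusion explanations.
8. **Sequence features** — GRAVY, molecular weight, keyword enrichment
   (Fisher exact + Benjamini–Hochberg) for stabilized/destabilized/null
   protein sets.
9. **Synthetic experiments** — a generator with analytically known ground
   truth (exact injected ΔT_m shifts) validates the entire pipeline end
   to end; `truthEvaluation()` scores sensitivity, specificity and sign
   accuracy.

## Worked example

```r
library(crowdTPP)

cfg <- SimConfig(nProteins = 80, seed = 42)   # 1 control + 6 crowders, CV 5%
sim <- simulateTppExperiment(cfg)
sim$quants$control
#> ProteomeQuant: 80 proteins x 10 channels, condition 'control'
#> temperatures (C): 30 34 38 43 47 52 56 60 66 70

fits <- do.call(rbind, lapply(sim$quants, fitProteome))
head(subset(fits, condition == "control"), 3)
#>           protein condition        a        b    plateau       tm       slope        r2 converged qc_pass reason
#> control.1 SYN0001   control 1864.420 31.70137 0.09056280 59.18503 -0.11981319 0.9772277      TRUE    TRUE   <NA>
#> control.2 SYN0002   control 1299.687 24.45530 0.18143151 54.14342 -0.08627109 0.9858433      TRUE    TRUE   <NA>
#> control.3 SYN0003   control 1362.021 25.66736 0.09907839 53.52484 -0.10578291 0.9623276      TRUE    TRUE   <NA>

calls <- stabilityCalls(fits, zCrit = 1.96)
head(subset(calls, call != "null"), 3)
#>    protein  crowder  delta_tm         z         call qc_reason
#> 8  SYN0008 ficoll70 -7.165585 -4.567605 destabilized      <NA>
#> 35 SYN0035 ficoll70 -4.567508 -2.875633 destabilized      <NA>
#> 45 SYN0045 ficoll70  6.375128  4.250652   stabilized      <NA>

concordanceSummary(calls)$histogram
#>   n_significant direction_profile count
#> 1             1  all-destabilized    13
#> 2             1    all-stabilized    10
#> 3             2  all-destabilized     1

truthEvaluation(calls, sim$truth)[c("sensitivity", "specificity", "sign_accuracy")]
#> $sensitivity
#> [1] 0.8928571
#> $specificity
#> [1] 0.9535398
#> $sign_accuracy
#> [1] 1
```

Each row of `fits` is one fitted melting curve: `tm` is the temperature
(°C) at which half the protein remains soluble, `slope` the steepness of
the transition at `tm`, `plateau` the residual soluble fraction at high
temperature, and `qc_pass` the stringency gate. In `calls`, `delta_tm`
is the crowder-induced melting-point shift and `call` its per-treatment
z-score classification; the concordance histogram counts proteins by how
many crowders affected them and in which direction. The truth evaluation
compares the calls with the generator's known classes: here 89% of truly
shifted protein–crowder pairs are recovered with their exact class, 95%
of null pairs are left uncalled, and every recovered shift has the
correct sign.

`runPipeline()` chains all stages and writes the TSV bundle
(`fits.tsv`, `calls.tsv`, `summary.tsv`, `concordance.tsv`,
`qc_correlations.tsv`, `pca.tsv`, `param_tests.tsv`, `mechanism.tsv`,
`biophysics.tsv`, `enrichment.tsv`) plus a run manifest. Real MaxQuant
proteinGroups-style tables are read with `readQuantTable()` using a
channel→temperature map (`readChannelMap()`), so column naming is never
hard-coded.

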