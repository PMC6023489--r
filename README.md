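# phonoformant

Speech-inspired analysis of heart sounds for non-invasive screening of
**pulmonary artery hypertension (PAH)** — mean pulmonary artery pressure
≥ 25 mmHg with wedge/left-atrial pressure ≤ 15 mmHg at rest.

The working hypothesis is that the hypertensive pulmonary circulation
vibrates in a sustained, ordered way, adding a *vowel-like* tonal
signature to heart sounds recorded over the pulmonary auscultation area
(2nd left intercostal space, 2LICS). The package detects that order with
the machinery of speech analysis:

1. resample each mono phonocardiogram to 8 kHz and cut it into 32-ms
   frames;
2. fit an 8th-order **LPC** model per frame and take the four strongest
   resonances of its all-pole spectrum as the frame's **formants**
   (frequency + envelope amplitude, sorted ascending);
3. resynthesize each formant trajectory as a time-varying sinusoid (the
   **sine-wave replica**), discarding everything else;
4. score each replica's spectrogram *S* with the log-power **entropy**

   E = Σ_i Σ_bins log( S²_{f,i} + ε ),

   which is maximized by spectrally spread (disordered) signals and
   driven down by concentrated, vowel-like ones — *low entropy = ordered
   pattern*;
5. select the informative site and formant with pooled two-sample
   t-tests over the 4 × 4 grid, sweep window lengths 1–20 s with
   **Holm–Bonferroni** correction, and classify subjects with a
   one-dimensional **LDA** under leave-one-out cross-validation,
   reporting sensitivity = 100·TP/(TP+FN) and
   specificity = 100·TN/(TN+FP);
6. check the design with the power formula
   n = 2 (z₁₋α/₂ + z_power)² σ² / Δ² per group.

Because no patient recordings ship with the method, a **synthetic cohort
generator** reproduces the stated study world (35 normal / 25 PAH
subjects, 20-s recordings at 4000 Hz from four sites, a stable ~300 Hz
harmonic signature at the 2LICS in PAH) so every stage is testable end
to end. See `vignette source in vignettes/phonoformant-methods.Rmd` for
the full model description and design rationale.

## Worked example

```r
library(phonoformant)

cohort <- synth_cohort(synth_config(n_normal = 10, n_pah = 8, seed = 42))
res <- run_pipeline(cohort)
print(res)
#> <pipeline_result>
#>   selected: site 2LICS, formant 1, window 7 s
#>   corrected p at optimum: 0.000142
#>   LOO: TP=7 FP=0 TN=10 FN=1 | sensitivity 87.50%, specificity 100.00%

head(res$site_formant_tests, 4)
#>    site formant        t df        p_raw  p_corrected
#> 1 2LICS       1 6.344343 16 9.739835e-06 0.0001558374
#> 2 2LICS       3 3.736265 16 1.799180e-03 0.0269876951
#> 3 2LICS       4 3.557130 16 2.626647e-03 0.0367730647
#> 4 2RICS       1 1.700854 16 1.083208e-01 1.0000000000
```

The pipeline recovered the planted structure: the signature site (2LICS)
and the first formant rank first by a wide margin, the corrected p-value
at the optimal window stays significant, and leave-one-out LDA separates
the groups almost perfectly (one missed PAH subject in this small
18-subject cohort).

Reference arithmetic used in screening reports:

```r
required_sample_size(mean_null = 4.75e5, mean_alt = 4.56e5, sd_null = 9.85e3)
#> 6                       # subjects per group for 90% power at alpha 0.05
confusion_metrics(TP = 21, FN = 4, TN = 31, FP = 4)
#> sensitivity 84%, specificity 88.57%
```

## Command line

```sh
Rscript inst/cli/phonoformant.R simulate --out cohort_dir --seed 1
Rscript inst/cli/phonoformant.R run --metadata cohort_dir/cohort.tsv --out run_dir
Rscript inst/cli/phonoformant.R power --mean-null 4.75e5 --mean-alt 4.56e5 --sd-null 9.85e3
```

Subcommands: `simulate`, `extract`, `features`, `cohort-test`,
`classify`, `power`, `run`. Every pipeline run writes its feature
tables, test tables, predictions, and a manifest echoing all parameters.

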