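# mitobook

Quantitative analysis of mitotic bookmarking dynamics in the early
Drosophila embryo, for researchers studying how transcription factors such
as GAF behave through the rapid syncytial divisions: whether they stay on
mitotic chromatin, with what kinetics they bind in interphase, which
genomic sites retain them, and whether retention translates into faster
post-mitotic reactivation of transcription (transcriptional memory).

The package covers five analysis stages, each with a seeded synthetic-data
generator so the whole pipeline runs and is tested without any raw data:

* **FRAP kinetics** — ROI correction and normalization of recovery traces,
  and bounded least-squares fitting of a reaction–diffusion model
  `F(t) = F_eq F_D(t) + C_eq F_exc(t)`, where `F_D` is the order-20 Axelrod
  Gaussian-spot series and `F_exc = F_inf − ((1−e^−K)/K − F_inf) e^(−k_off t)`;
  residence time is `1/k_off`, and `D = β(K) w²/(4τ½)` with an
  oracle-built `β(K)` table.
* **FCS** — two-species diffusion autocorrelation with triplet state,
  `G(t) = 1 + (1/N)(1 + T e^(−t/τ_T)/(1−T)) Σ f_i /((1+t/τ_i)√(1+t/(s²τ_i))) + G_∞`,
  confocal-volume calibration (`w_xy = √(4 D τ)`), plus a
  Brownian-dynamics oracle that validates the model shape independently.
* **ChIP-seq peaks** — RPM rescaling, input subtraction, replicate
  averaging, a threshold/run/gap peak caller on 50-bp binned coverage,
  mitotic-retention classification (≥1 bp overlap between interphase and
  mitotic peaks), GAGAG motif counting, promoter/enhancer annotation, and
  metagene matrices.
* **Imaging** — 3D Laplacian-of-Gaussian spot detection with relative
  thresholding, log-Otsu nuclei segmentation, background-normalized
  transcription-site intensities, de novo (post-mitotic) spot filtering,
  and mutual-nearest-neighbour DNA-FISH distances with anisotropic voxels
  and a 1 µm aberrant-pair cutoff.
* **Mitotic memory** — waiting-time extraction (`T_a = T_0 + T_r`),
  Kaplan–Meier survival, fitting of the mixed-Gamma survival law
  `S(t) = p₁e^(−t/τ) + p₂(1 − γ(2,t/τ)/Γ(2)) + p₃(1 − γ(3,t/τ)/Γ(3))`
  of a linear irreversible chain, the summaries `a = p₁+2p₂+3p₃`, `b = τ`,
  moment-based state counting `N = M²/V + 1`, memory scores, CTMC
  simulation, and cumulative-activation / t50 curves.

Everything is tidyverse-native: functions take a data frame first and
return tibbles, fitted objects have `tidy()`, `glance()` and `autoplot()`
methods, and calls chain with the pipe.

## Worked example: is there transcriptional memory?

Simulate two lineage subpopulations — daughters of transcriptionally
active and of inactive mothers — where inactive-mother daughters have a
two-fold longer OFF-state lifetime, then recover that bias end to end:

```r
library(mitobook)
library(dplyr)

g <- gen_lineage(n_active = 500, n_inactive = 500, tau_act = 100,
                 tau_in = 200, t_end = 2400, seed = 42)
wts <- extract_waiting_times(g$records)
f_act <- fit_survival(kaplan_meier(filter(wts, mother_state == "active")))
f_in  <- fit_survival(kaplan_meier(filter(wts, mother_state == "inactive")))
f_in
#> Mixed-Gamma memory fit (n_states = 4)
#>   p = (0.324, 0.341, 0.335)
#>   tau = 214.9 s  a = 2.011  b = 214.9 s  mean T_r = 432 s
#>   cost O = 0.02132
memory_score(f_in, f_act)
#> # A tibble: 1 × 2
#>   score_ab score_b
#>      <dbl>   <dbl>
#> 1     2.14    2.22
```

The fitted OFF-state lifetime for the inactive-mother subpopulation
(`b = 214.9 s`) lands near the generative 200 s, and both memory scores are
near 2: daughters of inactive mothers wait about twice as long to
reactivate, i.e. a strong memory bias (a score above 1 indicates bias).

Peak calling uses the same threshold/run/gap rule as the original tracks
(threshold 100, minimum run 50 bp, maximum gap 200 bp on 50-bp bins):

```r
trk <- coverage_track("chr2L", c(10, 120, 130, 5, 5, 140, 150, 150, 10, 10))
call_peaks(trk, threshold = 100, min_run = 50, max_gap = 200)
#> # A tibble: 1 × 5
#>   chrom start   end max_value n_enriched_bins
#>   <chr> <int> <int>     <dbl>           <int>
#> 1 chr2L    50   400       150               5
```

The two enriched runs (bins 1–2 and 5–7) merge across their 100-bp gap into
one peak spanning `[50, 400)`.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/mitobook.R` (subcommands `peaks`, `frap`, `fcs`, `memory`,
`spots`, `synth`; every run writes a seed-stamped manifest JSON so outputs
replay byte-identically).

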