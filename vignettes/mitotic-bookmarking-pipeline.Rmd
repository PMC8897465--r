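---
title: "Models and methods behind the mitotic-bookmarking pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the mitotic-bookmarking pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitobook)
```

mitobook implements the quantitative machinery used to ask whether a
transcription factor acts as a *mitotic bookmarker* in the early Drosophila
embryo: does it stay bound to mitotic chromatin, with what kinetics does it
bind in interphase, which genomic sites retain it through mitosis, and does
its presence translate into faster post-mitotic transcriptional
reactivation (*transcriptional memory*)? Each section below describes one
model or procedure, its assumptions, the parameters that matter, and the
numerical choices made where the design was genuinely open.

## Binding kinetics from FRAP

A circular spot in a nucleus is bleached and the fluorescence recovery
recorded (by default one frame every 53 ms, 1200 frames, bleach after 10
frames — metadata mirroring the acquisition the defaults emulate). The raw
bleached-ROI intensity is corrected by an unbleached neighbouring nucleus
and an extracellular ROI,
$$I_{corr}(t) = \frac{I_{bl}(t) - I_{out}(t)}{I_{unbl}(t) - I_{out}(t)},$$
then normalized to the pre-bleach plateau. The printed form of the
normalization divides by the mean of the *raw* pre-bleach bleached-ROI
intensities; that leaves the pre-bleach level in raw units rather than at 1,
so `frap_normalize()` defaults to dividing by the mean *corrected*
pre-bleach value (the literal variant is available via
`prebleach_mean = "raw"`).

Recovery is modelled as free diffusion plus chromatin exchange,
$$F(t) = F_{eq} F_D(t) + C_{eq} F_{exc}(t), \qquad C_{eq} = 1 - F_{eq},$$
with $F_D$ the order-20 truncation of the Axelrod Gaussian-spot series
$$F_D(t) = \frac{1-e^{-K}}{K}(1-M) + M \sum_{n=1}^{20}
  \frac{(-K)^n}{n!}\Big(1 + n + 2n\frac{t}{\tau}\Big)^{-1}$$
and
$$F_{exc}(t) = F_\infty - \Big(\frac{1-e^{-K}}{K} - F_\infty\Big) e^{-k_{off} t}.$$
$K$ measures bleach depth, $M$ the mobile fraction (constrained to
$[0.9, 1.1]$ so genuinely bound molecules are not absorbed into an immobile
pool), $\tau$ the characteristic diffusion time, $k_{off}$ the unbinding
rate — the residence time on chromatin is $1/k_{off}$ — and $F_\infty$ the
exchange asymptote.

Two numerical points deserve care:

* **The series' $n = 0$ term.** As printed, the series starts at $n = 1$,
  which gives $F_D(0) < 0$ for $M = 1$; including the $n = 0$ term (the
  classical Axelrod form) restores $F_D(0) = (1-e^{-K})/K$ and
  $F_D(\infty) = 1$. Both are provided (`variant = "literal"`, the default,
  and `variant = "standard_axelrod"`) rather than silently correcting
  either; all internal conversions (the $\beta$ table below) use the
  standard form, whose limits are well defined.
* **Amplitude degeneracy.** The model's constant term is algebraically
  determined by its two amplitude terms: writing $A = M F_{eq}$ and
  $C = -(1-F_{eq})\big(\tfrac{1-e^{-K}}{K} - F_\infty\big)$, the constant
  equals $\tfrac{1-e^{-K}}{K}(1-A) + C$ for *every* choice of
  $(M, F_{eq}, F_\infty)$ on a one-parameter family. At most two of the
  three are identifiable from a single curve. `fit_frap()` therefore pins
  $F_\infty = 1$ (complete long-time recovery) by default, making the rest
  identifiable; `fix_F_inf = NULL` restores the fully free parameterization
  for users who prefer the curve-level fit and accept ridge-valued
  parameters.

Fitting is bounded Levenberg–Marquardt least squares on the first 1100
post-bleach frames, multi-started from a fixed $3\times3\times3$ grid over
$(\tau, k_{off}, F_{eq})$ scaled to the trace duration; the best
sum-of-squares fit is kept, so the procedure is deterministic. On noiseless
model-generated traces all free parameters are recovered to machine
precision; at 2% measurement noise the median $k_{off}$ and $\tau$ over a
23-trace batch stay within a few percent of truth (the acceptance script
recomputes both).

Diffusion coefficients use $D = \beta(K)\, w^2 / (4\tau_{1/2})$ with
$w = 0.83\ \mu m$ the beam's $1/e^2$ radius. The $\beta(K)$ table referenced
by the original analysis is not reproduced there, so `build_beta_table()`
constructs one from first principles: for each $K$ it generates the
pure-diffusion standard-Axelrod recovery with unit characteristic time,
finds the half-recovery time numerically, and stores the ratio. The fitted
series time and the half-time convention are thereby kept mutually
consistent; the table is monotone in $K$ and converged to well below 1%
at the default truncation order.

## Concentrations and diffusion from FCS

Intensity-fluctuation autocorrelations are fitted with an $n$-species 3D
diffusion model with triplet blinking and a long-lag offset,
$$G(t) = 1 + \frac{1}{N}\Big(1 + \frac{T e^{-t/\tau_T}}{1-T}\Big)
  \sum_{i=1}^n \frac{f_i}{\big(1 + t/\tau_i\big)\big(1 + t/(s^2\tau_i)\big)^{1/2}}
  + G_\infty,$$
with $n = 2$ by default (a fast freely diffusing and a slow
chromatin-interacting population), $\tau_T \le 10\ \mu s$, $\sum f_i = 1$,
and $s = w_z / w_{xy}$ fixed — from a calibration
(`calibrate_volume()`, Rhodamine 6G at $D = 414\ \mu m^2 s^{-1}$) when one
exists, else at the typical confocal value 5, which must then be stated
explicitly. Diffusion times convert to coefficients via
$\tau_i = w_{xy}^2 / 4D$.

Two guards keep the two-species fit honest. Diffusion times are bounded
below by the 10-µs triplet window: a "species" faster than that is
indistinguishable from triplet blinking and otherwise absorbs a spurious
fraction. And when the two fitted times land within a factor of 2 of each
other — unresolvable at realistic noise — they are collapsed to their
mixture mean with the full fraction on one component, so single-species
data fit with $n = 2$ reports one dominant species instead of an arbitrary
split. Weights are uniform by default (`weights = "inv_g2"` offers $1/G^2$
weighting); fits are per-curve, with distributions summarized across
curves, mirroring a per-measurement analysis.

An independent physical check backs the model: `gen_acf_brownian()`
simulates point emitters random-walking through a 3D Gaussian detection
volume in a periodic box and autocorrelates the intensity trace directly.
Its normalized decay matches the single-species closed form within
Monte-Carlo error, sharing no code with `acf_model()`.

## Peak calling on binned coverage

ChIP and input libraries enter as fixed-step (50 bp) binned coverage. The
normalization chain is reads-per-million rescaling, per-bin input
subtraction (floored at zero — thresholds are positive, so negative
enrichment carries no information downstream), and replicate averaging.
Peaks are then called with three parameters: bins at or above `threshold`
are enriched (the comparison is `>=`; the verbal rule "value over which" is
ambiguous at the boundary and `>=` is the deterministic, testable choice);
maximal runs of enriched bins merge across gaps of at most `max_gap` bp;
merged regions at least `min_run` bp long are reported. The length filter
applies *after* merging, since the gap rule is what decides whether two
enriched regions are distinct. The published settings are threshold 100
(GAF) or 22 (H4K8ac), minimum run 50 bp, maximum gap 200 bp.

Classification of bookmarked sites is purely positional: an interphase peak
overlapping a mitotic peak by at least 1 bp is *mitotically retained*;
interphase peaks with no such overlap are *interphase-only*; mitotic peaks
with no interphase partner are *mitosis-only*. Each interphase peak is
counted once even when it overlaps several mitotic peaks. GAGAG motif
counts default to overlapping occurrences on both strands — (GA)$_k$ arrays
are self-overlapping, and both switches are exposed since the counting
convention is not pinned down by the source analyses. Promoter annotation
(±100 bp around a TSS) takes precedence over enhancer overlap, mirroring
the ordered annotation rule. `metagene_matrix()` builds the center-anchored
±1 kb coverage matrix used for accessibility profiles over peak classes.

## 3D spot detection and FISH distances

Transcription sites and DNA-FISH probes are detected by a negated 3D
Laplacian-of-Gaussian filter (σ = 1 voxel by default; the original "kernel
size 1" leaves units unstated, so voxels are assumed and the value is
configurable). The threshold is relative — $\mu + thr\,\sigma_f$ on the
filtered frame's own statistics, with `thr` common across frames of a movie
— and above-threshold voxels group into 26-connected components whose
intensities and intensity-weighted centers come from the *raw* voxel
values. A flat frame has $\sigma_f = 0$ and deliberately yields no spots.
Nuclei are segmented by Gaussian smoothing, a log transform (compressing
intensity inhomogeneity inside nuclei; offset `eps = 1` intensity unit
avoids $\log 0$), and per-slice Otsu thresholds.

FISH probe pairs are formed by mutual nearest neighbours on physical
coordinates — x, y scaled by the lateral voxel size and z by the axial one —
with ties broken by lowest index for reproducibility, and pairs farther
than 1 µm discarded as aberrant. Spots persisting from mitosis are removed
positionally: any post-mitotic spot within a configurable radius (0.5 µm
default) of a mitotic-frame spot is dropped, leaving only de novo punctae.
Whether the original removal was positional or identity-based is not
stated; positional filtering is the implementable reading and the radius is
exposed.

## Post-mitotic memory: the mixed-Gamma survival model

The post-mitotic activation delay decomposes as $T_a = T_0 + T_r$, with
$T_0$ a deterministic incompressible lag set to the first observed
activation (pooled across movies by default; a per-movie mode exists since
the pooling is not pinned down) and $T_r$ random. $T_r$ is modelled as the
first-passage time of a linear, irreversible continuous-time Markov chain
whose OFF states share a lifetime $\tau$; with $n = 4$ states (the selected
model size) the survival function is the Gamma mixture
$$S(t) = p_1 e^{-t/\tau}
  + p_2\Big(1 - \frac{\gamma(2, t/\tau)}{\Gamma(2)}\Big)
  + p_3\Big(1 - \frac{\gamma(3, t/\tau)}{\Gamma(3)}\Big),$$
where $p_k$ is the probability of reaching ON after $k$ jumps. The summary
parameters are $a = p_1 + 2p_2 + 3p_3$ (mean jump count) and $b = \tau$, so
the mean waiting time is $ab$; the moment identity $\int_0^\infty S = ab$
is verified by quadrature in the tests. `estimate_states()` gives the
moment estimate $N = M^2/V + 1$; an additive shift left in the data
inflates it, which is why $T_0$ must be removed first.

The empirical survival curve is the Kaplan–Meier product-limit estimate
with never-activated nuclei right-censored at movie end (their handling is
unstated in the source procedure; right-censoring is the statistically
standard default and `censoring = "drop"` reproduces the alternative). The
fit minimizes the unweighted sum of squared differences between the
empirical and model survival at the empirical event times — evaluation at
event times avoids inventing a grid — over the probability simplex
(softmax-reparameterized) and $\log\tau$, with six deterministic
Nelder–Mead starts. The reported $O$ is the cost at the optimum.

The *memory score* compares daughters of inactive versus active mothers:
$\text{score}_{ab} = (a_{in} b_{in})/(a_{act} b_{act})$, the ratio of mean
waiting times, with $\text{score}_b = b_{in}/b_{act}$ as the lifetime-only
variant; a ratio above 1 indicates a memory bias. At 500 nuclei per
subpopulation the fitted-$b$ ratio has a relative spread of roughly 14%
across replicate experiments, while $\text{score}_{ab}$ — effectively a
ratio of sample means — is about three times tighter, so conclusions should
rest on $\text{score}_{ab}$ and replicate experiments should be summarized
by medians (the acceptance checks do exactly that). `simulate_chain()`
draws jump counts from $p$ and waiting times as Gamma variates, and its
empirical survival agrees with the closed form to Kolmogorov–Smirnov
distance $\to 0$; `cumulative_activation()` yields the activation curve
and its t50, the time by which half of the eventually-active pattern has
activated.

## Synthetic data: what it does and does not show

Every input kind is generated in code with the statistical structure the
corresponding analysis assumes: FRAP traces from the recovery model plus
i.i.d. Gaussian noise (raw ROI channels emitted so the correction chain is
exercised); ACF curves from the closed form with multiplicative noise, plus
the Brownian-dynamics oracle; coverage tracks with |Normal| background and
rectangular planted peaks, a random genome with T-flanked (GA)$_k$ arrays
planted inside peaks (background occurrences of GAGAG/CTCTC are scrubbed by
point mutation so motif truths are exact); image stacks as sums of
well-separated 3D Gaussians plus noise; lineage tables from the memory
chain itself. One process-wide seed fans out to named substreams via a
stable hash, so adding a generator never shifts another's draws and every
generator is a deterministic function of its seed.

These generators are deliberately idealized: no read-level sequencing
artifacts, no realistic point-spread function or autofluorescence, no
photobleaching drift, no nuclei-tracking errors, and noise that is exactly
the form each fitter assumes. Passing tests therefore demonstrate that the
*algorithms* are implemented correctly and are well calibrated under their
own model assumptions — not that those assumptions hold on any particular
microscope or sequencing run.

## Problem sizes and reproducibility

The test-suite and acceptance problem sizes — 1000 random 200-bin tracks
for the peak-caller oracle, $10^4$ simulated nuclei for survival-fit
recovery, $10^5$ draws for moment state counting, 23 FRAP traces at 2%
noise, 7 FCS curves at 1% noise, 50 planted spots at SNR 10, 100 null
replicates of 500 nuclei per group — were chosen as the smallest scales at
which the statistical claims being checked are comfortably resolvable, and
they mirror the stated study conditions where those exist (23 FRAP nuclei,
n = 500 per lineage subpopulation, SNR-10 spot stacks). All stochastic
pathways take explicit seeds, and identical seeds reproduce byte-identical
outputs, including through the command-line interface's run manifests.
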