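---
title: "Copy-number genotyping from multiplex melt curves: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number genotyping from multiplex melt curves: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gracepcr)
```

## The measurement principle

Gene ratio assay copy enumeration PCR (GRACE-PCR) screens for alpha-thalassaemia
deletions by counting gene copies rather than detecting breakpoints. A limited-cycle
multiplex PCR co-amplifies three amplicons — the two alpha-globin genes *HBA1* and
*HBA2*, and the chloride-channel gene *CLCN7* as a two-copy reference — while the
reaction is still in its exponential phase, so the amount of each product stays
proportional to the number of template copies in the input DNA. The products are
designed to melt roughly 3 °C apart (79.4, 82.2 and 85.2 °C), so a single
high-resolution melt acquisition over 77–87 °C shows three distinct fluorescence
steps, and the size of each step encodes the copy number of the corresponding gene.

Two independent read-outs convert a melt curve into an (HBA1, HBA2) copy pair:

1. **Peak-height ratios.** On the −dF/dT plot each amplicon yields a peak at its
   Tm whose height is proportional to product amount. For target gene height $T$
   and reference height $R$, the statistic
   $$\text{ratio} = \frac{R_{ctrl}/T_{ctrl}}{R_{unk}/T_{unk}}$$
   cancels per-sample scale and per-amplicon efficiency against a wild-type
   control run alongside; under proportionality it equals the target copy number
   of the unknown divided by that of the (two-copy) control, so
   $\text{ratio}\times 2$ snaps to an integer copy number.

2. **Two-stage normalization windows.** The visual method used in HRM software,
   made computable. Stage 1 rescales each curve between a window below the
   reference melt (100 %) and one beyond the *HBA1* melt (0 %); the plateau
   between the reference and *HBA1* melts then reads
   $p_1 = A_{HBA1}/(A_{CLCN7}+A_{HBA1})$, so its odds $p_1/(1-p_1)$ equal the
   amplitude ratio *HBA1*:*CLCN7*. The odds ratio of unknown to control, times
   the control's two copies, gives *HBA1*. Stage 2 repeats this between a window
   before the *HBA1* melt and one beyond the *HBA2* melt; its odds ratio fixes
   *HBA2* once *HBA1* is known. The resolution order is strictly sequential:
   reference (assumed 2) → *HBA1* → *HBA2*.

Copy pairs are then interpreted as genotype classes — (2,1) single-gene deletion
pattern, (1,0) Hb H pattern, (2,3) duplication, and so on. The assay sees copy
number only: the hybrid gene of the −α3.7 deletion carries the *HBA1* primer
site and types as *HBA1*; the −(α)20.5 deletion presents as loss of *HBA2* only;
point mutations are invisible. These caveats ride along with every
interpretation the package emits.

## The simulator: what it emulates, and what it does not

No raw instrument exports are publicly deposited for this assay, so the package
ships a generative model used for fixtures, tests and cohort-scale validation:

$$F(T) = b_0 + b_1 (T - T_{min}) + \sum_i \frac{A_i}{1 + e^{(T - Tm_i)/w_i}} + \varepsilon(T),
\qquad A_i = s \cdot a_i \cdot c_i$$

a linear dye background plus one decreasing logistic per amplicon, amplitude
proportional to copy number $c_i$ (per-copy amplitude $a_i$, per-sample scale
$s$), with i.i.d. Gaussian acquisition noise. The logistic was chosen because it
reproduces the sigmoidal melt steps of real curves *and* has a closed-form
derivative peak, $A/(4w)$ at $Tm$, giving the tests an analytic oracle.

Default parameters, chosen once on physical grounds:

| parameter | default | rationale |
|---|---|---|
| grid | 77–87 °C, 0.2 °C step (51 pts) | the assay's acquisition range and a typical rotor instrument resolution |
| transition width $w$ | 0.2 °C | 10–90 % melt width ≈ 0.9 °C, realistic for 130–170 bp amplicons, and narrow enough that the three steps separate cleanly on a 2.8 °C Tm spacing |
| per-copy amplitude | 1.0 for all three amplicons | the wet assay balances peak sizes by reducing reference primer concentration; the simulator encodes the balanced end state |
| per-sample scale | log-normal, sdlog 0.15 | pipetting/amplification variation; forces every caller to be control-normalized |
| baseline | intercept 2, slope −0.02 /°C | slow dye-background decay |
| noise_sd | 0.02 signal units | ≈ 1 % of a two-copy melt amplitude, a clean but not idealized acquisition |

The simulator deliberately does **not** model PCR saturation (the assay stops at
27 cycles precisely to stay exponential — linear proportionality is the method's
own operating assumption), heteroduplex or point-mutation melt-shape changes, or
temperature calibration drift between samples. Passing tests therefore
demonstrate that the *analysis* recovers copy numbers whenever the proportional
three-step structure holds; they do not certify instrument-specific artefacts.

The bundled validation cohort (`table2_cohort()`) reproduces the composition of
the assay's 167-sample development-and-validation set: 17 genotypes, 108 samples
with abnormal copy pairs and 59 wild type.

## Numerical choices that matter

**Derivative estimator.** −dF/dT is computed with a 4th-order (five-point)
central-difference stencil on interior points, falling back to the 3-point
formula beside the boundary and one-sided differences at the ends. On a 0.2 °C
grid the plain 3-point formula underestimates a $w = 0.2$ °C logistic peak by
about 8 %, while the five-point stencil stays within ~2 % — tight enough that
peak heights can be checked against $A/(4w)$ directly.

**Smoothing.** Savitzky–Golay, window 7, order 2, applied before
differentiation. On noiseless curves it perturbs the signal by well under 1 % of
the melt amplitude; at the default noise level it roughly halves the derivative
noise.

**Shared-slope normalization.** `normalize_between()` fits the pre- and
post-window lines *jointly with a common slope* (separate intercepts). The dye
background has a single physical slope; fitting two independent slopes to
0.6 °C windows (4 points each) and extrapolating them ~3 °C into the inter-melt
region amplifies acquisition noise about seven-fold and was the dominant error
source for the window method in development experiments. With a shared slope
each window's line still passes exactly through that window's mean, so the
normalization rails (pre = 100, post = 0) hold by construction, and a linear
baseline is still absorbed exactly.

**Window placement.** The normalization regions are an analyst's choice in HRM
software and their coordinates are not standardized, so placement is automatic
with a manual override: each 0.6 °C window is centred on the flattest position
(minimum mean |dF/dT| of the control) within its eligible region, and placement
fails loudly — advising manual windows — if no position is flatter than 10 % of
the control's maximum derivative. Stage-1 windows: below the reference melt and
in the *HBA1*–*HBA2* gap. Stage-2 windows: in the *CLCN7*–*HBA1* gap (before
the *HBA1* melt) and above the *HBA2* melt. Plateaus are read over the central
50 % of the relevant inter-Tm gap to avoid shoulder contamination.

**Copy snapping and flags.** A candidate copy number (ratio × control copies)
snaps to the nearest allowed state {0, 1, 2, 3}; a distance above 0.35 copies
flags the call `ambiguous`. The per-state ratio ranges observed in validation do
not overlap, but a batch tool must route borderline values to confirmatory
testing rather than guess. Absence is decided on the scale-free
target/reference height ratio — below 10 % of the control's ratio for the same
gene calls 0 copies (`absent_target`) — because the peak-ratio formula divides
by the target height and the homozygous-deletion case it must detect would
otherwise divide by zero. A stage-1 ratio above 2.0, or a call outside the
allowed states, raises `improbable_reference`: reference-gene anomalies
masquerade as impossible *HBA1* copy numbers. The wild-type control's own call
must come out (2,2) or the run aborts — it is the quantification anchor.

**Degenerate inputs.** Constant curves fail normalization ("degenerate fit");
a missing reference peak is a run-level error, not a silent zero; a stage-2
plateau with no *HBA1* amplitude to ratio against is flagged rather than
resolved.

## Validation statistics

Screening performance is scored against a truth table with *abnormal* defined
as any copy pair ≠ (2,2). Sensitivity and specificity carry exact
Clopper–Pearson intervals, computed from beta quantiles; for $k = n$ the lower
bound is $(\alpha/2)^{1/n}$, which for 108/108 and 59/59 at 95 % confidence
gives 96.6 % and 93.9 %. Ambiguous calls are counted as discordant by default
(`as-discordant`), the conservative choice for a screening claim; `as-called`
and `excluded` policies are available. A zero denominator reports
not-applicable, never 0.

```{r cohort, eval = FALSE}
panel <- default_panel()
sim <- simulate_cohort(table2_cohort(), panel, seed = 1)
calls <- call_by_peaks(sim$run, panel)
keep <- calls$sample_id != sim$run$control_sample_id
run_validation(calls[keep, ], sim$truth[sim$truth$sample_id != "WT_control", ])
```

## Robustness envelope

The acceptance experiments run the full 167-sample cohort at the default noise
(`noise_sd = 0.02`) under a fixed seed; both calling methods recover every true
copy pair with zero unflagged discordance. The sweep below maps concordance as
noise grows; the `ambiguous` flag is designed to absorb the first failures, so
unflagged errors appear only well after flagged ones:

```{r sweep, eval = FALSE}
panel <- default_panel()
for (ns in c(0.02, 0.05, 0.08, 0.12)) {
  sim <- simulate_cohort(table2_cohort(), panel, seed = 1, noise_sd = ns)
  calls <- call_by_peaks(sim$run, panel)
  m <- match(calls$sample_id, sim$truth$sample_id)
  bad <- calls$hba1_copies != sim$truth$hba1[m] |
    calls$hba2_copies != sim$truth$hba2[m]
  cat(sprintf("noise %.2f: %d discordant (%d unflagged)\n", ns, sum(bad),
              sum(bad & !grepl("ambiguous", calls$flags))))
}
```

## Known limitations

- Copy pairs, not alleles: (2,1) cannot distinguish −α3.7 from −α4.2, and a
  deletion-plus-duplication compound can present a normal pair. Confirmatory
  gap-PCR/MLPA remains necessary for allele identity.
- The simulator's noise model is uncalibrated against real instruments (no raw
  data are deposited); the robustness envelope above is the honest statement of
  what the defaults demonstrate.
- Exactly one wild-type control per run is assumed; multi-control averaging and
  inter-run calibration are out of scope.
- Melt-shape (scanning) analysis of point mutations is out of scope by design —
  the assay's own validation shows point mutations do not disturb copy calls.
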