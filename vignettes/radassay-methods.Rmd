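---
title: "Models and methods behind radassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind radassay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radassay)
```

radassay implements the quantitative analysis chain of a classical cellular
radiobiology experiment on cultured cells (the motivating system is murine
embryonic stem cells after X-irradiation): DNA-content cell-cycle analysis by
flow cytometry, clonogenic survival, and MTT viability, plus a seeded
synthetic-data module that generates inputs with exactly the statistical
structure the analysis stages assume.

## The five-Gaussian DNA-content model

Ethanol-fixed, propidium-iodide stained cells carry fluorescence proportional
to DNA content: G1 cells define a reference channel $\mu_{G1}$, G2/M cells sit
at $2\mu_{G1}$, S-phase cells in between, apoptotic (sub-G1) fragments below
G1 and polyploid cells at twice the G2 channel. The histogram of gated events
is modelled as the sum of five Gaussians,

$$ y(c) = \sum_{k=1}^{5} A_k \exp\!\left(-\frac{(c-\mu_k)^2}{2\sigma_k^2}\right), $$

fit by least squares over the bins subject to the DNA-content ordering
$\mu_{subG1} < \mu_{G1} < \mu_S < \mu_{G2} < \mu_{poly}$, $\sigma_k > 0$,
$A_k \ge 0$. The phase fraction of component $k$ is its normalised Gaussian
area $A_k \sigma_k / \sum_j A_j \sigma_j$. This is deliberately *not* a
Dean–Jett–Fox or Watson model: the S phase is one plain (broader) Gaussian,
which is the model the assay's original analysis used.

Numerical choices:

* **Optimizer.** The contract is the constrained least-squares optimum, not a
  particular algorithm (the historical workflow used a spreadsheet GRG
  solver). We use `nls(algorithm = "port")` — bound-constrained Gauss–Newton
  — which converges in ~10–20 iterations, with an analytic-gradient L-BFGS-B
  polish whenever port stops on a flat direction (typically an amplitude
  pinned at zero) and as a fallback. The result is never allowed to be worse
  than its initialization; the relative-SSE convergence tolerance is
  $10^{-10}$.
* **Staging.** (1) estimate the G1 peak (user estimate → nearest local mode;
  otherwise the highest mode in the lower half of the occupied range, ties to
  the lower channel); (2) fit G1 alone on ±15% of its channel; (3) seed the
  other peaks stoichiometrically at $\{0.5, 1.5, 2, 4\}\times\mu_{G1}$ with
  amplitudes from the histogram heights (small positive floor) and sigmas
  from a 5% CV; (4) joint bounded refit, each $\mu_k$ boxed at the midpoints
  to its neighbours (which enforces the ordering), each $\sigma_k$ within
  3× of its initial value, each $A_k \ge 0$.
* **Binning.** 256 linear half-open bins on $[0, 1024)$ by default — classic
  cytometer resolution; overflow events accumulate in the last bin and are
  reported.
* **Doublet gate.** Two cells in one droplet sum their fluorescence area (a
  G1–G1 doublet mimics G2) but elongate the pulse; the gate is linear in
  width vs area, defaulting to a flat cut at 1.3× the median pulse width.
* **G1 anchoring under arrest.** During a strong G2 arrest the automatic
  lower-half mode rule can select the (now dominant) G2 peak, so the kinetics
  chain passes the known G1 channel as the user estimate — mirroring the
  user-defined G1 starting value of the original workflow.

## G2-arrest kinetics

Irradiated cells accumulate transiently in G2. For a series of timepoints
with replicate phase fractions and a matched mock-irradiated control series,
`g2_kinetics()` reports the **peak time** (argmax of the mean irradiated G2
fraction) and the **resolution time**: the earliest timepoint at/after the
peak where irradiated and control G2 fractions are no longer significantly
different (two-sided Welch t-test, $\alpha = 0.05$, one comparison per
timepoint, no multiplicity correction — matching the per-comparison testing
convention of the assay). As $\alpha$ decreases, the set of non-significant
timepoints grows, so the resolution time can only move earlier.

## Clonogenic survival: single-hit multi-target

Surviving fractions are plating-efficiency-corrected colony ratios,
$SF(D) = \overline{\text{colonies}/(N_{seeded}\,PE)}$, with $PE$ the 0 Gy
colonies-per-cell mean. The model is

$$ S(D) = 1 - \left(1 - e^{-D/D_0}\right)^n, $$

whose high-dose tail is $\ln S \approx \ln n - D/D_0$. The primary fit is the
unweighted linear regression of $\ln SF$ on dose: $D_0 = -1/\text{slope}$,
$n = e^{\text{intercept}}$ (clamped at 1), and the quasi-threshold
(shoulder) dose $D_q = D_0 \ln n$ — the dose where the back-extrapolated
tail crosses 100% survival. Because the source procedure both regresses "all
data" and defines $D_0$ "in the linear range", the default restricts the
regression to doses $\ge 2\hat{D_q}$ from an initial all-dose fit (one
iteration) and `all_doses = TRUE` reproduces the literal all-data
regression; for a narrow-shoulder curve ($D_q \approx 0.4$ Gy) the two
coincide. A nonlinear refinement of the full $S(D)$ (port algorithm,
including the 0 Gy point) is reported alongside but the linear parameters
stay primary. Zero-colony dishes stay in the per-dose means; a dose whose
mean SF is zero is excluded from the ln-regression and flagged.

## MTT viability

Per dose, with plate-mean blank and untreated ODs,

$$ \text{Viability}(\%) = \frac{OD_{treated} - OD_{blank}}
   {OD_{untreated} - OD_{blank}} \times 100, $$

which is invariant to adding a constant to, or rescaling, every OD. Pooling
across experiments weights experiment means by well counts and uses the
within-experiment pooled SD over all wells (the "SE of N wells" convention
for combined repeats). Near ~20% viability the formazan signal stops
tracking dose — the assay's limit of quantification — so doses whose
viability cannot be distinguished from the floor are **flagged**
(`at_loq`), never truncated. The flag uses a one-sided bound
(viability − 1.96·SE ≤ LOQ): a strict mean ≤ LOQ rule would toggle
randomly for doses sitting exactly at the floor, where the measured value
straddles it symmetrically.

## The synthetic-data module

The generators state the experimental world the tests live in:

* **Flow events**: multinomial population draws; area Gaussian around
  $\text{relative mean} \times \mu_{G1}$ with CV-scaled sd (S sd = 2× G1 sd,
  it spans G1→G2 content); sub-G1 at 0.5×, polyploid at 2× G2 — DNA-content
  stoichiometry; doublets as two summed G1 draws at 1.6× singlet pulse
  width. Default acquisition 2×10^4 events (instrument counts are rarely
  reported; configurable).
* **Colony counts**: Poisson around $N_{seeded}\,PE\,S(D)$, defaults
  $D_0 = 1.45$ Gy, $n = 1.327$, $PE = 0.64$, six dishes per dose in three
  independent experiments, seeding adjusted per dose for ~50 colonies per
  dish — the classic design.
* **OD plates**: blank and untreated strips plus treated wells at
  $OD_{blank} + (OD_{untreated}-OD_{blank})\max(v, \text{floor})/100$ with
  Gaussian noise (defaults: window 0.1–0.9 OD, noise sd 0.02, floor 20%).
* **Arrest time course**: the G2 fraction rises piecewise-linearly from
  baseline to a peak of 0.65 at 7 h, falls back to baseline at 41 h
  (published kinetics are qualitative about the peak height; 0.65 is a
  realistic strong arrest), with G1/S rescaled to keep fractions summing
  to 1.

Randomness flows from one root seed through per-operation Lehmer child
streams (`child_seed()`), so outputs are byte-identical per seed and
insensitive to reordering of other stages.

What a green test does *not* establish: the generators draw clean Gaussians
with independent events — no autofluorescence drift, no S-phase plateau
shape, no clumping beyond doublets, no plate-edge effects, no inter-
experiment batch variance beyond sampling noise. Recovery results bound
algorithmic error under the stated model, not instrument systematics.

## Runtime scaling in the test suite

Multi-seed recovery loops (50-seed clonogenic recovery; 50-seed arrest
kinetics, i.e. 2100 full deconvolutions) run against 4000-event samples
rather than the 2×10^4-event acquisition default, purely for runtime; the
per-sample binomial noise this adds is well inside the tested tolerances.

## Known limitations

* No FCS file reader: event input is the CSV schema (no FCS parser in the
  supported dependency stack); no compensation/spillover handling.
* The S phase is a single Gaussian by design; strongly non-Gaussian S
  distributions will bias the S fraction.
* No linear-quadratic survival model and no IC50/4PL dose-response fitting —
  out of scope for this assay chain.
* Bootstrap/uncertainty on $D_0$, $n$, $D_q$ is limited to the regression
  slope SE; the source assay reported none to compare against.
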