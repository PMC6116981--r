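---
title: "Two-point water content and relaxation mapping: models, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-point water content and relaxation mapping: models, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mriwater)
```

## The signal model and its assumptions

Every quantity in this package derives from the steady-state signal of a
perfectly spoiled gradient-echo sequence,

$$ S(TE) \;=\; M_0 \; \underbrace{e^{-TE/T_2^*}}_{C_{T_2^*}} \;
\underbrace{\frac{\sin\alpha_{\mathrm{eff}}\,(1-E)}{1-E\cos\alpha_{\mathrm{eff}}}}_{C_{T_1,B_1^+,\alpha}} \;
\underbrace{B_1^-}_{C_{B_1^-}}, \qquad E = e^{-TR/T_1},
\quad \alpha_{\mathrm{eff}} = B_1^+\,\alpha_{\mathrm{nom}}. $$

The model assumes ideal spoiling of transverse magnetisation between
excitations, a single relaxation compartment per voxel, and no
magnetisation-transfer effects.  Water content is the magnetisation
density $M_0$ after all three multiplicative corrections, calibrated so
that ventricular cerebrospinal fluid (CSF) — in good approximation 100%
MR-visible water — reads 100%.

The operating point wired into `default_protocols()` is two multi-echo
gradient-echo (meGRE) acquisitions at $TR = 50$ ms with nominal flip
angles 7° and 40° and 18 echoes ($TE_1 = 2.2$ ms, $\Delta TE = 2.55$ ms),
an AFI acquisition with $TR_1 = 125$ ms, $TR_2/TR_1 = 5$ at 40°, and a
fully relaxed long-TR reference ($TR = 10$ s, 90°, 32 echoes).  A long
TR relative to $T_2^*$ both permits the 18-echo readout and reduces the
impact of residual unspoiled magnetisation, which the model ignores.

## Transmit-field mapping

AFI interleaves two repetition times at one flip angle; the signal
ratio $r = S_2/S_1$ encodes the flip angle.  `afi_flip_angle()` applies
the classical short-TR approximation
$\alpha \approx \arccos\{(rn-1)/(n-r)\}$, which at tissue $T_1$ carries
a bias of a few percent (the acceptance suite measures up to ~4.7% over
$\alpha \in [20°, 60°]$, $T_1 \in [0.5, 4.5]$ s).  `afi_refine()`
therefore re-solves, per voxel, the **exact** two-pulse steady-state
ratio equation by bisection — the ratio is monotone decreasing in the
flip angle — to a 0.01° default tolerance.

The exact ratio depends (weakly) on $T_1$, which is unknown at this
stage of the chain, so a nominal value must be assumed; the default is
1000 ms, typical of white matter at 3 T.  The tests quantify the cost
of this choice: with the true $T_1$ supplied the round trip through the
exact forward model recovers flip angles to better than 0.1%; with the
assumed $T_1$ wrong by ±50% the residual error stays below 3%.  This
residual is the dominant error source of the AFI-based pipeline route
and is visible in the worked example of the README as a ~1% GM $T_1$
offset.  Supplying a measured transmit field bypasses the stage.

Numerical details: the arccos argument is clamped to $[-1, 1]$, with
excursions up to $10^{-3}$ treated as noise and clamped silently and
larger ones flagging the voxel invalid; $S_1 \le 0$ likewise flags the
voxel rather than raising an error.  Because transmit fields are
physically smooth, the calibrated $B_1^+$ map is median-filtered
(radius 1 voxel, 3³ window, optional) before trilinear resampling onto
the meGRE grid.

## Two-point T1 estimation

With both acquisitions sharing TR and echo times, the residual $T_2^*$
weighting is identical in both and cancels, so $T_1$ is the minimiser of

$$ \sum_{n=1}^{3}\Big|\frac{S_{\alpha_1}(TE_n)}{C_{T_1,B_1^+,\alpha_1}}
 - \frac{S_{\alpha_2}(TE_n)}{C_{T_1,B_1^+,\alpha_2}}\Big|^2 . $$

Only the first three echoes are used: they carry the highest SNR, and
late echoes suffer signal loss in regions of strong field
inhomogeneity.  Because the correction factor is echo-independent, the
sum collapses to three per-voxel echo moments, and the whole volume is
minimised simultaneously: a 120-point log-spaced bracketing grid over
$[1, 6000]$ ms locates the basin, and vectorised golden-section
iterations refine it to 0.01 ms.  The test suite keeps an exhaustive
0.1 ms grid search as the independent oracle; the two agree on 1000
random noisy voxels.  Estimates at the upper bound are set to exactly
6000 ms and flagged — CSF, the longest-$T_1$ tissue in the head, lies
below this bound, so the clip only fires on noise and model violations.
Voxels with zero signal in both acquisitions are flagged invalid.

## T2* estimation and the echo-time cutoff

$T_2^*$ comes from a weighted log-linear fit of $\ln S$ on $TE$ with
weights $|S(TE_n)|$, in closed form per voxel.  The weights counteract
the noise distortion introduced by the log transform (low-signal late
echoes would otherwise dominate); a Monte Carlo test confirms the
weighted estimator has lower variance than the unweighted one on Rician
data.

Macroscopic field gradients superimpose a non-exponential attenuation
on the decay.  The off-resonance map is estimated from the echo phases
(`fieldmap_from_phase()`), its per-voxel gradient is converted to an
across-voxel frequency spread $G$ (Hz), and echoes beyond

$$ TE_{\max} = \frac{1000\,q}{G}\ \text{ms}, \qquad q = 0.5\ \text{cycles} $$

are excluded from the fit.  The threshold $q$ is the through-voxel
phase dispersion at which the first zero of the sinc-shaped attenuation
of a linear gradient is approached; it is configurable.  Two guards
apply: every voxel always keeps at least the first three echoes (the
same echoes that enter $M_0$), flagged in `floor_used` when the cutoff
would demand fewer, and at least two usable echoes are required for a
fit at all.  Estimates at or above 1500 ms — including non-decaying
voxels, whose fitted rate is non-negative — are clipped there and
flagged.

Phase handling is deliberately simple: the field is the least-squares
slope of the temporally unwrapped per-voxel phase train, initialised
from the first echo pair.  With uniformly spaced echoes a frequency
beyond $\pm 1/(2\Delta TE)$ (±196 Hz at 2.55 ms) is fundamentally
ambiguous — every integer-cycle offset fits the train equally well —
so the implementation keeps the principal value there; when later echo
spacings differ from the first, candidate wrap counts are scored
against all later echoes and the ambiguity is resolved.  No spatial
unwrapping is attempted.

## Water content

`correct_m0()` averages the first $N = 3$ echoes of the low-flip-angle
acquisition after dividing out the three correction factors; the
high-flip acquisition influences water content only through the $T_1$
estimate.  Voxels where any factor is zero or undefined are flagged
invalid and logged, never divided through.  `normalize_h2o()` scales by
$C_{\mathrm{norm}} = 100/\overline{M_0}$ over the normalisation region,
so the region mean is 100% by construction and the result is invariant
under any global rescaling of the raw signal.

The normalisation region is ventricular CSF: CSF probability ≥ 0.99,
fitted $T_1 > 2900$ ms and $T_2^* > 500$ ms (both strict), intersected
with an ellipsoid around the lateral ventricles that excludes
subarachnoid CSF.  The thresholds keep only voxels whose fits are
CSF-like, i.e. well described by the model.  No anatomical default for
the ellipsoid is meaningful in general, so it is part of the
configuration; the brain phantom exports the ellipsoid that encloses
its own ventricles, and the pipeline interprets the centre and
semi-axes in world millimetres through the acquisition affine.  An
empty region is an error, not a silent fallback.

For the receive field the package substitutes a documented, testable
estimator for the external segmentation-based correction typically used
on in vivo data: within a brain mask, the log of the partially
corrected $M_0$ map is alternately decomposed into $k = 3$ intensity
classes (1-D k-means, quantile-initialised and hence deterministic) and
a smooth order-4 3-D polynomial field fitted to the log-residual, until
the field stabilises (tolerance $10^{-4}$, at most 20 rounds, best
iterate with a warning otherwise).  The field is normalised to mean 1
over the mask, leaving the calibration to the CSF stage.  Fitting the
log of a ±20% multiplicative field by a polynomial of the same order is
only approximate, but the recovery tests bound the error well below 2%
RMS on the brain phantom.  A measured receive field, when available,
is passed through unchanged.

The long-TR variant `h2o_long_tr()` implements the reference-style
mapping: at $TR \gg T_1$ and 90° excitation the saturation factor is 1,
so only the $T_2^*$ extrapolation to $TE = 0$ and the receive field
remain.  Its precondition is real: the function warns when
$TR < 5\,T_1$, and the tests demonstrate both sub-0.1 p.p. recovery
when the precondition holds and the saturation bias that appears when
it does not.  `propagate_t1_error()` gives the first-order sensitivity
of water content to a $T_1$ bias, $|\partial \ln C / \partial T_1|\,
\delta T_1$, verified against finite differences.

## The simulator and phantoms

`simulate_megre()` and `simulate_afi()` evaluate the forward models
voxel-wise and add complex Gaussian noise before taking the magnitude,
producing Rician statistics (Rayleigh floor $\sigma\sqrt{\pi/2}$ in
signal-free regions, verified in closed form).  SNR is defined as the
true first-echo signal of the low-flip acquisition divided by $\sigma$.
When a phantom defines an off-resonance field, echo phases encode
$2\pi\,\Delta f\,TE$ and, optionally, the magnitude is attenuated by
$\prod_i |\mathrm{sinc}(g_i d_i TE)|$ — the standard linear-gradient
dephasing factor, with $g_i d_i$ the across-voxel frequency difference
per axis.  All randomness flows through explicit seeds.

Two phantoms are provided.  The tube phantom mimics a physical
water/heavy-water dilution phantom: eight disjoint cylinders spanning
50–100% water content (one at exactly 100% for calibration) with
paramagnetically shortened $T_1$ values of 400–2500 ms; the exact
mixture ratios of such phantoms are implementation choices, so the
defaults spread evenly over the stated range with tissue-like values in
the middle tubes.  The brain phantom is piecewise constant on nested
ellipsoids — a subarachnoid CSF rim, a grey-matter shell, a
white-matter core and two ventricle ellipsoids — with WM 69.9% / 988 ms
/ 52 ms, GM 80.8% / 1580 ms / 57 ms and CSF 100% / 4300 ms / 800 ms,
overlaid with a smooth centre-peaked transmit field (±15%), an order-4
polynomial receive field (±20%) and a smooth ±30 Hz off-resonance
field.

What the phantoms deliberately do **not** contain: partial-volume
mixing, anatomical texture, motion or flow, imperfect spoiling,
magnetisation-transfer effects, k-space or parallel-imaging artefacts,
and phase offsets at $TE = 0$ (receive-coil phase).  Recovery on these
phantoms therefore demonstrates correctness of the inversion chain, not
in vivo accuracy: effects excluded here are exactly the systematic
deviations such a method faces on real data.

## Validation design and problem sizes

The recovery tests separate two questions.  *Is the inversion correct?*
— answered on noiseless phantoms where the forward signal follows the
fitted model exactly (intravoxel dephasing disabled); the full pipeline
then recovers water content to well under 0.5 p.p. and $T_1$/$T_2^*$ to
well under 1% in every class of a 64³ phantom, with true transmit and
receive fields supplied.  *Do the mitigations help under model
violations?* — answered separately: with strong simulated dephasing the
$TE_{\max}$ cutoff demonstrably reduces the $T_2^*$ bias relative to
fitting all echoes, and the AFI route is bounded as described above.
Long-$T_2^*$ compartments (CSF at 800 ms) are near the edge of what an
18-echo, 45.6 ms readout can determine, and even mild attenuation
biases them noticeably — the main reason the noiseless/dephasing split
matters, and a known limitation shared with any short-readout protocol.

Monte Carlo flip-angle optimisation simulates a white-matter-like
reference voxel (70%, 1000 ms, 50 ms; configurable) at $TR = 50$ ms,
SNR 20, 1000 replicates per candidate pair, and declares a pair
feasible when the relative bias and standard deviation of both water
content and $T_1$ stay below 10% of truth.  The (7°, 40°) operating
pair sits inside the feasible region, which empties as SNR drops to 2;
the spread metrics scale like $1/\mathrm{SNR}$ in the high-SNR regime,
as they must.  Validation sizes throughout the suite (64³ pipeline
grids, 1000-voxel oracle comparisons, 1000-replicate Monte Carlo cells)
were chosen so each property is measured with comfortable sampling
margin while the whole suite stays fast enough to run routinely.

## Known limitations

* Ideal spoiling is assumed end to end; residual unspoiled
  magnetisation on real scanners biases $T_1$ in a flip-angle- and
  TR-dependent way that neither the simulator nor the fits model.
* The AFI refinement's nominal-$T_1$ assumption leaves a percent-level
  transmit-field residual in tissue whose $T_1$ differs strongly from
  the assumed value.
* The receive-bias estimator presumes a smooth multiplicative field and
  a few-class intensity structure; it is not a substitute for a
  measured receive field on data that violate either.
* Off-resonance estimation is bounded by the echo-spacing Nyquist limit
  for uniformly spaced trains, and no spatial unwrapping is performed.
* CSF-like $T_2^*$ values are poorly constrained by the 45.6 ms echo
  train; the clip at 1.5 s bounds, but does not fix, this.
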