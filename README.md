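# mriwater

Quantitative mapping of free water content (H2O), longitudinal
relaxation time (T1) and effective transverse relaxation time (T2*) of
the brain from a two-point multi-echo gradient-echo (meGRE) protocol,
implemented in R, together with a forward simulator and digital phantoms
that validate every processing stage by parameter recovery.

## Who this is for

Researchers in quantitative MRI who want a self-contained, testable
implementation of two-point water-content relaxometry: the voxel-wise
fits, the transmit/receive field corrections, the cerebrospinal-fluid
(CSF) calibration, and the Monte Carlo flip-angle optimisation — plus a
signal simulator to study protocol choices without scanner time.

## The method

The spoiled meGRE signal at echo time TE is modelled as

    S(TE) = M0 · exp(-TE/T2*) · sin(α_eff) (1 - E) / (1 - E cos(α_eff)) · B1-,
    E = exp(-TR/T1),   α_eff = B1+ · α_nom

Two meGRE acquisitions at TR = 50 ms with nominal flip angles 7°
(M0-weighted) and 40° (T1-weighted), 18 echoes (TE = 2.2 ms, ΔTE =
2.55 ms), plus an actual-flip-angle-imaging (AFI) acquisition (TR1 =
125 ms, TR2/TR1 = 5, 40°) are processed in sequence:

1. **B1+**: closed-form AFI inversion `α_eff ≈ arccos((r n - 1)/(n - r))`
   with `r = S2/S1`, `n = TR2/TR1`, then per-voxel refinement against the
   exact two-TR steady state ([`afi_refine()`]).
2. **T1**: per-voxel minimisation of the difference of the two
   flip-angle signals after dividing each by its saturation factor
   `C(T1, B1+, α)`, over the first three echoes; estimates above 6 s are
   clipped ([`fit_t1_two_point()`]).
3. **T2***: weighted log-linear fit of the echo decay with weights
   |S(TE)|, restricted per voxel to echoes below `TE_max`, a cutoff set
   by the local field gradient from the echo phase; clipped at 1.5 s
   ([`fit_t2star()`], [`compute_te_max()`]).
4. **M0**: the first three echoes corrected for T2* decay, the
   T1/B1+/flip saturation factor and the receive field B1- (measured, or
   estimated by intensity clustering + polynomial bias fitting,
   [`estimate_receive_bias()`]).
5. **H2O**: calibration to 100% water over ventricular CSF (CSF
   probability ≥ 0.99, T1 > 2900 ms, T2* > 500 ms, inside a ventricle
   ellipsoid): `H2O = C_norm · M0` ([`normalize_h2o()`]).

A fully relaxed long-TR single-flip-angle variant ([`h2o_long_tr()`]),
Monte Carlo optimisation of the flip-angle pair
([`monte_carlo_optimize()`]) and Gaussian tissue-histogram statistics
([`fit_tissue_histogram()`]) complete the toolbox.

## Worked example

Simulate a noisy brain phantom at SNR 100 and run the full chain with
the transmit field estimated from AFI and a known receive field:

```r
library(mriwater)

ph  <- make_brain_phantom(dim = c(48, 48, 48), voxel_size = c(4, 4, 4), seed = 1)
pr  <- default_protocols()
sigma <- spgr_signal(69.9, 988, 52, 2.2, 50, 7) / 100     # SNR 100 in WM
low  <- simulate_megre(ph, pr$low,  noise_sigma = sigma, seed = 1)
high <- simulate_megre(ph, pr$high, noise_sigma = sigma, seed = 2)
afi  <- simulate_afi(ph)

rule <- normalization_rule(ellipsoid = ph$norm_ellipsoid)
maps <- run_pipeline(low, high, afi = afi, csf_prob = ph$class_probs$csf,
                     b1minus = ph$b1minus, rule = rule)
print(maps)
#> Quantitative parameter maps (T1, T2*, M0, H2O, B1+, B1-)
#>   b1_invalid_frac: 0.6187
#>   t1_clipped_frac: 4.521e-05
#>   t1_invalid_frac: 0.5342
#>   t2star_clipped_frac: 0.359
#>   t2star_invalid_frac: 0
#>   m0_invalid_frac: 0.5342
#>   norm_mask_voxels: 344
#>   c_norm: 1.013
```

The invalid/clipped fractions are dominated by the signal-free
background (Rayleigh noise has no decay to fit, so background T2*
clips at the 1.5 s bound); `c_norm` close to 1 means the corrected M0
is already on the percent scale in this simulation.  Tissue values from
Gaussian histogram fits over the 99% probability masks:

```r
wm <- tissue_mask(ph$class_probs$wm)
gm <- tissue_mask(ph$class_probs$gm)
fit_tissue_histogram(maps$h2o$h2o, wm, tissue = "wm")[c("mu", "sigma")]
```

|        | mu      | sigma |
|--------|---------|-------|
| WM H2O | 70.8 %  | 0.94  |
| GM H2O | 81.4 %  | 1.10  |
| WM T1  | 988 ms  | 11.5  |
| GM T1  | 1559 ms | 21.9  |

against ground truth WM 69.9% / 988 ms and GM 80.8% / 1580 ms.  The
residual GM offsets come from the nominal-T1 assumption inside the AFI
refinement; supplying the true transmit field instead recovers the
truth to numerical precision (see the methods vignette).

A thin command-line wrapper around the same functions is installed at
`inst/cli/mriwater.R` with subcommands `simulate`, `fit-b1`, `fit-t1`,
`fit-t2star`, `fit-h2o`, `optimize`, `evaluate` and `run`, reading and
writing NIfTI-1 volumes and a YAML configuration.

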