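# sparsedce

Quantifying **subtle blood–brain-barrier (BBB) leakage** from a sparsely
time-sampled DCE-MRI protocol built on quantitative T1 maps.

Subtle BBB disruption leaks gadolinium contrast agent into brain tissue at
rates of only $K_i \sim 10^{-4}$–$10^{-3}\ \mathrm{min^{-1}}$. Measuring it
reliably needs a long (>20 min) acquisition window — but because the tissue
signal changes so slowly, a few high-SNR quantitative T1 maps at strategic
times can replace continuous dynamic scanning, freeing scanner time for
other sequences. `sparsedce` is for imaging scientists designing or
analysing such protocols. It provides:

* **Pharmacokinetic core** — the extended Tofts forward model
  $C_t(t) = v_p C_p(t) + K^{trans}\!\int_0^t C_p(\tau)
  e^{-K^{trans}(t-\tau)/v_e} d\tau$, the Patlak graphical estimator
  ($y = C_t/C_p$ vs $x = \int_0^t C_p d\tau / C_p$; slope $K_i$, intercept
  $v_p$), and the signal conversions
  $C = \Delta R_1 / r_1$ (with $r_1 = 4.2\ \mathrm{mM^{-1}s^{-1}}$ at 7 T)
  and $C_p = C_b/(1-Hct)$ ($Hct = 0.45$).
* **Protocol simulator** — a vectorized Monte-Carlo engine
  (`run_monte_carlo()`, `sweep_num_maps()`, `sweep_last_time()`) for the
  two design questions: how many postcontrast T1 maps, and how late to
  place the last one.
* **Voxelwise pipeline** — `voxelwise_patlak()` turns a precontrast T1
  map, two or more postcontrast T1 maps and a venous blood curve into
  $K_i$ and $v_p$ maps, with percentile-trimmed ROI summaries
  (`roi_summary()`) and a paired WM-vs-GM Wilcoxon comparison
  (`compare_wm_gm()`).
* **Digital phantom** — `make_phantom()` generates a fully seeded synthetic
  dataset (T1 volumes, 90-volume dynamic blood series, masks, ground
  truth) for end-to-end validation without scanner data.

Tabular results are tibbles, fits have `tidy()`/`glance()`/`autoplot()`
methods, and volumes read/write NIfTI-1 via RNifti.

## Worked example

Precision of the two-map protocol (first map at 4 min 20 s, last at
30 min) versus continuous scanning (seven maps), at the default tissue
noise of 2.0e-3 mM and white-matter kinetics
($K^{trans} = 5\times10^{-4}\ \mathrm{min^{-1}}$, $v_p = 0.036$,
$v_e = 0.05$):

```r
library(sparsedce)
s2 <- run_monte_carlo(sim_config(scheme = make_scheme(4.333, 30, 0),
                                 n_runs = 250000L, seed = 7L))
s7 <- run_monte_carlo(sim_config(scheme = make_scheme(4.333, 30, 5),
                                 n_runs = 250000L, seed = 8L))
round(s2$sd_ki / s7$sd_ki, 3)
#> [1] 1.23
s2[, c("mean_ki", "sd_ki", "pct_diff")]
#>     mean_ki     sd_ki pct_diff
#> 1 0.0004174 8.104e-05   -16.53
```

Dropping from seven maps to two costs only a factor ~1.2 in precision,
while the accuracy (the negative bias from contrast backflux, here
−16.5%) is essentially unchanged — the basis for the sparse protocol.

End-to-end phantom validation — generate, quantify, compare against the
known truth (relative error is measured against the noiseless Patlak
value, which absorbs the predictable backflux bias):

```r
ph <- make_phantom(phantom_spec())      # 32^3 voxels, seeded
recovery_report(ph)
#>   class map   true noiseless_patlak recovered_mean recovered_sd n_kept rel_error
#> 1    WM  ki 0.0005          0.00043       0.000428     1.23e-04   9728  -0.00446
#> 2    WM  vp 0.0360          0.03625       0.036379     2.35e-03   9728   0.00365
#> 3    GM  ki 0.0008          0.00063       0.000626     6.63e-05   9728  -0.00618
#> 4    GM  vp 0.0490          0.04960       0.049788     1.35e-03   9728   0.00385
```

Class means land within ~0.6% of truth, and the phantom's higher GM
leakage and plasma volume are recovered. A five-subject paired comparison
(values in $10^{-4}\ \mathrm{min^{-1}}$):

```r
compare_wm_gm(wm = c(4.1, 4.6, 5.2, 4.4, 4.9),
              gm = c(7.6, 8.1, 8.4, 7.2, 8.3))
#>   statistic p_value mode           n
#> 1        15  0.0422 asymptotic     5
```

## Command line

A launcher script ships at `inst/cli/sparsedce`
(`system.file("cli", "sparsedce", package = "sparsedce")`):

```sh
sparsedce simulate-protocol --config cfg.yaml --out results.csv
sparsedce optimize-timing   --config cfg.yaml --out results.csv
sparsedce make-phantom      --config cfg.yaml --out-dir phantom/
sparsedce fit --pre pre.nii.gz --post post1.nii.gz post2.nii.gz \
  --post-times 4.333 25 --dynamic dyn.nii.gz --sss-mask sss.nii.gz \
  --wm-mask wm.nii.gz --gm-mask gm.nii.gz --out-dir results/
```

Configs are YAML overlaid on documented defaults (`default_config()`);
every run writes its resolved config and seed beside its outputs.

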