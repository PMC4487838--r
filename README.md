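# latrack

Left atrial (LA) feature tracking, volumetry and agreement statistics for
cine cardiovascular magnetic resonance (CMR).

## What it is for

LA size and phasic function — how the atrium fills as a *reservoir* during
ventricular systole, passively empties as a *conduit* in early diastole and
actively pumps as a *booster* in late diastole — are sensitive markers of
cardiovascular disease. On cine CMR these are quantified by drawing one
endocardial contour at the frame where the LA is largest (ventricular
end-systole) and letting template-matching *feature tracking* propagate it
through the whole cardiac cycle. `latrack` implements this chain for
researchers who want an open, testable version of that workflow:

* **Tracking** — each contour point carries a 10 × 10 mm intensity patch
  that is matched frame-to-frame by zero-normalized cross-correlation
  within a search window, with subpixel refinement, symmetric
  (forward–backward) matching and cyclic drift compensation.
* **Volumetry** — per-frame LA volume by the biplane area–length method
  from the 2- and 4-chamber views,

  `V = 0.848 · A_4ch · A_2ch / ((L_2ch + L_4ch)/2)`,

  (0.848 being the printed rounding of 8/(3π)), or by Simpson's rule of
  disks from a short-axis stack, `V = Σ A_i · (thickness + gap)`.
* **Phasic function** — V<sub>max</sub>, V<sub>min</sub> and the
  pre-atrial-contraction volume V<sub>preA</sub> (at the P wave, or where
  the volume rate is closest to zero at the conduit-to-booster
  transition), and the ejection fractions
  `LAEF = (Vmax−Vmin)/Vmax`, `LAPEF = (Vmax−VpreA)/Vmax`,
  `LAAEF = (VpreA−Vmin)/VpreA` (× 100).
* **Strain** — global longitudinal strain as the fractional change of
  endocardial arc length referenced to the minimum-volume frame, its time
  derivative, and the four peaks S<sub>max</sub>, SR<sub>max</sub>,
  SR<sub>e</sub>, SR<sub>a</sub>.
* **Agreement statistics** — the toolbox used to validate such
  measurements: Bland–Altman limits of agreement, paired t, graded Pearson
  correlation, two-way random single-measures ICC(2,1), Passing–Bablok
  regression, and the reliability indices `SEM = SD·√(1−ICC)` and
  `SDC = 1.96·√2·SEM`.
* **Phantom** — a synthetic deforming-atrium cine phantom (tri-phasic
  ellipsoid with advected speckle texture) with analytic ground-truth
  contours, volumes, strain and phase timing, so the entire chain is
  verifiable without any image download.

## Worked example

```r
library(latrack)

ph  <- make_phantom(phantom_config(seed = 42))   # 30 frames @ 35 ms, 1 mm/px
gt  <- ph$ground_truth
ref <- gt$phase_indices$i_max                    # contour drawn at end-systole

fit <- la_analyze(ph$cine_2ch, ph$cine_4ch,
                  gt$contours_2ch[[ref]], gt$contours_4ch[[ref]],
                  ref_frame = ref)
summary(fit)
```

```
Left atrial feature-tracking analysis

Frames: 30 (dt 35 ms), biplane method
LA phases (1-based frames): i_max 11, i_preA 24, i_min 30
LA volumes: Vmax 83.72, VpreA 68.12, Vmin 43.82 ml
LA function: LAEF 47.7%, LAPEF 18.6%, LAAEF 35.7%
Strain peaks: Smax 23.53%; SRmax 0.0964, SRe -0.0496, SRa -0.1110 %/ms
Tracking quality: 2ch mean 0.982 (closure 0.25 mm), 4ch mean 0.984 (closure 0.26 mm)
```

The phantom's analytic truth here is V<sub>max</sub> = 83.78 ml (a
40 × 25 × 20 mm ellipsoid), LAEF 46%, S<sub>max</sub> 22.8%: the tracked
estimates land within 2% on volume and ~1 percentage point on the ejection
fractions, and the detected phase frames (11, 24, 30) are exact.
`coef(fit)` returns the ten reported parameters as a named vector;
`plot(fit)` draws the volume / volume-rate / strain / strain-rate panels.

Agreement statistics work on any paired table:

```r
set.seed(1)
truth <- rnorm(22, 85, 30)
p <- paired_measurements(truth + rnorm(22, 0, 8), truth + rnorm(22, -2, 8),
                         labels = c("visit1", "visit2"),
                         parameter = "Vmax", units = "ml")
agreement_stats(p)
```

```
Vmax (ml) (n = 22)
  difference 0.014 +/- 8.553, LoA [-16.750, 16.779], t p = 0.994
  Pearson r 0.959 (excellent); ICC 0.960 (p = 3.24e-13)
  Passing-Bablok slope 0.994, intercept -0.109
  SEM 1.70, SDC 4.73
```

A command-line wrapper is installed at `inst/cli/latrack`
(`simulate`, `track`, `quantify`, `run-all`, `agree`).

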