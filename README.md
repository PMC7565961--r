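# myomorph

Automatic detection and morphometric characterization of cardiomyocytes
(CMs) in multi-channel immunofluorescence images of cardiac tissue, with
quantification of connexin-43 (CX43) expression and of its
polar-versus-lateral distribution.

## Who this is for

Cardiac electrophysiology and tissue-remodeling studies routinely need,
from confocal images of stained ventricular sections: how big the myocytes
are, how much CX43 they express, and how much of that CX43 has left the
intercalated discs at the cell poles for the lateral membrane —
lateralization being a structural correlate of arrhythmogenic remodeling.
Manual delineation takes hours per image; `myomorph` does the full chain
automatically and also scores how well the automatic delineation agrees
with a manually drawn mask.

## Method in brief

Given calibrated 8-bit channels `c1` (CM body marker: SERCA2 or F-actin),
`c2` (CX43) and `c3` (interstitium, e.g. WGA), each channel is optionally
histogram-equalized, binarized at a per-channel threshold (`pixel > thr`),
opened with an `nr x nr` square window to remove noise and grown by
`ng_it` dilations with an `ng x ng` window. The automatic CM mask keeps a
`Mc1` pixel unless it is active in both `Mc2` and `Mc3`. Cell boundaries
are traced by Moore border following on 8-connected components (external
contours only), kept if area > 100 um^2 and perimeter > 40 um, and each is
enclosed in its minimum-area rotated rectangle (rotating calipers). With a
diagonal vertex projection the rectangle is padded by
`h = 2 * ng_c2 * ng_it_c2` pixels to undo the cell-mask shrinkage caused by
CX43-mask dilation. Morphometry: `L` = mean long side of fitted and padded
box, `W` = fitted short side, `R = L/W`, `A = L*W`, with plausibility
filters `20 < L < 200` um, `5 < W < 50` um.

CX43 is quantified on `Mc4`, the equalized raw CX43 channel binarized at a
fixed threshold 254: expression `Cex = 100 |Mc4 ∩ Mt| / |Mt|` against the
tissue mask `Mt = Mc1 ∪ Mc2 ∪ Mc3`, noise `r = 100 |Mc4 \ Mt| / |¬Mt|`.
Each padded box is split into four equal compartments along its long axis
(`P0`, `P3` polar; `P1`, `P2` lateral), `F_i = |H_i ∩ Mc4| / N_i`, and

    Clat = 100 * (F1 + F2) / (F0 + F1 + F2 + F3)

is the lateralization percentage. The pooled Clat histogram is modeled by
`f(x) = a e^(-bx)`; its closed-form integral gives the fraction of cells
in any lateralization range. Agreement with a manual mask uses the box
overlap `I_ij = 100 |Bm_i ∩ Ba_j| / |Bm_i|`, per-manual-cell maxima, their
percentile curve (k = 1..100) and its trapezoidal AUC.

A seeded synthetic-scene generator renders rectangular cells with polar
CX43 bands and a planted lateral fraction, with exact vector ground truth,
so the whole pipeline is testable without microscopy data.

## Worked example

```r
library(myomorph)

scene    <- synthetic_scene(n_cells = 5, seed = 42)   # 768x768 px, 0.21 um/px
rendered <- render_scene(scene)
cfg      <- synthetic_scene_config(scene)             # pure-threshold config
records  <- detect_myocytes(rendered$channels, cfg)
cm_table(records)[, c("id", "L_um", "W_um", "R", "A_um2", "angle_deg", "Clat")]
#>   id L_um W_um    R A_um2 angle_deg Clat
#> 1  1 57.1 11.4 5.02   650      88.0 17.1
#> 2  2 51.6 10.1 5.12   520     -22.4 38.6
#> 3  3 35.7 12.7 2.81   453      59.1 50.0
#> 4  4 43.7 17.2 2.54   752      78.2 56.0
#> 5  5 45.6 17.4 2.62   791     -65.8 54.8
```

All five planted cells are recovered; lengths and widths match the ground
truth to sub-pixel accuracy, and each `Clat` sits within a fraction of a
percentage point of 100x the planted lateral fraction (17.2, 38.5, 49.8,
56.2, 54.9 for these five cells). Evaluating against the ground-truth
manual mask:

```r
res <- evaluate_manual_mask(ground_truth_manual_mask(scene), records, cfg)
res
#> <evaluation_result> Nm 5, Na 5, matched >50%: 5, AUC 1.000
```

Every manual cell is matched above 50% overlap and the overlap percentile
curve integrates to AUC = 1: perfect agreement. Integrating the reference
exponential lateralization model:

```r
m <- exp_fit_model(a = 0.03425, b = 0.033)
integrate_fraction(m, 0, 20)   # 0.501 - half the cells below 20% lateralization
integrate_fraction(m, 0, 50)   # 0.839 - polar CX43 dominant in ~84% of cells
```

A command-line wrapper covers the same workflow
(`inst/cli/myomorph.R detect|evaluate|synthesize`), reading a YAML
configuration that mirrors the per-channel parameter table
(`write_config(default_config(), "cfg.yaml")`).

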