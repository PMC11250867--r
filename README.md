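# ihcquant

Quantitative scoring of chromogenic (DAB/hematoxylin) brightfield
immunohistochemistry for R.

Chromogenic IHC reports antibody binding as a brown DAB precipitate
over a blue hematoxylin counterstain. Getting trustworthy numbers out
of such slides requires physical stain separation, a knockout-anchored
notion of specificity, and reproducible object-level scoring. This
package implements that whole chain:

- **Stain separation.** Stains mix additively in optical density
  (Beer–Lambert): `I_c = 255·10^(−(M·A)_c)` with the standard H-DAB
  stain-vector matrix `M`. `unmix_stains()` inverts the model per
  pixel into hematoxylin / DAB / residual OD maps.
- **Knockout-controlled specificity (S/N index).** For matched
  wild-type and knockout images, the per-bin ratio of masked DAB
  intensity frequencies `r_i = (f_wt,i + ε)/(f_ko,i + ε)` is
  integrated with intensity-proportional weights,
  `index = Σ_i (i/Σ_j j)·r_i`, so an uninformative antibody scores 1
  and specific staining scores ≫ 1.
- **Zonation.** Wide-line (27.4 µm) intensity profiles along
  hand-drawn anatomical axes, normalized-position averaging, and a
  LOWESS best fit (tricube, 2 robustness iterations).
- **Object scoring.** Nuclei segmentation with size/circularity
  classification (hepatocyte-like vs Kupffer-like), perinuclear
  cytosolic signal, endothelial signal inside SMA⁺ vessel rings, and
  percent area in the 50–255 intensity window.
- **Puncta.** Difference-of-Gaussian detection of necrosome-like spots
  with the 2×-of-cell-mean acceptance filter, per-cell summaries and
  per-100-cells regional rates.
- **Expression matrices.** Percent-of-cells-expressing tables with
  cross-ontology Pearson correlation, and zone-score aggregation of
  gene × cluster log-fold-change matrices (percent-of-maximum
  eligibility, top-5 selection).
- **Synthetic scenes.** A generator that renders two-stain brightfield
  images (nuclei, gradients, vessels, puncta, matched knockouts)
  through the same optical model, with exact ground truth — every
  stage above is validated against it.

Results come back as tibbles; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

Render a matched wild-type/knockout scene with a planted cytoplasmic
DAB OD of 0.5 and compute its specificity index:

```r
library(ihcquant)

pair <- make_wt_ko_pair(simulate_snr_scene(specific_od = 0.5,
                                           n_nuclei = 16, seed = 42))
res <- sn_from_images(pair$wt, pair$ko)
res
#> Knockout-controlled S/N result
#>   specificity index: 25.9493 (pseudocount 0.000141)
#>   masked pixels: WT 7094, KO 7094
```

The index is the weighted integral of the WT/KO ratio curve: 1 would
mean the "staining" is indistinguishable from the knockout; ~26 means
the masked DAB intensities are heavily enriched in high bins only when
the target protein is present. `tidy(res)` returns the 256-bin curve,
`autoplot(res)` draws it.

Segment and classify nuclei on the same synthetic liver-like field:

```r
out <- render_scene(simulate_nuclei_scene(10, 10, seed = 1))
gray <- to_inverted_gray(unmix_stains(out$image)$hematoxylin)
nuc  <- classify_nuclei(segment_nuclei(gray, pixel_size_um = 0.5))
dplyr::count(nuc, class)
#>   class          n
#> 1 hepatocyte    10
#> 2 kupffer       10
head(nuc[c("label", "area_um2", "circularity", "class")], 3)
#>   label area_um2 circularity      class
#> 1     1    62.75   0.9952093 hepatocyte
#> 2     2     9.25   0.6481985    kupffer
#> 3     3     9.25   0.6916378    kupffer
```

All 20 planted nuclei are recovered and classified correctly: large
round nuclei (~63 µm², circularity ≈ 1) versus small elongated ones
(~9 µm², circularity ≈ 0.65).

A thin command-line wrapper ships in `inst/cli/ihcquant`
(`simulate`, `separate`, `snr`, `area`, `run` subcommands) for
manifest-driven batch use.

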