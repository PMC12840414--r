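# toothface

Volumetric analysis of the 3-D correspondence between the maxillary
central incisor (MCI) and facial shape.

## The problem

How closely does the buccal surface of a person's upper central incisor
mirror the shape of their face? Classical prosthodontic guidelines (the
"law of harmony", golden-proportion rules) assert such a correspondence
and use it to choose anterior tooth forms, but most evidence rests on 2-D
photographs and linear ratios. A volumetric protocol instead measures the
correspondence directly on 3-D scans:

1. the buccal patch of the MCI is selected from the intraoral scan with a
   smoothed boundary and **extruded 6 mm** inward into a watertight solid;
2. the solid is **magnified by 15.56**, the mean bizygomatic-to-tooth
   width ratio, so tooth and face become commensurate;
3. tooth and face are aligned to a common reference frame through
   anatomical landmarks (incisal/cervical and proximal-edge midpoints on
   the tooth; glabella, pogonion, menton, labiale superius, zygion and
   alare on the face) and the tooth is placed by tangency rules;
4. a **Boolean intersection** of the tooth solid with the closed facial
   solid yields the superimposed volume, and

```
RTV  = V_total - V_superimposed          (remaining tooth volume, mm^3)
%SI  = V_superimposed / V_total * 100    (superimposition percentage)
```

Higher %SI (lower RTV) means the tooth's buccal morphology tracks the
facial surface more closely. A cohort-statistics layer then reproduces the
published analysis plan — descriptives, Shapiro–Wilk gating, Spearman
correlations, paired and Levene-gated two-sample *t*-tests, Mann–Whitney
U, Cohen's *dz*/*d*, and achieved power via the noncentral *t* and the
Fisher-*z* approximation — on per-subject tables of these volumes.

No raw scans or per-subject tables are public, so the package ships a
seeded synthetic generator with known ground truth: parametric tooth
patches, facial shells whose mid-face is blended toward the tooth surface
with a congruence parameter κ ∈ [0, 1], and cohort tables whose marginals
match the published summaries with a Gaussian-copula rank correlation
between total and remaining volume.

## Worked example

```r
library(toothface)

tooth <- gen_tooth()                                   # synthetic buccal patch
face  <- gen_face(face_shape_params(), tooth, kappa = 0.5)
res <- run_superimposition(tooth$patch, face$shell,
                           tooth$landmarks, face$landmarks,
                           config = pipeline_config())
print(res)
#> <superimposition_result>
#>   V_total            1739667.83 mm^3
#>   V_superimposed     1700049.01 mm^3
#>   RTV                  39618.82 mm^3
#>   %SI                     97.72 %
```

`V_total` is the extruded, scaled tooth solid (about 1.7 × 10⁶ mm³ at the
protocol presets); at half congruence the facial surface already covers
97.7% of it, and the 2.2 mm vertical residual reports how far the two
tangency constraints (incisal→menton, cervical→glabella) are from being
jointly satisfiable by one translation.

The statistics layer recomputes published derived quantities directly from
printed summary inputs:

```r
paired <- paired_t_with_ci(mean_diff = 285052.34, sd_diff = 137012.73, n = 98)
percent_of_mean_with_ci(paired, 1626120.79)
#> estimate      low     high
#>    17.53    15.84    19.22
cohen_dz(285052.34, 137012.73)
#> [1] 2.080481
power_correlation_fisher_z(0.448, n = 98)
#> [1] 0.9969271
```

## Analysis workflow

The `analysis/` scripts run the full study pipeline on synthetic data and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # cohort CSV + subject mesh fixture
Rscript analysis/02_superimpose.R         # end-to-end pipeline + kappa sweep
Rscript analysis/03_cohort_stats.R        # full statistical battery
Rscript analysis/04_power_recomputation.R # effect sizes and achieved power
```

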