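# prostamould

Patient-specific, 3D-printable prostate biopsy moulds with calibrated
needle guides — and the simulation machinery to verify that they target
what they claim to.

## The problem

Fresh, viable prostate-cancer tissue is hard to procure: tumour is not
visibly distinct from benign gland, and standard pathology processing
fixes the specimen. But every MR-US fusion biopsy patient already has 3D
surface segmentations — a prostate boundary and one mesh per MRI-defined
lesion (ROI), exportable as STL. `prostamould` turns those segmentations
into a printable mould: a material-optimised block with the gland cavity
subtracted, an open anterior face for specimen insertion, and cylindrical
needle-guide channels aimed at each lesion's centre of mass. At radical
prostatectomy the explanted gland is placed in the mould and re-biopsied
ex vivo through the guides, yielding fresh tumour tissue for research with
no disruption to the pathology workflow.

The package is for interventional-geometry and translational-research
groups who want to reproduce or extend this workflow, and for anyone who
needs watertight mesh booleans, signed-distance offsetting and targeting
simulation in R.

## The core calculation

For each ROI with centre of mass **c** (volumetric centroid of the closed
surface, by the divergence theorem), a guide is placed on each of the two
nearest block faces, its axis the inward face normal through **c**. With a
fixed needle insertion depth *D* = 50 mm and a needle whose specimen notch
centres *t* mm behind the tip, the notch centre lands exactly on **c**
when the guide-top entry point **e** satisfies

&nbsp;&nbsp;&nbsp;&nbsp;‖**e** − **c**‖ = *D* − *t*,

so the guide tower height is (*D* − *t*) minus the block-face-to-centroid
distance. This calibration identity holds by construction (tested to
10⁻⁶ mm on every emitted guide). Three moulds are built per case — the
original boundary and 1 mm / 2 mm outward signed-distance offsets — to
tolerate segmentation error; all three share one block and one guide plan.

Solids are composed as signed-distance fields (analytic box/cylinder
primitives, narrow-band mesh distances signed by watertight ray parity)
and remeshed by marching tetrahedra, so every emitted STL is watertight —
the printability gate — and volumes check out against independent
voxel-boolean oracles.

## Worked example

```r
library(prostamould)

ph <- generate_phantom(phantom_spec(seed = 5))   # 33 ml gland, one 0.5 ml ROI
models <- build_mould_variants(ph, mould_spec())
models[[2]]
#> mould_model 'phantom-5' offset 1 mm: solid 154.2 ml, cavity 38.4 ml, 2 guides
models[[2]]$guides[[1]]
#> needle_guide A:left-lateral: entry (55.0, -3.0, 4.0), tower 25.0 mm, channel d=2.61 mm
```

The solid is the printable mould (here 154.2 ml of material around a
38.4 ml cavity — the 33 ml gland offset by 1 mm); the guide tower rises
25 mm above the block so that a 50 mm insertion puts the needle notch on
the ROI centroid. Simulating that insertion:

```r
rep0 <- perturbed_hit_rate(models[[1]], ph, error_model(seed = 1), n_trials = 1)
rep0[, c("guide_id", "axis_to_centroid_mm", "notch_roi_intersection_mm", "hit")]
#>         guide_id axis_to_centroid_mm notch_roi_intersection_mm  hit
#> 1 A:left-lateral                   0                        10 TRUE
#> 2     A:superior                   0                        10 TRUE
```

Both guides pass through the centroid exactly (axis distance 0) and the
notch captures 10 mm of lesion — the full diameter of the 5 mm-radius ROI.
Under a 3 mm-SD rigid placement error the hit rate degrades, which is what
the offset variants are there to absorb:

```r
err <- error_model(translation_sigma_mm = 3, seed = 1)
perturbed_hit_rate(models[[1]], ph, err, n_trials = 500)[, c("guide_id", "hit_rate")]
#>         guide_id hit_rate
#> 1 A:left-lateral    0.714
#> 2     A:superior    0.724

summarize_cohort(load_reference_cohort())
#> cohort_summary (n=12)
#>   PSA median 6.38 ng/ml (4.57-14.24)
#>   PSA density median 0.18
#>   prostate size median 36.1 cc
#>   mould-biopsy positivity 100%, GG concordance 50%
```

`load_reference_cohort()` is the packaged 12-patient reference cohort
(`inst/extdata/cohort_table.csv`) from a mould-biopsy feasibility study;
all 12 ex vivo biopsies were cancer-positive and 6/12 matched the
diagnostic Gleason Grade Group.

## Command line

A thin script over the same functions
(`inst/cli/prostamould.R`) exposes `gen-phantom`, `build-mould`,
`validate-targeting`, `summarize-cohort` and `full-check`, driven by a
JSON/YAML config mirroring `run_config()`. Builds write one
`mould_offset<d>mm.stl` per variant plus `mould_manifest.json` (spec echo,
guide table, volumes, checks, seed); identical configs give byte-identical
outputs.

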