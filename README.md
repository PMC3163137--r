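# lvdquant

Whole-slide quantification of immunostained lymphatic vessels for digital
pathology. Given an RGB scan of a tumor section stained for podoplanin
(D2-40, permanent red) with hematoxylin counterstain, plus a manually
delineated tumor mask, `lvdquant` segments every lymphatic vessel section,
computes the lymphatic vessel density (LVD, vessel sections per mm² of
stromal tissue) over the whole section and the 2 mm peritumoral band, and
describes the spatial distribution of vessels around the tumor — replacing
the observer-dependent "hot spot" counting protocol with an objective
whole-slide measurement.

The core method:

* **Vessel walls** — excess-red transform *ER = 2R − B − G* followed by
  Kapur–Sahoo–Wong maximum-entropy thresholding of its histogram.
* **Vessel lumens** — rescued as the lightest structures in the tissue
  (luminance above a fraction of the background mean), kept only when
  adjacent to a detected wall; wall ∪ lumen is hole-filled and labeled
  8-connectedly into vessel objects. Non-lymphatic podoplanin-positive
  detections are removed via a user exclusion mask.
* **Tissue footprint** — Tsai moment-preserving thresholding of the
  8×-decimated blue channel; stroma = tissue − tumor.
* **Peritumoral band and spatial statistics** — exact Euclidean distance
  transform of the tumor complement; LVD = count/surface per region;
  vessel-to-tumor distance histograms; directional profiles in eight 45°
  sectors around the tumor mass centre with linear vessel density
  (vessels/mm) drawn on a polar graph.

A ground-truthed synthetic slide generator (`generate_slide()`) renders
realistic tile geometry (glass, tissue blob, red annular walls, bright
lumens, tumor blobs, confounder clumps, pixel noise) so the entire pipeline
is validated end to end without any real slide.

## Worked example

```r
library(lvdquant)

out <- generate_slide(synth_config(seed = 42))   # 2000x2000 px, 50 vessels
seg <- segment_slide(out$image)
seg
#> <vessel_segmentation> 50 vessel objects (0 excluded), wall t = 77,
#>   tissue t = 161, tissue area 1.12 mm^2

res <- run_pipeline(out$image, tumor_mask = out$truth$tumor_mask,
                    out_dir = "analysis")
res$lvd
#>         region surface_mm2 vessel_count lvd_per_mm2
#> 1 whole_tissue    1.015009           50    49.26067
#> 2  peritumoral    1.015009           50    49.26067

res$directional_profile
#>   sector_center_deg count density_per_mm
#> 1                 0     8            4.0
#> 2                45     5            2.5
#> ...
```

The wall threshold (77) separates red-stained endothelium (excess-red
≈ 300) from tissue (≈ 50); the tissue threshold (161) splits counterstained
tissue from glass on the blue channel. LVD is the vessel count divided by
the stromal surface in mm² — on this 1.3 × 1.3 mm tile the whole stroma
lies within 2 mm of the tumor, so the whole-tissue and peritumoral reports
coincide. The directional profile counts vessels per 45° sector within
(0, 2] mm of the tumor edge; `autoplot()` on it draws the polar graph.
Against the generator's ground truth:

```r
evaluate_detection(out$truth$vessel_labels, seg)
#>   n_true n_detected n_matched_true n_matched_detected recall precision
#> 1     50         50             50                 50      1         1
```

A thin shell entry point is installed at `inst/exec/lvdquant`
(subcommands `synth`, `segment`, `all`).

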