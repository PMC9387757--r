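# ielec — intracranial electrode localization in R

`ielec` is a headless pipeline for researchers working with stereo-EEG
(sEEG) and electrocorticography (ECoG): it takes a post-implant CT, a
pre-implant MR, the channel names from the recording, and (optionally) a
segmentation, a cortical surface and a template MR, and produces contact
positions in subject anatomy, anatomical labels per contact, and contact
positions warped to the template brain.

The chain, stage by stage:

* **CT → MR affine registration** by mutual-information maximization over a
  coarse-to-fine pyramid: `I(A;B) = Σᵢⱼ p(i,j) log[p(i,j)/(p(i)p(j))]` on a
  32-bin joint intensity histogram, optimized by a derivative-free
  coordinate search over translation → rigid → full affine parameters, with
  an optional manual pre-alignment seed for extreme poses.
* **Snap-to-center**: each roughly marked contact is refined to the
  intensity-weighted center of mass of the voxel region that monotonically
  decreases in intensity away from the brightest voxel near the seed
  (26-connectivity, intensity floor 0.25 × peak, 5 mm radius cap). Names are
  constrained to the predetermined channel list of the montage.
* **Brain-shift compensation**: ECoG grids sink below the pre-operative
  pial surface; selected contacts are moved to the exact nearest point on a
  leptomeningeal surface mesh (produced from a pial mesh by
  volume-preserving Laplacian smoothing).
* **Anatomical labeling**: labels sampled from an integer segmentation
  volume in a 2 mm ball per contact, reported as fractions against a
  FreeSurfer-style color LUT, including deep-to-superficial label sequences
  per sEEG shaft.
* **Template warping** by symmetric diffeomorphic registration (greedy
  demons with maintained forward/backward displacement fields), which maps
  contacts to template space more accurately than any affine
  (Talairach-style) transform when the underlying anatomy differs
  nonlinearly.

Everything is validated against a deterministic synthetic head phantom
(`make_phantom()`) that ships with known ground truth for every stage. See
the methods vignette (`vignettes/electrode-localization-methods.Rmd`) for
the algorithms, parameter defaults and design rationale.

## Worked example

```r
library(ielec)

# a synthetic head with known ground truth: CT misaligned from MR by a
# seeded rigid pose, 10 sEEG contacts + a 4x4 ECoG grid as CT blobs
ph <- make_phantom(phantom_spec(seed = 7))

# 1. register CT to MR by mutual information
reg <- compute_affine_registration(ph$ct, ph$mr,
                                   stages = c("translation", "rigid"))
transform_discrepancy(reg$affine, ph$true_ct_to_mr, c(31.5, 31.5, 31.5))
#> $translation_mm
#> [1] 0.0686        # well under half a voxel
#> $rotation_deg
#> [1] 0.863         # under a degree

# 2. snap a jittered contact estimate to its CT blob center
truth_ct <- apply_affine(invert(ph$true_ct_to_mr),
                         montage_positions(ph$montage_truth)["LPM4", ])
snap <- snap_to_center(ph$ct, truth_ct + c(1.5, -1, 0.5))
snap
#> <ielec_snap> center (20.14, 40.41, 33.65) mm, 45 voxels, moved 1.87 mm

# 3. project the ECoG grid back onto the leptomeningeal surface
proj <- project_sensors_onto_brain(ph$montage_truth, ph$lepto,
                                   channels = paste0("G", 1:16))
round(range(attr(proj, "shift_mm")), 2)
#> [1] 2.92 2.94     # the 3 mm brain-shift depression, undone

# 4. anatomical labels along the shaft, deep to superficial
shaft_label_sequence(ph$seg, ph$lut, ph$montage_truth, "LPM")[1:3, ]
#>   name number                 label fraction
#> 1 LPM1      1       Cerebral-Cortex    0.871
#> 2 LPM2      2 Cerebral-White-Matter    1.000
#> 3 LPM3      3 Cerebral-White-Matter    0.879

# 5. warp contacts to the template brain
field <- compute_sdr_registration(ph$mr, ph$template_mr)
warped <- apply_point_registration(montage_positions(ph$montage_truth),
                                   field, "forward")
```

The same chain runs end-to-end from files via `run_pipeline()` (JSON
config; see `pipeline_defaults()`) or from a shell through the bundled CLI:

```sh
ielec phantom  --out phantom/ --seed 7
ielec register --moving phantom/ct.nii.gz --fixed phantom/mr.nii.gz --out reg.json
ielec pipeline --config config.json
```

(`ielec` is installed at `exec/ielec` inside the package directory;
`system.file("exec", "ielec", package = "ielec")` gives the full path.)

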