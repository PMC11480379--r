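# tmjtrack

Automatic tracking of mandibular motion in real-time MRI of the
temporomandibular joint (TMJ), for researchers quantifying condylar
kinematics (orthodontics, maxillofacial surgery, joint biomechanics) who
today rely on placing two landmarks on every frame by hand.

## What it does

Real-time MRI records the jaw at ~10 frames/s, 0.75 mm resolution, a few
sagittal slices. `tmjtrack` recovers the rigid per-frame transform of the
mandible automatically:

1. **Intensity lift.** Pixels of the rater-drawn mandible area become 3D
   points `(x, y, z)` with `z` the normalized grey value scaled into
   spatial units
   (`scale = interdecile(minor-axis projections) / (8 · interdecile(greys))`,
   per-frame deciles matched to the first frame).
2. **Oriented, weighted cloud.** Per-point normals from 3×3 neighbourhood
   PCA; points with near-vertical normals (< 8° — flat intensity, no
   information) removed; condyle points ×2, middle-slice points ×2.5.
3. **Point-to-plane LMS registration.** Repeated cycles of nearest-point
   pairing, a rigid fit minimising
   `Σ wᵢ [nᵢ · (R xᵢ + T − qᵢ)]²`, and a diagonal-scaling refinement
   `y = T + R H x`, `H = diag(h11, h22)`, initialised from a rough transform
   fitted (SVD) to three mandibular landmarks interpolated between sparse
   keyframes (first/last scan frame, first/last cycle frame, every 25th —
   seven keyframes per 100-frame scan).
4. **Superimposition error.** `mean |nᵢ · (pᵢ − qᵢ)|` — pair offsets
   projected on the model normals; dimensionless (mixes grey and space).
5. **Analysis.** Pathways of condyle superior, circle-fit condyle centre
   (Pratt 1987), gonion; inclination; instantaneous centre of rotation
   (fixed point of the incremental motion, undefined under 0.1°);
   most-distant-third medians and one-sided Wilcoxon signed-rank tests
   against 1 mm / 1° thresholds.

The two-landmark **manual baseline** (translation from condyle superior,
rotation adjusted via gonion) is included, as is a **synthetic phantom**
(moving condyle disc + ramus bar over static temporal bone, known
ground-truth transforms, keyframe annotation, through-plane deformation
peaking at maximum mouth opening, Gaussian noise) that makes the entire
pipeline testable without patient data.

## Worked example

```r
library(tmjtrack)

ph  <- generate_phantom(phantom_spec(seed = 1))      # 100 frames, 3 slices
res <- track_sequence(ph$frames, ph$truth$annotation)
print(res)
#> <tracking_result> 100 frames, 0 failed, mean error 0.0550, model 3279 points

as.data.frame(res)[c(1, 50, 100), c("frame", "tx_mm", "ty_mm", "theta_deg",
                                    "superimposition_error")]
#>     frame    tx_mm   ty_mm theta_deg superimposition_error
#> 1       1   0.0000  0.0000    0.0000                0.0000
#> 50     50 -13.0975 33.7739  -29.7718                0.0593
#> 100   100   0.0000  0.0000    0.0000                0.0404
```

At frame 50 (maximum mouth opening) the recovered rotation is −29.77° vs a
ground truth of −30°, and the error is largest there — the through-plane
deformation the scaling step cannot fully compensate. Comparing against the
manual baseline with 1 px landmark noise:

```r
lms <- perturb_landmarks(ph$truth, sigma_px = 1, seed = 2)
man <- manual_track_sequence(ph$frames, ph$truth$annotation, lms)
c(auto = mean(res$errors), manual = mean(man$errors))
#>   auto manual
#> 0.0550 0.1272

rep <- compare_methods(res$transforms, man$transforms, ph$truth$annotation)
rep$upper_third
#> $condyle_superior 2.22   $condyle_center 2.09   $gonion 1.87   $ICR 85.2
rep$inclination_upper_third
#> 2.181
```

The automatic error is less than half the manual one; landmark pathways of
the two methods differ by ~2 mm in the most distant third of the movement,
the ICR by tens of millimetres (its derivative nature amplifies any
tracking noise), and the inclination by ~2.2°. The signed-rank test against
the 1 mm threshold gives p ≈ 2e−9 for the condyle-superior pathway.

## Command line

```sh
Rscript exec/tmjtrack simulate --out=study --seed=1
Rscript exec/tmjtrack track study/frames.txt study/annotation.json --out=study/auto
Rscript exec/tmjtrack manual-track study/frames.txt study/annotation.json landmarks.csv --out=study/man
Rscript exec/tmjtrack compare study/auto/transforms.csv study/man/manual_transforms.csv study/annotation.json --out=study
```

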