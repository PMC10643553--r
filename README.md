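# ptyroi

Unsupervised, physics-informed selection of region-of-interest (RoI) scan
positions in scanning X-ray diffraction (ptychography) datasets.

## The problem

A ptychographic scan records a far-field diffraction pattern at each of
`K` scan positions; reconstruction cost scales with `K`, but for
isolated samples most positions see empty background. `ptyroi` decides
*before reconstruction* which positions are informative, typically
shrinking the workload to a fraction of the dataset, using two
complementary per-pattern features and no manual thresholds:

* **absorption**: the pattern total `T^k = Σ_{i,j} P^k_{j,i}` — low where
  the object absorbed the beam;
* **scattering direction**: the pattern's intensity center of mass
  `O^k = ( Σ_i i Σ_j P^k_{j,i} / T^k , Σ_j j Σ_i P^k_{j,i} / T^k )`,
  standardized across the scan to zero mean and unit variance; its row
  norm `‖Ô^k‖` is large at object boundaries and phase gradients.

Each feature is mapped onto the scan grid, smoothed with a 3×3 mean
filter (the absorption map additionally log-scaled), and split by
**exact** two-cluster 1-D k-means (global optimum by threshold scan,
deterministic). The low-transmission cluster and the high-scattering
cluster are OR-combined into the RoI mask, with per-cell provenance.

Features smaller than the beam scatter to ±q symmetrically and cancel in
the whole-pattern CoM. Partitioning each pattern into `n` azimuthal
wedges (`θ = 360°/n`) and running the same recipe per wedge recovers
them: an oriented sub-beam scatterer throws its streak into individual
wedges where it no longer cancels. The final mask is the OR over all
wedges. `n = 1` reduces exactly to the whole-pattern recipe.

Also included: STXM / Hilbert-DPC / circular-mask dark-field baseline
contrasts with the same clustering; RoI morphology (border
growth/shrinkage in scan steps, hole fill-in, retained-fraction
accounting); TIFF-directory + CSV stack I/O; and a forward simulator
(far-field model, Poisson noise, exact ground truth) so every stage is
testable without instrument data.

## Worked example

```r
library(ptyroi)

scene <- make_scene("reference", seed = 0)   # frozen synthetic study scene
sim   <- simulate_scene(scene, seed = 1)     # far-field + Poisson noise
sim$stack
#> <DiffractionStack> K = 576 patterns of 64 x 64 pixels
#>   total counts: 9.681e+07 (mean 1.681e+05 per pattern)
estimate_snr(sim$stack, sim$clean)
#> [1] 6.46

roi1 <- run_pipeline(sim$stack, scene$grid, n_segments = 1)
roi8 <- run_pipeline(sim$stack, scene$grid, n_segments = 8)
roi8
#> <RoIMask> 24 x 24 grid, 157 cell(s) selected
retained_fraction(roi1, scene$grid)   # 30.2 (% of patterns kept, n = 1)
retained_fraction(roi8, scene$grid)   # 27.3 (n = 8)

score_roi(roi1, sim$truth)$detected   # satellites: FALSE FALSE FALSE
score_roi(roi8, sim$truth)$detected   # satellites: FALSE TRUE  TRUE
```

The whole-pattern run (`n = 1`) keeps 30.2% of the positions — the main
absorbing particle and its rim — but sees none of the three sub-beam
satellites. The 8-wedge run keeps a tighter 27.3% and detects two of the
three satellites (the third lies with its streak split across wedge
boundaries). Growing the border by one scan step for reconstruction
margin:

```r
retained_fraction(adjust_border(roi8, 1, 1, grid = scene$grid), scene$grid)
#> [1] 39.4
write_roi(roi8, scene$grid, "roi.csv")   # CSV + JSON summary
```

A thin CLI wraps the same functions
(`system.file("cli/ptyroi.R", package = "ptyroi")`) with subcommands
`simulate`, `classify` and `baselines` over TIFF-directory stacks and
`k,x_um,y_um` position CSVs.

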