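# kernem

Anatomically guided kernelized expectation-maximization reconstruction for
PET, with the quantitative pipeline used to assess [18F]-NaF uptake in
abdominal aortic aneurysm (AAA).

## The problem

AAA rupture risk is conventionally monitored through the aneurysm diameter,
but growth is hard to predict. [18F]-NaF PET visualises active
micro-calcification in the aneurysm wall and can identify disease earlier —
if the reconstruction preserves small lesions. PET's limited spatial
resolution and the partial volume effect work against this: lesions of a few
millimetres blur into their surroundings, and the hot spine adjacent to the
aorta spills activity into the target region.

`kernem` implements, for workers in PET reconstruction and quantitative
cardiovascular imaging, the two kernel-based reconstructions that address
this, alongside the clinical baseline:

- **OSEM+G** — ordered-subsets expectation maximization with Gaussian
  PSF modelling and a 5 mm post-reconstruction filter;
- **KEM** — kernelized EM: the image is represented as `λ = K α`, with the
  kernel matrix `K = K_m` built once from k-nearest-neighbour Gaussian
  weights on patch features of a co-registered CT image, so edges present in
  the anatomy are preserved during EM;
- **HKEM** — hybrid KEM: `K^(n) = K_m ∘ K_p^(n)`, the elementwise product of
  the anatomical kernel and a functional kernel rebuilt from the current
  iterate, so emission-only features survive even where the CT is silent.

The kernel weights follow

    k_m(v_j, v_f) = exp(−‖v_j − v_f‖² / 2σ_m²) · exp(−‖x_j − x_f‖² / 2σ_dm²)
    k_p(z_j, z_f) = exp(−‖z_j − z_f‖² / 2σ_p²) · exp(−‖x_j − x_f‖² / 2σ_dp²)

and the coefficients are estimated by the multiplicative EM update
`α ← α · (Kᵀ Pᵀ (y / (P K α + s))) / (Kᵀ Pᵀ 1)` over ordered subsets, where
`P` is the PSF-bearing projector, `y` the measured counts and `s` the
additive (scatter + randoms) term.

Quantification follows the clinical protocol: `TBRmax = SUVmax(T) /
SUVmean(B)` for the target aneurysm region T against the blood pool B, the
percentage uptake increase between T and the non-aneurysmal aorta A,

    Increase = 100 · (TBRmax(T) − TBRmax(A)) / TBRmax(A),

and the EORTC-style rule that an increase strictly above 25% calls the
subject positive. Cohort statistics include paired t-tests between
algorithms, ROC analysis with DeLong AUC comparison, Pearson correlation of
uptake increase with aneurysm diameter, and a balanced logistic regression of
positivity on TBRmax whose probability-0.5 crossing is the TBR classification
threshold.

Because the patient data behind the original study are not redistributable,
the package ships a first-class synthetic phantom module: 2D axial abdominal
slices with spine, aneurysmal aorta carrying calcified micro-lesions, normal
aorta and vena cava, plus their T/A/B masks and Poisson projection data, so
every part of the pipeline is exercised end to end.

## Worked example

```r
library(kernem)

# one synthetic AAA-positive subject
subject <- generateSubject(phantomSpec(lesionContrast = 2.5, seed = 7))
#> SubjectData: AAA-positive, aneurysm diameter 48.0 mm, grid 64x64

# acquisition model and noisy data
model    <- systemModel(c(64, 64), 3, nAngles = 63, psfFwhm = 4.4, nSubsets = 7)
additive <- uniformAdditive(model, 6e5, fraction = 0.3)
counts   <- simulateCounts(subject@activityTruth, model, additive,
                           totalCounts = 6e5, seed = 7)
#> Sinogram: 63 angles x 93 radial bins (3 mm), total counts 779583

# reconstruct with the three algorithms
osem <- reconstruct(counts, model, additive,
                    config = reconConfig("osem", nSubsets = 7, nIterations = 4))
kem  <- reconstruct(counts, model, additive, subject@anatomical,
                    config = reconConfig("kem", nSubsets = 7, nIterations = 4))
hkem <- reconstruct(counts, model, additive, subject@anatomical,
                    config = reconConfig("hkem", nSubsets = 7, nIterations = 4))

# quantify at the comparison iterations (3rd for OSEM+G, 4th for KEM/HKEM)
rbind(osem = subjectMetrics(iterationImage(osem, 3), subject@rois),
      kem  = subjectMetrics(iterationImage(kem, 4),  subject@rois),
      hkem = subjectMetrics(iterationImage(hkem, 4), subject@rois))
#>          tbrT     tbrA increase predicted        cov
#> osem 1.539287 1.226581 25.49414      TRUE 0.02859920
#> kem  1.807192 1.387461 30.25170      TRUE 0.05709043
#> hkem 1.806616 1.383007 30.62955      TRUE 0.06659828
```

The kernel reconstructions recover a higher lesion TBRmax (1.81 vs 1.54) and
a clearly supra-threshold uptake increase (≈30% vs 25.5%) for the same data:
OSEM+G's post-filter flattens the 6 mm lesion peak, while the CT-guided
kernel keeps the calcification edge sharp. `runExperiment()` repeats this
over a whole cohort and produces the t-test/ROC/correlation/logistic report;
see the methods vignette (`vignettes/kernelized-pet-reconstruction.Rmd`) for
the model, parameter and phantom-design details.

A thin CLI covering the same pipeline lives at `inst/cli/kernem.R`
(`simulate`, `reconstruct`, `analyze`, `stats`, `run` subcommands).

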