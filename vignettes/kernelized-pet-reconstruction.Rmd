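---
title: "Kernelized EM reconstruction and AAA uptake quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernelized EM reconstruction and AAA uptake quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kernem)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the synthetic data it is exercised on, and the
numerical and design choices that were genuinely open. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The image model and the EM update

The PET activity image is represented as a linear combination of kernel
basis functions centred on voxels,

$$\lambda_j = \sum_{f \in N_j} \alpha_f \, k_{fj},$$

where the kernel weight $k_{fj}$ couples voxel $j$ to its neighbour $f$ and
$\alpha$ is the coefficient vector actually estimated. Maximising the
Poisson log-likelihood of the measured counts $y$ over $\alpha$ yields the
familiar multiplicative update, here written in operator form:

$$\alpha^{(n+1)} = \alpha^{(n)} \cdot
  \frac{K^\top P^\top \left( y \,/\, (P K \alpha^{(n)} + s) \right)}
       {K^\top P^\top 1},$$

with $P$ the system projector, $s$ the additive (scatter + randoms)
sinogram, and all operations elementwise. Ordered subsets cycle this update
over interleaved groups of projection angles. Three kernels define the three
algorithms:

* **OSEM**: $K = I$; each stored image additionally receives a Gaussian
  post-filter (default 5 mm FWHM), the clinical "OSEM+G".
* **KEM**: $K = K_m$, built once from the anatomical (CT-like) image.
* **HKEM**: $K^{(n)} = K_m \circ K_p^{(n)}$, the elementwise product on the
  anatomical kernel's sparsity pattern, with $K_p^{(n)}$ rebuilt from the
  current coefficient iterate.

Kernel weights are Gaussian products of a feature-intensity distance and a
spatial distance. For each voxel, the `nNeighbors` candidates within a
spatial search window of half-width `patchRadius` whose patch feature
vectors are closest in Euclidean distance are retained; the voxel itself is
always its own first neighbour, and distance ties break deterministically by
voxel index.

### Parameters and defaults

| parameter | default | units | role |
|---|---|---|---|
| `nNeighbors` | 3 | voxels | sparsity of K; 1 reduces any kernel EM to plain MLEM |
| `patchRadius` | 1 | voxels | feature patch and search window half-width |
| `sigmaM`, `sigmaP` | 0.1 | sd-normalised intensity | edge sensitivity of the anatomical / functional factor |
| `sigmaDm`, `sigmaDp` | 3 | voxels | spatial reach of each factor |
| `normalizeRows` | TRUE | — | rows of K sum to 1, so constants map to constants |
| PSF FWHM | 4.4 | mm | scanner resolution model, inside projector and adjoint |
| subsets × iterations | 21 × 10 (clinical), 7 × 4 (desk runs) | — | EM schedule |
| post-filter FWHM | 5 | mm | OSEM+G only |
| threshold | 25 | % | strict uptake-increase positivity rule |

Feature intensities are divided by the source image's standard deviation
before entering the Gaussian, so `sigmaM = 0.1` has the same meaning across
guidance images of different dynamic range; that normalisation is what makes
a shared default for `sigmaM` and `sigmaP` meaningful. Row normalisation of
K is not dictated by the model; it was adopted because it makes the kernel
count-preserving on flat images and keeps the EM sensitivity well scaled.
The functional features are computed from the coefficient image $\alpha^{(n)}$
(not from $\lambda^{(n)}$); both conventions appear in the kernel-EM
literature and the package exposes the iterate it uses. The functional
kernel's rebuild cadence is per-subset-update by default, the finest
granularity consistent with a per-update kernel superscript; a
per-full-iteration mode (`updateKernel = "iteration"`) is provided and
tested as well.

### Degenerate limits worth knowing

Two exact limits anchor the test suite: with `nNeighbors = 1` the kernel is
the identity and KEM reproduces MLEM to machine precision; and when *both*
functional scales `sigmaP` and `sigmaDp` are made huge the functional factor
is identically 1 and HKEM collapses onto KEM. Note that inflating `sigmaP`
alone is **not** sufficient — the functional kernel also carries a spatial
Gaussian, and the hybrid product would retain that factor squared — so the
degenerate-limit tests flatten both.

## The projector

The system model is a parallel-beam discrete Radon transform with linear
interpolation onto radial bins, preceded (and, in the adjoint, followed) by
an isotropic image-space Gaussian PSF implemented with zero-padded separable
convolution, which keeps the operator pair exactly adjoint — the
inner-product identity is the gate for all EM correctness tests. Attenuation
is available as per-LOR multiplicative factors computed from a linear
attenuation map, default off: the clinical study takes all correction terms
from vendor software, so the simulator only needs a self-consistent model.
The additive term defaults to a flat sinogram carrying 30% of the true
counts, a generic stand-in for scatter plus randoms.

The Gaussian *post*-filter, by contrast, uses reflective boundaries, which
preserve the total image sum exactly; a post-filter should not bleed counts
off the image edge.

## The synthetic phantom and what it does (not) show

Each subject is a 2D axial abdominal slice on a 64×64 grid of 3 mm voxels
(desk scale; the API is agnostic to grid size): a bright, hot spine
(activity 5× background, mimicking NaF bone uptake and its spill-in hazard),
an aneurysmal aorta cross-section whose wall carries 1–3 calcified
micro-lesions (6 mm diameter by default, CT-bright, activity
`lesionContrast` × wall), a normal-calibre aorta cross-section, and the vena
cava. The T mask is the aneurysm wall annulus with voxels within 6 mm of the
spine excluded — reproducing the analysis-protocol practice of excluding
spill-in-contaminated voxels — A is the normal aorta wall, and B the vena
cava; the three are disjoint by construction and positives/controls are
separated at the truth level (truth increase is `(lesionContrast − 1)·100%`
for positives and 0 for controls).

Study conditions were fixed once: aneurysm diameter uniform on 35–65 mm
(bracketing the clinical cohort's 48.8 ± 7.7 mm), control aorta 18–28 mm,
lesion contrast uniform on 1.5–4, and 6×10⁵ expected true counts per slice,
which puts the blood-pool coefficient of variation at the comparison
iteration near 0.07 — the clinically representative 5–10% band in which
control subjects classify cleanly negative. Background soft-tissue uptake
equals blood (1.0): region A then sits in quasi-uniform surroundings, as in
the clinical ROI protocol, rather than being an artificial hot ridge whose
own partial-volume behaviour would dominate the increase metric.

What the phantom does *not* emulate: 3D acquisition and multi-bed stitching,
respiratory motion, CT noise/texture (the guidance image is noiseless by
default; an optional blur exists), scanner-specific geometry, and any
relationship between aneurysm diameter and lesion uptake — contrast is drawn
independently of diameter, so the cohort Pearson correlation tests a true
null and its reported `r` hovers near zero by design. Passing tests
therefore demonstrate internal correctness and the relative behaviour of the
algorithms under controlled partial-volume and noise conditions, not
clinical performance.

## Iteration choice and parameter selection

TBRmax keeps growing with iterations (it is a maximum statistic), so no
convergence rule is applied; a fixed budget is run and the comparison
iteration is chosen per algorithm. The package defaults to the 4th full
iteration for KEM/HKEM and the 3rd for OSEM+G, and `selectIteration()`
implements the alternative data-driven rule — the iteration with the most
true positives, earliest on ties. `selectKernelParams()` implements the
sweep rule used for kernel-parameter optimisation: among candidates whose
CoV lies within a relative band (default ±10%) of a reference noise level,
take the highest TBRmax. The CoV region is the blood pool by default (the
most uniform region; the A region is available via config), and the CoV uses
the population (n-denominator) standard deviation — the sample version would
differ only by a constant factor and never changes a comparison.

## Numerical choices

* Coefficients initialise to 1 everywhere; EM denominators are stabilised
  with `epsilon = 1e-10`, and voxels with zero sensitivity are frozen at
  their current value rather than raising an error — that keeps rays outside
  the field of view from generating NaNs without biasing supported voxels.
* The stored per-iteration image is $\lambda^{(n)} = K^{(n)}\alpha^{(n)}$
  with the kernel rebuilt from the final iterate of that iteration when
  hybrid.
* Border voxels whose search window leaves the grid duplicate the self
  neighbour with zero weight, keeping every kernel row the same length.
* The Poisson log-likelihood is reported up to its data-dependent constant;
  only differences across iterations are meaningful.

## Cohort statistics

Paired t-tests (two-sided, 95% CL) compare per-subject TBRmax between
algorithm pairs; degenerate difference vectors (all equal) are answered with
t = 0, p = 1 or an infinite t and p = 0 rather than an error. The ROC sweeps
all distinct score cutoffs with strict positivity, and its trapezoid AUC
coincides exactly with the Mann–Whitney pair-count AUC (ties one half) — a
property the tests assert on random instances. The DeLong comparison of two
correlated AUCs is implemented from structural components (placement
values), with the installed pROC package used in the test suite only as an
independent cross-check. The logistic regression of positivity on TBRmax is
fitted by `stats::glm`; Wald standard errors and p-values match the
coefficient ± SE reporting style of clinical tables, the in-sample accuracy
is labelled as such, and the TBR classification threshold $-\beta_0/\beta_1$
is withheld (NA, with `converged`/`separated` flags) when the fit is
separated or the slope is not significant at the 95% level — on strongly
separated synthetic cohorts this is the honest outcome. Balanced
sub-sampling (majority class down-sampled to the minority count,
deterministic per seed) precedes the regression, mirroring the clinical
analysis; no multiple-testing correction is applied across the three
pairwise tests, matching the protocol it follows.

## Problem sizes

The shipped defaults run the full pipeline — 40 subjects × 3 algorithms × 4
iterations on 64×64 grids with 63 angles — in well under a minute, and the
test suite's end-to-end property (sensitivity ordering HKEM ≥ KEM ≥ OSEM+G
with clean controls in at least 4 of 5 seeded cohorts) in about two minutes.
These sizes were chosen to keep a laptop-scale feedback loop; nothing in the
implementation is specific to them.

## Known limitations

HKEM has no theoretical convergence guarantee (the kernel changes between
updates); in practice the likelihood trace is monitored and fixed iteration
budgets are used. The projector is 2D parallel-beam — adequate for studying
the algorithms, not for modelling any particular scanner. The phantom's
anatomical image is a noiseless label-like map, which flatters
anatomy-guided methods relative to real down-sampled CT; the functional
kernel of HKEM partially compensates by design, but absolute differences
between KEM and HKEM on this phantom should be read with that in mind.
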