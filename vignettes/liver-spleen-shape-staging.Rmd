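---
title: "Statistical shape models of the liver and spleen for cirrhosis staging"
author: "morphostage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape models of the liver and spleen for cirrhosis staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphostage)
```

## The problem

Cirrhosis deforms the liver in a characteristic way — hypertrophy of the
left lobe, atrophy of the right lobe — and enlarges the spleen. These
morphological changes are visible in segmented CT, but visual grading is
subjective. `morphostage` turns segmented liver and spleen shapes into a
small number of quantitative morphometric features and maps them to a
continuous disease-progression score, supporting both normal/abnormal
classification and stage estimation (stages 0 = normal, 1 = early,
2 = middle/late).

## The model

Each organ surface is represented by $V$ corresponded vertices flattened
into a shape vector
$\mathbf{x} = [x_1, y_1, z_1, \dots, x_V, y_V, z_V]^T$ (3000 numbers at
the default $V = 1000$). The joint liver–spleen vector concatenates the
liver block before the spleen block (6000 numbers). Given $N$ training
shapes, the statistical shape model (a point distribution model) is the
eigen-decomposition of

$$
\mathbf{m} = \frac{1}{N}\sum_i \mathbf{x}_i,\qquad
\mathbf{S} = \frac{1}{N}\sum_i (\mathbf{x}_i-\mathbf{m})(\mathbf{x}_i-\mathbf{m})^T ,
$$

so any shape is $\mathbf{x} = \mathbf{m} + \sum_j b_j \mathbf{v}_j$ with
orthonormal eigenshapes $\mathbf{v}_j$ and coefficients
$b_j = \mathbf{v}_j^T(\mathbf{x}-\mathbf{m})$. Note the $1/N$ (not
$1/(N-1)$) normalization; it rescales eigenvalues only. The fit uses the
thin SVD of the centered data matrix, so the $D\times D$ covariance is
never formed; at most $N-1$ modes exist and modes below $10^{-10}$ of the
leading eigenvalue are dropped as numerical noise. Eigenvector signs are
arbitrary, so each eigenshape's largest-magnitude entry is made positive
— downstream regression needs a fixed sign, and refits become
bit-identical.

Three models are fitted: liver-only, spleen-only, and the joint model,
which captures correlated inter-organ deformation. Normal and abnormal
shapes are pooled in one PCA.

**Mode selection.** Modes useful for diagnosis are found by intersecting
two rankings: (i) the accumulated variance contribution rate
$\mathrm{AVCR}(k) = \sum_{j\le k}\lambda_j / \sum_j \lambda_j$ with
threshold 0.90 (the smallest qualifying prefix), and (ii) the *uncentered*
absolute cosine between a mode's per-subject coefficients
$\mathbf{b}_i$ and the binary label vector $\mathbf{r}$,

$$
\mathrm{corr}(i) \;=\; \frac{|\mathbf{r}^T\mathbf{b}_i|}
{\sqrt{(\mathbf{r}^T\mathbf{r})(\mathbf{b}_i^T\mathbf{b}_i)}},
$$

keeping the top 4. This is deliberately not the Pearson correlation — no
mean-centering is applied — and it is implemented exactly in that form
(a centered variant exists behind a flag, off by default). From the
product set, the single best-correlated mode per model is kept, giving a
three-dimensional feature per subject under the proposed multi-model
configuration. If the product set is empty (possible on small folds) the
best-correlated mode within the AVCR set is used and a warning logged.

**Staging.** A Gaussian-kernel $\varepsilon$-support-vector regression
maps the selected coefficients to the stage label. The machine is stored
in explicit dual form $f(\mathbf{b}) = \sum_i (\alpha_i-\alpha_i^*)
k(\mathbf{b}_i,\mathbf{b}) + a$, and the package evaluates predictions,
the dual objective and the KKT/tube conditions itself from those
coefficients; the inner solver is libsvm's SMO (via e1071) run at a
$10^{-8}$ termination tolerance, and tests confirm the solution against
an independent interior-point QP solve of the same dual. Normal/abnormal
classification uses a plain nearest-neighbour rule on the same features
(ties to the smaller subject index). Features are standardized with
training-fold statistics before NN/SVR; the parameters ride along in the
model for test-time reuse.

## Getting shapes into correspondence

The pipeline in front of the PCA mirrors standard practice:

1. **Surface extraction** from a binary label volume by a marching-
   tetrahedra isosurfacer (Kuhn 6-tetrahedra subdivision, linear edge
   interpolation) after Gaussian presmoothing ($\sigma = 1$ voxel,
   configurable). Presmoothing turns the staircase binary field into a
   subvoxel-accurate one: on a digital ball of radius 10 voxels the
   extracted area and volume land within a few percent of the analytic
   values, which pure binary marching would miss. Iso-level 0.5 is the
   natural choice for binary masks. Disconnected foreground keeps the
   largest component with a warning.
2. **Vertex-count standardization** to exactly 1000 vertices (default)
   by quadric-error-metric edge collapse, with manifold (link-condition)
   and normal-flip guards, validated against the input by a symmetric
   point-to-triangle Hausdorff distance (tolerance 2% of the bounding-box
   diagonal). Upsampling is not supported.
3. **Rigid normalization** of each organ to the corresponding organ of a
   reference subject: iterative closest point under a symmetric
   (forward + backward) nearest-neighbour cost, initialized by centroid
   alignment in the given orientation. A principal-axes orientation
   search exists behind a flag but is off by default, deliberately:
   segmented medical volumes arrive in a common patient orientation with
   only moderate pose differences, and a global orientation search can
   prefer an anatomically flipped pose once disease alters the organ's
   dominant proportions — severe left-lobe hypertrophy with right-lobe
   atrophy mirrors the lobe balance, and the flipped pose can have a
   genuinely lower geometric cost than the true one. Only rotation and
   translation are removed — never scale, since organ size (hypertrophy,
   splenomegaly) is the diagnostic signal. The reference is the first
   subject id in lexicographic order (recorded in the model);
   registration is per organ, independently for liver and spleen.
4. **Dense correspondence** by TPS-RPM: deterministic-annealing robust
   point matching alternating soft-assign updates (Gaussian affinities,
   Sinkhorn row/column normalization) with regularized thin-plate-spline
   refits of the reference onto its virtual targets. Two read-outs are
   provided. The hard one-to-one correspondence (greedy conflict-free
   argmax of the final soft-assign matrix) supports vertex reordering
   and is what the recovery tests check. For building shape vectors the
   pipeline instead uses *template propagation*: the converged warp is
   evaluated at every reference vertex and projected onto the subject
   surface, so the corresponded point is not quantized to the subject's
   vertex grid. At 162 vertices the grid spacing (~22 mm) exceeds the
   stage-linked deformations (~9 mm); snapping to vertices buries the
   signal in correspondence noise, while propagation leaves a residual
   of a few millimetres.

### TPS-RPM numerical choices

The annealing schedule is geometric with rate 0.93 and 5 inner
alternations per temperature. The initial temperature is the squared
largest reference-to-subject distance, so the first soft-assign sees
every pairing; the final temperature is the squared mean
nearest-neighbour spacing of the reference *divided by 25*. Stopping at
the spacing itself — a natural first guess — leaves the assignment
mixture still blurred across immediate neighbours and hard read-off
recovers barely half of a permuted self-match; a quarter of the spacing
(in distance) sharpens the mixture enough for exact recovery while
adding only ~40 outer iterations.

Two details matter for stability. First, with the 3-D radial kernel
$\phi(r)=r$, the conditionally positive-definite form on the
side-condition subspace is $-Q_2^T K Q_2$; using the raw sign would
*reward* bending and the alternation diverges. Second, the affine part
of the warp must be anchored to the identity (default weight $1 \cdot
\lambda$, annealed with temperature like the bending weight
$\lambda = T$): without the anchor, the unpenalized affine fit maps the
whole template onto the virtual-target centroid at high temperature —
the soft-assign rows become identical and the alternation is stuck in
the collapsed state forever — and with only a token anchor it can
rotate the template across the surface before the assignments commit
(measured as a median correspondence error of several vertex spacings
on cross-subject pairs, dropping to about one spacing at the default).
The warp refit enforces the TPS side condition
$P^T W = 0$ structurally, by solving in the null-space basis of the
affine design. The per-temperature energy
$\sum_{ij} m_{ij} d_{ij}^2 + T\sum m_{ij}\log m_{ij} + \lambda\,\text{bend}
+ \lambda\,\|A - A_{id}\|^2$ is tracked and tested to be non-increasing
within each temperature, up to a $10^{-4}$ relative tolerance: the
M-step runs a fixed number of Sinkhorn sweeps, so the alternation is an
inexact coordinate descent and sub-tolerance wobble near convergence is
expected.

With equal standardized vertex counts the outlier row/column is disabled
by default (configurable). Matching is deterministic: there is no
randomness anywhere in the pipeline apart from the cohort generator's
seeded draws. The final hard correspondence is the greedy conflict-free
argmax of the last soft-assign matrix, ties towards the smaller subject
index. Correspondence is computed on the standardized meshes (not a
denser cloud): at 1000 — or the generator's 162 — vertices the spacing
is well below the deformations of interest.

## The synthetic cohort

No clinical cohort ships with the package, so every quantitative claim
is validated on a synthetic one that emulates the qualitative morphology
of cirrhosis progression and the structure of the staged clinical cohort
(25 normal / 8 early / 2 middle-late; the generator also produces other
splits on request):

* the base liver is two fused ellipsoidal lobes (star-shaped about the
  origin, radius = larger ray-ellipsoid exit distance) at an 80 mm
  scale — a flat, tilted, superiorly displaced left lobe and a rounder,
  lower right lobe, plus a fixed chiral radial modulation; the spleen is
  a bean-like two-lobe shape at a 40 mm scale, offset laterally. The
  pronounced asymmetry is deliberate: real organs are chiral, and a
  mirror-symmetric fixture would make rigid registration and
  correspondence ill-posed up to 180° flips (the more so as stage
  scaling swaps which liver lobe is the larger one);
* per stage step the left lobe scales by $(1+e)$, the right by $(1-e)$
  and the spleen volume by $(1+e)$, compounded over stage, with
  $e = 0.15$ by default;
* each subject receives a smooth random radial deformation built from
  real spherical harmonics up to order 3, coefficient standard deviation
  $0.05/\ell$ (decaying with order keeps meshes valid and variation
  "shape-like") — this is the inter-subject anatomical variation the
  PCA must model;
* isotropic per-vertex jitter of 2% of organ size, a random rigid
  misalignment (rotation up to 20°, translation up to 10% of size)
  common to both organs, and a random relabelling of the vertex order,
  which is what makes correspondence recovery a genuine task rather than
  a no-op.

Everything is drawn from one seeded generator; identical seeds give
bit-identical cohorts. The default vertex count is 162 per organ (an
icosphere level): the stage signal and harmonic variation live at very
low spatial order, and this keeps a full leave-one-out experiment within
minutes on one CPU. The 1000-vertex setting of the standardization and
shape-vector conventions is exercised separately in the tests. What the
generator does *not* emulate: real anatomical detail (lobulation, vessel
indentations), CT intensities (hence no texture baseline), segmentation
error beyond isotropic jitter, and partially missing organs. Passing
tests therefore demonstrate the pipeline's correctness and its behaviour
under controlled morphological signal, not clinical performance.

## The leave-one-out experiment

```{r, eval = FALSE}
cohort <- generateCohort(CohortSpec(seed = 0))
comparison <- compareMethods(cohort, pipelineConfig(), verbose = TRUE)
comparison
```

For each held-out subject, the registration reference choice, SSM fits,
mode selection and NN/SVR training all use only the remaining subjects;
the held-out shape is then projected onto the fold-trained models. Mode
selection is re-run in every fold. The in-fold reference is the first
training subject by id, so at most two references occur across folds and
the pairwise (hence leak-free) subject-vs-reference preprocessing is
cached per reference; a dedicated test mutates a held-out subject and
verifies the fold's trained artifacts are bit-identical. Three
approaches are compared under identical configuration: liver SSM with
AVCR-only selection (baseline), liver SSM with combined selection, and
the proposed three-model combined selection.

Folds whose training set loses a class are skipped with a warning.
Reports carry per-class accuracies, per-subject scores and per-stage
score moments, a configuration hash, and serialize to JSON.

## Design choices that were genuinely open

* **Registration scope** — per organ independently (matching
  "organ-to-organ"); a config switch for liver-driven registration of
  both organs was considered unnecessary for the synthetic validation
  and is not implemented.
* **Binary labels for selection** even when stage labels exist; stages
  are used only by the SVR target.
* **"Top 4" correlation modes per SSM**, not pooled across SSMs, which
  is the reading consistent with one mode being selected from each
  model.
* **SVR features**: the three selected mode coefficients form one 3-D
  feature vector (rather than per-model scores fused later).
* **SVR hyperparameters**: there is no canonical choice for cohorts of
  this size; defaults are $C = 10$, $\varepsilon = 0.1$, $\gamma = 1/d$
  on standardized features. An inner grid search was deliberately left out:
  on cohorts of this size it mostly adds variance, and fixed defaults
  keep folds comparable.
* **Hard staging** by the nearest label in $\{0, 1, 2\}$; the continuous
  score is the primary output.

## Known limitations

* Decimation to very aggressive targets can fail the manifold guards on
  pathological meshes; the error is explicit rather than silent.
* TPS-RPM at 1000 vertices costs a dense $n \times n$ solve per
  refit; correspondence quality is excellent at the generator's 162
  vertices, but large-cohort, high-resolution runs would want the
  annealing floor raised or a compiled inner loop.
* The even-odd voxelizer assumes watertight input (guaranteed for
  package-produced meshes).
* Binary PLY/STL and compressed MetaImage are not read; NIfTI
  orientation metadata beyond voxel spacing is ignored.
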