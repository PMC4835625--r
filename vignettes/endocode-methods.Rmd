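---
title: "Methods: feature coding and classification of endomicroscopy video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature coding and classification of endomicroscopy video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Probe-based confocal laser endomicroscopy (CLE) delivers a real-time stream
of grayscale, histology-like frames from tissue at cellular resolution.
During neurosurgery the practical question is whether the tissue under the
probe is malignant (glioblastoma) or benign (meningioma). `endocode`
implements a bag-of-visual-words pipeline for that two-class frame
classification task: prune uninformative frames, describe local texture
densely, express each descriptor against a learned visual vocabulary, pool
per-frame histograms, classify with an SVM, and smooth the per-video label
stream by majority voting. The centrepiece is the locality-constrained
sparse coding (LSC) step and its ADMM solver.

## Entropy-based pruning

Off-tissue or low-contrast frames carry no diagnostic signal. Each frame is
scored by the Shannon entropy of its 256-bin gray-level histogram in bits
(`gray_entropy()`); the convention — 256 bins over [0, 255], log base 2 —
makes the score live on [0, 8] for 8-bit frames. The pruning threshold is
the empirical quantile of the observed entropy distribution at the discard
fraction (default 10%), and frames strictly below the threshold are
discarded. The strict-below rule keeps boundary frames and, on ties-free
data of size N, discards exactly `floor(0.1 * N)` frames. Entropy is
computed over the whole frame; the disc-shaped field of view of CLE probes
is not masked, since no mask geometry is part of the data contract. In the
full pipeline the threshold is estimated on training frames only and frozen
into the model archive, so the test side of a split can never influence it.

## Dense upright SIFT

Descriptors are extracted on a regular grid: 20 x 20 px patches every 10 px,
every position where the whole patch fits (at the native 464 x 336
resolution: 45 x 32 = 1440 patches). Dense sampling, rather than interest
points, is required because uniform low-contrast regions are themselves
informative for meningioma. Each patch yields the classical 4 x 4 spatial
cells x 8 orientation bins histogram of gradient magnitude (128
dimensions): gradients by central differences with replicated edges,
Gaussian spatial weighting (sigma = half the patch side, centred), trilinear
interpolation across cells and orientation bins, L2 normalisation, clipping
at 0.2, renormalisation. The extractor is upright and single-scale:
orientation normalisation and scale-space pyramids buy robustness to
rotations and zoom that a fixed-geometry probe stream does not exhibit, at
the cost of discriminative power. Zero-gradient patches return the zero
vector rather than an error. Note two border conventions: within
`extract_dense()` a patch's gradients use the frame's pixels, so a
descriptor depends on at most one pixel beyond each patch edge;
`sift_descriptor()` applied to an isolated patch replicates the patch's own
border instead.

## Vocabulary learning

A random subset of 100,000 non-zero training descriptors (stratified over
frames by the streaming sampler) is clustered into m = 256 codewords.
Two flavours are used, matching what each coder needs:

* **Flat k-means** (Lloyd + k-means++ initialisation) with exhaustive
  Euclidean assignment — used for the sparse/locality-constrained coders,
  which need actual nearest codewords. Controls: `max_iter = 100`,
  stopping at relative objective change `1e-4`. Empty clusters are
  re-seeded deterministically from the farthest unassigned point; the
  within-cluster sum of squares is recorded per iteration and asserted
  non-increasing in the tests. All random choices go through R's RNG so a
  seed fixes the codebook bit-for-bit.
* **Binary vocabulary tree** of depth 8 (recursive 2-means), giving at most
  2^8 = 256 leaves — used for Bag-of-Words, where greedy root-to-leaf
  descent replaces the exhaustive argmin. A smaller requested vocabulary
  caps the depth at `log_branch(m)` so both parameters stay consistent. Under-populated or degenerate
  nodes become leaves early, so the leaf count can fall below 256 on small
  samples. Greedy descent is approximate; its agreement with exhaustive
  search is a measured diagnostic (asserted ≥ 80% on the synthetic
  fixtures), not a guarantee.

## Feature coding

With codebook B (d x m) and descriptor x, the four coders are:

* **BoW**: the one-hot indicator of the nearest codeword.
* **SC** (sparse coding): `min ||x - Bc||^2 + lambda ||c||_1` subject to
  `1'c = 1`.
* **LLC** (locality-constrained linear coding):
  `min ||x - Bc||^2 + lambda ||d ⊙ c||^2` subject to `1'c = 1`, with the
  locality adaptor `d_j = exp(||x - b_j|| / sigma)`. The squared penalty is
  smooth, so the solution comes from one (m+1) x (m+1) KKT system; the
  constraint border is rescaled to the Hessian's magnitude so the system
  stays well-conditioned even for extreme `lambda`, and a logged ridge
  jitter is the fallback for exactly singular geometry.
* **LSC** (locality-constrained sparse coding):
  `min ||x - Bc||^2 + lambda ||d ⊙ c||_1` subject to `1'c = 1` — the
  weighted l1 penalty enforces sparsity *and* locality at once.

Distances in the locality adaptor are plain Euclidean distances between the
L2-normalised descriptors and codewords, not rescaled by any per-descriptor
statistic.

### The ADMM solver

LSC is solved by splitting `c = y`: the smooth reconstruction term and the
sum-to-one constraint live on `y`, the weighted l1 on `c`. With scaled dual
`u` and penalty `mu`, one iteration is

1. **y-update** — an equality-constrained least squares problem,
   `min ||x - By||^2 + mu ||c - y + u||^2` s.t. `1'y = 1`, solved exactly
   through a bordered KKT system whose (m+1) x (m+1) inverse is factored
   once per codebook (the system matrix does not depend on the descriptor);
2. **c-update** — elementwise soft-thresholding
   `c_j = S(y_j - u_j; lambda d_j / (2 mu))`, the proximal step of the
   weighted l1 norm;
3. **dual update** `u <- u + c - y`.

Enforcing the constraint exactly inside the y-update (rather than by a
penalty term) removes a tuning weight and keeps every iterate's `y`
feasible. Iterations stop when the primal residual `max|c - y|`, the
feasibility residual `|1'c - 1|`, *and* the scaled dual residual
`2 mu max|y_t - y_{t-1}|` all fall below `tol`; the dual residual matters
because a large `mu` can shrink `|c - y|` long before the iterate is
optimal. Three standard, optimum-preserving accelerations are built in:
each solve starts from the indicator of the descriptor's nearest basis
(each descriptor's solve remains independent — there is no warm-starting
across descriptors), the c/u updates use over-relaxation with alpha = 1.7,
and the penalty is rebalanced (doubled or halved, with the KKT system
re-factored) whenever the primal and dual residuals diverge by more than a
decade. Non-convergent solves return the best iterate with a
`converged = FALSE` flag and a warning.

Defaults: `lambda = 0.1`, `sigma = 1`, `mu = 0.1`, `tol = 1e-6`,
`max_iter = 500`, `K = 5`. None of these have a canonical value in the
literature for this pipeline. `lambda` and `sigma` were fixed once against
the convex oracles of the test suite (sub-`1e-4` relative objective gaps on
random small problems) and the synthetic fixtures; the solver controls
(`mu`, relaxation, rebalancing) were chosen on convergence diagnostics —
iteration counts and converged fractions on K = 5 subproblems of real
synthetic descriptors, where `mu = 0.1` converges in a few dozen
iterations. The full m = 256 problem prefers a larger initial `mu`
(around 1) and still needs several hundred iterations at `tol = 1e-6`,
which is exactly why the method has a fast variant. All values are recorded
in every model archive.

### Fast K-NN restriction

`encode_lsc_fast()` restricts the problem to the K = 5 nearest codewords,
solves the identical ADMM in K variables (its tiny KKT system factored per
descriptor), and scatters the coefficients back into a length-m code. The
restricted optimum can only be ≥ the full optimum — asserted on every test
instance — and equals it at K = m. At K = 1 the sum-to-one constraint
leaves a single feasible point, the BoW indicator.

Zero descriptors (constant patches) are assigned their BoW code under every
scheme, a stated convention that keeps pooled features well-defined for
blank-ish regions.

## Pooling, classification, evaluation

BoW codes pool by summed occurrence counts with L1 normalisation (a
histogram); the signed sparse codes pool by elementwise max of absolute
values, since "occurrence" is meaningless for real-valued coefficients.
Features are standardised per training split and classified by a linear
SVM with C = 1 (kernel and cost deliberately plain; an RBF SVM and a random
forest are available behind the same interface).

Evaluation follows the video-grouped protocol: 80% of videos per class
train, 20% test, no video on both sides, five independent seeded draws,
mean and sd of frame-level accuracy/sensitivity/specificity with
glioblastoma as the positive class. Because videos can lose different
numbers of frames to pruning, candidate splits are re-drawn (up to 100
times) until the test side holds 20 ± 5% of frames. The five splits are
independent random repeats, not a rotation — the grouped constraint plus
stratification makes an exact 5-fold rotation impossible for unequal video
counts, and repeats also decorrelate the split noise. Every split retrains
everything (threshold, codebook, classifier) on its training videos only.

## Majority voting

Raw per-frame labels of a video are smoothed with a centred window of
length T = 5 over the pruned stream, truncated at the boundaries (no
invented padding labels); ties fall back to the centre frame's own raw
label, which preserves information and is deterministic. A `causal = TRUE`
variant votes over the current frame and its T - 1 predecessors, the form
usable intraoperatively; the centred window remains the default because it
is the natural reading of a "surrounding" window and is what the
accuracy-versus-T sweep (`window_sweep()`) characterises. Under iid label
flips at rate p < 1/2 the interior smoothed error has the closed binomial
form `sum_{k > T/2} C(T,k) p^k (1-p)^{T-k}`, which the tests verify at
p = 0.3, T = 5 (0.16308) on a 10,000-frame stream. Voting uses hard labels
only; window length 1 is the identity.

## The synthetic data generator

No public CLE tumour dataset exists, so the package ships a generator
(`generate_dataset()`) that emulates the features the pipeline actually
exploits: acriflavine-stained nuclei appear as bright anti-aliased discs
with Gaussian-falloff rims (giving SIFT real gradients), drawn with a
Poisson count per frame and combined by per-pixel maximum over a dark
background with Gaussian pixel noise. The two classes differ in both blob
density and size — glioblastoma-like: 25 blobs per 100 x 100 px of radius
2–4; meningioma-like: 8 of radius 6–12 — mirroring hypercellular versus
more uniform texture and giving every coder a discriminative statistic.
Near-blank frames (constant level 40, noise sigma 1, entropy ≈ 2 bits,
far below any textured frame) are injected at a configurable rate; the
per-video blank count is deterministic (`round(rate * frames)`) with random
positions, so pruning behaviour is a property of the method rather than of
sampling luck. One global seed fans out as `seed + video_index`, making
each video reproducible in isolation.

What the generator does **not** emulate: vascular or connective structures,
motion blur, photobleaching, the disc-shaped field of view, inter-patient
variability, or class overlap. Passing tests on this data therefore
demonstrates that the machinery is correct and that the pipeline recovers a
clean two-class texture difference under grouped validation — not that any
particular accuracy carries over to patient video. The generator's default
parameters are a stand-in for unpublished texture statistics, chosen once
for plausibility, not a claim of realism.

## Problem sizes and numerical choices in the test suite

The end-to-end checks run the study-shaped configuration: 10 videos per
class x 100 frames at 464 x 336 with 10% blanks (2,000 frames, ~2.9M
descriptors), five grouped splits per scheme, with a shared single-precision
descriptor cache so each frame is extracted once per evaluation. Unit tests
use miniature datasets (3 videos/class x 10 frames at 120 x 100, m = 16)
and small random coding problems (d = 4, m = 6) where the l1 solutions can
be enumerated exactly by sign pattern — the independent oracle the solvers
are held to. Deterministic tie-breaks are stated everywhere they can bind:
nearest-codeword ties go to the lowest index, voting ties to the centre
frame's raw label, k-means empty clusters to the farthest point.

## Known limitations

* The absolute accuracies reported on the synthetic fixtures say nothing
  about patient data; only the relative behaviour of the coders is
  meaningful, and even that on clean textures.
* Greedy vocabulary-tree descent is an uncontrolled approximation to
  exhaustive quantization; its measured agreement is a regression
  diagnostic.
* Full-codebook LSC is expensive by construction (hundreds of ADMM
  iterations per descriptor at m = 256); the K-NN restriction is the
  intended operating point, and its objective gap to the full problem is
  reported, not bounded.
* The SVM is trained on frames, which are strongly correlated within a
  video; the grouped splits keep the *evaluation* honest, but the
  classifier's internal margin estimates ignore the correlation.
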