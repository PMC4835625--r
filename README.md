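# endocode

Tissue classification for confocal laser endomicroscopy (CLE) video
streams.

Probe-based CLE shows brain tissue at cellular resolution in real time
during surgery; the clinically relevant question is whether the tissue
under the probe is malignant (glioblastoma) or benign (meningioma).
`endocode` implements a complete bag-of-visual-words pipeline for that
two-class frame classification task:

1. **Entropy pruning** — frames are scored by the Shannon entropy of their
   256-bin gray-level histogram (bits); the lowest-entropy 10% (blank or
   low-contrast frames) are discarded.
2. **Dense upright SIFT** — 128-d gradient-orientation descriptors of
   20 × 20 px patches on a 10 px grid (1440 per native 464 × 336 frame).
3. **Visual vocabulary** — m = 256 codewords by k-means (flat, with
   k-means++ and exhaustive assignment) or a depth-8 binary vocabulary
   tree, learned from 100,000 sampled training descriptors.
4. **Feature coding** — each descriptor x becomes an m-length code c under
   one of four schemes:
   - *BoW*: one-hot at the nearest codeword;
   - *SC*: min ‖x − Bc‖² + λ‖c‖₁ s.t. 1ᵀc = 1;
   - *LLC*: min ‖x − Bc‖² + λ‖d ⊙ c‖² s.t. 1ᵀc = 1, closed form;
   - *LSC*: min ‖x − Bc‖² + λ‖d ⊙ c‖₁ s.t. 1ᵀc = 1 — the
     locality-constrained sparse coder at the heart of the package, with
     locality adaptor d\_j = exp(‖x − b\_j‖/σ), solved by ADMM
     (least-squares y-update with the sum-to-one constraint handled
     exactly, soft-thresholding c-update, dual update), plus a fast
     variant restricted to the K = 5 nearest codewords.
5. **Pooling + SVM** — per-frame histograms (sum-normalised for BoW,
   max-abs for signed codes), standardised, classified by a linear SVM
   under video-grouped 80/20 cross-validation (no video ever on both
   sides of a split).
6. **Majority voting** — per-video label streams are smoothed with a
   centred sliding window (T = 5), with a causal variant for real-time
   use.

Because no public CLE tumour dataset exists, the package includes a
synthetic generator that emulates stained-nuclei textures (class-dependent
blob density/size, Gaussian noise, injected near-blank frames), so every
stage is testable end to end.

## Worked example

```r
library(endocode)

# two-class synthetic study: 4 videos/class x 30 frames, 10% blank frames
ds <- generate_dataset(4, 30, blank_fraction = 0.1,
                       width = 232, height = 168, seed = 42)
ds
#> Synthetic CLE dataset: 8 videos, 240 frames (232x168)
#>
#> glioblastoma   meningioma
#>            4            4

cfg <- cle_config(scheme = "bow", m = 64, sample_n = 20000, window = 5)
model <- cle_train(ds, cfg, seed = 1)
model
#> CLE tissue classification model
#>   scheme: bow | pooling: sum_normalized | classifier: svm_linear
#>   vocabulary: m = 64 ( tree )
#>   entropy threshold: 5.784 bits | trained on 216 frames
#>   classes: glioblastoma, meningioma

ev <- cle_evaluate(ds, cfg, n_splits = 3, seed = 1)
ev
#> Video-grouped evaluation (3 splits, scheme = bow)
#>   accuracy               1.0000 +/- 0.0000
#>   sensitivity            1.0000 +/- 0.0000
#>   specificity            1.0000 +/- 0.0000
#>   accuracy_smoothed      1.0000 +/- 0.0000
#>   sensitivity_smoothed   1.0000 +/- 0.0000
#>   specificity_smoothed   1.0000 +/- 0.0000
#>   mean per-frame encode time: 0.00145 s
```

The entropy threshold (here 5.784 bits) is the 10% quantile of the
training frames' gray-level entropies — the injected blanks sit near 2
bits and are discarded, the textured frames near 5–6 bits survive.
`accuracy` is the frame-level test accuracy across grouped splits before
voting, `accuracy_smoothed` after T = 5 majority voting; the two default
texture classes are cleanly separable, so a correct pipeline reaches 1.0
at this size. For single-video prediction:

```r
stream <- predict(model, ds)      # video_id, frame_index, raw_label,
head(stream, 3)                   # raw_score, smoothed_label
```

A command-line front end over the same functions is installed at
`inst/cli/endocode.R` (`simulate | entropy | prune | train | predict |
evaluate | sweep-window`).

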