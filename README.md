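# VidVAE

Privacy-preserving variational autoencoding of clinical motor-task videos,
with the rater-agreement statistics needed to check that decoded videos
still carry clinical information.

## The problem

Videos of standardized motor tasks — here the finger-to-nose test used to
grade limb ataxia on the Neurostatus-EDSS ordinal scale 0–4 — are
identifiable personal data. Sharing them with the non-clinical engineers who
build automated severity-scoring systems is a privacy problem. A variational
autoencoder (VAE) addresses it by replacing each frame with a fixed-length
latent code: the code is not human-readable, but a paired decoder can
reconstruct a watchable video to verify that the movement information
survived the information bottleneck.

VidVAE provides, in one package:

- **The per-frame VAE**: a densely-connected convolutional encoder of
  `nBlocks` blocks (each halves the resolution and doubles the feature
  depth) predicting a latent Normal `N(μ, σ²)`, reparameterized sampling
  `z = μ + exp(½ log σ²) ⊙ ε` to a code of length 256, and a mirrored
  transposed-convolution decoder with nearest-neighbor upsampling skips.
  Layers, the reverse-mode autodiff tape, and the Adam optimizer are
  implemented in-package (im2col/GEMM convolution kernels in
  RcppArmadillo); every operator's gradient is tested against central
  differences.
- **The training objective**:
  `loss = (1 − MS-SSIM(x, x̂)) + β · KL(N(μ,σ²) ‖ N(0,I)) / codeLength`,
  the multi-scale structural-similarity perceptual loss with
  Kullback–Leibler regularization (β = 1 by default).
- **A synthetic benchmark**: seeded finger-to-nose videos whose fingertip
  trajectory carries a grade-dependent tremor (amplitude `2g` px) and jitter
  (sd `0.5g` px at 64×64), rendered as RGB or RGB-D frames over per-subject
  nuisance features, plus a Gaussian-discretized simulated-rater model with
  a "not ratable" (NR) state.
- **Agreement statistics**: linearly weighted Cohen kappa
  `κ = 1 − Σ w·O / Σ w·E` with `w_ij = |i−j|` (disagreements of 1, 2, 3
  grades weigh 1, 2, 3), intra-rater (original vs decoded) and inter-rater
  (mean of pairwise κ) aggregation, mean rating difference, ratable
  proportion, agreement bands (0.21–0.4 "fair", 0.41–0.6 "moderate", …),
  and a videos × raters agreement-grid plot.

## Worked example

Encode a synthetic severity-graded video into shareable codes:

```r
library(VidVAE)
cfg <- modelConfig(inputResolution = 64, inputChannels = 3)
cfg
#> ModelConfig: 64x64x3 input, 5 blocks, 8 initial filters, kernel 5, code length 256
blockOutputShape(cfg, 5)
#>        height         width feature_depth
#>             2             2           128

model <- createVAEModel(cfg, seed = 1)   # train() fits it; see below
v <- simulateVideo(syntheticVideoSpec("S01", grade = 3, resolution = 64,
                                      nFrames = 30, seed = 7))
codes <- encodeVideo(v$frames, model)
codes
#> CodeSequence: 30 frames x code length 256 (source 64x64, model 42256f38)
```

The code sequence is the artifact you would share; `decodeVideo(codes,
model)` reconstructs the frames (refusing a mismatched decoder via the model
fingerprint), and `train(dataset, cfg)` fits the weights — the shipped test
suite trains on 200 synthetic 64×64 frames for 20 epochs and verifies the
loss falls and held-out reconstruction beats untrained weights.

Rater agreement between an "original" and a noisier "decoded" condition:

```r
grades <- rep(0:4, each = 4)                                     # 20 videos
raters_orig <- lapply(1:10, function(j) raterModel(miscodeSd = 0.4, seed = j))
raters_dec  <- lapply(1:10, function(j)
  raterModel(miscodeSd = 0.8, notRatableProb = 0.1, seed = 100 + j))
orig <- simulateRatings(grades, raters_orig, condition = "original")
dec  <- simulateRatings(grades, raters_dec,  condition = "decoded")
dec
#> RatingTable [decoded]: 20 videos x 10 raters, 89.0% ratable

intraraterAgreement(orig, dec)$pooled
#> KappaResult: kappa = 0.6961 (linear weights, substantial), n = 178
interraterAgreement(orig)$meanKappa
#> [1] 0.8415315
interraterAgreement(dec)$meanKappa
#> [1] 0.5795155
meanRatingDifference(orig, dec)
#> [1] 0.02247191
```

Read: 178 of the 200 (video, rater) pairs were ratable in both conditions;
pooled intra-rater agreement between the two conditions is κ = 0.70
("substantial" band); the noisier decoded condition lowers inter-rater
agreement from 0.84 to 0.58; and there is no systematic severity shift
between conditions (mean difference ≈ 0.02 grades). `plotRatingGrid(dec)`
draws the videos × raters grid with NR in a distinct color.

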