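#' Architecture configuration of the frame autoencoder
#'
#' Describes the convolutional variational autoencoder: square input frames,
#' a ladder of resolution-halving encoder blocks that double the feature
#' depth, and the mirrored decoder. Defaults follow the reference
#' architecture (5 blocks, 8 initial filters, kernel size 5, code length
#' 256); the default 64-pixel resolution is a desk-scale setting, 256 is the
#' full-scale one.
#'
#' @slot inputResolution side length in pixels of the square input frame;
#'   must be divisible by `2^nBlocks`.
#' @slot inputChannels 3 (RGB) or 4 (RGB-D, depth as 4th channel).
#' @slot nBlocks number of encoder (and decoder) blocks.
#' @slot initialFilters feature depth after the first block; doubles per block.
#' @slot codeLength length of the latent code vector.
#' @slot kernelSize odd convolution kernel size in pixels.
#' @export
setClass("ModelConfig",
  representation(inputResolution = "integer", inputChannels = "integer",
                 nBlocks = "integer", initialFilters = "integer",
                 codeLength = "integer", kernelSize = "integer"),
  validity = function(object) {
    msg <- character()
    r <- object@inputResolution
    if (!is_count(r, 2)) msg <- c(msg, "inputResolution must be a positive integer")
    if (!object@inputChannels %in% c(3L, 4L))
      msg <- c(msg, "inputChannels must be 3 (RGB) or 4 (RGB-D)")
    for (s in c("nBlocks", "initialFilters", "codeLength", "kernelSize"))
      if (!is_count(slot(object, s))) msg <- c(msg, paste(s, "must be >= 1"))
    if (is_count(r, 2) && r %% 2^object@nBlocks != 0)
      msg <- c(msg, sprintf("inputResolution %d not divisible by 2^%d",
                            r, object@nBlocks))
    if (object@kernelSize %% 2 == 0)
      msg <- c(msg, "kernelSize must be odd")
    if (length(msg)) msg else TRUE
  })

#' @describeIn ModelConfig-class Constructor.
#' @param inputResolution,inputChannels,nBlocks,initialFilters,codeLength,kernelSize
#'   see slots.
#' @return A `ModelConfig`.
#' @export
modelConfig <- function(inputResolution = 64, inputChannels = 3, nBlocks = 5,
                        initialFilters = 8, codeLength = 256, kernelSize = 5) {
  new("ModelConfig",
      inputResolution = as.integer(inputResolution),
      inputChannels = as.integer(inputChannels),
      nBlocks = as.integer(nBlocks),
      initialFilters = as.integer(initialFilters),
      codeLength = as.integer(codeLength),
      kernelSize = as.integer(kernelSize))
}

#' Reconstruction/regularization loss configuration
#'
#' Parameters of the multi-scale structural similarity (MS-SSIM) perceptual
#' term and the Kullback-Leibler weight. Scale weights default to the
#' published five-scale MS-SSIM weights and are truncated and renormalized
#' automatically when the input resolution cannot support five dyadic scales
#' with the chosen window (at 64x64 with an 11-pixel window three scales
#' remain).
#'
#' @slot scales number of dyadic scales.
#' @slot scaleWeights per-scale exponents, non-negative, summing to 1.
#' @slot ssimWindow odd window size in pixels (default 11).
#' @slot k1,k2 SSIM stability constants (defaults 0.01, 0.03 on a [0,1] range).
#' @slot klWeight non-negative weight of the KL term (beta).
#' @export
setClass("LossConfig",
  representation(scales = "integer", scaleWeights = "numeric",
                 ssimWindow = "integer", k1 = "numeric", k2 = "numeric",
                 klWeight = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@scaleWeights) != object@scales)
      msg <- c(msg, "scaleWeights length must equal scales")
    if (any(object@scaleWeights < 0)) msg <- c(msg, "scaleWeights must be >= 0")
    if (abs(sum(object@scaleWeights) - 1) > 1e-9)
      msg <- c(msg, "scaleWeights must sum to 1 (within 1e-9)")
    if (object@ssimWindow %% 2 == 0 || object@ssimWindow < 3)
      msg <- c(msg, "ssimWindow must be odd and >= 3")
    if (object@klWeight < 0) msg <- c(msg, "klWeight must be >= 0")
    if (length(msg)) msg else TRUE
  })

# published five-scale MS-SSIM weights (normalized: the printed values sum
# to 1.0001)
.msssim_weights5 <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333) /
  sum(c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333))

#' @describeIn LossConfig-class Constructor. `resolution` (if given) truncates
#'   the scale pyramid so the coarsest scale still admits the window, i.e.
#'   `resolution / 2^(scales-1) >= ssimWindow`.
#' @param resolution optional input resolution used to auto-reduce scales.
#' @param scales,scaleWeights,ssimWindow,k1,k2,klWeight see slots.
#' @return A `LossConfig`.
#' @export
lossConfig <- function(resolution = NULL, scales = 5, scaleWeights = NULL,
                       ssimWindow = 11, k1 = 0.01, k2 = 0.03, klWeight = 1.0) {
  if (is.null(scaleWeights)) {
    scaleWeights <- if (scales == 5) .msssim_weights5 else rep(1 / scales, scales)
  }
  scaleWeights <- scaleWeights / sum(scaleWeights)
  if (!is.null(resolution)) {
    max_scales <- max(1L, 1L + floor(log2(resolution / ssimWindow)))
    if (scales > max_scales) {
      scales <- max_scales
      scaleWeights <- scaleWeights[seq_len(scales)]
      scaleWeights <- scaleWeights / sum(scaleWeights)
    }
  }
  new("LossConfig", scales = as.integer(scales), scaleWeights = scaleWeights,
      ssimWindow = as.integer(ssimWindow), k1 = k1, k2 = k2,
      klWeight = klWeight)
}

#' Training configuration
#'
#' @slot learningRate Adam step size (reference value 0.001).
#' @slot epochs number of passes over the training frames (reference 400;
#'   desk-scale default 20).
#' @slot batchSize frames per gradient step.
#' @slot seed integer seed controlling weight init, shuffling and sampling.
#' @slot checkpointEvery epochs between checkpoints (0 = none).
#' @slot checkpointDir directory for checkpoints ("" = none).
#' @slot validationFraction fraction of videos held out for validation.
#' @slot device compute device descriptor (only "cpu" is available).
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", epochs = "integer",
                 batchSize = "integer", seed = "integer",
                 checkpointEvery = "integer", checkpointDir = "character",
                 validationFraction = "numeric", device = "character"),
  validity = function(object) {
    msg <- character()
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
    if (!is_count(object@epochs)) msg <- c(msg, "epochs must be >= 1")
    if (!is_count(object@batchSize)) msg <- c(msg, "batchSize must be >= 1")
    if (object@validationFraction < 0 || object@validationFraction >= 1)
      msg <- c(msg, "validationFraction must be in [0, 1)")
    if (length(msg)) msg else TRUE
  })

#' @describeIn TrainConfig-class Constructor.
#' @param learningRate,epochs,batchSize,seed,checkpointEvery,checkpointDir,validationFraction,device
#'   see slots.
#' @return A `TrainConfig`.
#' @export
trainConfig <- function(learningRate = 0.001, epochs = 20, batchSize = 16,
                        seed = 1, checkpointEvery = 0, checkpointDir = "",
                        validationFraction = 0.1, device = "cpu") {
  new("TrainConfig", learningRate = learningRate, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), seed = as.integer(seed),
      checkpointEvery = as.integer(checkpointEvery),
      checkpointDir = checkpointDir,
      validationFraction = validationFraction, device = device)
}

#' A variational autoencoder model (architecture + weights + norm statistics)
#'
#' @slot config the [ModelConfig-class].
#' @slot params named list of weight arrays.
#' @slot state named list of batch-normalization running statistics.
#' @slot epochsTrained number of completed training epochs.
#' @export
setClass("VAEModel",
  representation(config = "ModelConfig", params = "list", state = "list",
                 epochsTrained = "integer"))

#' Per-frame latent Normal distributions
#'
#' One row per frame: the encoder's predicted mean and log-variance of the
#' latent Normal over the code space.
#'
#' @slot mean numeric matrix, frames x codeLength.
#' @slot logVariance numeric matrix, same shape.
#' @export
setClass("LatentDistribution",
  representation(mean = "matrix", logVariance = "matrix"),
  validity = function(object) {
    if (!all(dim(object@mean) == dim(object@logVariance)))
      return("mean and logVariance must have identical dimensions")
    if (!all(is.finite(object@mean)) || !all(is.finite(object@logVariance)))
      return("latent parameters must be finite")
    TRUE
  })

#' A sequence of per-frame latent codes (the shareable artifact)
#'
#' @slot codes numeric matrix, frames x codeLength, in frame order.
#' @slot header list with `format_version`, `code_length`, `n_frames`,
#'   `source_resolution`, `model_fingerprint`.
#' @export
setClass("CodeSequence",
  representation(codes = "matrix", header = "list"),
  validity = function(object) {
    h <- object@header
    need <- c("format_version", "code_length", "n_frames",
              "source_resolution", "model_fingerprint")
    if (!all(need %in% names(h)))
      return(paste("header missing:",
                   paste(setdiff(need, names(h)), collapse = ", ")))
    if (h$n_frames != nrow(object@codes))
      return("header n_frames does not match the code matrix")
    if (h$code_length != ncol(object@codes))
      return("header code_length does not match the code matrix")
    TRUE
  })

#' Videos x raters grid of ordinal severity ratings
#'
#' Ratings are integers 0-4; `NA` encodes the distinguished "not ratable"
#' (NR) judgment. Serialized as long CSV with rating values `0..4` or `"NR"`.
#'
#' @slot ratings integer matrix, videos x raters; `NA` = not ratable.
#' @slot videoIds,raterIds unique row/column identifiers.
#' @slot condition label, e.g. `"original"` or `"decoded"`.
#' @export
setClass("RatingTable",
  representation(ratings = "matrix", videoIds = "character",
                 raterIds = "character", condition = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@ratings) != length(object@videoIds) ||
        ncol(object@ratings) != length(object@raterIds))
      msg <- c(msg, "ratings dimensions must match id lengths")
    if (anyDuplicated(object@videoIds)) msg <- c(msg, "videoIds must be unique")
    if (anyDuplicated(object@raterIds)) msg <- c(msg, "raterIds must be unique")
    vals <- object@ratings[!is.na(object@ratings)]
    if (length(vals) && (any(vals < 0) || any(vals > 4) || any(vals != round(vals))))
      msg <- c(msg, "ratings must be integers in 0..4 or NA (not ratable)")
    if (length(msg)) msg else TRUE
  })

#' Result of a weighted-kappa computation
#'
#' @slot kappa the agreement coefficient in [-1, 1]; `NA` when undefined
#'   (no marginal variation), with the cause in `reason`.
#' @slot nPairsUsed rating pairs remaining after not-ratable exclusion.
#' @slot weightScheme `"linear"` or `"quadratic"`.
#' @slot interpretation agreement band label (see [interpretKappa()]).
#' @slot reason empty, or why kappa is undefined.
#' @export
setClass("KappaResult",
  representation(kappa = "numeric", nPairsUsed = "integer",
                 weightScheme = "character", interpretation = "character",
                 reason = "character"))

#' Identity (nuisance) features of one simulated subject
#'
#' The appearance features the latent bottleneck should conserve less well
#' than the movement: limb size, skin tone, background texture, body depth.
#'
#' @slot subjectId opaque identifier.
#' @slot limbThickness arm thickness in pixels (>= 1).
#' @slot skinTone RGB triple in [0,1].
#' @slot backgroundPatternSeed integer seeding the background texture.
#' @slot noseTarget (row, col) of the nose in 0-based frame coordinates.
#' @slot bodyDepthOffset base depth of the body in [0,1].
#' @export
setClass("SubjectIdentity",
  representation(subjectId = "character", limbThickness = "numeric",
                 skinTone = "numeric", backgroundPatternSeed = "integer",
                 noseTarget = "numeric", bodyDepthOffset = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@limbThickness < 1) msg <- c(msg, "limbThickness must be >= 1 pixel")
    if (length(object@skinTone) != 3 || any(object@skinTone < 0) ||
        any(object@skinTone > 1))
      msg <- c(msg, "skinTone must be an RGB triple in [0,1]")
    if (length(object@noseTarget) != 2 || any(object@noseTarget < 0))
      msg <- c(msg, "noseTarget must be a non-negative (row, col) point")
    if (object@bodyDepthOffset < 0 || object@bodyDepthOffset > 1)
      msg <- c(msg, "bodyDepthOffset must be in [0,1]")
    if (length(msg)) msg else TRUE
  })

#' Kinematic parameters of one simulated finger-to-nose trajectory
#'
#' The fingertip path is a straight start-to-nose interpolation plus a
#' sinusoidal tremor applied perpendicular to the path and Gaussian jitter;
#' both noise magnitudes grow with the ataxia grade and are exactly zero at
#' grade 0.
#'
#' @slot nFrames number of frames (>= 2).
#' @slot startPoint,endPoint (row, col) 0-based frame coordinates; the end
#'   point is the subject's nose target.
#' @slot tremorAmplitude sinusoid amplitude in pixels.
#' @slot tremorFrequency cycles per trajectory.
#' @slot jitterSd Gaussian jitter standard deviation in pixels.
#' @slot overshootProb probability of an overshoot-and-correct excursion.
#' @export
setClass("TrajectorySpec",
  representation(nFrames = "integer", startPoint = "numeric",
                 endPoint = "numeric", tremorAmplitude = "numeric",
                 tremorFrequency = "numeric", jitterSd = "numeric",
                 overshootProb = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@nFrames < 2) msg <- c(msg, "nFrames must be >= 2")
    if (length(object@startPoint) != 2 || length(object@endPoint) != 2)
      msg <- c(msg, "startPoint and endPoint must be (row, col) points")
    if (object@tremorAmplitude < 0 || object@jitterSd < 0)
      msg <- c(msg, "noise magnitudes must be >= 0")
    if (object@overshootProb < 0 || object@overshootProb > 1)
      msg <- c(msg, "overshootProb must be in [0,1]")
    if (length(msg)) msg else TRUE
  })

#' Ground-truth generative parameters of one synthetic video
#'
#' @slot subject the [SubjectIdentity-class].
#' @slot grade ataxia grade, integer in 0..4 (ordinal severity).
#' @slot trajectory the [TrajectorySpec-class].
#' @slot resolution square frame side in pixels (a power of two).
#' @slot channels 3 (RGB) or 4 (RGB-D).
#' @slot seed integer; together with the spec it fully determines the video.
#' @export
setClass("SyntheticVideoSpec",
  representation(subject = "SubjectIdentity", grade = "integer",
                 trajectory = "TrajectorySpec", resolution = "integer",
                 channels = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@grade %in% 0:4) msg <- c(msg, "grade must be in 0..4")
    r <- object@resolution
    if (r < 2 || bitwAnd(r, r - 1L) != 0)
      msg <- c(msg, "resolution must be a power of two")
    if (!object@channels %in% c(3L, 4L)) msg <- c(msg, "channels must be 3 or 4")
    if (any(object@subject@noseTarget >= r))
      msg <- c(msg, "nose target must lie inside the frame")
    if (length(msg)) msg else TRUE
  })

#' Behavioral model of one simulated rater
#'
#' Emitted rating for true grade g: with probability `notRatableProb` the
#' distinguished not-ratable value, otherwise
#' `clip(round(g + bias + Normal(0, miscodeSd)), 0, 4)`.
#'
#' @slot bias signed systematic offset in grade units.
#' @slot miscodeSd standard deviation of the rating noise in grade units.
#' @slot notRatableProb probability of declining to rate, in [0,1].
#' @slot seed integer seed for this rater's stream.
#' @export
setClass("RaterModel",
  representation(bias = "numeric", miscodeSd = "numeric",
                 notRatableProb = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@miscodeSd < 0) msg <- c(msg, "miscodeSd must be >= 0")
    if (object@notRatableProb < 0 || object@notRatableProb > 1)
      msg <- c(msg, "notRatableProb must be in [0,1]")
    if (length(msg)) msg else TRUE
  })

#' @describeIn SubjectIdentity-class Constructor.
#' @param subjectId,limbThickness,skinTone,backgroundPatternSeed,noseTarget,bodyDepthOffset
#'   see slots.
#' @return A `SubjectIdentity`.
#' @export
subjectIdentity <- function(subjectId, limbThickness = 3,
                            skinTone = c(0.85, 0.65, 0.5),
                            backgroundPatternSeed = 1,
                            noseTarget = c(16, 16), bodyDepthOffset = 0.6) {
  new("SubjectIdentity", subjectId = as.character(subjectId),
      limbThickness = limbThickness, skinTone = skinTone,
      backgroundPatternSeed = as.integer(backgroundPatternSeed),
      noseTarget = noseTarget, bodyDepthOffset = bodyDepthOffset)
}

#' @describeIn TrajectorySpec-class Constructor.
#' @param nFrames,startPoint,endPoint,tremorAmplitude,tremorFrequency,jitterSd,overshootProb
#'   see slots.
#' @return A `TrajectorySpec`.
#' @export
trajectorySpec <- function(nFrames, startPoint, endPoint,
                           tremorAmplitude = 0, tremorFrequency = 3,
                           jitterSd = 0, overshootProb = 0) {
  new("TrajectorySpec", nFrames = as.integer(nFrames),
      startPoint = as.numeric(startPoint), endPoint = as.numeric(endPoint),
      tremorAmplitude = tremorAmplitude, tremorFrequency = tremorFrequency,
      jitterSd = jitterSd, overshootProb = overshootProb)
}

#' @describeIn RaterModel-class Constructor.
#' @param bias,miscodeSd,notRatableProb,seed see slots.
#' @return A `RaterModel`.
#' @export
raterModel <- function(bias = 0, miscodeSd = 0, notRatableProb = 0, seed = 1) {
  new("RaterModel", bias = bias, miscodeSd = miscodeSd,
      notRatableProb = notRatableProb, seed = as.integer(seed))
}
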