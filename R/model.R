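#' Activation shape of one encoder block
#'
#' Each encoder block halves the spatial resolution and doubles the feature
#' depth, starting from `initialFilters` after the first block.
#'
#' @param config a [ModelConfig-class].
#' @param block_index block number in `1..nBlocks`.
#' @return integer `(height, width, feature_depth)` of the block's output.
#' @examples
#' cfg <- modelConfig(inputResolution = 256, inputChannels = 4)
#' blockOutputShape(cfg, 1) # 128 128 8
#' blockOutputShape(cfg, 5) # 8 8 128
#' @export
blockOutputShape <- function(config, block_index) {
  stopifnot(is(config, "ModelConfig"))
  if (!is_count(block_index) || block_index > config@nBlocks)
    stop(sprintf("block_index must be in 1..%d, got %s",
                 config@nBlocks, format(block_index)))
  side <- config@inputResolution %/% 2L^block_index
  depth <- config@initialFilters * 2L^(block_index - 1L)
  c(height = side, width = side, feature_depth = as.integer(depth))
}

# feature depth per encoder block
block_depths <- function(config) {
  config@initialFilters * 2L^(seq_len(config@nBlocks) - 1L)
}

#' Create a variational autoencoder with freshly initialized weights
#'
#' Encoder: `nBlocks` densely-connected blocks (convolution + batch norm +
#' leaky ReLU, with the block input concatenated to the sub-block output),
#' each followed by a strided 2x2 convolution that halves the resolution and
#' sets the feature depth to `initialFilters * 2^(i-1)`. A global average
#' pool and two affine heads predict the latent mean and log-variance.
#' Decoder: an affine map to the coarsest feature map, then `nBlocks`
#' transposed-convolution blocks, each doubling the resolution and halving
#' the depth, with a nearest-neighbor upsampling skip connection; the final
#' block maps to the input channels through a sigmoid.
#'
#' @param config a [ModelConfig-class].
#' @param seed integer seed for the weight initialization.
#' @return a [VAEModel-class].
#' @export
createVAEModel <- function(config, seed = 1) {
  stopifnot(is(config, "ModelConfig"))
  validObject(config)
  B <- config@nBlocks
  C <- config@inputChannels
  Dd <- config@codeLength
  k <- config@kernelSize
  f <- block_depths(config)
  hB <- config@inputResolution %/% 2L^B

  he <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
  params <- list()
  state <- list()
  with_seed(seed, {
    d_in <- C
    for (i in seq_len(B)) {
      params[[sprintf("enc%d.conv.w", i)]] <- he(c(k, k, d_in, f[i]), k * k * d_in)
      params[[sprintf("enc%d.conv.b", i)]] <- numeric(f[i])
      params[[sprintf("enc%d.bn.gamma", i)]] <- rep(1, f[i])
      params[[sprintf("enc%d.bn.beta", i)]] <- numeric(f[i])
      state[[sprintf("enc%d.bn", i)]] <- list(mean = numeric(f[i]), var = rep(1, f[i]))
      dc <- d_in + f[i]
      params[[sprintf("enc%d.down.w", i)]] <- he(c(2, 2, dc, f[i]), 4 * dc)
      params[[sprintf("enc%d.down.b", i)]] <- numeric(f[i])
      d_in <- f[i]
    }
    params[["head.mu.w"]] <- he(c(f[B], Dd), f[B])
    params[["head.mu.b"]] <- numeric(Dd)
    params[["head.lv.w"]] <- he(c(f[B], Dd), f[B]) * 0.1
    params[["head.lv.b"]] <- numeric(Dd)

    params[["dec.fc.w"]] <- he(c(Dd, hB * hB * f[B]), Dd)
    params[["dec.fc.b"]] <- numeric(hB * hB * f[B])
    for (i in seq_len(B)) {
      d <- f[B - i + 1L]
      o <- if (i < B) f[B - i] else C
      # transposed-conv weights stored as the matching conv's [k,k,Cout,Cin]
      params[[sprintf("dec%d.tconv.w", i)]] <- he(c(k, k, o, d), k * k * d)
      params[[sprintf("dec%d.tconv.b", i)]] <- numeric(o)
      params[[sprintf("dec%d.skip.w", i)]] <- he(c(1, 1, d, o), d)
      params[[sprintf("dec%d.skip.b", i)]] <- numeric(o)
      if (i < B) {
        params[[sprintf("dec%d.bn.gamma", i)]] <- rep(1, o)
        params[[sprintf("dec%d.bn.beta", i)]] <- numeric(o)
        state[[sprintf("dec%d.bn", i)]] <- list(mean = numeric(o), var = rep(1, o))
      }
    }
  })
  new("VAEModel", config = config, params = params, state = state,
      epochsTrained = 0L)
}

# leaf nodes for every parameter, for one forward/backward pass
make_leaves <- function(tape, params) {
  lapply(params, function(p) t_leaf(tape, p))
}

# encoder forward; returns mu/lv nodes, per-block shapes, bn nodes
forward_encoder <- function(tape, x, model, leaves, training) {
  cfg <- model@config
  B <- cfg@nBlocks
  pad <- (cfg@kernelSize - 1L) %/% 2L
  a <- x
  shapes <- vector("list", B)
  bn_nodes <- list()
  for (i in seq_len(B)) {
    c1 <- t_conv(tape, a, leaves[[sprintf("enc%d.conv.w", i)]],
                 leaves[[sprintf("enc%d.conv.b", i)]], 1L, pad)
    key <- sprintf("enc%d.bn", i)
    c1 <- t_bn(tape, c1, leaves[[sprintf("enc%d.bn.gamma", i)]],
               leaves[[sprintf("enc%d.bn.beta", i)]],
               model@state[[key]], training)
    bn_nodes[[key]] <- c1
    c1 <- t_lrelu(tape, c1)
    dense <- t_concat_c(tape, a, c1)
    a <- t_lrelu(tape, t_conv(tape, dense, leaves[[sprintf("enc%d.down.w", i)]],
                              leaves[[sprintf("enc%d.down.b", i)]], 2L, 0L))
    shapes[[i]] <- dim(a$v)[1:3]
  }
  pooled <- t_gap(tape, a)
  mu <- t_affine(tape, pooled, leaves[["head.mu.w"]], leaves[["head.mu.b"]])
  lv <- t_affine(tape, pooled, leaves[["head.lv.w"]], leaves[["head.lv.b"]])
  list(mu = mu, lv = lv, shapes = shapes, bn_nodes = bn_nodes)
}

# decoder forward from a code-matrix node [N, D]
forward_decoder <- function(tape, z, model, leaves, training) {
  cfg <- model@config
  B <- cfg@nBlocks
  C <- cfg@inputChannels
  k <- cfg@kernelSize
  pad <- (k - 1L) %/% 2L
  f <- block_depths(cfg)
  hB <- cfg@inputResolution %/% 2L^B
  n <- nrow(z$v)

  a <- t_affine(tape, z, leaves[["dec.fc.w"]], leaves[["dec.fc.b"]])
  a <- t_to_image(tape, a, c(hB, hB, f[B], n))
  a <- t_lrelu(tape, a)
  shapes <- vector("list", B)
  bn_nodes <- list()
  for (i in seq_len(B)) {
    h <- dim(a$v)[1]
    up <- t_upsample2(tape, a)
    skip <- t_conv(tape, up, leaves[[sprintf("dec%d.skip.w", i)]],
                   leaves[[sprintf("dec%d.skip.b", i)]], 1L, 0L)
    tc <- t_convT(tape, a, leaves[[sprintf("dec%d.tconv.w", i)]],
                  leaves[[sprintf("dec%d.tconv.b", i)]], 2L, pad,
                  c(2L * h, 2L * h))
    if (i < B) {
      key <- sprintf("dec%d.bn", i)
      tc <- t_bn(tape, tc, leaves[[sprintf("dec%d.bn.gamma", i)]],
                 leaves[[sprintf("dec%d.bn.beta", i)]],
                 model@state[[key]], training)
      bn_nodes[[key]] <- tc
      a <- t_lrelu(tape, t_add(tape, tc, skip))
    } else {
      a <- t_sigmoid(tape, t_add(tape, tc, skip))
    }
    shapes[[i]] <- dim(a$v)[1:3]
  }
  list(out = a, shapes = shapes, bn_nodes = bn_nodes)
}

# normalize frame input to a [H,W,C,N] array
as_frame_stack <- function(frames) {
  if (is.list(frames)) {
    if (!length(frames)) stop("empty frame sequence")
    d <- dim(frames[[1]])
    for (i in seq_along(frames))
      if (!identical(dim(frames[[i]]), d))
        stop(sprintf("frame %d has shape (%s), expected (%s)", i,
                     paste(dim(frames[[i]]), collapse = "x"),
                     paste(d, collapse = "x")))
    out <- array(0, dim = c(d, length(frames)))
    for (i in seq_along(frames)) out[, , , i] <- frames[[i]]
    return(out)
  }
  d <- dim(frames)
  if (is.null(d) || !length(d) %in% c(3L, 4L))
    stop("frames must be a [H,W,C] or [H,W,C,N] array or a list of frames")
  if (length(d) == 3L) dim(frames) <- c(d, 1L)
  if (dim(frames)[4] == 0L) stop("empty frame sequence")
  frames
}

check_frame_shape <- function(frames, config) {
  d <- dim(frames)
  want <- c(config@inputResolution, config@inputResolution,
            config@inputChannels)
  if (!identical(as.integer(d[1:3]), as.integer(want)))
    stop(sprintf("frame shape (%s) does not match model config (%s)",
                 paste(d[1:3], collapse = "x"), paste(want, collapse = "x")))
  invisible(TRUE)
}

#' Encode frames into per-frame latent Normal distributions
#'
#' Runs the encoder in inference mode (batch-norm running statistics, no
#' sampling). Encoding is strictly per frame: each frame is processed
#' without temporal context.
#'
#' @param frames one `[H,W,C]` frame, an `[H,W,C,N]` stack, or a list of
#'   frames, values in `[0,1]` and shape matching the model config.
#' @param model a [VAEModel-class].
#' @return a [LatentDistribution-class] with one row per frame.
#' @export
encodeFrame <- function(frames, model) {
  stopifnot(is(model, "VAEModel"))
  x <- as_frame_stack(frames)
  check_frame_shape(x, model@config)
  tape <- new_tape()
  leaves <- make_leaves(tape, model@params)
  enc <- forward_encoder(tape, t_leaf(tape, x), model, leaves, training = FALSE)
  new("LatentDistribution", mean = enc$mu$v, logVariance = enc$lv$v)
}

#' Sample a latent code from a latent distribution
#'
#' Reparameterized sampling: `code = mean + exp(0.5 * logVariance) * eps`
#' with `eps ~ Normal(0, I)` drawn from `seed`. With
#' `deterministic = TRUE` (inference mode) the code is the mean exactly.
#'
#' @param dist a [LatentDistribution-class].
#' @param seed integer seed for the Gaussian draw.
#' @param deterministic if TRUE return the mean (no sampling).
#' @return numeric code vector for a single frame, or a frames x codeLength
#'   matrix.
#' @export
sampleCode <- function(dist, seed = 1, deterministic = FALSE) {
  stopifnot(is(dist, "LatentDistribution"))
  m <- dist@mean
  if (deterministic) {
    codes <- m
  } else {
    eps <- with_seed(seed, matrix(rnorm(length(m)), nrow(m), ncol(m)))
    codes <- m + exp(0.5 * dist@logVariance) * eps
  }
  if (nrow(codes) == 1L) as.numeric(codes) else codes
}

#' Decode latent codes into frames
#'
#' @param code numeric code vector, or a frames x codeLength matrix.
#' @param model a [VAEModel-class].
#' @return an `[H,W,C]` frame for a single code, else an `[H,W,C,N]` stack;
#'   values in `[0,1]`.
#' @export
decodeCode <- function(code, model) {
  stopifnot(is(model, "VAEModel"))
  if (is.null(dim(code))) code <- matrix(code, nrow = 1)
  if (ncol(code) != model@config@codeLength)
    stop(sprintf("code length %d does not match config code length %d",
                 ncol(code), model@config@codeLength))
  tape <- new_tape()
  leaves <- make_leaves(tape, model@params)
  dec <- forward_decoder(tape, t_leaf(tape, code), model, leaves,
                         training = FALSE)
  out <- dec$out$v
  if (dim(out)[4] == 1L) {
    d <- dim(out)[1:3]
    dim(out) <- d
  }
  out
}

#' Realized activation shapes of encoder and decoder
#'
#' Runs one forward pass and reports the realized per-block activation
#' shapes, for checking against [blockOutputShape()].
#'
#' @param model a [VAEModel-class].
#' @param frames optional frames (defaults to a single zero frame).
#' @return list with `encoder` and `decoder`: each a list of
#'   `(height, width, feature_depth)` per block.
#' @export
activationShapes <- function(model, frames = NULL) {
  cfg <- model@config
  if (is.null(frames))
    frames <- array(0.5, dim = c(cfg@inputResolution, cfg@inputResolution,
                                 cfg@inputChannels, 1L))
  x <- as_frame_stack(frames)
  check_frame_shape(x, cfg)
  tape <- new_tape()
  leaves <- make_leaves(tape, model@params)
  enc <- forward_encoder(tape, t_leaf(tape, x), model, leaves, training = FALSE)
  z <- t_leaf(tape, enc$mu$v)
  dec <- forward_decoder(tape, z, model, leaves, training = FALSE)
  list(encoder = enc$shapes, decoder = dec$shapes)
}

#' Fingerprint of a model's architecture and weights
#'
#' A short hex digest over the configuration and per-parameter summaries,
#' embedded in [CodeSequence-class] headers so that codes are never decoded
#' by a mismatched decoder. An integrity check, not a cryptographic hash.
#'
#' @param model a [VAEModel-class].
#' @return 8-hex-digit character scalar.
#' @export
modelFingerprint <- function(model) {
  cfg <- model@config
  parts <- c(sprintf("%d|%d|%d|%d|%d|%d", cfg@inputResolution,
                     cfg@inputChannels, cfg@nBlocks, cfg@initialFilters,
                     cfg@codeLength, cfg@kernelSize),
             vapply(names(model@params), function(nm) {
               p <- model@params[[nm]]
               sprintf("%s:%s:%.10g:%.10g", nm,
                       paste(dim(p) %||% length(p), collapse = ","),
                       sum(p), sum(abs(p)))
             }, character(1)))
  string_hash(paste(parts, collapse = ";"))
}

#' Encode a video into a code sequence
#'
#' One latent code per frame, order preserved; the result carries a header
#' (format version, code length, frame count, source resolution, model
#' fingerprint) making it a self-describing shareable artifact.
#'
#' @param frames `[H,W,C,N]` array or list of frames.
#' @param model a [VAEModel-class].
#' @param mode `"deterministic"` (codes are the latent means; default) or
#'   `"sample"` (one reparameterized draw per frame).
#' @param seed seed for `mode = "sample"`.
#' @return a [CodeSequence-class].
#' @export
encodeVideo <- function(frames, model, mode = c("deterministic", "sample"),
                        seed = 1) {
  mode <- match.arg(mode)
  x <- as_frame_stack(frames)
  n <- dim(x)[4]
  # encode in batches to bound memory
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 32))
  codes <- matrix(0, n, model@config@codeLength)
  for (idx in chunks) {
    dist <- encodeFrame(x[, , , idx, drop = FALSE], model)
    codes[idx, ] <- if (mode == "deterministic") dist@mean else {
      cs <- sampleCode(dist, seed = seed + idx[1], deterministic = FALSE)
      if (is.null(dim(cs))) matrix(cs, nrow = 1) else cs
    }
  }
  new("CodeSequence", codes = codes,
      header = list(format_version = 1L,
                    code_length = model@config@codeLength,
                    n_frames = n,
                    source_resolution = model@config@inputResolution,
                    model_fingerprint = modelFingerprint(model)))
}

#' Decode a code sequence back into frames
#'
#' Refuses to decode when the sequence's model fingerprint does not match
#' the supplied model.
#'
#' @param codes a [CodeSequence-class].
#' @param model a [VAEModel-class].
#' @return `[H,W,C,N]` frame stack.
#' @export
decodeVideo <- function(codes, model) {
  stopifnot(is(codes, "CodeSequence"))
  fp <- modelFingerprint(model)
  if (!identical(codes@header$model_fingerprint, fp))
    stop(sprintf(
      "model fingerprint mismatch: codes were produced by %s, decoder is %s",
      codes@header$model_fingerprint, fp))
  n <- nrow(codes@codes)
  cfg <- model@config
  out <- array(0, dim = c(cfg@inputResolution, cfg@inputResolution,
                          cfg@inputChannels, n))
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 32))
  for (idx in chunks) {
    dec <- decodeCode(codes@codes[idx, , drop = FALSE], model)
    if (length(dim(dec)) == 3L) dim(dec) <- c(dim(dec), 1L)
    out[, , , idx] <- dec
  }
  out
}

#' Cosine distance between latent codes
#'
#' `1 - (a . b) / (|a| |b|)`, in `[0, 2]`. Visually similar frames map to
#' nearby codes under this metric after training.
#'
#' @param a,b numeric code vectors of equal length.
#' @return numeric scalar in `[0, 2]`.
#' @export
latentCosineDistance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop(sprintf("code lengths differ: %d vs %d", length(a), length(b)))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine distance undefined for a zero vector")
  1 - sum(a * b) / (na * nb)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full configuration, weights, normalization
#' statistics and training progress; loading reconstructs an identical
#' model (identical fingerprint).
#'
#' @param model a [VAEModel-class].
#' @param path file path.
#' @return `saveModel` the path invisibly; `loadModel` the model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "VAEModel"))
  saveRDS(list(format = "VidVAE-checkpoint-1",
               config = list(inputResolution = model@config@inputResolution,
                             inputChannels = model@config@inputChannels,
                             nBlocks = model@config@nBlocks,
                             initialFilters = model@config@initialFilters,
                             codeLength = model@config@codeLength,
                             kernelSize = model@config@kernelSize),
               params = model@params, state = model@state,
               epochsTrained = model@epochsTrained), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "VidVAE-checkpoint-1"))
    stop("not a recognized model checkpoint: ", path)
  new("VAEModel", config = do.call(modelConfig, x$config), params = x$params,
      state = x$state, epochsTrained = x$epochsTrained)
}
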