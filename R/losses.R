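# Structural-similarity losses and the Kullback-Leibler regularizer.
#
# The training objective is (1 - MS-SSIM(x, xhat)) + beta * KL / codeLength.
# MS-SSIM follows the standard construction: contrast-structure terms at
# every dyadic scale, luminance at the coarsest scale only, combined as a
# weighted geometric mean. Terms are clamped at a small positive floor
# before exponentiation so fractional powers stay real; on [0,1]-valued
# frames the terms are virtually always positive and the clamp is inactive.

.cs_floor <- 1e-8

# per-image luminance and contrast-structure means via tape ops;
# a, b: [H,W,C,N] nodes
t_ssim_components <- function(tape, a, b, kern, C1, C2) {
  mua <- t_blur(tape, a, kern)
  mub <- t_blur(tape, b, kern)
  mua2 <- t_mul(tape, mua, mua)
  mub2 <- t_mul(tape, mub, mub)
  muab <- t_mul(tape, mua, mub)
  va <- t_sub(tape, t_blur(tape, t_mul(tape, a, a), kern), mua2)
  vb <- t_sub(tape, t_blur(tape, t_mul(tape, b, b), kern), mub2)
  vab <- t_sub(tape, t_blur(tape, t_mul(tape, a, b), kern), muab)
  l_map <- t_div(tape,
                 t_addc(tape, t_scale(tape, muab, 2), C1),
                 t_addc(tape, t_add(tape, mua2, mub2), C1))
  cs_map <- t_div(tape,
                  t_addc(tape, t_scale(tape, vab, 2), C2),
                  t_addc(tape, t_add(tape, va, vb), C2))
  list(l = t_mean_hwc(tape, l_map), cs = t_mean_hwc(tape, cs_map),
       l_map = l_map, cs_map = cs_map)
}

# single-scale SSIM per image (mean over windows and channels of l*cs)
t_ssim <- function(tape, a, b, config) {
  kern <- gaussianWindow(config@ssimWindow)
  comp <- t_ssim_components(tape, a, b, kern, config@k1^2, config@k2^2)
  t_mean_hwc(tape, t_mul(tape, comp$l_map, comp$cs_map))
}

# multi-scale SSIM per image; returns an N-vector node
t_msssim <- function(tape, a, b, config) {
  M <- config@scales
  w <- config@scaleWeights
  kern <- gaussianWindow(config@ssimWindow)
  res <- dim(a$v)[1]
  if (res / 2^(M - 1) < config@ssimWindow)
    stop(sprintf(
      "input resolution %d supports only %d scales with window %d; lower `scales`",
      res, max(1L, 1L + floor(log2(res / config@ssimWindow))), config@ssimWindow))
  acc <- NULL
  for (j in seq_len(M)) {
    if (j > 1) {
      a <- t_avgpool2(tape, a)
      b <- t_avgpool2(tape, b)
    }
    comp <- t_ssim_components(tape, a, b, kern, config@k1^2, config@k2^2)
    # contrast-structure at the fine scales; the coarsest scale contributes
    # the full SSIM mean (luminance included), so scales = 1 reduces to ssim()
    base <- if (j < M) comp$cs
            else t_mean_hwc(tape, t_mul(tape, comp$l_map, comp$cs_map))
    term <- t_pow_const(tape, t_clamp_min(tape, base, .cs_floor), w[j])
    acc <- if (is.null(acc)) term else t_mul(tape, acc, term)
  }
  acc
}

check_pair <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("frame shapes differ: (%s) vs (%s)",
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  rng <- range(a, b)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("frame values must lie in [0,1]")
  invisible(TRUE)
}

#' Structural similarity (SSIM) between frames
#'
#' Mean over Gaussian-weighted sliding windows and channels of the SSIM
#' index `[(2 mu_a mu_b + C1)(2 sigma_ab + C2)] /
#' [(mu_a^2 + mu_b^2 + C1)(sigma_a^2 + sigma_b^2 + C2)]` with
#' `C1 = k1^2`, `C2 = k2^2` on a unit dynamic range. Symmetric; equals 1
#' iff the frames are identical. Channels (including a depth channel) are
#' averaged.
#'
#' @param a,b frames (`[H,W,C]`) or frame stacks (`[H,W,C,N]`) with values
#'   in `[0,1]` and identical shapes.
#' @param config a [LossConfig-class]; only the window and stability
#'   constants are used.
#' @return numeric scalar, or a per-frame vector for stacks.
#' @export
ssim <- function(a, b, config = lossConfig()) {
  a <- as_frame_stack(a); b <- as_frame_stack(b)
  check_pair(a, b)
  tape <- new_tape()
  v <- t_ssim(tape, t_leaf(tape, a), t_leaf(tape, b), config)$v
  if (length(v) == 1L) as.numeric(v) else v
}

#' Multi-scale structural similarity (MS-SSIM)
#'
#' The multi-scale extension of [ssim()]: contrast-structure terms computed
#' at `scales` dyadic resolutions (2x average-pool downsampling between
#' scales), luminance at the coarsest scale only, combined as a geometric
#' mean with the configured per-scale weights. `msSSIM(x, x) = 1`; with
#' `scales = 1` and weight 1 it degenerates to a luminance-times-
#' contrast-structure single-scale index equal to [ssim()].
#'
#' @inheritParams ssim
#' @param config a [LossConfig-class].
#' @return numeric scalar, or a per-frame vector for stacks.
#' @export
msSSIM <- function(a, b, config = NULL) {
  a <- as_frame_stack(a); b <- as_frame_stack(b)
  check_pair(a, b)
  if (is.null(config)) config <- lossConfig(resolution = dim(a)[1])
  tape <- new_tape()
  v <- t_msssim(tape, t_leaf(tape, a), t_leaf(tape, b), config)$v
  if (length(v) == 1L) as.numeric(v) else v
}

#' Kullback-Leibler divergence of latent Normals from the standard prior
#'
#' Closed form per frame:
#' `-0.5 * sum_d (1 + logvar_d - mean_d^2 - exp(logvar_d))`. Non-negative,
#' and zero exactly when mean = 0 and logvar = 0.
#'
#' @param dist a [LatentDistribution-class], or a numeric mean vector.
#' @param logVariance numeric log-variance vector when `dist` is a vector.
#' @return numeric scalar for one frame, else a per-frame vector.
#' @export
klNormal <- function(dist, logVariance = NULL) {
  if (is(dist, "LatentDistribution")) {
    m <- dist@mean; lv <- dist@logVariance
  } else {
    m <- rbind(as.numeric(dist)); lv <- rbind(as.numeric(logVariance))
    if (ncol(m) != ncol(lv)) stop("mean and logVariance lengths differ")
  }
  if (!all(is.finite(m)) || !all(is.finite(lv)))
    stop("latent parameters must be finite")
  kl <- -0.5 * rowSums(1 + lv - m^2 - exp(lv))
  if (length(kl) == 1L) as.numeric(kl) else kl
}

#' Total training loss
#'
#' `(1 - msSSIM(original, reconstruction)) + klWeight * KL / codeLength`,
#' averaged over frames. The KL term is normalized by the code length so the
#' two terms stay on comparable scales.
#'
#' @param original,reconstruction frames or frame stacks in `[0,1]`.
#' @param dist the [LatentDistribution-class] the codes were sampled from.
#' @param config a [LossConfig-class].
#' @return list with `total` and named `components`
#'   (`ms_ssim`, `reconstruction`, `kl`, `kl_weighted`).
#' @export
totalLoss <- function(original, reconstruction, dist, config = NULL) {
  original <- as_frame_stack(original)
  if (is.null(config)) config <- lossConfig(resolution = dim(original)[1])
  ms <- mean(msSSIM(original, reconstruction, config))
  kl <- mean(klNormal(dist))
  d <- ncol(dist@mean)
  klw <- config@klWeight * kl / d
  list(total = (1 - ms) + klw,
       components = list(ms_ssim = ms, reconstruction = 1 - ms,
                         kl = kl, kl_weighted = klw))
}
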