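# Independent oracles: naive loop-based implementations used only to check
# the package's vectorized code paths.

# single-scale SSIM statistics by explicit loops over window positions.
# Returns mean luminance term, mean contrast-structure term, and the mean
# of their product, over all valid windows and channels.
ssim_oracle_terms <- function(a, b, window = 11, k1 = 0.01, k2 = 0.03) {
  kern <- exp(-((seq_len(window) - (window + 1) / 2)^2) / (2 * 1.5^2))
  kern <- kern / sum(kern)
  w2 <- outer(kern, kern)
  C1 <- k1^2; C2 <- k2^2
  d <- dim(a)
  nh <- d[1] - window + 1
  nw <- d[2] - window + 1
  l_sum <- cs_sum <- prod_sum <- 0
  count <- 0
  for (ch in seq_len(d[3])) {
    for (i in seq_len(nh)) for (j in seq_len(nw)) {
      pa <- a[i:(i + window - 1), j:(j + window - 1), ch, 1]
      pb <- b[i:(i + window - 1), j:(j + window - 1), ch, 1]
      mua <- sum(w2 * pa); mub <- sum(w2 * pb)
      va <- sum(w2 * pa^2) - mua^2
      vb <- sum(w2 * pb^2) - mub^2
      vab <- sum(w2 * pa * pb) - mua * mub
      l <- (2 * mua * mub + C1) / (mua^2 + mub^2 + C1)
      cs <- (2 * vab + C2) / (va + vb + C2)
      l_sum <- l_sum + l; cs_sum <- cs_sum + cs; prod_sum <- prod_sum + l * cs
      count <- count + 1
    }
  }
  list(l = l_sum / count, cs = cs_sum / count, ssim = prod_sum / count)
}

# 2x average-pool downsampling by explicit loops
downsample2_oracle <- function(x) {
  d <- dim(x)
  out <- array(0, dim = c(d[1] %/% 2, d[2] %/% 2, d[3], d[4]))
  for (i in seq_len(d[1] %/% 2)) for (j in seq_len(d[2] %/% 2))
    out[i, j, , ] <- (x[2 * i - 1, 2 * j - 1, , ] + x[2 * i, 2 * j - 1, , ] +
                      x[2 * i - 1, 2 * j, , ] + x[2 * i, 2 * j, , ]) / 4
  out
}

# multi-scale SSIM by loops: contrast-structure at fine scales, full SSIM
# mean at the coarsest, weighted geometric mean (terms floored at 1e-8)
msssim_oracle <- function(a, b, scales, weights, window = 11,
                          k1 = 0.01, k2 = 0.03) {
  acc <- 1
  for (s in seq_len(scales)) {
    if (s > 1) {
      a <- downsample2_oracle(a)
      b <- downsample2_oracle(b)
    }
    terms <- ssim_oracle_terms(a, b, window, k1, k2)
    base <- if (s < scales) terms$cs else terms$ssim
    acc <- acc * max(base, 1e-8)^weights[s]
  }
  acc
}

# linearly weighted Cohen kappa by explicit double loops over categories
kappa_oracle <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  O <- matrix(0, 5, 5)
  for (i in seq_len(n)) O[a[i] + 1, b[i] + 1] <- O[a[i] + 1, b[i] + 1] + 1
  rm_ <- rowSums(O); cm_ <- colSums(O)
  num <- 0; den <- 0
  for (i in 1:5) for (j in 1:5) {
    w <- abs(i - j)
    num <- num + w * O[i, j]
    den <- den + w * rm_[i] * cm_[j] / n
  }
  if (den == 0) return(NA_real_)
  1 - num / den
}

# exact rating-category probabilities of the Gaussian-discretized rater:
# P(rating = i | grade g), clipping mass below 0 into 0 and above 4 into 4
rater_category_probs <- function(g, bias, sd) {
  if (sd == 0) {
    p <- numeric(5)
    p[min(4, max(0, round(g + bias))) + 1] <- 1
    return(p)
  }
  cuts <- c(-Inf, seq(0.5, 3.5, 1), Inf)
  diff(pnorm(cuts, mean = g + bias, sd = sd))
}

# analytic linearly weighted kappa of two independent simulated raters with
# the same model, over a known grade distribution
analytic_rater_kappa <- function(grade_probs, bias, sd) {
  P <- matrix(0, 5, 5)
  for (g in 0:4) {
    pg <- rater_category_probs(g, bias, sd)
    P <- P + grade_probs[g + 1] * outer(pg, pg)
  }
  w <- abs(outer(0:4, 0:4, "-"))
  E <- outer(rowSums(P), colSums(P))
  1 - sum(w * P) / sum(w * E)
}

# tiny architectures used across tests
tiny_config <- function(resolution = 16, channels = 3, blocks = 2,
                        filters = 4, code = 8)
  modelConfig(inputResolution = resolution, inputChannels = channels,
              nBlocks = blocks, initialFilters = filters, codeLength = code)

random_frames <- function(n, res = 16, channels = 3, seed = 1) {
  set.seed(seed)
  array(runif(res * res * channels * n), dim = c(res, res, channels, n))
}
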