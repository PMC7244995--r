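# Minimal reverse-mode automatic differentiation over dense arrays.
#
# A tape records nodes in creation order; each node holds its value, an
# accumulated gradient, references to its parents, and a backward closure
# that routes the node's gradient to the parents. Running the ops in forward
# order is a valid topological order, so the backward pass is a single
# reverse sweep. Arrays are [H, W, C, N] unless stated otherwise; matrices
# are [N, D].

new_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 64L)
  e$n <- 0L
  e
}

tnode <- function(tape, value, backward = NULL, parents = list()) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$bw <- backward
  nd$parents <- parents
  n <- tape$n + 1L
  if (n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

t_accum <- function(nd, g) {
  nd$g <- if (is.null(nd$g)) g else nd$g + g
  invisible(NULL)
}

tape_backward <- function(tape, root) {
  if (length(root$v) != 1L)
    stop("backward pass must start from a scalar node")
  root$g <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$g) && !is.null(nd$bw)) nd$bw(nd)
  }
  invisible(NULL)
}

t_leaf <- function(tape, value) tnode(tape, value)

## ---- elementwise ----

t_add <- function(tape, a, b) {
  tnode(tape, a$v + b$v, function(nd) { t_accum(a, nd$g); t_accum(b, nd$g) })
}

t_sub <- function(tape, a, b) {
  tnode(tape, a$v - b$v, function(nd) { t_accum(a, nd$g); t_accum(b, -nd$g) })
}

t_mul <- function(tape, a, b) {
  tnode(tape, a$v * b$v,
        function(nd) { t_accum(a, nd$g * b$v); t_accum(b, nd$g * a$v) })
}

t_div <- function(tape, a, b) {
  v <- a$v / b$v
  tnode(tape, v, function(nd) {
    t_accum(a, nd$g / b$v)
    t_accum(b, -nd$g * v / b$v)
  })
}

t_scale <- function(tape, a, s) {
  tnode(tape, a$v * s, function(nd) t_accum(a, nd$g * s))
}

t_addc <- function(tape, a, cst) {
  tnode(tape, a$v + cst, function(nd) t_accum(a, nd$g))
}

t_rsubc <- function(tape, cst, a) {
  tnode(tape, cst - a$v, function(nd) t_accum(a, -nd$g))
}

t_exp <- function(tape, a) {
  v <- exp(a$v)
  tnode(tape, v, function(nd) t_accum(a, nd$g * v))
}

t_pow_const <- function(tape, a, p) {
  v <- a$v^p
  tnode(tape, v, function(nd) t_accum(a, nd$g * p * a$v^(p - 1)))
}

t_clamp_min <- function(tape, a, m) {
  mask <- a$v > m
  v <- a$v
  v[!mask] <- m
  tnode(tape, v, function(nd) t_accum(a, nd$g * mask))
}

t_lrelu <- function(tape, a, alpha = 0.2) {
  slope <- (a$v > 0) * (1 - alpha) + alpha
  tnode(tape, a$v * slope, function(nd) t_accum(a, nd$g * slope))
}

t_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-a$v))
  tnode(tape, v, function(nd) t_accum(a, nd$g * v * (1 - v)))
}

## ---- reductions / reshapes ----

t_mean <- function(tape, a) {
  n <- length(a$v)
  tnode(tape, mean(a$v), function(nd) {
    g <- if (is.null(dim(a$v))) rep(nd$g / n, n)
         else array(nd$g / n, dim = dim(a$v))
    t_accum(a, g)
  })
}

# [H,W,C,N] -> per-image mean, numeric length N
t_mean_hwc <- function(tape, a) {
  d <- dim(a$v)
  m <- prod(d[1:3])
  v <- colMeans(matrix(a$v, m, d[4]))
  tnode(tape, v, function(nd) {
    t_accum(a, array(rep(nd$g / m, each = m), dim = d))
  })
}

t_reshape <- function(tape, a, dims) {
  v <- a$v
  dim(v) <- dims
  tnode(tape, v, function(nd) {
    g <- nd$g
    dim(g) <- dim(a$v)
    t_accum(a, g)
  })
}

# [N, M] matrix -> [h, w, c, N] image stack (transposes so N is last)
t_to_image <- function(tape, a, dims) {
  v <- array(t(a$v), dim = dims)
  tnode(tape, v, function(nd) {
    m <- prod(dims[1:3])
    t_accum(a, t(matrix(nd$g, m, dims[4])))
  })
}

# [H,W,C,N] -> [N, C] global average pool over H,W
t_gap <- function(tape, a) {
  d <- dim(a$v)
  hw <- d[1] * d[2]
  v <- t(matrix(colMeans(matrix(a$v, hw, d[3] * d[4])), d[3], d[4]))
  tnode(tape, v, function(nd) {
    g <- array(rep(as.vector(t(nd$g)) / hw, each = hw), dim = d)
    t_accum(a, g)
  })
}

## ---- structural ops ----

t_concat_c <- function(tape, a, b) {
  da <- dim(a$v); db <- dim(b$v)
  v <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  v[, , seq_len(da[3]), ] <- a$v
  v[, , da[3] + seq_len(db[3]), ] <- b$v
  tnode(tape, v, function(nd) {
    t_accum(a, nd$g[, , seq_len(da[3]), , drop = FALSE])
    t_accum(b, nd$g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

t_upsample2 <- function(tape, a) {
  d <- dim(a$v)
  ih <- rep(seq_len(d[1]), each = 2)
  iw <- rep(seq_len(d[2]), each = 2)
  v <- a$v[ih, iw, , , drop = FALSE]
  tnode(tape, v, function(nd) {
    g <- nd$g
    o1 <- seq(1L, 2L * d[1], 2L); o2 <- seq(1L, 2L * d[2], 2L)
    t_accum(a, g[o1, o2, , , drop = FALSE] + g[o1 + 1L, o2, , , drop = FALSE] +
               g[o1, o2 + 1L, , , drop = FALSE] + g[o1 + 1L, o2 + 1L, , , drop = FALSE])
  })
}

t_avgpool2 <- function(tape, a) {
  d <- dim(a$v)
  o1 <- seq(1L, d[1], 2L); o2 <- seq(1L, d[2], 2L)
  v <- (a$v[o1, o2, , , drop = FALSE] + a$v[o1 + 1L, o2, , , drop = FALSE] +
        a$v[o1, o2 + 1L, , , drop = FALSE] + a$v[o1 + 1L, o2 + 1L, , , drop = FALSE]) / 4
  tnode(tape, v, function(nd) {
    ih <- rep(seq_len(d[1] %/% 2L), each = 2)
    iw <- rep(seq_len(d[2] %/% 2L), each = 2)
    t_accum(a, nd$g[ih, iw, , , drop = FALSE] / 4)
  })
}

## ---- linear / convolutional layers ----

t_affine <- function(tape, x, w, b) {
  v <- sweep(x$v %*% w$v, 2L, b$v, "+")
  tnode(tape, v, function(nd) {
    t_accum(x, nd$g %*% t(w$v))
    t_accum(w, crossprod(x$v, nd$g))
    t_accum(b, colSums(nd$g))
  })
}

t_conv <- function(tape, x, w, b, stride, pad) {
  v <- .cpp_conv2d_forward(x$v, w$v, b$v, stride, pad)
  kd <- dim(w$v)
  dx_dim <- dim(x$v)
  tnode(tape, v, function(nd) {
    t_accum(x, .cpp_conv2d_backward_data(nd$g, w$v, dx_dim[1], dx_dim[2],
                                         stride, pad))
    fb <- .cpp_conv2d_backward_filter(x$v, nd$g, kd[1], kd[2], stride, pad)
    t_accum(w, fb$dw)
    t_accum(b, fb$db)
  })
}

# transposed convolution: weights [kh, kw, Cout, Cin]; output size explicit
t_convT <- function(tape, x, w, b, stride, pad, out_hw) {
  v <- .cpp_conv2d_backward_data(x$v, w$v, out_hw[1], out_hw[2], stride, pad)
  v <- v + bc_channel(b$v, dim(v))
  kd <- dim(w$v)
  tnode(tape, v, function(nd) {
    t_accum(x, .cpp_conv2d_forward(nd$g, w$v, numeric(kd[4]), stride, pad))
    fb <- .cpp_conv2d_backward_filter(nd$g, x$v, kd[1], kd[2], stride, pad)
    t_accum(w, fb$dw)
    t_accum(b, channel_sum(nd$g))
  })
}

# depthwise separable Gaussian filtering (valid); kern is a 1-D window
t_blur <- function(tape, a, kern) {
  v <- .cpp_dwconv_sep(a$v, kern, 0L)
  tnode(tape, v, function(nd) {
    t_accum(a, .cpp_dwconv_sep(nd$g, rev(kern), length(kern) - 1L))
  })
}

## ---- batch normalization ----

# gamma, beta: per-channel parameter nodes; running: list(mean, var) updated
# by the caller from nd$batch_mean / nd$batch_var when training.
t_bn <- function(tape, x, gamma, beta, running, training, eps = 1e-5) {
  d <- dim(x$v)
  m_count <- d[1] * d[2] * d[4]
  if (training) {
    mu <- channel_mean(x$v)
    s2 <- channel_mean(x$v^2) - mu^2
  } else {
    mu <- running$mean
    s2 <- running$var
  }
  istd <- 1 / sqrt(s2 + eps)
  xhat <- (x$v - bc_channel(mu, d)) * bc_channel(istd, d)
  v <- bc_channel(gamma$v, d) * xhat + bc_channel(beta$v, d)
  nd <- tnode(tape, v, function(nd) {
    g <- nd$g
    t_accum(gamma, channel_sum(g * xhat))
    t_accum(beta, channel_sum(g))
    dxhat <- g * bc_channel(gamma$v, d)
    if (training) {
      m1 <- channel_sum(dxhat) / m_count
      m2 <- channel_sum(dxhat * xhat) / m_count
      dx <- bc_channel(istd, d) *
        (dxhat - bc_channel(m1, d) - xhat * bc_channel(m2, d))
    } else {
      dx <- dxhat * bc_channel(istd, d)
    }
    t_accum(x, dx)
  })
  if (training) {
    nd$batch_mean <- mu
    nd$batch_var <- s2
  }
  nd
}

## ---- VAE-specific composite ops ----

# z = mu + exp(0.5 * logvar) * eps, eps a constant array
t_reparam <- function(tape, mu, logvar, eps) {
  s <- exp(0.5 * logvar$v)
  tnode(tape, mu$v + s * eps, function(nd) {
    t_accum(mu, nd$g)
    t_accum(logvar, nd$g * 0.5 * s * eps)
  })
}

# mean over rows (frames) of the per-frame KL to the standard normal prior:
# kl_i = -0.5 * sum_d (1 + lv - mu^2 - exp(lv))
t_kl_mean <- function(tape, mu, logvar) {
  n <- nrow(mu$v)
  elv <- exp(logvar$v)
  kl <- -0.5 * rowSums(1 + logvar$v - mu$v^2 - elv)
  tnode(tape, mean(kl), function(nd) {
    t_accum(mu, mu$v * (nd$g / n))
    t_accum(logvar, -0.5 * (1 - elv) * (nd$g / n))
  })
}
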