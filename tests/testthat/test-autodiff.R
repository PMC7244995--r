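# Numeric gradient checks of the reverse-mode tape against central
# differences on small random inputs.

ns <- asNamespace("VidVAE")

# build a scalar loss sum(wt * op(x)) and compare the tape gradient of x
# with central differences at `probe` random entries
check_grad_against_numeric <- function(build, x, probe = 6, tol = 1e-6,
                                       eps = 1e-5) {
  tape <- ns$new_tape()
  xn <- ns$t_leaf(tape, x)
  out <- build(tape, xn)
  wt <- array(rnorm(length(out$v)), dim = dim(out$v) %||% length(out$v))
  loss <- ns$t_mean(tape, ns$t_mul(tape, out, ns$t_leaf(tape, wt)))
  ns$tape_backward(tape, loss)
  analytic <- xn$g * length(out$v)

  f <- function(xv) {
    x2 <- x; x2[] <- xv
    tp <- ns$new_tape()
    sum(wt * build(tp, ns$t_leaf(tp, x2))$v)
  }
  idx <- sample(length(x), min(probe, length(x)))
  for (i in idx) {
    xp <- as.vector(x); xm <- xp
    xp[i] <- xp[i] + eps; xm[i] <- xm[i] - eps
    expect_equal(analytic[i], (f(xp) - f(xm)) / (2 * eps), tolerance = tol)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("convolution and transposed convolution gradients match numeric differentiation", {
  set.seed(7)
  x <- array(rnorm(6 * 6 * 2 * 2), dim = c(6, 6, 2, 2))
  w <- array(rnorm(3 * 3 * 2 * 3) * 0.4, dim = c(3, 3, 2, 3))
  b <- rnorm(3)
  # gradient w.r.t. input
  check_grad_against_numeric(function(tp, xn)
    ns$t_conv(tp, xn, ns$t_leaf(tp, w), ns$t_leaf(tp, b), 1L, 1L), x)
  # gradient w.r.t. weights
  check_grad_against_numeric(function(tp, wn)
    ns$t_conv(tp, ns$t_leaf(tp, x), wn, ns$t_leaf(tp, b), 1L, 1L), w)
  # strided
  check_grad_against_numeric(function(tp, xn)
    ns$t_conv(tp, xn, ns$t_leaf(tp, w), ns$t_leaf(tp, b), 2L, 0L), x)

  wT <- array(rnorm(5 * 5 * 3 * 2) * 0.3, dim = c(5, 5, 3, 2)) # [k,k,Cout,Cin]
  bT <- rnorm(3)
  check_grad_against_numeric(function(tp, xn)
    ns$t_convT(tp, xn, ns$t_leaf(tp, wT), ns$t_leaf(tp, bT), 2L, 2L,
               c(12L, 12L)), x)
  check_grad_against_numeric(function(tp, wn)
    ns$t_convT(tp, ns$t_leaf(tp, x), wn, ns$t_leaf(tp, bT), 2L, 2L,
               c(12L, 12L)), wT)
})

test_that("transposed convolution doubles the spatial resolution exactly", {
  ns <- asNamespace("VidVAE")
  for (h in c(2L, 4L, 8L)) {
    x <- array(rnorm(h * h * 2), dim = c(h, h, 2, 1))
    w <- array(rnorm(5 * 5 * 3 * 2), dim = c(5, 5, 3, 2))
    tp <- ns$new_tape()
    y <- ns$t_convT(tp, ns$t_leaf(tp, x), ns$t_leaf(tp, w),
                    ns$t_leaf(tp, rnorm(3)), 2L, 2L, c(2L * h, 2L * h))
    expect_identical(dim(y$v), c(2L * h, 2L * h, 3L, 1L))
  }
})

test_that("batch-norm, affine, blur and pooling gradients match numeric differentiation", {
  set.seed(11)
  x <- array(rnorm(6 * 6 * 3 * 2), dim = c(6, 6, 3, 2))
  gam <- runif(3, 0.5, 1.5); bet <- rnorm(3)
  check_grad_against_numeric(function(tp, xn)
    ns$t_bn(tp, xn, ns$t_leaf(tp, gam), ns$t_leaf(tp, bet), NULL, TRUE), x,
    tol = 1e-5)
  check_grad_against_numeric(function(tp, gn)
    ns$t_bn(tp, ns$t_leaf(tp, x), gn, ns$t_leaf(tp, bet), NULL, TRUE), gam)
  # inference mode with running stats
  run <- list(mean = rnorm(3) * 0.1, var = runif(3, 0.5, 2))
  check_grad_against_numeric(function(tp, xn)
    ns$t_bn(tp, xn, ns$t_leaf(tp, gam), ns$t_leaf(tp, bet), run, FALSE), x)

  xm <- matrix(rnorm(8), 2, 4)
  wm <- matrix(rnorm(12), 4, 3)
  bm <- rnorm(3)
  check_grad_against_numeric(function(tp, xn)
    ns$t_affine(tp, xn, ns$t_leaf(tp, wm), ns$t_leaf(tp, bm)), xm)
  check_grad_against_numeric(function(tp, wn)
    ns$t_affine(tp, ns$t_leaf(tp, xm), wn, ns$t_leaf(tp, bm)), wm)

  kern <- ns$gaussianWindow(3)
  check_grad_against_numeric(function(tp, xn) ns$t_blur(tp, xn, kern), x)
  check_grad_against_numeric(function(tp, xn) ns$t_avgpool2(tp, xn), x)
  check_grad_against_numeric(function(tp, xn) ns$t_upsample2(tp, xn), x)
  check_grad_against_numeric(function(tp, xn) ns$t_gap(tp, xn), x)
})

test_that("activation, reparameterization and KL gradients match numeric differentiation", {
  set.seed(13)
  x <- array(rnorm(5 * 5 * 2 * 2), dim = c(5, 5, 2, 2))
  check_grad_against_numeric(function(tp, xn) ns$t_sigmoid(tp, xn), x)
  check_grad_against_numeric(function(tp, xn) ns$t_lrelu(tp, xn), x)
  check_grad_against_numeric(function(tp, xn)
    ns$t_pow_const(tp, ns$t_clamp_min(tp, ns$t_sigmoid(tp, xn), 1e-8), 0.3), x)

  mu <- matrix(rnorm(6), 2, 3)
  lv <- matrix(rnorm(6) * 0.3, 2, 3)
  eps <- matrix(rnorm(6), 2, 3)
  check_grad_against_numeric(function(tp, mn)
    ns$t_reparam(tp, mn, ns$t_leaf(tp, lv), eps), mu)
  check_grad_against_numeric(function(tp, ln)
    ns$t_reparam(tp, ns$t_leaf(tp, mu), ln, eps), lv)

  # t_kl_mean is already scalar; check directly
  for (target in c("mu", "lv")) {
    tp <- ns$new_tape()
    mn <- ns$t_leaf(tp, mu); ln <- ns$t_leaf(tp, lv)
    kl <- ns$t_kl_mean(tp, mn, ln)
    ns$tape_backward(tp, kl)
    g <- if (target == "mu") mn$g else ln$g
    base <- if (target == "mu") mu else lv
    f <- function(bv) {
      b2 <- base; b2[] <- bv
      m2 <- if (target == "mu") b2 else mu
      l2 <- if (target == "lv") b2 else lv
      mean(-0.5 * rowSums(1 + l2 - m2^2 - exp(l2)))
    }
    for (i in sample(length(base), 4)) {
      bp <- as.vector(base); bm <- bp
      bp[i] <- bp[i] + 1e-5; bm[i] <- bm[i] - 1e-5
      expect_equal(g[i], (f(bp) - f(bm)) / 2e-5, tolerance = 1e-6)
    }
  }
})

test_that("gradients accumulate over reused nodes", {
  ns <- asNamespace("VidVAE")
  tp <- ns$new_tape()
  x <- ns$t_leaf(tp, c(1, 2, 3))
  y <- ns$t_mul(tp, x, x) # x^2: dy/dx = 2x
  l <- ns$t_mean(tp, y)
  ns$tape_backward(tp, l)
  expect_equal(x$g, 2 * c(1, 2, 3) / 3)
})
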