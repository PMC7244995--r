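# Reproducible training loop: Adam on (1 - MS-SSIM) + beta * KL / codeLength.

# flatten a dataset (list of simulateVideo() results, a list of frame
# stacks, or one array) into a [H,W,C,N] stack plus per-frame video ids
dataset_frames <- function(dataset) {
  if (is.list(dataset) && !length(dataset)) stop("dataset is empty")
  if (is.list(dataset) && !is.null(dataset[[1]]$frames))
    dataset <- lapply(dataset, `[[`, "frames")
  if (is.list(dataset)) {
    stacks <- lapply(dataset, as_frame_stack)
    video <- rep(seq_along(stacks), vapply(stacks, function(s) dim(s)[4],
                                           integer(1)))
    d <- dim(stacks[[1]])[1:3]
    x <- array(0, dim = c(d, length(video)))
    at <- 0L
    for (s in stacks) {
      n <- dim(s)[4]
      x[, , , at + seq_len(n)] <- s
      at <- at + n
    }
    list(x = x, video = video)
  } else {
    x <- as_frame_stack(dataset)
    list(x = x, video = seq_len(dim(x)[4]))
  }
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - b1^st$t
  c2 <- 1 - b2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(params = params, state = st)
}

# update batch-norm running statistics from the bn nodes of one step
update_bn_state <- function(state, bn_nodes, momentum = 0.1) {
  for (key in names(bn_nodes)) {
    nd <- bn_nodes[[key]]
    state[[key]]$mean <- (1 - momentum) * state[[key]]$mean +
      momentum * nd$batch_mean
    state[[key]]$var <- (1 - momentum) * state[[key]]$var +
      momentum * nd$batch_var
  }
  state
}

# one training step; returns loss components, grads and bn stats
vae_step <- function(x, model, leaves_params, loss_config) {
  tape <- new_tape()
  leaves <- make_leaves(tape, leaves_params)
  xn <- t_leaf(tape, x)
  enc <- forward_encoder(tape, xn, model, leaves, training = TRUE)
  eps <- matrix(rnorm(length(enc$mu$v)), nrow(enc$mu$v), ncol(enc$mu$v))
  z <- t_reparam(tape, enc$mu, enc$lv, eps)
  dec <- forward_decoder(tape, z, model, leaves, training = TRUE)
  ms <- t_mean(tape, t_msssim(tape, xn, dec$out, loss_config))
  kl <- t_kl_mean(tape, enc$mu, enc$lv)
  loss <- t_add(tape, t_rsubc(tape, 1, ms),
                t_scale(tape, kl, loss_config@klWeight /
                                  model@config@codeLength))
  tape_backward(tape, loss)
  list(loss = loss$v, ms_ssim = ms$v, kl = kl$v,
       grads = lapply(leaves, function(l) l$g),
       bn_nodes = c(enc$bn_nodes, dec$bn_nodes))
}

#' Train the variational autoencoder
#'
#' Adam at the configured learning rate on the per-batch objective
#' `(1 - MS-SSIM) + klWeight * KL / codeLength`, one reparameterized sample
#' per frame. Videos (not frames) are split into training and validation
#' sets so held-out frames come from unseen videos. The run is a pure
#' function of the seed. A non-finite loss aborts with the epoch and step in
#' the message.
#'
#' @param dataset list of [simulateVideo()] results, a list of frame stacks,
#'   or a single `[H,W,C,N]` array (then treated as independent frames).
#' @param model_config a [ModelConfig-class].
#' @param loss_config a [LossConfig-class] (default derived from the model
#'   resolution).
#' @param train_config a [TrainConfig-class].
#' @return list with `model` (a [VAEModel-class]) and `history` (data frame
#'   with per-epoch `epoch`, `loss`, `ms_ssim`, `kl`, `val_ms_ssim`).
#' @export
train <- function(dataset, model_config = modelConfig(),
                  loss_config = NULL, train_config = trainConfig()) {
  stopifnot(is(model_config, "ModelConfig"), is(train_config, "TrainConfig"))
  if (is.null(loss_config))
    loss_config <- lossConfig(resolution = model_config@inputResolution)
  ds <- dataset_frames(dataset)
  check_frame_shape(ds$x, model_config)
  n_all <- dim(ds$x)[4]
  if (!n_all) stop("dataset is empty")

  model <- createVAEModel(model_config, seed = train_config@seed)
  params <- model@params
  bn_state <- model@state
  opt <- adam_init(params)
  hist <- data.frame()

  with_seed(train_config@seed + 1L, {
    vids <- unique(ds$video)
    n_val_vid <- floor(train_config@validationFraction * length(vids))
    val_vids <- if (n_val_vid > 0) sample(vids, n_val_vid) else integer()
    train_idx <- which(!ds$video %in% val_vids)
    val_idx <- which(ds$video %in% val_vids)
    if (!length(train_idx)) stop("no training frames after validation split")

    for (epoch in seq_len(train_config@epochs)) {
      order <- sample(train_idx)
      batches <- split(order, ceiling(seq_along(order) / train_config@batchSize))
      ep <- c(loss = 0, ms = 0, kl = 0)
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        step <- vae_step(ds$x[, , , idx, drop = FALSE], model, params,
                         loss_config)
        if (!is.finite(step$loss))
          stop(sprintf("non-finite loss at epoch %d, step %d: aborting",
                       epoch, bi))
        upd <- adam_step(params, step$grads, opt, train_config@learningRate)
        params <- upd$params
        opt <- upd$state
        bn_state <- update_bn_state(bn_state, step$bn_nodes)
        w <- length(idx) / length(order)
        ep <- ep + w * c(step$loss, step$ms_ssim, step$kl)
      }
      model@params <- params
      model@state <- bn_state
      model@epochsTrained <- epoch
      val_ms <- if (length(val_idx)) {
        evaluateReconstruction(model, ds$x[, , , val_idx, drop = FALSE],
                               loss_config)$mean_ms_ssim
      } else NA_real_
      hist <- rbind(hist, data.frame(epoch = epoch, loss = ep[["loss"]],
                                     ms_ssim = ep[["ms"]], kl = ep[["kl"]],
                                     val_ms_ssim = val_ms))
      if (train_config@checkpointEvery > 0 &&
          nzchar(train_config@checkpointDir) &&
          epoch %% train_config@checkpointEvery == 0) {
        dir.create(train_config@checkpointDir, showWarnings = FALSE,
                   recursive = TRUE)
        saveModel(model, file.path(train_config@checkpointDir,
                                   sprintf("checkpoint_epoch%03d.rds", epoch)))
      }
    }
  })
  rownames(hist) <- NULL
  list(model = model, history = hist)
}

#' Reconstruction quality of a model over a dataset
#'
#' Deterministic inference-mode evaluation: frames are encoded to their
#' latent means, decoded, and compared with MS-SSIM; the per-frame KL of the
#' predicted latents is averaged as well.
#'
#' @param model a [VAEModel-class].
#' @param dataset frames in any form accepted by [train()].
#' @param loss_config a [LossConfig-class] (default from model resolution).
#' @return list with `mean_ms_ssim`, `mean_kl`, `n_frames`.
#' @export
evaluateReconstruction <- function(model, dataset, loss_config = NULL) {
  stopifnot(is(model, "VAEModel"))
  if (is.null(loss_config))
    loss_config <- lossConfig(resolution = model@config@inputResolution)
  x <- dataset_frames(dataset)$x
  check_frame_shape(x, model@config)
  n <- dim(x)[4]
  if (!n) stop("dataset is empty")
  ms <- numeric(n)
  kl <- numeric(n)
  for (idx in split(seq_len(n), ceiling(seq_len(n) / 16))) {
    xb <- x[, , , idx, drop = FALSE]
    dist <- encodeFrame(xb, model)
    recon <- decodeCode(dist@mean, model)
    if (length(dim(recon)) == 3L) dim(recon) <- c(dim(recon), 1L)
    ms[idx] <- msSSIM(xb, recon, loss_config)
    kl[idx] <- klNormal(dist)
  }
  list(mean_ms_ssim = mean(ms), mean_kl = mean(kl), n_frames = n)
}
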