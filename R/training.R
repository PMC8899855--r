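## Joint end-to-end training of encoder + simulator + decoder.
##
## The three components are treated as a single system: the task loss on the
## decoder output is backpropagated through the (linear, fixed) simulator
## and the straight-through estimator into the encoder.  The simulator
## itself has no trainable parameters.  Random restarts re-train from
## different weight initializations and keep the run with the lowest
## validation loss.

#' Training configuration
#'
#' @param task `"intensity"` (pixel-wise MSE), `"perceptual"` (deep-feature
#'   loss) or `"boundary"` (class-weighted cross-entropy against boundary
#'   maps).
#' @param simulator `"regular"` or `"custom"`.
#' @param kappa Relative sparsity weight in [0, 1] (default 0).
#' @param w Boundary class weight (default 0.925).
#' @param d Feature-loss depth (default 3).
#' @param spatial_reg_weight Weight of the spatial regularization term used
#'   with the custom simulator (default 1).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 16).
#' @param epochs Maximum epochs (default 100).
#' @param patience Early-stopping patience on validation loss in epochs;
#'   `Inf` disables early stopping (default 10).
#' @param restarts Number of random restarts (default 5).
#' @param seed Master seed; all stochastic components (weight init, batch
#'   shuffling) derive from it, restart r uses `seed + r`.
#' @param encoder,decoder Network configurations ([encoder_config()],
#'   [decoder_config()]).
#' @param sparsity_normalize Normalize the sparsity loss by electrode count.
#' @return A `train_config` list.
#' @export
train_config <- function(task = c("intensity", "perceptual", "boundary"),
                         simulator = c("regular", "custom"),
                         kappa = 0, w = 0.925, d = 3L,
                         spatial_reg_weight = 1, lr = 1e-3,
                         batch_size = 16L, epochs = 100L, patience = 10,
                         restarts = 5L, seed = 1L,
                         encoder = encoder_config(),
                         decoder = decoder_config(),
                         sparsity_normalize = TRUE) {
  task <- match.arg(task)
  simulator <- match.arg(simulator)
  if (kappa < 0 || kappa > 1) stop("kappa out of range [0, 1]")
  if (restarts < 1) stop("restarts must be >= 1")
  structure(list(task = task, simulator = simulator, kappa = kappa, w = w,
                 d = as.integer(d), spatial_reg_weight = spatial_reg_weight,
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = patience,
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 encoder = encoder, decoder = decoder,
                 sparsity_normalize = sparsity_normalize),
            class = "train_config")
}

## Build the full model for a config: seeded encoder/decoder plus the shared
## phosphene map and (for the perceptual task) the feature extractor.
build_model <- function(config, map, extractor = NULL, init_seed = NULL) {
  if (is.null(init_seed)) init_seed <- config$seed
  if (config$task == "perceptual" && is.null(extractor))
    extractor <- build_feature_extractor(seed = config$seed)
  list(encoder = build_encoder(config$encoder, seed = init_seed),
       decoder = build_decoder(config$decoder, seed = init_seed + 500000L),
       map = map, extractor = extractor, config = config, seed = init_seed)
}

## One forward/backward pass over a minibatch; returns loss components,
## parameter gradients for both networks, and the protocol batch.
model_step <- function(model, x, target, train = TRUE, backward = TRUE) {
  cfg <- model$config
  td <- dim(target)
  if (length(td) == 3) dim(target) <- c(td[1:2], 1L, td[3])
  enc <- network_forward(model$encoder, x, train = train)
  custom <- cfg$simulator == "custom"
  if (custom) {
    proto <- enc$out                               # (n, N)
    spv <- simulate_custom(proto, model$map)
  } else {
    pd <- dim(enc$out)                             # (Hp, Wp, 1, N)
    proto <- array(enc$out, pd[c(1, 2, 4)])
    spv <- simulate_regular(proto, model$map)
  }
  sd3 <- dim(spv)
  spv_in <- array(spv, c(sd3[1], sd3[2], 1L, sd3[3]))
  dec <- network_forward(model$decoder, spv_in, train = train)
  xhat <- dec$out

  L_task_r <- switch(cfg$task,
    intensity = mse_loss(target, xhat, grad = backward),
    perceptual = feature_loss(target, xhat, model$extractor, d = cfg$d,
                              grad = backward),
    boundary = weighted_bce_loss(xhat, target, w = cfg$w, grad = backward))
  L_S_r <- sparsity_loss(proto, normalize = cfg$sparsity_normalize,
                         grad = backward)
  L_task <- if (backward) L_task_r$loss else L_task_r
  L_S <- if (backward) L_S_r$loss else L_S_r
  loss <- total_loss(L_task, L_S, cfg$kappa)

  L_spat <- 0
  spat_r <- NULL
  if (custom && cfg$spatial_reg_weight > 0) {
    tgt3 <- if (length(dim(target)) == 4)
      array(target, dim(target)[c(1, 2, 4)]) else target
    spat_r <- spatial_reg_loss(proto, tgt3, model$map, grad = backward)
    L_spat <- if (backward) spat_r$loss else spat_r
    loss <- loss + cfg$spatial_reg_weight * L_spat
  }

  out <- list(loss = loss, L_task = L_task, L_S = L_S, L_spat = L_spat,
              proto = proto, xhat = xhat, spv = spv,
              enc_net = enc$net, dec_net = dec$net)
  if (!backward) return(out)

  g_xhat <- (1 - cfg$kappa) * L_task_r$grad
  if (length(dim(g_xhat)) < 4) dim(g_xhat) <- dim(xhat)
  dec_b <- network_backward(dec$net, dec$caches, g_xhat)
  g_spv <- array(dec_b$gx, sd3)
  g_proto <- if (custom) simulate_custom_grad(g_spv, model$map)
             else simulate_regular_grad(g_spv, model$map)
  g_proto <- g_proto + cfg$kappa * array(L_S_r$grad, dim(g_proto))
  if (!is.null(spat_r))
    g_proto <- g_proto + cfg$spatial_reg_weight * spat_r$grad
  g_enc_out <- g_proto
  dim(g_enc_out) <- dim2(if (custom) enc$out else enc$out)
  if (!custom) dim(g_enc_out) <- dim(enc$out)
  enc_b <- network_backward(enc$net, enc$caches, g_enc_out)
  out$enc_grads <- enc_b$grads
  out$dec_grads <- dec_b$grads
  out
}

## Evaluation loss over a dataset, in minibatches, eval-mode normalization.
eval_loss <- function(model, x, target, batch_size) {
  N <- dim(x)[3]
  tot <- 0; tot_task <- 0; tot_s <- 0; act <- 0
  idx <- seq_len(N)
  for (b in split(idx, ceiling(idx / batch_size))) {
    r <- model_step(model, x[, , b, drop = FALSE],
                    slice_target(target, b), train = FALSE, backward = FALSE)
    wt <- length(b) / N
    tot <- tot + r$loss * wt
    tot_task <- tot_task + r$L_task * wt
    tot_s <- tot_s + r$L_S * wt
    act <- act + mean(r$proto) * wt
  }
  list(loss = tot, L_task = tot_task, L_S = tot_s, pct_active = 100 * act)
}

slice_target <- function(target, b) {
  d <- dim(target)
  if (length(d) == 3) target[, , b, drop = FALSE]
  else target[, , , b, drop = FALSE]
}

#' Train the end-to-end model
#'
#' Encoder and decoder weights are updated jointly with Adam; the simulator
#' contributes no trainable parameters.  Per-epoch training and validation
#' losses are recorded and the checkpoint with the lowest validation loss
#' is returned.
#'
#' @param data List with `train`, `val` image arrays `(H, W, N)` and
#'   optionally `train_target`, `val_target` (defaults: the images
#'   themselves, i.e. auto-encoding).
#' @param config A [train_config()].
#' @param map Phosphene map shared across restarts (built from the config's
#'   geometry if omitted).
#' @param extractor Optional feature extractor for the perceptual task.
#' @param init_seed Weight-initialization seed (defaults to `config$seed`).
#' @param restart_index Recorded in the run record.
#' @return A `run_record`: `model` (best checkpoint), `history` (data frame
#'   epoch/train_loss/val_loss), `best_epoch`, `best_val_loss`,
#'   `restart_index`, `diverged`.
#' @export
train_end_to_end <- function(data, config, map = NULL, extractor = NULL,
                             init_seed = NULL, restart_index = 1L) {
  if (is.null(map)) map <- default_map_for(config)
  model <- build_model(config, map, extractor, init_seed)
  x <- data$train
  tt <- if (!is.null(data$train_target)) data$train_target else data$train
  xv <- data$val
  tv <- if (!is.null(data$val_target)) data$val_target else data$val
  N <- dim(x)[3]
  st_enc <- adam_init(model$encoder)
  st_dec <- adam_init(model$decoder)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  best <- list(val = Inf, model = model, epoch = 0L)
  wait <- 0
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(model$seed + 7919L * ep, sample.int(N))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (b in batches) {
      r <- model_step(model, x[, , b, drop = FALSE], slice_target(tt, b),
                      train = TRUE, backward = TRUE)
      if (!is.finite(r$loss)) {
        warning("training diverged (non-finite loss) at epoch ", ep)
        return(list(model = best$model, history = hist, best_epoch = best$epoch,
                    best_val_loss = best$val, restart_index = restart_index,
                    diverged = TRUE))
      }
      model$encoder <- r$enc_net
      model$decoder <- r$dec_net
      up_e <- adam_step(model$encoder, r$enc_grads, st_enc, config$lr)
      model$encoder <- up_e$net; st_enc <- up_e$state
      up_d <- adam_step(model$decoder, r$dec_grads, st_dec, config$lr)
      model$decoder <- up_d$net; st_dec <- up_d$state
      ep_loss <- ep_loss + r$loss * length(b) / N
    }
    ev <- eval_loss(model, xv, tv, config$batch_size)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                   val_loss = ev$loss))
    if (ev$loss < best$val) {
      best <- list(val = ev$loss, model = model, epoch = ep)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience) break
    }
  }
  list(model = best$model, history = hist, best_epoch = best$epoch,
       best_val_loss = best$val, restart_index = restart_index,
       diverged = FALSE)
}

## Build the phosphene map a config implies.
default_map_for <- function(config) {
  if (config$simulator == "custom") {
    sample_custom_map(config$encoder$n_phosphenes,
                      canvas_size = 2L * config$encoder$input_size,
                      seed = config$seed)
  } else {
    side <- config$encoder$input_size / 4L
    build_regular_grid_map(grid_shape = c(side, side),
                           canvas_size = 8L * side, spacing = 8,
                           seed = config$seed)
  }
}

#' Random restarts
#'
#' Trains `k` models differing only in weight-initialization seed
#' (`config$seed + restart`) on a fixed phosphene map and returns the run
#' with the lowest validation loss, plus all run records.
#'
#' @inheritParams train_end_to_end
#' @param k Number of restarts (defaults to `config$restarts`).
#' @return List: `best` (the selected run record) and `runs` (all records).
#' @export
random_restarts <- function(data, config, k = config$restarts, map = NULL,
                            extractor = NULL) {
  if (k < 1) stop("k must be >= 1")
  if (is.null(map)) map <- default_map_for(config)
  if (config$task == "perceptual" && is.null(extractor))
    extractor <- build_feature_extractor(seed = config$seed)
  runs <- vector("list", k)
  for (r in seq_len(k))
    runs[[r]] <- train_end_to_end(data, config, map = map,
                                  extractor = extractor,
                                  init_seed = config$seed + r,
                                  restart_index = r)
  ok <- !vapply(runs, `[[`, TRUE, "diverged")
  if (!any(ok)) stop("all restarts diverged")
  vals <- vapply(runs, `[[`, 1.0, "best_val_loss")
  vals[!ok] <- Inf
  list(best = runs[[which.min(vals)]], runs = runs)
}

#' Sparsity-weight (kappa) sweep
#'
#' Trains best-of-restarts models across a list of kappa values and
#' regresses the mean active-electrode percentage and the validation MSE on
#' kappa.
#'
#' @param kappas Numeric vector of kappa values in [0, 1].
#' @param data Dataset as for [train_end_to_end()].
#' @param config Base [train_config()]; its `kappa` is overridden per run.
#' @param k Restarts per kappa (defaults to `config$restarts`).
#' @return List: `table` (kappa, pct_active, val_mse, val_loss),
#'   `fit_active` and `fit_mse` (`lm` fits on kappa), and `records`.
#' @export
kappa_sweep <- function(kappas, data, config, k = config$restarts) {
  if (any(kappas < 0 | kappas > 1)) stop("kappa out of range [0, 1]")
  map <- default_map_for(config)
  tab <- data.frame(kappa = kappas, pct_active = NA_real_,
                    val_mse = NA_real_, val_loss = NA_real_)
  records <- vector("list", length(kappas))
  tv <- if (!is.null(data$val_target)) data$val_target else data$val
  for (i in seq_along(kappas)) {
    cfg <- config
    cfg$kappa <- kappas[i]
    rr <- random_restarts(data, cfg, k = k, map = map)
    ev <- eval_loss(rr$best$model, data$val, tv, cfg$batch_size)
    ## reconstruction quality measured as plain MSE regardless of task
    mse_v <- eval_val_mse(rr$best$model, data$val, tv, cfg$batch_size)
    tab$pct_active[i] <- ev$pct_active
    tab$val_mse[i] <- mse_v
    tab$val_loss[i] <- ev$loss
    records[[i]] <- rr$best
  }
  list(table = tab,
       fit_active = stats::lm(pct_active ~ kappa, data = tab),
       fit_mse = stats::lm(val_mse ~ kappa, data = tab),
       records = records)
}

eval_val_mse <- function(model, x, target, batch_size) {
  N <- dim(x)[3]
  tot <- 0
  for (b in split(seq_len(N), ceiling(seq_len(N) / batch_size))) {
    r <- model_step(model, x[, , b, drop = FALSE], slice_target(target, b),
                    train = FALSE, backward = FALSE)
    tot <- tot + mse_loss(slice_target(target, b),
                          array(r$xhat, dim2(slice_target(target, b)))) *
      length(b) / N
  }
  tot
}

#' Predict reconstructions with a trained model
#'
#' @param model A trained model (from a run record).
#' @param x Image batch `(H, W, N)`.
#' @param batch_size Evaluation batch size.
#' @return List with `xhat` `(H, W, N)` reconstructions and `proto`
#'   protocol batch.
#' @export
model_predict <- function(model, x, batch_size = 16L) {
  N <- dim(x)[3]
  xhat <- NULL; proto <- NULL
  for (b in split(seq_len(N), ceiling(seq_len(N) / batch_size))) {
    r <- model_step(model, x[, , b, drop = FALSE],
                    x[, , b, drop = FALSE], train = FALSE, backward = FALSE)
    xh <- r$xhat
    if (is.null(xhat)) {
      xhat <- array(0, c(dim(xh)[1:2], N))
      proto <- if (is.matrix(r$proto)) matrix(0, nrow(r$proto), N)
               else array(0, c(dim(r$proto)[1:2], N))
    }
    xhat[, , b] <- xh
    if (is.matrix(proto)) proto[, b] <- r$proto else proto[, , b] <- r$proto
  }
  list(xhat = xhat, proto = proto)
}
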