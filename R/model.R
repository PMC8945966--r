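#' Architecture configuration of the BP-estimation network
#'
#' The regressor maps one 128-sample ECG frame to a (SBP, DBP) pair through
#' four convolution + ReLU + max-pool blocks with 32, 64, 128 and 256
#' filters, global average pooling over time, a 128-unit feature layer, two
#' fully connected layers of 32 and 16 ReLU units, and a 2-output linear
#' head.
#'
#' @param frame_len input frame length in samples; must be divisible by
#'   `pool_size ^ 4`.
#' @param conv_filters filter counts of the four convolutional layers.
#' @param kernel_size odd convolution kernel width (stride 1, same
#'   padding).
#' @param pool_size max-pooling factor after each convolution.
#' @param feature_dim width of the dense feature layer fed by global
#'   average pooling.
#' @param fc_nodes widths of the two fully connected layers.
#' @param input_norm logical: z-score each input frame before the network
#'   (removes electrode-gain differences between recordings).
#' @param feature_pool how the last convolution stage feeds the dense
#'   feature layer: `"gap"` (default) averages the final feature map over
#'   time; `"flatten"` concatenates it instead, preserving position
#'   information at the cost of eight times as many feature-layer weights.
#' @return a list of class `model_config`.
#' @export
model_config <- function(frame_len = 128L, conv_filters = c(32L, 64L, 128L, 256L),
                         kernel_size = 5L, pool_size = 2L, feature_dim = 128L,
                         fc_nodes = c(32L, 16L), input_norm = TRUE,
                         feature_pool = c("gap", "flatten")) {
  feature_pool <- match.arg(feature_pool)
  if (length(conv_filters) != 4L) {
    stop("the architecture uses exactly four convolutional layers",
         call. = FALSE)
  }
  if (kernel_size %% 2L != 1L) stop("kernel_size must be odd", call. = FALSE)
  if (frame_len %% pool_size^4 != 0L) {
    stop("frame_len (", frame_len, ") must be divisible by pool_size^4 (",
         pool_size^4, ")", call. = FALSE)
  }
  structure(list(
    frame_len = as.integer(frame_len),
    conv_filters = as.integer(conv_filters),
    kernel_size = as.integer(kernel_size),
    pool_size = as.integer(pool_size),
    feature_dim = as.integer(feature_dim),
    fc_nodes = as.integer(fc_nodes),
    input_norm = isTRUE(input_norm),
    feature_pool = feature_pool
  ), class = "model_config")
}

#' Training configuration
#'
#' Defaults follow the training protocol the network was designed around:
#' batch size 32, learning rate 0.01, Adam, mean-squared-error loss on
#' standardized targets, and an 80/20 train/validation split. Early
#' stopping keeps the checkpoint with the lowest validation loss.
#'
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param max_epochs maximum number of epochs.
#' @param patience early-stopping patience in epochs (0 disables early
#'   stopping).
#' @param split_fraction fraction of labeled frames used for training; the
#'   rest form the validation split.
#' @param split_by `"frame"` (pooled random split, the default) or
#'   `"record"` (whole records assigned to one side — recommended when
#'   frames from the same recording should not leak across the split).
#' @param target_scaling logical: z-score SBP/DBP targets using statistics
#'   of the training split only; predictions are mapped back to mmHg.
#' @param restore_best logical: return the parameters of the epoch with the
#'   lowest validation loss (default) rather than the final epoch. Turning
#'   this off is useful for capacity checks that deliberately overfit.
#' @param clip_norm maximum global gradient norm per update; gradients are
#'   rescaled when their norm exceeds it (`Inf` disables). At the default
#'   learning rate of 0.01 — large for Adam — clipping keeps early updates
#'   from throwing the network into the flat constant-predictor regime.
#' @param warmup_epochs linear learning-rate warm-up: the step size ramps
#'   from 0 to `learning_rate` over this many epochs (0 disables). Adam
#'   moves every parameter by roughly the full step size from the first
#'   update onward, so at 0.01 an unwarmed start can collapse the network
#'   into predicting the target mean before any signal is learned.
#' @param rescue_after,max_restarts failure-to-launch recovery: if after
#'   `rescue_after` epochs the best validation loss is still no better
#'   than the constant mean predictor, training restarts from the initial
#'   weights with the learning rate quartered (at most `max_restarts`
#'   times; 0 disables). A network whose narrow ReLU bottleneck dies early
#'   cannot recover by further training at any rate — restarting at a
#'   gentler rate can. Restarts are recorded in the returned history.
#' @param lr_reductions reduce-on-plateau: when the early-stopping patience
#'   expires, instead of stopping immediately the learning rate is halved
#'   and training resumes from the best checkpoint, up to this many times
#'   (0 disables); only when no reductions remain does patience end the
#'   run. Also recorded in the returned history.
#' @param seed RNG seed governing the split, shuffling and any dropout-free
#'   stochasticity; fixed seed + fixed data gives identical training runs.
#' @return a list of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, learning_rate = 0.01,
                         max_epochs = 200L, patience = 20L,
                         split_fraction = 0.8, split_by = c("frame", "record"),
                         target_scaling = TRUE, restore_best = TRUE,
                         clip_norm = 1.0, warmup_epochs = 3L,
                         rescue_after = 5L, max_restarts = 3L,
                         lr_reductions = 2L, seed = 1L) {
  split_by <- match.arg(split_by)
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    split_fraction = split_fraction, split_by = split_by,
    target_scaling = isTRUE(target_scaling),
    restore_best = isTRUE(restore_best), clip_norm = clip_norm,
    warmup_epochs = as.integer(warmup_epochs),
    rescue_after = as.integer(rescue_after),
    max_restarts = as.integer(max_restarts),
    lr_reductions = as.integer(lr_reductions), seed = as.integer(seed)
  ), class = "train_config")
}

#' Build an untrained network
#'
#' Weight initialization (He-scaled normal draws) is deterministic under
#' `seed`: the same seed and configuration give bit-identical parameters.
#'
#' @param config a [model_config()].
#' @param seed RNG seed for weight initialization.
#' @return an object of class `bp_cnn` holding `config`, `params` and
#'   (after training) target-`scaling` statistics.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  structure(list(config = config, params = nn_init(config, seed),
                 scaling = NULL, seed = as.integer(seed)),
            class = "bp_cnn")
}

#' @export
print.bp_cnn <- function(x, ...) {
  npar <- sum(vapply(x$params, function(p) length(p$W) + length(p$b),
                     numeric(1)))
  cat(sprintf("<bp_cnn> %d-sample input, conv filters (%s), FC (%s), %s\n",
              x$config$frame_len,
              paste(x$config$conv_filters, collapse = ", "),
              paste(x$config$fc_nodes, collapse = ", "),
              if (is.null(x$scaling)) "untrained" else "trained"))
  cat(sprintf("  %d parameters\n", as.integer(npar)))
  invisible(x)
}

frame_input_matrix <- function(model, X) {
  if (ncol(X) != model$config$frame_len) {
    stop("frame length ", ncol(X), " does not match the model's frame_len ",
         model$config$frame_len, call. = FALSE)
  }
  if (model$config$input_norm) {
    mu <- rowMeans(X)
    sdv <- sqrt(pmax(rowMeans(X^2) - mu^2, 0))
    X <- (X - mu) / pmax(sdv, 1e-8)
  }
  X
}

nn_loss_forward <- function(params, X, Tstd, config, keep_cache = FALSE) {
  fw <- nn_forward(params, X, config, keep_cache = keep_cache)
  diff <- fw$Y - Tstd
  list(loss = mean(diff^2), dY = diff / (nrow(X)), fw = fw)
}

eval_loss <- function(params, X, Tstd, config, chunk = 256L) {
  n <- nrow(X)
  tot <- 0
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    fw <- nn_forward(params, X[i:j, , drop = FALSE], config)
    tot <- tot + sum((fw$Y - Tstd[i:j, , drop = FALSE])^2)
    i <- j + 1L
  }
  tot / (n * 2L)
}

#' Train the network on labeled frames
#'
#' Minimizes mean squared error on (standardized) SBP/DBP targets with
#' minibatch Adam. Frames flagged invalid by [label_frames()] are dropped
#' first; the remainder is split into training and validation sets, target
#' standardization statistics are estimated on the training split only, and
#' the returned model is the checkpoint of the epoch with the lowest
#' validation loss (`best_epoch`).
#'
#' @param model an untrained (or warm-start) [build_model()] object.
#' @param frames a labeled `frame_set` (see [label_frames()]).
#' @param cfg a [train_config()].
#' @param verbose print a one-line progress summary every few epochs.
#' @return list with `model` (the best-epoch `bp_cnn`, scaling attached)
#'   and `history` (class `training_history`: data frame of per-epoch
#'   training/validation loss plus `best_epoch`).
#' @export
train_model <- function(model, frames, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "bp_cnn"), inherits(frames, "frame_set"),
            inherits(cfg, "train_config"))
  if (is.null(frames$labels)) {
    stop("frames carry no labels; run label_frames() first", call. = FALSE)
  }
  keep <- frames$labels$valid
  if (!any(keep)) stop("no valid labeled frames to train on", call. = FALSE)
  X <- frames$ecg[keep, , drop = FALSE]
  Y <- cbind(frames$labels$sbp[keep], frames$labels$dbp[keep])
  rec <- frames$record_id[keep]
  n <- nrow(X)

  restore <- local_seed(cfg$seed)
  on.exit(restore())
  if (cfg$split_by == "frame") {
    n_train <- max(1L, floor(cfg$split_fraction * n))
    ord <- sample.int(n)
    tr <- ord[seq_len(n_train)]
    va <- ord[-seq_len(n_train)]
  } else {
    ids <- unique(rec)
    n_tr_rec <- max(1L, floor(cfg$split_fraction * length(ids)))
    tr_ids <- sample(ids, n_tr_rec)
    tr <- which(rec %in% tr_ids)
    va <- which(!(rec %in% tr_ids))
  }
  if (!length(tr) || !length(va)) {
    stop("train/validation split left one side empty", call. = FALSE)
  }

  if (cfg$target_scaling) {
    mu <- colMeans(Y[tr, , drop = FALSE])
    sdv <- apply(Y[tr, , drop = FALSE], 2, stats::sd)
    sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
  } else {
    mu <- c(0, 0); sdv <- c(1, 1)
  }
  scaling <- list(mean = as.numeric(mu), sd = as.numeric(sdv))
  Tstd <- sweep(sweep(Y, 2, mu), 2, sdv, "/")

  Xn <- frame_input_matrix(model, X)
  Xtr <- Xn[tr, , drop = FALSE]; Ttr <- Tstd[tr, , drop = FALSE]
  Xva <- Xn[va, , drop = FALSE]; Tva <- Tstd[va, , drop = FALSE]

  init_params <- model$params
  params <- init_params
  state <- adam_init(params)
  hist_tr <- numeric(0); hist_va <- numeric(0)
  best_va <- Inf; best_params <- params; best_epoch <- 0L
  step <- 0L
  warm_steps <- cfg$warmup_epochs * ceiling(nrow(Xtr) / cfg$batch_size)
  # validation loss of the constant mean predictor (targets are centred on
  # the training split, so this is just the mean square of Tva)
  baseline_va <- mean(Tva^2)
  lr_cur <- cfg$learning_rate
  n_restarts <- 0L
  n_reductions <- 0L
  last_restart <- 0L
  clock <- 0L  # patience anchor, advanced on restarts/reductions
  restart_log <- data.frame(epoch = integer(0), learning_rate = numeric(0),
                            type = character(0))
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(nrow(Xtr))
    tot <- 0; nb <- 0L
    i <- 1L
    while (i <= length(ord)) {
      j <- min(i + cfg$batch_size - 1L, length(ord))
      bi <- ord[i:j]
      lf <- nn_loss_forward(params, Xtr[bi, , drop = FALSE],
                            Ttr[bi, , drop = FALSE], model$config,
                            keep_cache = TRUE)
      if (!is.finite(lf$loss)) {
        stop("training diverged (non-finite loss at epoch ", epoch,
             "); lower the learning rate or check the labels", call. = FALSE)
      }
      grads <- nn_backward(params, lf$fw$cache, lf$dY, model$config)
      if (is.finite(cfg$clip_norm)) {
        gnorm <- sqrt(sum(vapply(grads, function(g)
          sum(g$W^2) + sum(g$b^2), numeric(1))))
        if (gnorm > cfg$clip_norm) {
          sc <- cfg$clip_norm / gnorm
          grads <- lapply(grads, function(g) list(W = g$W * sc, b = g$b * sc))
        }
      }
      step <- step + 1L
      lr_t <- if (step <= warm_steps) lr_cur * step / warm_steps
              else lr_cur
      upd <- adam_step(params, grads, state, lr_t, step)
      params <- upd$params; state <- upd$state
      tot <- tot + lf$loss * length(bi); nb <- nb + length(bi)
      i <- j + 1L
    }
    tr_loss <- tot / nb
    va_loss <- eval_loss(params, Xva, Tva, model$config)
    hist_tr <- c(hist_tr, tr_loss); hist_va <- c(hist_va, va_loss)
    if (va_loss < best_va) {
      best_va <- va_loss; best_params <- params; best_epoch <- epoch
    }
    if (verbose && (epoch %% 5L == 0L || epoch == 1L)) {
      message(sprintf("epoch %3d  train %.5f  val %.5f%s", epoch, tr_loss,
                      va_loss, if (epoch == best_epoch) "  *" else ""))
    }
    # failure-to-launch rescue: still no better than the mean predictor
    if (cfg$rescue_after > 0L && n_restarts < cfg$max_restarts &&
        epoch - last_restart >= cfg$rescue_after &&
        best_va >= 0.95 * baseline_va) {
      n_restarts <- n_restarts + 1L
      lr_cur <- lr_cur / 4
      params <- init_params
      state <- adam_init(params)
      step <- 0L  # re-applies warm-up and Adam bias correction
      best_va <- Inf; best_params <- params; best_epoch <- epoch
      last_restart <- epoch
      restart_log <- rbind(restart_log,
                           data.frame(epoch = epoch, learning_rate = lr_cur,
                                      type = "rescue"))
      if (verbose) {
        message(sprintf(
          "epoch %3d  no learning signal; restarting at learning rate %g",
          epoch, lr_cur))
      }
      next
    }
    if (cfg$patience > 0L && epoch - max(best_epoch, clock) >= cfg$patience) {
      if (n_reductions < cfg$lr_reductions) {
        # reduce on plateau: resume from the best checkpoint at half rate
        n_reductions <- n_reductions + 1L
        lr_cur <- lr_cur / 2
        params <- best_params
        state <- adam_init(params)
        step <- 0L
        clock <- epoch  # restart the patience clock (best tracking kept)
        restart_log <- rbind(restart_log,
                             data.frame(epoch = epoch, learning_rate = lr_cur,
                                        type = "plateau"))
        if (verbose) {
          message(sprintf(
            "epoch %3d  plateau; continuing from best checkpoint at %g",
            epoch, lr_cur))
        }
      } else break
    }
  }

  model$params <- if (cfg$restore_best) best_params else params
  model$scaling <- scaling
  history <- structure(list(
    epochs = data.frame(epoch = seq_along(hist_tr), train_loss = hist_tr,
                        val_loss = hist_va),
    best_epoch = best_epoch, best_val_loss = best_va,
    restarts = restart_log, final_learning_rate = lr_cur,
    # indices into the original frame_set rows (valid frames only)
    split = list(train = which(keep)[tr], validation = which(keep)[va])
  ), class = "training_history")
  list(model = model, history = history)
}

#' @export
print.training_history <- function(x, ...) {
  cat(sprintf("<training_history> %d epochs, best epoch %d (val loss %.5f)\n",
              nrow(x$epochs), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Predict SBP/DBP for ECG frames
#'
#' @param object a trained `bp_cnn`.
#' @param frames a `frame_set`, or a numeric matrix with one frame per row.
#' @param ... unused.
#' @return data frame with one row per frame: `sbp`, `dbp` in mmHg.
#' @export
predict.bp_cnn <- function(object, frames, ...) {
  X <- if (inherits(frames, "frame_set")) frames$ecg else as.matrix(frames)
  X <- frame_input_matrix(object, X)
  scl <- object$scaling
  if (is.null(scl)) scl <- list(mean = c(0, 0), sd = c(1, 1))
  n <- nrow(X)
  out <- matrix(NA_real_, n, 2)
  i <- 1L
  while (i <= n) {
    j <- min(i + 255L, n)
    fw <- nn_forward(object$params, X[i:j, , drop = FALSE], object$config)
    out[i:j, ] <- fw$Y
    i <- j + 1L
  }
  data.frame(sbp = out[, 1] * scl$sd[1] + scl$mean[1],
             dbp = out[, 2] * scl$sd[2] + scl$mean[2])
}

#' Save / load a trained model
#'
#' A model directory holds `config.json` (architecture, target scaling,
#' seed, package version and a weight checksum) and `weights.rds` (the
#' parameter arrays). [load_model()] refuses to load when files are
#' missing, shapes disagree with the stored configuration, or the checksum
#' does not match — a truncated or tampered weight file fails loudly.
#'
#' @param model a `bp_cnn`.
#' @param dir model directory (created if needed).
#' @return `dir` (for `save_model`) or the restored `bp_cnn` (for
#'   `load_model`).
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "bp_cnn"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  checksum <- sum(vapply(model$params,
                         function(p) sum(p$W) + sum(p$b), numeric(1)))
  meta <- list(
    config = unclass(model$config), scaling = model$scaling,
    seed = model$seed, checksum = checksum,
    package_version = as.character(utils::packageVersion("ecg2bp"))
  )
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # weights and scaling ride together in the binary payload so the round
  # trip is bit-exact; config.json carries the human-readable copy
  saveRDS(list(params = model$params, scaling = model$scaling),
          file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  w_path <- file.path(dir, "weights.rds")
  if (!file.exists(cfg_path) || !file.exists(w_path)) {
    stop("not a model directory (missing config.json or weights.rds): ",
         dir, call. = FALSE)
  }
  meta <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  config <- do.call(model_config, meta$config[
    c("frame_len", "conv_filters", "kernel_size", "pool_size",
      "feature_dim", "fc_nodes", "input_norm", "feature_pool")])
  payload <- try(readRDS(w_path), silent = TRUE)
  if (inherits(payload, "try-error") || !is.list(payload) ||
      is.null(payload$params)) {
    stop("corrupt weights file: ", w_path, call. = FALSE)
  }
  params <- payload$params
  ref <- nn_init(config, 1L)
  if (!identical(lapply(params, function(p) dim(p$W)),
                 lapply(ref, function(p) dim(p$W)))) {
    stop("weight shapes do not match the stored configuration", call. = FALSE)
  }
  checksum <- sum(vapply(params, function(p) sum(p$W) + sum(p$b), numeric(1)))
  if (!isTRUE(abs(checksum - meta$checksum) <= 1e-6 * max(1, abs(meta$checksum)))) {
    stop("weight checksum mismatch; the model files are inconsistent",
         call. = FALSE)
  }
  structure(list(config = config, params = params, scaling = payload$scaling,
                 seed = as.integer(meta$seed)), class = "bp_cnn")
}
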