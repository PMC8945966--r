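test_that("the built network matches the designed architecture", {
  m <- build_model(model_config(), seed = 1)
  p <- m$params
  # four conv blocks with the prescribed filter counts
  expect_equal(vapply(paste0("conv", 1:4), function(nm) nrow(p[[nm]]$W),
                      integer(1), USE.NAMES = FALSE),
               c(32L, 64L, 128L, 256L))
  # conv kernels span kernel_size x C_in
  expect_equal(ncol(p$conv1$W), 5L * 1L)
  expect_equal(ncol(p$conv4$W), 5L * 128L)
  # dense stack: time-averaged 256 features -> 128 -> 32 -> 16 -> 2
  expect_equal(dim(p$dense1$W), c(128L, 256L))
  fl <- build_model(model_config(feature_pool = "flatten"), seed = 1)
  expect_equal(dim(fl$params$dense1$W), c(128L, 2048L))  # 8 x 256 map
  expect_equal(dim(p$dense2$W), c(32L, 128L))
  expect_equal(dim(p$dense3$W), c(16L, 32L))
  expect_equal(dim(p$head$W), c(2L, 16L))
  # one frame in -> exactly two outputs
  out <- predict(m, matrix(rnorm(128), 1, 128))
  expect_equal(dim(out), c(1L, 2L))
  expect_true(all(is.finite(c(out$sbp, out$dbp))))
})

test_that("model configuration is validated", {
  expect_error(model_config(frame_len = 100), "divisible")
  expect_error(model_config(kernel_size = 4), "odd")
  expect_error(model_config(conv_filters = c(32, 64)), "four")
  m <- build_model(model_config(), seed = 1)
  expect_error(predict(m, matrix(rnorm(127), 1, 127)), "frame length")
})

test_that("initialization and forward pass are deterministic", {
  m1 <- build_model(model_config(), seed = 7)
  m2 <- build_model(model_config(), seed = 7)
  expect_identical(m1$params, m2$params)
  X <- matrix(rnorm(2 * 128), 2, 128)
  expect_identical(predict(m1, X), predict(m2, X))
  m3 <- build_model(model_config(), seed = 8)
  expect_false(identical(m1$params$conv1$W, m3$params$conv1$W))
  # identical frames in one batch give identical outputs
  Xdup <- rbind(X[1, ], X[1, ])
  pd <- predict(m1, Xdup)
  expect_equal(pd[1, ], pd[2, ], ignore_attr = TRUE)
  # batch prediction equals sample-by-sample prediction
  pb <- predict(m1, X)
  p1 <- predict(m1, X[1, , drop = FALSE])
  p2 <- predict(m1, X[2, , drop = FALSE])
  expect_equal(pb, rbind(p1, p2), ignore_attr = TRUE)
})

test_that("compiled convolution agrees with the pure-R reference", {
  set.seed(31)
  A <- array(rnorm(3 * 16 * 4), c(3, 16, 4))
  W <- matrix(rnorm(6 * 3 * 5), 6, 15)
  b <- rnorm(6)
  got <- ecg2bp:::conv1d_fw_cpp(A, W, b, 5L, 2L)
  Z <- got$Z; dim(Z) <- c(6, 16, 4)
  ref <- ecg2bp:::conv1d_forward_ref(A, W, b, 5L, 2L)
  expect_equal(Z, ref, tolerance = 1e-12)
})

test_that("backpropagation matches numerical gradients", {
  cfg <- tiny_model_config()
  params <- ecg2bp:::nn_init(cfg, 7)
  set.seed(42)
  X <- matrix(rnorm(4 * 128), 4, 128)
  Tm <- matrix(rnorm(8), 4, 2)
  lf <- ecg2bp:::nn_loss_forward(params, X, Tm, cfg, keep_cache = TRUE)
  gr <- ecg2bp:::nn_backward(params, lf$fw$cache, lf$dY, cfg)
  eps <- 1e-6
  for (nm in names(params)) for (fld in c("W", "b")) {
    p <- params[[nm]][[fld]]
    for (ii in sample(length(p), min(4, length(p)))) {
      pp <- params
      pp[[nm]][[fld]][ii] <- pp[[nm]][[fld]][ii] + eps
      l1 <- ecg2bp:::nn_loss_forward(pp, X, Tm, cfg)$loss
      pp[[nm]][[fld]][ii] <- pp[[nm]][[fld]][ii] - 2 * eps
      l2 <- ecg2bp:::nn_loss_forward(pp, X, Tm, cfg)$loss
      num <- (l1 - l2) / (2 * eps)
      expect_equal(gr[[nm]][[fld]][ii], num, tolerance = 1e-4)
    }
  }
})

test_that("training is reproducible and records a coherent history", {
  frames <- small_labeled_frames()
  cfg <- train_config(max_epochs = 4L, patience = 0L, seed = 5L)
  m <- build_model(tiny_model_config(), seed = 2)
  f1 <- train_model(m, frames, cfg)
  f2 <- train_model(m, frames, cfg)
  expect_identical(f1$history$epochs, f2$history$epochs)
  expect_identical(f1$model$params, f2$model$params)
  h <- f1$history
  expect_equal(nrow(h$epochs), 4L)
  # best epoch attains the minimum validation loss
  expect_equal(h$best_epoch, which.min(h$epochs$val_loss))
  expect_equal(h$best_val_loss, min(h$epochs$val_loss))
  # split is disjoint and exhaustive over the valid frames
  expect_length(intersect(h$split$train, h$split$validation), 0L)
  expect_setequal(c(h$split$train, h$split$validation),
                  which(frames$labels$valid))
})

test_that("record-level splits keep whole records on one side", {
  sim1 <- simulate_record(synth_config(duration_s = 30, seed = 41))
  sim2 <- simulate_record(synth_config(duration_s = 30, seed = 43))
  sim2$record$record_id <- "second"
  frames <- bind_frames(label_frames(preprocess_record(sim1$record)),
                        label_frames(preprocess_record(sim2$record)))
  fit <- train_model(build_model(tiny_model_config(), 1), frames,
                     train_config(max_epochs = 1L, split_by = "record",
                                  split_fraction = 0.5, seed = 3))
  tr_recs <- unique(frames$record_id[fit$history$split$train])
  va_recs <- unique(frames$record_id[fit$history$split$validation])
  expect_length(intersect(tr_recs, va_recs), 0L)
})

test_that("predictions ignore the ABP content of the frames", {
  frames <- small_labeled_frames()
  m <- build_model(tiny_model_config(), seed = 2)
  fit <- train_model(m, frames, train_config(max_epochs = 2L, seed = 5L))
  mutated <- frames
  mutated$abp <- mutated$abp * 0 + 999
  expect_identical(predict(fit$model, frames), predict(fit$model, mutated))
})

test_that("the network can memorize a small training set", {
  frames <- small_labeled_frames()
  vi <- which(frames$labels$valid)[1:16]
  sixteen <- subset_frames(frames, vi)
  m <- build_model(model_config(), seed = 3)
  fit <- train_model(m, sixteen, train_config(
    max_epochs = 500L, patience = 0L, restore_best = FALSE,
    max_restarts = 0L, split_fraction = 0.8, seed = 4))
  tr_frames <- subset_frames(sixteen, fit$history$split$train)
  pred <- predict(fit$model, tr_frames)
  mse <- mean(c((pred$sbp - tr_frames$labels$sbp)^2,
                (pred$dbp - tr_frames$labels$dbp)^2))
  expect_lt(mse, 1.0)  # mmHg^2, de-standardized
  # consequence: each memorized frame is predicted within ~1 mmHg
  expect_lt(max(abs(pred$sbp - tr_frames$labels$sbp)), 2.5)
})

test_that("divergence and degenerate inputs produce clear errors", {
  frames <- small_labeled_frames()
  m <- build_model(tiny_model_config(), seed = 2)
  expect_error(train_model(m, structure(frames[names(frames) != "labels"],
                                        class = "frame_set"),
                           train_config()), "no labels")
  bad <- frames
  bad$labels$valid[] <- FALSE
  expect_error(train_model(m, bad, train_config()), "no valid")
})

test_that("a saved model reloads with identical predictions", {
  frames <- small_labeled_frames()
  m <- build_model(tiny_model_config(), seed = 2)
  fit <- train_model(m, frames, train_config(max_epochs = 2L, seed = 5L))
  dir <- file.path(tempdir(), "model-rt")
  save_model(fit$model, dir)
  back <- load_model(dir)
  X <- frames$ecg[1:5, ]
  expect_identical(predict(fit$model, X), predict(back, X))
  expect_equal(back$scaling, fit$model$scaling)
  # tampering with the weights is detected
  w <- readRDS(file.path(dir, "weights.rds"))
  w$params$conv1$W[1] <- w$params$conv1$W[1] + 1
  saveRDS(w, file.path(dir, "weights.rds"))
  expect_error(load_model(dir), "checksum")
  # truncated file is detected
  writeBin(raw(10), file.path(dir, "weights.rds"))
  expect_error(load_model(dir), "corrupt")
  expect_error(load_model(file.path(tempdir(), "not-a-model")),
               "not a model directory")
})
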