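# 1D-CNN engine. The convolution and pooling kernels live in src/nn_ops.cpp
# (im2col + BLAS gemm); the thin layers (global average pooling, dense
# stack, Adam) stay in R. A pure-R reference convolution is kept below for
# cross-checking the compiled path in tests.

nn_init <- function(config, seed) {
  restore <- local_seed(seed)
  on.exit(restore())
  k <- config$kernel_size
  params <- list()
  C_in <- 1L
  for (i in seq_along(config$conv_filters)) {
    C_out <- config$conv_filters[i]
    fan_in <- C_in * k
    # slightly positive bias keeps ReLU units alive at initialization
    params[[paste0("conv", i)]] <- list(
      W = matrix(stats::rnorm(C_out * fan_in, 0, sqrt(2 / fan_in)),
                 C_out, fan_in),
      b = rep(0.1, C_out)
    )
    C_in <- C_out
  }
  L_final <- config$frame_len %/% config$pool_size^length(config$conv_filters)
  feat_in <- if (identical(config$feature_pool, "gap")) C_in
             else C_in * L_final
  dense_dims <- c(feat_in, config$feature_dim, config$fc_nodes, 2L)
  dense_names <- c(paste0("dense", seq_len(length(dense_dims) - 2L)), "head")
  for (i in seq_along(dense_names)) {
    din <- dense_dims[i]; dout <- dense_dims[i + 1L]
    sdv <- if (dense_names[i] == "head") sqrt(1 / din) else sqrt(2 / din)
    b0 <- if (dense_names[i] == "head") 0 else 0.1
    params[[dense_names[i]]] <- list(
      W = matrix(stats::rnorm(dout * din, 0, sdv), dout, din),
      b = rep(b0, dout)
    )
  }
  params
}

gap_forward <- function(A) {
  dm <- dim(A)  # (C, L, B)
  C <- dm[1]; L <- dm[2]; B <- dm[3]
  F_ <- matrix(0, C, B)
  for (l in seq_len(L)) F_ <- F_ + matrix(A[, l, ], C, B)
  F_ / L
}

gap_backward <- function(dF, L) {
  C <- nrow(dF); B <- ncol(dF)
  dA <- array(0, c(C, L, B))
  g <- dF / L
  for (l in seq_len(L)) dA[, l, ] <- g
  dA
}

# forward pass; X is (B, frame_len). Returns Y (B, 2) and, if keep_cache,
# the intermediates needed for backprop.
nn_forward <- function(params, X, config, keep_cache = FALSE) {
  B <- nrow(X)
  L <- config$frame_len
  k <- config$kernel_size
  pad <- (k - 1L) %/% 2L
  A <- array(t(X), c(1L, L, B))
  cache <- list()
  for (i in seq_along(config$conv_filters)) {
    nm <- paste0("conv", i)
    cf <- conv1d_fw_cpp(A, params[[nm]]$W, params[[nm]]$b, k, pad)
    Z <- cf$Z
    dim(Z) <- c(nrow(params[[nm]]$W), L, B)
    rp <- relu_pool_fw_cpp(Z)
    if (keep_cache) {
      cache[[nm]] <- list(P = cf$P, Z = Z, takefirst = rp$takefirst,
                          C_in = dim(A)[1], L = L)
    }
    A <- rp$out
    L <- L %/% 2L
  }
  if (identical(config$feature_pool, "gap")) {
    Fv <- gap_forward(A)
  } else {
    Fv <- A
    dim(Fv) <- c(dim(A)[1] * dim(A)[2], dim(A)[3])  # flatten (C*L, B)
  }
  if (keep_cache) cache$gap <- list(L = dim(A)[2], C = dim(A)[1])
  H <- Fv
  dense_names <- c(paste0("dense", seq_len(1L + length(config$fc_nodes))),
                   "head")
  for (nm in dense_names) {
    Zd <- params[[nm]]$W %*% H + params[[nm]]$b
    if (nm != "head") {
      Rd <- Zd; Rd[Rd < 0] <- 0
      if (keep_cache) cache[[nm]] <- list(Hin = H, relu_mask = Zd > 0)
      H <- Rd
    } else {
      if (keep_cache) cache[[nm]] <- list(Hin = H)
      H <- Zd
    }
  }
  list(Y = t(H), cache = cache)
}

# backprop of dY (B, 2); returns gradient list mirroring params
nn_backward <- function(params, cache, dY, config) {
  B <- nrow(dY)
  k <- config$kernel_size
  pad <- (k - 1L) %/% 2L
  grads <- list()
  dH <- t(dY)  # (2, B)
  dense_names <- rev(c(paste0("dense", seq_len(1L + length(config$fc_nodes))),
                       "head"))
  for (nm in dense_names) {
    cc <- cache[[nm]]
    if (nm != "head") dH <- dH * cc$relu_mask
    grads[[nm]] <- list(W = dH %*% t(cc$Hin), b = rowSums(dH))
    dH <- crossprod(params[[nm]]$W, dH)
  }
  # dH is now the gradient wrt the pooled/flattened feature vector
  if (identical(config$feature_pool, "gap")) {
    dA <- gap_backward(dH, cache$gap$L)
  } else {
    dA <- dH
    dim(dA) <- c(cache$gap$C, cache$gap$L, ncol(dH))
  }
  for (i in rev(seq_along(config$conv_filters))) {
    nm <- paste0("conv", i)
    cc <- cache[[nm]]
    dZ <- relu_pool_bw_cpp(dA, cc$takefirst, cc$Z)
    bk <- conv1d_bw_cpp(dZ, cc$P, params[[nm]]$W, cc$C_in, cc$L, B, k, pad)
    grads[[nm]] <- list(W = bk$dW, b = as.numeric(bk$db))
    dA <- bk$dA
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p) list(
    mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0
  ))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

# --- pure-R reference convolution (used to cross-check the compiled path) --

conv1d_forward_ref <- function(A, W, b, k, pad) {
  dm <- dim(A)
  C <- dm[1]; L <- dm[2]; B <- dm[3]
  Lp <- L + 2L * pad
  Apad <- array(0, c(C, Lp, B))
  Apad[, (pad + 1L):(pad + L), ] <- A
  rowoff <- as.vector(outer(seq_len(C), (seq_len(k) - 1L) * C, "+"))
  coloff <- as.vector(outer((seq_len(L) - 1L) * C,
                            (seq_len(B) - 1L) * C * Lp, "+"))
  P <- Apad[outer(rowoff, coloff, "+")]
  dim(P) <- c(C * k, L * B)
  Z <- W %*% P + b
  dim(Z) <- c(nrow(W), L, B)
  Z
}
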