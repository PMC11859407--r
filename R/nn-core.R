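# Internal numerical core for the 1-D convolutional intent classifiers.
#
# Convolution (im2col + GEMM), its backward pass and max pooling run in
# compiled code (src/conv1d.cpp); the dense head, softmax cross-entropy,
# dropout and Adam live here.  Batches are carried as (length, channels,
# batch) arrays; conv activations as (batch*Lout, filters) matrices with row
# index (b - 1) * Lout + t.

relu <- function(Z) {
  Z[Z < 0] <- 0
  Z
}

pool_backward <- function(dP, pool) {
  dY <- numeric(pool$Lout * pool$B * pool$FF)
  dY[pool$argmax] <- as.vector(dP)
  array(dY, c(pool$Lout, pool$B, pool$FF))
}

# (Lp, B, F) -> (B x Lp*F) with per-sample flatten order (t, f).
flatten_batch <- function(P) {
  d <- dim(P)
  t(matrix(aperm(P, c(1, 3, 2)), d[1] * d[3], d[2]))
}

unflatten_batch <- function(dXf, Lp, FF) {
  B <- nrow(dXf)
  aperm(array(t(dXf), c(Lp, FF, B)), c(1, 3, 2))
}

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

# Architecture plan + parameter initialization ------------------------------

nn_build <- function(config, input_shape) {
  L <- input_shape[1]; C <- input_shape[2]
  arch <- config$architecture
  params <- list()
  plan <- list(type = arch, L = L, C = C, n_classes = 9L,
               dropout = config$dropout_rate, l2 = config$l2_reg)
  if (arch == "cnn") {
    k1 <- 7L; p1 <- 4L; k2 <- 5L; p2 <- 4L
    f1 <- config$num_filters_1; f2 <- config$num_filters_2
    L1 <- L - k1 + 1L; L1p <- L1 %/% p1
    if (L1p < k2) rlang::abort("Input too short for the cnn architecture.")
    L2 <- L1p - k2 + 1L; L2p <- L2 %/% p2
    plan$stages <- list(
      list(k = k1, f = f1, pool = p1, Lin = L, Cin = C, Lout = L1, Lp = L1p),
      list(k = k2, f = f2, pool = p2, Lin = L1p, Cin = f1, Lout = L2, Lp = L2p)
    )
    flat <- L2p * f2
    params$Wc1 <- he_init(k1 * C, f1, k1 * C); params$bc1 <- numeric(f1)
    params$Wc2 <- he_init(k2 * f1, f2, k2 * f1); params$bc2 <- numeric(f2)
  } else {
    kernels <- c(3L, 9L, 27L); pool <- 15L
    f1 <- config$num_filters_1
    plan$streams <- lapply(kernels, function(k) {
      Lout <- L - k + 1L
      if (Lout < pool) rlang::abort("Input too short for the mlcnn architecture.")
      list(k = k, f = f1, pool = pool, Lout = Lout, Lp = Lout %/% pool)
    })
    flat <- sum(vapply(plan$streams, function(s) s$Lp * s$f, numeric(1)))
    for (s in seq_along(plan$streams)) {
      k <- plan$streams[[s]]$k
      params[[paste0("Wc", s)]] <- he_init(k * C, f1, k * C)
      params[[paste0("bc", s)]] <- numeric(f1)
    }
  }
  plan$flat <- flat
  params$Wd <- he_init(flat, config$dense_units, flat)
  params$bd <- numeric(config$dense_units)
  params$Wo <- he_init(config$dense_units, 9L, config$dense_units)
  params$bo <- numeric(9L)
  list(plan = plan, params = params)
}

nn_n_params <- function(net) {
  sum(vapply(net$params, length, numeric(1)))
}

nn_conv_params <- function(net) {
  nm <- grep("^(Wc|bc)", names(net$params), value = TRUE)
  sum(vapply(net$params[nm], length, numeric(1)))
}

# Forward pass ---------------------------------------------------------------

# X: (L, C, B) array.  Returns probabilities and, when train = TRUE, the
# cache needed for backprop.  Dropout draws from the current RNG stream.
nn_forward <- function(net, X, train = FALSE) {
  plan <- net$plan; pp <- net$params
  B <- dim(X)[3]
  cache <- list(B = B)
  if (plan$type == "cnn") {
    s1 <- plan$stages[[1]]; s2 <- plan$stages[[2]]
    Z1 <- conv1d_fwd(X, pp$Wc1, pp$bc1, s1$k)
    A1 <- relu(Z1)
    P1 <- pool1d_fwd(A1, s1$Lout, B, s1$pool)
    P1$Lout <- s1$Lout; P1$B <- B; P1$FF <- s1$f
    X2 <- aperm(P1$P, c(1, 3, 2))            # (L1p, f1, B) as (L, C, B)
    Z2 <- conv1d_fwd(X2, pp$Wc2, pp$bc2, s2$k)
    A2 <- relu(Z2)
    P2 <- pool1d_fwd(A2, s2$Lout, B, s2$pool)
    P2$Lout <- s2$Lout; P2$B <- B; P2$FF <- s2$f
    Xf <- flatten_batch(P2$P)
    if (train) cache <- c(cache, list(X1 = X, Z1pos = Z1 > 0, P1 = P1,
                                      X2 = X2, Z2pos = Z2 > 0, P2 = P2))
  } else {
    flats <- vector("list", length(plan$streams))
    for (s in seq_along(plan$streams)) {
      st <- plan$streams[[s]]
      Z <- conv1d_fwd(X, pp[[paste0("Wc", s)]], pp[[paste0("bc", s)]], st$k)
      A <- relu(Z)
      P <- pool1d_fwd(A, st$Lout, B, st$pool)
      P$Lout <- st$Lout; P$B <- B; P$FF <- st$f
      flats[[s]] <- flatten_batch(P$P)
      if (train) {
        cache[[paste0("Zpos", s)]] <- Z > 0
        cache[[paste0("P", s)]] <- P
      }
    }
    if (train) cache$X1 <- X
    Xf <- do.call(cbind, flats)
  }
  if (train && plan$dropout > 0) {
    keep <- 1 - plan$dropout
    mask <- matrix(runif(length(Xf)) < keep, nrow(Xf)) / keep
    Xf <- Xf * mask
    cache$dropmask <- mask
  }
  H <- sweep(Xf %*% pp$Wd, 2, pp$bd, "+")
  Hr <- relu(H)
  logits <- sweep(Hr %*% pp$Wo, 2, pp$bo, "+")
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  if (train) {
    cache$Xf <- Xf; cache$Hpos <- H > 0; cache$Hr <- Hr
  }
  list(probs = probs, cache = cache)
}

# Backward pass: y is an integer class vector (0-based), probs from forward.
nn_backward <- function(net, X, y, probs, cache) {
  plan <- net$plan; pp <- net$params
  B <- cache$B
  g <- list()
  dlogits <- probs
  idx <- cbind(seq_len(B), y + 1L)
  dlogits[idx] <- dlogits[idx] - 1
  dlogits <- dlogits / B
  g$Wo <- crossprod(cache$Hr, dlogits) + 2 * plan$l2 * pp$Wo
  g$bo <- colSums(dlogits)
  dH <- tcrossprod(dlogits, pp$Wo)
  dH[!cache$Hpos] <- 0
  g$Wd <- crossprod(cache$Xf, dH) + 2 * plan$l2 * pp$Wd
  g$bd <- colSums(dH)
  dXf <- tcrossprod(dH, pp$Wd)
  if (!is.null(cache$dropmask)) dXf <- dXf * cache$dropmask

  if (plan$type == "cnn") {
    s1 <- plan$stages[[1]]; s2 <- plan$stages[[2]]
    dP2 <- unflatten_batch(dXf, s2$Lp, s2$f)
    dA2 <- pool_backward(dP2, cache$P2)
    dZ2 <- matrix(dA2, s2$Lout * B, s2$f)
    dZ2[!cache$Z2pos] <- 0
    bw2 <- conv1d_bwd(cache$X2, pp$Wc2, dZ2, s2$k, TRUE)
    g$Wc2 <- bw2$dW + 2 * plan$l2 * pp$Wc2
    g$bc2 <- as.numeric(bw2$db)
    dP1 <- aperm(bw2$dX, c(1, 3, 2))         # back to (L1p, B, f1)
    dA1 <- pool_backward(dP1, cache$P1)
    dZ1 <- matrix(dA1, s1$Lout * B, s1$f)
    dZ1[!cache$Z1pos] <- 0
    bw1 <- conv1d_bwd(cache$X1, pp$Wc1, dZ1, s1$k, FALSE)
    g$Wc1 <- bw1$dW + 2 * plan$l2 * pp$Wc1
    g$bc1 <- as.numeric(bw1$db)
  } else {
    off <- 0L
    for (s in seq_along(plan$streams)) {
      st <- plan$streams[[s]]
      w <- st$Lp * st$f
      dflat <- dXf[, (off + 1L):(off + w), drop = FALSE]
      off <- off + w
      dP <- unflatten_batch(dflat, st$Lp, st$f)
      dA <- pool_backward(dP, cache[[paste0("P", s)]])
      dZ <- matrix(dA, st$Lout * B, st$f)
      dZ[!cache[[paste0("Zpos", s)]]] <- 0
      bw <- conv1d_bwd(cache$X1, pp[[paste0("Wc", s)]], dZ, st$k, FALSE)
      g[[paste0("Wc", s)]] <- bw$dW + 2 * plan$l2 * pp[[paste0("Wc", s)]]
      g[[paste0("bc", s)]] <- as.numeric(bw$db)
    }
  }
  g
}

# Adam ------------------------------------------------------------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Pack a list of (L x C) window matrices into an (L, C, B) array.
windows_to_array <- function(samples) {
  L <- nrow(samples[[1]]); C <- ncol(samples[[1]])
  array(unlist(samples, use.names = FALSE), c(L, C, length(samples)))
}
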