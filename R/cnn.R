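## ---- desk-scale residual convolutional network -----------------------------
##
## A small ResNet-style binary classifier written directly on BLAS matrix
## products. Activations for a batch of B images of side d with C channels
## are stored as a (B*d*d) x C matrix whose row index is
## (b-1)*d*d + spatial, spatial column-major within the image. 3x3
## convolutions are evaluated as nine shifted row-indexed matrix products;
## zero padding is realized by an extra all-zero row that out-of-range
## offsets point at.

## cache of shift/pool index vectors keyed by "d/B"
.idx_cache <- new.env(parent = emptyenv())

conv_offsets <- expand.grid(dy = -1:1, dx = -1:1)

get_indices <- function(d, B, stride = 1L) {
  key <- paste(d, stride, B, sep = "/")
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  HW <- d * d
  N_in <- B * HW
  d_out <- if (stride == 1L) d else d %/% stride
  HW_out <- d_out * d_out
  ## output-grid centers: stride 1 -> same grid; stride s -> s*j - 1 (pad 1)
  yo <- rep(seq_len(d_out), d_out)
  xo <- rep(seq_len(d_out), each = d_out)
  yc <- if (stride == 1L) yo else stride * yo - 1L
  xc <- if (stride == 1L) xo else stride * xo - 1L
  conv <- lapply(seq_len(9), function(k) {
    yy <- yc + conv_offsets$dy[k]
    xx <- xc + conv_offsets$dx[k]
    sp <- ifelse(yy >= 1 & yy <= d & xx >= 1 & xx <= d,
                 yy + (xx - 1) * d, NA_integer_)
    full <- rep(sp, B) + rep((0:(B - 1)) * HW, each = HW_out)
    full[is.na(full)] <- N_in + 1L       # pad row
    as.integer(full)
  })
  pool <- NULL
  if (stride == 1L && d %% 2 == 0) {
    d2 <- d %/% 2
    y2 <- rep(seq_len(d2), d2)
    x2 <- rep(seq_len(d2), each = d2)
    pool <- lapply(list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)), function(o) {
      sp <- (2 * y2 - 1 + o[1]) + (2 * x2 - 1 + o[2] - 1) * d
      as.integer(rep(sp, B) + rep((0:(B - 1)) * HW, each = d2 * d2))
    })
  }
  res <- list(conv = conv, pool = pool, N_in = N_in,
              N_out = B * HW_out)
  .idx_cache[[key]] <- res
  res
}

he_init <- function(Cin, Cout, fan) {
  matrix(stats::rnorm(Cin * Cout, sd = sqrt(2 / fan)), Cin, Cout)
}

new_conv <- function(Cin, Cout) {
  list(W = lapply(seq_len(9), function(k) he_init(Cin, Cout, 9 * Cin)),
       ## batch normalization: learned scale/shift plus running statistics
       ## for inference (standard residual-network composition
       ## conv -> BN -> ReLU)
       gamma = rep(1, Cout), beta = numeric(Cout),
       run_mean = numeric(Cout), run_var = rep(1, Cout))
}

bn_momentum <- 0.9
bn_eps <- 1e-5

## batch norm over the (batch*space) rows, one statistic per channel
bn_fwd <- function(Z, ly, train) {
  if (train) {
    mu <- colMeans(Z)
    zc <- Z - matrix(mu, nrow(Z), ncol(Z), byrow = TRUE)
    v <- colMeans(zc^2)
    inv_std <- 1 / sqrt(v + bn_eps)
    Zhat <- zc * matrix(inv_std, nrow(Z), ncol(Z), byrow = TRUE)
    out <- Zhat * matrix(ly$gamma, nrow(Z), ncol(Z), byrow = TRUE) +
      matrix(ly$beta, nrow(Z), ncol(Z), byrow = TRUE)
    list(out = out, Zhat = Zhat, inv_std = inv_std,
         new_mean = bn_momentum * ly$run_mean + (1 - bn_momentum) * mu,
         new_var = bn_momentum * ly$run_var + (1 - bn_momentum) * v)
  } else {
    inv_std <- 1 / sqrt(ly$run_var + bn_eps)
    scale <- ly$gamma * inv_std
    shift <- ly$beta - ly$run_mean * scale
    list(out = Z * matrix(scale, nrow(Z), ncol(Z), byrow = TRUE) +
           matrix(shift, nrow(Z), ncol(Z), byrow = TRUE))
  }
}

bn_bwd <- function(dOut, ly, cache) {
  n <- nrow(dOut)
  m <- ncol(dOut)
  dgamma <- colSums(dOut * cache$Zhat)
  dbeta <- colSums(dOut)
  dZhat <- dOut * matrix(ly$gamma, n, m, byrow = TRUE)
  dZ <- (dZhat -
           matrix(colMeans(dZhat), n, m, byrow = TRUE) -
           cache$Zhat * matrix(colMeans(dZhat * cache$Zhat), n, m,
                               byrow = TRUE)) *
    matrix(cache$inv_std, n, m, byrow = TRUE)
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

#' Build a residual CNN for MTF images
#'
#' Constructs a small residual network: per stage one channel-expanding 3x3
#' convolution followed by `blocks_per_stage` identity residual blocks (two
#' 3x3 convolutions with a skip connection), 2x2 average pooling between
#' stages, global average pooling, and a single logistic output unit. The
#' default two-stage, one-block configuration has seven weight layers; wider
#' and deeper variants (up to ResNet34-scale stacks) are reached through
#' `channels` and `blocks_per_stage`.
#'
#' @param input_size Input image side length (default 32).
#' @param channels Integer vector of channels per stage.
#' @param blocks_per_stage Residual blocks per stage (recycled).
#' @param stem_stride Stride of the stem convolution (default 2, the usual
#'   residual-network stem downsampling; 1 keeps full resolution).
#' @param seed Seed for weight initialization.
#' @return An object of class `sl_net`.
#' @export
build_resnet <- function(input_size = 32L, channels = c(8L, 16L),
                         blocks_per_stage = 1L, stem_stride = 2L,
                         seed = 1L) {
  blocks_per_stage <- rep_len(blocks_per_stage, length(channels))
  with_seed(derive_seed(seed, "init"), {
    layers <- list()
    d <- input_size
    Cin <- 1L
    for (s in seq_along(channels)) {
      C <- channels[s]
      stride <- if (s == 1) as.integer(stem_stride) else 1L
      if (d %% stride != 0) sl_stop("spatial size not divisible by stride",
                                    "spikeloop_invalid_configuration")
      layers[[length(layers) + 1]] <- c(list(type = "conv", d = d, Cin = Cin,
                                             Cout = C, relu = TRUE,
                                             stride = stride),
                                        new_conv(Cin, C))
      d <- d %/% stride
      for (bl in seq_len(blocks_per_stage[s])) {
        layers[[length(layers) + 1]] <- list(type = "resblock", d = d, C = C,
                                             conv1 = new_conv(C, C),
                                             conv2 = new_conv(C, C))
      }
      if (s < length(channels)) {
        if (d %% 2 != 0) sl_stop("spatial size not divisible by 2",
                                 "spikeloop_invalid_configuration")
        layers[[length(layers) + 1]] <- list(type = "pool", d = d)
        d <- d %/% 2L
      }
      Cin <- C
    }
    layers[[length(layers) + 1]] <- list(type = "gap", d = d, C = Cin)
    layers[[length(layers) + 1]] <- list(type = "dense",
                                         W = he_init(Cin, 1L, Cin),
                                         b = 0)
    structure(list(layers = layers, input_size = as.integer(input_size)),
              class = "sl_net")
  })
}

## stack the 3x3 weight list into a (9*Cin) x Cout matrix, rows k-major
stack_weights <- function(W) do.call(rbind, W)

## im2col: (N x Cin) activations -> (N x 9*Cin) patch matrix whose column
## order ((k-1)*Cin + c) matches stack_weights(); one zero pad row realizes
## the padding
im2col <- function(X, idx) {
  C <- ncol(X)
  N <- idx$N_out
  Xp <- rbind(X, matrix(0, 1, C))
  S <- Xp[unlist(idx$conv), , drop = FALSE]      # (9N) x C, k-major blocks
  dim(S) <- c(N, 9, C)
  S <- aperm(S, c(1, 3, 2))                      # N x C x 9
  dim(S) <- c(N, 9L * C)
  S
}

conv_fwd <- function(X, layer, idx, cache_env = NULL) {
  Xcol <- im2col(X, idx)
  if (!is.null(cache_env)) cache_env$Xcol <- Xcol
  Xcol %*% stack_weights(layer$W)   # bias is subsumed by the BN shift
}

## gradient of a conv given the cached im2col matrix and upstream dY;
## skip_dx spares the input gradient for the first layer
conv_bwd <- function(Xcol, dY, layer, idx, skip_dx = FALSE) {
  C <- ncol(Xcol) %/% 9L
  Wm <- stack_weights(layer$W)
  dWm <- crossprod(Xcol, dY)
  dW <- lapply(seq_len(9), function(k)
    dWm[(k - 1L) * C + seq_len(C), , drop = FALSE])
  if (skip_dx) return(list(dX = NULL, dW = dW))
  dXcol <- dY %*% t(Wm)
  dX <- matrix(0, idx$N_in, C)
  for (k in 1:9) {
    ik <- idx$conv[[k]]
    valid <- ik <= idx$N_in
    iv <- ik[valid]
    dX[iv, ] <- dX[iv, , drop = FALSE] +
      dXcol[valid, (k - 1L) * C + seq_len(C), drop = FALSE]
  }
  list(dX = dX, dW = dW)
}

## forward pass; returns logits and per-layer caches for backprop.
## `keep_cache = TRUE` is training mode (batch statistics in the BN layers),
## `FALSE` is inference mode (running statistics).
net_forward <- function(net, X, B, keep_cache = TRUE) {
  caches <- vector("list", length(net$layers))
  A <- X
  for (li in seq_along(net$layers)) {
    ly <- net$layers[[li]]
    switch(ly$type,
      conv = {
        idx <- get_indices(ly$d, B, ly$stride %||% 1L)
        ce <- if (keep_cache) new.env(parent = emptyenv()) else NULL
        Z <- conv_fwd(A, ly, idx, ce)
        bn <- bn_fwd(Z, ly, train = keep_cache)
        out <- if (isTRUE(ly$relu)) pmax(bn$out, 0) else bn$out
        if (keep_cache) caches[[li]] <- list(Xcol = ce$Xcol, bn = bn,
                                             mask = bn$out > 0)
        A <- out
      },
      resblock = {
        idx <- get_indices(ly$d, B)
        ce1 <- if (keep_cache) new.env(parent = emptyenv()) else NULL
        ce2 <- if (keep_cache) new.env(parent = emptyenv()) else NULL
        Z1 <- conv_fwd(A, ly$conv1, idx, ce1)
        bn1 <- bn_fwd(Z1, ly$conv1, train = keep_cache)
        A1 <- pmax(bn1$out, 0)
        Z2 <- conv_fwd(A1, ly$conv2, idx, ce2)
        bn2 <- bn_fwd(Z2, ly$conv2, train = keep_cache)
        S <- A + bn2$out
        out <- pmax(S, 0)
        if (keep_cache) caches[[li]] <- list(Xcol1 = ce1$Xcol, bn1 = bn1,
                                             mask1 = bn1$out > 0,
                                             Xcol2 = ce2$Xcol, bn2 = bn2,
                                             S = S)
        A <- out
      },
      pool = {
        idx <- get_indices(ly$d, B)
        A <- (A[idx$pool[[1]], , drop = FALSE] + A[idx$pool[[2]], , drop = FALSE] +
              A[idx$pool[[3]], , drop = FALSE] + A[idx$pool[[4]], , drop = FALSE]) / 4
      },
      gap = {
        grp <- rep(seq_len(B), each = ly$d * ly$d)
        A <- rowsum(A, grp) / (ly$d * ly$d)
      },
      dense = {
        if (keep_cache) caches[[li]] <- list(X = A)
        A <- A %*% ly$W + ly$b
      })
  }
  list(logits = as.numeric(A), caches = caches)
}

## backward pass from d(loss)/d(logit); returns gradient tree parallel to
## net$layers (only parameterized layers filled)
net_backward <- function(net, caches, dlogit, B) {
  grads <- vector("list", length(net$layers))
  dA <- matrix(dlogit, ncol = 1)
  for (li in rev(seq_along(net$layers))) {
    ly <- net$layers[[li]]
    switch(ly$type,
      dense = {
        X <- caches[[li]]$X
        grads[[li]] <- list(W = crossprod(X, dA), b = sum(dA))
        dA <- dA %*% t(ly$W)
      },
      gap = {
        HW <- ly$d * ly$d
        dA <- dA[rep(seq_len(B), each = HW), , drop = FALSE] / HW
      },
      pool = {
        idx <- get_indices(ly$d, B)
        up <- matrix(0, ly$d * ly$d * B, ncol(dA))
        for (j in 1:4) up[idx$pool[[j]], ] <- dA / 4
        dA <- up
      },
      resblock = {
        idx <- get_indices(ly$d, B)
        ca <- caches[[li]]
        dS <- dA * (ca$S > 0)
        b2 <- bn_bwd(dS, ly$conv2, ca$bn2)
        g2 <- conv_bwd(ca$Xcol2, b2$dZ, ly$conv2, idx)
        dA1 <- g2$dX * ca$mask1
        b1 <- bn_bwd(dA1, ly$conv1, ca$bn1)
        g1 <- conv_bwd(ca$Xcol1, b1$dZ, ly$conv1, idx)
        grads[[li]] <- list(conv1 = list(W = g1$dW, gamma = b1$dgamma,
                                         beta = b1$dbeta),
                            conv2 = list(W = g2$dW, gamma = b2$dgamma,
                                         beta = b2$dbeta))
        dA <- dS + g1$dX
      },
      conv = {
        idx <- get_indices(ly$d, B, ly$stride %||% 1L)
        ca <- caches[[li]]
        dOut <- if (isTRUE(ly$relu)) dA * ca$mask else dA
        bbn <- bn_bwd(dOut, ly, ca$bn)
        g <- conv_bwd(ca$Xcol, bbn$dZ, ly, idx, skip_dx = li == 1L)
        grads[[li]] <- list(W = g$dW, gamma = bbn$dgamma, beta = bbn$dbeta)
        dA <- g$dX
      })
  }
  grads
}

## recursive Adam over parallel param/grad/state trees (leaves are numerics)
adam_step <- function(param, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.list(param)) {
    out <- vector("list", length(param))
    names(out) <- names(param)
    st <- state %||% vector("list", length(param))
    for (i in seq_along(param)) {
      r <- adam_step(param[[i]], grad[[i]], st[[i]], lr, t, beta1, beta2, eps)
      out[[i]] <- r$param
      st[[i]] <- r$state
    }
    return(list(param = out, state = st))
  }
  st <- state %||% list(m = param * 0, v = param * 0)
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mh <- st$m / (1 - beta1^t)
  vh <- st$v / (1 - beta2^t)
  list(param = param - lr * mh / (sqrt(vh) + eps), state = st)
}

layer_params <- function(ly) {
  switch(ly$type,
         conv = list(W = ly$W, gamma = ly$gamma, beta = ly$beta),
         resblock = list(conv1 = list(W = ly$conv1$W, gamma = ly$conv1$gamma,
                                      beta = ly$conv1$beta),
                         conv2 = list(W = ly$conv2$W, gamma = ly$conv2$gamma,
                                      beta = ly$conv2$beta)),
         dense = list(W = ly$W, b = ly$b),
         NULL)
}

set_layer_params <- function(ly, p) {
  switch(ly$type,
         conv = { ly$W <- p$W; ly$gamma <- p$gamma; ly$beta <- p$beta },
         resblock = {
           ly$conv1$W <- p$conv1$W
           ly$conv1$gamma <- p$conv1$gamma
           ly$conv1$beta <- p$conv1$beta
           ly$conv2$W <- p$conv2$W
           ly$conv2$gamma <- p$conv2$gamma
           ly$conv2$beta <- p$conv2$beta
         },
         dense = { ly$W <- p$W; ly$b <- p$b })
  ly
}

## one optimization step over a batch; returns updated net + opt state + loss
net_train_batch <- function(net, X, y, alpha_pos, alpha_neg, gamma, lr,
                            opt_state, t) {
  B <- length(y)
  fw <- net_forward(net, X, B, keep_cache = TRUE)
  p <- 1 / (1 + exp(-fw$logits))
  q <- ifelse(y == 1, p, 1 - p)          # probability of the true class
  q <- pmin(pmax(q, 1e-7), 1 - 1e-15)
  a <- ifelse(y == 1, alpha_pos, alpha_neg)
  loss <- mean(-a * (1 - q)^gamma * log(q))
  ## d(loss)/d(logit) through q = y p + (1-y)(1-p)
  dldq <- a * (1 - q)^pmax(gamma - 1, 0) * (gamma * log(q) - (1 - q) / q)
  if (gamma == 0) dldq <- -a / q
  dlogit <- dldq * (2 * y - 1) * q * (1 - q) / B
  grads <- net_backward(net, fw$caches, dlogit, B)
  for (li in seq_along(net$layers)) {
    ly <- net$layers[[li]]
    ## roll the BN running statistics forward from this batch
    if (ly$type == "conv") {
      net$layers[[li]]$run_mean <- fw$caches[[li]]$bn$new_mean
      net$layers[[li]]$run_var <- fw$caches[[li]]$bn$new_var
    } else if (ly$type == "resblock") {
      net$layers[[li]]$conv1$run_mean <- fw$caches[[li]]$bn1$new_mean
      net$layers[[li]]$conv1$run_var <- fw$caches[[li]]$bn1$new_var
      net$layers[[li]]$conv2$run_mean <- fw$caches[[li]]$bn2$new_mean
      net$layers[[li]]$conv2$run_var <- fw$caches[[li]]$bn2$new_var
    }
    p0 <- layer_params(net$layers[[li]])
    if (is.null(p0)) next
    r <- adam_step(p0, grads[[li]], opt_state[[li]], lr, t)
    net$layers[[li]] <- set_layer_params(net$layers[[li]], r$param)
    opt_state[[li]] <- r$state
  }
  list(net = net, opt_state = opt_state, loss = loss)
}

## batched forward-only probabilities for a feature matrix (rows = images)
net_predict <- function(net, features, batch_size = 256L) {
  n <- nrow(features)
  d <- net$input_size
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    B <- j - i + 1L
    X <- matrix(t(features[i:j, , drop = FALSE]), ncol = 1)
    fw <- net_forward(net, X, B, keep_cache = FALSE)
    out[i:j] <- 1 / (1 + exp(-fw$logits))
    i <- j + 1L
  }
  out
}
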