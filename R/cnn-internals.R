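# Internal neural-network engine for the fixed small-CNN architecture.
#
# Activations for convolutional stages are stored as (B * H * W) x C
# matrices: row index (n - 1) * H * W + sp with spatial index
# sp = (w - 1) * H + h (column-major within each image), channels as
# columns. Convolutions are evaluated as im2col gathers followed by one
# BLAS GEMM per layer, which is where essentially all the arithmetic goes.
# Everything here is double precision and deterministic given the RNG
# state at initialization and shuffling.

# ---- im2col / pooling index plans (cached per (H, W, B)) ----

# offsets of the 3x3 valid convolution: off[p, q] is the within-image
# spatial index feeding kernel position q of output position p
.conv_offsets <- function(H, W) {
  oh <- H - 2L
  ow <- W - 2L
  P <- oh * ow
  off <- matrix(0L, P, 9L)
  for (kw in 1:3) {
    for (kh in 1:3) {
      q <- (kw - 1L) * 3L + kh
      # output position p = (j - 1) * oh + i for output coords (i, j)
      i <- rep(seq_len(oh), times = ow)
      j <- rep(seq_len(ow), each = oh)
      off[, q] <- (j + kw - 2L) * H + (i + kh - 1L)
    }
  }
  off
}

.conv_plan <- function(H, W, B) {
  off <- .conv_offsets(H, W)
  P <- nrow(off)
  HW <- H * W
  base <- rep((seq_len(B) - 1L) * HW, each = 9L * P)
  rowidx <- rep(as.vector(t(off)), times = B) + base   # q fastest, p, n
  tq <- lapply(1:9, function(q) {
    rep(off[, q], times = B) + rep((seq_len(B) - 1L) * HW, each = P)
  })
  list(rowidx = rowidx, tq = tq, P = P, H = H, W = W, B = B,
       out_h = H - 2L, out_w = W - 2L)
}

.pool_plan <- function(H, W, B) {
  oh <- H %/% 2L
  ow <- W %/% 2L
  P <- oh * ow
  HW <- H * W
  members <- vector("list", 4L)
  i <- rep(seq_len(oh), times = ow)
  j <- rep(seq_len(ow), each = oh)
  k <- 0L
  for (dw in 0:1) {
    for (dh in 0:1) {
      k <- k + 1L
      sp <- (2L * j - 2L + dw) * H + (2L * i - 1L + dh)
      members[[k]] <- rep(sp, times = B) + rep((seq_len(B) - 1L) * HW,
                                               each = P)
    }
  }
  list(members = members, P = P, out_h = oh, out_w = ow, B = B)
}

.get_plan <- function(net, key, builder) {
  if (is.null(net$plans[[key]])) net$plans[[key]] <- builder()
  net$plans[[key]]
}

# ---- parameter initialization ----

# He-normal for the ReLU convolutions, Glorot-uniform for the dense head.
# Consumes the current RNG state; callers seed.
.nn_init <- function(side, n_classes) {
  he <- function(fan_in, nr, nc) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  }
  glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
  }
  s3 <- side - 6L
  pool <- s3 %/% 2L
  flat <- pool * pool * 64L
  params <- list(
    W1 = he(9 * 1, 9L, 64L),    b1 = numeric(64),
    g1 = rep(1, 64),            be1 = numeric(64),
    W2 = he(9 * 64, 576L, 64L), b2 = numeric(64),
    g2 = rep(1, 64),            be2 = numeric(64),
    W3 = he(9 * 64, 576L, 64L), b3 = numeric(64),
    g3 = rep(1, 64),            be3 = numeric(64),
    W4 = glorot(flat, 6L),      b4 = numeric(6),
    W5 = glorot(6L, n_classes), b5 = numeric(n_classes)
  )
  bn <- list(
    rm1 = numeric(64), rv1 = rep(1, 64),
    rm2 = numeric(64), rv2 = rep(1, 64),
    rm3 = numeric(64), rv3 = rep(1, 64)
  )
  list(params = params, bn = bn, side = side, n_classes = n_classes,
       flat = flat)
}

.bcast <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

# ---- batch normalization (channels = columns) ----

.bn_forward <- function(X, gamma, beta, rm, rv, training,
                        momentum = 0.99, eps = 1e-5) {
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    xc <- X - .bcast(mu, n)
    v <- colMeans(xc * xc)
    istd <- 1 / sqrt(v + eps)
    xhat <- xc * .bcast(istd, n)
    out <- xhat * .bcast(gamma, n) + .bcast(beta, n)
    list(out = out, xhat = xhat, istd = istd,
         rm = momentum * rm + (1 - momentum) * mu,
         rv = momentum * rv + (1 - momentum) * v)
  } else {
    istd <- 1 / sqrt(rv + eps)
    out <- (X - .bcast(rm, n)) * .bcast(gamma * istd, n) + .bcast(beta, n)
    list(out = out)
  }
}

.bn_backward <- function(dY, xhat, istd, gamma) {
  n <- nrow(dY)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * .bcast(gamma, n)
  dX <- (dxhat - .bcast(colMeans(dxhat), n) -
           xhat * .bcast(colMeans(dxhat * xhat), n)) * .bcast(istd, n)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- convolution via im2col ----

.conv_forward <- function(A, plan, W, b, Cin) {
  G <- A[plan$rowidx, , drop = FALSE]            # (9*P*B) x Cin, q fastest
  dim(G) <- c(9L, plan$P, plan$B, Cin)
  Cmat <- aperm(G, c(2L, 3L, 1L, 4L))            # p, n, q, cin
  dim(Cmat) <- c(plan$P * plan$B, 9L * Cin)
  Z <- Cmat %*% W
  Z <- Z + .bcast(b, nrow(Z))
  list(Z = Z, Cmat = Cmat)
}

.conv_backward <- function(dZ, Cmat, plan, W, Cin, in_rows) {
  dW <- crossprod(Cmat, dZ)
  db <- colSums(dZ)
  dCmat <- tcrossprod(dZ, W)                     # (P*B) x (9*Cin)
  dA <- matrix(0, in_rows, Cin)
  for (q in 1:9) {
    cols_q <- q + 9L * (seq_len(Cin) - 1L)
    tq <- plan$tq[[q]]
    dA[tq, ] <- dA[tq, ] + dCmat[, cols_q, drop = FALSE]
  }
  list(dA = dA, dW = dW, db = db)
}

# ---- full forward pass ----
# X: B x (side^2) matrix of flattened images (column-major per image).
# Returns class probabilities and, when training, the cache for backward.

.nn_forward <- function(net, X, training = FALSE) {
  B <- nrow(X)
  side <- net$side
  p <- net$params
  bn <- net$bn
  cache <- if (training) list(B = B) else NULL

  A0 <- matrix(as.vector(t(X)), ncol = 1L)       # (B*side^2) x 1
  cp1 <- .get_plan(net, paste0("c1_", B),
                   function() .conv_plan(side, side, B))
  cv1 <- .conv_forward(A0, cp1, p$W1, p$b1, 1L)
  R1 <- pmax(cv1$Z, 0)
  b1 <- .bn_forward(R1, p$g1, p$be1, bn$rm1, bn$rv1, training)

  s2 <- side - 2L
  cp2 <- .get_plan(net, paste0("c2_", B),
                   function() .conv_plan(s2, s2, B))
  cv2 <- .conv_forward(b1$out, cp2, p$W2, p$b2, 64L)
  R2 <- pmax(cv2$Z, 0)
  b2 <- .bn_forward(R2, p$g2, p$be2, bn$rm2, bn$rv2, training)

  s3 <- s2 - 2L
  cp3 <- .get_plan(net, paste0("c3_", B),
                   function() .conv_plan(s3, s3, B))
  cv3 <- .conv_forward(b2$out, cp3, p$W3, p$b3, 64L)
  R3 <- pmax(cv3$Z, 0)
  b3 <- .bn_forward(R3, p$g3, p$be3, bn$rm3, bn$rv3, training)

  s4 <- s3 - 2L
  pp <- .get_plan(net, paste0("pool_", B),
                  function() .pool_plan(s4, s4, B))
  M <- b3$out[pp$members[[1L]], , drop = FALSE]
  amax <- matrix(1L, nrow(M), ncol(M))
  for (k in 2:4) {
    cand <- b3$out[pp$members[[k]], , drop = FALSE]
    upd <- cand > M
    M[upd] <- cand[upd]
    amax[upd] <- k
  }
  # flatten (P, B, C) -> B x (P*C)
  Fl <- M
  dim(Fl) <- c(pp$P, B, 64L)
  Fl <- aperm(Fl, c(2L, 1L, 3L))
  dim(Fl) <- c(B, pp$P * 64L)

  D1 <- Fl %*% p$W4 + .bcast(p$b4, B)            # linear dense
  logits <- D1 %*% p$W5 + .bcast(p$b5, B)
  mx <- apply(logits, 1L, max)
  e <- exp(logits - mx)
  probs <- e / rowSums(e)

  if (training) {
    cache <- list(B = B, A0 = A0,
                  cv1 = cv1, R1mask = cv1$Z > 0, b1 = b1, cp1 = cp1,
                  cv2 = cv2, R2mask = cv2$Z > 0, b2 = b2, cp2 = cp2,
                  cv3 = cv3, R3mask = cv3$Z > 0, b3 = b3, cp3 = cp3,
                  pp = pp, amax = amax, Fl = Fl, D1 = D1,
                  bn_new = list(rm1 = b1$rm, rv1 = b1$rv,
                                rm2 = b2$rm, rv2 = b2$rv,
                                rm3 = b3$rm, rv3 = b3$rv))
  }
  list(probs = probs, cache = cache)
}

# ---- backward pass: gradients of mean cross-entropy ----

.nn_backward <- function(net, cache, probs, Y) {
  p <- net$params
  B <- cache$B
  g <- list()

  dLogit <- (probs - Y) / B
  g$W5 <- crossprod(cache$D1, dLogit)
  g$b5 <- colSums(dLogit)
  dD1 <- tcrossprod(dLogit, p$W5)
  g$W4 <- crossprod(cache$Fl, dD1)
  g$b4 <- colSums(dD1)
  dFl <- tcrossprod(dD1, p$W4)                   # B x (P*64)

  pp <- cache$pp
  dM <- dFl
  dim(dM) <- c(B, pp$P, 64L)
  dM <- aperm(dM, c(2L, 1L, 3L))                 # back to (P, B, C)
  dim(dM) <- c(pp$P * B, 64L)
  dB3 <- matrix(0, nrow(cache$b3$out), 64L)
  for (k in 1:4) {
    sel <- cache$amax == k
    dMk <- dM * sel
    rk <- pp$members[[k]]
    dB3[rk, ] <- dB3[rk, ] + dMk
  }

  bb3 <- .bn_backward(dB3, cache$b3$xhat, cache$b3$istd, p$g3)
  g$g3 <- bb3$dgamma; g$be3 <- bb3$dbeta
  dZ3 <- bb3$dX * cache$R3mask
  cb3 <- .conv_backward(dZ3, cache$cv3$Cmat, cache$cp3, p$W3, 64L,
                        nrow(cache$b2$out))
  g$W3 <- cb3$dW; g$b3 <- cb3$db

  bb2 <- .bn_backward(cb3$dA, cache$b2$xhat, cache$b2$istd, p$g2)
  g$g2 <- bb2$dgamma; g$be2 <- bb2$dbeta
  dZ2 <- bb2$dX * cache$R2mask
  cb2 <- .conv_backward(dZ2, cache$cv2$Cmat, cache$cp2, p$W2, 64L,
                        nrow(cache$b1$out))
  g$W2 <- cb2$dW; g$b2 <- cb2$db

  bb1 <- .bn_backward(cb2$dA, cache$b1$xhat, cache$b1$istd, p$g1)
  g$g1 <- bb1$dgamma; g$be1 <- bb1$dbeta
  dZ1 <- bb1$dX * cache$R1mask
  cb1 <- .conv_backward(dZ1, cache$cv1$Cmat, cache$cp1, p$W1, 1L,
                        nrow(cache$A0))
  g$W1 <- cb1$dW; g$b1 <- cb1$db

  g
}

.nn_loss <- function(probs, Y) {
  -sum(Y * log(pmax(probs, 1e-12))) / nrow(Y)
}

# ---- Adam ----

.adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

.adam_step <- function(params, grads, adam, lr = 1e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  adam$t <- adam$t + 1L
  c1 <- 1 - beta1^adam$t
  c2 <- 1 - beta2^adam$t
  for (nm in names(grads)) {
    adam$m[[nm]] <- beta1 * adam$m[[nm]] + (1 - beta1) * grads[[nm]]
    adam$v[[nm]] <- beta2 * adam$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (adam$m[[nm]] / c1) / (sqrt(adam$v[[nm]] / c2) + eps)
  }
  list(params = params, adam = adam)
}
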