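# Layer primitives: forward passes paired with hand-derived backward passes.
# Internally every activation is a channels x positions matrix (channel-major),
# so per-channel affine operations use R's native vector recycling instead of
# explicit broadcasting. A forward returns list(out, cache); the matching
# backward consumes (cache, dout) and returns dx plus per-parameter
# gradients. Gradient correctness is checked against central finite
# differences in the test suite.

BN_EPS <- 1e-5
LN_EPS <- 1e-5

## ---- initialisation -------------------------------------------------------

# PyTorch-default linear/conv initialisation: weights Kaiming-uniform with
# a = sqrt(5), i.e. U(-1/sqrt(fan_in), 1/sqrt(fan_in)); biases the same range.
# W is stored fan_out x fan_in (acting on channel-major activations from the
# left).
init_linear <- function(fan_in, fan_out, bias = TRUE) {
  bound <- 1 / sqrt(fan_in)
  W <- matrix(runif(fan_in * fan_out, -bound, bound), fan_out, fan_in)
  if (bias) list(W = W, b = runif(fan_out, -bound, bound)) else list(W = W)
}

## ---- dense / convolution --------------------------------------------------

# X is (Cin x L); W (Cout x Cin); returns (Cout x L)
linear_fw <- function(X, W, b = NULL) {
  Y <- W %*% X
  if (!is.null(b)) Y <- Y + b
  list(out = Y, cache = list(X = X, has_b = !is.null(b)))
}

linear_bw <- function(cache, W, dY) {
  g <- list(W = tcrossprod(dY, cache$X))
  if (cache$has_b) g$b <- rowSums(dY)
  list(dx = crossprod(W, dY), grads = g)
}

# memoised im2col column indices, keyed by (k, L)
.im2col_idx <- new.env(parent = emptyenv())
im2col_idx <- function(k, L) {
  key <- paste0(k, "_", L)
  idx <- .im2col_idx[[key]]
  if (is.null(idx)) {
    idx <- as.vector(outer(seq_len(k), 0L:(L - 1L), "+"))
    .im2col_idx[[key]] <- idx
  }
  idx
}

# im2col for a same-padded 1-d convolution: (Cin x L) -> ((Cin*k) x L),
# taps stacked row-blockwise (tap t = rows (t-1)*Cin+1 .. t*Cin)
conv_im2col <- function(X, k) {
  L <- ncol(X); Cin <- nrow(X); pad <- (k - 1L) %/% 2L
  Xp <- cbind(matrix(0, Cin, pad), X, matrix(0, Cin, pad))
  matrix(Xp[, im2col_idx(k, L)], Cin * k, L)
}

# W is Cout x (Cin*k); width-1 convolutions skip the gather entirely
conv1d_fw <- function(X, W, b, k) {
  Xc <- if (k == 1L) X else conv_im2col(X, k)
  Y <- W %*% Xc + b
  list(out = Y, cache = list(Xc = Xc, k = k, Cin = nrow(X), L = ncol(X)))
}

conv1d_bw <- function(cache, W, dY) {
  k <- cache$k; Cin <- cache$Cin; L <- cache$L
  dW <- tcrossprod(dY, cache$Xc)
  db <- rowSums(dY)
  dXc <- crossprod(W, dY)          # (Cin*k) x L
  if (k == 1L) return(list(dx = dXc, grads = list(W = dW, b = db)))
  pad <- (k - 1L) %/% 2L
  dXp <- matrix(0, Cin, L + 2L * pad)
  for (t in seq_len(k)) {
    cols <- t:(t + L - 1L)
    dXp[, cols] <- dXp[, cols] + dXc[((t - 1L) * Cin + 1L):(t * Cin), , drop = FALSE]
  }
  list(dx = dXp[, (pad + 1L):(pad + L), drop = FALSE],
       grads = list(W = dW, b = db))
}

## ---- normalisation --------------------------------------------------------

# Channel-wise normalisation over positions. With the batch size of 1 used
# throughout the training recipe, statistics over batch x position reduce to
# statistics over position; the same statistics are used at evaluation time,
# so there are no running buffers and inference is deterministic.
batchnorm_fw <- function(X, gamma, beta) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * istd
  Y <- xhat * gamma + beta
  list(out = Y, cache = list(xhat = xhat, istd = istd))
}

batchnorm_bw <- function(cache, gamma, dY) {
  xhat <- cache$xhat
  dgamma <- rowSums(dY * xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * gamma
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * cache$istd
  list(dx = dX, grads = list(gamma = dgamma, beta = dbeta))
}

# per-position normalisation over channels (columns are positions)
layernorm_fw <- function(X, gamma, beta) {
  mu <- colMeans(X)
  xc <- sweep(X, 2L, mu)
  v <- colMeans(xc * xc)
  istd <- 1 / sqrt(v + LN_EPS)
  xhat <- sweep(xc, 2L, istd, "*")
  Y <- xhat * gamma + beta
  list(out = Y, cache = list(xhat = xhat, istd = istd))
}

layernorm_bw <- function(cache, gamma, dY) {
  xhat <- cache$xhat
  dgamma <- rowSums(dY * xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * gamma
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dX <- sweep(sweep(dxhat, 2L, m1) - sweep(xhat, 2L, m2, "*"),
              2L, cache$istd, "*")
  list(dx = dX, grads = list(gamma = dgamma, beta = dbeta))
}

## ---- elementwise ----------------------------------------------------------

gelu_fw <- function(X) {
  Phi <- pnorm(X)
  list(out = X * Phi, cache = list(X = X, Phi = Phi))
}
gelu_bw <- function(cache, dY) dY * (cache$Phi + cache$X * dnorm(cache$X))

relu_fw <- function(X) list(out = pmax(X, 0), cache = X > 0)
relu_bw <- function(cache, dY) dY * cache

softplus_fw <- function(X) list(out = softplus(X), cache = X)
softplus_bw <- function(cache, dY) dY * sigmoid(cache)

dropout_fw <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, cache = NULL))
  mask <- matrix((runif(length(X)) >= rate) / (1 - rate), nrow(X), ncol(X))
  list(out = X * mask, cache = mask)
}

dropout_bw <- function(cache, dY) if (is.null(cache)) dY else dY * cache

## ---- attention (softmax) pooling ------------------------------------------

# Two-fold pooling where, per channel, the two positions in a window are
# combined with softmax weights derived from a learned linear map of the
# inputs (initialised at 2 * identity, i.e. a soft approximation to max
# pooling that can relax towards mean pooling). X is (C x L), L even.
# Adjacent column pairs of the (C x L) column-major matrix are contiguous,
# so the pair split is a free reshape to (2C x L/2): rows 1..C are the first
# position of each window, rows C+1..2C the second.
attnpool_fw <- function(X, Wl) {
  C <- nrow(X); L <- ncol(X)
  stopifnot(L %% 2L == 0L)
  logits <- Wl %*% X
  dim(X) <- c(2L * C, L %/% 2L)
  dim(logits) <- c(2L * C, L %/% 2L)
  iA <- seq_len(C); iB <- (C + 1L):(2L * C)
  A <- X[iA, , drop = FALSE]; B <- X[iB, , drop = FALSE]
  la <- logits[iA, , drop = FALSE]; lb <- logits[iB, , drop = FALSE]
  m <- pmax(la, lb)
  wa <- exp(la - m); wb <- exp(lb - m)
  s <- wa + wb
  pa <- wa / s; pb <- wb / s
  Y <- pa * A + pb * B
  dim(X) <- c(C, L)
  list(out = Y, cache = list(X = X, A = A, B = B, pa = pa, pb = pb))
}

attnpool_bw <- function(cache, Wl, dY) {
  pa <- cache$pa; pb <- cache$pb
  dA <- pa * dY; dB <- pb * dY
  dpa <- cache$A * dY; dpb <- cache$B * dY
  dot <- pa * dpa + pb * dpb
  dla <- pa * (dpa - dot)
  dlb <- pb * (dpb - dot)
  C <- nrow(cache$X); L <- ncol(cache$X)
  dlogits <- rbind(dla, dlb)
  dim(dlogits) <- c(C, L)
  dX <- rbind(dA, dB)
  dim(dX) <- c(C, L)
  dX <- dX + crossprod(Wl, dlogits)
  list(dx = dX, grads = list(W = tcrossprod(dlogits, cache$X)))
}

## ---- relative-position features -------------------------------------------

# Fixed basis of relative-position features over distances -(L-1)..(L-1):
# three symmetric families (exponential decay at geometrically spaced
# half-lives, central masks of doubling width, gamma densities tiling the
# range), each then paired with its sign-antisymmetric copy. F must be
# divisible by 6. Returned as (2L-1) x F.
positional_features <- function(L, F) {
  d <- -(L - 1L):(L - 1L)
  ad <- abs(d)
  nb <- F %/% 6L
  seq_length <- L
  half_life <- 2^seq(3, log2(max(seq_length, 9)), length.out = nb)
  fe <- exp(outer(ad, half_life, function(p, h) -log(2) / h * p))
  widths <- 2^seq_len(nb) - 1
  fc <- outer(ad, widths, function(p, w) as.numeric(w > p))
  sdv <- seq_length / (2 * nb)
  mean_g <- seq(seq_length / nb, seq_length, length.out = nb)
  conc <- (mean_g / sdv)^2
  rate <- mean_g / sdv^2
  fg <- sapply(seq_len(nb), function(i) {
    p <- stats::dgamma(ad, shape = conc[i], rate = rate[i]) + 1e-8
    p / max(p)
  })
  sym <- cbind(fe, fc, matrix(fg, nrow = length(ad)))
  cbind(sym, sign(d) * sym)
}

# L x L matrix of indices into the relative-distance axis 1..(2L-1),
# entry (i, j) = j - i + L
rel_index_matrix <- function(L) {
  outer(seq_len(L), seq_len(L), function(i, j) j - i + L)
}

## ---- multi-head attention --------------------------------------------------

# Multi-head self-attention with relative positional information. X is
# (C x L). p carries Wq, Wk ((h*dk) x C), Wv (C x C), optionally Wo/bo,
# per-head content/position biases rw, rr (h x dk), and either Wr
# ((h*dk) x F, "enformer_basis") or relbias ((2L-1) x h,
# "simple_relative_bias"). static carries the precomputed feature matrix R
# ((2L-1) x F) and the distance index matrix. Attention matrices A are
# (L x L) with queries as rows.
mha_fw <- function(X, p, cfg, static) {
  L <- ncol(X); C <- cfg$channels
  h <- cfg$n_heads; dk <- cfg$key_size; dv <- C %/% h
  scale <- 1 / sqrt(dk)
  q <- p$Wq %*% X; k <- p$Wk %*% X; v <- p$Wv %*% X
  basis <- cfg$positional_scheme == "enformer_basis"
  relk <- if (basis) tcrossprod(p$Wr, static$R) else NULL  # (h*dk) x (2L-1)
  idxd <- static$idxd
  gsel <- cbind(as.vector(row(idxd)), as.vector(idxd))
  heads <- vector("list", h)
  O <- matrix(0, C, L)
  for (hh in seq_len(h)) {
    kc <- ((hh - 1L) * dk + 1L):(hh * dk)
    vc <- ((hh - 1L) * dv + 1L):(hh * dv)
    Qh <- q[kc, , drop = FALSE] * scale
    Kh <- k[kc, , drop = FALSE]
    Vh <- v[vc, , drop = FALSE]
    Qw <- Qh + p$rw[hh, ]
    logits <- crossprod(Qw, Kh)            # L x L, queries in rows
    if (basis) {
      Qr <- Qh + p$rr[hh, ]
      relfull <- crossprod(Qr, relk[kc, , drop = FALSE])  # L x (2L-1)
      logits <- logits + matrix(relfull[gsel], L, L)
      heads[[hh]] <- list(Kh = Kh, Vh = Vh, Qw = Qw, Qr = Qr)
    } else {
      logits <- logits + matrix(p$relbias[idxd, hh], L, L)
      heads[[hh]] <- list(Kh = Kh, Vh = Vh, Qw = Qw)
    }
    mx <- apply(logits, 1L, max)
    E <- exp(logits - mx)
    A <- E / rowSums(E)
    heads[[hh]]$A <- A
    O[vc, ] <- tcrossprod(Vh, A)
  }
  if (cfg$include_attention_linear) {
    Y <- p$Wo %*% O + p$bo
  } else {
    Y <- O
  }
  list(out = Y, cache = list(X = X, O = O, heads = heads, relk = relk,
                             L = L, scale = scale, gsel = gsel))
}

mha_bw <- function(cache, p, cfg, static, dY) {
  L <- cache$L; C <- cfg$channels
  h <- cfg$n_heads; dk <- cfg$key_size; dv <- C %/% h
  basis <- cfg$positional_scheme == "enformer_basis"
  idxd <- static$idxd
  gsel <- cache$gsel
  g <- list()
  if (cfg$include_attention_linear) {
    g$Wo <- tcrossprod(dY, cache$O)
    g$bo <- rowSums(dY)
    dO <- crossprod(p$Wo, dY)
  } else {
    dO <- dY
  }
  dq <- matrix(0, h * dk, L); dkm <- matrix(0, h * dk, L); dvm <- matrix(0, C, L)
  g$rw <- matrix(0, h, dk)
  if (basis) {
    g$rr <- matrix(0, h, dk)
    drelk <- matrix(0, h * dk, 2L * L - 1L)
  } else {
    g$relbias <- matrix(0, 2L * L - 1L, h)
  }
  for (hh in seq_len(h)) {
    kc <- ((hh - 1L) * dk + 1L):(hh * dk)
    vc <- ((hh - 1L) * dv + 1L):(hh * dv)
    hd <- cache$heads[[hh]]
    A <- hd$A
    dOh <- dO[vc, , drop = FALSE]
    # O_h = Vh %*% t(A)
    dA <- crossprod(dOh, hd$Vh)            # L x L
    dvm[vc, ] <- dOh %*% A
    dlog <- A * (dA - rowSums(A * dA))
    # content term: logits_c = t(Qw) %*% Kh
    dQw <- hd$Kh %*% t(dlog)               # dk x L
    dkm[kc, ] <- hd$Qw %*% dlog
    g$rw[hh, ] <- rowSums(dQw)
    dQh <- dQw
    if (basis) {
      drelfull <- matrix(0, L, 2L * L - 1L)
      drelfull[gsel] <- as.vector(dlog)
      relk_h <- cache$relk[kc, , drop = FALSE]
      dQr <- relk_h %*% t(drelfull)        # dk x L
      drelk[kc, ] <- hd$Qr %*% drelfull
      g$rr[hh, ] <- rowSums(dQr)
      dQh <- dQh + dQr
    } else {
      dfull <- matrix(0, L, 2L * L - 1L)
      dfull[gsel] <- as.vector(dlog)
      g$relbias[, hh] <- colSums(dfull)
    }
    dq[kc, ] <- dQh * cache$scale
  }
  if (basis) g$Wr <- drelk %*% static$R
  dX <- crossprod(p$Wq, dq) + crossprod(p$Wk, dkm) + crossprod(p$Wv, dvm)
  g$Wq <- tcrossprod(dq, cache$X)
  g$Wk <- tcrossprod(dkm, cache$X)
  g$Wv <- tcrossprod(dvm, cache$X)
  list(dx = dX, grads = g)
}
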