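# Plain-R forward/backward passes for the U-Net and transformer surrogate
# architectures.  These run per sequence in double precision; the heavily
# used FCN path has its own single-precision compute core in src/nn.cpp.
# All gradients here are checked against finite differences in the tests.

conv_r_fwd <- function(X, Wk, b, k) {
  din <- ncol(X); L <- nrow(X); pad <- (k - 1L) %/% 2L
  Y <- matrix(0, L, ncol(Wk))
  for (t in seq_len(k)) {
    o <- t - 1L - pad
    r0 <- max(1L, 1L - o); r1 <- min(L, L - o)
    if (r0 > r1) next
    Y[r0:r1, ] <- Y[r0:r1, ] +
      X[(r0 + o):(r1 + o), , drop = FALSE] %*%
      Wk[((t - 1L) * din + 1L):(t * din), , drop = FALSE]
  }
  sweep(Y, 2L, b, "+")
}

conv_r_bwd <- function(X, dY, Wk, k) {
  din <- ncol(X); L <- nrow(X); pad <- (k - 1L) %/% 2L
  dX <- matrix(0, L, din)
  gW <- matrix(0, nrow(Wk), ncol(Wk))
  for (t in seq_len(k)) {
    o <- t - 1L - pad
    r0 <- max(1L, 1L - o); r1 <- min(L, L - o)
    if (r0 > r1) next
    rows_in <- (r0 + o):(r1 + o)
    blk <- ((t - 1L) * din + 1L):(t * din)
    gW[blk, ] <- t(X[rows_in, , drop = FALSE]) %*% dY[r0:r1, , drop = FALSE]
    dX[rows_in, ] <- dX[rows_in, ] +
      dY[r0:r1, , drop = FALSE] %*% t(Wk[blk, , drop = FALSE])
  }
  list(dX = dX, gW = gW, gb = colSums(dY))
}

relu_r <- function(X) { X[X < 0] <- 0; X }

avgpool2_fwd <- function(X) {
  L <- nrow(X)
  (X[seq(1L, L, 2L), , drop = FALSE] + X[seq(2L, L, 2L), , drop = FALSE]) / 2
}
avgpool2_bwd <- function(dY, L) {
  dX <- matrix(0, L, ncol(dY))
  dX[seq(1L, L, 2L), ] <- dY / 2
  dX[seq(2L, L, 2L), ] <- dY / 2
  dX
}
upsample2_fwd <- function(X) X[rep(seq_len(nrow(X)), each = 2L), , drop = FALSE]
upsample2_bwd <- function(dY) {
  L2 <- nrow(dY)
  dY[seq(1L, L2, 2L), , drop = FALSE] + dY[seq(2L, L2, 2L), , drop = FALSE]
}

unet_len <- function(max_len, n_down = 3L) {
  f <- 2L^n_down
  as.integer(ceiling(max_len / f) * f)
}

# ---- U-Net ----------------------------------------------------------------

unet_fwd <- function(toks, params, cfg, keep_cache = FALSE) {
  k <- cfg$kernel
  Lu <- unet_len(cfg$max_len, cfg$unet_depth[1])
  toks <- c(toks, rep(6L, Lu - length(toks)))
  A <- params$E[toks, , drop = FALSE]
  cache <- list(toks = toks, A0 = A)
  skips <- list(); down_in <- list(); down_out <- list()
  for (s in seq_len(cfg$unet_depth[1])) {
    down_in[[s]] <- A
    C <- relu_r(conv_r_fwd(A, params[[sprintf("down%d_W", s)]],
                           params[[sprintf("down%d_b", s)]], k))
    down_out[[s]] <- C
    skips[[s]] <- C
    A <- avgpool2_fwd(C)
  }
  mid_in <- list()
  for (m in seq_len(cfg$unet_depth[2])) {
    mid_in[[m]] <- A
    A <- relu_r(conv_r_fwd(A, params[[sprintf("mid%d_W", m)]],
                           params[[sprintf("mid%d_b", m)]], k))
    cache[[sprintf("mid%d_out", m)]] <- if (keep_cache) A else NULL
  }
  up_in <- list(); up_out <- list()
  for (s in rev(seq_len(cfg$unet_depth[3]))) {
    U <- upsample2_fwd(A)
    cat_in <- cbind(U, skips[[s]])
    up_in[[s]] <- cat_in
    A <- relu_r(conv_r_fwd(cat_in, params[[sprintf("up%d_W", s)]],
                           params[[sprintf("up%d_b", s)]], k))
    up_out[[s]] <- A
  }
  pred <- drop(A %*% params$head_w) + params$head_b
  if (!keep_cache) return(pred[seq_len(cfg$max_len)])
  cache$down_in <- down_in; cache$down_out <- down_out
  cache$mid_in <- mid_in; cache$up_in <- up_in; cache$up_out <- up_out
  cache$final <- A
  list(pred = pred[seq_len(cfg$max_len)], cache = cache)
}

unet_bwd <- function(dpred, params, cfg, cache) {
  k <- cfg$kernel
  Lu <- unet_len(cfg$max_len, cfg$unet_depth[1])
  g <- list()
  dp <- c(dpred, rep(0, Lu - length(dpred)))
  g$head_w <- t(cache$final) %*% dp
  g$head_b <- sum(dp)
  dA <- dp %*% t(params$head_w)
  for (s in seq_len(cfg$unet_depth[3])) {
    dA[cache$up_out[[s]] <= 0] <- 0
    bw <- conv_r_bwd(cache$up_in[[s]], dA, params[[sprintf("up%d_W", s)]], k)
    g[[sprintf("up%d_W", s)]] <- bw$gW
    g[[sprintf("up%d_b", s)]] <- bw$gb
    d <- cfg$embed_dim
    dU <- bw$dX[, seq_len(d), drop = FALSE]
    dskip <- bw$dX[, d + seq_len(d), drop = FALSE]
    dA <- upsample2_bwd(dU)
    cache[[sprintf("skip%d_grad", s)]] <- dskip
  }
  for (m in rev(seq_len(cfg$unet_depth[2]))) {
    dA[cache[[sprintf("mid%d_out", m)]] <= 0] <- 0
    bw <- conv_r_bwd(cache$mid_in[[m]], dA, params[[sprintf("mid%d_W", m)]], k)
    g[[sprintf("mid%d_W", m)]] <- bw$gW
    g[[sprintf("mid%d_b", m)]] <- bw$gb
    dA <- bw$dX
  }
  for (s in rev(seq_len(cfg$unet_depth[1]))) {
    dC <- avgpool2_bwd(dA, nrow(cache$down_out[[s]])) +
      cache[[sprintf("skip%d_grad", s)]]
    dC[cache$down_out[[s]] <= 0] <- 0
    bw <- conv_r_bwd(cache$down_in[[s]], dC,
                     params[[sprintf("down%d_W", s)]], k)
    g[[sprintf("down%d_W", s)]] <- bw$gW
    g[[sprintf("down%d_b", s)]] <- bw$gb
    dA <- bw$dX
  }
  gE <- matrix(0, 6L, cfg$embed_dim)
  for (v in 1:6) {
    rows <- cache$toks == v
    if (any(rows)) gE[v, ] <- colSums(dA[rows, , drop = FALSE])
  }
  g$E <- gE
  g
}

# ---- transformer ----------------------------------------------------------

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  sd <- sqrt(rowMeans(Xc^2) + eps)
  Xh <- Xc / sd
  list(Y = sweep(Xh, 2L, g, "*") + matrix(b, nrow(X), length(b), byrow = TRUE),
       Xh = Xh, sd = sd)
}
layernorm_bwd <- function(dY, g, cache) {
  Xh <- cache$Xh
  dg <- colSums(dY * Xh)
  db <- colSums(dY)
  dyg <- sweep(dY, 2L, g, "*")
  m1 <- rowMeans(dyg)
  m2 <- rowMeans(dyg * Xh)
  dX <- (dyg - m1 - Xh * m2) / cache$sd
  list(dX = dX, dg = dg, db = db)
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

transformer_fwd <- function(toks, params, cfg, keep_cache = FALSE) {
  d <- cfg$embed_dim; H <- cfg$n_heads; dh <- d %/% H
  # accepts truncated inputs: padding keys are masked out of attention, so
  # rows beyond the last real residue never reach a valid output
  L <- length(toks)
  X <- params$E[toks, , drop = FALSE] + params$pos[seq_len(L), , drop = FALSE]
  padkey <- toks == 6L
  cache <- list(toks = toks, blocks = list())
  for (i in seq_len(cfg$n_layers)) {
    nm <- function(s) sprintf("blk%d_%s", i, s)
    bc <- list(X_in = X)
    ln1 <- layernorm_fwd(X, params[[nm("ln1_g")]], params[[nm("ln1_b")]])
    bc$ln1 <- ln1
    Q <- ln1$Y %*% params[[nm("Wq")]]
    K <- ln1$Y %*% params[[nm("Wk")]]
    V <- ln1$Y %*% params[[nm("Wv")]]
    O <- matrix(0, nrow(X), d)
    bc$heads <- vector("list", H)
    for (h in seq_len(H)) {
      idx <- (h - 1L) * dh + seq_len(dh)
      S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) / sqrt(dh)
      if (any(padkey)) S[, padkey] <- -1e30
      A <- softmax_rows(S)
      O[, idx] <- A %*% V[, idx, drop = FALSE]
      bc$heads[[h]] <- if (keep_cache) list(A = A) else NULL
    }
    attn <- O %*% params[[nm("Wo")]] +
      matrix(params[[nm("bo")]], nrow(X), d, byrow = TRUE)
    X <- X + attn
    bc$Q <- Q; bc$K <- K; bc$V <- V; bc$O <- O; bc$X_mid <- X
    ln2 <- layernorm_fwd(X, params[[nm("ln2_g")]], params[[nm("ln2_b")]])
    bc$ln2 <- ln2
    Hf <- ln2$Y %*% params[[nm("W1")]]
    Hf <- relu_r(sweep(Hf, 2L, params[[nm("b1")]], "+"))
    bc$Hf <- Hf
    Ff <- Hf %*% params[[nm("W2")]] +
      matrix(params[[nm("b2")]], nrow(X), d, byrow = TRUE)
    X <- X + Ff
    if (keep_cache) cache$blocks[[i]] <- bc
  }
  lnf <- layernorm_fwd(X, params$lnf_g, params$lnf_b)
  pred <- drop(lnf$Y %*% params$head_w) + params$head_b
  if (!keep_cache) return(pred)
  cache$lnf <- lnf; cache$X_last <- X; cache$padkey <- padkey
  list(pred = pred, cache = cache)
}

transformer_bwd <- function(dpred, params, cfg, cache) {
  d <- cfg$embed_dim; H <- cfg$n_heads; dh <- d %/% H
  g <- list()
  g$head_w <- t(cache$lnf$Y) %*% dpred
  g$head_b <- sum(dpred)
  dlnf <- dpred %*% t(params$head_w)
  lb <- layernorm_bwd(dlnf, params$lnf_g, cache$lnf)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dX <- lb$dX
  for (i in rev(seq_len(cfg$n_layers))) {
    nm <- function(s) sprintf("blk%d_%s", i, s)
    bc <- cache$blocks[[i]]
    # feed-forward sublayer
    dFf <- dX
    g[[nm("b2")]] <- colSums(dFf)
    g[[nm("W2")]] <- t(bc$Hf) %*% dFf
    dHf <- dFf %*% t(params[[nm("W2")]])
    dHf[bc$Hf <= 0] <- 0
    g[[nm("b1")]] <- colSums(dHf)
    g[[nm("W1")]] <- t(bc$ln2$Y) %*% dHf
    dln2 <- dHf %*% t(params[[nm("W1")]])
    lb2 <- layernorm_bwd(dln2, params[[nm("ln2_g")]], bc$ln2)
    g[[nm("ln2_g")]] <- lb2$dg; g[[nm("ln2_b")]] <- lb2$db
    dX <- dX + lb2$dX          # residual
    # attention sublayer
    dattn <- dX
    g[[nm("bo")]] <- colSums(dattn)
    g[[nm("Wo")]] <- t(bc$O) %*% dattn
    dO <- dattn %*% t(params[[nm("Wo")]])
    dQ <- matrix(0, nrow(dO), d); dK <- dQ; dV <- dQ
    for (h in seq_len(H)) {
      idx <- (h - 1L) * dh + seq_len(dh)
      A <- cache$blocks[[i]]$heads[[h]]$A
      dOh <- dO[, idx, drop = FALSE]
      dA <- dOh %*% t(bc$V[, idx, drop = FALSE])
      dV[, idx] <- t(A) %*% dOh
      dS <- A * (dA - rowSums(dA * A))      # softmax backward
      dS <- dS / sqrt(dh)
      dQ[, idx] <- dS %*% bc$K[, idx, drop = FALSE]
      dK[, idx] <- t(dS) %*% bc$Q[, idx, drop = FALSE]
    }
    g[[nm("Wq")]] <- t(bc$ln1$Y) %*% dQ
    g[[nm("Wk")]] <- t(bc$ln1$Y) %*% dK
    g[[nm("Wv")]] <- t(bc$ln1$Y) %*% dV
    dln1 <- dQ %*% t(params[[nm("Wq")]]) + dK %*% t(params[[nm("Wk")]]) +
      dV %*% t(params[[nm("Wv")]])
    lb1 <- layernorm_bwd(dln1, params[[nm("ln1_g")]], bc$ln1)
    g[[nm("ln1_g")]] <- lb1$dg; g[[nm("ln1_b")]] <- lb1$db
    dX <- dX + lb1$dX          # residual
  }
  g$pos <- rbind(dX, matrix(0, nrow(params$pos) - nrow(dX), ncol(dX)))
  gE <- matrix(0, 6L, d)
  for (v in 1:6) {
    rows <- cache$toks == v
    if (any(rows)) gE[v, ] <- colSums(dX[rows, , drop = FALSE])
  }
  g$E <- gE
  g
}

# ---- shared batch drivers -------------------------------------------------

r_predict_batch <- function(arch, tokens_mat, params, cfg) {
  B <- ncol(tokens_mat)
  fwd <- if (arch == "unet") unet_fwd else transformer_fwd
  n_out <- if (arch == "unet") cfg$max_len else nrow(tokens_mat)
  preds <- matrix(0, n_out, B)
  for (b in seq_len(B)) preds[seq_len(n_out), b] <-
    fwd(tokens_mat[, b], params, cfg)[seq_len(n_out)]
  preds
}

r_backprop_batch <- function(arch, tokens_mat, params, cfg, targets, mask) {
  B <- ncol(tokens_mat)
  M <- sum(mask)
  if (M <= 0) af_stop("no valid positions in batch")
  fwd <- if (arch == "unet") unet_fwd else transformer_fwd
  bwd <- if (arch == "unet") unet_bwd else transformer_bwd
  grads <- NULL
  loss <- 0
  for (b in seq_len(B)) {
    fc <- fwd(tokens_mat[, b], params, cfg, keep_cache = TRUE)
    err <- (fc$pred - targets[, b]) * mask[, b]
    loss <- loss + sum(err^2 * mask[, b]) / M
    dpred <- matrix(2 * err * mask[, b] / M, ncol = 1L)
    g <- bwd(dpred, params, cfg, fc$cache)
    grads <- if (is.null(grads)) g else
      Map(function(a, b2) a + b2, grads, g[names(grads)])
  }
  list(loss = loss, grads = grads)
}
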