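# Numerical core: forward and backward passes of the dual-branch attention
# network, written against vectorized base-R matrix algebra. Activations
# are stored as 4-d arrays (features, time, channels, batch); the channel
# axis collapses to 1 after the stage-1 spatial filters. All parameter
# gradients are exercised against finite-difference oracles in the tests.

# ---- primitive layers -------------------------------------------------

# temporal convolution, kernel (1 x K), 'same' padding along time.
# X: (Cin, T, C, N); W: (Cout, Cin, K); b: length Cout. Computed in the
# compiled im2col + GEMM kernel; the input gradient is the correlation of
# dY with the in/out-transposed, time-flipped kernel at complementary
# padding.
conv_temporal_fwd <- function(X, W, b) {
  K <- dim(W)[3]
  cpp_conv_t_fwd(X, W, as.numeric(rep_len(b, dim(W)[1])), (K - 1L) %/% 2L)
}

conv_temporal_bwd <- function(dY, X, W, need_dx = TRUE) {
  K <- dim(W)[3]
  out <- cpp_conv_t_bwd(dY, X, W, (K - 1L) %/% 2L, need_dx)
  list(dX = out$dX, dW = out$dW, db = as.numeric(out$db))
}

# spatial depthwise convolution over the channel axis, 'valid': collapses
# C to 1 with depth multiplier D. X: (F1, T, C, N); W: (C, F1, D).
dw_spatial_fwd <- function(X, W) {
  cpp_dws_fwd(X, W)
}

dw_spatial_bwd <- function(dY, X, W) {
  cpp_dws_bwd(dY, X, W)
}

# separable temporal convolution: depthwise (1 x K) then pointwise.
# X: (Fin, T, 1, N); Wd: (Fin, K); Wp: (Fout, Fin); b: length Fout.
sep_conv_fwd <- function(X, Wd, Wp, b) {
  d <- dim(X); Fin <- d[1]; Tt <- d[2]; N <- d[4]
  Z <- cpp_dwt_fwd(X, Wd, (ncol(Wd) - 1L) %/% 2L)
  Ym <- Wp %*% matrix(Z, Fin, Tt * N) + b
  dim(Ym) <- c(nrow(Wp), Tt, 1L, N)
  list(Y = Ym, Z = Z)
}

sep_conv_bwd <- function(dY, X, Z, Wd, Wp) {
  d <- dim(X); Fin <- d[1]; Tt <- d[2]; N <- d[4]
  Fout <- nrow(Wp)
  dYm <- matrix(dY, Fout, Tt * N)
  Zm <- matrix(Z, Fin, Tt * N)
  dWp <- tcrossprod(dYm, Zm)
  db <- rowSums(dYm)
  dZ <- crossprod(Wp, dYm)
  dim(dZ) <- c(Fin, Tt, 1L, N)
  dd <- cpp_dwt_bwd(dZ, X, Wd, (ncol(Wd) - 1L) %/% 2L)
  list(dX = dd$dX, dWd = dd$dWd, dWp = dWp, db = db)
}

# batch normalisation over the leading (feature) axis (compiled, fused).
# Frozen layers (and eval mode) normalise with the stored running
# statistics and never update them.
bn_fwd <- function(X, p, mode, frozen, momentum = 0.9, eps = 1e-3) {
  use_batch <- (mode == "train") && !frozen
  r <- cpp_bn_fwd(X, p$g, p$b, p$rm, p$rv, momentum, eps, use_batch)
  if (use_batch) {
    p$rm <- as.numeric(r$rm)
    p$rv <- as.numeric(r$rv)
  }
  list(Y = r$Y, p = p,
       cache = list(x = X, mu = r$mu, istd = r$istd, use_batch = use_batch))
}

bn_bwd <- function(dY, p, cache) {
  r <- cpp_bn_bwd(dY, cache$x, p$g, cache$mu, cache$istd, cache$use_batch)
  list(dX = r$dX, dg = as.numeric(r$dg), db = as.numeric(r$db))
}

# ELU (alpha = 1): y = x for x > 0, exp(x) - 1 otherwise.
elu_fwd <- function(X) {
  list(Y = cpp_elu_fwd(X))
}

elu_bwd <- function(dY, cache) {
  cpp_elu_bwd(dY, cache$Y)
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

dropout_fwd <- function(X, rate, mode) {
  if (mode != "train" || rate <= 0) return(list(Y = X, mask = NULL))
  mask <- array((stats::runif(length(X)) >= rate) / (1 - rate), dim(X))
  list(Y = X * mask, mask = mask)
}

# average pooling (1 x P) along time; trims an incomplete trailing window.
pool_fwd <- function(X, P) {
  d <- dim(X); Ff <- d[1]; Tt <- d[2]; N <- d[4]
  T2 <- Tt %/% P
  arr <- array(X[, seq_len(P * T2), 1L, , drop = FALSE], c(Ff, P, T2, N))
  Y <- array(0, c(Ff, T2, 1L, N))
  for (p in seq_len(P)) Y <- Y + array(arr[, p, , , drop = FALSE], c(Ff, T2, 1L, N))
  Y / P
}

pool_bwd <- function(dY, P, Tt) {
  d <- dim(dY); Ff <- d[1]; T2 <- d[2]; N <- d[4]
  dX <- array(0, c(Ff, Tt, 1L, N))
  g <- dY / P
  for (p in seq_len(P)) {
    dX[, p + P * (seq_len(T2) - 1L), 1L, ] <- g
  }
  dX
}

# ---- attention block --------------------------------------------------
# Spatial attention (mean/max over features -> (1 x Ks) conv -> norm ->
# sigmoid gate over time) followed by channel attention (global average and
# max descriptors -> per-path two-layer MLPs -> summed sigmoid gate over
# features).
att_fwd <- function(Z, pp, mode, frozen_bn) {
  d <- dim(Z); M <- d[1]; Tt <- d[2]; N <- d[4]
  Zm <- matrix(Z, M, Tt * N)
  smean <- colMeans(Zm)
  sidx <- max.col(t(Zm), ties.method = "first")
  smax <- Zm[cbind(sidx, seq_len(Tt * N))]
  S <- array(0, c(2L, Tt, 1L, N))
  S[1L, , 1L, ] <- smean
  S[2L, , 1L, ] <- smax
  G <- conv_temporal_fwd(S, pp$sa_conv$W, pp$sa_conv$b)
  bn <- bn_fwd(G, pp$sa_bn, mode, frozen_bn)
  pp$sa_bn <- bn$p
  sg <- sigmoid(bn$Y)
  sgv <- as.vector(sg)
  Z2m <- Zm * rep(sgv, each = M)
  # channel descriptors
  ap <- matrix(aperm(array(Z2m, c(M, Tt, N)), c(2, 1, 3)), Tt, M * N)
  cavg <- matrix(colMeans(ap), M, N)
  cidx <- max.col(t(ap), ties.method = "first")
  cmax <- matrix(ap[cbind(cidx, seq_len(M * N))], M, N)
  havg <- relu(pp$d1a$W %*% cavg + pp$d1a$b)
  aavg <- pp$d2a$W %*% havg + pp$d2a$b
  hmax <- relu(pp$d1m$W %*% cmax + pp$d1m$b)
  amax <- pp$d2m$W %*% hmax + pp$d2m$b
  cg <- sigmoid(aavg + amax)
  G3 <- aperm(array(cg, c(M, N, Tt)), c(1, 3, 2))
  arr2 <- array(Z2m, c(M, Tt, N))
  Y <- arr2 * G3
  dim(Y) <- c(M, Tt, 1L, N)
  list(Y = Y, pp = pp,
       cache = list(Zm = Zm, sidx = sidx, S = S, bn = bn$cache, sg = sgv,
                    Z2m = Z2m, ap = ap, cavg = cavg, cidx = cidx,
                    cmax = cmax, havg = havg, hmax = hmax, cg = cg,
                    G3 = G3, M = M, Tt = Tt, N = N))
}

att_bwd <- function(dY, pp, cache) {
  M <- cache$M; Tt <- cache$Tt; N <- cache$N
  arr2 <- array(cache$Z2m, c(M, Tt, N))
  dYa <- array(dY, c(M, Tt, N))
  dZ2 <- dYa * cache$G3                                   # via product
  dcg <- matrix(colSums(matrix(aperm(dYa * arr2, c(2, 1, 3)), Tt, M * N)), M, N)
  dsum <- dcg * cache$cg * (1 - cache$cg)
  # avg path
  dW2a <- dsum %*% t(cache$havg); db2a <- rowSums(dsum)
  dhavg <- t(pp$d2a$W) %*% dsum
  dhavg[cache$havg <= 0] <- 0
  dW1a <- dhavg %*% t(cache$cavg); db1a <- rowSums(dhavg)
  dcavg <- t(pp$d1a$W) %*% dhavg
  # max path
  dW2m <- dsum %*% t(cache$hmax); db2m <- rowSums(dsum)
  dhmax <- t(pp$d2m$W) %*% dsum
  dhmax[cache$hmax <= 0] <- 0
  dW1m <- dhmax %*% t(cache$cmax); db1m <- rowSums(dhmax)
  dcmax <- t(pp$d1m$W) %*% dhmax
  # descriptors -> Z2
  dZ2 <- matrix(dZ2, M, Tt * N)
  dap <- matrix(0, Tt, M * N)
  dap[cbind(cache$cidx, seq_len(M * N))] <- as.vector(dcmax)
  dap <- dap + matrix(rep(as.vector(dcavg) / Tt, each = Tt), Tt, M * N)
  dZ2 <- dZ2 + matrix(aperm(array(dap, c(Tt, M, N)), c(2, 1, 3)), M, Tt * N)
  # spatial gate
  dsgv <- colSums(dZ2 * cache$Zm)
  dZm <- dZ2 * rep(cache$sg, each = M)
  dGbn <- dsgv * cache$sg * (1 - cache$sg)
  dim(dGbn) <- c(1L, Tt, 1L, N)
  bnb <- bn_bwd(dGbn, pp$sa_bn, cache$bn)
  cvb <- conv_temporal_bwd(bnb$dX, cache$S, pp$sa_conv$W)
  dS <- cvb$dX
  dZm <- dZm + rep(as.vector(dS[1L, , 1L, ]) / M, each = M)
  dsm <- matrix(0, M, Tt * N)
  dsm[cbind(cache$sidx, seq_len(Tt * N))] <- as.vector(dS[2L, , 1L, ])
  dZm <- dZm + dsm
  dim(dZm) <- c(M, Tt, 1L, N)
  list(dZ = dZm,
       grads = list(
         sa_conv = list(W = cvb$dW, b = cvb$db),
         sa_bn = list(g = bnb$dg, b = bnb$db),
         d1a = list(W = dW1a, b = db1a), d2a = list(W = dW2a, b = db2a),
         d1m = list(W = dW1m, b = db1m), d2m = list(W = dW2m, b = db2m)))
}

# ---- parameter initialisation ----------------------------------------

glorot <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

bn_init <- function(nf) list(g = rep(1, nf), b = rep(0, nf),
                             rm = rep(0, nf), rv = rep(1, nf))

dense_init <- function(n_out, n_in) {
  list(W = glorot(c(n_out, n_in), n_in, n_out), b = rep(0, n_out))
}

init_params <- function(arch, seed) {
  a <- arch
  with_local_seed(seed, {
    p <- list()
    p[["2"]] <- list(W = glorot(c(a$F1, 1, a$K1), a$K1, a$F1),
                     b = rep(0, a$F1))
    p[["3"]] <- bn_init(a$F1)
    p[["7"]] <- list(W = glorot(c(a$C, a$F1, a$D), a$C, a$D))
    p[["8"]] <- bn_init(a$FD)
    p[["11"]] <- list(W = rep(1, a$F2))     # degenerate 1x1 depthwise: per-map gain
    p[["12"]] <- bn_init(a$F2)
    p[["18"]] <- list(Wd = glorot(c(a$F1, a$KE2), a$KE2, 1),
                      Wp = glorot(c(a$FD, a$F1), a$F1, a$FD),
                      b = rep(0, a$FD))
    p[["19"]] <- bn_init(a$FD)
    p[["22"]] <- list(Wd = glorot(c(a$F2, a$KE2b), a$KE2b, 1),
                      Wp = glorot(c(a$F2, a$F2), a$F2, a$F2),
                      b = rep(0, a$F2))
    p[["23"]] <- bn_init(a$F2)
    p[["32"]] <- list(W = glorot(c(1, 2, a$Ks), 2 * a$Ks, 1), b = 0)
    p[["33"]] <- bn_init(1L)
    p[["39"]] <- dense_init(a$H1, a$M1)
    p[["41"]] <- dense_init(a$M1, a$H1)
    p[["43"]] <- dense_init(a$H1, a$M1)
    p[["45"]] <- dense_init(a$M1, a$H1)
    p[["50"]] <- list(W = glorot(c(a$F2, a$M1, 1), a$M1, a$F2),
                      b = rep(0, a$F2))
    p[["51"]] <- bn_init(a$F2)
    p[["52"]] <- list(W = glorot(c(a$F2, a$F2, a$K2), a$F2 * a$K2, a$F2),
                      b = rep(0, a$F2))
    p[["53"]] <- bn_init(a$F2)
    p[["59"]] <- list(W = glorot(c(1, 2, a$Ks), 2 * a$Ks, 1), b = 0)
    p[["60"]] <- bn_init(1L)
    p[["65"]] <- dense_init(a$H2, a$M2)
    p[["67"]] <- dense_init(a$M2, a$H2)
    p[["69"]] <- dense_init(a$H2, a$M2)
    p[["71"]] <- dense_init(a$M2, a$H2)
    p[["77"]] <- dense_init(a$n_classes, a$M2 * a$T2)
    p
  })
}

att_param_view <- function(p, idx) {
  list(sa_conv = p[[as.character(idx[1])]], sa_bn = p[[as.character(idx[2])]],
       d1a = p[[as.character(idx[3])]], d2a = p[[as.character(idx[4])]],
       d1m = p[[as.character(idx[5])]], d2m = p[[as.character(idx[6])]])
}

ATT1_IDX <- c(32L, 33L, 39L, 41L, 43L, 45L)
ATT2_IDX <- c(59L, 60L, 65L, 67L, 69L, 71L)

# ---- full network forward / backward ---------------------------------

net_forward <- function(model, X, mode = "eval", keep = FALSE) {
  a <- model$arch
  p <- model$params
  fz <- model$registry$frozen
  frozen <- function(i) fz[i]
  dropout_rate <- model$dropout_rate
  cc <- list()

  a1 <- conv_temporal_fwd(X, p[["2"]]$W, p[["2"]]$b)
  b3 <- bn_fwd(a1, p[["3"]], mode, frozen(3)); p[["3"]] <- b3$p
  # branch A (spatial filters)
  u1 <- dw_spatial_fwd(b3$Y, p[["7"]]$W)
  b8 <- bn_fwd(u1, p[["8"]], mode, frozen(8)); p[["8"]] <- b8$p
  e9 <- elu_fwd(b8$Y)
  d10 <- dropout_fwd(e9$Y, dropout_rate, mode)
  # branch B (channel mean + separable)
  v1 <- cpp_chmean_fwd(b3$Y)
  s18 <- sep_conv_fwd(v1, p[["18"]]$Wd, p[["18"]]$Wp, p[["18"]]$b)
  b19 <- bn_fwd(s18$Y, p[["19"]], mode, frozen(19)); p[["19"]] <- b19$p
  e20 <- elu_fwd(b19$Y)
  d21 <- dropout_fwd(e20$Y, dropout_rate, mode)
  # concat 1
  N <- dim(X)[4]
  z1 <- array(0, c(a$M1, a$T, 1L, N))
  z1[seq_len(a$FD), , , ] <- d10$Y
  z1[a$FD + seq_len(a$FD), , , ] <- d21$Y
  at1 <- att_fwd(z1, att_param_view(p, ATT1_IDX), mode, frozen(33))
  p[["33"]] <- at1$pp$sa_bn
  # projection + stage-2 temporal conv
  w50 <- conv_temporal_fwd(at1$Y, p[["50"]]$W, p[["50"]]$b)
  b51 <- bn_fwd(w50, p[["51"]], mode, frozen(51)); p[["51"]] <- b51$p
  t52 <- conv_temporal_fwd(b51$Y, p[["52"]]$W, p[["52"]]$b)
  b53 <- bn_fwd(t52, p[["53"]], mode, frozen(53)); p[["53"]] <- b53$p
  # stage-2 branch A: per-map gain
  g11 <- p[["11"]]$W * b53$Y
  b12 <- bn_fwd(g11, p[["12"]], mode, frozen(12)); p[["12"]] <- b12$p
  e13 <- elu_fwd(b12$Y)
  p14 <- pool_fwd(e13$Y, a$pool)
  d15 <- dropout_fwd(p14, dropout_rate, mode)
  # stage-2 branch B: separable
  s22 <- sep_conv_fwd(b53$Y, p[["22"]]$Wd, p[["22"]]$Wp, p[["22"]]$b)
  b23 <- bn_fwd(s22$Y, p[["23"]], mode, frozen(23)); p[["23"]] <- b23$p
  e24 <- elu_fwd(b23$Y)
  p25 <- pool_fwd(e24$Y, a$pool)
  d26 <- dropout_fwd(p25, dropout_rate, mode)
  # concat 2 + attention 2
  y1 <- array(0, c(a$M2, a$T2, 1L, N))
  y1[seq_len(a$F2), , , ] <- d15$Y
  y1[a$F2 + seq_len(a$F2), , , ] <- d26$Y
  at2 <- att_fwd(y1, att_param_view(p, ATT2_IDX), mode, frozen(60))
  p[["60"]] <- at2$pp$sa_bn
  # flatten + dense + softmax
  flat <- matrix(at2$Y, a$M2 * a$T2, N)
  logits <- p[["77"]]$W %*% flat + p[["77"]]$b
  sm <- exp(sweep(logits, 2, apply(logits, 2, max)))
  probs <- sweep(sm, 2, colSums(sm), "/")

  out <- list(probs = probs, logits = logits, params = p)
  if (keep) {
    out$cache <- list(X = X, a1 = a1, b3 = b3, u1 = u1, b8 = b8, e9 = e9,
                      d10 = d10, v1 = v1, s18 = s18, b19 = b19, e20 = e20,
                      d21 = d21, z1 = z1, at1 = at1, w50 = w50, b51 = b51,
                      t52 = t52, b53 = b53, g11 = g11, b12 = b12, e13 = e13,
                      p14 = p14, d15 = d15, s22 = s22, b23 = b23, e24 = e24,
                      p25 = p25, d26 = d26, y1 = y1, at2 = at2, flat = flat,
                      N = N)
  }
  out
}

net_backward <- function(model, fw, dlogits) {
  a <- model$arch
  p <- fw$params
  cc <- fw$cache
  g <- list()
  N <- cc$N

  g[["77"]] <- list(W = dlogits %*% t(cc$flat), b = rowSums(dlogits))
  dflat <- t(p[["77"]]$W) %*% dlogits
  dY2 <- array(dflat, c(a$M2, a$T2, 1L, N))
  ab2 <- att_bwd(dY2, att_param_view(p, ATT2_IDX), cc$at2$cache)
  for (j in seq_along(ATT2_IDX)) {
    g[[as.character(ATT2_IDX[j])]] <- ab2$grads[[j]]
  }
  dy1 <- ab2$dZ
  d15g <- dy1[seq_len(a$F2), , , , drop = FALSE]
  d26g <- dy1[a$F2 + seq_len(a$F2), , , , drop = FALSE]
  if (!is.null(cc$d15$mask)) d15g <- d15g * cc$d15$mask
  if (!is.null(cc$d26$mask)) d26g <- d26g * cc$d26$mask
  # branch B of stage 2
  dp25 <- pool_bwd(d26g, a$pool, a$T)
  de24 <- elu_bwd(dp25, list(Y = cc$e24$Y, neg = cc$e24$neg))
  bb23 <- bn_bwd(de24, p[["23"]], cc$b23$cache)
  g[["23"]] <- list(g = bb23$dg, b = bb23$db)
  sb22 <- sep_conv_bwd(bb23$dX, cc$b53$Y, cc$s22$Z, p[["22"]]$Wd, p[["22"]]$Wp)
  g[["22"]] <- list(Wd = sb22$dWd, Wp = sb22$dWp, b = sb22$db)
  # branch A of stage 2
  dp14 <- pool_bwd(d15g, a$pool, a$T)
  de13 <- elu_bwd(dp14, list(Y = cc$e13$Y, neg = cc$e13$neg))
  bb12 <- bn_bwd(de13, p[["12"]], cc$b12$cache)
  g[["12"]] <- list(g = bb12$dg, b = bb12$db)
  g[["11"]] <- list(W = rowSums(matrix(bb12$dX * cc$b53$Y, a$F2)))
  dg11 <- p[["11"]]$W * bb12$dX
  # merge into stage-2 conv output
  db53Y <- dg11 + sb22$dX
  bb53 <- bn_bwd(db53Y, p[["53"]], cc$b53$cache)
  g[["53"]] <- list(g = bb53$dg, b = bb53$db)
  cb52 <- conv_temporal_bwd(bb53$dX, cc$b51$Y, p[["52"]]$W)
  g[["52"]] <- list(W = cb52$dW, b = cb52$db)
  bb51 <- bn_bwd(cb52$dX, p[["51"]], cc$b51$cache)
  g[["51"]] <- list(g = bb51$dg, b = bb51$db)
  cb50 <- conv_temporal_bwd(bb51$dX, cc$at1$Y, p[["50"]]$W)
  g[["50"]] <- list(W = cb50$dW, b = cb50$db)
  ab1 <- att_bwd(cb50$dX, att_param_view(p, ATT1_IDX), cc$at1$cache)
  for (j in seq_along(ATT1_IDX)) {
    g[[as.character(ATT1_IDX[j])]] <- ab1$grads[[j]]
  }
  dz1 <- ab1$dZ
  d10g <- dz1[seq_len(a$FD), , , , drop = FALSE]
  d21g <- dz1[a$FD + seq_len(a$FD), , , , drop = FALSE]
  if (!is.null(cc$d10$mask)) d10g <- d10g * cc$d10$mask
  if (!is.null(cc$d21$mask)) d21g <- d21g * cc$d21$mask
  # branch B of stage 1
  de20 <- elu_bwd(d21g, list(Y = cc$e20$Y, neg = cc$e20$neg))
  bb19 <- bn_bwd(de20, p[["19"]], cc$b19$cache)
  g[["19"]] <- list(g = bb19$dg, b = bb19$db)
  sb18 <- sep_conv_bwd(bb19$dX, cc$v1, cc$s18$Z, p[["18"]]$Wd, p[["18"]]$Wp)
  g[["18"]] <- list(Wd = sb18$dWd, Wp = sb18$dWp, b = sb18$db)
  db3Y_b <- cpp_chmean_bwd(sb18$dX, a$C)
  # branch A of stage 1
  de9 <- elu_bwd(d10g, list(Y = cc$e9$Y, neg = cc$e9$neg))
  bb8 <- bn_bwd(de9, p[["8"]], cc$b8$cache)
  g[["8"]] <- list(g = bb8$dg, b = bb8$db)
  dwb <- dw_spatial_bwd(bb8$dX, cc$b3$Y, p[["7"]]$W)
  g[["7"]] <- list(W = dwb$dW)
  bb3 <- bn_bwd(dwb$dX + db3Y_b, p[["3"]], cc$b3$cache)
  g[["3"]] <- list(g = bb3$dg, b = bb3$db)
  cb2 <- conv_temporal_bwd(bb3$dX, cc$X, p[["2"]]$W, need_dx = FALSE)
  g[["2"]] <- list(W = cb2$dW, b = cb2$db)
  g
}

# cross-entropy loss and its gradient with respect to the logits.
xent_loss <- function(probs, labels) {
  N <- ncol(probs)
  idx <- cbind(labels, seq_len(N))
  pr <- pmax(probs[idx], 1e-12)
  loss <- -mean(log(pr))
  dlog <- probs
  dlog[idx] <- dlog[idx] - 1
  list(loss = loss, dlogits = dlog / N)
}
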