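## nn: minimal neural-network machinery for the CNN and RNN text
## classifiers -- trained-from-scratch embeddings, Adam, binary
## cross-entropy via 2-class softmax. Pure matrix R; adequate at the
## sentence-classification scale this package targets (vectorized over the
## batch at every time step / convolution position).

## ---- nested-list parameter utilities -------------------------------------

nl_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, nl_map, f = f)
    names(out) <- names(a)
    out
  } else f(a)
}

nl_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- nl_map2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}

nl_sumsq <- function(a) {
  if (is.list(a)) sum(vapply(a, nl_sumsq, 0)) else sum(a * a)
}

## ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = nl_map(params, function(x) x * 0),
       v = nl_map(params, function(x) x * 0),
       t = 0L)
}

adam_update <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- nl_map2(st$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  st$v <- nl_map2(st$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  upd <- nl_map2(st$m, st$v, function(m, v)
    lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- nl_map2(params, upd, function(p, u) p - u)
  list(params = params, state = st)
}

clip_grads <- function(grads, max_norm) {
  nrm <- sqrt(nl_sumsq(grads))
  if (is.finite(nrm) && nrm > max_norm) {
    grads <- nl_map(grads, function(g) g * (max_norm / nrm))
  }
  grads
}

## ---- shared pieces -------------------------------------------------------

softmax2 <- function(z) {
  m <- pmax(z[, 1L], z[, 2L])
  e <- exp(z - m)
  e / rowSums(e)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

onehot2 <- function(y) cbind(1 - y, y)

## embedding rows for batch at position t; ids are 0-based
emb_at <- function(E, ids, t) E[ids[, t] + 1L, , drop = FALSE]

## scatter-add `contrib` (B x d) into dE rows given 1-based row indices
scatter_add <- function(dE, idx, contrib) {
  rs <- rowsum(contrib, idx)
  rows <- as.integer(rownames(rs))
  dE[rows, ] <- dE[rows, ] + rs
  dE
}

## ---- CNN: parallel widths, ReLU, global max-pool, softmax ----------------

cnn_init <- function(V, d, widths, f) {
  conv <- lapply(widths, function(w) {
    list(W = lapply(seq_len(w), function(j) glorot(d, f)),
         b = numeric(f))
  })
  list(E = matrix(stats::runif(V * d, -0.05, 0.05), V, d),
       conv = conv,
       Wd = glorot(length(widths) * f, 2L),
       bd = numeric(2L))
}

cnn_forward <- function(p, ids) {
  B <- nrow(ids)
  L <- ncol(ids)
  Emb <- lapply(seq_len(L), function(t) emb_at(p$E, ids, t))
  pooled <- vector("list", length(p$conv))
  caches <- vector("list", length(p$conv))
  for (wi in seq_along(p$conv)) {
    cv <- p$conv[[wi]]
    w <- length(cv$W)
    f <- length(cv$b)
    Lw <- L - w + 1L
    maxZ <- matrix(-Inf, B, f)
    amax <- matrix(1L, B, f)
    for (t in seq_len(Lw)) {
      Z <- matrix(cv$b, B, f, byrow = TRUE)
      for (j in seq_len(w)) Z <- Z + Emb[[t + j - 1L]] %*% cv$W[[j]]
      upd <- Z > maxZ
      amax[upd] <- t
      maxZ[upd] <- Z[upd]
    }
    pooled[[wi]] <- pmax(maxZ, 0)
    caches[[wi]] <- list(maxZ = maxZ, amax = amax)
  }
  P <- do.call(cbind, pooled)
  logits <- P %*% p$Wd + matrix(p$bd, B, 2L, byrow = TRUE)
  list(probs = softmax2(logits), Emb = Emb, caches = caches, P = P)
}

cnn_backward <- function(p, ids, y, fw) {
  B <- nrow(ids)
  dlogits <- (fw$probs - onehot2(y)) / B
  dWd <- t(fw$P) %*% dlogits
  dbd <- colSums(dlogits)
  dP <- dlogits %*% t(p$Wd)
  dE <- p$E * 0
  dconv <- vector("list", length(p$conv))
  off <- 0L
  for (wi in seq_along(p$conv)) {
    cv <- p$conv[[wi]]
    w <- length(cv$W)
    f <- length(cv$b)
    ca <- fw$caches[[wi]]
    dpool <- dP[, off + seq_len(f), drop = FALSE]
    off <- off + f
    dmax <- dpool * (ca$maxZ > 0)
    dW <- lapply(cv$W, function(W) W * 0)
    db <- numeric(f)
    live <- dmax != 0
    for (t in sort(unique(ca$amax[live]))) {
      sel <- live & (ca$amax == t)
      if (!any(sel)) next
      dZt <- dmax * sel
      for (j in seq_len(w)) {
        Ej <- fw$Emb[[t + j - 1L]]
        dW[[j]] <- dW[[j]] + t(Ej) %*% dZt
        dE <- scatter_add(dE, ids[, t + j - 1L] + 1L, dZt %*% t(cv$W[[j]]))
      }
      db <- db + colSums(dZt)
    }
    dconv[[wi]] <- list(W = dW, b = db)
  }
  list(E = dE, conv = dconv, Wd = dWd, bd = dbd)
}

## ---- bidirectional GRU, final-state concatenation ------------------------
## Gated cells are required here: a vanilla tanh recurrence forgets
## mid-sentence relational cues by the time it reaches the final state.

sigmoid <- function(x) 1 / (1 + exp(-x))

rnn_init <- function(V, d, h) {
  dir <- function() list(
    Wxz = glorot(d, h), Whz = glorot(h, h), bz = numeric(h),
    Wxr = glorot(d, h), Whr = glorot(h, h), br = numeric(h),
    Wxc = glorot(d, h), Whc = glorot(h, h), bc = numeric(h)
  )
  list(E = matrix(stats::runif(V * d, -0.05, 0.05), V, d),
       fwd = dir(), bwd = dir(),
       Wd = glorot(2L * h, 2L),
       bd = numeric(2L))
}

## One direction over the (possibly reversed) time order. `order_t` is the
## sequence of positions to visit. States are carried unchanged past each
## example's true length (pads never update the state).
rnn_scan <- function(dirp, E, ids, len, order_t) {
  B <- nrow(ids)
  h <- length(dirp$bz)
  state <- matrix(0, B, h)
  cache <- vector("list", length(order_t))
  brow <- function(b) matrix(b, B, h, byrow = TRUE)
  for (k in seq_along(order_t)) {
    t <- order_t[[k]]
    x <- emb_at(E, ids, t)
    z <- sigmoid(x %*% dirp$Wxz + state %*% dirp$Whz + brow(dirp$bz))
    r <- sigmoid(x %*% dirp$Wxr + state %*% dirp$Whr + brow(dirp$br))
    cc <- tanh(x %*% dirp$Wxc + (r * state) %*% dirp$Whc + brow(dirp$bc))
    m <- as.numeric(t <= len)
    new_state <- ((1 - z) * state + z * cc) * m + state * (1 - m)
    cache[[k]] <- list(z = z, r = r, cc = cc, prev = state)
    state <- new_state
  }
  list(final = state, cache = cache)
}

rnn_forward <- function(p, ids) {
  L <- ncol(ids)
  len <- rowSums(ids != 0L)
  f_scan <- rnn_scan(p$fwd, p$E, ids, len, seq_len(L))
  b_scan <- rnn_scan(p$bwd, p$E, ids, len, rev(seq_len(L)))
  H <- cbind(f_scan$final, b_scan$final)
  B <- nrow(ids)
  logits <- H %*% p$Wd + matrix(p$bd, B, 2L, byrow = TRUE)
  list(probs = softmax2(logits), H = H, len = len,
       f_scan = f_scan, b_scan = b_scan)
}

rnn_scan_backward <- function(dirp, E, ids, len, order_t, scan, dfinal) {
  g <- nl_map(dirp, function(x) x * 0)
  dE <- E * 0
  dstate <- dfinal
  for (k in rev(seq_along(order_t))) {
    t <- order_t[[k]]
    m <- as.numeric(t <= len)
    ca <- scan$cache[[k]]
    dupd <- dstate * m          # gradient through the updated state
    dcarry <- dstate * (1 - m)  # pads carry the state through
    z <- ca$z
    r <- ca$r
    cc <- ca$cc
    prev <- ca$prev
    x <- emb_at(E, ids, t)
    dz <- dupd * (cc - prev)
    dcc <- dupd * z
    dprev <- dupd * (1 - z)
    dcc_pre <- dcc * (1 - cc * cc)
    drh <- dcc_pre %*% t(dirp$Whc)
    dr <- drh * prev
    dprev <- dprev + drh * r
    dz_pre <- dz * z * (1 - z)
    dr_pre <- dr * r * (1 - r)
    g$Wxc <- g$Wxc + t(x) %*% dcc_pre
    g$Whc <- g$Whc + t(r * prev) %*% dcc_pre
    g$bc <- g$bc + colSums(dcc_pre)
    g$Wxz <- g$Wxz + t(x) %*% dz_pre
    g$Whz <- g$Whz + t(prev) %*% dz_pre
    g$bz <- g$bz + colSums(dz_pre)
    g$Wxr <- g$Wxr + t(x) %*% dr_pre
    g$Whr <- g$Whr + t(prev) %*% dr_pre
    g$br <- g$br + colSums(dr_pre)
    dprev <- dprev + dz_pre %*% t(dirp$Whz) + dr_pre %*% t(dirp$Whr)
    dx <- dcc_pre %*% t(dirp$Wxc) + dz_pre %*% t(dirp$Wxz) +
      dr_pre %*% t(dirp$Wxr)
    dE <- scatter_add(dE, ids[, t] + 1L, dx)
    dstate <- dcarry + dprev
  }
  list(g = g, dE = dE)
}

rnn_backward <- function(p, ids, y, fw) {
  B <- nrow(ids)
  h <- length(p$fwd$bz)
  L <- ncol(ids)
  dlogits <- (fw$probs - onehot2(y)) / B
  dWd <- t(fw$H) %*% dlogits
  dbd <- colSums(dlogits)
  dH <- dlogits %*% t(p$Wd)
  gf <- rnn_scan_backward(p$fwd, p$E, ids, fw$len, seq_len(L), fw$f_scan,
                          dH[, seq_len(h), drop = FALSE])
  gb <- rnn_scan_backward(p$bwd, p$E, ids, fw$len, rev(seq_len(L)), fw$b_scan,
                          dH[, h + seq_len(h), drop = FALSE])
  list(E = gf$dE + gb$dE, fwd = gf$g, bwd = gb$g, Wd = dWd, bd = dbd)
}

## ---- training loop -------------------------------------------------------

## Caller is responsible for seeding (shuffling uses the current RNG).
## `weight_decay` is decoupled (AdamW-style): params shrink by lr * wd each
## step, independent of the adaptive gradient scaling.
nn_fit <- function(params, forward, backward, ids, y, epochs, batch_size,
                   lr, clip = 5, weight_decay = 0) {
  n <- nrow(ids)
  st <- adam_init(params)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (b0 in seq(1L, n, by = batch_size)) {
      bi <- ord[b0:min(b0 + batch_size - 1L, n)]
      fw <- forward(params, ids[bi, , drop = FALSE])
      gr <- backward(params, ids[bi, , drop = FALSE], y[bi], fw)
      gr <- clip_grads(gr, clip)
      res <- adam_update(params, gr, st, lr)
      params <- res$params
      st <- res$state
      if (weight_decay > 0) {
        params <- nl_map(params, function(p) p * (1 - lr * weight_decay))
      }
    }
  }
  params
}
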