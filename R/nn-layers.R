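## Minimal deep-learning primitives used by the SE-ResNet regressor.
## Tensors are arrays dim (N, H, W, C); convolutions are computed as
## cross-correlations via im2col + BLAS matrix products, with
## hand-written backward passes. Everything is deterministic given the
## R RNG state.

.im2col <- function(x, k, stride, pad) {
  d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  HP <- H + 2L * pad; WP <- W + 2L * pad
  Ho <- (HP - k) %/% stride + 1L; Wo <- (WP - k) %/% stride + 1L
  if (pad > 0) {
    xp <- array(0, c(N, HP, WP, C))
    xp[, pad + seq_len(H), pad + seq_len(W), ] <- x
  } else xp <- x
  col <- matrix(0, N * Ho * Wo, k * k * C)
  i0 <- (seq_len(Ho) - 1L) * stride
  j0 <- (seq_len(Wo) - 1L) * stride
  o <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    o <- o + 1L
    col[, ((o - 1L) * C + 1L):(o * C)] <-
      matrix(xp[, i0 + di, j0 + dj, , drop = FALSE], N * Ho * Wo, C)
  }
  list(col = col, N = N, Ho = Ho, Wo = Wo)
}

.col2im <- function(dcol, k, stride, pad, d) {
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  HP <- H + 2L * pad; WP <- W + 2L * pad
  Ho <- (HP - k) %/% stride + 1L; Wo <- (WP - k) %/% stride + 1L
  dxp <- array(0, c(N, HP, WP, C))
  i0 <- (seq_len(Ho) - 1L) * stride
  j0 <- (seq_len(Wo) - 1L) * stride
  o <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    o <- o + 1L
    blk <- array(dcol[, ((o - 1L) * C + 1L):(o * C)], c(N, Ho, Wo, C))
    dxp[, i0 + di, j0 + dj, ] <-
      dxp[, i0 + di, j0 + dj, , drop = FALSE] + blk
  }
  if (pad > 0) dxp[, pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
  else dxp
}

## He-initialized convolution layer. Weight matrix rows are ordered
## (channel fastest within each kernel offset, offsets (di, dj) with di
## fastest) to match .im2col's column layout.
.convLayer <- function(k, cin, cout, stride = 1L, pad = 0L) {
  fanIn <- k * k * cin
  list(kind = "conv",
       par = list(W = matrix(rnorm(fanIn * cout, sd = sqrt(2 / fanIn)),
                             fanIn, cout),
                  b = numeric(cout)),
       cfg = list(k = as.integer(k), stride = as.integer(stride),
                  pad = as.integer(pad), cin = cin, cout = cout))
}

.convF <- function(layer, x) {
  cfg <- layer$cfg
  d <- dim(x)
  if (d[4] != cfg$cin)
    stop("shape error: conv expects ", cfg$cin, " channels, got ", d[4])
  if (cfg$k == 1L && cfg$stride == 1L && cfg$pad == 0L) {
    col <- matrix(x, prod(d[1:3]), d[4])
    y <- sweep(col %*% layer$par$W, 2, layer$par$b, "+")
    dim(y) <- c(d[1], d[2], d[3], cfg$cout)
    return(list(y = y, cache = list(col = col, xdim = d, fast1 = TRUE)))
  }
  ic <- .im2col(x, cfg$k, cfg$stride, cfg$pad)
  y <- sweep(ic$col %*% layer$par$W, 2, layer$par$b, "+")
  dim(y) <- c(ic$N, ic$Ho, ic$Wo, cfg$cout)
  list(y = y, cache = list(col = ic$col, xdim = d, fast1 = FALSE))
}

.convB <- function(layer, cache, dy, needDx = TRUE) {
  cfg <- layer$cfg
  dym <- matrix(dy, prod(dim(dy)[1:3]), cfg$cout)
  grads <- list(W = crossprod(cache$col, dym), b = colSums(dym))
  if (!needDx) return(list(dx = NULL, grads = grads))
  dcol <- tcrossprod(dym, layer$par$W)
  dx <- if (cache$fast1) array(dcol, cache$xdim)
  else .col2im(dcol, cfg$k, cfg$stride, cfg$pad, cache$xdim)
  list(dx = dx, grads = grads)
}

.bnLayer <- function(C, momentum = 0.1, eps = 1e-5) {
  list(kind = "bn",
       par = list(gamma = rep(1, C), beta = numeric(C)),
       stat = list(mean = numeric(C), var = rep(1, C)),
       cfg = list(momentum = momentum, eps = eps))
}

.bnF <- function(layer, x, train) {
  d <- dim(x); C <- d[4]; m <- prod(d[1:3])
  xm <- matrix(x, m, C)
  if (train) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colMeans(xc * xc)
    mo <- layer$cfg$momentum
    layer$stat$mean <- (1 - mo) * layer$stat$mean + mo * mu
    layer$stat$var <- (1 - mo) * layer$stat$var + mo * v
  } else {
    xc <- sweep(xm, 2, layer$stat$mean)
    v <- layer$stat$var
  }
  istd <- 1 / sqrt(v + layer$cfg$eps)
  xh <- sweep(xc, 2, istd, "*")
  y <- sweep(sweep(xh, 2, layer$par$gamma, "*"), 2, layer$par$beta, "+")
  dim(y) <- d
  list(y = y, cache = list(xh = xh, istd = istd, d = d), layer = layer)
}

.bnB <- function(layer, cache, dy) {
  d <- cache$d; C <- d[4]; m <- prod(d[1:3])
  dym <- matrix(dy, m, C)
  grads <- list(gamma = colSums(dym * cache$xh), beta = colSums(dym))
  dxh <- sweep(dym, 2, layer$par$gamma, "*")
  t1 <- sweep(dxh, 2, colMeans(dxh))
  t2 <- sweep(cache$xh, 2, colMeans(dxh * cache$xh), "*")
  dx <- sweep(t1 - t2, 2, cache$istd, "*")
  dim(dx) <- d
  list(dx = dx, grads = grads)
}

.denseLayer <- function(din, dout) {
  list(kind = "dense",
       par = list(W = matrix(rnorm(din * dout, sd = sqrt(2 / din)),
                             din, dout),
                  b = numeric(dout)))
}

.denseF <- function(layer, x)
  list(y = sweep(x %*% layer$par$W, 2, layer$par$b, "+"), cache = x)

.denseB <- function(layer, cache, dy)
  list(dx = tcrossprod(dy, layer$par$W),
       grads = list(W = crossprod(cache, dy), b = colSums(dy)))

.poolF <- function(cfg, x) {
  d <- dim(x); N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  k <- cfg$k; s <- cfg$stride; p <- cfg$pad
  HP <- H + 2L * p; WP <- W + 2L * p
  Ho <- (HP - k) %/% s + 1L; Wo <- (WP - k) %/% s + 1L
  xp <- array(-Inf, c(N, HP, WP, C))
  xp[, p + seq_len(H), p + seq_len(W), ] <- x
  i0 <- (seq_len(Ho) - 1L) * s; j0 <- (seq_len(Wo) - 1L) * s
  best <- matrix(-Inf, N * Ho * Wo, C)
  argo <- matrix(0L, N * Ho * Wo, C)
  o <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    o <- o + 1L
    cur <- matrix(xp[, i0 + di, j0 + dj, , drop = FALSE], N * Ho * Wo, C)
    upd <- cur > best
    best[upd] <- cur[upd]
    argo[upd] <- o
  }
  y <- best; dim(y) <- c(N, Ho, Wo, C)
  list(y = y, cache = list(argo = argo, d = d, Ho = Ho, Wo = Wo))
}

.poolB <- function(cfg, cache, dy) {
  d <- cache$d; N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  k <- cfg$k; s <- cfg$stride; p <- cfg$pad
  dxp <- array(0, c(N, H + 2L * p, W + 2L * p, C))
  i0 <- (seq_len(cache$Ho) - 1L) * s; j0 <- (seq_len(cache$Wo) - 1L) * s
  dym <- matrix(dy, N * cache$Ho * cache$Wo, C)
  o <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    o <- o + 1L
    blk <- dym * (cache$argo == o)
    dim(blk) <- c(N, cache$Ho, cache$Wo, C)
    dxp[, i0 + di, j0 + dj, ] <-
      dxp[, i0 + di, j0 + dj, , drop = FALSE] + blk
  }
  if (p > 0) dxp[, p + seq_len(H), p + seq_len(W), , drop = FALSE]
  else dxp
}

## Global average pool: (N,H,W,C) -> (N,C)
.gapF <- function(x) {
  d <- dim(x); hw <- d[2] * d[3]
  grp <- rep(seq_len(d[1]), hw)
  y <- rowsum(matrix(x, d[1] * hw, d[4]), grp) / hw
  list(y = y, cache = d)
}

.gapB <- function(cache, dy) {
  d <- cache; hw <- d[2] * d[3]
  dx <- (dy / hw)[rep(seq_len(d[1]), hw), , drop = FALSE]
  dim(dx) <- d
  dx
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

## Squeeze-and-excitation unit: squeeze = per-channel global average;
## excitation = bottleneck C -> C/r -> C with sigmoid gate; output =
## input scaled channel-wise. cfg$pinned (numeric C) bypasses the
## excitation with fixed gates (all-ones = SE ablation).
.seLayer <- function(C, reduction) {
  mid <- C %/% reduction
  list(kind = "se",
       par = list(W1 = matrix(rnorm(C * mid, sd = sqrt(2 / C)), C, mid),
                  b1 = numeric(mid),
                  W2 = matrix(rnorm(mid * C, sd = sqrt(1 / mid)), mid, C),
                  b2 = numeric(C)),
       cfg = list(C = C, reduction = reduction, pinned = NULL))
}

.seF <- function(layer, x) {
  d <- dim(x); hw <- d[2] * d[3]
  g <- .gapF(x)
  s <- g$y                                     # N x C squeeze
  if (!is.null(layer$cfg$pinned)) {
    z <- matrix(layer$cfg$pinned, d[1], d[4], byrow = TRUE)
    zb <- z[rep(seq_len(d[1]), hw), , drop = FALSE]
    dim(zb) <- d
    return(list(y = x * zb, cache = list(pinned = TRUE, zb = zb)))
  }
  h <- pmax(s %*% layer$par$W1 +
              matrix(layer$par$b1, d[1], length(layer$par$b1),
                     byrow = TRUE), 0)
  zlin <- h %*% layer$par$W2 +
    matrix(layer$par$b2, d[1], d[4], byrow = TRUE)
  z <- .sigmoid(zlin)
  zb <- z[rep(seq_len(d[1]), hw), , drop = FALSE]
  dim(zb) <- d
  list(y = x * zb,
       cache = list(pinned = FALSE, x = x, s = s, h = h, z = z, zb = zb,
                    d = d))
}

.seB <- function(layer, cache, dy) {
  if (isTRUE(cache$pinned))
    return(list(dx = dy * cache$zb,
                grads = list(W1 = layer$par$W1 * 0, b1 = layer$par$b1 * 0,
                             W2 = layer$par$W2 * 0,
                             b2 = layer$par$b2 * 0)))
  d <- cache$d; hw <- d[2] * d[3]; N <- d[1]
  dx1 <- dy * cache$zb
  grp <- rep(seq_len(N), hw)
  dz <- rowsum(matrix(dy * cache$x, N * hw, d[4]), grp)   # N x C
  dzlin <- dz * cache$z * (1 - cache$z)
  gW2 <- crossprod(cache$h, dzlin)
  gb2 <- colSums(dzlin)
  dh <- tcrossprod(dzlin, layer$par$W2) * (cache$h > 0)
  gW1 <- crossprod(cache$s, dh)
  gb1 <- colSums(dh)
  ds <- tcrossprod(dh, layer$par$W1)
  dx2 <- .gapB(d, ds)
  list(dx = dx1 + dx2,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
}

## SE-residual bottleneck block: 1x1 reduce -> 3x3 (stride) -> 1x1
## expand, BN after each conv, SE recalibration on the expanded map,
## identity (or projected) shortcut, final ReLU.
.blockLayer <- function(cin, cout, stride, reduction) {
  cmid <- cout %/% 4L
  proj <- (cin != cout) || (stride != 1L)
  list(kind = "block",
       conv1 = .convLayer(1L, cin, cmid),
       bn1 = .bnLayer(cmid),
       conv2 = .convLayer(3L, cmid, cmid, stride = stride, pad = 1L),
       bn2 = .bnLayer(cmid),
       conv3 = .convLayer(1L, cmid, cout),
       bn3 = .bnLayer(cout),
       se = .seLayer(cout, reduction),
       short = if (proj) list(conv = .convLayer(1L, cin, cout,
                                                stride = stride),
                              bn = .bnLayer(cout)) else NULL)
}

.blockF <- function(blk, x, train) {
  c1 <- .convF(blk$conv1, x)
  b1 <- .bnF(blk$bn1, c1$y, train); blk$bn1 <- b1$layer
  a1 <- pmax(b1$y, 0)
  c2 <- .convF(blk$conv2, a1)
  b2 <- .bnF(blk$bn2, c2$y, train); blk$bn2 <- b2$layer
  a2 <- pmax(b2$y, 0)
  c3 <- .convF(blk$conv3, a2)
  b3 <- .bnF(blk$bn3, c3$y, train); blk$bn3 <- b3$layer
  se <- .seF(blk$se, b3$y)
  if (!is.null(blk$short)) {
    sc <- .convF(blk$short$conv, x)
    sb <- .bnF(blk$short$bn, sc$y, train); blk$short$bn <- sb$layer
    shortY <- sb$y
    shortCache <- list(conv = sc$cache, bn = sb$cache)
  } else {
    shortY <- x
    shortCache <- NULL
  }
  s <- se$y + shortY
  y <- pmax(s, 0)
  list(y = y, layer = blk,
       cache = list(c1 = c1$cache, b1 = b1$cache, m1 = b1$y > 0,
                    c2 = c2$cache, b2 = b2$cache, m2 = b2$y > 0,
                    c3 = c3$cache, b3 = b3$cache, se = se$cache,
                    short = shortCache, mOut = s > 0))
}

.blockB <- function(blk, cache, dy) {
  ds <- dy * cache$mOut
  g <- list()
  seb <- .seB(blk$se, cache$se, ds); g$se <- seb$grads
  b3 <- .bnB(blk$bn3, cache$b3, seb$dx); g$bn3 <- b3$grads
  c3 <- .convB(blk$conv3, cache$c3, b3$dx); g$conv3 <- c3$grads
  da2 <- c3$dx * cache$m2
  b2 <- .bnB(blk$bn2, cache$b2, da2); g$bn2 <- b2$grads
  c2 <- .convB(blk$conv2, cache$c2, b2$dx); g$conv2 <- c2$grads
  da1 <- c2$dx * cache$m1
  b1 <- .bnB(blk$bn1, cache$b1, da1); g$bn1 <- b1$grads
  c1 <- .convB(blk$conv1, cache$c1, b1$dx); g$conv1 <- c1$grads
  if (!is.null(blk$short)) {
    sb <- .bnB(blk$short$bn, cache$short$bn, ds)
    sc <- .convB(blk$short$conv, cache$short$conv, sb$dx)
    g$short <- list(conv = sc$grads, bn = sb$grads)
    dx <- c1$dx + sc$dx
  } else {
    dx <- c1$dx + ds
  }
  list(dx = dx, grads = g)
}

## ---------------------------------------------------------------------------
## Adam over the nested layer tree. A node with $par is a trainable
## leaf layer; grads mirror the tree with plain lists.

.adamInit <- function() list(t = 0L)

.adamLeaf <- function(par, g, st, lr, b1, b2, eps, t, wd) {
  if (is.null(st)) st <- list(m = par * 0, v = par * 0)
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g * g
  mh <- st$m / (1 - b1^t)
  vh <- st$v / (1 - b2^t)
  list(par = par - lr * (mh / (sqrt(vh) + eps) + wd * par), st = st)
}

## Decoupled weight decay applies to weight matrices only, never to
## biases or batch-norm affine parameters.
.WD_LEAVES <- c("W", "W1", "W2")

.adamTree <- function(node, gnode, snode, lr, b1, b2, eps, t, wd = 0) {
  if (is.null(gnode)) return(list(node = node, st = snode))
  if (!is.null(node$par)) {
    for (nm in names(gnode)) {
      r <- .adamLeaf(node$par[[nm]], gnode[[nm]], snode[[nm]],
                     lr, b1, b2, eps, t,
                     if (nm %in% .WD_LEAVES) wd else 0)
      node$par[[nm]] <- r$par
      snode[[nm]] <- r$st
    }
    return(list(node = node, st = snode))
  }
  for (nm in names(gnode)) {
    r <- .adamTree(node[[nm]], gnode[[nm]], snode[[nm]],
                   lr, b1, b2, eps, t, wd)
    node[[nm]] <- r$node
    snode[[nm]] <- r$st
  }
  list(node = node, st = snode)
}

.countTree <- function(node) {
  if (!is.list(node)) return(0)
  if (!is.null(node$par))
    return(sum(vapply(node$par, length, numeric(1))))
  kids <- node[vapply(node, is.list, logical(1))]
  sum(vapply(kids, .countTree, numeric(1)))
}
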