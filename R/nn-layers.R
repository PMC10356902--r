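# Minimal CNN layer engine.
#
# Activations are stored channel-fastest: spatial tensors are (C, H, W, N)
# arrays, dense features (F, N) matrices. Convolution is im2col (C++) plus a
# BLAS matrix product. Each layer implements a forward returning (out, cache)
# and a backward returning (dx, grads); networks are lists of named layers.
# There is deliberately no batch normalization anywhere: all normalization is
# group norm, which depends on single samples only and is therefore
# compatible with per-sample gradient clipping in DP-SGD.

.he_init <- function(fan_in, n, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed %% 2147483647))
  stats::rnorm(n) * sqrt(2 / fan_in)
}

nn_conv <- function(cin, cout, k = 3L, stride = 1L, pad = 1L, name, seed = 1L) {
  W <- matrix(.he_init(cin * k * k, cin * k * k * cout, seed), cin * k * k, cout)
  list(type = "conv", name = name, cin = cin, cout = cout, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       params = list(W = W, b = numeric(cout)))
}

nn_groupnorm <- function(C, groups = 4L, name, eps = 1e-5) {
  if (C %% groups != 0L) groups <- max(which(C %% seq_len(groups) == 0L))
  list(type = "groupnorm", name = name, C = as.integer(C),
       groups = as.integer(groups), eps = eps,
       params = list(gamma = rep(1, C), beta = numeric(C)))
}

nn_relu <- function(name) list(type = "relu", name = name, params = list())

nn_gap <- function(name = "gap") list(type = "gap", name = name, params = list())

nn_flatten <- function(name = "flatten") list(type = "flatten", name = name, params = list())

nn_linear <- function(fin, fout, name, seed = 1L) {
  W <- matrix(.he_init(fin, fin * fout, seed), fout, fin)
  list(type = "linear", name = name, fin = fin, fout = fout,
       params = list(W = W, b = numeric(fout)))
}

nn_resblock <- function(cin, cout, stride = 1L, name, seed = 1L) {
  sub <- list(conv1 = nn_conv(cin, cout, 3L, stride, 1L, paste0(name, ".conv1"), seed),
              gn1 = nn_groupnorm(cout, name = paste0(name, ".gn1")),
              conv2 = nn_conv(cout, cout, 3L, 1L, 1L, paste0(name, ".conv2"), seed + 1L),
              gn2 = nn_groupnorm(cout, name = paste0(name, ".gn2")))
  # zero-init the residual branch's final norm scale so each block starts as
  # (near-)identity; stabilizes early training at high learning rates
  sub$gn2$params$gamma <- rep(0, cout)
  if (stride != 1L || cin != cout) {
    sub$proj <- nn_conv(cin, cout, 1L, stride, 0L, paste0(name, ".proj"), seed + 2L)
    sub$gnp <- nn_groupnorm(cout, name = paste0(name, ".gnp"))
  }
  list(type = "resblock", name = name, sub = sub, params = list())
}

# ---- simple layer forward/backward ------------------------------------------

.conv_fwd <- function(layer, x) {
  d <- dim(x)
  cols <- im2col_cpp(x, d[1], d[2], d[3], d[4], layer$k, layer$k,
                     layer$stride, layer$pad)
  Ho <- (d[2] + 2 * layer$pad - layer$k) %/% layer$stride + 1L
  Wo <- (d[3] + 2 * layer$pad - layer$k) %/% layer$stride + 1L
  out <- crossprod(layer$params$W, cols) + layer$params$b
  dim(out) <- c(layer$cout, Ho, Wo, d[4])
  list(out = out, cache = list(cols = cols, dims = d, Ho = Ho, Wo = Wo))
}

.conv_bwd <- function(layer, dout, cache, need_dx = TRUE) {
  d <- cache$dims
  dmat <- matrix(dout, layer$cout, cache$Ho * cache$Wo * d[4])
  dW <- tcrossprod(cache$cols, dmat)
  db <- rowSums(dmat)
  dx <- NULL
  if (need_dx) {
    dcols <- layer$params$W %*% dmat
    dx <- col2im_cpp(dcols, d[1], d[2], d[3], d[4], layer$k, layer$k,
                     layer$stride, layer$pad)
    dim(dx) <- d
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

.gn_fwd <- function(layer, x) {
  d <- dim(x)
  r <- gn_fwd_cpp(x, d[1], d[2] * d[3], d[4], layer$groups,
                  layer$params$gamma, layer$params$beta, layer$eps)
  y <- r$y
  dim(y) <- d
  list(out = y, cache = list(x = x, mu = r$mu, istd = r$istd, dims = d))
}

.gn_bwd <- function(layer, dout, cache, need_dx = TRUE) {
  d <- cache$dims
  r <- gn_bwd_cpp(cache$x, dout, d[1], d[2] * d[3], d[4], layer$groups,
                  layer$params$gamma, cache$mu, cache$istd)
  dx <- NULL
  if (need_dx) { dx <- r$dx; dim(dx) <- d }
  list(dx = dx, grads = list(gamma = r$dgamma, beta = r$dbeta))
}

.relu_fwd <- function(layer, x) {
  mask <- x > 0
  y <- x * mask
  list(out = y, cache = list(mask = mask))
}

.relu_bwd <- function(layer, dout, cache, need_dx = TRUE) {
  list(dx = dout * cache$mask, grads = list())
}

.gap_fwd <- function(layer, x) {
  d <- dim(x)
  C <- d[1]; HW <- d[2] * d[3]; N <- d[4]
  y <- rowsum(matrix(x, C * HW, N), rep(seq_len(C), times = HW)) / HW
  list(out = y, cache = list(dims = d))
}

.gap_bwd <- function(layer, dout, cache, need_dx = TRUE) {
  d <- cache$dims
  HW <- d[2] * d[3]
  dx <- dout[, rep(seq_len(d[4]), each = HW), drop = FALSE] / HW
  # columns above are ordered (hw within n); rows are channels -> (C,H,W,N)
  dim(dx) <- d
  list(dx = dx, grads = list())
}

.flatten_fwd <- function(layer, x) {
  d <- dim(x)
  y <- matrix(x, prod(d[1:3]), d[4])
  list(out = y, cache = list(dims = d))
}

.flatten_bwd <- function(layer, dout, cache, need_dx = TRUE) {
  dx <- dout
  dim(dx) <- cache$dims
  list(dx = dx, grads = list())
}

.linear_fwd <- function(layer, x) {
  list(out = layer$params$W %*% x + layer$params$b, cache = list(x = x))
}

.linear_bwd <- function(layer, dout, cache, need_dx = TRUE) {
  list(dx = if (need_dx) crossprod(layer$params$W, dout) else NULL,
       grads = list(W = tcrossprod(dout, cache$x), b = rowSums(dout)))
}

.layer_fwd <- function(layer, x) {
  switch(layer$type,
    conv = .conv_fwd(layer, x),
    groupnorm = .gn_fwd(layer, x),
    relu = .relu_fwd(layer, x),
    gap = .gap_fwd(layer, x),
    flatten = .flatten_fwd(layer, x),
    linear = .linear_fwd(layer, x),
    resblock = .resblock_fwd(layer, x),
    stop("unknown layer type ", layer$type))
}

.layer_bwd <- function(layer, dout, cache, need_dx = TRUE) {
  switch(layer$type,
    conv = .conv_bwd(layer, dout, cache, need_dx),
    groupnorm = .gn_bwd(layer, dout, cache, need_dx),
    relu = .relu_bwd(layer, dout, cache, need_dx),
    gap = .gap_bwd(layer, dout, cache, need_dx),
    flatten = .flatten_bwd(layer, dout, cache, need_dx),
    linear = .linear_bwd(layer, dout, cache, need_dx),
    resblock = .resblock_bwd(layer, dout, cache, need_dx),
    stop("unknown layer type ", layer$type))
}

.resblock_fwd <- function(layer, x) {
  s <- layer$sub
  f1 <- .conv_fwd(s$conv1, x)
  g1 <- .gn_fwd(s$gn1, f1$out)
  r1 <- .relu_fwd(NULL, g1$out)
  f2 <- .conv_fwd(s$conv2, r1$out)
  g2 <- .gn_fwd(s$gn2, f2$out)
  if (!is.null(s$proj)) {
    fp <- .conv_fwd(s$proj, x)
    gp <- .gn_fwd(s$gnp, fp$out)
    sc <- gp$out
  } else {
    fp <- NULL; gp <- NULL; sc <- x
  }
  z <- g2$out + sc
  rout <- .relu_fwd(NULL, z)
  list(out = rout$out,
       cache = list(f1 = f1$cache, g1 = g1$cache, r1 = r1$cache,
                    f2 = f2$cache, g2 = g2$cache,
                    fp = if (is.null(fp)) NULL else fp$cache,
                    gp = if (is.null(gp)) NULL else gp$cache,
                    rout = rout$cache, has_proj = !is.null(s$proj)))
}

.resblock_bwd <- function(layer, dout, cache, need_dx = TRUE) {
  s <- layer$sub
  dz <- .relu_bwd(NULL, dout, cache$rout)$dx
  # main branch
  b2 <- .gn_bwd(s$gn2, dz, cache$g2)
  c2 <- .conv_bwd(s$conv2, b2$dx, cache$f2)
  dr1 <- .relu_bwd(NULL, c2$dx, cache$r1)$dx
  b1 <- .gn_bwd(s$gn1, dr1, cache$g1)
  c1 <- .conv_bwd(s$conv1, b1$dx, cache$f1, need_dx)
  grads <- list(conv1 = c1$grads, gn1 = b1$grads, conv2 = c2$grads, gn2 = b2$grads)
  if (cache$has_proj) {
    bp <- .gn_bwd(s$gnp, dz, cache$gp)
    cp <- .conv_bwd(s$proj, bp$dx, cache$fp, need_dx)
    grads$proj <- cp$grads
    grads$gnp <- bp$grads
    dx <- if (need_dx) c1$dx + cp$dx else NULL
  } else {
    dx <- if (need_dx) c1$dx + dz else NULL
  }
  list(dx = dx, grads = grads)
}
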