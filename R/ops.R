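# Differentiable operations on (H, W, C, N) feature maps.
#
# Each op takes and returns `hf_tensor` nodes; backward closures capture the
# forward values they need. Convolutions call the compiled im2col/GEMM
# kernels; everything else is vectorized R.

.dims4 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

# per-channel sums of a (H,W,C,N) array -> length-C vector
.channel_sum <- function(a, d) {
  dim(a) <- c(d[1] * d[2], d[3] * d[4])
  s <- colSums(a)
  rowSums(matrix(s, d[3], d[4]))
}

# expand a per-channel vector to a full (H,W,C,N) array
.expand_channel <- function(v, d) {
  array(rep(rep(v, each = d[1] * d[2]), times = d[4]), dim = d)
}

op_conv <- function(x, w, b = NULL, pad = 0L, stride = 1L, groups = 1L) {
  xd <- .dims4(x$value)
  wd <- dim(w$value)
  bias <- if (is.null(b)) numeric(0) else as.numeric(b$value)
  y <- conv2d_fwd_cpp(x$value, as.integer(xd), w$value, as.integer(wd),
                      bias, as.integer(pad), as.integer(stride),
                      as.integer(groups))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  tensor(y, parents = parents, backward = function(g) {
    bw <- conv2d_bwd_cpp(x$value, as.integer(xd), w$value, as.integer(wd),
                         g, as.integer(pad), as.integer(stride),
                         as.integer(groups), !is.null(b))
    if (is.null(b)) list(bw$dx, bw$dw) else list(bw$dx, bw$dw, bw$db)
  })
}

# Apply `f(plane_matrix, channel_vector)` with the per-channel vector
# recycled over samples: reshapes a (H,W,C,N) array to (H*W*C, N) so plain
# vector recycling (rep(v, each = H*W)) broadcasts per channel without
# materializing a full-size expansion.
.bcast_channel <- function(a, v, d, op = `*`) {
  dim(a) <- c(d[1] * d[2] * d[3], d[4])
  out <- op(a, rep(v, each = d[1] * d[2]))
  dim(out) <- d
  out
}

# Batch normalization over (H, W, N) per channel. `layer` is the layer
# environment holding running statistics; `training` selects batch vs
# running statistics.
op_bn <- function(x, gamma, beta, layer, training = TRUE, eps = 1e-5,
                  momentum = 0.1) {
  d <- .dims4(x$value)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mu <- .channel_sum(x$value, d) / m
    xc <- .bcast_channel(x$value, mu, d, `-`)
    v <- .channel_sum(xc * xc, d) / m
    layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
    layer$running_var <- (1 - momentum) * layer$running_var +
      momentum * v * m / max(m - 1, 1)
  } else {
    mu <- layer$running_mean
    xc <- .bcast_channel(x$value, mu, d, `-`)
    v <- layer$running_var
  }
  ivar <- 1 / sqrt(v + eps)
  # y = xc * (ivar * gamma) + beta, fused per channel
  y <- .bcast_channel(.bcast_channel(xc, ivar * as.vector(gamma$value), d),
                      as.vector(beta$value), d, `+`)
  tensor(y, parents = list(x, gamma, beta), backward = function(g) {
    dgamma <- .channel_sum(g * xc, d) * ivar
    dbeta <- .channel_sum(g, d)
    # dxhat folded with ivar: dxi = g * gamma * ivar
    gi <- as.vector(gamma$value) * ivar
    dxi <- .bcast_channel(g, gi, d)
    if (training) {
      dvar <- .channel_sum(dxi * xc, d) * (-0.5) * ivar^2
      dmu <- -.channel_sum(dxi, d)
      dx <- dxi + .bcast_channel(
        .bcast_channel(xc, 2 * dvar / m, d), dmu / m, d, `+`)
    } else {
      dx <- dxi
    }
    list(dx, array(dgamma), array(dbeta))
  })
}

op_relu <- function(x) {
  mask <- x$value > 0
  tensor(x$value * mask, parents = list(x),
         backward = function(g) list(g * mask))
}

# leaky variant used in the channel-attention bottleneck so squeeze units
# cannot go completely dead (gradient flow is structural, not luck of init)
op_leaky_relu <- function(x, slope = 0.01) {
  fac <- ifelse(x$value > 0, 1, slope)
  tensor(x$value * fac, parents = list(x),
         backward = function(g) list(g * fac))
}

op_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$value))
  tensor(y, parents = list(x), backward = function(g) list(g * y * (1 - y)))
}

op_add <- function(a, b) {
  stopifnot(identical(dim(a$value), dim(b$value)))
  tensor(a$value + b$value, parents = list(a, b),
         backward = function(g) list(g, g))
}

op_concat_c <- function(a, b) {
  da <- .dims4(a$value); db <- .dims4(b$value)
  stopifnot(da[c(1, 2, 4)] == db[c(1, 2, 4)])
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a$value
  out[, , da[3] + seq_len(db[3]), ] <- b$value
  tensor(out, parents = list(a, b), backward = function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

op_gap <- function(x) {
  d <- .dims4(x$value)
  a <- x$value
  dim(a) <- c(d[1] * d[2], d[3] * d[4])
  y <- array(colMeans(a), dim = c(1, 1, d[3], d[4]))
  tensor(y, parents = list(x), backward = function(g) {
    list(array(rep(as.vector(g) / (d[1] * d[2]), each = d[1] * d[2]), dim = d))
  })
}

# x: (H,W,C,N) scaled by a spatial map a: (H,W,1,N), broadcast over channels
op_scale_spatial <- function(x, a) {
  d <- .dims4(x$value)
  aexp <- a$value[, , rep(1L, d[3]), , drop = FALSE]
  tensor(x$value * aexp, parents = list(x, a), backward = function(g) {
    m <- g * x$value
    dim(m) <- c(d[1] * d[2], d[3], d[4])
    da <- array(0, dim = c(d[1] * d[2], d[4]))
    for (ci in seq_len(d[3])) da <- da + m[, ci, ]
    dim(da) <- c(d[1], d[2], 1, d[4])
    list(g * aexp, da)
  })
}

# x: (H,W,C,N) scaled by per-channel weights a: (1,1,C,N)
op_scale_channel <- function(x, a) {
  d <- .dims4(x$value)
  aexp <- array(rep(as.vector(a$value), each = d[1] * d[2]), dim = d)
  tensor(x$value * aexp, parents = list(x, a), backward = function(g) {
    m <- g * x$value
    dim(m) <- c(d[1] * d[2], d[3] * d[4])
    da <- array(colSums(m), dim = c(1, 1, d[3], d[4]))
    list(g * aexp, da)
  })
}

# ---- bilinear x2 upsampling (half-pixel center alignment) ----

.lin_map <- function(n_in) {
  n_out <- 2L * n_in
  f <- seq_len(n_out) / 2 + 0.25
  i0 <- floor(f)
  w <- f - i0
  i0 <- pmin(pmax(i0, 1L), n_in)
  i1 <- pmin(i0 + 1L, n_in)
  list(i0 = as.integer(i0), i1 = as.integer(i1), w = w)
}

.up_dim1 <- function(x, mp) {
  x[mp$i0, , , , drop = FALSE] * (1 - mp$w) + x[mp$i1, , , , drop = FALSE] * mp$w
}

.up_dim1_adj <- function(g, mp, n_in) {
  d <- dim(g)
  gm <- g
  dim(gm) <- c(d[1], prod(d[-1]))
  out <- matrix(0, n_in, prod(d[-1]))
  r0 <- rowsum(gm * (1 - mp$w), mp$i0)
  out[as.integer(rownames(r0)), ] <- out[as.integer(rownames(r0)), ] + r0
  r1 <- rowsum(gm * mp$w, mp$i1)
  out[as.integer(rownames(r1)), ] <- out[as.integer(rownames(r1)), ] + r1
  dim(out) <- c(n_in, d[-1])
  out
}

.swap12 <- function(x) aperm(x, c(2, 1, 3, 4))

op_upsample2 <- function(x) {
  d <- .dims4(x$value)
  mh <- .lin_map(d[1]); mw <- .lin_map(d[2])
  y <- .up_dim1(x$value, mh)
  y <- .swap12(.up_dim1(.swap12(y), mw))
  tensor(y, parents = list(x), backward = function(g) {
    dg <- .swap12(.up_dim1_adj(.swap12(g), mw, d[2]))
    list(.up_dim1_adj(dg, mh, d[1]))
  })
}

# ---- Haar subband stack ----
# (H,W,C,N) -> (H/2, W/2, 4C, N); per input channel c the output channels
# 4(c-1)+1..4 hold (ll, lh, hl, hh), under the averaging (/2) convention.

.haar_split4 <- function(x) {
  d <- dim(x)
  oj <- seq(1L, d[2], 2L); ej <- oj + 1L
  L <- (x[, oj, , , drop = FALSE] + x[, ej, , , drop = FALSE]) / 2
  Hh <- (x[, oj, , , drop = FALSE] - x[, ej, , , drop = FALSE]) / 2
  oi <- seq(1L, d[1], 2L); ei <- oi + 1L
  list(ll = (L[oi, , , , drop = FALSE] + L[ei, , , , drop = FALSE]) / 2,
       lh = (L[oi, , , , drop = FALSE] - L[ei, , , , drop = FALSE]) / 2,
       hl = (Hh[oi, , , , drop = FALSE] + Hh[ei, , , , drop = FALSE]) / 2,
       hh = (Hh[oi, , , , drop = FALSE] - Hh[ei, , , , drop = FALSE]) / 2)
}

# adjoint of .haar_split4 (each /2 pair stage is self-adjoint)
.haar_split4_adj <- function(dll, dlh, dhl, dhh, d) {
  h2 <- d[1] / 2
  dL <- array(0, dim = c(d[1], d[2] / 2, d[3], d[4]))
  dH <- dL
  oi <- seq(1L, d[1], 2L); ei <- oi + 1L
  dL[oi, , , ] <- (dll + dlh) / 2
  dL[ei, , , ] <- (dll - dlh) / 2
  dH[oi, , , ] <- (dhl + dhh) / 2
  dH[ei, , , ] <- (dhl - dhh) / 2
  dx <- array(0, dim = d)
  oj <- seq(1L, d[2], 2L); ej <- oj + 1L
  dx[, oj, , ] <- (dL + dH) / 2
  dx[, ej, , ] <- (dL - dH) / 2
  dx
}

op_haar_subbands <- function(x) {
  d <- .dims4(x$value)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L) {
    stop("Haar subband stage requires even spatial dimensions, got ",
         d[1], "x", d[2])
  }
  s <- .haar_split4(x$value)
  out <- array(0, dim = c(d[1] / 2, d[2] / 2, 4L * d[3], d[4]))
  sel <- seq(1L, 4L * d[3], 4L)
  out[, , sel, ] <- s$ll
  out[, , sel + 1L, ] <- s$lh
  out[, , sel + 2L, ] <- s$hl
  out[, , sel + 3L, ] <- s$hh
  tensor(out, parents = list(x), backward = function(g) {
    list(.haar_split4_adj(g[, , sel, , drop = FALSE],
                          g[, , sel + 1L, , drop = FALSE],
                          g[, , sel + 2L, , drop = FALSE],
                          g[, , sel + 3L, , drop = FALSE], d))
  })
}
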