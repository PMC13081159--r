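# Layer containers (environments holding parameter tensors) and the
# RMSprop optimizer. Layers whose output feeds a batch-normalization are
# built without bias: BN subtracts the per-channel mean, so a preceding
# bias is exactly non-identifiable and would receive zero gradient.

.he_init <- function(kh, kw, cin_g, cout) {
  fan_in <- kh * kw * cin_g
  array(stats::rnorm(kh * kw * cin_g * cout, sd = sqrt(2 / fan_in)),
        dim = c(kh, kw, cin_g, cout))
}

conv_layer <- function(kh, kw, cin, cout, groups = 1L, pad = NULL,
                       bias = TRUE) {
  stopifnot(cin %% groups == 0L, cout %% groups == 0L)
  if (is.null(pad)) pad <- (kh - 1L) %/% 2L
  layer <- new.env(parent = emptyenv())
  layer$kind <- "conv"
  layer$kh <- kh; layer$kw <- kw; layer$cin <- cin; layer$cout <- cout
  layer$groups <- groups; layer$pad <- pad
  layer$w <- tensor(.he_init(kh, kw, cin %/% groups, cout),
                    requires_grad = TRUE)
  layer$b <- if (bias) tensor(array(0, dim = cout), requires_grad = TRUE)
  class(layer) <- "hf_layer"
  layer
}

bn_layer <- function(channels) {
  layer <- new.env(parent = emptyenv())
  layer$kind <- "bn"
  layer$channels <- channels
  layer$gamma <- tensor(array(1, dim = channels), requires_grad = TRUE)
  layer$beta <- tensor(array(0, dim = channels), requires_grad = TRUE)
  layer$running_mean <- rep(0, channels)
  layer$running_var <- rep(1, channels)
  class(layer) <- "hf_layer"
  layer
}

fwd_conv <- function(layer, x) {
  op_conv(x, layer$w, layer$b, pad = layer$pad, groups = layer$groups)
}

fwd_bn <- function(layer, x, training) {
  op_bn(x, layer$gamma, layer$beta, layer, training = training)
}

# Recursively collect parameter tensors from a nested model structure.
collect_params <- function(x) {
  if (is_tensor(x)) {
    if (x$requires_grad) return(list(x)) else return(list())
  }
  if (inherits(x, "hf_layer")) {
    out <- list()
    for (nm in c("w", "b", "gamma", "beta")) {
      if (!is.null(x[[nm]])) out <- c(out, list(x[[nm]]))
    }
    return(out)
  }
  if (is.list(x)) {
    out <- list()
    for (el in x) out <- c(out, collect_params(el))
    return(out)
  }
  list()
}

# Layers with running state (batch norm) in creation order.
collect_bn_layers <- function(x) {
  if (inherits(x, "hf_layer")) {
    return(if (identical(x$kind, "bn")) list(x) else list())
  }
  if (is.list(x)) {
    out <- list()
    for (el in x) out <- c(out, collect_bn_layers(el))
    return(out)
  }
  list()
}

rmsprop_step <- function(params, lr = 1e-4, alpha = 0.99, eps = 1e-8) {
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    if (is.null(p$rms_v)) p$rms_v <- g * 0
    p$rms_v <- alpha * p$rms_v + (1 - alpha) * g * g
    p$value <- p$value - lr * g / (sqrt(p$rms_v) + eps)
  }
  invisible(NULL)
}
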