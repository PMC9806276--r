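# Minimal neural-network kernels for the detector, in base R.
#
# Feature maps are numeric arrays of dim (H, W, C), one sample at a time
# (the public 4-axis (N, C, H, W) interface loops over N). Convolutions
# are evaluated by kernel-offset decomposition: a k x k convolution is a
# sum of k^2 strided-slice matrix products against (Cin x Cout) weight
# slabs, which keeps all heavy lifting in BLAS. Every layer stores what
# its backward pass needs; gradients are exact (checked against finite
# differences in the test suite).

NN_BN_EPS <- 1e-5
NN_BN_MOMENTUM <- 0.1

# ---- padding and slicing -------------------------------------------------

pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  xp
}

conv_out_len <- function(n, k, stride) (n + 2 * ((k - 1) %/% 2) - k) %/% stride + 1

# ---- dense convolution ---------------------------------------------------

conv_forward <- function(x, W, b, stride) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  p <- (k - 1) %/% 2
  H <- dim(x)[1]; Wd <- dim(x)[2]
  Ho <- conv_out_len(H, k, stride); Wo <- conv_out_len(Wd, k, stride)
  xp <- pad_hw(x, p)
  acc <- matrix(0, Ho * Wo, cout)
  for (i in seq_len(k)) {
    ri <- seq(i, by = stride, length.out = Ho)
    for (j in seq_len(k)) {
      cj <- seq(j, by = stride, length.out = Wo)
      sl <- xp[ri, cj, , drop = FALSE]
      dim(sl) <- c(Ho * Wo, cin)
      acc <- acc + sl %*% matrix(W[i, j, , ], cin, cout)
    }
  }
  if (!is.null(b)) acc <- acc + rep(b, each = Ho * Wo)
  dim(acc) <- c(Ho, Wo, cout)
  acc
}

conv_backward <- function(dy, x, W, stride, has_bias) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  p <- (k - 1) %/% 2
  H <- dim(x)[1]; Wd <- dim(x)[2]
  Ho <- dim(dy)[1]; Wo <- dim(dy)[2]
  xp <- pad_hw(x, p)
  dxp <- array(0, dim(xp))
  dW <- array(0, dim(W))
  dym <- dy; dim(dym) <- c(Ho * Wo, cout)
  for (i in seq_len(k)) {
    ri <- seq(i, by = stride, length.out = Ho)
    for (j in seq_len(k)) {
      cj <- seq(j, by = stride, length.out = Wo)
      sl <- xp[ri, cj, , drop = FALSE]
      dim(sl) <- c(Ho * Wo, cin)
      dW[i, j, , ] <- crossprod(sl, dym)
      dsl <- dym %*% t(matrix(W[i, j, , ], cin, cout))
      dim(dsl) <- c(Ho, Wo, cin)
      dxp[ri, cj, ] <- dxp[ri, cj, ] + dsl
    }
  }
  dx <- dxp[p + seq_len(H), p + seq_len(Wd), , drop = FALSE]
  list(dx = dx, dW = dW, db = if (has_bias) colSums(dym) else NULL)
}

# ---- depthwise convolution ----------------------------------------------

dwconv_forward <- function(x, W, stride) {
  k <- dim(W)[1]; ch <- dim(W)[3]
  p <- (k - 1) %/% 2
  H <- dim(x)[1]; Wd <- dim(x)[2]
  Ho <- conv_out_len(H, k, stride); Wo <- conv_out_len(Wd, k, stride)
  xp <- pad_hw(x, p)
  acc <- matrix(0, Ho * Wo, ch)
  for (i in seq_len(k)) {
    ri <- seq(i, by = stride, length.out = Ho)
    for (j in seq_len(k)) {
      cj <- seq(j, by = stride, length.out = Wo)
      sl <- xp[ri, cj, , drop = FALSE]
      dim(sl) <- c(Ho * Wo, ch)
      acc <- acc + sl * rep(W[i, j, ], each = Ho * Wo)
    }
  }
  dim(acc) <- c(Ho, Wo, ch)
  acc
}

dwconv_backward <- function(dy, x, W, stride) {
  k <- dim(W)[1]; ch <- dim(W)[3]
  p <- (k - 1) %/% 2
  H <- dim(x)[1]; Wd <- dim(x)[2]
  Ho <- dim(dy)[1]; Wo <- dim(dy)[2]
  xp <- pad_hw(x, p)
  dxp <- array(0, dim(xp))
  dW <- array(0, dim(W))
  dym <- dy; dim(dym) <- c(Ho * Wo, ch)
  for (i in seq_len(k)) {
    ri <- seq(i, by = stride, length.out = Ho)
    for (j in seq_len(k)) {
      cj <- seq(j, by = stride, length.out = Wo)
      sl <- xp[ri, cj, , drop = FALSE]
      dim(sl) <- c(Ho * Wo, ch)
      dW[i, j, ] <- colSums(sl * dym)
      dsl <- dym * rep(W[i, j, ], each = Ho * Wo)
      dim(dsl) <- c(Ho, Wo, ch)
      dxp[ri, cj, ] <- dxp[ri, cj, ] + dsl
    }
  }
  list(dx = dxp[p + seq_len(H), p + seq_len(Wd), , drop = FALSE], dW = dW)
}

# ---- batch normalisation (per channel over H x W) ------------------------

bn_forward <- function(x, layer, train) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- x; dim(xm) <- c(n, d[3])
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    layer$run_mu <- (1 - NN_BN_MOMENTUM) * layer$run_mu + NN_BN_MOMENTUM * mu
    layer$run_var <- (1 - NN_BN_MOMENTUM) * layer$run_var + NN_BN_MOMENTUM * v
  } else {
    mu <- layer$run_mu
    v <- layer$run_var
  }
  inv_std <- 1 / sqrt(v + NN_BN_EPS)
  xhat <- (xm - rep(mu, each = n)) * rep(inv_std, each = n)
  y <- xhat * rep(layer$gamma, each = n) + rep(layer$beta, each = n)
  dim(y) <- d
  layer$bn_cache <- list(xhat = xhat, inv_std = inv_std, train = train)
  y
}

bn_backward <- function(dy, layer) {
  cc <- layer$bn_cache
  d <- dim(dy); n <- d[1] * d[2]
  dym <- dy; dim(dym) <- c(n, d[3])
  layer$g_gamma <- layer$g_gamma + colSums(dym * cc$xhat)
  layer$g_beta <- layer$g_beta + colSums(dym)
  dxhat <- dym * rep(layer$gamma, each = n)
  if (cc$train) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * cc$xhat)
    dxm <- (dxhat - rep(m1, each = n) - cc$xhat * rep(m2, each = n)) *
      rep(cc$inv_std, each = n)
  } else {
    dxm <- dxhat * rep(cc$inv_std, each = n)
  }
  dim(dxm) <- d
  dxm
}

# ---- activations ---------------------------------------------------------

act_forward <- function(x, type) {
  switch(type,
    linear = x,
    relu = pmax(x, 0),
    hswish = x * pmin(pmax(x + 3, 0), 6) / 6,
    sigmoid = 1 / (1 + exp(-x)),
    stop("unknown activation: ", type))
}

act_grad <- function(x, type) {
  switch(type,
    linear = array(1, dim(x)),
    relu = (x > 0) * 1,
    hswish = ifelse(x <= -3, 0, ifelse(x >= 3, 1, (2 * x + 3) / 6)),
    sigmoid = { s <- 1 / (1 + exp(-x)); s * (1 - s) },
    stop("unknown activation: ", type))
}

# ---- parameter initialisation -------------------------------------------

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  e
}

# conv (+ optional BN) (+ activation); bias only when BN is off
l_conv <- function(cin, cout, k = 1, stride = 1, act = "hswish",
                   use_bn = TRUE) {
  l <- new_layer("conv", cin = cin, cout = cout, k = k, stride = stride,
                 act = act, use_bn = use_bn,
                 W = he_init(c(k, k, cin, cout), k * k * cin))
  if (use_bn) {
    l$gamma <- rep(1, cout); l$beta <- rep(0, cout)
    l$run_mu <- rep(0, cout); l$run_var <- rep(1, cout)
  } else {
    l$b <- rep(0, cout)
  }
  l
}

l_dwconv <- function(ch, k = 3, stride = 1, act = "relu") {
  l <- new_layer("dwconv", ch = ch, k = k, stride = stride, act = act,
                 W = he_init(c(k, k, ch), k * k))
  l$gamma <- rep(1, ch); l$beta <- rep(0, ch)
  l$run_mu <- rep(0, ch); l$run_var <- rep(1, ch)
  l
}

l_se <- function(ch, reduction = 4) {
  if (ch %% reduction != 0) {
    stop_config(sprintf(
      "SE block: %d channels not divisible by reduction %d", ch, reduction))
  }
  hidden <- ch %/% reduction
  new_layer("se", ch = ch, hidden = hidden,
            W1 = he_init(c(ch, hidden), ch), b1 = rep(0, hidden),
            W2 = he_init(c(hidden, ch), hidden), b2 = rep(0, ch))
}

l_bneck <- function(cin, cexp, cout, k = 3, stride = 1, use_se = FALSE,
                    act = "relu", se_reduction = 4) {
  new_layer("bneck", cin = cin, cexp = cexp, cout = cout,
            stride = stride, shortcut = (stride == 1 && cin == cout),
            expand = if (cexp != cin) l_conv(cin, cexp, 1, 1, act) else NULL,
            dw = l_dwconv(cexp, k, stride, act),
            se = if (use_se) l_se(cexp, se_reduction) else NULL,
            project = l_conv(cexp, cout, 1, 1, "linear"))
}

# ---- layer forward / backward -------------------------------------------

layer_forward <- function(l, x, train = FALSE) {
  switch(l$type,
    conv = {
      l$x <- x
      z <- conv_forward(x, l$W, if (l$use_bn) NULL else l$b, l$stride)
      if (l$use_bn) z <- bn_forward(z, l, train)
      l$z <- z
      act_forward(z, l$act)
    },
    dwconv = {
      l$x <- x
      z <- dwconv_forward(x, l$W, l$stride)
      z <- bn_forward(z, l, train)
      l$z <- z
      act_forward(z, l$act)
    },
    se = {
      d <- dim(x); n <- d[1] * d[2]
      xm <- x; dim(xm) <- c(n, d[3])
      s <- colMeans(xm)
      z1 <- drop(s %*% l$W1) + l$b1
      h <- pmax(z1, 0)
      z2 <- drop(h %*% l$W2) + l$b2
      wgt <- 1 / (1 + exp(-z2))
      y <- xm * rep(wgt, each = n)
      dim(y) <- d
      l$cache <- list(xm = xm, s = s, z1 = z1, h = h, wgt = wgt, d = d)
      y
    },
    bneck = {
      l$x <- x
      h <- x
      if (!is.null(l$expand)) h <- layer_forward(l$expand, h, train)
      h <- layer_forward(l$dw, h, train)
      if (!is.null(l$se)) h <- layer_forward(l$se, h, train)
      h <- layer_forward(l$project, h, train)
      if (l$shortcut) h <- h + x
      h
    },
    stop("unknown layer type: ", l$type))
}

layer_backward <- function(l, dy) {
  switch(l$type,
    conv = {
      dz <- dy * act_grad(l$z, l$act)
      if (l$use_bn) {
        dz <- bn_backward(dz, l)
        gr <- conv_backward(dz, l$x, l$W, l$stride, has_bias = FALSE)
      } else {
        gr <- conv_backward(dz, l$x, l$W, l$stride, has_bias = TRUE)
        l$g_b <- l$g_b + gr$db
      }
      l$g_W <- l$g_W + gr$dW
      gr$dx
    },
    dwconv = {
      dz <- dy * act_grad(l$z, l$act)
      dz <- bn_backward(dz, l)
      gr <- dwconv_backward(dz, l$x, l$W, l$stride)
      l$g_W <- l$g_W + gr$dW
      gr$dx
    },
    se = {
      cc <- l$cache
      n <- cc$d[1] * cc$d[2]
      dym <- dy; dim(dym) <- c(n, cc$d[3])
      dwgt <- colSums(dym * cc$xm)
      dx1 <- dym * rep(cc$wgt, each = n)
      dz2 <- dwgt * cc$wgt * (1 - cc$wgt)
      l$g_W2 <- l$g_W2 + outer(cc$h, dz2)
      l$g_b2 <- l$g_b2 + dz2
      dh <- drop(l$W2 %*% dz2)
      dz1 <- dh * (cc$z1 > 0)
      l$g_W1 <- l$g_W1 + outer(cc$s, dz1)
      l$g_b1 <- l$g_b1 + dz1
      ds <- drop(l$W1 %*% dz1)
      dx <- dx1 + rep(ds / n, each = n)
      dim(dx) <- cc$d
      dx
    },
    bneck = {
      d <- layer_backward(l$project, dy)
      if (!is.null(l$se)) d <- layer_backward(l$se, d)
      d <- layer_backward(l$dw, d)
      if (!is.null(l$expand)) d <- layer_backward(l$expand, d)
      if (l$shortcut) d <- d + dy
      d
    },
    stop("unknown layer type: ", l$type))
}

# ---- nearest-neighbour 2x upsampling ------------------------------------

upsample2_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
    drop = FALSE]
}

upsample2_backward <- function(dy) {
  d <- dim(dy)
  odd_r <- seq(1, d[1], by = 2); odd_c <- seq(1, d[2], by = 2)
  dy[odd_r, odd_c, , drop = FALSE] +
    dy[odd_r + 1, odd_c, , drop = FALSE] +
    dy[odd_r, odd_c + 1, , drop = FALSE] +
    dy[odd_r + 1, odd_c + 1, , drop = FALSE]
}

# ---- parameter bookkeeping ----------------------------------------------

layer_param_names <- function(l) {
  switch(l$type,
    conv = if (l$use_bn) c("W", "gamma", "beta") else c("W", "b"),
    dwconv = c("W", "gamma", "beta"),
    se = c("W1", "b1", "W2", "b2"),
    bneck = character(0))
}

# flat list of references (layer env + field name) over a layer tree
collect_params <- function(l) {
  if (l$type == "bneck") {
    subs <- Filter(Negate(is.null), list(l$expand, l$dw, l$se, l$project))
    return(do.call(c, lapply(subs, collect_params)))
  }
  lapply(layer_param_names(l), function(nm) list(layer = l, name = nm))
}

zero_grads <- function(params) {
  for (p in params) {
    val <- get(p$name, envir = p$layer)
    assign(paste0("g_", p$name),
           if (is.array(val)) array(0, dim(val)) else numeric(length(val)),
           envir = p$layer)
  }
}

n_param_values <- function(params) {
  sum(vapply(params, function(p) length(get(p$name, envir = p$layer)),
             numeric(1)))
}

# deep copy / restore of parameter values (checkpointing)
snapshot_params <- function(params) {
  lapply(params, function(p) get(p$name, envir = p$layer))
}

restore_params <- function(params, snap) {
  for (i in seq_along(params)) {
    assign(params[[i]]$name, snap[[i]], envir = params[[i]]$layer)
  }
}

# running BN statistics live outside `params`; snapshot them separately
collect_bn_layers <- function(l) {
  if (l$type == "bneck") {
    subs <- Filter(Negate(is.null), list(l$expand, l$dw, l$se, l$project))
    return(do.call(c, lapply(subs, collect_bn_layers)))
  }
  if (l$type %in% c("conv", "dwconv") && !is.null(l$run_mu)) list(l) else list()
}

# ---- Adam optimiser ------------------------------------------------------

adam_state <- function(params) {
  lapply(params, function(p) {
    val <- get(p$name, envir = p$layer)
    list(m = if (is.array(val)) array(0, dim(val)) else numeric(length(val)),
         v = if (is.array(val)) array(0, dim(val)) else numeric(length(val)))
  })
}

adam_step <- function(params, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- get(paste0("g_", p$name), envir = p$layer)
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    state[[i]] <- st
    val <- get(p$name, envir = p$layer)
    assign(p$name, val - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps),
           envir = p$layer)
  }
  state
}

#' Cosine-annealed learning rate
#'
#' `lr(t) = lr_min + (lr_max - lr_min) * (1 + cos(pi t / T)) / 2`, so the
#' schedule starts at `lr_max` at `t = 0` and ends at `lr_min` at `t = T`.
#'
#' @param t current step (0-based), `0 <= t <= t_total`.
#' @param t_total total number of steps in the annealing cycle.
#' @param lr_max,lr_min endpoints of the schedule.
#' @return the learning rate at step `t`.
#' @export
cosine_lr <- function(t, t_total, lr_max, lr_min = lr_max / 100) {
  lr_min + (lr_max - lr_min) * (1 + cos(pi * t / t_total)) / 2
}
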