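# Shared toy fixtures for detector tests (built in code, deterministic).

toy_samples <- function(n = 10, size = 64, seed = 7) {
  gen_detection_data(n, size = size, weeds_per_image = 2, seed = seed)
}

toy_anchors <- function(samples, seed = 1) {
  wh <- do.call(rbind, lapply(samples, function(s) {
    cbind(s$boxes$x2 - s$boxes$x1, s$boxes$y2 - s$boxes$y1)
  }))
  if (nrow(wh) < 9) wh <- wh[rep(seq_len(nrow(wh)), length.out = 9), ]
  unclass(kmeans_anchors(wh, k = 9, seed = seed))
}

toy_detector <- function(samples = NULL, size = 64, seed = 1) {
  anchors <- if (!is.null(samples)) toy_anchors(samples) else NULL
  cfg <- detector_config(input_size = size, width_mult = 0.25,
                         neck_channels = 32, anchors = anchors)
  build_detector(cfg, seed = seed)
}

# add small random jitter to every parameter: moves BN shifts and SE
# pre-activations off their measure-zero initial values (exact zeros sit
# on the ReLU kink, where two-sided finite differences are undefined)
jitter_params <- function(params, sd = 0.05, seed = 99) {
  set.seed(seed)
  for (p in params) {
    val <- get(p$name, envir = p$layer)
    assign(p$name, val + stats::rnorm(length(val), 0, sd), envir = p$layer)
  }
}

# naive direct convolution oracle (same padding): quadruple loop
naive_conv <- function(x, W, stride) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  p <- (k - 1) %/% 2
  H <- dim(x)[1]; Wd <- dim(x)[2]
  Ho <- (H + 2 * p - k) %/% stride + 1
  Wo <- (Wd + 2 * p - k) %/% stride + 1
  xp <- array(0, c(H + 2 * p, Wd + 2 * p, cin))
  xp[p + seq_len(H), p + seq_len(Wd), ] <- x
  y <- array(0, c(Ho, Wo, cout))
  for (oi in seq_len(Ho)) for (oj in seq_len(Wo)) for (oc in seq_len(cout)) {
    acc <- 0
    for (ki in seq_len(k)) for (kj in seq_len(k)) for (ci in seq_len(cin)) {
      acc <- acc + xp[(oi - 1) * stride + ki, (oj - 1) * stride + kj, ci] *
        W[ki, kj, ci, oc]
    }
    y[oi, oj, oc] <- acc
  }
  y
}

# brute-force MAC counter: one multiply per (output position, input
# channel, kernel tap) resp. per (output position, cin, cout)
count_macs_dsc <- function(h, w, c_in, c_out, k, stride = 1) {
  p <- (k - 1) %/% 2
  ho <- (h + 2 * p - k) %/% stride + 1
  wo <- (w + 2 * p - k) %/% stride + 1
  dw <- 0; pw <- 0
  for (i in seq_len(ho)) for (j in seq_len(wo)) {
    dw <- dw + c_in * k * k
    pw <- pw + c_in * c_out
  }
  dw + pw
}

count_macs_std <- function(h, w, c_in, c_out, k, stride = 1) {
  p <- (k - 1) %/% 2
  ho <- (h + 2 * p - k) %/% stride + 1
  wo <- (w + 2 * p - k) %/% stride + 1
  total <- 0
  for (i in seq_len(ho)) for (j in seq_len(wo)) {
    total <- total + k * k * c_in * c_out
  }
  total
}
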