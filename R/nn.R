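# Minimal neural-network core shared by the GAN, the segmenter and the
# classifier.  Tensors are numeric arrays (H, W, C); convolutions are 3x3,
# stride 1, zero-padded (implemented in src/convops.cpp).  Backpropagation is
# written out layer by layer; nothing here depends on an external framework.

as_t3 <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

he_weights <- function(k, cin, cout, gain = sqrt(2)) {
  array(stats::rnorm(k * k * cin * cout, sd = gain / sqrt(k * k * cin)),
        dim = c(k, k, cin, cout))
}

conv_layer <- function(cin, cout, k = 3L, gain = sqrt(2)) {
  list(kind = "conv", W = he_weights(k, cin, cout, gain), b = numeric(cout),
       k = k)
}
in_layer <- function(c) list(kind = "in", g = rep(1, c), b = numeric(c))
leaky_layer <- function(a = 0.2) list(kind = "leaky", a = a)
tanh_layer <- function() list(kind = "tanh")

# A plain conv tower: head conv -> [norm] -> leaky, (n_layers - 2) body
# blocks, tail conv with optional tanh.  Used for the per-scale GAN
# generator (norm = TRUE, tanh tail) and critic (norm = FALSE, linear tail).
make_tower <- function(cin, cmid, cout, n_layers, norm = TRUE, leak = 0.2,
                       tail = c("tanh", "none")) {
  tail <- match.arg(tail)
  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l
  add(conv_layer(cin, cmid))
  if (norm) add(in_layer(cmid))
  add(leaky_layer(leak))
  if (n_layers > 2L) {
    for (i in seq_len(n_layers - 2L)) {
      add(conv_layer(cmid, cmid))
      if (norm) add(in_layer(cmid))
      add(leaky_layer(leak))
    }
  }
  add(conv_layer(cmid, cout, gain = 1))
  if (tail == "tanh") add(tanh_layer())
  layers
}

in_fwd <- function(layer, x) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  sd <- sqrt(colMeans(xc^2) + 1e-5)
  xhat <- sweep(xc, 2, sd, "/")
  y <- sweep(sweep(xhat, 2, layer$g, "*"), 2, layer$b, "+")
  list(out = array(y, d), cache = list(xhat = xhat, sd = sd, d = d))
}

in_bwd <- function(layer, cache, gy) {
  d <- cache$d
  n <- d[1] * d[2]
  gym <- matrix(gy, n, d[3])
  gg <- colSums(gym * cache$xhat)
  gb <- colSums(gym)
  gxhat <- sweep(gym, 2, layer$g, "*")
  m1 <- colMeans(gxhat)
  m2 <- colMeans(gxhat * cache$xhat)
  gx <- sweep(sweep(sweep(gxhat, 2, m1), 1, rep(1, n), "*") -
                sweep(cache$xhat, 2, m2, "*"), 2, cache$sd, "/")
  list(g = array(gx, d), grads = list(g = gg, b = gb))
}

# Forward pass through a tower; cache holds what backward needs.  When
# `record_t` is set (gradient-penalty double backprop) net_input_grad also
# records the gradient entering each conv layer.
net_fwd <- function(layers, x) {
  x <- as_t3(x)
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$kind == "conv") {
      caches[[i]] <- list(x = x)
      x <- cpp_conv_fwd(x, l$W, l$b)
    } else if (l$kind == "in") {
      f <- in_fwd(l, x)
      caches[[i]] <- f$cache
      x <- f$out
    } else if (l$kind == "leaky") {
      m <- ifelse(x > 0, 1, l$a)
      caches[[i]] <- list(m = m)
      x <- x * m
    } else if (l$kind == "tanh") {
      x <- tanh(x)
      caches[[i]] <- list(y = x)
    }
  }
  list(out = x, caches = caches)
}

# Backward pass: returns input gradient, per-layer parameter gradients and,
# for conv layers, the gradient that entered the layer (needed by the
# gradient-penalty pass).
net_bwd <- function(layers, caches, g) {
  grads <- vector("list", length(layers))
  tins <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$kind == "conv") {
      tins[[i]] <- g
      gw <- cpp_conv_gradw(caches[[i]]$x, g, l$k)
      grads[[i]] <- list(W = gw$gw, b = gw$gb)
      g <- cpp_conv_gradx(g, l$W)
    } else if (l$kind == "in") {
      bk <- in_bwd(l, caches[[i]], g)
      grads[[i]] <- bk$grads
      g <- bk$g
    } else if (l$kind == "leaky") {
      g <- g * caches[[i]]$m
    } else if (l$kind == "tanh") {
      g <- g * (1 - caches[[i]]$y^2)
    }
  }
  list(g = g, grads = grads, tins = tins)
}

# Input gradient only (no parameter gradients): used to push the critic's
# signal into the generator and to evaluate grad_x D for the penalty.
net_input_grad <- function(layers, caches, g) {
  tins <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$kind == "conv") {
      tins[[i]] <- g
      g <- cpp_conv_gradx(g, l$W)
    } else if (l$kind == "leaky") {
      g <- g * caches[[i]]$m
    } else if (l$kind == "tanh") {
      g <- g * (1 - caches[[i]]$y^2)
    } else if (l$kind == "in") {
      stop("input-grad pass not supported through normalization layers")
    }
  }
  list(g = g, tins = tins)
}

# Double backprop for the gradient penalty of a piecewise-linear critic
# (conv + leaky only).  `tins` are the gradients that entered each conv
# layer while computing g = grad_x D; `s` is dPenalty/dg.  Activation masks
# are treated as constants (exact almost everywhere for leaky rectifiers).
net_gp_grads <- function(layers, caches, tins, s) {
  grads <- vector("list", length(layers))
  zero_b <- NULL
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$kind == "conv") {
      gw <- cpp_conv_gradw(s, tins[[i]], l$k)$gw
      grads[[i]] <- list(W = gw, b = numeric(length(l$b)))
      s <- cpp_conv_fwd(s, l$W, numeric(dim(l$W)[4]))
    } else if (l$kind == "leaky") {
      s <- s * caches[[i]]$m
    } else {
      stop("gradient penalty requires a conv/leaky critic")
    }
  }
  grads
}

# --- optimizers ------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (is.null(l$W) && is.null(l$g)) return(NULL)
    p <- if (!is.null(l$W)) list(W = l$W, b = l$b) else list(g = l$g, b = l$b)
    list(m = lapply(p, function(z) z * 0), v = lapply(p, function(z) z * 0),
         t = 0)
  })
}

adam_step <- function(layers, grads, state, lr, b1 = 0.5, b2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]])) next
    st <- state[[i]]
    st$t <- st$t + 1
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
      st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
      mhat <- st$m[[nm]] / (1 - b1^st$t)
      vhat <- st$v[[nm]] / (1 - b2^st$t)
      layers[[i]][[nm]] <- layers[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    state[[i]] <- st
  }
  list(layers = layers, state = state)
}

sgd_step <- function(layers, grads, lr) {
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]]))
      layers[[i]][[nm]] <- layers[[i]][[nm]] - lr * grads[[i]][[nm]]
  }
  layers
}

acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(b)) {
    if (is.null(b[[i]])) next
    for (nm in names(b[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  }
  a
}

scale_grads <- function(g, f) {
  lapply(g, function(l) if (is.null(l)) NULL else lapply(l, function(z) z * f))
}

# --- resampling helpers ----------------------------------------------------

up_nearest2 <- function(x) {
  x <- as_t3(x)
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

down_sum2 <- function(g) {
  d <- dim(g)
  h <- d[1] / 2; w <- d[2] / 2
  out <- array(0, c(h, w, d[3]))
  for (c in seq_len(d[3])) {
    m <- g[, , c]
    out[, , c] <- m[seq(1, d[1], 2), seq(1, d[2], 2)] +
      m[seq(2, d[1], 2), seq(1, d[2], 2)] +
      m[seq(1, d[1], 2), seq(2, d[2], 2)] +
      m[seq(2, d[1], 2), seq(2, d[2], 2)]
  }
  out
}

# Bilinear / nearest resize of a plain matrix via EBImage.
resize_matrix <- function(m, h, w, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (nrow(m) == h && ncol(m) == w) return(m)
  filt <- if (method == "bilinear") "bilinear" else "none"
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(m), w = h, h = w,
                                            filter = filt, antialias = FALSE))
  dim(out) <- c(h, w)
  out
}
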