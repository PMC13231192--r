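# Minimal feed-forward layer framework with explicit forward/backward passes.
# A network is a nested list: type "seq" (children in $layers) or a leaf layer
# ("conv", "bn", "relu", "maxpool", "resblock"). Parameters live in $par,
# non-learnable state (batch-norm running moments) in $buf. All passes are
# functional: forward returns the (possibly updated) network alongside the
# output and a cache; backward returns input gradients plus a gradient
# structure mirroring $par.

nn_conv <- function(cin, cout, k, stride = 1L, pad = 0L, bias = TRUE) {
  # He initialisation, appropriate for ReLU nets
  w <- matrix(rnorm(cout * k * k * cin, sd = sqrt(2 / (k * k * cin))),
              nrow = cout)
  par <- list(w = w)
  if (bias) par$b <- numeric(cout)
  list(type = "conv", par = par,
       cfg = list(cin = cin, cout = cout, k = as.integer(k),
                  stride = as.integer(stride), pad = as.integer(pad),
                  bias = bias))
}

nn_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  list(type = "bn",
       par = list(gamma = rep(1, c), beta = numeric(c)),
       buf = list(rm = numeric(c), rv = rep(1, c)),
       cfg = list(c = as.integer(c), eps = eps, momentum = momentum))
}

nn_relu <- function() list(type = "relu", par = list())

nn_maxpool <- function(k, stride, pad = 0L)
  list(type = "maxpool", par = list(),
       cfg = list(k = as.integer(k), stride = as.integer(stride),
                  pad = as.integer(pad)))

nn_seq <- function(...) list(type = "seq", layers = list(...))

# residual basic block (two 3x3 convs; 1x1 projection shortcut when needed)
nn_resblock <- function(cin, cout, stride = 1L) {
  short <- NULL
  if (stride != 1L || cin != cout)
    short <- list(conv = nn_conv(cin, cout, 1L, stride, 0L, bias = FALSE),
                  bn = nn_bn(cout))
  list(type = "resblock",
       conv1 = nn_conv(cin, cout, 3L, stride, 1L, bias = FALSE),
       bn1 = nn_bn(cout),
       conv2 = nn_conv(cout, cout, 3L, 1L, 1L, bias = FALSE),
       bn2 = nn_bn(cout),
       short = short)
}

bn_fwd <- function(layer, x, training) {
  r <- bn_fwd_cpp(x, layer$par$gamma, layer$par$beta,
                  layer$buf$rm, layer$buf$rv, layer$cfg$eps,
                  layer$cfg$momentum, training)
  if (training) {
    layer$buf$rm <- r$rm
    layer$buf$rv <- r$rv
  }
  list(y = r$y, layer = layer,
       cache = list(xhat = r$xhat, sdv = r$sdv, training = training))
}

bn_bwd <- function(layer, cache, dy) {
  r <- bn_bwd_cpp(dy, cache$xhat, cache$sdv, layer$par$gamma, cache$training)
  list(dx = r$dx, grad = list(gamma = r$dgamma, beta = r$dbeta))
}

layer_fwd <- function(layer, x, training) {
  switch(layer$type,
    conv = {
      b <- if (isTRUE(layer$cfg$bias)) layer$par$b else numeric(0)
      y <- conv2d_fwd_cpp(x, layer$par$w, b, layer$cfg$stride, layer$cfg$pad)
      list(y = y, layer = layer, cache = list(x = x))
    },
    bn = bn_fwd(layer, x, training),
    relu = {
      y <- pmax(x, 0)
      dim(y) <- dim(x)
      list(y = y, layer = layer, cache = list(pos = x > 0))
    },
    maxpool = {
      r <- maxpool_fwd_cpp(x, layer$cfg$k, layer$cfg$stride, layer$cfg$pad)
      list(y = r$y, layer = layer, cache = list(idx = r$idx, xdim = dim(x)))
    },
    seq = {
      caches <- vector("list", length(layer$layers))
      for (i in seq_along(layer$layers)) {
        r <- layer_fwd(layer$layers[[i]], x, training)
        layer$layers[[i]] <- r$layer
        caches[[i]] <- r$cache
        x <- r$y
      }
      list(y = x, layer = layer, cache = caches)
    },
    resblock = {
      r1 <- layer_fwd(layer$conv1, x, training); layer$conv1 <- r1$layer
      r2 <- layer_fwd(layer$bn1, r1$y, training); layer$bn1 <- r2$layer
      a <- pmax(r2$y, 0); dim(a) <- dim(r2$y)
      r3 <- layer_fwd(layer$conv2, a, training); layer$conv2 <- r3$layer
      r4 <- layer_fwd(layer$bn2, r3$y, training); layer$bn2 <- r4$layer
      if (is.null(layer$short)) {
        sh <- x; csh <- NULL
      } else {
        s1 <- layer_fwd(layer$short$conv, x, training); layer$short$conv <- s1$layer
        s2 <- layer_fwd(layer$short$bn, s1$y, training); layer$short$bn <- s2$layer
        sh <- s2$y; csh <- list(c1 = s1$cache, c2 = s2$cache)
      }
      pre <- r4$y + sh
      y <- pmax(pre, 0); dim(y) <- dim(pre)
      list(y = y, layer = layer,
           cache = list(c1 = r1$cache, c2 = r2$cache, relu1 = r2$y > 0,
                        c3 = r3$cache, c4 = r4$cache, csh = csh,
                        relu2 = pre > 0))
    },
    stop("unknown layer type: ", layer$type))
}

layer_bwd <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      r <- conv2d_bwd_cpp(cache$x, layer$par$w, dy, layer$cfg$stride,
                          layer$cfg$pad, isTRUE(layer$cfg$bias))
      g <- list(w = r$dw)
      if (isTRUE(layer$cfg$bias)) g$b <- r$db
      list(dx = r$dx, grad = g)
    },
    bn = bn_bwd(layer, cache, dy),
    relu = {
      dx <- dy * cache$pos
      dim(dx) <- dim(dy)
      list(dx = dx, grad = list())
    },
    maxpool = list(dx = maxpool_bwd_cpp(dy, cache$idx, cache$xdim),
                   grad = list()),
    seq = {
      grads <- vector("list", length(layer$layers))
      for (i in rev(seq_along(layer$layers))) {
        r <- layer_bwd(layer$layers[[i]], cache[[i]], dy)
        grads[[i]] <- r$grad
        dy <- r$dx
      }
      list(dx = dy, grad = grads)
    },
    resblock = {
      dpre <- dy * cache$relu2
      dim(dpre) <- dim(dy)
      g4 <- layer_bwd(layer$bn2, cache$c4, dpre)
      g3 <- layer_bwd(layer$conv2, cache$c3, g4$dx)
      da <- g3$dx * cache$relu1
      dim(da) <- dim(g3$dx)
      g2 <- layer_bwd(layer$bn1, cache$c2, da)
      g1 <- layer_bwd(layer$conv1, cache$c1, g2$dx)
      if (is.null(layer$short)) {
        dx <- g1$dx + dpre
        gsh <- NULL
      } else {
        s2 <- layer_bwd(layer$short$bn, cache$csh$c2, dpre)
        s1 <- layer_bwd(layer$short$conv, cache$csh$c1, s2$dx)
        dx <- g1$dx + s1$dx
        gsh <- list(conv = s1$grad, bn = s2$grad)
      }
      list(dx = dx,
           grad = list(conv1 = g1$grad, bn1 = g2$grad,
                       conv2 = g3$grad, bn2 = g4$grad, short = gsh))
    },
    stop("unknown layer type: ", layer$type))
}

# extract / re-insert the learnable parameters of a network (nested list
# mirroring the network structure; leaves are numeric arrays)
net_params <- function(layer) {
  if (is.null(layer)) return(NULL)
  switch(layer$type,
    seq = lapply(layer$layers, net_params),
    resblock = list(conv1 = layer$conv1$par, bn1 = layer$bn1$par,
                    conv2 = layer$conv2$par, bn2 = layer$bn2$par,
                    short = if (is.null(layer$short)) NULL else
                      list(conv = layer$short$conv$par, bn = layer$short$bn$par)),
    layer$par)
}

net_set_params <- function(layer, p) {
  if (is.null(layer)) return(NULL)
  switch(layer$type,
    seq = {
      for (i in seq_along(layer$layers))
        layer$layers[[i]] <- net_set_params(layer$layers[[i]], p[[i]])
      layer
    },
    resblock = {
      layer$conv1$par <- p$conv1; layer$bn1$par <- p$bn1
      layer$conv2$par <- p$conv2; layer$bn2$par <- p$bn2
      if (!is.null(layer$short)) {
        layer$short$conv$par <- p$short$conv
        layer$short$bn$par <- p$short$bn
      }
      layer
    },
    { layer$par <- p; layer })
}
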