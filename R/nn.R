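# Seeded, deterministic dense-network engine: forward/backward passes with
# batch normalization, inverted dropout, RMSprop and Adam. All randomness
# (weight init, batch shuffling, dropout masks) flows through R's RNG, so a
# fixed seed gives bit-identical training runs on the same platform.

nn_new <- function(sizes, activations, batchnorm = TRUE, dropout = 0) {
  stopifnot(length(sizes) >= 2, length(activations) == length(sizes) - 1)
  layers <- vector("list", length(sizes) - 1)
  for (l in seq_along(layers)) {
    d_in <- sizes[l]; d_out <- sizes[l + 1]
    limit <- sqrt(6 / (d_in + d_out))
    last <- l == length(layers)
    layers[[l]] <- list(
      W = matrix(runif(d_in * d_out, -limit, limit), d_in, d_out),
      b = rep(0, d_out),
      act = activations[l],
      # batch norm and dropout on hidden layers only, never on the output
      bn = if (batchnorm && !last) {
        list(gamma = rep(1, d_out), beta = rep(0, d_out),
             rmean = rep(0, d_out), rvar = rep(1, d_out))
      },
      dropout = if (!last) dropout else 0
    )
  }
  structure(list(layers = layers, sizes = sizes), class = "dense_net")
}

act_fun <- function(z, act) {
  switch(act,
    sigmoid = 1 / (1 + exp(-z)),
    relu = pmax(z, 0),
    linear = z,
    abort(paste0("unknown activation: ", act))
  )
}

act_grad <- function(a, z, act) {
  switch(act,
    sigmoid = a * (1 - a),
    relu = (z > 0) * 1,
    linear = array(1, dim(z)),
    abort(paste0("unknown activation: ", act))
  )
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  a <- x
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    z <- a %*% ly$W
    z <- sweep(z, 2, ly$b, "+")
    cache <- list(x = a, z = z)
    if (!is.null(ly$bn)) {
      if (training) {
        mu <- colMeans(z)
        v <- colMeans(z^2) - mu^2
        net$layers[[l]]$bn$rmean <- BN_MOMENTUM * ly$bn$rmean + (1 - BN_MOMENTUM) * mu
        net$layers[[l]]$bn$rvar <- BN_MOMENTUM * ly$bn$rvar + (1 - BN_MOMENTUM) * v
      } else {
        mu <- ly$bn$rmean
        v <- ly$bn$rvar
      }
      zc <- sweep(z, 2, mu, "-")
      inv_sd <- 1 / sqrt(v + BN_EPS)
      zn <- sweep(zc, 2, inv_sd, "*")
      zb <- sweep(sweep(zn, 2, ly$bn$gamma, "*"), 2, ly$bn$beta, "+")
      cache$zn <- zn; cache$inv_sd <- inv_sd; cache$zb <- zb
    } else {
      zb <- z
    }
    a <- act_fun(zb, ly$act)
    cache$a_pre <- a
    if (training && ly$dropout > 0) {
      mask <- matrix(runif(length(a)) >= ly$dropout, nrow(a), ncol(a)) /
        (1 - ly$dropout)
      a <- a * mask
      cache$mask <- mask
    }
    caches[[l]] <- cache
  }
  list(out = a, caches = caches, net = net)
}

# d_out: gradient at the network output. wrt = "activation" means d_out is
# dL/dA (post-dropout activation); "preact" means the caller already folded
# the output activation derivative in (e.g. sigmoid + cross-entropy) and
# d_out is dL/dZ of the final layer.
nn_backward <- function(net, caches, d_out, wrt = c("activation", "preact")) {
  wrt <- match.arg(wrt)
  grads <- vector("list", length(net$layers))
  da <- d_out
  for (l in rev(seq_along(net$layers))) {
    ly <- net$layers[[l]]
    cache <- caches[[l]]
    last <- l == length(net$layers)
    if (last && wrt == "preact") {
      dzb <- da
    } else {
      if (!is.null(cache$mask)) da <- da * cache$mask
      zb <- if (!is.null(ly$bn)) cache$zb else cache$z
      dzb <- da * act_grad(cache$a_pre, zb, ly$act)
    }
    if (!is.null(ly$bn)) {
      m <- nrow(dzb)
      dgamma <- colSums(dzb * cache$zn)
      dbeta <- colSums(dzb)
      dzn <- sweep(dzb, 2, ly$bn$gamma, "*")
      # standard batch-norm backward in normalized coordinates
      dz <- sweep(
        dzn - matrix(colMeans(dzn), m, ncol(dzn), byrow = TRUE) -
          sweep(cache$zn, 2, colMeans(dzn * cache$zn), "*"),
        2, cache$inv_sd, "*")
    } else {
      dz <- dzb
      dgamma <- NULL; dbeta <- NULL
    }
    grads[[l]] <- list(
      W = crossprod(cache$x, dz),
      b = colSums(dz),
      gamma = dgamma, beta = dbeta
    )
    da <- tcrossprod(dz, ly$W)
  }
  list(grads = grads, d_input = da)
}

opt_new <- function(net, type = c("rmsprop", "adam"), lr) {
  type <- match.arg(type)
  state <- map(net$layers, function(ly) {
    slot <- function(p) {
      if (is.null(p)) return(NULL)
      s <- list(v = p * 0)
      if (type == "adam") s$m <- p * 0
      s
    }
    list(W = slot(ly$W), b = slot(ly$b),
         gamma = slot(ly$bn$gamma), beta = slot(ly$bn$beta))
  })
  list(type = type, lr = lr, t = 0, state = state)
}

OPT_EPS <- 1e-8

opt_step <- function(net, grads, opt) {
  opt$t <- opt$t + 1
  for (l in seq_along(net$layers)) {
    for (p in c("W", "b", "gamma", "beta")) {
      g <- grads[[l]][[p]]
      if (is.null(g)) next
      s <- opt$state[[l]][[p]]
      theta <- if (p %in% c("gamma", "beta")) net$layers[[l]]$bn[[p]] else net$layers[[l]][[p]]
      if (opt$type == "rmsprop") {
        s$v <- 0.9 * s$v + 0.1 * g^2
        theta <- theta - opt$lr * g / (sqrt(s$v) + OPT_EPS)
      } else {
        s$m <- 0.9 * s$m + 0.1 * g
        s$v <- 0.999 * s$v + 0.001 * g^2
        mhat <- s$m / (1 - 0.9^opt$t)
        vhat <- s$v / (1 - 0.999^opt$t)
        theta <- theta - opt$lr * mhat / (sqrt(vhat) + OPT_EPS)
      }
      opt$state[[l]][[p]] <- s
      if (p %in% c("gamma", "beta")) {
        net$layers[[l]]$bn[[p]] <- theta
      } else {
        net$layers[[l]][[p]] <- theta
      }
    }
  }
  list(net = net, opt = opt)
}

# Losses return the scalar value and the gradient at the output layer's
# pre-activation (both output layers here are sigmoid).
loss_mse_sigmoid <- function(out, target) {
  d <- out - target
  list(value = mean(d^2),
       d_preact = (2 * d / length(d)) * out * (1 - out))
}

loss_bce_sigmoid <- function(out, target) {
  p <- pmin(pmax(out, 1e-12), 1 - 1e-12)
  list(value = -mean(target * log(p) + (1 - target) * log(1 - p)),
       d_preact = (out - target) / length(out))
}
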