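# Minimal batched neural-network kernels: dense / activation / batch-norm /
# dropout / residual-block ops with hand-derived backward passes, an
# RMSprop optimizer, and the forward-over-reverse pass that differentiates
# the WGAN gradient penalty with respect to critic weights.
#
# Networks are plain lists of ops; a batch is a rows-are-samples matrix.
# Everything is base R matrix arithmetic: no external autodiff is involved,
# and every backward pass is covered by finite-difference tests.

op_dense <- function(in_dim, out_dim, init = c("he", "glorot")) {
  init <- match.arg(init)
  sdev <- if (init == "he") sqrt(2 / in_dim) else sqrt(2 / (in_dim + out_dim))
  list(kind = "dense",
       W = matrix(stats::rnorm(in_dim * out_dim, sd = sdev), in_dim, out_dim),
       b = rep(0, out_dim))
}

op_act <- function(fun, slope = 0.2) list(kind = "act", fun = fun, slope = slope)

op_bn <- function(dim, momentum = 0.9, eps = 1e-5) {
  list(kind = "bn", gamma = rep(1, dim), beta = rep(0, dim),
       rmean = rep(0, dim), rvar = rep(1, dim),
       momentum = momentum, eps = eps)
}

op_drop <- function(rate) list(kind = "drop", rate = rate)

# residual block x -> x + W2 act(W1 x + b1) + b2 (activation LeakyReLU)
op_res <- function(dim, slope = 0.2) {
  list(kind = "res",
       W1 = matrix(stats::rnorm(dim * dim, sd = sqrt(2 / dim)), dim, dim),
       b1 = rep(0, dim),
       W2 = matrix(stats::rnorm(dim * dim, sd = sqrt(2 / dim)), dim, dim),
       b2 = rep(0, dim),
       slope = slope)
}

# column-major recycling (rep(each = nrow)) avoids the aperm that sweep()
# and matrix(byrow = TRUE) pay on every call in the training inner loop
add_bias <- function(X, b) X + rep(b, each = nrow(X))
lrelu_mask <- function(X, slope) 1 + (slope - 1) * (X <= 0)

#' @noRd
net_forward <- function(net, X, training = FALSE) {
  cache <- vector("list", length(net))
  for (i in seq_along(net)) {
    op <- net[[i]]
    switch(op$kind,
      dense = {
        cache[[i]] <- list(X = X)
        X <- add_bias(X %*% op$W, op$b)
      },
      act = {
        if (op$fun == "lrelu") {
          mask <- lrelu_mask(X, op$slope)
          cache[[i]] <- list(mask = mask)
          X <- X * mask
        } else if (op$fun == "tanh") {
          X <- tanh(X); cache[[i]] <- list(Y = X)
        } else if (op$fun == "sigmoid") {
          X <- 1 / (1 + exp(-X)); cache[[i]] <- list(Y = X)
        } else cache[[i]] <- list()
      },
      bn = {
        N <- nrow(X)
        if (training) {
          mu <- colMeans(X)
          v <- colMeans(X^2) - mu^2
          istd <- 1 / sqrt(v + op$eps)
          xhat <- (X - rep(mu, each = N)) * rep(istd, each = N)
          net[[i]]$rmean <- op$momentum * op$rmean + (1 - op$momentum) * mu
          net[[i]]$rvar <- op$momentum * op$rvar + (1 - op$momentum) * v
          cache[[i]] <- list(xhat = xhat, istd = istd)
        } else {
          istd <- 1 / sqrt(op$rvar + op$eps)
          xhat <- (X - rep(op$rmean, each = N)) * rep(istd, each = N)
          cache[[i]] <- list(xhat = xhat, istd = istd)
        }
        X <- xhat * rep(op$gamma, each = N) + rep(op$beta, each = N)
      },
      drop = {
        if (training && op$rate > 0) {
          mask <- (matrix(stats::runif(length(X)), nrow(X)) >= op$rate) /
            (1 - op$rate)
          cache[[i]] <- list(mask = mask)
          X <- X * mask
        } else cache[[i]] <- list(mask = NULL)
      },
      res = {
        A <- add_bias(X %*% op$W1, op$b1)
        mask <- lrelu_mask(A, op$slope)
        H <- A * mask
        cache[[i]] <- list(X = X, H = H, mask = mask)
        X <- X + add_bias(H %*% op$W2, op$b2)
      },
      stop_gexmol("unknown op kind '%s'", op$kind, class = "gexmol_config_error"))
  }
  list(out = X, cache = cache, net = net)
}

#' @noRd
net_backward <- function(net, cache, dY) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    op <- net[[i]]
    cc <- cache[[i]]
    switch(op$kind,
      dense = {
        grads[[i]] <- list(W = crossprod(cc$X, dY), b = colSums(dY))
        dY <- tcrossprod(dY, op$W)
      },
      act = {
        if (op$fun == "lrelu") dY <- dY * cc$mask
        else if (op$fun == "tanh") dY <- dY * (1 - cc$Y^2)
        else if (op$fun == "sigmoid") dY <- dY * cc$Y * (1 - cc$Y)
      },
      bn = {
        N <- nrow(dY)
        dxh <- dY * rep(op$gamma, each = N)
        grads[[i]] <- list(gamma = colSums(dY * cc$xhat), beta = colSums(dY))
        dY <- (dxh - rep(colMeans(dxh), each = N) -
                 cc$xhat * rep(colMeans(dxh * cc$xhat), each = N)) *
          rep(cc$istd, each = N)
      },
      drop = {
        if (!is.null(cc$mask)) dY <- dY * cc$mask
      },
      res = {
        dH <- tcrossprod(dY, op$W2)
        dA <- dH * cc$mask
        grads[[i]] <- list(W1 = crossprod(cc$X, dA), b1 = colSums(dA),
                           W2 = crossprod(cc$H, dY), b2 = colSums(dY))
        dY <- dY + tcrossprod(dA, op$W1)
      })
  }
  list(grads = grads, dX = dY)
}

# ---------------------------------------------------------------------------
# Gradient penalty double-backprop
#
# For a piecewise-linear critic (dense / LeakyReLU / dropout only) the
# penalty P = lambda * mean_b (||g_b|| - 1)^2 with g_b = dD/dx at x_b has
# parameter gradient dP/dW obtainable without second derivatives of the
# activations: with u_b = 2*lambda/B * (||g_b|| - 1)/||g_b|| * g_b held
# fixed, dP/dW = d(sum_b u_b . g_b)/dW, and u.g is the directional
# derivative of D along u, a forward-tangent pass through the linearization
# of the cached forward. Reverse-mode over that tangent pass yields the
# weight gradients (biases and the activation pattern drop out almost
# everywhere).

critic_input_grad <- function(net, cache) {
  B <- nrow(cache[[1]]$X)
  net_backward(net, cache, matrix(1, B, 1L))$dX
}

gp_tangent_grads <- function(net, cache, U) {
  tin <- vector("list", length(net))
  V <- U
  for (i in seq_along(net)) {
    op <- net[[i]]
    cc <- cache[[i]]
    switch(op$kind,
      dense = { tin[[i]] <- V; V <- V %*% op$W },
      act = {
        if (op$fun == "lrelu") V <- V * cc$mask
        else if (op$fun != "linear")
          stop_gexmol("gradient penalty requires a piecewise-linear critic",
                      class = "gexmol_config_error")
      },
      drop = { if (!is.null(cc$mask)) V <- V * cc$mask },
      stop_gexmol("gradient penalty requires a piecewise-linear critic",
                  class = "gexmol_config_error"))
  }
  delta <- matrix(1, nrow(U), ncol(V))
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    op <- net[[i]]
    cc <- cache[[i]]
    switch(op$kind,
      dense = {
        grads[[i]] <- list(W = crossprod(tin[[i]], delta),
                           b = rep(0, length(op$b)))
        delta <- tcrossprod(delta, op$W)
      },
      act = { if (op$fun == "lrelu") delta <- delta * cc$mask },
      drop = { if (!is.null(cc$mask)) delta <- delta * cc$mask })
  }
  grads
}

# Penalty value and critic-parameter gradients at interpolates Xhat.
gp_value_grads <- function(net, Xhat, lambda, training = TRUE) {
  fw <- net_forward(net, Xhat, training = training)
  G <- net_backward(fw$net, fw$cache, matrix(1, nrow(Xhat), 1L))$dX
  gn <- sqrt(rowSums(G^2))
  B <- nrow(Xhat)
  value <- lambda * mean((gn - 1)^2)
  coef <- 2 * lambda / B * (gn - 1) / pmax(gn, 1e-12)
  U <- G * coef
  grads <- gp_tangent_grads(fw$net, fw$cache, U)
  list(value = value, grads = grads, grad_norms = gn, cache = fw$cache,
       net = fw$net)
}

# ---------------------------------------------------------------------------
# Structure arithmetic + RMSprop

PARAM_FIELDS <- list(dense = c("W", "b"), bn = c("gamma", "beta"),
                     res = c("W1", "b1", "W2", "b2"))

grads_zero_like <- function(net) {
  lapply(net, function(op) {
    f <- PARAM_FIELDS[[op$kind]]
    if (is.null(f)) return(NULL)
    g <- lapply(f, function(nm) op[[nm]] * 0)
    names(g) <- f
    g
  })
}

grads_add <- function(a, b, scale = 1) {
  for (i in seq_along(b)) {
    if (is.null(b[[i]])) next
    for (nm in names(b[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + scale * b[[i]][[nm]]
  }
  a
}

rmsprop_state <- function(net) grads_zero_like(net)

rmsprop_step <- function(net, grads, state, lr, rho = 0.9, eps = 1e-7) {
  for (i in seq_along(net)) {
    f <- PARAM_FIELDS[[net[[i]]$kind]]
    if (is.null(f) || is.null(grads[[i]])) next
    for (nm in f) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      v <- rho * state[[i]][[nm]] + (1 - rho) * g^2
      state[[i]][[nm]] <- v
      net[[i]][[nm]] <- net[[i]][[nm]] - lr * g / (sqrt(v) + eps)
    }
  }
  list(net = net, state = state)
}

# flatten / unflatten for finite-difference testing
net_flatten <- function(net) {
  unlist(lapply(net, function(op) {
    f <- PARAM_FIELDS[[op$kind]]
    if (is.null(f)) NULL else unlist(lapply(f, function(nm) op[[nm]]))
  }))
}

net_unflatten <- function(net, theta) {
  pos <- 1L
  for (i in seq_along(net)) {
    f <- PARAM_FIELDS[[net[[i]]$kind]]
    if (is.null(f)) next
    for (nm in f) {
      n <- length(net[[i]][[nm]])
      val <- theta[pos:(pos + n - 1L)]
      if (is.matrix(net[[i]][[nm]])) dim(val) <- dim(net[[i]][[nm]])
      net[[i]][[nm]] <- val
      pos <- pos + n
    }
  }
  net
}

grads_flatten <- function(net, grads) {
  unlist(lapply(seq_along(net), function(i) {
    f <- PARAM_FIELDS[[net[[i]]$kind]]
    if (is.null(f)) return(NULL)
    unlist(lapply(f, function(nm) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) net[[i]][[nm]] * 0 else g
    }))
  }))
}
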