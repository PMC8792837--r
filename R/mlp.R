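# Small fully-connected network: two sigmoid hidden layers and a softmax
# output, trained by L-BFGS on the cross-entropy loss with a light L2
# penalty. Written in-package because the pipeline's ANN has two hidden
# layers (16 and 6 units), which single-hidden-layer fitters do not cover.

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_dims <- function(p, hidden, k) {
  sizes <- c(p, hidden, k)
  lapply(seq_len(length(sizes) - 1L),
         function(i) c(inp = sizes[i], out = sizes[i + 1L]))
}

mlp_unflatten <- function(theta, dims) {
  out <- vector("list", length(dims))
  pos <- 0L
  for (i in seq_along(dims)) {
    nw <- dims[[i]]["inp"] * dims[[i]]["out"]
    W <- matrix(theta[pos + seq_len(nw)], nrow = dims[[i]]["inp"])
    pos <- pos + nw
    b <- theta[pos + seq_len(dims[[i]]["out"])]
    pos <- pos + dims[[i]]["out"]
    out[[i]] <- list(W = W, b = b)
  }
  out
}

mlp_forward <- function(layers, X) {
  acts <- list(X)
  n_l <- length(layers)
  for (i in seq_len(n_l)) {
    Z <- sweep(acts[[i]] %*% layers[[i]]$W, 2, layers[[i]]$b, `+`)
    if (i < n_l) acts[[i + 1L]] <- sigmoid(Z)
    else {
      # row-wise softmax, max-shifted for stability
      Z <- Z - apply(Z, 1, max)
      E <- exp(Z)
      acts[[i + 1L]] <- E / rowSums(E)
    }
  }
  acts
}

mlp_loss_grad <- function(theta, dims, X, Y, lambda) {
  layers <- mlp_unflatten(theta, dims)
  acts <- mlp_forward(layers, X)
  n <- nrow(X)
  P <- acts[[length(acts)]]
  loss <- -sum(Y * log(pmax(P, 1e-12))) / n +
    lambda * sum(vapply(layers, function(l) sum(l$W^2), numeric(1)))
  delta <- (P - Y) / n
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    grads[[i]] <- list(W = crossprod(acts[[i]], delta) +
                         2 * lambda * layers[[i]]$W,
                       b = colSums(delta))
    if (i > 1L) {
      A <- acts[[i]]
      delta <- (delta %*% t(layers[[i]]$W)) * A * (1 - A)
    }
  }
  gr <- unlist(lapply(grads, function(g) c(as.vector(g$W), g$b)))
  list(loss = loss, grad = gr)
}

mlp_train <- function(X, y_factor, hidden, seed, maxit = 500,
                      lambda = 1e-4) {
  k <- nlevels(y_factor)
  Y <- diag(k)[as.integer(y_factor), , drop = FALSE]
  dims <- mlp_dims(ncol(X), hidden, k)
  n_par <- sum(vapply(dims, function(d) d["inp"] * d["out"] + d["out"],
                      numeric(1)))
  theta0 <- with_local_seed(seed, function() {
    unlist(lapply(dims, function(d) {
      lim <- sqrt(6 / (d["inp"] + d["out"]))  # Glorot-uniform
      c(runif(d["inp"] * d["out"], -lim, lim), numeric(d["out"]))
    }))
  })
  stopifnot(length(theta0) == n_par)
  fit <- optim(theta0,
               fn = function(th) mlp_loss_grad(th, dims, X, Y, lambda)$loss,
               gr = function(th) mlp_loss_grad(th, dims, X, Y, lambda)$grad,
               method = "L-BFGS-B",
               control = list(maxit = maxit))
  list(layers = mlp_unflatten(fit$par, dims), dims = dims,
       levels = levels(y_factor), converged = fit$convergence == 0)
}

mlp_predict <- function(model, X) {
  acts <- mlp_forward(model$layers, X)
  P <- acts[[length(acts)]]
  factor(model$levels[max.col(P, ties.method = "first")],
         levels = model$levels)
}
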