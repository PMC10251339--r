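# Small dense networks -------------------------------------------------------
#
# Encoders and heads are tiny fully-connected networks (linear, or one tanh
# hidden layer).  Parameters live in a single flat numeric vector so that
# virtual steps, Hessian-vector products and finite differences operate on
# plain vectors.  Every forward/backward routine below is written to be safe
# for complex-valued parameters: this makes complex-step differentiation of
# the analytic gradient functions available as a machine-precision route to
# the mixed second derivatives that the hypergradient needs.

#' Create a small dense network
#'
#' Builds a fully-connected network mapping `in_dim` inputs to `out_dim`
#' outputs, with optional tanh hidden layers. Weights are drawn from
#' N(0, init_sd^2) using the current RNG state; biases start at zero.
#'
#' @param in_dim,out_dim Input and output dimension.
#' @param hidden Integer vector of hidden-layer widths (empty for a linear map).
#' @param init_sd Standard deviation of the weight initialization.
#' @param pre Optional fixed (non-trainable) linear preprocessing matrix
#'   (m x in_dim), e.g. an average-pooling operator; the trainable layers
#'   then see m inputs.
#' @return An object of class `tw_net`.
#' @keywords internal
net_new <- function(in_dim, out_dim, hidden = integer(0), init_sd = 0.1,
                    pre = NULL) {
  if (!is.null(pre)) {
    stopifnot(ncol(pre) == in_dim)
    in_dim <- nrow(pre)
  }
  dims <- c(in_dim, hidden, out_dim)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    layers[[l]] <- list(
      W = matrix(stats::rnorm(dims[l + 1L] * dims[l], sd = init_sd),
                 nrow = dims[l + 1L], ncol = dims[l]),
      b = numeric(dims[l + 1L])
    )
  }
  structure(list(dims = dims, layers = layers, pre = pre), class = "tw_net")
}

# Fixed average-pooling operator over an H x W grid (column-major pixel
# order, as produced by flattening feature matrices).
pool_matrix <- function(H, W, factor) {
  if (factor <= 1L || H %% factor != 0L || W %% factor != 0L) return(NULL)
  Ho <- H %/% factor; Wo <- W %/% factor
  P <- matrix(0, Ho * Wo, H * W)
  for (jo in seq_len(Wo)) for (io in seq_len(Ho)) {
    out <- (jo - 1L) * Ho + io
    for (dj in seq_len(factor)) for (di in seq_len(factor)) {
      i <- (io - 1L) * factor + di
      j <- (jo - 1L) * factor + dj
      P[out, (j - 1L) * H + i] <- 1 / factor^2
    }
  }
  P
}

net_nparams <- function(net) {
  sum(vapply(net$layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

net_get_params <- function(net) {
  unlist(lapply(net$layers, function(l) c(as.vector(l$W), l$b)),
         use.names = FALSE)
}

net_set_params <- function(net, theta) {
  stopifnot(length(theta) == net_nparams(net))
  off <- 0L
  for (l in seq_along(net$layers)) {
    nw <- length(net$layers[[l]]$W)
    nb <- length(net$layers[[l]]$b)
    W <- theta[(off + 1L):(off + nw)]
    dim(W) <- dim(net$layers[[l]]$W)
    net$layers[[l]]$W <- W
    net$layers[[l]]$b <- theta[(off + nw + 1L):(off + nw + nb)]
    off <- off + nw + nb
  }
  net
}

# Forward pass with cached activations. X is n x in_dim (rows = examples).
net_forward_cache <- function(net, X) {
  if (!is.null(net$pre)) X <- X %*% t(net$pre)
  acts <- vector("list", length(net$layers) + 1L)
  acts[[1L]] <- X
  nl <- length(net$layers)
  for (l in seq_len(nl)) {
    A <- acts[[l]] %*% t(net$layers[[l]]$W)
    A <- sweep(A, 2L, net$layers[[l]]$b, "+")
    if (l < nl) A <- tanh(A)
    acts[[l + 1L]] <- A
  }
  acts
}

net_forward <- function(net, X) {
  acts <- net_forward_cache(net, X)
  acts[[length(acts)]]
}

# Backpropagate an upstream cotangent G (n x out_dim) through the network.
# Returns the flat parameter gradient and the gradient with respect to the
# input rows. `acts` must come from net_forward_cache on the same X.
net_backprop <- function(net, acts, G) {
  nl <- length(net$layers)
  pieces <- vector("list", nl)
  D <- G
  for (l in rev(seq_len(nl))) {
    A_in <- acts[[l]]
    gW <- t(D) %*% A_in
    gb <- colSums(D)
    pieces[[l]] <- c(as.vector(gW), gb)
    D <- D %*% net$layers[[l]]$W
    if (l > 1L) D <- D * (1 - acts[[l]]^2)  # tanh' through the cached output
  }
  list(params = unlist(pieces, use.names = FALSE), input = D)
}

# Softmax cross-entropy -------------------------------------------------------

# Per-row cross-entropy of logits Z (n x K) against 0-based labels y.
# Complex-safe: the log-sum-exp shift uses only the real part, and a real
# constant shift cancels exactly in logsumexp(z) - z_y.
softmax_ce <- function(Z, y) {
  m <- apply(Re(Z), 1L, max)
  Zs <- Z - m
  lse <- log(rowSums(exp(Zs)))
  zy <- Zs[cbind(seq_len(nrow(Z)), y + 1L)]
  lse - zy
}

# Gradient of per-row cross-entropy with respect to the logits, each row
# multiplied by w (per-example weight): rows are w_i * (softmax(z_i) - e_{y_i}).
softmax_ce_grad <- function(Z, y, w = NULL) {
  m <- apply(Re(Z), 1L, max)
  E <- exp(Z - m)
  P <- E / rowSums(E)
  P[cbind(seq_len(nrow(Z)), y + 1L)] <- P[cbind(seq_len(nrow(Z)), y + 1L)] - 1
  if (!is.null(w)) P <- P * w
  P
}

softmax_probs <- function(Z) {
  m <- apply(Re(Z), 1L, max)
  E <- exp(Z - m)
  E / rowSums(E)
}

# Classifier loss and gradients -----------------------------------------------
#
# A classifier is encoder + head; slice rows are encoded individually and
# mean-aggregated per example (em$agg) before the head, so stacks and
# single images share one code path.

# Per-example cross-entropy vector for an examples_matrix `em`.
clf_ce <- function(enc, head, em) {
  E <- net_forward(enc, em$X)
  A <- em$agg %*% E
  Z <- net_forward(head, A)
  softmax_ce(Z, em$labels)
}

# Weighted classifier loss sum_i w_i * CE_i.
clf_loss <- function(enc, head, em, w = NULL) {
  ce <- clf_ce(enc, head, em)
  if (is.null(w)) sum(ce) else sum(w * ce)
}

# Flat parameter gradients of the weighted classifier loss for both nets.
clf_grad <- function(enc, head, em, w = NULL) {
  acts_e <- net_forward_cache(enc, em$X)
  E <- acts_e[[length(acts_e)]]
  A <- em$agg %*% E
  acts_h <- net_forward_cache(head, A)
  Z <- acts_h[[length(acts_h)]]
  dZ <- softmax_ce_grad(Z, em$labels, w)
  bh <- net_backprop(head, acts_h, dZ)
  dE <- t(em$agg) %*% bh$input
  be <- net_backprop(enc, acts_e, dE)
  list(enc = be$params, head = bh$params)
}

# Hessian-vector products ------------------------------------------------------

#' Finite-difference Hessian-vector product
#'
#' Approximates the product of the Jacobian of a gradient function with a
#' direction vector by the symmetric difference
#' \eqn{(g(\theta + \epsilon v) - g(\theta - \epsilon v)) / (2\epsilon)},
#' with \eqn{\epsilon = \epsilon_{scale} / \lVert v \rVert} (the DARTS
#' convention). When `gradient_function` returns the gradient with respect to
#' a *different* parameter block than `at_params`, the result is the
#' corresponding mixed second-derivative product.
#'
#' @param gradient_function Function of a flat parameter vector returning a
#'   gradient vector (not necessarily of the same length).
#' @param at_params Flat numeric parameter vector at which to evaluate.
#' @param vector Direction vector, same length as `at_params`.
#' @param eps_scale Positive scale for the step; the actual step is
#'   `eps_scale / ||vector||`.
#' @return The product vector; a zero vector of the gradient's length when
#'   `vector` is all zeros (no division by zero is attempted).
#' @examples
#' A <- matrix(c(2, 1, 1, 3), 2, 2)
#' g <- function(th) as.vector(A %*% th)   # gradient of 0.5 t(th) A th
#' hvp_finite_difference(g, c(1, 1), c(1, 0))  # ~ A %*% c(1, 0)
#' @export
hvp_finite_difference <- function(gradient_function, at_params, vector,
                                  eps_scale = 0.01) {
  stopifnot(length(vector) == length(at_params), eps_scale > 0)
  nv <- sqrt(sum(vector^2))
  if (nv == 0) {
    return(numeric(length(gradient_function(at_params))))
  }
  eps <- eps_scale / nv
  gp <- gradient_function(at_params + eps * vector)
  gm <- gradient_function(at_params - eps * vector)
  (gp - gm) / (2 * eps)
}

# Complex-step directional derivative of a gradient function: exact to
# machine precision because there is no subtractive cancellation. Requires
# gradient_function to be complex-safe (all routines in this package are).
hvp_complex_step <- function(gradient_function, at_params, vector,
                             eps = 1e-20) {
  nv <- sqrt(sum(vector^2))
  if (nv == 0) {
    return(numeric(length(gradient_function(at_params))))
  }
  g <- gradient_function(at_params + (0+1i) * eps * vector)
  Im(g) / eps
}

mixed_hvp <- function(gradient_function, at_params, vector,
                      method = c("fd", "exact"), eps_scale = 0.01) {
  method <- match.arg(method)
  if (method == "fd") {
    hvp_finite_difference(gradient_function, at_params, vector, eps_scale)
  } else {
    hvp_complex_step(gradient_function, at_params, vector)
  }
}
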