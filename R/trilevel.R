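# Three-level optimizer ------------------------------------------------------
#
# Stage I:  train the source model on importance-weighted cross-entropy.
# Stage II: train the target model on target cross-entropy plus the CDRS
#           hinge penalty, with pairs labeled by the one-step-updated
#           source encoder.
# Stage III: update the importance weights C by descending the target
#           model's validation loss, with the gradient obtained by chaining
#           the two mixed second derivatives through the one-step virtual
#           updates (Hessian-vector products, finite-difference by default).

#' Architecture specification for the source/target model pair
#'
#' Encoders are small dense networks (linear, or tanh hidden layers) and
#' heads are linear. Source and target encoders are independent and may
#' have different embedding dimensions.
#'
#' @param d_s,d_t Embedding dimensions of the source and target encoders.
#' @param hidden_s,hidden_t Hidden-layer widths (empty = linear encoder).
#' @param init_sd Weight initialization standard deviation.
#' @param pool Average-pooling factor applied as a fixed front end of both
#'   encoders (1 = none). The default 2 halves each image axis, keeping
#'   the trainable encoders smaller than the source sample so conflicted
#'   source examples cannot simply be memorized.
#' @return A list of class `tw_model_spec`.
#' @export
model_spec <- function(d_s = 8L, d_t = 8L, hidden_s = integer(0),
                       hidden_t = integer(0), init_sd = 0.1, pool = 2L) {
  structure(list(d_s = as.integer(d_s), d_t = as.integer(d_t),
                 hidden_s = hidden_s, hidden_t = hidden_t,
                 init_sd = init_sd, pool = as.integer(pool)),
            class = "tw_model_spec")
}

# Instantiate the four networks for a given image geometry and class
# counts. Uses the current RNG state.
model_pair_new <- function(spec, image_dim, target_classes) {
  H <- image_dim[1]; W <- image_dim[2]
  P <- pool_matrix(H, W, spec$pool)
  in_dim <- H * W
  list(enc_s = net_new(in_dim, spec$d_s, spec$hidden_s, spec$init_sd,
                       pre = P),
       head_s = net_new(spec$d_s, 2L, init_sd = spec$init_sd),
       enc_t = net_new(in_dim, spec$d_t, spec$hidden_t, spec$init_sd,
                       pre = P),
       head_t = net_new(spec$d_t, target_classes, init_sd = spec$init_sd))
}

#' Training configuration
#'
#' Defaults mirror the method's stated settings (lambda 0.1, learning rate
#' 1e-3, batch size 64, convergence over the last 4 epochs at 5% of the
#' mean) with plain gradient descent as the commit optimizer for exact
#' reproducibility; `optimizer_mode = "adam"` selects Adam with betas
#' (0.5, 0.999) for the commit phase. Virtual (one-step) updates always
#' use plain gradient descent regardless of the commit optimizer.
#'
#' @param lambda Nonnegative CDRS tradeoff parameter.
#' @param eta_es,eta_hs,eta_et,eta_ht,eta_c Positive learning rates for the
#'   source encoder/head, target encoder/head, and importance weights.
#' @param batch_size Minibatch size k.
#' @param max_epochs Epoch cap.
#' @param convergence_window,convergence_threshold Convergence rule: stop
#'   when every tracked loss has sd(last window) < threshold * mean.
#' @param seed Integer seed for all randomness in a fit.
#' @param optimizer_mode `"literal_sgd"` or `"adam"` (commit phase only).
#' @param fd_epsilon_scale Scale for finite-difference HVP steps.
#' @param hvp_method `"fd"` (finite differences) or `"exact"`
#'   (complex-step, exact to machine precision).
#' @param val_full_batch Use the full validation set for each weight
#'   update instead of a size-k minibatch.
#' @param weight_decay,cosine_lr Optional commit-phase L2 decay and cosine
#'   learning-rate schedule; off by default.
#' @param max_pairs Optional cap on the number of target pairs per batch.
#' @return A list of class `tw_train_config`.
#' @export
train_config <- function(lambda = 0.1,
                         eta_es = 1e-3, eta_hs = 1e-3,
                         eta_et = 1e-3, eta_ht = 1e-3, eta_c = 1e-3,
                         batch_size = 64L,
                         max_epochs = 150L,
                         convergence_window = 4L,
                         convergence_threshold = 0.05,
                         seed = 0L,
                         optimizer_mode = c("literal_sgd", "adam"),
                         fd_epsilon_scale = 1e-4,
                         hvp_method = c("fd", "exact"),
                         val_full_batch = FALSE,
                         weight_decay = 0,
                         cosine_lr = FALSE,
                         max_pairs = Inf) {
  optimizer_mode <- match.arg(optimizer_mode)
  hvp_method <- match.arg(hvp_method)
  rates <- c(eta_es, eta_hs, eta_et, eta_ht, eta_c)
  if (any(rates <= 0)) stop("all learning rates must be positive")
  if (lambda < 0) stop("lambda must be nonnegative")
  if (convergence_window < 2L) stop("convergence window must be >= 2")
  if (convergence_threshold <= 0 || convergence_threshold >= 1)
    stop("convergence threshold must lie in (0,1)")
  if (fd_epsilon_scale <= 0) stop("fd_epsilon_scale must be positive")
  structure(as.list(environment())[setdiff(names(formals()), "rates")],
            class = "tw_train_config")
}

#' Desk-scale reference training configuration
#'
#' The settings used throughout this package's diagnostics on the default
#' synthetic domains: minibatch 16, a full 50-epoch budget (the
#' convergence threshold is lowered so the flatness rule does not fire
#' while the losses are still moving slowly), SGD rate 0.01 for all four
#' networks (inside the stability bound of the summed-loss updates on
#' pooled 8x8 inputs), the full validation split for each weight update,
#' and weight decay 5e-4 on the commit phase. The weight rate compensates
#' for the eta_es * eta_et factor that the chained hypergradient carries
#' (see the methods vignette), so weights can traverse a substantial part
#' of \[0,1\] within the epoch budget.
#'
#' @param ... Overrides passed to [train_config()].
#' @return A `tw_train_config`.
#' @export
reference_config <- function(...) {
  defaults <- list(batch_size = 16L, max_epochs = 50L,
                   eta_es = 0.01, eta_hs = 0.01,
                   eta_et = 0.01, eta_ht = 0.01,
                   eta_c = 50,
                   weight_decay = 5e-4,
                   val_full_batch = TRUE,
                   convergence_threshold = 0.005)
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

#' Importance-weighted source training loss
#'
#' `sum_i c_i * L_i` where `L_i` is the cross-entropy of source example i:
#' a weight near 0 effectively excludes the example from source training.
#'
#' @param encoder,head Source encoder and head networks.
#' @param source_batch List of source [example()]s.
#' @param weights Numeric vector of importance weights, one per batch
#'   member (same order).
#' @return Scalar weighted loss.
#' @export
weighted_source_loss <- function(encoder, head, source_batch, weights) {
  if (length(weights) != length(source_batch))
    stop("weights must align one-to-one with the source batch")
  clf_loss(encoder, head, examples_matrix(source_batch), weights)
}

#' One-step virtual update of the source model
#'
#' Returns one-gradient-step views `E_s'` and `H_s'` of the source encoder
#' and head on the weighted source loss, at rates `eta_es` / `eta_hs`,
#' without mutating the inputs. `E_s'` is the labeling (teacher) encoder
#' of the second stage.
#'
#' @inheritParams weighted_source_loss
#' @param eta_es,eta_hs Step sizes (0 allowed for testing: identity view).
#' @return A list with stepped networks `enc` and `head`.
#' @export
virtual_source_step <- function(encoder, head, source_batch, weights,
                                eta_es, eta_hs) {
  em <- if (is.list(source_batch) && !is.null(source_batch$X))
    source_batch else examples_matrix(source_batch)
  g <- clf_grad(encoder, head, em, weights)
  if (any(!is.finite(g$enc)) || any(!is.finite(g$head)))
    stop("non-finite gradient in the virtual source step")
  list(enc = net_set_params(encoder, net_get_params(encoder) - eta_es * g$enc),
       head = net_set_params(head, net_get_params(head) - eta_hs * g$head))
}

#' Stage-II objective: target loss plus CDRS penalty
#'
#' `O = L(E_t, H_t, D_t) + lambda * sum over pairs of the hinge penalty`,
#' with pairs labeled by `labeling_encoder` (a constant of this stage;
#' no gradient flows through it) and student margins from `enc_t`.
#'
#' @param enc_t,head_t Target encoder and head.
#' @param target_batch,source_batch Example lists for the two minibatches.
#' @param labeling_encoder The one-step-updated source encoder `E_s'`.
#' @param lambda Nonnegative tradeoff parameter.
#' @return Scalar objective value.
#' @export
stage2_objective <- function(enc_t, head_t, target_batch, source_batch,
                             labeling_encoder, lambda) {
  if (length(target_batch) == 0L || length(source_batch) == 0L)
    stop("batches must be nonempty")
  em_t <- if (!is.null(target_batch$X)) target_batch
          else examples_matrix(target_batch)
  em_s <- if (!is.null(source_batch$X)) source_batch
          else examples_matrix(source_batch)
  ce <- sum(clf_ce(enc_t, head_t, em_t))
  pen <- penalty_terms(em_t, em_s, labeling_encoder, enc_t, lambda)
  ce + pen$value
}

# Gradient machinery for the CDRS penalty ------------------------------------

# Gradient of the summed hinge penalty with respect to either the student
# or the teacher encoder parameters. The pair set and the argmin source
# neighbors are treated as locally constant (they are piecewise constant
# in the parameters); gradients flow through the distances of the selected
# branch. Complex-safe throughout.
penalty_grad <- function(em_t, em_s, teacher, student, lambda,
                         wrt = c("student", "teacher"), max_pairs = Inf) {
  wrt <- match.arg(wrt)
  n <- length(em_t$labels)
  diff_net <- if (wrt == "student") student else teacher
  other_net <- if (wrt == "student") teacher else student
  nz_len <- net_nparams(diff_net)
  if (n < 2L || lambda == 0) return(numeric(nz_len))

  # forward caches through the differentiated net; plain forward for the
  # other (its distances are constants of this gradient)
  acts_t <- net_forward_cache(diff_net, em_t$X)
  acts_s <- net_forward_cache(diff_net, em_s$X)
  ET <- em_t$agg %*% acts_t[[length(acts_t)]]
  ES <- em_s$agg %*% acts_s[[length(acts_s)]]
  sd_diff <- set_distances_emb(ET, ES)
  d_other <- set_distances_emb(encode_examples(other_net, em = em_t),
                               encode_examples(other_net, em = em_s))$d

  pr <- pair_index(n)
  if (is.finite(max_pairs) && length(pr$i) > max_pairs) {
    keep <- seq_len(max_pairs)
    pr <- list(i = pr$i[keep], j = pr$j[keep])
  }
  m_diff <- sd_diff$d[pr$i] - sd_diff$d[pr$j]
  m_other <- d_other[pr$i] - d_other[pr$j]
  p <- if (wrt == "student") m_other else m_diff   # teacher margin
  q <- if (wrt == "student") m_diff else m_other   # student margin
  # pairs exist only for strict teacher margins; hinge active when pq < 0
  active <- (Re(p) != 0) & (Re(p * q) < 0)
  if (!any(active)) return(numeric(nz_len))

  cx <- is.complex(ET)
  zero <- if (cx) 0+0i else 0
  # d(penalty)/d(differentiated margin) = -lambda * (other margin)
  add <- -lambda * m_other[active]
  co_d <- rep(zero, n)                 # cotangent on the n set distances
  ii <- pr$i[active]; jj <- pr$j[active]
  for (idx in seq_along(ii)) {
    co_d[ii[idx]] <- co_d[ii[idx]] + add[idx]
    co_d[jj[idx]] <- co_d[jj[idx]] - add[idx]
  }

  # distance -> embedding cotangents through the selected min branch
  jmin <- sd_diff$argmin
  diffs <- ET - ES[jmin, , drop = FALSE]
  scale <- rep(zero, n)
  pos <- Re(sd_diff$d) > 0
  scale[pos] <- co_d[pos] / sd_diff$d[pos]
  GT <- diffs * as.vector(scale)
  GS <- matrix(zero, nrow(ES), ncol(ES))
  for (x in seq_len(n)) {
    if (scale[x] != zero)
      GS[jmin[x], ] <- GS[jmin[x], ] - diffs[x, ] * scale[x]
  }

  g_t <- net_backprop(diff_net, acts_t, t(em_t$agg) %*% GT)$params
  g_s <- net_backprop(diff_net, acts_s, t(em_s$agg) %*% GS)$params
  g_t + g_s
}

# Gradients of the full stage-II objective with respect to the target
# encoder and head parameters.
stage2_grads <- function(enc_t, head_t, em_t, em_s, labeling_encoder,
                         lambda, max_pairs = Inf) {
  g_ce <- clf_grad(enc_t, head_t, em_t)
  g_pen <- penalty_grad(em_t, em_s, labeling_encoder, enc_t, lambda,
                        wrt = "student", max_pairs = max_pairs)
  list(enc = g_ce$enc + g_pen, head = g_ce$head)
}

#' One-step virtual update of the target model
#'
#' Returns one-gradient-step views of the target encoder and head on the
#' stage-II objective, without mutating the inputs.
#'
#' @inheritParams stage2_objective
#' @param eta_et,eta_ht Step sizes (0 allowed: identity view).
#' @return A list with stepped networks `enc` and `head`.
#' @export
virtual_target_step <- function(enc_t, head_t, target_batch, source_batch,
                                labeling_encoder, lambda, eta_et, eta_ht) {
  em_t <- if (!is.null(target_batch$X)) target_batch
          else examples_matrix(target_batch)
  em_s <- if (!is.null(source_batch$X)) source_batch
          else examples_matrix(source_batch)
  g <- stage2_grads(enc_t, head_t, em_t, em_s, labeling_encoder, lambda)
  if (any(!is.finite(g$enc)) || any(!is.finite(g$head)))
    stop("non-finite gradient in the virtual target step")
  list(enc = net_set_params(enc_t, net_get_params(enc_t) - eta_et * g$enc),
       head = net_set_params(head_t, net_get_params(head_t) - eta_ht * g$head))
}

#' Hypergradient of the validation loss with respect to the weights
#'
#' Chains the validation-loss gradient at the virtually updated target
#' model through the two mixed second-derivative factors: the dependence
#' of the target virtual step on the teacher encoder, and the dependence
#' of the source virtual step on the weights. Each factor is realized as a
#' Hessian-vector product — symmetric finite differences by default, or
#' complex-step ("exact") differentiation of the analytic gradients.
#' Entries for source examples outside `batch_index` are zero.
#'
#' @param state List with networks `enc_s`, `head_s`, `enc_t`, `head_t`
#'   and weights `C` (length M).
#' @param source A [source_dataset()] (or list of M source examples).
#' @param batch_index Positions of the current source minibatch in the
#'   source dataset.
#' @param target_batch,val_batch Lists of target train / validation
#'   examples for this step.
#' @param config A [train_config()].
#' @return A length-M numeric gradient vector.
#' @export
hypergradient_weights <- function(state, source, batch_index, target_batch,
                                  val_batch, config) {
  if (length(target_batch) == 0L || length(val_batch) == 0L ||
      length(batch_index) == 0L)
    stop("all batches must be nonempty")
  examples <- if (inherits(source, "tw_source_dataset")) source$examples
              else source
  M <- length(examples)
  em_s <- examples_matrix(examples[batch_index])
  em_t <- if (!is.null(target_batch$X)) target_batch
          else examples_matrix(target_batch)
  em_v <- if (!is.null(val_batch$X)) val_batch
          else examples_matrix(val_batch)
  C_b <- state$C[batch_index]

  # Stage-I virtual step -> teacher encoder E_s'
  vs <- virtual_source_step(state$enc_s, state$head_s, em_s, C_b,
                            config$eta_es, config$eta_hs)
  teacher <- vs$enc
  # Stage-II virtual step -> (E_t', H_t')
  vt <- virtual_target_step(state$enc_t, state$head_t, em_t, em_s,
                            teacher, config$lambda,
                            config$eta_et, config$eta_ht)

  # validation-loss gradient at the virtually updated target model
  v <- clf_grad(vt$enc, vt$head, em_v)$enc
  if (any(!is.finite(v)))
    stop("non-finite validation gradient (factor: validation loss)")

  # Factor A (teacher -> target step): d/dE_t of grad_{E_s'} O, applied to v
  theta_t0 <- net_get_params(state$enc_t)
  grad_teacher_of_O <- function(theta_t) {
    student <- net_set_params(state$enc_t, theta_t)
    penalty_grad(em_t, em_s, teacher, student, config$lambda,
                 wrt = "teacher", max_pairs = config$max_pairs)
  }
  u <- -config$eta_et *
    mixed_hvp(grad_teacher_of_O, theta_t0, v,
              method = config$hvp_method,
              eps_scale = config$fd_epsilon_scale)
  if (any(!is.finite(u)))
    stop("non-finite Hessian-vector product (factor: stage-II mixed term)")

  # Factor B (weights -> source step): d/dE_s of the per-example CE vector,
  # applied to u; grad_C of the weighted loss is just the CE vector.
  theta_s0 <- net_get_params(state$enc_s)
  ce_vec <- function(theta_s) {
    enc <- net_set_params(state$enc_s, theta_s)
    clf_ce(enc, state$head_s, em_s)
  }
  g_batch <- -config$eta_es *
    mixed_hvp(ce_vec, theta_s0, u,
              method = config$hvp_method,
              eps_scale = config$fd_epsilon_scale)
  if (any(!is.finite(g_batch)))
    stop("non-finite Hessian-vector product (factor: stage-I mixed term)")

  g <- numeric(M)
  g[batch_index] <- g_batch
  g
}

#' Gradient step on the importance weights with clipping
#'
#' `C' = clip(C - eta_c * grad, 0, 1)`: the weights remain in \[0,1\]
#' after every update.
#'
#' @param C Current weight vector.
#' @param grad Gradient vector of the same length.
#' @param eta_c Positive step size.
#' @return The updated, clipped weight vector.
#' @export
update_weights <- function(C, grad, eta_c) {
  if (length(C) != length(grad)) stop("weight/gradient length mismatch")
  pmin(pmax(C - eta_c * grad, 0), 1)
}

#' Convergence check over recent epochs
#'
#' Converged when, for every tracked loss history, the standard deviation
#' of the most recent `window` values is below `threshold` times their
#' mean. Histories shorter than the window, or with nonpositive means, are
#' not converged.
#'
#' @param histories List of numeric loss histories (stage I, stage II,
#'   validation).
#' @param window Number of recent epochs considered (>= 2).
#' @param threshold Fraction of the mean the sd must stay below.
#' @return `TRUE` or `FALSE`.
#' @export
check_convergence <- function(histories, window = 4L, threshold = 0.05) {
  if (window < 2L) stop("window must be >= 2")
  if (!is.list(histories)) histories <- list(histories)
  for (h in histories) {
    if (length(h) < window) return(FALSE)
    tail_h <- utils::tail(h, window)
    m <- mean(tail_h)
    if (!is.finite(m) || m <= 0) return(FALSE)
    if (stats::sd(tail_h) >= threshold * m) return(FALSE)
  }
  TRUE
}

# Commit-phase optimizer ------------------------------------------------------

adam_state_new <- function() list(m = NULL, v = NULL, t = 0L)

adam_step <- function(theta, grad, st, lr, betas = c(0.5, 0.999),
                      eps = 1e-8) {
  if (is.null(st$m)) { st$m <- numeric(length(theta)); st$v <- st$m }
  st$t <- st$t + 1L
  st$m <- betas[1] * st$m + (1 - betas[1]) * grad
  st$v <- betas[2] * st$v + (1 - betas[2]) * grad^2
  mhat <- st$m / (1 - betas[1]^st$t)
  vhat <- st$v / (1 - betas[2]^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}

commit_update <- function(net, grad, lr, mode, opt_env, key, weight_decay) {
  theta <- net_get_params(net)
  if (weight_decay > 0) grad <- grad + weight_decay * theta
  if (mode == "adam") {
    res <- adam_step(theta, grad, opt_env[[key]], lr)
    opt_env[[key]] <- res$state
    net_set_params(net, res$theta)
  } else {
    net_set_params(net, theta - lr * grad)
  }
}

# The fitting function --------------------------------------------------------

#' Fit the three-level source-reweighting model
#'
#' Runs the full three-stage loop on a source dataset and a target dataset:
#' per minibatch, a one-step virtual source update produces the teacher
#' encoder; a one-step virtual target update produces the virtually
#' updated target model; the validation-loss hypergradient updates the
#' importance weights (clipped to \[0,1\]); then the source and target
#' models take committed optimizer steps at the new weights. Weights start
#' at 1, so the first steps coincide with unweighted training and any
#' later down-weighting is attributable to the validation signal.
#'
#' @param source A [source_dataset()].
#' @param target A [target_dataset()].
#' @param model A [model_spec()].
#' @param config A [train_config()] (or [reference_config()]).
#' @param reweight If `FALSE`, the weights stay frozen at 1 (the NoWt
#'   ablation); everything else is unchanged.
#' @param val_examples Optional override of the validation examples used
#'   for stage III (e.g. the A half of an A/B tuning split).
#' @return An object of class `triweight`; see [coef.triweight()],
#'   [predict.triweight()], [summary.triweight()].
#' @export
triweight <- function(source, target, model = model_spec(),
                      config = train_config(), reweight = TRUE,
                      val_examples = NULL, checkpoint_dir = NULL,
                      resume = FALSE) {
  stopifnot(inherits(source, "tw_source_dataset"),
            inherits(target, "tw_target_dataset"))
  if (length(target$train) == 0L || length(target$val) == 0L)
    stop("target train and validation splits must be nonempty")
  if (source$M == 0L) stop("source dataset must be nonempty")
  val_list <- if (is.null(val_examples)) target$val else val_examples

  em_src <- examples_matrix(source$examples)
  em_trn <- examples_matrix(target$train)
  em_val <- examples_matrix(val_list)
  in_dim <- ncol(em_src$X)
  if (ncol(em_trn$X) != in_dim)
    stop("source and target images must share pixel dimensions")
  f1 <- source$examples[[1]]$features
  image_dim <- if (length(dim(f1)) == 2L) dim(f1) else dim(f1)[2:3]

  M <- source$M
  n_trn <- length(target$train)
  k <- min(config$batch_size, n_trn)

  ckpt <- NULL
  if (resume) {
    if (is.null(checkpoint_dir)) stop("resume requires a checkpoint_dir")
    files <- sort(list.files(checkpoint_dir, "^epoch-\\d+\\.rds$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no checkpoints found in ", checkpoint_dir)
    ckpt <- readRDS(files[length(files)])
  }

  run_fit <- function() {
    nets <- model_pair_new(model, image_dim, target$class_count)
    C <- rep(1, M)
    opt_env <- new.env(parent = emptyenv())
    for (key in c("enc_s", "head_s", "enc_t", "head_t"))
      opt_env[[key]] <- adam_state_new()

    hist <- list(stage1 = numeric(0), stage2 = numeric(0),
                 val = numeric(0), same_class = numeric(0),
                 c_min = numeric(0), c_max = numeric(0),
                 mean_wt_clean = numeric(0), mean_wt_corrupt = numeric(0))
    converged <- FALSE
    last_good <- NULL
    epochs_run <- 0L
    start_epoch <- 1L
    if (!is.null(ckpt)) {
      nets <- ckpt$nets; C <- ckpt$C; hist <- ckpt$hist
      for (key in names(ckpt$opt)) opt_env[[key]] <- ckpt$opt[[key]]
      start_epoch <- ckpt$epoch + 1L
      epochs_run <- ckpt$epoch
      last_good <- list(nets = nets, C = C)
      assign(".Random.seed", ckpt$rng, envir = globalenv())
      if (start_epoch > config$max_epochs || ckpt$converged)
        return(build_triweight(nets, C, hist, source, target, model,
                               config, reweight, epochs_run,
                               ckpt$converged, em_trn, em_src))
    }

    for (epoch in start_epoch:config$max_epochs) {
      lr_scale <- if (config$cosine_lr)
        0.5 * (1 + cos(pi * (epoch - 1) / config$max_epochs)) else 1
      perm <- sample.int(n_trn)
      n_batches <- ceiling(n_trn / k)
      s1 <- s2 <- 0
      for (b in seq_len(n_batches)) {
        t_idx <- perm[((b - 1L) * k + 1L):min(b * k, n_trn)]
        s_idx <- sample.int(M, min(k, M))
        v_idx <- if (config$val_full_batch || length(val_list) <= k)
          seq_along(val_list) else sample.int(length(val_list), k)

        em_t <- em_subset(em_trn, t_idx)
        em_s <- em_subset(em_src, s_idx)
        em_v <- em_subset(em_val, v_idx)

        if (reweight) {
          state <- list(enc_s = nets$enc_s, head_s = nets$head_s,
                        enc_t = nets$enc_t, head_t = nets$head_t, C = C)
          g_C <- hypergradient_weights(state, source$examples, s_idx,
                                       em_t, em_v, config)
          C <- update_weights(C, g_C, config$eta_c)
        }

        # committed source update at the new weights
        g_s <- clf_grad(nets$enc_s, nets$head_s, em_s, C[s_idx])
        loss1 <- clf_loss(nets$enc_s, nets$head_s, em_s, C[s_idx])
        nets$enc_s <- commit_update(nets$enc_s, g_s$enc,
                                    config$eta_es * lr_scale,
                                    config$optimizer_mode, opt_env, "enc_s",
                                    config$weight_decay)
        nets$head_s <- commit_update(nets$head_s, g_s$head,
                                     config$eta_hs * lr_scale,
                                     config$optimizer_mode, opt_env, "head_s",
                                     config$weight_decay)

        # committed target update; the freshly committed source encoder
        # labels the pairs, with gradients blocked through it
        teacher <- nets$enc_s
        loss2 <- sum(clf_ce(nets$enc_t, nets$head_t, em_t)) +
          penalty_terms(em_t, em_s, teacher, nets$enc_t,
                        config$lambda, config$max_pairs)$value
        g_t <- stage2_grads(nets$enc_t, nets$head_t, em_t, em_s, teacher,
                            config$lambda, config$max_pairs)
        nets$enc_t <- commit_update(nets$enc_t, g_t$enc,
                                    config$eta_et * lr_scale,
                                    config$optimizer_mode, opt_env, "enc_t",
                                    config$weight_decay)
        nets$head_t <- commit_update(nets$head_t, g_t$head,
                                     config$eta_ht * lr_scale,
                                     config$optimizer_mode, opt_env, "head_t",
                                     config$weight_decay)

        if (!is.finite(loss1) || !is.finite(loss2)) {
          warning("non-finite training loss at epoch ", epoch,
                  "; aborting with the last completed epoch's state")
          if (!is.null(last_good)) {
            nets <- last_good$nets; C <- last_good$C
          }
          converged <- FALSE
          epochs_run <- epoch - 1L
          return(build_triweight(nets, C, hist, source, target, model,
                                 config, reweight, epochs_run,
                                 converged, em_trn, em_src, diverged = TRUE))
        }
        s1 <- s1 + loss1
        s2 <- s2 + loss2
      }

      val_loss <- mean(clf_ce(nets$enc_t, nets$head_t, em_val))
      hist$stage1 <- c(hist$stage1, s1 / n_batches)
      hist$stage2 <- c(hist$stage2, s2 / n_batches)
      hist$val <- c(hist$val, val_loss)

      rk <- global_ranking(target$train, source$examples, nets$enc_s)
      hist$same_class <- c(hist$same_class, same_class_percentage(rk))
      hist$c_min <- c(hist$c_min, min(C))
      hist$c_max <- c(hist$c_max, max(C))
      if (!is.null(source$corruption_mask) &&
          any(source$corruption_mask) && !all(source$corruption_mask)) {
        ws <- weight_separation(C, source$corruption_mask)
        hist$mean_wt_clean <- c(hist$mean_wt_clean, ws$mean_clean)
        hist$mean_wt_corrupt <- c(hist$mean_wt_corrupt, ws$mean_corrupted)
      }

      last_good <- list(nets = nets, C = C)
      epochs_run <- epoch
      converged <- check_convergence(list(hist$stage1, hist$stage2, hist$val),
                                     config$convergence_window,
                                     config$convergence_threshold)
      if (!is.null(checkpoint_dir)) {
        dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        saveRDS(list(nets = nets, C = C, hist = hist, epoch = epoch,
                     converged = converged,
                     opt = as.list(opt_env),
                     rng = get(".Random.seed", envir = globalenv())),
                file.path(checkpoint_dir, sprintf("epoch-%04d.rds", epoch)))
      }
      if (converged) break
    }
    build_triweight(nets, C, hist, source, target, model, config,
                    reweight, epochs_run, converged, em_trn, em_src)
  }
  local_seed(config$seed, run_fit())
}

build_triweight <- function(nets, C, hist, source, target, model, config,
                            reweight, epochs_run, converged,
                            em_trn, em_src, diverged = FALSE) {
  n <- length(hist$stage1)
  history <- data.frame(
    epoch = seq_len(n),
    stage1_loss = hist$stage1,
    stage2_loss = hist$stage2,
    val_loss = hist$val,
    same_class_pct = hist$same_class,
    c_min = hist$c_min,
    c_max = hist$c_max
  )
  if (length(hist$mean_wt_clean) == n) {
    history$mean_weight_clean <- hist$mean_wt_clean
    history$mean_weight_corrupted <- hist$mean_wt_corrupt
  }
  structure(list(
    networks = nets,
    weights = C,
    history = history,
    source = source,
    target = target,
    model = model,
    config = config,
    reweight = reweight,
    epochs = epochs_run,
    converged = converged,
    diverged = diverged
  ), class = "triweight")
}
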