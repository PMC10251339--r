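test_that("weighted source loss is the weighted sum of per-example losses", {
  set.seed(20)
  inst <- tiny_instance(1)
  em <- triweight:::examples_matrix(inst$src)
  ce <- triweight:::clf_ce(inst$nets$enc_s, inst$nets$head_s, em)
  w <- c(0.5, 0, 1, 0.2, 0.9, 0.3)
  expect_equal(weighted_source_loss(inst$nets$enc_s, inst$nets$head_s,
                                    inst$src, w),
               sum(w * ce))
  expect_equal(weighted_source_loss(inst$nets$enc_s, inst$nets$head_s,
                                    inst$src, rep(0, 6)), 0)
  expect_equal(weighted_source_loss(inst$nets$enc_s, inst$nets$head_s,
                                    inst$src, rep(1, 6)), sum(ce))
  # the weighted-sum rule itself: weights (0.5, 0) on losses (2, 7) give 1
  expect_equal(sum(c(0.5, 0) * c(2, 7)), 1)
  expect_error(weighted_source_loss(inst$nets$enc_s, inst$nets$head_s,
                                    inst$src, 1:3), "align")
})

test_that("virtual source step is a non-mutating one-step descent view", {
  inst <- tiny_instance(2)
  th0 <- triweight:::net_get_params(inst$nets$enc_s)
  vs0 <- virtual_source_step(inst$nets$enc_s, inst$nets$head_s, inst$src,
                             inst$C, 0, 0)
  expect_equal(triweight:::net_get_params(vs0$enc), th0)
  vs_zero_w <- virtual_source_step(inst$nets$enc_s, inst$nets$head_s,
                                   inst$src, rep(0, 6), 0.5, 0.5)
  expect_equal(triweight:::net_get_params(vs_zero_w$enc), th0)

  # the step moves along the analytic gradient, which matches numeric
  # differentiation of the weighted loss
  eta <- 0.3
  vs <- virtual_source_step(inst$nets$enc_s, inst$nets$head_s, inst$src,
                            inst$C, eta, eta)
  f <- function(th) triweight:::clf_loss(
    triweight:::net_set_params(inst$nets$enc_s, th), inst$nets$head_s,
    triweight:::examples_matrix(inst$src), inst$C)
  g_num <- vapply(seq_along(th0), function(i) {
    h <- 1e-6
    tp <- th0; tp[i] <- tp[i] + h
    tm <- th0; tm[i] <- tm[i] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
  expect_equal((th0 - triweight:::net_get_params(vs$enc)) / eta, g_num,
               tolerance = 1e-4)
  # original encoder untouched
  expect_equal(triweight:::net_get_params(inst$nets$enc_s), th0)
})

test_that("stage-II objective decomposes into cross-entropy plus penalty", {
  inst <- tiny_instance(3)
  teacher <- inst$nets$enc_s
  lam <- 0.4
  O <- stage2_objective(inst$nets$enc_t, inst$nets$head_t, inst$tgt,
                        inst$src, teacher, lam)
  ce <- sum(triweight:::clf_ce(inst$nets$enc_t, inst$nets$head_t,
                               triweight:::examples_matrix(inst$tgt)))
  pen <- cdrs_penalty(inst$tgt, inst$src, teacher, inst$nets$enc_t, lam)
  expect_equal(O, ce + pen)
  expect_equal(stage2_objective(inst$nets$enc_t, inst$nets$head_t, inst$tgt,
                                inst$src, teacher, 0), ce)
  # a student identical to the teacher incurs no penalty
  expect_equal(stage2_objective(inst$nets$enc_s, inst$nets$head_t, inst$tgt,
                                inst$src, teacher, lam),
               sum(triweight:::clf_ce(inst$nets$enc_s, inst$nets$head_t,
                                      triweight:::examples_matrix(inst$tgt))))
})

test_that("virtual target step matches numeric gradients of the objective", {
  inst <- tiny_instance(4)
  teacher <- virtual_source_step(inst$nets$enc_s, inst$nets$head_s,
                                 inst$src, inst$C, 0.1, 0.1)$enc
  lam <- 0.4; eta <- 0.2
  vt0 <- virtual_target_step(inst$nets$enc_t, inst$nets$head_t, inst$tgt,
                             inst$src, teacher, lam, 0, 0)
  expect_equal(triweight:::net_get_params(vt0$enc),
               triweight:::net_get_params(inst$nets$enc_t))

  vt <- virtual_target_step(inst$nets$enc_t, inst$nets$head_t, inst$tgt,
                            inst$src, teacher, lam, eta, eta)
  th0 <- triweight:::net_get_params(inst$nets$enc_t)
  f <- function(th) stage2_objective(
    triweight:::net_set_params(inst$nets$enc_t, th), inst$nets$head_t,
    inst$tgt, inst$src, teacher, lam)
  g_num <- vapply(seq_along(th0), function(i) {
    h <- 1e-6
    tp <- th0; tp[i] <- tp[i] + h
    tm <- th0; tm[i] <- tm[i] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
  expect_equal((th0 - triweight:::net_get_params(vt$enc)) / eta, g_num,
               tolerance = 1e-4)

  # H_t' does not depend on the teacher: its step comes from the
  # cross-entropy term only
  teacher2 <- triweight:::net_set_params(teacher,
    triweight:::net_get_params(teacher) + 0.05)
  vt2 <- virtual_target_step(inst$nets$enc_t, inst$nets$head_t, inst$tgt,
                             inst$src, teacher2, lam, eta, eta)
  expect_equal(triweight:::net_get_params(vt$head),
               triweight:::net_get_params(vt2$head))
})

test_that("hypergradient vanishes when either virtual step is frozen", {
  inst <- tiny_instance(5)
  base <- train_config(eta_es = 0.1, eta_hs = 0.1, eta_et = 0.1,
                       eta_ht = 0.1, lambda = 0.5, batch_size = 6)
  for (mode in c("fd", "exact")) {
    cfg0_et <- train_config(eta_es = 0.1, eta_hs = 0.1, eta_et = 1e-12,
                            eta_ht = 0.1, lambda = 0.5, hvp_method = mode)
    cfg0_es <- train_config(eta_es = 1e-12, eta_hs = 0.1, eta_et = 0.1,
                            eta_ht = 0.1, lambda = 0.5, hvp_method = mode)
    g_et <- hypergradient_weights(inst$state, inst$src, 1:6, inst$tgt,
                                  inst$val, cfg0_et)
    g_es <- hypergradient_weights(inst$state, inst$src, 1:6, inst$tgt,
                                  inst$val, cfg0_es)
    expect_lt(max(abs(g_et)), 1e-10)
    expect_lt(max(abs(g_es)), 1e-10)
  }
  # entries outside the source minibatch are exactly zero
  g <- hypergradient_weights(inst$state, inst$src, c(2, 5), inst$tgt,
                             inst$val, base)
  expect_identical(g[c(1, 3, 4, 6)], rep(0, 4))
})

test_that("hypergradient matches the unrolled-pipeline oracle on tiny instances", {
  for (seed in 0:2) {
    inst <- tiny_instance(seed)
    eta <- 0.1; lam <- 0.5
    oracle <- unrolled_hypergrad_fd(inst, eta, lam)
    cfg_ex <- train_config(eta_es = eta, eta_hs = eta, eta_et = eta,
                           eta_ht = eta, lambda = lam, hvp_method = "exact")
    g_ex <- hypergradient_weights(inst$state, inst$src, 1:6, inst$tgt,
                                  inst$val, cfg_ex)
    expect_equal(g_ex, oracle, tolerance = 1e-3)
  }
})

test_that("weight updates descend and clip into the unit interval", {
  C <- c(0.1, 0.5, 0.9)
  expect_equal(update_weights(C, c(0, 0, 0), 0.5), C)
  expect_equal(update_weights(0.1, 5, 0.1), 0)
  expect_equal(update_weights(0.9, -5, 0.1), 1)
  set.seed(21)
  C <- stats::runif(20); g <- stats::rnorm(20, sd = 3)
  expect_equal(update_weights(C, g, 0.2),
               pmin(1, pmax(0, C - 0.2 * g)))
  expect_error(update_weights(1:3 / 3, 1:2, 0.1), "mismatch")
})

test_that("convergence rule compares sd to a fraction of the mean per loss", {
  const <- rep(2, 4)
  expect_true(check_convergence(list(const, const, const), 4, 0.05))
  expect_false(check_convergence(list(const, c(1, 2, 3, 4), const), 4, 0.05))
  expect_false(check_convergence(list(c(2, 2, 2)), 4, 0.05))
  # nonpositive means guard
  expect_false(check_convergence(list(rep(0, 4)), 4, 0.05))
  expect_false(check_convergence(list(rep(-1, 4)), 4, 0.05))
  # sd exactly at the boundary is not converged (strict inequality)
  h <- c(10, 10, 10, 10 + 1e-9)
  expect_true(check_convergence(list(h), 4, 0.05))
  expect_error(check_convergence(list(const), 1, 0.05), ">= 2")
})

test_that("fits are bit-identical across runs in literal SGD mode", {
  doms <- generate_domains(synth_config(n_source = 20, n_target = 30,
                                        seed = 6))
  cfg <- reference_config(seed = 3, max_epochs = 3)
  f1 <- triweight(doms$source, doms$target, model_spec(), cfg)
  f2 <- triweight(doms$source, doms$target, model_spec(), cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$networks, f2$networks)
})

test_that("weights stay in the unit interval every epoch and histories append", {
  doms <- generate_domains(synth_config(n_source = 20, n_target = 30,
                                        seed = 7))
  cfg <- reference_config(seed = 1, max_epochs = 4, eta_c = 500)
  fit <- triweight(doms$source, doms$target, model_spec(), cfg)
  expect_equal(nrow(fit$history), fit$epochs)
  expect_true(all(fit$history$c_min >= 0))
  expect_true(all(fit$history$c_max <= 1))
  expect_true(all(fit$weights >= 0 & fit$weights <= 1))
  expect_true(all(c("mean_weight_clean", "mean_weight_corrupted") %in%
                  names(fit$history)))
})

test_that("frozen weights reproduce unweighted joint training when lambda is 0", {
  # with lambda = 0 and C = 1 the commit phase reduces to two independent
  # supervised models: source gradients equal the unweighted gradients and
  # target gradients equal plain cross-entropy gradients
  inst <- tiny_instance(6)
  em_s <- triweight:::examples_matrix(inst$src)
  em_t <- triweight:::examples_matrix(inst$tgt)
  g_w <- triweight:::clf_grad(inst$nets$enc_s, inst$nets$head_s, em_s,
                              rep(1, 6))
  g_u <- triweight:::clf_grad(inst$nets$enc_s, inst$nets$head_s, em_s)
  expect_equal(g_w$enc, g_u$enc, tolerance = 1e-12)
  expect_equal(g_w$head, g_u$head, tolerance = 1e-12)
  g_t <- triweight:::stage2_grads(inst$nets$enc_t, inst$nets$head_t, em_t,
                                  em_s, inst$nets$enc_s, 0)
  g_ce <- triweight:::clf_grad(inst$nets$enc_t, inst$nets$head_t, em_t)
  expect_equal(g_t$enc, g_ce$enc, tolerance = 1e-12)
  expect_equal(g_t$head, g_ce$head, tolerance = 1e-12)
})

test_that("training works on slice stacks with mean aggregation", {
  doms <- generate_domains(synth_config(n_source = 16, n_target = 20,
                                        slices_per_stack = 3, seed = 9))
  cfg <- reference_config(seed = 2, max_epochs = 2)
  fit <- triweight(doms$source, doms$target, model_spec(), cfg)
  expect_equal(fit$epochs, 2)
  pred <- predict(fit, doms$target$test)
  expect_true(all(pred %in% 0:2))
})

test_that("adam and cosine options run and stay finite", {
  doms <- generate_domains(synth_config(n_source = 16, n_target = 20,
                                        seed = 10))
  cfg <- reference_config(seed = 2, max_epochs = 2, optimizer_mode = "adam",
                          eta_es = 1e-3, eta_hs = 1e-3, eta_et = 1e-3,
                          eta_ht = 1e-3, cosine_lr = TRUE)
  fit <- triweight(doms$source, doms$target, model_spec(), cfg)
  expect_true(all(is.finite(as.matrix(fit$history[, -1]))))
})

test_that("checkpointed runs resume to the identical final state", {
  doms <- generate_domains(synth_config(n_source = 16, n_target = 20,
                                        seed = 11))
  cfg_full <- reference_config(seed = 4, max_epochs = 4)
  full <- triweight(doms$source, doms$target, model_spec(), cfg_full)

  ckdir <- file.path(tempdir(), "ck-resume")
  unlink(ckdir, recursive = TRUE)
  cfg_half <- reference_config(seed = 4, max_epochs = 2)
  triweight(doms$source, doms$target, model_spec(), cfg_half,
            checkpoint_dir = ckdir)
  resumed <- triweight(doms$source, doms$target, model_spec(), cfg_full,
                       checkpoint_dir = ckdir, resume = TRUE)
  expect_equal(resumed$history, full$history)
  expect_identical(resumed$weights, full$weights)
})

test_that("model S3 methods expose weights, predictions and summaries", {
  run <- reference_runs(0)
  fit <- run$fit
  expect_identical(coef(fit), fit$weights)
  expect_output(print(fit), "Three-level")
  s <- summary(fit)
  expect_s3_class(s, "summary.triweight")
  expect_true(!is.null(s$weight_separation))
  expect_output(print(s), "weight separation")
  pr <- predict(fit, fit$target$test, type = "prob")
  expect_equal(dim(pr), c(length(fit$target$test), 3))
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-9)
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
})
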