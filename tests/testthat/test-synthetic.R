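test_that("corruption mask marks exactly the configured floor counts", {
  cfg <- synth_config(n_source = 100, corrupt_fraction = 0.3,
                      shift_fraction = 0.1, label_flip_fraction = 0.1,
                      n_target = 20, seed = 7)
  doms <- generate_domains(cfg)
  expect_equal(sum(doms$source$corruption_mask), 50)
  ty <- doms$source$corruption_type
  expect_equal(sum(ty == "artifact"), 30)
  expect_equal(sum(ty == "shift"), 10)
  expect_equal(sum(ty == "flip"), 10)

  clean <- generate_domains(synth_config(n_source = 20, n_target = 20,
                                         corrupt_fraction = 0,
                                         shift_fraction = 0,
                                         label_flip_fraction = 0, seed = 1))
  expect_false(any(clean$source$corruption_mask))

  expect_error(generate_domains(synth_config(n_source = 10, n_target = 20,
                                             corrupt_fraction = 0.5,
                                             shift_fraction = 0.4,
                                             label_flip_fraction = 0.4,
                                             seed = 1)),
               "exceed")
})

test_that("generation is a pure function of the config", {
  cfg <- synth_config(n_source = 12, n_target = 15, seed = 42)
  a <- generate_domains(cfg)
  b <- generate_domains(cfg)
  a$source$corruption_type <- NULL; b$source$corruption_type <- NULL
  expect_identical(a, b)
  c2 <- generate_domains(synth_config(n_source = 12, n_target = 15,
                                      seed = 43))
  expect_false(identical(a$source$examples[[1]]$features,
                         c2$source$examples[[1]]$features))
})

test_that("target splits follow the 7:1.5:1.5 protocol and stacks share labels", {
  doms <- generate_domains(synth_config(n_target = 100, n_source = 10,
                                        slices_per_stack = 3, seed = 2))
  expect_length(doms$target$train, 70)
  expect_length(doms$target$val, 15)
  expect_length(doms$target$test, 15)
  e <- doms$target$train[[1]]
  expect_equal(dim(e$features)[1], 3)
  expect_equal(length(dim(e$features)), 3)
})

test_that("artifact injection changes exactly the support, deterministically", {
  img <- matrix(0.5, 16, 16)
  set.seed(11)
  boxed <- inject_artifact(img, "box")
  g <- attr(boxed, "artifact")
  expect_equal(sum(boxed != 0.5), g$support)
  expect_equal(g$support, 2 * g$h + 2 * g$w - 4)
  expect_true(all(boxed[boxed != 0.5] == 1))
  # pixels outside the support are untouched
  inside <- matrix(FALSE, 16, 16)
  inside[g$r0:(g$r0 + g$h - 1), c(g$c0, g$c0 + g$w - 1)] <- TRUE
  inside[c(g$r0, g$r0 + g$h - 1), g$c0:(g$c0 + g$w - 1)] <- TRUE
  expect_identical(boxed[!inside], img[!inside])

  set.seed(13)
  arrow <- inject_artifact(img, "arrow")
  ga <- attr(arrow, "artifact")
  expect_equal(sum(arrow != 0.5), ga$support)

  set.seed(99); once <- inject_artifact(img, "box")
  set.seed(99); twice <- inject_artifact(img, "box")
  expect_identical(once, twice)

  expect_error(inject_artifact(matrix(0.5, 3, 3), "box"), "larger")
  expect_error(inject_artifact(matrix(0.5, 2, 4), "arrow"), "larger")
})

test_that("domain shift composes gamma, rescale and offset with clipping", {
  img <- matrix(0.5, 8, 8)
  idp <- list(contrast_gamma = 1, scale_factor = 1, brightness_offset = 0)
  expect_identical(apply_domain_shift(img, idp), img)

  g2 <- apply_domain_shift(img, list(contrast_gamma = 2, scale_factor = 1,
                                     brightness_offset = 0))
  expect_true(all(g2 == 0.25))

  clip <- apply_domain_shift(img, list(contrast_gamma = 1, scale_factor = 1,
                                       brightness_offset = 0.9))
  expect_true(all(clip == 1))

  sc <- apply_domain_shift(matrix(stats::runif(64), 8, 8),
                           list(contrast_gamma = 1, scale_factor = 1.5,
                                brightness_offset = 0))
  expect_equal(dim(sc), c(8, 8))
  sm <- apply_domain_shift(matrix(stats::runif(64), 8, 8),
                           list(contrast_gamma = 1, scale_factor = 0.5,
                                brightness_offset = 0))
  expect_equal(dim(sm), c(8, 8))
  expect_error(apply_domain_shift(img, list(contrast_gamma = 1,
                                            scale_factor = 0,
                                            brightness_offset = 0)),
               "positive")
})

test_that("source class mean intensities separate by class_signal", {
  # Monte-Carlo check at n = 200 source images, fixed seed: the two source
  # classes' sample mean intensities differ by class_signal within 3
  # standard errors.
  doms <- generate_domains(synth_config(n_source = 200, n_target = 20,
                                        corrupt_fraction = 0,
                                        shift_fraction = 0,
                                        label_flip_fraction = 0,
                                        class_signal = 0.4, noise_sd = 0.1,
                                        seed = 5))
  means <- vapply(doms$source$examples, function(e) mean(e$features),
                  numeric(1))
  labs <- vapply(doms$source$examples, function(e) e$label, integer(1))
  diff_obs <- mean(means[labs == 1]) - mean(means[labs == 0])
  se <- sqrt(stats::var(means[labs == 1]) / sum(labs == 1) +
             stats::var(means[labs == 0]) / sum(labs == 0))
  expect_lt(abs(diff_obs - 0.4), 3 * se)
})

test_that("clean synthetic source carries linearly learnable class signal", {
  # a small independent linear classifier (logistic regression on the top
  # principal components) exceeds 90% held-out accuracy at signal/noise 4
  doms <- generate_domains(synth_config(n_source = 200, n_target = 20,
                                        corrupt_fraction = 0,
                                        shift_fraction = 0,
                                        label_flip_fraction = 0, seed = 8))
  X <- t(vapply(doms$source$examples, function(e) as.vector(e$features),
                numeric(256)))
  y <- vapply(doms$source$examples, function(e) e$label, integer(1))
  tr <- seq_len(140); te <- 141:200
  pc <- stats::prcomp(X[tr, ], rank. = 10)
  df_tr <- data.frame(y = y[tr], pc$x)
  df_te <- data.frame(stats::predict(pc, X[te, ]))
  m <- suppressWarnings(stats::glm(y ~ ., data = df_tr,
                                   family = stats::binomial()))
  acc <- mean((stats::predict(m, df_te, type = "response") > 0.5) == y[te])
  expect_gt(acc, 0.9)
})
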