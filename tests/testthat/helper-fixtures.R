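# Fixtures shared across the suite. Everything is generated in code at
# test time; nothing is read from disk.

# A deterministic random example of given geometry.
mk_example <- function(id, label, H = 4, W = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  example(matrix(stats::runif(H * W), H, W), label, id)
}

mk_examples <- function(n, labels, prefix = "e", H = 4, W = 4) {
  lapply(seq_len(n), function(i)
    mk_example(paste0(prefix, i), labels[(i - 1) %% length(labels) + 1],
               H, W))
}

# The tiny instance used for hypergradient fidelity checks: 4x4 images,
# linear dim-2 encoders without pooling, M = 6 source, 6 target train,
# 6 validation examples.
tiny_instance <- function(seed = 0) {
  set.seed(seed)
  src <- mk_examples(6, 0:1, "s")
  tgt <- mk_examples(6, 0:2, "t")
  val <- mk_examples(6, 0:2, "v")
  nets <- triweight:::model_pair_new(model_spec(d_s = 2, d_t = 2, pool = 1),
                                     c(4L, 4L), 3L)
  C <- stats::runif(6, 0.3, 0.9)
  list(src = src, tgt = tgt, val = val, nets = nets, C = C,
       state = c(nets, list(C = C)))
}

# Validation loss of the fully unrolled two-virtual-step pipeline as a
# function of the weight vector: the independent oracle for the
# hypergradient (central finite differences over each c_i).
unrolled_val_loss <- function(inst, C, eta, lambda) {
  vs <- virtual_source_step(inst$nets$enc_s, inst$nets$head_s, inst$src, C,
                            eta, eta)
  vt <- virtual_target_step(inst$nets$enc_t, inst$nets$head_t, inst$tgt,
                            inst$src, vs$enc, lambda, eta, eta)
  triweight:::clf_loss(vt$enc, vt$head,
                       triweight:::examples_matrix(inst$val))
}

unrolled_hypergrad_fd <- function(inst, eta, lambda, h = 1e-5) {
  vapply(seq_along(inst$C), function(i) {
    Cp <- inst$C; Cp[i] <- Cp[i] + h
    Cm <- inst$C; Cm[i] <- Cm[i] - h
    (unrolled_val_loss(inst, Cp, eta, lambda) -
       unrolled_val_loss(inst, Cm, eta, lambda)) / (2 * h)
  }, numeric(1))
}

# Reference runs on the default synthetic conditions, fitted once per
# session and shared by the diagnostics tests (reweighted + weights-frozen
# pair per seed).
.ref_cache <- new.env(parent = emptyenv())

reference_runs <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(.ref_cache[[key]])) {
    doms <- generate_domains(synth_config(seed = seed))
    cfg <- reference_config(seed = seed)
    fit <- triweight(doms$source, doms$target, model_spec(), cfg)
    nowt <- triweight(doms$source, doms$target, model_spec(), cfg,
                      reweight = FALSE)
    .ref_cache[[key]] <- list(doms = doms, fit = fit, nowt = nowt)
  }
  .ref_cache[[key]]
}

test_macro_f1 <- function(fit, doms) {
  truth <- vapply(doms$target$test, function(e) e$label, integer(1))
  m <- class_metrics(predict(fit), truth, doms$target$class_count)
  m$f1[m$class == "macro"]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
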