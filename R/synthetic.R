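# Synthetic two-domain generator ---------------------------------------------
#
# Emulates the statistical structure the reweighting method assumes: a
# binary-labeled 2-d source domain and a multi-class target domain sharing
# an intensity/texture class signal, with a configurable fraction of source
# examples corrupted by non-clinical artifacts (bounding boxes, arrows),
# domain-shifted (contrast/scale/brightness) or label-flipped. The flagged
# index sets are drawn disjointly by default so weight-recovery checks have
# unambiguous ground truth.

#' Configuration for the synthetic two-domain generator
#'
#' Defaults define the package's desk-scale reference conditions: 16x16
#' images, 3 target classes, 120 target stacks, 100 source images of which
#' 30 carry artifacts, 10 are domain-shifted and 10 label-flipped.
#' `class_signal` is the mean-intensity separation between adjacent source
#' classes (target class means span the same intensity band); `noise_sd`
#' is the per-pixel Gaussian noise level, so `class_signal / noise_sd` is
#' the signal-to-noise ratio of the class structure.
#'
#' @param image_size Integer (H, W).
#' @param target_classes Number of target classes (>= 2).
#' @param n_target Number of target examples before the 7:1.5:1.5 split.
#' @param n_source Number of source examples M (>= 4).
#' @param corrupt_fraction,shift_fraction,label_flip_fraction Fractions of
#'   source examples receiving artifacts, domain shift, label flips.
#' @param class_signal Adjacent-class mean-intensity separation.
#' @param noise_sd Per-pixel noise standard deviation.
#' @param shift_params List with `contrast_gamma`, `scale_factor`,
#'   `brightness_offset` applied to domain-shifted source examples.
#' @param slices_per_stack Slices per target example (stacks share one
#'   label; slices differ by independent noise).
#' @param disjoint If `TRUE` (default) the corrupt/shift/flip sets are
#'   disjoint; their total may then not exceed `n_source`.
#' @param seed Integer seed; generation is a pure function of this config.
#' @return A list of class `tw_synth_config`.
#' @export
synth_config <- function(image_size = c(16L, 16L),
                         target_classes = 3L,
                         n_target = 120L,
                         n_source = 100L,
                         corrupt_fraction = 0.3,
                         shift_fraction = 0.1,
                         label_flip_fraction = 0.1,
                         class_signal = 0.4,
                         noise_sd = 0.1,
                         shift_params = list(contrast_gamma = 2.5,
                                             scale_factor = 1.75,
                                             brightness_offset = 0.35),
                         slices_per_stack = 1L,
                         disjoint = TRUE,
                         seed = 0L) {
  fr <- c(corrupt_fraction, shift_fraction, label_flip_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0,1]")
  if (n_source < 4L) stop("n_source must be at least 4")
  if (class_signal <= 0) stop("class_signal must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (slices_per_stack < 1L) stop("slices_per_stack must be >= 1")
  if (target_classes < 2L) stop("target_classes must be >= 2")
  structure(as.list(environment()), class = "tw_synth_config")
}

# Class-specific zero-mean low-frequency texture: oriented sinusoid whose
# frequency/orientation index is the class. Amplitude rides on class_signal
# so texture and intensity separate together.
class_texture <- function(class_idx, H, W, amplitude) {
  i <- matrix(seq_len(H), H, W)
  j <- matrix(seq_len(W), H, W, byrow = TRUE)
  f <- 1 + class_idx %% 3
  ang <- pi * class_idx / 4
  pat <- sin(2 * pi * f * (cos(ang) * i / H + sin(ang) * j / W))
  amplitude * (pat - mean(pat))
}

# Per-image nuisance structure mimicking scan-appearance variability: a
# bounded uniform brightness offset plus a zero-mean low-frequency
# distractor field from randomly oriented sinusoids. Both scale with the
# class signal so the classes stay confusable but learnable at any signal
# level: the brightness jitter (half-width 0.375 * class_signal) exceeds
# half the adjacent-class mean gap on a 3-class layout, so per-image mean
# intensity alone cannot separate adjacent target classes and the
# class-specific textures carry part of the signal.
appearance_field <- function(H, W, class_signal) {
  i <- matrix(seq_len(H), H, W)
  j <- matrix(seq_len(W), H, W, byrow = TRUE)
  field <- matrix(stats::runif(1, -0.75, 0.75) * class_signal, H, W)
  # cross-class pattern contamination: sub-threshold amounts of other
  # classes' textures, so per-image pattern evidence is mixed and margins
  # are thin while the strongest pattern still identifies the class
  for (rep in 1:2) {
    other <- sample(0:5, 1L)
    field <- field + stats::runif(1, -0.9, 0.9) *
      class_texture(other, H, W, class_signal / 4)
  }
  ang <- stats::runif(1, 0, pi)
  ph <- stats::runif(1, 0, 2 * pi)
  pat <- sin(2 * pi * (cos(ang) * i / H + sin(ang) * j / W) + ph)
  field + 0.2 * class_signal * (pat - mean(pat))
}

# One clean image for a class whose mean intensity is mu.
synth_image <- function(mu, class_idx, H, W, noise_sd, class_signal) {
  base <- mu + class_texture(class_idx, H, W, class_signal / 4) +
    appearance_field(H, W, class_signal)
  img <- base + matrix(stats::rnorm(H * W, sd = noise_sd), H, W)
  pmin(pmax(img, 0), 1)
}

# A slice stack: one appearance realization (the "anatomy" of the stack)
# shared by all slices, with independent per-slice pixel noise.
synth_stack <- function(mu, class_idx, S, H, W, noise_sd, class_signal) {
  base <- mu + class_texture(class_idx, H, W, class_signal / 4) +
    appearance_field(H, W, class_signal)
  out <- array(0, c(S, H, W))
  for (s in seq_len(S))
    out[s, , ] <- pmin(pmax(base +
      matrix(stats::rnorm(H * W, sd = noise_sd), H, W), 0), 1)
  out
}

# Class mean intensities: source classes sit at 0.25 and
# 0.25 + class_signal; target classes span the same band so the extreme
# target classes resemble the two source classes.
source_class_means <- function(class_signal) c(0.25, 0.25 + class_signal)

target_class_means <- function(K, class_signal) {
  0.25 + class_signal * (seq_len(K) - 1) / (K - 1)
}

#' Stamp a non-clinical artifact onto an image
#'
#' Emulates annotation artifacts found in literature-scraped scans: a
#' bounding-box outline or an arrow. Pixels on the artifact support are set
#' to 1.0; all other pixels are untouched. Geometry is drawn from the
#' current RNG state and recorded in the `"artifact"` attribute.
#'
#' @param image Grayscale matrix in \[0,1\].
#' @param kind `"box"` or `"arrow"`.
#' @return The image with the artifact stamped in; attribute `"artifact"`
#'   holds the kind and geometry.
#' @export
inject_artifact <- function(image, kind = c("box", "arrow")) {
  kind <- match.arg(kind)
  H <- nrow(image); W <- ncol(image)
  if (kind == "box") {
    if (H < 4L || W < 4L) stop("artifact larger than image")
    h <- sample(3:H, 1L)
    w <- sample(3:W, 1L)
    r0 <- sample.int(H - h + 1L, 1L)
    c0 <- sample.int(W - w + 1L, 1L)
    rows <- r0:(r0 + h - 1L)
    cols <- c0:(c0 + w - 1L)
    image[rows, c(c0, c0 + w - 1L)] <- 1
    image[c(r0, r0 + h - 1L), cols] <- 1
    geom <- list(kind = "box", r0 = r0, c0 = c0, h = h, w = w,
                 support = 2L * h + 2L * w - 4L)
  } else {
    if (W < 5L || H < 3L) stop("artifact larger than image")
    len <- sample(4:(W - 1L), 1L)
    r <- sample(2:(H - 1L), 1L)
    c0 <- sample.int(W - len + 1L, 1L)
    tip <- c0 + len - 1L
    image[r, c0:tip] <- 1
    image[r - 1L, tip - 1L] <- 1
    image[r + 1L, tip - 1L] <- 1
    geom <- list(kind = "arrow", r = r, c0 = c0, len = len,
                 support = len + 2L)
  }
  attr(image, "artifact") <- geom
  image
}

# Annotation burden of a corrupted source image: literature-scraped scans
# typically carry several overlapping markings, so each corrupted example
# receives several artifacts of random kind and geometry — enough that the
# markings obscure much of the underlying class signal.
stamp_artifacts <- function(image, n = sample(6:12, 1L)) {
  for (i in seq_len(n))
    image <- inject_artifact(image, sample(c("box", "arrow"), 1L))
  attr(image, "artifact") <- NULL
  image
}

#' Apply a contrast/scale/brightness domain shift
#'
#' Output is `clip(offset + recrop(resize(image^gamma, scale)))` with
#' nearest-neighbor resizing followed by a center recrop (scale > 1) or
#' edge-replicating pad (scale < 1) back to the original size. Identity
#' parameters (gamma 1, scale 1, offset 0) return the input unchanged.
#'
#' @param image Grayscale matrix in \[0,1\].
#' @param shift_params List with `contrast_gamma`, `scale_factor`,
#'   `brightness_offset`.
#' @return The shifted image, same size as the input.
#' @export
apply_domain_shift <- function(image, shift_params) {
  g <- shift_params$contrast_gamma
  s <- shift_params$scale_factor
  off <- shift_params$brightness_offset
  if (s <= 0) stop("scale_factor must be positive")
  H <- nrow(image); W <- ncol(image)
  out <- image^g
  if (s != 1) {
    Hs <- max(1L, round(H * s)); Ws <- max(1L, round(W * s))
    ri <- pmin(H, pmax(1L, round((seq_len(Hs) - 0.5) / s + 0.5)))
    ci <- pmin(W, pmax(1L, round((seq_len(Ws) - 0.5) / s + 0.5)))
    big <- out[ri, ci, drop = FALSE]
    if (Hs >= H && Ws >= W) {
      r0 <- (Hs - H) %/% 2L; c0 <- (Ws - W) %/% 2L
      out <- big[r0 + seq_len(H), c0 + seq_len(W), drop = FALSE]
    } else {
      # pad by edge replication to recover the original frame
      rpick <- pmin(Hs, pmax(1L, seq_len(H) - (H - Hs) %/% 2L))
      cpick <- pmin(Ws, pmax(1L, seq_len(W) - (W - Ws) %/% 2L))
      out <- big[rpick, cpick, drop = FALSE]
    }
  }
  pmin(pmax(out + off, 0), 1)
}

#' Generate paired synthetic source and target domains
#'
#' Draws `n_source` binary-labeled source images and `n_target` target
#' stacks sharing the configured class signal, then corrupts exactly
#' `floor(corrupt_fraction * M)` source examples with artifacts,
#' `floor(shift_fraction * M)` with a domain shift and
#' `floor(label_flip_fraction * M)` with label flips (disjoint sets by
#' default). The corruption mask marks the union. Target examples are split
#' 7:1.5:1.5 into train/val/test. The output is a pure function of the
#' config (including its seed).
#'
#' @param cfg A [synth_config()].
#' @return A list with elements `source` ([source_dataset()]) and `target`
#'   ([target_dataset()]).
#' @export
generate_domains <- function(cfg) {
  stopifnot(inherits(cfg, "tw_synth_config"))
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  M <- cfg$n_source
  local_seed(cfg$seed, {
    n_cor <- floor(cfg$corrupt_fraction * M)
    n_shift <- floor(cfg$shift_fraction * M)
    n_flip <- floor(cfg$label_flip_fraction * M)
    if (cfg$disjoint && n_cor + n_shift + n_flip > M)
      stop("disjoint corruption demands exceed n_source")
    if (cfg$disjoint) {
      pick <- sample.int(M, n_cor + n_shift + n_flip)
      idx_cor <- pick[seq_len(n_cor)]
      idx_shift <- pick[n_cor + seq_len(n_shift)]
      idx_flip <- pick[n_cor + n_shift + seq_len(n_flip)]
    } else {
      idx_cor <- sample.int(M, n_cor)
      idx_shift <- sample.int(M, n_shift)
      idx_flip <- sample.int(M, n_flip)
    }

    mu_s <- source_class_means(cfg$class_signal)
    src_labels <- (seq_len(M) - 1L) %% 2L
    src_labels <- src_labels[sample.int(M)]
    src <- vector("list", M)
    for (i in seq_len(M)) {
      y <- src_labels[i]
      img <- synth_image(mu_s[y + 1L], y, H, W, cfg$noise_sd,
                         cfg$class_signal)
      if (i %in% idx_cor)
        img <- stamp_artifacts(img)
      if (i %in% idx_shift)
        img <- apply_domain_shift(img, cfg$shift_params)
      lab <- if (i %in% idx_flip) 1L - y else y
      src[[i]] <- example(img, lab, sprintf("src-%06d", i))
    }
    mask <- seq_len(M) %in% c(idx_cor, idx_shift, idx_flip)
    types <- rep("clean", M)
    types[idx_cor] <- "artifact"
    types[idx_shift] <- ifelse(types[idx_shift] == "clean", "shift",
                               paste0(types[idx_shift], "+shift"))
    types[idx_flip] <- ifelse(types[idx_flip] == "clean", "flip",
                              paste0(types[idx_flip], "+flip"))

    K <- cfg$target_classes
    mu_t <- target_class_means(K, cfg$class_signal)
    tgt_labels <- (seq_len(cfg$n_target) - 1L) %% K
    tgt_labels <- tgt_labels[sample.int(cfg$n_target)]
    tgt <- vector("list", cfg$n_target)
    for (i in seq_len(cfg$n_target)) {
      y <- tgt_labels[i]
      if (cfg$slices_per_stack == 1L) {
        feats <- synth_image(mu_t[y + 1L], y, H, W, cfg$noise_sd,
                             cfg$class_signal)
      } else {
        feats <- synth_stack(mu_t[y + 1L], y, cfg$slices_per_stack, H, W,
                             cfg$noise_sd, cfg$class_signal)
      }
      tgt[[i]] <- example(feats, y, sprintf("syn-%06d", i))
    }
    splits <- split_dataset(tgt, c(0.7, 0.15, 0.15), seed = cfg$seed)
    src_ds <- source_dataset(src, mask)
    src_ds$corruption_type <- types
    list(source = src_ds,
         target = target_dataset(splits$train, splits$val, splits$test, K))
  })
}
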