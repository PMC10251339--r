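# Domain types and dataset I/O -----------------------------------------------
#
# An example is a grayscale image (H x W matrix in [0,1]) or a stack of
# slices (S x H x W array, slice-major) with a 0-based class label and a
# stable string id.  Datasets are plain lists of examples; masks and
# importance weights index examples by position in the dataset's frozen
# ordering, which is what gets serialized.

#' Construct a labeled example
#'
#' @param features Numeric matrix (H x W) or 3-d array (S x H x W, slices
#'   first) with all values in \[0,1\]. Out-of-range values are an error,
#'   never clipped silently.
#' @param label Integer class index, 0-based.
#' @param id Stable string identifier, unique within a dataset.
#' @param class_count Declared number of classes; `label` must be below it.
#' @return A list of class `tw_example`.
#' @export
example <- function(features, label, id, class_count = NULL) {
  if (!is.numeric(features) || !(length(dim(features)) %in% c(2L, 3L)))
    stop("features must be a numeric matrix or a slice-major 3-d array")
  if (anyNA(features) || min(features) < 0 || max(features) > 1)
    stop("feature values must lie in [0,1] (example '", id,
         "'); clipping is not applied silently")
  label <- as.integer(label)
  if (label < 0L) stop("labels are 0-based; got ", label)
  if (!is.null(class_count) && label >= class_count)
    stop("label ", label, " outside declared class count ", class_count)
  structure(list(features = features, label = label, id = as.character(id)),
            class = "tw_example")
}

check_unique_ids <- function(examples) {
  ids <- vapply(examples, function(e) e$id, character(1))
  if (anyDuplicated(ids)) stop("example ids must be unique within a dataset")
  ids
}

#' Construct a source dataset
#'
#' A source dataset holds M 2-d examples with binary labels and, for
#' synthetic data, a ground-truth corruption mask marking which examples
#' were artifact-corrupted, domain-shifted or label-flipped at generation.
#'
#' @param examples List of [example()]s (2-d features, labels in \{0,1\}).
#' @param corruption_mask Optional logical vector of length M.
#' @return A list of class `tw_source_dataset` with elements `examples`,
#'   `M` and `corruption_mask`.
#' @export
source_dataset <- function(examples, corruption_mask = NULL) {
  check_unique_ids(examples)
  M <- length(examples)
  labs <- vapply(examples, function(e) e$label, integer(1))
  if (any(labs > 1L)) stop("source labels must be binary (0/1)")
  if (!is.null(corruption_mask)) {
    if (!is.logical(corruption_mask) || length(corruption_mask) != M)
      stop("corruption_mask must be a logical vector of length M = ", M)
  }
  structure(list(examples = examples, M = M,
                 corruption_mask = corruption_mask),
            class = "tw_source_dataset")
}

#' Construct a target dataset with train/val/test splits
#'
#' @param train,val,test Disjoint lists of [example()]s.
#' @param class_count Number of target classes (>= 2).
#' @return A list of class `tw_target_dataset`.
#' @export
target_dataset <- function(train, val, test, class_count) {
  class_count <- as.integer(class_count)
  if (class_count < 2L) stop("class_count must be at least 2")
  ids <- c(vapply(train, function(e) e$id, character(1)),
           vapply(val, function(e) e$id, character(1)),
           vapply(test, function(e) e$id, character(1)))
  if (anyDuplicated(ids)) stop("train/val/test splits must be disjoint by id")
  for (e in c(train, val, test))
    if (e$label >= class_count)
      stop("label ", e$label, " outside declared class count ", class_count)
  structure(list(train = train, val = val, test = test,
                 class_count = class_count),
            class = "tw_target_dataset")
}

#' Split a list of examples into train/validation/test
#'
#' Sizes follow a floor-remainder rule: `n_val = floor(r_val * n)`,
#' `n_test = floor(r_test * n)`, and the remainder goes to train, so train
#' is always the largest split. The permutation is a pure function of
#' `seed`. The default 0.7/0.15/0.15 ratio is the conventional 7:1.5:1.5
#' protocol for this task.
#'
#' @param examples Nonempty list of [example()]s.
#' @param ratios Length-3 numeric vector (train, val, test) summing to 1.
#' @param seed Integer seed controlling the shuffle.
#' @param stratify If `TRUE`, the floor-remainder rule is applied within
#'   each class label separately.
#' @return A list with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(examples, ratios = c(0.7, 0.15, 0.15), seed = 0L,
                          stratify = FALSE) {
  if (length(examples) == 0L) stop("cannot split an empty example list")
  if (length(examples) < 3L) stop("need at least 3 examples to split")
  if (abs(sum(ratios) - 1) > 1e-9) stop("split ratios must sum to 1")
  if (any(ratios < 0)) stop("split ratios must be nonnegative")
  take <- function(idx) {
    n <- length(idx)
    n_val <- floor(ratios[2] * n)
    n_test <- floor(ratios[3] * n)
    list(val = idx[seq_len(n_val)],
         test = idx[n_val + seq_len(n_test)],
         train = idx[-seq_len(n_val + n_test)])
  }
  local_seed(seed, {
    if (stratify) {
      labs <- vapply(examples, function(e) e$label, integer(1))
      parts <- lapply(split(seq_along(examples), labs), function(ix) {
        take(ix[sample.int(length(ix))])
      })
      idx <- list(train = unlist(lapply(parts, `[[`, "train")),
                  val = unlist(lapply(parts, `[[`, "val")),
                  test = unlist(lapply(parts, `[[`, "test")))
    } else {
      idx <- take(sample.int(length(examples)))
    }
    list(train = examples[sort(idx$train)],
         val = examples[sort(idx$val)],
         test = examples[sort(idx$test)])
  })
}

#' Split a validation set into two equal halves
#'
#' The A/B protocol for hyperparameter tuning: importance weights are
#' learned against half A and configurations are compared on half B.
#' `|A| = floor(n/2)`; the remainder goes to B.
#'
#' @param val List of at least 2 examples.
#' @param seed Integer seed.
#' @return A list with elements `A` and `B`.
#' @export
split_validation_ab <- function(val, seed = 0L) {
  n <- length(val)
  if (n < 2L) stop("need at least 2 validation examples to split")
  local_seed(seed, {
    perm <- sample.int(n)
    nA <- floor(n / 2)
    list(A = val[sort(perm[seq_len(nA)])], B = val[sort(perm[-seq_len(nA)])])
  })
}

# Run an expression under a temporary RNG state; the caller's global RNG
# state is restored afterwards, so no function here leaks RNG side effects.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# I/O -------------------------------------------------------------------------

#' Write a dataset of examples to disk
#'
#' Two backends: `"png"` writes a directory of grayscale PNG files plus a
#' `labels.csv` manifest (columns `file,label`; 2-d examples only);
#' `"container"` writes a single serialized array container (`.rds`)
#' holding `features`, `labels` and `ids`, and supports slice stacks.
#'
#' @param examples List of [example()]s.
#' @param path Directory (png) or file path (container).
#' @param format `"png"` or `"container"`.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(examples, path, format = c("png", "container")) {
  format <- match.arg(format)
  check_unique_ids(examples)
  if (format == "png") {
    dims <- vapply(examples, function(e) length(dim(e$features)), integer(1))
    if (any(dims != 2L))
      stop("the png backend stores 2-d examples only; use the container ",
           "backend for slice stacks")
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    files <- paste0(vapply(examples, function(e) e$id, character(1)), ".png")
    for (i in seq_along(examples))
      png::writePNG(examples[[i]]$features, file.path(path, files[i]))
    manifest <- data.frame(
      file = files,
      label = vapply(examples, function(e) e$label, integer(1))
    )
    utils::write.csv(manifest, file.path(path, "labels.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    obj <- list(
      features = lapply(examples, function(e) e$features),
      labels = vapply(examples, function(e) e$label, integer(1)),
      ids = vapply(examples, function(e) e$id, character(1))
    )
    saveRDS(obj, path)
  }
  invisible(path)
}

#' Read a dataset of examples from disk
#'
#' Accepts a PNG directory with a `labels.csv` manifest, or a single array
#' container file written by [write_dataset()]. PNG images must be
#' grayscale; the offending file is named in any error.
#'
#' @param path Directory or container file path.
#' @param class_count Optional declared class count for label validation.
#' @return A list of [example()]s in manifest/container order.
#' @export
read_dataset <- function(path, class_count = NULL) {
  if (dir.exists(path)) {
    manifest_path <- file.path(path, "labels.csv")
    if (!file.exists(manifest_path))
      stop("missing manifest labels.csv in ", path)
    manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
    if (!all(c("file", "label") %in% names(manifest)))
      stop("manifest must have columns 'file' and 'label'")
    examples <- vector("list", nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      f <- file.path(path, manifest$file[i])
      if (!file.exists(f)) stop("manifest references absent file: ",
                                manifest$file[i])
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) {
        # drop an alpha channel if present, then demand equal color channels
        color <- if (dim(img)[3] %in% c(2L, 4L))
          img[, , seq_len(dim(img)[3] - 1L), drop = FALSE] else img
        if (dim(color)[3] > 1L &&
            !all(color == as.vector(color[, , 1])))
          stop("non-grayscale image: ", manifest$file[i])
        img <- color[, , 1]
      }
      examples[[i]] <- example(img, manifest$label[i],
                               sub("\\.png$", "", manifest$file[i]),
                               class_count = class_count)
    }
    examples
  } else if (file.exists(path)) {
    obj <- readRDS(path)
    if (!all(c("features", "labels", "ids") %in% names(obj)))
      stop("container is missing features/labels/ids: ", path)
    lapply(seq_along(obj$ids), function(i)
      example(obj$features[[i]], obj$labels[i], obj$ids[i],
              class_count = class_count))
  } else {
    stop("no dataset at ", path)
  }
}

#' Serialize split membership as JSON id lists
#'
#' @param splits A list with elements `train`, `val`, `test` as produced by
#'   [split_dataset()] or a [target_dataset()].
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_splits <- function(splits, path) {
  ids <- lapply(splits[c("train", "val", "test")], function(part)
    vapply(part, function(e) e$id, character(1)))
  jsonlite::write_json(ids, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_splits
#' @export
read_splits <- function(path) {
  lapply(jsonlite::read_json(path), function(x)
    vapply(x, as.character, character(1)))
}

# Feature access helpers ------------------------------------------------------

# Flatten an example's features to one row per slice; 2-d examples are a
# single slice.
example_slices <- function(e) {
  f <- e$features
  if (length(dim(f)) == 2L) {
    matrix(as.vector(f), nrow = 1L)
  } else {
    S <- dim(f)[1]
    t(vapply(seq_len(S), function(s) as.vector(f[s, , ]),
             numeric(prod(dim(f)[2:3]))))
  }
}

# Stack all slices of a list of examples into one matrix, with a grouping
# index mapping slice rows back to examples and a mean-aggregation matrix
# `agg` (n_examples x n_rows) so that `agg %*% embeddings` averages slice
# embeddings per example (the aggregation is linear, which keeps every
# derivative path simple and complex-safe).
examples_matrix <- function(examples) {
  mats <- lapply(examples, example_slices)
  ns <- vapply(mats, nrow, integer(1))
  group <- rep(seq_along(examples), ns)
  agg <- matrix(0, length(examples), sum(ns))
  agg[cbind(group, seq_along(group))] <- 1 / ns[group]
  list(X = do.call(rbind, mats),
       group = group,
       agg = agg,
       labels = vapply(examples, function(e) e$label, integer(1)),
       ids = vapply(examples, function(e) e$id, character(1)))
}

# Restrict an examples_matrix to a subset of example positions.
em_subset <- function(em, idx) {
  rows <- which(em$group %in% idx)
  group <- match(em$group[rows], idx)
  ns <- tabulate(group, nbins = length(idx))
  agg <- matrix(0, length(idx), length(rows))
  agg[cbind(group, seq_along(rows))] <- 1 / ns[group]
  list(X = em$X[rows, , drop = FALSE], group = group, agg = agg,
       labels = em$labels[idx], ids = em$ids[idx])
}
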