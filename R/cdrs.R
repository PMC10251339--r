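# Cross-domain relative similarity (CDRS) ------------------------------------
#
# The transfer signal between source and target models: for a target
# example, its distance to the source set is the minimum L2 distance in a
# given encoder's embedding space; for two target examples the one closer
# to the source set wins the pair. A teacher (source) encoder labels pairs;
# a student (target) encoder is penalized by a pairwise hinge whenever its
# own distance ordering disagrees.

#' Euclidean distance between two embeddings
#'
#' @param a,b Numeric vectors of equal length.
#' @return The L2 norm of `a - b`.
#' @export
embed_distance <- function(a, b) {
  if (length(a) != length(b)) stop("embedding dimension mismatch")
  sqrt(sum((a - b)^2))
}

# All cross distances between the rows of A (n x d) and B (m x d).
# Written with plain squares (not Mod) so it stays complex-step safe.
cross_distances <- function(A, B) {
  sa <- rowSums(A * A)
  sb <- rowSums(B * B)
  D2 <- outer(sa, sb, "+") - 2 * A %*% t(B)
  if (is.complex(D2)) {
    D2[Re(D2) < 0 & abs(D2) < 1e-12] <- 0
  } else {
    D2[D2 < 0] <- 0
  }
  sqrt(D2)
}

# Encode a list of examples with a net: slices are encoded individually and
# averaged per example (mean aggregation stands in for a learned sequence
# encoder). Accepts a precomputed examples_matrix() via `em`.
encode_examples <- function(net, examples = NULL, em = NULL) {
  if (is.null(em)) em <- examples_matrix(examples)
  em$agg %*% net_forward(net, em$X)
}

#' Distance from one example to a source batch
#'
#' The set distance e(x, D; E): the minimum embedding-space L2 distance
#' between `x` and any member of `source_batch`, all encoded by `encoder`.
#' In training, a source minibatch stands in for the full source set.
#'
#' @param x A single [example()].
#' @param source_batch Nonempty list of source [example()]s.
#' @param encoder A network mapping feature rows to embeddings.
#' @return A nonnegative scalar.
#' @export
set_distance <- function(x, source_batch, encoder) {
  if (length(source_batch) == 0L) stop("source batch must be nonempty")
  ex <- encode_examples(encoder, list(x))
  es <- encode_examples(encoder, source_batch)
  min(cross_distances(ex, es))
}

# Set distances for all rows of target embeddings ET against source
# embeddings ES (vectorized path used everywhere internally). Returns the
# distances and the argmin source index per target.
set_distances_emb <- function(ET, ES) {
  D <- cross_distances(ET, ES)
  j <- apply(Re(D), 1L, which.min)
  list(d = D[cbind(seq_len(nrow(D)), j)], argmin = j, D = D)
}

#' Label all target pairs by relative closeness to the source batch
#'
#' For every unordered pair of target examples whose set distances under
#' `labeling_encoder` differ strictly, emits one ordered pair whose winner
#' is the example closer to the source batch, with signed margin
#' `p = e(winner) - e(loser) < 0`. Exact ties produce no pair.
#'
#' @param target_batch List of >= 2 target [example()]s.
#' @param source_batch Nonempty list of source [example()]s.
#' @param labeling_encoder Teacher encoder used to compute set distances.
#' @return A data.frame with columns `winner_id`, `loser_id`, `p`.
#' @export
label_pairs <- function(target_batch, source_batch, labeling_encoder) {
  if (length(target_batch) < 2L) {
    return(data.frame(winner_id = character(0), loser_id = character(0),
                      p = numeric(0)))
  }
  ET <- encode_examples(labeling_encoder, target_batch)
  ES <- encode_examples(labeling_encoder, source_batch)
  d <- set_distances_emb(ET, ES)$d
  ids <- vapply(target_batch, function(e) e$id, character(1))
  pr <- pair_index(length(target_batch))
  p <- d[pr$i] - d[pr$j]
  win <- ifelse(p < 0, pr$i, pr$j)
  lose <- ifelse(p < 0, pr$j, pr$i)
  keep <- p != 0
  data.frame(winner_id = ids[win[keep]], loser_id = ids[lose[keep]],
             p = -abs(p[keep]), stringsAsFactors = FALSE)
}

# All unordered index pairs i < j among n items.
pair_index <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  list(i = i, j = j)
}

#' Pairwise hinge penalty
#'
#' The continuous relaxation of the ordering constraint for one pair:
#' `lambda * max(0, -p * q)` where `p` and `q` are the teacher's and
#' student's signed distance differences. Zero exactly when `p * q >= 0`
#' (the student predicts the relation correctly), `-lambda * p * q`
#' otherwise. Vectorized over `p`/`q`.
#'
#' @param p,q Signed distance differences (teacher, student).
#' @param lambda Nonnegative tradeoff parameter.
#' @return Nonnegative penalty value(s).
#' @export
hinge_penalty <- function(p, q, lambda) {
  if (lambda < 0) stop("lambda must be nonnegative")
  lambda * pmax(0, -p * q)
}

#' Total CDRS penalty of a student encoder on a batch
#'
#' Sums [hinge_penalty()] over all pairs produced by [label_pairs()] under
#' the teacher (`labeling_encoder`), with the student's margins `q`
#' computed as set-distance differences under `student_encoder`.
#'
#' @inheritParams label_pairs
#' @param student_encoder Encoder being trained to respect the ordering.
#' @param lambda Nonnegative tradeoff parameter.
#' @return Nonnegative scalar penalty.
#' @export
cdrs_penalty <- function(target_batch, source_batch, labeling_encoder,
                         student_encoder, lambda) {
  if (length(source_batch) == 0L) stop("source batch must be nonempty")
  if (length(target_batch) == 0L) stop("target batch must be nonempty")
  pen <- penalty_terms(examples_matrix(target_batch),
                       examples_matrix(source_batch),
                       labeling_encoder, student_encoder, lambda)
  pen$value
}

# Core of the penalty: p from the teacher, q from the student, hinge summed
# over all unordered target pairs (ties under the teacher excluded).
# Complex-safe; branches are decided on real parts so the same code serves
# the finite-difference and complex-step derivative paths.
penalty_terms <- function(em_t, em_s, teacher, student, lambda,
                          max_pairs = Inf) {
  n <- length(unique(em_t$group))
  if (n < 2L || lambda == 0) {
    return(list(value = if (lambda == 0) 0 else 0, pairs = NULL))
  }
  dT <- set_distances_emb(encode_examples(teacher, em = em_t),
                          encode_examples(teacher, em = em_s))$d
  pr <- pair_index(n)
  if (is.finite(max_pairs) && length(pr$i) > max_pairs) {
    keep <- seq_len(max_pairs)
    pr <- list(i = pr$i[keep], j = pr$j[keep])
  }
  p <- dT[pr$i] - dT[pr$j]
  live <- Re(p) != 0
  ET <- encode_examples(student, em = em_t)
  ES <- encode_examples(student, em = em_s)
  sd <- set_distances_emb(ET, ES)
  q <- sd$d[pr$i] - sd$d[pr$j]
  prod <- p * q
  active <- live & (Re(prod) < 0)
  value <- lambda * sum(-prod[active])
  list(value = value, p = p, q = q, active = active, pr = pr, sd = sd,
       ET = ET, ES = ES)
}

#' Global ranking of target examples by distance to the source domain
#'
#' Orders target examples by ascending set distance under `encoder`; exact
#' ties break by id order so the ranking is deterministic. Every pair from
#' [label_pairs()] has its winner ahead of its loser in this order.
#'
#' @param target_set List of target [example()]s.
#' @param source_batch Nonempty list of source [example()]s.
#' @param encoder Encoder used for the distances.
#' @return A list of class `tw_ranking` with `ids`, `distances`, `labels`.
#' @export
global_ranking <- function(target_set, source_batch, encoder) {
  if (length(target_set) == 0L) stop("target set must be nonempty")
  if (length(source_batch) == 0L) stop("source batch must be nonempty")
  ET <- encode_examples(encoder, target_set)
  ES <- encode_examples(encoder, source_batch)
  d <- set_distances_emb(ET, ES)$d
  ids <- vapply(target_set, function(e) e$id, character(1))
  labs <- vapply(target_set, function(e) e$label, integer(1))
  ord <- order(d, ids)
  structure(list(ids = ids[ord], distances = d[ord], labels = labs[ord]),
            class = "tw_ranking")
}

#' Fraction of adjacent ranked pairs sharing a class label
#'
#' The ranking-quality diagnostic: among the n-1 adjacent pairs of a
#' global ranking, the fraction whose class labels agree. Higher values
#' mean same-class examples are grouped together along the ranking.
#'
#' @param ranking A `tw_ranking` from [global_ranking()].
#' @param labels Optional named vector of labels by id (defaults to the
#'   labels stored in the ranking).
#' @return A fraction in \[0,1\].
#' @export
same_class_percentage <- function(ranking, labels = NULL) {
  labs <- if (is.null(labels)) ranking$labels else unname(labels[ranking$ids])
  n <- length(labs)
  if (n < 2L) stop("need at least 2 ranked items")
  mean(labs[-n] == labs[-1L])
}

#' Retrieve the k nearest source neighbors of a query example
#'
#' @param query A single [example()].
#' @param source_set Nonempty list of source [example()]s.
#' @param encoder Encoder defining the embedding space.
#' @param k Number of neighbors (capped at the source-set size).
#' @return A data.frame with columns `id`, `distance`, ascending.
#' @export
nearest_neighbors <- function(query, source_set, encoder, k) {
  if (length(source_set) == 0L) stop("source set must be nonempty")
  if (k < 1L) stop("k must be >= 1")
  eq <- encode_examples(encoder, list(query))
  es <- encode_examples(encoder, source_set)
  d <- as.vector(cross_distances(eq, es))
  ids <- vapply(source_set, function(e) e$id, character(1))
  ord <- order(d, ids)[seq_len(min(k, length(source_set)))]
  data.frame(id = ids[ord], distance = d[ord], stringsAsFactors = FALSE)
}

#' Export a ranking or neighbor list as CSV
#'
#' @param x A `tw_ranking` or the data.frame from [nearest_neighbors()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(x, path) {
  df <- if (inherits(x, "tw_ranking"))
    data.frame(id = x$ids, distance = x$distances, label = x$labels)
  else x
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
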