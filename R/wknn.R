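#' WKNN preprocessing configuration
#'
#' Parameters for the weighted K-nearest-neighbour profile smoothing that
#' replaces zero adjacency entries with interaction-likelihood scores
#' before factorization.
#'
#' @param K Neighbour count (>= 1); default 5.
#' @param alpha Decay term in \[0, 1\] applied as `alpha^(i-1)` to the
#'   i-th nearest neighbour's weight; default 0.9.
#' @param a1,a2 Non-negative combination weights for the microbe- and
#'   disease-derived profiles (both 1 by convention).
#' @param normalize_with_decay If `TRUE`, the normalizer sums the decayed
#'   weights `alpha^(i-1) * S` instead of the plain similarities. The
#'   default (`FALSE`) follows the literal formulation in which the
#'   normalizer ignores the decay.
#' @return A `wknn_config` list.
#' @export
wknn_config <- function(K = 5, alpha = 0.9, a1 = 1, a2 = 1,
                        normalize_with_decay = FALSE) {
  stopifnot(K >= 1, alpha >= 0, alpha <= 1, a1 >= 0, a2 >= 0, a1 + a2 > 0)
  structure(list(K = as.integer(K), alpha = alpha, a1 = a1, a2 = a2,
                 normalize_with_decay = isTRUE(normalize_with_decay)),
            class = "wknn_config")
}

#' Weighted K-nearest-neighbour interaction profiles
#'
#' For every entity `q` on the chosen axis, finds its `K` most similar
#' *known* entities (entities with at least one known association in the
#' original binary `Y`, excluding `q` itself), sorted by descending
#' similarity with lexicographic label tie-break, and forms the new
#' profile
#' \deqn{\tilde Y(q) = \frac{1}{Q} \sum_{i=1}^{K} \alpha^{i-1}
#'       S(i, q)\, Y(i,\cdot), \qquad Q = \sum_{i=1}^{K} S(i, q).}
#' When all `K` neighbour similarities are zero (`Q = 0`) the profile is
#' all zeros. `K` larger than the number of available known entities is
#' truncated with a warning.
#'
#' @param Y Binary labelled adjacency matrix (microbes x diseases).
#' @param S Similarity matrix on the chosen axis (labels must match that
#'   axis of `Y`).
#' @param axis `"microbe"` (rows smoothed using microbe similarity) or
#'   `"disease"` (columns smoothed using disease similarity).
#' @param cfg A [wknn_config()].
#' @return A real-valued matrix with the shape and labels of `Y`, entries
#'   in \[0, 1\].
#' @export
wknn_profiles <- function(Y, S, axis = c("microbe", "disease"),
                          cfg = wknn_config()) {
  axis <- match.arg(axis)
  assert_labelled_matrix(Y, "adjacency matrix")
  assert_binary(Y)
  assert_labelled_matrix(S, "similarity matrix")
  P <- if (axis == "microbe") Y else t(Y)
  if (!identical(rownames(P), rownames(S)))
    stop("similarity labels do not match the ", axis, " axis of Y",
         call. = FALSE)
  labs <- rownames(P)
  known <- labs[rowSums(P) > 0]
  if (!length(known))
    stop("no entity on the ", axis, " axis has a known association",
         call. = FALSE)
  K <- cfg$K
  newP <- matrix(0, nrow(P), ncol(P), dimnames = dimnames(P))
  warned <- FALSE
  for (q in labs) {
    nb <- setdiff(known, q)
    if (!length(nb)) next  # only known entity is q itself: leave zeros
    k_q <- min(K, length(nb))
    if (k_q < K && !warned) {
      warning("K = ", K, " exceeds the number of known neighbours; ",
              "truncated to ", k_q, call. = FALSE)
      warned <- TRUE
    }
    sims <- S[nb, q]
    ord <- order(-sims, nb)[seq_len(k_q)]
    sel <- nb[ord]
    s_sel <- sims[ord]
    w <- cfg$alpha^(seq_len(k_q) - 1) * s_sel
    Q <- if (cfg$normalize_with_decay) sum(w) else sum(s_sel)
    if (Q > 0)
      newP[q, ] <- as.numeric(w %*% P[sel, , drop = FALSE]) / Q
  }
  out <- if (axis == "microbe") newP else t(newP)
  # weights are <= the similarities summed in Q, so entries stay in [0,1]
  out
}

#' Combine axis-wise WKNN profiles and update the adjacency matrix
#'
#' Averages the microbe- and disease-derived profile matrices with
#' weights `a1`, `a2` and takes the elementwise maximum with the original
#' binary matrix, so known associations are never downgraded:
#' `Y_new = max(Y, (a1*Ym + a2*Yd) / (a1 + a2))`.
#'
#' @param Y Original binary adjacency matrix.
#' @param Ym,Yd Profile matrices from [wknn_profiles()] on the microbe
#'   and disease axes.
#' @param cfg A [wknn_config()].
#' @return Real-valued matrix in \[0, 1\] with `Y`'s labels.
#' @export
combine_and_update <- function(Y, Ym, Yd, cfg = wknn_config()) {
  assert_labelled_matrix(Y, "adjacency matrix")
  if (!same_labels(Y, Ym) || !same_labels(Y, Yd))
    stop("Y, Ym, Yd must share shape and labels", call. = FALSE)
  Ymd <- (cfg$a1 * Ym + cfg$a2 * Yd) / (cfg$a1 + cfg$a2)
  pmax(Y, Ymd)
}

#' One-call WKNN preprocessing
#'
#' Convenience wrapper running [wknn_profiles()] on both axes and
#' [combine_and_update()].
#'
#' @inheritParams wknn_profiles
#' @param Sm Microbe similarity matrix.
#' @param Sd Disease similarity matrix (the integrated one).
#' @return Preprocessed adjacency matrix.
#' @export
wknn_preprocess <- function(Y, Sm, Sd, cfg = wknn_config()) {
  Ym <- wknn_profiles(Y, Sm, "microbe", cfg)
  Yd <- wknn_profiles(Y, Sd, "disease", cfg)
  combine_and_update(Y, Ym, Yd, cfg)
}
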