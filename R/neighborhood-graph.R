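#' Greedy cohesiveness clustering (simplified ClusterONE)
#'
#' Grows clusters greedily from unassigned high-degree seeds, maximizing
#' the cohesiveness \eqn{w_{in} / (w_{in} + w_{bound})}, where
#' \eqn{w_{in}} is the total internal edge weight and \eqn{w_{bound}} the
#' total weight on the cluster boundary. Grown clusters whose weighted
#' density \eqn{2 w_{in} / (|V|(|V|-1))} falls below `density_threshold`
#' are discarded; cluster pairs with Jaccard overlap at least
#' `merge_overlap` are merged; vertices covered by no cluster are
#' returned as singletons. Self-similarities (the diagonal) carry no
#' edge weight. All tie-breaks are lexicographic on labels, so the
#' result is deterministic.
#'
#' This is a simplified reimplementation of the greedy cohesive core of
#' the ClusterONE algorithm; the published penalty term and overlap
#' scoring are intentionally omitted.
#'
#' @param S Symmetric non-negative labelled similarity matrix.
#' @param density_threshold Minimum weighted density of a kept cluster
#'   (default 0.5).
#' @param merge_overlap Jaccard overlap at or above which two clusters
#'   merge (default 0.8).
#' @return A `cluster_set`: list with `clusters` (list of character
#'   vectors of labels, possibly overlapping after merging) and
#'   `method_tag`.
#' @export
cluster_one <- function(S, density_threshold = 0.5, merge_overlap = 0.8) {
  assert_labelled_matrix(S, "similarity matrix")
  labs <- rownames(S)
  n <- length(labs)
  A <- unname(S)
  diag(A) <- 0
  deg <- rowSums(A)
  assigned <- rep(FALSE, n)
  clusters <- list()
  repeat {
    cand <- which(!assigned)
    if (!length(cand)) break
    seed <- cand[order(-deg[cand], labs[cand])][1]
    members <- seed
    in_set <- rep(FALSE, n)
    in_set[seed] <- TRUE
    w_in <- 0
    w_bound <- deg[seed]
    coh <- if (w_in + w_bound > 0) w_in / (w_in + w_bound) else 0
    repeat {
      outside <- which(!in_set)
      if (!length(outside)) break
      # cut(v, members) for all outside v at once
      cut_v <- if (length(members) == 1) A[outside, members]
               else rowSums(A[outside, members, drop = FALSE])
      coh_new <- (w_in + cut_v) / (w_in + w_bound + deg[outside] - cut_v)
      coh_new[!is.finite(coh_new)] <- 0
      best <- order(-coh_new, labs[outside])[1]
      if (coh_new[best] <= coh + 1e-12) break
      v <- outside[best]
      w_in <- w_in + cut_v[best]
      w_bound <- w_bound + deg[v] - 2 * cut_v[best]
      in_set[v] <- TRUE
      members <- c(members, v)
      coh <- coh_new[best]
    }
    assigned[members] <- TRUE
    k <- length(members)
    dens <- if (k > 1) 2 * w_in / (k * (k - 1)) else 0
    if (k > 1 && dens >= density_threshold)
      clusters[[length(clusters) + 1]] <- sort(labs[members])
  }
  clusters <- merge_by_jaccard(clusters, merge_overlap)
  covered <- unique(unlist(clusters))
  for (u in setdiff(labs, covered))
    clusters[[length(clusters) + 1]] <- u
  structure(list(clusters = clusters, method_tag = "greedy-cohesiveness"),
            class = "cluster_set")
}

merge_by_jaccard <- function(clusters, threshold) {
  repeat {
    merged <- FALSE
    n <- length(clusters)
    if (n < 2) break
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        jac <- length(intersect(clusters[[i]], clusters[[j]])) /
          length(union(clusters[[i]], clusters[[j]]))
        if (jac >= threshold) {
          clusters[[i]] <- sort(union(clusters[[i]], clusters[[j]]))
          clusters[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  clusters
}

#' p-nearest-neighbour / cluster weight matrix
#'
#' Builds the three-valued weight matrix X used to sparsify a similarity
#' matrix into a regularization graph:
#' `X[i, j] = 1` when i and j are mutual p-nearest neighbours *and* share
#' at least one cluster; `0` when neither is a neighbour of the other
#' *and* they share no cluster; `0.5` otherwise (mixed evidence). The
#' diagonal is set to 1. Neighbour ties are broken lexicographically.
#'
#' @param S Symmetric labelled similarity matrix.
#' @param clusters A `cluster_set` from [cluster_one()] (or built from an
#'   external cluster file).
#' @param p Neighbourhood size (default 5; must be < number of
#'   entities).
#' @return A symmetric matrix with entries in \{0, 0.5, 1\}.
#' @export
neighbor_weight_matrix <- function(S, clusters, p = 5) {
  assert_labelled_matrix(S, "similarity matrix")
  labs <- rownames(S)
  n <- length(labs)
  stopifnot(p >= 1, p < n)
  bad <- setdiff(unlist(clusters$clusters), labs)
  if (length(bad))
    stop("cluster labels absent from similarity matrix: ",
         paste(bad, collapse = ", "), call. = FALSE)
  # N[i, j] = TRUE iff j is among the p most similar entities to i
  N <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[i] <- -Inf
    nb <- order(-s, labs)[seq_len(p)]
    N[i, nb] <- TRUE
  }
  # co-membership in >= 1 cluster
  co <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  for (cl in clusters$clusters) {
    idx <- match(cl, labs)
    co[idx, idx] <- TRUE
  }
  mutual <- N & t(N)
  neither <- (!N) & t(!N)
  X <- matrix(0.5, n, n, dimnames = list(labs, labs))
  X[mutual & co] <- 1
  X[neither & !co] <- 0
  diag(X) <- 1
  X
}

#' Masked regularization graph and Laplacian
#'
#' Applies the weight mask elementwise, `S*[i, j] = X[i, j] * S[i, j]`,
#' and derives the degree matrix `D = diag(rowSums(S*))` and graph
#' Laplacian `L = D - S*`. For symmetric non-negative `S*` the Laplacian
#' is symmetric positive semi-definite with zero row sums.
#'
#' @param S Symmetric labelled similarity matrix.
#' @param X Weight mask from [neighbor_weight_matrix()] (or all-ones for
#'   the unmasked graph).
#' @return A `regularized_graph`: list with `weights` (S*), `degree`
#'   (diagonal matrix), `laplacian`, `labels`.
#' @export
masked_graph <- function(S, X) {
  assert_labelled_matrix(S, "similarity matrix")
  if (!identical(dim(S), dim(X)))
    stop("similarity and mask shapes differ", call. = FALSE)
  Sstar <- unname(S) * unname(X)
  if (max(abs(Sstar - t(Sstar))) > 1e-10)
    stop("internal error: masked graph is not symmetric", call. = FALSE)
  Sstar <- (Sstar + t(Sstar)) / 2
  d <- rowSums(Sstar)
  L <- diag(d, nrow = length(d)) - Sstar
  labs <- rownames(S)
  dimnames(Sstar) <- dimnames(L) <- list(labs, labs)
  structure(list(weights = Sstar,
                 degree = diag(d, nrow = length(d)),
                 laplacian = L,
                 labels = labs),
            class = "regularized_graph")
}

#' Build both regularization graphs for a preprocessed problem
#'
#' Runs [cluster_one()], [neighbor_weight_matrix()] and [masked_graph()]
#' on one similarity matrix.
#'
#' @param S Similarity matrix.
#' @param p Neighbourhood size.
#' @param density_threshold,merge_overlap Passed to [cluster_one()].
#' @param clusters Optional externally supplied `cluster_set`, bypassing
#'   [cluster_one()].
#' @return A `regularized_graph`.
#' @export
build_regularization_graph <- function(S, p = 5, density_threshold = 0.5,
                                       merge_overlap = 0.8,
                                       clusters = NULL) {
  if (is.null(clusters))
    clusters <- cluster_one(S, density_threshold, merge_overlap)
  X <- neighbor_weight_matrix(S, clusters, p = min(p, nrow(S) - 1))
  masked_graph(S, X)
}

#' Read an external cluster file
#'
#' One cluster per line, tab-separated labels.
#'
#' @param path Path to the cluster file.
#' @return A `cluster_set`.
#' @export
read_cluster_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  structure(list(clusters = lapply(strsplit(lines, "\t", fixed = TRUE),
                                   trimws),
                 method_tag = "external"),
            class = "cluster_set")
}
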