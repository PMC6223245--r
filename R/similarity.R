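#' Gaussian interaction profile kernel similarity
#'
#' Computes the GIP kernel similarity between entities on one axis of a
#' binary adjacency matrix. The interaction profile of a microbe is its
#' row of `Y`; of a disease, its column. For microbes
#' \deqn{S(i, j) = \exp(-\gamma_m \|Y(m_i) - Y(m_j)\|^2), \quad
#'       \gamma_m = \gamma'_m \Big/ \frac{1}{m}\sum_i \|Y(m_i)\|^2}
#' and symmetrically on columns for diseases. The bandwidth is the
#' supplied `gamma_prime` normalized by the mean squared profile norm, so
#' entities with no known associations still contribute 0 to the
#' normalization sum; only a fully zero matrix is rejected.
#'
#' @param Y Binary labelled adjacency matrix.
#' @param axis `"microbe"` (rows) or `"disease"` (columns).
#' @param gamma_prime Raw bandwidth \eqn{\gamma'} (default 1, the
#'   convention of the originating kernel-similarity literature).
#' @return A symmetric similarity matrix with unit diagonal, entries in
#'   (0, 1], labels of the chosen axis, and the normalized bandwidth in
#'   `attr(, "bandwidth")`.
#' @examples
#' Y <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2, byrow = TRUE,
#'             dimnames = list(c("m1", "m2", "m3"), c("d1", "d2")))
#' S <- gip_kernel(Y, "microbe")
#' attr(S, "bandwidth")  # 0.75
#' @export
gip_kernel <- function(Y, axis = c("microbe", "disease"), gamma_prime = 1) {
  axis <- match.arg(axis)
  assert_labelled_matrix(Y, "adjacency matrix")
  assert_binary(Y)
  stopifnot(gamma_prime > 0)
  if (all(Y == 0))
    stop("all-zero adjacency matrix: GIP bandwidth normalization undefined",
         call. = FALSE)
  P <- if (axis == "microbe") Y else t(Y)
  sq <- rowSums(P * P)
  gamma <- gamma_prime / mean(sq)
  # squared profile distances via the Gram matrix
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(P)
  D2[D2 < 0] <- 0
  S <- exp(-gamma * D2)
  diag(S) <- 1
  S <- (S + t(S)) / 2
  attr(S, "bandwidth") <- gamma
  S
}

#' Integrate GIP disease similarity with an external similarity matrix
#'
#' Averages the GIP kernel similarity with a precomputed disease
#' similarity matrix (e.g. a symptom-based similarity), aligned by label:
#' `S_d = (S_gip + SDM) / 2`. The external matrix is cleaned first:
#' values clipped to \[0, 1\], symmetrized by averaging with the
#' transpose (a warning is raised when either changes an entry by more
#' than 1e-9), and the diagonal set to 1. Diseases missing from `sdm`
#' receive external similarity 0 before averaging (with a warning), or an
#' error when `strict = TRUE`.
#'
#' @param gip GIP disease similarity matrix (from [gip_kernel()]).
#' @param sdm Optional external square labelled similarity matrix whose
#'   labels are ideally a superset of `gip`'s. `NULL` returns `gip`
#'   unchanged with a warning.
#' @param strict Error (instead of zero-filling) when a `gip` label is
#'   absent from `sdm`.
#' @return Integrated symmetric similarity matrix on `gip`'s labels.
#' @export
integrate_disease_similarity <- function(gip, sdm = NULL, strict = FALSE) {
  assert_labelled_matrix(gip, "GIP similarity")
  if (is.null(sdm)) {
    warning("no external disease similarity supplied; ",
            "using GIP kernel similarity alone", call. = FALSE)
    return(gip)
  }
  assert_labelled_matrix(sdm, "external similarity")
  if (!identical(rownames(sdm), colnames(sdm)))
    stop("external similarity must be square with matching labels",
         call. = FALSE)
  sdm_clean <- clean_similarity(sdm)
  labs <- rownames(gip)
  missing <- setdiff(labs, rownames(sdm_clean))
  if (length(missing)) {
    if (strict)
      stop("diseases absent from external similarity: ",
           paste(missing, collapse = ", "), call. = FALSE)
    warning(length(missing), " disease(s) absent from external similarity; ",
            "their external entries default to 0", call. = FALSE)
  }
  A <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  shared <- intersect(labs, rownames(sdm_clean))
  A[shared, shared] <- sdm_clean[shared, shared]
  out <- (gip + A) / 2
  attr(out, "bandwidth") <- attr(gip, "bandwidth")
  out
}

# Clip to [0,1], symmetrize by transpose-averaging, unit diagonal.
clean_similarity <- function(S) {
  out <- pmin(pmax(S, 0), 1)
  sym <- (out + t(out)) / 2
  if (max(abs(S - sym)) > 1e-9)
    warning("external similarity clipped/symmetrized (max change ",
            format(max(abs(S - sym)), digits = 3), ")", call. = FALSE)
  diag(sym) <- 1
  sym
}
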