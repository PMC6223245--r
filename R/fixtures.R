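#' Synthetic fixture specification
#'
#' Describes a planted low-rank bipartite association problem: each
#' microbe and disease is assigned to one of `true_rank` latent groups,
#' within-group factor loadings are high and between-group loadings low,
#' and the binary adjacency matrix is sampled from the resulting score
#' matrix. The defaults describe the package's reference study
#' condition: a 60 x 25 network with 4 latent groups, 10% association
#' density and 2% flip noise, together with a disease similarity matrix
#' derived from the disease factors plus Gaussian noise.
#'
#' @param n_microbes,n_diseases Network dimensions (default 60 x 25).
#' @param true_rank Number of planted latent groups (default 4).
#' @param density Fraction of cells set to 1 before noise (default 0.1).
#' @param noise_flip_prob Probability of flipping each cell after
#'   thresholding (default 0.02).
#' @param sdm_noise_sd Standard deviation of the Gaussian noise added to
#'   the cosine disease similarity (default 0.1).
#' @param seed Integer seed; all outputs are deterministic given it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_microbes = 60, n_diseases = 25, true_rank = 4,
                         density = 0.1, noise_flip_prob = 0.02,
                         sdm_noise_sd = 0.1, seed = 1L) {
  stopifnot(n_microbes >= 2, n_diseases >= 2,
            true_rank >= 1, true_rank <= min(n_microbes, n_diseases),
            density > 0, density < 1,
            noise_flip_prob >= 0, noise_flip_prob < 1,
            sdm_noise_sd >= 0)
  if (density * n_microbes * n_diseases < true_rank)
    stop("infeasible spec: fewer planted ones than latent groups",
         call. = FALSE)
  structure(list(n_microbes = as.integer(n_microbes),
                 n_diseases = as.integer(n_diseases),
                 true_rank = as.integer(true_rank),
                 density = density,
                 noise_flip_prob = noise_flip_prob,
                 sdm_noise_sd = sdm_noise_sd,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic association problem
#'
#' Draws block-structured non-negative factors `W0` (m x r) and `H0`
#' (n x r): each entity belongs to one latent group with loading drawn
#' from uniform(0.8, 1.2), off-group loadings from uniform(0, 0.1). The
#' ground-truth score matrix is `P = W0 %*% t(H0)` rescaled to \[0, 1\]
#' by its maximum. The binary adjacency matrix sets the top
#' `round(density * m * n)` cells of `P` to 1 and then flips every cell
#' independently with probability `noise_flip_prob`. The disease
#' similarity matrix is the cosine similarity of the rows of `H0` plus
#' Gaussian noise, clipped to \[0, 1\], symmetrized, with unit diagonal.
#' Labels are synthetic (`M0001...`, `D001...`).
#'
#' @param spec A [fixture_spec()].
#' @return List with `table` (an `association_table` of the ones of Y,
#'   with evidence ids), `Y` (the binary adjacency matrix),
#'   `truth` (the labelled ground-truth score matrix P), `sdm` (the
#'   noisy disease similarity), and the group assignments
#'   `microbe_groups`, `disease_groups`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, generate_fixture_impl(spec))
}

generate_fixture_impl <- function(spec) {
  m <- spec$n_microbes; n <- spec$n_diseases; r <- spec$true_rank
  mlab <- sprintf("M%04d", seq_len(m))
  dlab <- sprintf("D%03d", seq_len(n))
  # round-robin group sizes, shuffled assignment; every group non-empty
  gm <- sample(rep_len(seq_len(r), m))
  gd <- sample(rep_len(seq_len(r), n))
  W0 <- matrix(stats::runif(m * r, 0, 0.1), m, r)
  W0[cbind(seq_len(m), gm)] <- stats::runif(m, 0.8, 1.2)
  H0 <- matrix(stats::runif(n * r, 0, 0.1), n, r)
  H0[cbind(seq_len(n), gd)] <- stats::runif(n, 0.8, 1.2)
  P <- W0 %*% t(H0)
  P <- P / max(P)
  dimnames(P) <- list(mlab, dlab)
  n_ones <- max(spec$true_rank, round(spec$density * m * n))
  Y <- matrix(0, m, n, dimnames = list(mlab, dlab))
  Y[order(-P, seq_along(P))[seq_len(n_ones)]] <- 1
  if (spec$noise_flip_prob > 0) {
    flip <- stats::runif(m * n) < spec$noise_flip_prob
    Y[flip] <- 1 - Y[flip]
  }
  # cosine similarity of disease factor rows
  Hn <- H0 / sqrt(rowSums(H0 * H0))
  C <- tcrossprod(Hn)
  if (spec$sdm_noise_sd > 0)
    C <- C + matrix(stats::rnorm(n * n, 0, spec$sdm_noise_sd), n, n)
  C <- pmin(pmax((C + t(C)) / 2, 0), 1)
  diag(C) <- 1
  dimnames(C) <- list(dlab, dlab)
  ones <- which(Y == 1, arr.ind = TRUE)
  ord <- order(ones[, 1], ones[, 2])
  ones <- ones[ord, , drop = FALSE]
  table <- association_table(mlab[ones[, 1]], dlab[ones[, 2]],
                             sprintf("E%05d", seq_len(nrow(ones))))
  list(table = table, Y = Y, truth = P, sdm = C,
       microbe_groups = gm, disease_groups = gd)
}

#' Inject duplicate records into an association table
#'
#' Appends `n_dups` records sampled with replacement from the existing
#' ones, with fresh evidence ids, exercising the deduplication path of
#' [build_adjacency()].
#'
#' @param table An `association_table`.
#' @param n_dups Number of duplicate records to append.
#' @param seed Integer seed.
#' @return An `association_table` with `nrow(table) + n_dups` records.
#' @export
duplicate_some <- function(table, n_dups, seed = 1L) {
  stopifnot(n_dups >= 0, n_dups <= nrow(table))
  if (n_dups == 0) return(table)
  idx <- with_seed(seed, sample(nrow(table), n_dups, replace = TRUE))
  extra <- table[idx, ]
  extra$evidence <- sprintf("EDUP%04d", seq_len(n_dups))
  out <- rbind(table, extra)
  rownames(out) <- NULL
  class(out) <- c("association_table", "data.frame")
  out
}
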