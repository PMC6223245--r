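#' GRNMF solver configuration
#'
#' @param rank_k Inner factorization dimension k (default 10).
#' @param lambda_l Tikhonov (L2) coefficient on both factors (default
#'   0.01).
#' @param lambda_m,lambda_d Graph-Laplacian coefficients for the microbe
#'   and disease graphs (default 0.01).
#' @param max_iter Maximum multiplicative-update iterations (default
#'   1000).
#' @param tol Relative objective-change stopping tolerance (default
#'   1e-6).
#' @param seed Integer seed for the uniform(0,1) factor initialization.
#' @param eps Denominator floor protecting the multiplicative ratio
#'   (default 1e-12). Flooring the denominator (rather than smoothing the
#'   numerator) preserves the zero-locking property of multiplicative
#'   updates.
#' @return A `solver_config` list.
#' @export
solver_config <- function(rank_k = 10, lambda_l = 0.01, lambda_m = 0.01,
                          lambda_d = 0.01, max_iter = 1000, tol = 1e-6,
                          seed = 1L, eps = 1e-12) {
  stopifnot(rank_k >= 1, lambda_l >= 0, lambda_m >= 0, lambda_d >= 0,
            max_iter >= 1, tol > 0, eps > 0)
  structure(list(rank_k = as.integer(rank_k), lambda_l = lambda_l,
                 lambda_m = lambda_m, lambda_d = lambda_d,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), eps = eps),
            class = "solver_config")
}

#' GRNMF objective value
#'
#' Evaluates
#' \deqn{\|Y - WH^\top\|_F^2 + \lambda_l(\|W\|_F^2 + \|H\|_F^2)
#'       + \lambda_m \mathrm{Tr}(W^\top L_m W)
#'       + \lambda_d \mathrm{Tr}(H^\top L_d H).}
#'
#' @param Y Adjacency (or preprocessed score) matrix, m x n.
#' @param W,H Non-negative factors, m x k and n x k.
#' @param graph_m,graph_d `regularized_graph` objects for the microbe and
#'   disease axes (their `laplacian` components are used).
#' @param cfg A [solver_config()].
#' @return Non-negative scalar (for PSD Laplacians).
#' @export
grnmf_objective <- function(Y, W, H, graph_m, graph_d, cfg) {
  if (!all(is.finite(Y), is.finite(W), is.finite(H)))
    stop("non-finite inputs to objective", call. = FALSE)
  R <- Y - tcrossprod(W, H)
  obj <- sum(R * R) +
    cfg$lambda_l * (sum(W * W) + sum(H * H)) +
    cfg$lambda_m * sum(W * (graph_m$laplacian %*% W)) +
    cfg$lambda_d * sum(H * (graph_d$laplacian %*% H))
  obj
}

#' One multiplicative update of both factors
#'
#' Applies the update rules
#' \deqn{w_{ik} \leftarrow w_{ik}
#'   \frac{(YH + \lambda_m S^{m*} W)_{ik}}
#'        {(W H^\top H + \lambda_l W + \lambda_m D_m W)_{ik}}}
#' then, using the updated W,
#' \deqn{h_{jk} \leftarrow h_{jk}
#'   \frac{(Y^\top W + \lambda_d S^{d*} H)_{jk}}
#'        {(H W^\top W + \lambda_l H + \lambda_d D_d H)_{jk}}.}
#' Denominators are floored at `cfg$eps`; non-negativity is preserved and
#' zero entries stay zero.
#'
#' @inheritParams grnmf_objective
#' @return List with updated `W` and `H`.
#' @export
multiplicative_step <- function(Y, W, H, graph_m, graph_d, cfg) {
  dm <- diag(graph_m$degree)
  dd <- diag(graph_d$degree)
  numW <- Y %*% H + cfg$lambda_m * (graph_m$weights %*% W)
  denW <- W %*% crossprod(H) + cfg$lambda_l * W + cfg$lambda_m * (dm * W)
  W <- W * numW / pmax(denW, cfg$eps)
  numH <- crossprod(Y, W) + cfg$lambda_d * (graph_d$weights %*% H)
  denH <- H %*% crossprod(W) + cfg$lambda_l * H + cfg$lambda_d * (dd * H)
  H <- H * numH / pmax(denH, cfg$eps)
  list(W = W, H = H)
}

#' Fit GRNMF by multiplicative updates
#'
#' Initializes W and H from a seeded uniform(0, 1) draw and iterates
#' [multiplicative_step()] until the relative objective change
#' `|obj_t - obj_{t-1}| / max(obj_{t-1}, eps)` drops below `cfg$tol` or
#' `cfg$max_iter` is reached. The R session's RNG state is left
#' untouched. Deterministic given `cfg$seed`.
#'
#' @param Y Preprocessed adjacency matrix (real values in \[0, 1\]
#'   allowed).
#' @param graph_m,graph_d `regularized_graph` objects whose labels match
#'   the rows / columns of `Y`.
#' @param cfg A [solver_config()].
#' @return A `grnmf_fit`: list with non-negative factors `W` (m x k) and
#'   `H` (n x k), `objective_trace`, `iterations_run`, `converged`, and
#'   the `config` used.
#' @export
grnmf_fit <- function(Y, graph_m, graph_d, cfg = solver_config()) {
  assert_labelled_matrix(Y, "adjacency matrix")
  m <- nrow(Y); n <- ncol(Y)
  if (cfg$rank_k > min(m, n))
    stop("rank_k = ", cfg$rank_k, " exceeds min(m, n) = ", min(m, n),
         call. = FALSE)
  if (!identical(graph_m$labels, rownames(Y)) ||
      !identical(graph_d$labels, colnames(Y)))
    stop("graph labels do not match Y", call. = FALSE)
  init <- local_runif(cfg$seed, m * cfg$rank_k + n * cfg$rank_k)
  W <- matrix(init[seq_len(m * cfg$rank_k)], m, cfg$rank_k)
  H <- matrix(init[-seq_len(m * cfg$rank_k)], n, cfg$rank_k)
  trace <- numeric(cfg$max_iter + 1)
  trace[1] <- grnmf_objective(Y, W, H, graph_m, graph_d, cfg)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(cfg$max_iter)) {
    st <- multiplicative_step(Y, W, H, graph_m, graph_d, cfg)
    W <- st$W; H <- st$H
    trace[it + 1] <- grnmf_objective(Y, W, H, graph_m, graph_d, cfg)
    rel <- abs(trace[it + 1] - trace[it]) / max(trace[it], cfg$eps)
    if (rel < cfg$tol) {
      converged <- TRUE
      break
    }
  }
  rownames(W) <- rownames(Y)
  rownames(H) <- colnames(Y)
  structure(list(W = W, H = H,
                 objective_trace = trace[seq_len(it + 1)],
                 iterations_run = it,
                 converged = converged,
                 config = cfg),
            class = "grnmf_fit")
}

#' Predicted association scores
#'
#' The score matrix `Y* = W %*% t(H)` with the original labels; a higher
#' score means the pair is more likely to be associated.
#'
#' @param fit A `grnmf_fit`.
#' @return Labelled m x n score matrix.
#' @export
predict_scores <- function(fit) {
  stopifnot(inherits(fit, "grnmf_fit"))
  tcrossprod(fit$W, fit$H)
}

#' @export
print.grnmf_fit <- function(x, ...) {
  cat("GRNMF fit:", nrow(x$W), "x", nrow(x$H), "matrix, rank",
      ncol(x$W), "\n")
  cat("  iterations:", x$iterations_run,
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  cat("  final objective:",
      format(x$objective_trace[length(x$objective_trace)], digits = 6),
      "\n")
  invisible(x)
}

#' KKT stationarity residual of a fit
#'
#' Elementwise `min(W, |grad_W|)` and `min(H, |grad_H|)` where the
#' gradients are those of the objective with the non-negativity
#' multipliers dropped; at a KKT point each entry is (near) zero because
#' either the variable or its gradient vanishes.
#'
#' @inheritParams grnmf_objective
#' @return Max-norm of the combined residual.
#' @export
kkt_residual <- function(Y, W, H, graph_m, graph_d, cfg) {
  gW <- -2 * Y %*% H + 2 * W %*% crossprod(H) + 2 * cfg$lambda_l * W +
    2 * cfg$lambda_m * (graph_m$laplacian %*% W)
  gH <- -2 * crossprod(Y, W) + 2 * H %*% crossprod(W) +
    2 * cfg$lambda_l * H + 2 * cfg$lambda_d * (graph_d$laplacian %*% H)
  max(pmin(W, abs(gW)), pmin(H, abs(gH)))
}

#' Grid search over solver hyperparameters
#'
#' Fits every combination of the supplied parameter values and reports
#' the final objective (and optionally a user-supplied score function,
#' e.g. a cross-validation AUC).
#'
#' @inheritParams grnmf_fit
#' @param rank_k,lambda_l,lambda_m,lambda_d Vectors of candidate values.
#' @param cfg Base [solver_config()] supplying the remaining fields.
#' @param score_fn Optional `function(fit)` returning a scalar to record.
#' @return Data frame with one row per combination.
#' @export
grnmf_grid <- function(Y, graph_m, graph_d, rank_k = c(5, 10),
                       lambda_l = 0.01, lambda_m = 0.01, lambda_d = 0.01,
                       cfg = solver_config(), score_fn = NULL) {
  grid <- expand.grid(rank_k = rank_k, lambda_l = lambda_l,
                      lambda_m = lambda_m, lambda_d = lambda_d)
  grid$final_objective <- NA_real_
  if (!is.null(score_fn)) grid$score <- NA_real_
  for (i in seq_len(nrow(grid))) {
    ci <- cfg
    ci$rank_k <- as.integer(grid$rank_k[i])
    ci$lambda_l <- grid$lambda_l[i]
    ci$lambda_m <- grid$lambda_m[i]
    ci$lambda_d <- grid$lambda_d[i]
    fit <- grnmf_fit(Y, graph_m, graph_d, ci)
    grid$final_objective[i] <-
      fit$objective_trace[length(fit$objective_trace)]
    if (!is.null(score_fn)) grid$score[i] <- score_fn(fit)
  }
  grid
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Draw n uniform(0,1) deviates under `seed`, RNG state preserved.
local_runif <- function(seed, n) {
  with_seed(seed, stats::runif(n))
}
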