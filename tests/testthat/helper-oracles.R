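# Independent literal-formula oracles: explicit double loops, no shared
# code with the package implementation.

oracle_gip <- function(Y, axis, gamma_prime = 1) {
  P <- if (axis == "microbe") Y else t(Y)
  n <- nrow(P)
  gamma <- gamma_prime / (mean(sapply(seq_len(n), function(i)
    sum(P[i, ]^2))))
  S <- matrix(NA_real_, n, n, dimnames = list(rownames(P), rownames(P)))
  for (i in seq_len(n))
    for (j in seq_len(n))
      S[i, j] <- exp(-gamma * sum((P[i, ] - P[j, ])^2))
  S
}

oracle_wknn <- function(Y, S, axis, K, alpha) {
  P <- if (axis == "microbe") Y else t(Y)
  labs <- rownames(P)
  known <- labs[apply(P, 1, function(r) any(r == 1))]
  out <- P * 0
  for (q in labs) {
    nb <- setdiff(known, q)
    if (!length(nb)) next
    k_q <- min(K, length(nb))
    sims <- sapply(nb, function(x) S[x, q])
    ord <- order(-sims, nb)
    sel <- nb[ord][seq_len(k_q)]
    Q <- 0
    acc <- rep(0, ncol(P))
    for (i in seq_len(k_q)) {
      s_i <- S[sel[i], q]
      acc <- acc + alpha^(i - 1) * s_i * P[sel[i], ]
      Q <- Q + s_i
    }
    if (Q > 0) out[q, ] <- acc / Q
  }
  if (axis == "microbe") out else t(out)
}

oracle_objective <- function(Y, W, H, Lm, Ld, lambda_l, lambda_m, lambda_d) {
  m <- nrow(Y); n <- ncol(Y)
  recon <- 0
  for (i in seq_len(m))
    for (j in seq_len(n))
      recon <- recon + (Y[i, j] - sum(W[i, ] * H[j, ]))^2
  tr_m <- 0
  for (i in seq_len(m))
    for (p in seq_len(m))
      tr_m <- tr_m + Lm[i, p] * sum(W[i, ] * W[p, ])
  tr_d <- 0
  for (j in seq_len(n))
    for (q in seq_len(n))
      tr_d <- tr_d + Ld[j, q] * sum(H[j, ] * H[q, ])
  recon + lambda_l * (sum(W^2) + sum(H^2)) + lambda_m * tr_m +
    lambda_d * tr_d
}

oracle_predict <- function(W, H) {
  out <- matrix(0, nrow(W), nrow(H))
  for (i in seq_len(nrow(W)))
    for (j in seq_len(nrow(H)))
      out[i, j] <- sum(W[i, ] * H[j, ])
  out
}

# Projected gradient descent with Armijo backtracking on the GRNMF
# objective; an independent generic minimizer used as a solver oracle.
pgd_fit <- function(Y, graph_m, graph_d, cfg, n_iter) {
  m <- nrow(Y); n <- ncol(Y); k <- cfg$rank_k
  set.seed(cfg$seed)
  W <- matrix(runif(m * k), m, k)
  H <- matrix(runif(n * k), n, k)
  Lm <- graph_m$laplacian; Ld <- graph_d$laplacian
  f <- function(W, H) {
    R <- Y - W %*% t(H)
    sum(R^2) + cfg$lambda_l * (sum(W^2) + sum(H^2)) +
      cfg$lambda_m * sum(W * (Lm %*% W)) +
      cfg$lambda_d * sum(H * (Ld %*% H))
  }
  tW <- 1e-2; tH <- 1e-2
  for (it in seq_len(n_iter)) {
    gW <- -2 * Y %*% H + 2 * W %*% (t(H) %*% H) + 2 * cfg$lambda_l * W +
      2 * cfg$lambda_m * (Lm %*% W)
    f0 <- f(W, H)
    tW <- tW * 2
    repeat {
      Wn <- pmax(W - tW * gW, 0)
      if (f(Wn, H) <= f0 - 1e-4 * sum(gW * (W - Wn)) || tW < 1e-14) break
      tW <- tW / 2
    }
    W <- Wn
    gH <- -2 * t(Y) %*% W + 2 * H %*% (t(W) %*% W) + 2 * cfg$lambda_l * H +
      2 * cfg$lambda_d * (Ld %*% H)
    f0 <- f(W, H)
    tH <- tH * 2
    repeat {
      Hn <- pmax(H - tH * gH, 0)
      if (f(W, Hn) <= f0 - 1e-4 * sum(gH * (H - Hn)) || tH < 1e-14) break
      tH <- tH / 2
    }
    H <- Hn
  }
  list(W = W, H = H, objective = f(W, H))
}

# Within-fold Mann-Whitney U normalization with ties mid-ranked:
# each positive is compared against its own fold's candidate scores.
oracle_u_auc <- function(pos_scores, neg_score_lists) {
  num <- 0
  den <- 0
  for (f in seq_along(pos_scores)) {
    neg <- neg_score_lists[[f]]
    num <- num + sum(pos_scores[f] > neg) + 0.5 * sum(pos_scores[f] == neg)
    den <- den + length(neg)
  }
  # equal candidate counts assumed by callers; then pooled U equals the
  # unweighted mean of per-fold fractions
  num / den
}
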