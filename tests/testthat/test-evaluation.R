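test_that("roc_auc reproduces hand cases and ROC invariants", {
  # single fold, rank 1 of 10 candidates: perfect
  r1 <- roc_auc(data.frame(rank = 1, candidates = 10))
  expect_equal(r1$auc, 1.0)
  # two folds, ranks 1/5 and 5/5: Mann-Whitney on pooled within-fold lists
  r2 <- roc_auc(data.frame(rank = c(1, 5), candidates = c(5, 5)))
  expect_equal(r2$auc, 0.6)
  # curve starts at (0,0), ends at (1,1), monotone in both coordinates
  set.seed(1)
  rk <- data.frame(rank = sample(1:21, 40, TRUE), candidates = 20)
  r3 <- roc_auc(rk)
  pts <- r3$roc_points
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_error(roc_auc(data.frame(rank = numeric(), candidates = integer())),
               "no folds")
})

test_that("roc_auc equals the mid-rank Mann-Whitney U identity", {
  set.seed(2)
  for (rep in 1:20) {
    nf <- sample(3:30, 1)
    c_all <- sample(5:40, 1)
    # discrete score grid provokes ties between positives and negatives
    negs <- lapply(seq_len(nf), function(i)
      sample(seq(0, 1, by = 0.1), c_all, TRUE))
    pos <- sample(seq(0, 1, by = 0.1), nf, TRUE)
    ranks <- data.frame(
      rank = vapply(seq_len(nf), function(i)
        1 + sum(negs[[i]] > pos[i]) + 0.5 * sum(negs[[i]] == pos[i]), 0),
      candidates = c_all)
    expect_lt(abs(roc_auc(ranks)$auc - oracle_u_auc(pos, negs)), 1e-12)
  }
})

test_that("roc_auc agrees with pROC on a pooled continuous instance", {
  skip_if_not_installed("pROC")
  set.seed(3)
  n_neg <- 50
  neg <- runif(n_neg)
  pos <- runif(15, 0.2, 1.2)  # positives against one shared candidate set
  ranks <- data.frame(
    rank = vapply(pos, function(p) 1 + sum(neg > p), 0),
    candidates = n_neg)
  ref <- as.numeric(pROC::auc(
    pROC::roc(response = c(rep(1, 15), rep(0, n_neg)),
              predictor = c(pos, neg), quiet = TRUE,
              direction = "<")))
  expect_equal(roc_auc(ranks)$auc, ref, tolerance = 1e-12)
})

test_that("uniform random ranks give chance-level AUC", {
  set.seed(4)
  c_all <- 50
  # Monte-Carlo s.e. of the mean is ~0.0046 at 4000 folds, so the 0.02
  # band sits at >4 sigma
  ranks <- data.frame(rank = sample(seq_len(c_all + 1), 4000, TRUE),
                      candidates = c_all)
  expect_equal(roc_auc(ranks)$auc, 0.5, tolerance = 0.02)
})

test_that("loocv builds one fold per association with the right candidates", {
  Y <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("m1", "m2"), c("d1", "d2")))
  # oracle scorer independent of the pipeline
  res <- loocv(Y, mode = "global",
               score_fn = function(Yr) Yr * 0 + 0.5)
  expect_equal(nrow(res$per_fold_ranks), 2)
  expect_equal(res$per_fold_ranks$candidates, c(2, 2))
  # perfect oracle: held-out pair always outscores candidates
  truth <- matrix(c(1, 0.1, 0.1, 1), 2, 2, dimnames = dimnames(Y))
  res2 <- loocv(Y, mode = "global", score_fn = function(Yr) truth)
  expect_equal(res2$auc, 1)
  # local mode ranks only within the held-out disease
  res3 <- loocv(Y, mode = "local", score_fn = function(Yr) truth)
  expect_equal(res3$per_fold_ranks$candidates, c(1, 1))
  expect_equal(res3$auc, 1)
  expect_error(loocv(matrix(1, 2, 2, dimnames = dimnames(Y))),
               "no unknown pairs")
})

test_that("the held-out association is invisible to the scorer", {
  fx <- generate_fixture(fixture_spec(n_microbes = 10, n_diseases = 6,
                                      true_rank = 2, density = 0.2,
                                      noise_flip_prob = 0, seed = 5))
  seen <- new.env()
  seen$leaked <- FALSE
  Y <- fx$Y
  pos <- which(Y == 1, arr.ind = TRUE)
  k <- 0
  res <- loocv(Y, mode = "global", score_fn = function(Yr) {
    k <<- k + 1
    if (Yr[pos[k, 1], pos[k, 2]] != 0) seen$leaked <- TRUE
    matrix(runif(length(Yr)), nrow(Yr), ncol(Yr), dimnames = dimnames(Yr))
  })
  expect_false(seen$leaked)
  # flipping the held-out cell after reduction cannot change the score:
  # the scorer output is a deterministic function of the reduced matrix
  Yr_probe <- Y
  Yr_probe[pos[1, 1], pos[1, 2]] <- 0
  probe_cfg <- run_config(wknn = wknn_config(K = 3),
                          solver = solver_config(rank_k = 4, max_iter = 30))
  s1 <- pipeline_scores(Yr_probe, fx$sdm, probe_cfg)
  s2 <- pipeline_scores(Yr_probe, fx$sdm, probe_cfg)
  expect_identical(s1$scores, s2$scores)
})

test_that("global LOOCV AUC is invariant to entity relabeling", {
  fx <- generate_fixture(fixture_spec(n_microbes = 8, n_diseases = 5,
                                      true_rank = 2, density = 0.25,
                                      noise_flip_prob = 0, seed = 6))
  Y <- fx$Y
  score_fn <- function(Yr) {
    out <- (Yr %*% t(Yr)) %*% Yr  # label-equivariant two-step diffusion
    dimnames(out) <- dimnames(Yr)
    out
  }
  a1 <- loocv(Y, mode = "global", score_fn = score_fn)$auc
  perm_m <- sample(nrow(Y)); perm_d <- sample(ncol(Y))
  a2 <- loocv(Y[perm_m, perm_d], mode = "global", score_fn = score_fn)$auc
  expect_equal(a1, a2)
})
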