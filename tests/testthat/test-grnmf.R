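test_that("objective matches its definition and the loop oracle", {
  Y <- rand_binary_Y(6, 4, seed = 1)
  gm <- rand_graph(rownames(Y), seed = 2)
  gd <- rand_graph(colnames(Y), seed = 3)
  cfg <- solver_config(rank_k = 2, lambda_l = 0.3, lambda_m = 0.2,
                       lambda_d = 0.1)
  # zero factors, all lambda = 0: plain ||Y||_F^2
  cfg0 <- solver_config(rank_k = 2, lambda_l = 0, lambda_m = 0, lambda_d = 0)
  W0 <- matrix(0, 6, 2); H0 <- matrix(0, 4, 2)
  expect_equal(grnmf_objective(Y, W0, H0, gm, gd, cfg0), sum(Y^2))
  # exact factorization, lambda = 0: zero objective
  set.seed(4)
  W <- matrix(runif(12), 6, 2); H <- matrix(runif(8), 4, 2)
  Yx <- W %*% t(H)
  dimnames(Yx) <- dimnames(Y)
  expect_equal(grnmf_objective(Yx, W, H, gm, gd, cfg0), 0, tolerance = 1e-12)
  # random instance vs explicit double-loop trace evaluation
  o <- grnmf_objective(Y, W, H, gm, gd, cfg)
  expect_lt(abs(o - oracle_objective(Y, W, H, gm$laplacian, gd$laplacian,
                                     0.3, 0.2, 0.1)), 1e-10)
  expect_error(grnmf_objective(Y, W * NA, H, gm, gd, cfg), "non-finite")
})

test_that("multiplicative step fixes exact factorizations and locks zeros", {
  set.seed(5)
  W <- matrix(runif(12), 6, 2); H <- matrix(runif(8), 4, 2)
  W[2, 1] <- 0
  Y <- W %*% t(H)
  dimnames(Y) <- list(sprintf("m%d", 1:6), sprintf("d%d", 1:4))
  gm <- rand_graph(rownames(Y), seed = 6)
  gd <- rand_graph(colnames(Y), seed = 7)
  cfg0 <- solver_config(rank_k = 2, lambda_l = 0, lambda_m = 0, lambda_d = 0)
  st <- multiplicative_step(Y, W, H, gm, gd, cfg0)
  expect_lt(max(abs(st$W - W)), 1e-12)
  expect_lt(max(abs(st$H - H)), 1e-12)
  # zero entries stay zero under repeated regularized steps
  cfg <- solver_config(rank_k = 2, lambda_l = 0.05, lambda_m = 0.05,
                       lambda_d = 0.05)
  Wz <- W; Hz <- H
  for (i in 1:25) {
    st <- multiplicative_step(Y, Wz, Hz, gm, gd, cfg)
    Wz <- st$W; Hz <- st$H
  }
  expect_identical(unname(Wz[2, 1]), 0)
  expect_true(all(Wz >= 0) && all(Hz >= 0))
})

test_that("objective trace is non-increasing across random instances", {
  for (seed in 1:10) {
    Y <- rand_binary_Y(8, 5, seed = seed)
    gm <- rand_graph(rownames(Y), seed = seed + 30)
    gd <- rand_graph(colnames(Y), seed = seed + 60)
    cfg <- solver_config(rank_k = 2, max_iter = 120, tol = 1e-12,
                         seed = seed)
    fit <- grnmf_fit(Y, gm, gd, cfg)
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
    expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  }
})

test_that("fit honours the stopping contract and is seed-deterministic", {
  Y <- rand_binary_Y(6, 4, seed = 9)
  gm <- rand_graph(rownames(Y), seed = 1)
  gd <- rand_graph(colnames(Y), seed = 2)
  cfg_huge <- solver_config(rank_k = 2, tol = 1e9, seed = 3)
  fit1 <- grnmf_fit(Y, gm, gd, cfg_huge)
  expect_equal(fit1$iterations_run, 1)
  expect_true(fit1$converged)

  cfg <- solver_config(rank_k = 2, max_iter = 50, seed = 42)
  fa <- grnmf_fit(Y, gm, gd, cfg)
  fb <- grnmf_fit(Y, gm, gd, cfg)
  expect_identical(fa$W, fb$W)
  expect_identical(fa$H, fb$H)

  expect_error(grnmf_fit(Y, gm, gd, solver_config(rank_k = 5)),
               "rank_k")
})

test_that("fit recovers a planted rank-4 score matrix", {
  fx <- generate_fixture(fixture_spec(seed = 2))
  cfg <- run_config(solver = solver_config(rank_k = 4, max_iter = 500,
                                           seed = 11))
  Sm <- gip_kernel(fx$Y, "microbe")
  Sd <- integrate_disease_similarity(gip_kernel(fx$Y, "disease"), fx$sdm)
  gm <- build_regularization_graph(Sm)
  gd <- build_regularization_graph(Sd)
  fit <- grnmf_fit(fx$truth, gm, gd, cfg$solver)
  rel <- norm(fx$truth - predict_scores(fit), "F") / norm(fx$truth, "F")
  expect_lt(rel, 0.15)
})

test_that("predict_scores is the labelled outer product", {
  fit <- structure(list(W = matrix(c(1, 2), 2, 1,
                                   dimnames = list(c("m1", "m2"), NULL)),
                        H = matrix(c(3, 4), 2, 1,
                                   dimnames = list(c("d1", "d2"), NULL))),
                   class = "grnmf_fit")
  expect_equal(unname(predict_scores(fit)),
               matrix(c(3, 6, 4, 8), 2, 2))
  fit$W <- fit$W * 0
  expect_true(all(predict_scores(fit) == 0))
  set.seed(10)
  W <- matrix(runif(12), 4, 3); H <- matrix(runif(15), 5, 3)
  f2 <- structure(list(W = W, H = H), class = "grnmf_fit")
  expect_lt(max(abs(predict_scores(f2) - oracle_predict(W, H))), 1e-12)
})

test_that("least-squares reconstruction scales linearly with Y (lambda = 0)", {
  set.seed(12)
  W <- matrix(runif(12), 6, 2); H <- matrix(runif(8), 4, 2)
  Y <- W %*% t(H)
  dimnames(Y) <- list(sprintf("m%d", 1:6), sprintf("d%d", 1:4))
  gm <- rand_graph(rownames(Y), seed = 3)
  gd <- rand_graph(colnames(Y), seed = 4)
  cfg <- solver_config(rank_k = 2, lambda_l = 0, lambda_m = 0,
                       lambda_d = 0, max_iter = 2000, tol = 1e-12, seed = 5)
  rel <- function(Yin) {
    fit <- grnmf_fit(Yin, gm, gd, cfg)
    norm(Yin - predict_scores(fit), "F") / norm(Yin, "F")
  }
  r1 <- rel(Y)
  r3 <- rel(3 * Y)
  expect_lt(r1, 0.02)
  expect_lt(abs(r3 - r1), 0.02)
})
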