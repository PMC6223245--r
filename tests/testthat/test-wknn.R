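test_that("K = 1 copies the nearest known neighbour's binary profile", {
  Y <- matrix(c(1, 0,
                0, 1,
                0, 0), 3, 2, byrow = TRUE,
              dimnames = list(c("m1", "m2", "m3"), c("d1", "d2")))
  S <- matrix(c(1, 0.2, 0.9,
                0.2, 1, 0.4,
                0.9, 0.4, 1), 3, 3, byrow = TRUE,
              dimnames = list(rownames(Y), rownames(Y)))
  out <- wknn_profiles(Y, S, "microbe", wknn_config(K = 1, alpha = 0.7))
  # m3's nearest known neighbour is m1 (0.9 > 0.4); weight cancels with Q
  expect_equal(out["m3", ], Y["m1", ])
  # m1's nearest known neighbour (excluding itself) is m2
  expect_equal(out["m1", ], Y["m2", ])
})

test_that("equal-similarity neighbours with alpha = 1 halve the profiles", {
  Y <- matrix(c(1, 0,
                0, 1,
                0, 0), 3, 2, byrow = TRUE,
              dimnames = list(c("m1", "m2", "m3"), c("d1", "d2")))
  S <- diag(3) * 0.4 + 0.6
  dimnames(S) <- list(rownames(Y), rownames(Y))
  # m1/m2 themselves see only one known neighbour; that truncation is
  # expected and irrelevant to the m3 row under test
  out <- suppressWarnings(
    wknn_profiles(Y, S, "microbe", wknn_config(K = 2, alpha = 1)))
  # Q sums plain similarities (2s) while the weighted sum uses s each
  expect_equal(unname(out["m3", ]), c(0.5, 0.5))
})

test_that("wknn_profiles matches the literal-loop oracle on both axes", {
  for (seed in 1:4) {
    Y <- rand_binary_Y(8, 5, seed = seed)
    Sm <- rand_similarity(rownames(Y), seed = seed + 10)
    Sd <- rand_similarity(colnames(Y), seed = seed + 20)
    cfg <- wknn_config(K = 3, alpha = 0.9)
    expect_lt(max(abs(wknn_profiles(Y, Sm, "microbe", cfg) -
                        oracle_wknn(Y, Sm, "microbe", 3, 0.9))), 1e-10)
    expect_lt(max(abs(wknn_profiles(Y, Sd, "disease", cfg) -
                        oracle_wknn(Y, Sd, "disease", 3, 0.9))), 1e-10)
  }
})

test_that("zero neighbour similarity yields a zero profile, K truncates", {
  Y <- matrix(c(1, 0,
                0, 1,
                0, 0), 3, 2, byrow = TRUE,
              dimnames = list(c("m1", "m2", "m3"), c("d1", "d2")))
  S0 <- diag(3)
  dimnames(S0) <- list(rownames(Y), rownames(Y))
  out <- suppressWarnings(
    wknn_profiles(Y, S0, "microbe", wknn_config(K = 2)))
  expect_equal(unname(out["m3", ]), c(0, 0))  # Q = 0 handled, no NaN
  S <- rand_similarity(rownames(Y), seed = 1)
  expect_warning(wknn_profiles(Y, S, "microbe", wknn_config(K = 5)),
                 "truncated")
  expect_error(wknn_profiles(Y * 0 + 0, S, "microbe"), "binary|known")
})

test_that("combine_and_update never downgrades known associations", {
  Y <- rand_binary_Y(7, 4, seed = 6)
  Sm <- rand_similarity(rownames(Y), seed = 7)
  Sd <- rand_similarity(colnames(Y), seed = 8)
  cfg <- wknn_config(K = 3)
  Ym <- wknn_profiles(Y, Sm, "microbe", cfg)
  Yd <- wknn_profiles(Y, Sd, "disease", cfg)
  out <- combine_and_update(Y, Ym, Yd, cfg)
  # elementwise oracle
  expect_lt(max(abs(out - pmax(Y, (Ym + Yd) / 2))), 1e-12)
  expect_true(all(out >= Y))
  expect_true(all(out[Y == 1] == 1))
  expect_true(all(out >= 0 & out <= 1))
  # spot values
  expect_equal(unname(pmax(1, 0.3)), 1)
  Ya <- matrix(0, 1, 1, dimnames = list("m", "d"))
  expect_equal(combine_and_update(
    Ya,
    matrix(0.4, 1, 1, dimnames = dimnames(Ya)),
    matrix(0.8, 1, 1, dimnames = dimnames(Ya)),
    wknn_config())[1, 1], 0.6)
})

test_that("wknn output stays in [0,1] across decay settings", {
  for (alpha in c(0, 0.5, 1)) {
    Y <- rand_binary_Y(9, 6, seed = 3)
    S <- rand_similarity(rownames(Y), seed = 4)
    out <- wknn_profiles(Y, S, "microbe", wknn_config(K = 4, alpha = alpha))
    expect_true(all(out >= 0 & out <= 1 + 1e-12))
  }
  # decay-normalized variant is a convex combination of binary profiles
  Y <- rand_binary_Y(9, 6, seed = 3)
  S <- rand_similarity(rownames(Y), seed = 4)
  out <- wknn_profiles(Y, S, "microbe",
                       wknn_config(K = 4, alpha = 0.5,
                                   normalize_with_decay = TRUE))
  expect_true(all(out >= 0 & out <= 1 + 1e-12))
})
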