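# Small labelled test matrices built in code.

rand_binary_Y <- function(m, n, density = 0.3, seed = 1) {
  set.seed(seed)
  Y <- matrix(rbinom(m * n, 1, density), m, n,
              dimnames = list(sprintf("m%02d", seq_len(m)),
                              sprintf("d%02d", seq_len(n))))
  if (all(Y == 0)) Y[1, 1] <- 1
  storage.mode(Y) <- "double"
  Y
}

rand_similarity <- function(labs, seed = 1) {
  n <- length(labs)
  set.seed(seed)
  S <- matrix(runif(n * n), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(labs, labs)
  S
}

# Dense (all-ones-mask) regularization graph from a random similarity.
rand_graph <- function(labs, seed = 1) {
  S <- rand_similarity(labs, seed)
  X <- matrix(1, length(labs), length(labs), dimnames = list(labs, labs))
  masked_graph(S, X)
}

# The worked 3x2 example used for hand-derived GIP values.
hand_Y <- function() {
  matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE,
         dimnames = list(c("m1", "m2", "m3"), c("d1", "d2")))
}
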