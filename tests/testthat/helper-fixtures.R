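# Toy five-sample example: 3-gene predictor block, 2-gene target block.
toy_predictor <- function() {
  m <- rbind(r1 = c(-0.38, 0.27, 1.82),
             r2 = c(-0.24, 0.36, 0.94),
             r3 = c(-0.32, -0.36, -0.62),
             r4 = c(-0.05, 0.25, 0.37),
             r5 = c(0.05, 0.09, 0.02))
  colnames(m) <- paste0("x", 1:3)
  m
}

toy_target <- function() {
  m <- rbind(r1 = c(0.17, 1.88),
             r2 = c(4.33, 1.83),
             r3 = c(-0.87, 0.61),
             r4 = c(-2.37, 0.43),
             r5 = c(2.55, 2.03))
  colnames(m) <- paste0("y", 1:2)
  m
}

# Independent CID oracle: plain triple loop over samples, subgroups and
# comparison rows, no shared code with the vectorized implementation.
cid_oracle <- function(Y, labels, normalizer) {
  Y <- as.matrix(Y)
  N <- nrow(Y)
  leq <- function(a, b) all(a <= b)
  G <- numeric(N)
  for (i in seq_len(N)) {
    cnt <- 0L
    for (j in seq_len(N)) if (leq(Y[j, ], Y[i, ])) cnt <- cnt + 1L
    G[i] <- cnt / N
  }
  D <- numeric(N)
  for (i in seq_len(N)) {
    for (s in sort(unique(labels))) {
      members <- which(labels == s)
      cnt <- 0L
      for (j in members) if (leq(Y[j, ], Y[i, ])) cnt <- cnt + 1L
      Gs <- cnt / length(members)
      D[i] <- D[i] + (length(members) / N) * (Gs - G[i])^2
    }
  }
  mean(D) / normalizer
}

# Brute-force oracle for the first regularized canonical correlation of
# 2-column blocks: exhaustive search over unit vectors on an angular
# grid, maximizing the ridge-regularized correlation.
grid_cancor_oracle <- function(X, Y, lambda_x, lambda_y, n_grid = 4000L) {
  Sxx <- cov(X); Syy <- cov(Y); Sxy <- cov(X, Y)
  Rx <- Sxx + diag(lambda_x, 2L)
  Ry <- Syy + diag(lambda_y, 2L)
  th <- seq(0, pi, length.out = n_grid)
  A <- rbind(cos(th), sin(th))
  B <- A
  num <- t(A) %*% Sxy %*% B
  da <- colSums(A * (Rx %*% A))
  db <- colSums(B * (Ry %*% B))
  max(abs(num) / sqrt(outer(da, db)))
}

# Two well-separated Gaussian blobs plus the true memberships.
make_blobs <- function(n_per = 20L, sep = 10, seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 2L), n_per, 2L),
             matrix(rnorm(n_per * 2L, mean = sep), n_per, 2L))
  list(X = X, truth = rep(1:2, each = n_per))
}
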