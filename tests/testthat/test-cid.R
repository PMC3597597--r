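test_that("toy example reproduces the printed distances, partition and ecdfs", {
  X <- toy_predictor()
  Y <- toy_target()
  d <- as.matrix(dist(X))
  expect_equal(round(d["r1", "r2"], 4), 0.8956)
  expect_equal(round(d["r4", "r5"], 4), 0.3976)
  expect_equal(round(d["r2", "r4"], 4), 0.6108)

  asg <- subgroup_by_clustering(X, 3)
  grp <- split(rownames(X), asg$labels)
  expect_setequal(vapply(grp, paste, "", collapse = ","),
                  c("r1,r2", "r3", "r4,r5"))

  marg <- vapply(1:5, function(i) marginal_ecdf(Y, Y[i, ]), numeric(1))
  expect_equal(marg, c(0.6, 0.6, 0.4, 0.2, 0.8))

  # all 15 conditional values, rows = (r1,r2)-, r3-, (r4,r5)-group
  expected_cond <- rbind(c(0.5, 0.5, 0, 0, 0.5),
                         c(1, 1, 1, 0, 1),
                         c(0.5, 0.5, 0.5, 0.5, 1))
  s_of <- c(asg$labels[1], asg$labels[3], asg$labels[4])
  cond <- t(vapply(s_of, function(s) {
    vapply(1:5, function(i) conditional_ecdf(Y, asg, s, Y[i, ]),
           numeric(1))
  }, numeric(5)))
  expect_equal(cond, expected_cond, ignore_attr = TRUE)
})

test_that("toy CID matches the hand-derived decomposition", {
  asg <- subgroup_by_clustering(toy_predictor(), 3)
  res <- cid(toy_target(), asg)
  expect_equal(res$normalizer, 0.16)
  expect_equal(unname(sort(res$per_sample)),
               sort(c(0.04, 0.04, 0.14, 0.06, 0.06)))
  expect_equal(res$value, 0.425)
  expect_equal(sum(res$per_subgroup_share), 1)
})

test_that("normalizer formula, boundary cases and degenerate subgroupings", {
  expect_equal(cid_normalizer(5), 0.16)
  expect_equal(cid_normalizer(2), 0.125)
  expect_equal(cid_normalizer(1e6), 1 / 6, tolerance = 1e-5)
  expect_error(cid_normalizer(1), "at least 2")

  # full dependence: distinct univariate targets, singleton subgroups
  set.seed(7)
  for (N in c(4, 9, 17)) {
    y <- matrix(rnorm(N), N, 1)
    expect_equal(cid(y, subgroup_assignment(seq_len(N)))$value, 1)
  }
  # K = 1: conditional equals marginal
  Y <- toy_target()
  expect_equal(cid(Y, subgroup_assignment(rep(1, 5)))$value, 0)
})

test_that("ecdf boundary values and dimension errors", {
  Y <- toy_target()
  expect_equal(marginal_ecdf(Y, apply(Y, 2, min) - 1), 0)
  expect_equal(marginal_ecdf(Y, apply(Y, 2, max)), 1)
  expect_error(marginal_ecdf(Y, c(0, 0, 0)), "dimension mismatch")
  expect_error(conditional_ecdf(Y, subgroup_assignment(rep(1, 5)), 2,
                                Y[1, ]), "out of range")
})

test_that("clustering recovers separated structure and handles K extremes", {
  blobs <- make_blobs(20, sep = 10, seed = 3)
  asg <- subgroup_by_clustering(blobs$X, 2)
  # brute-force check: every point is assigned with its nearest center
  centers <- rbind(colMeans(blobs$X[blobs$truth == 1, ]),
                   colMeans(blobs$X[blobs$truth == 2, ]))
  nearest <- apply(blobs$X, 1, function(x) {
    which.min(colSums((t(centers) - x)^2))
  })
  expect_equal(length(unique(paste(asg$labels, nearest))), 2L)

  X <- toy_predictor()
  expect_equal(subgroup_by_clustering(X, 5)$sizes, rep(1L, 5))
  expect_equal(subgroup_by_clustering(X, 1)$K, 1L)
  expect_error(subgroup_by_clustering(X, 6), "exceed")
  expect_error(subgroup_by_clustering(X, 0), "at least 1")

  # alternative backends produce valid, seeded-reproducible partitions
  for (m in c("kmeans", "som")) {
    a1 <- subgroup_by_clustering(blobs$X, 2, method = m, seed = 11)
    a2 <- subgroup_by_clustering(blobs$X, 2, method = m, seed = 11)
    expect_equal(a1$labels, a2$labels)
    expect_equal(a1$K, 2L)
    expect_true(all(a1$sizes > 0))
  }
})

test_that("vectorized CID matches the triple-loop oracle to 1e-12", {
  set.seed(42)
  for (case in 1:50) {
    N <- sample(5:30, 1)
    q <- sample(1:3, 1)
    K <- sample(1:min(5, N), 1)
    Y <- matrix(rnorm(N * q), N, q)
    labels <- sample(rep(seq_len(K), length.out = N))
    res <- cid(Y, subgroup_assignment(labels))
    expect_equal(res$value, cid_oracle(Y, labels, res$normalizer),
                 tolerance = 1e-12)
  }
})

test_that("CID is within [0,1] (empirical normalizer) and nonnegative", {
  set.seed(101)
  for (case in 1:60) {
    N <- sample(5:25, 1)
    q <- sample(1:3, 1)
    K <- sample(2:min(5, N), 1)
    X <- matrix(rnorm(N * 2), N, 2)
    Y <- matrix(rnorm(N * q), N, q)
    # inject strong dependence in half the cases
    if (case %% 2 == 0) Y <- Y + 2 * X[, 1]
    asg <- subgroup_by_clustering(X, K)
    v_emp <- cid(Y, asg, "empirical")$value
    expect_gte(v_emp, 0)
    expect_lte(v_emp, 1 + 1e-12) # exact bound up to float roundoff
    expect_gte(cid(Y, asg)$value, 0)
    if (q == 1) { # fixed normalizer provably bounded for univariate target
      expect_lte(cid(Y, asg)$value, 1 + 1e-12)
    }
  }
})

test_that("CID is invariant under strictly increasing per-coordinate transforms", {
  set.seed(55)
  for (case in 1:20) {
    N <- sample(8:25, 1)
    q <- sample(1:3, 1)
    K <- sample(2:4, 1)
    Y <- matrix(rnorm(N * q), N, q)
    labels <- sample(rep(seq_len(K), length.out = N))
    asg <- subgroup_assignment(labels)
    Yt <- Y
    for (d in seq_len(q)) Yt[, d] <- exp(3 * Y[, d]) + d
    expect_equal(cid(Yt, asg)$value, cid(Y, asg)$value)
  }
})

test_that("CID depends on X only through the partition", {
  set.seed(66)
  Y <- matrix(rnorm(30), 15, 2)
  X <- matrix(rnorm(45), 15, 3)
  asg <- subgroup_by_clustering(X, 3)
  v1 <- cid(Y, asg)$value
  # any transformation of X that leaves the partition unchanged is inert
  asg2 <- subgroup_by_clustering(10 * X + 2, 3)
  expect_equal(asg2$labels, asg$labels)
  expect_equal(cid(Y, asg2)$value, v1)
})

test_that("symmetric CID averages the two directions and both lie in [0,1]", {
  pair <- paired_gene_sets(toy_predictor(), toy_target())
  s <- symmetric_cid(pair, 3)
  expect_equal(s$value, (s$y_given_x$value + s$x_given_y$value) / 2)
  expect_true(s$y_given_x$value >= 0 && s$x_given_y$value >= 0)

  # X identical to Y: the two directions coincide
  pair2 <- paired_gene_sets(toy_target(), toy_target())
  s2 <- symmetric_cid(pair2, 2)
  expect_equal(s2$y_given_x$value, s2$x_given_y$value)
  expect_equal(s2$value, s2$y_given_x$value)

  # asymmetry is permitted and expected in general
  expect_false(isTRUE(all.equal(s$y_given_x$value, s$x_given_y$value)))
})
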