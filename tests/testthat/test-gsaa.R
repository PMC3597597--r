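# Build a small expression matrix with planted association: set A's
# common signal linearly drives set B; sets C and D are pure noise.
make_planted_expr <- function(N = 60, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(N * 4), N, 4)
  u <- rowSums(A) / 2
  B <- 0.95 * matrix(u, N, 3) + sqrt(1 - 0.95^2) * matrix(rnorm(N * 3), N, 3)
  C <- matrix(rnorm(N * 3), N, 3)
  D <- matrix(rnorm(N * 4), N, 4)
  vals <- cbind(A, B, C, D)
  colnames(vals) <- paste0("g", seq_len(ncol(vals)))
  expr <- expression_matrix(vals, paste0("s", seq_len(N)))
  sets <- gene_set_collection(list(
    gene_set("setA", paste0("g", 1:4)),
    gene_set("setB", paste0("g", 5:7)),
    gene_set("setC", paste0("g", 8:10)),
    gene_set("setD", paste0("g", 11:14))
  ))
  list(expr = expr, sets = sets)
}

test_that("config defaults: supervised mode implies the one-tenth K rule", {
  expect_equal(gsaa_config("supervised")$K_rule, "n_over_10")
  expect_equal(gsaa_config("unsupervised")$K_rule, "fixed")
  expect_equal(gsaa_config("supervised", K_rule = "fixed")$K_rule, "fixed")
})

test_that("supervised K rule follows the one-tenth convention", {
  expect_equal(choose_k(60), 6L)
  expect_equal(choose_k(48), 5L)
  expect_equal(choose_k(152), 15L)
  expect_warning(k <- choose_k(12), "smaller than 20")
  expect_equal(k, 2L)
})

test_that("unsupervised GSAA yields G(G-1) values and flags the planted pair", {
  fx <- make_planted_expr(60, seed = 2)
  cfg <- gsaa_config("unsupervised", K_fixed = 3, seed = 42)
  res <- run_unsupervised_gsaa(fx$expr, fx$sets, cfg)

  G <- length(fx$sets)
  expect_equal(nrow(res$table), G * (G - 1))
  expect_length(res$skipped, 0L)

  # the planted direction (B | A) dominates its predictor column
  rawA <- res$adjusted$raw[, "setA"]
  expect_equal(names(which.max(rawA)), "setB")
  # and is well above the noise pairs in raw CID
  noise <- res$table$cid[res$table$predictor_set %in% c("setC", "setD") &
                           res$table$target_set %in% c("setC", "setD")]
  expect_gt(res$adjusted$raw["setB", "setA"], max(noise))

  # re-running with the same seed reproduces every value bit-identically
  res2 <- run_unsupervised_gsaa(fx$expr, fx$sets, cfg)
  expect_identical(res$adjusted$raw, res2$adjusted$raw)

  # reduction applied iff a block has >= threshold genes (none here)
  expect_false(any(res$table$reduced))
})

test_that("unsupervised GSAA reduces high-dimensional blocks", {
  fx <- make_planted_expr(40, seed = 3)
  # widen set A beyond the reduction threshold with noise genes
  vals <- cbind(unclass(fx$expr),
                matrix(rnorm(40 * 8), 40,
                       dimnames = list(NULL, paste0("h", 1:8))))
  expr <- expression_matrix(vals)
  sets <- gene_set_collection(list(
    gene_set("wide", c(paste0("g", 1:4), paste0("h", 1:8))),
    gene_set("setB", paste0("g", 5:7)),
    gene_set("setC", paste0("g", 8:10))
  ))
  cfg <- gsaa_config("unsupervised", K_fixed = 3, seed = 7,
                     lambda_x = 0.1, lambda_y = 0.1)
  res <- run_unsupervised_gsaa(expr, sets, cfg)
  tab <- res$table
  wide_rows <- tab$predictor_set == "wide" | tab$target_set == "wide"
  expect_true(all(tab$reduced[wide_rows]))
  expect_false(any(tab$reduced[!wide_rows]))
})

test_that("supervised GSAA detects a planted association, not a shuffled one", {
  fx <- make_planted_expr(60, seed = 4)
  cfg <- gsaa_config("supervised", K_rule = "n_over_10", B = 199, seed = 9)
  res <- run_supervised_gsaa(fx$expr, fx$sets$setA, fx$sets$setB,
                             cfg = cfg)
  expect_equal(res$K, 6L)
  expect_equal(res$N, 60L)
  expect_lte(res$p_value, 0.05)
  expect_true(res$significant)

  # break the sample alignment of the target block: association vanishes
  set.seed(10)
  vals <- unclass(fx$expr)
  vals[, 5:7] <- vals[sample(60), 5:7]
  res0 <- run_supervised_gsaa(expression_matrix(vals), fx$sets$setA,
                              fx$sets$setB, cfg = cfg)
  expect_gt(res0$p_value, 0.05)

  # cohort restriction honors the sample subset
  res_sub <- run_supervised_gsaa(fx$expr, fx$sets$setA, fx$sets$setB,
                                 cohort_samples = paste0("s", 1:48),
                                 cfg = cfg)
  expect_equal(res_sub$N, 48L)
  expect_equal(res_sub$K, 5L)
  expect_error(
    run_supervised_gsaa(fx$expr, fx$sets$setA, fx$sets$setB,
                        cohort_samples = c("s1", "nope"), cfg = cfg),
    "absent"
  )
})

test_that("association tables serialize to TSV", {
  fx <- make_planted_expr(30, seed = 5)
  res <- run_unsupervised_gsaa(fx$expr, fx$sets,
                               gsaa_config("unsupervised", seed = 1))
  path <- tempfile(fileext = ".tsv")
  write_association_table(res, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(res$table))
  expect_true(all(c("target_set", "predictor_set", "cid", "adjusted",
                    "significant") %in% names(back)))
})
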