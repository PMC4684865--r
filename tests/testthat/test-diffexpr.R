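test_that("identical treatment and control give zero fold change and p = 1", {
  r <- test_gene(c(1.2, 0.8, 1.0), c(1.2, 0.8, 1.0))
  expect_equal(r$mean_log2fc, 0)
  expect_equal(r$p_value, 1)
})

test_that("the pooled t-test matches a hand-computed statistic", {
  treat <- c(3.1, 2.9, 3.0)
  ctrl <- c(0.1, -0.1, 0.0)
  r <- test_gene(treat, ctrl)
  expect_equal(r$mean_log2fc, 3.0)
  expect_equal(2^r$mean_log2fc, 8.0)
  # independent oracle: textbook pooled two-sample t with df = 4
  sp2 <- (2 * var(treat) + 2 * var(ctrl)) / 4
  t_stat <- (mean(treat) - mean(ctrl)) / sqrt(sp2 * (2 / 3))
  expect_equal(r$p_value, 2 * pt(-abs(t_stat), df = 4))
  # and against the reference implementation
  expect_equal(r$p_value,
               t.test(treat, ctrl, var.equal = TRUE)$p.value)
})

test_that("pooled and Welch variants agree with t.test on random data", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(3 + i %% 3, mean = runif(1, -1, 2), sd = runif(1, 0.05, 0.5))
    y <- rnorm(3, sd = runif(1, 0.05, 0.5))
    for (ve in c(TRUE, FALSE)) {
      r <- test_gene(x, y, var_equal = ve)
      ref <- t.test(x, y, var.equal = ve)
      expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
      expect_equal(r$mean_log2fc, unname(diff(rev(ref$estimate))),
                   tolerance = 1e-12)
    }
  }
})

test_that("sign flip of all inputs negates the fold change but keeps p", {
  set.seed(9)
  x <- rnorm(4, 1)
  y <- rnorm(4)
  a <- test_gene(x, y)
  b <- test_gene(-x, -y)
  expect_equal(b$mean_log2fc, -a$mean_log2fc)
  expect_equal(b$p_value, a$p_value)
})

test_that("degenerate zero-variance genes are handled, not propagated as NaN", {
  same <- test_gene(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)
  diff <- test_gene(c(3, 3, 3), c(1, 1, 1))
  expect_gt(diff$p_value, 0)
  expect_lt(diff$p_value, 1e-100)
  expect_error(test_gene(c(1), c(0, 0.1)), "two non-missing")
})

test_that("upregulated calls require p strictly below alpha and positive effect", {
  res <- data.frame(
    gene_id = c("down", "boundary", "up", "na"),
    mean_log2fc = c(-2, 1, 1, 1),
    fold_change = 2^c(-2, 1, 1, 1),
    p_value = c(0.0005, 0.001, 0.0005, NA),
    stringsAsFactors = FALSE
  )
  expect_equal(upregulated_set(res, 0.001), "up")
})

test_that("upregulated sets are nested across cutoffs", {
  set.seed(21)
  mat <- matrix(rnorm(3000 * 6, sd = 0.2), nrow = 3000,
                dimnames = list(sprintf("g%04d", 1:3000), paste0("a", 1:6)))
  mat[1:100, 1:3] <- mat[1:100, 1:3] + rnorm(300, 0.5, 0.5)
  design <- data.frame(array_id = paste0("a", 1:6),
                       condition = rep(c("combo", "control"), each = 3))
  res <- de_test(mat, design, "combo")
  alphas <- c(1e-4, 1e-3, 1e-2, 0.1)
  sets <- lapply(alphas, function(a) upregulated_set(res, a))
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("type-I rate of upregulation calls is calibrated on null data", {
  set.seed(314)
  n <- 10000
  mat <- matrix(rnorm(n * 6, sd = 0.15), nrow = n,
                dimnames = list(sprintf("g%05d", 1:n), paste0("a", 1:6)))
  design <- data.frame(array_id = paste0("a", 1:6),
                       condition = rep(c("combo", "control"), each = 3))
  res <- de_test(mat, design, "combo")
  n_up <- length(upregulated_set(res, 0.001))
  # one-sided alpha/2 for the upregulated tail; binomial 4*SE band
  expected <- n * 0.0005
  tol <- 4 * sqrt(n * 0.0005 * 0.9995)
  expect_lt(abs(n_up - expected), tol)
})

test_that("fold change is invariant to a constant shift of both groups", {
  x <- c(1.0, 1.3, 0.9)
  y <- c(0.1, -0.2, 0.05)
  a <- test_gene(x, y)
  b <- test_gene(x + 5, y + 5)
  expect_equal(2^a$mean_log2fc, 2^b$mean_log2fc, tolerance = 1e-12)
})

test_that("top-k mean fold change averages the most significant upregulated genes", {
  res <- data.frame(
    gene_id = c("a", "b", "c"),
    mean_log2fc = log2(c(2, 4, 6)),
    fold_change = c(2, 4, 6),
    p_value = c(1e-5, 1e-4, 1e-3),
    stringsAsFactors = FALSE
  )
  expect_equal(top_k_mean_fc(res, k = 3), 4.0)

  flat <- data.frame(gene_id = letters[1:5], mean_log2fc = 1e-9,
                     fold_change = 1, p_value = runif(5),
                     stringsAsFactors = FALSE)
  expect_equal(top_k_mean_fc(flat, k = 5), 1.0)
  expect_warning(top_k_mean_fc(res, k = 50), "using all")
})

test_that("top-k ties break by fold change then gene id, deterministically", {
  res <- data.frame(
    gene_id = c("z", "a", "m"),
    mean_log2fc = c(1, 2, 1),
    fold_change = c(2, 4, 2),
    p_value = c(0.001, 0.001, 0.001),
    stringsAsFactors = FALSE
  )
  # equal p: highest fold change first ("a"), then "m" before "z" by id
  expect_equal(top_k_mean_fc(res, k = 1), 4)
  expect_equal(top_k_mean_fc(res, k = 2), 3)
})

test_that("genes with too few replicates are skipped and reported", {
  mat <- matrix(rnorm(12), nrow = 2,
                dimnames = list(c("ok", "sparse"), paste0("a", 1:6)))
  mat["sparse", 1:2] <- NA
  design <- data.frame(array_id = paste0("a", 1:6),
                       condition = rep(c("combo", "control"), each = 3))
  expect_message(res <- de_test(mat, design, "combo"), "skipped")
  expect_true(is.na(res$p_value[res$gene_id == "sparse"]))
  expect_false(is.na(res$p_value[res$gene_id == "ok"]))
})
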