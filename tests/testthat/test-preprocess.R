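make_spots <- function(ref, smp, flag = FALSE) {
  data.frame(gene_id = sprintf("g%02d", seq_along(ref)),
             ch_reference = ref, ch_sample = smp,
             flag = rep_len(flag, length(ref)), stringsAsFactors = FALSE)
}

test_that("background correction subtracts and floors per channel", {
  out <- background_correct(make_spots(500, 300), 100, 100)
  expect_equal(out$ch_reference, 400)
  expect_equal(out$ch_sample, 200)

  floored <- background_correct(make_spots(50, 40), 100, 100, floor = 1)
  expect_equal(floored$ch_reference, 1)
  expect_equal(floored$ch_sample, 1)

  tab <- make_spots(runif(20, 100, 1000), runif(20, 100, 1000))
  expect_equal(background_correct(tab, 0, 0), tab)
  expect_error(background_correct(tab, -5, 0), "non-negative")
})

test_that("spot filtering removes flagged spots and both-dim spots only", {
  tab <- make_spots(c(80, 80, 5000, 500), c(90, 150, 5000, 500),
                    flag = c(FALSE, FALSE, TRUE, FALSE))
  out <- filter_spots(tab)
  # (80, 90): both below 100 -> removed; (80, 150): one bright channel ->
  # retained; (5000, 5000) flagged -> removed
  expect_setequal(out$gene_id, c("g02", "g04"))
})

test_that("log ratios are log2(sample/reference) with antisymmetry", {
  tab <- make_spots(c(100, 200, 400), c(400, 200, 100))
  ma <- log_ratios(tab)
  expect_equal(ma$M, c(2, 0, -2))
  expect_equal(ma$A, 0.5 * log2(tab$ch_sample * tab$ch_reference))
  expect_error(log_ratios(make_spots(0, 10)), "positive")
})

test_that("the lowess smoother absorbs a constant offset", {
  set.seed(1)
  ma <- data.frame(gene_id = sprintf("g%03d", 1:200),
                   M = rep(0.7, 200), A = rnorm(200, 9, 1.5))
  out <- normalize_intensity(ma)
  expect_lt(max(abs(out$M)), 1e-8)
})

test_that("normalization recovers an injected smooth dye bias", {
  ca <- clean_array(n_genes = 3000L, noise_sd = 0, dye_bias_amplitude = 0.3)
  ma <- log_ratios(filter_spots(ca$tab))
  out <- normalize_intensity(ma)
  # truth is null and noiseless, so any residual M is normalization error
  expect_lt(max(abs(out$M)), 0.05)
})

test_that("normalization is idempotent up to smoother tolerance", {
  ca <- clean_array(n_genes = 5000L, noise_sd = 0.15,
                    dye_bias_amplitude = 0.3)
  ma <- log_ratios(filter_spots(ca$tab))
  once <- normalize_intensity(ma)
  twice <- normalize_intensity(once)
  delta <- abs(twice$M - once$M)
  # boundary windows of any local smoother are high-variance, so the
  # guarantee is over the bulk of the intensity range
  central <- ma$A > quantile(ma$A, 0.005) & ma$A < quantile(ma$A, 0.995)
  expect_lt(max(delta[central]), 0.01)
  expect_lt(stats::quantile(delta, 0.99), 0.01)
})

test_that("normalization refuses arrays with too few spots", {
  ma <- data.frame(gene_id = c("a", "b"), M = c(0, 0), A = c(8, 9))
  expect_error(normalize_intensity(ma), "spots")
})

test_that("lowess trend agrees with an independent local-regression fit", {
  skip_if_not_installed("limma")
  set.seed(33)
  A <- rnorm(1000, 9, 1.5)
  M <- dye_bias(A, 0.4) + rnorm(1000, 0, 0.1)
  ma <- data.frame(gene_id = sprintf("g%04d", 1:1000), M = M, A = A)
  ours <- normalize_intensity(ma, span = 0.3)
  theirs <- M - limma::loessFit(M, A, span = 0.3)$fitted
  # two different smoothers, same target curve
  expect_lt(stats::median(abs(ours$M - theirs)), 0.02)
})

test_that("presence filter keeps genes on strictly more than the cutoff fraction", {
  mat <- matrix(NA_real_, nrow = 3, ncol = 6,
                dimnames = list(c("four", "three", "six"), paste0("a", 1:6)))
  mat["four", 1:4] <- 0
  mat["three", 1:3] <- 0
  mat["six", ] <- 0
  out <- presence_filter(mat, 0.5)
  expect_setequal(rownames(out), c("four", "six"))   # 4/6 > 0.5, 3/6 is not
  all_in <- presence_filter(mat, 0)
  expect_setequal(rownames(all_in), c("four", "three", "six"))
})

test_that("full preprocessing keeps binned medians near zero under bias and noise", {
  cfg <- null_config(n_genes = 4000L, seed = 77L, noise_sd = 0.2,
                     dye_bias_amplitude = 0.3)
  truth <- simulate_truth(cfg)
  arrs <- simulate_arrays(truth, cfg)
  mat <- preprocess_arrays(arrs$spot_tables)
  tab <- arrs$spot_tables[[1]]
  ma <- log_ratios(filter_spots(tab))
  ma <- ma[ma$gene_id %in% rownames(mat), , drop = FALSE]
  m <- mat[ma$gene_id, 1]
  bins <- cut(rank(ma$A, ties.method = "first"), 10)
  med <- tapply(m, bins, stats::median, na.rm = TRUE)
  expect_true(all(abs(med) <= 0.05))
})

test_that("normalization never changes the gene complement; only filters do", {
  cfg <- small_config()
  truth <- simulate_truth(cfg)
  arrs <- simulate_arrays(truth, cfg)
  tab <- arrs$spot_tables[[1]]
  filtered <- filter_spots(tab)
  ma <- log_ratios(filtered)
  out <- normalize_intensity(ma)
  expect_identical(out$gene_id, ma$gene_id)
  expect_lt(nrow(filtered), nrow(tab))  # flags/low spots were present
})

test_that("preprocessing records its provenance in order", {
  cfg <- small_config()
  arrs <- simulate_arrays(simulate_truth(cfg), cfg)
  mat <- preprocess_arrays(arrs$spot_tables)
  prov <- attr(mat, "provenance")
  expect_match(prov[1], "background")
  expect_match(prov[2], "filter_spots")
  expect_match(prov[3], "log2")
  expect_match(prov[4], "lowess")
  expect_match(prov[5], "presence_filter")
})
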