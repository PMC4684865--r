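test_that("truth and arrays are bit-identical under the same config", {
  cfg <- small_config()
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1, t2)
  a1 <- simulate_arrays(t1, cfg)
  a2 <- simulate_arrays(t2, cfg)
  expect_identical(a1, a2)
})

test_that("no-effect configuration yields all-null truth with unit fold changes", {
  truth <- simulate_truth(null_config())
  expect_true(all(truth$synergy_class == "null"))
  expect_true(all(truth$fc_a == 1))
  expect_true(all(truth$fc_b == 1))
  expect_true(all(truth$fc_combo == 1))
})

test_that("class fractions summing above one are rejected", {
  expect_error(sim_config(frac_regulated_a = 0.5, frac_regulated_b = 0.4,
                          frac_supra = 0.2),
               "must not exceed 1")
})

test_that("supra-additive class count equals an independent re-draw of the class uniforms", {
  cfg <- sim_config(n_genes = 10000L, frac_supra = 0.02,
                    frac_regulated_a = 0, frac_regulated_b = 0, seed = 99L)
  truth <- simulate_truth(cfg)
  # oracle: replay the first draw of the documented stream layout
  set.seed(99L)
  expected <- sum(stats::runif(10000L) < 0.02)
  expect_identical(sum(truth$synergy_class == "supra_additive"), expected)
})

test_that("truth satisfies the per-class fold-change invariants", {
  truth <- simulate_truth(small_config())
  expect_true(all(truth$fc_a > 0 & truth$fc_b > 0 & truth$fc_combo > 0))
  nul <- truth$synergy_class == "null"
  expect_true(all(truth$fc_combo[nul] == 1))
  sup <- truth$synergy_class == "supra_additive"
  expect_true(any(sup))
  expect_true(all(truth$fc_combo[sup] /
                    (truth$fc_a[sup] + truth$fc_b[sup]) >= 1.5))
  add <- truth$synergy_class == "additive"
  unfloored <- add & (truth$fc_a + truth$fc_b - 1 >= 2^-6)
  expect_equal(truth$fc_combo[unfloored],
               pmax(truth$fc_a + truth$fc_b - 1, 2^-6)[unfloored])
})

test_that("every gene appears exactly once in every simulated spot table", {
  cfg <- small_config()
  truth <- simulate_truth(cfg)
  arrs <- simulate_arrays(truth, cfg)
  expect_length(arrs$spot_tables, 4 * cfg$n_replicates)
  for (tab in arrs$spot_tables) {
    expect_setequal(tab$gene_id, truth$gene_id)
    expect_equal(anyDuplicated(tab$gene_id), 0L)
  }
})

test_that("noiseless bias-free null arrays have sample equal to reference", {
  ca <- clean_array(n_genes = 500L)
  for (tab in ca$arrs$spot_tables) {
    expect_equal(tab$ch_sample, tab$ch_reference)
  }
})

test_that("replicate means of observed log2 ratios track the true fold change", {
  cfg <- sim_config(n_genes = 300L, seed = 11L, noise_sd = 0.1,
                    dye_bias_amplitude = 0, flag_rate = 0,
                    low_intensity_rate = 0, n_replicates = 3L)
  truth <- simulate_truth(cfg)
  arrs <- simulate_arrays(truth, cfg)
  combo_ids <- arrs$design$array_id[arrs$design$condition == "combo"]
  g <- which.max(truth$fc_combo)  # a strongly induced gene
  obs <- vapply(combo_ids, function(a) {
    tab <- arrs$spot_tables[[a]]
    log2(tab$ch_sample[g] / tab$ch_reference[g])
  }, numeric(1))
  # sampling distribution of the mean of 3 replicates at sd 0.1
  expect_lt(abs(mean(obs) - log2(truth$fc_combo[g])), 3 * 0.1 / sqrt(3))
})

test_that("flagged spot count equals an independent re-draw of the flag substream", {
  cfg <- sim_config(n_genes = 1000L, flag_rate = 0.05, seed = 123L)
  truth <- simulate_truth(cfg)
  arrs <- simulate_arrays(truth, cfg)
  # array k = 1 uses base seed seed + 1000, flags at offset +5
  set.seed(123L + 1000L + 5L)
  expected <- sum(stats::runif(1000L) < 0.05)
  expect_identical(sum(arrs$spot_tables[[1]]$flag), expected)
})

test_that("null unflagged log2 ratios are centred at zero within sampling error", {
  cfg <- null_config(n_genes = 2000L, noise_sd = 0.1,
                     dye_bias_amplitude = 0, low_intensity_rate = 0)
  truth <- simulate_truth(cfg)
  arrs <- simulate_arrays(truth, cfg)
  tab <- arrs$spot_tables[[1]]
  m <- log2(tab$ch_sample / tab$ch_reference)[!tab$flag]
  expect_lt(abs(mean(m)), 4 * 0.1 / sqrt(length(m)))
})

test_that("planted network nodes have the requested out-degrees", {
  genes <- sprintf("g%03d", 1:100)
  net <- simulate_network(genes, n_major = 1, n_minor = 0,
                          coverage_major = 0.40, sparse_rate = 0, seed = 5L)
  major <- attr(net, "major_nodes")
  expect_length(major, 1)
  expect_equal(sum(net$edges$regulator == major), 40L)
})

test_that("major target-set union matches an explicit set-union oracle", {
  genes <- sprintf("g%03d", 1:100)
  net <- simulate_network(genes, n_major = 4, n_minor = 0,
                          coverage_major = 0.40, sparse_rate = 0, seed = 8L)
  majors <- attr(net, "major_nodes")
  union_targets <- Reduce(union, lapply(majors, function(m) {
    net$edges$target[net$edges$regulator == m]
  }))
  expect_gte(length(union_targets), 40L)
  expect_lte(length(union_targets), 100L)
  got <- set_coverage(net, majors)
  expect_equal(got, length(setdiff(union_targets, majors)) /
                 length(setdiff(genes, majors)))
})

test_that("a network with no planted nodes and zero sparse rate is empty", {
  net <- simulate_network(sprintf("g%02d", 1:20), n_major = 0, n_minor = 0,
                          sparse_rate = 0, seed = 3L)
  expect_equal(nrow(net$edges), 0L)
})

test_that("impossible coverage requests error", {
  genes <- sprintf("g%02d", 1:20)
  expect_error(simulate_network(genes, n_major = 1, coverage_major = 1.2),
               "coverage")
  expect_error(simulate_network(genes, n_minor = 1, n_major = 0,
                                coverage_minor = 0.05),
               "coverage_minor")
})
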