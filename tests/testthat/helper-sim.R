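# Small configurations used across tests: fast but structurally identical
# to the defaults.
small_config <- function(...) {
  sim_config(n_genes = 400L, seed = 42L, ...)
}

null_config <- function(n_genes = 400L, seed = 42L, ...) {
  sim_config(n_genes = n_genes, seed = seed,
             frac_regulated_a = 0, frac_regulated_b = 0, frac_supra = 0, ...)
}

# A clean single array (no flags, no forced-low spots, no bias) for
# preprocessing tests.
clean_array <- function(n_genes = 2000L, seed = 7L, noise_sd = 0,
                        dye_bias_amplitude = 0, ...) {
  cfg <- sim_config(n_genes = n_genes, seed = seed, noise_sd = noise_sd,
                    dye_bias_amplitude = dye_bias_amplitude,
                    flag_rate = 0, low_intensity_rate = 0,
                    frac_regulated_a = 0, frac_regulated_b = 0,
                    frac_supra = 0, ...)
  truth <- simulate_truth(cfg)
  arrs <- simulate_arrays(truth, cfg)
  list(cfg = cfg, truth = truth, arrs = arrs,
       tab = arrs$spot_tables[[1]])
}

# Random regulator network over n nodes with edge probability p, for
# oracle comparisons.
random_network <- function(n = 40L, p = 0.08, seed = 1L) {
  set.seed(seed)
  genes <- sprintf("n%03d", seq_len(n))
  adj <- matrix(stats::runif(n * n) < p, n, n)
  diag(adj) <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  edges <- data.frame(regulator = genes[idx[, 1]], target = genes[idx[, 2]],
                      stringsAsFactors = FALSE)
  as_regnetwork(edges, genes)
}

# Brute-force directed reachability by iterative frontier expansion,
# independent of the igraph-based implementation.
brute_reachable <- function(edges, start) {
  seen <- character()
  frontier <- start
  repeat {
    nxt <- unique(edges$target[edges$regulator %in% frontier])
    nxt <- setdiff(nxt, c(seen, start))
    if (length(nxt) == 0) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}
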