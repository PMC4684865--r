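#' Significance cutoffs for upregulation calling
#'
#' The strict cutoff defines the primary upregulated gene sets; the
#' relaxed cutoff (one order of magnitude looser) is used by the
#' recruitment analysis; `top_k` genes enter the mean fold-change summary.
#'
#' @param strict_alpha Strict p-value cutoff (default 0.001).
#' @param relaxed_alpha Relaxed p-value cutoff (default 0.01).
#' @param top_k Number of top genes for the magnitude summary (default 50).
#' @return A validated `cutoffs` list.
#' @export
cutoffs <- function(strict_alpha = 0.001, relaxed_alpha = 0.01, top_k = 50) {
  stopifnot(strict_alpha > 0, strict_alpha < relaxed_alpha,
            relaxed_alpha < 1, is_count(top_k), top_k >= 1)
  structure(list(strict_alpha = strict_alpha, relaxed_alpha = relaxed_alpha,
                 top_k = as.integer(top_k)), class = "cutoffs")
}

# Vectorized two-sample t statistics over matrix rows. Returns mean
# difference, p-value and per-group counts; rows with fewer than two
# usable values in either group get NA.
row_t_test <- function(x, y, var_equal = TRUE) {
  stopifnot(is.matrix(x), is.matrix(y), nrow(x) == nrow(y))
  n1 <- rowSums(!is.na(x))
  n2 <- rowSums(!is.na(y))
  m1 <- rowMeans(x, na.rm = TRUE)
  m2 <- rowMeans(y, na.rm = TRUE)
  v1 <- rowSums((x - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((y - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  dm <- m1 - m2
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  p <- 2 * stats::pt(-abs(dm / se), df)
  # degenerate rows: zero spread in both groups
  zero_se <- is.finite(dm) & !is.na(se) & se == 0
  p[zero_se & dm == 0] <- 1
  p[zero_se & dm != 0] <- .Machine$double.xmin
  p <- pmax(pmin(p, 1), .Machine$double.xmin)
  bad <- n1 < 2 | n2 < 2
  dm[bad] <- NA_real_
  p[bad] <- NA_real_
  list(mean_diff = dm, p_value = p, n1 = n1, n2 = n2, df = df)
}

#' Test one gene for differential expression
#'
#' Two-sample two-sided t-test (pooled variance by default, Welch by flag)
#' comparing treatment and control log2 ratios for a single gene.
#'
#' @param treat_values,ctrl_values Numeric vectors of log2 ratios
#'   (at least two non-missing values each).
#' @param var_equal Pooled-variance test if `TRUE` (default), Welch
#'   otherwise.
#' @return List with `mean_log2fc` (mean treatment minus mean control) and
#'   `p_value`.
#' @examples
#' test_gene(c(3.1, 2.9, 3.0), c(0.1, -0.1, 0))
#' @export
test_gene <- function(treat_values, ctrl_values, var_equal = TRUE) {
  r <- row_t_test(matrix(treat_values, nrow = 1),
                  matrix(ctrl_values, nrow = 1), var_equal = var_equal)
  if (is.na(r$p_value)) {
    stop("test_gene needs at least two non-missing values per group")
  }
  list(mean_log2fc = r$mean_diff, p_value = r$p_value)
}

#' Per-gene differential expression against control
#'
#' Compares every gene's log2 ratios under one treatment condition with
#' those under control, by two-sided t-test on the available replicates.
#' Genes with fewer than two usable replicates in either group are skipped
#' (reported with `NA` statistics and logged).
#'
#' @param mat Genes x arrays log2-ratio matrix (see
#'   [preprocess_arrays()]).
#' @param design `data.frame` with columns `array_id` and `condition`.
#' @param condition Treatment condition to test.
#' @param control Name of the control condition (default `"control"`).
#' @param var_equal Pooled-variance t-test (default) or Welch.
#' @param one_sample If `TRUE`, ignore the control arrays and test the
#'   treatment log2 ratios against zero (for designs in which each array
#'   is already a sample/control comparison).
#' @return `data.frame` with columns `gene_id`, `condition`,
#'   `mean_log2fc`, `fold_change` (`2^mean_log2fc`), `p_value`, `n_treat`,
#'   `n_ctrl`.
#' @export
de_test <- function(mat, design, condition, control = "control",
                    var_equal = TRUE, one_sample = FALSE) {
  stopifnot(is.matrix(mat), is.data.frame(design),
            all(c("array_id", "condition") %in% names(design)))
  treat_ids <- intersect(design$array_id[design$condition == condition],
                         colnames(mat))
  if (length(treat_ids) < 2) stop("need at least two treatment arrays")
  x <- mat[, treat_ids, drop = FALSE]
  if (one_sample) {
    n1 <- rowSums(!is.na(x))
    m1 <- rowMeans(x, na.rm = TRUE)
    v1 <- rowSums((x - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
    se <- sqrt(v1 / n1)
    p <- 2 * stats::pt(-abs(m1 / se), n1 - 1)
    p[se == 0 & m1 == 0] <- 1
    p[se == 0 & m1 != 0] <- .Machine$double.xmin
    p <- pmax(pmin(p, 1), .Machine$double.xmin)
    p[n1 < 2] <- NA_real_
    m1[n1 < 2] <- NA_real_
    r <- list(mean_diff = m1, p_value = p, n1 = n1, n2 = rep(0L, nrow(x)))
  } else {
    ctrl_ids <- intersect(design$array_id[design$condition == control],
                          colnames(mat))
    if (length(ctrl_ids) < 2) stop("need at least two control arrays")
    r <- row_t_test(x, mat[, ctrl_ids, drop = FALSE], var_equal = var_equal)
  }
  n_skipped <- sum(is.na(r$p_value))
  if (n_skipped > 0) {
    message(sprintf("de_test(%s): %d gene(s) skipped (<2 replicates per group)",
                    condition, n_skipped))
  }
  data.frame(
    gene_id = rownames(mat),
    condition = condition,
    mean_log2fc = r$mean_diff,
    fold_change = 2^r$mean_diff,
    p_value = r$p_value,
    n_treat = r$n1,
    n_ctrl = r$n2,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Significantly upregulated genes at a cutoff
#'
#' Genes with `p_value < alpha` *and* positive mean log2 fold change; the
#' analysis is one of upregulation, so significant downregulation never
#' qualifies.
#'
#' @param results A [de_test()] result.
#' @param alpha P-value cutoff (strict inequality).
#' @return Character vector of gene ids.
#' @export
upregulated_set <- function(results, alpha) {
  stopifnot(is.data.frame(results), alpha > 0, alpha <= 1)
  ok <- !is.na(results$p_value) & results$p_value < alpha &
    results$mean_log2fc > 0
  results$gene_id[ok]
}

#' Mean linear fold change of the top-k upregulated genes
#'
#' Ranks genes with positive mean log2 fold change by ascending p-value
#' (ties broken by descending fold change, then gene id) and averages the
#' linear fold changes of the first `k`. If fewer than `k` genes are
#' eligible, all of them are used and a warning is issued.
#'
#' @param results A [de_test()] result.
#' @param k Number of genes to average (default 50).
#' @return Scalar mean linear fold change.
#' @export
top_k_mean_fc <- function(results, k = 50) {
  stopifnot(is.data.frame(results), is_count(k), k >= 1)
  elig <- results[!is.na(results$p_value) & results$mean_log2fc > 0, ,
                  drop = FALSE]
  if (nrow(elig) == 0) stop("no upregulated-tested genes to rank")
  if (nrow(elig) < k) {
    warning(sprintf("only %d eligible genes; using all of them", nrow(elig)))
    k <- nrow(elig)
  }
  ord <- order(elig$p_value, -elig$fold_change, elig$gene_id)
  mean(elig$fold_change[ord][seq_len(k)])
}
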