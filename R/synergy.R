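#' Synergy ratio of a costimulation response
#'
#' The ratio of the costimulation fold change to the sum of the two
#' single-ligand fold changes, `fc_combo / (fc_a + fc_b)`. Fold changes
#' are linear ("fold over nonstimulated control"), never log-scale. A
#' ratio of 1 means the combination induced exactly the sum of the single
#' responses; genes at or above 1.5 are classified as synergistically
#' (supra-additively) regulated.
#'
#' @param fc_a,fc_b Linear fold changes under each single ligand.
#' @param fc_combo Linear fold change under costimulation.
#' @return Numeric vector of synergy ratios. Reported values are
#'   conventionally rounded half-up to one decimal ([round_half_up()]).
#' @examples
#' synergy_ratio(2.4, 6.1, 64.2)            # 7.553
#' round_half_up(synergy_ratio(2.4, 6.1, 64.2))  # 7.6
#' @export
synergy_ratio <- function(fc_a, fc_b, fc_combo) {
  v <- c(fc_a, fc_b, fc_combo)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("fold changes must be finite and strictly positive")
  }
  fc_combo / (fc_a + fc_b)
}

#' Classify genes as synergistically regulated
#'
#' Computes the synergy ratio for each record and applies the inclusive
#' 1.5 threshold: `is_synergistic` is true when the ratio is at least
#' `threshold` (a gene whose combination response reaches 1.5-fold the sum
#' of the single-ligand responses counts as synergistic).
#'
#' @param records `data.frame` with columns `fc_a`, `fc_b`, `fc_combo`
#'   and optionally a gene identifier column (`gene_id` or
#'   `gene_symbol`).
#' @param threshold Synergy-ratio threshold (default 1.5, boundary
#'   inclusive).
#' @return The input plus columns `ratio` (exact), `ratio_rounded`
#'   (half-up to one decimal) and `is_synergistic`.
#' @export
classify_synergy <- function(records, threshold = 1.5) {
  stopifnot(is.data.frame(records),
            all(c("fc_a", "fc_b", "fc_combo") %in% names(records)),
            is.numeric(threshold), threshold > 0)
  ratio <- synergy_ratio(records$fc_a, records$fc_b, records$fc_combo)
  records$ratio <- ratio
  records$ratio_rounded <- round_half_up(ratio, 1)
  # tolerance guards exact-boundary ratios (e.g. 4.2 / 2.8) against
  # floating-point representation error
  records$is_synergistic <- ratio >= threshold - 1e-9
  records
}

#' Reference fold-change table of synergistically upregulated genes
#'
#' The published fold changes of the 62 genes synergistically upregulated
#' in CAL-1 plasmacytoid dendritic cells by combined stimulation with the
#' TLR7 ligands 9.2s RNA and CL264: per gene, the linear fold change over
#' unstimulated control under 9.2s RNA alone (`fc_a`), CL264 alone
#' (`fc_b`), the combination (`fc_combo`), and the reported synergy ratio
#' (`reported_ratio`, one decimal).
#'
#' @return `data.frame` with columns `gene_symbol`, `unigene_id`, `fc_a`,
#'   `fc_b`, `fc_combo`, `reported_ratio` (62 rows).
#' @export
cal1_synergy_table <- function() {
  path <- system.file("extdata", "cal1_tlr7_costim_synergy.tsv",
                      package = "costimr", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric",
                                   "numeric", "numeric", "numeric"))
}

#' Validate recomputed synergy ratios against reported values
#'
#' Recomputes the synergy ratio from the fold-change columns of a
#' reference table, rounds half-up to one decimal, and compares with the
#' reported ratio per gene. Small discrepancies (typically 0.1) arise when
#' the reported ratio was computed from unrounded fold changes while the
#' table prints rounded ones; the tolerance absorbs these.
#'
#' @param table Reference table with columns `gene_symbol`, `fc_a`,
#'   `fc_b`, `fc_combo`, `reported_ratio`; defaults to
#'   [cal1_synergy_table()].
#' @param records Optional externally recomputed records (a
#'   [classify_synergy()] result keyed by `gene_symbol`); if supplied,
#'   their rounded ratios are validated instead of ratios recomputed from
#'   `table` itself. Missing keys are an error.
#' @param tolerance Maximum allowed absolute difference between the
#'   recomputed rounded ratio and the reported one (default 0.1).
#' @return `data.frame` of class `synergy_validation` with per-gene
#'   `recomputed`, `reported`, `delta`, `pass`; attributes `n_fail` and
#'   `tolerance`.
#' @export
validate_synergy_table <- function(table = cal1_synergy_table(),
                                   records = NULL, tolerance = 0.1) {
  stopifnot(is.data.frame(table),
            all(c("gene_symbol", "fc_a", "fc_b", "fc_combo",
                  "reported_ratio") %in% names(table)))
  if (is.null(records)) {
    records <- classify_synergy(table)
    records$gene_id <- records$gene_symbol
  } else {
    key <- if ("gene_symbol" %in% names(records)) "gene_symbol" else "gene_id"
    missing <- setdiff(table$gene_symbol, records[[key]])
    if (length(missing) > 0) {
      stop("records are missing genes: ", paste(missing, collapse = ", "))
    }
    records <- records[match(table$gene_symbol, records[[key]]), , drop = FALSE]
  }
  out <- data.frame(
    gene_symbol = table$gene_symbol,
    recomputed = records$ratio_rounded,
    reported = table$reported_ratio,
    stringsAsFactors = FALSE
  )
  out$delta <- abs(out$recomputed - out$reported)
  out$pass <- out$delta <= tolerance + 1e-9
  attr(out, "n_fail") <- sum(!out$pass)
  attr(out, "tolerance") <- tolerance
  class(out) <- c("synergy_validation", class(out))
  out
}

#' @export
print.synergy_validation <- function(x, ...) {
  cat(sprintf("synergy validation: %d/%d genes within +/-%g of reported ratio\n",
              sum(x$pass), nrow(x), attr(x, "tolerance")))
  if (any(!x$pass)) {
    cat("failures:\n")
    print.data.frame(x[!x$pass, , drop = FALSE])
  }
  invisible(x)
}
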