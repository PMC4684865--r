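#' Venn accounting of mono- versus costimulation gene sets
#'
#' Set algebra over the strict-cutoff upregulated sets of the two single
#' ligands and their combination: how many combination genes overlap the
#' union of the single-ligand sets, and how many are unique to
#' costimulation.
#'
#' @param set_a,set_b,set_combo Character vectors of upregulated gene ids
#'   (ligand A, ligand B, combination).
#' @return List with `n_a`, `n_b`, `n_combo`, `n_mono_union` (size of A
#'   union B), `n_overlap` (combo genes also mono-upregulated),
#'   `n_unique_combo`, and the gene vectors `overlap` and `unique_combo`.
#'   `n_overlap + n_unique_combo == n_combo` holds by construction.
#' @examples
#' venn_counts(c("a"), c("a", "b"), c("a", "b", "c"))
#' @export
venn_counts <- function(set_a, set_b, set_combo) {
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  set_combo <- unique(as.character(set_combo))
  mono <- union(set_a, set_b)
  overlap <- intersect(set_combo, mono)
  uniq <- setdiff(set_combo, mono)
  list(
    n_a = length(set_a),
    n_b = length(set_b),
    n_combo = length(set_combo),
    n_mono_union = length(mono),
    n_overlap = length(overlap),
    n_unique_combo = length(uniq),
    overlap = overlap,
    unique_combo = uniq
  )
}

#' Recruit combination-unique genes at a relaxed cutoff
#'
#' Counts how many genes upregulated only by costimulation at the strict
#' cutoff become significant under either single ligand once the cutoff is
#' relaxed ("recruited" to the monostimulatory groups). Genes absent from
#' a result table are counted as not recruited and logged.
#'
#' @param unique_combo Gene ids significant only under costimulation at
#'   the strict cutoff.
#' @param results_a,results_b [de_test()] results for the two single
#'   ligands.
#' @param relaxed_alpha Relaxed p-value cutoff (default 0.01).
#' @return List with `n_recruited` and the gene vector `recruited`.
#' @export
recruit <- function(unique_combo, results_a, results_b, relaxed_alpha = 0.01) {
  unique_combo <- unique(as.character(unique_combo))
  covered <- union(results_a$gene_id, results_b$gene_id)
  missing <- setdiff(unique_combo, covered)
  if (length(missing) > 0) {
    message(sprintf("recruit: %d gene(s) missing from DE results, counted as not recruited",
                    length(missing)))
  }
  relaxed <- union(upregulated_set(results_a, relaxed_alpha),
                   upregulated_set(results_b, relaxed_alpha))
  recruited <- intersect(unique_combo, relaxed)
  list(n_recruited = length(recruited), recruited = recruited)
}

#' Full Venn/recruitment report
#'
#' Combines [venn_counts()] at the strict cutoff with [recruit()] at the
#' relaxed cutoff into the complete accounting: how much of the
#' costimulation response is attributable to the single ligands. Because
#' the upregulated sets are nested in the cutoff, a recruited gene can
#' never already lie in a strict mono set; the report asserts this.
#'
#' @param results_a,results_b,results_combo [de_test()] results for
#'   ligand A, ligand B and the combination.
#' @param cuts A [cutoffs()] object.
#' @return List of class `venn_report`: the [venn_counts()] fields plus
#'   `n_recruited`, `n_mono_attributable` (`n_overlap + n_recruited`),
#'   `fraction_attributable` (of `n_combo`), and two readings of the
#'   mono-overlap fraction whose denominator is ambiguous in practice:
#'   `overlap_frac_union` (`n_overlap / |A u B|`) and `overlap_frac_sum`
#'   (`n_overlap / (n_a + n_b)`).
#' @export
recruitment_report <- function(results_a, results_b, results_combo,
                               cuts = cutoffs()) {
  stopifnot(inherits(cuts, "cutoffs"))
  A <- upregulated_set(results_a, cuts$strict_alpha)
  B <- upregulated_set(results_b, cuts$strict_alpha)
  C <- upregulated_set(results_combo, cuts$strict_alpha)
  vc <- venn_counts(A, B, C)
  rec <- recruit(vc$unique_combo, results_a, results_b, cuts$relaxed_alpha)
  # nested cutoffs guarantee no double counting
  stopifnot(length(intersect(rec$recruited, union(A, B))) == 0)
  n_attr <- vc$n_overlap + rec$n_recruited
  rep <- c(vc[c("n_a", "n_b", "n_combo", "n_mono_union", "n_overlap",
                "n_unique_combo")],
           list(
             n_recruited = rec$n_recruited,
             n_mono_attributable = n_attr,
             fraction_attributable = if (vc$n_combo > 0) n_attr / vc$n_combo else NA_real_,
             overlap_frac_union = if (vc$n_mono_union > 0) vc$n_overlap / vc$n_mono_union else NA_real_,
             overlap_frac_sum = if (vc$n_a + vc$n_b > 0) vc$n_overlap / (vc$n_a + vc$n_b) else NA_real_,
             strict_alpha = cuts$strict_alpha,
             relaxed_alpha = cuts$relaxed_alpha,
             genes = list(set_a = A, set_b = B, set_combo = C,
                          recruited = rec$recruited)
           ))
  class(rep) <- "venn_report"
  rep
}

#' @export
print.venn_report <- function(x, ...) {
  cat("Venn/recruitment report (strict p <", x$strict_alpha,
      ", relaxed p <", x$relaxed_alpha, ")\n")
  cat(sprintf("  upregulated: ligand A %d, ligand B %d, combination %d\n",
              x$n_a, x$n_b, x$n_combo))
  cat(sprintf("  combo genes also mono-upregulated (strict): %d\n", x$n_overlap))
  cat(sprintf("  combo-unique genes: %d, of which recruited at relaxed cutoff: %d\n",
              x$n_unique_combo, x$n_recruited))
  cat(sprintf("  attributable to monostimulation: %d (%d%% of %d)\n",
              x$n_mono_attributable,
              round(100 * x$fraction_attributable), x$n_combo))
  invisible(x)
}
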