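#' Background-correct a spot table
#'
#' Subtracts a background estimate from each channel and floors the result
#' at a small positive value so that downstream log ratios stay defined.
#' Backgrounds may be scalars (a global per-array constant) or per-spot
#' vectors when the scanner exports local backgrounds.
#'
#' @param spots Spot table: `data.frame` with columns `gene_id`,
#'   `ch_reference`, `ch_sample`, `flag`.
#' @param bg_reference,bg_sample Background estimate(s) for the reference
#'   and sample channel; non-negative scalar or vector of `nrow(spots)`.
#' @param floor Minimum retained intensity after subtraction (default 1).
#' @return The spot table with corrected channels.
#' @examples
#' tab <- data.frame(gene_id = "g1", ch_reference = 500, ch_sample = 300,
#'                   flag = FALSE)
#' background_correct(tab, 100, 100)
#' @export
background_correct <- function(spots, bg_reference = 0, bg_sample = 0,
                               floor = 1) {
  check_spot_table(spots)
  if (any(bg_reference < 0) || any(bg_sample < 0)) {
    stop("background estimates must be non-negative")
  }
  stopifnot(floor > 0)
  spots$ch_reference <- pmax(spots$ch_reference - bg_reference, floor)
  spots$ch_sample <- pmax(spots$ch_sample - bg_sample, floor)
  spots
}

#' Estimate a global per-channel background constant
#'
#' The median of the spots in the lowest `quantile` of that channel's
#' intensities; a simple global background for scanners that do not export
#' local backgrounds.
#'
#' @param x Channel intensities.
#' @param quantile Fraction of lowest-intensity spots used (default 0.05).
#' @return A scalar background estimate.
#' @export
estimate_background <- function(x, quantile = 0.05) {
  stopifnot(is.numeric(x), length(x) > 0, is_prop(quantile), quantile > 0)
  cut <- stats::quantile(x, quantile, names = FALSE)
  stats::median(x[x <= cut])
}

#' Remove flagged and low-intensity spots
#'
#' Drops every flagged spot, and every spot in which *both* channels are
#' below `low_threshold`. A spot with exactly one dim channel is retained:
#' strong single-channel signals are informative (they carry the extreme
#' ratios).
#'
#' @param spots Spot table (normally background-corrected).
#' @param low_threshold Intensity below which a channel counts as dim
#'   (default 100).
#' @return The filtered spot table.
#' @export
filter_spots <- function(spots, low_threshold = 100) {
  check_spot_table(spots)
  keep <- !spots$flag &
    !(spots$ch_reference < low_threshold & spots$ch_sample < low_threshold)
  spots[keep, , drop = FALSE]
}

#' Per-spot log2 ratio and mean log2 intensity
#'
#' Computes M = log2(sample/reference) and A = mean log2 intensity for each
#' retained spot, the (M, A) coordinates used by intensity-dependent
#' normalization.
#'
#' @param spots Filtered spot table with strictly positive channels.
#' @return `data.frame` with columns `gene_id`, `M`, `A`.
#' @export
log_ratios <- function(spots) {
  check_spot_table(spots)
  if (any(spots$ch_reference <= 0) || any(spots$ch_sample <= 0)) {
    stop("log ratios require strictly positive channel intensities")
  }
  data.frame(
    gene_id = spots$gene_id,
    M = log2(spots$ch_sample / spots$ch_reference),
    A = 0.5 * log2(spots$ch_sample * spots$ch_reference),
    stringsAsFactors = FALSE
  )
}

#' Lowess intensity-dependent normalization of one array
#'
#' Fits a locally weighted regression of M on A ([stats::lowess()]) and
#' subtracts the fitted trend from each spot's M value, removing smooth
#' intensity-dependent dye bias. The smoother absorbs any constant offset,
#' so a globally shifted array is centred as a side effect.
#'
#' The fit is robustified by trimmed refitting: after each pass, spots
#' whose residual exceeds 6 times the residual MAD are dropped and the
#' trend is refit on the rest. This keeps genuinely regulated genes (large
#' |M|) from dragging the trend toward themselves and attenuating their
#' own fold changes. The MAD is floored at `scale_floor` so that on
#' arrays with very little replicate noise the smoother's own small
#' misfit is never mistaken for outliers (which would discard the
#' extreme-intensity spots and extrapolate the trend past them).
#'
#' @param ma `data.frame` with columns `gene_id`, `M`, `A` (from
#'   [log_ratios()]).
#' @param span Lowess smoother span (fraction of spots in each local fit,
#'   default 0.2; small enough that the local fit tracks the bias curve
#'   out to the sparse intensity extremes).
#' @param iterations Trimmed-refit robustness iterations (default 2; 0
#'   gives a single plain local regression).
#' @param scale_floor Lower bound on the residual scale used for
#'   trimming, in log2-ratio units (default 0.01).
#' @param min_spots Minimum number of spots required for a stable fit
#'   (default 50); fewer is an error.
#' @return The input with `M` replaced by the normalized values.
#' @export
normalize_intensity <- function(ma, span = 0.2, iterations = 2,
                                scale_floor = 0.01, min_spots = 50) {
  stopifnot(is.data.frame(ma), all(c("gene_id", "M", "A") %in% names(ma)))
  if (nrow(ma) < min_spots) {
    stop(sprintf("array has %d spots; at least %d required for normalization",
                 nrow(ma), min_spots))
  }
  trend_at <- function(x, y, xout) {
    fit <- stats::lowess(x, y, f = span, iter = 0)
    stats::approx(fit$x, fit$y, xout = xout, rule = 2, ties = mean)$y
  }
  trend <- trend_at(ma$A, ma$M, ma$A)
  for (i in seq_len(iterations)) {
    res <- ma$M - trend
    s <- max(stats::mad(res), scale_floor)
    keep <- abs(res) <= 6 * s
    if (all(keep) || sum(keep) < min_spots) break
    trend <- trend_at(ma$A[keep], ma$M[keep], ma$A)
  }
  ma$M <- ma$M - trend
  ma
}

#' Presence filter across arrays
#'
#' Retains genes observed (non-missing) on strictly more than
#' `min_fraction` of the arrays.
#'
#' @param mat Genes x arrays matrix of normalized log2 ratios with `NA`
#'   for spots lost to filtering.
#' @param min_fraction Presence threshold; the inequality is strict, so at
#'   `0.5` a gene present on exactly half of the arrays is dropped.
#' @return The row-subset matrix; provenance attribute is extended.
#' @export
presence_filter <- function(mat, min_fraction = 0.5) {
  stopifnot(is.matrix(mat), is_prop(min_fraction))
  frac <- rowMeans(!is.na(mat))
  out <- mat[frac > min_fraction, , drop = FALSE]
  attr(out, "provenance") <- c(attr(mat, "provenance"),
                               sprintf("presence_filter(>%g)", min_fraction))
  out
}

#' Full preprocessing of a set of two-channel arrays
#'
#' Runs the fixed per-array chain background correction -> flag /
#' low-intensity filtering -> log2 ratios -> lowess intensity-dependent
#' normalization, then assembles the genes x arrays log2-ratio matrix and
#' applies the cross-array presence filter. The applied steps are recorded
#' in the matrix's `provenance` attribute.
#'
#' @param spot_tables Named list of spot tables (one per array), as
#'   produced by [simulate_arrays()] or [read_spot_table()].
#' @param background Either `"none"` (default: intensities are already
#'   background-free), `"auto"` (per-array global constant from
#'   [estimate_background()]), or a list with numeric `reference` and
#'   `sample` entries applied to every array.
#' @param bg_quantile Low-intensity quantile for `background = "auto"`.
#' @param floor Post-subtraction intensity floor.
#' @param low_threshold Both-channels-dim filter threshold.
#' @param span,iterations Lowess span and robustness iterations.
#' @param min_spots Minimum spots per array for normalization.
#' @param min_fraction Presence-filter threshold.
#' @return Genes x arrays numeric matrix of normalized log2 ratios with
#'   `NA` for filtered spots; attributes `provenance` (character vector of
#'   steps) and `arrays` (array ids).
#' @export
preprocess_arrays <- function(spot_tables,
                              background = "none",
                              bg_quantile = 0.05,
                              floor = 1,
                              low_threshold = 100,
                              span = 0.2,
                              iterations = 2,
                              min_spots = 50,
                              min_fraction = 0.5) {
  stopifnot(is.list(spot_tables), length(spot_tables) > 0,
            !is.null(names(spot_tables)))
  per_array <- lapply(spot_tables, function(tab) {
    if (identical(background, "auto")) {
      tab <- background_correct(
        tab,
        bg_reference = estimate_background(tab$ch_reference, bg_quantile),
        bg_sample = estimate_background(tab$ch_sample, bg_quantile),
        floor = floor
      )
    } else if (is.list(background)) {
      tab <- background_correct(tab, background$reference, background$sample,
                                floor = floor)
    }
    ma <- log_ratios(filter_spots(tab, low_threshold))
    normalize_intensity(ma, span = span, iterations = iterations,
                        min_spots = min_spots)
  })
  genes <- sort(unique(unlist(lapply(per_array, `[[`, "gene_id"))))
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(per_array),
                dimnames = list(genes, names(per_array)))
  for (a in names(per_array)) {
    ma <- per_array[[a]]
    mat[ma$gene_id, a] <- ma$M
  }
  bg_step <- if (identical(background, "none")) {
    "background_correct(none)"
  } else if (identical(background, "auto")) {
    sprintf("background_correct(auto,q=%g)", bg_quantile)
  } else {
    "background_correct(constant)"
  }
  attr(mat, "provenance") <- c(
    bg_step,
    sprintf("filter_spots(flagged, both<%g)", low_threshold),
    "log2_ratio",
    sprintf("lowess_normalize(span=%g)", span)
  )
  attr(mat, "arrays") <- names(per_array)
  presence_filter(mat, min_fraction)
}

check_spot_table <- function(spots) {
  if (!is.data.frame(spots) ||
      !all(c("gene_id", "ch_reference", "ch_sample", "flag") %in% names(spots))) {
    stop("a spot table needs columns gene_id, ch_reference, ch_sample, flag")
  }
  if (anyDuplicated(spots$gene_id)) {
    stop("gene_id must be unique within an array")
  }
  invisible(spots)
}
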