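#' Configuration for a simulated two-color costimulation experiment
#'
#' Bundles every tunable of the synthetic-data generator. The defaults
#' emulate a dual TLR7-ligand costimulation experiment on a pDC line read
#' out on two-channel arrays: a weak ligand A regulating few genes, a
#' stronger ligand B, and a class of supra-additively induced genes that
#' respond far beyond the sum of the two single-ligand effects. Conditions
#' are labelled `control`, `ligandA`, `ligandB` and `combo`, each measured
#' on `n_replicates` arrays hybridised against a common reference channel.
#'
#' @param n_genes Number of genes (one spot per gene per array).
#' @param frac_regulated_a,frac_regulated_b Proportion of genes regulated by
#'   ligand A alone resp. ligand B alone. Together with `frac_supra` these
#'   partition the genes into disjoint classes and must sum to at most 1.
#' @param frac_supra Proportion of genes whose costimulation response is
#'   supra-additive (fold change at least 1.5 times the sum of the two
#'   single-ligand fold changes).
#' @param effect_log2_mean,effect_log2_sd Mean and sd of the log2 effect
#'   size distribution for singly regulated genes.
#' @param supra_mono_a_log2_mean,supra_mono_a_log2_sd Log2 distribution of
#'   the *ligand A alone* response of supra-additive genes; kept very mild
#'   (the weak ligand barely moves these genes on its own).
#' @param supra_mono_b_log2_mean,supra_mono_b_log2_sd Log2 distribution of
#'   the *ligand B alone* response of supra-additive genes; mild enough
#'   that most of these genes are not called under monostimulation, which
#'   is what makes them unique to the costimulation gene set.
#' @param supra_factor_min,supra_factor_max Range of the supra-additivity
#'   factor `s`: for a supra-additive gene the combo fold change is
#'   `s * (fc_a + fc_b)` with `s` drawn uniformly on this interval.
#'   `supra_factor_min` must be >= 1.5 so the class invariant holds.
#' @param noise_sd Replicate standard deviation of log2 ratios.
#' @param baseline_log2_mean,baseline_log2_sd Log2-scale location and spread
#'   of the reference-channel spot intensities.
#' @param dye_bias_amplitude Amplitude (log2-ratio units) of the smooth
#'   intensity-dependent dye bias injected into every array; see
#'   [dye_bias()].
#' @param flag_rate Proportion of spots flagged bad by the scanner.
#' @param low_intensity_rate Proportion of spots forced below the 100-unit
#'   intensity threshold in both channels.
#' @param n_replicates Arrays per condition (>= 2).
#' @param additive_mode How non-supra-additive regulated genes respond to
#'   costimulation: `"linear"` gives `fc_combo = fc_a + fc_b - 1` (additive
#'   on the linear fold-change scale), `"log2"` gives `fc_combo =
#'   fc_a * fc_b` (additive on the log2 scale).
#' @param reference_channel Which dye carries the common reference
#'   (`"cy3"` by default, swap to `"cy5"` for dye-swapped designs). Stored
#'   as metadata on the simulated tables.
#' @param seed Integer seed; every random draw in the generator derives
#'   from it (see Details).
#'
#' @details Reproducibility follows a fixed substream discipline. Gene-level
#' truth uses `seed` directly, with draws in a documented order (class
#' uniforms first, then the effect-size vectors, then the supra factors).
#' Array `k` (1-based, conditions ordered control, ligandA, ligandB, combo,
#' replicates innermost) uses base seed `seed + 1000 * k`, with offsets
#' +1 reference intensities, +2 replicate noise, +3 low-intensity mask,
#' +4 low-intensity replacement values, +5 flags. This lets any component
#' be re-drawn independently.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_truth()], [simulate_arrays()], [simulate_network()]
#' @export
sim_config <- function(n_genes = 5000L,
                       frac_regulated_a = 0.005,
                       frac_regulated_b = 0.02,
                       frac_supra = 0.06,
                       effect_log2_mean = 2.4,
                       effect_log2_sd = 0.8,
                       supra_mono_a_log2_mean = 0.25,
                       supra_mono_a_log2_sd = 0.35,
                       supra_mono_b_log2_mean = 0.6,
                       supra_mono_b_log2_sd = 0.5,
                       supra_factor_min = 1.5,
                       supra_factor_max = 4,
                       noise_sd = 0.15,
                       baseline_log2_mean = 9,
                       baseline_log2_sd = 1.5,
                       dye_bias_amplitude = 0.3,
                       flag_rate = 0.02,
                       low_intensity_rate = 0.05,
                       n_replicates = 3L,
                       additive_mode = c("linear", "log2"),
                       reference_channel = c("cy3", "cy5"),
                       seed = 1L) {
  additive_mode <- match.arg(additive_mode)
  reference_channel <- match.arg(reference_channel)
  stopifnot(
    is_count(n_genes), n_genes >= 1,
    is_prop(frac_regulated_a), is_prop(frac_regulated_b), is_prop(frac_supra),
    is_prop(flag_rate), is_prop(low_intensity_rate),
    is.numeric(noise_sd), noise_sd >= 0,
    is.numeric(effect_log2_sd), effect_log2_sd >= 0,
    is_count(n_replicates), n_replicates >= 2,
    is.numeric(supra_factor_min), supra_factor_min >= 1.5,
    supra_factor_max >= supra_factor_min,
    is_count(abs(seed))
  )
  if (frac_regulated_a + frac_regulated_b + frac_supra > 1) {
    stop("frac_regulated_a + frac_regulated_b + frac_supra must not exceed 1")
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    frac_regulated_a = frac_regulated_a,
    frac_regulated_b = frac_regulated_b,
    frac_supra = frac_supra,
    effect_log2_mean = effect_log2_mean,
    effect_log2_sd = effect_log2_sd,
    supra_mono_a_log2_mean = supra_mono_a_log2_mean,
    supra_mono_a_log2_sd = supra_mono_a_log2_sd,
    supra_mono_b_log2_mean = supra_mono_b_log2_mean,
    supra_mono_b_log2_sd = supra_mono_b_log2_sd,
    supra_factor_min = supra_factor_min,
    supra_factor_max = supra_factor_max,
    noise_sd = noise_sd,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    dye_bias_amplitude = dye_bias_amplitude,
    flag_rate = flag_rate,
    low_intensity_rate = low_intensity_rate,
    n_replicates = as.integer(n_replicates),
    additive_mode = additive_mode,
    reference_channel = reference_channel,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Intensity-dependent dye bias curve
#'
#' The smooth bias injected into simulated log2 ratios as a function of
#' spot log2 intensity, mimicking the channel-specific labelling
#' efficiencies that lowess normalization is meant to remove. A saturating
#' monotone curve (scaled tanh) centred on the bulk of the intensity
#' distribution: dim spots are biased toward one dye, bright spots toward
#' the other, flattening out at the extremes. Smooth enough to be
#' recoverable by a local regression of M on A.
#'
#' @param a Log2 intensity values.
#' @param amplitude Peak bias in log2-ratio units.
#' @param scale,center Shape parameters (log2-intensity units).
#' @return Bias values, same length as `a`.
#' @export
dye_bias <- function(a, amplitude, scale = 2, center = 9) {
  amplitude * tanh((a - center) / scale)
}

#' Simulate gene-level ground truth
#'
#' Draws, for every gene, true linear fold changes under ligand A, ligand B
#' and costimulation, together with a class label: `null` (no response),
#' `additive` (regulated by one ligand; the combo response is the additive
#' combination of the single-ligand responses) or `supra_additive` (the
#' combo fold change is `s * (fc_a + fc_b)` with `s >= 1.5`).
#'
#' @param config A [sim_config()].
#' @return A `data.frame` of class `sim_truth` with columns `gene_id`,
#'   `synergy_class`, `fc_a`, `fc_b`, `fc_combo`; the generating config is
#'   attached as attribute `config`.
#' @examples
#' truth <- simulate_truth(sim_config(n_genes = 200, seed = 7))
#' table(truth$synergy_class)
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  set.seed(config$seed)
  ## draw order is part of the reproducibility contract: class uniforms,
  ## effect vectors (always full length), supra factors
  u <- stats::runif(n)
  f_s <- config$frac_supra
  f_a <- config$frac_regulated_a
  f_b <- config$frac_regulated_b
  supra <- u < f_s
  resp_a <- u >= f_s & u < f_s + f_a
  resp_b <- u >= f_s + f_a & u < f_s + f_a + f_b
  eff_a <- stats::rnorm(n, config$effect_log2_mean, config$effect_log2_sd)
  eff_b <- stats::rnorm(n, config$effect_log2_mean, config$effect_log2_sd)
  sup_a <- stats::rnorm(n, config$supra_mono_a_log2_mean, config$supra_mono_a_log2_sd)
  sup_b <- stats::rnorm(n, config$supra_mono_b_log2_mean, config$supra_mono_b_log2_sd)
  s_fac <- stats::runif(n, config$supra_factor_min, config$supra_factor_max)

  fc_a <- rep(1, n)
  fc_b <- rep(1, n)
  fc_a[resp_a] <- 2^eff_a[resp_a]
  fc_b[resp_b] <- 2^eff_b[resp_b]
  fc_a[supra] <- 2^sup_a[supra]
  fc_b[supra] <- 2^sup_b[supra]

  fc_combo <- rep(1, n)
  add <- resp_a | resp_b
  if (config$additive_mode == "linear") {
    # floored at a small positive value: two sub-unity responses can push
    # the linear-additive combination below zero
    fc_combo[add] <- pmax(fc_a[add] + fc_b[add] - 1, 2^-6)
  } else {
    fc_combo[add] <- fc_a[add] * fc_b[add]
  }
  fc_combo[supra] <- s_fac[supra] * (fc_a[supra] + fc_b[supra])

  cls <- rep("null", n)
  cls[add] <- "additive"
  cls[supra] <- "supra_additive"

  truth <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    synergy_class = cls,
    fc_a = fc_a,
    fc_b = fc_b,
    fc_combo = fc_combo,
    stringsAsFactors = FALSE
  )
  attr(truth, "config") <- config
  class(truth) <- c("sim_truth", class(truth))
  truth
}

sim_conditions <- c("control", "ligandA", "ligandB", "combo")

#' Simulate spot-level two-channel arrays
#'
#' Generates one spot table per array for the four conditions (control,
#' ligand A, ligand B, combo) times `n_replicates`. Each spot carries a
#' reference-channel intensity drawn from a log-normal baseline and a
#' sample-channel intensity equal to reference times the condition fold
#' change times log-normal replicate noise, with a smooth
#' intensity-dependent dye bias added on the log2-ratio scale. A fraction
#' of spots is flagged, and a fraction is forced below 100 units in both
#' channels (these fall to the low-intensity filter downstream).
#'
#' @param truth A [simulate_truth()] result.
#' @param config The same [sim_config()] the truth was generated from.
#' @return A list with `spot_tables` (named list of per-array
#'   `data.frame`s with columns `gene_id`, `ch_reference`, `ch_sample`,
#'   `flag`) and `design` (`data.frame` with `array_id`, `condition`,
#'   `replicate`).
#' @export
simulate_arrays <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  if (nrow(truth) != config$n_genes) {
    stop("truth and config disagree on the number of genes")
  }
  n <- config$n_genes
  fc_by_cond <- list(
    control = rep(1, n),
    ligandA = truth$fc_a,
    ligandB = truth$fc_b,
    combo = truth$fc_combo
  )
  short <- c(control = "ctrl", ligandA = "ligA", ligandB = "ligB", combo = "combo")

  spot_tables <- list()
  design <- data.frame(array_id = character(), condition = character(),
                       replicate = integer(), stringsAsFactors = FALSE)
  k <- 0L
  for (cond in sim_conditions) {
    for (r in seq_len(config$n_replicates)) {
      k <- k + 1L
      array_id <- sprintf("%s_r%d", short[[cond]], r)
      base <- config$seed + 1000L * k
      set.seed(base + 1L)
      ref <- 2^stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
      set.seed(base + 2L)
      noise <- stats::rnorm(n, 0, config$noise_sd)
      set.seed(base + 3L)
      low <- stats::runif(n) < config$low_intensity_rate
      set.seed(base + 4L)
      lowval <- stats::runif(n, 20, 99)
      set.seed(base + 5L)
      flag <- stats::runif(n) < config$flag_rate

      bias <- dye_bias(log2(ref), config$dye_bias_amplitude)
      smp <- ref * fc_by_cond[[cond]] * 2^(noise + bias)
      # forced low-intensity spots get the same sub-100 value in both
      # channels; they are removed by the <100-in-both filter anyway
      ref[low] <- lowval[low]
      smp[low] <- lowval[low]

      tab <- data.frame(
        gene_id = truth$gene_id,
        ch_reference = ref,
        ch_sample = smp,
        flag = flag,
        stringsAsFactors = FALSE
      )
      attr(tab, "array_id") <- array_id
      attr(tab, "reference_channel") <- config$reference_channel
      spot_tables[[array_id]] <- tab
      design <- rbind(design, data.frame(
        array_id = array_id, condition = cond, replicate = r,
        stringsAsFactors = FALSE
      ))
    }
  }
  list(spot_tables = spot_tables, design = design)
}

#' Simulate a regulator-to-target network with planted hub structure
#'
#' Builds a directed network over a gene universe in which `n_major`
#' designated nodes each regulate `ceiling(coverage_major * N)` distinct
#' targets, `n_minor` nodes each regulate `ceiling(coverage_minor * N)`,
#' and all remaining nodes receive sparse random out-edges covering fewer
#' than 10% of the universe. Self-edges are never drawn.
#'
#' @param gene_universe Character vector of gene identifiers.
#' @param n_major,n_minor Number of planted major / minor regulator nodes.
#' @param coverage_major Target coverage of each major node; must exceed
#'   0.30, the class boundary for a major regulator.
#' @param coverage_minor Target coverage of each minor node; in
#'   `[0.10, 0.30]`.
#' @param sparse_rate Per-pair edge probability for non-planted nodes.
#' @param seed Integer seed.
#' @return A `reg_network` (see [as_regnetwork()]) with attributes
#'   `major_nodes` and `minor_nodes` naming the planted regulators.
#' @export
simulate_network <- function(gene_universe, n_major = 4, n_minor = 6,
                             coverage_major = 0.5, coverage_minor = 0.15,
                             sparse_rate = 0.02, seed = 1L) {
  N <- length(gene_universe)
  stopifnot(is_count(n_major), is_count(n_minor),
            n_major + n_minor <= N)
  if (coverage_major > 1 || coverage_minor > 1) {
    stop("requested coverage exceeds 1")
  }
  if (n_major > 0 && coverage_major <= 0.30) {
    stop("coverage_major must exceed 0.30 (the major-regulator boundary)")
  }
  if (n_minor > 0 && (coverage_minor < 0.10 || coverage_minor > 0.30)) {
    stop("coverage_minor must lie in [0.10, 0.30]")
  }
  set.seed(as.integer(seed))
  regs <- sample(gene_universe, n_major + n_minor)
  majors <- regs[seq_len(n_major)]
  minors <- setdiff(regs, majors)
  others <- setdiff(gene_universe, regs)

  draw_targets <- function(node, n_targets) {
    pool <- setdiff(gene_universe, node)
    if (n_targets > length(pool)) {
      stop("requested coverage implies more targets than available genes")
    }
    sample(pool, n_targets)
  }
  edges <- list()
  for (node in majors) {
    edges[[node]] <- draw_targets(node, ceiling(coverage_major * N))
  }
  for (node in minors) {
    edges[[node]] <- draw_targets(node, ceiling(coverage_minor * N))
  }
  cap <- max(ceiling(0.1 * (N - 1)) - 1L, 0L)
  for (node in others) {
    d <- min(stats::rbinom(1, N - 1L, sparse_rate), cap)
    if (d > 0) edges[[node]] <- draw_targets(node, d)
  }
  edge_df <- if (length(edges)) {
    data.frame(
      regulator = rep(names(edges), lengths(edges)),
      target = unlist(edges, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(regulator = character(), target = character(),
               stringsAsFactors = FALSE)
  }
  net <- as_regnetwork(edge_df, gene_universe)
  attr(net, "major_nodes") <- majors
  attr(net, "minor_nodes") <- minors
  net
}
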