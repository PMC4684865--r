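#' Configuration of a full pipeline run
#'
#' Collects everything a run needs: either a simulation config (the
#' default) or paths to external inputs, the significance cutoffs, the
#' synergy threshold and the network-coverage mode. A config plus its seed
#' fully determines every output.
#'
#' @param sim A [sim_config()]; used when `simulate = TRUE`.
#' @param simulate Simulate the input arrays (default) or read them from
#'   `input` paths.
#' @param input List of input paths for `simulate = FALSE`: either
#'   `spot_tables` (named character vector of per-array files) plus
#'   `design`, or `synergy_table` (a fold-change table validated directly
#'   by the synergy stage). Optional `edges` + `universe` supply a user
#'   network.
#' @param cuts A [cutoffs()] object.
#' @param synergy_threshold Synergy-ratio threshold (default 1.5).
#' @param synergy_scope `"combo_strict"` (default: classify only genes in
#'   the strict-cutoff costimulation set, the set the synergy criterion is
#'   defined on) or `"all"` (every tested gene).
#' @param netreg_mode Coverage mode for node classification.
#' @param network Parameters for the simulated regulator network planted
#'   on the costimulation gene set, or `NULL` to skip the network stage.
#' @param out_dir Directory for tabular outputs and the JSON run report,
#'   or `NULL` to skip writing.
#' @param seed Global seed; defaults to the simulation seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       simulate = TRUE,
                       input = NULL,
                       cuts = cutoffs(),
                       synergy_threshold = 1.5,
                       synergy_scope = c("combo_strict", "all"),
                       netreg_mode = c("direct", "reachable"),
                       network = list(n_major = 4, n_minor = 6,
                                      coverage_major = 0.5,
                                      coverage_minor = 0.15,
                                      sparse_rate = 0.02),
                       out_dir = NULL,
                       seed = NULL) {
  synergy_scope <- match.arg(synergy_scope)
  netreg_mode <- match.arg(netreg_mode)
  stopifnot(inherits(cuts, "cutoffs"), synergy_threshold > 0)
  if (simulate) stopifnot(inherits(sim, "sim_config"))
  if (!simulate && is.null(input)) {
    stop("simulate = FALSE requires input paths")
  }
  cfg <- list(sim = if (simulate) sim else NULL,
              simulate = simulate,
              input = input,
              cuts = cuts,
              synergy_threshold = synergy_threshold,
              synergy_scope = synergy_scope,
              netreg_mode = netreg_mode,
              network = network,
              out_dir = out_dir,
              seed = as.integer(if (is.null(seed)) {
                if (simulate) sim$seed else 1L
              } else seed))
  class(cfg) <- "run_config"
  cfg
}

config_fingerprint <- function(config) {
  flat <- config
  flat$out_dir <- NULL  # output location must not change the science
  string_fingerprint(jsonlite::toJSON(unclass_deep(flat), auto_unbox = TRUE,
                                      digits = 10))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Run the full costimulation-synergy pipeline
#'
#' Orchestrates simulate (or read) -> preprocess -> differential
#' expression -> Venn/recruitment -> synergy classification -> network
#' node classification, and assembles a machine-readable run report.
#' Given the same config (including seed) the report is byte-identical
#' across runs.
#'
#' If the config supplies only a fold-change table
#' (`input$synergy_table`), the expression stages are skipped and the
#' synergy stage validates that table directly.
#'
#' @param config A [run_config()].
#' @return List of class `costim_run` with elements `report` (plain-list
#'   summary, serialisable with [report_json()]) and `stages`
#'   (intermediate objects: truth, expression matrix, DE tables, Venn
#'   report, synergy records, node classes).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stages <- list()
  report <- list(
    tool = "costimr",
    version = as.character(utils::packageVersion("costimr")),
    config_fingerprint = config_fingerprint(config),
    seed = config$seed
  )

  ## ---- synergy-table-only mode -------------------------------------
  if (!config$simulate && !is.null(config$input$synergy_table)) {
    tab <- if (identical(config$input$synergy_table, "packaged")) {
      cal1_synergy_table()
    } else {
      utils::read.delim(config$input$synergy_table, stringsAsFactors = FALSE)
    }
    cls <- classify_synergy(tab, threshold = config$synergy_threshold)
    val <- validate_synergy_table(table = tab)
    stages$synergy <- cls
    stages$validation <- val
    report$synergy <- list(
      n_genes = nrow(cls),
      n_synergistic = sum(cls$is_synergistic),
      threshold = config$synergy_threshold,
      validation_n_pass = sum(val$pass),
      validation_n_fail = attr(val, "n_fail"),
      validation_tolerance = attr(val, "tolerance")
    )
    out <- structure(list(report = report, stages = stages),
                     class = "costim_run")
    write_run_outputs(out, config)
    return(out)
  }

  ## ---- expression inputs -------------------------------------------
  if (config$simulate) {
    truth <- simulate_truth(config$sim)
    arrs <- simulate_arrays(truth, config$sim)
    stages$truth <- truth
    spot_tables <- arrs$spot_tables
    design <- arrs$design
  } else {
    spot_tables <- lapply(config$input$spot_tables, read_spot_table)
    names(spot_tables) <- names(config$input$spot_tables)
    design <- read_design(config$input$design)
  }
  report$n_arrays <- length(spot_tables)

  mat <- preprocess_arrays(spot_tables)
  stages$expr <- mat
  report$preprocess <- list(
    n_genes_retained = nrow(mat),
    provenance = attr(mat, "provenance")
  )

  ## ---- differential expression -------------------------------------
  res <- list(
    ligandA = de_test(mat, design, "ligandA"),
    ligandB = de_test(mat, design, "ligandB"),
    combo = de_test(mat, design, "combo")
  )
  stages$de <- res
  report$top_k_mean_fc <- lapply(res, top_k_mean_fc, k = config$cuts$top_k)

  ## ---- Venn / recruitment ------------------------------------------
  vr <- recruitment_report(res$ligandA, res$ligandB, res$combo, config$cuts)
  stages$venn <- vr
  report$venn <- vr[c("n_a", "n_b", "n_combo", "n_mono_union", "n_overlap",
                      "n_unique_combo", "n_recruited", "n_mono_attributable",
                      "fraction_attributable")]

  ## ---- synergy ------------------------------------------------------
  fc <- data.frame(gene_id = res$ligandA$gene_id,
                   fc_a = res$ligandA$fold_change,
                   fc_b = res$ligandB$fold_change,
                   fc_combo = res$combo$fold_change,
                   stringsAsFactors = FALSE)
  if (config$synergy_scope == "combo_strict") {
    fc <- fc[fc$gene_id %in% vr$genes$set_combo, , drop = FALSE]
  }
  dropped <- !stats::complete.cases(fc)
  if (any(dropped)) {
    message(sprintf("synergy: %d gene(s) without complete fold changes dropped",
                    sum(dropped)))
    fc <- fc[!dropped, , drop = FALSE]
  }
  syn <- classify_synergy(fc, threshold = config$synergy_threshold)
  stages$synergy <- syn
  report$synergy <- list(
    scope = config$synergy_scope,
    threshold = config$synergy_threshold,
    n_eligible = nrow(syn),
    n_synergistic = sum(syn$is_synergistic)
  )

  ## ---- regulatory network -------------------------------------------
  universe <- vr$genes$set_combo
  if (!is.null(config$input$edges) && !is.null(config$input$universe)) {
    uni <- utils::read.delim(config$input$universe, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
    net <- as_regnetwork(read_edge_list(config$input$edges), uni)
  } else if (!is.null(config$network) && config$simulate &&
             length(universe) >= 20) {
    np <- config$network
    net <- simulate_network(universe,
                            n_major = np$n_major, n_minor = np$n_minor,
                            coverage_major = np$coverage_major,
                            coverage_minor = np$coverage_minor,
                            sparse_rate = np$sparse_rate,
                            seed = config$seed + 999L)
  } else {
    net <- NULL
  }
  if (!is.null(net)) {
    nodes <- classify_nodes(net, mode = config$netreg_mode)
    majors <- nodes$node[nodes$klass == "major"]
    stages$network <- net
    stages$nodes <- nodes
    report$netreg <- list(
      mode = config$netreg_mode,
      n_nodes = nrow(nodes),
      n_major = sum(nodes$klass == "major"),
      n_minor = sum(nodes$klass == "minor"),
      major_set_coverage = set_coverage(net, majors, mode = config$netreg_mode)
    )
  }

  out <- structure(list(report = report, stages = stages),
                   class = "costim_run")
  write_run_outputs(out, config)
  out
}

#' Serialise a run report to canonical JSON
#'
#' @param run A `costim_run` (or its `report` element).
#' @return A JSON string; stable across runs of the same config and seed.
#' @export
report_json <- function(run) {
  rep <- if (inherits(run, "costim_run")) run$report else run
  as.character(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = 10,
                                pretty = TRUE))
}

write_run_outputs <- function(run, config) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  st <- run$stages
  if (!is.null(st$expr)) write_expr_matrix(st$expr,
                                           file.path(config$out_dir, "expr_matrix.tsv"))
  if (!is.null(st$de)) {
    for (cond in names(st$de)) w(st$de[[cond]], sprintf("de_%s.tsv", cond))
  }
  if (!is.null(st$synergy)) w(st$synergy, "synergy_records.tsv")
  if (!is.null(st$nodes)) w(st$nodes, "node_classes.tsv")
  writeLines(report_json(run), file.path(config$out_dir, "run_report.json"))
  invisible(NULL)
}

#' @export
print.costim_run <- function(x, ...) {
  r <- x$report
  cat("costimr run", r$config_fingerprint, "\n")
  if (!is.null(r$venn)) {
    cat(sprintf("  upregulated (strict): A %d, B %d, combo %d; attributable %d (%.0f%%)\n",
                r$venn$n_a, r$venn$n_b, r$venn$n_combo,
                r$venn$n_mono_attributable,
                100 * r$venn$fraction_attributable))
  }
  if (!is.null(r$synergy)) {
    n_elig <- if (is.null(r$synergy$n_eligible)) r$synergy$n_genes else r$synergy$n_eligible
    cat(sprintf("  synergistic genes: %d of %d eligible (threshold %.2g)\n",
                r$synergy$n_synergistic, n_elig, r$synergy$threshold))
  }
  if (!is.null(r$netreg)) {
    cat(sprintf("  network: %d major, %d minor regulators; majors cover %.0f%%\n",
                r$netreg$n_major, r$netreg$n_minor,
                100 * r$netreg$major_set_coverage))
  }
  invisible(x)
}
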