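#' Read and write the package's tab-delimited formats
#'
#' Spot tables are tab-delimited with columns `gene_id`, `ch_reference`,
#' `ch_sample`, `flag` (0/1 or logical); design tables have `array_id`,
#' `condition`, `replicate`; edge lists have `regulator`, `target`;
#' expression matrices are written with a `gene_id` first column and one
#' column per array.
#'
#' @param path File path.
#' @param reference_channel Which dye the `ch_reference` column carries
#'   (`"cy3"` default); `"cy5"` swaps the two channel columns on read, for
#'   dye-swapped hybridizations.
#' @return `read_spot_table()`: a spot table `data.frame`.
#' @name costimr-io
NULL

#' @rdname costimr-io
#' @export
read_spot_table <- function(path, reference_channel = c("cy3", "cy5")) {
  reference_channel <- match.arg(reference_channel)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (reference_channel == "cy5") {
    tab[c("ch_reference", "ch_sample")] <- tab[c("ch_sample", "ch_reference")]
  }
  tab$flag <- as.logical(tab$flag)
  check_spot_table(tab)
  tab
}

#' @rdname costimr-io
#' @param spots Spot table to write.
#' @export
write_spot_table <- function(spots, path) {
  check_spot_table(spots)
  spots$flag <- as.integer(spots$flag)
  utils::write.table(spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname costimr-io
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("array_id", "condition", "replicate") %in% names(d)))
  d
}

#' @rdname costimr-io
#' @param design Design table to write.
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname costimr-io
#' @export
read_edge_list <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("regulator", "target") %in% names(e))) {
    # headerless two-column edge list
    e <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(e) <- c("regulator", "target")
  }
  e
}

#' @rdname costimr-io
#' @param mat Genes x arrays matrix to write.
#' @export
write_expr_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname costimr-io
#' @export
read_expr_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene_id
  mat
}
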