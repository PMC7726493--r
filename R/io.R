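# Plain-text readers/writers for the pipeline's interchange formats:
# tab-delimited expression matrix (first column probe ID), CSV sample sheet,
# TSV DE tables and overlap summaries, one-ID-per-line gene lists, CSV
# dose-response curves, JSON ground truth and run manifests.

#' Write / read an expression matrix and its sample sheet
#'
#' The matrix is tab-delimited with a `probe_id` first column and sample IDs
#' as the header; the sample sheet is CSV with columns `sample_id`,
#' `cell_line`, `treatment`, `replicate`.
#'
#' @param em an [expression_matrix()].
#' @param matrix_path,samples_path output/input file paths.
#' @return `write_expression_matrix` returns the paths invisibly;
#'   `read_expression_matrix` returns an [expression_matrix()].
#' @export
write_expression_matrix <- function(em, matrix_path, samples_path) {
  df <- data.frame(probe_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(em$samples, samples_path, row.names = FALSE, quote = FALSE)
  invisible(c(matrix = matrix_path, samples = samples_path))
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(matrix_path, samples_path) {
  df <- utils::read.delim(matrix_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  expression_matrix(values, samples)
}

#' Write / read a differential-expression table as TSV
#'
#' Columns: `probe_id`, `log2fc`, `t_stat`, `p_raw`, `p_adj`, `call`.
#'
#' @param de a [de_table()] result.
#' @param path file path.
#' @return The path (write) or the table with `call` restored as a factor
#'   (read).
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  de <- utils::read.delim(path, stringsAsFactors = FALSE)
  de$call <- factor(de$call, levels = c("up", "down", "ns"))
  de
}

#' Write / read a gene list (one identifier per line)
#'
#' @param ids character vector of probe identifiers.
#' @param path file path.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) readLines(path)

#' Write / read a dose-response curve as CSV
#'
#' Columns `concentration_uM` and `response_pct` (mean over replicates).
#'
#' @param curve a [dose_curve()].
#' @param path file path.
#' @export
write_dose_curve <- function(curve, path) {
  utils::write.csv(data.frame(concentration_uM = curve$concentration,
                              response_pct = curve$response),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dose_curve
#' @export
read_dose_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dose_curve(df$concentration_uM, df$response_pct)
}

#' Write the simulation ground truth as JSON
#'
#' @param truth the `truth` data.frame from [generate_expression()].
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE),
                stringsAsFactors = FALSE)
}
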