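#' Expression matrix with sample annotations
#'
#' Container for a normalized log2 expression matrix (probes in rows, samples
#' in columns) together with a sample sheet annotating each sample with a cell
#' line, a treatment label and a replicate index. All downstream contrasts,
#' overlap and concordance computations consume this container.
#'
#' @param values numeric matrix of log2 intensities, probes x samples, with
#'   rownames (probe identifiers) and colnames (sample identifiers).
#' @param samples data.frame with columns `sample_id`, `cell_line`,
#'   `treatment`, `replicate`; one row per column of `values`, in any order.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix, columns reordered to match the sample sheet) and `samples`.
#' @export
expression_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe identifiers in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in `values`")
  required <- c("sample_id", "cell_line", "treatment", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols))
    stop("sample sheet lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample identifiers in sample sheet")
  if (!setequal(samples$sample_id, colnames(values)))
    stop("sample sheet and matrix columns disagree")
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$samples$treatment)
  cat("treatments:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Columns of the matrix belonging to a treatment label; errors name the label.
sample_columns <- function(em, label) {
  idx <- which(em$samples$treatment == label)
  if (!length(idx))
    stop(sprintf("treatment label '%s' not present in sample sheet", label))
  idx
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
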