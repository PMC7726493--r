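#' Select the probes with highest across-sample variance
#'
#' The standard pre-filter for expression PCA: the `k` probes with largest
#' sample variance on the log2 scale. Ties are broken deterministically by
#' probe order in the matrix.
#'
#' @param em an [expression_matrix()].
#' @param k number of probes to keep (default 1000).
#' @return Character vector of `k` probe identifiers, ordered by decreasing
#'   variance.
#' @export
select_top_variance <- function(em, k = 1000L) {
  k <- as.integer(k)
  if (k <= 0L) stop("`k` must be positive")
  if (k > nrow(em$values)) stop("`k` exceeds the number of probes")
  v <- apply(em$values, 1, var)
  ord <- order(-v, seq_along(v))
  rownames(em$values)[ord[seq_len(k)]]
}

#' Principal component analysis of samples
#'
#' Mean-centers each probe (no unit-variance scaling, the convention for
#' log2 expression data) and decomposes by SVD over samples. Percent variance
#' explained per component is `100 * sigma_i^2 / sum(sigma_j^2)`.
#'
#' @param em an [expression_matrix()].
#' @param probes optional probe subset (e.g. from [select_top_variance()]);
#'   default all probes.
#' @return List with `scores` (samples x components), `percent_var`
#'   (non-increasing, sums to 100), `probes` (the subset used), and
#'   `samples` (the annotation data.frame).
#' @export
pca_samples <- function(em, probes = NULL) {
  if (ncol(em$values) < 2L) stop("PCA needs at least 2 samples")
  vals <- em$values
  if (!is.null(probes)) {
    missing <- setdiff(probes, rownames(vals))
    if (length(missing))
      stop("unknown probes: ", paste(utils::head(missing, 5), collapse = ", "))
    vals <- vals[probes, , drop = FALSE]
  }
  fit <- prcomp(t(vals), center = TRUE, scale. = FALSE)
  pv <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x,
       percent_var = pv,
       probes = rownames(vals),
       samples = em$samples)
}
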