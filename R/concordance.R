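#' Spearman rank correlation with a t-approximation p-value
#'
#' Computes the Spearman coefficient as the Pearson correlation of
#' average-ranked values (midranks for ties) and a two-sided p-value from the
#' large-sample t approximation `t = R * sqrt((n - 2) / (1 - R^2))` on
#' `n - 2` degrees of freedom. Used to compare genome-wide log2 fold-change
#' profiles between compounds.
#'
#' @param x,y numeric vectors of equal length >= 3 on a matched probe order.
#' @return List with `R` (the coefficient), `p` (two-sided), and `n`.
#' @export
spearman_cc <- function(x, y) {
  if (length(x) != length(y)) stop("profiles differ in length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not supported")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("undefined correlation: a ranked vector has zero variance")
  R <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  p <- if (abs(R) >= 1) 0 else {
    t_stat <- R * sqrt((n - 2) / (1 - R^2))
    2 * pt(-abs(t_stat), n - 2)
  }
  list(R = R, p = p, n = n)
}

#' Format a p-value with the conventional 2.2e-16 floor
#'
#' @param p p-value.
#' @return `"< 2.2e-16"` for values below that floor, otherwise the value
#'   formatted with [format.pval()].
#' @export
format_pval_floor <- function(p) {
  ifelse(p < 2.2e-16, "< 2.2e-16", format.pval(p, digits = 3))
}

#' Pairwise Spearman concordance of fold-change profiles
#'
#' Takes per-condition log2 fold-change profiles on one common, ordered probe
#' universe and returns the symmetric matrix of Spearman coefficients with
#' their p-values. This is the genome-wide compound-similarity analysis:
#' profiles are compared over all probes, not only the differentially
#' expressed subset.
#'
#' @param profiles named list of equal-length numeric vectors, or a named
#'   list of data.frames with `probe_id` and `log2fc` columns (probe sets
#'   must then be identical; order is aligned on the first profile).
#' @return List with matrices `R` (unit diagonal) and `p`, plus `n`.
#' @export
pairwise_concordance <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least two profiles")
  if (is.null(names(profiles))) names(profiles) <- paste0("profile", seq_along(profiles))
  if (is.data.frame(profiles[[1]])) {
    ref <- profiles[[1]]$probe_id
    profiles <- lapply(profiles, function(p) {
      diff_ids <- c(setdiff(p$probe_id, ref), setdiff(ref, p$probe_id))
      if (length(diff_ids))
        stop("profiles disagree on the probe universe; symmetric difference: ",
             paste(utils::head(diff_ids, 10), collapse = ", "))
      p$log2fc[match(ref, p$probe_id)]
    })
  }
  lens <- vapply(profiles, length, 1L)
  if (length(unique(lens)) != 1L)
    stop("profiles differ in length: ", paste(lens, collapse = ", "))
  k <- length(profiles)
  R <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(R) <- dimnames(p) <- list(names(profiles), names(profiles))
  diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    s <- spearman_cc(profiles[[i]], profiles[[j]])
    R[i, j] <- R[j, i] <- s$R
    p[i, j] <- p[j, i] <- s$p
  }
  list(R = R, p = p, n = lens[[1]])
}
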