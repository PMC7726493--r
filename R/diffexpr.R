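#' Per-probe log2 fold changes for a treatment-vs-control contrast
#'
#' Fold change is the difference of group means on the log2 scale, so a value
#' of `log2(1.5) = 0.585` corresponds to the 1.5-fold linear threshold used
#' for differential-expression calling.
#'
#' @param em an [expression_matrix()].
#' @param treatment,control treatment labels present in the sample sheet.
#' @return Named numeric vector of log2 fold changes (treated mean - control
#'   mean), one per probe.
#' @export
log2_fold_changes <- function(em, treatment, control) {
  ti <- sample_columns(em, treatment)
  ci <- sample_columns(em, control)
  rowMeans(em$values[, ti, drop = FALSE]) -
    rowMeans(em$values[, ci, drop = FALSE])
}

#' Pooled-variance two-sample t test per probe
#'
#' Classical equal-variance two-sample t statistic with `n_t + n_c - 2`
#' degrees of freedom and a two-sided p-value, vectorized over probes.
#' Degenerate probes follow a documented convention: zero pooled variance
#' with zero mean difference gives t = 0, p = 1; zero pooled variance with a
#' nonzero difference gives an infinite t and p = 0.
#'
#' @inheritParams log2_fold_changes
#' @return data.frame with columns `t_stat`, `p_raw`, `df`, rownames = probes.
#' @export
two_sample_test <- function(em, treatment, control) {
  ti <- sample_columns(em, treatment)
  ci <- sample_columns(em, control)
  nt <- length(ti); nc <- length(ci)
  if (nt < 2L || nc < 2L)
    stop("need >= 2 replicates per group for the two-sample test")
  xt <- em$values[, ti, drop = FALSE]
  xc <- em$values[, ci, drop = FALSE]
  mt <- rowMeans(xt); mc <- rowMeans(xc)
  sst <- rowSums((xt - mt)^2)
  ssc <- rowSums((xc - mc)^2)
  df <- nt + nc - 2L
  pooled_var <- (sst + ssc) / df
  se <- sqrt(pooled_var * (1 / nt + 1 / nc))
  delta <- mt - mc
  t_stat <- ifelse(se == 0, ifelse(delta == 0, 0, sign(delta) * Inf),
                   delta / se)
  p_raw <- ifelse(is.infinite(t_stat), 0, 2 * pt(-abs(t_stat), df))
  data.frame(t_stat = t_stat, p_raw = p_raw, df = df,
             row.names = rownames(em$values))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Validating front end over the standard step-up adjustment: each p-value is
#' multiplied by m over its ascending rank, monotonicity is enforced by a
#' cumulative minimum from the largest rank, and results are capped at 1 and
#' returned in the original order.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differential expression from fold-change and FDR thresholds
#'
#' A probe is called `up` when its linear fold change strictly exceeds
#' `fc_threshold` and its adjusted p-value is strictly below `alpha`; `down`
#' when the linear fold change is strictly below `1/fc_threshold` at the same
#' FDR gate; `ns` otherwise. Defaults are the 1.5-fold / 5% FDR rule.
#'
#' @param de data.frame with columns `log2fc` and `p_adj`.
#' @param fc_threshold linear fold-change threshold, > 1.
#' @param alpha FDR level in (0, 1).
#' @return `de` with a `call` factor column (`up`, `down`, `ns`) added.
#' @export
call_de <- function(de, fc_threshold = 1.5, alpha = 0.05) {
  stopifnot(is.data.frame(de), all(c("log2fc", "p_adj") %in% names(de)))
  if (fc_threshold <= 1) stop("`fc_threshold` must be > 1")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  fc <- 2^de$log2fc
  sig <- de$p_adj < alpha
  de$call <- factor(ifelse(sig & fc > fc_threshold, "up",
                    ifelse(sig & fc < 1 / fc_threshold, "down", "ns")),
                    levels = c("up", "down", "ns"))
  de
}

#' Full differential-expression table for one contrast
#'
#' Combines [log2_fold_changes()], [two_sample_test()], [bh_adjust()] and
#' [call_de()] into the per-probe table used by the overlap and concordance
#' stages.
#'
#' @inheritParams log2_fold_changes
#' @inheritParams call_de
#' @return data.frame with columns `probe_id`, `log2fc`, `t_stat`, `p_raw`,
#'   `p_adj`, `call`.
#' @export
de_table <- function(em, treatment, control, fc_threshold = 1.5,
                     alpha = 0.05) {
  tt <- two_sample_test(em, treatment, control)
  de <- data.frame(probe_id = rownames(em$values),
                   log2fc = unname(log2_fold_changes(em, treatment, control)),
                   t_stat = tt$t_stat,
                   p_raw = tt$p_raw,
                   p_adj = bh_adjust(tt$p_raw),
                   stringsAsFactors = FALSE)
  rownames(de) <- NULL
  call_de(de, fc_threshold = fc_threshold, alpha = alpha)
}

#' Extract the up- or downregulated probe set from a DE table
#'
#' @param de a [de_table()] result.
#' @param direction `"up"`, `"down"`, or `"deregulated"` (union of both).
#' @return Character vector of probe identifiers.
#' @export
de_probes <- function(de, direction = c("up", "down", "deregulated")) {
  direction <- match.arg(direction)
  keep <- if (direction == "deregulated") de$call != "ns"
          else de$call == direction
  de$probe_id[keep]
}
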