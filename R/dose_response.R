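#' Normalize raw assay readouts to a vehicle-control group
#'
#' Expresses per-sample readouts (e.g. luminescence from CYP activity or ATP
#' assays) relative to the mean of the control group, either as percent of
#' control (the convention for concentration-response curves) or as fold
#' change over control (the convention for caspase induction).
#'
#' @param values numeric vector of raw readouts.
#' @param group vector of group labels, same length.
#' @param control_group label of the vehicle-control group.
#' @param mode `"percent"` (100 * value / control mean) or `"fold"`
#'   (value / control mean).
#' @return Numeric vector of normalized values, same length and order.
#' @export
normalize_to_control <- function(values, group, control_group,
                                 mode = c("percent", "fold")) {
  mode <- match.arg(mode)
  if (length(values) != length(group)) stop("`values`/`group` length mismatch")
  ctrl <- values[group == control_group]
  if (!length(ctrl))
    stop(sprintf("control group '%s' is empty", control_group))
  m <- mean(ctrl)
  if (!is.finite(m) || m <= 0)
    stop("control group mean must be positive")
  if (mode == "percent") 100 * values / m else values / m
}

#' Build a dose-response curve from concentration/response pairs
#'
#' @param concentration strictly increasing concentrations, uM, first = 0.
#' @param response percent-of-control responses (replicates at the same
#'   concentration should be averaged first or supplied via `replicates`).
#' @param replicates optional matrix (points x replicates) of per-well
#'   responses; `response` is then its row mean.
#' @return An object of class `dose_curve`.
#' @export
dose_curve <- function(concentration, response = NULL, replicates = NULL) {
  if (is.null(response)) {
    if (is.null(replicates)) stop("supply `response` or `replicates`")
    response <- rowMeans(replicates)
  }
  if (length(concentration) != length(response))
    stop("concentration/response length mismatch")
  if (anyDuplicated(concentration) || any(diff(concentration) <= 0))
    stop("`concentration` must be strictly increasing")
  structure(list(concentration = as.numeric(concentration),
                 response = as.numeric(response),
                 replicates = replicates,
                 n_replicates = if (is.null(replicates)) 1L else ncol(replicates),
                 response_sd = if (is.null(replicates)) NULL else
                   apply(replicates, 1, sd)),
            class = "dose_curve")
}

#' Estimate the IC50 from a percent-of-control curve
#'
#' The half-maximal inhibitory concentration is estimated from a straight
#' line `f(x) = a*x + b`. In the default `"segment"` mode the line is fitted
#' through the first consecutive concentration pair whose mean responses
#' bracket 50% of control (response_i >= 50 >= response_{i+1}); the IC50 is
#' the solution of `a*x + b = 50`, which always lies inside the bracketing
#' interval, and equals a tested concentration exactly when that
#' concentration's response is exactly 50. If the mean response never falls
#' to 50% at any tested concentration the result is `not_reached` — the
#' behaviour of a compound whose toxicity stays below half-maximal in the
#' tested range. The `"global"` mode instead fits one least-squares line to
#' all points and solves it at 50 (reported only when the solution falls
#' within the tested range).
#'
#' @param curve a [dose_curve()] (responses in percent of control; replicate
#'   responses at a concentration are averaged before crossing detection).
#' @param mode `"segment"` (two-point bracketing line, default) or
#'   `"global"` (least-squares line through all points).
#' @return List of class `ic50_result` with `status` (`"estimated"` or
#'   `"not_reached"`), `ic50` (uM, NA when not reached), and the line
#'   coefficients `a` (percent per uM) and `b` (percent).
#' @export
estimate_ic50 <- function(curve, mode = c("segment", "global")) {
  mode <- match.arg(mode)
  if (!inherits(curve, "dose_curve")) stop("`curve` must be a dose_curve")
  conc <- curve$concentration
  resp <- curve$response
  if (length(conc) < 2L) stop("need at least 2 concentration points")
  not_reached <- structure(list(status = "not_reached", ic50 = NA_real_,
                                a = NA_real_, b = NA_real_, mode = mode),
                           class = "ic50_result")
  if (all(resp > 50)) return(not_reached)
  if (mode == "global") {
    fit <- lm(resp ~ conc)
    b <- unname(coef(fit)[1]); a <- unname(coef(fit)[2])
    if (a == 0) return(not_reached)
    x <- (50 - b) / a
    if (x < min(conc) || x > max(conc)) return(not_reached)
    return(structure(list(status = "estimated", ic50 = x, a = a, b = b,
                          mode = mode), class = "ic50_result"))
  }
  # first downward crossing of 50% between consecutive tested concentrations
  for (i in seq_len(length(conc) - 1L)) {
    if (resp[i] >= 50 && resp[i + 1L] <= 50) {
      if (resp[i] == resp[i + 1L]) {            # both exactly 50
        x <- conc[i]; a <- 0; b <- 50
      } else {
        a <- (resp[i + 1L] - resp[i]) / (conc[i + 1L] - conc[i])
        b <- resp[i] - a * conc[i]
        x <- (50 - b) / a
      }
      return(structure(list(status = "estimated", ic50 = x, a = a, b = b,
                            mode = mode), class = "ic50_result"))
    }
  }
  not_reached
}

#' @export
print.ic50_result <- function(x, ...) {
  if (x$status == "estimated")
    cat(sprintf("IC50 = %.4g uM (line f(x) = %.4g x + %.4g, %s mode)\n",
                x$ic50, x$a, x$b, x$mode))
  else
    cat("IC50 not reached: response stays above 50% of control\n")
  invisible(x)
}
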