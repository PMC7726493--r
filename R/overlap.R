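#' Overlap-ratio statistics for deregulated gene sets
#'
#' The overlap ratio quantifies how strongly the intersection of k gene sets
#' exceeds the intersection expected if each set of the same size were drawn
#' uniformly at random, and independently of the others, from a universe of N
#' probes. For two sets the expected overlap is `E = n1 * n2 / N` and the
#' ratio is `O * N / (n1 * n2)`; for three sets `E = n1 * n2 * n3 / N^2` and
#' the ratio is `O * N^2 / (n1 * n2 * n3)`. In both cases the ratio equals
#' observed / expected, so 1.0 indicates a random overlap and large values
#' indicate concordant deregulation.
#'
#' @param n1,n2,n3 set sizes (counts of deregulated probes per condition).
#' @param O observed intersection count.
#' @param N universe size (number of probes on the array).
#' @return An object of class `overlap_summary`: list with `k`, `n` (set
#'   sizes), `O`, `N`, `expected`, and `ratio`. The identity
#'   `ratio * expected == O` holds exactly.
#' @name overlap_ratio
NULL

new_overlap_summary <- function(n, O, N) {
  k <- length(n)
  if (any(n < 0) || any(n > N))
    stop("inconsistent sets: each set size must satisfy 0 <= n_i <= N")
  if (O < 0 || O > min(n))
    stop("inconsistent overlap: O must satisfy 0 <= O <= min(n_i)")
  if (any(n == 0))
    stop("overlap ratio undefined: a set has size 0")
  expected <- prod(n) / N^(k - 1)
  structure(list(k = k, n = n, O = O, N = N,
                 expected = expected, ratio = O / expected),
            class = "overlap_summary")
}

#' @rdname overlap_ratio
#' @export
overlap_ratio_pairwise <- function(n1, n2, O, N)
  new_overlap_summary(c(n1, n2), O, N)

#' @rdname overlap_ratio
#' @export
overlap_ratio_threeway <- function(n1, n2, n3, O, N)
  new_overlap_summary(c(n1, n2, n3), O, N)

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("%d-way overlap over N = %d: sets (%s), observed %g, expected %g\n",
              x$k, x$N, paste(x$n, collapse = ", "), x$O,
              signif(x$expected, 4)))
  cat(sprintf("overlap ratio = %g (1.0 = random overlap)\n",
              signif(x$ratio, 6)))
  invisible(x)
}

#' Overlap ratio from an observed and an expected count
#'
#' Directly forms observed / expected, the form in which multi-set overlap
#' enrichment is usually reported (e.g. "12 genes observed against 0.02218
#' expected").
#'
#' @param O observed intersection count, >= 0.
#' @param E expected intersection count, > 0.
#' @return The ratio O / E as a bare number.
#' @export
ratio_from_observed_expected <- function(O, E) {
  if (!is.numeric(E) || E <= 0) stop("expected count E must be > 0")
  if (!is.numeric(O) || O < 0) stop("observed count O must be >= 0")
  O / E
}

#' Venn partition of three gene sets over a finite universe
#'
#' Counts the seven non-empty Venn regions of three named sets plus the
#' outside region; the eight counts sum to the universe size, and every
#' pairwise or triple overlap count is recoverable by summing regions.
#'
#' @param sets named list of three character vectors (probe identifiers).
#' @param universe character vector of all probe identifiers, or a single
#'   integer N (in which case sets must be subsets of `1..N` as characters or
#'   integers).
#' @return Named integer vector with elements `A_only`, `B_only`, `C_only`,
#'   `AB_only`, `AC_only`, `BC_only`, `ABC`, `outside`, where A, B, C are the
#'   three sets in list order, plus attributes `set_names` and `N`.
#' @export
venn_partition <- function(sets, universe) {
  if (length(sets) != 3L) stop("`sets` must contain exactly three sets")
  if (length(universe) == 1L && is.numeric(universe))
    universe <- as.character(seq_len(universe))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  outside_members <- lapply(sets, setdiff, y = universe)
  bad <- vapply(outside_members, length, 1L) > 0
  if (any(bad))
    stop("set member(s) outside the universe in set(s): ",
         paste(which(bad), collapse = ", "))
  inA <- universe %in% sets[[1]]
  inB <- universe %in% sets[[2]]
  inC <- universe %in% sets[[3]]
  counts <- c(
    A_only  = sum(inA & !inB & !inC),
    B_only  = sum(!inA & inB & !inC),
    C_only  = sum(!inA & !inB & inC),
    AB_only = sum(inA & inB & !inC),
    AC_only = sum(inA & !inB & inC),
    BC_only = sum(!inA & inB & inC),
    ABC     = sum(inA & inB & inC),
    outside = sum(!inA & !inB & !inC))
  attr(counts, "set_names") <- names(sets)
  attr(counts, "N") <- length(universe)
  counts
}

#' Monte-Carlo null distribution of the overlap count
#'
#' Draws `reps` independent replicates in which each of the two or three sets
#' is sampled uniformly without replacement from the universe, independently
#' of the other sets, and records the intersection count. The empirical mean
#' converges to the analytic expectation (`n1*n2/N` or `n1*n2*n3/N^2`),
#' providing a simulation check of the independence model behind the overlap
#' ratio. The one-sided exceedance probability for an observed count is an
#' add-on beyond the analytic statistic, computed with the standard +1
#' correction.
#'
#' @param n1,n2 set sizes; `n3` optional for the three-way null.
#' @param N universe size.
#' @param reps number of Monte-Carlo replicates, >= 1.
#' @param seed RNG seed.
#' @param observed optional observed overlap count for which to report the
#'   exceedance probability `(#\{O_rep >= O_obs\} + 1) / (reps + 1)`.
#' @return List with `overlaps` (integer vector, length `reps`), `mean`,
#'   `expected` (analytic), and `p_exceed` (NA when `observed` is missing).
#' @export
monte_carlo_null <- function(n1, n2, n3 = NULL, N, reps = 10000L, seed = 1L,
                             observed = NULL) {
  n <- c(n1, n2, n3)
  if (any(n < 0) || any(n > N)) stop("set sizes must satisfy 0 <= n_i <= N")
  if (reps < 1L) stop("`reps` must be >= 1")
  k <- length(n)
  overlaps <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      draws <- lapply(n, function(ni) sample.int(N, ni))
      members <- tabulate(unlist(draws), nbins = N)
      sum(members == k)
    }, integer(1))
  })
  list(overlaps = overlaps,
       mean = mean(overlaps),
       expected = prod(n) / N^(k - 1),
       p_exceed = if (is.null(observed)) NA_real_ else
         (sum(overlaps >= observed) + 1) / (reps + 1))
}

#' Overlap summaries for DE probe sets from several contrasts
#'
#' Convenience layer over [overlap_ratio_pairwise()] and
#' [overlap_ratio_threeway()]: takes named probe sets (e.g. the up-sets of
#' three compounds), the universe size, and tabulates all pairwise summaries
#' plus the three-way summary when three sets are given. Empty sets make the
#' ratio undefined; such rows carry `NA` ratios and are flagged rather than
#' raising an error, so whole-study reports degrade gracefully.
#'
#' @param sets named list of >= 2 character vectors.
#' @param N universe size.
#' @return data.frame with one row per comparison: `comparison`, `k`,
#'   `n_sets` (comma-separated sizes), `observed`, `expected`, `ratio`,
#'   `defined`.
#' @export
overlap_table <- function(sets, N) {
  if (length(sets) < 2L) stop("need at least two sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("`sets` must be named")
  sizes <- vapply(sets, length, 1L)
  row_for <- function(idx) {
    n <- sizes[idx]
    O <- length(Reduce(intersect, sets[idx]))
    defined <- all(n > 0)
    data.frame(
      comparison = paste(names(sets)[idx], collapse = "&"),
      k = length(idx),
      n_sets = paste(n, collapse = ","),
      observed = O,
      expected = if (defined) prod(n) / N^(length(idx) - 1) else NA_real_,
      ratio = if (defined) O / (prod(n) / N^(length(idx) - 1)) else NA_real_,
      defined = defined,
      stringsAsFactors = FALSE)
  }
  pairs <- utils::combn(seq_along(sets), 2L, simplify = FALSE)
  rows <- lapply(pairs, row_for)
  if (length(sets) >= 3L)
    rows <- c(rows, lapply(utils::combn(seq_along(sets), 3L, simplify = FALSE),
                           row_for))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
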