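# Independent reference implementations used as oracles. These deliberately
# take the slow, literal route so they share no code with the package paths
# they check.

# Benjamini-Hochberg by its definition: adj_(i) = min over ranks j >= i of
# m * p_(j) / j, capped at 1, returned in input order.
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# Exact permutation p-value for the pooled two-sample t, enumerating all
# group assignments of the combined sample.
perm_t_pvalue <- function(x, y) {
  pooled_t <- function(a, b) {
    na <- length(a); nb <- length(b)
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
    if (sp2 == 0) return(if (mean(a) == mean(b)) 0 else Inf)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  z <- c(x, y)
  n <- length(x)
  splits <- utils::combn(length(z), n)
  t_obs <- abs(pooled_t(x, y))
  t_perm <- apply(splits, 2, function(idx) abs(pooled_t(z[idx], z[-idx])))
  mean(t_perm >= t_obs - 1e-12)
}

# Expected size of the intersection of a fixed set 1..n1 with a uniformly
# drawn size-n2 subset of 1..N, by literal enumeration of every subset.
expected_overlap_enumerated <- function(n1, n2, N) {
  subsets <- utils::combn(N, n2)
  mean(apply(subsets, 2, function(b) sum(b <= n1)))
}

# Same expectation via the hypergeometric pmf (independent of the analytic
# n1*n2/N path under test).
expected_overlap_hyper <- function(n1, n2, N) {
  x <- 0:min(n1, n2)
  sum(x * dhyper(x, n1, N - n1, n2))
}

# Exact permutation p-value for the Spearman coefficient, n <= 8.
spearman_perm_pvalue <- function(x, y) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  r_obs <- abs(cor(rank(x), rank(y)))
  rs <- vapply(perms(y), function(py) abs(cor(rank(x), rank(py))), numeric(1))
  mean(rs >= r_obs - 1e-12)
}

# Small standard simulated study shared across test files.
small_study <- function(seed = 42, ...) {
  args <- modifyList(
    list(n_probes = 2000L, n_replicates = 4L,
         shared_de_count = 100L, private_de_count = 0L,
         effect_mean = 1.5, effect_sd = 0.25,
         effect_correlation = 0.5, noise_sd = 0.1, seed = seed),
    list(...))
  generate_expression(do.call(sim_config, args))
}
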