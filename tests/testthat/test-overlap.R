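test_that("pairwise overlap ratio matches its closed form and edge cases", {
  s <- overlap_ratio_pairwise(10, 10, 1, 100)
  expect_equal(s$expected, 1.0)
  expect_equal(s$ratio, 1.0)
  expect_equal(overlap_ratio_pairwise(100, 100, 50, 20000)$ratio, 100.0)
  # nested identical sets: ratio = N / n
  expect_equal(overlap_ratio_pairwise(25, 25, 25, 400)$ratio, 400 / 25)
  expect_error(overlap_ratio_pairwise(10, 10, 11, 100), "inconsistent")
  expect_error(overlap_ratio_pairwise(10, 200, 5, 100), "inconsistent")
  expect_error(overlap_ratio_pairwise(0, 10, 0, 100), "undefined")
})

test_that("three-way overlap ratio uses E = n1 n2 n3 / N^2", {
  s <- overlap_ratio_threeway(10, 10, 10, 0, 100)
  expect_equal(s$expected, 0.1)
  expect_equal(s$ratio, 0)
  s2 <- overlap_ratio_threeway(40, 50, 60, 12, 1000)
  expect_equal(s2$expected, 40 * 50 * 60 / 1000^2)
  expect_equal(s2$ratio * s2$expected, s2$O)
})

test_that("ratio * expected = observed identity holds across random inputs", {
  set.seed(13)
  for (i in 1:200) {
    N <- sample(10:5000, 1)
    k <- sample(2:3, 1)
    n <- sample.int(N, k, replace = TRUE)
    O <- sample.int(min(n) + 1L, 1) - 1L
    s <- if (k == 2) overlap_ratio_pairwise(n[1], n[2], O, N)
         else overlap_ratio_threeway(n[1], n[2], n[3], O, N)
    expect_equal(s$ratio * s$expected, O, tolerance = 1e-12)
    # symmetry under permutation of set arguments
    np <- sample(n)
    sp <- if (k == 2) overlap_ratio_pairwise(np[1], np[2], O, N)
          else overlap_ratio_threeway(np[1], np[2], np[3], O, N)
    expect_equal(sp$ratio, s$ratio, tolerance = 1e-12)
  }
})

test_that("observed/expected ratio reproduces reported worked examples", {
  expect_equal(ratio_from_observed_expected(12, 0.02218), 12 / 0.02218)
  expect_equal(round(ratio_from_observed_expected(12, 0.02218), 2), 541.03)
  expect_equal(ratio_from_observed_expected(5, 5), 1.0)
  expect_equal(ratio_from_observed_expected(0, 0.5), 0.0)
  expect_error(ratio_from_observed_expected(3, 0), "E must be > 0")
})

test_that("analytic expectation equals enumerated/hypergeometric expectation", {
  # literal enumeration of every size-n2 subset for small universes
  for (N in c(6L, 9L, 12L)) {
    for (n1 in c(1L, 3L, N %/% 2)) {
      for (n2 in c(2L, N %/% 3 + 1L)) {
        expect_equal(expected_overlap_enumerated(n1, n2, N), n1 * n2 / N,
                     tolerance = 1e-12)
      }
    }
  }
  # hypergeometric pmf route for all configurations up to N = 30
  for (N in c(17L, 24L, 30L)) {
    for (n1 in seq(1L, N, by = 4L)) {
      for (n2 in seq(2L, N, by = 5L)) {
        expect_equal(expected_overlap_hyper(n1, n2, N), n1 * n2 / N,
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("venn partition reproduces enumerated regions and sums to N", {
  A <- as.character(1:20); B <- as.character(11:40); C <- as.character(31:60)
  v <- venn_partition(list(A = A, B = B, C = C), 100)
  expect_equal(unname(v[c("A_only", "AB_only", "B_only", "BC_only", "C_only",
                          "AC_only", "ABC", "outside")]),
               c(10L, 10L, 10L, 10L, 20L, 0L, 0L, 40L))
  expect_equal(sum(v), 100L)

  ident <- venn_partition(list(A = A, B = A, C = A), 100)
  expect_equal(unname(ident["ABC"]), 20L)
  expect_equal(sum(ident[setdiff(names(ident), c("ABC", "outside"))]), 0L)

  disjoint <- venn_partition(list(A = as.character(1:5),
                                  B = as.character(6:10),
                                  C = as.character(11:15)), 20)
  expect_equal(unname(disjoint[c("A_only", "B_only", "C_only")]), c(5L, 5L, 5L))
  expect_equal(unname(disjoint["outside"]), 5L)

  expect_error(venn_partition(list(A = "999", B = A, C = B), 100), "outside")
})

test_that("pairwise overlaps are reconstructible from venn regions", {
  set.seed(23)
  uni <- sprintf("g%03d", 1:300)
  sets <- lapply(1:3, function(i) sample(uni, sample(30:120, 1)))
  names(sets) <- c("A", "B", "C")
  v <- venn_partition(sets, uni)
  expect_equal(length(intersect(sets$A, sets$B)),
               unname(v["AB_only"] + v["ABC"]))
  expect_equal(length(intersect(sets$A, sets$C)),
               unname(v["AC_only"] + v["ABC"]))
  expect_equal(length(Reduce(intersect, sets)), unname(v["ABC"]))
})

test_that("Monte-Carlo null matches analytic expectations", {
  mc2 <- monte_carlo_null(20, 30, N = 100, reps = 20000, seed = 5)
  se <- sd(mc2$overlaps) / sqrt(length(mc2$overlaps))
  expect_equal(mc2$expected, 6.0)
  expect_lt(abs(mc2$mean - 6.0), 3 * se)

  mc3 <- monte_carlo_null(10, 10, 10, N = 100, reps = 20000, seed = 6)
  se3 <- sd(mc3$overlaps) / sqrt(length(mc3$overlaps))
  expect_equal(mc3$expected, 0.1)
  expect_lt(abs(mc3$mean - 0.1), 3 * se3)

  # saturated set: every replicate's pairwise overlap is exactly n2
  sat <- monte_carlo_null(100, 37, N = 100, reps = 200, seed = 7)
  expect_true(all(sat$overlaps == 37L))

  # exceedance probability uses the +1 correction
  mc <- monte_carlo_null(20, 30, N = 100, reps = 999, seed = 8, observed = 999)
  expect_equal(mc$p_exceed, 1 / 1000)
  expect_identical(monte_carlo_null(5, 5, N = 50, reps = 100, seed = 1)$overlaps,
                   monte_carlo_null(5, 5, N = 50, reps = 100, seed = 1)$overlaps)
})

test_that("overlap table covers all comparisons and flags empty sets", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = character(0))
  tab <- overlap_table(sets, 100)
  expect_equal(nrow(tab), 4L)  # three pairs + one triple
  ab <- tab[tab$comparison == "A&B", ]
  expect_equal(ab$observed, 2L)
  expect_equal(ab$ratio, 2 * 100 / 9)
  expect_false(tab$defined[tab$comparison == "A&C"])
  expect_true(is.na(tab$ratio[tab$comparison == "A&B&C"]))
})
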