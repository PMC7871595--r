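test_that("haplotype collapsing counts variants by population", {
  x <- toy_dataset(c("AAAA", "AAAA", "TTAA", "TTAA", "TTAA"),
                   pops = c("P1", "P1", "P1", "P2", "P2"))
  ht <- collapse_haplotypes(x)
  expect_equal(length(ht$sequences), 2L)
  # H1 is the commoner variant (3 carriers)
  expect_equal(unname(ht$totals), c(3L, 2L))
  expect_equal(ht$counts["H1", c("P1", "P2")], c(P1 = 1L, P2 = 2L))
  expect_equal(ht$counts["H2", c("P1", "P2")], c(P1 = 2L, P2 = 0L))

  same <- toy_dataset(rep("ACGT", 4L), "P1")
  expect_equal(length(collapse_haplotypes(same)$sequences), 1L)
})

test_that("haplotype count matches an independent de-duplication oracle", {
  x <- small_sim()$combined
  ht <- collapse_haplotypes(x)
  # oracle: naive O(n^2) row-by-row duplicate scan
  m <- popgenmt:::pg_mat(x)
  n <- nrow(m)
  is_dup <- rep(FALSE, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (!is_dup[j] && all(m[i, ] == m[j, ])) is_dup[j] <- TRUE
  oracle_hn <- sum(!is_dup)
  expect_equal(length(ht$sequences), oracle_hn)
  # re-expanding counts reproduces N in every population
  expect_equal(colSums(ht$counts),
               table(x$meta$population)[colnames(ht$counts)],
               ignore_attr = TRUE)
})

test_that("site summary applies the complete-deletion rule", {
  x <- toy_dataset(c("AAAA", "AAAT", "AATT", "ACG-"), "P1")
  ss <- site_summary(x)
  expect_equal(ss$analyzed_sites, 3L)      # gapped column excluded
  expect_equal(ss$excluded_sites, 4L)
  expect_equal(ss$S, 2L)                   # columns 3 and 4 dropped/counted
  y <- toy_dataset(c("AAAA", "AAAA", "ATAA", "ATAA"), "P1")
  sy <- site_summary(y)
  expect_equal(sy$S, 1L)                   # A,A,T,T column is variable...
  expect_equal(sy$parsimony_informative, 1L)  # ...and parsimony-informative
  expect_equal(sum(sy$base_composition), 1, tolerance = 1e-12)
})

test_that("group-unique and singleton haplotypes are counted separately", {
  # 3 haplotypes: h1 in both pops, h2 only P1 (2 copies), h3 only P2 (1 copy)
  x <- toy_dataset(c("AAAA", "AAAA", "CCCC", "CCCC", "AAAA", "GGGG"),
                   pops = c("P1", "P1", "P1", "P1", "P2", "P2"))
  ht <- collapse_haplotypes(x)
  us <- unique_haplotype_stats(ht, "population")
  expect_equal(us$n_haplotypes, 3L)
  expect_equal(us$unique_n, 2L)
  expect_equal(us$unique_percent, round(100 * 2 / 3, 1))
  expect_equal(us$singleton_n, 1L)

  one_group <- toy_dataset(c("AAAA", "TTTT", "GGGG"), "P1")
  us1 <- unique_haplotype_stats(collapse_haplotypes(one_group), "population")
  expect_equal(us1$unique_percent, 100)
})

test_that("frequency report gives one-decimal percentages of total N", {
  x <- toy_dataset(c(rep("AAAA", 6L), rep("TTTT", 3L), "GGGG"), "P1")
  fr <- haplotype_frequency_report(collapse_haplotypes(x))
  expect_equal(fr$count, c(6L, 3L, 1L))
  expect_equal(fr$percent, c(60, 30, 10))
})

test_that("rarefaction matches the exact subset enumeration", {
  # counts (2,2): all C(4,2)=6 subsamples -> mean distinct = 10/6
  x <- toy_dataset(c("AAAA", "AAAA", "TTTT", "TTTT"), "P1")
  ht <- collapse_haplotypes(x)
  r <- coleman_rarefaction(ht, sizes = c(1, 2, 4), replicates = 3000, seed = 9)
  expect_equal(r$expected[r$g == 2], 10 / 6, tolerance = 1e-12)
  expect_equal(r$expected[r$g == 1], 1, tolerance = 1e-12)    # single draw
  expect_equal(r$expected[r$g == 4], 2, tolerance = 1e-12)    # full sample
  expect_equal(r$mean[r$g == 4], 2)                           # zero spread
  expect_equal(r$sd[r$g == 4], 0)
  expect_error(coleman_rarefaction(ht, sizes = 5, seed = 1), "range error")
})

test_that("permutation rarefaction converges on the hypergeometric curve", {
  ht <- collapse_haplotypes(small_sim()$combined)
  N <- sum(ht$totals)
  sizes <- c(5, 15, 30)
  reps <- 10000
  r <- coleman_rarefaction(ht, sizes, replicates = reps, seed = 101)
  se <- r$sd / sqrt(reps)
  expect_true(all(abs(r$mean - r$expected) <= 3 * se))
  # monotone non-decreasing expectation over the full range
  full <- coleman_rarefaction(ht, seq(1, N, by = 4), replicates = 2,
                              seed = 1)
  expect_true(all(diff(full$expected) >= -1e-12))
})
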