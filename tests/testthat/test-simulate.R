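test_that("generators are bit-reproducible under a fixed seed", {
  s1 <- simulate_neutral_coalescent(12, 2, seed = 99, L = 150)
  s2 <- simulate_neutral_coalescent(12, 2, seed = 99, L = 150)
  expect_identical(s1$alignment, s2$alignment)

  cfg <- sim_config(regions = "A", pops_per_region = 2,
                    samples_per_population = 6,
                    marker_lengths = c(m = 120), theta = c(m = 1),
                    expansion = NULL, seed = 5)
  d1 <- simulate_structured_dataset(cfg)
  d2 <- simulate_structured_dataset(cfg)
  expect_identical(d1$alignments$m, d2$alignments$m)
  expect_identical(d1$meta, d2$meta)
})

test_that("datasets honour configured lengths, sizes and base bias", {
  ds <- small_sim()
  expect_equal(ncol(ds$alignments$COI), 300L)
  expect_equal(ncol(ds$alignments$Cytb), 200L)
  expect_equal(as.integer(table(ds$meta$population)[unique(ds$meta$population)]),
               c(10L, 8L, 12L, 10L, 9L, 11L))
  ss <- site_summary(popgen_data(ds$alignments$COI, ds$meta))
  expect_lt(abs(ss$at_content - 0.70), 0.03)
})

test_that("the coalescent simulator matches Watterson expectations", {
  set.seed(77)
  n <- 10; theta <- 2
  sims <- vapply(1:500, function(i) {
    s <- simulate_neutral_coalescent(n, theta)
    c(s$S, s$k)
  }, numeric(2))
  a1 <- sum(1 / 1:(n - 1))
  se_S <- sd(sims[1, ]) / sqrt(ncol(sims))
  se_k <- sd(sims[2, ]) / sqrt(ncol(sims))
  expect_lt(abs(mean(sims[1, ]) - theta * a1), 3 * se_S)
  expect_lt(abs(mean(sims[2, ]) - theta), 3 * se_k)
})

test_that("migration limits produce panmixia or deep regional splits", {
  # equal high migration everywhere ~ panmixia: Phi_ST near 0
  phis <- vapply(1:5, function(s) {
    cfg <- sim_config(regions = c("A", "B"), pops_per_region = c(2, 2),
                      samples_per_population = 8, marker_lengths = c(m = 300),
                      theta = c(m = 1), migration_within = 20,
                      migration_between = 20, expansion = NULL, seed = 300 + s)
    ds <- simulate_structured_dataset(cfg)
    x <- popgen_data(ds$alignments$m, ds$meta)
    amova(pairwise_distance_matrix(x), x$meta, "one-level",
          permutations = 0)$indices[["F_ST"]]
  }, numeric(1))
  expect_lt(abs(mean(phis)), 0.05)

  # near-zero between-region migration: strong F_CT, private haplotypes
  cfg <- sim_config(regions = c("A", "B"), pops_per_region = c(2, 2),
                    samples_per_population = 10, marker_lengths = c(m = 400),
                    theta = c(m = 1.5), migration_within = 10,
                    migration_between = 0.01, expansion = NULL, seed = 12)
  ds <- simulate_structured_dataset(cfg)
  x <- popgen_data(ds$alignments$m, ds$meta)
  a <- amova(pairwise_distance_matrix(x), x$meta, "two-level",
             permutations = 0)
  expect_gt(a$indices[["F_CT"]], 0.3)
  us <- unique_haplotype_stats(collapse_haplotypes(x), "region")
  expect_gt(us$unique_n, 0)
})

test_that("completely linked markers share one genealogy", {
  ds <- small_sim()
  d1 <- pairwise_distance_matrix(popgen_data(ds$alignments$COI, ds$meta))
  d2 <- pairwise_distance_matrix(popgen_data(ds$alignments$Cytb, ds$meta))
  lt <- lower.tri(d1)
  expect_gt(cor(d1[lt], d2[lt]), 0.5)
})

test_that("fixture suite exposes its designed structure", {
  expect_equal(length(collapse_haplotypes(fx$star)$sequences), 7L)
  ht <- collapse_haplotypes(fx$star)
  expect_gt(ht$totals[["H1"]], max(ht$totals[-1]))
  d <- pairwise_distance_matrix(fx$two_deme)
  a <- amova(d, fx$two_deme$meta, "one-level", permutations = 0)
  expect_equal(unname(a$indices[["F_ST"]]), 1)
})
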