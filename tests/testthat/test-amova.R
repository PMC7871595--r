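test_that("variance components match the hand-computed 9-sample worksheet", {
  # 3 populations x 3 samples (P1,P2 in region RA; P3 in RB), distances small
  # enough to sum by hand:
  #   SS_total = 126/9 = 14;  SS within pops = 4/3 * 3 = 4
  #   SS within regions = 34/6 + 4/3 = 7  ->  SS_AG = 7, SS_AP = 3
  #   MS = (7, 3, 2/3);  n1 = 3, n2 = 3, n3 = 4
  #   sigma2 = (1, 7/9, 2/3);  F_CT = 9/22, F_SC = 7/13, F_ST = 16/22
  x <- fx$amova_toy
  d <- pairwise_distance_matrix(x)
  a <- amova(d, x$meta, "two-level", permutations = 0)
  expect_equal(unname(a$SS),
               c(7, 3, 4), tolerance = 1e-12)
  expect_equal(unname(a$df), c(1, 1, 6))
  expect_equal(unname(a$sigma2), c(1, 7 / 9, 2 / 3), tolerance = 1e-12)
  expect_equal(unname(a$indices), c(9 / 22, 7 / 13, 16 / 22),
               tolerance = 1e-12)
  expect_equal(sum(a$percent), 100, tolerance = 1e-9)
})

test_that("(1-F_CT)(1-F_SC) = (1-F_ST) on every two-level run", {
  for (ds in list(fx$amova_toy, small_sim()$combined)) {
    a <- amova(pairwise_distance_matrix(ds), ds$meta, "two-level",
               permutations = 0)
    expect_equal((1 - a$indices[["F_CT"]]) * (1 - a$indices[["F_SC"]]),
                 1 - a$indices[["F_ST"]], tolerance = 1e-9)
  }
})

test_that("panmictic split gives Phi_ST near zero; fixed split gives one", {
  sim <- simulate_neutral_coalescent(40, 3, seed = 31, L = 300)
  meta <- data.frame(sample = rownames(sim$alignment),
                     population = rep(c("P1", "P2"), 20),
                     region = "R1", lat = 0, lon = 0)
  x <- popgen_data(sim$alignment, meta)
  a <- amova(pairwise_distance_matrix(x), x$meta, "one-level",
             permutations = 199, seed = 4)
  expect_lt(abs(a$indices[["F_ST"]]), 0.1)
  expect_gt(a$p_values[["F_ST"]], 0.05)

  d2 <- pairwise_distance_matrix(fx$two_deme)
  a2 <- amova(d2, fx$two_deme$meta, "one-level", permutations = 0)
  expect_equal(unname(a2$indices[["F_ST"]]), 1)
})

test_that("pairwise Phi_ST agrees with a direct one-level AMOVA per pair", {
  x <- small_sim()$combined
  d <- pairwise_distance_matrix(x)
  pp <- pairwise_phi_st(d, x$meta, permutations = 0)
  pops <- rownames(pp$phi_st)
  for (pair in list(c(1, 2), c(1, 4), c(3, 6))) {
    keep <- x$meta$population %in% pops[pair]
    dd <- d[keep, keep]
    a <- amova(dd, x$meta, "one-level", permutations = 0)
    expect_equal(pp$phi_st[pair[1], pair[2]], unname(a$indices[["F_ST"]]),
                 tolerance = 1e-12)
  }
  # permutation p-values reproducible and in (0, 1]
  p1 <- pairwise_phi_st(d, x$meta, permutations = 99, seed = 8)
  p2 <- pairwise_phi_st(d, x$meta, permutations = 99, seed = 8)
  expect_identical(p1$p, p2$p)
  expect_true(all(p1$p[lower.tri(p1$p)] > 0 & p1$p[lower.tri(p1$p)] <= 1))
})

test_that("negative pairwise estimates are retained, not truncated", {
  # one panmictic pool split at random often yields slightly negative Phi_ST
  sims <- vapply(1:12, function(s) {
    sim <- simulate_neutral_coalescent(20, 2, seed = 600 + s, L = 200)
    meta <- data.frame(sample = rownames(sim$alignment),
                       population = rep(c("A", "B"), 10),
                       region = "R1", lat = 0, lon = 0)
    x <- popgen_data(sim$alignment, meta)
    amova(pairwise_distance_matrix(x), x$meta, "one-level",
          permutations = 0)$indices[["F_ST"]]
  }, numeric(1))
  expect_true(any(sims < 0))
  expect_true(all(is.finite(sims)))
})

test_that("gene flow conversion follows the island-model identity", {
  expect_equal(unname(gene_flow_nm(0.2)), 1)           # (1-0.2)/(4*0.2)
  fst <- seq(0.05, 0.95, by = 0.05)
  nm <- gene_flow_nm(fst)
  expect_true(all(diff(nm) < 0))                       # strictly decreasing
  expect_identical(as.numeric(gene_flow_nm(0)), Inf)
  expect_identical(as.numeric(gene_flow_nm(1)), 0)
  expect_equal(attr(gene_flow_nm(c(-0.01, 0.5)), "flag")[1], "infinite-flow")
})
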