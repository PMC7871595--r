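test_that("the parsimony probability matches an inclusion-exclusion oracle", {
  # oracle: occupancy probability via surjection counts,
  # O(j | h) = C(L,j) * sum_i (-1)^i C(j,i) (j-i)^h / L^h
  oracle_prob <- function(j, L) {
    occ <- function(h) {
      i <- 0:j
      choose(L, j) * sum((-1)^i * choose(j, i) * (j - i)^h) / L^h
    }
    t0 <- occ(j)
    tot <- 0
    for (h in j:(j + 80)) tot <- tot + occ(h)
    t0 / tot
  }
  for (j in c(1, 3, 6, 9))
    expect_equal(popgenmt:::parsimony_probability(j, 652),
                 oracle_prob(j, 652), tolerance = 1e-6)
})

test_that("the connection limit is monotone in confidence and vacuous at 0", {
  l95 <- parsimony_connection_limit(652, 0.95)
  l99 <- parsimony_connection_limit(652, 0.99)
  expect_lte(l99, l95)
  expect_gte(l95, 1)
  # vanishing threshold connects everything
  expect_equal(parsimony_connection_limit(20, 1e-12), 20)
  # longer fragments support longer parsimonious connections
  expect_gte(parsimony_connection_limit(652), parsimony_connection_limit(421))
})

test_that("simple pairs are linked with the right intermediates", {
  one <- toy_dataset(c("AAAA", "AAAT", "AAAA", "AAAT"), "P1")
  net1 <- build_network(collapse_haplotypes(one), limit = 5)
  expect_equal(sum(net1$nodes$observed), 2L)
  expect_equal(length(net1$inferred), 0L)
  expect_equal(igraph::ecount(net1$graph), 1L)

  three <- toy_dataset(c("AAAAAA", "TTTAAA"), "P1")
  net3 <- build_network(collapse_haplotypes(three), limit = 5)
  expect_equal(sum(net3$nodes$observed), 2L)
  expect_equal(length(net3$inferred), 2L)     # d-1 intermediates
  expect_equal(igraph::ecount(net3$graph), 3L)  # one edge per step
  expect_true(all(net3$nodes$total[!net3$nodes$observed] == 0L))
})

test_that("a star-shaped dataset yields a star centred on H1", {
  ht <- collapse_haplotypes(fx$star)
  net <- build_network(ht, limit = 10)
  deg <- igraph::degree(net$graph)
  expect_equal(unname(deg["H1"]), 6)          # centre = commonest haplotype
  expect_equal(sum(net$nodes$observed), 7L)
  expect_equal(igraph::components(net$graph)$no, 1L)
})

test_that("inferred-node count and edge bound hold on simulated data", {
  ht <- collapse_haplotypes(small_sim()$combined)
  limit <- parsimony_connection_limit(length(small_sim()$combined$analyzed))
  net <- build_network(ht, limit)
  hn <- sum(net$nodes$observed)
  ncomp <- igraph::components(net$graph)$no
  expect_gte(igraph::ecount(net$graph), hn - ncomp)   # spanning lower bound
  # every observed node in the table, inferred nodes zero-count
  expect_equal(hn, length(ht$sequences))
  expect_true(all(net$nodes$total[!net$nodes$observed] == 0L))
  # path length between observed haplotypes >= their Hamming distance
  s <- strsplit(ht$sequences[c("H1", "H2")], "")
  hd <- sum(s[[1]] != s[[2]])
  sp <- igraph::distances(net$graph, "H1", "H2")[1, 1]
  if (is.finite(sp)) expect_gte(sp, hd)
})

test_that("the edge set ignores haplotype input order when counts differ", {
  seqs <- c(rep("AAAA", 5L), rep("AAAT", 3L), rep("AATT", 2L), "ATTT")
  x1 <- toy_dataset(seqs, "P1")
  x2 <- toy_dataset(rev(seqs), "P1")
  e1 <- igraph::as_edgelist(build_network(collapse_haplotypes(x1), 6)$graph)
  e2 <- igraph::as_edgelist(build_network(collapse_haplotypes(x2), 6)$graph)
  canon <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_setequal(canon(e1), canon(e2))
})
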