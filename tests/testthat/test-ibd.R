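test_that("great-circle distances match closed forms and geosphere", {
  expect_equal(great_circle_km(31.5, 107, 31.5, 107), 0)
  # antipodal points on the equator: half the circumference
  expect_equal(great_circle_km(0, 0, 0, 180), pi * 6371.0088,
               tolerance = 1e-9)
  expect_error(great_circle_km(95, 0, 0, 0), "range error")
  if (requireNamespace("geosphere", quietly = TRUE)) {
    # two study-like sites (NW vs CE China)
    got <- great_circle_km(36.0, 102.5, 31.8, 117.5)
    ref <- geosphere::distHaversine(c(102.5, 36.0), c(117.5, 31.8),
                                    r = 6371.0088)
    expect_equal(got, ref, tolerance = 5e-3 * ref)
  }
})

test_that("IBD matrices apply the linearising transforms and clamps", {
  phi <- matrix(c(NA, 0.5, 0, 0.5, NA, -0.02, 0, -0.02, NA), 3, 3,
                dimnames = list(c("P1", "P2", "P3"), c("P1", "P2", "P3")))
  meta <- data.frame(sample = c("a", "b", "c"),
                     population = c("P1", "P2", "P3"), region = "R",
                     lat = c(30, 31, 33), lon = c(100, 102, 105))
  mats <- ibd_matrices(phi, meta)
  expect_equal(mats$genetic["P1", "P2"], 1)          # 0.5 / (1 - 0.5)
  expect_equal(mats$genetic["P1", "P3"], 0)          # Fst = 0
  expect_equal(mats$genetic["P2", "P3"], 0)          # negative clamped
  expect_equal(mats$clamped, 1L)
  km <- great_circle_km(30, 100, 31, 102)
  expect_equal(mats$geographic["P1", "P2"], log(km))
})

test_that("Mantel statistic behaves as a correlation", {
  set.seed(2)
  m <- matrix(runif(36), 6, 6); m <- m + t(m); diag(m) <- 0
  expect_equal(mantel_test(m, m, permutations = 99, seed = 1)$r, 1)
  expect_equal(mantel_test(m, 3 * m + 2, permutations = 99, seed = 1)$r, 1)
  expect_error(mantel_test(m, matrix(1, 6, 6) - diag(6) * 0, 99, seed = 1),
               "degenerate")
})

test_that("Mantel p matches exhaustive enumeration over all 4! relabelings", {
  x <- matrix(c(0, 1, 2, 3,
                1, 0, 4, 5,
                2, 4, 0, 6,
                3, 5, 6, 0), 4, 4)
  y <- matrix(c(0, 2, 1, 5,
                2, 0, 3, 4,
                1, 3, 0, 7,
                5, 4, 7, 0), 4, 4)
  lt <- lower.tri(x)
  r_obs <- cor(x[lt], y[lt])
  perms <- list()
  for (p in combinat_perms(4)) {
    yp <- y[p, p]
    perms[[length(perms) + 1L]] <- cor(x[lt], yp[lt])
  }
  exact_p <- mean(unlist(perms) >= r_obs - 1e-12)
  got <- mantel_test(x, y, permutations = 4999, seed = 3)
  expect_equal(got$r, r_obs, tolerance = 1e-12)
  expect_lt(abs(got$p - exact_p), 0.03)
  # vegan reference agrees on the statistic
  if (requireNamespace("vegan", quietly = TRUE)) {
    vg <- vegan::mantel(as.dist(x), as.dist(y), permutations = 99)
    expect_equal(got$r, unname(vg$statistic), tolerance = 1e-10)
  }
})

test_that("Mantel test holds its size under independent matrices", {
  set.seed(11)
  rej <- 0L
  for (i in 1:100) {
    a <- matrix(runif(49), 7, 7); a <- a + t(a); diag(a) <- 0
    b <- matrix(runif(49), 7, 7); b <- b + t(b); diag(b) <- 0
    p <- mantel_test(a, b, permutations = 199, seed = 7000 + i)$p
    rej <- rej + (p <= 0.05)
  }
  # binomial 99% envelope around 0.05 for 100 trials: at most ~11 rejections
  expect_lte(rej, 11L)
})
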