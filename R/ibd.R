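#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere with the IUGG mean Earth radius
#' 6371.0088 km. Vectorised over coordinate pairs.
#'
#' @param lat1,lon1,lat2,lon2 Decimal-degree coordinates.
#' @return Distance(s) in kilometres.
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop("range error: invalid coordinates")
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Isolation-by-distance matrices
#'
#' Builds the two matrices compared in the Mantel test of isolation by
#' distance: linearised genetic distance `Fst / (1 - Fst)` and log
#' geographic distance `ln(km)` between population sites. Each population is
#' assumed to have a single collection site (the coordinates shared by its
#' samples). Negative pairwise Fst values are clamped to genetic distance 0
#' (counted in `clamped`); `Fst >= 1` or coincident sites give `NA` with a
#' warning and the pair is excluded from the test.
#'
#' @param phi Symmetric matrix of pairwise fixation indices labelled by
#'   population.
#' @param meta Sample metadata containing those populations.
#' @return List with `genetic`, `geographic` (matrices), `clamped` (count of
#'   negative-Fst cells set to 0), and `excluded` (count of NA pairs).
#' @export
ibd_matrices <- function(phi, meta) {
  pops <- rownames(phi)
  coord <- unique(meta[c("population", "lat", "lon")])
  if (anyDuplicated(coord$population))
    stop("population with more than one coordinate")
  coord <- coord[match(pops, coord$population), ]
  if (any(is.na(coord$lat)))
    stop("population coordinates missing for: ",
         paste(pops[is.na(coord$lat)], collapse = ", "))
  k <- length(pops)
  gen <- matrix(NA_real_, k, k, dimnames = dimnames(phi))
  geo <- gen
  clamped <- 0L
  excluded <- 0L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { gen[i, j] <- 0; geo[i, j] <- 0; next }
    f <- phi[i, j]
    if (is.na(f) || f >= 1) {
      excluded <- excluded + (i < j)
      if (!is.na(f) && i < j)
        warning("Fst >= 1 for pair ", pops[i], "-", pops[j], "; excluded")
    } else if (f < 0) {
      gen[i, j] <- 0
      clamped <- clamped + (i < j)
    } else gen[i, j] <- f / (1 - f)
    km <- great_circle_km(coord$lat[i], coord$lon[i],
                          coord$lat[j], coord$lon[j])
    if (km <= 0) {
      excluded <- excluded + (i < j)
      if (i < j)
        warning("zero distance between distinct populations ",
                pops[i], "-", pops[j], "; excluded")
    } else geo[i, j] <- log(km)
  }
  list(genetic = gen, geographic = geo, clamped = clamped,
       excluded = excluded)
}

#' Mantel permutation test
#'
#' Pearson correlation between the lower triangles of two distance matrices,
#' with significance from simultaneous row/column permutation of the second
#' matrix. The test is one-tailed for positive association (the direction
#' isolation by distance predicts):
#' `p = (count of permuted r >= observed + 1) / (permutations + 1)`.
#' Cells that are `NA` in either matrix are excluded pairwise.
#'
#' @param x,y Symmetric matrices with identical labels/order.
#' @param permutations Number of permutations (default 10000).
#' @param seed Integer seed (required).
#' @return A `mantel_result` list: `r`, `p`, `permutations`, `seed`, `n`
#'   (matrix order).
#' @export
mantel_test <- function(x, y, permutations = 10000, seed) {
  stopifnot(nrow(x) == ncol(x), all(dim(x) == dim(y)))
  if (!is.null(rownames(x)) && !is.null(rownames(y)) &&
      !identical(rownames(x), rownames(y)))
    stop("matrices must share labels and order")
  n <- nrow(x)
  if (n < 4L) stop("need n >= 4")
  lt <- lower.tri(x)
  ok_base <- !is.na(x) & lt
  r_of <- function(ym) {
    ok <- ok_base & !is.na(ym)
    xv <- x[ok]; yv <- ym[ok]
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
      stop("degenerate (constant) matrix in Mantel test")
    stats::cor(xv, yv)
  }
  r_obs <- r_of(y)
  cnt <- with_seed(seed, {
    sum(vapply(seq_len(permutations), function(b) {
      p <- sample.int(n)
      r_of(y[p, p]) >= r_obs
    }, logical(1)))
  })
  structure(list(r = r_obs, p = (cnt + 1) / (permutations + 1),
                 permutations = permutations, seed = seed, n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$r, x$p, x$permutations, x$n))
  invisible(x)
}

#' Isolation-by-distance analysis
#'
#' Convenience wrapper: builds the `Fst/(1-Fst)` and `ln(km)` matrices from a
#' pairwise Phi-ST matrix and runs the Mantel test.
#'
#' @param phi Pairwise fixation-index matrix (populations).
#' @param meta Sample metadata.
#' @inheritParams mantel_test
#' @return List with `mantel` (a `mantel_result`), `scatter` (data frame of
#'   pair, ln-km, linearised Fst), and the matrices.
#' @export
ibd_test <- function(phi, meta, permutations = 10000, seed) {
  mats <- ibd_matrices(phi, meta)
  res <- mantel_test(mats$geographic, mats$genetic,
                     permutations = permutations, seed = seed)
  pops <- rownames(phi)
  pr <- which(lower.tri(phi), arr.ind = TRUE)
  scatter <- data.frame(
    pair = paste(pops[pr[, 2L]], pops[pr[, 1L]], sep = "-"),
    ln_km = mats$geographic[pr],
    gen_dist = mats$genetic[pr],
    stringsAsFactors = FALSE)
  list(mantel = res, scatter = scatter, genetic = mats$genetic,
       geographic = mats$geographic, clamped = mats$clamped,
       excluded = mats$excluded)
}
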