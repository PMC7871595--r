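#' Pairwise raw nucleotide difference matrix
#'
#' Counts, for every pair of samples, the number of analyzed sites at which
#' they differ (the p-distance numerator; no substitution-model correction).
#' These counts are used directly as squared distances by [amova()].
#'
#' @param x A `popgen_data`.
#' @return A symmetric numeric matrix with a zero diagonal, labelled by
#'   sample id, with attribute `metric = "raw_differences"`.
#' @export
pairwise_distance_matrix <- function(x) {
  stopifnot(inherits(x, "popgen_data"))
  m <- pg_mat(x)
  if (nrow(m) < 2L) stop("need at least 2 samples")
  L <- ncol(m)
  match_ct <- matrix(0, nrow(m), nrow(m))
  for (b in BASES) {
    ind <- (m == b) * 1
    match_ct <- match_ct + tcrossprod(ind)
  }
  d <- L - match_ct
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  attr(d, "metric") <- "raw_differences"
  d
}

# Core per-group diversity computation on an analyzed-site matrix.
group_diversity <- function(m) {
  N <- nrow(m)
  if (N < 2L) stop("insufficient sample: need N >= 2")
  L <- ncol(m)
  key <- apply(m, 1L, paste, collapse = "")
  tab <- table(key)
  p <- as.numeric(tab) / N
  Hd <- N / (N - 1) * (1 - sum(p^2))
  nstate <- apply(m, 2L, function(col) length(unique(col)))
  S <- sum(nstate >= 2L)
  match_ct <- matrix(0, N, N)
  for (b in BASES) {
    ind <- (m == b) * 1
    match_ct <- match_ct + tcrossprod(ind)
  }
  d <- L - match_ct
  k <- sum(d[upper.tri(d)]) / choose(N, 2)
  list(N = N, S = S, Hn = length(tab), Hd = Hd, k = k,
       pi = k / L, analyzed_sites = L)
}

#' Diversity statistics per group
#'
#' Computes, for each population, each region and the pooled total: sample
#' size N, segregating sites S, haplotype number Hn, haplotype diversity Hd
#' (Nei's unbiased form, \eqn{Hd = N/(N-1)(1 - \sum p_h^2)}), mean pairwise
#' nucleotide differences k, and nucleotide diversity \eqn{\pi = k/L} over the
#' analyzed sites.
#'
#' @param x A `popgen_data`.
#' @param level One of `"population"`, `"region"`, `"total"`, or `"all"`
#'   (populations, then regions, then the pooled total row).
#' @return A data frame with one row per group (columns `group`, `level`,
#'   `region`, `N`, `S`, `Hn`, `Hd`, `pi`, `k`).
#' @export
diversity_stats <- function(x, level = c("all", "population", "region", "total")) {
  level <- match.arg(level)
  m <- pg_mat(x)
  p2r <- unique(x$meta[c("population", "region")])
  rows <- list()
  grab <- function(idx, name, lev, region) {
    st <- group_diversity(m[idx, , drop = FALSE])
    data.frame(group = name, level = lev, region = region,
               N = st$N, S = st$S, Hn = st$Hn, Hd = st$Hd,
               pi = st$pi, k = st$k, stringsAsFactors = FALSE)
  }
  if (level %in% c("all", "population"))
    for (p in unique(x$meta$population))
      rows[[length(rows) + 1L]] <-
        grab(x$meta$population == p, p, "population",
             p2r$region[p2r$population == p])
  if (level %in% c("all", "region"))
    for (r in unique(x$meta$region))
      rows[[length(rows) + 1L]] <-
        grab(x$meta$region == r, r, "region", r)
  if (level %in% c("all", "total"))
    rows[[length(rows) + 1L]] <-
      grab(rep(TRUE, nrow(m)), "Total", "total", NA_character_)
  do.call(rbind, rows)
}

#' Tajima's D
#'
#' The normalised difference between the pairwise-difference and
#' segregating-site estimators of theta (Tajima 1989):
#' \deqn{D = (k - S/a_1) / \sqrt{e_1 S + e_2 S (S - 1)}}
#' with the standard constants computed from the sample size.
#'
#' @param S Number of segregating sites.
#' @param N Sample size (>= 4).
#' @param k Mean pairwise nucleotide differences.
#' @return The statistic, or `NA` (with attribute `undefined = TRUE`) when
#'   `S == 0`.
#' @export
tajimas_d <- function(S, N, k) {
  if (N < 4) stop("Tajima's D requires N >= 4")
  if (S == 0) return(structure(NA_real_, undefined = TRUE))
  i <- seq_len(N - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (N + 1) / (3 * (N - 1))
  b2 <- 2 * (N^2 + N + 3) / (9 * N * (N - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (N + 2) / (a1 * N) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# log unsigned Stirling numbers of the first kind, row n: log|s(n, 1..n)|.
log_stirling1_row <- function(n) {
  row <- 0   # |s(1,1)| = 1
  if (n == 1L) return(row)
  for (m in seq_len(n - 1L)) {
    # |s(m+1,k)| = m*|s(m,k)| + |s(m,k-1)|
    up <- c(-Inf, row)                     # shift: |s(m, k-1)|
    stay <- c(row, -Inf) + log(m)          # m * |s(m, k)|
    mx <- pmax(up, stay)
    row <- mx + log(exp(up - mx) + exp(stay - mx))
    row[!is.finite(mx)] <- -Inf
  }
  row
}

#' Fu's Fs
#'
#' Computes \eqn{S' = P(K \ge k_0 \mid \theta)} under the Ewens sampling
#' formula, with allele-count probabilities
#' \eqn{P(K = j) = |s(N, j)| \theta^j / (\theta)_N} (unsigned Stirling numbers
#' of the first kind, rising factorial denominator), all in log space, and
#' returns \eqn{F_s = \ln(S' / (1 - S'))}. Theta is conventionally estimated
#' by the mean pairwise differences k.
#'
#' @param N Sample size.
#' @param k0 Observed number of alleles (haplotypes).
#' @param theta Scaled mutation parameter (> 0), typically k.
#' @return List with `Fs`, `S_prime`, and logical `undefined` (set when
#'   `theta <= 0` or when S' is exactly 0 or 1, e.g. `k0 = 1`).
#' @export
fu_fs <- function(N, k0, theta) {
  stopifnot(N >= 2, k0 >= 1, k0 <= N)
  if (!is.finite(theta) || theta <= 0)
    return(list(Fs = NA_real_, S_prime = NA_real_, undefined = TRUE))
  ls <- log_stirling1_row(N)
  j <- seq_len(N)
  logp <- ls + j * log(theta) - sum(log(theta + 0:(N - 1)))
  log_ge <- logsumexp(logp[j >= k0])    # log S'
  log_lt <- if (k0 > 1) logsumexp(logp[j < k0]) else -Inf  # log(1 - S')
  if (!is.finite(log_lt)) {
    warning("S' = 1 (every sample has at least k0 alleles); Fs undefined")
    return(list(Fs = NA_real_, S_prime = 1, undefined = TRUE))
  }
  list(Fs = log_ge - log_lt, S_prime = exp(log_ge), undefined = FALSE)
}

#' Neutrality tests with coalescent simulation p-values
#'
#' Computes Tajima's D and Fu's Fs for a group of sequences and their
#' p-values from `reps` neutral constant-size coalescent simulations of the
#' same sample size conditioned on the observed \eqn{\hat\theta = k}
#' (infinite-sites mutation). For both statistics the p-value is the fraction
#' of simulated values less than or equal to the observed one (one-tailed for
#' the negative, expansion-side alternative).
#'
#' @param x A `popgen_data` (or subset via `samples`).
#' @param samples Optional sample ids/indices defining the group.
#' @param reps Number of coalescent replicates (>= 100; default 1000).
#' @param seed Integer seed (required).
#' @return A `neutrality_result` list: `N`, `S`, `k`, `Hn`, `D`, `p_D`, `Fs`,
#'   `p_Fs`, `reps`, `seed`.
#' @export
neutrality_test <- function(x, samples = NULL, reps = 1000, seed) {
  if (reps < 100) stop("reps must be >= 100")
  if (!is.null(samples)) x <- pg_subset(x, samples)
  st <- group_diversity(pg_mat(x))
  D <- tajimas_d(st$S, st$N, st$k)
  Fs <- fu_fs(st$N, st$Hn, st$k)$Fs
  if (st$S == 0) {
    return(structure(list(N = st$N, S = 0L, k = 0, Hn = st$Hn,
                          D = NA_real_, p_D = NA_real_,
                          Fs = NA_real_, p_Fs = NA_real_,
                          reps = reps, seed = seed),
                     class = "neutrality_result"))
  }
  sims <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      s <- simulate_neutral_coalescent(st$N, st$k)
      simD <- if (s$S == 0) NA_real_ else tajimas_d(s$S, st$N, s$k)
      simFs <- if (s$k <= 0) NA_real_ else {
        f <- fu_fs(st$N, s$hap_n, s$k)
        if (isTRUE(f$undefined)) Inf else f$Fs
      }
      c(simD, simFs)
    }, numeric(2))
  })
  p_D <- if (is.na(D)) NA_real_ else mean(sims[1L, !is.na(sims[1L, ])] <= D)
  p_Fs <- if (is.na(Fs)) NA_real_ else mean(sims[2L, !is.na(sims[2L, ])] <= Fs)
  structure(list(N = st$N, S = st$S, k = st$k, Hn = st$Hn,
                 D = D, p_D = p_D, Fs = Fs, p_Fs = p_Fs,
                 reps = reps, seed = seed),
            class = "neutrality_result")
}

#' @export
print.neutrality_result <- function(x, ...) {
  cat(sprintf("neutrality_result (N = %d, S = %d, k = %.3f, Hn = %d)\n",
              x$N, x$S, x$k, x$Hn))
  cat(sprintf("  Tajima's D = %s (p = %s)   Fu's Fs = %s (p = %s)  [%d coalescent reps]\n",
              format(round(x$D, 3)), format(round(x$p_D, 4)),
              format(round(x$Fs, 3)), format(round(x$p_Fs, 4)), x$reps))
  invisible(x)
}

#' Diversity and neutrality table
#'
#' A Table-1-style summary: per population, per region and pooled total rows
#' of diversity indices with neutrality statistics and simulation p-values.
#'
#' @inheritParams neutrality_test
#' @return Data frame with columns `group`, `level`, `region`, `N`, `S`,
#'   `Hn`, `Hd`, `pi`, `k`, `D`, `p_D`, `Fs`, `p_Fs`.
#' @export
diversity_neutrality_table <- function(x, reps = 1000, seed) {
  div <- diversity_stats(x, "all")
  res <- lapply(seq_len(nrow(div)), function(i) {
    idx <- switch(div$level[i],
                  population = which(x$meta$population == div$group[i]),
                  region = which(x$meta$region == div$group[i]),
                  total = seq_len(nrow(x$meta)))
    nt <- neutrality_test(x, idx, reps = reps,
                          seed = derive_seed(seed, paste0("nt-", div$group[i])))
    data.frame(D = nt$D, p_D = nt$p_D, Fs = nt$Fs, p_Fs = nt$p_Fs)
  })
  cbind(div, do.call(rbind, res))
}
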