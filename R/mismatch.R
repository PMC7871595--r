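# Mismatch distributions and the sudden-expansion (two-epoch) model.
#
# The expected pairwise-difference spectrum under an instantaneous expansion
# at mutational time tau from theta0 to theta1 follows from the pairwise
# coalescence-time density: with hazard 1/theta1 until tau and 1/theta0
# beyond, and Poisson(x) differences given coalescence at mutational time x,
#   F_j = Fhat_j(theta1) * P(Gamma(j+1) <= tau (1+theta1)/theta1)
#         + exp(-tau (1+theta1)/theta1) * sum_{m=0}^{j} dpois(j-m, tau) *
#           e^{tau} ... (computed below with regularised incomplete gammas
#           and Poisson weights; reduces to the equilibrium geometric-like
#           spectrum Fhat_j(theta) = theta^j / (1+theta)^{j+1} when tau = 0
#           or theta0 = theta1).

#' Expected mismatch spectrum under sudden expansion
#'
#' Probability of observing j pairwise differences under the
#' Rogers-Harpending sudden-expansion model with parameters `tau`, `theta0`
#' (pre-expansion) and `theta1` (post-expansion).
#'
#' @param j Non-negative integer difference counts (vectorised).
#' @param tau Expansion time in mutational units (>= 0).
#' @param theta0,theta1 Scaled mutation parameters (>= 0; `theta1 > 0`).
#' @return Probabilities `F_j`; sums to 1 over `j = 0, 1, 2, ...`.
#' @export
expected_mismatch <- function(j, tau, theta0, theta1) {
  stopifnot(all(j >= 0), tau >= 0, theta0 >= 0, theta1 > 0)
  jmax <- max(j)
  jj <- 0:jmax
  eq <- function(th, v) {   # theta^v / (1+theta)^(v+1), log-space for large v
    if (th == 0) as.numeric(v == 0)
    else exp(v * log(th) - (v + 1) * log1p(th))
  }
  a <- (1 + theta1) / theta1
  recent <- eq(theta1, jj) * stats::pgamma(tau * a, shape = jj + 1)
  pois <- stats::dpois(jj, tau)           # tau^v e^-tau / v!
  old_eq <- eq(theta0, jj)
  conv <- vapply(jj, function(v)
    sum(pois[1:(v + 1)] * old_eq[(v + 1):1]), numeric(1))
  f <- recent + exp(-tau / theta1) * conv
  f[match(j, jj)]
}

#' Observed mismatch distribution
#'
#' Histogram of all pairwise difference counts among a group of sequences,
#' normalised to frequencies, on support `0..max`.
#'
#' @param x A `popgen_data` (or a pairwise difference matrix).
#' @param samples Optional sample subset.
#' @return Numeric vector of frequencies named `"0", "1", ...`; sums to 1.
#' @export
mismatch_observed <- function(x, samples = NULL) {
  if (inherits(x, "popgen_data")) {
    if (!is.null(samples)) x <- pg_subset(x, samples)
    if (nrow(x$seq) < 3L) stop("need N >= 3 sequences")
    d <- pairwise_distance_matrix(x)
  } else d <- x
  v <- d[lower.tri(d)]
  tab <- tabulate(v + 1L, nbins = max(v) + 1L)
  stats::setNames(tab / sum(tab), 0:max(v))
}

# SSD between an observed spectrum (named frequencies) and the model
# expectation over the observed support.
mismatch_ssd <- function(obs, tau, theta0, theta1) {
  j <- as.integer(names(obs))
  sum((obs - expected_mismatch(j, tau, theta0, theta1))^2)
}

#' Harpending's raggedness index
#'
#' \eqn{r = \sum_{j=1}^{d+1} (f_j - f_{j-1})^2} over the observed spectrum,
#' with the frequency beyond the support taken as 0. Smooth unimodal
#' (expansion-like) spectra give small values.
#'
#' @param obs Observed mismatch frequencies (vector over `0..d`).
#' @return The raggedness index.
#' @export
raggedness <- function(obs) {
  f <- c(as.numeric(obs), 0)
  sum(diff(f)^2)
}

#' Fit the sudden-expansion model to a mismatch spectrum
#'
#' Minimises the sum of squared deviations (SSD) between the observed
#' spectrum and the model expectation by bounded nonlinear least squares
#' (`optim` L-BFGS-B) from a deterministic grid of starting points.
#' `theta1` is bounded above at 99999, the conventional cap, and may sit on
#' that bound.
#'
#' @param obs Observed mismatch frequencies (from [mismatch_observed()]), or
#'   a `popgen_data` from which they are computed.
#' @param theta1_max Upper bound for `theta1` (default 99999).
#' @param starts Optional matrix/data frame of starting points
#'   `(tau, theta0, theta1 - theta0)`; by default a deterministic grid spread
#'   around the spectrum mean. Bootstrap refits pass the parent fit here.
#' @return A `mismatch_fit` list: `observed`, `tau`, `theta0`, `theta1`,
#'   `SSD`, `raggedness`, `fitted` (expected frequencies on the observed
#'   support), `convergence`, `starts` (grid SSDs).
#' @export
fit_sudden_expansion <- function(obs, theta1_max = 99999, starts = NULL) {
  if (inherits(obs, "popgen_data")) obs <- mismatch_observed(obs)
  j <- as.integer(names(obs))
  if (is.null(names(obs))) { j <- seq_along(obs) - 1L; names(obs) <- j }
  mean_d <- sum(j * obs)
  objective <- function(par) {
    tau <- par[1L]
    th0 <- max(par[2L], 0)
    th1 <- min(max(th0 + par[3L], 1e-8), theta1_max)
    v <- mismatch_ssd(obs, tau, th0, th1)
    if (!is.finite(v)) 1e10 else v
  }
  # no variation: the no-expansion point mass limit
  if (mean_d == 0)
    return(structure(list(observed = obs, tau = 0, theta0 = 0,
                          theta1 = theta1_max, SSD = 0,
                          raggedness = raggedness(obs),
                          fitted = expected_mismatch(j, 0, 0, theta1_max),
                          convergence = 0L, starts = NULL),
                     class = "mismatch_fit"))
  if (is.null(starts)) {
    tau_grid <- unique(pmax(0.05, c(0.5, mean_d / 2, mean_d, 2 * mean_d)))
    th0_grid <- c(0.01, max(0.1, mean_d / 4))
    starts <- expand.grid(tau = tau_grid, th0 = th0_grid, dth = c(10, 1000))
  }
  starts <- as.matrix(starts)
  best <- NULL
  start_ssd <- numeric(nrow(starts))
  for (i in seq_len(nrow(starts))) {
    p0 <- as.numeric(starts[i, ])
    start_ssd[i] <- objective(p0)
    fit <- try(stats::optim(p0, objective, method = "L-BFGS-B",
                            lower = c(0, 0, 0),
                            upper = c(10 * max(j) + 10, theta1_max,
                                      theta1_max)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("fit error: sudden-expansion optimisation failed at every start")
  tau <- max(best$par[1L], 0)
  th0 <- max(best$par[2L], 0)
  th1 <- min(max(th0 + best$par[3L], 1e-8), theta1_max)
  structure(list(observed = obs, tau = tau, theta0 = th0, theta1 = th1,
                 SSD = best$value, raggedness = raggedness(obs),
                 fitted = expected_mismatch(j, tau, th0, th1),
                 convergence = best$convergence, starts = start_ssd),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf("Sudden-expansion mismatch fit: tau = %.3f, theta0 = %.3f, theta1 = %.3f\n",
              x$tau, x$theta0, x$theta1))
  cat(sprintf("  SSD = %.5f, raggedness = %.5f, support 0..%s\n",
              x$SSD, x$raggedness, utils::tail(names(x$observed), 1L)))
  if (!is.null(x$p_SSD))
    cat(sprintf("  bootstrap: p_SSD = %.4g, p_rag = %.4g (%d reps)\n",
                x$p_SSD, x$p_rag, x$bootstrap_reps))
  invisible(x)
}

#' @export
coef.mismatch_fit <- function(object, ...) {
  c(tau = object$tau, theta0 = object$theta0, theta1 = object$theta1)
}

#' @export
fitted.mismatch_fit <- function(object, ...) object$fitted

#' @export
residuals.mismatch_fit <- function(object, ...) {
  as.numeric(object$observed) - object$fitted
}

#' @export
plot.mismatch_fit <- function(x, main = "Mismatch distribution", ...) {
  j <- as.integer(names(x$observed))
  graphics::plot(j, as.numeric(x$observed), type = "h", lwd = 3,
                 col = "grey60", xlab = "Pairwise differences",
                 ylab = "Frequency", main = main, ...)
  graphics::lines(j, x$fitted, col = "red3", lwd = 2)
  graphics::legend("topright", legend = c("observed", "expected (model)"),
                   col = c("grey60", "red3"), lwd = c(3, 2), bty = "n")
  invisible(x)
}

#' Goodness of fit of the sudden-expansion model
#'
#' Parametric bootstrap: simulates `reps` coalescent samples of size `n`
#' under the fitted two-epoch history, refits the model to each simulated
#' spectrum, and compares the simulated SSD and raggedness values with the
#' observed ones; `p = (count simulated >= observed + 1) / (reps + 1)`.
#'
#' @param fit A `mismatch_fit`.
#' @param n Sample size of the group the spectrum came from.
#' @param reps Bootstrap replicates (default 1000; < 100 warns).
#' @param seed Integer seed (required).
#' @return The fit, augmented with `p_SSD`, `p_rag`, `bootstrap_reps`,
#'   `seed`.
#' @export
ssd_raggedness_test <- function(fit, n, reps = 1000, seed) {
  stopifnot(inherits(fit, "mismatch_fit"), n >= 3)
  if (reps < 100) warning("fewer than 100 bootstrap replicates")
  th0 <- max(fit$theta0, 1e-3)
  th1 <- max(fit$theta1, th0)
  sims <- with_seed(seed, {
    vapply(seq_len(reps), function(b) {
      s <- simulate_two_epoch(n, fit$tau, th0, th1)
      cc <- vapply(s$mutations, length, integer(1))
      v <- if (length(cc)) {
        mm <- mutation_matrix(s$mutations, n)
        dd <- as.matrix(stats::dist(mm, method = "manhattan"))
        dd[lower.tri(dd)]
      } else rep(0, choose(n, 2))
      tab <- tabulate(v + 1L, nbins = max(v) + 1L)
      obs_b <- stats::setNames(tab / sum(tab), 0:max(v))
      mean_b <- mean(v)
      fit_b <- fit_sudden_expansion(obs_b, starts = rbind(
        c(fit$tau, max(fit$theta0, 0.01), max(fit$theta1 - fit$theta0, 1)),
        c(max(mean_b, 0.05), 0.01, 1000)))
      c(fit_b$SSD, raggedness(obs_b))
    }, numeric(2))
  })
  fit$p_SSD <- (sum(sims[1L, ] >= fit$SSD) + 1) / (reps + 1)
  fit$p_rag <- (sum(sims[2L, ] >= fit$raggedness) + 1) / (reps + 1)
  fit$bootstrap_reps <- reps
  fit$seed <- seed
  fit
}

#' Expansion time from tau
#'
#' Converts the mutational expansion index via \eqn{t = \tau / (2 \mu L)}
#' (from \eqn{\tau = 2 \mu L t}), where `rate` is the substitution rate per
#' site per year and `L` the number of sites. A divergence rate quoted as
#' "2.3% per million years" enters as `rate = 2.3e-8`.
#'
#' @param tau Expansion index in mutational units (>= 0).
#' @param rate Substitution rate per site per year (> 0).
#' @param L Sequence length in sites (> 0).
#' @return List with `years` and `ka` (thousands of years; unrounded — round
#'   for reporting).
#' @export
expansion_time <- function(tau, rate, L) {
  if (any(tau < 0) || rate <= 0 || L <= 0)
    stop("range error: tau must be >= 0 and rate, L > 0")
  years <- tau / (2 * rate * L)
  list(years = years, ka = years / 1000)
}
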