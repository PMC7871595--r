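# Hierarchical analysis of molecular variance on squared inter-individual
# molecular distances (Excoffier-Smouse-Quattro framework): sums of squares
# from distance-matrix block sums, method-of-moments variance components with
# unequal group sizes, Phi-statistics, and permutation significance tests.

# Sum over groups of (1/n_g) * sum_{i<j in g} d2_ij, via block sums.
ss_within_groups <- function(d2, grouping) {
  g <- as.integer(factor(grouping))
  block <- rowsum(t(rowsum(d2, g)), g)   # group x group sums of d2
  n_g <- tabulate(g)
  sum(diag(block) / (2 * n_g))
}

amova_components <- function(d2, pop, region = NULL) {
  N <- nrow(d2)
  ss_total <- sum(d2) / (2 * N)
  ss_wp <- ss_within_groups(d2, pop)
  n_p <- as.integer(table(pop))
  P <- length(n_p)
  if (is.null(region)) {
    df_ap <- P - 1L
    df_wp <- N - P
    ss_ap <- ss_total - ss_wp
    ms_wp <- ss_wp / df_wp
    ms_ap <- ss_ap / df_ap
    n_c <- (N - sum(n_p^2) / N) / df_ap
    sigma_c <- ms_wp
    sigma_a <- (ms_ap - ms_wp) / n_c
    tot <- sigma_a + sigma_c
    list(design = "one-level",
         df = c(among_populations = df_ap, within_populations = df_wp),
         SS = c(among_populations = ss_ap, within_populations = ss_wp),
         sigma2 = c(among = sigma_a, within = sigma_c),
         percent = 100 * c(sigma_a, sigma_c) / tot,
         indices = c(F_ST = sigma_a / tot))
  } else {
    reg_of_pop <- tapply(as.character(region), pop, function(z) z[1L])
    G <- length(unique(region))
    if (G < 2L) stop("design error: two-level AMOVA needs >= 2 regions")
    df_ag <- G - 1L
    df_ap <- P - G
    df_wp <- N - P
    ss_wg <- ss_within_groups(d2, region)
    ss_ag <- ss_total - ss_wg
    ss_ap <- ss_wg - ss_wp
    ms_wp <- ss_wp / df_wp
    ms_ap <- ss_ap / df_ap
    ms_ag <- ss_ag / df_ag
    n_g <- as.integer(table(region))
    # A = sum over regions of (sum of n_p^2 within region) / n_region
    np_by_reg <- split(n_p, as.character(reg_of_pop[names(table(pop))]))
    A <- sum(vapply(np_by_reg, function(np) sum(np^2) / sum(np), numeric(1)))
    n1 <- (N - A) / df_ap
    n2 <- (A - sum(n_p^2) / N) / df_ag
    n3 <- (N - sum(n_g^2) / N) / df_ag
    sigma_c <- ms_wp
    sigma_b <- (ms_ap - sigma_c) / n1
    sigma_a <- (ms_ag - sigma_c - n2 * sigma_b) / n3
    tot <- sigma_a + sigma_b + sigma_c
    list(design = "two-level",
         df = c(among_regions = df_ag, among_populations_within_regions = df_ap,
                within_populations = df_wp),
         SS = c(among_regions = ss_ag,
                among_populations_within_regions = ss_ap,
                within_populations = ss_wp),
         sigma2 = c(among_regions = sigma_a, among_pops = sigma_b,
                    within = sigma_c),
         percent = 100 * c(sigma_a, sigma_b, sigma_c) / tot,
         indices = c(F_CT = sigma_a / tot,
                     F_SC = sigma_b / (sigma_b + sigma_c),
                     F_ST = (sigma_a + sigma_b) / tot))
  }
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions squared inter-individual molecular distances (raw pairwise
#' difference counts, see [pairwise_distance_matrix()]) among hierarchy
#' strata, estimates variance components by method of moments with unequal
#' group sizes, and derives Phi-type fixation indices: `F_ST` for the
#' one-level (populations only) design; `F_CT` (among regions), `F_SC`
#' (among populations within regions) and `F_ST` (within populations) for the
#' two-level design. Significance is assessed by permutation: individuals
#' among all populations for `F_ST`, individuals among populations within
#' their region for `F_SC`, and whole populations among regions for `F_CT`;
#' each p-value is `(count of permuted >= observed + 1) / (permutations + 1)`.
#'
#' @param d Distance matrix of raw pairwise difference counts (used as
#'   squared distances), labelled by sample id.
#' @param meta A `sample_metadata` (or data frame with `sample`,
#'   `population`, `region`) covering the matrix labels.
#' @param design `"one-level"` (populations) or `"two-level"`
#'   (regions/populations).
#' @param region_subset Optional character vector of regions to restrict to
#'   (e.g. a region pair).
#' @param permutations Number of permutations (0 skips testing). Default 1023
#'   for the hierarchical test.
#' @param seed Integer seed (required when `permutations > 0`).
#' @return An `amova_result` with `df`, `SS`, `sigma2`, `percent`, `indices`,
#'   `p_values`, `permutations`, `seed`, and `flags` (e.g. negative variance
#'   components, singleton populations).
#' @export
amova <- function(d, meta, design = c("two-level", "one-level"),
                  region_subset = NULL, permutations = 1023, seed = NULL) {
  design <- match.arg(design)
  ids <- rownames(d)
  m <- meta[match(ids, meta$sample), , drop = FALSE]
  if (any(is.na(m$sample))) stop("distance labels missing from metadata")
  if (!is.null(region_subset)) {
    keep <- m$region %in% region_subset
    d <- d[keep, keep, drop = FALSE]
    m <- m[keep, , drop = FALSE]
  }
  pop <- m$population
  reg <- if (design == "two-level") m$region else NULL
  if (length(unique(pop)) < 2L) stop("design error: need >= 2 populations")
  if (design == "two-level" && length(unique(reg)) < 2L)
    stop("design error: need >= 2 regions in two-level design")
  flags <- character(0)
  if (any(table(pop) < 2L))
    flags <- c(flags, "population with a single sample in within stratum")
  obs <- amova_components(d, pop, reg)
  if (any(obs$sigma2 < 0))
    flags <- c(flags, "negative variance component (reported as-is)")

  p_values <- NULL
  if (permutations > 0) {
    if (is.null(seed)) stop("seed required when permutations > 0")
    idx <- obs$indices
    count <- stats::setNames(numeric(length(idx)), names(idx))
    with_seed(seed, {
      for (b in seq_len(permutations)) {
        if (design == "one-level") {
          perm_pop <- sample(pop)
          st <- amova_components(d, perm_pop)
          count["F_ST"] <- count["F_ST"] +
            isTRUE(st$indices[["F_ST"]] >= idx[["F_ST"]])
        } else {
          # F_ST: individuals among all populations (hierarchy kept)
          sh <- sample(length(pop))
          st <- amova_components(d, pop[sh], reg[sh])
          count["F_ST"] <- count["F_ST"] +
            isTRUE(st$indices[["F_ST"]] >= idx[["F_ST"]])
          # F_SC: individuals among populations within their region
          perm_pop <- pop
          for (r in unique(reg)) {
            i <- which(reg == r)
            perm_pop[i] <- pop[i][sample(length(i))]
          }
          st <- amova_components(d, perm_pop, reg)
          count["F_SC"] <- count["F_SC"] +
            isTRUE(st$indices[["F_SC"]] >= idx[["F_SC"]])
          # F_CT: whole populations among regions
          upops <- unique(pop)
          nreg_of_pop <- tapply(reg, pop, function(z) z[1L])[upops]
          perm_assign <- sample(as.character(nreg_of_pop))
          perm_reg <- perm_assign[match(pop, upops)]
          if (length(unique(perm_reg)) >= 2L) {
            st <- amova_components(d, pop, perm_reg)
            count["F_CT"] <- count["F_CT"] +
              isTRUE(st$indices[["F_CT"]] >= idx[["F_CT"]])
          } else {
            count["F_CT"] <- count["F_CT"] + 1
          }
        }
      }
    })
    p_values <- (count + 1) / (permutations + 1)
  }
  structure(c(obs, list(p_values = p_values, permutations = permutations,
                        seed = seed, flags = flags,
                        N = nrow(d), n_populations = length(unique(pop)))),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA (%s design, N = %d, %d populations)\n",
              x$design, x$N, x$n_populations))
  tab <- data.frame(df = x$df, SS = round(x$SS, 3),
                    percent = round(x$percent, 2))
  print(tab)
  cat("Fixation indices:",
      paste(names(x$indices), round(x$indices, 4), sep = " = ",
            collapse = ", "), "\n")
  if (!is.null(x$p_values))
    cat(sprintf("Permutation p-values (%d permutations): %s\n",
                x$permutations,
                paste(names(x$p_values), signif(x$p_values, 4),
                      sep = " = ", collapse = ", ")))
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Pairwise Phi-ST between populations
#'
#' Each cell is the one-level AMOVA fixation index between one pair of
#' populations, with a permutation test shuffling individuals between the two
#' populations. Small negative estimates are retained.
#'
#' @param d Distance matrix of raw pairwise difference counts.
#' @param meta Sample metadata covering the matrix labels.
#' @param permutations Permutations per pair (default 1000).
#' @param seed Integer seed.
#' @param level Group samples by `"population"` (default) or `"region"`.
#' @return List with `phi_st` (symmetric matrix, `NA` diagonal) and `p`
#'   (matching permutation p-values).
#' @export
pairwise_phi_st <- function(d, meta, permutations = 1000, seed = NULL,
                            level = c("population", "region")) {
  level <- match.arg(level)
  ids <- rownames(d)
  m <- meta[match(ids, meta$sample), , drop = FALSE]
  grp <- if (level == "population") m$population else m$region
  groups <- unique(grp)
  k <- length(groups)
  if (k < 2L) stop("need >= 2 groups")
  phi <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  pv <- phi
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    keep <- grp %in% groups[c(i, j)]
    dd <- d[keep, keep, drop = FALSE]
    gg <- grp[keep]
    obs <- amova_components(dd, gg)$indices["F_ST"]
    phi[i, j] <- phi[j, i] <- obs
    if (!is.finite(obs)) next   # no molecular variance at all in this pair
    if (permutations > 0) {
      if (is.null(seed)) stop("seed required when permutations > 0")
      cnt <- with_seed(derive_seed(seed, paste0("phi-", groups[i], "-", groups[j])), {
        sum(vapply(seq_len(permutations), function(b) {
          isTRUE(amova_components(dd, sample(gg))$indices["F_ST"] >= obs)
        }, logical(1)))
      })
      pv[i, j] <- pv[j, i] <- (cnt + 1) / (permutations + 1)
    }
  }
  list(phi_st = phi, p = pv, permutations = permutations, seed = seed,
       level = level)
}

#' Island-model gene flow from a fixation index
#'
#' Converts a fixation index into effective migrants per generation via
#' `Nm = (1 - Fst) / (4 Fst)`.
#'
#' @param fst Fixation index (vectorised).
#' @return `Nm`; `Inf` when `fst <= 0` (no detectable differentiation) and
#'   `0` when `fst >= 1`, each flagged via the `"flag"` attribute.
#' @export
gene_flow_nm <- function(fst) {
  nm <- ifelse(fst <= 0, Inf, ifelse(fst >= 1, 0, (1 - fst) / (4 * fst)))
  flag <- ifelse(is.na(fst), NA_character_,
                 ifelse(fst <= 0, "infinite-flow",
                        ifelse(fst >= 1, "zero-flow", "")))
  if (any(flag != "", na.rm = TRUE)) attr(nm, "flag") <- flag
  nm
}
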