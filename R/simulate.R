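# Coalescent simulation engine: genealogies, infinite-sites mutations, and
# structured / two-epoch demographies. Time is measured in units of 2N_ref
# generations (haploid reference deme size), so a deme of relative size s
# coalesces pairs at rate 1/s and a mutation parameter theta places
# theta/2 mutations per lineage per unit time (E[pairwise diffs] = theta
# within a size-1 deme at equilibrium).

# Kingman coalescent genealogy for a single panmictic population with a
# piecewise-constant relative size. `epochs`: data.frame(start, size), first
# start must be 0, starts increasing (time measured into the past).
sim_genealogy <- function(n, epochs = data.frame(start = 0, size = 1)) {
  stopifnot(n >= 2, epochs$start[1] == 0, all(diff(epochs$start) > 0))
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  active <- seq_len(n)
  nxt <- n + 1L
  t <- 0
  ep <- 1L
  n_ep <- nrow(epochs)
  while (length(active) > 1L) {
    i <- length(active)
    rate <- choose(i, 2) / epochs$size[ep]
    wait <- stats::rexp(1L, rate)
    bound <- if (ep < n_ep) epochs$start[ep + 1L] else Inf
    if (t + wait > bound) { t <- bound; ep <- ep + 1L; next }
    t <- t + wait
    pair <- sample.int(i, 2L)
    parent[active[pair]] <- nxt
    node_time[nxt] <- t
    active <- c(active[-pair], nxt)
    nxt <- nxt + 1L
  }
  list(n = n, parent = parent, node_time = node_time)
}

# Leaf sets per node (list over nodes 1..2n-1 of integer leaf indices).
genealogy_leafsets <- function(gen) {
  n_nodes <- length(gen$parent)
  sets <- vector("list", n_nodes)
  for (i in seq_len(gen$n)) sets[[i]] <- i
  for (v in (gen$n + 1L):n_nodes) sets[[v]] <- integer(0)
  # children always get smaller ids than their parent, so one ascending pass
  # accumulates complete leaf sets
  for (v in seq_len(n_nodes - 1L)) {
    p <- gen$parent[v]
    if (p > 0L) sets[[p]] <- c(sets[[p]], sets[[v]])
  }
  sets
}

# Drop infinite-sites mutations on a genealogy: returns a list of integer
# leaf-index vectors, one per mutation (the derived carriers).
drop_mutations <- function(gen, theta) {
  n_nodes <- length(gen$parent)
  sets <- genealogy_leafsets(gen)
  muts <- list()
  for (v in seq_len(n_nodes)) {
    p <- gen$parent[v]
    if (p == 0L) next
    len <- gen$node_time[p] - gen$node_time[v]
    nm <- stats::rpois(1L, theta / 2 * len)
    if (nm > 0L) muts <- c(muts, rep(list(sets[[v]]), nm))
  }
  muts
}

# Binary (sample x mutation) matrix from a mutation list.
mutation_matrix <- function(muts, n) {
  if (!length(muts)) return(matrix(0L, n, 0L))
  m <- matrix(0L, n, length(muts))
  for (j in seq_along(muts)) m[muts[[j]], j] <- 1L
  m
}

# Summary statistics straight from the mutation list (no sequences needed).
mutation_summaries <- function(muts, n) {
  S <- length(muts)
  if (!S) return(list(S = 0L, k = 0, hap_n = 1L))
  cc <- vapply(muts, length, integer(1))
  k <- sum(cc * (n - cc)) / choose(n, 2)
  mm <- mutation_matrix(muts, n)
  hap_n <- nrow(unique(mm))
  list(S = S, k = k, hap_n = hap_n)
}

# Map an infinite-sites mutation list onto an L-site AT-biased background.
mutations_to_alignment <- function(muts, n, L, at_bias = 0.70, ids = NULL,
                                   marker = "sim") {
  if (length(muts) > L)
    stop("more mutations (", length(muts), ") than sites (", L,
         "); increase L or lower theta")
  w <- c(A = at_bias / 2, C = (1 - at_bias) / 2,
         G = (1 - at_bias) / 2, T = at_bias / 2)
  anc <- sample(BASES, L, replace = TRUE, prob = w)
  mat <- matrix(rep(anc, each = n), nrow = n)
  pos <- sample.int(L, length(muts))
  for (j in seq_along(muts)) {
    others <- setdiff(BASES, anc[pos[j]])
    mat[muts[[j]], pos[j]] <- sample(others, 1L, prob = w[others])
  }
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(n))
  dimnames(mat) <- list(ids, NULL)
  structure(mat, marker = marker, class = c("dna_alignment", "matrix", "array"))
}

#' Simulate a neutral constant-size coalescent sample
#'
#' Standard n-coalescent with exponential waiting times and infinite-sites
#' mutations placed by a Poisson process on branches. Used as the null engine
#' for neutrality-test p-values and available directly for calibration.
#'
#' @param n Sample size (>= 2).
#' @param theta Scaled mutation parameter (> 0); `E[S] = theta * a1(n)`,
#'   `E[k] = theta`.
#' @param seed Optional integer seed (omit to draw from the ambient RNG
#'   stream, e.g. inside an outer seeded loop).
#' @param L Optional sequence length; when given, sequences are emitted by
#'   mapping mutations onto an AT-biased background.
#' @param at_bias Target A+T fraction of the background (default 0.70).
#' @return List with `S`, `k`, `hap_n`, `mutations` (list of carrier sets)
#'   and, when `L` is given, `alignment` (a `dna_alignment`).
#' @export
simulate_neutral_coalescent <- function(n, theta, seed = NULL, L = NULL,
                                        at_bias = 0.70) {
  stopifnot(n >= 2, theta > 0)
  with_seed(seed, {
    gen <- sim_genealogy(n)
    muts <- drop_mutations(gen, theta)
    out <- mutation_summaries(muts, n)
    out$mutations <- muts
    if (!is.null(L))
      out$alignment <- mutations_to_alignment(muts, n, L, at_bias)
    out
  })
}

#' Simulate a sample under a sudden (two-epoch) expansion
#'
#' Coalescent with an instantaneous size change: the population has scaled
#' mutation parameter `theta1` more recently than the expansion and `theta0`
#' before it, with the switch at mutational time `tau` (so at coalescent time
#' `tau / theta1` in units of the recent size).
#'
#' @param n Sample size.
#' @param tau Expansion time in mutational units (>= 0).
#' @param theta0,theta1 Pre-/post-expansion scaled mutation parameters
#'   (`theta1 >= theta0 > 0`).
#' @inheritParams simulate_neutral_coalescent
#' @return As [simulate_neutral_coalescent()].
#' @export
simulate_two_epoch <- function(n, tau, theta0, theta1, seed = NULL, L = NULL,
                               at_bias = 0.70) {
  stopifnot(n >= 2, tau >= 0, theta0 > 0, theta1 >= theta0)
  with_seed(seed, {
    epochs <- if (tau > 0)
      data.frame(start = c(0, tau / theta1), size = c(1, theta0 / theta1))
    else data.frame(start = 0, size = theta0 / theta1)
    gen <- sim_genealogy(n, epochs)
    muts <- drop_mutations(gen, theta1)
    out <- mutation_summaries(muts, n)
    out$mutations <- muts
    if (!is.null(L))
      out$alignment <- mutations_to_alignment(muts, n, L, at_bias)
    out
  })
}

# Structured-coalescent genealogy: `deme` assigns each sample to a deme;
# `mig` is a deme x deme matrix of backward migration rates per lineage;
# `size_recent`/`size_old` are per-deme relative sizes with an instantaneous
# switch at time `t_switch` (Inf for a single epoch).
sim_structured_genealogy <- function(deme, mig, size_recent,
                                     size_old = size_recent, t_switch = Inf) {
  n <- length(deme)
  n_demes <- nrow(mig)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  lin <- seq_len(n)        # active lineage node ids
  lin_deme <- as.integer(deme)
  nxt <- n + 1L
  t <- 0
  mig_row_tot <- rowSums(mig)
  repeat {
    if (length(lin) == 1L) break
    sizes <- if (t < t_switch) size_recent else size_old
    kd <- tabulate(lin_deme, n_demes)
    coal_rate <- ifelse(kd >= 2L, kd * (kd - 1) / 2 / sizes, 0)
    mig_rate <- mig_row_tot[lin_deme]
    tot <- sum(coal_rate) + sum(mig_rate)
    if (tot <= 0) stop("structured coalescent stalled: zero total rate")
    wait <- stats::rexp(1L, tot)
    if (t < t_switch && t + wait > t_switch) { t <- t_switch; next }
    t <- t + wait
    if (stats::runif(1L) < sum(coal_rate) / tot) {
      d <- sample.int(n_demes, 1L, prob = coal_rate)
      here <- which(lin_deme == d)
      pair <- here[sample.int(length(here), 2L)]
      parent[lin[pair]] <- nxt
      node_time[nxt] <- t
      lin <- c(lin[-pair], nxt)
      lin_deme <- c(lin_deme[-pair], d)
      nxt <- nxt + 1L
    } else {
      i <- sample.int(length(lin), 1L, prob = mig_rate)
      lin_deme[i] <- sample.int(n_demes, 1L, prob = mig[lin_deme[i], ])
    }
  }
  list(n = n, parent = parent, node_time = node_time)
}

#' Simulation configuration for structured datasets
#'
#' Defines the deme layout and demography that [simulate_structured_dataset()]
#' realises. Defaults emulate the 15-population, 3-region sampling design of
#' a two-marker mitochondrial survey: markers of 652 and 421 bp with ~70% A+T,
#' per-population sample sizes between 8 and 37 individuals, stronger
#' within-region than between-region gene flow, and a sudden expansion in the
#' central region.
#'
#' @param regions Region labels.
#' @param pops_per_region Number of populations per region.
#' @param samples_per_population Integer sample sizes (recycled across
#'   populations); defaults to the study-like sizes 34, 34, 24, 30, 30, 35,
#'   30, 8, 32, 37, 21, 34, 26, 31, 31.
#' @param marker_lengths Named integer lengths of the (completely linked)
#'   markers.
#' @param at_bias Target A+T fraction.
#' @param theta Named per-marker scaled mutation parameter of a reference
#'   deme.
#' @param migration_within,migration_between Scaled per-lineage migration
#'   rates, split among same-region / other-region demes.
#' @param migration_model `"hierarchical"` (island model within/between
#'   regions) or `"stepping_stone"` (demes on a line with nearest-neighbour
#'   migration; the canonical isolation-by-distance scenario).
#' @param expansion `NULL`, or `list(region, tau, theta0, theta1)` applying a
#'   sudden expansion to one region's demes (`tau` in mutational units of the
#'   first marker).
#' @param seed Integer seed (mandatory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(regions = c("NW", "CC", "CE"),
                       pops_per_region = c(3, 6, 6),
                       samples_per_population = c(34, 34, 24, 30, 30, 35, 30,
                                                  8, 32, 37, 21, 34, 26, 31, 31),
                       marker_lengths = c(COI = 652, Cytb = 421),
                       at_bias = 0.70,
                       theta = c(COI = 0.30, Cytb = 0.21),
                       migration_within = 5,
                       migration_between = 0.12,
                       migration_model = c("hierarchical", "stepping_stone"),
                       expansion = list(region = "CC", tau = 2.2,
                                        theta0 = 0.02, theta1 = 0.30),
                       seed) {
  migration_model <- match.arg(migration_model)
  stopifnot(length(regions) == length(pops_per_region),
            all(pops_per_region >= 1),
            migration_within >= 0, migration_between >= 0,
            all(theta > 0), at_bias > 0, at_bias < 1)
  if (migration_model == "hierarchical" &&
      migration_within < migration_between)
    stop("config error: within-region migration must be >= between-region")
  if (!is.null(expansion)) {
    stopifnot(expansion$region %in% regions, expansion$tau >= 0,
              expansion$theta0 > 0, expansion$theta1 >= expansion$theta0)
  }
  if (missing(seed)) stop("config error: seed is mandatory")
  n_pops <- sum(pops_per_region)
  samples_per_population <- rep_len(as.integer(samples_per_population), n_pops)
  if (any(samples_per_population < 2))
    stop("config error: each population needs >= 2 samples")
  structure(list(regions = regions, pops_per_region = pops_per_region,
                 samples_per_population = samples_per_population,
                 marker_lengths = marker_lengths, at_bias = at_bias,
                 theta = theta, migration_within = migration_within,
                 migration_between = migration_between,
                 migration_model = migration_model,
                 expansion = expansion, seed = as.integer(seed)),
            class = "sim_config")
}

# Region centres used for synthetic coordinates (decimal degrees); spaced so
# between-region distances exceed within-region deme scatter.
region_centres <- function(k) {
  base <- cbind(lat = c(36.0, 31.5, 31.8, 39.5, 27.0, 41.0),
                lon = c(102.5, 107.0, 117.5, 111.0, 112.0, 122.0))
  base[((seq_len(k) - 1L) %% nrow(base)) + 1L, , drop = FALSE]
}

#' Simulate a structured multi-population dataset
#'
#' Realises a hierarchical island (or stepping-stone) structured coalescent
#' for all sampled individuals, drops infinite-sites mutations independently
#' for each completely linked marker on the single shared genealogy, maps
#' them onto AT-biased sequences, and emits FASTA-ready alignments plus a
#' metadata table with population/region labels and coordinates.
#'
#' @param config A [sim_config()].
#' @return List with `alignments` (named list of `dna_alignment`), `meta`
#'   (a `sample_metadata`), and `config`.
#' @export
simulate_structured_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n_regions <- length(cfg$regions)
  n_pops <- sum(cfg$pops_per_region)
  pop_region <- rep(seq_len(n_regions), cfg$pops_per_region)
  pop_names <- unlist(lapply(seq_len(n_regions), function(r)
    paste0(cfg$regions[r], seq_len(cfg$pops_per_region[r]))))
  sizes_n <- cfg$samples_per_population
  deme_of_sample <- rep(seq_len(n_pops), sizes_n)

  # backward migration matrix
  mig <- matrix(0, n_pops, n_pops)
  if (cfg$migration_model == "hierarchical") {
    for (i in seq_len(n_pops)) for (j in seq_len(n_pops)) {
      if (i == j) next
      same <- pop_region[i] == pop_region[j]
      n_same <- sum(pop_region == pop_region[i]) - 1L
      n_other <- n_pops - 1L - n_same
      mig[i, j] <- if (same) {
        if (n_same > 0) cfg$migration_within / n_same else 0
      } else {
        if (n_other > 0) cfg$migration_between / n_other else 0
      }
    }
  } else {
    # linear stepping stone: nearest-neighbour migration only
    for (i in seq_len(n_pops)) for (j in seq_len(n_pops))
      if (abs(i - j) == 1L) mig[i, j] <- cfg$migration_within / 2
  }

  theta_ref <- cfg$theta[[1L]]
  size_recent <- rep(1, n_pops)
  size_old <- rep(1, n_pops)
  t_switch <- Inf
  if (!is.null(cfg$expansion)) {
    in_reg <- pop_region == match(cfg$expansion$region, cfg$regions)
    size_recent[in_reg] <- cfg$expansion$theta1 / theta_ref
    size_old[in_reg] <- cfg$expansion$theta0 / theta_ref
    t_switch <- cfg$expansion$tau / theta_ref
  }

  with_seed(cfg$seed, {
    gen <- sim_structured_genealogy(deme_of_sample, mig, size_recent,
                                    size_old, t_switch)
    ids <- sprintf("%s_%02d", pop_names[deme_of_sample],
                   unlist(lapply(sizes_n, seq_len)))
    alignments <- lapply(seq_along(cfg$marker_lengths), function(mi) {
      muts <- drop_mutations(gen, cfg$theta[[mi]])
      mutations_to_alignment(muts, gen$n, cfg$marker_lengths[[mi]],
                             cfg$at_bias, ids,
                             marker = names(cfg$marker_lengths)[mi])
    })
    names(alignments) <- names(cfg$marker_lengths)

    if (cfg$migration_model == "stepping_stone") {
      coords <- cbind(lat = rep(32, n_pops),
                      lon = 100 + 2.5 * seq_len(n_pops))
    } else {
      ctr <- region_centres(n_regions)
      coords <- ctr[pop_region, , drop = FALSE]
      coords <- coords + cbind(stats::runif(n_pops, -0.9, 0.9),
                               stats::runif(n_pops, -0.9, 0.9))
    }
    meta <- as_sample_metadata(data.frame(
      sample = ids,
      population = pop_names[deme_of_sample],
      region = cfg$regions[pop_region[deme_of_sample]],
      lat = coords[deme_of_sample, 1L],
      lon = coords[deme_of_sample, 2L],
      stringsAsFactors = FALSE))
    list(alignments = alignments, meta = meta, config = cfg)
  })
}

#' Small deterministic fixture datasets
#'
#' Tiny constructed datasets used throughout the test suite: a star-shaped
#' haplotype configuration, a two-deme fixed difference (Phi-ST = 1), a
#' simulated sudden-expansion deme, and a 9-sample, 3-population AMOVA toy
#' whose sums of squares are checkable by hand.
#'
#' @param seed Integer seed (used only by the simulated expansion fixture).
#' @return Named list of `popgen_data` objects: `star`, `two_deme`,
#'   `expansion`, `amova_toy`.
#' @export
make_fixture_suite <- function(seed = 1) {
  mk <- function(seqs, pops, regions, lat, lon, marker) {
    ids <- sprintf("s%02d", seq_along(seqs))
    aln <- new_alignment(seqs, ids, marker)
    meta <- as_sample_metadata(data.frame(
      sample = ids, population = pops, region = regions,
      lat = lat, lon = lon, stringsAsFactors = FALSE))
    popgen_data(aln, meta)
  }
  centre <- "AAAAAAAAAAAAAAAAAAAA"
  leaves <- vapply(1:6, function(i) {
    s <- strsplit(centre, "")[[1L]]
    s[3L * i] <- "T"
    paste(s, collapse = "")
  }, character(1))
  star <- mk(c(rep(centre, 8L), rep(leaves, each = 2L)),
             "P1", "R1", 30, 100, "star")

  two <- mk(c(rep("AAAAAAAAAA", 5L), rep("TTTAAAAAAA", 5L)),
            rep(c("P1", "P2"), each = 5L), rep(c("R1", "R2"), each = 5L),
            rep(c(30, 34), each = 5L), rep(c(100, 108), each = 5L), "two_deme")

  sim <- simulate_two_epoch(40, tau = 3, theta0 = 0.5, theta1 = 50,
                            seed = derive_seed(seed, "fixture-expansion"),
                            L = 400)
  expa <- popgen_data(sim$alignment, data.frame(
    sample = rownames(sim$alignment), population = "E1", region = "RE",
    lat = 31, lon = 107, stringsAsFactors = FALSE))

  toy <- mk(c("AAAAAA", "AAAAAT", "AAAATT",
              "TTAAAA", "TTAAAT", "TTAATT",
              "GGGGAA", "GGGGAT", "GGGGTT"),
            rep(c("P1", "P2", "P3"), each = 3L),
            rep(c("RA", "RA", "RB"), each = 3L),
            rep(c(30, 30, 35), each = 3L),
            rep(c(100, 101, 110), each = 3L), "amova_toy")

  list(star = star, two_deme = two, expansion = expa, amova_toy = toy)
}
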