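# Shared fixtures, built in code. `fx` holds the deterministic tiny datasets;
# `small_sim()` caches one small structured simulation reused across files.

fx <- make_fixture_suite(seed = 1)

.sim_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.sim_cache$ds)) {
    cfg <- sim_config(regions = c("NW", "CC", "CE"), pops_per_region = c(2, 2, 2),
                      samples_per_population = c(10, 8, 12, 10, 9, 11),
                      marker_lengths = c(COI = 300, Cytb = 200),
                      theta = c(COI = 0.8, Cytb = 0.5),
                      migration_within = 5, migration_between = 0.15,
                      expansion = list(region = "CC", tau = 1.5,
                                       theta0 = 0.05, theta1 = 0.8),
                      seed = 42)
    ds <- simulate_structured_dataset(cfg)
    ds$combined <- popgen_data(
      suppressWarnings(concatenate_loci(ds$alignments$COI, ds$alignments$Cytb)),
      ds$meta)
    .sim_cache$ds <- ds
  }
  .sim_cache$ds
}

# Build a popgen_data from raw sequence strings and population/region labels.
toy_dataset <- function(seqs, pops, regions = "R1", lat = 30, lon = 100,
                        marker = "toy") {
  ids <- sprintf("t%02d", seq_along(seqs))
  n <- length(seqs)
  meta <- data.frame(sample = ids,
                     population = rep_len(pops, n),
                     region = rep_len(regions, n),
                     lat = rep_len(lat, n), lon = rep_len(lon, n),
                     stringsAsFactors = FALSE)
  # one coordinate per population
  meta$lat <- ave(meta$lat, meta$population, FUN = function(z) z[1L])
  meta$lon <- ave(meta$lon, meta$population, FUN = function(z) z[1L])
  popgen_data(popgenmt:::new_alignment(seqs, ids, marker), meta)
}

# All permutations of 1..n (recursive enumeration, for exact Mantel nulls).
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in combinat_perms(n - 1L))
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
  out
}

write_fasta_text <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
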