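#' Collapse sequences into haplotypes
#'
#' Identical sequences over the analyzed sites collapse to one haplotype.
#' Haplotypes are named H1, H2, ... in descending total-count order (ties by
#' first occurrence in input order), so H1 is always the most common variant.
#'
#' @param x A `popgen_data`.
#' @return A `haplotype_table`: list with `sequences` (named character vector
#'   of analyzed-site haplotype strings), `counts` (haplotype x population
#'   integer matrix), `totals` (per-haplotype counts), `assignment` (haplotype
#'   name per sample) and `meta`.
#' @export
collapse_haplotypes <- function(x) {
  stopifnot(inherits(x, "popgen_data"))
  m <- pg_mat(x)
  if (!nrow(m)) stop("empty input: no sequences to collapse")
  key <- apply(m, 1L, paste, collapse = "")
  first <- !duplicated(key)
  uniq <- key[first]
  tot <- as.integer(table(factor(key, levels = uniq)))
  ord <- order(-tot, seq_along(uniq))
  uniq <- uniq[ord]
  nm <- paste0("H", seq_along(uniq))
  names(uniq) <- nm
  assignment <- nm[match(key, uniq)]
  pops <- unique(x$meta$population)
  counts <- table(factor(assignment, levels = nm),
                  factor(x$meta$population, levels = pops))
  counts <- matrix(as.integer(counts), nrow = length(nm),
                   dimnames = list(nm, pops))
  structure(list(sequences = uniq,
                 counts = counts,
                 totals = rowSums(counts),
                 assignment = stats::setNames(assignment, x$meta$sample),
                 meta = x$meta),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d haplotypes from %d samples in %d populations\n",
              length(x$sequences), sum(x$counts), ncol(x$counts)))
  top <- utils::head(x$totals, 5L)
  cat("  top counts:", paste(names(top), top, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Site summary of an alignment
#'
#' Counts variable (segregating) and parsimony-informative sites over the
#' analyzed-site set (columns containing any gap or ambiguity code are
#' excluded, complete-deletion style) and the base composition over all
#' unambiguous bases in the full alignment.
#'
#' @param x A `popgen_data`.
#' @return A `site_summary` list: `S`, `parsimony_informative`,
#'   `analyzed_sites`, `percent_variable` (of the full alignment length, one
#'   decimal), `base_composition` (A,C,G,T frequencies), `at_content`,
#'   `excluded_sites` (indices of non-analyzed columns).
#' @export
site_summary <- function(x) {
  stopifnot(inherits(x, "popgen_data"))
  m <- pg_mat(x)
  if (!nrow(m)) stop("empty input")
  nstate <- apply(m, 2L, function(col) length(unique(col)))
  variable <- nstate >= 2L
  pis <- apply(m, 2L, function(col) {
    tab <- table(col)
    sum(tab >= 2L) >= 2L
  })
  all_bases <- x$seq[x$seq %in% BASES]
  comp <- table(factor(all_bases, levels = BASES))
  comp <- as.numeric(comp) / sum(comp)
  names(comp) <- BASES
  structure(list(S = sum(variable),
                 parsimony_informative = sum(pis & variable),
                 analyzed_sites = ncol(m),
                 percent_variable = fmt_pct(sum(variable) / x$n_sites),
                 base_composition = comp,
                 at_content = comp[["A"]] + comp[["T"]],
                 excluded_sites = setdiff(seq_len(x$n_sites), x$analyzed)),
            class = "site_summary")
}

#' @export
print.site_summary <- function(x, ...) {
  cat(sprintf("site_summary: S = %d (%.1f%% of alignment), %d parsimony-informative, %d analyzed sites\n",
              x$S, x$percent_variable, x$parsimony_informative,
              x$analyzed_sites))
  cat(sprintf("  base composition A=%.3f C=%.3f G=%.3f T=%.3f (A+T = %.1f%%)\n",
              x$base_composition["A"], x$base_composition["C"],
              x$base_composition["G"], x$base_composition["T"],
              100 * x$at_content))
  invisible(x)
}

#' Unique and singleton haplotype counts per group
#'
#' A haplotype is *unique to a group* (population or region) if all its
#' carriers belong to that single group; a *singleton* is carried by exactly
#' one individual. Both counters are reported.
#'
#' @param ht A `haplotype_table`.
#' @param level `"population"` or `"region"`.
#' @return List with `n_haplotypes`, `unique_n`, `unique_percent` (one
#'   decimal), `singleton_n`, `per_group` (data frame of group-unique counts).
#' @export
unique_haplotype_stats <- function(ht, level = c("population", "region")) {
  level <- match.arg(level)
  counts <- ht$counts
  if (level == "region") {
    p2r <- unique(ht$meta[c("population", "region")])
    reg <- p2r$region[match(colnames(counts), p2r$population)]
    counts <- t(rowsum(t(counts), reg))
  }
  ngroups <- rowSums(counts > 0L)
  uniq <- ngroups == 1L
  hn <- nrow(counts)
  group_of <- colnames(counts)[apply(counts, 1L, which.max)]
  per_group <- data.frame(group = colnames(counts),
                          unique_haplotypes = vapply(colnames(counts),
                            function(g) sum(uniq & group_of == g), integer(1)),
                          stringsAsFactors = FALSE)
  list(n_haplotypes = hn,
       unique_n = sum(uniq),
       unique_percent = fmt_pct(sum(uniq) / hn),
       singleton_n = sum(ht$totals == 1L),
       per_group = per_group)
}

#' Haplotype frequency report
#'
#' Per-haplotype carrier counts and their percentage of all individuals
#' (one decimal place).
#'
#' @param ht A `haplotype_table`.
#' @return Data frame with columns `haplotype`, `count`, `percent`.
#' @export
haplotype_frequency_report <- function(ht) {
  n <- sum(ht$totals)
  data.frame(haplotype = names(ht$totals),
             count = as.integer(ht$totals),
             percent = fmt_pct(ht$totals / n),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Coleman rarefaction of haplotype richness
#'
#' Expected number of distinct haplotypes in random subsamples of size g,
#' estimated by seeded random subsampling without replacement, together with
#' the exact (hypergeometric) expectation
#' \deqn{E[S_g] = Hn - \sum_h \binom{N - N_h}{g} / \binom{N}{g}.}
#'
#' @param ht A `haplotype_table`.
#' @param sizes Integer subsample sizes (each in 1..N). Default `1:N`.
#' @param replicates Random subsamples per size (default 1000).
#' @param seed Integer seed (required: the permutation curve is stochastic).
#' @return Data frame with columns `g`, `mean`, `sd`, `expected`.
#' @export
coleman_rarefaction <- function(ht, sizes = NULL, replicates = 1000, seed) {
  tot <- as.integer(ht$totals)
  N <- sum(tot)
  if (is.null(sizes)) sizes <- seq_len(N)
  sizes <- as.integer(sizes)
  if (any(sizes < 1L) || any(sizes > N))
    stop("range error: subsample sizes must be in 1..N")
  # exact hypergeometric expectation (log-scale binomials for stability)
  expected <- vapply(sizes, function(g) {
    miss <- vapply(tot, function(nh) {
      if (N - nh < g) 0 else exp(lchoose(N - nh, g) - lchoose(N, g))
    }, numeric(1))
    length(tot) - sum(miss)
  }, numeric(1))
  labels <- rep.int(seq_along(tot), tot)
  res <- with_seed(seed, {
    vapply(sizes, function(g) {
      draws <- vapply(seq_len(replicates), function(i) {
        length(unique(labels[sample.int(N, g)]))
      }, numeric(1))
      c(mean(draws), stats::sd(draws))
    }, numeric(2))
  })
  data.frame(g = sizes, mean = res[1L, ], sd = res[2L, ], expected = expected)
}

#' Write haplotype outputs
#'
#' Writes the haplotype sequences as FASTA (names H1..Hn) and the haplotype
#' x population count table as CSV.
#'
#' @param ht A `haplotype_table`.
#' @param fasta,csv Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_haplotypes <- function(ht, fasta = NULL, csv = NULL) {
  if (!is.null(fasta))
    seqinr::write.fasta(as.list(ht$sequences), names = names(ht$sequences),
                        file.out = fasta, nbchar = 70)
  if (!is.null(csv)) {
    df <- data.frame(haplotype = rownames(ht$counts), ht$counts,
                     total = ht$totals, check.names = FALSE)
    utils::write.csv(df, csv, row.names = FALSE)
  }
  invisible(c(fasta = fasta, csv = csv))
}
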