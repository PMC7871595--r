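# End-to-end orchestration: load -> concatenate -> haplotypes -> diversity &
# neutrality -> AMOVA designs -> pairwise Phi-ST & Nm -> Mantel IBD ->
# mismatch & expansion dating -> rarefaction -> network, with CSV/figure/JSON
# outputs. A single run seed deterministically derives one seed per
# stochastic stage, so any stage can be reproduced in isolation.

#' Run configuration
#'
#' @param fasta Named character vector/list of per-marker FASTA paths, or
#'   `NULL` when `dataset` is supplied directly to [run_full_analysis()].
#' @param metadata Path to the metadata TSV (with `fasta`).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer run seed (mandatory).
#' @param permutations Permutations for AMOVA/pairwise tests (0 disables all
#'   permutation p-values for a fast deterministic run).
#' @param mantel_permutations Permutations for the Mantel test.
#' @param bootstrap Mismatch bootstrap replicates.
#' @param neutrality_reps Coalescent replicates for neutrality p-values.
#' @param rate Substitution rate per site per year for expansion dating.
#' @param confidence Statistical-parsimony connection confidence.
#' @param rarefaction_replicates Subsampling replicates for rarefaction.
#' @return A `run_config` list.
#' @export
run_config <- function(fasta = NULL, metadata = NULL, out_dir = "popgenmt-out",
                       seed, permutations = 1023,
                       mantel_permutations = 10000, bootstrap = 1000,
                       neutrality_reps = 1000, rate = 2.3e-8,
                       confidence = 0.95, rarefaction_replicates = 1000) {
  if (missing(seed)) stop("seed is mandatory")
  counts <- c(permutations, mantel_permutations, bootstrap, neutrality_reps)
  if (any(counts > 0 & counts < 100))
    warning("replicate/permutation count below 100; p-values will be coarse")
  structure(list(fasta = fasta, metadata = metadata, out_dir = out_dir,
                 seed = as.integer(seed), permutations = permutations,
                 mantel_permutations = mantel_permutations,
                 bootstrap = bootstrap, neutrality_reps = neutrality_reps,
                 rate = rate, confidence = confidence,
                 rarefaction_replicates = rarefaction_replicates),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full analysis workflow
#'
#' Executes every stage of the marker survey on a dataset (either loaded from
#' the config's FASTA/TSV paths, or passed directly as a list with
#' `alignments` and `meta`, e.g. from [simulate_structured_dataset()]):
#' haplotype and site summaries per marker, a diversity/neutrality table
#' (populations, regions, total) on the combined data, hierarchical AMOVA for
#' the all-population, all-region and every region-pair design, pairwise
#' Phi-ST with island-model Nm, Mantel isolation-by-distance, mismatch
#' distributions with sudden-expansion fits, goodness-of-fit bootstraps and
#' expansion dating per region, rarefaction curves, and the statistical-
#' parsimony network. Writes table-shaped CSVs, vector figures (PDF) and a
#' full-precision JSON summary into `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param dataset Optional list with `alignments` (named list of
#'   `dna_alignment`) and `meta`; overrides the config paths.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_full_analysis <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  logf <- function(stage, ...) {
    cat(sprintf("[%s] %s\n", stage, sprintf(...)), file = log_path,
        append = TRUE)
  }
  cat(sprintf("run seed: %d\n", config$seed), file = log_path)
  stage <- "load"
  res <- list(seed = config$seed)
  tryCatch({
    if (is.null(dataset)) {
      if (is.null(config$fasta)) stop("no dataset and no fasta paths")
      alns <- lapply(seq_along(config$fasta), function(i)
        read_alignment(config$fasta[[i]],
                       names(config$fasta)[i] %||% paste0("m", i)))
      names(alns) <- vapply(alns, attr, "", "marker")
      meta <- read_metadata(config$metadata)
    } else {
      alns <- dataset$alignments
      meta <- dataset$meta
    }
    logf(stage, "%d marker(s): %s", length(alns),
         paste(names(alns), collapse = ", "))

    stage <- "concatenate"
    combined_aln <- Reduce(concatenate_loci, alns)
    per_marker <- lapply(alns, popgen_data, meta = meta)
    x <- popgen_data(combined_aln, meta)

    stage <- "haplotypes"
    res$markers <- lapply(per_marker, function(pm) {
      ss <- site_summary(pm)
      ht <- collapse_haplotypes(pm)
      us <- unique_haplotype_stats(ht, "region")
      list(marker = pm$marker, n_sites = pm$n_sites,
           analyzed_sites = ss$analyzed_sites, S = ss$S,
           percent_variable = ss$percent_variable,
           parsimony_informative = ss$parsimony_informative,
           at_content = ss$at_content, Hn = length(ht$sequences),
           unique_region_haplotypes = us$unique_n,
           unique_region_percent = us$unique_percent)
    })
    ht <- collapse_haplotypes(x)
    write_haplotypes(ht, fasta = file.path(out, "haplotypes.fasta"),
                     csv = file.path(out, "haplotype_by_population.csv"))

    stage <- "diversity-neutrality"
    reps <- max(config$neutrality_reps, 100)
    tab1 <- diversity_neutrality_table(x, reps = reps,
                                       seed = derive_seed(config$seed, "neutrality"))
    utils::write.csv(format_table1(tab1), file.path(out, "diversity_neutrality.csv"),
                     row.names = FALSE)
    res$diversity <- tab1
    logf(stage, "neutrality reps = %d", reps)

    stage <- "amova"
    d <- pairwise_distance_matrix(x)
    regions <- unique(x$meta$region)
    designs <- list(list(name = "all_populations", design = "one-level",
                         subset = NULL),
                    list(name = "all_regions", design = "two-level",
                         subset = NULL))
    if (length(regions) >= 2L)
      for (pair in utils::combn(regions, 2L, simplify = FALSE))
        designs[[length(designs) + 1L]] <-
          list(name = paste(pair, collapse = "_vs_"), design = "two-level",
               subset = pair)
    res$amova <- lapply(designs, function(ds) {
      a <- amova(d, x$meta, design = ds$design, region_subset = ds$subset,
                 permutations = config$permutations,
                 seed = derive_seed(config$seed, paste0("amova-", ds$name)))
      keep <- a[c("design", "df", "SS", "sigma2", "percent", "indices",
                  "p_values", "permutations")]
      # named vectors become named lists so JSON keeps the keys
      for (f in c("df", "SS", "sigma2", "indices", "p_values"))
        if (!is.null(keep[[f]])) keep[[f]] <- as.list(keep[[f]])
      c(list(name = ds$name), keep)
    })
    names(res$amova) <- vapply(designs, `[[`, "", "name")
    write_amova_csv(res$amova, file.path(out, "amova.csv"))

    stage <- "pairwise-fst"
    pp <- pairwise_phi_st(d, x$meta, permutations = min(config$permutations, 1000),
                          seed = derive_seed(config$seed, "pairwise"))
    utils::write.csv(round(pp$phi_st, 4), file.path(out, "pairwise_phist.csv"))
    rr <- pairwise_phi_st(d, x$meta, permutations = min(config$permutations, 1000),
                          seed = derive_seed(config$seed, "pairwise-region"),
                          level = "region")
    reg_mat <- rr$phi_st
    nm_mat <- gene_flow_nm(reg_mat)
    fstnm <- reg_mat
    fstnm[upper.tri(fstnm)] <- nm_mat[upper.tri(nm_mat)]
    utils::write.csv(round(fstnm, 3), file.path(out, "region_fst_nm.csv"))
    res$pairwise_phi_st <- pp$phi_st
    res$region_phi_st <- reg_mat
    res$region_nm <- nm_mat

    stage <- "mantel"
    if (length(unique(x$meta$population)) >= 4L) {
      ibd <- ibd_test(pp$phi_st, x$meta,
                      permutations = config$mantel_permutations,
                      seed = derive_seed(config$seed, "mantel"))
      utils::write.csv(ibd$scatter, file.path(out, "ibd_scatter.csv"),
                       row.names = FALSE)
      grDevices::pdf(file.path(out, "ibd_scatter.pdf"), width = 5, height = 5)
      graphics::plot(ibd$scatter$ln_km, ibd$scatter$gen_dist,
                     xlab = "ln(geographic distance, km)",
                     ylab = "Fst / (1 - Fst)", pch = 19, col = "grey30",
                     main = sprintf("IBD: r = %.3f, p = %.4g",
                                    ibd$mantel$r, ibd$mantel$p))
      graphics::abline(stats::lm(gen_dist ~ ln_km, data = ibd$scatter),
                       col = "red3")
      grDevices::dev.off()
      res$mantel <- list(r = ibd$mantel$r, p = ibd$mantel$p,
                         permutations = ibd$mantel$permutations,
                         clamped = ibd$clamped, excluded = ibd$excluded)
    }

    stage <- "mismatch"
    res$mismatch <- list()
    for (r in regions) {
      idx <- which(x$meta$region == r)
      if (length(idx) < 3L) next
      obs <- mismatch_observed(x, idx)
      fit <- fit_sudden_expansion(obs)
      fit <- ssd_raggedness_test(fit, n = length(idx),
                                 reps = config$bootstrap,
                                 seed = derive_seed(config$seed,
                                                    paste0("mismatch-", r)))
      et <- expansion_time(fit$tau, config$rate, length(x$analyzed))
      res$mismatch[[r]] <- list(tau = fit$tau, theta0 = fit$theta0,
                                theta1 = fit$theta1, SSD = fit$SSD,
                                p_SSD = fit$p_SSD, raggedness = fit$raggedness,
                                p_rag = fit$p_rag, t_years = et$years,
                                t_ka = et$ka)
      utils::write.csv(data.frame(differences = as.integer(names(obs)),
                                  observed = as.numeric(obs),
                                  fitted = fit$fitted),
                       file.path(out, paste0("mismatch_", r, ".csv")),
                       row.names = FALSE)
      grDevices::pdf(file.path(out, paste0("mismatch_", r, ".pdf")),
                     width = 5, height = 4)
      plot(fit, main = sprintf("%s: tau = %.2f, p_SSD = %.3f", r, fit$tau,
                               fit$p_SSD))
      grDevices::dev.off()
    }
    write_mismatch_csv(res$mismatch, file.path(out, "mismatch_summary.csv"))

    stage <- "rarefaction"
    N <- sum(ht$totals)
    sizes <- unique(pmin(N, round(seq(1, N, length.out = min(40, N)))))
    rar <- coleman_rarefaction(ht, sizes,
                               replicates = config$rarefaction_replicates,
                               seed = derive_seed(config$seed, "rarefaction"))
    utils::write.csv(rar, file.path(out, "rarefaction.csv"), row.names = FALSE)

    stage <- "network"
    limit <- parsimony_connection_limit(length(x$analyzed), config$confidence)
    net <- build_network(ht, limit)
    write_network(net, graphml = file.path(out, "network.graphml"),
                  dot = file.path(out, "network.dot"),
                  csv = file.path(out, "network_nodes.csv"))
    res$network <- list(limit = limit,
                        observed_nodes = sum(net$nodes$observed),
                        inferred_nodes = length(net$inferred),
                        edges = igraph::ecount(net$graph),
                        components = igraph::components(net$graph)$no)

    stage <- "summary"
    jsonlite::write_json(res, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    logf(stage, "complete")
  }, error = function(e) {
    logf(stage, "ERROR: %s", conditionMessage(e))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}

# Report-layer rounding only (JSON keeps full precision): 3 decimals for
# diversity and fixation indices, 1 decimal for percentages.
format_table1 <- function(tab) {
  tab$Hd <- round(tab$Hd, 3)
  tab$pi <- round(tab$pi, 5)
  tab$k <- round(tab$k, 3)
  tab$D <- round(tab$D, 3)
  tab$Fs <- round(tab$Fs, 3)
  tab
}

write_amova_csv <- function(amova_list, path) {
  rows <- do.call(rbind, lapply(amova_list, function(a) {
    strata <- names(a$df)
    data.frame(design = a$name, stratum = strata, df = as.integer(a$df),
               SS = round(as.numeric(a$SS), 3),
               percent_variation = round(as.numeric(a$percent), 2),
               index = names(a$indices)[seq_along(strata)] %||% NA,
               value = round(as.numeric(a$indices)[seq_along(strata)], 4),
               p = if (!is.null(a$p_values))
                 signif(as.numeric(a$p_values)[seq_along(strata)], 4)
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
}

write_mismatch_csv <- function(mm, path) {
  if (!length(mm)) return(invisible(NULL))
  rows <- do.call(rbind, lapply(names(mm), function(r) {
    m <- mm[[r]]
    data.frame(region = r, tau = round(m$tau, 3),
               theta0 = round(m$theta0, 3), theta1 = round(m$theta1, 3),
               SSD = round(m$SSD, 5), p_SSD = signif(m$p_SSD, 4),
               raggedness = round(m$raggedness, 5),
               p_rag = signif(m$p_rag, 4),
               t_ka = round(m$t_ka), stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
}
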