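# Statistical-parsimony haplotype networks: a probabilistic connection limit
# plus a distance-ordered linking algorithm that expands multi-step links
# through inferred ("missing") intermediate haplotypes.

# log Stirling numbers of the second kind S2(h, 1..h), row h.
log_stirling2_row <- function(h) {
  row <- 0     # S2(1,1) = 1
  if (h == 1L) return(row)
  for (m in seq_len(h - 1L)) {
    # S2(m+1, k) = k S2(m, k) + S2(m, k-1)
    k <- seq_len(m + 1L)
    stay <- c(row, -Inf) + log(k)
    up <- c(-Inf, row)
    mx <- pmax(stay, up)
    row <- mx + log(exp(stay - mx) + exp(up - mx))
    row[!is.finite(mx)] <- -Inf
  }
  row
}

# P(parsimony | j observed differences, L sites): Bayesian multiple-hit
# estimator. With h true substitutions thrown uniformly on L sites, the
# probability that exactly j sites show a change is the occupancy probability
# O(j | h) = C(L, j) S2(h, j) j! / L^h. Under a uniform prior on h >= j,
# parsimony (no superimposed change) has posterior O(j|j) / sum_{h>=j} O(j|h).
parsimony_probability <- function(j, L) {
  if (j == 0L) return(1)
  log_term <- function(h) {
    ls2 <- log_stirling2_row(h)[j]
    lchoose(L, j) + ls2 + lgamma(j + 1) - h * log(L)
  }
  t0 <- log_term(j)
  total <- t0
  h <- j
  repeat {
    h <- h + 1L
    t <- log_term(h)
    total <- logsumexp(c(total, t))
    if (t < total + log(1e-12) || h > j + 200L) break
  }
  exp(t0 - total)
}

#' Statistical-parsimony connection limit
#'
#' Largest number of mutational steps j at which two haplotypes are still
#' connected with probability of parsimony above `confidence`, for an
#' alignment of `L` analyzed sites. The probability of parsimony is the
#' posterior probability that j observed differences arose from exactly j
#' substitutions (no superimposed hits), under uniform placement of
#' substitutions across sites and a uniform prior on their true number.
#'
#' @param L Number of analyzed sites (> 0).
#' @param confidence Required probability of parsimony (default 0.95).
#' @return Integer maximum number of steps (at least 1; equals `L` as
#'   `confidence` approaches 0).
#' @export
parsimony_connection_limit <- function(L, confidence = 0.95) {
  stopifnot(L > 0, confidence > 0, confidence < 1)
  limit <- 0L
  for (j in seq_len(L)) {
    if (parsimony_probability(j, L) > confidence) limit <- j else break
  }
  max(limit, 1L)
}

#' Build a statistical-parsimony haplotype network
#'
#' Joins haplotypes in ascending pairwise-distance order up to the connection
#' limit; a d-step link between two components inserts d-1 inferred
#' ("missing") intermediate nodes, so every edge represents exactly one
#' mutational step. Within equal-distance ties, pairs involving
#' higher-frequency haplotypes are linked first, then lexicographically
#' earlier names; same-component pairs whose distance and tie-break keys
#' exactly match the link that merged their components are added as reported
#' loops.
#'
#' @param ht A `haplotype_table`.
#' @param limit Maximum connection steps (e.g. from
#'   [parsimony_connection_limit()]).
#' @return A `haplotype_network`: list with `graph` (igraph, one edge per
#'   step), `nodes` (data frame: name, observed, total count, per-population
#'   counts), `inferred` (names of intermediate nodes), `loops` (data frame
#'   of reported tie loops), `limit`.
#' @export
build_network <- function(ht, limit) {
  stopifnot(inherits(ht, "haplotype_table"), limit >= 1)
  seqs <- ht$sequences
  hn <- length(seqs)
  nm <- names(seqs)
  tot <- as.numeric(ht$totals)
  edges <- list()
  inferred <- character(0)
  n_inferred <- 0L
  if (hn > 1L) {
    smat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                   nrow = hn, byrow = TRUE)
    dmat <- matrix(0L, hn, hn)
    for (i in seq_len(hn - 1L)) for (j in (i + 1L):hn)
      dmat[i, j] <- dmat[j, i] <- sum(smat[i, ] != smat[j, ])
    pr <- which(upper.tri(dmat), arr.ind = TRUE)
    pd <- dmat[upper.tri(dmat)]
    keep <- pd <= limit & pd >= 1L
    pr <- pr[keep, , drop = FALSE]
    pd <- pd[keep]
    fmax <- pmax(tot[pr[, 1L]], tot[pr[, 2L]])
    fmin <- pmin(tot[pr[, 1L]], tot[pr[, 2L]])
    nm1 <- pmin(nm[pr[, 1L]], nm[pr[, 2L]])
    ord <- order(pd, -fmax, -fmin, nm1)
    comp <- seq_len(hn)                  # union-find (flat)
    merge_key <- list()
    loops <- list()
    for (e in ord) {
      i <- pr[e, 1L]; j <- pr[e, 2L]
      key <- c(pd[e], fmax[e], fmin[e])
      ci <- comp[i]; cj <- comp[j]
      if (ci != cj) {
        comp[comp == cj] <- ci
        merge_key[[paste(sort(c(i, j)), collapse = "-")]] <- key
      } else {
        # loop only when this tie is indistinguishable from the accepted link
        tie <- any(vapply(merge_key, function(kk)
          isTRUE(all(kk == key)), logical(1)))
        if (!tie) next
        loops[[length(loops) + 1L]] <-
          data.frame(from = nm[i], to = nm[j], steps = pd[e])
      }
      # expand the link through pd[e]-1 intermediates
      chain <- nm[i]
      if (pd[e] > 1L) {
        for (s in seq_len(pd[e] - 1L)) {
          n_inferred <- n_inferred + 1L
          inferred <- c(inferred, paste0("m", n_inferred))
          chain <- c(chain, paste0("m", n_inferred))
        }
      }
      chain <- c(chain, nm[j])
      for (s in seq_len(length(chain) - 1L))
        edges[[length(edges) + 1L]] <- c(chain[s], chain[s + 1L])
    }
    loops <- if (length(loops)) do.call(rbind, loops) else
      data.frame(from = character(0), to = character(0),
                 steps = integer(0))
  } else {
    loops <- data.frame(from = character(0), to = character(0),
                        steps = integer(0))
  }
  all_names <- c(nm, inferred)
  nodes <- data.frame(name = all_names,
                      observed = c(rep(TRUE, hn), rep(FALSE, n_inferred)),
                      total = c(ht$totals, rep(0L, n_inferred)),
                      stringsAsFactors = FALSE)
  popc <- rbind(ht$counts,
                matrix(0L, n_inferred, ncol(ht$counts),
                       dimnames = list(inferred, colnames(ht$counts))))
  nodes <- cbind(nodes, as.data.frame(popc))
  rownames(nodes) <- NULL
  el <- if (length(edges)) do.call(rbind, edges) else
    matrix(character(0), ncol = 2L)
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1L], to = el[, 2L], stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  structure(list(graph = g, nodes = nodes, inferred = inferred,
                 loops = loops, limit = limit),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  nc <- igraph::components(x$graph)$no
  cat(sprintf("haplotype_network: %d observed + %d inferred nodes, %d edges, %d component(s), limit %d steps\n",
              sum(x$nodes$observed), length(x$inferred),
              igraph::ecount(x$graph), nc, x$limit))
  if (nrow(x$loops)) cat(sprintf("  %d reported tie loop(s)\n", nrow(x$loops)))
  invisible(x)
}

#' @export
plot.haplotype_network <- function(x, ...) {
  g <- x$graph
  size <- ifelse(x$nodes$observed, 6 + 2 * sqrt(x$nodes$total), 2)
  col <- ifelse(x$nodes$observed, "steelblue", "black")
  igraph::plot.igraph(g, vertex.size = size, vertex.color = col,
                      vertex.label.cex = 0.7, ...)
  invisible(x)
}

#' Export a haplotype network
#'
#' Writes the network graph as GraphML and/or DOT, and the node attribute
#' table (haplotype, total, per-population counts) as CSV.
#'
#' @param net A `haplotype_network`.
#' @param graphml,dot,csv Output paths (any may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_network <- function(net, graphml = NULL, dot = NULL, csv = NULL) {
  if (!is.null(graphml))
    igraph::write_graph(net$graph, graphml, format = "graphml")
  if (!is.null(dot))
    igraph::write_graph(net$graph, dot, format = "dot")
  if (!is.null(csv))
    utils::write.csv(net$nodes, csv, row.names = FALSE)
  invisible(c(graphml = graphml, dot = dot, csv = csv))
}
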