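#' Spearman correlation matrix with permutation p-values
#'
#' Computes the Spearman correlation (Pearson correlation of average ranks,
#' so ties are handled exactly) between all taxon pairs, plus two-sided
#' permutation p-values obtained by permuting one margin's ranks
#' independently for each pair, and a BH adjustment over the upper triangle.
#' Constant taxa have undefined correlations; their entries are `NA` and
#' they can never form edges.
#'
#' @param table relative `abundance_table` (taxa x samples), >= 4 samples.
#' @param n_permutations permutations per pair (default 999).
#' @param seed optional integer seed.
#' @return list with `rho`, `p`, `q` (all taxa x taxa matrices) and
#'   `n_permutations`.
#' @export
spearman_matrix <- function(table, n_permutations = 999, seed = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values
  if (ncol(v) < 4) stop("need >= 4 samples for correlation inference")
  if (nrow(v) < 2) stop("need >= 2 taxa")
  if (!is.null(seed)) set.seed(seed)
  ranks <- t(apply(v, 1, rank))  # average ranks for ties
  res <- spearman_perm_cpp(ranks, as.integer(n_permutations))
  rho <- res$rho; p <- res$p
  dimnames(rho) <- dimnames(p) <- list(rownames(v), rownames(v))
  ut <- upper.tri(p)
  q <- p
  q[ut] <- p.adjust(p[ut], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  list(rho = rho, p = p, q = q, n_permutations = n_permutations)
}

#' Build a co-occurrence network from correlation matrices
#'
#' Nodes pass a prevalence / mean-abundance filter (computed on the same
#' relative table); an undirected signed edge i--j is kept iff
#' `|rho| >= min_abs_rho` and `q <= max_q`. Density, Freeman degree
#' centralization and the connected-component partition are computed over
#' the filtered node set.
#'
#' @param corr result of [spearman_matrix()].
#' @param table the relative `abundance_table` the correlations came from
#'   (used for the node filter); `NULL` skips node filtering.
#' @param min_abs_rho minimal absolute correlation (default 0.3).
#' @param max_q maximal BH-adjusted permutation p (default 0.05).
#' @param min_prevalence minimal fraction of samples in which a taxon is
#'   present (default 0.5).
#' @param min_mean_abundance minimal mean relative abundance (default
#'   0.001).
#' @return a `correlation_network`: `nodes`, `edges` (data.frame `taxon_a`,
#'   `taxon_b`, `rho`, `q`, `sign`), `density`, `centralization`,
#'   `components` (named membership vector).
#' @export
build_network <- function(corr, table = NULL, min_abs_rho = 0.3,
                          max_q = 0.05, min_prevalence = 0.5,
                          min_mean_abundance = 0.001) {
  rho <- corr$rho
  q <- corr$q
  nodes <- rownames(rho)
  if (!is.null(table)) {
    v <- table$values[nodes, , drop = FALSE]
    prev <- rowMeans(v > 0)
    mab <- rowMeans(v)
    nodes <- nodes[prev >= min_prevalence & mab >= min_mean_abundance]
  }
  if (length(nodes) < 2) stop("fewer than 2 nodes after filtering")
  rho <- rho[nodes, nodes, drop = FALSE]
  q <- q[nodes, nodes, drop = FALSE]

  idx <- which(upper.tri(rho) & !is.na(rho) & abs(rho) >= min_abs_rho &
                 !is.na(q) & q <= max_q, arr.ind = TRUE)
  edges <- data.frame(
    taxon_a = nodes[idx[, 1]], taxon_b = nodes[idx[, 2]],
    rho = rho[idx], q = q[idx],
    sign = ifelse(rho[idx] >= 0, "+", "-"), stringsAsFactors = FALSE)

  net <- structure(list(nodes = nodes, edges = edges),
                   class = "correlation_network")
  net$density <- network_density(net)
  net$centralization <- if (length(nodes) >= 3)
    network_centralization(net) else NA_real_
  g <- as_igraph(net)
  net$components <- igraph::components(g)$membership[nodes]
  net
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf(
    "Co-occurrence network: %d nodes, %d edges (density %.3f, centralization %.3f)\n",
    length(x$nodes), nrow(x$edges), x$density, x$centralization))
  invisible(x)
}

degree_vector <- function(net) {
  deg <- setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    t1 <- table(net$edges$taxon_a)
    t2 <- table(net$edges$taxon_b)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  deg
}

#' Network density
#'
#' The realized fraction of all possible undirected edges,
#' `2E / (n (n - 1))`.
#'
#' @param net a `correlation_network`.
#' @return density in \[0, 1\].
#' @export
network_density <- function(net) {
  n <- length(net$nodes)
  if (n < 2) stop("density undefined for fewer than 2 nodes")
  2 * nrow(net$edges) / (n * (n - 1))
}

#' Freeman degree centralization
#'
#' `sum(max(deg) - deg) / ((n - 1) (n - 2))`: 1 for a star, 0 for any
#' regular graph (e.g. a complete graph or a cycle).
#'
#' @param net a `correlation_network`.
#' @return centralization in \[0, 1\].
#' @export
network_centralization <- function(net) {
  n <- length(net$nodes)
  if (n < 3) stop("centralization undefined for fewer than 3 nodes")
  deg <- degree_vector(net)
  sum(max(deg) - deg) / ((n - 1) * (n - 2))
}

#' Convert a correlation network to an igraph object
#'
#' Edge attributes `rho`, `q` and `sign` are preserved; `weight` is
#' `|rho|`.
#'
#' @param net a `correlation_network`.
#' @return an `igraph` graph.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("taxon_a", "taxon_b", "rho", "q", "sign")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
  if (igraph::ecount(g) > 0)
    igraph::E(g)$weight <- abs(igraph::E(g)$rho)
  g
}

#' Core interaction network (largest connected component)
#'
#' Returns the node-induced sub-network on the largest connected component;
#' size ties are broken by the lexicographically smallest node-id set.
#'
#' @param net a `correlation_network`.
#' @return a `correlation_network` restricted to the core component.
#' @export
largest_component <- function(net) {
  if (length(net$nodes) == 0) return(net)
  comp <- net$components
  sizes <- table(comp)
  best <- names(sizes)[sizes == max(sizes)]
  if (length(best) > 1) {
    # tie-break: component whose sorted node-id vector is smallest
    keysets <- lapply(best, function(b) sort(names(comp)[comp == b]))
    best <- best[order(vapply(keysets, paste, character(1),
                              collapse = "\r"))][1]
  }
  keep <- names(comp)[comp == as.integer(best)]
  sub_edges <- net$edges[net$edges$taxon_a %in% keep &
                           net$edges$taxon_b %in% keep, , drop = FALSE]
  out <- structure(list(nodes = sort(keep), edges = sub_edges),
                   class = "correlation_network")
  out$density <- if (length(keep) >= 2) network_density(out) else NA_real_
  out$centralization <- if (length(keep) >= 3)
    network_centralization(out) else NA_real_
  out$components <- setNames(rep(1L, length(keep)), sort(keep))
  out
}

#' Signed neighbors of a taxon set
#'
#' Genera adjacent to any queried taxon, partitioned by edge sign — e.g.
#' the genera negatively correlated with the Lactobacillus nodes of a
#' network. Queried ids absent from the network are reported with a warning
#' and contribute no neighbors.
#'
#' @param net a `correlation_network`.
#' @param taxa character vector of queried taxon ids.
#' @return list with `positive` and `negative` neighbor id vectors (never
#'   including the queried taxa themselves).
#' @export
neighbors_of <- function(net, taxa) {
  missing <- setdiff(taxa, net$nodes)
  if (length(missing))
    warning("queried taxa absent from network: ",
            paste(missing, collapse = ", "))
  taxa <- intersect(taxa, net$nodes)
  e <- net$edges
  touch <- e$taxon_a %in% taxa | e$taxon_b %in% taxa
  e <- e[touch, , drop = FALSE]
  if (nrow(e) == 0)
    return(list(positive = character(0), negative = character(0)))
  other <- ifelse(e$taxon_a %in% taxa, e$taxon_b, e$taxon_a)
  pos <- sort(setdiff(unique(other[e$sign == "+"]), taxa))
  neg <- sort(setdiff(unique(other[e$sign == "-"]), taxa))
  list(positive = pos, negative = neg)
}

#' Pooled and per-period co-occurrence networks
#'
#' Builds the pooled network across all listed periods plus one network per
#' period, mirroring the analysis of longitudinal designs where samples
#' from several days are first pooled for a global picture and then split
#' to follow network dynamics. Periods with fewer than `min_samples`
#' samples are skipped with a warning.
#'
#' @param table relative `abundance_table`.
#' @param metadata paired metadata (`age_days` defines the period).
#' @param periods numeric vector of age-days to analyze (default: all
#'   observed).
#' @param min_samples minimal samples per period (default 4).
#' @param seed integer seed for the permutation tests.
#' @param ... passed to [build_network()].
#' @inheritParams spearman_matrix
#' @return list with `pooled` (a `correlation_network`) and `periods`
#'   (named list of networks); each network additionally carries
#'   `mean_abs_rho`, the mean |rho| over retained edges.
#' @export
temporal_networks <- function(table, metadata, periods = NULL,
                              min_samples = 4, n_permutations = 999,
                              seed = 1, ...) {
  validate_pairing(table, metadata)
  meta <- metadata[match(sample_ids(table), metadata$sample_id), ]
  if (is.null(periods)) periods <- sort(unique(meta$age_days))

  build_one <- function(ids, label) {
    sub <- subset_table(table, samples = ids)
    corr <- spearman_matrix(sub, n_permutations = n_permutations,
                            seed = seed)
    net <- build_network(corr, sub, ...)
    net$mean_abs_rho <- if (nrow(net$edges)) mean(abs(net$edges$rho)) else
      NA_real_
    net$label <- label
    net
  }

  pool_ids <- meta$sample_id[meta$age_days %in% periods]
  pooled <- build_one(pool_ids, "pooled")
  per_period <- list()
  for (d in periods) {
    ids <- meta$sample_id[meta$age_days == d]
    if (length(ids) < min_samples) {
      warning("period ", d, " has fewer than ", min_samples,
              " samples; skipped")
      next
    }
    per_period[[as.character(d)]] <- build_one(ids, as.character(d))
  }
  list(pooled = pooled, periods = per_period)
}

#' Write network artifacts
#'
#' `write_edge_list()` writes the TSV edge list
#' (`taxon_a taxon_b rho q sign`); `write_network_graphml()` writes GraphML
#' for external visualization tools.
#'
#' @param net a `correlation_network`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_edge_list <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
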