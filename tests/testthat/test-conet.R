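test_that("spearman matrix: monotone pairs, exact tie handling, constant taxa", {
  x <- seq_len(12)
  v <- rbind(up = x, up2 = x^3, down = 13 - x, flat = rep(1, 12))
  colnames(v) <- sprintf("s%02d", 1:12)
  sm <- spearman_matrix(abundance_table(v, kind = "abundance"),
                        n_permutations = 99, seed = 1)
  expect_equal(sm$rho["up", "up2"], 1)
  expect_equal(sm$rho["up", "down"], -1)
  expect_true(is.na(sm$rho["up", "flat"]))  # constant taxon undefined

  # ties: compare against exhaustive average-rank computation
  set.seed(2)
  a <- sample(rep(1:4, 3)); b <- sample(rep(1:3, 4))
  sm2 <- spearman_matrix(abundance_table(rbind(a = a, b = b) |>
    `colnames<-`(sprintf("s%d", 1:12)), kind = "abundance"),
    n_permutations = 9, seed = 1)
  oracle <- cor(rank(a), rank(b))  # Pearson on average ranks
  expect_equal(sm2$rho["a", "b"], oracle, tolerance = 1e-12)
  expect_equal(sm2$rho["a", "b"], cor(a, b, method = "spearman"),
               tolerance = 1e-12)
  expect_error(spearman_matrix(abundance_table(rbind(a = 1:3, b = 3:1) |>
    `colnames<-`(c("x", "y", "z")), kind = "abundance")), ">= 4 samples")
})

test_that("rho is invariant under strictly monotone transforms and sample permutation", {
  set.seed(3)
  v <- matrix(rlnorm(5 * 20), 5, 20,
              dimnames = list(paste0("t", 1:5), sprintf("s%02d", 1:20)))
  tab <- abundance_table(v, kind = "abundance")
  sm <- spearman_matrix(tab, n_permutations = 9, seed = 1)
  v2 <- v; v2[2, ] <- exp(v2[2, ])  # monotone transform of one taxon
  sm2 <- spearman_matrix(abundance_table(v2, kind = "abundance"),
                         n_permutations = 9, seed = 1)
  expect_equal(sm$rho, sm2$rho, tolerance = 1e-12)
  perm <- sample(20)
  sm3 <- spearman_matrix(abundance_table(v[, perm], kind = "abundance"),
                         n_permutations = 9, seed = 1)
  expect_equal(sm$rho, sm3$rho, tolerance = 1e-12)
})

test_that("network building filters edges and nodes canonically", {
  blk <- generate_correlated_block(
    40, list(list(size = 4, sign = "+", strength = 1)), n_noise_taxa = 4,
    seed = 4)
  sm <- spearman_matrix(blk$table, n_permutations = 199, seed = 4)
  net <- build_network(sm, blk$table, min_mean_abundance = 0)
  # comonotone block of 4 forms a complete subgraph (6 edges, rho = 1)
  in_block <- net$edges$taxon_a %in% paste0("block1_taxon", 1:4) &
    net$edges$taxon_b %in% paste0("block1_taxon", 1:4)
  expect_identical(sum(in_block), 6L)
  expect_true(all(net$edges$rho[in_block] == 1))
  # canonical i < j form, no duplicates, no self loops
  expect_true(all(net$edges$taxon_a != net$edges$taxon_b))
  key <- paste(pmin(net$edges$taxon_a, net$edges$taxon_b),
               pmax(net$edges$taxon_a, net$edges$taxon_b))
  expect_identical(anyDuplicated(key), 0L)

  # unreachable threshold: empty edge set, zero density
  net0 <- build_network(sm, blk$table, min_abs_rho = 1.01,
                        min_mean_abundance = 0)
  expect_identical(nrow(net0$edges), 0L)
  expect_equal(net0$density, 0)
})

test_that("density and centralization match closed forms", {
  nodes5 <- paste0("n", 1:5)
  star <- graph_fixture(nodes5, lapply(2:5, function(i) c("n1", paste0("n", i))))
  expect_equal(network_density(star), 2 * 4 / (5 * 4))
  expect_equal(network_centralization(star), 1)

  complete <- graph_fixture(nodes5, combn(nodes5, 2, identity,
                                          simplify = FALSE))
  expect_equal(network_density(complete), 1)
  expect_equal(network_centralization(complete), 0)

  path4 <- graph_fixture(paste0("n", 1:4),
                         list(c("n1", "n2"), c("n2", "n3"), c("n3", "n4")))
  expect_equal(network_centralization(path4), 2 / 6)  # Freeman by hand

  empty5 <- graph_fixture(nodes5, list())
  expect_equal(network_density(empty5), 0)
  expect_error(network_centralization(graph_fixture(paste0("n", 1:2),
                                                    list())), "fewer than 3")

  # random graphs vs direct combinatorial evaluation
  set.seed(5)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    ids <- paste0("v", seq_len(n))
    pairs <- combn(ids, 2, identity, simplify = FALSE)
    keep <- pairs[runif(length(pairs)) < 0.4]
    g <- graph_fixture(ids, keep)
    expect_equal(network_density(g), 2 * length(keep) / (n * (n - 1)))
    deg <- table(factor(unlist(keep), levels = ids))
    expect_equal(network_centralization(g),
                 sum(max(deg) - deg) / ((n - 1) * (n - 2)))
  }
})

test_that("largest component and signed neighbor queries", {
  g <- graph_fixture(c(LETTERS[1:5], "X", "Y", "Z"),
                     list(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "E"),
                          c("X", "Y"), c("Y", "Z")))
  g$components <- igraph::components(as_igraph(g))$membership[g$nodes]
  core <- largest_component(g)
  expect_setequal(core$nodes, LETTERS[1:5])

  # equal-size tie broken by lexicographically smallest node set
  g2 <- graph_fixture(c("A", "B", "C", "X", "Y", "Z"),
                      list(c("X", "Y"), c("Y", "Z"), c("A", "B"), c("B", "C")))
  g2$components <- igraph::components(as_igraph(g2))$membership[g2$nodes]
  expect_setequal(largest_component(g2)$nodes, c("A", "B", "C"))

  # neighbors partitioned by sign; negative hub pattern
  blk <- generate_correlated_block(
    60, list(list(size = 15, sign = "-", strength = 1)), seed = 6)
  sm <- spearman_matrix(blk$table, n_permutations = 199, seed = 6)
  net <- build_network(sm, blk$table, min_mean_abundance = 0)
  nb <- neighbors_of(net, "block1_taxon1")
  expect_identical(length(nb$negative), 14L)  # hub anti-correlated with rest
  expect_identical(length(nb$positive), 0L)
  expect_warning(nb2 <- neighbors_of(net, "absent_taxon"), "absent")
  expect_identical(nb2, list(positive = character(0),
                             negative = character(0)))
})

test_that("temporal networks: pooled + per-period, planted decay shows up", {
  set.seed(7)
  strengths <- c(`7` = 0.95, `28` = 0.8, `42` = 0.65)
  tabs <- list(); metas <- list()
  for (d in names(strengths)) {
    blk <- generate_correlated_block(
      30, list(list(size = 6, sign = "+", strength = strengths[[d]])),
      n_noise_taxa = 2, seed = 7 + as.integer(d))
    v <- blk$table$values
    colnames(v) <- sprintf("d%s_s%02d", d, seq_len(ncol(v)))
    tabs[[d]] <- v
    metas[[d]] <- toy_metadata(colnames(v), "g", rep(as.integer(d), ncol(v)))
  }
  tab <- abundance_table(do.call(cbind, tabs), kind = "abundance")
  meta <- do.call(rbind, metas)
  res <- temporal_networks(tab, meta, n_permutations = 199, seed = 7,
                           min_mean_abundance = 0)
  expect_named(res$periods, c("7", "28", "42"))
  rhos <- vapply(res$periods, `[[`, numeric(1), "mean_abs_rho")
  expect_true(rhos[["7"]] > rhos[["42"]])  # planted decay recovered

  # a single period pools to itself
  one <- temporal_networks(abundance_table(tabs[["7"]], kind = "abundance"),
                           metas[["7"]], n_permutations = 99, seed = 1,
                           min_mean_abundance = 0)
  canon <- function(e) {
    e <- e[order(e$taxon_a, e$taxon_b), ]
    rownames(e) <- NULL
    e
  }
  expect_equal(canon(one$pooled$edges), canon(one$periods[["7"]]$edges))
})

test_that("edge lists and GraphML round-trip through igraph", {
  blk <- generate_correlated_block(
    30, list(list(size = 4, sign = "+", strength = 1)), seed = 8)
  sm <- spearman_matrix(blk$table, n_permutations = 99, seed = 8)
  net <- build_network(sm, blk$table, min_mean_abundance = 0)
  ep <- withr::local_tempfile(fileext = ".tsv")
  gp <- withr::local_tempfile(fileext = ".graphml")
  write_edge_list(net, ep)
  expect_identical(read.delim(ep)$taxon_a, net$edges$taxon_a)
  write_network_graphml(net, gp)
  g <- igraph::read_graph(gp, format = "graphml")
  expect_identical(as.integer(igraph::ecount(g)), nrow(net$edges))
  expect_setequal(igraph::V(g)$name, net$nodes)
})
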