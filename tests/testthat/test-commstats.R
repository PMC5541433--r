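test_that("alpha diversity matches the closed forms", {
  # uniform 10 taxa x 100 counts
  v <- matrix(100, 10, 1, dimnames = list(paste0("t", 1:10), "u"))
  a <- alpha_diversity(abundance_table(v, kind = "counts"))
  expect_equal(a$shannon, log(10), tolerance = 1e-12)
  expect_equal(a$simpson, 0.9, tolerance = 1e-12)
  expect_identical(a$observed, 10L)

  # single taxon
  v1 <- matrix(c(7, 0), 2, 1, dimnames = list(c("t1", "t2"), "s"))
  a1 <- alpha_diversity(abundance_table(v1, kind = "counts"))
  expect_equal(unlist(a1[c("observed", "shannon", "simpson", "chao1")],
                      use.names = FALSE), c(1, 0, 0, 1))

  # bias-corrected Chao1: S = 20, F1 = 2, F2 = 1 -> 20.5
  cnt <- c(rep(10, 17), 2, 1, 1)
  v2 <- matrix(cnt, 20, 1, dimnames = list(paste0("t", 1:20), "s"))
  a2 <- alpha_diversity(abundance_table(v2, kind = "counts"))
  expect_equal(a2$chao1, 20 + 2 * 1 / (2 * (1 + 1)))
  # F1 = 0 => chao1 == observed
  v3 <- matrix(rep(5, 8), 8, 1, dimnames = list(paste0("t", 1:8), "s"))
  a3 <- alpha_diversity(abundance_table(v3, kind = "counts"))
  expect_equal(a3$chao1, a3$observed)

  # Shannon maximal iff uniform
  set.seed(1)
  for (i in 1:20) {
    p <- rmultinom(1, 500, prob = runif(10))[, 1]
    vv <- cbind(uniform = rep(50, 10), ragged = p)
    rownames(vv) <- paste0("t", 1:10)
    aa <- alpha_diversity(abundance_table(vv, kind = "counts"))
    expect_lte(aa$shannon[2], aa$shannon[1] + 1e-12)
  }
})

test_that("beta distance: identity, disjoint supports, formula oracle", {
  v <- matrix(c(5, 3, 2, 0,
                5, 3, 2, 0,
                0, 0, 0, 10), 4, 3,
              dimnames = list(paste0("t", 1:4), c("a", "b", "c")))
  d <- as.matrix(beta_distance(abundance_table(v, kind = "counts")))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)  # disjoint supports

  set.seed(2)
  x <- runif(6); y <- runif(6)
  x <- x / sum(x); y <- y / sum(y)
  vv <- cbind(s1 = x, s2 = y); rownames(vv) <- paste0("t", 1:6)
  d2 <- as.matrix(beta_distance(abundance_table(vv, kind = "relative")))
  expect_equal(d2["s1", "s2"], sum(abs(x - y)) / sum(x + y),
               tolerance = 1e-12)
  expect_error(beta_distance(abundance_table(vv, kind = "relative"),
                             metric = "warp9"), "unknown metric")
})

test_that("permanova/anosim agree with vegan on a fixed dataset", {
  # dual route: our permutation implementations vs vegan's on the same
  # distance matrix; statistics must match exactly, p-values to permutation
  # noise
  set.seed(3)
  v <- matrix(rlnorm(20 * 18), 20, 18,
              dimnames = list(paste0("t", 1:20), paste0("s", 1:18)))
  grp <- rep(c("a", "b", "c"), each = 6)
  v[1:5, grp == "b"] <- v[1:5, grp == "b"] * 4
  tab <- abundance_table(v, kind = "abundance")
  d <- beta_distance(tab)

  ours <- permanova(d, grp, n_permutations = 499, seed = 1)
  ref <- vegan::adonis2(d ~ g, data = data.frame(g = grp),
                        permutations = 499)
  expect_equal(ours$statistic, ref$F[1], tolerance = 1e-10)
  expect_lt(abs(ours$p - ref$`Pr(>F)`[1]), 0.05)

  ours_a <- anosim(d, grp, n_permutations = 499, seed = 1)
  ref_a <- vegan::anosim(d, grp, permutations = 99)
  expect_equal(ours_a$statistic, ref_a$statistic, tolerance = 1e-10)
})

test_that("anosim: perfect separation gives R = 1 and rank invariance holds", {
  # two tight clusters far apart
  pts <- c(rnorm(6, 0, 0.01), rnorm(6, 100, 0.01))
  d <- dist(pts)
  grp <- rep(c("a", "b"), each = 6)
  res <- anosim(d, grp, n_permutations = 199, seed = 2)
  expect_equal(res$statistic, 1)
  # strictly monotone transform of distances leaves R unchanged
  res2 <- anosim(d^3, grp, n_permutations = 199, seed = 2)
  expect_equal(res2$statistic, res$statistic)
})

test_that("degenerate distance matrices are flagged, singleton groups error", {
  d <- dist(rep(1, 8))
  res <- permanova(d, rep(c("a", "b"), each = 4), n_permutations = 99,
                   seed = 1)
  expect_true(is.na(res$statistic))
  expect_equal(res$p, 1)
  expect_error(permanova(dist(rnorm(5)), c("a", "a", "a", "a", "b")),
               ">= 2 samples")
})

test_that("per-genus Kruskal tests stratify by day and handle degeneracy", {
  set.seed(4)
  days <- rep(c(7, 28), each = 12)
  grp <- rep(rep(c("a", "b", "c"), each = 4), 2)
  v <- matrix(rlnorm(6 * 24), 6, 24,
              dimnames = list(paste0("g", 1:6), sprintf("s%02d", 1:24)))
  v["g1", days == 7 & grp == "b"] <- v["g1", days == 7 & grp == "b"] * 50
  v["g2", ] <- 3  # constant genus
  meta <- toy_metadata(colnames(v), grp, days)
  res <- genus_kruskal(abundance_table(v, kind = "abundance"), meta)
  expect_setequal(unique(res$age_days), c(7, 28))
  expect_lt(res$p[res$age_days == 7 & res$taxon == "g1"], 0.05)
  expect_equal(res$p[res$taxon == "g2"], rep(1, 2))
  # BH within each time point
  for (d in c(7, 28)) {
    sub <- res[res$age_days == d, ]
    expect_equal(sub$p_adj, p.adjust(sub$p, "BH"))
  }
})
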