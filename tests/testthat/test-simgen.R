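test_that("trajectory expectation follows the logistic closed form", {
  flat <- taxon_trajectory("t", baseline = 3, amplitude = 0,
                           midpoint_day = 10, rate = 0.4)
  expect_equal(taxon_expected_abundance(flat, c(0, 5, 100)), rep(3, 3))

  tr <- taxon_trajectory("t", baseline = 1, amplitude = 2,
                         midpoint_day = 15, rate = 0.4)
  # logistic at its midpoint is exactly 1/2
  expect_equal(taxon_expected_abundance(tr, 15, warp = 1), 2.0)
  # asymptote: baseline + amplitude
  expect_equal(taxon_expected_abundance(tr, 1e6), 3, tolerance = 1e-12)
  # warp semantics: E[x | age t, warp g] == E[x | age g*t, warp 1], exactly
  ages <- c(0, 3.5, 10, 21, 42)
  for (g in c(0.5, 2, 3))
    expect_equal(taxon_expected_abundance(tr, ages, warp = g),
                 taxon_expected_abundance(tr, g * ages, warp = 1))

  expect_error(taxon_expected_abundance(tr, 10, warp = 0), "warp")
  expect_error(taxon_trajectory("t", 1, 1, 10, rate = 0), "rate")
  expect_error(taxon_trajectory("t", 1, -5, 10, 0.3), "negative")
})

test_that("generate_cohort conserves depth, reproduces under a seed, and labels truth", {
  cfg <- cohort_config(n_taxa = 15, n_age_taxa = 5,
                       sampling_days = c(1, 7, 28, 42), n_per_day = 3,
                       depth = 500, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$table$values, b$table$values)  # seed determinism
  expect_identical(a$metadata, b$metadata)
  expect_true(all(colSums(a$table$values) == 500))  # multinomial conservation
  expect_identical(a$truth$age_taxa, paste0("age_taxon_", 1:5))
  expect_identical(a$truth$warp, cfg$groups)
  expect_setequal(unique(a$metadata$age_days), c(1, 7, 28, 42))
  expect_equal(nrow(a$metadata), 3 * 4 * 3)
})

test_that("equal warps give statistically indistinguishable group trajectories", {
  # two groups with identical warp: per-day group mean abundances of the age
  # taxa should look like draws from one distribution (KS test on the pooled
  # per-day means across seeds)
  days <- c(1, 7, 28, 42)
  mean_a <- c(); mean_b <- c()
  for (s in 1:8) {
    sim <- generate_cohort(cohort_config(
      n_taxa = 12, n_age_taxa = 4, sampling_days = days, n_per_day = 4,
      groups = c(g1 = 1, g2 = 1), depth = 1000, seed = 100 + s))
    rel <- to_relative(sim$table)$values[sim$truth$age_taxa, ]
    grp <- sim$metadata$group
    day <- sim$metadata$age_days
    for (d in days) {
      mean_a <- c(mean_a, rowMeans(rel[, grp == "g1" & day == d]))
      mean_b <- c(mean_b, rowMeans(rel[, grp == "g2" & day == d]))
    }
  }
  expect_gt(suppressWarnings(ks.test(mean_a, mean_b))$p.value, 0.01)
})

test_that("ko study plants multiplicative shifts in exactly one group", {
  cfg <- ko_study_config(n_kos = 100, n_pathways = 10, kos_per_pathway = 5,
                         enriched_pathways = c("ko00001", "ko00002"),
                         effect_size = 3, n_samples_per_group = 8, seed = 4)
  ks <- generate_ko_study(cfg)
  expect_identical(ks$truth$shifted_group, "probiotic")
  expect_identical(dim(ks$table$values), c(100L, 24L))
  expect_identical(generate_ko_study(cfg)$table$values, ks$table$values)

  enriched_kos <- unlist(ks$pathways[c("ko00001", "ko00002")])
  grp <- ks$metadata$group
  v <- ks$table$values
  lfc <- log(rowMeans(v[, grp == "probiotic"])) -
    log(rowMeans(v[, grp == "control"]))
  expect_gt(median(lfc[enriched_kos]), log(2))            # shifted up ~3x
  expect_lt(abs(median(lfc[setdiff(rownames(v), enriched_kos)])), 0.35)

  expect_error(ko_study_config(n_kos = 10, n_pathways = 5,
                               kos_per_pathway = 5), "must be <=")
  expect_error(ko_study_config(enriched_pathways = "nope"), "not among")
})

test_that("correlated blocks plant the requested Spearman structure", {
  # strength 1, positive block: comonotone, rho exactly 1
  b1 <- generate_correlated_block(30, list(list(size = 3, sign = "+",
                                                strength = 1)), seed = 1)
  r <- cor(t(b1$table$values[1:3, ]), method = "spearman")
  expect_equal(unname(r[upper.tri(r)]), rep(1, 3))

  # strength 1, negative pair: antitone, rho exactly -1
  b2 <- generate_correlated_block(30, list(list(size = 2, sign = "-",
                                                strength = 1)), seed = 2)
  expect_equal(unname(cor(b2$table$values[1, ], b2$table$values[2, ],
                          method = "spearman")), -1)

  # strength 0: independent; mean |rho| small at large n
  b3 <- generate_correlated_block(500, list(list(size = 6, sign = "+",
                                                 strength = 0)), seed = 3)
  r3 <- cor(t(b3$table$values), method = "spearman")
  expect_lt(mean(abs(r3[upper.tri(r3)])), 0.1)

  expect_error(generate_correlated_block(2, list(list(size = 2, sign = "+",
                                                      strength = 0.5))),
               "n_samples")
})
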