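# fast settings throughout: small forests are plenty for these contracts

test_that("importance ranking puts an age-tracking taxon first and is order-invariant", {
  set.seed(10)
  n <- 60
  ages <- rep(c(1, 7, 14, 21, 28, 42), each = 10)
  v <- rbind(
    age_like = ages / 42 * exp(rnorm(n, 0, 0.05)),
    noise1 = runif(n), noise2 = runif(n), noise3 = runif(n))
  colnames(v) <- paste0("s", 1:n)
  tab <- to_relative(abundance_table(v, kind = "abundance"))
  cfg <- fast_config(seed = 5, iters = 5)
  rk <- rank_taxa_by_importance(tab, ages, cfg)
  expect_identical(rk$taxon[1], "age_like")
  expect_true(rk$discriminatory[1])

  # permuting sample order leaves the ranking unchanged under fixed seeds
  perm <- sample(n)
  tab2 <- subset_table(tab, samples = perm)
  rk2 <- rank_taxa_by_importance(tab2, ages[perm], cfg)
  expect_identical(rk$taxon, rk2$taxon)

  expect_error(rank_taxa_by_importance(tab, rep(7, n), cfg), "distinct ages")
  few <- c(1, 11, 21)  # three samples (two distinct ages) < cv_folds
  expect_error(rank_taxa_by_importance(subset_table(tab, samples = few),
                                       ages[few], cfg), "cv_folds")
})

test_that("feature-count selection returns the tolerant minimum; p = 1 edge case", {
  sim <- small_cohort(seed = 21, groups = c(control = 1))
  rel <- to_relative(sim$table)
  ages <- sim$metadata$age_days
  cfg <- fast_config(seed = 2, n_trees = 100, iters = 5)
  rk <- rank_taxa_by_importance(rel, ages, cfg)
  sel <- select_feature_count(rel, ages, rk, cfg)
  expect_true(sel$k >= 1 && sel$k <= nrow(rk))
  # definition check: k is the smallest size within (1+tau) of the minimum
  tol <- (1 + cfg$cv_tolerance) * min(sel$cv_curve$cv_mse)
  expect_identical(sel$k, sel$cv_curve$k[sel$cv_curve$cv_mse <= tol][1])
  expect_true(all(diff(sel$cv_curve$k) > 0))

  # single-candidate: with one taxon the only choice is k = 1
  one <- subset_table(rel, taxa = rk$taxon[1])
  sel1 <- select_feature_count(one, ages, rk[1, , drop = FALSE], cfg)
  expect_identical(sel1$k, 1L)
})

test_that("age model predicts within range, OOB for training samples, zero-imputes missing taxa", {
  sim <- small_cohort(seed = 31, groups = c(control = 1))
  rel <- to_relative(sim$table)
  ages <- sim$metadata$age_days
  cfg <- fast_config(seed = 3, n_trees = 200, iters = 5)
  rk <- rank_taxa_by_importance(rel, ages, cfg)
  model <- fit_age_model(rel, ages, rk, k = 6, cfg)
  expect_identical(nrow(model$selected_taxa), 6L)
  expect_true(model$train_r2 > 0 && model$train_r2 <= 1)

  pred_oob <- predict_microbiota_age(model, rel)
  pred_in <- predict_microbiota_age(model, rel, use_oob = FALSE)
  expect_true(all(pred_oob >= 1 & pred_oob <= 42))  # ensemble-of-means bound
  expect_false(identical(pred_oob, pred_in))        # OOB really differs
  # duplicated sample column gives identical (full-forest) predictions
  dup <- abundance_table(rel$values[, c(1, 1)] |>
                           `colnames<-`(c("d1", "d2")), kind = "relative")
  pd <- predict_microbiota_age(model, dup, use_oob = FALSE)
  expect_identical(unname(pd[1]), unname(pd[2]))

  # dropping a selected taxon triggers zero-imputation warning, not an error
  drop1 <- model$selected_taxa$taxon[1]
  sub <- subset_table(rel, taxa = setdiff(taxon_ids(rel), drop1))
  expect_warning(predict_microbiota_age(model, sub), "imputed as 0")
})

test_that("maturity curve finds the analytic plateau on known shapes", {
  # linear growth: plateau is the first grid day >= 0.95 * max
  chrono <- rep(1:42, each = 2)
  linear <- chrono + rnorm(length(chrono), 0, 1e-6)
  cv <- fit_maturity_curve(linear, chrono, group = "lin", delta = 0.05)
  analytic <- cv$grid_ages[cv$fitted >= 0.95 * max(cv$fitted)][1]
  expect_identical(cv$plateau_age, analytic)
  expect_equal(cv$plateau_value / max(cv$fitted), 1, tolerance = 0.06)

  # logistic with known parameters: compare to the closed-form
  # (1 - delta) crossing of the asymptote-limited curve
  set.seed(6)
  chrono <- rep(seq(1, 42, 1), each = 3)
  mid <- 15; rate <- 0.4; asym <- 40
  y <- asym / (1 + exp(-rate * (chrono - mid))) + rnorm(length(chrono), 0, 0.5)
  cv2 <- fit_maturity_curve(y, chrono, group = "logis", delta = 0.05)
  # crossing of 0.95 * max(fitted); the max over the grid is f(42)
  fmax <- asym / (1 + exp(-rate * (42 - mid)))
  q <- 0.95 * fmax / asym            # logistic level at the crossing
  t_cross <- mid + log(q / (1 - q)) / rate
  expect_lt(abs(cv2$plateau_age - t_cross), 2.5)

  expect_error(fit_maturity_curve(1:3, c(1, 7, 7), delta = 0.05),
               "insufficient time points")
})

test_that("IMMI: self-reference, censoring, and model provenance", {
  chrono <- rep(1:42, each = 2)
  y <- 30 / (1 + exp(-0.5 * (chrono - 12)))
  ctrl <- fit_maturity_curve(y, chrono, group = "control", model_id = "m1")
  expect_identical(compute_immi(ctrl, ctrl)$immi_days, ctrl$plateau_age)

  low <- fit_maturity_curve(y * 0.5, chrono, group = "slow", model_id = "m1")
  im <- compute_immi(ctrl, low)
  expect_true(im$censored)
  expect_identical(im$immi_days, 42)

  other <- fit_maturity_curve(y, chrono, group = "x", model_id = "m2")
  expect_error(compute_immi(ctrl, other), "different age models")
})

test_that("warped groups order correctly through the full pipeline", {
  sim <- small_cohort(seed = 41)
  res <- run_maturity_analysis(sim$table, sim$metadata, "control",
                               config = fast_config(seed = 41, n_trees = 150,
                                                    iters = 5))
  immi <- vapply(res$immi, `[[`, numeric(1), "immi_days")
  expect_lt(immi[["probiotic"]], immi[["control"]])   # accelerated
  expect_lt(immi[["control"]], immi[["antibiotic"]])  # delayed
  # fast group's predicted age at a mid trajectory day exceeds control's
  pr <- res$predictions
  d10 <- pr$age_days == 10
  expect_gt(mean(pr$microbiota_age[d10 & pr$group == "probiotic"]),
            mean(pr$microbiota_age[d10 & pr$group == "control"]))
})
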