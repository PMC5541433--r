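#' Microbiota-age model configuration
#'
#' Defaults follow the conventional regression-forest setup for
#' microbiota-for-age modelling: 5000 trees with `mtry = floor(p/3)`,
#' importance ranking averaged over 100 independently seeded forests, and
#' 10-fold cross-validation to choose the minimal taxon subset.
#'
#' @param n_trees trees per forest (default 5000).
#' @param mtry_fraction fraction of features tried per split (default 1/3,
#'   i.e. `mtry = floor(p/3)`).
#' @param n_importance_iters forests averaged for the importance ranking
#'   (default 100).
#' @param cv_folds cross-validation folds (default 10).
#' @param cv_tolerance relative slack tau for the minimal-subset rule: the
#'   selected size is the smallest k whose CV error is within `(1 + tau)` of
#'   the minimum (default 0.05).
#' @param min_node minimal tree node size (default 5).
#' @param seed integer master seed for the module.
#' @return an `age_model_config` list.
#' @export
age_model_config <- function(n_trees = 5000, mtry_fraction = 1 / 3,
                             n_importance_iters = 100, cv_folds = 10,
                             cv_tolerance = 0.05, min_node = 5, seed = 1) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (mtry_fraction <= 0 || mtry_fraction > 1)
    stop("mtry_fraction must be in (0, 1]")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  structure(list(n_trees = n_trees, mtry_fraction = mtry_fraction,
                 n_importance_iters = n_importance_iters,
                 cv_folds = cv_folds, cv_tolerance = cv_tolerance,
                 min_node = min_node, seed = as.integer(seed)),
            class = "age_model_config")
}

# taxa x samples relative table -> samples x taxa feature matrix
features_from_table <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  t(table$values)
}

config_mtry <- function(config, p) max(floor(p * config$mtry_fraction), 1)

#' Rank taxa by age-discriminatory importance
#'
#' Trains `n_importance_iters` independently seeded regression forests of
#' the taxa against chronologic age on the reference-group samples and ranks
#' taxa by their mean OOB permutation importance (descending). Taxa with
#' non-positive mean importance are flagged non-discriminatory.
#'
#' @param table relative `abundance_table` of the reference group's samples.
#' @param ages chronologic age (days) per sample, aligned with the table's
#'   columns.
#' @param config an [age_model_config()].
#' @return data.frame with `taxon`, `mean_importance`, `discriminatory`,
#'   sorted by decreasing importance.
#' @export
rank_taxa_by_importance <- function(table, ages, config = age_model_config()) {
  x <- features_from_table(table)
  ages <- as.numeric(ages)
  if (nrow(x) != length(ages)) stop("ages must align with table samples")
  if (length(unique(ages)) < 2) stop("need >= 2 distinct ages")
  if (nrow(x) < config$cv_folds)
    stop("fewer samples than cv_folds")
  p <- ncol(x)
  imp <- matrix(0, config$n_importance_iters, p,
                dimnames = list(NULL, colnames(x)))
  for (i in seq_len(config$n_importance_iters)) {
    fit <- regression_forest(x, ages, ntree = config$n_trees,
                             mtry = config_mtry(config, p),
                             min_node = config$min_node, importance = TRUE,
                             seed = config$seed + i)
    imp[i, ] <- fit$importance
  }
  mi <- colMeans(imp)
  ord <- order(mi, decreasing = TRUE)
  data.frame(taxon = colnames(x)[ord], mean_importance = unname(mi[ord]),
             discriminatory = unname(mi[ord] > 0), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Choose the minimal number of top-ranked taxa
#'
#' Evaluates `cv_folds`-fold cross-validation MSE of forests restricted to
#' nested top-k taxon subsets (k halving from p down to 1, plus every
#' k <= 20), then picks the smallest k whose error is within
#' `(1 + cv_tolerance)` of the minimum — beyond that size additional taxa
#' buy only minimal improvement.
#'
#' @inheritParams rank_taxa_by_importance
#' @param ranking data.frame from [rank_taxa_by_importance()].
#' @return list with `k` (selected size) and `cv_curve` (data.frame of
#'   `k`, `cv_mse`).
#' @export
select_feature_count <- function(table, ages, ranking,
                                 config = age_model_config()) {
  x <- features_from_table(table)[, ranking$taxon, drop = FALSE]
  ages <- as.numeric(ages)
  n <- nrow(x)
  p <- ncol(x)
  if (n < config$cv_folds) stop("fewer samples than cv_folds")
  ks <- p
  while (ks[length(ks)] > 1) ks <- c(ks, floor(ks[length(ks)] / 2))
  ks <- sort(unique(c(ks, seq_len(min(20, p)))))

  set.seed(config$seed)
  folds <- sample(rep(seq_len(config$cv_folds), length.out = n))
  cv_mse <- numeric(length(ks))
  for (ki in seq_along(ks)) {
    k <- ks[ki]
    xs <- x[, seq_len(k), drop = FALSE]
    err <- 0
    for (f in seq_len(config$cv_folds)) {
      test <- folds == f
      fit <- regression_forest(xs[!test, , drop = FALSE], ages[!test],
                               ntree = config$n_trees,
                               mtry = config_mtry(config, k),
                               min_node = config$min_node,
                               seed = config$seed + 1000L * f + k)
      pred <- predict(fit, xs[test, , drop = FALSE])
      err <- err + sum((pred - ages[test])^2)
    }
    cv_mse[ki] <- err / n
  }
  tol <- (1 + config$cv_tolerance) * min(cv_mse)
  k_star <- ks[which(cv_mse <= tol)[1]]
  list(k = k_star, cv_curve = data.frame(k = ks, cv_mse = cv_mse))
}

#' Fit the microbiota-age model on the reference group
#'
#' Trains a regression forest of the top `k` ranked taxa against chronologic
#' age. The training-group fit quality is reported as out-of-bag R-squared
#' (fraction of age variance explained), which avoids the optimism of
#' in-sample predictions.
#'
#' @inheritParams select_feature_count
#' @param k number of top-ranked taxa to use (from
#'   [select_feature_count()]).
#' @return an `age_model` object: `forest`, `selected_taxa` (with mean
#'   importance), `train_r2`, `train_sample_ids`, `train_oob` (per-sample
#'   OOB predictions), `age_range`, `config`, `model_id`.
#' @export
fit_age_model <- function(table, ages, ranking, k,
                          config = age_model_config()) {
  x <- features_from_table(table)
  ages <- as.numeric(ages)
  if (nrow(x) < 2) stop("degenerate input: need >= 2 training samples")
  if (k < 1 || k > nrow(ranking)) stop("k out of range")
  sel <- ranking$taxon[seq_len(k)]
  xs <- x[, sel, drop = FALSE]
  fit <- regression_forest(xs, ages, ntree = config$n_trees,
                           mtry = config_mtry(config, k),
                           min_node = config$min_node, importance = FALSE,
                           seed = config$seed)
  structure(
    list(forest = fit,
         selected_taxa = ranking[seq_len(k), c("taxon", "mean_importance")],
         train_r2 = fit$oob_r2,
         train_sample_ids = rownames(x),
         train_oob = setNames(fit$oob_pred, rownames(x)),
         age_range = range(ages),
         config = config,
         model_id = sprintf("agemodel_seed%d_k%d_%s", config$seed, k,
                            paste0(substr(sel, 1, 3), collapse = ""))),
    class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat("Microbiota-age model\n")
  cat(sprintf("  selected taxa: %d; OOB R-squared on training group: %.3f\n",
              nrow(x$selected_taxa), x$train_r2))
  invisible(x)
}

#' Predict per-sample microbiota age
#'
#' Applies the trained model to any group's samples. Samples that were part
#' of the training set receive their out-of-bag predictions (so the
#' reference group's maturity curve is not optimistically biased); all other
#' samples use the full forest. Selected taxa missing from the table are
#' imputed as zero abundance with a warning.
#'
#' @param model an `age_model`.
#' @param table relative `abundance_table` of samples to predict.
#' @param use_oob use OOB predictions for training samples (default TRUE).
#' @return named numeric vector of microbiota ages (days) per sample.
#' @export
predict_microbiota_age <- function(model, table, use_oob = TRUE) {
  stopifnot(inherits(model, "age_model"))
  sel <- model$selected_taxa$taxon
  v <- table$values
  missing <- setdiff(sel, rownames(v))
  if (length(missing)) {
    warning("selected taxa absent from table, imputed as 0: ",
            paste(missing, collapse = ", "))
    pad <- matrix(0, length(missing), ncol(v),
                  dimnames = list(missing, colnames(v)))
    v <- rbind(v, pad)
  }
  x <- t(v[sel, , drop = FALSE])
  pred <- predict(model$forest, x)
  names(pred) <- colnames(v)
  if (use_oob) {
    trained <- intersect(names(pred), model$train_sample_ids)
    oob <- model$train_oob[trained]
    usable <- trained[!is.na(oob)]
    pred[usable] <- model$train_oob[usable]
  }
  pred
}

#' Fit a maturity curve and locate its plateau
#'
#' Fits a cubic smoothing spline (smoothing parameter chosen by generalized
#' cross-validation) of microbiota age against chronologic age, evaluates it
#' on a daily grid, and defines the plateau as the earliest grid day whose
#' fitted value reaches `(1 - delta)` of the curve's maximum. The fitted
#' microbiota age at the plateau, `M*`, is the group's full-maturity level.
#'
#' @param microbiota_age predicted ages (days) per sample.
#' @param chrono_age chronologic ages (days), aligned.
#' @param group group label stored on the curve.
#' @param delta plateau tolerance (default 0.05).
#' @param model_id provenance string from the `age_model` (curves from
#'   different models are never compared).
#' @return a `maturity_curve`: `group`, `grid_ages`, `fitted`,
#'   `plateau_age`, `plateau_value`, `delta`, `model_id`.
#' @export
fit_maturity_curve <- function(microbiota_age, chrono_age, group = "group",
                               delta = 0.05, model_id = NA_character_) {
  ok <- !is.na(microbiota_age) & !is.na(chrono_age)
  microbiota_age <- microbiota_age[ok]
  chrono_age <- chrono_age[ok]
  if (length(unique(chrono_age)) < 4)
    stop("insufficient time points for plateau detection (need >= 4 distinct ages)")
  sp <- smooth.spline(chrono_age, microbiota_age, cv = FALSE)
  grid <- seq(min(chrono_age), max(chrono_age), by = 1)
  fitted <- predict(sp, grid)$y
  if (any(!is.finite(fitted))) stop("spline produced non-finite values")
  target <- (1 - delta) * max(fitted)
  idx <- which(fitted >= target)[1]
  structure(list(group = group, grid_ages = grid, fitted = fitted,
                 plateau_age = grid[idx], plateau_value = fitted[idx],
                 delta = delta, model_id = model_id),
            class = "maturity_curve")
}

#' @export
print.maturity_curve <- function(x, ...) {
  cat(sprintf(
    "Maturity curve [%s]: plateau at day %g (microbiota age %.2f, delta %.2f)\n",
    x$group, x$plateau_age, x$plateau_value, x$delta))
  invisible(x)
}

#' Intestinal microbiota maturation index (IMMI)
#'
#' IMMI is the chronologic time a group needs to reach the full maturity of
#' the gut microbiota as defined by the additive-free (reference) group:
#' the earliest grid day at which the group's fitted maturity curve reaches
#' the reference curve's plateau value `M*`. If the curve never reaches
#' `M*` within the observed window the result is censored at the last grid
#' day.
#'
#' @param control_curve reference-group `maturity_curve`.
#' @param group_curve `maturity_curve` for the group of interest (may be the
#'   reference itself, in which case IMMI equals its plateau age).
#' @return an `immi_result`: `group`, `immi_days`, `reference_value`,
#'   `censored`.
#' @export
compute_immi <- function(control_curve, group_curve) {
  stopifnot(inherits(control_curve, "maturity_curve"),
            inherits(group_curve, "maturity_curve"))
  if (!identical(control_curve$model_id, group_curve$model_id))
    stop("curves come from different age models; IMMI is undefined")
  m_star <- control_curve$plateau_value
  idx <- which(group_curve$fitted >= m_star)[1]
  censored <- is.na(idx)
  structure(list(group = group_curve$group,
                 immi_days = if (censored)
                   max(group_curve$grid_ages) else group_curve$grid_ages[idx],
                 reference_value = m_star, censored = censored),
            class = "immi_result")
}

#' @export
print.immi_result <- function(x, ...) {
  cat(sprintf("IMMI [%s]: %g days%s (reference maturity %.2f)\n", x$group,
              x$immi_days, if (x$censored) " [censored]" else "",
              x$reference_value))
  invisible(x)
}

#' Full microbiota-maturation analysis
#'
#' Convenience driver for the whole maturity workflow: rank taxa on the
#' reference group, choose the minimal subset by cross-validation, fit the
#' age model, predict microbiota age for every group, fit per-group maturity
#' curves and derive IMMI against the reference plateau.
#'
#' @param table `abundance_table` (counts or relative; counts are closed to
#'   relative abundances internally).
#' @param metadata metadata data.frame pairing the table's samples.
#' @param control_group label of the additive-free reference group.
#' @param config an [age_model_config()].
#' @param delta plateau tolerance (default 0.05).
#' @return a `maturity_analysis` list: `ranking`, `selection`, `model`,
#'   `predictions` (per-sample data.frame), `curves` (per group), `immi`
#'   (per group).
#' @export
run_maturity_analysis <- function(table, metadata, control_group = "control",
                                  config = age_model_config(),
                                  delta = 0.05) {
  validate_pairing(table, metadata)
  if (!control_group %in% metadata$group)
    stop("control_group '", control_group, "' not present in metadata")
  rel <- to_relative(table)
  meta <- metadata[match(sample_ids(rel), metadata$sample_id), ]

  ctrl_ids <- meta$sample_id[meta$group == control_group]
  ctrl <- subset_table(rel, samples = ctrl_ids)
  ctrl_ages <- meta$age_days[match(ctrl_ids, meta$sample_id)]

  ranking <- rank_taxa_by_importance(ctrl, ctrl_ages, config)
  selection <- select_feature_count(ctrl, ctrl_ages, ranking, config)
  model <- fit_age_model(ctrl, ctrl_ages, ranking, selection$k, config)

  pred <- predict_microbiota_age(model, rel)
  predictions <- data.frame(sample_id = names(pred),
                            group = meta$group,
                            age_days = meta$age_days,
                            microbiota_age = unname(pred),
                            stringsAsFactors = FALSE)

  groups <- unique(meta$group)
  curves <- lapply(setNames(groups, groups), function(g) {
    sub <- predictions[predictions$group == g, ]
    fit_maturity_curve(sub$microbiota_age, sub$age_days, group = g,
                       delta = delta, model_id = model$model_id)
  })
  immi <- lapply(curves, function(cv) compute_immi(curves[[control_group]], cv))
  structure(list(ranking = ranking, selection = selection, model = model,
                 predictions = predictions, curves = curves, immi = immi,
                 control_group = control_group),
            class = "maturity_analysis")
}

#' @export
print.maturity_analysis <- function(x, ...) {
  cat("Microbiota maturation analysis\n")
  cat(sprintf("  model: %d taxa, OOB R2 = %.3f\n",
              nrow(x$model$selected_taxa), x$model$train_r2))
  for (g in names(x$immi)) {
    im <- x$immi[[g]]
    cat(sprintf("  IMMI [%s]: %g days%s\n", g, im$immi_days,
                if (im$censored) " (censored)" else ""))
  }
  invisible(x)
}
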