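#' Alpha diversity of count samples
#'
#' Per sample: observed richness (taxa with count > 0), Shannon index in
#' natural log units (`-sum(p log p)`), Gini-Simpson index
#' (`1 - sum(p^2)`), and the bias-corrected Chao1 richness estimate
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` with `F1`/`F2` the singleton and
#' doubleton counts (defined even when `F2 = 0`).
#'
#' @param table `abundance_table` of counts.
#' @param base logarithm base for Shannon (default `exp(1)`; use 2 for
#'   bits).
#' @return data.frame with `sample_id`, `observed`, `shannon`, `simpson`,
#'   `chao1`.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$kind != "counts")
    stop("alpha diversity (observed/chao1) requires counts")
  v <- table$values
  out <- lapply(seq_len(ncol(v)), function(j) {
    cnt <- v[, j]
    tot <- sum(cnt)
    if (tot < 1) stop("empty sample: ", colnames(v)[j])
    p <- cnt[cnt > 0] / tot
    f1 <- sum(cnt == 1)
    f2 <- sum(cnt == 2)
    s_obs <- sum(cnt > 0)
    data.frame(sample_id = colnames(v)[j], observed = s_obs,
               shannon = -sum(p * log(p, base = base)),
               simpson = 1 - sum(p^2),
               chao1 = s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Between-sample distance matrix
#'
#' Computes a symmetric beta-diversity distance matrix on relative
#' abundances. Bray-Curtis is the default; any dissimilarity supported by
#' `vegan::vegdist` may be named.
#'
#' @param table `abundance_table`; counts are closed to relative
#'   abundances first.
#' @param metric distance name (default `"bray"`; `"bray-curtis"` is an
#'   accepted alias).
#' @return a `dist` object over samples.
#' @export
beta_distance <- function(table, metric = "bray") {
  rel <- to_relative(table)
  metric <- tolower(metric)
  if (metric %in% c("bray-curtis", "braycurtis")) metric <- "bray"
  supported <- c("bray", "jaccard", "euclidean", "manhattan", "canberra",
                 "kulczynski", "gower", "horn", "binomial", "chao")
  if (!metric %in% supported)
    stop("unknown metric '", metric, "'; supported: ",
         paste(supported, collapse = ", "))
  vegan::vegdist(t(rel$values), method = metric)
}

as_label_ints <- function(groups) {
  f <- as.factor(groups)
  if (nlevels(f) < 2) stop("need >= 2 groups")
  if (any(table(f) < 2)) stop("every group needs >= 2 samples")
  as.integer(f) - 1L
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F statistic
#' is computed from among/within sums of squared distances and its p-value
#' from random label permutations,
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_permutations)`. A distance
#' matrix with no variation is degenerate and reported with `NA` statistic
#' and p = 1.
#'
#' @param dist a `dist` or symmetric distance matrix.
#' @param groups group label per sample.
#' @param n_permutations label permutations (default 999).
#' @param seed optional integer seed.
#' @return a `group_test_result`: `method`, `statistic`, `p`,
#'   `n_permutations`.
#' @export
permanova <- function(dist, groups, n_permutations = 999, seed = NULL) {
  d <- as.matrix(dist)
  if (nrow(d) != length(groups)) stop("groups must align with dist")
  g <- as_label_ints(groups)
  if (!is.null(seed)) set.seed(seed)
  if (max(d) == 0) {
    res <- list(statistic = NA_real_, p = 1)
  } else {
    res <- permanova_perm_cpp(d^2, g, as.integer(n_permutations))
    if (!is.finite(res$statistic)) res <- list(statistic = NA_real_, p = 1)
  }
  structure(list(method = "PERMANOVA", statistic = res$statistic,
                 p = res$p, n_permutations = n_permutations),
            class = "group_test_result")
}

#' ANOSIM on a distance matrix
#'
#' Analysis of similarities: the R statistic contrasts mean between-group
#' and within-group distance ranks, scaled to \[-1, 1\]; the p-value comes
#' from label permutations (one-sided, large R). R is invariant to any
#' strictly monotone transform of the distances.
#'
#' @inheritParams permanova
#' @return a `group_test_result` with `method = "ANOSIM"`.
#' @export
anosim <- function(dist, groups, n_permutations = 999, seed = NULL) {
  d <- as.matrix(dist)
  if (nrow(d) != length(groups)) stop("groups must align with dist")
  g <- as_label_ints(groups)
  if (!is.null(seed)) set.seed(seed)
  # average ranks over the n(n-1)/2 unique distances, mirrored into a matrix
  ut <- upper.tri(d)
  rd <- d
  rd[ut] <- rank(d[ut])
  rd[lower.tri(rd)] <- t(rd)[lower.tri(rd)]
  res <- anosim_perm_cpp(rd, g, as.integer(n_permutations))
  structure(list(method = "ANOSIM", statistic = res$statistic, p = res$p,
                 n_permutations = n_permutations),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%d permutations)\n",
              x$method, x$statistic, x$p, x$n_permutations))
  invisible(x)
}

#' Per-genus Kruskal-Wallis tests, stratified by time point
#'
#' For every time point with at least two groups present, runs a
#' tie-corrected Kruskal-Wallis test of each genus across groups and
#' adjusts p-values (BH) within the time point. Genera constant across a
#' time point's samples get p = 1.
#'
#' @param table `abundance_table` (relative or counts).
#' @param metadata paired metadata (`group`, `age_days`).
#' @return data.frame with `age_days`, `taxon`, `statistic`, `p`, `p_adj`.
#' @export
genus_kruskal <- function(table, metadata) {
  validate_pairing(table, metadata)
  meta <- metadata[match(sample_ids(table), metadata$sample_id), ]
  out <- list()
  for (d in sort(unique(meta$age_days))) {
    ids <- meta$sample_id[meta$age_days == d]
    grp <- as.factor(meta$group[meta$age_days == d])
    if (nlevels(droplevels(grp)) < 2) next
    sub <- table$values[, ids, drop = FALSE]
    res <- apply(sub, 1, function(row) {
      if (max(row) == min(row)) return(c(NA_real_, 1))
      kt <- kruskal.test(row, droplevels(grp))
      c(unname(kt$statistic), kt$p.value)
    })
    df <- data.frame(age_days = d, taxon = rownames(sub),
                     statistic = res[1, ], p = res[2, ],
                     stringsAsFactors = FALSE, row.names = NULL)
    df$p_adj <- p.adjust(df$p, method = "BH")
    out[[as.character(d)]] <- df
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
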