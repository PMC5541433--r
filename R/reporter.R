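#' Per-KO differential testing across treatment groups
#'
#' Tie-corrected Kruskal-Wallis test of each KO's abundance across the
#' treatment groups, with Benjamini-Hochberg adjustment over all tested
#' KOs. KOs with adjusted p below `marker_alpha` form the functional-marker
#' set. A KO constant across all samples is degenerate and reported with
#' p = 1 rather than raising an error.
#'
#' @param table KO `abundance_table` (KO x samples).
#' @param groups group label per sample, aligned with the table's columns.
#' @param marker_alpha adjusted-p cutoff flagging marker KOs (default 0.1).
#' @return data.frame with `ko`, `statistic`, `p`, `p_adj`, `marker`.
#' @export
ko_differential_test <- function(table, groups, marker_alpha = 0.1) {
  stopifnot(inherits(table, "abundance_table"))
  groups <- as.factor(groups)
  if (length(groups) != ncol(table$values))
    stop("groups must align with table samples")
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 samples")
  v <- table$values
  res <- apply(v, 1, function(row) {
    if (max(row) == min(row)) return(c(NA_real_, 1))
    kt <- kruskal.test(row, groups)
    c(unname(kt$statistic), kt$p.value)
  })
  out <- data.frame(ko = rownames(v), statistic = res[1, ], p = res[2, ],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$marker <- out$p_adj < marker_alpha
  out
}

#' KO Z-score from an adjusted p-value
#'
#' `z = qnorm(1 - p_adj)`, the inverse normal CDF of one minus the adjusted
#' p-value. p-values are clipped to `[eps, 1 - eps]` (default
#' `eps = 1e-15`) so the score stays finite at p = 0 or 1. The score is
#' significance-only: direction of change is not encoded.
#'
#' @param p_adj adjusted p-value(s) in \[0, 1\].
#' @param eps clipping bound (default 1e-15).
#' @return finite Z score(s).
#' @export
ko_zscore <- function(p_adj, eps = 1e-15) {
  if (any(p_adj < 0 | p_adj > 1, na.rm = TRUE))
    stop("p_adj must lie in [0, 1]")
  # clip the upper-tail probability directly: numerically equivalent to
  # clipping p and forming 1 - p, but avoids cancellation near p = 1
  qnorm(pmin(pmax(1 - p_adj, eps), 1 - eps))
}

#' Aggregated pathway Z-score
#'
#' `z_pathway = sum(z) / sqrt(k)` where `k` is the number of member KOs
#' that have test results.
#'
#' @param z Z-scores of the pathway's tested member KOs (length k >= 1).
#' @return the aggregated score.
#' @export
pathway_zscore <- function(z) {
  if (length(z) < 1) stop("pathway has no tested member KOs")
  sum(z) / sqrt(length(z))
}

#' Background-correct a pathway score against random KO sets
#'
#' Draws `n_sets` random size-`k` KO subsets (without replacement within a
#' set) from all tested KOs, computes their aggregated scores, and
#' standardizes the pathway score by the background mean and SD:
#' `z_adjusted = (z_pathway - mu_k) / sigma_k`.
#'
#' @param z_pathway aggregated score of the pathway.
#' @param k member count of the pathway.
#' @param all_ko_z Z-scores of the whole tested KO universe.
#' @param n_sets number of random background sets (default 1000).
#' @param seed optional integer seed.
#' @return list with `mu_k`, `sigma_k`, `z_adjusted`.
#' @export
background_correct <- function(z_pathway, k, all_ko_z, n_sets = 1000,
                               seed = NULL) {
  if (k > length(all_ko_z)) stop("k exceeds the tested KO universe")
  if (n_sets < 2) stop("n_sets must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  bg <- vapply(seq_len(n_sets), function(i)
    sum(all_ko_z[sample.int(length(all_ko_z), k)]) / sqrt(k), numeric(1))
  mu <- mean(bg)
  sigma <- sd(bg)
  if (!is.finite(sigma) || sigma == 0)
    stop("background SD is zero; adjusted score undefined for this pathway")
  list(mu_k = mu, sigma_k = sigma, z_adjusted = (z_pathway - mu) / sigma)
}

#' Reporter scores for a set of pathways
#'
#' End-to-end pathway enrichment: per-KO Kruskal-Wallis tests, KO Z-scores
#' from BH-adjusted p-values, aggregated pathway scores scaled by
#' `1/sqrt(k)`, and background standardization against `n_sets` random
#' same-size KO sets drawn from the tested KO universe. A pathway whose
#' member set has no tested KOs is skipped with a warning. Pathways with
#' `z_adjusted >= threshold` are called significantly enriched.
#'
#' @inheritParams ko_differential_test
#' @param pathways a `pathway_map` (named list of KO id vectors).
#' @param threshold detection threshold on the adjusted score (default 1.6,
#'   inclusive).
#' @param n_sets random background sets (default 1000).
#' @param seed optional integer seed for the background draws.
#' @param ko_results optionally, a precomputed [ko_differential_test()]
#'   result to reuse.
#' @return a `reporter_result`: `ko_results` and `scores` (data.frame with
#'   `pathway`, `k`, `z_pathway`, `mu_k`, `sigma_k`, `z_adjusted`,
#'   `significant`).
#' @export
reporter_scores <- function(table, groups, pathways, threshold = 1.6,
                            n_sets = 1000, seed = NULL, ko_results = NULL) {
  if (is.null(ko_results))
    ko_results <- ko_differential_test(table, groups)
  z <- setNames(ko_zscore(ko_results$p_adj), ko_results$ko)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(pathways), function(pw) {
    members <- intersect(pathways[[pw]], names(z))
    if (length(members) == 0) {
      warning("pathway ", pw, " has no tested member KOs; skipped")
      return(NULL)
    }
    k <- length(members)
    zp <- pathway_zscore(z[members])
    bg <- background_correct(zp, k, z, n_sets = n_sets)
    data.frame(pathway = pw, k = k, z_pathway = zp, mu_k = bg$mu_k,
               sigma_k = bg$sigma_k, z_adjusted = bg$z_adjusted,
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, rows)
  if (is.null(scores))
    scores <- data.frame(pathway = character(0), k = integer(0),
                         z_pathway = numeric(0), mu_k = numeric(0),
                         sigma_k = numeric(0), z_adjusted = numeric(0))
  scores$significant <- scores$z_adjusted >= threshold
  structure(list(ko_results = ko_results, scores = scores,
                 threshold = threshold),
            class = "reporter_result")
}

#' @export
print.reporter_result <- function(x, ...) {
  cat(sprintf(
    "Reporter-score enrichment: %d pathways scored, %d significant (>= %.2f)\n",
    nrow(x$scores), sum(x$scores$significant), x$threshold))
  invisible(x)
}

#' Call enriched pathways from reporter scores
#'
#' @param scores the `scores` data.frame of a [reporter_scores()] result
#'   (or the result object itself).
#' @param threshold adjusted-score threshold, inclusive (default 1.6).
#' @return character vector of significant pathway ids.
#' @export
call_enriched_pathways <- function(scores, threshold = 1.6) {
  if (inherits(scores, "reporter_result")) scores <- scores$scores
  if (nrow(scores) == 0) return(character(0))
  scores$pathway[scores$z_adjusted >= threshold]
}

#' PCA group separation on KO profiles
#'
#' Centered principal component analysis of the samples x KO matrix,
#' reporting each component's variance fraction and pairwise two-group
#' t-test p-values on the component scores.
#'
#' @inheritParams ko_differential_test
#' @param n_components components to test (default 2).
#' @return list with `variance_fraction` (full spectrum) and `tests`
#'   (data.frame: `component`, `group_a`, `group_b`, `p`).
#' @export
pc_group_separation <- function(table, groups, n_components = 2) {
  stopifnot(inherits(table, "abundance_table"))
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  x <- t(table$values)
  if (nrow(x) < 3) stop("need >= 3 samples for PCA group tests")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  n_components <- min(n_components, ncol(pc$x))
  combos <- utils::combn(levels(groups), 2)
  tests <- do.call(rbind, lapply(seq_len(n_components), function(ci) {
    do.call(rbind, lapply(seq_len(ncol(combos)), function(j) {
      a <- pc$x[groups == combos[1, j], ci]
      b <- pc$x[groups == combos[2, j], ci]
      data.frame(component = ci, group_a = combos[1, j],
                 group_b = combos[2, j],
                 p = tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(variance_fraction = varfrac, tests = tests)
}
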