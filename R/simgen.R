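#' Logistic taxon trajectory
#'
#' Describes how one taxon's expected (un-normalized) abundance changes with
#' host age: a logistic rise (or fall) from `baseline` towards
#' `baseline + amplitude`, centred at `midpoint_day` with steepness `rate`.
#' Decreasing taxa carry a negative amplitude. These trajectories emulate
#' age-discriminatory genera whose relative abundance tracks host age.
#'
#' @param taxon_id identifier.
#' @param baseline non-negative mean abundance at young age (arbitrary units).
#' @param amplitude signed change magnitude; `baseline + min(0, amplitude)`
#'   must be >= 0 so expected abundance stays non-negative.
#' @param midpoint_day day at which half the change has occurred.
#' @param rate logistic steepness (1/day), > 0.
#' @return a `taxon_trajectory` object.
#' @export
taxon_trajectory <- function(taxon_id, baseline, amplitude, midpoint_day,
                             rate) {
  if (baseline < 0) stop("baseline must be non-negative")
  if (rate <= 0) stop("rate must be > 0")
  if (baseline + min(0, amplitude) < -1e-12)
    stop("decreasing trajectory would go negative: |amplitude| > baseline")
  structure(list(taxon_id = as.character(taxon_id), baseline = baseline,
                 amplitude = amplitude, midpoint_day = midpoint_day,
                 rate = rate,
                 direction = if (amplitude >= 0) "increasing" else "decreasing"),
            class = "taxon_trajectory")
}

#' Expected abundance of a trajectory at a (possibly warped) age
#'
#' Computes `baseline + amplitude * sigma(rate * (warp * age - midpoint))`
#' with `sigma` the logistic function, clipped at 0. The time-warp factor
#' `warp` rescales chronologic age: `warp > 1` models accelerated maturation
#' (e.g. a probiotic additive), `warp < 1` delayed maturation (e.g.
#' antibiotics). By construction the expected abundance at age `t` under
#' warp `g` equals the abundance at age `g * t` under warp 1.
#'
#' @param traj a [taxon_trajectory()].
#' @param age_days chronologic age(s), >= 0.
#' @param warp positive time-scale factor (default 1).
#' @return non-negative expected abundance(s).
#' @export
taxon_expected_abundance <- function(traj, age_days, warp = 1) {
  stopifnot(inherits(traj, "taxon_trajectory"))
  if (any(age_days < 0)) stop("age_days must be >= 0")
  if (warp <= 0) stop("warp must be > 0")
  s <- 1 / (1 + exp(-traj$rate * (warp * age_days - traj$midpoint_day)))
  pmax(traj$baseline + traj$amplitude * s, 0)
}

#' Default trajectory set for a synthetic cohort
#'
#' Draws `n_age_taxa` logistic trajectories (half increasing, half
#' decreasing) plus `n_taxa - n_age_taxa` flat taxa whose constant baselines
#' come from a long-tailed log-normal, so that importance ranking faces
#' realistic competition. Midpoints are drawn uniformly on `midpoint_range`
#' and rates on `rate_range`; the defaults (midpoints in days 12-24, rates
#' 0.4-0.6/day) are calibrated so that the reference group's fitted
#' microbiota-age curve reaches 95% of its plateau at about day 30 and is
#' genuinely flat before the end of the observation window - the engineered
#' "full maturity" behaviour the recovery tests invert.
#'
#' @param n_taxa total number of taxa (default 40).
#' @param n_age_taxa number of age-tracking taxa (default 12).
#' @param midpoint_range,rate_range uniform draw ranges for midpoint day and
#'   logistic rate.
#' @param seed optional integer seed.
#' @return list of [taxon_trajectory()] objects, length `n_taxa`; the first
#'   `n_age_taxa` are the age-discriminatory ones (ids `age_taxon_1` ...).
#' @export
make_trajectories <- function(n_taxa = 40, n_age_taxa = 12,
                              midpoint_range = c(12, 24),
                              rate_range = c(0.4, 0.6), seed = NULL) {
  if (n_age_taxa > n_taxa) stop("n_age_taxa must be <= n_taxa")
  if (!is.null(seed)) set.seed(seed)
  trajs <- vector("list", n_taxa)
  for (i in seq_len(n_age_taxa)) {
    increasing <- (i %% 2 == 1)
    base <- rlnorm(1, meanlog = 3, sdlog = 0.6)
    amp <- rlnorm(1, meanlog = 3.5, sdlog = 0.4)
    if (!increasing) {
      # start high, decay towards a small floor
      base <- base + amp
      amp <- -amp * runif(1, 0.7, 0.95)
    }
    trajs[[i]] <- taxon_trajectory(
      paste0("age_taxon_", i), baseline = base, amplitude = amp,
      midpoint_day = runif(1, midpoint_range[1], midpoint_range[2]),
      rate = runif(1, rate_range[1], rate_range[2]))
  }
  for (i in seq_len(n_taxa - n_age_taxa)) {
    trajs[[n_age_taxa + i]] <- taxon_trajectory(
      paste0("taxon_", i), baseline = rlnorm(1, meanlog = 3, sdlog = 1.2),
      amplitude = 0, midpoint_day = 20, rate = 0.4)
  }
  trajs
}

#' Cohort simulation configuration
#'
#' @param n_taxa,n_age_taxa totals passed to [make_trajectories()] when no
#'   explicit trajectory list is supplied.
#' @param sampling_days strictly increasing sampling days, all >= 1. The
#'   default is a dense grid every 3 days over the 42-day rearing period;
#'   the study-like sparse design `c(1, 7, 28, 42)` can be requested but
#'   makes plateau detection coarse.
#' @param n_per_day samples per day per group (default 6).
#' @param groups named numeric vector of time-warp factors, one per group
#'   (default `c(control = 1, probiotic = 2, antibiotic = 0.75)`).
#' @param noise_sd SD of per-sample log-scale multiplicative noise
#'   (default 0.3).
#' @param depth multinomial sequencing depth per sample (default 2490, the
#'   conventional rarefaction depth for this design).
#' @param seed integer seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_taxa = 40, n_age_taxa = 12,
                          sampling_days = seq(1, 42, by = 3), n_per_day = 6,
                          groups = c(control = 1, probiotic = 2,
                                     antibiotic = 0.75),
                          noise_sd = 0.3, depth = 2490, seed = 1) {
  if (n_age_taxa > n_taxa) stop("n_age_taxa must be <= n_taxa")
  if (any(diff(sampling_days) <= 0) || any(sampling_days < 1))
    stop("sampling_days must be strictly increasing and >= 1")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named vector of warp factors")
  if (any(groups <= 0)) stop("group warp factors must be > 0")
  if (depth < 1) stop("depth must be >= 1")
  if (n_per_day < 1) stop("n_per_day must be >= 1")
  structure(list(n_taxa = n_taxa, n_age_taxa = n_age_taxa,
                 sampling_days = sampling_days, n_per_day = n_per_day,
                 groups = groups, noise_sd = noise_sd, depth = depth,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic longitudinal cohort
#'
#' For every group and sampling day, expected per-taxon abundances are read
#' off the (time-warped) trajectories, multiplied by per-sample log-normal
#' noise, closed to a composition and sampled as multinomial counts at the
#' configured depth. Samples are treated as independent (within-subject
#' longitudinal correlation is not modelled).
#'
#' @param config a [cohort_config()].
#' @param trajectories optional list of [taxon_trajectory()]; default
#'   [make_trajectories()] drawn from the config's seed.
#' @return list with `table` (an `abundance_table` of counts), `metadata`
#'   (sample_id/subject_id/group/age_days), and `truth` (per-group warp and
#'   the age-taxon ids).
#' @export
generate_cohort <- function(config, trajectories = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  if (is.null(trajectories))
    trajectories <- make_trajectories(config$n_taxa, config$n_age_taxa)
  n_taxa <- length(trajectories)
  taxa <- vapply(trajectories, `[[`, character(1), "taxon_id")
  n_per <- config$n_per_day
  days <- config$sampling_days
  n_samples <- length(config$groups) * length(days) * n_per
  if (n_samples == 0) stop("configuration yields zero samples")

  values <- matrix(0L, n_taxa, n_samples, dimnames = list(taxa, NULL))
  meta <- data.frame(sample_id = character(n_samples),
                     subject_id = character(n_samples),
                     group = character(n_samples),
                     age_days = integer(n_samples),
                     stringsAsFactors = FALSE)
  col <- 0L
  for (g in names(config$groups)) {
    warp <- config$groups[[g]]
    for (d in days) {
      expected <- vapply(trajectories, taxon_expected_abundance,
                         numeric(1), age_days = d, warp = warp)
      for (r in seq_len(n_per)) {
        col <- col + 1L
        noisy <- expected * exp(rnorm(n_taxa, 0, config$noise_sd))
        if (sum(noisy) <= 0) noisy <- rep(1, n_taxa)
        prob <- noisy / sum(noisy)
        values[, col] <- rmultinom(1, size = config$depth, prob = prob)[, 1]
        meta$sample_id[col] <- sprintf("%s_d%02d_r%d", g, d, r)
        meta$subject_id[col] <- sprintf("%s_subj%d", g, r)
        meta$group[col] <- g
        meta$age_days[col] <- as.integer(d)
      }
    }
  }
  colnames(values) <- meta$sample_id
  list(table = abundance_table(values, kind = "counts"),
       metadata = meta,
       truth = list(warp = config$groups,
                    age_taxa = taxa[seq_len(min(config$n_age_taxa, n_taxa))]))
}

#' KO study simulation configuration
#'
#' @param n_kos total KOs (default 400).
#' @param n_pathways number of pathways (default 40).
#' @param kos_per_pathway members per pathway (default 10); pathways tile
#'   the first `n_pathways * kos_per_pathway` KOs, so this product must not
#'   exceed `n_kos`.
#' @param enriched_pathways pathway ids carrying a group shift (default
#'   none).
#' @param effect_size multiplicative mean shift applied to member KOs in
#'   exactly one group (default 2).
#' @param n_samples_per_group samples per group (default 10).
#' @param groups group labels (default control/probiotic/antibiotic; the
#'   shift lands on the second group).
#' @param noise_sd log-normal noise SD around KO means (default 0.5).
#' @param seed integer seed.
#' @return a `ko_study_config` list.
#' @export
ko_study_config <- function(n_kos = 400, n_pathways = 40,
                            kos_per_pathway = 10,
                            enriched_pathways = character(0),
                            effect_size = 2, n_samples_per_group = 10,
                            groups = c("control", "probiotic", "antibiotic"),
                            noise_sd = 0.5, seed = 1) {
  if (n_pathways * kos_per_pathway > n_kos)
    stop("n_pathways * kos_per_pathway must be <= n_kos")
  if (effect_size <= 0) stop("effect_size must be > 0")
  ids <- sprintf("ko%05d", seq_len(n_pathways))
  unknown <- setdiff(enriched_pathways, ids)
  if (length(unknown))
    stop("enriched_pathways not among defined pathways: ",
         paste(unknown, collapse = ", "))
  structure(list(n_kos = n_kos, n_pathways = n_pathways,
                 kos_per_pathway = kos_per_pathway,
                 enriched_pathways = enriched_pathways,
                 effect_size = effect_size,
                 n_samples_per_group = n_samples_per_group,
                 groups = groups, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ko_study_config")
}

#' Generate a synthetic KO abundance study
#'
#' Non-enriched KOs share one group-independent log-normal distribution;
#' member KOs of each enriched pathway have their mean multiplied by
#' `effect_size` in exactly one group (the second group label). Pathways
#' partition the first `n_pathways * kos_per_pathway` KOs.
#'
#' @param config a [ko_study_config()].
#' @return list with `table` (`abundance_table`, KO x samples), `metadata`,
#'   `pathways` (a `pathway_map`), and `truth` (enriched pathway ids and the
#'   shifted group).
#' @export
generate_ko_study <- function(config) {
  stopifnot(inherits(config, "ko_study_config"))
  set.seed(config$seed)
  kos <- sprintf("K%05d", seq_len(config$n_kos))
  pw_ids <- sprintf("ko%05d", seq_len(config$n_pathways))
  members <- split(kos[seq_len(config$n_pathways * config$kos_per_pathway)],
                   rep(pw_ids, each = config$kos_per_pathway))
  members <- members[pw_ids]
  pathways <- structure(members, class = "pathway_map")

  ko_mean <- rlnorm(config$n_kos, meanlog = 4, sdlog = 0.8)
  names(ko_mean) <- kos
  shifted_group <- config$groups[min(2, length(config$groups))]
  enriched_kos <- unlist(members[config$enriched_pathways], use.names = FALSE)

  n_per <- config$n_samples_per_group
  n_samples <- n_per * length(config$groups)
  values <- matrix(0, config$n_kos, n_samples, dimnames = list(kos, NULL))
  meta <- data.frame(sample_id = character(n_samples),
                     subject_id = character(n_samples),
                     group = character(n_samples),
                     age_days = 42L, stringsAsFactors = FALSE)
  col <- 0L
  for (g in config$groups) {
    mu <- ko_mean
    if (g == shifted_group && length(enriched_kos))
      mu[enriched_kos] <- mu[enriched_kos] * config$effect_size
    for (r in seq_len(n_per)) {
      col <- col + 1L
      values[, col] <- mu * exp(rnorm(config$n_kos, 0, config$noise_sd))
      meta$sample_id[col] <- sprintf("%s_s%02d", g, r)
      meta$subject_id[col] <- sprintf("%s_subj%d", g, r)
      meta$group[col] <- g
    }
  }
  colnames(values) <- meta$sample_id
  list(table = abundance_table(values, kind = "abundance"),
       metadata = meta, pathways = pathways,
       truth = list(enriched_pathways = config$enriched_pathways,
                    shifted_group = unname(shifted_group)))
}

#' Generate abundance blocks with planted monotone dependence
#'
#' Each block shares a latent Gaussian factor: within a block every taxon is
#' `loading * sqrt(strength) * factor + sqrt(1 - strength) * noise`, pushed
#' through `exp()` so abundances are positive and Spearman correlations are
#' preserved. Positive-sign blocks use all-positive loadings (pairwise rho
#' -> +strength for large n); negative-sign blocks make the first taxon a
#' hub with positive loading and the rest negative, so hub-vs-member
#' correlations approach `-strength` (for a block of size 2 this is a simple
#' antitone pair). Blocks are mutually independent.
#'
#' @param n_samples number of samples (>= 3).
#' @param blocks list of blocks, each `list(size =, sign = "+"/"-",
#'   strength = in [0,1])`.
#' @param n_noise_taxa additional independent taxa appended (default 0).
#' @param seed optional integer seed.
#' @return list with `table` (an `abundance_table` of positive raw values,
#'   kind `"abundance"`; columns are not closed, see source comment) and
#'   `truth` (block membership per taxon).
#' @export
generate_correlated_block <- function(n_samples, blocks, n_noise_taxa = 0,
                                      seed = NULL) {
  if (n_samples < 3)
    stop("n_samples must be >= 3 for meaningful rank correlation")
  if (!is.null(seed)) set.seed(seed)
  mats <- list()
  membership <- character(0)
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    if (bl$strength < 0 || bl$strength > 1)
      stop("strength must be in [0, 1]")
    if (bl$size < 1) stop("block size must be >= 1")
    u <- rnorm(n_samples)
    m <- matrix(0, bl$size, n_samples)
    for (i in seq_len(bl$size)) {
      loading <- if (identical(bl$sign, "-") && i > 1) -1 else 1
      m[i, ] <- loading * sqrt(bl$strength) * u +
        sqrt(1 - bl$strength) * rnorm(n_samples)
    }
    rownames(m) <- sprintf("block%d_taxon%d", b, seq_len(bl$size))
    mats[[b]] <- m
    membership <- c(membership, rep(paste0("block", b), bl$size))
  }
  if (n_noise_taxa > 0) {
    m <- matrix(rnorm(n_noise_taxa * n_samples), n_noise_taxa, n_samples)
    rownames(m) <- sprintf("noise_taxon%d", seq_len(n_noise_taxa))
    mats[[length(mats) + 1]] <- m
    membership <- c(membership, rep("noise", n_noise_taxa))
  }
  latent <- do.call(rbind, mats)
  colnames(latent) <- sprintf("S%03d", seq_len(n_samples))
  # exp() is monotone (keeps the Spearman structure) and makes values
  # positive; columns are deliberately NOT closed to 1 - compositional
  # closure would induce spurious negative correlation among taxa and break
  # the planted independence across blocks
  ab <- exp(latent)
  list(table = abundance_table(ab, kind = "abundance"),
       truth = setNames(membership, rownames(latent)))
}
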