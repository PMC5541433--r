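# Shared in-code fixtures; everything is generated, nothing read from disk.

toy_counts <- function() {
  matrix(c(2, 1,
           3, 0,
           5, 4), nrow = 3, byrow = TRUE,
         dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
}

toy_table <- function() abundance_table(toy_counts(), kind = "counts")

toy_metadata <- function(ids, groups, ages) {
  data.frame(sample_id = ids, subject_id = paste0("subj_", seq_along(ids)),
             group = groups, age_days = as.integer(ages),
             stringsAsFactors = FALSE)
}

# small cohort for fast maturity tests
small_cohort <- function(seed = 1, groups = c(control = 1, probiotic = 2,
                                              antibiotic = 0.75)) {
  generate_cohort(cohort_config(n_taxa = 25, n_age_taxa = 8,
                                sampling_days = seq(1, 42, by = 3),
                                n_per_day = 4, groups = groups,
                                depth = 800, seed = seed))
}

fast_config <- function(seed = 1, n_trees = 150, iters = 10)
  age_model_config(n_trees = n_trees, n_importance_iters = iters,
                   cv_folds = 5, seed = seed)

# build a correlation_network directly from an edge list (test scaffolding
# for the closed-form graph metrics)
graph_fixture <- function(nodes, edges) {
  e <- if (length(edges)) do.call(rbind, lapply(edges, function(p)
    data.frame(taxon_a = p[1], taxon_b = p[2], rho = 0.5, q = 0.01,
               sign = "+", stringsAsFactors = FALSE)))
  else data.frame(taxon_a = character(0), taxon_b = character(0),
                  rho = numeric(0), q = numeric(0), sign = character(0))
  structure(list(nodes = nodes, edges = e), class = "correlation_network")
}
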