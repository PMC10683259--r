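# Ground-truth validation studies: parameter recovery, selection
# calibration and enrichment calibration on synthetic cohorts. These
# drive the package's acceptance checks and give users a template for
# judging whether the pipeline can recover structure like that of
# their own data.

#' Parameter-recovery study on synthetic cohorts
#'
#' For each seed: generate a default cohort, impute and fit the
#' risk-profile model, extract sparse-PLS patterns using the selected
#' dimensions as the response, and project the patterns onto follow-up
#' and external-cohort methylation. Per planted latent factor it
#' records the best-matched absolute correlations of (a) a selected
#' dimension, (b) a training component score, (c) projected follow-up
#' and (d) external component scores, plus the precision with which
#' the matched component's top representative CpGs recover the planted
#' pattern membership.
#'
#' @param n_seeds number of independent replicates.
#' @param base_seed seed from which per-replicate seeds derive.
#' @param n_dims,n_components,keep_x analysis settings.
#' @param config_fn function(seed) returning a [generator_config()];
#'   defaults to the package's reference study conditions.
#' @return data.frame, one row per seed x latent factor, with columns
#'   `dim_r`, `comp_r`, `precision`, `followup_r`, `external_r`.
#' @export
parameter_recovery_study <- function(n_seeds = 20L, base_seed = 1L,
                                     n_dims = 5L, n_components = 20L,
                                     keep_x = 250L,
                                     config_fn = function(seed)
                                       generator_config(seed = seed)) {
  rows <- list()
  for (i in seq_len(n_seeds)) {
    seed <- derive_seed(base_seed, i)
    sim <- generate_cohort(config_fn(seed))
    truth <- sim$truth
    k <- truth$config$n_latent

    completed <- suppressWarnings(
      impute_famd(sim$cohort, variables = truth$risk_variable_names,
                  n_dims = n_dims))
    mrp <- famd_fit(completed, truth$risk_variable_names)
    dims <- select_dimensions(mrp, "top_k", k = n_dims)
    dim_scores <- mrp$scores[, dims, drop = FALSE]

    patterns <- spls_fit(sim$meth, dim_scores,
                         n_components = n_components, keep_x = keep_x)
    followup <- generate_followup_methylation(truth, age_label = 7,
                                              seed = derive_seed(seed, 1L))
    external <- generate_external_cohort(truth,
                                         n = truth$config$n_subjects,
                                         seed = derive_seed(seed, 2L))
    proj_fu <- project_patterns(patterns, followup)
    proj_ex <- project_patterns(patterns, external$meth)

    r_dim <- abs(stats::cor(dim_scores, truth$latent_scores))
    r_comp <- abs(stats::cor(patterns$scores, truth$latent_scores))
    r_fu <- abs(stats::cor(proj_fu, truth$latent_scores))
    r_ex <- abs(stats::cor(proj_ex, external$latent_scores))
    for (j in seq_len(k)) {
      h <- which.max(r_comp[, j])
      members <- names(which(truth$pattern_membership == j))
      top <- representative_cpgs(patterns, h, top = length(members))$cpg
      rows[[length(rows) + 1L]] <- data.frame(
        seed = seed, latent = j,
        dim_r = max(r_dim[, j]),
        comp_r = max(r_comp[, j]),
        precision = mean(top %in% members),
        followup_r = max(r_fu[, j]),
        external_r = max(r_ex[, j]))
    }
  }
  do.call(rbind, rows)
}

#' Selection calibration under a global null
#'
#' Runs shadow-variable selection on pure-noise predictors and
#' outcomes and reports the confirmed fraction per seed; under the
#' null its mean estimates the procedure's false-confirmation rate.
#'
#' @param n_seeds number of replicates.
#' @param n,p cases and candidate predictors per replicate.
#' @param base_seed seed from which replicate seeds derive.
#' @param config a [boruta_config()] template (its seed is replaced
#'   per replicate).
#' @return data.frame with `seed` and `confirmed_fraction`.
#' @export
selection_null_study <- function(n_seeds = 50L, n = 200L, p = 20L,
                                 base_seed = 1L,
                                 config = boruta_config(max_runs = 40L)) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    seed <- derive_seed(base_seed, 1000L + i)
    dat <- with_seed(seed, {
      list(X = as.data.frame(matrix(stats::rnorm(n * p), n, p,
                                    dimnames = list(NULL, paste0("v", seq_len(p))))),
           y = stats::rnorm(n))
    })
    cfg <- config
    cfg$seed <- seed
    sel <- boruta_select(dat$X, dat$y, config = cfg)
    data.frame(seed = seed,
               confirmed_fraction = length(sel$confirmed) / p)
  })
  do.call(rbind, rows)
}

#' Selection power on planted pattern-driven outcomes
#'
#' Per seed: generate a synthetic cohort, compute the ground-truth
#' pattern scores, build an outcome driven by pattern 1 plus early
#' growth, and run shadow-variable selection over the pattern scores
#' and noise decoys. Reports whether the causal pattern and each decoy
#' were confirmed.
#'
#' @param n_seeds number of replicates.
#' @param base_seed base seed.
#' @param n_decoys number of pure-noise decoy predictors added.
#' @param config a [boruta_config()] template.
#' @return data.frame with per-seed logicals `causal_confirmed` and
#'   counts `decoys_confirmed` (out of decoy patterns + noise decoys).
#' @export
selection_power_study <- function(n_seeds = 20L, base_seed = 1L,
                                  n_decoys = 7L,
                                  config = boruta_config(max_runs = 40L)) {
  rows <- lapply(seq_len(n_seeds), function(i) {
    seed <- derive_seed(base_seed, 2000L + i)
    sim <- generate_cohort(generator_config(seed = seed))
    truth <- sim$truth
    scores <- true_pattern_scores(truth, sim$meth)
    scores <- scale(scores)
    growth <- truth$covariates$growth
    y <- with_seed(derive_seed(seed, 3L), {
      scores[, 1L] + 0.5 * growth + stats::rnorm(nrow(scores), sd = 0.5)
    })
    decoys <- with_seed(derive_seed(seed, 4L), {
      matrix(stats::rnorm(nrow(scores) * n_decoys), nrow(scores),
             dimnames = list(NULL, paste0("decoy", seq_len(n_decoys))))
    })
    X <- data.frame(scores, decoys)
    cfg <- config
    cfg$seed <- seed
    sel <- boruta_select(X, y, covariates = data.frame(growth = growth),
                         config = cfg)
    non_causal <- setdiff(names(X), "pattern1")
    data.frame(seed = seed,
               causal_confirmed = "pattern1" %in% sel$confirmed,
               decoys_confirmed = length(intersect(sel$confirmed,
                                                   non_causal)),
               n_non_causal = length(non_causal))
  })
  do.call(rbind, rows)
}

#' Permutation-p uniformity under random queries
#'
#' Draws random query sets from a synthetic CpG universe with a fixed
#' feature track and collects the permutation overlap p-values; under
#' the null they should be approximately uniform.
#'
#' @param n_reps number of random queries.
#' @param n_cpgs universe size.
#' @param query_size CpGs per query.
#' @param coverage background feature coverage.
#' @param n_perm permutations per test.
#' @param base_seed base seed.
#' @return Numeric vector of `n_reps` p-values.
#' @export
enrichment_uniformity_study <- function(n_reps = 200L, n_cpgs = 1000L,
                                        query_size = 100L,
                                        coverage = 0.3, n_perm = 199L,
                                        base_seed = 1L) {
  sim <- generate_cohort(generator_config(
    n_subjects = 30L, n_cpgs = n_cpgs,
    pattern_sizes = c(0L, 0L, 0L), n_confounder_cpgs = 10L,
    seed = derive_seed(base_seed, 1L)))
  tracks <- generate_feature_tracks(sim$truth, enrichment_factor = 1,
                                    background_coverage = coverage,
                                    seed = derive_seed(base_seed, 2L))
  universe <- sim$truth$coords$cpg
  vapply(seq_len(n_reps), function(i) {
    seed <- derive_seed(base_seed, 100L + i)
    query <- with_seed(seed, sample(universe, query_size))
    permutation_overlap_test(query, tracks, universe, sim$truth$coords,
                             n_perm = n_perm, seed = seed + 1L)$p_value
  }, 0)
}
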