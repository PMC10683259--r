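# Synthetic cohort generator with planted ground truth.
#
# Emulates the structure of a birth-cohort study: eight mixed-type
# familial-smoking risk variables driven by shared latent factors, a
# cord-blood-style beta matrix in which small disjoint CpG groups covary
# with those factors, sex / cell-composition / batch confounding, child
# outcomes that are partly non-linear functions of the planted patterns,
# follow-up methylation at later ages, an external cohort with shifted
# marginals, and feature tracks enriched near planted CpGs. Every
# generator records enough state that downstream stages can be scored
# against the truth.

#' Configuration for the synthetic cohort generator
#'
#' Defaults define the package's reference study conditions: 500
#' subjects, 2,000 CpGs, three latent risk factors each driving a
#' disjoint block of graded risk variables (propensity loadings 0.97
#' with staggered thresholds; the continuous birth-weight variable
#' loads -0.92), three disjoint planted
#' CpG patterns of 40 sites, a logit-scale methylation effect of 0.5 SD
#' against unit biological noise, and 20% missingness in risk variables
#' (missing at random given maternal education).
#'
#' @param n_subjects number of subjects (>= 30).
#' @param n_cpgs number of CpG sites.
#' @param n_latent number of planted latent risk factors.
#' @param pattern_sizes integer vector, CpGs per planted pattern
#'   (length `n_latent`; the pattern CpG sets are disjoint).
#' @param effect_size_dnam latent effect on logit-beta, in SD units of
#'   the per-CpG noise.
#' @param noise_sd_dnam SD of per-cell logit-scale biological noise.
#' @param confounder_effects named list with elements `sex`, `cell`,
#'   `batch`: logit-scale effect sizes on dedicated confounder CpG sets.
#' @param n_confounder_cpgs CpGs per confounder set (disjoint from the
#'   planted patterns and from each other).
#' @param outcome_spec list of outcome definitions; see
#'   [default_outcome_spec()].
#' @param missing_fraction_risk overall missing fraction in risk
#'   variables, in `[0, 1)`.
#' @param missing_mechanism `"MAR"` (default; probability depends on
#'   maternal education) or `"MCAR"`.
#' @param followup_drift_sd default SD of age-related logit-beta drift
#'   used by [generate_followup_methylation()].
#' @param seed integer seed; all randomness derives from it.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 500L,
                             n_cpgs = 2000L,
                             n_latent = 3L,
                             pattern_sizes = rep(40L, n_latent),
                             effect_size_dnam = 0.5,
                             noise_sd_dnam = 1,
                             confounder_effects = list(sex = 1, cell = 1,
                                                       batch = 0.5),
                             n_confounder_cpgs = 50L,
                             outcome_spec = default_outcome_spec(n_latent),
                             missing_fraction_risk = 0.2,
                             missing_mechanism = c("MAR", "MCAR"),
                             followup_drift_sd = 0.3,
                             seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_cpgs = as.integer(n_cpgs),
              n_latent = as.integer(n_latent),
              pattern_sizes = as.integer(pattern_sizes),
              effect_size_dnam = effect_size_dnam,
              noise_sd_dnam = noise_sd_dnam,
              confounder_effects = confounder_effects,
              n_confounder_cpgs = as.integer(n_confounder_cpgs),
              outcome_spec = outcome_spec,
              missing_fraction_risk = missing_fraction_risk,
              missing_mechanism = missing_mechanism,
              followup_drift_sd = followup_drift_sd,
              seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_subjects < 30L) {
    stop_methrisk("n_subjects must be >= 30", "methrisk_invalid_config")
  }
  if (length(cfg$pattern_sizes) != cfg$n_latent) {
    stop_methrisk("pattern_sizes must have one entry per latent factor",
                  "methrisk_invalid_config")
  }
  if (any(cfg$pattern_sizes > cfg$n_cpgs) ||
      sum(cfg$pattern_sizes) + 3L * cfg$n_confounder_cpgs > cfg$n_cpgs) {
    stop_methrisk("pattern and confounder CpG sets do not fit in n_cpgs",
                  "methrisk_invalid_config")
  }
  fracs <- c(cfg$missing_fraction_risk,
             vapply(cfg$outcome_spec, function(o) o$missing_fraction, 0))
  if (any(fracs < 0 | fracs >= 1)) {
    stop_methrisk("all missing fractions must lie in [0, 1)",
                  "methrisk_invalid_config")
  }
  effs <- c(cfg$effect_size_dnam, cfg$noise_sd_dnam,
            unlist(cfg$confounder_effects), cfg$followup_drift_sd)
  if (!all(is.finite(effs))) {
    stop_methrisk("effect sizes must be finite", "methrisk_invalid_config")
  }
  invisible(cfg)
}

#' Default outcome specifications
#'
#' Two internal z-score outcomes: a cardiometabolic one driven linearly
#' by latent factor 1 plus early growth, with a quadratic term in factor
#' 3; and a neurocognitive one driven by factor 2 plus paternal social
#' status, with an education interaction. Noise SDs (0.6 / 0.8) keep the
#' planted signal at the moderate strength typical of cohort outcome
#' models, and the neurocognitive outcome is missing more often,
#' mirroring real follow-up attrition.
#'
#' @param n_latent number of latent factors in the generator.
#' @return List of outcome specs (`name`, `beta_latent`, `quad_latent`,
#'   `beta_growth`, `beta_social`, `educ_interaction`, `noise_sd`,
#'   `missing_fraction`).
#' @export
default_outcome_spec <- function(n_latent = 3L) {
  pad <- function(x) c(x, rep(0, max(0L, n_latent - length(x))))[seq_len(n_latent)]
  list(
    list(name = "cardiometabolic_z",
         beta_latent = pad(c(0.8, 0, 0)),
         quad_latent = pad(c(0, 0, 0.25)),
         beta_growth = 0.5, beta_social = 0, educ_interaction = 0,
         noise_sd = 0.6, missing_fraction = 0.1),
    list(name = "neurocognitive_z",
         beta_latent = pad(c(0, 0.6, 0)),
         quad_latent = pad(c(0, 0, 0)),
         beta_growth = 0, beta_social = 0.3, educ_interaction = 0.3,
         noise_sd = 0.8, missing_fraction = 0.2)
  )
}

# Risk-variable design: disjoint blocks of graded familial-smoking
# items per latent factor. Within a block the items behave like a
# Guttman scale: each propensity g = loading * L + sqrt(1 - loading^2)
# * e is cut at staggered normal quantiles, so the items' joint
# partition of the liability is fine even though each item alone is
# coarse (and marginals are skewed, as in real smoking tables).
risk_variable_design <- function(n_latent) {
  vars <- list(
    list(name = "birth_weight",              kind = "continuous",  latent = 1L,
         loading = -0.92),
    list(name = "maternal_smoking",          kind = "categorical", latent = 1L,
         loading = 0.97, cuts = c(0.45, 0.70, 0.88),
         levels = c("non_smoker", "non_sustained", "sustained",
                    "heavy_sustained")),
    list(name = "maternal_ever_smoked",      kind = "categorical", latent = 1L,
         loading = 0.97, cuts = 0.30, levels = c("false", "true")),
    list(name = "grandmother_ever_smoked",   kind = "categorical", latent = 2L,
         loading = 0.97, cuts = c(0.35, 0.65),
         levels = c("never", "former", "current")),
    list(name = "grandmother_smoked_pregnant", kind = "categorical", latent = 2L,
         loading = 0.97, cuts = c(0.55, 0.80),
         levels = c("false", "dont_know", "true")),
    list(name = "grandfather_ever_smoked",   kind = "categorical", latent = 2L,
         loading = 0.97, cuts = 0.20, levels = c("false", "true")),
    list(name = "partner_smoked",            kind = "categorical", latent = 3L,
         loading = 0.97, cuts = c(0.20, 0.50, 0.80),
         levels = c("never", "former", "occasional", "regular")),
    list(name = "household_others_smoke",    kind = "categorical", latent = 3L,
         loading = 0.97, cuts = c(0.40, 0.70),
         levels = c("none", "some", "many"))
  )
  for (i in seq_along(vars)) {
    vars[[i]]$latent <- ((vars[[i]]$latent - 1L) %% n_latent) + 1L
    if (vars[[i]]$kind == "categorical") {
      vars[[i]]$thresholds <- stats::qnorm(vars[[i]]$cuts)
    }
  }
  vars
}

draw_risk_variables <- function(latent, design, shift = 0) {
  n <- nrow(latent)
  out <- list()
  for (v in design) {
    g <- v$loading * latent[, v$latent] +
      sqrt(max(0, 1 - v$loading^2)) * stats::rnorm(n) + shift
    if (v$kind == "continuous") {
      out[[v$name]] <- g
    } else {
      idx <- findInterval(g, v$thresholds) + 1L
      out[[v$name]] <- factor(v$levels[idx], levels = v$levels)
    }
  }
  out
}

draw_covariates <- function(n) {
  sex <- factor(sample(c("female", "male"), n, replace = TRUE),
                levels = c("female", "male"))
  maternal_education <- factor(
    sample(c("non_degree", "degree"), n, replace = TRUE, prob = c(0.86, 0.14)),
    levels = c("non_degree", "degree"))
  paternal_social_status <- factor(
    sample(c("manual", "non_manual", "professional"), n, replace = TRUE,
           prob = c(0.45, 0.35, 0.20)),
    levels = c("manual", "non_manual", "professional"))
  batch <- factor(sample(paste0("batch", 1:3), n, replace = TRUE),
                  levels = paste0("batch", 1:3))
  # Dirichlet via gamma draws; alpha mirrors cord-blood deconvolution
  # (granulocyte-dominant, rare nucleated red blood cells).
  alpha <- c(12, 6, 4, 3, 2, 1)
  g <- matrix(stats::rgamma(n * 6L, shape = rep(alpha, each = n)),
              nrow = n, ncol = 6L)
  cells <- g / rowSums(g)
  if (n == 0L) cells <- matrix(numeric(0), 0L, 6L)
  colnames(cells) <- paste0("cell_", 1:6)
  list(sex = sex, maternal_education = maternal_education,
       paternal_social_status = paternal_social_status, batch = batch,
       cells = cells)
}

draw_outcomes <- function(spec, latent, growth, covs) {
  n <- nrow(latent)
  social_num <- as.integer(covs$paternal_social_status) -
    mean(as.integer(covs$paternal_social_status))
  educ_ind <- as.numeric(covs$maternal_education == "degree")
  out <- list()
  for (o in spec) {
    y <- drop(latent %*% o$beta_latent) +
      drop((latent^2 - 1) %*% o$quad_latent) +
      o$beta_growth * growth +
      o$beta_social * social_num +
      o$educ_interaction * drop(latent %*% o$beta_latent) * educ_ind +
      stats::rnorm(n, sd = o$noise_sd)
    if (o$missing_fraction > 0) {
      y[stats::runif(n) < o$missing_fraction] <- NA
    }
    out[[o$name]] <- y
  }
  out
}

make_cpg_coords <- function(n_cpgs) {
  chrom <- paste0("chr", rep_len(1:22, n_cpgs))
  start <- integer(n_cpgs)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    # spacing >= 600 bp keeps flanked track intervals from spilling onto
    # neighbouring CpGs
    start[idx] <- 10000L + cumsum(600L + stats::rpois(length(idx), 900L))
  }
  data.frame(cpg = sprintf("cg%07d", seq_len(n_cpgs)), chrom = chrom,
             start = start, end = start + 1L, stringsAsFactors = FALSE)
}

apply_risk_missingness <- function(tab, risk_names, fraction, mechanism,
                                   educ) {
  if (fraction <= 0) return(tab)
  n <- nrow(tab)
  w <- if (mechanism == "MAR") {
    ifelse(educ == "non_degree", 1.25, 0.5)
  } else rep(1, n)
  p <- pmin(fraction * w / mean(w), 0.95)
  for (v in risk_names) {
    tab[[v]][stats::runif(n) < p] <- NA
  }
  tab
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws latent risk-factor scores, derives eight mixed-type risk
#' variables from them (one continuous, seven categorical, via
#' quantile-cut latent propensities), builds a beta-value matrix in
#' which each planted CpG pattern covaries with its latent factor on the
#' logit scale (plus sex, cell-composition and batch effects on disjoint
#' confounder CpG sets, plus noise), draws outcomes per the outcome
#' spec, and applies missingness. All randomness derives from
#' `config$seed`; the returned `true_structure` reproduces the data
#' exactly under the same config.
#'
#' @param config a [generator_config()].
#' @return List with elements `cohort` ([cohort_table()]), `meth`
#'   ([methylation_matrix()]) and `truth` (a `true_structure` list:
#'   latent scores, variable loadings, pattern membership and signed CpG
#'   weights, baseline and realized logit matrix, confounder
#'   assignments, outcome functions).
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  with_seed(config$seed, {
    n <- config$n_subjects
    p <- config$n_cpgs
    k <- config$n_latent
    ids <- sprintf("S%04d", seq_len(n))

    latent <- matrix(stats::rnorm(n * k), n, k,
                     dimnames = list(ids, paste0("latent", seq_len(k))))
    design <- risk_variable_design(k)
    risk <- draw_risk_variables(latent, design)
    covs <- draw_covariates(n)
    growth <- 0.2 * latent[, 1L] + stats::rnorm(n, sd = sqrt(1 - 0.04))
    outcomes <- draw_outcomes(config$outcome_spec, latent, growth, covs)

    coords <- make_cpg_coords(p)
    cpg_ids <- coords$cpg

    # disjoint CpG sets: planted patterns first, then confounder sets
    pool <- sample.int(p)
    pattern_membership <- rep(NA_integer_, p)
    names(pattern_membership) <- cpg_ids
    offset <- 0L
    for (j in seq_len(k)) {
      take <- pool[offset + seq_len(config$pattern_sizes[j])]
      pattern_membership[take] <- j
      offset <- offset + config$pattern_sizes[j]
    }
    conf_sets <- list()
    for (nm in c("sex", "cell", "batch")) {
      take <- pool[offset + seq_len(config$n_confounder_cpgs)]
      conf_sets[[nm]] <- cpg_ids[sort(take)]
      offset <- offset + config$n_confounder_cpgs
    }

    cpg_weights <- rep(0, p)
    names(cpg_weights) <- cpg_ids
    member <- !is.na(pattern_membership)
    cpg_weights[member] <- config$effect_size_dnam *
      sample(c(-1, 1), sum(member), replace = TRUE)

    baseline <- stats::rnorm(p, mean = 0, sd = 1.5)
    logit <- matrix(rep(baseline, each = n), n, p,
                    dimnames = list(ids, cpg_ids))
    for (j in seq_len(k)) {
      in_j <- which(!is.na(pattern_membership) & pattern_membership == j)
      if (length(in_j)) {
        logit[, in_j] <- logit[, in_j] +
          outer(latent[, j], cpg_weights[in_j])
      }
    }
    sex_num <- as.numeric(covs$sex == "male") - 0.5
    cell_num <- scale(covs$cells[, 1L])[, 1L]
    batch_num <- as.integer(covs$batch) - 2L
    logit[, conf_sets$sex] <- logit[, conf_sets$sex] +
      config$confounder_effects$sex * sex_num
    logit[, conf_sets$cell] <- logit[, conf_sets$cell] +
      config$confounder_effects$cell * cell_num
    logit[, conf_sets$batch] <- logit[, conf_sets$batch] +
      config$confounder_effects$batch * batch_num
    logit <- logit + matrix(stats::rnorm(n * p, sd = config$noise_sd_dnam),
                            n, p)
    beta <- pmin(pmax(stats::plogis(logit), 1e-6), 1 - 1e-6)

    samples <- data.frame(subject_id = ids, sex = as.character(covs$sex),
                          age = 0, batch = as.character(covs$batch),
                          covs$cells, stringsAsFactors = FALSE)
    meth <- methylation_matrix(beta, coords, samples)

    df <- data.frame(subject_id = ids, risk, check.names = FALSE,
                     stringsAsFactors = FALSE)
    df$sex <- covs$sex
    df$maternal_education <- covs$maternal_education
    df$paternal_social_status <- covs$paternal_social_status
    df$batch <- covs$batch
    df$growth_rate <- growth
    for (cc in colnames(covs$cells)) df[[cc]] <- covs$cells[, cc]
    for (o in names(outcomes)) df[[o]] <- outcomes[[o]]

    risk_names <- vapply(design, `[[`, "", "name")
    vt <- c(stats::setNames(
      vapply(design, `[[`, "", "kind"), risk_names),
      sex = "categorical", maternal_education = "categorical",
      paternal_social_status = "categorical", batch = "categorical",
      growth_rate = "continuous",
      stats::setNames(rep("continuous", 6L), colnames(covs$cells)),
      stats::setNames(rep("continuous", length(outcomes)), names(outcomes)))
    tab <- cohort_table(df, vt)
    tab <- apply_risk_missingness(tab, risk_names,
                                  config$missing_fraction_risk,
                                  config$missing_mechanism,
                                  covs$maternal_education)

    truth <- structure(list(
      config = config,
      subject_ids = ids,
      latent_scores = latent,
      variable_design = design,
      risk_variable_names = risk_names,
      pattern_membership = pattern_membership,
      cpg_weights = cpg_weights,
      baseline = baseline,
      logit = logit,
      coords = coords,
      confounder_assignments = c(conf_sets,
                                 list(effects = config$confounder_effects)),
      outcome_functions = config$outcome_spec,
      covariates = list(sex = covs$sex, batch = covs$batch,
                        cells = covs$cells, growth = growth,
                        maternal_education = covs$maternal_education,
                        paternal_social_status = covs$paternal_social_status)
    ), class = "true_structure")

    list(cohort = tab, meth = meth, truth = truth)
  })
}

#' Pattern scores implied by the planted truth
#'
#' Scores a beta matrix with the recorded signed CpG weights of each
#' planted pattern (columns centered on the supplied matrix), giving the
#' oracle analogue of a fitted pattern score for recovery checks.
#'
#' @param truth a `true_structure`.
#' @param meth a [methylation_matrix()] over the same CpGs.
#' @return Matrix, subjects x patterns.
#' @export
true_pattern_scores <- function(truth, meth) {
  k <- truth$config$n_latent
  beta_c <- scale(meth$beta, center = TRUE, scale = FALSE)
  out <- matrix(0, nrow(beta_c), k,
                dimnames = list(rownames(beta_c), paste0("pattern", seq_len(k))))
  for (j in seq_len(k)) {
    members <- names(which(truth$pattern_membership == j))
    out[, j] <- beta_c[, members, drop = FALSE] %*%
      truth$cpg_weights[members]
  }
  out
}

#' Generate follow-up methylation for the same subjects
#'
#' Adds age-related drift to the recorded logit-scale matrix: a per-CpG
#' systematic shift and independent per-cell stochastic drift, both with
#' SD `drift_sd`, plus optional extra measurement noise. The planted
#' pattern structure is preserved.
#'
#' @param truth a `true_structure` from [generate_cohort()].
#' @param age_label numeric or character age tag stored in the sample
#'   metadata.
#' @param drift_sd SD (logit scale) of the drift terms.
#' @param noise_sd SD of additional measurement noise (default 0).
#' @param seed integer seed.
#' @return A [methylation_matrix()] over the same subjects and CpGs.
#' @export
generate_followup_methylation <- function(truth, age_label,
                                          drift_sd = truth$config$followup_drift_sd,
                                          noise_sd = 0, seed = 1L) {
  if (!inherits(truth, "true_structure")) {
    stop_methrisk("truth must come from generate_cohort()",
                  "methrisk_invalid_input")
  }
  with_seed(seed, {
    n <- nrow(truth$logit)
    p <- ncol(truth$logit)
    logit <- truth$logit
    if (drift_sd > 0) {
      logit <- logit +
        matrix(rep(stats::rnorm(p, sd = drift_sd), each = n), n, p) +
        matrix(stats::rnorm(n * p, sd = drift_sd), n, p)
    }
    if (noise_sd > 0) {
      logit <- logit + matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
    }
    beta <- pmin(pmax(stats::plogis(logit), 1e-6), 1 - 1e-6)
    samples <- data.frame(subject_id = truth$subject_ids,
                          sex = as.character(truth$covariates$sex),
                          age = age_label,
                          batch = as.character(truth$covariates$batch),
                          truth$covariates$cells, stringsAsFactors = FALSE)
    methylation_matrix(beta, truth$coords, samples)
  })
}

#' Generate an external validation cohort
#'
#' Draws new subjects whose risk-variable marginals are shifted by
#' `marginal_shift` (added to every latent propensity and to the
#' continuous variable, in SD units) while the CpG-level pattern
#' loadings, baselines and confounder assignments are identical to the
#' training truth, emulating an independent cohort measured on the same
#' array.
#'
#' @param truth a `true_structure` from [generate_cohort()].
#' @param marginal_shift shift of the risk-variable marginals (SD units).
#' @param n number of external subjects (0 gives empty tables with full
#'   headers).
#' @param seed integer seed.
#' @return List with `cohort`, `meth`, and `latent_scores` of the new
#'   subjects.
#' @export
generate_external_cohort <- function(truth, marginal_shift = 0.5, n = 500L,
                                     seed = 1L) {
  if (!inherits(truth, "true_structure")) {
    stop_methrisk("truth must come from generate_cohort()",
                  "methrisk_invalid_input")
  }
  config <- truth$config
  with_seed(seed, {
    k <- config$n_latent
    ids <- if (n > 0) sprintf("E%04d", seq_len(n)) else character(0)
    latent <- matrix(stats::rnorm(n * k), n, k,
                     dimnames = list(ids, paste0("latent", seq_len(k))))
    risk <- draw_risk_variables(latent, truth$variable_design,
                                shift = marginal_shift)
    covs <- draw_covariates(n)
    growth <- if (n > 0) 0.2 * latent[, 1L] + stats::rnorm(n, sd = sqrt(1 - 0.04)) else numeric(0)
    outcomes <- draw_outcomes(config$outcome_spec, latent, growth, covs)

    p <- config$n_cpgs
    logit <- matrix(rep(truth$baseline, each = n), n, p,
                    dimnames = list(ids, truth$coords$cpg))
    for (j in seq_len(k)) {
      in_j <- which(!is.na(truth$pattern_membership) &
                      truth$pattern_membership == j)
      if (length(in_j) && n > 0) {
        logit[, in_j] <- logit[, in_j] +
          outer(latent[, j], truth$cpg_weights[in_j])
      }
    }
    if (n > 0) {
      conf <- truth$confounder_assignments
      sex_num <- as.numeric(covs$sex == "male") - 0.5
      cell_num <- scale(covs$cells[, 1L])[, 1L]
      batch_num <- as.integer(covs$batch) - 2L
      logit[, conf$sex] <- logit[, conf$sex] + conf$effects$sex * sex_num
      logit[, conf$cell] <- logit[, conf$cell] + conf$effects$cell * cell_num
      logit[, conf$batch] <- logit[, conf$batch] +
        conf$effects$batch * batch_num
      logit <- logit + matrix(stats::rnorm(n * p, sd = config$noise_sd_dnam),
                              n, p)
    }
    beta <- logit  # keep dims even for an empty cohort
    beta[] <- pmin(pmax(stats::plogis(logit), 1e-6), 1 - 1e-6)

    samples <- data.frame(subject_id = ids, sex = as.character(covs$sex),
                          age = if (n > 0) 0 else numeric(0),
                          batch = as.character(covs$batch),
                          covs$cells, stringsAsFactors = FALSE)
    meth <- methylation_matrix(beta, truth$coords, samples)

    df <- data.frame(subject_id = ids, risk, check.names = FALSE,
                     stringsAsFactors = FALSE)
    df$sex <- covs$sex
    df$maternal_education <- covs$maternal_education
    df$paternal_social_status <- covs$paternal_social_status
    df$batch <- covs$batch
    df$growth_rate <- growth
    for (cc in colnames(covs$cells)) df[[cc]] <- covs$cells[, cc]
    for (o in names(outcomes)) df[[o]] <- outcomes[[o]]
    vt <- c(stats::setNames(
      vapply(truth$variable_design, `[[`, "", "kind"),
      truth$risk_variable_names),
      sex = "categorical", maternal_education = "categorical",
      paternal_social_status = "categorical", batch = "categorical",
      growth_rate = "continuous",
      stats::setNames(rep("continuous", 6L), colnames(covs$cells)),
      stats::setNames(rep("continuous", length(outcomes)), names(outcomes)))
    tab <- cohort_table(df, vt)
    if (n > 0) {
      tab <- apply_risk_missingness(tab, truth$risk_variable_names,
                                    config$missing_fraction_risk,
                                    config$missing_mechanism,
                                    covs$maternal_education)
    }
    list(cohort = tab, meth = meth, latent_scores = latent)
  })
}

#' Generate feature tracks enriched near planted pattern CpGs
#'
#' Builds a BED-style interval set in which each CpG is covered
#' independently: background CpGs with probability
#' `background_coverage`, planted-pattern CpGs with probability
#' `min(1, enrichment_factor * background_coverage)`. Covered CpGs get a
#' +/-100 bp interval (CpG spacing in the synthetic coordinates keeps
#' these from spilling onto neighbouring sites).
#'
#' @param truth a `true_structure`.
#' @param enrichment_factor coverage multiplier for pattern CpGs
#'   (must be >= 1; depletion is not supported).
#' @param background_coverage background coverage probability.
#' @param seed integer seed.
#' @return A `GRanges` of merged covered intervals.
#' @export
generate_feature_tracks <- function(truth, enrichment_factor = 5,
                                    background_coverage = 0.1, seed = 1L) {
  if (enrichment_factor < 1) {
    stop_methrisk("enrichment_factor must be >= 1 (depletion unsupported)",
                  "methrisk_invalid_config")
  }
  with_seed(seed, {
    member <- !is.na(truth$pattern_membership)
    p_cov <- ifelse(member, pmin(1, enrichment_factor * background_coverage),
                    background_coverage)
    covered <- stats::runif(length(p_cov)) < p_cov
    co <- truth$coords[covered, , drop = FALSE]
    if (!nrow(co)) {
      return(GenomicRanges::GRanges())
    }
    gr <- interval_set(co$chrom, pmax(co$start - 100L, 0L), co$start + 101L)
    GenomicRanges::reduce(gr)
  })
}

#' Printed descriptive-statistics fixtures
#'
#' Returns the contingency tables from the published cohort description
#' that the descriptives module reproduces exactly: the sex-by-smoking
#' 2x4 table and the partner-smoking-by-category 2x3 table, read from
#' the packaged TSV fixtures.
#'
#' @return List with `sex_by_smoking`, `partner_by_smoking` (integer
#'   matrices with dimnames) and `totals` (named totals derived from the
#'   printed cells).
#' @export
table2_fixtures <- function() {
  dir <- system.file("extdata", "table2", package = "methrisk")
  read_fix <- function(f) {
    df <- utils::read.table(file.path(dir, f), sep = "\t", header = TRUE,
                            row.names = 1L, check.names = FALSE)
    as.matrix(df)
  }
  sex <- read_fix("sex_by_smoking.tsv")
  partner <- read_fix("partner_by_smoking.tsv")
  list(sex_by_smoking = sex,
       partner_by_smoking = partner,
       totals = c(male = sum(sex["male", ]),
                  female = sum(sex["female", ]),
                  with_sex = sum(sex),
                  partner_sustained = sum(partner[, "sustained"])))
}
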