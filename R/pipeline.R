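# Pipeline orchestration: ties the stages into one reproducible run
# with configuration, stage logging, seed management and
# standard-format outputs (TSV tables/scores/metrics, BED intervals,
# JSON models/flags/manifest).

#' Pipeline configuration
#'
#' @param out_dir output directory for all artifacts.
#' @param seed global seed; every stage derives its own stream from it
#'   and the manifest records it.
#' @param simulate if `TRUE` (default) generate a synthetic cohort with
#'   `generator` (+ follow-up, external cohort and feature tracks);
#'   otherwise `inputs` must name existing files.
#' @param generator a [generator_config()] used when simulating.
#' @param inputs named list of input paths (`cohort` TSV,
#'   `meth_prefix`, optional `features` BED) when not simulating.
#' @param n_dims number of risk-profile dimensions to keep.
#' @param n_components,keep_x sparse-PLS settings.
#' @param boruta a [boruta_config()] (its seed is overridden by the
#'   pipeline seed).
#' @param screen_alpha,screen_r_min confounder-screen thresholds.
#' @param n_perm permutations for the feature-overlap test.
#' @param covariate_assignments named list: outcome name -> extra
#'   covariate columns included in its models (on top of sex, maternal
#'   education, paternal social status and cell proportions).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = TRUE,
                            generator = generator_config(seed = seed),
                            inputs = NULL,
                            n_dims = 5L, n_components = 20L, keep_x = 250L,
                            boruta = boruta_config(),
                            screen_alpha = 1e-3, screen_r_min = 0.3,
                            n_perm = 999L,
                            covariate_assignments = list(
                              cardiometabolic_z = "growth_rate")) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, generator = generator,
                 inputs = inputs, n_dims = as.integer(n_dims),
                 n_components = as.integer(n_components),
                 keep_x = as.integer(keep_x), boruta = boruta,
                 screen_alpha = screen_alpha, screen_r_min = screen_r_min,
                 n_perm = as.integer(n_perm),
                 covariate_assignments = covariate_assignments),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    read_json_file(path)
  }
  gen_args <- raw$generator %||% list()
  gen <- do.call(generator_config,
                 c(gen_args, if (is.null(gen_args$seed))
                   list(seed = raw$seed %||% 1L)))
  bor <- do.call(boruta_config, raw$boruta %||% list())
  args <- raw[setdiff(names(raw), c("generator", "boruta"))]
  do.call(pipeline_config, c(args, list(generator = gen, boruta = bor)))
}

#' Validate pipeline input files
#'
#' Checks that the cohort TSV has its variable-type sidecar, that beta
#' values lie in (0, 1) (violations are listed by CpG and subject),
#' that subject ids align between the cohort and methylation tables
#' (reordering is tolerated and noted), and that coordinates are sane.
#'
#' @param paths named list: `cohort` (TSV path) and `meth_prefix`.
#' @return List of diagnostics (`ok`, `notes`); errors on violations.
#' @export
validate_inputs <- function(paths) {
  notes <- character(0)
  for (nm in c("cohort", "meth_prefix")) {
    if (is.null(paths[[nm]])) {
      stop_methrisk(paste0("missing required input path: ", nm),
                    "methrisk_validation")
    }
  }
  if (!file.exists(paths$cohort)) {
    stop_methrisk(paste0("input file does not exist: ", paths$cohort),
                  "methrisk_validation")
  }
  cohort <- read_cohort_table(paths$cohort)
  meth <- read_methylation_matrix(paths$meth_prefix)
  bad <- which(meth$beta <= 0 | meth$beta >= 1, arr.ind = TRUE)
  if (nrow(bad)) {
    ex <- utils::head(bad, 5L)
    stop_methrisk(paste0(
      "beta values outside (0,1): ",
      paste(sprintf("%s@%s", colnames(meth$beta)[ex[, 2L]],
                    rownames(meth$beta)[ex[, 1L]]), collapse = ", "),
      if (nrow(bad) > 5L) sprintf(" (+%d more)", nrow(bad) - 5L)),
      "methrisk_validation")
  }
  ids_c <- as.character(cohort$subject_id)
  ids_m <- rownames(meth$beta)
  shared <- intersect(ids_c, ids_m)
  if (!length(shared)) {
    stop_methrisk(sprintf(
      "no shared subject ids (%d cohort-only, %d methylation-only)",
      length(setdiff(ids_c, ids_m)), length(setdiff(ids_m, ids_c))),
      "methrisk_validation")
  }
  if (!identical(ids_c[ids_c %in% shared], ids_m[ids_m %in% shared])) {
    notes <- c(notes, "subject ids match after reordering")
  }
  if (length(setdiff(ids_c, ids_m)) || length(setdiff(ids_m, ids_c))) {
    notes <- c(notes, sprintf("%d cohort-only and %d methylation-only subjects",
                              length(setdiff(ids_c, ids_m)),
                              length(setdiff(ids_m, ids_c))))
  }
  if (any(meth$coords$start < 0) ||
      any(meth$coords$end <= meth$coords$start)) {
    stop_methrisk("invalid CpG coordinates (need 0 <= start < end)",
                  "methrisk_validation")
  }
  list(ok = TRUE, notes = notes, n_shared = length(shared))
}

pipeline_stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop_methrisk(sprintf("stage '%s' failed: %s", name,
                          conditionMessage(e)),
                  "methrisk_stage_failure")
  })
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) simulate, impute + fit risk profiles, fit
#' sparse-PLS patterns, screen confounders, select + evaluate per
#' outcome, project to follow-up and external data, and enrich, writing
#' every artifact under `config$out_dir` together with a manifest
#' recording the seed, the config hash and per-file MD5 hashes. Any
#' stage failure aborts with a stage-named error; artifacts written by
#' earlier stages are retained.
#'
#' @param config a [pipeline_config()].
#' @return The manifest list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  seed <- config$seed
  artifacts <- character(0)
  add <- function(path) artifacts <<- c(artifacts, path)

  if (config$simulate) {
    sim <- pipeline_stage("simulate", {
      gen <- config$generator
      gen$seed <- derive_seed(seed, 1L)
      sim <- generate_cohort(gen)
      write_cohort_table(sim$cohort, out("cohort.tsv"))
      write_methylation_matrix(sim$meth, out("meth"))
      sim
    })
    add(out("cohort.tsv"))
    cohort <- sim$cohort
    meth <- sim$meth
    truth <- sim$truth
    followup <- pipeline_stage("simulate-followup", {
      generate_followup_methylation(truth, age_label = 7,
                                    seed = derive_seed(seed, 2L))
    })
    external <- pipeline_stage("simulate-external", {
      generate_external_cohort(truth, n = config$generator$n_subjects,
                               seed = derive_seed(seed, 3L))
    })
    features <- pipeline_stage("simulate-tracks", {
      gr <- generate_feature_tracks(truth, seed = derive_seed(seed, 4L))
      write_bed(gr, out("feature_tracks.bed"))
      gr
    })
    add(out("feature_tracks.bed"))
  } else {
    pipeline_stage("validate", validate_inputs(config$inputs))
    cohort <- read_cohort_table(config$inputs$cohort)
    meth <- read_methylation_matrix(config$inputs$meth_prefix)
    truth <- NULL
    followup <- NULL
    external <- NULL
    features <- if (!is.null(config$inputs$features)) {
      read_bed(config$inputs$features)
    } else NULL
  }

  risk_vars <- intersect(
    c("birth_weight", "maternal_smoking", "maternal_ever_smoked",
      "grandmother_ever_smoked", "grandmother_smoked_pregnant",
      "grandfather_ever_smoked", "partner_smoked",
      "household_others_smoke"),
    names(variable_types(cohort)))

  mrp <- pipeline_stage("fit-mrp", {
    completed <- impute_famd(cohort, variables = risk_vars,
                             n_dims = config$n_dims)
    model <- famd_fit(completed, variables = risk_vars)
    write_risk_profile_model(model, out("mrp_model.json"))
    dims <- select_dimensions(model, "top_k", k = config$n_dims)
    scores <- model$scores[, dims, drop = FALSE]
    utils::write.table(
      data.frame(subject_id = rownames(scores), scores),
      out("dimension_scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    list(model = model, dims = dims, scores = scores)
  })
  add(out("mrp_model.json"))
  add(out("dimension_scores.tsv"))

  patterns <- pipeline_stage("fit-patterns", {
    model <- spls_fit(meth, mrp$scores,
                      n_components = config$n_components,
                      keep_x = config$keep_x)
    write_pattern_model(model, out("pattern_model.json"))
    write_pattern_weights(model, out("pattern_weights.tsv"))
    utils::write.table(
      data.frame(subject_id = rownames(model$scores), model$scores),
      out("component_scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    model
  })
  add(out("pattern_model.json"))
  add(out("pattern_weights.tsv"))
  add(out("component_scores.tsv"))

  screen <- pipeline_stage("screen", {
    conf <- data.frame(
      sex = factor(meth$samples$sex),
      batch = factor(meth$samples$batch),
      meth$samples[, grep("^cell_", names(meth$samples)), drop = FALSE])
    cohort_df <- as.data.frame(cohort)
    for (v in c("maternal_education", "paternal_social_status")) {
      if (v %in% names(cohort_df)) conf[[v]] <- cohort_df[[v]]
    }
    report <- flag_confounded_patterns(patterns$scores, conf,
                                       alpha = config$screen_alpha,
                                       r_min = config$screen_r_min)
    write_confounder_report(report, out("confounder_pvalues.tsv"),
                            out("confounder_flags.json"))
    report
  })
  add(out("confounder_pvalues.tsv"))
  add(out("confounder_flags.json"))

  outcome_cols <- intersect(
    names(variable_types(cohort))[variable_types(cohort) == "continuous"],
    unique(c(names(config$covariate_assignments),
             grep("_z$", names(variable_types(cohort)), value = TRUE))))
  models <- pipeline_stage("select-evaluate", {
    cohort_df <- as.data.frame(cohort)
    cells <- meth$samples[, grep("^cell_", names(meth$samples)),
                          drop = FALSE]
    base_cov <- data.frame(sex = factor(meth$samples$sex),
                           maternal_education = cohort_df$maternal_education,
                           paternal_social_status = cohort_df$paternal_social_status,
                           cells)
    res <- list()
    for (oc in outcome_cols) {
      extra <- config$covariate_assignments[[oc]]
      cov <- base_cov
      for (v in intersect(extra, names(cohort_df))) cov[[v]] <- cohort_df[[v]]
      bor <- config$boruta
      bor$seed <- derive_seed(seed, 100L + match(oc, outcome_cols))
      sel <- boruta_select(as.data.frame(patterns$scores), cohort_df[[oc]],
                           covariates = cov, config = bor)
      write_selection_result(sel, out(paste0("selection_", oc, ".json")))
      add(out(paste0("selection_", oc, ".json")))
      vars <- if (length(sel$confirmed)) sel$confirmed
              else colnames(patterns$scores)
      met <- evaluate_model(
        cbind(as.data.frame(patterns$scores)[, vars, drop = FALSE], cov),
        cohort_df[[oc]], ntree = bor$ntree, seed = bor$seed)
      res[[oc]] <- list(selection = sel, metrics = met)
    }
    tab <- do.call(rbind, lapply(names(res), function(oc) {
      s <- res[[oc]]$metrics$summary
      data.frame(outcome = oc, n = res[[oc]]$metrics$n,
                 selected = paste(res[[oc]]$selection$confirmed,
                                  collapse = ","),
                 mse = s$mse[["mean"]], mae = s$mae[["mean"]],
                 r_squared = s$r_squared[["mean"]])
    }))
    utils::write.table(tab, out("outcome_metrics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res
  })
  add(out("outcome_metrics.tsv"))

  if (!is.null(followup)) {
    pipeline_stage("project", {
      proj_f <- project_patterns(patterns, followup)
      utils::write.table(
        data.frame(subject_id = rownames(proj_f), proj_f),
        out("projected_followup.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      proj_e <- project_patterns(patterns, external$meth)
      utils::write.table(
        data.frame(subject_id = rownames(proj_e), proj_e),
        out("projected_external.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    })
    add(out("projected_followup.tsv"))
    add(out("projected_external.tsv"))
  }

  if (!is.null(features)) {
    pipeline_stage("enrich", {
      universe <- meth$coords$cpg
      rows <- lapply(seq_len(patterns$n_components), function(h) {
        q <- representative_cpgs(patterns, h)$cpg
        res <- permutation_overlap_test(
          q, features, universe, meth$coords, n_perm = config$n_perm,
          seed = derive_seed(seed, 200L + h))
        data.frame(component = h, observed = res$observed,
                   n_query = res$n_query, null_mean = res$null_mean,
                   p_value = res$p_value)
      })
      utils::write.table(do.call(rbind, rows), out("enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
    add(out("enrichment.tsv"))
  }

  manifest <- pipeline_stage("manifest", {
    cfg_json <- out("pipeline_config.json")
    strip <- function(x) {
      if (is.list(x)) lapply(unclass(x), strip) else x
    }
    # paths are excluded so the config hash identifies the analysis
    # parameters, not the output location
    hashable <- strip(config)[setdiff(names(config),
                                      c("out_dir", "inputs"))]
    write_json_file(hashable, cfg_json)
    files <- c(artifacts, cfg_json)
    files <- files[file.exists(files)]
    hashes <- tools::md5sum(files)
    names(hashes) <- basename(names(hashes))
    m <- list(seed = seed,
              config_hash = unname(tools::md5sum(cfg_json)),
              files = as.list(hashes))
    write_json_file(m, out("manifest.json"))
    m
  })
  invisible(manifest)
}
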