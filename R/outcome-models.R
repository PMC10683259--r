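# Two-step random-forest outcome modelling. Step one: all-relevant
# variable selection against shadow variables (independently permuted
# copies of the predictors) with a binomial hit test. Step two:
# repeated k-fold cross-validated evaluation of a regression forest on
# the selected variables. Forests are fitted with ranger; importance is
# out-of-bag permutation increase in MSE, the regression analogue of
# mean decrease in accuracy.

rf_fit <- function(data, ntree = 500L, mtry = NULL, seed = 1L,
                   importance = "none", scale_importance = FALSE) {
  mtry <- mtry %||% max(1L, floor((ncol(data) - 1L) / 3L))
  ranger::ranger(
    dependent.variable.name = ".outcome", data = data,
    num.trees = ntree, mtry = min(mtry, ncol(data) - 1L),
    importance = importance,
    scale.permutation.importance = scale_importance,
    seed = seed, num.threads = 1L,
    respect.unordered.factors = "order"
  )
}

#' Out-of-bag permutation importance of a regression forest
#'
#' Fits a regression forest and returns per-variable permutation
#' importance: the mean increase in out-of-bag MSE when the variable's
#' values are permuted.
#'
#' @param X data.frame of predictors.
#' @param y numeric outcome.
#' @param ntree number of trees (default 500).
#' @param mtry variables tried per split; default `max(1, floor(p/3))`.
#' @param seed integer seed.
#' @return Named numeric vector of importances.
#' @export
permutation_importance <- function(X, y, ntree = 500L, mtry = NULL,
                                   seed = 1L) {
  data <- data.frame(X, .outcome = y, check.names = FALSE)
  fit <- rf_fit(data, ntree = ntree, mtry = mtry, seed = seed,
                importance = "permutation")
  ranger::importance(fit)
}

#' Configuration for shadow-variable selection
#'
#' @param ntree trees per forest (default 500; minimum 50).
#' @param alpha significance level of the binomial hit test.
#' @param max_runs maximum number of selection runs.
#' @param mtry optional variables-per-split override.
#' @param adjust `"bonferroni"` (default: alpha divided by the number
#'   of candidates, the convention of the reference all-relevant
#'   selection implementation) or `"none"` (raw binomial test per
#'   candidate). Without the adjustment, chance in-sample correlations
#'   of null predictors are confirmed far above alpha, because
#'   selection runs on a fixed dataset are not independent trials.
#' @param seed integer seed driving all shadow permutations and
#'   forests.
#' @return A `boruta_config` list.
#' @export
boruta_config <- function(ntree = 500L, alpha = 0.05, max_runs = 100L,
                          mtry = NULL, adjust = c("bonferroni", "none"),
                          seed = 1L) {
  adjust <- match.arg(adjust)
  stopifnot(alpha > 0, alpha < 1)
  if (ntree < 50L) {
    stop_methrisk("ntree must be >= 50", "methrisk_invalid_config")
  }
  structure(list(ntree = as.integer(ntree), alpha = alpha,
                 max_runs = as.integer(max_runs), mtry = mtry,
                 adjust = adjust, seed = as.integer(seed)),
            class = "boruta_config")
}

#' Minimum hits needed to confirm a variable
#'
#' A variable scores a "hit" in a run when its importance exceeds the
#' maximum shadow importance. Confirmation uses a two-sided binomial
#' test with success probability 0.5: a variable with `k` hits in
#' `runs` runs is confirmed when `2 * P(X >= k) < alpha`. This returns
#' the smallest such `k`.
#'
#' @param runs number of completed runs.
#' @param alpha significance level.
#' @return Minimum number of hits, or `NA` if unreachable.
#' @export
boruta_confirm_threshold <- function(runs, alpha = 0.05) {
  k <- which(2 * stats::pbinom(seq_len(runs) - 1L, runs, 0.5,
                               lower.tail = FALSE) < alpha)
  if (!length(k)) NA_integer_ else min(k)
}

#' All-relevant variable selection with shadow variables
#'
#' Iteratively fits regression forests on the candidate predictors,
#' mandatory covariates, and shadow variables (independently permuted
#' copies of all predictors). Each run, a candidate whose permutation
#' importance exceeds the maximum shadow importance scores a hit; a
#' two-sided binomial test (success probability 0.5) then confirms
#' (upper tail) or rejects (lower tail) candidates, rejected ones being
#' dropped from subsequent runs. Candidates still undecided after
#' `max_runs` are resolved by comparing their median importance to the
#' median shadow maximum. Mandatory covariates are always included in
#' every forest but are not subject to selection.
#'
#' @param X data.frame of candidate predictors (>= 2 columns).
#' @param y numeric outcome.
#' @param covariates optional data.frame of mandatory covariates (sex,
#'   maternal education, paternal social status, cell proportions, ...).
#' @param config a [boruta_config()].
#' @return A `selection_result`: per-variable `decisions`
#'   (`Confirmed` / `Rejected` / `Tentative-resolved` final states in
#'   `final`), importance history, shadow-max per run, hit counts.
#' @export
boruta_select <- function(X, y, covariates = NULL,
                          config = boruta_config()) {
  X <- as.data.frame(X)
  if (ncol(X) < 2L) {
    stop_methrisk("need >= 2 candidate variables", "methrisk_invalid_input")
  }
  keep <- stats::complete.cases(X, y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- keep & stats::complete.cases(covariates)
    covariates <- covariates[keep, , drop = FALSE]
  }
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (length(y) < 30L) {
    stop_methrisk(sprintf("only %d complete cases (< 30): refusing to fit",
                          length(y)), "methrisk_too_few_cases")
  }
  if (stats::sd(y) == 0) {
    stop_methrisk("constant outcome", "methrisk_degenerate_response")
  }
  cand <- names(X)
  n <- length(y)
  decisions <- stats::setNames(rep("Tentative", length(cand)), cand)
  hits <- runs <- stats::setNames(integer(length(cand)), cand)
  imp_history <- matrix(NA_real_, config$max_runs, length(cand),
                        dimnames = list(NULL, cand))
  shadow_max <- rep(NA_real_, config$max_runs)

  run <- 0L
  while (run < config$max_runs && any(decisions == "Tentative")) {
    run <- run + 1L
    active <- cand[decisions == "Tentative"]
    preds <- X[, active, drop = FALSE]
    if (!is.null(covariates)) preds <- cbind(preds, covariates)
    # keep at least 5 shadow columns: a shrinking shadow set would
    # weaken the shadow-maximum bar as candidates are rejected, letting
    # lucky survivors accumulate hits under the null
    shadow_src <- preds
    while (ncol(shadow_src) < 5L) shadow_src <- cbind(shadow_src, preds)
    shadows <- with_seed(derive_seed(config$seed, run), {
      as.data.frame(lapply(shadow_src, function(col) col[sample.int(n)]))
    })
    names(shadows) <- paste0(".shadow_", seq_along(shadows), "_",
                             rep_len(names(preds), ncol(shadow_src)))
    data <- data.frame(preds, shadows, .outcome = y, check.names = FALSE)
    # z-scored permutation importance (importance / SE over trees): the
    # shadow maximum then sits at a high quantile of a unit-scale null,
    # a bar that weak chance correlations do not clear
    fit <- rf_fit(data, ntree = config$ntree, mtry = config$mtry,
                  seed = derive_seed(config$seed, 10000L + run),
                  importance = "permutation", scale_importance = TRUE)
    imp <- ranger::importance(fit)
    smax <- max(imp[startsWith(names(imp), ".shadow_")])
    shadow_max[run] <- smax
    imp_history[run, active] <- imp[active]
    hit <- imp[active] > smax
    hits[active] <- hits[active] + as.integer(hit)
    runs[active] <- runs[active] + 1L
    alpha_eff <- if (identical(config$adjust, "bonferroni")) {
      config$alpha / length(cand)
    } else config$alpha
    for (v in active) {
      p_up <- stats::pbinom(hits[v] - 1L, runs[v], 0.5, lower.tail = FALSE)
      p_dn <- stats::pbinom(hits[v], runs[v], 0.5)
      if (2 * p_up < alpha_eff) {
        decisions[v] <- "Confirmed"
      } else if (2 * p_dn < alpha_eff) {
        decisions[v] <- "Rejected"
      }
    }
  }
  final <- decisions
  tentative <- names(decisions)[decisions == "Tentative"]
  for (v in tentative) {
    med_imp <- stats::median(imp_history[, v], na.rm = TRUE)
    med_shadow <- stats::median(shadow_max[seq_len(run)], na.rm = TRUE)
    final[v] <- if (med_imp > med_shadow) "Confirmed" else "Rejected"
    decisions[v] <- "Tentative-resolved"
  }
  stopifnot(!any(startsWith(names(final)[final == "Confirmed"], ".shadow_")))
  structure(list(
    decisions = decisions, final = final,
    confirmed = names(final)[final == "Confirmed"],
    hits = hits, runs_per_variable = runs, n_runs = run,
    importance_history = imp_history[seq_len(run), , drop = FALSE],
    shadow_max = shadow_max[seq_len(run)],
    n = n, config = config
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d runs on %d cases; %d Confirmed, %d Rejected (%d resolved from Tentative)\n",
              x$n_runs, x$n, sum(x$final == "Confirmed"),
              sum(x$final == "Rejected"),
              sum(x$decisions == "Tentative-resolved")))
  if (length(x$confirmed)) {
    cat("  confirmed:", paste(x$confirmed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Repeated cross-validated evaluation of a regression forest
#'
#' Repeated k-fold cross-validation (default 5-fold, 3 repeats) of a
#' regression forest (default 500 trees) on the supplied predictors.
#' Per fold: MSE, MAE and R-squared defined as `1 - SSE/SST` (so a
#' no-signal model scores near or below zero).
#'
#' @param X data.frame of predictors (complete cases with `y` used).
#' @param y numeric outcome.
#' @param k folds per repeat.
#' @param repeats number of repeats.
#' @param ntree trees per forest.
#' @param mtry optional override.
#' @param seed integer seed (fold assignment and forests).
#' @return A `model_metrics` object: per-fold table, summary (mean and
#'   SD per metric), CV scheme, n.
#' @export
evaluate_model <- function(X, y, k = 5L, repeats = 3L, ntree = 500L,
                           mtry = NULL, seed = 1L) {
  X <- as.data.frame(X)
  if (ncol(X) < 1L) {
    stop_methrisk("need >= 1 predictor", "methrisk_invalid_input")
  }
  keep <- stats::complete.cases(X, y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  if (n < 2L * k) {
    stop_methrisk("too few complete cases for the requested folds",
                  "methrisk_too_few_cases")
  }
  folds <- with_seed(derive_seed(seed, 1L), {
    lapply(seq_len(repeats), function(r) sample(rep_len(seq_len(k), n)))
  })
  rows <- list()
  for (r in seq_len(repeats)) {
    for (f in seq_len(k)) {
      test <- folds[[r]] == f
      if (sum(test) < 2L || sum(!test) < 2L) {
        stop_methrisk("fold with < 2 samples", "methrisk_invalid_input")
      }
      fit <- rf_fit(data.frame(X[!test, , drop = FALSE],
                               .outcome = y[!test], check.names = FALSE),
                    ntree = ntree, mtry = mtry,
                    seed = derive_seed(seed, 100L * r + f))
      pred <- stats::predict(
        fit, data.frame(X[test, , drop = FALSE], check.names = FALSE)
      )$predictions
      err <- y[test] - pred
      sst <- sum((y[test] - mean(y[test]))^2)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = r, fold = f, n_test = sum(test),
        mse = mean(err^2), mae = mean(abs(err)),
        r_squared = 1 - sum(err^2) / sst)
    }
  }
  fold_metrics <- do.call(rbind, rows)
  summarise <- function(col) c(mean = mean(col), sd = stats::sd(col))
  structure(list(
    fold_metrics = fold_metrics,
    summary = list(mse = summarise(fold_metrics$mse),
                   mae = summarise(fold_metrics$mae),
                   r_squared = summarise(fold_metrics$r_squared)),
    cv = list(k = k, repeats = repeats), ntree = ntree, n = n
  ), class = "model_metrics")
}

#' @export
print.model_metrics <- function(x, ...) {
  s <- x$summary
  cat(sprintf("model_metrics (n = %d, %d-fold x %d repeats, %d trees):\n",
              x$n, x$cv$k, x$cv$repeats, x$ntree))
  cat(sprintf("  MSE %.4f (SD %.4f) | MAE %.4f (SD %.4f) | R2 %.4f (SD %.4f)\n",
              s$mse["mean"], s$mse["sd"], s$mae["mean"], s$mae["sd"],
              s$r_squared["mean"], s$r_squared["sd"]))
  invisible(x)
}

#' Compare outcome models over different predictor sets
#'
#' Runs shadow-variable selection followed by cross-validated
#' evaluation for each named predictor set (typically model 1 = raw
#' risk variables, model 2 = risk-profile dimensions, model 3 = pattern
#' scores), each on its own complete cases. Mandatory covariates are
#' included in every model.
#'
#' @param y numeric outcome.
#' @param models named list of predictor data.frames.
#' @param covariates optional data.frame of mandatory covariates.
#' @param config a [boruta_config()].
#' @param pair_map optional named character vector pairing variables
#'   across models (e.g. dimension -> best-correlated component);
#'   jointly selected pairs are flagged in the report.
#' @param cv list with `k` and `repeats` for the evaluation step.
#' @return A `comparison_report`: per-model n, selected variables and
#'   metrics, plus jointly selected pairs.
#' @export
compare_models <- function(y, models, covariates = NULL,
                           config = boruta_config(), pair_map = NULL,
                           cv = list(k = 5L, repeats = 3L)) {
  stopifnot(is.list(models), length(models) >= 1L, !is.null(names(models)))
  res <- list()
  for (nm in names(models)) {
    sel <- boruta_select(models[[nm]], y, covariates = covariates,
                         config = config)
    eval_vars <- if (length(sel$confirmed)) sel$confirmed else names(models[[nm]])
    Xe <- models[[nm]][, eval_vars, drop = FALSE]
    if (!is.null(covariates)) Xe <- cbind(Xe, covariates)
    met <- evaluate_model(Xe, y, k = cv$k, repeats = cv$repeats,
                          ntree = config$ntree, seed = config$seed)
    res[[nm]] <- list(selection = sel, metrics = met,
                      n = sel$n, selected = sel$confirmed)
  }
  tab <- do.call(rbind, lapply(names(res), function(nm) {
    s <- res[[nm]]$metrics$summary
    data.frame(model = nm, n = res[[nm]]$n,
               n_selected = length(res[[nm]]$selected),
               selected = paste(res[[nm]]$selected, collapse = ","),
               mse = s$mse[["mean"]], mae = s$mae[["mean"]],
               r_squared = s$r_squared[["mean"]],
               stringsAsFactors = FALSE)
  }))
  joint_pairs <- character(0)
  if (!is.null(pair_map)) {
    all_selected <- unlist(lapply(res, `[[`, "selected"))
    joint <- names(pair_map)[names(pair_map) %in% all_selected &
                               pair_map %in% all_selected]
    joint_pairs <- paste(joint, pair_map[joint], sep = "/")
  }
  structure(list(table = tab, models = res, joint_pairs = joint_pairs),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (length(x$joint_pairs)) {
    cat("jointly selected pairs:", paste(x$joint_pairs, collapse = "; "), "\n")
  }
  invisible(x)
}

# Mean/mode fill followed by regularized rank-2 SVD refinement of the
# (standardized) numeric block; used by the imputed sensitivity variant.
impute_mixed_simple <- function(X, rank = 2L, iter = 50L) {
  X <- as.data.frame(X)
  num <- names(X)[vapply(X, is.numeric, TRUE)]
  for (v in setdiff(names(X), num)) {
    x <- X[[v]]
    if (anyNA(x)) {
      x[is.na(x)] <- stat_mode(x)
      X[[v]] <- x
    }
  }
  if (length(num) >= 2L && anyNA(X[, num])) {
    M <- as.matrix(X[, num])
    obs <- !is.na(M)
    ctr <- colMeans(M, na.rm = TRUE)
    scl <- apply(M, 2L, stats::sd, na.rm = TRUE)
    scl[scl == 0 | is.na(scl)] <- 1
    Z <- scale(M, center = ctr, scale = scl)
    Z[!obs] <- 0
    r <- min(rank, dim(Z) - 1L)
    for (i in seq_len(iter)) {
      sv <- svd(Z, nu = r, nv = r)
      fit <- sv$u %*% (sv$d[seq_len(r)] * t(sv$v))
      Z[!obs] <- fit[!obs]
    }
    M <- sweep(sweep(Z, 2L, scl, "*"), 2L, ctr, "+")
    M[obs] <- as.matrix(X[, num])[obs]
    for (j in seq_along(num)) X[[num[j]]] <- M[, j]
  }
  X
}

#' Sensitivity analysis variants of an outcome model
#'
#' Evaluates the outcome model under one of three data-handling
#' variants: `"raw"` (all variables, complete cases), `"selected"`
#' (shadow-variable-confirmed variables only, complete cases) or
#' `"imputed"` (all variables with missing predictor cells imputed by
#' mean/mode fill plus model-based low-rank refinement; only subjects
#' with an observed outcome enter the evaluation).
#'
#' @param X data.frame of predictors.
#' @param y numeric outcome.
#' @param variant `"raw"`, `"selected"` or `"imputed"`.
#' @param covariates optional mandatory covariates.
#' @param config a [boruta_config()].
#' @param cv list with `k` and `repeats`.
#' @return A `model_metrics` object with a `variant` attribute (and the
#'   selection result for `"selected"`).
#' @export
sensitivity_models <- function(X, y, variant = c("raw", "selected", "imputed"),
                               covariates = NULL, config = boruta_config(),
                               cv = list(k = 5L, repeats = 3L)) {
  variant <- match.arg(variant)
  X <- as.data.frame(X)
  Xfull <- X
  if (!is.null(covariates)) Xfull <- cbind(X, as.data.frame(covariates))
  met <- switch(variant,
    raw = evaluate_model(Xfull, y, k = cv$k, repeats = cv$repeats,
                         ntree = config$ntree, seed = config$seed),
    selected = {
      sel <- boruta_select(X, y, covariates = covariates, config = config)
      vars <- if (length(sel$confirmed)) sel$confirmed else names(X)
      Xs <- X[, vars, drop = FALSE]
      if (!is.null(covariates)) Xs <- cbind(Xs, covariates)
      m <- evaluate_model(Xs, y, k = cv$k, repeats = cv$repeats,
                          ntree = config$ntree, seed = config$seed)
      attr(m, "selection") <- sel
      m
    },
    imputed = {
      Ximp <- impute_mixed_simple(Xfull)
      evaluate_model(Ximp, y, k = cv$k, repeats = cv$repeats,
                     ntree = config$ntree, seed = config$seed)
    }
  )
  attr(met, "variant") <- variant
  met
}

#' Plot-ready importance table from a selection result
#'
#' Per-variable importance distribution over runs (median and
#' quartiles) plus a reference row for the shadow-maximum distribution,
#' mirroring the grey reference line of an all-relevant selection plot.
#'
#' @param selection a `selection_result`.
#' @return data.frame with one row per variable plus one
#'   `.shadow_max` reference row.
#' @export
importance_report <- function(selection) {
  ih <- selection$importance_history
  qs <- function(x) {
    x <- x[!is.na(x)]
    c(median = stats::median(x),
      q1 = unname(stats::quantile(x, 0.25)),
      q3 = unname(stats::quantile(x, 0.75)))
  }
  rows <- lapply(colnames(ih), function(v) {
    q <- qs(ih[, v])
    data.frame(variable = v, decision = selection$final[[v]],
               median = q["median"], q1 = q["q1"], q3 = q["q3"],
               hits = selection$hits[[v]],
               runs = selection$runs_per_variable[[v]],
               stringsAsFactors = FALSE)
  })
  q <- qs(selection$shadow_max)
  rows[[length(rows) + 1L]] <- data.frame(
    variable = ".shadow_max", decision = "reference",
    median = q["median"], q1 = q["q1"], q3 = q["q3"],
    hits = NA_integer_, runs = selection$n_runs, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize / load a selection result as JSON
#'
#' @param selection a `selection_result`.
#' @param path JSON file path.
#' @return `path` invisibly (writer); a `selection_result` (reader).
#' @export
write_selection_result <- function(selection, path) {
  payload <- list(
    decisions = as.list(selection$decisions),
    final = as.list(selection$final),
    confirmed = selection$confirmed,
    hits = as.list(selection$hits),
    runs_per_variable = as.list(selection$runs_per_variable),
    n_runs = selection$n_runs,
    importance_history = list(values = as.vector(selection$importance_history),
                              variables = colnames(selection$importance_history)),
    shadow_max = selection$shadow_max,
    n = selection$n,
    config = unclass(selection$config)
  )
  write_json_file(payload, path)
}

#' @rdname write_selection_result
#' @export
read_selection_result <- function(path) {
  p <- read_json_file(path)
  ih <- matrix(p$importance_history$values, nrow = p$n_runs,
               dimnames = list(NULL, p$importance_history$variables))
  cfg <- p$config
  structure(list(
    decisions = unlist(p$decisions), final = unlist(p$final),
    confirmed = as.character(unlist(p$confirmed)),
    hits = unlist(p$hits), runs_per_variable = unlist(p$runs_per_variable),
    n_runs = p$n_runs, importance_history = ih,
    shadow_max = p$shadow_max, n = p$n,
    config = structure(list(ntree = cfg$ntree, alpha = cfg$alpha,
                            max_runs = cfg$max_runs, mtry = cfg$mtry,
                            seed = cfg$seed), class = "boruta_config")
  ), class = "selection_result")
}
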