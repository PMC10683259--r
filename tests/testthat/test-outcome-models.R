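test_that("binomial confirm threshold matches exact tail enumeration", {
  # independent oracle: accumulate the exact binomial tail by summation
  oracle_threshold <- function(runs, alpha) {
    tail <- rev(cumsum(rev(choose(runs, 0:runs) * 0.5^runs)))
    min(which(2 * tail[-1] < alpha))  # tail[k+1] = P(X >= k)
  }
  expect_equal(boruta_confirm_threshold(20, 0.05), 15L)
  expect_equal(oracle_threshold(20, 0.05), 15L)
  for (runs in c(10, 25, 40)) {
    expect_equal(boruta_confirm_threshold(runs, 0.05),
                 oracle_threshold(runs, 0.05))
  }
})

test_that("permutation importance ranks a deterministic driver first", {
  ranks <- vapply(1:3, function(sd) {
    methrisk:::with_seed(sd, {
      n <- 150
      X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                      x4 = rnorm(n), x5 = rnorm(n))
      imp <- permutation_importance(X, X$x1, ntree = 300L, seed = sd)
      which.max(imp)
    })
  }, 0L)
  expect_true(all(ranks == 1L))
  # a variable independent of everything has importance near zero
  methrisk:::with_seed(4, {
    n <- 300
    X <- data.frame(signal = rnorm(n), noise = rnorm(n))
    y <- X$signal + rnorm(n, sd = 0.3)
    imp <- permutation_importance(X, y, ntree = 500L, seed = 4)
    expect_lt(abs(imp["noise"]), 0.1 * imp["signal"])
  })
})

test_that("shadow-variable selection confirms drivers and rejects noise", {
  methrisk:::with_seed(61, {
    n <- 150
    X <- as.data.frame(matrix(rnorm(n * 10), n, 10))
    names(X) <- paste0("v", 1:10)
    y <- 2 * X$v1 + rnorm(n, sd = 0.5)
    sel <- boruta_select(X, y, config = boruta_config(seed = 61L,
                                                      max_runs = 50L))
    expect_true("v1" %in% sel$confirmed)
    expect_lte(length(setdiff(sel$confirmed, "v1")), 1L)
    expect_false(any(startsWith(sel$confirmed, ".shadow_")))
    expect_setequal(names(sel$final), names(X))

    # seeded determinism of the full result
    sel2 <- boruta_select(X, y, config = boruta_config(seed = 61L,
                                                       max_runs = 50L))
    expect_identical(sel$final, sel2$final)
    expect_identical(sel$importance_history, sel2$importance_history)
  })
})

test_that("selection rejects degenerate inputs", {
  X <- data.frame(a = rnorm(40), b = rnorm(40))
  expect_error(boruta_select(X, rep(1, 40)),
               class = "methrisk_degenerate_response")
  expect_error(boruta_select(X[1:10, ], rnorm(10)),
               class = "methrisk_too_few_cases")
  expect_error(boruta_select(X[, 1, drop = FALSE], rnorm(40)),
               class = "methrisk_invalid_input")
})

test_that("cross-validated metrics behave at the signal extremes", {
  methrisk:::with_seed(67, {
    n <- 400
    x <- rnorm(n)
    y_strong <- x + rnorm(n, sd = 0.1)
    strong <- evaluate_model(data.frame(x = x), y_strong,
                             ntree = 300L, seed = 1L)
    expect_gt(strong$summary$r_squared[["mean"]], 0.9)
    expect_equal(nrow(strong$fold_metrics), 15L)

    flat <- evaluate_model(data.frame(x = rnorm(n)),
                           rnorm(n, sd = 0.01) + 5,
                           ntree = 200L, seed = 2L)
    expect_lt(flat$summary$r_squared[["mean"]], 0.1)
    # MSE near the tiny noise variance, far from the outcome scale
    expect_lt(flat$summary$mse[["mean"]], 5e-4)

    again <- evaluate_model(data.frame(x = x), y_strong,
                            ntree = 300L, seed = 1L)
    # same seed: bit-for-fold reproducible
    expect_identical(strong$fold_metrics, again$fold_metrics)
  })
})

test_that("model comparison reports one row per model and flags pairs", {
  methrisk:::with_seed(71, {
    n <- 200
    z <- rnorm(n)
    X1 <- data.frame(dim1 = z + rnorm(n, sd = 0.4), junk1 = rnorm(n))
    X2 <- data.frame(comp1 = z + rnorm(n, sd = 0.4), junk2 = rnorm(n))
    y <- z + rnorm(n, sd = 0.5)
    cmp <- compare_models(y, list(m_dims = X1, m_patterns = X2, m_same = X1),
                          config = boruta_config(seed = 71L, max_runs = 30L),
                          pair_map = c(dim1 = "comp1"),
                          cv = list(k = 5L, repeats = 2L))
    expect_equal(nrow(cmp$table), 3L)
    # identical inputs give identical metrics
    expect_equal(cmp$table$mse[cmp$table$model == "m_dims"],
                 cmp$table$mse[cmp$table$model == "m_same"])
    expect_equal(cmp$joint_pairs, "dim1/comp1")
  })
})

test_that("sensitivity variants relate as designed", {
  methrisk:::with_seed(73, {
    n <- 250
    # correlated predictors so the imputation has structure to exploit
    z <- rnorm(n)
    X <- data.frame(a = z + rnorm(n, sd = 0.5), b = z + rnorm(n, sd = 0.5),
                    c = rnorm(n))
    y <- z + rnorm(n, sd = 0.5)
    cfg <- boruta_config(seed = 73L, max_runs = 30L)
    cv <- list(k = 5L, repeats = 2L)

    raw <- sensitivity_models(X, y, "raw", config = cfg, cv = cv)
    imp <- sensitivity_models(X, y, "imputed", config = cfg, cv = cv)
    expect_identical(raw$fold_metrics, imp$fold_metrics)

    selm <- sensitivity_models(X, y, "selected", config = cfg, cv = cv)
    sel <- attr(selm, "selection")
    expect_true(all(sel$confirmed %in% names(X)))

    Xm <- X
    # missingness hits one informative predictor (its correlate stays
    # complete, so imputation has signal to restore) and the noise one
    Xm$a[sample(n, round(0.2 * n))] <- NA
    Xm$c[sample(n, round(0.2 * n))] <- NA
    raw_m <- sensitivity_models(Xm, y, "raw", config = cfg, cv = cv)
    imp_m <- sensitivity_models(Xm, y, "imputed", config = cfg, cv = cv)
    rel <- abs(raw_m$summary$mse[["mean"]] - imp_m$summary$mse[["mean"]]) /
      raw_m$summary$mse[["mean"]]
    expect_lt(rel, 0.2)
    expect_gt(imp_m$n, raw_m$n)

    expect_error(sensitivity_models(X, y, "bogus"), "arg")
  })
})

test_that("importance report carries every variable plus the shadow reference", {
  methrisk:::with_seed(79, {
    n <- 120
    X <- as.data.frame(matrix(rnorm(n * 5), n, 5))
    names(X) <- paste0("v", 1:5)
    y <- X$v1 + rnorm(n, sd = 0.4)
    sel <- boruta_select(X, y, config = boruta_config(seed = 79L,
                                                      max_runs = 25L))
    rep <- importance_report(sel)
    expect_equal(nrow(rep), 6L)
    expect_equal(rep$variable[6], ".shadow_max")
    conf_rows <- rep[rep$decision == "Confirmed", ]
    expect_true(all(conf_rows$median > rep$median[6]))

    path <- tempfile(fileext = ".json")
    write_selection_result(sel, path)
    sel2 <- read_selection_result(path)
    expect_identical(sel2$final, sel$final)
    expect_equal(sel2$importance_history, sel$importance_history,
                 tolerance = 1e-12)
    expect_identical(importance_report(sel2)$decision, rep$decision)
  })
})
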