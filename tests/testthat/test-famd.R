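# Oracles: standardized PCA (independent eigendecomposition of the
# correlation matrix under the population convention) for continuous
# input; direct multiple correspondence analysis on the indicator
# matrix for categorical input.

pca_oracle <- function(X) {
  n <- nrow(X)
  Z <- apply(X, 2, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2)))
  eg <- eigen(crossprod(Z) / n, symmetric = TRUE)
  scores <- Z %*% eg$vectors
  list(eigenvalues = eg$values, scores = scores)
}

test_that("mixed coding has the MCA scaling and inertia identity", {
  tab <- tiny_cohort()
  enc <- encode_mixed(tab, c("age", "weight", "smoker", "parity"))
  Z <- enc$Z
  n <- nrow(Z)
  expect_equal(unname(colMeans(Z)), rep(0, ncol(Z)), tolerance = 1e-12)
  # continuous columns are population z-scores
  age <- as.data.frame(tab)$age
  expect_equal(unname(Z[, "age"]),
               (age - mean(age)) / sqrt(mean((age - mean(age))^2)),
               tolerance = 1e-12)
  # level column sum of squares = n * (1 - freq)
  for (lv in levels(tab$smoker)) {
    p <- mean(tab$smoker == lv)
    expect_equal(sum(Z[, paste0("smoker.", lv)]^2), n * (1 - p),
                 tolerance = 1e-9)
  }
  # total inertia = p_continuous + (total levels - p_categorical)
  inertia <- sum(colSums(Z^2)) / n
  expect_equal(inertia, 2 + (nlevels(tab$smoker) + nlevels(tab$parity) - 2),
               tolerance = 1e-9)
  expect_error(encode_mixed(tab, c("age"))$Z, NA)
  const <- cohort_table(data.frame(subject_id = c("a", "b"), x = c(1, 1)),
                        c(x = "continuous"))
  expect_error(encode_mixed(const), class = "methrisk_degenerate_variable")
})

test_that("all-continuous fit equals standardized PCA", {
  tab <- tiny_cohort()
  m <- famd_fit(tab, c("age", "weight", "outcome"))
  oracle <- pca_oracle(as.matrix(as.data.frame(tab)[, c("age", "weight",
                                                        "outcome")]))
  expect_equal(m$eigenvalues[1:3], oracle$eigenvalues, tolerance = 1e-8)
  for (j in 1:3) {
    expect_equal(abs(cor(m$scores[, j], oracle$scores[, j])), 1,
                 tolerance = 1e-8)
    expect_equal(max(abs(abs(m$scores[, j]) - abs(oracle$scores[, j]))), 0,
                 tolerance = 1e-8)
  }
})

test_that("two standardized variables with known correlation give exact eigenvalues", {
  n <- 100
  base <- methrisk:::with_seed(3, matrix(rnorm(n * 2), n, 2))
  Q <- qr.Q(qr(scale(base, scale = FALSE)))  # exactly orthonormal
  z1 <- Q[, 1] * sqrt(n)
  z2 <- 0.6 * z1 + 0.8 * Q[, 2] * sqrt(n)   # empirical r exactly 0.6
  tab <- cohort_table(data.frame(subject_id = as.character(1:n),
                                 x = z1, y = z2),
                      c(x = "continuous", y = "continuous"))
  m <- famd_fit(tab)
  expect_equal(m$eigenvalues[1:2], c(1.6, 0.4), tolerance = 1e-10)
})

test_that("all-categorical fit matches direct correspondence analysis", {
  tab <- tiny_cohort()
  vars <- c("smoker", "parity", "sex")
  m <- famd_fit(tab, vars)
  # independent MCA oracle on the scaled indicator matrix
  df <- as.data.frame(tab)[, vars]
  ind <- do.call(cbind, lapply(vars, function(v) {
    stats::model.matrix(~ x - 1, data.frame(x = df[[v]]))
  }))
  p <- colMeans(ind)
  Zo <- sweep(sweep(ind, 2, sqrt(p), "/"), 2, sqrt(p), "-")
  sv <- svd(Zo / sqrt(nrow(Zo)))
  oracle_scores <- Zo %*% sv$v
  for (j in 1:3) {
    expect_equal(abs(cor(m$scores[, j], oracle_scores[, j])), 1,
                 tolerance = 1e-8)
  }
  expect_equal(m$eigenvalues[1:3], sv$d[1:3]^2, tolerance = 1e-8)
})

test_that("contributions sum to 100 and dimension scores are uncorrelated", {
  sim <- small_sim()
  comp <- suppressWarnings(
    impute_famd(sim$cohort, variables = sim$truth$risk_variable_names))
  m <- famd_fit(comp, sim$truth$risk_variable_names)
  expect_equal(unname(colSums(m$contributions)),
               rep(100, ncol(m$contributions)), tolerance = 1e-6)
  cc <- cor(m$scores[, 1:m$rank])
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  expect_equal(unname(colMeans(m$scores)), rep(0, ncol(m$scores)),
               tolerance = 1e-9)
  # variance accounted sums to 1 over all dimensions
  expect_equal(sum(m$eigenvalues) / m$total_inertia, 1, tolerance = 1e-9)
})

test_that("dimension selection criteria follow their definitions", {
  mock <- structure(list(eigenvalues = c(3, 2, 1, 0.5, 0.5), rank = 5L),
                    class = "risk_profile_model")
  expect_equal(select_dimensions(mock, "kaiser"), c(1L, 2L))
  expect_equal(select_dimensions(mock, "top_k", k = 5), 1:5)
  expect_error(select_dimensions(mock, "top_k", k = 6),
               class = "methrisk_invalid_input")
  elbow <- structure(list(eigenvalues = c(5, 1, 0.9, 0.8), rank = 4L),
                     class = "risk_profile_model")
  expect_equal(select_dimensions(elbow, "elbow"), 1L)
  expect_equal(contribution_threshold(
    structure(list(variables = letters[1:8]), class = "risk_profile_model")),
    12.5)
  expect_equal(contribution_threshold(
    structure(list(variables = letters[1:4]), class = "risk_profile_model")),
    25)
})

test_that("scoring reproduces training scores and rejects unseen levels", {
  tab <- tiny_cohort()
  m <- famd_fit(tab, c("age", "smoker", "parity"))
  sc <- score_subjects(m, tab)
  expect_equal(max(abs(sc - m$scores)), 0, tolerance = 1e-10)

  df <- as.data.frame(tab)
  df$parity <- factor(as.character(df$parity),
                      levels = c(levels(tab$parity), "twins"))
  df$parity[1] <- "twins"
  bad <- cohort_table(df, variable_types(tab))
  expect_error(score_subjects(m, bad), class = "methrisk_unseen_level",
               regexp = "parity.*twins")
})

test_that("imputation recovers exact low-rank structure and is monotone", {
  # complete table returned unchanged (modulo the imputation log)
  tab <- tiny_cohort()
  same <- impute_famd(tab)
  attr(same, "impute_info") <- NULL
  expect_identical(as.data.frame(same), as.data.frame(tab))

  # rank-1 continuous table: x2 = 2 * x1, 10% of cells deleted
  n <- 80
  x1 <- methrisk:::with_seed(5, rnorm(n))
  full <- data.frame(subject_id = as.character(1:n), x1 = x1, x2 = 2 * x1)
  holes <- methrisk:::with_seed(6, {
    cbind(sample(n, 8), sample(2:3, 8, replace = TRUE))
  })
  df <- full
  for (i in seq_len(nrow(holes))) df[holes[i, 1], holes[i, 2]] <- NA
  tab1 <- cohort_table(df, c(x1 = "continuous", x2 = "continuous"))
  imp <- impute_famd(tab1, n_dims = 1L, shrinkage = "none", tol = 1e-9,
                     max_iter = 2000L)
  expect_equal(as.data.frame(imp)$x1, full$x1, tolerance = 1e-6)
  expect_equal(as.data.frame(imp)$x2, full$x2, tolerance = 1e-6)

  # observed-cell objective is non-increasing
  sim <- small_sim()
  imp2 <- suppressWarnings(
    impute_famd(sim$cohort, variables = sim$truth$risk_variable_names,
                shrinkage = "none", max_iter = 60L))
  obj <- attr(imp2, "impute_info")$objective
  expect_true(all(diff(obj) <= 1e-8 * max(obj[1], 1)))

  # imputation error shrinks as the missing fraction shrinks (noisy
  # rank-1 toy, averaged over seeds)
  n2 <- 200
  err_at <- function(f) {
    mean(vapply(1:3, function(sd) {
      methrisk:::with_seed(sd, {
        x <- rnorm(n2)
        fullm <- cbind(x1 = x, x2 = 2 * x + rnorm(n2, sd = 0.1))
        df <- data.frame(subject_id = as.character(1:n2), fullm)
        del <- cbind(sample(n2, round(f * n2)),
                     sample(2:3, round(f * n2), TRUE))
        for (i in seq_len(nrow(del))) df[del[i, 1], del[i, 2]] <- NA
        tabf <- cohort_table(df, c(x1 = "continuous", x2 = "continuous"))
        impf <- suppressWarnings(impute_famd(tabf, n_dims = 1L,
                                             max_iter = 500L))
        mean(abs(as.matrix(as.data.frame(impf)[, 2:3]) - fullm))
      })
    }, 0))
  }
  errs <- c(err_at(0.4), err_at(0.2), err_at(0.05))
  expect_lt(errs[3], errs[1])

  expect_error(impute_famd(cohort_table(
    data.frame(subject_id = c("a", "b"), x = c(NA_real_, NA_real_)),
    c(x = "continuous"))), class = "methrisk_invalid_input")
})

test_that("risk-profile model serialization round-trips scoring", {
  tab <- tiny_cohort()
  m <- famd_fit(tab, c("age", "smoker", "parity"))
  path <- tempfile(fileext = ".json")
  write_risk_profile_model(m, path)
  m2 <- read_risk_profile_model(path)
  expect_equal(score_subjects(m2, tab), score_subjects(m, tab),
               tolerance = 1e-9)
  expect_equal(m2$eigenvalues, m$eigenvalues, tolerance = 1e-12)
})
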