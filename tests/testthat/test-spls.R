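# Dense-limit oracle: with sparsity disabled the first weight vector
# must equal the leading left singular vector of centered-X' x
# standardized-Y, and the full fit must match an independently coded
# SVD-based dense PLS with the same deflation convention.

dense_pls_oracle <- function(X, Y, ncomp) {
  E <- scale(X, center = TRUE, scale = FALSE)
  Ys <- scale(Y)
  W <- matrix(0, ncol(X), ncomp)
  T <- matrix(0, nrow(X), ncomp)
  for (h in seq_len(ncomp)) {
    sv <- svd(crossprod(E, Ys), nu = 1, nv = 0)
    w <- sv$u[, 1]
    if (w[which.max(abs(w))] < 0) w <- -w
    t_h <- drop(E %*% w)
    p_h <- drop(crossprod(E, t_h)) / sum(t_h^2)
    E <- E - tcrossprod(t_h, p_h)
    W[, h] <- w
    T[, h] <- t_h
  }
  list(weights = W, scores = T)
}

toy_xy <- function(n = 30, p = 10, q = 2, seed = 13) {
  methrisk:::with_seed(seed, {
    ids <- sprintf("S%02d", seq_len(n))
    lat <- matrix(rnorm(n * q), n, q)
    X <- lat %*% matrix(rnorm(q * p), q, p) + matrix(rnorm(n * p), n, p)
    dimnames(X) <- list(ids, sprintf("cg%03d", seq_len(p)))
    Y <- lat + matrix(rnorm(n * q, sd = 0.5), n, q)
    dimnames(Y) <- list(ids, paste0("dim", seq_len(q)))
    list(X = X, Y = Y)
  })
}

test_that("sparsity-disabled fit matches the SVD dense-PLS oracle", {
  d <- toy_xy()
  fit <- spls_fit(d$X, d$Y, n_components = 3L, keep_x = ncol(d$X))
  oracle <- dense_pls_oracle(d$X, d$Y, 3L)
  for (h in 1:3) {
    expect_equal(unname(fit$weights[, h]), oracle$weights[, h],
                 tolerance = 1e-6)
    expect_equal(unname(fit$scores[, h]), oracle$scores[, h],
                 tolerance = 1e-6)
  }
})

test_that("dense first component agrees with an established sPLS implementation", {
  d <- toy_xy(seed = 17)
  Ys <- scale(d$Y)  # shared response scaling for both implementations
  fit <- spls_fit(d$X, Ys, n_components = 1L, keep_x = ncol(d$X))
  mo <- suppressMessages(mixOmics::spls(
    d$X, Ys, ncomp = 1, keepX = ncol(d$X), mode = "regression",
    scale = FALSE))
  w_ref <- mo$loadings$X[, 1]
  w_ref <- w_ref * sign(w_ref[which.max(abs(w_ref))])
  expect_equal(unname(fit$weights[, 1]), unname(w_ref), tolerance = 1e-6)
})

test_that("sparsity keeps exactly keep_x CpGs, chosen by cross-covariance", {
  d <- toy_xy(seed = 19)
  fit <- spls_fit(d$X, d$Y, n_components = 2L, keep_x = 3L)
  expect_equal(unname(colSums(fit$weights != 0)), c(3L, 3L))
  # brute-force ranking oracle on the first component
  E <- scale(d$X, center = TRUE, scale = FALSE)
  M <- crossprod(E, scale(d$Y))
  v <- svd(M)$v[, 1]
  z <- drop(M %*% v)
  # iterate v to the sparse fixed point exactly as the contract states
  for (i in 1:200) {
    lam <- sort(abs(z), decreasing = TRUE)[4]
    w <- sign(z) * pmax(abs(z) - lam, 0)
    w <- w / sqrt(sum(w^2))
    v <- drop(crossprod(M, w)); v <- v / sqrt(sum(v^2))
    z <- drop(M %*% v)
  }
  top3 <- names(sort(abs(z), decreasing = TRUE))[1:3]
  expect_setequal(names(which(fit$weights[, 1] != 0)), top3)

  big <- toy_xy(n = 40, p = 60, seed = 23)
  fit20 <- spls_fit(big$X, big$Y, n_components = 20L, keep_x = 5L)
  expect_equal(fit20$n_components, 20L)
  expect_equal(unname(colSums(fit20$weights != 0)), rep(5L, 20L))
})

test_that("component scores are orthogonal and fits are order-stable", {
  d <- toy_xy(n = 50, p = 30, seed = 29)
  fit <- spls_fit(d$X, d$Y, n_components = 4L, keep_x = 10L)
  cc <- cor(fit$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)

  perm <- methrisk:::with_seed(1, sample(nrow(d$X)))
  fit_p <- spls_fit(d$X[perm, ], d$Y[perm, ], n_components = 4L,
                    keep_x = 10L)
  expect_equal(fit_p$weights, fit$weights, tolerance = 1e-10)
})

test_that("projection reproduces training scores and validates CpG sets", {
  sim <- small_sim()
  comp <- suppressWarnings(
    impute_famd(sim$cohort, variables = sim$truth$risk_variable_names))
  m <- famd_fit(comp, sim$truth$risk_variable_names)
  fit <- spls_fit(sim$meth, m$scores[, 1:4], n_components = 5L,
                  keep_x = 50L)
  reproj <- project_patterns(fit, sim$meth)
  expect_lt(max(abs(reproj - fit$scores)), 1e-8)

  same_age <- generate_followup_methylation(sim$truth, 7, drift_sd = 0,
                                            noise_sd = 0, seed = 1L)
  expect_lt(max(abs(project_patterns(fit, same_age) - fit$scores)), 1e-8)

  crippled <- sim$meth$beta[, setdiff(colnames(sim$meth$beta),
                                      fit$support[1:5])]
  expect_error(project_patterns(fit, crippled),
               class = "methrisk_cpg_mismatch",
               regexp = fit$support[1])

  with_missing <- sim$meth$beta
  with_missing[3, ] <- NA
  expect_warning(pr <- project_patterns(fit, with_missing),
                 "all-missing")
  expect_equal(nrow(pr), nrow(sim$meth$beta) - 1L)
})

test_that("representative CpGs are ranked by |weight| with stable ties", {
  d <- toy_xy(seed = 31)
  fit <- spls_fit(d$X, d$Y, n_components = 2L, keep_x = 4L)
  rep1 <- representative_cpgs(fit, 1)
  expect_equal(nrow(rep1), 4L)
  expect_true(all(diff(abs(rep1$weight)) <= 1e-15))
  expect_equal(rep1$rank, 1:4)
  expect_error(representative_cpgs(fit, 99), class = "methrisk_invalid_input")
})

test_that("pattern-dimension correlations behave at the edges", {
  methrisk:::with_seed(37, {
    n <- 500
    dims <- matrix(rnorm(n * 3), n, 3)
    self <- pattern_dimension_correlation(dims[, 1, drop = FALSE],
                                          dims[, 1, drop = FALSE])
    expect_equal(unname(self[1, 1]), 1)
    noise <- matrix(rnorm(n * 4), n, 4)
    r <- pattern_dimension_correlation(noise, dims)
    expect_lt(max(r), 0.15)
    degen <- cbind(noise[, 1], rep(1, n))
    expect_warning(rd <- pattern_dimension_correlation(degen, dims),
                   "zero-variance")
    expect_true(all(is.na(rd[2, ])))
  })
})

test_that("pattern model serialization round-trips projection", {
  sim <- small_sim()
  fit <- spls_fit(sim$meth, sim$truth$latent_scores, n_components = 3L,
                  keep_x = 30L)
  path <- tempfile(fileext = ".json")
  write_pattern_model(fit, path)
  fit2 <- read_pattern_model(path)
  expect_equal(project_patterns(fit2, sim$meth),
               project_patterns(fit, sim$meth), tolerance = 1e-9)
  tsv <- tempfile(fileext = ".tsv")
  write_pattern_weights(fit, tsv)
  w <- read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(nrow(w), 3L * 30L)
})
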