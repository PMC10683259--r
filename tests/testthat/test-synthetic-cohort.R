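test_that("generation is deterministic and respects the beta-value contract", {
  cfg <- generator_config(n_subjects = 60L, n_cpgs = 200L,
                          pattern_sizes = c(10L, 10L, 10L), seed = 5L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$meth$beta, b$meth$beta)
  expect_identical(as.data.frame(a$cohort), as.data.frame(b$cohort))
  expect_identical(a$truth$latent_scores, b$truth$latent_scores)
  expect_true(all(a$meth$beta > 0 & a$meth$beta < 1))
  expect_false(anyNA(a$meth$beta))
  # missingness only where declared: outcomes + risk variables
  df <- as.data.frame(a$cohort)
  covs <- c("sex", "batch", "growth_rate", paste0("cell_", 1:6))
  expect_false(anyNA(df[, covs]))
})

test_that("invalid generator configs are rejected", {
  expect_error(generator_config(n_subjects = 10L), class = "methrisk_invalid_config")
  expect_error(generator_config(n_cpgs = 50L, pattern_sizes = c(60L, 10L, 10L)),
               class = "methrisk_invalid_config")
  expect_error(generator_config(missing_fraction_risk = 1.2),
               class = "methrisk_invalid_config")
  expect_error(generator_config(effect_size_dnam = Inf),
               class = "methrisk_invalid_config")
})

test_that("planted methylation signal tracks the latent factors", {
  cfg <- generator_config(seed = 21L)
  sim <- generate_cohort(cfg)
  for (j in 1:3) {
    members <- names(which(sim$truth$pattern_membership == j))
    pc1 <- prcomp(sim$meth$beta[, members], center = TRUE)$x[, 1]
    expect_gt(abs(cor(pc1, sim$truth$latent_scores[, j])), 0.7)
  }
  # disjoint pattern + confounder CpG sets
  sets <- c(split(names(sim$truth$pattern_membership)[
    !is.na(sim$truth$pattern_membership)],
    sim$truth$pattern_membership[!is.na(sim$truth$pattern_membership)]),
    sim$truth$confounder_assignments[c("sex", "cell", "batch")])
  expect_equal(length(unlist(sets)), length(unique(unlist(sets))))
})

test_that("zero methylation effect leaves no latent signal", {
  cfg <- generator_config(effect_size_dnam = 0, seed = 31L)
  sim <- generate_cohort(cfg)
  for (j in 1:3) {
    members <- names(which(sim$truth$pattern_membership == j))
    mb <- rowMeans(sim$meth$beta[, members])
    expect_lt(abs(cor(mb, sim$truth$latent_scores[, j])), 0.1)
  }
})

test_that("follow-up methylation preserves the planted pattern under drift", {
  sim <- small_sim()
  same <- generate_followup_methylation(sim$truth, 7, drift_sd = 0,
                                        noise_sd = 0, seed = 2L)
  expect_equal(same$beta, sim$meth$beta, tolerance = 1e-12)

  wild <- generate_followup_methylation(sim$truth, 7, drift_sd = 5, seed = 3L)
  per_cpg <- vapply(seq_len(ncol(wild$beta)), function(j) {
    cor(wild$beta[, j], sim$meth$beta[, j])
  }, 0)
  expect_lt(median(per_cpg), 0.2)

  fu <- generate_followup_methylation(sim$truth, 7, seed = 4L)
  sc <- true_pattern_scores(sim$truth, fu)
  for (j in 1:3) {
    expect_gt(abs(cor(sc[, j], sim$truth$latent_scores[, j])), 0.5)
  }
})

test_that("external cohort is exchangeable at zero shift and recoverable at default", {
  sim <- small_sim()
  ext0 <- generate_external_cohort(sim$truth, marginal_shift = 0, n = 500L,
                                   seed = 8L)
  df_tr <- as.data.frame(sim$cohort)
  df_ex <- as.data.frame(ext0$cohort)
  pvals <- vapply(sim$truth$risk_variable_names, function(v) {
    if (is.numeric(df_tr[[v]])) {
      suppressWarnings(ks.test(df_tr[[v]], df_ex[[v]]))$p.value
    } else {
      tab <- rbind(table(df_tr[[v]]), table(df_ex[[v]]))
      suppressWarnings(chisq.test(tab))$p.value
    }
  }, 0)
  expect_gte(sum(pvals > 0.01), 6L)

  ext <- generate_external_cohort(sim$truth, n = 300L, seed = 9L)
  sc <- true_pattern_scores(sim$truth, ext$meth)
  for (j in 1:3) {
    expect_gt(abs(cor(sc[, j], ext$latent_scores[, j])), 0.7)
  }

  empty <- generate_external_cohort(sim$truth, n = 0L, seed = 1L)
  expect_equal(nrow(empty$cohort), 0L)
  expect_equal(names(empty$cohort), names(sim$cohort))
  expect_equal(dim(empty$meth$beta), c(0L, sim$truth$config$n_cpgs))
})

test_that("feature tracks hit the requested coverage enrichment", {
  # wide patterns so coverage fractions are estimated precisely
  sim <- generate_cohort(generator_config(
    n_subjects = 40L, n_cpgs = 2000L, pattern_sizes = c(150L, 150L, 150L),
    seed = 14L))
  member <- !is.na(sim$truth$pattern_membership)
  cover_frac <- function(truth, gr, which_cpgs) {
    cg <- map_cpgs_to_intervals(which_cpgs, truth$coords)
    mean(GenomicRanges::countOverlaps(cg, gr) > 0)
  }
  flat <- generate_feature_tracks(sim$truth, enrichment_factor = 1,
                                  background_coverage = 0.3, seed = 5L)
  ratio <- cover_frac(sim$truth, flat, names(which(member))) /
    cover_frac(sim$truth, flat, names(which(!member)))
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)

  rich <- generate_feature_tracks(sim$truth, enrichment_factor = 5,
                                  background_coverage = 0.1, seed = 6L)
  rich_frac <- cover_frac(sim$truth, rich, names(which(member)))
  expect_lt(abs(rich_frac - 0.5), 0.1)

  expect_error(generate_feature_tracks(sim$truth, enrichment_factor = 0.5),
               class = "methrisk_invalid_config")

  nopat <- generate_cohort(generator_config(
    n_subjects = 40L, n_cpgs = 2000L, pattern_sizes = c(0L, 0L, 0L),
    seed = 12L))
  bg <- generate_feature_tracks(nopat$truth, enrichment_factor = 5,
                                background_coverage = 0.2, seed = 7L)
  bg_frac <- cover_frac(nopat$truth, bg, nopat$truth$coords$cpg)
  expect_lt(abs(bg_frac - 0.2), 0.05)
})

test_that("published contingency fixtures carry the printed margins", {
  fx <- table2_fixtures()
  expect_equal(unname(rowSums(fx$sex_by_smoking)), c(7573, 7121))
  expect_equal(sum(fx$sex_by_smoking), 14694)
  expect_equal(unname(fx$totals["partner_sustained"]), 3518)
})
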