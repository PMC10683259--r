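# Shared fixture builders. Everything is generated in code at test
# time; sizes are kept small so individual tests stay fast.

# Tiny mixed-type cohort table with a known structure.
tiny_cohort <- function(n = 60, seed = 7) {
  withr_seed <- function(expr) methrisk:::with_seed(seed, expr)
  withr_seed({
    df <- data.frame(
      subject_id = sprintf("T%03d", seq_len(n)),
      age = rnorm(n, 30, 4),
      weight = rnorm(n, 70, 10),
      smoker = factor(sample(c("no", "yes"), n, replace = TRUE)),
      parity = factor(sample(c("first", "second", "more"), n,
                             replace = TRUE)),
      sex = factor(sample(c("female", "male"), n, replace = TRUE)),
      outcome = rnorm(n),
      stringsAsFactors = FALSE
    )
    cohort_table(df, c(age = "continuous", weight = "continuous",
                       smoker = "categorical", parity = "categorical",
                       sex = "categorical", outcome = "continuous"))
  })
}

# Small beta matrix with coordinates and sample metadata.
tiny_meth <- function(n = 30, p = 50, seed = 11) {
  methrisk:::with_seed(seed, {
    ids <- sprintf("T%03d", seq_len(n))
    cpgs <- sprintf("cg%07d", seq_len(p))
    beta <- matrix(plogis(rnorm(n * p)), n, p,
                   dimnames = list(ids, cpgs))
    coords <- data.frame(cpg = cpgs,
                         chrom = paste0("chr", rep_len(1:3, p)),
                         start = 1000L + 500L * seq_len(p),
                         end = 1001L + 500L * seq_len(p),
                         stringsAsFactors = FALSE)
    samples <- data.frame(subject_id = ids,
                          sex = sample(c("female", "male"), n, TRUE),
                          age = 0, batch = sample(c("b1", "b2"), n, TRUE),
                          stringsAsFactors = FALSE)
    methylation_matrix(beta, coords, samples)
  })
}

# Small default cohort simulation shared by several tests (cached per
# session to avoid regenerating).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_subjects = 200L, n_cpgs = 600L,
                              pattern_sizes = c(25L, 25L, 25L),
                              seed = 99L)
      cache <<- generate_cohort(cfg)
    }
    cache
  }
})
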