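test_that("CpG-to-interval mapping respects 0-based half-open semantics", {
  coords <- data.frame(cpg = c("cgA", "cgB"), chrom = c("chr1", "chr1"),
                       start = c(100L, 500L), end = c(101L, 501L))
  gr0 <- map_cpgs_to_intervals("cgA", coords, flank = 0L)
  expect_equal(GenomicRanges::start(gr0), 101L)  # 0-based 100 -> 1-based 101
  expect_equal(GenomicRanges::width(gr0), 1L)
  gr50 <- map_cpgs_to_intervals("cgA", coords, flank = 50L)
  expect_equal(GenomicRanges::width(gr50), 101L)
  expect_error(map_cpgs_to_intervals("cgZ", coords),
               class = "methrisk_unknown_cpg", regexp = "cgZ")

  # adjacent half-open intervals do not overlap
  a <- interval_set("chr1", 0L, 5L)
  b <- interval_set("chr1", 5L, 10L)
  expect_equal(GenomicRanges::countOverlaps(a, b), 0L)

  # BED round-trip preserves coordinates
  path <- tempfile(fileext = ".bed")
  write_bed(gr50, path)
  back <- read_bed(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr50))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr50))
})

test_that("permutation overlap test honours its estimator bounds", {
  meth <- tiny_meth(p = 80)
  universe <- meth$coords$cpg
  query <- universe[1:10]

  # features covering every CpG: every draw ties the observed count
  all_feat <- interval_set(meth$coords$chrom, meth$coords$start - 10L,
                           meth$coords$end + 10L)
  res_all <- permutation_overlap_test(query, all_feat, universe,
                                      meth$coords, n_perm = 199L, seed = 1L)
  expect_equal(res_all$observed, 10L)
  expect_equal(res_all$p_value, 1)

  # features covering exactly the query: observed beats every draw
  q_feat <- map_cpgs_to_intervals(query, meth$coords)
  res_q <- permutation_overlap_test(query, q_feat, universe, meth$coords,
                                    n_perm = 999L, seed = 2L)
  expect_equal(res_q$observed, 10L)
  expect_equal(res_q$p_value, 1 / 1000)

  expect_error(permutation_overlap_test(universe, q_feat, query,
                                        meth$coords),
               class = "methrisk_invalid_input")
  expect_error(permutation_overlap_test(query, q_feat, universe,
                                        meth$coords, n_perm = 10L),
               class = "methrisk_invalid_input")
})

test_that("planted five-fold feature enrichment is detected", {
  sim <- small_sim()
  tracks <- generate_feature_tracks(sim$truth, enrichment_factor = 5,
                                    background_coverage = 0.1, seed = 3L)
  members <- names(sim$truth$pattern_membership)[
    !is.na(sim$truth$pattern_membership)]
  res <- permutation_overlap_test(members, tracks, sim$truth$coords$cpg,
                                  sim$truth$coords, n_perm = 999L,
                                  seed = 4L)
  expect_lt(res$p_value, 0.01)
})

test_that("Fisher enrichment equals the hypergeometric tail and ranks planted sets first", {
  meth <- tiny_meth(n = 10, p = 200, seed = 5)
  universe <- meth$coords$cpg
  methrisk:::with_seed(59, {
    query <- sample(universe, 40)
    db <- list(
      planted = map_cpgs_to_intervals(
        c(sample(query, 25), sample(setdiff(universe, query), 10)),
        meth$coords),
      random1 = map_cpgs_to_intervals(sample(universe, 35), meth$coords),
      random2 = map_cpgs_to_intervals(sample(universe, 35), meth$coords)
    )
    res <- locus_overlap_enrichment(query, universe, meth$coords, db)
    expect_equal(res$region_set[1], "planted")
    expect_equal(res$combined_rank[1], 1)
    expect_lt(res$q_value[1], 0.05)

    # oracle: one-sided Fisher p equals the hypergeometric upper tail
    for (i in seq_len(nrow(res))) {
      a <- res$support[i]
      inside_total <- local({
        inside <- GenomicRanges::countOverlaps(
          map_cpgs_to_intervals(universe, meth$coords),
          db[[res$region_set[i]]]) > 0
        sum(inside)
      })
      p_oracle <- phyper(a - 1, inside_total,
                         length(universe) - inside_total,
                         length(query), lower.tail = FALSE)
      expect_equal(res$p_value[i], p_oracle, tolerance = 1e-10)
    }
  })

  # a region set identical to the query footprint is capped, rank 1
  qset <- list(exact = map_cpgs_to_intervals(universe[1:15], meth$coords))
  res_exact <- locus_overlap_enrichment(universe[1:15], universe,
                                        meth$coords, qset)
  expect_true(is.finite(res_exact$odds_ratio[1]))
  expect_equal(res_exact$combined_rank[1], 1)

  expect_error(locus_overlap_enrichment(universe[1:5], character(0),
                                        meth$coords, qset),
               class = "methrisk_invalid_input")
})

test_that("region database round-trips through BED + manifest", {
  meth <- tiny_meth(p = 60, seed = 6)
  db <- list(setA = map_cpgs_to_intervals(meth$coords$cpg[1:10],
                                          meth$coords, flank = 20L),
             setB = map_cpgs_to_intervals(meth$coords$cpg[30:40],
                                          meth$coords, flank = 20L))
  dir <- tempfile()
  write_region_db(db, dir)
  back <- read_region_db(dir)
  expect_setequal(names(back), names(db))
  expect_equal(GenomicRanges::start(back$setA),
               GenomicRanges::start(db$setA))
})

test_that("overlap tallies match set algebra and the binomial expectation", {
  comps <- list(comp1 = paste0("cg", 1:20), comp2 = paste0("cg", 21:50))
  none <- overlap_tally(comps, paste0("cg", 100:120))
  expect_equal(none$per_component$overlap, c(0L, 0L))

  all_of_them <- overlap_tally(comps, unlist(comps),
                               flags = c(comp1 = "confounded",
                                         comp2 = "clear"))
  expect_equal(all_of_them$per_component$overlap,
               all_of_them$per_component$size)
  expect_equal(all_of_them$per_component$flagged, c(TRUE, FALSE))
  expect_equal(all_of_them$totals$unique_cpgs, 50L)

  gm <- setNames(rep(c("geneA", "geneB"), each = 25), paste0("cg", 1:50))
  with_genes <- overlap_tally(comps, paste0("cg", 1:30), gene_map = gm)
  expect_equal(with_genes$totals$unique_genes, 2L)

  # random candidates: counts within 3 binomial SDs of m * size / |U|
  methrisk:::with_seed(83, {
    U <- paste0("cg", 1:2000)
    comp <- list(c = sample(U, 200))
    m <- 400
    cand <- sample(U, m)
    cnt <- overlap_tally(comp, cand)$per_component$overlap
    expected <- m * 200 / 2000
    sd3 <- 3 * sqrt(m * 0.1 * 0.9)
    expect_gt(cnt, expected - sd3)
    expect_lt(cnt, expected + sd3)
  })
})
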