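# Genomic contextualisation of pattern CpGs: permutation overlap tests
# against feature tracks, Fisher-exact locus-overlap enrichment with
# combined ranking and BH q-values, and overlap tallies against an
# external candidate CpG list. The background universe is always the
# full CpG set of the array, since array design bias is the explicit
# concern these tests control for.

# Indicator of which universe CpGs fall inside any feature interval.
cpg_in_features <- function(universe, coords, features) {
  gr <- map_cpgs_to_intervals(universe, coords, flank = 0L)
  GenomicRanges::countOverlaps(gr, features) > 0L
}

#' Permutation test of CpG-set overlap with a feature track
#'
#' Observed statistic: the number of query CpGs inside any feature
#' interval. Null: `n_perm` same-size draws without replacement from
#' the background universe. p-value uses the add-one estimator
#' `(1 + #{perm >= observed}) / (1 + n_perm)`, so it is never zero and
#' is floored at `1/(n_perm + 1)`.
#'
#' @param query character vector of query CpG ids (subset of
#'   `universe`).
#' @param features a `GRanges` feature track.
#' @param universe character vector of background CpG ids.
#' @param coords CpG coordinate table covering the universe.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return An `enrichment_result`: observed count, null summary,
#'   permutation p-value.
#' @export
permutation_overlap_test <- function(query, features, universe, coords,
                                     n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) {
    stop_methrisk("n_perm must be >= 99", "methrisk_invalid_input")
  }
  if (length(query) > length(universe)) {
    stop_methrisk("query larger than background universe",
                  "methrisk_invalid_input")
  }
  if (!all(query %in% universe)) {
    stop_methrisk("query must be a subset of the universe",
                  "methrisk_invalid_input")
  }
  inside <- cpg_in_features(universe, coords, features)
  names(inside) <- universe
  observed <- sum(inside[query])
  m <- length(query)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sum(sample(inside, m)), 0L)
  })
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  structure(list(
    observed = observed, n_query = m,
    null_mean = mean(null), null_sd = stats::sd(null),
    null_quantiles = stats::quantile(null, c(0.025, 0.5, 0.975)),
    p_value = p, n_perm = n_perm
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: observed %d/%d in features (null %.1f +/- %.1f), permutation p = %.4g\n",
              x$observed, x$n_query, x$null_mean, x$null_sd, x$p_value))
  invisible(x)
}

#' Locus-overlap enrichment against a region-set database
#'
#' For each named region set, builds the 2x2 table of query/non-query
#' CpGs inside/outside the set (within the universe), computes the
#' one-tailed Fisher exact p-value, the odds ratio
#' (Haldane-Anscombe 0.5 correction for reporting when a cell is zero;
#' the test itself is exact) and the support (overlap count). Region
#' sets are ranked by p, by odds ratio and by support; the combined
#' rank is the maximum of the three (lower = stronger evidence), and
#' Benjamini-Hochberg q-values are computed across the sets of this
#' query.
#'
#' @param query character vector of query CpG ids.
#' @param universe character vector of background CpG ids.
#' @param coords CpG coordinate table.
#' @param region_db named list of `GRanges` region sets.
#' @return data.frame, one row per region set, sorted by combined
#'   rank: `region_set`, `support`, `odds_ratio`, `p_value`, `q_value`,
#'   `p_rank`, `odds_rank`, `support_rank`, `combined_rank`.
#' @export
locus_overlap_enrichment <- function(query, universe, coords, region_db) {
  if (!length(universe)) {
    stop_methrisk("empty universe", "methrisk_invalid_input")
  }
  if (!length(region_db)) {
    stop_methrisk("empty region database", "methrisk_invalid_input")
  }
  if (!all(query %in% universe)) {
    stop_methrisk("query must be a subset of the universe",
                  "methrisk_invalid_input")
  }
  is_query <- universe %in% query
  rows <- lapply(names(region_db), function(nm) {
    inside <- cpg_in_features(universe, coords, region_db[[nm]])
    a <- sum(is_query & inside)
    b <- sum(is_query & !inside)
    c_ <- sum(!is_query & inside)
    d <- sum(!is_query & !inside)
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE),
                             alternative = "greater")
    or <- if (any(c(a, b, c_, d) == 0)) {
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    } else {
      (a * d) / (b * c_)
    }
    data.frame(region_set = nm, support = a, odds_ratio = or,
               p_value = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$p_rank <- rank(out$p_value, ties.method = "min")
  out$odds_rank <- rank(-out$odds_ratio, ties.method = "min")
  out$support_rank <- rank(-out$support, ties.method = "min")
  out$combined_rank <- pmax(out$p_rank, out$odds_rank, out$support_rank)
  out[order(out$combined_rank, out$p_value), , drop = FALSE]
}

#' Tally component CpG overlaps with an external candidate list
#'
#' Counts, per pattern component, how many of its representative CpGs
#' appear in an external candidate list (e.g. hits of a large
#' epigenome-wide meta-analysis), annotating components flagged by the
#' confounder screen and reporting totals: all overlaps, unique CpGs,
#' and unique genes if a CpG-to-gene map is supplied.
#'
#' @param component_sets named list of CpG-id vectors, one per
#'   component.
#' @param candidates character vector of candidate CpG ids.
#' @param flags optional named character vector from
#'   [flag_confounded_patterns()] (`"confounded"`/`"clear"`).
#' @param gene_map optional named character vector, CpG id -> gene.
#' @return List with `per_component` (data.frame: component, size,
#'   overlap, flagged) and `totals` (overlaps, unique CpGs, unique
#'   genes).
#' @export
overlap_tally <- function(component_sets, candidates, flags = NULL,
                          gene_map = NULL) {
  stopifnot(is.list(component_sets), !is.null(names(component_sets)))
  per <- do.call(rbind, lapply(names(component_sets), function(nm) {
    ov <- intersect(component_sets[[nm]], candidates)
    data.frame(component = nm, size = length(component_sets[[nm]]),
               overlap = length(ov),
               flagged = if (!is.null(flags)) {
                 identical(unname(flags[nm]), "confounded")
               } else NA,
               stringsAsFactors = FALSE)
  }))
  all_overlaps <- unlist(lapply(component_sets, intersect, candidates),
                         use.names = FALSE)
  uniq <- unique(all_overlaps)
  totals <- list(overlaps = length(all_overlaps),
                 unique_cpgs = length(uniq))
  if (!is.null(gene_map)) {
    totals$unique_genes <- length(unique(stats::na.omit(gene_map[uniq])))
  }
  list(per_component = per, totals = totals)
}

#' Read / write a region-set database as a directory of BED files
#'
#' The directory holds one BED file per region set plus a
#' `manifest.json` naming them.
#'
#' @param region_db named list of `GRanges` (writer).
#' @param dir database directory.
#' @return `dir` invisibly (writer); named list of `GRanges` (reader).
#' @export
write_region_db <- function(region_db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- stats::setNames(paste0(names(region_db), ".bed"),
                           names(region_db))
  for (nm in names(region_db)) {
    write_bed(region_db[[nm]], file.path(dir, files[[nm]]))
  }
  write_json_file(list(sets = as.list(files)),
                  file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_region_db
#' @export
read_region_db <- function(dir) {
  manifest <- read_json_file(file.path(dir, "manifest.json"))
  out <- lapply(manifest$sets, function(f) read_bed(file.path(dir, f)))
  names(out) <- names(manifest$sets)
  out
}
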