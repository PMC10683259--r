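# SVD-based screening of methylation variability against known
# confounders (sex, estimated cell proportions, batch) and flagging of
# pattern components whose scores track a confounder. The screen only
# annotates: pattern scores are never altered.

#' SVD decomposition of a methylation matrix
#'
#' Column-centers the beta matrix and returns the top-k singular
#' triplets with subject-side component scores and variance explained.
#'
#' @param M a [methylation_matrix()] or numeric matrix (subjects x
#'   CpGs).
#' @param k number of components (default 20).
#' @return List with `scores` (subjects x k, scaled as U d),
#'   `variance_explained` (length k, fractions of total variance) and
#'   `d` (singular values).
#' @export
svd_decompose <- function(M, k = 20L) {
  if (inherits(M, "methylation_matrix")) M <- M$beta
  if (!is_count(k) || k <= 0L) {
    stop_methrisk("k must be a positive integer", "methrisk_invalid_input")
  }
  k <- min(k, nrow(M), ncol(M))
  Mc <- scale(M, center = TRUE, scale = FALSE)
  sv <- svd(Mc)
  total <- sum(sv$d^2)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  dimnames(scores) <- list(rownames(M), paste0("svd", seq_len(k)))
  list(scores = scores,
       variance_explained = sv$d[seq_len(k)]^2 / total,
       d = sv$d,
       v = sv$v[, seq_len(k), drop = FALSE])
}

# Association between one score vector and one confounder: Pearson test
# for continuous confounders, Kruskal-Wallis for categorical ones. The
# effect size is |r| for continuous and the correlation ratio
# (square root of the between-group variance fraction) for categorical,
# so both live on the same [0, 1] scale.
associate_one <- function(score, conf) {
  if (is.numeric(conf)) {
    ct <- stats::cor.test(score, conf)
    list(p = ct$p.value, effect = unname(abs(ct$estimate)),
         test = "pearson")
  } else {
    conf <- droplevels(factor(conf))
    if (nlevels(conf) < 2L) return(NULL)
    kw <- stats::kruskal.test(score, conf)
    gm <- tapply(score, conf, mean)
    eta2 <- sum(tabulate(conf) * (gm - mean(score))^2) /
      sum((score - mean(score))^2)
    list(p = kw$p.value, effect = sqrt(eta2), test = "kruskal-wallis")
  }
}

#' Associate component scores with confounders
#'
#' Tests every score column against every confounder column: Pearson
#' correlation test for continuous confounders, Kruskal-Wallis for
#' categorical ones. Single-level factors are skipped with a warning.
#'
#' @param scores subjects x components matrix.
#' @param confounders data.frame of confounder columns (same subjects,
#'   same order).
#' @return List with `p_values` and `effects` matrices (components x
#'   confounders).
#' @export
associate_confounders <- function(scores, confounders) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == nrow(confounders))
  comp_names <- colnames(scores) %||% paste0("comp", seq_len(ncol(scores)))
  pm <- em <- matrix(NA_real_, ncol(scores), ncol(confounders),
                     dimnames = list(comp_names, names(confounders)))
  for (j in seq_along(confounders)) {
    conf <- confounders[[j]]
    if (!is.numeric(conf) && nlevels(droplevels(factor(conf))) < 2L) {
      warning(sprintf("skipping single-level confounder '%s'",
                      names(confounders)[j]))
      next
    }
    for (i in seq_len(ncol(scores))) {
      res <- associate_one(scores[, i], conf)
      pm[i, j] <- res$p
      em[i, j] <- res$effect
    }
  }
  list(p_values = pm, effects = em)
}

#' Flag pattern components confounded by technical covariates
#'
#' A pattern is flagged "confounded" when, for any confounder in the
#' dismissal set (by default sex, cell proportions and batch), its
#' association passes both `p < alpha` and `|effect| >= r_min`. Social
#' covariates (maternal education, paternal social status) are screened
#' and reported but never dismiss a pattern; they stay covariates
#' downstream.
#'
#' @param pattern_scores subjects x components matrix.
#' @param confounders data.frame of confounder columns.
#' @param alpha p-value threshold (default 1e-3).
#' @param r_min minimum effect size (default 0.3).
#' @param dismissal_set confounder names allowed to dismiss a pattern;
#'   defaults to every column except the social covariates.
#' @return A `confounder_report`: p-value and effect matrices,
#'   per-pattern flags (`confounded` / `clear`) with the implicated
#'   confounders.
#' @export
flag_confounded_patterns <- function(pattern_scores, confounders,
                                     alpha = 1e-3, r_min = 0.3,
                                     dismissal_set = NULL) {
  social <- c("maternal_education", "paternal_social_status")
  dismissal_set <- dismissal_set %||% setdiff(names(confounders), social)
  assoc <- associate_confounders(pattern_scores, confounders)
  hits <- !is.na(assoc$p_values) & assoc$p_values < alpha &
    !is.na(assoc$effects) & assoc$effects >= r_min
  hits[, setdiff(colnames(hits), dismissal_set)] <- FALSE
  flags <- ifelse(rowSums(hits) > 0, "confounded", "clear")
  implicated <- apply(hits, 1L, function(h) colnames(hits)[h],
                      simplify = FALSE)
  structure(list(p_values = assoc$p_values, effects = assoc$effects,
                 flags = flags, implicated = implicated,
                 alpha = alpha, r_min = r_min,
                 dismissal_set = dismissal_set),
            class = "confounder_report")
}

#' @export
print.confounder_report <- function(x, ...) {
  n_conf <- sum(x$flags == "confounded")
  cat(sprintf("confounder_report: %d/%d patterns flagged (p < %g and effect >= %g)\n",
              n_conf, length(x$flags), x$alpha, x$r_min))
  if (n_conf) {
    for (i in which(x$flags == "confounded")) {
      cat(sprintf("  %s: %s\n", names(x$flags)[i] %||% i,
                  paste(x$implicated[[i]], collapse = ", ")))
    }
  }
  invisible(x)
}

#' Write a confounder report (heatmap TSV + JSON flags)
#'
#' @param report a `confounder_report`.
#' @param tsv_path path for the component-by-confounder p-value TSV.
#' @param json_path path for the JSON flag report.
#' @return `json_path`, invisibly.
#' @export
write_confounder_report <- function(report, tsv_path, json_path) {
  pv <- data.frame(component = rownames(report$p_values),
                   report$p_values, check.names = FALSE)
  utils::write.table(pv, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_json_file(list(flags = as.list(report$flags),
                       implicated = report$implicated,
                       alpha = report$alpha, r_min = report$r_min,
                       dismissal_set = report$dismissal_set),
                  json_path)
}
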