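# Factor analysis of mixed data (FAMD): the PCA/MCA hybrid used to turn
# the eight mixed-type risk variables into continuous risk-profile
# dimensions. Conventions follow the classical FAMD formulation:
# population (1/n) variances throughout, continuous columns
# standardized, each categorical level coded as indicator / sqrt(level
# frequency) and centered. On purely continuous input this reduces
# exactly to standardized PCA; on purely categorical input, to multiple
# correspondence analysis.

# Build (or apply) the FAMD coding. `map` is NULL to learn the coding
# from the data, or a frozen map to re-apply training centers, scales
# and level frequencies to new data. Categorical blocks may be fuzzy
# (numeric membership matrices), which the imputation uses.
famd_code <- function(blocks, kinds, map = NULL) {
  learn <- is.null(map)
  if (learn) map <- list()
  out <- list()
  for (v in names(blocks)) {
    b <- blocks[[v]]
    if (kinds[[v]] == "continuous") {
      x <- b[, 1L]
      if (learn) {
        ctr <- mean(x)
        scl <- sqrt(mean((x - ctr)^2))
        if (scl == 0) {
          stop_methrisk(paste0("constant continuous variable: ", v),
                        "methrisk_degenerate_variable")
        }
        map[[v]] <- list(kind = "continuous", center = ctr, scale = scl)
      }
      z <- (x - map[[v]]$center) / map[[v]]$scale
      out[[v]] <- matrix(z, ncol = 1L, dimnames = list(NULL, v))
    } else {
      if (learn) {
        freq <- colMeans(b)
        if (sum(freq > 0) < 2L) {
          stop_methrisk(paste0("single-level categorical variable: ", v),
                        "methrisk_degenerate_variable")
        }
        keep <- freq > 0
        map[[v]] <- list(kind = "categorical", levels = colnames(b)[keep],
                         freq = freq[keep])
      }
      lv <- map[[v]]$levels
      z <- sweep(b[, lv, drop = FALSE], 2L, sqrt(map[[v]]$freq), "/")
      z <- sweep(z, 2L, sqrt(map[[v]]$freq), "-")
      colnames(z) <- paste(v, lv, sep = ".")
      out[[v]] <- z
    }
  }
  Z <- do.call(cbind, out)
  column_of <- rep(names(blocks), vapply(out, ncol, 0L))
  list(Z = Z, map = map, column_of = column_of)
}

# Turn a cohort table's columns into raw blocks (continuous column or
# 0/1 indicator matrix over the declared levels).
famd_blocks <- function(table, variables, frozen_levels = NULL) {
  vt <- variable_types(table)
  blocks <- list()
  kinds <- list()
  for (v in variables) {
    kinds[[v]] <- vt[[v]]
    if (vt[[v]] == "continuous") {
      blocks[[v]] <- matrix(table[[v]], ncol = 1L)
    } else {
      x <- table[[v]]
      lv <- if (!is.null(frozen_levels) && !is.null(frozen_levels[[v]])) {
        frozen_levels[[v]]
      } else levels(x)
      unseen <- setdiff(unique(as.character(x[!is.na(x)])), lv)
      if (length(unseen)) {
        stop_methrisk(paste0("unseen level(s) in variable '", v, "': ",
                             paste(unseen, collapse = ", ")),
                      "methrisk_unseen_level")
      }
      ind <- matrix(0, nrow(table), length(lv), dimnames = list(NULL, lv))
      ok <- !is.na(x)
      ind[cbind(which(ok), match(as.character(x[ok]), lv))] <- 1
      ind[!ok, ] <- NA
      blocks[[v]] <- ind
    }
  }
  list(blocks = blocks, kinds = kinds)
}

#' Encode a mixed-type table in FAMD coordinates
#'
#' Continuous columns are standardized to mean 0, population SD 1; each
#' categorical level becomes an indicator divided by the square root of
#' its relative frequency and then column-centered (MCA scaling). The
#' total inertia of the coded matrix is the number of continuous
#' variables plus (total levels - number of categorical variables).
#'
#' @param table a [cohort_table()] with no missing values in
#'   `variables` (impute first, e.g. with [impute_famd()]).
#' @param variables variables to encode (default: all).
#' @param map optional frozen coding map from a previous encode, to
#'   apply training centers/scales/frequencies to new data.
#' @return List with `Z` (coded matrix), `map` (coding map),
#'   `column_of` (variable owning each coded column).
#' @export
encode_mixed <- function(table, variables = NULL, map = NULL) {
  vt <- variable_types(table)
  variables <- variables %||% names(vt)
  if (anyNA(as.data.frame(table)[, variables, drop = FALSE])) {
    stop_methrisk("missing values present: impute before encoding",
                  "methrisk_missing_values")
  }
  frozen_levels <- if (!is.null(map)) {
    lapply(map, function(m) m$levels)
  } else NULL
  bl <- famd_blocks(table, variables, frozen_levels)
  famd_code(bl$blocks, bl$kinds, map = map)
}

# Core eigendecomposition of a coded matrix under the 1/n convention.
famd_core <- function(Z, n_keep = NULL) {
  n <- nrow(Z)
  sv <- svd(Z / sqrt(n))
  eig <- sv$d^2
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  n_keep <- min(n_keep %||% length(eig), length(eig))
  V <- sv$v[, seq_len(n_keep), drop = FALSE]
  # sign convention: largest-|loading| coded column positive
  for (j in seq_len(ncol(V))) {
    s <- sign(V[which.max(abs(V[, j])), j])
    if (s < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(Z)
  scores <- Z %*% V
  colnames(scores) <- colnames(V) <- paste0("dim", seq_len(n_keep))
  list(eigenvalues = eig, loadings = V, scores = scores, rank = rank)
}

#' Fit a risk-profile model by factor analysis of mixed data
#'
#' Eigendecomposition of the FAMD-coded matrix. Subject dimension
#' scores are principal coordinates (zero mean; per-dimension variance
#' equal to the eigenvalue under the 1/n convention), and each
#' dimension is oriented so its largest-|loading| coded column is
#' positive. The contribution of a variable to a dimension is the sum
#' over its coded columns of the squared loading, expressed as a
#' percentage of the dimension.
#'
#' @param table a complete [cohort_table()] (see [impute_famd()]).
#' @param variables variables entering the model (default: all).
#' @return A `risk_profile_model`: coding map, eigenvalues, loadings,
#'   variable-by-dimension contributions (percent), subject scores,
#'   numerical rank, total inertia.
#' @export
famd_fit <- function(table, variables = NULL) {
  vt <- variable_types(table)
  variables <- variables %||% names(vt)
  enc <- encode_mixed(table, variables)
  if (nrow(enc$Z) <= length(variables)) {
    stop_methrisk("need more subjects than variables",
                  "methrisk_invalid_input")
  }
  core <- famd_core(enc$Z)
  ctr_col <- 100 * core$loadings^2
  contrib <- rowsum(ctr_col, group = enc$column_of, reorder = FALSE)
  contrib <- contrib[match(variables, rownames(contrib)), , drop = FALSE]
  scores <- core$scores
  rownames(scores) <- as.character(table$subject_id)
  structure(list(
    variables = variables,
    coding_map = enc$map,
    column_of = enc$column_of,
    eigenvalues = core$eigenvalues,
    loadings = core$loadings,
    contributions = contrib,
    scores = scores,
    rank = core$rank,
    total_inertia = sum(core$eigenvalues),
    n = nrow(enc$Z)
  ), class = "risk_profile_model")
}

#' @export
print.risk_profile_model <- function(x, ...) {
  ve <- 100 * x$eigenvalues / x$total_inertia
  cat(sprintf("risk_profile_model: %d subjects, %d variables, rank %d\n",
              x$n, length(x$variables), x$rank))
  cat("  variance explained (%):",
      paste(sprintf("%.1f", utils::head(ve, 5L)), collapse = ", "),
      if (length(ve) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Select risk-profile dimensions
#'
#' @param model a `risk_profile_model`.
#' @param criterion `"top_k"` (default, k = 5), `"kaiser"` (eigenvalue
#'   above the mean eigenvalue) or `"elbow"` (argmax of the second
#'   difference of the scree).
#' @param k number of dimensions for `"top_k"`.
#' @return Integer vector of selected dimension indices (ordered).
#' @export
select_dimensions <- function(model, criterion = c("top_k", "kaiser", "elbow"),
                              k = 5L) {
  criterion <- match.arg(criterion)
  eig <- model$eigenvalues[seq_len(model$rank)]
  switch(criterion,
    top_k = {
      if (k > length(eig)) {
        stop_methrisk(sprintf("k = %d exceeds available dimensions (%d)",
                              k, length(eig)), "methrisk_invalid_input")
      }
      seq_len(k)
    },
    kaiser = which(eig > mean(model$eigenvalues)),
    elbow = {
      if (length(eig) < 3L) return(1L)
      d2 <- diff(diff(eig))  # second difference of the scree
      seq_len(which.max(d2))
    }
  )
}

#' Contribution threshold for representative variables
#'
#' Expected average contribution under uniformity: `100 / n_variables`
#' percent. Variables whose contribution to a dimension exceeds it are
#' considered the most representative of that dimension.
#'
#' @param model a `risk_profile_model`.
#' @return Percentage threshold.
#' @export
contribution_threshold <- function(model) {
  100 / length(model$variables)
}

#' Score new subjects on fitted risk-profile dimensions
#'
#' Applies the stored coding map (training centers, scales and level
#' frequencies) and loadings. Scoring the training table reproduces the
#' training scores exactly; missing values in the new table are first
#' completed with [impute_famd()].
#'
#' @param model a `risk_profile_model`.
#' @param new_table a [cohort_table()] with the model's variables.
#' @param dims dimension indices to return (default: all fitted).
#' @return Matrix of dimension scores, subjects x dims.
#' @export
score_subjects <- function(model, new_table, dims = NULL) {
  missing_vars <- setdiff(model$variables, names(variable_types(new_table)))
  if (length(missing_vars)) {
    stop_methrisk(paste0("new table lacks variables: ",
                         paste(missing_vars, collapse = ", ")),
                  "methrisk_invalid_input")
  }
  if (anyNA(as.data.frame(new_table)[, model$variables, drop = FALSE])) {
    new_table <- impute_famd(new_table, variables = model$variables)
  }
  enc <- encode_mixed(new_table, model$variables, map = model$coding_map)
  scores <- enc$Z %*% model$loadings
  rownames(scores) <- as.character(new_table$subject_id)
  dims <- dims %||% seq_len(ncol(scores))
  scores[, dims, drop = FALSE]
}

#' Impute missing mixed-type values by regularized iterative FAMD
#'
#' Missing cells are initialized with column means (continuous) or
#' observed level frequencies (categorical, as fuzzy memberships); the
#' coded matrix is then alternately fitted by a rank-`n_dims`
#' reconstruction (with eigenvalue shrinkage toward the mean of the
#' discarded eigenvalues when `shrinkage = "regularized"`) and refilled
#' at the missing cells, until the relative change of the imputed cells
#' falls below `tol` or `max_iter` is reached. Column scales and level
#' frequencies are frozen at initialization (fixed units for the
#' objective); column centers are re-estimated each iteration, so
#' exactly low-rank structure is recovered exactly. Categorical cells
#' are finally imputed to their highest-scoring level.
#'
#' @param table a [cohort_table()].
#' @param variables variables to complete (default: all).
#' @param n_dims rank of the reconstruction (default 5, the number of
#'   selected risk-profile dimensions).
#' @param shrinkage `"regularized"` (default) or `"none"`.
#' @param tol relative-change convergence tolerance.
#' @param max_iter iteration cap; non-convergence yields a warning, not
#'   a failure.
#' @return The completed cohort table, with an `impute_info` attribute
#'   (iterations, convergence flag, per-iteration observed-cell
#'   objective).
#' @export
impute_famd <- function(table, variables = NULL, n_dims = 5L,
                        shrinkage = c("regularized", "none"),
                        tol = 1e-6, max_iter = 200L) {
  shrinkage <- match.arg(shrinkage)
  vt <- variable_types(table)
  variables <- variables %||% names(vt)
  df <- as.data.frame(table)
  if (!anyNA(df[, variables, drop = FALSE])) {
    attr(table, "impute_info") <- list(iterations = 0L, converged = TRUE,
                                       objective = numeric(0))
    return(table)
  }
  for (v in variables) {
    if (all(is.na(df[[v]]))) {
      stop_methrisk(paste0("variable '", v, "' has no observed values"),
                    "methrisk_invalid_input")
    }
  }
  stopifnot(n_dims >= 1L)

  bl <- famd_blocks(table, variables)
  blocks <- bl$blocks
  obs <- lapply(blocks, function(b) !is.na(b[, 1L]))
  # initial fill with observed means / frequencies; scales and level
  # frequencies are then frozen so the objective keeps fixed units
  map <- list()
  for (v in variables) {
    b <- blocks[[v]]
    if (bl$kinds[[v]] == "continuous") {
      xo <- b[obs[[v]], 1L]
      scl <- sqrt(mean((xo - mean(xo))^2))
      if (scl == 0) {
        stop_methrisk(paste0("constant continuous variable: ", v),
                      "methrisk_degenerate_variable")
      }
      b[!obs[[v]], 1L] <- mean(xo)
      map[[v]] <- list(kind = "continuous", scale = scl)
    } else {
      freq <- colMeans(b[obs[[v]], , drop = FALSE])
      keep_lv <- freq > 0
      if (sum(keep_lv) < 2L) {
        stop_methrisk(paste0("single-level categorical variable: ", v),
                      "methrisk_degenerate_variable")
      }
      b[!obs[[v]], ] <- matrix(rep(freq, each = sum(!obs[[v]])),
                               ncol = ncol(b))
      b <- b[, keep_lv, drop = FALSE]
      map[[v]] <- list(kind = "categorical",
                       levels = colnames(blocks[[v]])[keep_lv],
                       freq = freq[keep_lv])
    }
    blocks[[v]] <- b
  }
  # scaled-but-uncentered matrix: x / s, indicator / sqrt(freq)
  Zr <- do.call(cbind, lapply(variables, function(v) {
    if (map[[v]]$kind == "continuous") {
      blocks[[v]] / map[[v]]$scale
    } else {
      sweep(blocks[[v]], 2L, sqrt(map[[v]]$freq), "/")
    }
  }))
  col_var <- rep(variables, vapply(blocks, ncol, 0L))
  miss_mask <- matrix(FALSE, nrow(Zr), ncol(Zr))
  for (j in seq_len(ncol(Zr))) miss_mask[, j] <- !obs[[col_var[j]]]

  n <- nrow(Zr)
  objective <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    mu <- colMeans(Zr)
    Zc <- sweep(Zr, 2L, mu)
    sv <- svd(Zc / sqrt(n))
    d2 <- sv$d^2
    keep <- seq_len(min(n_dims, length(sv$d)))
    sigma2 <- if (shrinkage == "regularized" && length(sv$d) > n_dims) {
      mean(d2[-keep])
    } else 0
    d_shrunk <- pmax(d2[keep] - sigma2, 0) / pmax(sv$d[keep], 1e-300)
    fit <- sv$u[, keep, drop = FALSE] %*%
      (d_shrunk * t(sv$v[, keep, drop = FALSE])) * sqrt(n)
    objective <- c(objective, sum((Zc[!miss_mask] - fit[!miss_mask])^2))
    old <- Zr[miss_mask]
    Zr[miss_mask] <- sweep(fit, 2L, mu, "+")[miss_mask]
    delta <- sqrt(sum((Zr[miss_mask] - old)^2) / max(sum(old^2), 1e-300))
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("impute_famd did not converge in %d iterations", max_iter))
  }

  # decode imputed cells back to the original variable scales
  for (v in variables) {
    idx <- which(col_var == v)
    mi <- !obs[[v]]
    if (!any(mi)) next
    if (bl$kinds[[v]] == "continuous") {
      df[[v]][mi] <- Zr[mi, idx] * map[[v]]$scale
    } else {
      ind <- sweep(Zr[mi, idx, drop = FALSE], 2L,
                   sqrt(map[[v]]$freq), "*")
      pick <- map[[v]]$levels[max.col(ind, ties.method = "first")]
      df[[v]][mi] <- factor(pick, levels = levels(df[[v]]))
    }
  }
  out <- cohort_table(df, vt)
  attr(out, "impute_info") <- list(iterations = it, converged = converged,
                                   objective = objective)
  out
}

#' Serialize / load a risk-profile model as JSON
#'
#' @param model a `risk_profile_model`.
#' @param path JSON file path.
#' @return `path` invisibly (writer); a `risk_profile_model` (reader).
#' @export
write_risk_profile_model <- function(model, path) {
  payload <- list(
    variables = model$variables,
    coding_map = model$coding_map,
    column_of = model$column_of,
    eigenvalues = model$eigenvalues,
    loadings = list(values = as.vector(model$loadings),
                    rownames = rownames(model$loadings),
                    ncol = ncol(model$loadings)),
    contributions = list(values = as.vector(model$contributions),
                         rownames = rownames(model$contributions),
                         ncol = ncol(model$contributions)),
    rank = model$rank,
    total_inertia = model$total_inertia,
    n = model$n
  )
  write_json_file(payload, path)
}

#' @rdname write_risk_profile_model
#' @export
read_risk_profile_model <- function(path) {
  p <- read_json_file(path)
  remat <- function(m) {
    out <- matrix(m$values, ncol = m$ncol)
    rownames(out) <- m$rownames
    colnames(out) <- paste0("dim", seq_len(m$ncol))
    out
  }
  cm <- lapply(p$coding_map, function(m) {
    if (m$kind == "categorical") m$freq <- stats::setNames(unlist(m$freq), m$levels)
    m
  })
  structure(list(variables = p$variables, coding_map = cm,
                 column_of = p$column_of, eigenvalues = p$eigenvalues,
                 loadings = remat(p$loadings),
                 contributions = remat(p$contributions),
                 scores = NULL, rank = p$rank,
                 total_inertia = p$total_inertia, n = p$n),
            class = "risk_profile_model")
}
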