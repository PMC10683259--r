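# Sparse partial least squares: extracts genome-wide methylation
# patterns ("components") whose subject scores covary maximally with
# the risk-profile dimension scores, keeping a fixed number of CpGs per
# component. NIPALS-style extraction in regression mode: per component
# the X-weight vector is proportional to the cross-covariance of the
# deflated X with the current Y direction, hard-thresholded so exactly
# `keep_x` CpGs retain nonzero weight; X is deflated by regression on
# the component scores (Y is left intact).

# Threshold z to its keep largest-|z| entries (soft-thresholding at the
# (keep+1)-th magnitude), deterministic tie-break by column id order.
sparse_threshold <- function(z, keep, ids) {
  p <- length(z)
  if (keep >= p) return(z)
  ord <- order(-abs(z), ids)
  kept <- ord[seq_len(keep)]
  lambda <- max(abs(z[ord[(keep + 1L):p]]))
  w <- numeric(p)
  w[kept] <- sign(z[kept]) * (abs(z[kept]) - lambda)
  # exact ties at the threshold would zero a kept entry; keep it at a
  # negligible magnitude so the sparsity contract (exactly keep_x
  # nonzero) holds
  dead <- kept[w[kept] == 0]
  if (length(dead)) w[dead] <- sign(z[dead]) * max(abs(z)) * 1e-12
  w
}

#' Fit sparse-PLS methylation patterns
#'
#' @param X a [methylation_matrix()] or numeric matrix (subjects x
#'   CpGs, rownames = subject ids).
#' @param Y matrix of risk-profile dimension scores (subjects x
#'   dimensions), same subjects as `X`.
#' @param n_components number of patterns to extract (default 20).
#' @param keep_x number of CpGs retained per component (scalar or
#'   per-component vector; default 250).
#' @param scale_x scale X columns to unit variance (default `FALSE`:
#'   beta values share a scale, so columns are centered only).
#' @param max_iter,tol inner NIPALS iteration controls.
#' @return A `pattern_model`: sparse X-weights, Y-weights, X loadings
#'   and the deflation cross-products needed for projection, training
#'   component scores, centers/scales, CpG coordinates if available.
#' @export
spls_fit <- function(X, Y, n_components = 20L, keep_x = 250L,
                     scale_x = FALSE, max_iter = 500L, tol = 1e-9) {
  coords <- NULL
  if (inherits(X, "methylation_matrix")) {
    coords <- X$coords
    X <- X$beta
  }
  Y <- as.matrix(Y)
  if (is.null(rownames(X)) || is.null(rownames(Y)) ||
      !identical(rownames(X), rownames(Y))) {
    stop_methrisk("X and Y must cover the same subjects in the same order",
                  "methrisk_invalid_input")
  }
  n <- nrow(X)
  p <- ncol(X)
  q <- ncol(Y)
  n_components <- as.integer(n_components)
  keep_x <- rep_len(as.integer(keep_x), n_components)
  if (any(keep_x < 1L)) {
    stop_methrisk("keep_x must be >= 1", "methrisk_invalid_input")
  }
  if (any(keep_x > p)) {
    stop_methrisk("keep_x cannot exceed the number of CpGs",
                  "methrisk_invalid_input")
  }
  if (n_components > n - 1L) {
    stop_methrisk("n_components must be <= n_subjects - 1",
                  "methrisk_invalid_input")
  }
  y_center <- colMeans(Y)
  y_scale <- apply(Y, 2L, stats::sd)
  if (any(y_scale == 0)) {
    stop_methrisk("constant Y column: zero cross-covariance",
                  "methrisk_degenerate_response")
  }
  Ys <- scale(Y, center = y_center, scale = y_scale)
  x_center <- colMeans(X)
  x_scale <- if (scale_x) apply(X, 2L, stats::sd) else rep(1, p)
  if (any(x_scale == 0)) {
    stop_methrisk("constant X column cannot be scaled",
                  "methrisk_invalid_input")
  }
  E <- scale(X, center = x_center, scale = if (scale_x) x_scale else FALSE)

  cpg_ids <- colnames(X)
  W <- matrix(0, p, n_components, dimnames = list(cpg_ids, NULL))
  V <- matrix(0, q, n_components,
              dimnames = list(colnames(Y) %||% paste0("y", seq_len(q)), NULL))
  P <- matrix(0, p, n_components, dimnames = list(cpg_ids, NULL))
  T <- matrix(0, n, n_components, dimnames = list(rownames(X), NULL))

  for (h in seq_len(n_components)) {
    M <- crossprod(E, Ys)  # p x q cross-covariance (up to 1/n)
    if (max(abs(M)) == 0) {
      stop_methrisk(sprintf("zero cross-covariance at component %d", h),
                    "methrisk_degenerate_response")
    }
    v <- svd(M, nu = 0L, nv = 1L)$v[, 1L]
    w <- numeric(p)
    for (iter in seq_len(max_iter)) {
      z <- drop(M %*% v)
      w_new <- sparse_threshold(z, keep_x[h], cpg_ids)
      w_new <- w_new / sqrt(sum(w_new^2))
      v_new <- drop(crossprod(M, w_new))
      v_new <- v_new / sqrt(sum(v_new^2))
      if (sum((w_new - w)^2) < tol^2) {
        w <- w_new
        v <- v_new
        break
      }
      w <- w_new
      v <- v_new
    }
    # sign convention: largest-|weight| CpG positive
    imax <- which.max(abs(w))
    if (w[imax] < 0) {
      w <- -w
      v <- -v
    }
    t_h <- drop(E %*% w)
    p_h <- drop(crossprod(E, t_h)) / sum(t_h^2)
    E <- E - tcrossprod(t_h, p_h)
    W[, h] <- w
    V[, h] <- v
    P[, h] <- p_h
    T[, h] <- t_h
  }
  comp_names <- paste0("comp", seq_len(n_components))
  colnames(W) <- colnames(V) <- colnames(P) <- colnames(T) <- comp_names
  # cross-products of loadings with later weights: all a projection needs
  # besides the sparse weight support
  C <- crossprod(P, W)
  support <- cpg_ids[rowSums(W != 0) > 0]
  structure(list(
    weights = W, y_weights = V, x_loadings = P, scores = T,
    deflation_cross = C, support = support,
    x_center = x_center, x_scale = x_scale, scale_x = scale_x,
    y_center = y_center, y_scale = y_scale,
    keep_x = keep_x, n_components = n_components,
    coords = coords, deflation = "regression"
  ), class = "pattern_model")
}

#' @export
print.pattern_model <- function(x, ...) {
  cat(sprintf("pattern_model: %d components, keep_x = %s, %d CpGs in support\n",
              x$n_components,
              paste(unique(x$keep_x), collapse = "/"), length(x$support)))
  invisible(x)
}

#' Project a fitted pattern model onto new methylation data
#'
#' Centers the new beta matrix with the training centers and applies
#' the stored sparse weights with the training deflation recursion
#' (`t_h = X w_h - sum_{g<h} t_g (p_g' w_h)`), so only the CpGs in the
#' sparse support are required. Projecting the training matrix
#' reproduces the training scores.
#'
#' @param model a `pattern_model`.
#' @param X_new a [methylation_matrix()] or matrix containing every
#'   support CpG (missing CpGs raise an error listing them).
#' @return Matrix of component scores, subjects x components. Subjects
#'   with all-missing support values are dropped with a warning.
#' @export
project_patterns <- function(model, X_new) {
  if (inherits(X_new, "methylation_matrix")) X_new <- X_new$beta
  missing_cpgs <- setdiff(model$support, colnames(X_new))
  if (length(missing_cpgs)) {
    stop_methrisk(paste0("new data lacks support CpGs: ",
                         paste(utils::head(missing_cpgs, 10L), collapse = ", "),
                         if (length(missing_cpgs) > 10L) " ..."),
                  "methrisk_cpg_mismatch")
  }
  Xs <- X_new[, model$support, drop = FALSE]
  all_missing <- rowSums(!is.na(Xs)) == 0L
  if (any(all_missing)) {
    warning(sprintf("excluding %d all-missing subject(s)", sum(all_missing)))
    Xs <- Xs[!all_missing, , drop = FALSE]
  }
  E <- scale(Xs, center = model$x_center[model$support],
             scale = if (model$scale_x) model$x_scale[model$support] else FALSE)
  H <- model$n_components
  T_new <- matrix(0, nrow(E), H,
                  dimnames = list(rownames(E), colnames(model$weights)))
  Wsup <- model$weights[model$support, , drop = FALSE]
  for (h in seq_len(H)) {
    t_h <- drop(E %*% Wsup[, h])
    if (h > 1L) {
      t_h <- t_h - drop(T_new[, seq_len(h - 1L), drop = FALSE] %*%
                          model$deflation_cross[seq_len(h - 1L), h])
    }
    T_new[, h] <- t_h
  }
  T_new
}

#' Representative CpGs of a pattern component
#'
#' Nonzero-weight CpGs of a component, ranked by absolute weight
#' (descending, deterministic tie-break by CpG id), with coordinates
#' when the model was fitted from a [methylation_matrix()].
#'
#' @param model a `pattern_model`.
#' @param component component index.
#' @param top optional cap on the number of CpGs returned.
#' @return data.frame with `cpg`, `weight`, `rank` (+ coordinates).
#' @export
representative_cpgs <- function(model, component, top = NULL) {
  if (!is_count(component) || component < 1L ||
      component > model$n_components) {
    stop_methrisk("component index out of range", "methrisk_invalid_input")
  }
  w <- model$weights[, component]
  nz <- which(w != 0)
  ord <- nz[order(-abs(w[nz]), names(w)[nz])]
  out <- data.frame(cpg = names(w)[ord], weight = unname(w[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  if (!is.null(model$coords)) {
    out <- cbind(out, model$coords[match(out$cpg, model$coords$cpg),
                                   c("chrom", "start", "end")])
    rownames(out) <- NULL
  }
  if (!is.null(top)) out <- out[seq_len(min(top, nrow(out))), , drop = FALSE]
  out
}

#' Absolute correlations between component and dimension scores
#'
#' @param component_scores subjects x components matrix.
#' @param dimension_scores subjects x dimensions matrix (same
#'   subjects).
#' @return Matrix of |Pearson r|, components x dimensions;
#'   zero-variance columns give `NA` entries and a warning.
#' @export
pattern_dimension_correlation <- function(component_scores,
                                          dimension_scores) {
  component_scores <- as.matrix(component_scores)
  dimension_scores <- as.matrix(dimension_scores)
  if (nrow(component_scores) != nrow(dimension_scores)) {
    stop_methrisk("score matrices must cover the same subjects",
                  "methrisk_invalid_input")
  }
  sd_c <- apply(component_scores, 2L, stats::sd)
  sd_d <- apply(dimension_scores, 2L, stats::sd)
  if (any(sd_c == 0) || any(sd_d == 0)) {
    warning("zero-variance column(s): correlation undefined, set to NA")
  }
  r <- suppressWarnings(abs(stats::cor(component_scores, dimension_scores)))
  r[sd_c == 0, ] <- NA_real_
  r[, sd_d == 0] <- NA_real_
  r
}

#' Export nonzero pattern weights as a TSV (BED-compatible columns)
#'
#' @param model a `pattern_model` fitted from a [methylation_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pattern_weights <- function(model, path) {
  rows <- do.call(rbind, lapply(seq_len(model$n_components), function(h) {
    df <- representative_cpgs(model, h)
    df$component <- h
    df
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize / load a pattern model as JSON
#'
#' Weights are stored sparsely (support CpGs only); centers are kept
#' for the full CpG set so refitting-related checks can reuse them.
#'
#' @param model a `pattern_model`.
#' @param path JSON file path.
#' @return `path` invisibly (writer); a `pattern_model` (reader).
#' @export
write_pattern_model <- function(model, path) {
  nz <- lapply(seq_len(model$n_components), function(h) {
    w <- model$weights[, h]
    idx <- which(w != 0)
    list(cpg = names(w)[idx], weight = unname(w[idx]))
  })
  payload <- list(
    n_components = model$n_components,
    keep_x = model$keep_x,
    cpg_ids = rownames(model$weights),
    nonzero_weights = nz,
    y_weights = list(values = as.vector(model$y_weights),
                     rownames = rownames(model$y_weights)),
    x_loadings_support = list(values = as.vector(
      model$x_loadings[model$support, , drop = FALSE]),
      rownames = model$support),
    deflation_cross = as.vector(model$deflation_cross),
    support = model$support,
    x_center_support = as.list(stats::setNames(
      model$x_center[model$support], model$support)),
    scale_x = model$scale_x,
    y_center = as.list(model$y_center),
    y_scale = as.list(model$y_scale),
    deflation = model$deflation
  )
  write_json_file(payload, path)
}

#' @rdname write_pattern_model
#' @export
read_pattern_model <- function(path) {
  p <- read_json_file(path)
  H <- p$n_components
  cpgs <- p$cpg_ids
  W <- matrix(0, length(cpgs), H,
              dimnames = list(cpgs, paste0("comp", seq_len(H))))
  nz <- p$nonzero_weights
  for (h in seq_len(H)) {
    # jsonlite may simplify the per-component records to a data.frame
    # of list-columns
    cpg_h <- if (is.data.frame(nz)) nz$cpg[[h]] else nz[[h]]$cpg
    w_h <- if (is.data.frame(nz)) nz$weight[[h]] else nz[[h]]$weight
    W[unlist(cpg_h), h] <- unlist(w_h)
  }
  V <- matrix(p$y_weights$values, ncol = H,
              dimnames = list(p$y_weights$rownames,
                              paste0("comp", seq_len(H))))
  Psup <- matrix(p$x_loadings_support$values, ncol = H,
                 dimnames = list(p$x_loadings_support$rownames,
                                 paste0("comp", seq_len(H))))
  P <- matrix(0, length(cpgs), H,
              dimnames = list(cpgs, paste0("comp", seq_len(H))))
  P[rownames(Psup), ] <- Psup
  C <- matrix(p$deflation_cross, H, H,
              dimnames = list(paste0("comp", seq_len(H)),
                              paste0("comp", seq_len(H))))
  x_center <- stats::setNames(rep(NA_real_, length(cpgs)), cpgs)
  x_center[names(p$x_center_support)] <- unlist(p$x_center_support)
  structure(list(
    weights = W, y_weights = V, x_loadings = P, scores = NULL,
    deflation_cross = C, support = p$support,
    x_center = x_center, x_scale = rep(1, length(cpgs)),
    scale_x = p$scale_x,
    y_center = unlist(p$y_center), y_scale = unlist(p$y_scale),
    keep_x = p$keep_x, n_components = H, coords = NULL,
    deflation = p$deflation
  ), class = "pattern_model")
}
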