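#' Pearson correlation matrix of a questionnaire panel
#'
#' Computes the item correlation matrix on complete cases (listwise deletion
#' of respondents with any missing response), the classical starting point for
#' exploratory factor analysis.
#'
#' @param panel Numeric matrix, respondents x items (e.g. a
#'   [gen_likert_panel()] result); `NA` marks a missing response.
#' @return An object of class `correlation_matrix` with elements `values`
#'   (items x items symmetric matrix with unit diagonal) and `n_used` (number
#'   of complete-case respondents).
#' @export
compute_correlation <- function(panel) {
  X <- unclass(panel)
  if (!is.matrix(X) || !is.numeric(X)) {
    nim_stop("nimcdm_shape_error", "`panel` must be a numeric matrix")
  }
  complete <- stats::complete.cases(X)
  X <- X[complete, , drop = FALSE]
  if (nrow(X) < 3L) {
    nim_stop("nimcdm_insufficient_data",
             sprintf("only %d complete-case respondents; need at least 3", nrow(X)))
  }
  v <- apply(X, 2L, stats::var)
  if (any(v == 0)) {
    bad <- colnames(X)[v == 0] %||% which(v == 0)
    nim_stop("nimcdm_degenerate_item",
             sprintf("zero-variance item(s) among complete cases: %s",
                     paste(bad, collapse = ", ")))
  }
  R <- stats::cor(X)
  diag(R) <- 1
  structure(list(values = R, n_used = nrow(X)), class = "correlation_matrix")
}

#' Principal-component extraction with varimax rotation
#'
#' Extracts principal components of a correlation matrix, retains those with
#' eigenvalue strictly above `eigen_threshold` (Kaiser criterion), forms
#' loadings `a_ik = sqrt(lambda_k) * beta_ik` from eigenvalues and
#' eigenvectors, and, when two or more components are retained, applies
#' varimax rotation with Kaiser row normalization. Each loading column is
#' sign-flipped so its largest-magnitude entry is positive, which makes the
#' result deterministic across eigen-solvers.
#'
#' @param R A [compute_correlation()] result or a plain correlation matrix.
#' @param eigen_threshold Retain components with eigenvalue strictly greater
#'   than this (default 1, the Kaiser criterion).
#' @return An object of class `loading_matrix`: `loadings` (items x retained
#'   factors, rotated), `unrotated` (same shape, pre-rotation), `eigenvalues`
#'   (all item eigenvalues, descending), `retained` (indices kept), and
#'   `rotated` (logical).
#' @export
extract_and_rotate <- function(R, eigen_threshold = 1) {
  Rm <- if (inherits(R, "correlation_matrix")) R$values else R
  check_square_numeric(Rm, "R")
  if (max(abs(Rm - t(Rm))) > 1e-8 || any(abs(diag(Rm) - 1) > 1e-8)) {
    nim_stop("nimcdm_invalid_spec", "`R` must be symmetric with unit diagonal")
  }
  eg <- eigen((Rm + t(Rm)) / 2, symmetric = TRUE)
  lambda <- eg$values
  keep <- which(lambda > eigen_threshold)
  if (length(keep) == 0L) {
    nim_stop("nimcdm_no_factor",
             sprintf("no eigenvalue exceeds the threshold %g", eigen_threshold))
  }
  A <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(lambda[keep]), nrow = length(keep))
  rownames(A) <- rownames(Rm) %||% paste0("I", seq_len(nrow(Rm)))
  rotated <- FALSE
  loadings <- A
  if (length(keep) >= 2L) {
    vr <- stats::varimax(A, normalize = TRUE, eps = 1e-8)
    loadings <- A %*% vr$rotmat
    rotated <- TRUE
  }
  loadings <- flip_loading_signs(loadings)
  colnames(loadings) <- colnames(A) <- paste0("F", seq_along(keep))
  structure(
    list(loadings = loadings,
         unrotated = flip_loading_signs(A),
         eigenvalues = lambda,
         retained = keep,
         rotated = rotated),
    class = "loading_matrix"
  )
}

# Flip each column so its maximum-magnitude entry is positive.
flip_loading_signs <- function(A) {
  for (k in seq_len(ncol(A))) {
    j <- which.max(abs(A[, k]))
    if (A[j, k] < 0) A[, k] <- -A[, k]
  }
  A
}

#' Assign items to dimensions by their dominant rotated loading
#'
#' Each item goes to the factor holding its maximum absolute loading; items
#' whose maximum absolute loading falls below `cutoff` are deleted (and
#' reported in the result). Factors that end up with at least one item become
#' the dimensions of the evaluation framework.
#'
#' @param L A [extract_and_rotate()] result, or a plain items x factors
#'   loading matrix.
#' @param cutoff Minimum absolute loading for an item to be retained
#'   (strict: an item at exactly the cutoff is kept; below it is deleted).
#' @param labels Optional character vector naming the dimensions, one per
#'   retained factor (in factor order); defaults to `D1`, `D2`, ...
#' @return An object of class `evaluation_framework`: `dimensions` (named
#'   list, dimension -> ordered criterion ids), `assignment` (data frame with
#'   item, dimension, loading), and `deleted` (items below the cutoff).
#' @export
assign_items <- function(L, cutoff = 0.6, labels = NULL) {
  A <- if (inherits(L, "loading_matrix")) L$loadings else L
  if (!is.matrix(A) || !is.numeric(A)) {
    nim_stop("nimcdm_shape_error", "`L` must be a loading matrix")
  }
  items <- rownames(A) %||% paste0("I", seq_len(nrow(A)))
  best <- apply(abs(A), 1L, which.max)
  best_loading <- A[cbind(seq_len(nrow(A)), best)]
  keep <- abs(best_loading) >= cutoff
  if (!any(keep)) {
    nim_stop("nimcdm_empty_framework",
             sprintf("all items fall below the loading cutoff %g", cutoff))
  }
  used_factors <- sort(unique(best[keep]))
  if (is.null(labels)) {
    labels <- paste0("D", seq_along(used_factors))
  } else if (length(labels) < length(used_factors)) {
    nim_stop("nimcdm_invalid_spec", "not enough dimension labels supplied")
  } else {
    labels <- labels[seq_along(used_factors)]
  }
  dim_of <- stats::setNames(labels, used_factors)
  assignment <- data.frame(
    item = items[keep],
    dimension = unname(dim_of[as.character(best[keep])]),
    loading = best_loading[keep],
    stringsAsFactors = FALSE
  )
  dimensions <- lapply(labels, function(d) assignment$item[assignment$dimension == d])
  names(dimensions) <- labels
  structure(
    list(dimensions = dimensions,
         assignment = assignment,
         deleted = items[!keep]),
    class = "evaluation_framework"
  )
}

# Cronbach's alpha: (k/(k-1)) * (1 - sum(item variances) / variance of sums),
# on complete cases of the given items.
cronbach_alpha <- function(panel, items) {
  X <- unclass(panel)[, items, drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  k <- ncol(X)
  if (k < 2L || nrow(X) < 3L) return(NA_real_)
  total_var <- stats::var(rowSums(X))
  if (total_var == 0) return(NA_real_)
  (k / (k - 1)) * (1 - sum(apply(X, 2L, stats::var)) / total_var)
}

# Kaiser-Meyer-Olkin measure of sampling adequacy from the anti-image
# (partial) correlations, overall value only.
kmo_overall <- function(R) {
  Rinv <- tryCatch(solve(R), error = function(e) {
    nim_stop("nimcdm_degenerate_matrix",
             "correlation matrix is singular; KMO undefined")
  })
  d <- 1 / sqrt(diag(Rinv))
  P <- -Rinv * outer(d, d)  # partial correlations, off-diagonal
  diag(P) <- 0
  R0 <- R
  diag(R0) <- 0
  sum(R0^2) / (sum(R0^2) + sum(P^2))
}

#' Reliability statistics for an assembled evaluation framework
#'
#' Reports Cronbach's alpha overall (all retained items) and per dimension,
#' the overall Kaiser-Meyer-Olkin sampling adequacy, and the cumulative
#' percentage of variance explained by the retained components. Alpha is
#' undefined (`NA`, with a note) for a dimension holding fewer than two
#' items.
#'
#' @param panel The Likert panel the framework was built from.
#' @param framework An [assign_items()] result whose items all occur in
#'   `panel`.
#' @param L The [extract_and_rotate()] result (supplies the eigenvalues).
#' @return An object of class `reliability_report` with `cronbach_alpha`
#'   (named vector: overall then one per dimension), `kmo`,
#'   `cumulative_variance_pct`, and `notes`.
#' @export
reliability_stats <- function(panel, framework, L) {
  stopifnot(inherits(framework, "evaluation_framework"),
            inherits(L, "loading_matrix"))
  items <- framework$assignment$item
  if (!all(items %in% colnames(panel))) {
    nim_stop("nimcdm_schema_error", "framework items missing from the panel")
  }
  alphas <- c(overall = cronbach_alpha(panel, items))
  notes <- character(0)
  for (d in names(framework$dimensions)) {
    di <- framework$dimensions[[d]]
    if (length(di) < 2L) {
      alphas[d] <- NA_real_
      notes <- c(notes, sprintf("alpha undefined for dimension %s (<2 items)", d))
    } else {
      alphas[d] <- cronbach_alpha(panel, di)
    }
  }
  kmo <- kmo_overall(compute_correlation(panel)$values)
  n_items <- nrow(L$loadings)
  cum_var <- 100 * sum(L$eigenvalues[L$retained]) / length(L$eigenvalues)
  structure(
    list(cronbach_alpha = alphas,
         kmo = kmo,
         cumulative_variance_pct = cum_var,
         n_items = n_items,
         notes = notes),
    class = "reliability_report"
  )
}
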