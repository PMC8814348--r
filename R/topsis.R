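#' Vector-normalize a decision matrix
#'
#' Divides every criterion column by its Euclidean norm over the
#' alternatives, so each normalized column has unit sum of squares.
#'
#' @param X Numeric matrix, alternatives x criteria, with at least two
#'   alternatives and no all-zero criterion column.
#' @return The normalized matrix, same shape and dimnames.
#' @export
normalize_decision <- function(X) {
  if (!is.matrix(X) || !is.numeric(X) || nrow(X) < 2L) {
    nim_stop("nimcdm_shape_error",
             "`X` must be a numeric matrix with at least 2 alternatives")
  }
  if (any(!is.finite(X))) {
    nim_stop("nimcdm_invalid_spec", "decision matrix entries must be finite")
  }
  norms <- sqrt(colSums(X^2))
  if (any(norms == 0)) {
    bad <- colnames(X)[norms == 0] %||% which(norms == 0)
    nim_stop("nimcdm_degenerate_criterion",
             sprintf("all-zero criterion column(s): %s", paste(bad, collapse = ", ")))
  }
  sweep(X, 2L, norms, "/")
}

#' Weighted normalized matrix and ideal solutions
#'
#' Multiplies each normalized column by its criterion weight and finds the
#' positive ideal (per-criterion maximum over alternatives for benefit
#' criteria, minimum for cost criteria) and the negative ideal (the
#' reverse).
#'
#' @param N Normalized decision matrix from [normalize_decision()].
#' @param w Non-negative criterion weights summing to 1 (within 1e-8). A
#'   named vector is matched to `colnames(N)`.
#' @param directions Character vector, `"benefit"` or `"cost"` per
#'   criterion; default all benefit.
#' @return A list with `weighted` (v_ij), `positive_ideal` and
#'   `negative_ideal` (named vectors).
#' @export
weighted_ideals <- function(N, w, directions = NULL) {
  if (!is.matrix(N) || !is.numeric(N)) {
    nim_stop("nimcdm_shape_error", "`N` must be a numeric matrix")
  }
  if (length(w) != ncol(N)) {
    nim_stop("nimcdm_shape_error", "one weight per criterion is required")
  }
  if (!is.null(names(w)) && !is.null(colnames(N))) {
    if (!setequal(names(w), colnames(N))) {
      nim_stop("nimcdm_shape_error", "weight names do not match criterion names")
    }
    w <- w[colnames(N)]
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    nim_stop("nimcdm_invalid_spec",
             "weights must be non-negative and sum to 1 over the evaluated criteria")
  }
  directions <- directions %||% rep("benefit", ncol(N))
  if (length(directions) != ncol(N) ||
      !all(directions %in% c("benefit", "cost"))) {
    nim_stop("nimcdm_invalid_spec",
             "`directions` must be 'benefit' or 'cost', one per criterion")
  }
  V <- sweep(N, 2L, w, "*")
  hi <- apply(V, 2L, max)
  lo <- apply(V, 2L, min)
  cost <- directions == "cost"
  Ap <- ifelse(cost, lo, hi)
  An <- ifelse(cost, hi, lo)
  names(Ap) <- names(An) <- colnames(V)
  list(weighted = V, positive_ideal = Ap, negative_ideal = An)
}

#' Separations, relative proximity, and ranking
#'
#' Computes each alternative's Euclidean separation from the positive and
#' negative ideal solutions and its relative proximity
#' `R = d- / (d+ + d-)`, then ranks alternatives by decreasing proximity
#' (ties broken by input order). When an alternative has `d+ = d- = 0` (all
#' alternatives identical on every criterion) its proximity is defined as
#' 0.5 and flagged degenerate.
#'
#' @param V Weighted normalized matrix.
#' @param positive_ideal,negative_ideal Ideal-solution vectors from
#'   [weighted_ideals()].
#' @return An object of class `topsis_result`: `weighted`, `positive_ideal`,
#'   `negative_ideal`, `separation_pos` (d+), `separation_neg` (d-),
#'   `proximity` (R), `ranking` (alternative ids, best first), and
#'   `degenerate_flags`.
#' @export
proximity_and_rank <- function(V, positive_ideal, negative_ideal) {
  if (length(positive_ideal) != ncol(V) || length(negative_ideal) != ncol(V)) {
    nim_stop("nimcdm_shape_error", "ideal solutions do not match the matrix shape")
  }
  alts <- rownames(V) %||% paste0("A", seq_len(nrow(V)))
  dp <- sqrt(rowSums(sweep(V, 2L, positive_ideal)^2))
  dn <- sqrt(rowSums(sweep(V, 2L, negative_ideal)^2))
  denom <- dp + dn
  degenerate <- denom == 0
  R <- ifelse(degenerate, 0.5, dn / ifelse(denom == 0, 1, denom))
  names(R) <- names(dp) <- names(dn) <- alts
  ord <- order(-R)  # stable: ties keep input order
  structure(
    list(weighted = V,
         positive_ideal = positive_ideal,
         negative_ideal = negative_ideal,
         separation_pos = dp,
         separation_neg = dn,
         proximity = R,
         ranking = alts[ord],
         degenerate_flags = stats::setNames(degenerate, alts)),
    class = "topsis_result"
  )
}

#' Full TOPSIS evaluation of a raw decision matrix
#'
#' Convenience composition of [normalize_decision()], [weighted_ideals()]
#' and [proximity_and_rank()].
#'
#' @param X Raw decision matrix, alternatives x criteria.
#' @param w Criterion weights (non-negative, sum 1).
#' @param directions Benefit/cost direction per criterion; default all
#'   benefit.
#' @param normalized Set `TRUE` when `X` is already vector-normalized (e.g.
#'   published normalized values), skipping the normalization step.
#' @return A `topsis_result` with the normalized matrix attached as
#'   `normalized`.
#' @export
topsis <- function(X, w, directions = NULL, normalized = FALSE) {
  N <- if (normalized) X else normalize_decision(X)
  wi <- weighted_ideals(N, w, directions)
  res <- proximity_and_rank(wi$weighted, wi$positive_ideal, wi$negative_ideal)
  res$normalized <- N
  res
}

#' Per-dimension TOPSIS evaluation from expert score tables
#'
#' Averages the expert score tables elementwise into a single decision
#' matrix, then runs TOPSIS separately within each dimension of the
#' evaluation framework using that dimension's criterion-local weights
#' (which sum to 1 inside the dimension), mirroring the per-dimension
#' presentation of hospital performance results. A pooled mode running one
#' TOPSIS over all criteria with global weights is also available.
#'
#' @param scores A list of expert score matrices (alternatives x criteria),
#'   all the same shape, or a single matrix of already-aggregated scores.
#' @param framework An [assign_items()] result (or a named list of criterion
#'   ids per dimension).
#' @param weights A [limit_weights()] `weight_set`, or a named numeric
#'   vector of weights covering all framework criteria (rescaled to sum to 1
#'   within each dimension for per-dimension mode).
#' @param directions Named character vector of benefit/cost per criterion;
#'   default all benefit.
#' @param mode `"per-dimension"` (default) or `"pooled"`.
#' @return Named list of `topsis_result`, one per dimension (or a single
#'   element `pooled`).
#' @export
evaluate_by_dimension <- function(scores, framework, weights,
                                  directions = NULL,
                                  mode = c("per-dimension", "pooled")) {
  mode <- match.arg(mode)
  X <- average_scores(scores)
  dims <- if (inherits(framework, "evaluation_framework")) {
    framework$dimensions
  } else {
    framework
  }
  crit <- unlist(dims, use.names = FALSE)
  if (!all(crit %in% colnames(X))) {
    missing <- setdiff(crit, colnames(X))
    nim_stop("nimcdm_schema_error",
             sprintf("criterion column(s) absent from the score tables: %s",
                     paste(missing, collapse = ", ")))
  }
  wvec <- extract_weights(weights, crit)
  dir_for <- function(cols) {
    if (is.null(directions)) return(NULL)
    d <- directions[cols]
    d[is.na(d)] <- "benefit"
    unname(d)
  }
  if (mode == "pooled") {
    w <- wvec[crit] / sum(wvec[crit])
    return(list(pooled = topsis(X[, crit, drop = FALSE], w, dir_for(crit))))
  }
  out <- lapply(names(dims), function(d) {
    cols <- dims[[d]]
    w <- wvec[cols] / sum(wvec[cols])
    topsis(X[, cols, drop = FALSE], w, dir_for(cols))
  })
  names(out) <- names(dims)
  out
}

average_scores <- function(scores) {
  if (is.matrix(scores)) return(scores)
  mats <- unclass(scores)
  if (!is.list(mats) || length(mats) == 0L) {
    nim_stop("nimcdm_shape_error", "`scores` must be a matrix or list of matrices")
  }
  dims <- dim(mats[[1L]])
  if (!all(vapply(mats, function(m) identical(dim(m), dims), logical(1)))) {
    nim_stop("nimcdm_shape_error", "expert score tables differ in shape")
  }
  Reduce(`+`, mats) / length(mats)
}

extract_weights <- function(weights, criteria) {
  w <- if (inherits(weights, "weight_set")) weights$global else weights
  if (is.null(names(w))) {
    if (length(w) != length(criteria)) {
      nim_stop("nimcdm_shape_error", "unnamed weights must match the criterion count")
    }
    names(w) <- criteria
  }
  if (!all(criteria %in% names(w))) {
    nim_stop("nimcdm_schema_error", "weights missing for some framework criteria")
  }
  w
}
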