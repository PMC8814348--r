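#' Aggregate expert direct-influence matrices and check consensus
#'
#' Averages the H expert matrices elementwise into the average direct
#' influence matrix A, and measures expert consensus by the average gap
#' ratio: the mean, over off-diagonal cells, of the relative change in the
#' cell mean when the final expert is added,
#' `100/(n(n-1)) * sum |a_ij(H) - a_ij(H-1)| / a_ij(H)`.
#' Cells whose full-panel mean is zero cannot contribute a relative gap;
#' they are skipped and their count reported. A gap ratio below the
#' threshold (default 5%) marks the panel as stable.
#'
#' Nonzero diagonal entries in an expert matrix are zeroed with a warning:
#' a criterion does not influence itself on this scale.
#'
#' @param surveys A list of square integer matrices on the 0-4 scale, all of
#'   the same size (e.g. a [gen_influence_survey()] result).
#' @param threshold_pct Consensus threshold on the gap ratio, in percent.
#' @return A list with `average` (class `average_influence`: `values`,
#'   `expert_count`) and `consensus` (class `consensus_report`:
#'   `gap_ratio_pct`, `threshold_pct`, `stable`, `skipped_cells`).
#' @export
aggregate_experts <- function(surveys, threshold_pct = 5) {
  mats <- unclass(surveys)
  if (!is.list(mats) || length(mats) < 2L) {
    nim_stop("nimcdm_insufficient_experts",
             "need at least 2 expert matrices for a consensus check")
  }
  n <- nrow(mats[[1L]])
  mats <- lapply(seq_along(mats), function(h) {
    E <- mats[[h]]
    check_square_numeric(E, sprintf("expert matrix %d", h))
    if (nrow(E) != n) {
      nim_stop("nimcdm_shape_error", "expert matrices differ in size")
    }
    if (any(E < 0) || any(E > 4) || any(E != round(E))) {
      nim_stop("nimcdm_invalid_spec",
               sprintf("expert matrix %d has entries outside the 0..4 integer scale", h))
    }
    if (any(diag(E) != 0)) {
      warning(sprintf("expert matrix %d has nonzero diagonal entries; zeroing them", h))
      diag(E) <- 0
    }
    E
  })
  H <- length(mats)
  A_full <- Reduce(`+`, mats) / H
  A_prev <- Reduce(`+`, mats[-H]) / (H - 1)
  off <- which(diag(n) == 0)
  nonzero <- off[A_full[off] > 0]
  skipped <- length(off) - length(nonzero)
  gap <- 100 / (n * (n - 1)) *
    sum(abs(A_full[nonzero] - A_prev[nonzero]) / A_full[nonzero])
  avg <- structure(list(values = A_full, expert_count = H),
                   class = "average_influence")
  cons <- structure(list(gap_ratio_pct = gap,
                         threshold_pct = threshold_pct,
                         stable = gap < threshold_pct,
                         skipped_cells = skipped),
                    class = "consensus_report")
  list(average = avg, consensus = cons)
}

#' Normalize the average direct-influence matrix
#'
#' Scales A by `b = min(1 / max row sum, 1 / max column sum)` so that every
#' row and column sum of the normalized matrix D is at most 1, the standard
#' DEMATEL normalization guaranteeing the influence power series converges
#' for non-degenerate surveys.
#'
#' @param A An `average_influence` object or a plain non-negative square
#'   matrix with zero diagonal.
#' @return An object of class `normalized_influence` with `values` (the
#'   matrix D) and `scale_factor` (b).
#' @export
normalize_direct <- function(A) {
  Am <- if (inherits(A, "average_influence")) A$values else A
  check_square_numeric(Am, "A")
  if (all(Am == 0)) {
    nim_stop("nimcdm_degenerate_matrix",
             "all-zero influence matrix cannot be normalized")
  }
  b <- min(1 / max(rowSums(Am)), 1 / max(colSums(Am)))
  structure(list(values = b * Am, scale_factor = b),
            class = "normalized_influence")
}

#' Total-influence matrix of DEMATEL
#'
#' Sums the geometric series of direct and indirect influence,
#' `T = D + D^2 + ... = D (I - D)^(-1)`, which converges exactly when the
#' spectral radius of D is below 1. Row sums `o` (influence given) and
#' column sums `r` (influence received) are attached.
#'
#' @param D A [normalize_direct()] result or a plain matrix with spectral
#'   radius below 1.
#' @return An object of class `total_influence` with `values`, `row_sums`
#'   (o) and `col_sums` (r).
#' @export
total_influence <- function(D) {
  Dm <- if (inherits(D, "normalized_influence")) D$values else D
  check_square_numeric(Dm, "D")
  rho <- max(Mod(eigen(Dm, only.values = TRUE)$values))
  if (rho >= 1 - 1e-10) {
    nim_stop("nimcdm_non_convergent",
             sprintf("influence series diverges (spectral radius %.6f >= 1); the survey is degenerate", rho))
  }
  n <- nrow(Dm)
  Tm <- Dm %*% solve(diag(n) - Dm)
  dimnames(Tm) <- dimnames(Dm)
  structure(list(values = Tm,
                 row_sums = rowSums(Tm),
                 col_sums = colSums(Tm)),
            class = "total_influence")
}

#' Influential network relation map (INRM) coordinates and edges
#'
#' For each criterion, prominence `o + r` (total involvement in the influence
#' network) and relation `o - r` (net dispatcher when positive, net receiver
#' when negative), plus the list of influence edges strong enough to draw:
#' those with `t_ij` strictly above the threshold (default: the mean
#' off-diagonal total influence).
#'
#' @param T A [total_influence()] result.
#' @param edge_threshold Numeric threshold for retaining an edge; `NULL`
#'   (default) uses the mean off-diagonal entry of the total-influence
#'   matrix.
#' @return An object of class `inrm_profile` with `nodes` (data frame:
#'   criterion, given, received, prominence, relation), `edges` (data frame:
#'   source, target, weight) and `edge_threshold`.
#' @export
inrm_profile <- function(T, edge_threshold = NULL) {
  stopifnot(inherits(T, "total_influence"))
  Tm <- T$values
  n <- nrow(Tm)
  ids <- rownames(Tm) %||% paste0("C", seq_len(n))
  o <- T$row_sums
  r <- T$col_sums
  nodes <- data.frame(criterion = ids,
                      given = unname(o),
                      received = unname(r),
                      prominence = unname(o + r),
                      relation = unname(o - r),
                      stringsAsFactors = FALSE)
  offd <- Tm[which(diag(n) == 0)]
  thr <- edge_threshold %||% mean(offd)
  idx <- which(Tm > thr & diag(n) == 0, arr.ind = TRUE)
  edges <- data.frame(source = ids[idx[, 1L]],
                      target = ids[idx[, 2L]],
                      weight = Tm[idx],
                      stringsAsFactors = FALSE)
  edges <- edges[order(-edges$weight), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, edge_threshold = thr),
            class = "inrm_profile")
}
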