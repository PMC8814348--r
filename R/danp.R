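#' Partition of criteria into ordered dimensions (clusters)
#'
#' @param blocks Named list, dimension id -> character vector of criterion
#'   ids, in presentation order. Blocks must be non-empty and disjoint.
#' @return An object of class `dimension_partition`.
#' @export
dimension_partition <- function(blocks) {
  if (!is.list(blocks) || is.null(names(blocks)) || any(names(blocks) == "")) {
    nim_stop("nimcdm_invalid_spec", "`blocks` must be a named list of criterion ids")
  }
  crit <- unlist(blocks, use.names = FALSE)
  if (length(crit) == 0L || anyDuplicated(crit)) {
    nim_stop("nimcdm_invalid_spec", "partition blocks must be non-empty and disjoint")
  }
  structure(list(blocks = blocks, criteria = crit), class = "dimension_partition")
}

as_partition <- function(partition, criteria) {
  if (is.null(partition)) {
    partition <- dimension_partition(list(D1 = criteria))
  } else if (inherits(partition, "evaluation_framework")) {
    partition <- dimension_partition(partition$dimensions)
  } else if (!inherits(partition, "dimension_partition")) {
    partition <- dimension_partition(partition)
  }
  if (!setequal(partition$criteria, criteria)) {
    nim_stop("nimcdm_invalid_spec",
             "partition criteria do not match the matrix criteria")
  }
  partition
}

# Indices of each dimension's criteria within the partition ordering.
block_index <- function(partition) {
  idx <- integer(0)
  out <- list()
  pos <- 0L
  for (d in names(partition$blocks)) {
    k <- length(partition$blocks[[d]])
    out[[d]] <- pos + seq_len(k)
    pos <- pos + k
  }
  out
}

#' Block-normalize a total-influence matrix by dimensions
#'
#' Reorders the criterion-level total-influence matrix to the partition's
#' ordering and, within every (row-dimension, column-dimension) block,
#' divides each row by its block row sum, so that every nonzero block row
#' sums to 1. All-zero block rows are left as zeros and reported in the
#' `zero_rows` attribute.
#'
#' @param T_C A [total_influence()] result at the criterion level (or plain
#'   matrix with criterion dimnames).
#' @param partition A [dimension_partition()], an `evaluation_framework`, or
#'   a named list of criterion ids; `NULL` treats all criteria as one
#'   dimension.
#' @return The block-normalized matrix (criteria reordered to the partition
#'   ordering), with attributes `partition` and `zero_rows`.
#' @export
block_normalize <- function(T_C, partition = NULL) {
  Tm <- if (inherits(T_C, "total_influence")) T_C$values else T_C
  check_square_numeric(Tm, "T_C")
  ids <- rownames(Tm) %||% paste0("C", seq_len(nrow(Tm)))
  dimnames(Tm) <- list(ids, ids)
  partition <- as_partition(partition, ids)
  ord <- partition$criteria
  Tm <- Tm[ord, ord, drop = FALSE]
  bi <- block_index(partition)
  out <- Tm
  zero_rows <- data.frame(criterion = character(0), row_block = character(0),
                          col_block = character(0), stringsAsFactors = FALSE)
  for (di in names(bi)) {
    for (dj in names(bi)) {
      block <- Tm[bi[[di]], bi[[dj]], drop = FALSE]
      rs <- rowSums(block)
      zr <- rs == 0
      rs[zr] <- 1
      out[bi[[di]], bi[[dj]]] <- block / rs
      if (any(zr)) {
        zero_rows <- rbind(zero_rows, data.frame(
          criterion = rownames(block)[zr], row_block = di, col_block = dj,
          stringsAsFactors = FALSE))
      }
    }
  }
  attr(out, "partition") <- partition
  attr(out, "zero_rows") <- zero_rows
  out
}

#' Unweighted ANP supermatrix from the block-normalized influence matrix
#'
#' The unweighted supermatrix is the transpose of the block-normalized
#' total-influence matrix, so that each column describes how one criterion
#' distributes influence weight over the others.
#'
#' @param T_C_alpha A [block_normalize()] result.
#' @return An object of class `supermatrix` with `values` and
#'   `kind = "unweighted"`; the partition travels along.
#' @export
unweighted_supermatrix <- function(T_C_alpha) {
  check_square_numeric(T_C_alpha, "T_C_alpha")
  W <- t(T_C_alpha)
  structure(list(values = W, kind = "unweighted",
                 partition = attr(T_C_alpha, "partition")),
            class = "supermatrix")
}

#' Dimension-level total-influence matrix from criterion-level influence
#'
#' Averages each (row-dimension, column-dimension) block of the
#' criterion-level total-influence matrix into a single scalar, giving the
#' m x m dimension-level influence matrix used to weight the supermatrix.
#'
#' @param T_C A [total_influence()] result (or plain matrix).
#' @param partition A [dimension_partition()] (or coercible) over the
#'   criteria of `T_C`.
#' @return An m x m numeric matrix with dimension ids as dimnames.
#' @export
dimension_influence <- function(T_C, partition) {
  Tm <- if (inherits(T_C, "total_influence")) T_C$values else T_C
  check_square_numeric(Tm, "T_C")
  ids <- rownames(Tm) %||% paste0("C", seq_len(nrow(Tm)))
  dimnames(Tm) <- list(ids, ids)
  partition <- as_partition(partition, ids)
  dn <- names(partition$blocks)
  TD <- matrix(0, length(dn), length(dn), dimnames = list(dn, dn))
  for (di in dn) for (dj in dn) {
    TD[di, dj] <- mean(Tm[partition$blocks[[di]], partition$blocks[[dj]], drop = FALSE])
  }
  TD
}

#' Weight the unweighted supermatrix by dimension-level influence
#'
#' Row-normalizes the dimension-level total-influence matrix and scales each
#' (row-dimension i, column-dimension j) block of the unweighted supermatrix
#' by the normalized dimension influence of j on i, so that the weighted
#' supermatrix stays column-stochastic. With a single dimension the weighted
#' supermatrix equals the unweighted one.
#'
#' @param T_D The m x m dimension-level total-influence matrix (e.g. from
#'   [dimension_influence()]); ignored when there is a single dimension.
#' @param W_alpha An [unweighted_supermatrix()] result.
#' @param partition Optional partition override; defaults to the one carried
#'   by `W_alpha`.
#' @return An object of class `supermatrix` with `kind = "weighted"`.
#' @export
weighted_supermatrix <- function(T_D, W_alpha, partition = NULL) {
  stopifnot(inherits(W_alpha, "supermatrix"))
  W <- W_alpha$values
  partition <- partition %||% W_alpha$partition
  partition <- as_partition(partition, rownames(W))
  bi <- block_index(partition)
  m <- length(bi)
  if (m == 1L) {
    return(structure(list(values = W, kind = "weighted", partition = partition,
                          dimension_weights = matrix(1, 1, 1,
                            dimnames = list(names(bi), names(bi)))),
                     class = "supermatrix"))
  }
  check_square_numeric(T_D, "T_D")
  if (nrow(T_D) != m) {
    nim_stop("nimcdm_shape_error",
             "`T_D` must be m x m where m is the number of dimensions")
  }
  ds <- rowSums(T_D)
  if (any(ds == 0)) {
    nim_stop("nimcdm_degenerate_dimension",
             "a dimension row of T_D sums to zero; cannot normalize")
  }
  TDa <- T_D / ds
  out <- W
  dn <- names(bi)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    # block (i, j) of the supermatrix receives the normalized influence of
    # dimension j on dimension i, keeping columns stochastic
    out[bi[[i]], bi[[j]]] <- W[bi[[i]], bi[[j]]] * TDa[j, i]
  }
  structure(list(values = out, kind = "weighted", partition = partition,
                 dimension_weights = {
                   dimnames(TDa) <- list(dn, dn); TDa
                 }),
            class = "supermatrix")
}

#' Influence weights from the limit of the weighted supermatrix
#'
#' Raises the column-stochastic weighted supermatrix to increasing powers
#' (by repeated squaring) until successive powers agree in max-norm. The
#' columns of the limit give the global influence weights; dimension-local
#' weights are the sums of member criteria, and criterion-local weights are
#' global weights rescaled to sum to 1 within each dimension.
#'
#' A period-2 oscillation (possible for permutation-like supermatrices) is
#' detected and resolved by averaging the two accumulation points (Cesaro
#' limit), with `cyclic = TRUE` flagged. A reducible supermatrix whose limit
#' columns disagree is flagged `reducible = TRUE` and the column average is
#' used.
#'
#' @param W A weighted [weighted_supermatrix()] result, or a plain
#'   column-stochastic matrix.
#' @param tol Max-norm convergence tolerance between successive powers.
#' @param max_iter Maximum number of squarings.
#' @return An object of class `weight_set`: `weights` (data frame: criterion,
#'   dimension, global, criterion_local), `dimension_local` (named vector),
#'   `global` (named vector), and `convergence` (iterations, final gap,
#'   cyclic/reducible flags).
#' @export
limit_weights <- function(W, tol = 1e-9, max_iter = 10000L) {
  partition <- NULL
  Wm <- W
  if (inherits(W, "supermatrix")) {
    if (!identical(W$kind, "weighted")) {
      nim_stop("nimcdm_invalid_spec", "limit requires the weighted supermatrix")
    }
    partition <- W$partition
    Wm <- W$values
  }
  check_square_numeric(Wm, "W")
  if (max(abs(colSums(Wm) - 1)) > 1e-6 || any(Wm < -1e-12)) {
    nim_stop("nimcdm_invalid_spec", "`W` must be column-stochastic and non-negative")
  }
  ids <- rownames(Wm) %||% paste0("C", seq_len(nrow(Wm)))
  partition <- as_partition(partition, ids)

  P <- Wm
  gap <- Inf
  iters <- 0L
  while (iters < max_iter) {
    P2 <- P %*% P
    gap <- max(abs(P2 - P))
    P <- P2
    iters <- iters + 1L
    if (gap < tol) break
  }
  cyclic <- FALSE
  if (gap >= tol) {
    nim_stop("nimcdm_non_convergence",
             sprintf("supermatrix powers did not converge in %d squarings (gap %.3g)",
                     iters, gap))
  }
  PW <- P %*% Wm
  if (max(abs(PW - P)) > sqrt(tol)) {
    # period-2 cycle: squaring converged to one accumulation point; take the
    # Cesaro average of the two
    cyclic <- TRUE
    P <- (P + PW) / 2
  }
  col_spread <- max(apply(P, 1L, function(x) diff(range(x))))
  reducible <- col_spread > 1e-6
  w <- rowMeans(P)
  w <- w / sum(w)
  names(w) <- ids

  dims <- rep(names(partition$blocks), lengths(partition$blocks))
  names(dims) <- unlist(partition$blocks, use.names = FALSE)
  dims <- dims[ids]
  dim_local <- tapply(w, dims, sum)
  dim_local <- dim_local[unique(dims)]
  crit_local <- w / dim_local[dims]
  weights <- data.frame(criterion = ids,
                        dimension = unname(dims),
                        global = unname(w),
                        criterion_local = unname(crit_local),
                        stringsAsFactors = FALSE)
  structure(
    list(weights = weights,
         global = w,
         dimension_local = stats::setNames(as.numeric(dim_local), names(dim_local)),
         convergence = list(iterations = iters, final_gap = gap,
                            cyclic = cyclic, reducible = reducible)),
    class = "weight_set"
  )
}
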