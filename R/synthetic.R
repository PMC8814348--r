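#' Specification of a planted factor structure for Likert panels
#'
#' Describes the latent structure used to simulate questionnaire responses:
#' each item loads on the factors according to `loading_pattern`, with
#' independent Gaussian item noise on top. Every item must have exactly one
#' salient loading (absolute value at least 0.6) so the planted assignment of
#' items to factors is unambiguous, and each row's communality (sum of squared
#' loadings) may not exceed 1.
#'
#' @param loading_pattern Numeric matrix, items x factors, entries in
#'   \[-1, 1\]. Row names (if any) become item identifiers.
#' @param noise_sd Standard deviation of the unique (item-specific) noise;
#'   non-negative.
#' @param missing_rate Probability that any one response is masked as missing;
#'   in \[0, 1).
#' @return An object of class `factor_spec`.
#' @seealso [gen_likert_panel()]
#' @export
factor_spec <- function(loading_pattern, noise_sd = 0.5, missing_rate = 0) {
  if (!is.matrix(loading_pattern) || !is.numeric(loading_pattern)) {
    nim_stop("nimcdm_invalid_spec", "`loading_pattern` must be a numeric matrix")
  }
  if (any(abs(loading_pattern) > 1)) {
    nim_stop("nimcdm_invalid_spec", "loadings must lie in [-1, 1]")
  }
  salient <- rowSums(abs(loading_pattern) >= 0.6)
  if (any(salient != 1L)) {
    nim_stop("nimcdm_invalid_spec",
             sprintf("every item needs exactly one loading with |a| >= 0.6 (items violating: %s)",
                     paste(which(salient != 1L), collapse = ", ")))
  }
  communality <- rowSums(loading_pattern^2)
  if (any(communality > 1 + 1e-12)) {
    nim_stop("nimcdm_invalid_spec", "row communalities must not exceed 1")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    nim_stop("nimcdm_invalid_spec", "`noise_sd` must be a single non-negative number")
  }
  if (!is.numeric(missing_rate) || length(missing_rate) != 1L ||
      missing_rate < 0 || missing_rate >= 1) {
    nim_stop("nimcdm_invalid_spec", "`missing_rate` must lie in [0, 1)")
  }
  if (is.null(rownames(loading_pattern))) {
    rownames(loading_pattern) <- paste0("I", seq_len(nrow(loading_pattern)))
  }
  if (is.null(colnames(loading_pattern))) {
    colnames(loading_pattern) <- paste0("F", seq_len(ncol(loading_pattern)))
  }
  structure(
    list(loading_pattern = loading_pattern,
         n_items = nrow(loading_pattern),
         n_factors = ncol(loading_pattern),
         noise_sd = noise_sd,
         missing_rate = missing_rate),
    class = "factor_spec"
  )
}

#' Simulate a Likert (1-5) questionnaire panel with planted factors
#'
#' Draws standard-normal latent factor scores per respondent, forms each
#' item's latent response as `scores %*% t(loading_pattern)` plus Gaussian
#' noise, standardizes each item by its model-implied standard deviation, and
#' discretizes to the five response categories with fixed symmetric cut points
#' at z = -1.5, -0.5, 0.5, 1.5. Responses are then masked missing (`NA`)
#' independently at `missing_rate`.
#'
#' @param spec A [factor_spec()].
#' @param n_respondents Number of respondents; must be at least twice the
#'   number of items so downstream correlation estimates are sane.
#' @param seed Integer seed; identical `(spec, n_respondents, seed)` yields a
#'   bit-identical panel.
#' @return An integer matrix (class `likert_panel`), respondents x items,
#'   values in 1..5 with `NA` for missing responses.
#' @export
gen_likert_panel <- function(spec, n_respondents, seed) {
  stopifnot(inherits(spec, "factor_spec"))
  if (n_respondents < 2L * spec$n_items) {
    nim_stop("nimcdm_invalid_spec",
             "`n_respondents` must be at least twice the number of items")
  }
  L <- spec$loading_pattern
  item_sd <- sqrt(rowSums(L^2) + spec$noise_sd^2)
  item_sd[item_sd == 0] <- 1  # all-zero row impossible given salient-loading rule
  with_seed(seed, {
    scores <- matrix(stats::rnorm(n_respondents * spec$n_factors),
                     nrow = n_respondents)
    latent <- scores %*% t(L)
    if (spec$noise_sd > 0) {
      latent <- latent + spec$noise_sd *
        matrix(stats::rnorm(length(latent)), nrow = n_respondents)
    }
    z <- sweep(latent, 2L, item_sd, "/")
    panel <- matrix(findInterval(z, c(-1.5, -0.5, 0.5, 1.5)) + 1L,
                    nrow = n_respondents)
    if (spec$missing_rate > 0) {
      mask <- matrix(stats::runif(length(panel)) < spec$missing_rate,
                     nrow = n_respondents)
      panel[mask] <- NA_integer_
    }
    dimnames(panel) <- list(paste0("R", seq_len(n_respondents)), rownames(L))
    class(panel) <- c("likert_panel", class(panel))
    panel
  })
}

#' Specification of an expert direct-influence survey
#'
#' The ground truth is the consensus direct-influence matrix on the 0-4 scale
#' (0 = no influence, 4 = very high influence, zero diagonal). Each simulated
#' expert reproduces the ground truth except that any off-diagonal cell
#' independently deviates by +/-1 with probability `disagreement` (clamped
#' back into 0..4).
#'
#' @param ground_truth Square integer matrix with entries in {0,..,4} and zero
#'   diagonal. Dimnames (if any) become criterion identifiers.
#' @param expert_count Number of experts H to simulate.
#' @param disagreement Per-cell probability of a +/-1 deviation; in \[0, 1\].
#' @return An object of class `influence_spec`.
#' @seealso [gen_influence_survey()]
#' @export
influence_spec <- function(ground_truth, expert_count, disagreement = 0) {
  check_square_numeric(ground_truth, "ground_truth")
  if (any(ground_truth != round(ground_truth)) ||
      any(ground_truth < 0) || any(ground_truth > 4)) {
    nim_stop("nimcdm_invalid_spec", "ground truth entries must be integers in 0..4")
  }
  if (any(diag(ground_truth) != 0)) {
    nim_stop("nimcdm_invalid_spec", "ground truth diagonal must be identically 0")
  }
  if (!is.numeric(disagreement) || disagreement < 0 || disagreement > 1) {
    nim_stop("nimcdm_invalid_spec", "`disagreement` must lie in [0, 1]")
  }
  if (is.null(rownames(ground_truth))) {
    ids <- paste0("C", seq_len(nrow(ground_truth)))
    dimnames(ground_truth) <- list(ids, ids)
  }
  structure(
    list(ground_truth = ground_truth,
         expert_count = as.integer(expert_count),
         disagreement = disagreement),
    class = "influence_spec"
  )
}

#' Simulate a set of expert direct-influence matrices
#'
#' @param spec An [influence_spec()]; `expert_count` must be at least 2 (a
#'   consensus check needs more than one voice).
#' @param seed Integer seed.
#' @return A list (class `influence_survey`) of `expert_count` integer
#'   matrices on the 0-4 scale with zero diagonals.
#' @export
gen_influence_survey <- function(spec, seed) {
  stopifnot(inherits(spec, "influence_spec"))
  if (spec$expert_count < 2L) {
    nim_stop("nimcdm_insufficient_experts", "at least 2 experts are required")
  }
  G <- spec$ground_truth
  n <- nrow(G)
  off <- which(diag(n) == 0)
  with_seed(seed, {
    surveys <- lapply(seq_len(spec$expert_count), function(h) {
      E <- G
      if (spec$disagreement > 0) {
        hit <- off[stats::runif(length(off)) < spec$disagreement]
        if (length(hit)) {
          step <- ifelse(stats::runif(length(hit)) < 0.5, -1L, 1L)
          E[hit] <- pmin(4L, pmax(0L, E[hit] + step))
        }
      }
      E
    })
    names(surveys) <- paste0("expert", seq_along(surveys))
    structure(surveys, class = "influence_survey")
  })
}

#' Specification of expert performance scoring of alternatives
#'
#' @param true_quality Numeric matrix, alternatives x criteria, entries in
#'   \[0, 10\]: the latent quality each expert's 0-10 score is centered on.
#' @param expert_count Number of experts; at least 1.
#' @param score_sd Standard deviation of the Gaussian scoring noise;
#'   non-negative.
#' @return An object of class `performance_spec`.
#' @seealso [gen_performance_scores()]
#' @export
performance_spec <- function(true_quality, expert_count, score_sd = 1) {
  if (!is.matrix(true_quality) || !is.numeric(true_quality)) {
    nim_stop("nimcdm_invalid_spec", "`true_quality` must be a numeric matrix")
  }
  if (any(true_quality < 0) || any(true_quality > 10)) {
    nim_stop("nimcdm_invalid_spec", "true qualities must lie in [0, 10]")
  }
  if (!is.numeric(score_sd) || length(score_sd) != 1L || score_sd < 0) {
    nim_stop("nimcdm_invalid_spec", "`score_sd` must be a single non-negative number")
  }
  if (expert_count < 1L) {
    nim_stop("nimcdm_insufficient_experts", "at least 1 expert is required")
  }
  if (is.null(rownames(true_quality))) {
    rownames(true_quality) <- paste0("A", seq_len(nrow(true_quality)))
  }
  if (is.null(colnames(true_quality))) {
    colnames(true_quality) <- paste0("C", seq_len(ncol(true_quality)))
  }
  structure(
    list(true_quality = true_quality,
         expert_count = as.integer(expert_count),
         score_sd = score_sd),
    class = "performance_spec"
  )
}

#' Simulate per-expert 0-10 performance score tables
#'
#' Each expert's table is the true quality plus independent Gaussian noise,
#' clamped to the 0-10 scale; the expert-mean table therefore converges to
#' the true quality as `score_sd` shrinks.
#'
#' @param spec A [performance_spec()].
#' @param seed Integer seed.
#' @return A list (class `performance_scores`) of `expert_count` numeric
#'   matrices, alternatives x criteria, values in \[0, 10\].
#' @export
gen_performance_scores <- function(spec, seed) {
  stopifnot(inherits(spec, "performance_spec"))
  with_seed(seed, {
    tabs <- lapply(seq_len(spec$expert_count), function(h) {
      X <- spec$true_quality
      if (spec$score_sd > 0) {
        X <- X + spec$score_sd * matrix(stats::rnorm(length(X)), nrow = nrow(X))
      }
      X[X < 0] <- 0
      X[X > 10] <- 10
      X
    })
    names(tabs) <- paste0("expert", seq_along(tabs))
    structure(tabs, class = "performance_scores")
  })
}
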