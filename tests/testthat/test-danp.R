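test_that("block normalization divides each block row by its block row sum", {
  Tm <- matrix(c(1, 1, 2, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  Tca <- block_normalize(Tm, list(D1 = c("a", "b")))
  expect_equal(unname(Tca), rbind(c(1 / 3, 2 / 3), c(1 / 2, 1 / 2)),
               ignore_attr = TRUE)

  # two singleton dimensions: each diagonal block collapses to the scalar 1
  Td <- diag(c(2, 5)); dimnames(Td) <- list(c("a", "b"), c("a", "b"))
  Tca2 <- block_normalize(Td, list(D1 = "a", D2 = "b"))
  expect_equal(diag(unname(Tca2)), c(1, 1))
  # the off-diagonal blocks were all-zero rows, reported not rescaled
  expect_equal(nrow(attr(Tca2, "zero_rows")), 2L)

  # contract: every nonzero block row sums to 1
  spec <- random_survey_spec(n = 8, H = 5, disagreement = 0.1, seed = 3)
  sv <- gen_influence_survey(spec, seed = 30)
  Tt <- total_influence(normalize_direct(aggregate_experts(sv)$average))
  part <- list(D1 = rownames(Tt$values)[1:4], D2 = rownames(Tt$values)[5:8])
  Tca3 <- block_normalize(Tt, part)
  for (di in names(part)) for (dj in names(part)) {
    rs <- rowSums(Tca3[part[[di]], part[[dj]]])
    expect_equal(unname(rs), rep(1, 4), tolerance = 1e-10)
  }
})

test_that("the unweighted supermatrix is the block-normalized transpose", {
  Tm <- matrix(c(1, 1, 2, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  Tca <- block_normalize(Tm, list(D1 = c("a", "b")))
  Wa <- unweighted_supermatrix(Tca)
  expect_equal(unname(Wa$values), rbind(c(1 / 3, 1 / 2), c(2 / 3, 1 / 2)),
               ignore_attr = TRUE)
  expect_equal(unname(colSums(Wa$values)), c(1, 1), tolerance = 1e-10)
  # symmetric input is a fixed point of transposition
  S <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, dimnames = list(c("a", "b"), c("a", "b")))
  attr(S, "partition") <- dimension_partition(list(D1 = c("a", "b")))
  expect_equal(unweighted_supermatrix(S)$values, t(S), ignore_attr = TRUE)
})

test_that("dimension weighting keeps the supermatrix column-stochastic", {
  spec <- random_survey_spec(n = 8, H = 5, disagreement = 0.1, seed = 4)
  sv <- gen_influence_survey(spec, seed = 44)
  Tt <- total_influence(normalize_direct(aggregate_experts(sv)$average))
  part <- list(D1 = rownames(Tt$values)[1:4], D2 = rownames(Tt$values)[5:8])
  Wa <- unweighted_supermatrix(block_normalize(Tt, part))
  TD <- dimension_influence(Tt, part)
  Ww <- weighted_supermatrix(TD, Wa)
  expect_equal(unname(colSums(Ww$values)), rep(1, 8), tolerance = 1e-8)
  # and so are its powers
  P <- Ww$values %*% Ww$values %*% Ww$values
  expect_equal(unname(colSums(P)), rep(1, 8), tolerance = 1e-8)

  # single dimension: weighting is the identity operation
  Tca1 <- block_normalize(Tt, NULL)
  Wa1 <- unweighted_supermatrix(Tca1)
  expect_equal(weighted_supermatrix(NULL, Wa1)$values, Wa1$values)

  # diagonal dimension influence leaves the supermatrix block-diagonal
  TDdiag <- diag(diag(TD))
  Wdiag <- weighted_supermatrix(TDdiag, Wa)$values
  expect_equal(unname(Wdiag[1:4, 5:8]), matrix(0, 4, 4))
  expect_equal(unname(Wdiag[5:8, 1:4]), matrix(0, 4, 4))

  expect_error(weighted_supermatrix(matrix(0, 2, 2), Wa),
               class = "nimcdm_degenerate_dimension")
})

test_that("limit weights agree with the stationary vector of the supermatrix", {
  # already stationary
  W0 <- matrix(0.5, 2, 2)
  ws0 <- limit_weights(W0)
  expect_equal(unname(ws0$global), c(0.5, 0.5))

  # hand-solved stationary vector (3/7, 4/7), checked against power iteration
  W1 <- matrix(c(1 / 3, 2 / 3, 1 / 2, 1 / 2), 2)
  ws1 <- limit_weights(W1)
  expect_equal(unname(ws1$global), c(3 / 7, 4 / 7), tolerance = 1e-9)
  expect_equal(unname(ws1$global), power_iteration_weights(W1), tolerance = 1e-6)

  # period-2 permutation: Cesaro average with a flag
  W2 <- matrix(c(0, 1, 1, 0), 2)
  ws2 <- limit_weights(W2)
  expect_true(ws2$convergence$cyclic)
  expect_equal(unname(ws2$global), c(0.5, 0.5))

  expect_error(limit_weights(matrix(c(0.9, 0.2, 0.1, 0.8), 2)),
               class = "nimcdm_invalid_spec")  # not column-stochastic
})

test_that("weight bookkeeping: sums, local weights, eigen consistency", {
  spec <- random_survey_spec(n = 8, H = 6, disagreement = 0.1, seed = 6)
  sv <- gen_influence_survey(spec, seed = 66)
  Tt <- total_influence(normalize_direct(aggregate_experts(sv)$average))
  part <- list(D1 = rownames(Tt$values)[1:4], D2 = rownames(Tt$values)[5:8])
  Ww <- weighted_supermatrix(dimension_influence(Tt, part),
                             unweighted_supermatrix(block_normalize(Tt, part)))
  ws <- limit_weights(Ww)
  expect_equal(sum(ws$global), 1, tolerance = 1e-10)
  expect_true(all(ws$global >= 0))
  for (d in c("D1", "D2")) {
    sub <- ws$weights[ws$weights$dimension == d, ]
    expect_equal(sum(sub$criterion_local), 1, tolerance = 1e-8)
    expect_equal(sub$global / ws$dimension_local[[d]], sub$criterion_local,
                 tolerance = 1e-8)
  }
  # the limit weights are the dominant right eigen-structure: W w = w
  expect_lt(max(abs(Ww$values %*% ws$global - ws$global)), 1e-6)
  # and match a plain power-iteration oracle
  expect_equal(unname(ws$global), power_iteration_weights(Ww$values),
               tolerance = 1e-6)
})

test_that("a criterion dominating every column receives the top global weight", {
  # every criterion directs maximal influence toward criterion 1, so the
  # limit supermatrix concentrates weight there
  G <- matrix(1L, 5, 5)
  G[, 1] <- 4L
  diag(G) <- 0L
  sv <- gen_influence_survey(influence_spec(G, 10L, disagreement = 0), seed = 1)
  Tt <- total_influence(normalize_direct(aggregate_experts(sv)$average))
  Ww <- weighted_supermatrix(NULL, unweighted_supermatrix(block_normalize(Tt, NULL)))
  ws <- limit_weights(Ww)
  expect_equal(unname(which.max(ws$global)), 1L)
})
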