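test_that("vector normalization gives unit-sum-of-squares columns", {
  X <- cbind(a = c(3, 4), b = c(1, 1))
  N <- normalize_decision(X)
  expect_equal(N[, "a"], c(0.6, 0.8), ignore_attr = TRUE)
  expect_equal(unname(colSums(N^2)), c(1, 1), tolerance = 1e-10)

  # positive rescaling of a raw column leaves the normalized column unchanged
  X2 <- X; X2[, "a"] <- 17 * X2[, "a"]
  expect_equal(normalize_decision(X2), N)

  X3 <- cbind(a = c(1, 2), b = c(0, 0))
  expect_error(normalize_decision(X3), class = "nimcdm_degenerate_criterion")
  expect_error(normalize_decision(X3), "b")
})

test_that("ideal solutions follow the benefit/cost directions", {
  V <- rbind(c(0.1, 0.3), c(0.2, 0.2))
  colnames(V) <- c("c1", "c2")
  wi <- weighted_ideals(V, c(0.5, 0.5))
  # weights halve the entries; ideals are elementwise extrema of the weighted matrix
  expect_equal(unname(wi$positive_ideal), c(0.1, 0.15))
  expect_equal(unname(wi$negative_ideal), c(0.05, 0.1))
  # flipping one criterion to cost swaps its ideal entries
  wi2 <- weighted_ideals(V, c(0.5, 0.5), c("cost", "benefit"))
  expect_equal(unname(wi2$positive_ideal), c(0.05, 0.15))
  expect_equal(unname(wi2$negative_ideal), c(0.1, 0.1))

  expect_error(weighted_ideals(V, c(0.5, 0.4)), class = "nimcdm_invalid_spec")
  expect_error(weighted_ideals(V, c(0.5)), class = "nimcdm_shape_error")
})

test_that("proximity is d-/(d+ + d-) with stable ranking and degenerate guard", {
  # one alternative dominates on every criterion
  X <- rbind(A = c(9, 8), B = c(3, 2))
  res <- topsis(X, c(0.6, 0.4))
  expect_equal(unname(res$proximity), c(1, 0))
  expect_equal(res$ranking, c("A", "B"))
  expect_true(all(res$proximity >= 0 & res$proximity <= 1))

  # identical alternatives: both flagged degenerate at 0.5
  X2 <- rbind(A = c(2, 2), B = c(2, 2))
  res2 <- topsis(X2, c(0.5, 0.5))
  expect_equal(unname(res2$proximity), c(0.5, 0.5))
  expect_true(all(res2$degenerate_flags))
  expect_equal(res2$ranking, c("A", "B"))  # tie broken by input order

  # duplicating an alternative's scores gives the duplicate equal proximity
  X3 <- rbind(A = c(5, 1), B = c(2, 4), B2 = c(2, 4))
  res3 <- topsis(X3, c(0.5, 0.5))
  expect_equal(res3$proximity[["B"]], res3$proximity[["B2"]], tolerance = 1e-12)
})

test_that("bundled case study reproduces the published proximities and rankings", {
  res <- case_study_evaluation()
  expect_equal(unname(res$D1$proximity[c("SYUH", "GZMH", "ZCWH")]),
               c(0.214, 0.565, 0.660), tolerance = 0.005)
  expect_equal(unname(res$D2$proximity[c("SYUH", "GZMH", "ZCWH")]),
               c(0.433, 0.369, 0.619), tolerance = 0.005)
  expect_equal(res$D1$ranking, c("ZCWH", "GZMH", "SYUH"))
  expect_equal(res$D2$ranking, c("ZCWH", "SYUH", "GZMH"))
})

test_that("published normalized columns have unit sums of squares", {
  N <- case_study_normalized_scores()
  ss <- colSums(N^2)
  expect_true(all(ss >= 0.995 & ss <= 1.005))
})

test_that("per-dimension evaluation composes the elementary operations", {
  N <- case_study_normalized_scores()
  w <- case_study_weights()
  fw <- list(D1 = paste0("C1", 1:4), D2 = paste0("C2", 1:4))
  # single expert, raw-score path: running the stages by hand must agree
  X <- abs(N) * 10
  res <- evaluate_by_dimension(list(expert1 = X), fw,
                               stats::setNames(w$weight, w$criterion))
  for (d in names(fw)) {
    cols <- fw[[d]]
    wd <- stats::setNames(w$weight[match(cols, w$criterion)], cols)
    manual <- topsis(X[, cols], wd / sum(wd))
    expect_equal(res[[d]]$proximity, manual$proximity, tolerance = 1e-12)
  }
  expect_error(evaluate_by_dimension(X[, 1:5], fw, stats::setNames(w$weight, w$criterion)),
               class = "nimcdm_schema_error")
})

test_that("many low-noise experts converge to the single-expert result", {
  truth <- with_fixed_seed(31, matrix(runif(24, 2, 9), nrow = 3,
                  dimnames = list(c("A", "B", "C"), paste0("c", 1:8))))
  fw <- list(D1 = paste0("c", 1:4), D2 = paste0("c", 5:8))
  w <- stats::setNames(rep(1 / 8, 8), paste0("c", 1:8))
  exact <- evaluate_by_dimension(truth, fw, w)
  noisy <- gen_performance_scores(performance_spec(truth, 15L, score_sd = 0.01),
                                  seed = 2)
  approx <- evaluate_by_dimension(noisy, fw, w)
  for (d in names(fw)) {
    expect_equal(approx[[d]]$proximity, exact[[d]]$proximity, tolerance = 0.02)
  }
})

test_that("an alternative dominating the heavy-weight criteria ranks first", {
  # ZCWH-like alternative: best on the top-weighted criterion of each dimension
  truth <- rbind(SYUH = c(5, 4, 5, 4, 6, 5, 5, 7),
                 GZMH = c(6, 5, 4, 5, 4, 7, 4, 5),
                 ZCWH = c(8, 7, 8, 7, 8, 6, 9, 6))
  colnames(truth) <- c(paste0("C1", 1:4), paste0("C2", 1:4))
  fw <- list(D1 = paste0("C1", 1:4), D2 = paste0("C2", 1:4))
  w <- case_study_weights()
  scores <- gen_performance_scores(performance_spec(truth, 15L, score_sd = 0.5),
                                   seed = 7)
  res <- evaluate_by_dimension(scores, fw, stats::setNames(w$weight, w$criterion))
  expect_equal(res$D1$ranking[1], "ZCWH")
  expect_equal(res$D2$ranking[1], "ZCWH")
})

test_that("proximities stay in [0,1] across random decision problems", {
  for (s in 1:20) {
    with_fixed_seed(s, {
      X <- matrix(runif(5 * 4, 0, 10), 5, 4)
      w <- runif(4); w <- w / sum(w)
      dirs <- sample(c("benefit", "cost"), 4, replace = TRUE)
      res <- topsis(X, w, dirs)
      expect_true(all(res$proximity >= 0 & res$proximity <= 1))
    })
  }
})
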