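test_that("quadratic scores equal term-by-term evaluation of the rule", {
  means <- list(a = c(0, 0), b = c(1, 1))
  covs <- list(a = matrix(c(1, 0.2, 0.2, 1), 2),
               b = matrix(c(2, -0.3, -0.3, 1.5), 2))
  priors <- c(a = 0.4, b = 0.6)
  model <- structure(list(
    classes = c("a", "b"), means = means, covariances = covs,
    priors = priors, chol = lapply(covs, chol),
    logdet = lapply(covs, function(S) log(det(S))), d = 2L,
    location_id = NULL), class = "rc_qda")
  xs <- rbind(c(0.5, 0.2), c(-1, 2), c(3, 0))
  got <- qda_scores(model, xs)
  for (i in seq_len(nrow(xs))) for (cl in c("a", "b")) {
    x <- xs[i, ]
    want <- -0.5 * log(det(covs[[cl]])) -
      0.5 * t(x - means[[cl]]) %*% solve(covs[[cl]]) %*% (x - means[[cl]]) +
      log(priors[[cl]])
    expect_equal(unname(got[i, cl]), as.numeric(want), tolerance = 1e-10)
  }
})

test_that("fit_qda estimates class moments and detects rank deficiency", {
  set.seed(21)
  x <- rbind(matrix(rnorm(200, 0), ncol = 2), matrix(rnorm(200, 4), ncol = 2))
  y <- rep(c("lo", "hi"), each = 100)
  m <- fit_qda(x, y)
  expect_equal(m$means$lo, colMeans(x[y == "lo", ]), ignore_attr = TRUE)
  expect_equal(m$covariances$hi, cov(x[y == "hi", ]), ignore_attr = TRUE)
  expect_equal(sum(m$priors), 1)

  # constant vectors: zero covariance is rank-deficient, named by location
  const <- rbind(matrix(1, 10, 3), matrix(2, 10, 3))
  expect_error(fit_qda(const, rep(c("a", "b"), each = 10), location_id = 4),
               "rank-deficient.*location 4")
  # n must exceed dimension
  expect_error(fit_qda(x[c(1:2, 101:200), ], y[c(1:2, 101:200)]), "exceed")
})

test_that("classification: class means, tie-breaks, and the 1-D boundary", {
  # equal priors, equal covariances: a class mean classifies to its class
  set.seed(4)
  x <- rbind(matrix(rnorm(120, 0, 1), ncol = 2),
             matrix(rnorm(120, 5, 1), ncol = 2))
  y <- rep(c("a", "b"), each = 60)
  m <- fit_qda(x, y)
  expect_equal(classify(m, m$means$a), "a")
  expect_equal(classify(m, m$means$b), "b")

  # symmetric two-class setup: midpoint is a tie, logged, first class returned
  covs <- list(a = diag(2), b = diag(2))
  sym <- structure(list(classes = c("a", "b"),
                        means = list(a = c(-1, 0), b = c(1, 0)),
                        covariances = covs, priors = c(a = 0.5, b = 0.5),
                        chol = lapply(covs, chol),
                        logdet = list(a = 0, b = 0), d = 2L,
                        location_id = NULL), class = "rc_qda")
  expect_message(lab <- classify(sym, c(0, 0)), "tie")
  expect_equal(lab, "a")

  # 1-D unequal variances: decision flips exactly at the quadratic roots
  set.seed(9)
  x1 <- matrix(rnorm(400, 0, 1)); x2 <- matrix(rnorm(400, 3, 2))
  m1 <- fit_qda(rbind(x1, x2), rep(c("a", "b"), each = 400))
  f <- function(z) qda_scores(m1, z)[, "a"] - qda_scores(m1, z)[, "b"]
  r1 <- uniroot(f, c(0, 3), tol = 1e-12)$root   # boundary between the means
  eps <- 1e-4
  expect_equal(classify(m1, r1 - eps), "a")
  expect_equal(classify(m1, r1 + eps), "b")

  # prior invariance: scaling all priors by a constant shifts every score by
  # log(c), leaving the classification unchanged
  xq <- matrix(c(0.2, 2.9), ncol = 1)
  sc <- qda_scores(m1, xq)
  m3 <- m1; m3$priors <- m1$priors * 3
  expect_equal(qda_scores(m3, xq), sc + log(3))
  expect_equal(classify(m3, xq), classify(m1, xq))
})

test_that("separable classes are learned nearly perfectly", {
  set.seed(77)
  d <- 6
  f <- list(lo = matrix(rnorm(100 * d, 0, 1), ncol = d),
            hi = matrix(rnorm(100 * d, 6, 1), ncol = d))
  sw <- qda_experiment(f, training_sizes = c(20, 50), n_test = 50,
                       n_repeats = 5, seed = 1)
  expect_lt(max(sw$misclassification), 0.02)
  # rate non-increasing in training size (within noise) on separable classes
  expect_lte(sw$misclassification[2], sw$misclassification[1] + 2 * sw$se[1] + 0.01)
})

test_that("qda_experiment enforces pool limits and skips rank deficiency", {
  f <- list(a = matrix(rnorm(60), ncol = 2), b = matrix(rnorm(60), ncol = 2))
  expect_error(qda_experiment(f, training_sizes = 25, n_test = 10),
               "exceeds available pool")
  const <- list(a = matrix(1, 30, 2) + 1e-15, b = matrix(2, 30, 2))
  expect_warning(
    out <- qda_experiment(const, training_sizes = 5, n_test = 10,
                          n_repeats = 2, seed = 1, location_id = 5,
                          on_rank_deficiency = "skip"),
    "skipped")
  expect_null(out)
})

test_that("implementation agrees with the reference QDA on a fixed split", {
  skip_if_not_installed("MASS")
  set.seed(123)
  tr <- rbind(matrix(rnorm(300, 0), ncol = 3), matrix(rnorm(300, 1.5), ncol = 3))
  ytr <- rep(c("a", "b"), each = 100)
  te <- rbind(matrix(rnorm(150, 0), ncol = 3), matrix(rnorm(150, 1.5), ncol = 3))
  ours <- classify(fit_qda(tr, ytr), te)
  ref <- as.character(predict(MASS::qda(tr, grouping = ytr), te)$class)
  expect_gt(mean(ours == ref), 0.98)
})
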