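#' Fit a quadratic discriminant model on RLD-by-depth vectors
#'
#' Per class `i`, estimates the sample mean vector and covariance matrix and
#' stores the prior `p_i`; classification maximises the quadratic score
#'
#' \deqn{S_i(x) = -\tfrac12 \log|S_i| - \tfrac12 (x-\bar x_i)' S_i^{-1}
#'   (x-\bar x_i) + \log p_i.}
#'
#' A class covariance that is not numerically positive-definite (Cholesky
#' failure or condition number above `cond_tol`) raises a rank-deficiency
#' error — the situation that excludes the mid-row coring locations, whose
#' shallow bins recover almost no roots.
#'
#' @param x Numeric matrix `[n x d]` of feature vectors (RLD by depth bin).
#' @param labels Class labels, length `n`.
#' @param priors Named numeric priors summing to 1; default equal
#'   (0.5 for two classes, 1/3 for three).
#' @param cond_tol Condition-number threshold for rank deficiency.
#' @param location_id Optional label used in rank-deficiency messages.
#' @return An `rc_qda`: `classes`, `means`, `covariances`, `priors`,
#'   Cholesky factors and log-determinants.
#' @export
fit_qda <- function(x, labels, priors = NULL, cond_tol = 1e10,
                    location_id = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stop_if(nrow(x) != length(labels), "labels must match rows of x")
  classes <- sort(unique(labels))
  stop_if(length(classes) < 2, "need >= 2 classes")
  d <- ncol(x)
  if (is.null(priors))
    priors <- setNames(rep(1 / length(classes), length(classes)), classes)
  stop_if(!isTRUE(all.equal(sum(priors), 1, tolerance = 1e-9)),
          "priors must sum to 1")
  where <- if (is.null(location_id)) "" else sprintf(" at location %s", location_id)
  means <- list(); chols <- list(); logdets <- list()
  for (cl in classes) {
    xi <- x[labels == cl, , drop = FALSE]
    stop_if(nrow(xi) <= d,
            sprintf("class '%s'%s: n (%d) must exceed dimension (%d)",
                    cl, where, nrow(xi), d))
    S <- stats::cov(xi)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch) || kappa(S, exact = TRUE) > cond_tol)
      stop(sprintf("rank-deficient covariance for class '%s'%s", cl, where),
           call. = FALSE)
    means[[cl]] <- colMeans(xi)
    chols[[cl]] <- ch
    logdets[[cl]] <- 2 * sum(log(diag(ch)))
  }
  structure(list(classes = classes, means = means,
                 covariances = lapply(chols, crossprod),
                 priors = priors[classes], chol = chols,
                 logdet = logdets, d = d, location_id = location_id),
            class = "rc_qda")
}

#' Quadratic discriminant scores for new samples
#'
#' @param model An [fit_qda()] model.
#' @param x Numeric vector of length `d` or matrix `[m x d]`.
#' @return Matrix `[m x k]` of per-class scores.
#' @export
qda_scores <- function(model, x) {
  stopifnot(inherits(model, "rc_qda"))
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  stop_if(ncol(x) != model$d, "x dimension does not match model")
  out <- matrix(NA_real_, nrow(x), length(model$classes),
                dimnames = list(NULL, model$classes))
  for (cl in model$classes) {
    cen <- sweep(x, 2, model$means[[cl]])
    # quadratic form via triangular solve: ||R^-T (x - mu)||^2
    z <- backsolve(model$chol[[cl]], t(cen), transpose = TRUE)
    out[, cl] <- -0.5 * model$logdet[[cl]] - 0.5 * colSums(z^2) +
      log(model$priors[[cl]])
  }
  out
}

#' Classify samples with a QDA model
#'
#' Assigns each sample to the class with the largest quadratic score; exact
#' ties are broken by class order and logged as a message.
#'
#' @param model An [fit_qda()] model.
#' @param x Vector (one sample) or matrix `[m x d]`.
#' @return Character vector of class labels.
#' @export
classify <- function(model, x) {
  sc <- qda_scores(model, x)
  ties <- apply(sc, 1, function(r) sum(r == max(r)) > 1)
  if (any(ties))
    message(sum(ties), " tie(s) in QDA scores broken by class order")
  model$classes[apply(sc, 1, which.max)]
}

#' @export
print.rc_qda <- function(x, ...) {
  cat(sprintf("<rc_qda> %d classes (%s), d = %d\n", length(x$classes),
              paste(x$classes, collapse = ", "), x$d))
  invisible(x)
}

#' QDA training-size sweep at one coring location
#'
#' Implements the study protocol: reserve a fixed random test set of
#' `n_test` systems per phenotype, then for each training size draw
#' `n_repeats` random training sets from the remainder, fit QDA, and record
#' the misclassification rate on the test set (mean and SE over repeats).
#' Rank-deficient locations abort with the fitting error unless
#' `on_rank_deficiency = "skip"`.
#'
#' @param features_by_class Named list (class label -> `[n x d]` matrix) of
#'   per-replicate feature vectors at the location; use two entries for the
#'   shallow-vs-deep variant, three for the full classification.
#' @param training_sizes Training-set sizes to sweep (study values
#'   8, 10, 15, 20, 25, 30, 35, 40, 45, 50).
#' @param n_test Test-set size per class (study value 50).
#' @param n_repeats Random training draws per size.
#' @param seed Seed for the test split and training draws.
#' @param location_id Metadata label.
#' @return An `rc_qda_sweep` data.frame: `training_size`,
#'   `misclassification`, `se`, `n_repeats`; or `NULL` with a warning when
#'   skipped for rank deficiency.
#' @export
qda_experiment <- function(features_by_class,
                           training_sizes = c(8, 10, 15, 20, 25, 30, 35, 40, 45, 50),
                           n_test = 50, n_repeats = 20, seed = NULL,
                           location_id = NA,
                           on_rank_deficiency = c("error", "skip")) {
  on_rank_deficiency <- match.arg(on_rank_deficiency)
  k <- length(features_by_class)
  stop_if(k < 2, "need >= 2 classes")
  ns <- vapply(features_by_class, nrow, 1L)
  stop_if(any(ns <= n_test), "n_test must leave a non-empty training pool")
  pool_n <- min(ns) - n_test
  stop_if(any(training_sizes > pool_n),
          sprintf("training size exceeds available pool (%d)", pool_n))
  run <- function() with_seed(seed, {
    test_idx <- lapply(features_by_class, function(m)
      sample.int(nrow(m), n_test))
    test_x <- do.call(rbind, Map(function(m, idx) m[idx, , drop = FALSE],
                                 features_by_class, test_idx))
    test_y <- rep(names(features_by_class), each = n_test)
    train_pool <- Map(function(m, idx) m[-idx, , drop = FALSE],
                      features_by_class, test_idx)
    rows <- lapply(training_sizes, function(sz) {
      errs <- vapply(seq_len(n_repeats), function(r) {
        tr <- lapply(train_pool, function(m)
          m[sample.int(nrow(m), sz), , drop = FALSE])
        x <- do.call(rbind, tr)
        y <- rep(names(train_pool), vapply(tr, nrow, 1L))
        model <- fit_qda(x, y, location_id = location_id)
        mean(suppressMessages(classify(model, test_x)) != test_y)
      }, numeric(1))
      data.frame(training_size = sz, misclassification = mean(errs),
                 se = stats::sd(errs) / sqrt(n_repeats),
                 n_repeats = n_repeats)
    })
    do.call(rbind, rows)
  })
  res <- if (on_rank_deficiency == "skip") {
    tryCatch(run(), error = function(e) {
      if (grepl("rank-deficient", conditionMessage(e))) {
        warning(sprintf("location %s skipped: %s", format(location_id),
                        conditionMessage(e)), call. = FALSE)
        NULL
      } else stop(e)
    })
  } else run()
  if (is.null(res)) return(NULL)
  structure(res, class = c("rc_qda_sweep", "data.frame"),
            location_id = location_id, n_test = n_test)
}
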