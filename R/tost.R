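#' Configuration for TOST equivalence testing
#'
#' The study declares two estimators equivalent when both one-sided t-tests
#' reject at `alpha`; the equivalence bounds themselves are a declared
#' convention here (the protocol reports only the alpha), defaulting to
#' +-20% of the reference mean per depth.
#'
#' @param margin_type `"relative"` (fraction of the reference mean) or
#'   `"absolute"` (cm cm^-3).
#' @param margin Positive margin value.
#' @param alpha Significance level (default 0.05).
#' @return An `rc_tost_config`.
#' @export
tost_config <- function(margin_type = c("relative", "absolute"),
                        margin = 0.2, alpha = 0.05) {
  margin_type <- match.arg(margin_type)
  stop_if(margin <= 0, "margin must be > 0")
  stop_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  structure(list(margin_type = margin_type, margin = margin, alpha = alpha),
            class = "rc_tost_config")
}

#' Two one-sided tests (TOST) of equivalence
#'
#' Welch-type two-sample TOST: tests whether the mean difference
#' `mean(sample_a) - mean(reference)` lies within `(-delta, +delta)`, where
#' `delta` is the absolute margin or `margin * mean(reference)` for a
#' relative margin.  The TOST p-value is the larger of the two one-sided
#' p-values; equivalence is declared iff `p < alpha`.  The reference is
#' treated as a replicate sample, not a constant.
#'
#' @param sample_a Numeric vector (n >= 2), the estimator's replicate values.
#' @param reference Numeric vector (n >= 2), the reference replicate values.
#' @param config An [tost_config()].
#' @return An `rc_tost`: `p_value`, `equivalent`, `bounds`, `diff`, the two
#'   one-sided p-values and the Welch degrees of freedom.
#' @export
tost_equivalence <- function(sample_a, reference, config = tost_config()) {
  stopifnot(inherits(config, "rc_tost_config"))
  stop_if(length(sample_a) < 2 || length(reference) < 2,
          "each sample needs n >= 2")
  delta <- if (config$margin_type == "relative")
    config$margin * abs(mean(reference)) else config$margin
  stop_if(delta <= 0, "equivalence margin is zero (reference mean is zero?)")
  d <- mean(sample_a) - mean(reference)
  va <- stats::var(sample_a) / length(sample_a)
  vr <- stats::var(reference) / length(reference)
  se <- sqrt(va + vr)
  if (se == 0) {
    if (d == 0) {
      return(structure(list(p_value = .Machine$double.eps, equivalent = TRUE,
                            bounds = c(-delta, delta), diff = 0,
                            p_lower = .Machine$double.eps,
                            p_upper = .Machine$double.eps, df = Inf,
                            alpha = config$alpha),
                       class = "rc_tost"))
    }
    stop("zero variance in both samples with unequal means: TOST undefined",
         call. = FALSE)
  }
  df <- se^4 / (va^2 / (length(sample_a) - 1) + vr^2 / (length(reference) - 1))
  t_lower <- (d + delta) / se            # H0: d <= -delta vs H1: d > -delta
  t_upper <- (d - delta) / se            # H0: d >= +delta vs H1: d < +delta
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df, lower.tail = TRUE)
  p <- max(p_lower, p_upper)
  structure(list(p_value = p, equivalent = p < config$alpha,
                 bounds = c(-delta, delta), diff = d,
                 p_lower = p_lower, p_upper = p_upper, df = df,
                 alpha = config$alpha),
            class = "rc_tost")
}

#' @export
print.rc_tost <- function(x, ...) {
  cat(sprintf("<rc_tost> diff %.4g in (%.4g, %.4g): p = %.4g -> %s\n",
              x$diff, x$bounds[1], x$bounds[2], x$p_value,
              if (x$equivalent) "equivalent" else "not equivalent"))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Standard F-test across groups followed by Tukey honest significant
#' differences; used by depth to ask which phenotypes differ in RLD.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2) or
#'   a data.frame with columns `value` and `group`.
#' @param alpha Significance level for the pairwise flags.
#' @return List with `f_statistic`, `p_value`, `df`, and `pairs` (data.frame:
#'   `pair`, `diff`, `p_adj`, `significant`).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    df <- data.frame(value = groups$value, group = factor(groups$group))
  } else {
    stop_if(length(groups) < 2, "need >= 2 groups")
    stop_if(any(vapply(groups, length, 1L) < 2), "each group needs n >= 2")
    nm <- names(groups) %||% as.character(seq_along(groups))
    df <- data.frame(value = unlist(groups, use.names = FALSE),
                     group = factor(rep(nm, vapply(groups, length, 1L))))
  }
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL)
  list(f_statistic = an[1, "F value"], p_value = an[1, "Pr(>F)"],
       df = c(an[1, "Df"], an[2, "Df"]), pairs = pairs)
}

#' Two-way phenotype-by-depth ANOVA with per-depth Tukey HSD
#'
#' Fits `rld ~ phenotype * depth` and then runs [anova_tukey()] within each
#' depth bin, the protocol used to confirm the simulated phenotypes differ by
#' depth.
#'
#' @param data Data frame with columns `rld`, `phenotype`, `depth`.
#' @param alpha Significance level.
#' @return List with `anova` (the two-way table as a data.frame) and
#'   `by_depth` (named list of [anova_tukey()] results).
#' @export
anova_tukey_by_depth <- function(data, alpha = 0.05) {
  stop_if(!all(c("rld", "phenotype", "depth") %in% names(data)),
          "data needs columns rld, phenotype, depth")
  d <- data.frame(rld = data$rld, phenotype = factor(data$phenotype),
                  depth = factor(data$depth))
  fit <- stats::aov(rld ~ phenotype * depth, data = d)
  an <- as.data.frame(summary(fit)[[1]])
  an$term <- trimws(rownames(an)); rownames(an) <- NULL
  by_depth <- lapply(split(d, d$depth), function(sub)
    anova_tukey(data.frame(value = sub$rld, group = sub$phenotype), alpha))
  list(anova = an, by_depth = by_depth)
}

# Vectorised balanced one-way F across many resamples: `mats` is a list (one
# per group) of [n x reps] matrices. Returns p-values per replicate.
oneway_p_vec <- function(mats) {
  k <- length(mats); n <- nrow(mats[[1]]); reps <- ncol(mats[[1]])
  gm <- vapply(mats, colMeans, numeric(reps))            # [reps x k]
  grand <- rowMeans(gm)
  ssb <- n * rowSums((gm - grand)^2)
  ssw <- Reduce(`+`, lapply(seq_len(k), function(g) {
    colSums((mats[[g]] - rep(gm[, g], each = n))^2)
  }))
  f <- (ssb / (k - 1)) / (ssw / (k * (n - 1)))
  p <- stats::pf(f, k - 1, k * (n - 1), lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1    # all values identical: no evidence
  p[ssw == 0 & ssb > 0] <- 0
  p
}

#' Resampling power analysis for a depth metric at one coring location
#'
#' For each sample size `n` in `n_range`, repeatedly draws (with replacement)
#' `n` cores per phenotype from the per-phenotype pools of depth-metric
#' values, runs a one-way ANOVA across the phenotypes, and records the
#' proportion of draws in which the ANOVA is significant at `alpha` —
#' the study's indicator of how reliably a location detects rooting-depth
#' differences (2000 replicates per size in full mode).
#'
#' @param dp_by_phenotype Named list of numeric vectors: the depth-metric
#'   (e.g. D50) values of every replicate core, per phenotype.  `NA` entries
#'   (cores with no recovered roots, for which the metric is undefined) are
#'   dropped from the pool; their count is recorded.
#' @param n_range Integer sample sizes (default 2:20).
#' @param reps Resampling replicates per size (default 2000).
#' @param alpha ANOVA significance level.
#' @param metric_p Percentile the values represent (metadata).
#' @param location_id Location label (metadata).
#' @return An `rc_power_curve`: data.frame `n`, `proportion_significant`,
#'   plus attributes `reps`, `alpha`, `n_dropped`.
#' @export
resampling_power <- function(dp_by_phenotype, n_range = 2:20, reps = 2000,
                             alpha = 0.05, metric_p = NA, location_id = NA) {
  stop_if(length(dp_by_phenotype) < 2, "need >= 2 phenotypes")
  n_dropped <- sum(vapply(dp_by_phenotype, function(v) sum(is.na(v)), 1L))
  pools <- lapply(dp_by_phenotype, function(v) v[!is.na(v)])
  stop_if(any(vapply(pools, length, 1L) < 2),
          "each phenotype pool needs >= 2 defined metric values")
  prop <- vapply(n_range, function(n) {
    mats <- lapply(pools, function(pool)
      matrix(pool[sample.int(length(pool), n * reps, replace = TRUE)],
             n, reps))
    mean(oneway_p_vec(mats) < alpha)
  }, numeric(1))
  structure(data.frame(n = n_range, proportion_significant = prop),
            class = c("rc_power_curve", "data.frame"),
            reps = reps, alpha = alpha, metric_p = metric_p,
            location_id = location_id, n_dropped = n_dropped)
}
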