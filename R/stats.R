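#' Brunner-Munzel generalized Wilcoxon test
#'
#' Two-sample rank test of the stochastic-dominance parameter
#' \eqn{p = P(X < Y) + \tfrac12 P(X = Y)} against \eqn{p = 1/2}. Unlike
#' the Mann-Whitney U test it assumes neither equal variances nor a pure
#' location shift, which suits highly heterogeneous indoor-air data.
#' Midranks handle ties; the studentised statistic is referred to a t
#' distribution with Satterthwaite-type degrees of freedom, or (with
#' `method = "permutation"`) to the permutation distribution of the same
#' statistic, enumerated exhaustively when the number of group
#' assignments is small enough and sampled otherwise.
#'
#' @param x,y Numeric samples (>= 2 values each).
#' @param alpha Significance level recorded on the result.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm Resamples when sampling the permutation distribution;
#'   exact enumeration is used when `choose(n, nx) <= exact_limit`.
#' @param exact_limit Enumeration cutoff for the exact permutation null.
#' @param seed Seed for sampled permutations.
#' @return An object of class `ivoc_test`: list with `test_name`,
#'   `statistic`, `df`, `p_raw`, `effect` (the relative effect
#'   \eqn{\hat p}), `groups`, `alpha`, `method`.
#' @examples
#' brunner_munzel(rnorm(12), rnorm(12, 1))
#' @export
brunner_munzel <- function(x, y, alpha = 0.05,
                           method = c("t", "permutation"),
                           n_perm = 10000, exact_limit = 40000,
                           seed = 1L) {
  method <- match.arg(method)
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least two values per group", call. = FALSE)
  if (length(unique(c(x, y))) == 1L)
    stop("degenerate input: all values tied across both groups",
         call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2

  bm_stat <- function(x, y) {
    n1 <- length(x); n2 <- length(y); N <- n1 + n2
    r <- rank(c(x, y))
    r1 <- r[seq_len(n1)]; r2 <- r[n1 + seq_len(n2)]
    m1 <- mean(r1); m2 <- mean(r2)
    v1 <- sum((r1 - rank(x) - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
    v2 <- sum((r2 - rank(y) - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
    sig <- n1 * v1 + n2 * v2
    stat <- if (sig > 0) n1 * n2 * (m2 - m1) / (N * sqrt(sig))
    else if (m2 == m1) 0 else sign(m2 - m1) * Inf
    list(stat = stat, v1 = v1, v2 = v2,
         effect = (m2 - (n2 + 1) / 2) / n1)
  }

  obs <- bm_stat(x, y)
  if (method == "t") {
    sig1 <- n1 * obs$v1; sig2 <- n2 * obs$v2
    df <- if (sig1 + sig2 > 0)
      (sig1 + sig2)^2 / (sig1^2 / (n1 - 1) + sig2^2 / (n2 - 1)) else NA_real_
    p <- if (is.finite(obs$stat) && !is.na(df))
      2 * stats::pt(-abs(obs$stat), df) else 0
  } else {
    df <- NA_real_
    pool <- c(x, y)
    n_comb <- choose(N, n1)
    stat_of_split <- function(idx) bm_stat(pool[idx], pool[-idx])$stat
    if (n_comb <= exact_limit) {
      splits <- utils::combn(N, n1)
      perm <- apply(splits, 2L, stat_of_split)
    } else {
      old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv()))
      set.seed(seed)
      perm <- vapply(seq_len(n_perm),
                     function(i) stat_of_split(sample.int(N, n1)),
                     numeric(1))
    }
    p <- mean(abs(perm) >= abs(obs$stat) - 1e-12)
  }
  structure(list(test_name = "Brunner-Munzel", statistic = obs$stat,
                 df = df, p_raw = p, effect = obs$effect,
                 groups = c(deparse(substitute(x)), deparse(substitute(y))),
                 alpha = alpha, method = method),
            class = "ivoc_test")
}

#' @export
print.ivoc_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g", x$test_name, x$statistic))
  if (!is.null(x$df) && !is.na(x$df)) cat(sprintf(", df = %.2f", x$df))
  cat(sprintf(", p = %.4g\n", x$p_raw))
  if (!is.null(x$effect))
    cat(sprintf("  relative effect P(X<Y)+0.5*P(X=Y) = %.4f\n", x$effect))
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Ties-corrected H statistic on midranks with a chi-squared reference
#' (k - 1 degrees of freedom), computed via `stats::kruskal.test()`
#' behind this module's result contract.
#'
#' @param groups List (>= 2) of non-empty numeric samples, optionally
#'   named.
#' @return An `ivoc_test`: `statistic` (H), `df`, `p_raw`, `groups`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) == 0L))
    stop("all groups must be non-empty", call. = FALSE)
  if (length(unique(unlist(groups))) == 1L)
    return(structure(list(test_name = "Kruskal-Wallis", statistic = 0,
                          df = length(groups) - 1L, p_raw = 1,
                          effect = NULL,
                          groups = names(groups) %||%
                            as.character(seq_along(groups)),
                          alpha = 0.05, method = "chi-squared"),
                     class = "ivoc_test"))
  kt <- stats::kruskal.test(groups)
  structure(list(test_name = "Kruskal-Wallis",
                 statistic = unname(kt$statistic),
                 df = unname(kt$parameter), p_raw = kt$p.value,
                 effect = NULL,
                 groups = names(groups) %||% as.character(seq_along(groups)),
                 alpha = 0.05, method = "chi-squared"),
            class = "ivoc_test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dunn post hoc pairwise comparisons
#'
#' All pairwise z statistics from the pooled midranks with the usual tie
#' correction,
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12(N-1)}\right)
#'   \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}}
#' with two-sided normal p-values adjusted for multiple comparisons
#' (Holm by default). Intended as the follow-up to a significant
#' [kruskal_wallis()] test.
#'
#' @param groups Named list (>= 2) of numeric samples.
#' @param adjust Adjustment method for [stats::p.adjust()].
#' @return Data frame: `group1`, `group2`, `mean_rank_diff`, `z`,
#'   `p_raw`, `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, adjust = "holm") {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) == 0L))
    stop("all groups must be non-empty", call. = FALSE)
  k <- length(groups)
  labels <- names(groups) %||% as.character(seq_len(k))
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  g <- rep(seq_len(k), vapply(groups, length, 1L))
  rbar <- tapply(r, g, mean)
  n <- tabulate(g, k)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term

  pairs <- utils::combn(k, 2L)
  z <- numeric(ncol(pairs)); dif <- numeric(ncol(pairs))
  for (m in seq_len(ncol(pairs))) {
    i <- pairs[1L, m]; j <- pairs[2L, m]
    dif[m] <- rbar[i] - rbar[j]
    z[m] <- dif[m] / sqrt(var_base * (1 / n[i] + 1 / n[j]))
  }
  p_raw <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = labels[pairs[1L, ]], group2 = labels[pairs[2L, ]],
             mean_rank_diff = dif, z = z, p_raw = p_raw,
             p_adjusted = stats::p.adjust(p_raw, method = adjust))
}

#' Holm step-down multiple-testing adjustment
#'
#' Family-wise-error-controlling step-down adjustment (via
#' `stats::p.adjust`); output order matches input order, adjusted values
#' are never below the raw ones and are capped at 1.
#'
#' @param p_values Probabilities in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' holm_adjust(c(0.01, 0.04))
#' @export
holm_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(is.na(p_values)) ||
      any(p_values < 0) || any(p_values > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "holm")
}

#' Bootstrap percentile confidence interval
#'
#' Percentile CI of an arbitrary statistic over seeded with-replacement
#' resamples (default 1000). Deterministic given the seed; the caller's
#' RNG state is left untouched.
#'
#' @param values Numeric sample (>= 1 value).
#' @param statistic Function of a numeric vector returning a scalar.
#' @param n_resamples Number of resamples (>= 1).
#' @param seed Integer seed (required for reproducibility).
#' @param conf Confidence level (default 0.95).
#' @return An object of class `bootstrap_ci`: list with `point` (the
#'   statistic on the original sample), `lower`, `upper`, `n_resamples`,
#'   `seed`, `conf`.
#' @examples
#' bootstrap_ci(rnorm(50), mean, seed = 7)
#' @export
bootstrap_ci <- function(values, statistic = mean, n_resamples = 1000,
                         seed = 1L, conf = 0.95) {
  if (length(values) < 1L) stop("empty sample", call. = FALSE)
  if (n_resamples < 1L) stop("'n_resamples' must be >= 1", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  n <- length(values)
  idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE), nrow = n)
  reps <- vapply(seq_len(n_resamples),
                 function(b) statistic(values[idx[, b]]), numeric(1))
  qs <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  structure(list(point = statistic(values), lower = qs[1], upper = qs[2],
                 n_resamples = n_resamples, seed = seed, conf = conf),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("point %.4g, %g%% percentile bootstrap CI [%.4g, %.4g] (%d resamples, seed %d)\n",
              x$point, 100 * x$conf, x$lower, x$upper, x$n_resamples,
              x$seed))
  invisible(x)
}

#' Boxplot percentile summary
#'
#' The study's boxplot convention: 5th, 25th, 50th, 75th and 95th
#' percentiles (linear interpolation between order statistics, R quantile
#' type 7), with values outside the 5-95 band reported as outliers.
#'
#' @param values Non-empty numeric sample.
#' @return List with `percentiles` (named `p5`, `p25`, `p50`, `p75`,
#'   `p95`), `lower_outliers` and `upper_outliers`.
#' @export
boxplot_summary <- function(values) {
  if (length(values) == 0L) stop("empty sample", call. = FALSE)
  q <- stats::quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95),
                       names = FALSE, type = 7)
  names(q) <- c("p5", "p25", "p50", "p75", "p95")
  list(percentiles = q,
       lower_outliers = values[values < q["p5"]],
       upper_outliers = values[values > q["p95"]])
}

#' Grouped comparison runner for tidy tables
#'
#' Applies the study's comparison logic to one value column of a tidy
#' table: Brunner-Munzel for a binary grouping, Kruskal-Wallis plus Dunn
#' post hoc for more levels, with Holm adjustment.
#'
#' @param data Data frame.
#' @param value Name of the numeric value column.
#' @param group Name of the grouping column.
#' @param alpha Significance level.
#' @return List with `omnibus` (an `ivoc_test`) and, for > 2 groups,
#'   `pairwise` (the Dunn table).
#' @export
compare_groups <- function(data, value, group, alpha = 0.05) {
  stopifnot(is.data.frame(data), all(c(value, group) %in% names(data)))
  groups <- split(data[[value]], data[[group]])
  groups <- groups[vapply(groups, length, 1L) > 0L]
  if (length(groups) < 2L)
    stop("need at least two non-empty groups", call. = FALSE)
  if (length(groups) == 2L) {
    res <- brunner_munzel(groups[[1L]], groups[[2L]], alpha = alpha)
    res$groups <- names(groups)
    list(omnibus = res, pairwise = NULL)
  } else {
    list(omnibus = kruskal_wallis(groups),
         pairwise = dunn_posthoc(groups, adjust = "holm"))
  }
}
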