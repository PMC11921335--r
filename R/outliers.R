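#' Modified Z-scores on the log scale
#'
#' Robust outlier statistic for right-skewed concentration data: values
#' are log-transformed, and each is scored as
#' \deqn{mz_i = 0.6745\,\frac{\log x_i - \mathrm{median}(\log x)}{\mathrm{MAD}(\log x)}}
#' where MAD is the (unscaled) median absolute deviation from the median.
#' The 0.6745 factor puts the score on the scale of an ordinary Z-score
#' for normal data. The base of the logarithm is immaterial: a base change
#' rescales numerator and MAD equally.
#'
#' @param values Strictly positive concentrations (>= 2 values).
#' @param log_base Base of the log transform (default natural log);
#'   provided only to make the invariance checkable.
#' @return Numeric vector of scores, one per input, in input order.
#' @examples
#' modified_z_scores(exp(0:4))
#' @export
modified_z_scores <- function(values, log_base = exp(1)) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("need at least two numeric values", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("all values must be finite and > 0 (log transform)", call. = FALSE)
  lx <- log(values, base = log_base)
  med <- stats::median(lx)
  mad0 <- stats::median(abs(lx - med))
  if (mad0 == 0)
    stop("MAD is zero: at least half the group is identical, modified ",
         "Z-scores are degenerate", call. = FALSE)
  0.6745 * (lx - med) / mad0
}

#' Treat episodic concentration outliers
#'
#' Single-pass filter for episodic high outliers (e.g. painting-driven
#' aromatic bursts): values whose log-scale modified Z-score exceeds
#' `threshold` are removed; retained values are returned unchanged (the
#' exponential back-transform is the exact inverse of the log transform).
#' The filter is one-sided high by default; set `two_sided = TRUE` to also
#' remove scores below `-threshold`.
#'
#' @inheritParams modified_z_scores
#' @param threshold Score above which a value is an outlier (default 3.5).
#' @param two_sided Also flag scores below `-threshold`? Default `FALSE`.
#' @return An object of class `outlier_report`: list with `values_in`,
#'   `scores`, `flagged` (indices removed), `values_out` (retained
#'   concentrations), `group_median` and `mad` (both on the log scale),
#'   `threshold`, `two_sided`.
#' @examples
#' rep <- treat_outliers(exp(c(0:4, 100)))
#' rep$flagged
#' @export
treat_outliers <- function(values, threshold = 3.5, two_sided = FALSE) {
  scores <- modified_z_scores(values)
  flagged <- which(scores > threshold |
                     (two_sided & scores < -threshold))
  lx <- log(values)
  structure(list(values_in = values, scores = scores, flagged = flagged,
                 values_out = if (length(flagged)) values[-flagged] else values,
                 group_median = stats::median(lx),
                 mad = stats::median(abs(lx - stats::median(lx))),
                 threshold = threshold, two_sided = two_sided),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Modified Z-score outlier report: %d values, %d flagged (> %s%.1f)\n",
              length(x$values_in), length(x$flagged),
              if (x$two_sided) "|" else "", x$threshold))
  if (length(x$flagged))
    cat("  flagged indices:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Grouped outlier treatment over a tidy concentration table
#'
#' Applies [treat_outliers()] per VOC to the indoor concentrations of a
#' tidy table, over a configurable scope (default: the aromatic BTEX and
#' trimethylbenzene species, where episodic painting bursts occur).
#' Out-of-scope VOCs pass through untouched.
#'
#' @param conc Data frame with columns `home_id`, `voc` and `indoor`.
#' @param scope Character vector of VOC names to treat; default the
#'   `aromatics` class.
#' @param threshold,two_sided Passed to [treat_outliers()].
#' @return List with `treated` (the table minus flagged rows) and
#'   `removed` (flagged rows with columns `voc`, `home_id`, `indoor`,
#'   `score`).
#' @export
treat_outliers_by_voc <- function(conc, scope = voc_classes()$aromatics,
                                  threshold = 3.5, two_sided = FALSE) {
  stopifnot(is.data.frame(conc),
            all(c("home_id", "voc", "indoor") %in% names(conc)))
  drop <- integer()
  removed <- list()
  for (v in intersect(scope, unique(conc$voc))) {
    idx <- which(conc$voc == v)
    if (length(idx) < 2L) next
    rep <- treat_outliers(conc$indoor[idx], threshold = threshold,
                          two_sided = two_sided)
    if (length(rep$flagged)) {
      hit <- idx[rep$flagged]
      drop <- c(drop, hit)
      removed[[v]] <- data.frame(voc = v, home_id = conc$home_id[hit],
                                 indoor = conc$indoor[hit],
                                 score = rep$scores[rep$flagged])
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed)
  else data.frame(voc = character(), home_id = character(),
                  indoor = numeric(), score = numeric())
  rownames(removed) <- NULL
  treated <- if (length(drop)) conc[-drop, ] else conc
  rownames(treated) <- NULL
  list(treated = treated, removed = removed)
}
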