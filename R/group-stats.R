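#' @include AllClasses.R
NULL

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided rank-sum test of a location difference between two samples.
#' The statistic U counts pairs where x exceeds y, with half credit for
#' ties. The p-value is exact (from the null U distribution) when
#' `n1 * n2 <= exactMax` and there are no ties; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' When every value in both samples is identical, p = 1.
#'
#' @param x,y numeric samples (each non-empty; NAs dropped).
#' @param exactMax exact-p switch point on `n1 * n2` (default 400).
#' @return list with `u`, `p`, `n1`, `n2`, `exact`.
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))$p  # 1/3
#' @export
wilcoxonRankSum <- function(x, y, exactMax = 400L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  hasTies <- any(ties > 1)
  if (!hasTies && n1 * n2 <= exactMax) {
    ## exact two-sided p from the null distribution of U
    p <- min(1, 2 * min(stats::pwilcox(u, n1, n2),
                        1 - stats::pwilcox(u - 1, n1, n2)))
    return(list(u = u, p = p, n1 = n1, n2 = n2, exact = TRUE))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(u = u, p = 1, n1 = n1, n2 = n2, exact = FALSE))
  z <- u - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(u = u, p = p, n1 = n1, n2 = n2, exact = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR q-values: sort p ascending, `q_(i) = min_{j >= i} p_(j) m/j`,
#' restored to the input order. Delegates to [stats::p.adjust()] (method
#' "BH"), which implements exactly this procedure.
#'
#' @param p vector of p-values in [0, 1].
#' @return vector of q-values, same order as `p`.
#' @examples
#' bhFdr(c(0.002, 0.01, 0.03, 0.04))  # 0.008 0.020 0.040 0.040
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cliff's delta effect size
#'
#' Nonparametric effect size
#' `delta = (#(x_i > y_j) - #(x_i < y_j)) / (n1 n2)` in [-1, 1]: 0 means the
#' distributions overlap completely, +1/-1 means no overlap. Ties contribute
#' zero. Magnitude labels follow the conventional thresholds
#' |d| < 0.147 negligible, < 0.33 small, < 0.474 medium, else large.
#'
#' @param x,y numeric samples (NAs dropped).
#' @return list with `delta` and `magnitude`.
#' @examples
#' cliffsDelta(c(4, 5, 6), c(1, 2, 3))  # delta 1, "large"
#' @export
cliffsDelta <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  delta <- mean(sign(outer(x, y, "-")))
  list(delta = delta, magnitude = deltaMagnitude(delta))
}

#' @rdname cliffsDelta
#' @param delta a Cliff's delta value.
#' @export
deltaMagnitude <- function(delta) {
  a <- abs(delta)
  if (a < 0.147) "negligible"
  else if (a < 0.33) "small"
  else if (a < 0.474) "medium"
  else "large"
}

#' Two-group comparison battery over a feature table
#'
#' For each feature column, compares the two groups with medians, the
#' Wilcoxon rank-sum test and Cliff's delta; q-values are BH-adjusted
#' jointly across the whole battery (the set of features in this call).
#' Rows with a missing feature value are dropped per feature and the
#' remaining group sizes reported. Output is sorted by q.
#'
#' @param featureTable data.frame holding the feature columns and a group
#'   column.
#' @param features character vector of feature column names to compare.
#' @param groupCol name of the group column (default "group").
#' @param groups length-2 character: which level is group 1 and group 2
#'   (default `c("Common BE", "Other")`).
#' @return data.frame with columns `feature n1 n2 median1 median2 U p q
#'   delta magnitude`, sorted by q.
#' @export
compareGroups <- function(featureTable, features,
                          groupCol = "group",
                          groups = c("Common BE", "Other")) {
  stopifnot(all(features %in% names(featureTable)),
            groupCol %in% names(featureTable))
  g <- featureTable[[groupCol]]
  rows <- lapply(features, function(f) {
    v <- featureTable[[f]]
    x <- v[g == groups[1] & !is.na(v)]
    y <- v[g == groups[2] & !is.na(v)]
    if (length(x) < 2 || length(y) < 2)
      stop("feature '", f, "' has fewer than 2 observations in a group")
    wt <- wilcoxonRankSum(x, y)
    cd <- cliffsDelta(x, y)
    data.frame(feature = f, n1 = length(x), n2 = length(y),
               median1 = stats::median(x), median2 = stats::median(y),
               U = wt$u, p = wt$p, q = NA_real_, delta = cd$delta,
               magnitude = cd$magnitude, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bhFdr(out$p)
  out[order(out$q, out$p), , drop = FALSE]
}
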