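# Group-level summaries and nonparametric genotype comparisons.

#' Summarise one metric within a genotype group
#'
#' Cells lacking the metric (NA, e.g. no second peak) are excluded from the
#' moment statistics but counted in the denominator of
#' `fraction_with_metric` (reported in percent, as in "a second peak was
#' observed in 96% of WT").
#'
#' @param metrics data.frame from [metrics_table()] (one genotype, or use
#'   `genotype` to filter).
#' @param metric column name to summarise.
#' @param genotype optional genotype filter.
#' @return one-row data.frame: genotype, metric, n (cells with the metric),
#'   mean, sd, median, min, max, fraction_with_metric (percent).
#' @export
summarize_group <- function(metrics, metric, genotype = NULL) {
  if (!metric %in% names(metrics)) stop("unknown metric: ", metric)
  if (!is.null(genotype)) metrics <- metrics[metrics$genotype == genotype, ]
  if (!nrow(metrics)) stop("no cells in group")
  g <- if (is.null(genotype)) paste(unique(metrics$genotype), collapse = "+")
       else genotype
  x <- metrics[[metric]]
  ok <- x[!is.na(x)]
  n <- length(ok)
  data.frame(genotype = g, metric = metric, n = n,
             mean = if (n) mean(ok) else NA_real_,
             sd = if (n > 1) stats::sd(ok) else if (n == 1) 0 else NA_real_,
             median = if (n) stats::median(ok) else NA_real_,
             min = if (n) min(ok) else NA_real_,
             max = if (n) max(ok) else NA_real_,
             fraction_with_metric = 100 * n / nrow(metrics),
             stringsAsFactors = FALSE)
}

#' Kruskal-Wallis omnibus test with Dunn's multiple-comparison post hoc
#'
#' The omnibus H statistic and p-value come from the rank-based
#' Kruskal-Wallis test on pooled mid-ranks with tie correction. Pairwise
#' comparisons use Dunn's z on mean-rank differences,
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) \Big/
#'   \sqrt{\Big(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12(N-1)}\Big)
#'   \Big(\frac{1}{n_i} + \frac{1}{n_j}\Big)}}
#' with two-sided normal p-values adjusted over all unordered pairs
#' (Bonferroni by default, matching the usual Dunn's-multiple-comparison
#' convention; Holm optional). NA values are dropped per group.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 1).
#' @param p_adjust `"bonferroni"` (default) or `"holm"`.
#' @param alpha significance level used for the `significant` flag.
#' @return list of class `kw_dunn`: `H`, `df`, `p_value`, `n`, and
#'   `pairwise`, a data.frame over all unordered pairs with z, unadjusted
#'   and adjusted p, significance stars and flag.
#' @export
kruskal_wallis_dunn <- function(groups, p_adjust = c("bonferroni", "holm"),
                                alpha = 0.05) {
  p_adjust <- match.arg(p_adjust)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2) stop("need at least two groups")
  if (any(!vapply(groups, length, integer(1))))
    stop("every group needs at least one value")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  N <- length(x)
  if (length(unique(x)) == 1) {
    H <- 0; p <- 1
  } else {
    kw <- stats::kruskal.test(x, g)
    H <- unname(kw$statistic); p <- kw$p.value
  }
  r <- rank(x)  # mid-ranks
  mean_rank <- tapply(r, g, mean)
  n_g <- tabulate(g)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  var_base <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  z <- p_unadj <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(var_base * (1 / n_g[match(i, names(groups))] +
                           1 / n_g[match(j, names(groups))]))
    z[k] <- if (se > 0) (mean_rank[[i]] - mean_rank[[j]]) / se else 0
    p_unadj[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  p_adj <- stats::p.adjust(p_unadj, method = p_adjust)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   z = z, p_unadj = p_unadj, p_adj = p_adj,
                   stars = significance_stars(p_adj),
                   significant = p_adj < alpha,
                   stringsAsFactors = FALSE)
  structure(list(H = H, df = length(groups) - 1, p_value = p,
                 n = N, pairwise = pw, p_adjust = p_adjust),
            class = "kw_dunn")
}

#' @export
print.kw_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (n = %d)\n",
              x$H, x$df, x$p_value, x$n))
  cat("Dunn pairwise (", x$p_adjust, "-adjusted):\n", sep = "")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Significance stars using the reporting convention of the study
#' (`***` p < 0.0001, `**` p < 0.01, `*` p < 0.05, `ns` otherwise)
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
significance_stars <- function(p) {
  ifelse(p < 1e-4, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}
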