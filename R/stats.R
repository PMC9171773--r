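#' Two-sided Wilcoxon rank sum test
#'
#' Rank-sum test with midranks for ties. When both samples have at most 10
#' observations and the pooled data are tie-free, the exact two-sided
#' p-value is computed by enumerating all `choose(n1 + n2, n1)` rank
#' assignments; otherwise the normal approximation with tie correction and
#' a 0.5 continuity correction is used. The method actually used is
#' reported so analyses can log it.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_max Largest per-group size for exact enumeration
#'   (default 10).
#' @return List: `statistic` (rank sum of `x`, `W` form `statistic - n1*(n1+1)/2`),
#'   `p_value`, `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)  # midranks
  W1 <- sum(rk[seq_len(n1)])
  ties <- any(duplicated(pooled))
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(n, n1)
    sums <- colSums(matrix(seq_len(n)[combs], nrow = n1))
    # two-sided: double the smaller tail (distribution is symmetric)
    p <- 2 * min(mean(sums <= W1), mean(sums >= W1))
    p <- min(p, 1)
    method <- "exact"
  } else {
    mu <- n1 * (n + 1) / 2
    tie_tab <- table(pooled)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_corr)
    zn <- W1 - mu
    z <- (zn - sign(zn) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(statistic = W1 - n1 * (n1 + 1) / 2, rank_sum = W1,
       p_value = p, method = method)
}

#' Benjamini-Hochberg step-up correction
#'
#' Standard BH step-up at the given false discovery rate: order the m
#' p-values, find the largest i with `p(i) <= i/m * fdr`, and reject all
#' hypotheses up to it. Returns both the rejection flags (monotone:
#' rejecting a p-value implies rejecting every smaller one) and the
#' BH-adjusted p-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param fdr Target false discovery rate in (0, 1) (default 0.1).
#' @return List: `reject` (logical, original order), `adjusted`.
#' @export
bh_adjust <- function(p, fdr = 0.1) {
  stopifnot(all(p >= 0 & p <= 1), fdr > 0, fdr < 1)
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- rev(cummin(rev(ranked * m / seq_len(m))))
  adj <- pmin(adj, 1)
  adjusted <- numeric(m)
  adjusted[o] <- adj
  pass <- ranked <= seq_len(m) / m * fdr
  k <- if (any(pass)) max(which(pass)) else 0L
  reject <- logical(m)
  if (k > 0L) reject[o[seq_len(k)]] <- TRUE
  list(reject = reject, adjusted = adjusted)
}

#' Box-plot summary with IQR outlier fences
#'
#' Median and quartiles by linear interpolation (type-7 quantiles);
#' outliers are points beyond `Q1 - 1.5 IQR` or `Q3 + 1.5 IQR`; whiskers
#' extend to the extreme non-outlier values.
#'
#' @param values Non-empty numeric vector.
#' @param coef Fence multiplier (default 1.5).
#' @return List: `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
box_summary <- function(values, coef = 1.5) {
  stopifnot(length(values) >= 1L)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3L] - q[1L]
  lo <- q[1L] - coef * iqr; hi <- q[3L] + coef * iqr
  out <- values[values < lo | values > hi]
  inliers <- values[values >= lo & values <= hi]
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       whisker_low = min(inliers), whisker_high = max(inliers),
       outliers = out)
}

#' Absolute per-family abundance from totals and proportions
#'
#' Multiplies each sample's absolute total 16S copy number (per unit mass
#' of feces) by the per-family proportions from sequencing. Proportions may
#' sum to less than 1; the remainder is an "Other" bucket. For logarithmic
#' display a companion column substitutes zeros with one; raw zeros are
#' preserved in the data.
#'
#' @param table data.frame with `sample_id`, `total`, and one proportion
#'   column per family (`prop_<family>`).
#' @return Long data.frame: `sample_id`, `family`, `abundance`,
#'   `log_display` (`log10` of abundance with zeros -> 1).
#' @export
absolute_family_abundance <- function(table) {
  stopifnot(all(table$total >= 0))
  prop_cols <- grep("^prop_", names(table), value = TRUE)
  fams <- sub("^prop_", "", prop_cols)
  props <- as.matrix(table[, prop_cols, drop = FALSE])
  if (any(props < 0 | props > 1)) stop("proportions must be in [0, 1]")
  sums <- rowSums(props)
  if (any(sums > 1 + 1e-9)) {
    stop("family proportions sum to more than 1 in sample(s): ",
         paste(table$sample_id[sums > 1 + 1e-9], collapse = ", "))
  }
  other <- pmax(0, 1 - sums)
  long <- do.call(rbind, lapply(seq_len(nrow(table)), function(i) {
    ab <- c(table$total[i] * props[i, ], Other = table$total[i] * other[i])
    data.frame(sample_id = table$sample_id[i],
               family = c(fams, "Other"), abundance = unname(ab))
  }))
  long$log_display <- log10(ifelse(long$abundance == 0, 1, long$abundance))
  rownames(long) <- NULL
  long
}

#' Group comparison of a metric between two conditions
#'
#' Convenience wrapper producing the comparison record used for
#' condition-versus-condition summaries: Wilcoxon rank sum p-value, group
#' medians and their ratio.
#'
#' @param values Numeric vector.
#' @param groups Two-level factor/character of the same length.
#' @param metric Name recorded in the output.
#' @return One-row data.frame (`metric`, `group1`, `group2`, `n1`, `n2`,
#'   `median1`, `median2`, `median_ratio`, `p_value`, `method`).
#' @export
group_comparison <- function(values, groups, metric = "metric") {
  g <- unique(groups)
  stopifnot(length(g) == 2L)
  x <- values[groups == g[1L]]; y <- values[groups == g[2L]]
  wt <- wilcoxon_rank_sum(x, y)
  data.frame(metric = metric, group1 = g[1L], group2 = g[2L],
             n1 = length(x), n2 = length(y),
             median1 = stats::median(x), median2 = stats::median(y),
             median_ratio = stats::median(y) / stats::median(x),
             p_value = wt$p_value, method = wt$method)
}
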