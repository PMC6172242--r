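#' Paired two-tailed t-test on accessibility replicates
#'
#' Standard paired t on the differences `a - b` with `n - 1` degrees of
#' freedom (closed form; cross-checked against [stats::t.test()] in the test
#' suite). Degenerate cases are defined rather than errors: zero variance of
#' the differences gives `t = 0, p = 1` when the mean difference is zero, and
#' `p = 0` (flagged `degenerate`) when it is not.
#'
#' @param a,b paired replicate vectors of equal length `n >= 2`.
#' @return list `t`, `dof`, `p`, `diff` (mean of a - b), `degenerate`.
#' @export
#' @examples
#' paired_t_test(c(0.1, 0.2, 0.3), c(0, 0, 0))  # t = 3.4641, dof 2, p ~ 0.0742
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2L) stop("need at least 2 complete pairs")
  d <- a - b
  m <- mean(d); s <- sd(d)
  dof <- n - 1L
  if (s == 0) {
    if (m == 0) return(list(t = 0, dof = dof, p = 1, diff = 0, degenerate = TRUE))
    return(list(t = sign(m) * Inf, dof = dof, p = 0, diff = m, degenerate = TRUE))
  }
  t <- m / (s / sqrt(n))
  list(t = t, dof = dof, p = 2 * pt(-abs(t), dof), diff = m, degenerate = FALSE)
}

#' Region-wise strain comparison table
#'
#' Runs [paired_t_test()] for every region shared between two strains'
#' replicate accessibility matrices.
#'
#' @param a,b matrices of normalized accessibilities (regions x replicates),
#'   same rownames (region ids).
#' @param taRNA_id optional per-region sRNA labels (recycled).
#' @return data.frame `region`, `taRNA_id`, `diff` (mean a - b), `t`, `dof`,
#'   `p`, `degenerate`.
#' @export
compare_strains <- function(a, b, taRNA_id = NA_character_) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    common <- intersect(rownames(a), rownames(b))
    a <- a[common, , drop = FALSE]; b <- b[common, , drop = FALSE]
  } else if (nrow(a) != nrow(b)) stop("strain matrices must share regions")
  res <- lapply(seq_len(nrow(a)), function(i) paired_t_test(a[i, ], b[i, ]))
  data.frame(region = rownames(a) %||% seq_len(nrow(a)),
             taRNA_id = rep_len(taRNA_id, nrow(a)),
             diff = vapply(res, `[[`, 0, "diff"),
             t = vapply(res, `[[`, 0, "t"),
             dof = vapply(res, `[[`, 0L, "dof"),
             p = vapply(res, `[[`, 0, "p"),
             degenerate = vapply(res, `[[`, TRUE, "degenerate"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Classify chaperone (Hfq) dependency of an sRNA
#'
#' An sRNA is called Hfq-dependent when any of its regions shows a
#' significant accessibility difference between the parent and the hfq-null
#' strain — strictly `p < alpha` (a region at exactly `alpha` does not
#' count). With no testable regions the call is `"unclassified"`.
#'
#' @param p per-region p-values for one sRNA (NAs are not testable).
#' @param alpha significance level (default 0.05).
#' @return `"dependent"`, `"independent"` or `"unclassified"`.
#' @export
classify_hfq <- function(p, alpha = 0.05) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) return("unclassified")
  if (any(p < alpha)) "dependent" else "independent"
}

#' N-1 chi-squared test of extreme-accessibility proportions
#'
#' Classifies each accessibility value as "extreme" when strictly below `lo`
#' or strictly above `hi` (defaults 0.125/0.875: the top quarter of the 0-1
#' scale at each end), forms the 2x2 group-by-extreme table, and tests equal
#' proportions with the N-1 chi-squared statistic: the Pearson chi-squared
#' multiplied by `(N - 1)/N`, referred to a 1-dof chi-squared distribution.
#'
#' @param group1,group2 accessibility vectors for the two groups.
#' @param lo,hi extremeness thresholds (strict inequalities).
#' @return list `chisq` (N-1 statistic), `pearson`, `p`, `table`,
#'   `proportions` (share of extremes per group).
#' @export
#' @examples
#' # table 8/2 vs 2/8: Pearson 7.2, N-1 variant 7.2 * 19/20 = 6.84
n1_chi2_extremes <- function(group1, group2, lo = 0.125, hi = 0.875) {
  if (length(group1) == 0L || length(group2) == 0L)
    stop("both groups must be non-empty")
  ex1 <- group1 < lo | group1 > hi
  ex2 <- group2 < lo | group2 > hi
  tab <- rbind(group1 = c(extreme = sum(ex1), other = sum(!ex1)),
               group2 = c(extreme = sum(ex2), other = sum(!ex2)))
  N <- sum(tab)
  if (any(colSums(tab) == 0L) || any(rowSums(tab) == 0L)) {
    warning("empty margin; test undefined")
    return(list(chisq = NA_real_, pearson = NA_real_, p = NA_real_,
                table = tab, proportions = c(mean(ex1), mean(ex2))))
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  pearson <- N * (a * d - b * c)^2 /
    (as.numeric(a + b) * (c + d) * (a + c) * (b + d))
  chisq <- pearson * (N - 1) / N
  list(chisq = chisq, pearson = pearson,
       p = pchisq(chisq, df = 1, lower.tail = FALSE),
       table = tab, proportions = c(mean(ex1), mean(ex2)))
}

#' Skew summary of significant accessibility differences
#'
#' Descriptive summary of the parent-minus-mutant accessibility differences
#' among significant regions: a positive skew indicates the chaperone
#' increases hybridization accessibility overall.
#'
#' @param diffs differences (parent - hfq-null) of significant regions.
#' @return list `n`, `mean`, `median`, `share_positive` (empty input gives
#'   `n = 0` and NAs).
#' @export
diff_skew <- function(diffs) {
  diffs <- diffs[!is.na(diffs)]
  if (length(diffs) == 0L)
    return(list(n = 0L, mean = NA_real_, median = NA_real_,
                share_positive = NA_real_))
  list(n = length(diffs), mean = mean(diffs), median = stats::median(diffs),
       share_positive = mean(diffs > 0))
}
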