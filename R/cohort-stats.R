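#' Group summary for effect-size computation
#' @param n Sample size (>= 2).
#' @param mean Group mean.
#' @param sd Sample standard deviation.
#' @return A `group_summary` list.
#' @export
group_summary <- function(n, mean, sd) {
  stopifnot(n >= 2, sd >= 0)
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

pooled_sd <- function(g1, g2) {
  sqrt(((g1$n - 1) * g1$sd^2 + (g2$n - 1) * g2$sd^2) / (g1$n + g2$n - 2))
}

#' Cohen's d from group summary statistics
#'
#' `d = (mean1 - mean2) / s_pooled` with the pooled sample SD. By the
#' cohort-table reporting convention group 1 is women, so negative d
#' means the men's mean is larger.
#' @param g1,g2 `group_summary` objects (or lists with n/mean/sd).
#' @return Numeric scalar.
#' @examples
#' cohens_d(group_summary(63, 81.7, 6.94), group_summary(34, 86.2, 5.90))
#' @export
cohens_d <- function(g1, g2) {
  sp <- pooled_sd(g1, g2)
  if (sp == 0) stop("zero pooled SD: Cohen's d undefined")
  (g1$mean - g2$mean) / sp
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Student's t with pooled variance; `df = n1 + n2 - 2`; two-sided p.
#' @param g1,g2 `group_summary` objects.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(g1, g2) {
  sp <- pooled_sd(g1, g2)
  if (sp == 0) stop("zero pooled SD: t undefined")
  se <- sp * sqrt(1 / g1$n + 1 / g2$n)
  t <- (g1$mean - g2$mean) / se
  df <- g1$n + g2$n - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Mann-Whitney U test
#'
#' U for the first sample with midrank ties; p by the normal
#' approximation with tie correction (no continuity correction).
#' @param x,y Numeric vectors.
#' @return List with `U`, `p`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; p by the t approximation.
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return List with `rho`, `p`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(flagged(list(rho = NA_real_, p = NA_real_), "constant_input"))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Chi-square test on a 2x2 table
#'
#' Pearson chi-square with df 1; continuity correction off by default
#' (matching the cohort-table convention).
#' @param table 2x2 numeric matrix of counts.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return List with `chi2`, `df`, `p`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0), sum(table) > 0)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero marginal: chi-square undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value)
}

#' Cohort comparison table from a scores data.frame
#'
#' Emits a demographics-table-shaped data.frame: per numeric variable,
#' group summaries by `group` (women first), pooled t, df, p and Cohen's
#' d.
#' @param scores data.frame of numeric variables plus a `group` column
#'   with two levels.
#' @param group Name of the grouping column (default `"gender"`).
#' @param group_order Optional length-2 character giving group 1 and 2.
#' @return data.frame, one row per variable.
#' @export
cohort_report <- function(scores, group = "gender", group_order = NULL) {
  stopifnot(group %in% names(scores))
  g <- as.character(scores[[group]])
  levs <- group_order %||% sort(unique(g))
  stopifnot(length(levs) == 2)
  vars <- names(scores)[vapply(scores, is.numeric, logical(1))]
  rows <- lapply(vars, function(v) {
    x1 <- scores[[v]][g == levs[1]]; x1 <- x1[!is.na(x1)]
    x2 <- scores[[v]][g == levs[2]]; x2 <- x2[!is.na(x2)]
    if (length(x1) < 2 || length(x2) < 2) return(NULL)
    g1 <- group_summary(length(x1), mean(x1), stats::sd(x1))
    g2 <- group_summary(length(x2), mean(x2), stats::sd(x2))
    tt <- tryCatch(two_sample_t(g1, g2),
                   error = function(e) list(t = NA, df = NA, p = NA))
    d <- tryCatch(cohens_d(g1, g2), error = function(e) NA_real_)
    data.frame(variable = v,
               n1 = g1$n, mean1 = g1$mean, sd1 = g1$sd,
               n2 = g2$n, mean2 = g2$mean, sd2 = g2$sd,
               t = tt$t, df = tt$df, p = tt$p, cohens_d = d,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
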