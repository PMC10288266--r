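#' Normality-gated test selection
#'
#' Mirrors the study's statistical decision tree: every sample is checked
#' for normality with the Shapiro-Wilk test; if all samples have p > 0.05
#' the parametric branch is taken (unpaired t-test, one-way ANOVA with Holm
#' multiple comparisons, or paired t-test depending on the design),
#' otherwise the rank-based branch (Mann-Whitney, Kruskal-Wallis, or
#' Friedman). Branch selection is a pure function of the Shapiro-Wilk
#' p-values and the design.
#'
#' @param samples list of numeric vectors (one per group or timepoint).
#' @param design `"two_indep"`, `"multi_indep"` or `"repeated"`.
#' @param alpha_normality Shapiro-Wilk significance level for the gate.
#' @return the test name: one of `"t_test"`, `"mann_whitney"`, `"anova"`,
#'   `"kruskal_wallis"`, `"paired_t"`, `"friedman"`.
#' @export
select_test <- function(samples, design = c("two_indep", "multi_indep", "repeated"),
                        alpha_normality = 0.05) {
  design <- match.arg(design)
  if (any(vapply(samples, length, 1L) < 3))
    stop("insufficient sample: every group needs n >= 3")
  sw_p <- vapply(samples, function(x) {
    if (stats::sd(x) == 0) return(0)       # degenerate: treat as non-normal
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  normal <- all(sw_p > alpha_normality)
  switch(design,
         two_indep = if (normal) "t_test" else "mann_whitney",
         multi_indep = if (normal) "anova" else "kruskal_wallis",
         repeated = if (!normal) "friedman"
                    else if (length(samples) == 2L) "paired_t" else "friedman")
}

#' Run a group comparison on a cohort table
#'
#' Selects the test via [select_test()] and runs it; all p-values are
#' two-tailed and flagged significant at 0.05. For multi-group designs on
#' the parametric branch, Holm-adjusted pairwise t-tests accompany the
#' omnibus ANOVA.
#'
#' @param table long-format data.frame with columns `subject`, `group`,
#'   `day` and the biomarker named by `value`.
#' @param value name of the biomarker column to compare.
#' @param contrast list of cells, each `list(group =, day =)`; rows matching
#'   each cell form one sample.
#' @param design passed to [select_test()]; `"two_indep"` by default when
#'   the contrast has two cells.
#' @param test optional explicit test name (one of the [select_test()]
#'   return values), bypassing the normality gate -- e.g. to force the
#'   rank-based branch in a sensitivity analysis.
#' @return list with `test`, `statistic`, `p`, `significant`, `shapiro_p`
#'   and (multi-group parametric) `pairwise_p` (Holm-adjusted).
#' @export
compare_groups <- function(table, value, contrast,
                           design = if (length(contrast) == 2L) "two_indep"
                                    else "multi_indep",
                           test = NULL) {
  samples <- lapply(contrast, function(cell) {
    rows <- rep(TRUE, nrow(table))
    if (!is.null(cell$group)) rows <- rows & table$group == cell$group
    if (!is.null(cell$day)) rows <- rows & table$day == cell$day
    x <- table[[value]][rows]
    if (length(x) == 0)
      stop("contrast cell matches no rows (group ", cell$group,
           ", day ", cell$day, ")")
    x
  })
  if (is.null(test)) test <- select_test(samples, design)
  out <- switch(
    test,
    t_test = {
      r <- stats::t.test(samples[[1]], samples[[2]], var.equal = FALSE)
      list(statistic = unname(r$statistic), p = r$p.value)
    },
    mann_whitney = {
      # ties force the normal approximation; that is expected, not an error
      r <- suppressWarnings(
        stats::wilcox.test(samples[[1]], samples[[2]], exact = NULL))
      list(statistic = unname(r$statistic), p = r$p.value)
    },
    paired_t = {
      r <- stats::t.test(samples[[1]], samples[[2]], paired = TRUE)
      list(statistic = unname(r$statistic), p = r$p.value)
    },
    anova = {
      g <- factor(rep(seq_along(samples), vapply(samples, length, 1L)))
      y <- unlist(samples)
      r <- stats::oneway.test(y ~ g, var.equal = TRUE)
      pw <- stats::pairwise.t.test(y, g, p.adjust.method = "holm")
      list(statistic = unname(r$statistic), p = r$p.value,
           pairwise_p = pw$p.value)
    },
    kruskal_wallis = {
      g <- factor(rep(seq_along(samples), vapply(samples, length, 1L)))
      y <- unlist(samples)
      r <- stats::kruskal.test(y, g)
      pw <- suppressWarnings(
        stats::pairwise.wilcox.test(y, g, p.adjust.method = "holm"))
      list(statistic = unname(r$statistic), p = r$p.value,
           pairwise_p = pw$p.value)
    },
    friedman = {
      n <- unique(vapply(samples, length, 1L))
      if (length(n) != 1L)
        stop("repeated design requires equal sample sizes per timepoint")
      m <- do.call(cbind, samples)
      r <- stats::friedman.test(m)
      list(statistic = unname(r$statistic), p = r$p.value)
    })
  sw <- vapply(samples, function(x)
    if (stats::sd(x) == 0) 0 else stats::shapiro.test(x)$p.value, numeric(1))
  c(list(test = test), out,
    list(significant = out$p < 0.05, shapiro_p = sw))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks on ties; two-tailed p-value.
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @return list with `r_s` and `p`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4)
    stop("need paired vectors with n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  r <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(r_s = unname(r$estimate), p = r$p.value)
}
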