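# Statistical decision tree: Monte-Carlo Lilliefors normality gate, then a
# parametric branch (Student's t / one-way ANOVA with Tukey HSD) or a
# nonparametric branch (Wilcoxon rank-sum / Kruskal-Wallis), plus exact
# incidence tests for tinnitus percentages.

# Half-away-from-zero rounding to one decimal, the convention of the printed
# incidence percentages (5/16 = 31.25% prints as 31.3); base round() would
# give 31.2.
round_pct <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  f <- pnorm(z)
  max(seq_len(n) / n - f, f - (seq_len(n) - 1) / n)
}

#' Lilliefors normality test with a Monte-Carlo null
#'
#' Kolmogorov-Smirnov distance of the sample against a normal distribution
#' with mean and SD estimated from the same sample; the null distribution of
#' the statistic is built by Monte Carlo (normal samples of equal size, with
#' parameters re-estimated per replicate), which handles any n without
#' recourse to tabulated critical values.
#'
#' @param x numeric sample (n >= 5, non-degenerate).
#' @param n_mc number of Monte-Carlo replicates.
#' @param seed optional seed for the null draws.
#' @return list: `statistic` (D), `p_value`, `n`, `n_mc`.
#' @export
lilliefors_test <- function(x, n_mc = 10000, seed = NULL) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 5) stop("Lilliefors test needs n >= 5, got ", n)
  if (sd(x) == 0) stop("degenerate (constant) sample")
  if (!is.null(seed)) set.seed(seed)
  d <- lilliefors_statistic(x)
  null_d <- vapply(seq_len(n_mc),
                   function(i) lilliefors_statistic(rnorm(n)), 0)
  list(statistic = d,
       p_value = (1 + sum(null_d >= d)) / (n_mc + 1),
       n = n, n_mc = n_mc)
}

#' Compare group means with a normality-gated test choice
#'
#' Each group is screened with the Lilliefors test; when every group is
#' consistent with normality at `alpha` the parametric branch is taken
#' (Student's t-test for two groups, one-way ANOVA with Tukey HSD post-hoc
#' for more), otherwise the nonparametric branch (Wilcoxon rank-sum or
#' Kruskal-Wallis). Groups too small to screen (n < 5) pass the gate, since
#' the test cannot reject there. All tests are two-sided.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each n >= 3).
#' @param alpha normality-gate level.
#' @param n_mc,seed Monte-Carlo settings for the gate.
#' @return list of class `group_comparison`: `test`, `statistic`, `p_value`,
#'   `branch`, `normality_p` per group, `n` per group, and `posthoc`
#'   (Tukey HSD table) when applicable.
#' @export
compare_groups <- function(groups, alpha = 0.05, n_mc = 2000, seed = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  groups <- lapply(groups, function(g) g[is.finite(g)])
  ns <- lengths(groups)
  if (any(ns < 3)) stop("every group needs n >= 3; sizes: ",
                        paste(ns, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  norm_p <- vapply(groups, function(g) {
    if (length(g) < 5 || sd(g) == 0) return(NA_real_)
    lilliefors_test(g, n_mc = n_mc)$p_value
  }, 0)
  normal <- all(is.na(norm_p) | norm_p > alpha)
  k <- length(groups)
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), ns))
  posthoc <- NULL
  if (normal) {
    branch <- "parametric"
    if (k == 2) {
      ht <- t.test(groups[[1]], groups[[2]], var.equal = TRUE)
      test <- "Student t-test"
    } else {
      fit <- aov(values ~ labels)
      ht <- list(statistic = summary(fit)[[1]]$`F value`[1],
                 p.value = summary(fit)[[1]]$`Pr(>F)`[1])
      posthoc <- as.data.frame(TukeyHSD(fit)$labels)
      test <- "one-way ANOVA"
    }
  } else {
    branch <- "nonparametric"
    if (k == 2) {
      ht <- wilcox.test(groups[[1]], groups[[2]])
      test <- "Wilcoxon rank-sum"
    } else {
      ht <- kruskal.test(values, labels)
      test <- "Kruskal-Wallis"
    }
  }
  structure(list(
    test = test, statistic = unname(ht$statistic[1]),
    p_value = unname(ht$p.value),
    branch = branch, normality_p = norm_p, n = ns, posthoc = posthoc
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (%s branch): statistic = %.4g, p = %.4g\n",
              x$test, x$branch, x$statistic, x$p_value))
  cat("  n =", paste(x$n, collapse = ", "), "\n")
  if (!is.null(x$posthoc)) {
    cat("  Tukey HSD:\n")
    print(round(x$posthoc, 4))
  }
  invisible(x)
}

#' Exact test for a difference in tinnitus incidence
#'
#' Two observed proportions k1/n1 vs k2/n2 compared with Fisher's exact test
#' (default) or a conditional one-sample binomial (k1 out of n1 against the
#' proportion observed in group 2).
#'
#' @param k1,n1,k2,n2 counts.
#' @param method `"fisher"` or `"binomial"`.
#' @return list: `p_value`, `method`, `incidence_pct`, `htest`.
#' @export
binomial_incidence_test <- function(k1, n1, k2, n2,
                                    method = c("fisher", "binomial")) {
  method <- match.arg(method)
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  ht <- if (method == "fisher") {
    fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2))
  } else {
    p2 <- k2 / n2
    if (p2 <= 0) p2 <- 0.5 / n2      # continuity guard for a zero reference
    if (p2 >= 1) p2 <- 1 - 0.5 / n2
    binom.test(k1, n1, p = p2)
  }
  list(p_value = ht$p.value, method = method,
       incidence_pct = round_pct(100 * c(k1 / n1, k2 / n2)), htest = ht)
}
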