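# Tinnitus classification from changes in final gap-startle ratios:
# Gaussian null fitted to the control change distribution, threshold at
# mu + 2 sigma, per-mouse labeling, threshold sweep and incidence comparison.

#' Per-mouse, per-frequency changes in final gap-startle ratio
#'
#' Change = post-exposure minus pre-exposure final gap ratio, the sign
#' convention under which a gap-detection deficit (larger post-exposure gap
#' ratio) is positive and the tinnitus threshold sits in the upper tail.
#' Frequencies missing either phase yield no change score.
#'
#' @param ratio_table a [process_cohort()]-style table (`measure == "gap"`
#'   rows are used).
#' @return data.frame: `mouse_id`, (`cohort` if present), `frequency_khz`,
#'   `delta`.
#' @export
delta_ratios <- function(ratio_table) {
  g <- ratio_table[ratio_table$measure == "gap", ]
  pre <- g[g$phase == "pre", ]
  post <- g[g$phase == "post", ]
  key <- function(d) paste(d$mouse_id, d$frequency_khz)
  i <- match(key(post), key(pre))
  out <- data.frame(
    mouse_id = post$mouse_id,
    frequency_khz = post$frequency_khz,
    delta = post$ratio - pre$ratio[i],
    stringsAsFactors = FALSE
  )
  if (!is.null(post$cohort)) out$cohort <- post$cohort
  out[!is.na(out$delta), , drop = FALSE]
}

#' Fit the Gaussian null to control change scores
#'
#' Normal fit by sample moments (mean and SD), the maximum-likelihood fit up
#' to the usual n/(n-1) variance factor; bin-free, unlike a histogram curve
#' fit. A Monte-Carlo Lilliefors p-value is attached as a goodness summary.
#'
#' @param deltas numeric vector of control change scores (post minus pre).
#' @param min_n smallest admissible sample size.
#' @param lilliefors attach a normality p-value (set FALSE to skip).
#' @param seed seed for the Lilliefors Monte-Carlo null.
#' @return an object of class `delta_fit`: `mu`, `sigma`, `threshold`
#'   (mu + 2 sigma), `n`, `degenerate` flag, `lilliefors_p`.
#' @export
fit_control_distribution <- function(deltas, min_n = 10, lilliefors = TRUE,
                                     seed = NULL) {
  deltas <- deltas[is.finite(deltas)]
  n <- length(deltas)
  if (n < min_n) stop("need at least ", min_n, " change scores, got ", n)
  mu <- mean(deltas)
  sigma <- sd(deltas)
  degenerate <- sigma == 0
  p <- if (lilliefors && !degenerate)
    lilliefors_test(deltas, seed = seed)$p_value else NA_real_
  structure(list(
    mu = mu, sigma = sigma, threshold = tinnitus_threshold(mu, sigma),
    n = n, degenerate = degenerate, lilliefors_p = p, deltas = deltas
  ), class = "delta_fit")
}

#' @export
print.delta_fit <- function(x, ...) {
  cat(sprintf(
    "Gaussian null for control change scores (n = %d)\n  mu = %.4f, sigma = %.4f, threshold (mu + 2 sigma) = %.4f\n",
    x$n, x$mu, x$sigma, x$threshold))
  if (!is.na(x$lilliefors_p))
    cat(sprintf("  Lilliefors p = %.3f\n", x$lilliefors_p))
  invisible(x)
}

#' Tinnitus threshold: two standard deviations above the control mean
#'
#' @param mu,sigma Gaussian null parameters (sigma >= 0).
#' @return `mu + 2 * sigma`.
#' @export
tinnitus_threshold <- function(mu, sigma) {
  stopifnot(sigma >= 0)
  mu + 2 * sigma
}

#' Classify one mouse from its per-frequency change scores
#'
#' A mouse is labeled tinnitus when its change score strictly exceeds the
#' threshold at one or more tested frequencies.
#'
#' @param deltas numeric vector of change scores, named by frequency (kHz);
#'   NAs (excluded frequencies) are ignored.
#' @param threshold classification threshold.
#' @return list: `label` ("tinnitus"/"non_tinnitus"), `exceeding_frequencies`,
#'   `max_delta`.
#' @export
classify_mouse <- function(deltas, threshold) {
  usable <- deltas[is.finite(deltas)]
  if (length(usable) == 0) stop("no usable frequency: mouse is unclassifiable")
  exceed <- usable[usable > threshold]
  list(
    label = if (length(exceed) > 0) "tinnitus" else "non_tinnitus",
    exceeding_frequencies = as.numeric(names(exceed)),
    max_delta = max(usable)
  )
}

#' Classify every mouse in a change-score table
#'
#' Mice with no usable frequency are reported with label `"unclassifiable"`
#' rather than silently dropped.
#'
#' @param delta_table a [delta_ratios()] data.frame.
#' @param threshold classification threshold.
#' @return data.frame: `mouse_id`, `label`, `exceeding_frequencies`
#'   (comma-separated kHz), `max_delta`, plus `cohort` when available.
#' @export
classify_cohort <- function(delta_table, threshold) {
  ids <- unique(delta_table$mouse_id)
  rows <- lapply(ids, function(id) {
    d <- delta_table[delta_table$mouse_id == id, ]
    dv <- d$delta
    names(dv) <- d$frequency_khz
    res <- tryCatch(classify_mouse(dv, threshold),
                    error = function(e) list(label = "unclassifiable",
                                             exceeding_frequencies = numeric(0),
                                             max_delta = NA_real_))
    data.frame(
      mouse_id = id, label = res$label,
      exceeding_frequencies = paste(res$exceeding_frequencies, collapse = ","),
      max_delta = res$max_delta,
      cohort = if (!is.null(d$cohort)) d$cohort[1] else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Compare two change-score distributions over a sweep of thresholds
#'
#' For thresholds from 1 to -1 in steps of 0.02, reports the fraction of
#' change scores above the threshold in each group; two identical
#' distributions trace the diagonal.
#'
#' @param deltas_a,deltas_b numeric vectors of change scores.
#' @param thresholds sweep grid.
#' @return list: `curve` (data.frame `threshold`, `frac_a`, `frac_b`) and
#'   `max_deviation` (largest |frac_b - frac_a|).
#' @export
threshold_sweep <- function(deltas_a, deltas_b,
                            thresholds = seq(1, -1, by = -0.02)) {
  stopifnot(length(deltas_a) > 0, length(deltas_b) > 0)
  fa <- vapply(thresholds, function(t) mean(deltas_a > t), 0)
  fb <- vapply(thresholds, function(t) mean(deltas_b > t), 0)
  list(curve = data.frame(threshold = thresholds, frac_a = fa, frac_b = fb),
       max_deviation = max(abs(fb - fa)))
}

#' Compare tinnitus incidence between two groups
#'
#' Reports both incidences (as percentages, one decimal) and an exact
#' two-group test: Fisher's exact test by default, with a conditional
#' one-sample binomial option (group 1 count tested against group 2's
#' observed proportion).
#'
#' @param k1,n1,k2,n2 tinnitus counts and group sizes.
#' @param method `"fisher"` or `"binomial"`.
#' @return list: `incidence_pct` (length 2), `p_value`, `method`, plus the
#'   underlying `htest`.
#' @export
compare_incidence <- function(k1, n1, k2, n2, method = c("fisher", "binomial")) {
  method <- match.arg(method)
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  binomial_incidence_test(k1, n1, k2, n2, method = method)
}
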