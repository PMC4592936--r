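# Trial-level quality control and ratio averaging for the gap-detection /
# prepulse-inhibition battery.  Raw trial pairs enter; one final gap-startle
# and PPI ratio per mouse x frequency x phase leaves, with every elimination
# reason recorded.

#' Root-mean-square of baseline movement preceding the startle stimulus
#'
#' @param x a `startle_trial` or a numeric vector of baseline samples.
#' @return RMS (AU).
#' @export
rms_baseline <- function(x) {
  if (inherits(x, "startle_trial")) x <- x$waveform[x$baseline_window]
  if (length(x) == 0) stop("empty baseline window")
  sqrt(mean(x^2))
}

#' Peak-to-peak startle amplitude over the response window
#'
#' @param x a `startle_trial` or a numeric vector of response samples.
#' @return max minus min (AU).
#' @export
peak_to_peak <- function(x) {
  if (inherits(x, "startle_trial")) x <- x$waveform[seq(x$onset_index, length(x$waveform))]
  if (length(x) == 0) stop("empty response window")
  max(x) - min(x)
}

#' Per-trial summary metrics for a session
#'
#' Computes, for every trial, the response-window peak-to-peak amplitude, the
#' maximum absolute amplitude (stored for provenance) and the baseline RMS.
#'
#' @param session a [generate_session()] result.
#' @return the session's `trials` data.frame with columns `p2p`,
#'   `max_abs_amp`, `rms_base` appended.
#' @export
session_metrics <- function(session) {
  w <- session$waveforms
  resp <- w[, seq(session$onset_index, ncol(w)), drop = FALSE]
  base <- w[, session$baseline_window, drop = FALSE]
  m <- session$trials
  m$p2p <- apply(resp, 1, max) - apply(resp, 1, min)
  m$max_abs_amp <- apply(abs(w), 1, max)
  m$rms_base <- sqrt(rowMeans(base^2))
  m
}

#' Eliminate trials with aberrant baseline movement
#'
#' Within each pooling unit (by default each session round, pooling gap,
#' no-gap, prepulse and startle-only trials), trials whose baseline RMS lies
#' outside mean +/- 2.5 SD of the pooled RMS distribution are eliminated;
#' when a trial is eliminated its paired trial is eliminated with it.
#'
#' @param metrics a [session_metrics()] data.frame.
#' @param n_sd elimination width in pooled SDs.
#' @param pool_by column(s) defining the pooling unit.
#' @return `metrics` with logical `keep` and character `qc_flag` columns.
#' @export
filter_trials_by_baseline <- function(metrics, n_sd = 2.5,
                                      pool_by = "round_index") {
  if (nrow(metrics) < 2) stop("need at least 2 trials to define mean/SD")
  key <- interaction(metrics[pool_by], drop = TRUE)
  out_of_band <- logical(nrow(metrics))
  for (k in levels(key)) {
    i <- key == k
    m <- mean(metrics$rms_base[i])
    s <- sd(metrics$rms_base[i])
    if (!is.finite(s)) s <- 0  # single trial in pool: nothing to eliminate
    out_of_band[i] <- abs(metrics$rms_base[i] - m) > n_sd * s
  }
  pair_hit <- stats::ave(out_of_band, metrics$pair_id, FUN = any)
  metrics$keep <- !pair_hit
  metrics$qc_flag <- ifelse(out_of_band, "baseline_rms",
                            ifelse(pair_hit, "paired_trial", NA_character_))
  metrics
}

#' Per-pair startle ratios
#'
#' Ratio of probe (gap or prepulse) peak-to-peak amplitude over its paired
#' reference (no-gap or startle-only) amplitude. Pairs with a zero reference
#' amplitude are flagged invalid and dropped.
#'
#' @param metrics a QC'd metrics data.frame (rows with `keep == FALSE`
#'   excluded if the column is present).
#' @return data.frame: one row per retained pair with columns `mouse_id`,
#'   `phase`, `round_index`, `frequency_khz`, `measure`, `ratio`.
#' @export
compute_pair_ratios <- function(metrics) {
  if (!is.null(metrics$keep)) metrics <- metrics[metrics$keep, , drop = FALSE]
  probe <- metrics[metrics$trial_type %in% c("gap", "prepulse"), ]
  ref <- metrics[metrics$trial_type %in% c("no_gap", "startle_only"), ]
  i <- match(probe$pair_id, ref$pair_id)
  ok <- !is.na(i)
  probe <- probe[ok, ]
  denom <- ref$p2p[i[ok]]
  valid <- denom > 0
  data.frame(
    mouse_id = probe$mouse_id[valid], phase = probe$phase[valid],
    round_index = probe$round_index[valid],
    frequency_khz = probe$frequency_khz[valid],
    measure = probe$measure[valid],
    ratio = probe$p2p[valid] / denom[valid],
    stringsAsFactors = FALSE
  )
}

#' Sorted-jump filter for gap-startle ratios of one frequency and round
#'
#' Ratios are sorted ascending; at the first increase of more than
#' `max_jump` over the preceding value, that ratio and all larger ones are
#' excluded. If more than `max_excluded` ratios are excluded the frequency is
#' not used for this round.
#'
#' @param ratios numeric vector of pair ratios from one frequency and round.
#' @param max_jump largest admissible increase between consecutive sorted
#'   ratios.
#' @param max_excluded largest admissible number of excluded ratios.
#' @return list with `retained` (sorted numeric), `n_excluded`, and `dropped`
#'   (TRUE when the frequency's ratio is unusable for this round).
#' @export
filter_sorted_ratios <- function(ratios, max_jump = 0.5, max_excluded = 5) {
  if (length(ratios) == 0)
    return(list(retained = numeric(0), n_excluded = 0L, dropped = TRUE))
  s <- sort(ratios)
  jump <- which(diff(s) > max_jump)
  if (length(jump) == 0)
    return(list(retained = s, n_excluded = 0L, dropped = FALSE))
  cut <- jump[1]
  n_excl <- length(s) - cut
  list(retained = s[seq_len(cut)], n_excluded = as.integer(n_excl),
       dropped = n_excl > max_excluded)
}

#' Round-level average ratios for one session
#'
#' Applies baseline QC and the sorted-jump filter (gap ratios only), then
#' averages retained pair ratios within each frequency and round.
#'
#' @param session a [generate_session()] result.
#' @param jump_filter_ppi also apply the sorted-jump filter to PPI ratios
#'   (default FALSE: the rule is defined for gap-detection trials).
#' @return data.frame: `mouse_id`, `phase`, `round_index`, `frequency_khz`,
#'   `measure`, `ratio` (NA when dropped), `n_pairs_used`, `n_excluded`.
#' @export
session_round_ratios <- function(session, jump_filter_ppi = FALSE) {
  metrics <- filter_trials_by_baseline(session_metrics(session))
  pairs <- compute_pair_ratios(metrics)
  grid <- expand.grid(round_index = 1:3, frequency_khz = startle_frequencies,
                      measure = c("gap", "ppi"), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(j) {
    g <- grid[j, ]
    r <- pairs$ratio[pairs$round_index == g$round_index &
                       pairs$frequency_khz == g$frequency_khz &
                       pairs$measure == g$measure]
    if (g$measure == "gap" || jump_filter_ppi) {
      fl <- filter_sorted_ratios(r)
    } else {
      fl <- list(retained = r, n_excluded = 0L, dropped = length(r) == 0)
    }
    data.frame(
      mouse_id = session$trials$mouse_id[1], phase = session$trials$phase[1],
      g,
      ratio = if (fl$dropped || length(fl$retained) == 0) NA_real_ else mean(fl$retained),
      n_pairs_used = length(fl$retained),
      n_excluded = fl$n_excluded,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Final per-frequency ratios for one mouse (both phases)
#'
#' Averages the round-level ratios across the three rounds of each phase,
#' then applies the final exclusion rules: gap-startle ratios above
#' `gap_max_pre` pre-exposure or above `gap_max_post` post-exposure are
#' excluded, and PPI ratios above `ppi_max` in either phase are excluded.
#' Absence is a recorded outcome (`drop_reason`), never an error.
#'
#' @param round_ratios rbind of [session_round_ratios()] for the mouse's pre
#'   and post sessions.
#' @param gap_max_pre,gap_max_post,ppi_max exclusion limits.
#' @return data.frame: `mouse_id`, `phase`, `frequency_khz`, `measure`,
#'   `ratio` (NA when excluded/dropped), `n_rounds_used`, `drop_reason`.
#' @export
finalize_ratios <- function(round_ratios, gap_max_pre = 0.9,
                            gap_max_post = 1.1, ppi_max = 1.0) {
  grid <- expand.grid(phase = c("pre", "post"),
                      frequency_khz = startle_frequencies,
                      measure = c("gap", "ppi"), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(j) {
    g <- grid[j, ]
    sel <- round_ratios$phase == g$phase &
      round_ratios$frequency_khz == g$frequency_khz &
      round_ratios$measure == g$measure
    r <- round_ratios$ratio[sel]
    usable <- r[!is.na(r)]
    reason <- NA_character_
    final <- NA_real_
    if (length(usable) == 0) {
      reason <- "all_rounds_dropped"
    } else {
      final <- mean(usable)
      limit_hit <-
        (g$measure == "gap" && g$phase == "pre" && final > gap_max_pre) ||
        (g$measure == "gap" && g$phase == "post" && final > gap_max_post) ||
        (g$measure == "ppi" && final > ppi_max)
      if (limit_hit) {
        reason <- "ratio_limit"
        final <- NA_real_
      }
    }
    data.frame(
      mouse_id = round_ratios$mouse_id[1], g,
      ratio = final, n_rounds_used = length(usable), drop_reason = reason,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Run the full behavioral QC pipeline over a cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @param ... passed to [session_round_ratios()].
#' @return a tidy ratio table: one row per mouse x phase x frequency x
#'   measure, with a `cohort` column from the generating profile.
#' @export
process_cohort <- function(cohort, ...) {
  rows <- lapply(names(cohort$sessions), function(id) {
    rr <- rbind(
      session_round_ratios(cohort$sessions[[id]]$pre, ...),
      session_round_ratios(cohort$sessions[[id]]$post, ...)
    )
    out <- finalize_ratios(rr)
    out$cohort <- cohort$profiles[[id]]$cohort
    out
  })
  do.call(rbind, rows)
}
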