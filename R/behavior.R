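#' Causal half-Gaussian filter weights
#'
#' Weights for the recent-reward-history filter: a Gaussian restricted to
#' the past (lag >= 1 press), truncated at `max_lag` and normalized to sum
#' to one over the available history. Operates in the press domain: the
#' filter input is the binary sequence of delivered (1) or denied (0)
#' rewards.
#'
#' @param width s.d. of the half-Gaussian, in presses.
#' @param n_lags number of past presses available.
#' @param max_lag truncation (default `ceiling(4 * width)`).
#' @return numeric weights for lags `1..min(n_lags, max_lag)`, summing to
#'   1 (empty when no history).
#' @export
half_gaussian_weights <- function(width, n_lags,
                                  max_lag = ceiling(4 * width)) {
  stopifnot(width > 0, n_lags >= 0)
  k <- min(n_lags, max_lag)
  if (k == 0) return(numeric(0))
  lags <- seq_len(k)
  w <- exp(-lags^2 / (2 * width^2))
  w / sum(w)
}

#' Per-press reward predictors
#'
#' Expands a session into the per-press analysis table: the waiting time
#' (time since the preceding press on either box), its log, the causally
#' filtered reward ratio of the pressed box, the oracle probability of
#' reward availability (from the schedule and the time since the last
#' press on the pressed box), the scheduled reward rate, the reward
#' outcome, the stay/switch choice (location of the next press), and the
#' next waiting time. Presses with waiting time above `max_wait` are
#' excluded from the table (the session's first press has no waiting time
#' and is likewise dropped).
#'
#' @param session a [behavioral_session()].
#' @param filter_width half-Gaussian width in presses (default 5).
#' @param max_wait exclusion bound on the waiting time, seconds.
#' @return a `press_table` data.frame; attribute `filter_width` records
#'   the filter used.
#' @export
build_press_table <- function(session, filter_width = 5, max_wait = 60) {
  stopifnot(is_behavioral_session(session))
  if (nrow(session) < 2) stop("need at least 2 presses")
  s <- as.data.frame(session)
  n <- nrow(s)
  vis <- press_vis(session)
  vi_press <- ifelse(s$box == 1, vis[, 1], vis[, 2])
  dt <- session_schedule(session)$dt

  waiting <- c(NA, diff(s$time_s))
  ## time since the previous press on the same box (availability clock);
  ## first press on a box accrues from session start
  t_same <- numeric(n)
  last_seen <- c(0, 0)
  for (i in seq_len(n)) {
    t_same[i] <- s$time_s[i] - last_seen[s$box[i]]
    last_seen[s$box[i]] <- s$time_s[i]
  }
  prob_avail <- 1 - exp((t_same / dt) * log1p(-dt / vi_press))

  rr <- reward_ratio_series(s$box, s$rewarded, filter_width)
  choice <- c(ifelse(s$box[-n] == s$box[-1], "stay", "switch"), NA)
  next_wait <- c(waiting[-1], NA)

  tab <- data.frame(
    press_index = seq_len(n),
    time_s = s$time_s,
    box = s$box,
    waiting_time = waiting,
    log_waiting_time = log(waiting),
    reward_ratio = rr,
    prob_avail = prob_avail,
    scheduled_rate = 1 / vi_press,
    rewarded = s$rewarded,
    choice = choice,
    next_waiting_time = next_wait,
    block_index = s$block_index
  )
  keep <- !is.na(tab$waiting_time) & tab$waiting_time <= max_wait
  tab <- tab[keep, , drop = FALSE]
  structure(tab, filter_width = filter_width, max_wait = max_wait,
            class = c("press_table", "data.frame"))
}

## reward ratio at each press: half-Gaussian-filtered rewards of the
## pressed box over filtered rewards of both boxes (lags >= 1). Empty
## filtered denominator -> 0.5 (uninformative prior).
reward_ratio_series <- function(box, rewarded, width) {
  n <- length(box)
  out <- numeric(n)
  max_lag <- ceiling(4 * width)
  rew <- as.numeric(rewarded)
  for (i in seq_len(n)) {
    w <- half_gaussian_weights(width, i - 1L, max_lag)
    if (!length(w)) { out[i] <- 0.5; next }
    idx <- i - seq_along(w)
    den <- sum(w * rew[idx])
    if (den <= 0) { out[i] <- 0.5; next }
    num <- sum(w * rew[idx] * (box[idx] == box[i]))
    out[i] <- num / den
  }
  out
}

## scheduled reward ratio of the pressed box: (1/vi_pressed) / sum(1/vi)
scheduled_reward_ratio <- function(session) {
  vis <- press_vis(session)
  rate1 <- 1 / vis[, 1]; rate2 <- 1 / vis[, 2]
  ifelse(session$box == 1, rate1, rate2) / (rate1 + rate2)
}

#' Tune the half-Gaussian filter width
#'
#' Returns the candidate width whose observed reward ratio best tracks
#' the scheduled reward ratio (pooled Pearson correlation across
#' sessions); ties break toward the smallest width.
#'
#' @param sessions a [behavioral_session()] or list of them; at least two
#'   schedule conditions must be represented.
#' @param candidate_widths numeric vector of widths (presses).
#' @return the selected width; attribute `correlations` has the pooled r
#'   per candidate.
#' @export
tune_filter_width <- function(sessions, candidate_widths = c(2, 3, 5, 8, 12, 20)) {
  if (is_behavioral_session(sessions)) sessions <- list(sessions)
  stopifnot(length(candidate_widths) >= 1)
  sched_rr <- unlist(lapply(sessions, scheduled_reward_ratio))
  if (stats::sd(sched_rr) < .Machine$double.eps)
    stop("scheduled reward ratio is constant; width cannot be tuned")
  rs <- vapply(candidate_widths, function(w) {
    obs <- unlist(lapply(sessions, function(s)
      reward_ratio_series(s$box, s$rewarded, w)))
    stats::cor(obs, sched_rr)
  }, numeric(1))
  best <- candidate_widths[which.max(rs)]  # which.max takes the first tie
  structure(best, correlations = stats::setNames(rs, candidate_widths))
}

#' Press-binned reward-prediction correlation
#'
#' Sorts presses by a predictor, chunks them into bins of `presses_per_bin`
#' (the last bin may be short), and correlates the per-bin mean predictor
#' with the per-bin rewarded fraction — the standard reward-predictability
#' summary for a candidate variable.
#'
#' @param table a [build_press_table()] output (tables may be pooled with
#'   `rbind` across sessions first).
#' @param predictor column name, e.g. `"prob_avail"`, `"waiting_time"`,
#'   `"reward_ratio"`, `"scheduled_rate"`.
#' @param presses_per_bin bin size in presses (default 50).
#' @return a `binned_stat`: data.frame of per-bin means and rewarded
#'   fractions with the Pearson `r` as attribute `r`.
#' @export
bin_and_correlate <- function(table, predictor, presses_per_bin = 50) {
  stopifnot(predictor %in% names(table))
  x <- table[[predictor]]
  y <- as.numeric(table$rewarded)
  ok <- !is.na(x)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 * presses_per_bin)
    stop("need at least 2 bins (", 2 * presses_per_bin, " presses)")
  ord <- order(x)
  bin <- ceiling(seq_along(ord) / presses_per_bin)
  mean_pred <- tapply(x[ord], bin, mean)
  frac_rew <- tapply(y[ord], bin, mean)
  r <- stats::cor(mean_pred, frac_rew)
  structure(data.frame(bin = as.integer(names(mean_pred)),
                       mean_predictor = as.numeric(mean_pred),
                       rewarded_fraction = as.numeric(frac_rew)),
            r = r, predictor = predictor,
            class = c("binned_stat", "data.frame"))
}

#' Conditional next-wait analysis
#'
#' Splits presses into short/medium/long wait (or reward-ratio) categories
#' and compares the next waiting time after rewarded versus unrewarded
#' presses within each category: mean next waits, the percent change for
#' unrewarded relative to rewarded, and the AUC with which the next wait
#' discriminates the two outcomes.
#'
#' @param table a press table (pooled tables allowed).
#' @param bounds either `"percentile"` (tercile edges of the in-range
#'   waits) or an explicit numeric vector of category edges such as
#'   `c(3, 5, 8, 60)`.
#' @param variable the conditioning column (default `"waiting_time"`; use
#'   `"reward_ratio"` for the reward-history version).
#' @return data.frame with one row per category: mean next wait by
#'   outcome, `pct_change`, `auc`, and cell sizes (empty cells flagged
#'   with `NA`).
#' @export
conditional_wait_analysis <- function(table, bounds = "percentile",
                                      variable = "waiting_time") {
  x <- table[[variable]]
  ok <- !is.na(x) & !is.na(table$next_waiting_time)
  x <- x[ok]
  nw <- table$next_waiting_time[ok]
  rew <- table$rewarded[ok]
  if (identical(bounds, "percentile")) {
    edges <- stats::quantile(x, probs = c(0, 1/3, 2/3, 1), names = FALSE)
    edges[1] <- -Inf; edges[length(edges)] <- Inf
  } else {
    edges <- as.numeric(bounds)
  }
  cat_ix <- cut(x, edges, include.lowest = TRUE,
                labels = c("short", "medium", "long")[seq_len(length(edges) - 1)])
  out <- do.call(rbind, lapply(levels(cat_ix), function(lv) {
    sel <- which(cat_ix == lv)
    nr <- nw[sel][!rew[sel]]; rr <- nw[sel][rew[sel]]
    if (!length(nr) || !length(rr)) {
      return(data.frame(category = lv, n_rewarded = length(rr),
                        n_unrewarded = length(nr),
                        mean_next_rewarded = NA_real_,
                        mean_next_unrewarded = NA_real_,
                        pct_change = NA_real_, auc = NA_real_))
    }
    data.frame(category = lv, n_rewarded = length(rr),
               n_unrewarded = length(nr),
               mean_next_rewarded = mean(rr),
               mean_next_unrewarded = mean(nr),
               pct_change = 100 * (mean(nr) - mean(rr)) / mean(rr),
               auc = auc(c(nr, rr), c(rep(1, length(nr)), rep(0, length(rr)))))
  }))
  out
}

#' Switch probability by category and reward outcome
#'
#' Fraction of presses followed by a switch, per conditioning category and
#' reward outcome. Switching after rewarded presses is rare and reported
#' separately.
#'
#' @inheritParams conditional_wait_analysis
#' @return data.frame with per-category switch rates after unrewarded
#'   presses, the overall rewarded-press switch rate as attribute
#'   `p_switch_rewarded`.
#' @export
switch_probability <- function(table, bounds = "percentile",
                               variable = "waiting_time") {
  x <- table[[variable]]
  ok <- !is.na(x) & !is.na(table$choice)
  x <- x[ok]; sw <- table$choice[ok] == "switch"; rew <- table$rewarded[ok]
  if (identical(bounds, "percentile")) {
    edges <- stats::quantile(x, probs = c(0, 1/3, 2/3, 1), names = FALSE)
    edges[1] <- -Inf; edges[length(edges)] <- Inf
  } else edges <- as.numeric(bounds)
  cat_ix <- cut(x, edges, include.lowest = TRUE,
                labels = c("short", "medium", "long")[seq_len(length(edges) - 1)])
  out <- do.call(rbind, lapply(levels(cat_ix), function(lv) {
    sel <- which(cat_ix == lv & !rew)
    data.frame(category = lv, n = length(sel),
               p_switch_unrewarded = if (length(sel)) mean(sw[sel]) else NA_real_)
  }))
  structure(out, p_switch_rewarded = if (any(rew)) mean(sw[rew]) else NA_real_)
}
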