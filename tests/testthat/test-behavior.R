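test_that("half-Gaussian filter weights are causal, nonnegative, normalized", {
  w <- half_gaussian_weights(width = 3, n_lags = 10)
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1)
  expect_true(all(diff(w) < 0))              # heavier on the recent past
  expect_length(half_gaussian_weights(2, 0), 0)
  # truncation at 4 sd
  expect_length(half_gaussian_weights(2, 100), 8)
})

test_that("reward ratio matches a hand-computed five-press example", {
  sched <- vi_schedule(data.frame(box1_vi = 20, box2_vi = 20, n_rewards = 5))
  df <- data.frame(time_s = c(2, 8, 15, 21, 30),
                   box = c(1, 2, 1, 1, 2),
                   rewarded = c(TRUE, TRUE, FALSE, TRUE, FALSE),
                   block_index = 1)
  s <- behavioral_session(df, sched)
  tab <- build_press_table(s, filter_width = 2)
  # independent weighted-sum computation
  wts <- function(k) { w <- exp(-(1:k)^2 / (2 * 4)); w / sum(w) }
  expect_ratio <- function(i) {
    w <- wts(min(i - 1, 8))
    idx <- i - seq_along(w)
    den <- sum(w * df$rewarded[idx])
    if (den == 0) return(0.5)
    sum(w * df$rewarded[idx] * (df$box[idx] == df$box[i])) / den
  }
  for (i in 2:5) {
    expect_equal(tab$reward_ratio[tab$press_index == i], expect_ratio(i),
                 tolerance = 1e-12)
  }
})

test_that("reward ratios of the two boxes sum to one at the same instant", {
  s <- run_mvt_agent(mvt_agent_params(), reversal_schedule(15, 25),
                     n_rewards_total = 25, seed = 13)
  n <- min(nrow(s), 50)
  box <- s$box[1:n]; rew <- s$rewarded[1:n]
  rr_same <- forageVI:::reward_ratio_series(box, rew, 5)
  # the other box's share at press i: flip only that press's box label
  # (the history feeding the filter is unchanged)
  for (i in 2:n) {
    box_i <- box; box_i[i] <- 3 - box_i[i]
    rr_other <- forageVI:::reward_ratio_series(box_i, rew, 5)[i]
    w <- forageVI:::half_gaussian_weights(5, i - 1)
    den <- sum(w * rew[i - seq_along(w)])
    if (den > 0) {
      expect_equal(rr_same[i] + rr_other, 1, tolerance = 1e-12)
    } else {
      expect_equal(c(rr_same[i], rr_other), c(0.5, 0.5))
    }
  }
})

test_that("press table fields follow their definitions", {
  s <- tiny_session()
  tab <- build_press_table(s, filter_width = 2)
  # first press has no waiting time and is dropped
  expect_false(1 %in% tab$press_index)
  expect_equal(tab$waiting_time, diff(s$time_s))
  expect_equal(tab$log_waiting_time, log(tab$waiting_time))
  # choice is the location of the NEXT press
  expect_equal(tab$choice[tab$press_index == 3], "switch")
  expect_equal(tab$choice[tab$press_index == 5], "stay")
  expect_true(is.na(tab$choice[tab$press_index == 8]))
  expect_equal(tab$next_waiting_time[-nrow(tab)], tab$waiting_time[-1])
  # scheduled rate follows block and box
  expect_equal(tab$scheduled_rate[tab$press_index == 2], 1 / 10)
  expect_equal(tab$scheduled_rate[tab$press_index == 8], 1 / 20)
})

test_that("long waits are excluded from the press table", {
  sched <- vi_schedule(data.frame(box1_vi = 20, box2_vi = 20, n_rewards = 4))
  df <- data.frame(time_s = c(1, 5, 100, 104), box = c(1, 1, 1, 1),
                   rewarded = c(TRUE, FALSE, TRUE, FALSE), block_index = 1)
  tab <- build_press_table(behavioral_session(df, sched))
  expect_setequal(tab$press_index, c(2, 4))   # the 95 s wait is dropped
})

test_that("availability oracle uses the pressed box's own clock", {
  s <- tiny_session()
  tab <- build_press_table(s)
  dt <- 0.01
  # press 4 is the first on box 2: clock runs from session start (t = 20)
  expect_equal(tab$prob_avail[tab$press_index == 4],
               prob_reward_available(20, vi = 20, dt = dt))
  # press 7 is on box 1, last box-1 press at 13 s -> wait 28 s, block 2 vi 20
  expect_equal(tab$prob_avail[tab$press_index == 7],
               prob_reward_available(41 - 13, vi = 20, dt = dt))
})

test_that("binned correlation behaves at its extremes", {
  s <- run_mvt_agent(mvt_agent_params(), reversal_schedule(10, 30),
                     n_rewards_total = 220, seed = 17)
  tab <- build_press_table(s)
  # the rewarded flag predicts itself perfectly
  tab$self <- as.numeric(tab$rewarded)
  expect_equal(attr(bin_and_correlate(tab, "self"), "r"), 1)
  # a permuted predictor carries no signal
  set.seed(1)
  tab$noise <- sample(tab$prob_avail)
  expect_lt(abs(attr(bin_and_correlate(tab, "noise"), "r")), 0.5)
  # bins hold exactly 50 presses except possibly the last
  bs <- bin_and_correlate(tab, "prob_avail")
  sizes <- table(ceiling(seq_len(sum(!is.na(tab$prob_avail))) / 50))
  expect_equal(nrow(bs), length(sizes))
  expect_error(bin_and_correlate(tab[1:80, ], "prob_avail"), "bins")
})

test_that("binned correlation is invariant to input row order", {
  # distinct predictor values so the sort is unambiguous
  set.seed(2)
  n <- 400
  tab <- data.frame(pred = sample(seq_len(n)) + runif(n, 0, 0.5),
                    rewarded = runif(n) < 0.4)
  shuffled <- tab[sample(n), ]
  expect_equal(attr(bin_and_correlate(tab, "pred"), "r"),
               attr(bin_and_correlate(shuffled, "pred"), "r"),
               tolerance = 1e-12)
})

test_that("conditional wait analysis matches its degenerate cases", {
  # identical next-wait distributions for both outcomes within category
  cells <- expand.grid(nw = c(3, 7, 12, 20), rewarded = c(TRUE, FALSE),
                       wt = c(4, 6, 10), rep = 1:5)
  tab <- data.frame(waiting_time = cells$wt,
                    next_waiting_time = cells$nw,
                    rewarded = cells$rewarded,
                    choice = "stay")
  res <- conditional_wait_analysis(tab, bounds = c(3, 5, 8, 60))
  expect_equal(res$auc, rep(0.5, 3), tolerance = 1e-12)
  expect_equal(res$pct_change, rep(0, 3), tolerance = 1e-12)
  # a 4 s wait falls in the short category
  expect_equal(as.character(res$category[1]), "short")
  expect_equal(res$n_rewarded[1] + res$n_unrewarded[1], 40)
})

test_that("tercile bounds split in-range presses into equal thirds", {
  set.seed(3)
  tab <- data.frame(waiting_time = runif(300, 3, 59),
                    next_waiting_time = runif(300, 3, 59),
                    rewarded = rep(c(TRUE, FALSE), 150),
                    choice = "stay")
  res <- conditional_wait_analysis(tab, bounds = "percentile")
  n_cell <- res$n_rewarded + res$n_unrewarded
  expect_equal(sum(n_cell), 300)
  expect_true(max(n_cell) - min(n_cell) <= 2)
})

test_that("switch probabilities reflect the generating rule", {
  params <- threshold_agent_params(loss_mean = 1, loss_sd = 0)
  sched <- vi_schedule(data.frame(box1_vi = 15, box2_vi = 15,
                                  n_rewards = 120))
  tab <- build_press_table(run_threshold_agent(params, sched, seed = 23))
  sp <- switch_probability(tab, bounds = "percentile")
  expect_equal(sp$p_switch_unrewarded, rep(1, 3))
  expect_equal(attr(sp, "p_switch_rewarded"), 0)
})

test_that("filter-width tuning honors its contract", {
  sessions <- lapply(1:2, function(i)
    run_mvt_agent(mvt_agent_params(), reversal_schedule(10, 30),
                  n_rewards_total = 120, seed = 30 + i))
  # single candidate returned unchanged
  expect_equal(as.numeric(tune_filter_width(sessions, 4)), 4)
  # the returned width attains the maximal pooled correlation
  w <- tune_filter_width(sessions, c(2, 5, 10, 20))
  rs <- attr(w, "correlations")
  expect_equal(rs[[as.character(as.numeric(w))]], max(rs))
  # duplicated candidates tie; the first (smallest) is returned
  w2 <- tune_filter_width(sessions, c(6, 6))
  expect_equal(as.numeric(w2), 6)
  # constant scheduled ratio cannot be tuned
  flat <- run_mvt_agent(mvt_agent_params(), reversal_schedule(20, 20),
                        n_rewards_total = 60, seed = 33)
  expect_error(tune_filter_width(list(flat), c(2, 5)), "constant")
})
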