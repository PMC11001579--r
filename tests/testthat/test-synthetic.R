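test_that("locomotion dwells at boxes and transits on switches", {
  sched <- vi_schedule(data.frame(box1_vi = 20, box2_vi = 20, n_rewards = 5))
  # a single switch in the middle
  df <- data.frame(time_s = c(10, 20, 40, 50),
                   box = c(1, 1, 2, 2),
                   rewarded = c(TRUE, FALSE, TRUE, FALSE),
                   block_index = 1)
  s <- behavioral_session(df, sched)
  loco <- generate_locomotion(s, jitter_sd = 0.3, seed = 2)
  expect_equal(median(diff(loco$time_s)), 1 / 6, tolerance = 1e-9)
  expect_true(all(loco$speed >= 0))
  # stationary except during the transit before the switch press at 40 s
  still <- loco$time_s < 36 | loco$time_s > 41
  expect_lt(max(loco$speed[still]), 15)
  # the transit covers the 120 cm separation
  transit <- loco$time_s >= 36.5 & loco$time_s <= 40.5
  travelled <- sum(abs(diff(loco$x[loco$time_s >= 36 & loco$time_s <= 41])))
  expect_gt(travelled, 100)
  expect_lt(travelled, 145)
  # without switches the animal stays put
  df2 <- df; df2$box <- 1
  loco2 <- generate_locomotion(behavioral_session(df2, sched),
                               jitter_sd = 0.3, seed = 3)
  expect_lt(diff(range(loco2$x)), 10)
})

test_that("a weightless population fires at its baseline", {
  b <- small_bundle()
  spec <- encoding_spec(n_units = 3, baseline_range = c(6, 6),
                        gains = c(wait = 0, reward_ratio = 0, press = 0,
                                  reward = 0, choice = 0, speed = 0,
                                  belief = 0),
                        noise_sd = 0)
  pop <- generate_population(b$session, b$locomotion, spec, seed = 5)
  dur <- max(b$session$time_s) + 2
  for (u in 1:3) {
    n <- length(pop$spikes[[u]])
    # Poisson count CI around rate 6
    expect_lt(abs(n / dur - 6), 4 * sqrt(6 / dur) + 0.1)
  }
})

test_that("a pure ramp unit fires more after longer waits", {
  b <- small_bundle()
  spec <- encoding_spec(n_units = 5, baseline_range = c(5, 5),
                        gains = c(wait = 2, reward_ratio = 0, press = 0,
                                  reward = 0, choice = 0, speed = 0,
                                  belief = 0),
                        noise_sd = 0)
  pop <- generate_population(b$session, b$locomotion, spec, seed = 6)
  w <- pop$ground_truth$weights[, "wait"]
  u <- which.max(abs(w))                 # clearest planted ramp
  tab <- build_press_table(b$session)
  cc <- prepress_counts(pop$spikes, tab$time_s)[, u]
  rho <- suppressWarnings(
    cor(cc, tab$waiting_time, method = "spearman")) * sign(w[u])
  expect_gt(rho, 0.25)
})

test_that("a pure locomotion unit is silenced by the projection", {
  b <- small_bundle()
  spec <- encoding_spec(n_units = 1, baseline_range = c(8, 8),
                        gains = c(wait = 0, reward_ratio = 0, press = 0,
                                  reward = 0, choice = 0, speed = 2,
                                  belief = 0),
                        noise_sd = 0)
  pop <- generate_population(b$session, b$locomotion, spec, seed = 7)
  rm <- bin_and_smooth(pop$spikes, 0, max(b$session$time_s) + 2,
                       width = 0.2, step = 0.2)
  out <- remove_locomotion(rm, b$locomotion)
  L <- forageVI:::interp_trace(b$locomotion$time_s, b$locomotion$speed,
                               forageVI:::rate_bin_centers(rm))
  expect_lt(abs(cor(out$rates[1, ], L)), 1e-10)
})

test_that("spiking is Poisson-like given the rate", {
  # constant-rate unit: Fano factor near 1, negligible lag correlation
  b <- small_bundle()
  spec <- encoding_spec(n_units = 1, baseline_range = c(10, 10),
                        gains = c(wait = 0, reward_ratio = 0, press = 0,
                                  reward = 0, choice = 0, speed = 0,
                                  belief = 0),
                        noise_sd = 0)
  pop <- generate_population(b$session, b$locomotion, spec, seed = 8)
  rm <- bin_and_smooth(pop$spikes, 0, max(b$session$time_s) + 2,
                       width = 0.5, step = 0.5, smooth_window = 0)
  counts <- rm$rates[1, ] * 0.5
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.15)
  expect_lt(abs(cor(counts[-1], counts[-length(counts)])), 0.1)
})

test_that("the belief latent is higher on switch presses", {
  sch <- vi_schedule(data.frame(box1_vi = 20, box2_vi = 20, n_rewards = 150))
  s <- run_mvt_agent(mvt_agent_params(belief_sd = 1.5, switching_cost = 0.9),
                     sch, seed = 31)
  eps <- session_meta <- attr(s, "meta")$press_eps
  is_switch <- c(FALSE, s$box[-1] != s$box[-nrow(s)])
  expect_gt(mean(eps[is_switch]) - mean(eps[!is_switch]), 0.5)
})

test_that("dataset bundles are reproducible and honor their contract", {
  cfg <- list(spec = encoding_spec(n_units = 4),
              schedule = vi_schedule(data.frame(box1_vi = 15, box2_vi = 15,
                                                n_rewards = 15)))
  b1 <- generate_dataset(cfg, seed = 99)
  b2 <- generate_dataset(cfg, seed = 99)
  expect_identical(b1$session$time_s, b2$session$time_s)
  expect_identical(b1$spikes, b2$spikes)
  expect_identical(b1$locomotion, b2$locomotion)
  # a different seed gives a different session
  b3 <- generate_dataset(cfg, seed = 100)
  expect_false(identical(b1$session$time_s, b3$session$time_s))
  # seed is mandatory
  expect_error(generate_dataset(cfg), "seed")
  # units = 0 gives a behavioral-only bundle
  cfg0 <- cfg; cfg0$spec <- encoding_spec(n_units = 0)
  b0 <- generate_dataset(cfg0, seed = 1)
  expect_length(b0$spikes, 0)
  expect_true(is_behavioral_session(b0$session))
})

test_that("the default bundle feeds every downstream stage", {
  b <- small_bundle()
  expect_true(is_behavioral_session(b$session))
  prep <- prepare_analysis(b)
  expect_equal(nrow(prep$Xm), nrow(prep$Ym))
  expect_equal(ncol(prep$Xm), 51)
  expect_gte(max(as.integer(prep$blocks)), 2)
  expect_true(all(sort(unique(prep$folds)) %in% unique(as.integer(prep$blocks))))
  m <- fit_scca(prep$Xm, prep$Ym, K = 6, fullness = 0.3)
  expect_length(m$cors, 6)
  expect_true(all(diff(m$cors) <= 1e-9))
})
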