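test_that("binning converts single spikes to the right rate", {
  spikes <- structure(list(u1 = c(5.5), u2 = numeric(0)),
                      class = "spike_train_set")
  rm <- bin_and_smooth(spikes, 0, 10, width = 1, step = 1, smooth_window = 0)
  expect_equal(dim(rm$rates), c(2, 10))
  expect_equal(rm$rates[1, ], c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0))
  expect_equal(rm$rates[2, ], rep(0, 10))   # empty unit: all-zero row
})

test_that("boxcar smoothing conserves the total spike count", {
  set.seed(4)
  spikes <- structure(list(u = sort(runif(400, 5, 45))),
                      class = "spike_train_set")
  raw <- bin_and_smooth(spikes, 0, 50, width = 0.2, step = 0.2,
                        smooth_window = 0)
  sm <- bin_and_smooth(spikes, 0, 50, width = 0.2, step = 0.2,
                       smooth_window = 1)
  expect_equal(sum(sm$rates) * 0.2, sum(raw$rates) * 0.2, tolerance = 1e-9)
  expect_equal(sum(raw$rates) * 0.2, 400)
})

test_that("smoothed rate of a constant-rate train approximates the rate", {
  set.seed(5)
  rate <- 12
  tt <- cumsum(rexp(3000, rate))
  tt <- tt[tt < 200]
  spikes <- structure(list(u = tt), class = "spike_train_set")
  rm <- bin_and_smooth(spikes, 0, 200, width = 0.2, step = 0.2)
  interior <- 50:900
  expect_lt(abs(mean(rm$rates[1, interior]) - rate), 1)
})

test_that("press-locked slices reproduce a manual three-press binning", {
  presses <- c(10, 20, 30)
  spikes <- structure(list(u = c(9.25, 9.95, 10.45, 19.25, 19.95, 20.45,
                                 29.25, 29.95, 30.45)),
                      class = "spike_train_set")
  pl <- press_locked(spikes, presses, window = c(-1, 1), min_separation = 2,
                     t_end = 40)
  expect_equal(dim(pl$tensor), c(3, 10, 1))
  # identical spike patterns -> identical slices
  expect_equal(pl$tensor[1, , 1], pl$tensor[2, , 1])
  expect_equal(pl$tensor[1, , 1], pl$tensor[3, , 1])
  # manual binning: spikes at -0.75, -0.05, +0.45 relative to the press
  manual <- numeric(10)
  rel <- c(-0.75, -0.05, 0.45)
  for (r in rel) {
    j <- floor((r + 1) / 0.2) + 1
    manual[j] <- manual[j] + 1 / 0.2
  }
  expect_equal(pl$tensor[1, , 1], manual)
})

test_that("press-locked exclusions follow the separation and edge rules", {
  spikes <- structure(list(u = seq(0.5, 49.5, by = 0.5)),
                      class = "spike_train_set")
  # second press only 1 s after the first -> excluded
  pl <- press_locked(spikes, c(10, 11, 20), window = c(-2, 1), t_end = 50)
  expect_equal(pl$press_index, c(1, 3))
  # press at the very start falls off the window -> dropped with warning
  expect_warning(
    pl2 <- press_locked(spikes, c(1, 20), window = c(-2, 1), t_end = 50),
    "edge")
  expect_equal(pl2$press_index, 2)
})

test_that("pre-press counts use the -1.1 to -0.1 s interval", {
  spikes <- structure(list(
    active = c(8.95, 9.5, 9.85, 9.95),
    silent_before = c(10.5, 11)), class = "spike_train_set")
  cc <- prepress_counts(spikes, c(10, 30))
  expect_equal(unname(cc[1, "active"]), 3)   # 8.95 outside; 9.95 > -0.1 excluded
  expect_equal(unname(cc[1, "silent_before"]), 0)
  expect_equal(unname(cc[2, ]), c(active = 0, silent_before = 0),
               ignore_attr = TRUE)
})

test_that("engagement mask equals a brute-force distance scan", {
  presses <- c(3, 7, 40, 44, 120)
  centers <- seq(0.1, 150, by = 0.2)
  got <- engagement_mask(presses, centers, max_gap = 5)
  brute <- sapply(centers, function(tc) min(abs(tc - presses)) <= 5)
  expect_equal(got, brute)
  # presses every 4 s keep every bin engaged
  expect_true(all(engagement_mask(seq(0, 100, 4), seq(0.1, 99, 0.2))))
  # a 60 s gap disengages the middle
  m <- engagement_mask(c(10, 70), seq(0.1, 80, 0.2))
  expect_false(any(m[seq(0.1, 80, 0.2) > 15.2 & seq(0.1, 80, 0.2) < 64.8]))
})

test_that("locomotion projection removes exactly the speed component", {
  set.seed(6)
  n <- 500
  L <- abs(rnorm(n, 10, 4))
  R <- rbind(3 * L,                                  # pure locomotion unit
             rnorm(n),                               # random unit
             rnorm(n) + 0.5 * L)                     # mixed unit
  rm <- rate_matrix(R, 0, 0.2, 0.2)
  out <- remove_locomotion(rm, L)
  # the pure-locomotion unit collapses to (a constant) zero-variance row
  expect_lt(sd(out$rates[1, ]), 1e-10)
  for (k in 2:3) expect_lt(abs(cor(out$rates[k, ], L)), 1e-10)
  # idempotence
  out2 <- remove_locomotion(out, L)
  expect_lt(max(abs(out2$rates - out$rates)), 1e-12)
  # projection never increases a row's sum of squares (centered energy)
  for (k in 1:3) {
    expect_lte(sum(scale(out$rates[k, ], scale = FALSE)^2),
               sum(scale(R[k, ], scale = FALSE)^2) + 1e-9)
  }
})

test_that("a unit orthogonal to locomotion passes through unchanged", {
  n <- 400
  L <- rep(c(1, 3), n / 2)
  r <- rep(c(1, 1, -1, -1), n / 4)      # centered, orthogonal to centered L
  stopifnot(abs(sum((L - mean(L)) * (r - mean(r)))) < 1e-9)
  rm <- rate_matrix(matrix(r, 1), 0, 0.2, 0.2)
  out <- remove_locomotion(rm, L)
  expect_equal(out$rates[1, ], r, tolerance = 1e-12)
})

test_that("zero locomotion leaves rates untouched with a warning", {
  rm <- rate_matrix(matrix(rnorm(100), 2), 0, 0.2, 0.2)
  expect_warning(out <- remove_locomotion(rm, rep(0, 50)), "zero")
  expect_equal(out$rates, rm$rates)
})

test_that("the bare (uncentered) projection zeroes the dot product", {
  set.seed(7)
  L <- abs(rnorm(300, 5, 2))
  R <- matrix(rnorm(600) + 2, 2)
  rm <- rate_matrix(R, 0, 0.2, 0.2)
  out <- remove_locomotion(rm, L, center = FALSE)
  for (k in 1:2) expect_lt(abs(sum(out$rates[k, ] * L)), 1e-8)
})
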