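#' Parameters for the threshold (win-stay/lose-switch) agent
#'
#' The threshold agent stays on its current box until the run of
#' consecutive unrewarded presses reaches a per-visit threshold drawn from
#' a Gaussian. It is blind to the schedules and to elapsed time: its
#' choices depend only on the sequence of reward outcomes.
#'
#' @param loss_mean mean of the Gaussian threshold on consecutive losses.
#' @param loss_sd standard deviation of that threshold (>= 0).
#' @param wait_meanlog,wait_sdlog log-normal parameters of the wait
#'   sampler (seconds between presses on the same box).
#' @param travel_time seconds added when switching boxes (the boxes sit
#'   120 cm apart).
#' @return a parameter list of class `threshold_agent_params`.
#' @export
threshold_agent_params <- function(loss_mean = 3, loss_sd = 1.5,
                                   wait_meanlog = log(6), wait_sdlog = 0.5,
                                   travel_time = 3) {
  stopifnot(loss_sd >= 0, travel_time >= 0)
  structure(list(loss_mean = loss_mean, loss_sd = loss_sd,
                 wait_meanlog = wait_meanlog, wait_sdlog = wait_sdlog,
                 travel_time = travel_time),
            class = "threshold_agent_params")
}

#' Parameters for the marginal-value-theorem (MVT) agent
#'
#' The MVT agent has complete information about the schedules. It tracks
#' the probability of reward availability on both boxes, presses its
#' current box once that probability reaches `theta_press`, and switches
#' when the other box's availability probability exceeds the current
#' box's by `switching_cost`. An optional AR(1) belief-noise process
#' perturbs the agent's subjective availability estimates (on the
#' log-odds scale), tying its choice variability to a latent that the
#' synthetic neural generator can share.
#'
#' @param switching_cost fixed probability margin the other box must
#'   exceed before the agent switches (>= 0).
#' @param theta_press subjective availability at which the agent presses
#'   the current box (0 < theta_press < 1).
#' @param wait_policy how the agent times its presses:
#'   `"threshold"` presses once the current box's availability reaches
#'   `theta_press` (jittered per wait by `press_jitter_sd`);
#'   `"sampled"` draws each wait from a log-normal
#'   (`wait_meanlog`, `wait_sdlog`), pressing on schedule-independent
#'   times while the MVT switch rule can still preempt the press.
#' @param press_jitter_sd s.d. (log-odds scale) of the private per-wait
#'   jitter on the press threshold; varies the waiting times without
#'   entering the belief latent (threshold policy only).
#' @param wait_meanlog,wait_sdlog log-normal wait parameters (sampled
#'   policy only).
#' @param travel_time seconds to move between boxes.
#' @param decision_dt resolution of the agent's internal decision clock,
#'   seconds.
#' @param belief_sd stationary s.d. of the AR(1) belief noise (0 disables
#'   it).
#' @param belief_tau AR(1) time constant, seconds.
#' @return a parameter list of class `mvt_agent_params`.
#' @export
mvt_agent_params <- function(switching_cost = 0.8, theta_press = 0.6,
                             wait_policy = c("threshold", "sampled"),
                             press_jitter_sd = 0.8,
                             wait_meanlog = log(8), wait_sdlog = 0.8,
                             travel_time = 3, decision_dt = 0.25,
                             belief_sd = 0, belief_tau = 10) {
  wait_policy <- match.arg(wait_policy)
  stopifnot(switching_cost >= 0, theta_press > 0, theta_press < 1,
            press_jitter_sd >= 0, decision_dt > 0, belief_sd >= 0,
            belief_tau > 0)
  structure(list(switching_cost = switching_cost, theta_press = theta_press,
                 wait_policy = wait_policy,
                 press_jitter_sd = press_jitter_sd,
                 wait_meanlog = wait_meanlog, wait_sdlog = wait_sdlog,
                 travel_time = travel_time, decision_dt = decision_dt,
                 belief_sd = belief_sd, belief_tau = belief_tau),
            class = "mvt_agent_params")
}

#' Simulate the threshold agent on a VI schedule
#'
#' @param params a [threshold_agent_params()].
#' @param schedule a [vi_schedule()]; blocks recycle if more rewards are
#'   requested than the block list provides.
#' @param n_rewards_total stop after this many delivered rewards
#'   (default: one pass through the schedule's blocks).
#' @param seed integer seed for this simulation.
#' @param outcome_fn optional replay hook: a `function(press_index, box,
#'   time)` returning the rewarded flag, used instead of the simulated
#'   availability process (for blindness checks). Block accounting still
#'   follows delivered rewards.
#' @return a [behavioral_session()].
#' @export
run_threshold_agent <- function(params, schedule, n_rewards_total = NULL,
                                seed = 1L, outcome_fn = NULL) {
  stopifnot(inherits(params, "threshold_agent_params"),
            inherits(schedule, "vi_schedule"))
  if (is.null(n_rewards_total)) n_rewards_total <- sum(schedule$blocks$n_rewards)
  if (n_rewards_total <= 0) stop("n_rewards_total must be positive")
  with_seed(seed, {
    sim <- new_session_sim(schedule, n_rewards_total, lazy = is.null(outcome_fn))
    box <- sample(1:2, 1)
    t <- stats::rlnorm(1, params$wait_meanlog, params$wait_sdlog)
    losses <- 0
    threshold <- stats::rnorm(1, params$loss_mean, params$loss_sd)
    while (!sim$done()) {
      rewarded <- sim$press(box, t, outcome_fn)
      if (rewarded) {
        losses <- 0
      } else {
        losses <- losses + 1
      }
      wait <- stats::rlnorm(1, params$wait_meanlog, params$wait_sdlog)
      if (!rewarded && losses >= threshold) {
        box <- 3L - box
        losses <- 0
        threshold <- stats::rnorm(1, params$loss_mean, params$loss_sd)
        wait <- wait + params$travel_time
      }
      t <- t + wait
    }
    sim$session(meta = list(agent = "threshold", params = unclass(params)))
  })
}

#' Simulate the MVT agent on a VI schedule
#'
#' @inheritParams run_threshold_agent
#' @param params an [mvt_agent_params()].
#' @return a [behavioral_session()]; when belief noise is enabled the
#'   session's `meta` carries the noise trace (`belief` data.frame with
#'   `time_s`, `eps`) and the per-press noise value (`press_eps`).
#' @export
run_mvt_agent <- function(params, schedule, n_rewards_total = NULL,
                          seed = 1L) {
  stopifnot(inherits(params, "mvt_agent_params"),
            inherits(schedule, "vi_schedule"))
  if (is.null(n_rewards_total)) n_rewards_total <- sum(schedule$blocks$n_rewards)
  if (n_rewards_total <= 0) stop("n_rewards_total must be positive")
  dd <- params$decision_dt
  ## AR(1) x_{t+dd} = a x_t + sqrt(1-a^2) sd z, stationary s.d. belief_sd
  a <- exp(-dd / params$belief_tau)
  innov_sd <- params$belief_sd * sqrt(1 - a^2)
  with_seed(seed, {
    sim <- new_session_sim(schedule, n_rewards_total, lazy = TRUE)
    box <- sample(1:2, 1)
    last_press <- c(-Inf, -Inf)   # availability accrues from session start
    start_accrual <- c(0, 0)
    t <- dd
    eps <- stats::rnorm(1, 0, params$belief_sd)
    eps_t <- numeric(0); eps_v <- numeric(0)
    press_eps <- numeric(0)
    dt <- schedule$dt
    ## private per-wait press timing: jittered availability threshold or
    ## a sampled schedule-independent wait
    theta_lo <- stats::qlogis(params$theta_press)
    sampled <- params$wait_policy == "sampled"
    theta_now <- stats::plogis(theta_lo +
                                 stats::rnorm(1, 0, params$press_jitter_sd))
    next_wait <- stats::rlnorm(1, params$wait_meanlog, params$wait_sdlog)
    t_last_press <- 0
    while (!sim$done()) {
      eps <- a * eps + stats::rnorm(1, 0, innov_sd)
      if (params$belief_sd > 0) { eps_t <- c(eps_t, t); eps_v <- c(eps_v, eps) }
      vis <- sim$current_vis()
      other <- 3L - box
      el_cur <- t - max(last_press[box], start_accrual[box])
      el_oth <- t - max(last_press[other], start_accrual[other])
      p_cur <- prob_reward_available(max(el_cur, 0), vis[box], dt)
      p_oth <- prob_reward_available(max(el_oth, 0), vis[other], dt)
      ## the belief latent perturbs the subjective estimate of the
      ## ALTERNATIVE (unobserved) box on the log-odds scale: positive
      ## noise inflates it and triggers early switches
      p_oth_s <- stats::plogis(stats::qlogis(pmin(pmax(p_oth, 1e-12), 1 - 1e-12)) + eps)
      pressed <- FALSE
      press_due <- if (sampled) t - t_last_press >= next_wait
                   else p_cur >= theta_now
      if (p_oth_s > p_cur + params$switching_cost) {
        box <- other
        t <- t + params$travel_time
        if (sampled) {
          ## relocate, then wait a fresh interval before pressing
          t_last_press <- t
          next_wait <- stats::rlnorm(1, params$wait_meanlog,
                                     params$wait_sdlog)
        } else {
          pressed <- TRUE
        }
      } else if (press_due) {
        pressed <- TRUE
      }
      if (pressed) {
        sim$press(box, t, NULL)
        press_eps <- c(press_eps, eps)
        last_press[box] <- t
        t_last_press <- t
        theta_now <- stats::plogis(theta_lo +
                                     stats::rnorm(1, 0, params$press_jitter_sd))
        next_wait <- stats::rlnorm(1, params$wait_meanlog, params$wait_sdlog)
      }
      t <- t + dd
    }
    meta <- list(agent = "mvt", params = unclass(params),
                 press_eps = press_eps)
    if (params$belief_sd > 0)
      meta$belief <- data.frame(time_s = eps_t, eps = eps_v)
    sim$session(meta = meta)
  })
}

## Shared event-driven session bookkeeping for both agents: tracks the
## availability tracker, the block counter (advance after the block's
## n_rewards-th delivered reward, silently), and the press log.
new_session_sim <- function(schedule, n_rewards_total, lazy = TRUE) {
  blocks <- schedule$blocks
  dt <- schedule$dt
  block_row <- 1L
  block_rewards <- 0L
  total_rewards <- 0L
  times <- numeric(0); boxes <- integer(0)
  rewards <- logical(0); block_ix <- integer(0)
  cur_vis <- function() {
    r <- ((block_row - 1L) %% nrow(blocks)) + 1L
    c(blocks$box1_vi[r], blocks$box2_vi[r])
  }
  tracker <- if (lazy) new_avail_tracker(cur_vis(), dt) else NULL
  max_presses <- max(100L * n_rewards_total, 1000L)
  list(
    current_vis = cur_vis,
    done = function() total_rewards >= n_rewards_total ||
      length(times) >= max_presses,
    press = function(box, time, outcome_fn) {
      if (length(times) && time <= times[length(times)])
        stop("presses must advance in time")
      if (is.null(outcome_fn)) {
        res <- tracker_press(tracker, box, time)
        tracker <<- res$tracker
        rewarded <- res$rewarded
      } else {
        rewarded <- isTRUE(outcome_fn(length(times) + 1L, box, time))
      }
      times <<- c(times, time); boxes <<- c(boxes, box)
      rewards <<- c(rewards, rewarded)
      block_ix <<- c(block_ix, ((block_row - 1L) %% nrow(blocks)) + 1L)
      if (rewarded) {
        total_rewards <<- total_rewards + 1L
        block_rewards <<- block_rewards + 1L
        r <- ((block_row - 1L) %% nrow(blocks)) + 1L
        if (block_rewards >= blocks$n_rewards[r]) {
          block_row <<- block_row + 1L
          block_rewards <<- 0L
          if (!is.null(tracker))
            tracker <<- tracker_reschedule(tracker, cur_vis(), time)
        }
      }
      rewarded
    },
    session = function(meta = list()) {
      behavioral_session(
        data.frame(time_s = times, box = boxes, rewarded = rewards,
                   block_index = block_ix),
        schedule, meta = meta)
    }
  )
}

#' Generalized matching-law fit
#'
#' Regresses the log press ratio on the log obtained-reward ratio, one
#' point per schedule block, pooling the supplied sessions. A slope below
#' 1 is undermatching; above 1, overmatching.
#'
#' @param sessions a [behavioral_session()] or list of them.
#' @return a `matching_fit`: `slope`, `intercept`, and the per-block
#'   `points` (`log_reward_ratio`, `log_press_ratio`).
#' @export
matching_law_fit <- function(sessions) {
  if (is_behavioral_session(sessions)) sessions <- list(sessions)
  pts <- do.call(rbind, lapply(seq_along(sessions), function(si) {
    s <- sessions[[si]]
    do.call(rbind, lapply(split(as.data.frame(s), s$block_index), function(b) {
      n1 <- sum(b$box == 1); n2 <- sum(b$box == 2)
      r1 <- sum(b$rewarded & b$box == 1); r2 <- sum(b$rewarded & b$box == 2)
      data.frame(session = si, block = b$block_index[1],
                 press1 = n1, press2 = n2, rew1 = r1, rew2 = r2)
    }))
  }))
  ok <- pts$press1 > 0 & pts$press2 > 0 & pts$rew1 > 0 & pts$rew2 > 0
  if (any(!ok))
    warning(sum(!ok), " block(s) with a zero press or reward count excluded")
  pts <- pts[ok, , drop = FALSE]
  pts$log_press_ratio <- log(pts$press1 / pts$press2)
  pts$log_reward_ratio <- log(pts$rew1 / pts$rew2)
  if (length(unique(round(pts$log_reward_ratio, 10))) < 2)
    stop("matching fit needs at least 2 distinct reward-ratio conditions")
  fit <- stats::lm(log_press_ratio ~ log_reward_ratio, data = pts)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 points = pts),
            class = "matching_fit")
}

#' @export
print.matching_fit <- function(x, ...) {
  cat(sprintf("<matching_fit> slope = %.3f, intercept = %.3f, %d block(s)\n",
              x$slope, x$intercept, nrow(x$points)))
  invisible(x)
}
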