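#' Concurrent variable-interval schedule
#'
#' A VI schedule describes, block by block, the mean waiting time (in
#' seconds) before a reward becomes available at each of the two boxes.
#' Availability is simulated as a latching Bernoulli (telegraph) process:
#' in every time bin of width `dt` an unavailable box becomes available
#' with probability `dt / vi`, and once available a reward stays available
#' until the box is pressed. A block ends after `n_rewards` rewards have
#' been delivered, and the schedule switches to the next block silently.
#'
#' @param blocks a data.frame with columns `box1_vi`, `box2_vi` (seconds)
#'   and `n_rewards` (rewards per block), one row per block. A numeric
#'   vector of length 3 is accepted for a single block.
#' @param dt availability-simulation bin width in seconds (default 0.01,
#'   i.e. 10 ms).
#' @return an object of class `vi_schedule`.
#' @examples
#' sched <- vi_schedule(data.frame(box1_vi = 15, box2_vi = 25, n_rewards = 34))
#' @export
vi_schedule <- function(blocks, dt = 0.01) {
  if (is.numeric(blocks) && length(blocks) == 3L) {
    blocks <- data.frame(box1_vi = blocks[1], box2_vi = blocks[2],
                         n_rewards = blocks[3])
  }
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("box1_vi", "box2_vi", "n_rewards") %in% names(blocks)))
  if (any(blocks$box1_vi <= 0) || any(blocks$box2_vi <= 0))
    stop("all VI means must be positive")
  if (any(blocks$n_rewards <= 0))
    stop("n_rewards must be positive in every block")
  if (dt <= 0) stop("dt must be positive")
  if (dt >= min(blocks$box1_vi, blocks$box2_vi))
    stop("dt must be smaller than the smallest VI mean")
  structure(list(blocks = blocks, dt = dt), class = "vi_schedule")
}

#' @export
print.vi_schedule <- function(x, ...) {
  cat("<vi_schedule>", nrow(x$blocks), "block(s), dt =", x$dt, "s\n")
  print(x$blocks, row.names = FALSE)
  invisible(x)
}

#' Closed-form probability of reward availability
#'
#' Under a latching Bernoulli VI process with per-bin availability
#' probability `dt / vi`, the probability that a reward is waiting after
#' `t` seconds of not pressing is `1 - (1 - dt/vi)^(t/dt)`. It increases
#' exponentially toward 1 with waiting time; its continuous-time limit is
#' `1 - exp(-t/vi)`.
#'
#' @param t waiting time(s) since the preceding press, seconds (vectorized).
#' @param vi schedule mean, seconds.
#' @param dt simulation bin width, seconds.
#' @return probability in \[0, 1\], same length as `t`.
#' @examples
#' prob_reward_available(20, vi = 20, dt = 0.01)
#' @export
prob_reward_available <- function(t, vi, dt = 0.01) {
  if (vi <= 0) stop("vi must be positive")
  if (dt <= 0 || dt > vi) stop("dt must satisfy 0 < dt <= vi")
  if (any(t < 0)) stop("waiting time t must be nonnegative")
  ## log-space for numerical robustness at large t/dt
  1 - exp((t / dt) * log1p(-dt / vi))
}

#' Two-box availability state
#'
#' @param dt bin width in seconds (used by the stepping simulator).
#' @return a `box_state`: per-box availability flag and time since the
#'   last press on that box.
#' @export
box_state <- function(dt = 0.01) {
  structure(list(available = c(FALSE, FALSE),
                 time_since_press = c(0, 0),
                 dt = dt),
            class = "box_state")
}

#' Advance availability by one simulation bin
#'
#' Per-bin telegraph stepping: each unavailable box becomes available with
#' probability `dt / vi`; available boxes latch. This is the literal
#' Bernoulli scheme; [sample_availability_delay()] is its exact lazy
#' equivalent used by the event-driven simulator.
#'
#' @param state a [box_state()].
#' @param vis length-2 vector of current VI means (seconds).
#' @return the updated state after one bin of width `state$dt`.
#' @export
step_availability <- function(state, vis) {
  stopifnot(inherits(state, "box_state"), length(vis) == 2L)
  p <- state$dt / vis
  flip <- !state$available & (stats::runif(2) < p)
  state$available <- state$available | flip
  state$time_since_press <- state$time_since_press + state$dt
  state
}

#' Sample the delay until a reward becomes available
#'
#' Draws the first-success bin of the per-bin Bernoulli process (a
#' geometric variable with success probability `dt/vi`) and returns the
#' corresponding delay in seconds. Distributionally identical to stepping
#' [step_availability()] until the box turns available.
#'
#' @inheritParams prob_reward_available
#' @param n number of delays to draw.
#' @return delay(s) in seconds, positive multiples of `dt`.
#' @export
sample_availability_delay <- function(n, vi, dt = 0.01) {
  if (vi <= 0 || dt <= 0) stop("vi and dt must be positive")
  (stats::rgeom(n, prob = dt / vi) + 1) * dt
}

#' Press a box and resolve the outcome
#'
#' A press collects the reward if one is available on the pressed box,
#' which resets that box's availability; the other box is untouched.
#' Pressing an unavailable box delivers nothing and, because the telegraph
#' process is memoryless, leaves the availability dynamics unchanged.
#'
#' @param state a [box_state()].
#' @param box which box was pressed (1 or 2).
#' @return list with `rewarded` flag and the updated `state` (the pressed
#'   box's availability cleared and its press clock reset).
#' @export
press_box <- function(state, box) {
  stopifnot(inherits(state, "box_state"), box %in% c(1, 2))
  rewarded <- state$available[box]
  state$available[box] <- FALSE
  state$time_since_press[box] <- 0
  list(rewarded = rewarded, state = state)
}

## Internal event-driven availability tracker used by the agents.
## Keeps, per box, the absolute time at which the pending reward becomes
## available. Memorylessness of the geometric delay makes the lazy draws
## exact: a fresh delay is drawn only when the process restarts (session
## start, reward collection) or when the VI mean changes mid-delay.
new_avail_tracker <- function(vis, dt, t0 = 0) {
  list(avail_at = t0 + c(sample_availability_delay(1, vis[1], dt),
                         sample_availability_delay(1, vis[2], dt)),
       vis = vis, dt = dt)
}

tracker_press <- function(tr, box, time) {
  rewarded <- tr$avail_at[box] <= time
  if (rewarded) {
    tr$avail_at[box] <- time + sample_availability_delay(1, tr$vis[box], tr$dt)
  }
  list(rewarded = rewarded, tracker = tr)
}

## Re-sample pending delays when the schedule changes at time t_change.
tracker_reschedule <- function(tr, vis, t_change) {
  for (b in 1:2) {
    if (tr$avail_at[b] > t_change && tr$vis[b] != vis[b]) {
      tr$avail_at[b] <- t_change + sample_availability_delay(1, vis[b], tr$dt)
    }
  }
  tr$vis <- vis
  tr
}
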