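#' Synthetic locomotion trace
#'
#' Emulates an overhead-camera position trace for a two-box arena: the
#' animal dwells at the pressed box, walks to the other box during the
#' `travel_time` seconds preceding a switch press (smooth cosine
#' transit), and jitters around its station otherwise. Sampled at
#' `rate` frames per second; speed is the magnitude of the position
#' difference between consecutive frames divided by their time
#' difference.
#'
#' @param session a [behavioral_session()].
#' @param box_distance separation of the two boxes, cm (default 120).
#' @param rate sampling rate, frames/s (default 6).
#' @param jitter_sd s.d. of smoothed positional jitter, cm.
#' @param travel_time seconds taken by a transit.
#' @param seed integer seed.
#' @return a `locomotion_trace` data.frame: `time_s`, `x`, `y` (cm) and
#'   `speed` (cm/s; first sample 0).
#' @export
generate_locomotion <- function(session, box_distance = 120, rate = 6,
                                jitter_sd = 1.5, travel_time = 3,
                                seed = 1L) {
  stopifnot(is_behavioral_session(session))
  s <- as.data.frame(session)
  t_end <- max(s$time_s) + 2
  with_seed(seed, {
    ts <- seq(0, t_end, by = 1 / rate)
    box_x <- c(0, box_distance)
    ## station occupied at each frame: the box last pressed (before the
    ## first press, the box about to be pressed); transits overwrite the
    ## window before each switch press
    press_t <- s$time_s; press_box <- s$box
    prev <- findInterval(ts, press_t)
    x <- box_x[press_box[pmax(prev, 1L)]]
    ## smooth transits: for each switch press, ramp during the preceding
    ## travel window
    sw <- which(c(FALSE, press_box[-1] != press_box[-length(press_box)]))
    for (i in sw) {
      t1 <- press_t[i]; t0 <- t1 - travel_time
      seg <- ts >= t0 & ts <= t1
      frac <- (ts[seg] - t0) / travel_time
      from <- box_x[press_box[i - 1]]; to <- box_x[press_box[i]]
      x[seg] <- from + (to - from) * (1 - cos(pi * frac)) / 2
    }
    ## smoothed Gaussian jitter on both coordinates
    smooth_noise <- function(n) {
      z <- stats::rnorm(n, 0, jitter_sd)
      k <- min(7, n)
      as.numeric(stats::filter(z, rep(1 / k, k), sides = 2, circular = TRUE))
    }
    x <- x + smooth_noise(length(ts))
    y <- 30 + smooth_noise(length(ts))
    sp <- c(0, sqrt(diff(x)^2 + diff(y)^2) / diff(ts))
    structure(data.frame(time_s = ts, x = x, y = y, speed = sp),
              box_distance = box_distance,
              class = c("locomotion_trace", "data.frame"))
  })
}

#' Encoding specification for a synthetic population
#'
#' Each unit's firing rate is `softplus(baseline + sum(weights * latent
#' channels))` on a 10 ms grid; weights are drawn independently per unit
#' and channel (mixed selectivity). Channels are z-scored before
#' weighting, so gains are in comparable units.
#'
#' @param n_units number of units (default 60).
#' @param baseline_range uniform range of baseline rates, spikes/s.
#' @param gains named s.d. of unit weights per latent channel:
#'   `wait` (within-interval ramp), `reward_ratio`, `press`, `reward`,
#'   `choice` (post-event kernels), `speed` (locomotion), `belief`
#'   (shared belief-noise latent).
#' @param noise_sd s.d. of each unit's private slow noise channel.
#' @return an `encoding_spec` list.
#' @export
encoding_spec <- function(n_units = 60,
                          baseline_range = c(2, 10),
                          gains = c(wait = 0.8, reward_ratio = 0.8,
                                    press = 1, reward = 1, choice = 0.8,
                                    speed = 0.6, belief = 1.5),
                          noise_sd = 0.3) {
  stopifnot(n_units >= 0, all(baseline_range > 0), noise_sd >= 0)
  need <- c("wait", "reward_ratio", "press", "reward", "choice", "speed",
            "belief")
  if (!all(need %in% names(gains)))
    stop("gains must name all channels: ", paste(need, collapse = ", "))
  structure(list(n_units = n_units, baseline_range = baseline_range,
                 gains = gains[need], noise_sd = noise_sd),
            class = "encoding_spec")
}

## latent channel matrix on the simulation grid (columns z-scored)
build_latent_channels <- function(session, locomotion, grid_dt = 0.01) {
  s <- as.data.frame(session)
  t_end <- max(s$time_s) + 2
  tg <- seq(0, t_end, by = grid_dt)
  press_t <- s$time_s
  last <- findInterval(tg, press_t)
  ## waiting-time ramp: elapsed time since the last press (0 before first)
  wait <- ifelse(last == 0, tg, tg - press_t[pmax(last, 1)])
  ## reward ratio: piecewise constant, jumps at presses
  rrp <- reward_ratio_series(s$box, s$rewarded, width = 5)
  rr <- c(0.5, rrp)[last + 1L]
  ev_kernel <- function(events, tau, span) {
    out <- numeric(length(tg))
    if (!length(events)) return(out)
    for (e in events) {
      i0 <- findInterval(e, tg) + 1L
      i1 <- min(length(tg), i0 + round(span / grid_dt))
      if (i0 > length(tg)) next
      seg <- i0:i1
      out[seg] <- out[seg] + exp(-(tg[seg] - e) / tau)
    }
    out
  }
  press_k <- ev_kernel(press_t, tau = 0.2, span = 1)
  reward_k <- ev_kernel(press_t[s$rewarded], tau = 0.3, span = 2)
  switches <- press_t[c(FALSE, s$box[-1] != s$box[-nrow(s)])]
  choice_k <- ev_kernel(switches, tau = 0.2, span = 1)
  speed <- if (is.null(locomotion)) numeric(length(tg)) else
    interp_trace(locomotion$time_s, locomotion$speed, tg)
  belief <- session_meta(session)$belief
  bel <- if (is.null(belief)) numeric(length(tg)) else
    interp_trace(belief$time_s, belief$eps, tg)
  ch <- cbind(wait = wait, reward_ratio = rr, press = press_k,
              reward = reward_k, choice = choice_k, speed = speed,
              belief = bel)
  list(time = tg, raw = ch, z = zscore_cols(ch))
}

#' Generate a mixed-selectivity Poisson population
#'
#' Draws unit weights per the [encoding_spec()], builds latent task
#' channels from the session (within-interval waiting-time ramp,
#' piecewise-constant reward ratio, 200 ms-scale post-press/-reward/
#' -choice kernels, locomotion speed, and the agent's shared belief-noise
#' latent when present), and samples inhomogeneous Poisson spike trains
#' with rate `softplus(baseline + weights %*% channels)` on a 10 ms grid.
#'
#' @param session a [behavioral_session()].
#' @param locomotion a [generate_locomotion()] trace (or `NULL`).
#' @param spec an [encoding_spec()].
#' @param grid_dt simulation bin width, seconds (default 0.01).
#' @param seed integer seed.
#' @return list with `spikes` (a `spike_train_set`: per-unit sorted spike
#'   time vectors) and `ground_truth` (channel time series, true weights,
#'   baselines, grid).
#' @export
generate_population <- function(session, locomotion, spec = encoding_spec(),
                                grid_dt = 0.01, seed = 1L) {
  stopifnot(is_behavioral_session(session), inherits(spec, "encoding_spec"))
  lat <- build_latent_channels(session, locomotion, grid_dt)
  U <- spec$n_units
  with_seed(seed, {
    nC <- ncol(lat$z)
    W <- matrix(stats::rnorm(U * nC), U, nC) *
      matrix(spec$gains, U, nC, byrow = TRUE)
    colnames(W) <- colnames(lat$z)
    base_rate <- stats::runif(U, spec$baseline_range[1], spec$baseline_range[2])
    b <- log(expm1(base_rate))        # softplus^{-1}: softplus(b) = base_rate
    nT <- length(lat$time)
    ## slow private noise per unit (AR(1), tau 5 s)
    a <- exp(-grid_dt / 5)
    spikes <- vector("list", U)
    for (u in seq_len(U)) {
      drive <- as.numeric(lat$z %*% W[u, ])
      if (spec$noise_sd > 0) {
        z <- stats::rnorm(nT, 0, spec$noise_sd * sqrt(1 - a^2))
        noise <- as.numeric(stats::filter(z, a, method = "recursive"))
        drive <- drive + noise
      }
      rate <- softplus(b[u] + drive)
      counts <- stats::rpois(nT, rate * grid_dt)
      hit <- which(counts > 0)
      tt <- rep(lat$time[hit], counts[hit]) +
        stats::runif(sum(counts[hit]), 0, grid_dt)
      spikes[[u]] <- sort(tt)
    }
    names(spikes) <- paste0("unit", seq_len(U))
    list(spikes = structure(spikes, class = "spike_train_set"),
         ground_truth = list(time = lat$time, channels = lat$z,
                             channels_raw = lat$raw, weights = W,
                             baseline = base_rate))
  })
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat("<spike_train_set>", length(x), "units,",
      sum(lengths(x)), "spikes\n")
  invisible(x)
}

#' Generate a complete synthetic session bundle
#'
#' Runs an agent on a VI schedule, synthesizes the locomotion trace and
#' the spiking population, and returns everything needed by the
#' downstream analyses, fully reproducible from `(config, seed)`.
#'
#' @param config named list; recognized entries (all optional):
#'   `agent` ("mvt" or "threshold"), `agent_params`, `schedule` (a
#'   [vi_schedule()]), `n_rewards`, `spec` (an [encoding_spec()]),
#'   `grid_dt`, `locomotion` (logical).
#' @param seed integer seed; required (reproducibility contract).
#' @return list with `session`, `locomotion`, `spikes`, `ground_truth`,
#'   `config`, `seed`.
#' @export
generate_dataset <- function(config = list(), seed) {
  if (missing(seed) || is.null(seed))
    stop("generate_dataset() requires an explicit seed")
  defaults <- list(
    agent = "mvt",
    agent_params = NULL,
    schedule = vi_schedule(data.frame(box1_vi = 20, box2_vi = 20,
                                      n_rewards = 300)),
    n_rewards = NULL,
    spec = encoding_spec(),
    grid_dt = 0.01,
    locomotion = TRUE)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$agent_params)) {
    ## bundle study conditions: a balanced schedule with strong, slow
    ## belief noise and a high switching cost, so that switches are
    ## driven by the shared subjective latent rather than by the
    ## observable task state
    config$agent_params <- switch(config$agent,
      mvt = mvt_agent_params(belief_sd = 2, switching_cost = 0.95),
      threshold = threshold_agent_params(),
      stop("unknown agent: ", config$agent))
  }
  session <- switch(config$agent,
    mvt = run_mvt_agent(config$agent_params, config$schedule,
                        config$n_rewards, seed = child_seed(seed, "agent")),
    threshold = run_threshold_agent(config$agent_params, config$schedule,
                                    config$n_rewards,
                                    seed = child_seed(seed, "agent")))
  loco <- if (isTRUE(config$locomotion))
    generate_locomotion(session, seed = child_seed(seed, "locomotion"))
  else NULL
  pop <- if (config$spec$n_units > 0)
    generate_population(session, loco, config$spec, config$grid_dt,
                        seed = child_seed(seed, "population"))
  else list(spikes = structure(list(), class = "spike_train_set"),
            ground_truth = NULL)
  list(session = session, locomotion = loco, spikes = pop$spikes,
       ground_truth = pop$ground_truth, config = config, seed = seed)
}
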