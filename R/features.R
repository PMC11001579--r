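#' Boxcar delay-tile basis for event variables
#'
#' Expands an event raster into contiguous 200 ms offset tiles: column
#' `j` is 1 at time `t` when some event lies at an offset within tile
#' `j` of the window. Tiles partition the window, so the indicators for
#' a single event sum to at most one at any time.
#'
#' @param event_times event times, seconds.
#' @param bin_centers time-grid bin centers, seconds.
#' @param window offset window `c(lo, hi)`, seconds (negative offsets =
#'   pre-event tiles); its width must equal `n_tiles * tile_width`.
#' @param n_tiles number of tiles.
#' @param tile_width tile (boxcar) width, seconds, default 0.2.
#' @return bins x `n_tiles` indicator matrix.
#' @export
event_basis <- function(event_times, bin_centers, window, n_tiles,
                        tile_width = 0.2) {
  stopifnot(n_tiles >= 1, length(window) == 2)
  if (abs(diff(window) - n_tiles * tile_width) > 1e-9)
    stop("window width must equal n_tiles * tile_width (contiguous tiles)")
  out <- matrix(0, length(bin_centers), n_tiles)
  if (!length(event_times)) return(out)
  for (e in event_times) {
    rel <- bin_centers - e
    inside <- rel >= window[1] & rel < window[2]
    if (!any(inside)) next
    tile <- floor((rel[inside] - window[1]) / tile_width) + 1L
    tile[tile > n_tiles] <- n_tiles
    out[cbind(which(inside), tile)] <- 1
  }
  out
}

#' Monomial power basis for continuous variables
#'
#' Evaluates `x^a` for powers `a` in \{0.5, 1, 2, 3, 5\} instantaneously.
#' The trace is min-max rescaled to \[0, 1\] first (default) so that the
#' fractional power is defined and the fifth power cannot blow up.
#'
#' @param x numeric trace.
#' @param powers exponents (default `c(0.5, 1, 2, 3, 5)`).
#' @param rescale rescale `x` to \[0, 1\] before exponentiation.
#' @return length(x) x length(powers) matrix.
#' @export
power_basis <- function(x, powers = c(0.5, 1, 2, 3, 5), rescale = TRUE) {
  if (rescale) x <- rescale01(x)
  if (any(x < 0) && any(powers %% 1 != 0))
    stop("negative input to a fractional power; rescale the trace first")
  out <- vapply(powers, function(a) x^a, numeric(length(x)))
  matrix(out, nrow = length(x), ncol = length(powers))
}

#' Build the 51-column task feature matrix
#'
#' Basis-expands the six task variables onto a uniform time grid:
#' \itemize{
#'   \item press events: 7 pre-press tiles covering \[-1.4, 0) s and 7
#'     post-press tiles covering \[0, 1.4) s;
#'   \item choice (switch) events: 7 post-choice tiles, \[0, 1.4) s;
#'   \item reward deliveries: 10 post-reward tiles spanning 2 s;
#'   \item waiting time: a ramp resetting to 0 at each press, through 5
#'     monomial powers;
#'   \item reward ratio: piecewise constant, jumping at presses, through
#'     5 powers;
#'   \item 2-D location: x and y, 5 powers each.
#' }
#' Continuous traces are rescaled to \[0, 1\] per session before the
#' powers. Columns are left on their natural scale; standardization
#' happens inside the CCA.
#'
#' @param session a [behavioral_session()].
#' @param locomotion a [generate_locomotion()] trace, or `NULL` (location
#'   columns then use the session-mean position and are flagged in the
#'   metadata).
#' @param bin_centers time-grid bin centers, seconds.
#' @param filter_width half-Gaussian width (presses) for the reward-ratio
#'   channel.
#' @return a `feature_matrix`: bins x 51 numeric matrix with attribute
#'   `meta` (per-column variable, basis kind and index).
#' @export
build_feature_matrix <- function(session, locomotion, bin_centers,
                                 filter_width = 5) {
  stopifnot(is_behavioral_session(session))
  s <- as.data.frame(session)
  press_t <- s$time_s
  rewards_t <- press_t[s$rewarded]
  switch_t <- press_t[c(FALSE, s$box[-1] != s$box[-nrow(s)])]

  press_pre <- event_basis(press_t, bin_centers, c(-1.4, 0), 7)
  press_post <- event_basis(press_t, bin_centers, c(0, 1.4), 7)
  choice_post <- event_basis(switch_t, bin_centers, c(0, 1.4), 7)
  reward_post <- event_basis(rewards_t, bin_centers, c(0, 2), 10)

  last <- findInterval(bin_centers, press_t)
  ## before the first press the clock runs from the grid origin
  wait <- ifelse(last == 0, bin_centers - bin_centers[1],
                 bin_centers - press_t[pmax(last, 1)])
  rrp <- reward_ratio_series(s$box, s$rewarded, filter_width)
  rr <- c(0.5, rrp)[last + 1L]

  missing_loc <- is.null(locomotion)
  if (missing_loc) {
    loc_x <- rep(0.5, length(bin_centers))
    loc_y <- rep(0.5, length(bin_centers))
  } else {
    loc_x <- interp_trace(locomotion$time_s, locomotion$x, bin_centers)
    loc_y <- interp_trace(locomotion$time_s, locomotion$y, bin_centers)
  }

  X <- cbind(press_pre, press_post, choice_post, reward_post,
             power_basis(wait), power_basis(rr),
             power_basis(loc_x), power_basis(loc_y))
  meta <- data.frame(
    column = seq_len(ncol(X)),
    variable = rep(c("press", "press", "choice", "reward", "waiting_time",
                     "reward_ratio", "location_x", "location_y"),
                   c(7, 7, 7, 10, 5, 5, 5, 5)),
    kind = rep(c("event_pre", "event_post", "event_post", "event_post",
                 "power", "power", "power", "power"),
               c(7, 7, 7, 10, 5, 5, 5, 5)),
    index = c(1:7, 1:7, 1:7, 1:10,
              rep(c(0.5, 1, 2, 3, 5), 4)))
  colnames(X) <- paste0(meta$variable, "_", meta$kind, "_", meta$index)
  structure(X, meta = meta, missing_location = missing_loc,
            class = c("feature_matrix", "matrix", "array"))
}

feature_meta <- function(X) attr(X, "meta", exact = TRUE)

## column indices of a variable group
feature_cols <- function(X, variables) {
  which(feature_meta(X)$variable %in% variables)
}
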