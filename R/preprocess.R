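#' Rate matrix container
#'
#' Units-by-time-bins firing rates on a uniform grid of half-open bins
#' `[start, start + width)` spaced `step` apart, with an optional
#' engagement mask per bin.
#'
#' @param rates units x bins numeric matrix (spikes/s).
#' @param t_start first bin start, seconds.
#' @param width bin width, seconds.
#' @param step bin spacing, seconds.
#' @param mask logical per-bin inclusion mask (default all `TRUE`).
#' @return a `rate_matrix`.
#' @export
rate_matrix <- function(rates, t_start, width, step, mask = NULL) {
  rates <- as.matrix(rates)
  if (is.null(mask)) mask <- rep(TRUE, ncol(rates))
  stopifnot(length(mask) == ncol(rates), width > 0, step > 0)
  structure(list(rates = rates, t_start = t_start, width = width,
                 step = step, mask = mask),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("<rate_matrix>", nrow(x$rates), "units x", ncol(x$rates), "bins,",
      "width", x$width, "s, step", x$step, "s,",
      sum(x$mask), "bins masked in\n")
  invisible(x)
}

## bin start times / centers
rate_bin_starts <- function(rm) rm$t_start + (seq_len(ncol(rm$rates)) - 1) * rm$step
rate_bin_centers <- function(rm) rate_bin_starts(rm) + rm$width / 2

#' Bin and smooth spike trains into a rate matrix
#'
#' Counts spikes per half-open bin, converts to spikes/s, and smooths
#' each unit with a sliding boxcar (default 1 s). The boxcar is
#' zero-padded, so the total spike count is conserved for units away
#' from the session edges.
#'
#' @param spikes a `spike_train_set` (list of sorted spike-time vectors).
#' @param t_start,t_end grid span, seconds.
#' @param width bin width, seconds (default 0.2).
#' @param step bin spacing, seconds (default `width`).
#' @param smooth_window boxcar length, seconds (default 1; 0 disables).
#' @return a [rate_matrix()].
#' @export
bin_and_smooth <- function(spikes, t_start, t_end, width = 0.2,
                           step = width, smooth_window = 1) {
  stopifnot(t_end > t_start, width > 0, step > 0)
  starts <- seq(t_start, t_end - width, by = step)
  counts <- t(vapply(spikes, function(tt) {
    tt <- sort(tt)
    findInterval(starts + width, tt, left.open = TRUE) -
      findInterval(starts, tt, left.open = TRUE)
  }, numeric(length(starts))))
  if (length(spikes) == 0)
    counts <- matrix(0, 0, length(starts))
  rates <- counts / width
  if (smooth_window > 0) {
    k <- max(1L, round(smooth_window / step))
    if (k > 1) {
      kern <- rep(1 / k, k)
      rates <- t(apply(rates, 1, function(r) {
        padded <- c(rep(0, k), r, rep(0, k))
        sm <- stats::filter(padded, kern, sides = 2)
        as.numeric(sm)[(k + 1):(k + length(r))]
      }))
    }
  }
  rate_matrix(rates, t_start, width, step)
}

#' Press-locked rate tensor
#'
#' Aligns spike counts on press times: for each retained press, rates in
#' 200 ms windows at offsets covering `window` (offset 0 = the press
#' time). Presses closer than `min_separation` to the previous press are
#' excluded, as are presses whose window would leave the recorded span
#' (dropped with a warning).
#'
#' @param spikes a `spike_train_set`.
#' @param press_times press times, seconds.
#' @param window offsets spanned, seconds (default `c(-2, 1)`).
#' @param width,step sliding-window width and step, seconds (default 0.2).
#' @param min_separation exclusion bound on the preceding inter-press
#'   interval, seconds (default 2).
#' @param t_end recording end (default: last spike).
#' @return a `press_locked` list: `tensor` (press x offset x unit,
#'   spikes/s), `offsets` (window start offsets), `press_index` (indices
#'   of retained presses).
#' @export
press_locked <- function(spikes, press_times, window = c(-2, 1),
                         width = 0.2, step = 0.2, min_separation = 2,
                         t_end = NULL) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (is.null(t_end)) t_end <- max(unlist(spikes), 0)
  keep <- c(TRUE, diff(press_times) >= min_separation)
  edge <- press_times + window[1] >= 0 & press_times + window[2] <= t_end
  if (any(keep & !edge))
    warning(sum(keep & !edge), " press(es) too close to the session edge dropped")
  keep <- keep & edge
  idx <- which(keep)
  offsets <- seq(window[1], window[2] - width, by = step)
  tensor <- array(NA_real_,
                  dim = c(length(idx), length(offsets), length(spikes)),
                  dimnames = list(NULL, NULL, names(spikes)))
  for (u in seq_along(spikes)) {
    tt <- sort(spikes[[u]])
    for (j in seq_along(offsets)) {
      lo <- press_times[idx] + offsets[j]
      tensor[, j, u] <- (findInterval(lo + width, tt, left.open = TRUE) -
                           findInterval(lo, tt, left.open = TRUE)) / width
    }
  }
  structure(list(tensor = tensor, offsets = offsets, press_index = idx,
                 width = width),
            class = "press_locked")
}

#' Pre-press spike counts
#'
#' Spike counts per unit in the pre-press interval from -1.1 to -0.1 s
#' relative to each press, the standard 1 s window preceding arm
#' movement.
#'
#' @param spikes a `spike_train_set`.
#' @param press_times press times, seconds.
#' @param window pre-press interval, seconds relative to the press.
#' @return presses x units count matrix.
#' @export
prepress_counts <- function(spikes, press_times, window = c(-1.1, -0.1)) {
  vapply(spikes, function(tt) {
    tt <- sort(tt)
    findInterval(press_times + window[2], tt, left.open = TRUE) -
      findInterval(press_times + window[1], tt, left.open = TRUE)
  }, numeric(length(press_times)))
}

#' Task-engagement mask
#'
#' A time bin is engaged if its center lies within `max_gap` seconds of
#' some press; bins preceding or following every press by more than
#' `max_gap` are excluded from continuous-time analyses.
#'
#' @param press_times press times, seconds.
#' @param bin_centers bin center times, seconds.
#' @param max_gap engagement bound, seconds (default 5).
#' @return logical mask, one entry per bin.
#' @export
engagement_mask <- function(press_times, bin_centers, max_gap = 5) {
  stopifnot(length(press_times) >= 1)
  press_times <- sort(press_times)
  i <- findInterval(bin_centers, press_times)
  d_prev <- ifelse(i >= 1, bin_centers - press_times[pmax(i, 1)], Inf)
  d_next <- ifelse(i < length(press_times),
                   press_times[pmin(i + 1, length(press_times))] - bin_centers,
                   Inf)
  pmin(d_prev, d_next) <= max_gap
}

#' Remove the locomotion confound by orthogonal projection
#'
#' Projects each unit's rate vector onto the orthogonal complement of the
#' locomotion speed regressor: `r_perp = r - L (L'L)^{-1} L' r`, with `L`
#' the locomotion time series resampled onto the rate grid. The
#' projection is computed over masked-in bins only; residual rows are
#' exactly uncorrelated with `L` (up to the mean-centering convention,
#' see `center`). Applying the projection twice changes nothing.
#'
#' @param rm a [rate_matrix()] (its `mask` defines the fit bins).
#' @param locomotion a [generate_locomotion()] trace, or a numeric vector
#'   already on the rate grid.
#' @param center if `TRUE` (default), `L` and rates are mean-centered
#'   before projecting, so the Pearson correlation of every residual row
#'   with `L` is zero to machine precision; `FALSE` applies the bare
#'   projection formula (residuals orthogonal to `L` in the dot-product
#'   sense only).
#' @return the `rate_matrix` with masked-in bins replaced by residuals.
#' @export
remove_locomotion <- function(rm, locomotion, center = TRUE) {
  stopifnot(inherits(rm, "rate_matrix"))
  centers <- rate_bin_centers(rm)
  L_full <- if (is.numeric(locomotion)) {
    stopifnot(length(locomotion) == ncol(rm$rates))
    locomotion
  } else interp_trace(locomotion$time_s, locomotion$speed, centers)
  sel <- which(rm$mask)
  L <- L_full[sel]
  R <- rm$rates[, sel, drop = FALSE]
  if (center) {
    Lc <- L - mean(L)
    Rc <- R - rowMeans(R)
  } else {
    Lc <- L; Rc <- R
  }
  denom <- sum(Lc^2)
  if (denom < .Machine$double.eps) {
    warning("locomotion regressor is identically zero; rates unchanged")
    return(rm)
  }
  proj <- (Rc %*% Lc) / denom          # per-unit coefficients
  resid <- R - proj %*% t(Lc)          # r - Pi r (plus untouched mean if center)
  rm$rates[, sel] <- resid
  attr(rm, "locomotion_removed") <- TRUE
  rm
}
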