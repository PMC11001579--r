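#' Gap-based cross-validation blocks
#'
#' Presses are grouped into contiguous blocks delimited by gaps in press
#' times larger than `gap` seconds; decoders hold out one block at a time.
#'
#' @param press_times numeric vector of press times, seconds, increasing.
#' @param gap gap threshold, seconds (default 30).
#' @return integer block id per press (class `cv_blocks`).
#' @export
make_blocks <- function(press_times, gap = 30) {
  stopifnot(length(press_times) >= 2, !is.unsorted(press_times))
  ids <- cumsum(c(1, as.integer(diff(press_times) > gap)))
  if (max(ids) < 2)
    stop("only one cross-validation block; session too short or gaps < ",
         gap, " s absent")
  structure(as.integer(ids), class = "cv_blocks")
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, with ties counting one half — the
#' rank-sum (Mann-Whitney) form.
#'
#' @param scores numeric predictor output.
#' @param labels binary labels (logical or 0/1); both classes must be
#'   present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
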