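#' Behavioral session container
#'
#' A behavioral session is the ordered record of button presses produced
#' by an animal or a simulated agent: one row per press with its time,
#' the pressed box, whether a reward was delivered, and the schedule block
#' it occurred in. The generating [vi_schedule()] rides along as an
#' attribute so downstream analyses can compute oracle quantities such as
#' the probability of reward availability.
#'
#' @param presses data.frame with columns `time_s` (strictly increasing),
#'   `box` (1 or 2), `rewarded` (logical), `block_index` (integer).
#' @param schedule the [vi_schedule()] that generated the session.
#' @param meta optional named list of extras (agent parameters, planted
#'   latents); kept as an attribute.
#' @return a `behavioral_session` (a data.frame subclass).
#' @export
behavioral_session <- function(presses, schedule, meta = list()) {
  presses <- as.data.frame(presses)
  validate_presses(presses)
  structure(presses,
            schedule = schedule,
            meta = meta,
            class = c("behavioral_session", "data.frame"))
}

validate_presses <- function(presses) {
  req <- c("time_s", "box", "rewarded", "block_index")
  missing_cols <- setdiff(req, names(presses))
  if (length(missing_cols))
    stop("press table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(presses) == 0) stop("session has no presses")
  bad <- which(diff(presses$time_s) <= 0)
  if (length(bad))
    stop("press times must be strictly increasing (violated at row ",
         bad[1] + 1L, ")")
  if (!all(presses$box %in% c(1, 2)))
    stop("box must be 1 or 2")
  if (!is.logical(presses$rewarded))
    stop("rewarded must be logical")
  invisible(presses)
}

#' @export
print.behavioral_session <- function(x, ...) {
  cat("<behavioral_session> ", nrow(x), " presses, ",
      sum(x$rewarded), " rewarded, ",
      length(unique(x$block_index)), " block(s), ",
      sprintf("%.0f s", max(x$time_s)), "\n", sep = "")
  invisible(x)
}

#' @rdname behavioral_session
#' @param x object to test.
#' @export
is_behavioral_session <- function(x) inherits(x, "behavioral_session")

session_schedule <- function(session) attr(session, "schedule", exact = TRUE)
session_meta <- function(session) attr(session, "meta", exact = TRUE)

## vi means in force at each press, from block_index
press_vis <- function(session) {
  sched <- session_schedule(session)
  blocks <- sched$blocks
  cbind(box1 = blocks$box1_vi[session$block_index],
        box2 = blocks$box2_vi[session$block_index])
}

#' Write / read a behavioral session
#'
#' Sessions round-trip as a tab-separated press table plus a YAML sidecar
#' (`<path>.yml`) carrying the schedule blocks and `dt`. Reading validates
#' the schema: monotone press times, boxes in \{1, 2\}.
#'
#' @param session a [behavioral_session()].
#' @param path file path for the press table (the sidecar gets `.yml`
#'   appended).
#' @return `write_session` returns `path` invisibly; `read_session`
#'   returns the reconstructed session.
#' @export
write_session <- function(session, path) {
  stopifnot(is_behavioral_session(session))
  df <- as.data.frame(session)
  df$rewarded <- as.integer(df$rewarded)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sched <- session_schedule(session)
  yaml::write_yaml(list(dt = sched$dt,
                        blocks = lapply(seq_len(nrow(sched$blocks)), function(i)
                          as.list(sched$blocks[i, ]))),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  side <- yaml::read_yaml(paste0(path, ".yml"))
  blocks <- do.call(rbind, lapply(side$blocks, as.data.frame))
  df$rewarded <- as.logical(df$rewarded)
  behavioral_session(df, vi_schedule(blocks, dt = side$dt))
}
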