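#' Prepare a synthetic bundle for continuous-time analysis
#'
#' The shared preprocessing chain: bins and smooths the spikes onto a
#' uniform grid, masks non-engaged time, removes the locomotion
#' confound, builds the 51-column feature matrix, the press table, and
#' the grid-level cross-validation fold labels (each grid bin inherits
#' the CV block of its nearest press).
#'
#' @param bundle a [generate_dataset()] bundle.
#' @param step grid step, seconds (default 0.2; bins are `step` wide).
#' @param smooth_window neural smoothing boxcar, seconds (default 1).
#' @param max_gap engagement bound, seconds (default 5).
#' @param gap CV gap, seconds (default 30).
#' @param filter_width half-Gaussian width for reward-ratio columns.
#' @return list: `rates` (locomotion-decorrelated [rate_matrix()]),
#'   `X` (feature matrix, all bins), `Xm`, `Ym` (masked bins x columns /
#'   units), `grid_centers`, `mask`, `table` (press table), `folds`
#'   (per masked bin), `blocks` (per table row), `wait_trace`,
#'   `reward_ratio_trace` (masked-bin target traces).
#' @export
prepare_analysis <- function(bundle, step = 0.2, smooth_window = 1,
                             max_gap = 5, gap = 30, filter_width = 5) {
  session <- bundle$session
  s <- as.data.frame(session)
  t_end <- max(s$time_s) + 2
  rm0 <- bin_and_smooth(bundle$spikes, 0, t_end, width = step, step = step,
                        smooth_window = smooth_window)
  rm_raw <- bin_and_smooth(bundle$spikes, 0, t_end, width = step, step = step,
                           smooth_window = 0)
  centers <- rate_bin_centers(rm0)
  mask <- engagement_mask(s$time_s, centers, max_gap = max_gap)
  rm0$mask <- mask
  rm_raw$mask <- mask
  rmp <- rm0; rmp_raw <- rm_raw
  if (!is.null(bundle$locomotion)) {
    rmp <- remove_locomotion(rm0, bundle$locomotion)
    rmp_raw <- remove_locomotion(rm_raw, bundle$locomotion)
  }
  X <- build_feature_matrix(session, bundle$locomotion, centers,
                            filter_width = filter_width)
  table <- build_press_table(session, filter_width = filter_width)
  blocks <- make_blocks(table$time_s, gap = gap)
  ## per-bin fold labels from the nearest analyzed press
  pt <- table$time_s
  i0 <- pmin(pmax(findInterval(centers, pt), 1L), length(pt))
  i1 <- pmin(i0 + 1L, length(pt))
  nearer <- abs(centers - pt[i0]) <= abs(pt[i1] - centers)
  bin_block <- as.integer(blocks)[ifelse(nearer, i0, i1)]
  last <- findInterval(centers, s$time_s)
  wait <- ifelse(last == 0, centers, centers - s$time_s[pmax(last, 1)])
  rrp <- reward_ratio_series(s$box, s$rewarded, filter_width)
  rr <- c(0.5, rrp)[last + 1L]
  Xm <- unclass(X)[mask, , drop = FALSE]
  attr(Xm, "meta") <- feature_meta(X)
  list(rates = rmp,
       rates_raw = rmp_raw,
       X = X,
       Xm = Xm,
       Ym = t(rmp$rates[, mask, drop = FALSE]),
       grid_centers = centers,
       mask = mask,
       table = table,
       folds = bin_block[mask],
       blocks = blocks,
       wait_trace = wait[mask],
       reward_ratio_trace = rr[mask])
}

#' Run the full analysis pipeline
#'
#' Chains simulation, preprocessing, feature construction, sparse CCA
#' with component assignment, ground-truth recovery, and time-resolved
#' prediction into one reproducible run.
#'
#' @param config configuration list forwarded to [generate_dataset()];
#'   extra entries `fullness` (default 0.3), `K` (default 10),
#'   `prediction` (logical, default TRUE) control the analysis stages.
#' @param seed root seed; required. All stage seeds derive from it.
#' @param out_dir optional directory; when given, the session, press
#'   table, locomotion trace and a manifest (with a config hash) are
#'   written there as delimited/structured text.
#' @return list: `bundle`, `prep`, `cca`, `assignment`, `recovery`
#'   (held-out correlation of assigned components with the true latent
#'   traces), `prediction` (when enabled), `manifest`.
#' @export
run_pipeline <- function(config = list(), seed, out_dir = NULL) {
  if (missing(seed) || is.null(seed))
    stop("run_pipeline() requires an explicit seed")
  fullness <- config$fullness %||% 0.3
  K <- config$K %||% 10
  do_pred <- config$prediction %||% TRUE
  cv_gap <- config$cv_gap %||% 30
  config[c("fullness", "K", "prediction", "cv_gap")] <- NULL
  bundle <- generate_dataset(config, seed = seed)
  prep <- prepare_analysis(bundle, gap = cv_gap)
  model <- fit_scca(prep$Xm, prep$Ym, K = K,
                    fullness = fullness, folds = prep$folds)
  assignment <- assign_components(model)
  recovery <- component_recovery(model, prep)
  prediction <- if (do_pred) {
    ## unsmoothed rates: press-locked decoding must not let the 1 s
    ## smoother leak post-press activity into pre-press bins
    Yfull <- t(prep$rates_raw$rates)
    time_resolved_prediction(prep$X, Yfull, prep$grid_centers, prep$table,
                             K = K, gap = cv_gap, mask = prep$mask)
  } else NULL
  manifest <- list(seed = seed, config_hash = config_hash(bundle$config),
                   n_presses = nrow(bundle$session),
                   n_units = length(bundle$spikes),
                   timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_session(bundle$session, file.path(out_dir, "session.tsv"))
    utils::write.table(as.data.frame(prep$table),
                       file.path(out_dir, "press_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(bundle$locomotion))
      utils::write.table(bundle$locomotion,
                         file.path(out_dir, "locomotion.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yml"))
  }
  list(bundle = bundle, prep = prep, cca = model, assignment = assignment,
       recovery = recovery, prediction = prediction, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Held-out recovery of the true latent traces by assigned components
#'
#' For each reward predictor (waiting time, reward ratio): refits the
#' sparse CCA on every training fold, assigns the predictor's component
#' by its task-side weights, projects the held-out population activity
#' onto that component's neural direction, and averages the absolute
#' held-out Pearson correlation with the true trace.
#'
#' @param model a full-data `cca_model` (carries K and fullness).
#' @param prep a [prepare_analysis()] output.
#' @return data.frame: `variable`, `component` (full-data assignment),
#'   `heldout_r`.
#' @export
component_recovery <- function(model, prep) {
  asg <- assign_components(model)
  targets <- list(waiting_time = prep$wait_trace,
                  reward_ratio = prep$reward_ratio_trace)
  ids <- sort(unique(prep$folds))
  meta <- model$meta
  out <- lapply(names(targets), function(v) {
    rs <- vapply(ids, function(f) {
      tr <- prep$folds != f
      m <- scca_core(prep$Xm[tr, , drop = FALSE],
                     prep$Ym[tr, , drop = FALSE],
                     length(model$cors), model$fullness, 1e-10)
      m$meta <- meta
      k <- assign_components(structure(m, class = "cca_model"),
                             variables = v)[[1]]
      if (is.na(k)) return(NA_real_)
      proj <- scale(prep$Ym[!tr, , drop = FALSE], m$y_center, m$y_scale) %*%
        m$yweights_std[, k]
      abs(stats::cor(proj, targets[[v]][!tr]))
    }, numeric(1))
    data.frame(variable = v, component = asg[[v]],
               heldout_r = mean(rs, na.rm = TRUE))
  })
  do.call(rbind, out)
}

## configuration hash for the manifest: md5 of the YAML serialization
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  drop_fns <- function(x) {
    if (is.function(x)) return("<function>")
    if (inherits(x, "vi_schedule")) return(list(blocks = x$blocks, dt = x$dt))
    if (is.list(x)) return(lapply(x, drop_fns))
    x
  }
  yaml::write_yaml(drop_fns(config), f)
  unname(tools::md5sum(f))
}
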