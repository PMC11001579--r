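## ridge-stabilized logistic / linear fits via glmnet at a fixed tiny
## penalty; returns a scoring function or NULL when the fold degenerates
fit_scorer <- function(x, y, kind = c("binomial", "gaussian", "gamma")) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (kind == "binomial" && length(unique(y)) < 2) return(NULL)
  if (kind != "binomial" && stats::sd(y) == 0) return(NULL)
  if (kind == "gamma") {
    ## ridge-stabilized log-link Gamma; falls back to a linear model on
    ## the log wait if the ridge Gamma fit fails
    pad <- ncol(x) < 2
    xx <- if (pad) cbind(x, 0) else x
    fit <- tryCatch(
      suppressWarnings(glmnet::glmnet(xx, y,
                                      family = stats::Gamma(link = "log"),
                                      alpha = 0, lambda = 1e-6)),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit2 <- fit_scorer(x, log(y), "gaussian")
      if (is.null(fit2)) return(NULL)
      return(function(newx) exp(fit2(newx)))
    }
    return(function(newx) {
      newx <- as.matrix(newx)
      if (pad) newx <- cbind(newx, 0)
      as.numeric(stats::predict(fit, newx))
    })
  }
  ## glmnet needs >= 2 columns; pad with a zero column when univariate
  pad <- ncol(x) < 2
  if (pad) x <- cbind(x, 0)
  fit <- tryCatch(
    glmnet::glmnet(x, y, family = kind, alpha = 0, lambda = 1e-6,
                   standardize = TRUE),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  function(newx) {
    newx <- as.matrix(newx)
    if (pad) newx <- cbind(newx, 0)
    as.numeric(glmnet::predict.glmnet(fit, newx))
  }
}

#' Cross-validated binary prediction over time bins
#'
#' Trains a ridge-stabilized logistic regression per time bin on the
#' training blocks and scores the held-out block; held-out scores are
#' pooled over folds and summarized by the AUC per bin. Folds with a
#' single class are skipped and reported.
#'
#' @param feats press x bin x predictor array (see
#'   [press_feature_tensor()]).
#' @param labels logical per press.
#' @param blocks CV block id per press ([make_blocks()]).
#' @return data.frame with `bin` (offset index), `auc`, `n_folds_used`.
#' @export
predict_binary <- function(feats, labels, blocks) {
  stopifnot(dim(feats)[1] == length(labels), length(blocks) == length(labels))
  nb <- dim(feats)[2]
  ids <- sort(unique(blocks))
  out <- lapply(seq_len(nb), function(b) {
    scores <- rep(NA_real_, length(labels))
    used <- 0L
    for (f in ids) {
      tr <- blocks != f
      sc <- fit_scorer(feats[tr, b, , drop = FALSE][, 1, ],
                       labels[tr], "binomial")
      if (is.null(sc)) next
      scores[!tr] <- sc(feats[!tr, b, , drop = FALSE][, 1, ])
      used <- used + 1L
    }
    ok <- !is.na(scores)
    a <- if (length(unique(labels[ok])) == 2) auc(scores[ok], labels[ok])
         else NA_real_
    data.frame(bin = b, auc = a, n_folds_used = used)
  })
  do.call(rbind, out)
}

#' Cross-validated continuous prediction over time bins
#'
#' As [predict_binary()] but for a positive continuous target (the next
#' waiting time uses a log-link Gamma GLM; other targets a ridge linear
#' model). Performance is the Pearson correlation between pooled
#' held-out predictions and measured values per bin.
#'
#' @inheritParams predict_binary
#' @param target numeric per press.
#' @param family `"gamma"` (log link, positive targets) or
#'   `"gaussian"`.
#' @return data.frame with `bin`, `r`, `n_folds_used`.
#' @export
predict_continuous <- function(feats, target, blocks, family = "gaussian") {
  stopifnot(dim(feats)[1] == length(target))
  nb <- dim(feats)[2]
  ids <- sort(unique(blocks))
  out <- lapply(seq_len(nb), function(b) {
    pred <- rep(NA_real_, length(target))
    used <- 0L
    for (f in ids) {
      tr <- blocks != f
      sc <- fit_scorer(feats[tr, b, , drop = FALSE][, 1, ], target[tr], family)
      if (is.null(sc)) next
      pred[!tr] <- sc(feats[!tr, b, , drop = FALSE][, 1, ])
      used <- used + 1L
    }
    ok <- is.finite(pred)
    r <- if (sum(ok) > 2 && stats::sd(target[ok]) > 0 &&
             stats::sd(pred[ok]) > 0)
      stats::cor(pred[ok], target[ok]) else NA_real_
    data.frame(bin = b, r = r, n_folds_used = used)
  })
  do.call(rbind, out)
}

## map press-relative offsets onto grid bin indices (rows of the
## continuous-time matrices); offsets index the bin containing
## [press + offset, press + offset + step)
press_bin_index <- function(grid_centers, press_times, offsets) {
  step <- stats::median(diff(grid_centers))
  idx <- outer(press_times, offsets + step / 2, "+")
  ix <- round((idx - grid_centers[1]) / step) + 1L
  ix[ix < 1L] <- 1L
  ix[ix > length(grid_centers)] <- length(grid_centers)
  ix
}

#' Time-resolved prediction of reward, choice and next waiting time
#'
#' The headline population analysis: predicts each press's reward
#' outcome, stay/switch choice, and next waiting time from three
#' predictor families — task canonical components, their neural
#' counterparts, and the full population — in every 200 ms bin from 3 s
#' before to 1 s after the press, with leave-one-block-out
#' cross-validation. Canonical directions are refit within each training
#' set (unsparsified, in the 10-D reward-predictor task space by
#' default). The peak summary is the mean of the five best pre-press
#' bins.
#'
#' @inheritParams press_bin_index
#' @param X,Y,grid_centers continuous-time matrices and their grid.
#' @param table a [build_press_table()] (press times, outcomes, choices
#'   and next waits are read from it).
#' @param families subset of
#'   `c("task_components", "neural_components", "full_population")`.
#' @param targets subset of `c("reward", "choice", "next_wait")`.
#' @param window,step,K,predictor_variables see details.
#' @param gap CV gap, seconds.
#' @return a `prediction_result`: data.frame (`family`, `target`,
#'   `offset`, `metric`, `value`) plus a `peaks` attribute (per
#'   family x target, mean of the 5 best pre-press bins).
#' @export
time_resolved_prediction <- function(X, Y, grid_centers, table,
                                     families = c("task_components",
                                                  "neural_components",
                                                  "full_population"),
                                     targets = c("reward", "choice",
                                                 "next_wait"),
                                     window = c(-3, 1), step = 0.2,
                                     K = 10, gap = 30, mask = NULL,
                                     predictor_variables =
                                       c("waiting_time", "reward_ratio")) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(X))
  X <- as.matrix(X)
  meta <- attr(X, "meta", exact = TRUE)
  cols <- if (!is.null(meta)) which(meta$variable %in% predictor_variables)
          else seq_len(ncol(X))
  Xp <- unclass(X)[, cols, drop = FALSE]
  press_t <- table$time_s
  blocks <- make_blocks(press_t, gap = gap)
  offsets <- seq(window[1], window[2] - step, by = step)
  ix <- press_bin_index(grid_centers, press_t, offsets)
  n_press <- length(press_t); n_off <- length(offsets)
  ids <- sort(unique(blocks))
  ## per-fold canonical projections on the full grid
  proj_task <- vector("list", length(ids))
  proj_neur <- vector("list", length(ids))
  names(proj_task) <- names(proj_neur) <- as.character(ids)
  need_cca <- any(c("task_components", "neural_components") %in% families)
  if (need_cca) {
    ## each grid bin belongs to the block of its nearest press, so a
    ## held-out block's bins never enter that fold's CCA fit
    i0 <- findInterval(grid_centers, press_t)
    i0 <- pmin(pmax(i0, 1L), length(press_t))
    i1 <- pmin(i0 + 1L, length(press_t))
    nearer <- abs(grid_centers - press_t[i0]) <= abs(press_t[i1] - grid_centers)
    bin_block <- blocks[ifelse(nearer, i0, i1)]
    for (f in ids) {
      tr_bins <- bin_block != f & mask
      m <- scca_core(Xp[tr_bins, , drop = FALSE], Y[tr_bins, , drop = FALSE],
                     min(K, ncol(Xp)), fullness = 1, tol = 1e-10)
      proj_task[[as.character(f)]] <-
        scale(Xp, m$x_center, m$x_scale) %*% m$xweights_std
      proj_neur[[as.character(f)]] <-
        scale(Y, m$y_center, m$y_scale) %*% m$yweights_std
    }
  }
  family_feats <- function(fam, fold) {
    src <- switch(fam,
      task_components = proj_task[[as.character(fold)]],
      neural_components = proj_neur[[as.character(fold)]],
      full_population = Y)
    arr <- array(NA_real_, c(n_press, n_off, ncol(src)))
    for (j in seq_len(n_off))
      arr[, j, ] <- src[ix[, j], , drop = FALSE]
    arr
  }
  target_spec <- list(
    reward = list(y = table$rewarded, kind = "binomial"),
    choice = list(y = table$choice == "switch", kind = "binomial"),
    next_wait = list(y = table$next_waiting_time, kind = "gamma"))
  rows <- list(); peaks <- list()
  for (fam in families) {
    feats_by_fold <- lapply(ids, function(f) family_feats(fam, f))
    names(feats_by_fold) <- as.character(ids)
    for (tg in targets) {
      ts <- target_spec[[tg]]
      ok <- !is.na(ts$y)
      metric_vals <- rep(NA_real_, n_off)
      for (j in seq_len(n_off)) {
        pooled_scores <- rep(NA_real_, n_press)
        for (f in ids) {
          tr <- blocks != f & ok
          te <- blocks == f & ok
          if (!any(te) || !any(tr)) next
          feats <- feats_by_fold[[as.character(f)]]
          xtr <- feats[tr, j, , drop = FALSE][, 1, , drop = TRUE]
          xte <- feats[te, j, , drop = FALSE][, 1, , drop = TRUE]
          if (is.null(dim(xtr))) xtr <- matrix(xtr, ncol = dim(feats)[3])
          if (is.null(dim(xte))) xte <- matrix(xte, ncol = dim(feats)[3])
          sc <- fit_scorer(xtr, ts$y[tr],
                           if (ts$kind == "binomial") "binomial" else "gamma")
          if (is.null(sc)) next
          pooled_scores[te] <- sc(xte)
        }
        okp <- ok & is.finite(pooled_scores)
        if (ts$kind == "binomial") {
          metric_vals[j] <- if (length(unique(ts$y[okp])) == 2)
            auc(pooled_scores[okp], ts$y[okp]) else NA_real_
        } else {
          metric_vals[j] <- if (sum(okp) > 2 &&
                                stats::sd(pooled_scores[okp]) > 0)
            stats::cor(pooled_scores[okp], ts$y[okp]) else NA_real_
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, target = tg, offset = offsets,
        metric = if (ts$kind == "binomial") "auc" else "r",
        value = metric_vals)
      pre <- metric_vals[offsets < 0]
      pre <- pre[!is.na(pre)]
      peaks[[paste(fam, tg, sep = ".")]] <-
        if (length(pre)) mean(sort(pre, decreasing = TRUE)[seq_len(min(5, length(pre)))])
        else NA_real_
    }
  }
  structure(do.call(rbind, rows),
            peaks = unlist(peaks), blocks = blocks,
            class = c("prediction_result", "data.frame"))
}

#' Peak prediction summary
#'
#' @param result a [time_resolved_prediction()] output.
#' @return named numeric vector `family.target` -> mean of the five best
#'   pre-press bins.
#' @export
prediction_peaks <- function(result) attr(result, "peaks", exact = TRUE)

#' Neuron-dropping curve
#'
#' Decoding performance as a function of population size: for each
#' subset size, draws random unit subsets, decodes the target from
#' pre-press activity with leave-one-block-out ridge regression, and
#' reports the mean and s.e.m. across draws.
#'
#' @param counts press x unit activity matrix (e.g. [prepress_counts()]).
#' @param target numeric target per press.
#' @param blocks CV block per press.
#' @param sizes subset sizes (default powers of 2 up to the population).
#' @param n_draws random subsets per size (default 20).
#' @param seed integer seed.
#' @return data.frame: `size`, `mean_r`, `sem_r`.
#' @export
neuron_dropping_curve <- function(counts, target, blocks, sizes = NULL,
                                  n_draws = 20, seed = 1L) {
  counts <- as.matrix(counts)
  U <- ncol(counts)
  if (is.null(sizes)) {
    sizes <- unique(pmin(c(2^(0:10)), U))
    sizes <- sizes[sizes <= U]
  }
  if (any(sizes > U)) {
    warning("subset sizes above the population size truncated")
    sizes <- unique(pmin(sizes, U))
  }
  ids <- sort(unique(blocks))
  decode_r <- function(cols) {
    pred <- rep(NA_real_, length(target))
    for (f in ids) {
      tr <- blocks != f
      sc <- fit_scorer(counts[tr, cols, drop = FALSE], target[tr], "gaussian")
      if (is.null(sc)) next
      pred[!tr] <- sc(counts[!tr, cols, drop = FALSE])
    }
    ok <- is.finite(pred)
    if (sum(ok) > 2 && stats::sd(pred[ok]) > 0)
      stats::cor(pred[ok], target[ok]) else NA_real_
  }
  with_seed(seed, {
    out <- lapply(sizes, function(sz) {
      rs <- if (sz == U) decode_r(seq_len(U))
            else vapply(seq_len(n_draws), function(d)
              decode_r(sample.int(U, sz)), numeric(1))
      data.frame(size = sz, mean_r = mean(rs, na.rm = TRUE),
                 sem_r = stats::sd(rs) / sqrt(length(rs)))
    })
    do.call(rbind, out)
  })
}
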