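## symmetric inverse square root with rank truncation
inv_sqrt <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  r <- sum(keep)
  W <- e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), r) %*% t(e$vectors[, keep, drop = FALSE])
  list(W = W, rank = r)
}

## soft threshold
soft <- function(x, d) sign(x) * pmax(abs(x) - d, 0)

## project a unit vector onto {||u||_2 = 1, ||u||_1 <= c} by binary search
## on the soft threshold (penalized matrix decomposition convention)
l1_unit <- function(x, c1) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) return(x)
  u <- x / nrm
  if (sum(abs(u)) <= c1) return(u)
  lo <- 0; hi <- max(abs(x))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    v <- soft(x, mid)
    nv <- sqrt(sum(v^2))
    l1 <- if (nv == 0) 0 else sum(abs(v)) / nv
    if (l1 > c1) lo <- mid else hi <- mid
  }
  v <- soft(x, hi)
  v / sqrt(sum(v^2))
}

#' Sparsified canonical correlation analysis of task and neural spaces
#'
#' Finds up to `K` paired directions maximizing the correlation between
#' the basis-expanded task space and the neural population space. Both
#' sides are z-scored and whitened; components come from a penalized
#' singular value decomposition of the whitened cross-covariance with an
#' l1 budget on the task-side weights controlled by the `fullness`
#' constant: the budget is `1 + fullness * (sqrt(p) - 1)`, so
#' `fullness = 1` releases the penalty and the fit coincides with
#' classical CCA, while smaller values force each component onto fewer
#' task predictors. The neural side is l2-constrained only. Components
#' are deflated rank-one and ordered by descending training correlation.
#'
#' @param X bins x p task feature matrix (a [build_feature_matrix()]
#'   output or any numeric matrix).
#' @param Y bins x U neural matrix (masked-in bins of a rate matrix,
#'   transposed to bins x units).
#' @param K number of components (default 10; reduced with a warning if
#'   either side has lower rank).
#' @param fullness task-side sparsity constant in (0, 1\] (default 0.3).
#' @param folds optional cross-validation assignment: integer vector of
#'   fold ids per bin. Held-out canonical correlations are then computed
#'   by refitting on each training set.
#' @param tol eigenvalue tolerance for the whitening rank truncation.
#' @return a `cca_model`: `xweights` (p x K, original column space),
#'   `xweights_sparse` (whitened-basis task weights carrying the l1
#'   budget), `yweights` (U x K), `cors` (training canonical
#'   correlations), `heldout_cors` (fold-averaged, when `folds` given),
#'   `fullness`, `meta` (feature metadata when available).
#' @export
fit_scca <- function(X, Y, K = 10, fullness = 0.3, folds = NULL,
                     tol = 1e-10) {
  meta <- attr(X, "meta", exact = TRUE)
  X <- unclass(as.matrix(X)); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), fullness > 0, fullness <= 1)
  fit <- scca_core(X, Y, K, fullness, tol)
  heldout <- NULL
  if (!is.null(folds)) {
    stopifnot(length(folds) == nrow(X))
    ids <- sort(unique(folds))
    if (length(ids) < 2) stop("need at least 2 cross-validation folds")
    hc <- sapply(ids, function(f) {
      tr <- folds != f
      m <- scca_core(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                     K, fullness, tol)
      px <- scale(X[!tr, , drop = FALSE], center = m$x_center,
                  scale = m$x_scale) %*% m$xweights_std
      py <- scale(Y[!tr, , drop = FALSE], center = m$y_center,
                  scale = m$y_scale) %*% m$yweights_std
      k2 <- min(ncol(px), ncol(py), length(fit$cors))
      vapply(seq_len(k2), function(k) stats::cor(px[, k], py[, k]),
             numeric(1))[seq_len(length(fit$cors))]
    })
    heldout <- rowMeans(hc, na.rm = TRUE)
  }
  structure(c(fit, list(heldout_cors = heldout, fullness = fullness,
                        meta = meta)),
            class = "cca_model")
}

## core penalized-whitened-SVD fit on one data split
scca_core <- function(X, Y, K, fullness, tol) {
  n <- nrow(X)
  x_center <- colMeans(X); y_center <- colMeans(Y)
  x_scale <- apply(X, 2, stats::sd); y_scale <- apply(Y, 2, stats::sd)
  x_scale[x_scale < .Machine$double.eps] <- 1
  y_scale[y_scale < .Machine$double.eps] <- 1
  Xc <- scale(X, center = x_center, scale = x_scale)
  Yc <- scale(Y, center = y_center, scale = y_scale)
  Sx <- crossprod(Xc) / (n - 1)
  Sy <- crossprod(Yc) / (n - 1)
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  wx <- inv_sqrt(Sx, tol); wy <- inv_sqrt(Sy, tol)
  Kmat <- wx$W %*% Sxy %*% wy$W
  kmax <- min(wx$rank, wy$rank)
  if (K > kmax) {
    warning("rank-deficient inputs: K reduced from ", K, " to ", kmax)
    K <- kmax
  }
  p <- ncol(X)
  c1 <- 1 + fullness * (sqrt(p) - 1)
  penalized <- fullness < 1
  U <- matrix(0, p, K); V <- matrix(0, ncol(Y), K)
  cors <- numeric(K)
  Kw <- Kmat
  for (k in seq_len(K)) {
    sv <- svd(Kw, nu = 1, nv = 1)
    u <- sv$u[, 1]; v <- sv$v[, 1]
    if (penalized) {
      for (it in 1:100) {
        u_new <- l1_unit(as.numeric(Kw %*% v), c1)
        kv <- as.numeric(crossprod(Kw, u_new))
        nv <- sqrt(sum(kv^2))
        v_new <- if (nv > 0) kv / nv else v
        if (max(abs(u_new - u), abs(v_new - v)) < 1e-10) {
          u <- u_new; v <- v_new; break
        }
        u <- u_new; v <- v_new
      }
    }
    d <- as.numeric(t(u) %*% Kw %*% v)
    Kw <- Kw - d * tcrossprod(u, v)
    U[, k] <- u; V[, k] <- v
    ax <- Xc %*% (wx$W %*% u); by <- Yc %*% (wy$W %*% v)
    cors[k] <- if (stats::sd(ax) > 0 && stats::sd(by) > 0)
      stats::cor(ax, by) else 0
  }
  ord <- order(cors, decreasing = TRUE)
  U <- U[, ord, drop = FALSE]; V <- V[, ord, drop = FALSE]
  cors <- cors[ord]
  ## structure correlations: how much each task column loads on each
  ## component's task-side projection (used for component assignment)
  xs <- suppressWarnings(stats::cor(Xc, Xc %*% (wx$W %*% U)))
  xs[!is.finite(xs)] <- 0
  list(xweights = wx$W %*% U,            # original (standardized) column space
       xweights_sparse = U,              # whitened basis, carries the l1 budget
       yweights = wy$W %*% V,
       xweights_std = wx$W %*% U,        # used with the stored centering
       yweights_std = wy$W %*% V,
       xstructure = xs,
       x_center = x_center, x_scale = x_scale,
       y_center = y_center, y_scale = y_scale,
       cors = cors)
}

#' @export
print.cca_model <- function(x, ...) {
  cat("<cca_model>", length(x$cors), "components, fullness", x$fullness, "\n")
  cat("  train cors:", paste(sprintf("%.3f", x$cors), collapse = " "), "\n")
  if (!is.null(x$heldout_cors))
    cat("  held-out:  ", paste(sprintf("%.3f", x$heldout_cors), collapse = " "),
        "\n")
  invisible(x)
}

#' Project data onto fitted canonical directions
#'
#' @param model a `cca_model`.
#' @param X,Y new task / neural matrices on the same columns as the fit
#'   (either may be `NULL`).
#' @return list with `task` and `neural` projection matrices (bins x K).
#' @export
cca_project <- function(model, X = NULL, Y = NULL) {
  out <- list()
  if (!is.null(X))
    out$task <- scale(unclass(as.matrix(X)), model$x_center, model$x_scale) %*%
      model$xweights_std
  if (!is.null(Y))
    out$neural <- scale(as.matrix(Y), model$y_center, model$y_scale) %*%
      model$yweights_std
  out
}

#' Assign canonical components to task variables
#'
#' For each requested variable, finds the component whose task-side
#' loading pattern concentrates most on that variable's columns: the
#' component maximizing the variable's share of the total absolute
#' task-side weight. Because the fitted directions live in a whitened
#' basis, weights are taken in the structure-correlation convention
#' (correlation of each task column with the component's task
#' projection). Ties go to the lower component index; a variable whose
#' columns carry zero weight in every component is returned as `NA` with
#' a warning.
#'
#' @param model a fitted `cca_model` whose `meta` is present (fit on a
#'   [build_feature_matrix()]).
#' @param variables variables to assign (default the four headline ones).
#' @return named integer vector of component indices.
#' @export
assign_components <- function(model,
                              variables = c("reward", "choice",
                                            "waiting_time", "reward_ratio")) {
  meta <- model$meta
  if (is.null(meta)) stop("model carries no feature metadata")
  W <- abs(model$xstructure %||% model$xweights)
  tot <- colSums(W)
  tot[tot == 0] <- 1
  out <- stats::setNames(integer(length(variables)), variables)
  for (v in variables) {
    rows <- meta$variable == v
    if (!any(rows)) stop("unknown variable: ", v)
    share <- colSums(W[rows, , drop = FALSE]) / tot
    if (all(share == 0)) {
      warning("no component carries weight for ", v)
      out[v] <- NA_integer_
    } else {
      out[v] <- which.max(share)   # first maximum = lowest index
    }
  }
  out
}

#' Cluster neurons by reconstructed task-driven activity
#'
#' Fits each unit's rate with a ridge regression on the task features,
#' then hierarchically clusters units on the correlation distance between
#' their reconstructed traces (average linkage). Clusters smaller than
#' `min_size` are discarded.
#'
#' @param Y bins x U neural matrix.
#' @param X bins x p task feature matrix.
#' @param min_size smallest reported cluster (default 5).
#' @param n_clusters number of tree cuts; `NULL` picks the cut in
#'   `2..min(10, U-1)` with the best mean silhouette.
#' @param ridge ridge penalty for the per-unit fits.
#' @return list: `assignment` (cluster id per unit, `NA` = discarded),
#'   `clusters` (list of member indices), `reconstruction` (bins x U).
#' @export
cluster_neurons_by_reconstruction <- function(Y, X, min_size = 5,
                                              n_clusters = NULL,
                                              ridge = 1e-6) {
  Y <- as.matrix(Y); X <- unclass(as.matrix(X))
  U <- ncol(Y)
  if (U < min_size)
    return(list(assignment = rep(NA_integer_, U), clusters = list(),
                reconstruction = NULL))
  Xs <- cbind(1, zscore_cols(X))
  G <- crossprod(Xs) + diag(ridge, ncol(Xs))
  B <- solve(G, crossprod(Xs, Y))
  recon <- Xs %*% B
  cc <- suppressWarnings(stats::cor(recon))
  cc[!is.finite(cc)] <- 0
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  ks <- if (is.null(n_clusters)) 2:max(2, min(10, U - 1)) else n_clusters
  best <- NULL; best_sil <- -Inf
  dm <- as.matrix(d)
  for (k in ks) {
    a <- stats::cutree(hc, k = k)
    sil <- mean_silhouette(dm, a)
    if (sil > best_sil) { best_sil <- sil; best <- a }
  }
  assignment <- best
  keep <- names(which(table(assignment) >= min_size))
  assignment[!(assignment %in% as.integer(keep))] <- NA_integer_
  clusters <- lapply(as.integer(keep), function(k) which(best == k))
  list(assignment = assignment, clusters = clusters, reconstruction = recon)
}

## mean silhouette over points, given a distance matrix and assignment
mean_silhouette <- function(dm, a) {
  n <- nrow(dm)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- a == a[i]; own[i] <- FALSE
    ai <- if (any(own)) mean(dm[i, own]) else 0
    others <- setdiff(unique(a), a[i])
    if (!length(others)) return(-Inf)
    bi <- min(vapply(others, function(k) mean(dm[i, a == k]), numeric(1)))
    s[i] <- if (max(ai, bi) > 0) (bi - ai) / max(ai, bi) else 0
  }
  mean(s)
}

#' Compare canonical components with single units and clusters
#'
#' For each target trace (a reward predictor on the analysis grid),
#' reports the held-out correlation achieved by (a) the best single
#' unit, (b) the best cluster-mean, and (c) the assigned canonical
#' component, using the same folds throughout. "Best" is chosen on the
#' training folds; correlations are evaluated on held-out bins and
#' averaged (absolute value, since the sign of a component is
#' arbitrary).
#'
#' @param X bins x p feature matrix (with metadata).
#' @param Y bins x U neural matrix.
#' @param targets named list of target traces (bins-long numeric
#'   vectors), e.g. waiting time and reward ratio.
#' @param folds integer fold id per bin.
#' @param K,fullness passed to [fit_scca()].
#' @param target_variable named map from target name to feature-variable
#'   name used for component assignment (defaults to the target names).
#' @return data.frame: target, r_unit, r_cluster, r_component.
#' @export
component_vs_single_unit <- function(X, Y, targets, folds, K = 10,
                                     fullness = 0.3,
                                     target_variable = NULL) {
  stopifnot(is.list(targets), !is.null(names(targets)))
  if (is.null(target_variable))
    target_variable <- stats::setNames(names(targets), names(targets))
  ids <- sort(unique(folds))
  meta <- attr(X, "meta", exact = TRUE)
  cl <- cluster_neurons_by_reconstruction(Y, X)
  res <- lapply(names(targets), function(nm) {
    z <- targets[[nm]]
    per_fold <- sapply(ids, function(f) {
      tr <- folds != f; te <- !tr
      m <- scca_core(unclass(as.matrix(X))[tr, , drop = FALSE],
                     Y[tr, , drop = FALSE], K, fullness, 1e-10)
      m$meta <- meta
      assigned <- assign_components(structure(m, class = "cca_model"),
                                    variables = target_variable[[nm]])
      k <- assigned[[1]]
      proj <- scale(Y[te, , drop = FALSE], m$y_center, m$y_scale) %*%
        m$yweights_std[, k]
      r_comp <- abs(stats::cor(proj, z[te]))
      r_tr <- abs(suppressWarnings(stats::cor(Y[tr, , drop = FALSE], z[tr])))
      r_tr[!is.finite(r_tr)] <- -Inf
      best_u <- which.max(r_tr)
      r_unit <- abs(stats::cor(Y[te, best_u], z[te]))
      r_clu <- NA_real_
      if (length(cl$clusters)) {
        means_tr <- sapply(cl$clusters, function(ix)
          rowMeans(Y[tr, ix, drop = FALSE]))
        rc <- abs(suppressWarnings(stats::cor(means_tr, z[tr])))
        rc[!is.finite(rc)] <- -Inf
        bc <- which.max(rc)
        r_clu <- abs(stats::cor(rowMeans(Y[te, cl$clusters[[bc]],
                                           drop = FALSE]), z[te]))
      }
      c(r_unit, r_clu, r_comp)
    })
    data.frame(target = nm,
               r_unit = mean(per_fold[1, ], na.rm = TRUE),
               r_cluster = mean(per_fold[2, ], na.rm = TRUE),
               r_component = mean(per_fold[3, ], na.rm = TRUE))
  })
  do.call(rbind, res)
}
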