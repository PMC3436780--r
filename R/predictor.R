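# Model-averaged phenotype prediction: stochastic shotgun-style search over
# subsets of metaprotein factors for a binary outcome, scored by a
# closed-form Zellner g-prior marginal likelihood, with posterior-weighted
# model averaging.  The search space is explored by add/delete/swap moves
# from the current model, evaluating the full neighborhood at each step and
# sampling the next model proportionally to posterior mass.

# log marginal likelihood (up to a model-independent constant) of subset S
# under the g-prior on a centered Gaussian regression:
#   -|S|/2 log(1+g) - (n-1)/2 log(1 - g/(1+g) R^2_S)
# plus a uniform-over-sizes model prior, uniform within each size.
model_log_score <- function(S, gram, K, n, g, max_size) {
  k <- length(S)
  if (k > max_size) return(-Inf)
  r2 <- 0
  if (k > 0) {
    b <- tryCatch(solve(gram$XtX[S, S, drop = FALSE], gram$Xty[S]),
                  error = function(e) NULL)
    if (is.null(b)) return(-Inf)
    r2 <- sum(b * gram$Xty[S]) / gram$yty
    r2 <- min(max(r2, 0), 1 - 1e-12)
  }
  -0.5 * k * log(1 + g) - 0.5 * (n - 1) * log(1 - g / (1 + g) * r2) -
    log(max_size + 1) - lchoose(K, k)
}

model_key <- function(S) paste(sort(S), collapse = ",")

neighborhood <- function(S, K) {
  out <- list()
  for (j in setdiff(seq_len(K), S)) out[[length(out) + 1L]] <- sort(c(S, j))
  for (j in S) out[[length(out) + 1L]] <- setdiff(S, j)
  for (j in S) {
    for (l in setdiff(seq_len(K), S)) {
      out[[length(out) + 1L]] <- sort(c(setdiff(S, j), l))
    }
  }
  out
}

#' Fit a model-averaged binary-outcome predictor over metaprotein factors
#'
#' Variable selection with model averaging for settings with more candidate
#' factors than samples: a stochastic search with add/delete/swap moves
#' explores subsets of factor-score columns, each model scored by the
#' closed-form Zellner g-prior marginal likelihood of the centered outcome
#' (g = n, unit-information) under a model prior uniform over sizes up to
#' \code{max_size}.  Visited models are weighted by normalized posterior
#' mass; predictions are the weight-averaged posterior-mean linear
#' predictors, usable directly as classification scores.
#'
#' When a 3-d array of per-MCMC-draw factor matrices is supplied, a
#' predictor is built per draw and inclusion frequencies are aggregated
#' across draws -- the draw-wise candidate-biomarker analysis.
#'
#' @param Lambda Factor-score matrix (samples x factors), or an array
#'   (draws x samples x factors) of retained MCMC draws.
#' @param phenotype Binary labels (0/1 or two-level factor).
#' @param max_size Maximum model size.
#' @param n_iter Search iterations (full-neighborhood evaluations).
#' @param g g-prior scale; default \code{length(phenotype)}.
#' @param seed Integer seed for the stochastic search.
#' @return A list of class \code{mp_predictor}: \code{inclusion} (named
#'   per-factor posterior inclusion frequency), \code{models} (tibble of
#'   visited models with log scores and weights), \code{coef_avg}
#'   (model-averaged coefficients), training centering info and
#'   configuration.  For draw arrays, additionally
#'   \code{inclusion_by_draw}.
#' @export
fit_predictor <- function(Lambda, phenotype, max_size = 5, n_iter = 200,
                          g = NULL, seed = 1) {
  if (length(dim(Lambda)) == 3) {
    return(fit_predictor_draws(Lambda, phenotype, max_size, n_iter, g, seed))
  }
  Lambda <- as.matrix(Lambda)
  if (is.null(colnames(Lambda))) {
    colnames(Lambda) <- paste0("f", seq_len(ncol(Lambda)))
  }
  y <- as.numeric(factor(phenotype)) - 1
  if (length(unique(y[!is.na(y)])) != 2) {
    stop("phenotype must have exactly two classes", call. = FALSE)
  }
  ok <- !is.na(y)
  Lambda <- Lambda[ok, , drop = FALSE]
  y <- y[ok]
  n <- length(y)
  if (is.null(g)) g <- n

  sds <- apply(Lambda, 2, stats::sd)
  dropped <- colnames(Lambda)[sds == 0]
  if (length(dropped) > 0) {
    warning("dropping zero-variance factor(s): ",
            paste(dropped, collapse = ", "))
    Lambda <- Lambda[, sds > 0, drop = FALSE]
  }
  K <- ncol(Lambda)
  x_center <- colMeans(Lambda)
  Xc <- sweep(Lambda, 2, x_center)
  y_center <- mean(y)
  yc <- y - y_center
  gram <- list(XtX = crossprod(Xc), Xty = as.vector(crossprod(Xc, yc)),
               yty = sum(yc^2))

  set.seed(as.integer(seed))
  scores <- new.env(hash = TRUE, parent = emptyenv())
  models <- list()
  score_of <- function(S) {
    key <- paste0("m:", model_key(S))   # prefix: "" is not a legal env name
    if (!is.null(scores[[key]])) return(scores[[key]])
    s <- model_log_score(S, gram, K, n, g, max_size)
    scores[[key]] <- s
    models[[length(models) + 1L]] <<- list(S = S, score = s)
    s
  }
  S <- integer(0)
  score_of(S)
  for (it in seq_len(n_iter)) {
    nb <- neighborhood(S, K)
    nb <- nb[vapply(nb, length, 1L) <= max_size]
    if (length(nb) == 0) break
    sc <- vapply(nb, score_of, numeric(1))
    w <- exp(sc - max(sc))
    S <- nb[[sample.int(length(nb), 1, prob = w)]]
  }

  sc_all <- vapply(models, `[[`, numeric(1), "score")
  keep <- is.finite(sc_all)
  models <- models[keep]; sc_all <- sc_all[keep]
  w <- exp(sc_all - max(sc_all))
  w <- w / sum(w)
  inclusion <- numeric(K)
  coef_avg <- numeric(K)
  for (m in seq_along(models)) {
    S <- models[[m]]$S
    if (length(S) > 0) {
      inclusion[S] <- inclusion[S] + w[m]
      b <- solve(gram$XtX[S, S, drop = FALSE], gram$Xty[S]) * g / (1 + g)
      coef_avg[S] <- coef_avg[S] + w[m] * b
    }
  }
  names(inclusion) <- names(coef_avg) <- colnames(Lambda)

  structure(
    list(inclusion = inclusion,
         models = tibble::tibble(
           model = vapply(models, function(m) model_key(m$S), character(1)),
           size = vapply(models, function(m) length(m$S), integer(1)),
           log_score = sc_all, weight = w),
         coef_avg = coef_avg,
         x_center = x_center, y_center = y_center,
         factor_names = colnames(Lambda),
         config = list(max_size = max_size, n_iter = n_iter, g = g,
                       seed = seed, prior = "uniform over sizes",
                       link = "model-averaged g-prior linear score")),
    class = "mp_predictor")
}

fit_predictor_draws <- function(Lambda_draws, phenotype, max_size, n_iter,
                                g, seed) {
  nd <- dim(Lambda_draws)[1]
  fits <- vector("list", nd)
  for (d in seq_len(nd)) {
    fits[[d]] <- fit_predictor(Lambda_draws[d, , ], phenotype,
                               max_size = max_size, n_iter = n_iter,
                               g = g, seed = seed + d)
  }
  incl <- do.call(rbind, lapply(fits, `[[`, "inclusion"))
  out <- fits[[nd]]
  out$inclusion <- colMeans(incl)
  out$inclusion_by_draw <- incl
  out
}

#' @export
print.mp_predictor <- function(x, ...) {
  top <- sort(x$inclusion, decreasing = TRUE)
  top <- top[top > 0][seq_len(min(5, sum(x$inclusion > 0)))]
  cat(sprintf("<mp_predictor> %d factors, %d models visited\n",
              length(x$inclusion), nrow(x$models)))
  cat("  top inclusion:",
      paste(sprintf("%s (%.2f)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.mp_predictor <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(object$factor_names %in% colnames(newdata))) {
    newdata <- newdata[, object$factor_names, drop = FALSE]
  }
  Xc <- sweep(newdata, 2, object$x_center)
  as.vector(object$y_center + Xc %*% object$coef_avg)
}

#' Tidy a model-averaged predictor
#'
#' @param x An \code{mp_predictor}.
#' @param ... Unused.
#' @return A tibble with per-factor inclusion frequency and averaged
#'   coefficient, sorted by inclusion.
#' @export
tidy.mp_predictor <- function(x, ...) {
  dplyr::arrange(
    tibble::tibble(metaprotein = names(x$inclusion),
                   inclusion = unname(x$inclusion),
                   coefficient = unname(x$coef_avg)),
    dplyr::desc(.data$inclusion))
}

# --- ROC ---------------------------------------------------------------------

#' Empirical ROC points of a score against binary labels
#'
#' @param scores Numeric classification scores (larger = class 1).
#' @param labels Binary labels.
#' @return A tibble of (threshold, fpr, tpr) stepping through the unique
#'   score values.
#' @export
roc_points <- function(scores, labels) {
  y <- as.numeric(factor(labels)) - 1
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  tibble::tibble(threshold = c(Inf, scores[ord]),
                 tpr = c(0, tp / sum(y)),
                 fpr = c(0, fp / sum(1 - y)))
}

#' Area under the ROC curve
#'
#' Computed by the rank (pairwise-concordance) formula; ties count 1/2.
#'
#' @inheritParams roc_points
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  y <- as.numeric(factor(labels)) - 1
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("need both classes for AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC with a covariance-matched random-predictor null band
#'
#' Evaluates the real predictor's ROC/AUC, then builds a null distribution:
#' each null draw generates factor scores from a mean-zero multivariate
#' normal with the covariance of the supplied factor matrix, permutes the
#' outcome, fits a fresh predictor to the permuted outcome, and records its
#' ROC/AUC.  Separation of the real curve from the null band is the
#' evidence that the predictor captures outcome-linked structure rather
#' than search flexibility.
#'
#' @param predictor A fitted [fit_predictor()].
#' @param Lambda Factor-score matrix to evaluate on.
#' @param phenotype Binary labels for those samples.
#' @param n_draws Number of null predictors.
#' @param n_iter_null Search iterations per null fit (smaller than the real
#'   fit's for speed).
#' @param seed Integer seed.
#' @return A list of class \code{mp_roc}: \code{roc} (real ROC points),
#'   \code{auc}, \code{null_auc} (vector), \code{null_roc} (long tibble of
#'   null curves).
#' @export
roc_with_random_null <- function(predictor, Lambda, phenotype,
                                 n_draws = 200, n_iter_null = 30, seed = 1) {
  y <- as.numeric(factor(phenotype)) - 1
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  Lambda <- as.matrix(Lambda)
  scores <- stats::predict(predictor, Lambda)
  real_roc <- roc_points(scores, y)
  real_auc <- auc(scores, y)

  set.seed(as.integer(seed))
  n <- nrow(Lambda)
  covL <- stats::cov(Lambda)
  ev <- eigen(covL, symmetric = TRUE)
  rt <- ev$vectors %*% (t(ev$vectors) * sqrt(pmax(ev$values, 0)))
  null_auc <- numeric(n_draws)
  null_roc <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    Xnull <- matrix(stats::rnorm(n * ncol(Lambda)), n) %*% rt
    colnames(Xnull) <- colnames(Lambda)
    yperm <- sample(y)
    pn <- fit_predictor(Xnull, yperm, max_size = predictor$config$max_size,
                        n_iter = n_iter_null, seed = seed + d)
    # score the null predictor against the *actual* labels: its training
    # outcome was permuted, so by exchangeability these AUCs center at 0.5
    # (scoring against the permuted training labels would only measure how
    # far a flexible search can overfit noise)
    sn <- stats::predict(pn, Xnull)
    null_auc[d] <- auc(sn, y)
    null_roc[[d]] <- dplyr::mutate(roc_points(sn, y), draw = d)
  }
  structure(
    list(roc = real_roc, auc = real_auc, null_auc = null_auc,
         null_roc = dplyr::bind_rows(null_roc)),
    class = "mp_roc")
}

#' @export
print.mp_roc <- function(x, ...) {
  cat(sprintf("<mp_roc> AUC %.3f; null AUC %.3f +/- %.3f over %d draws\n",
              x$auc, mean(x$null_auc), stats::sd(x$null_auc),
              length(x$null_auc)))
  invisible(x)
}

#' Plot a real ROC curve over its random-predictor null band
#'
#' @param object An \code{mp_roc}.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mp_roc <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = object$null_roc,
      ggplot2::aes(.data$fpr, .data$tpr, group = .data$draw),
      color = "grey70", alpha = 0.4) +
    ggplot2::geom_line(data = object$roc,
                       ggplot2::aes(.data$fpr, .data$tpr),
                       color = "firebrick", linewidth = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC %.3f (null mean %.3f)", object$auc,
                                  mean(object$null_auc)))
}
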