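#' Fit the metaprotein factor model by Gibbs sampling
#'
#' Cycles the conjugate full-conditional updates (row means, systematic
#' factors, membership or spike-and-slab loadings, metaprotein loadings,
#' factor scores, precisions) for \code{n_iterations} sweeps, then discards
#' burn-in, thins, and aggregates posterior membership frequencies and
#' factor-score means.  Runs are fully reproducible given the chain seed.
#'
#' Column order of the systematic factors is reported by decreasing
#' explained variance, so a dominant batch effect lands in the first column
#' of \code{H_mean}.
#'
#' @param x Filtered, log-transformed [mp_intensity].
#' @param ids Identification tibble ([read_identifications()]).
#' @param hyper An [mp_hyper].
#' @param chain An [mp_chain].
#' @return An object of class \code{mp_fit} with elements
#'   \code{membership_freq} (P x K), \code{map_assignment} (named integer
#'   vector), \code{Lambda_mean} (N x K), \code{H_mean} (N x J, variance
#'   ordered), \code{log_joint_trace}, optional \code{Lambda_draws} and
#'   \code{z_draws}, \code{factor_labels}, \code{hyper}, \code{chain}.
#' @export
run_mcmc <- function(x, ids, hyper = mp_hyper(), chain = mp_chain()) {
  stopifnot(inherits(chain, "mp_chain"))
  data <- mp_model_data(x, ids, hyper)
  state <- init_state_impl(data, hyper, chain$seed)
  P <- data$P; N <- data$N; K <- data$K; J <- hyper$J

  keep_iters <- seq_len(chain$n_iterations)
  keep <- keep_iters > chain$n_burnin &
    ((keep_iters - chain$n_burnin - 1L) %% chain$thin == 0L)
  n_keep <- sum(keep)

  memb_counts <- matrix(0, P, K)
  Lambda_sum <- matrix(0, N, K)
  BH_sum <- if (J > 0) matrix(0, P, N) else NULL
  trace <- numeric(chain$n_iterations)
  Lambda_draws <- if (chain$record_factors) {
    array(NA_real_, c(n_keep, N, K))
  } else NULL
  z_draws <- if (chain$record_membership) {
    matrix(NA_integer_, n_keep, P)
  } else NULL

  d <- 0L
  for (it in seq_len(chain$n_iterations)) {
    state <- gibbs_sweep(state, data, hyper)
    trace[it] <- tryCatch(
      log_joint(state, data, hyper),
      error = function(e) {
        stop(sprintf("chain diverged at iteration %d: %s", it,
                     conditionMessage(e)), call. = FALSE)
      })
    if (keep[it]) {
      d <- d + 1L
      if (hyper$mixture) {
        memb_counts <- memb_counts + (state$A != 0)
      } else {
        memb_counts[cbind(seq_len(P), state$z)] <-
          memb_counts[cbind(seq_len(P), state$z)] + 1
      }
      Lambda_sum <- Lambda_sum + state$Lambda
      if (J > 0) BH_sum <- BH_sum + state$B %*% t(state$H)
      if (chain$record_factors) Lambda_draws[d, , ] <- state$Lambda
      if (chain$record_membership && !hyper$mixture) z_draws[d, ] <- state$z
    }
  }

  rs <- rowSums(memb_counts)
  membership_freq <- memb_counts / ifelse(rs > 0, rs, 1)
  membership_freq[rs == 0, ] <- 1 / K
  fl <- make.unique(data$factor_labels, sep = "_")
  dimnames(membership_freq) <- list(data$isotope_group_ids, fl)
  map_assignment <- max.col(membership_freq, ties.method = "first")
  names(map_assignment) <- data$isotope_group_ids
  Lambda_mean <- Lambda_sum / n_keep
  dimnames(Lambda_mean) <- list(data$sample_ids, fl)
  H_mean <- NULL
  if (J > 0) {
    # the systematic subspace B H' is identified only up to rotation, so the
    # reported scores are the right singular vectors of its posterior mean,
    # ordered by singular value: the leading column is the dominant
    # sample-wide pattern (typically the batch shift), scaled so a
    # block-constant pattern has entries near +/-1
    sv <- svd(BH_sum / n_keep, nu = J, nv = J)
    H_mean <- sv$v * sqrt(N)
    for (j in seq_len(J)) {
      if (sum(sv$u[, j]) < 0) H_mean[, j] <- -H_mean[, j]
    }
    dimnames(H_mean) <- list(data$sample_ids, paste0("h", seq_len(J)))
  }

  structure(
    list(membership_freq = membership_freq,
         map_assignment = map_assignment,
         Lambda_mean = Lambda_mean,
         H_mean = H_mean,
         Lambda_draws = Lambda_draws,
         z_draws = z_draws,
         log_joint_trace = trace,
         factor_labels = data$factor_labels,
         isotope_group_ids = data$isotope_group_ids,
         sample_ids = data$sample_ids,
         samples = data$samples,
         id_factor = data$id_factor,
         n_draws = n_keep,
         hyper = hyper, chain = chain),
    class = "mp_fit"
  )
}

#' @export
print.mp_fit <- function(x, ...) {
  cat(sprintf(
    "<mp_fit> %d isotope groups, %d samples, %d metaprotein factors (%d labeled), %d systematic\n",
    length(x$map_assignment), length(x$sample_ids),
    ncol(x$membership_freq), sum(x$factor_labels != "noise"),
    if (is.null(x$H_mean)) 0L else ncol(x$H_mean)))
  cat(sprintf("  %d retained draws; final log joint %.1f\n",
              x$n_draws, utils::tail(x$log_joint_trace, 1)))
  invisible(x)
}

#' Tidy a fitted metaprotein model
#'
#' @param x An [run_mcmc()] fit.
#' @param type One of \code{"membership"} (one row per isotope group x
#'   factor with posterior frequency, MAP flag and identified-protein
#'   label), \code{"factors"} (long factor-score table), \code{"systematic"}
#'   (long systematic-score table) or \code{"trace"} (log-joint trace).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mp_fit <- function(x, type = c("membership", "factors", "systematic",
                                    "trace"), ...) {
  type <- match.arg(type)
  fl <- colnames(x$membership_freq)
  switch(type,
    membership = tibble::tibble(
      isotope_group_id = rep(rownames(x$membership_freq), times = ncol(x$membership_freq)),
      metaprotein = rep(fl, each = nrow(x$membership_freq)),
      frequency = as.vector(x$membership_freq),
      is_map = as.vector(col(x$membership_freq) ==
                           x$map_assignment[row(x$membership_freq)])
    ),
    factors = tibble::tibble(
      sample_id = rep(rownames(x$Lambda_mean), times = ncol(x$Lambda_mean)),
      metaprotein = rep(fl, each = nrow(x$Lambda_mean)),
      score = as.vector(x$Lambda_mean)
    ),
    systematic = {
      if (is.null(x$H_mean)) {
        tibble::tibble(sample_id = character(), factor = character(),
                       score = numeric())
      } else {
        tibble::tibble(
          sample_id = rep(rownames(x$H_mean), times = ncol(x$H_mean)),
          factor = rep(colnames(x$H_mean), each = nrow(x$H_mean)),
          score = as.vector(x$H_mean))
      }
    },
    trace = tibble::tibble(iteration = seq_along(x$log_joint_trace),
                           log_joint = x$log_joint_trace)
  )
}

#' One-line summary of a metaprotein fit
#'
#' @param x An \code{mp_fit}.
#' @param ... Unused.
#' @return A one-row tibble with dimensions, draw count and log-joint
#'   summaries.
#' @export
glance.mp_fit <- function(x, ...) {
  post <- x$log_joint_trace[(x$chain$n_burnin + 1):x$chain$n_iterations]
  tibble::tibble(
    n_isotope_groups = length(x$map_assignment),
    n_samples = length(x$sample_ids),
    n_factors = ncol(x$membership_freq),
    n_labeled = sum(x$factor_labels != "noise"),
    n_systematic = if (is.null(x$H_mean)) 0L else ncol(x$H_mean),
    n_draws = x$n_draws,
    log_joint_mean = mean(post),
    log_joint_final = utils::tail(x$log_joint_trace, 1)
  )
}

#' Plot a fitted metaprotein model
#'
#' @param object An \code{mp_fit}.
#' @param type \code{"trace"} for the log-joint trace, \code{"factors"} for
#'   a factor-score heatmap, \code{"membership"} for a membership-frequency
#'   heatmap.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mp_fit <- function(object, type = c("trace", "factors",
                                             "membership"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    df <- tidy.mp_fit(object, "trace")
    return(ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$log_joint)) +
             ggplot2::geom_line(color = "steelblue") +
             ggplot2::geom_vline(xintercept = object$chain$n_burnin,
                                 linetype = 2) +
             ggplot2::labs(x = "Gibbs sweep", y = "log joint density"))
  }
  if (type == "factors") {
    df <- tidy.mp_fit(object, "factors")
    return(ggplot2::ggplot(df, ggplot2::aes(.data$sample_id,
                                            .data$metaprotein,
                                            fill = .data$score)) +
             ggplot2::geom_tile() +
             ggplot2::scale_fill_gradient2() +
             ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
             ggplot2::labs(x = "sample", y = "metaprotein",
                           fill = "factor score"))
  }
  df <- tidy.mp_fit(object, "membership")
  ggplot2::ggplot(df, ggplot2::aes(.data$metaprotein,
                                   .data$isotope_group_id,
                                   fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme(axis.text = ggplot2::element_blank()) +
    ggplot2::labs(x = "metaprotein", y = "isotope group",
                  fill = "membership\nfrequency")
}

#' Write the posterior summary artifacts of a fit
#'
#' Emits the membership table (TSV), factor-score and systematic-score
#' means (CSV), the log-joint trace (CSV) and a JSON run-metadata block
#' echoing hyperparameters, chain configuration and seed.
#'
#' @param fit An \code{mp_fit}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_posterior <- function(fit, dir) {
  stopifnot(inherits(fit, "mp_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  memb <- tibble::tibble(
    isotope_group_id = names(fit$map_assignment),
    map_metaprotein = colnames(fit$membership_freq)[fit$map_assignment])
  memb <- dplyr::bind_cols(memb, tibble::as_tibble(fit$membership_freq))
  readr::write_tsv(memb, file.path(dir, "membership.tsv"), progress = FALSE)
  lam <- tibble::as_tibble(fit$Lambda_mean)
  lam <- dplyr::bind_cols(tibble::tibble(sample_id = fit$sample_ids), lam)
  readr::write_csv(lam, file.path(dir, "lambda_mean.csv"), progress = FALSE)
  if (!is.null(fit$H_mean)) {
    h <- dplyr::bind_cols(tibble::tibble(sample_id = fit$sample_ids),
                          tibble::as_tibble(fit$H_mean))
    readr::write_csv(h, file.path(dir, "h_mean.csv"), progress = FALSE)
  }
  readr::write_csv(tidy.mp_fit(fit, "trace"),
                   file.path(dir, "log_joint_trace.csv"), progress = FALSE)
  readr::write_tsv(fit$samples, file.path(dir, "samples.tsv"),
                   progress = FALSE)
  meta <- list(hyper = unclass(fit$hyper), chain = unclass(fit$chain),
               n_draws = fit$n_draws,
               factor_labels = fit$factor_labels)
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Reload posterior summary artifacts written by [write_posterior()]
#'
#' Reconstructs a lightweight \code{mp_fit} (membership frequencies, MAP
#' assignment, factor-score means, sample metadata) sufficient for the
#' downstream quantitation, association and prediction steps; per-draw
#' quantities are not persisted.
#'
#' @param dir Directory written by [write_posterior()].
#' @return An \code{mp_fit}.
#' @export
read_posterior <- function(dir) {
  memb <- readr::read_tsv(file.path(dir, "membership.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  lam <- readr::read_csv(file.path(dir, "lambda_mean.csv"),
                         show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "run_metadata.json"),
                              simplifyVector = TRUE)
  samples <- readr::read_tsv(file.path(dir, "samples.tsv"),
                             show_col_types = FALSE, progress = FALSE)
  mf <- as.matrix(memb[, -(1:2), drop = FALSE])
  rownames(mf) <- memb$isotope_group_id
  Lm <- as.matrix(lam[, -1, drop = FALSE])
  rownames(Lm) <- lam$sample_id
  h_path <- file.path(dir, "h_mean.csv")
  Hm <- NULL
  if (file.exists(h_path)) {
    h <- readr::read_csv(h_path, show_col_types = FALSE, progress = FALSE)
    Hm <- as.matrix(h[, -1, drop = FALSE])
    rownames(Hm) <- h$sample_id
  }
  trace <- readr::read_csv(file.path(dir, "log_joint_trace.csv"),
                           show_col_types = FALSE, progress = FALSE)
  map <- match(memb$map_metaprotein, colnames(mf))
  names(map) <- memb$isotope_group_id
  structure(
    list(membership_freq = mf, map_assignment = map, Lambda_mean = Lm,
         H_mean = Hm, Lambda_draws = NULL, z_draws = NULL,
         log_joint_trace = trace$log_joint,
         factor_labels = meta$factor_labels,
         isotope_group_ids = memb$isotope_group_id,
         sample_ids = lam$sample_id, samples = samples,
         id_factor = NULL, n_draws = meta$n_draws,
         hyper = do.call(mp_hyper, meta$hyper[setdiff(names(meta$hyper),
                                                      character(0))]),
         chain = do.call(mp_chain, meta$chain)),
    class = "mp_fit")
}
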