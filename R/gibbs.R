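# Gibbs sampler for the metaprotein factor model.
#
# All full conditionals are conjugate.  Missing cells are excluded from every
# likelihood sum (missing-at-random); the mask matrix M holds 1 for observed
# cells and 0 for missing, and Xo holds the data with missing cells zeroed so
# that (Xo - fitted) * M is the observed-cell residual.

#' Prepare model data from an intensity matrix and identifications
#'
#' Resolves the factor structure: one labeled factor per protein with at
#' least two identified isotope groups present in \code{x}, plus
#' \code{K_noise} unlabeled noise factors.  Isotope groups identified to a
#' protein below the two-group threshold are treated as unidentified for the
#' membership prior (their identification points at no factor).
#'
#' @param x Log-transformed [mp_intensity].
#' @param ids Identification tibble.
#' @param hyper An [mp_hyper] object.
#' @return An internal list with the data matrices, the Dirichlet prior
#'   matrix and the factor labels.
#' @keywords internal
mp_model_data <- function(x, ids, hyper) {
  stopifnot(inherits(x, "mp_intensity"), inherits(hyper, "mp_hyper"))
  if (x$raw) stop("model expects log-transformed intensities", call. = FALSE)
  ids <- validate_identifications(ids)
  X <- x$values
  M <- 1 - x$missing
  storage.mode(M) <- "double"
  Xo <- X
  Xo[x$missing] <- 0
  P <- nrow(X); N <- ncol(X)

  idm <- ids[ids$identified & ids$isotope_group_id %in% rownames(X), , drop = FALSE]
  prot_counts <- table(idm$protein_accession)
  labeled <- names(prot_counts)[prot_counts >= 2]
  labeled <- sort(labeled)
  K <- length(labeled) + hyper$K_noise
  if (K == 0) {
    stop("no protein has >= 2 identified isotope groups and K_noise = 0",
         call. = FALSE)
  }
  factor_labels <- c(labeled, rep("noise", hyper$K_noise))

  id_factor <- rep(NA_integer_, P)
  m <- match(rownames(X), idm$isotope_group_id)
  has <- !is.na(m)
  id_factor[has] <- match(idm$protein_accession[m[has]], labeled)

  alpha <- matrix(hyper$alpha0, P, K)
  w <- which(!is.na(id_factor))
  alpha[cbind(w, id_factor[w])] <- hyper$alphak

  list(X = X, Xo = Xo, M = M, P = P, N = N, K = K,
       n_obs = rowSums(M), factor_labels = factor_labels,
       id_factor = id_factor, alpha = alpha, sample_ids = colnames(X),
       isotope_group_ids = rownames(X), samples = x$samples)
}

#' Initialize the Gibbs sampler state
#'
#' Identified isotope groups start in their annotated protein's factor;
#' unidentified ones are spread uniformly over the noise factors (or over all
#' factors when there are none).  Row means start at the observed row means,
#' precisions at 1, factors at standard-normal draws, and each row of
#' \code{A} carries a single unit loading at its starting factor.
#'
#' @param x Log-transformed [mp_intensity].
#' @param ids Identification tibble.
#' @param hyper An [mp_hyper].
#' @param seed Integer seed.
#' @return A list of class \code{mp_state}.
#' @export
init_state <- function(x, ids, hyper = mp_hyper(), seed = 1) {
  data <- mp_model_data(x, ids, hyper)
  state <- init_state_impl(data, hyper, seed)
  state
}

init_state_impl <- function(data, hyper, seed) {
  set.seed(as.integer(seed))
  P <- data$P; N <- data$N; K <- data$K; J <- hyper$J
  n_noise <- hyper$K_noise
  z <- data$id_factor
  free <- is.na(z)
  pool <- if (n_noise > 0) (K - n_noise + 1):K else 1:K
  if (any(free)) {
    pool_rep <- rep(pool, length.out = sum(free))
    z[free] <- pool_rep[sample.int(length(pool_rep))]
  }
  mu <- ifelse(data$n_obs > 0, rowSums(data$Xo) / pmax(data$n_obs, 1), hyper$mu0)
  A <- matrix(0, P, K)
  A[cbind(seq_len(P), z)] <- 1
  q <- data$alpha / rowSums(data$alpha)
  # labeled factors start at the standardized mean centered pattern of their
  # identified members; random starts invite sign-cancelled local modes
  Lambda <- matrix(stats::rnorm(N * K), N, K)
  for (k in seq_len(K - n_noise)) {
    members <- which(data$id_factor == k)
    if (length(members) >= 1) {
      R <- data$Xo[members, , drop = FALSE]
      Mg <- data$M[members, , drop = FALSE]
      rowm <- rowSums(R) / pmax(rowSums(Mg), 1)
      C <- (R - rowm) * Mg
      pattern <- colSums(C) / pmax(colSums(Mg), 1)
      if (stats::sd(pattern) > 0) Lambda[, k] <- pattern / stats::sd(pattern)
    }
  }
  structure(
    list(mu = mu,
         B = matrix(0, P, J),
         H = matrix(stats::rnorm(N * J), N, J),
         A = A,
         Lambda = Lambda,
         z = z, q = q,
         tau = rep(1, P),
         qk_mix = rep(hyper$mixture_nu0 /
                        (hyper$mixture_nu0 + hyper$mixture_gamma0), K),
         factor_labels = data$factor_labels, K = K, J = J),
    class = "mp_state"
  )
}

# fitted systematic + metaprotein parts
fit_BH <- function(state) {
  if (state$J > 0) state$B %*% t(state$H) else 0
}
fit_AL <- function(state) state$A %*% t(state$Lambda)

# --- full conditionals -------------------------------------------------------

#' Gibbs update of the row means mu
#'
#' Each \eqn{\mu_i} has the conjugate Gaussian full conditional with
#' precision \eqn{1/\phi_0 + n_i \tau_i} and mean
#' \eqn{(\mu_0/\phi_0 + \tau_i \sum_n r_{i,n}) / (1/\phi_0 + n_i \tau_i)}
#' where \eqn{r_i} is row i's residual after removing \eqn{BH'} and
#' \eqn{A\Lambda'} over observed cells.  Rows with no observed cells draw
#' from the prior.
#'
#' @param state An \code{mp_state}.
#' @param data Prepared model data ([mp_model_data()]).
#' @param hyper An [mp_hyper].
#' @return The updated state.
#' @export
update_mu <- function(state, data, hyper) {
  E <- (data$Xo - fit_BH(state) - fit_AL(state)) * data$M
  cond <- mu_conditional(rowSums(E), data$n_obs, state$tau, hyper)
  state$mu <- stats::rnorm(data$P, cond$mean, sqrt(cond$var))
  state
}

mu_conditional <- function(rsum, n_obs, tau, hyper) {
  prec <- 1 / hyper$phi0 + n_obs * tau
  list(mean = (hyper$mu0 / hyper$phi0 + tau * rsum) / prec, var = 1 / prec)
}

#' Gibbs update of the systematic factors B and H
#'
#' Dense sample-wide structure (batch / sensitivity shifts).  Loadings
#' \eqn{b_{i,j}} carry the N(0, v0) prior and the factor scores
#' \eqn{h_{n,j}} the N(0, 1) prior; both have standard Gaussian-regression
#' full conditionals over observed cells.  Columns are updated in turn.
#'
#' @inheritParams update_mu
#' @return The updated state.
#' @export
update_systematic <- function(state, data, hyper) {
  if (state$J == 0) return(state)
  E <- (data$Xo - state$mu - fit_AL(state) - fit_BH(state)) * data$M
  for (j in seq_len(state$J)) {
    Rj <- E + outer(state$B[, j], state$H[, j]) * data$M
    cb <- b_conditional(Rj, data$M, state$H[, j], state$tau, hyper)
    state$B[, j] <- stats::rnorm(data$P, cb$mean, sqrt(cb$var))
    ch <- h_conditional(Rj, data$M, state$B[, j], state$tau)
    state$H[, j] <- stats::rnorm(data$N, ch$mean, sqrt(ch$var))
    E <- Rj - outer(state$B[, j], state$H[, j]) * data$M
  }
  state
}

b_conditional <- function(Rj, M, h, tau, hyper) {
  prec <- 1 / hyper$v0 + tau * as.vector(M %*% (h^2))
  list(mean = tau * as.vector(Rj %*% h) / prec, var = 1 / prec)
}

h_conditional <- function(Rj, M, b, tau) {
  prec <- 1 + as.vector(t(M) %*% (tau * b^2))
  list(mean = as.vector(t(Rj) %*% (tau * b)) / prec, var = 1 / prec)
}

# Marginal-likelihood pieces for membership: for each row i and factor k,
# s1 = sum_n lambda_{n,k} r_{i,n}, s2 = sum_n lambda_{n,k}^2 over observed
# cells, and the log marginal of the residual with a integrated out under
# N(0, v0):  -0.5 log v0 - 0.5 log(1/v0 + tau s2) + (tau s1)^2 / 2(1/v0+tau s2)
# (dropping row-constant terms).
membership_suffstats <- function(state, data) {
  E <- (data$Xo - state$mu - fit_BH(state)) * data$M
  list(S1 = E %*% state$Lambda, S2 = data$M %*% (state$Lambda^2), E = E)
}

membership_logweights <- function(S1, S2, tau, alpha, v0) {
  pv <- 1 / v0 + tau * S2
  log(alpha) - 0.5 * log(v0) - 0.5 * log(pv) + 0.5 * (tau * S1)^2 / pv
}

#' Gibbs update of metaprotein membership (z, q) and the A row pattern
#'
#' For each isotope group the factor indicator \eqn{z_i} is resampled from
#' the K-way discrete distribution with weights proportional to the
#' Dirichlet pseudocount (\code{alphak} on the identified factor,
#' \code{alpha0} elsewhere) times the marginal likelihood of row i's
#' residual with the loading integrated out under its N(0, v0) slab --
#' collapsing the loading is what lets a strongly co-expressing factor
#' overturn a 500:1 identification prior.  The membership probabilities
#' \eqn{q_i} are then drawn from their Dirichlet posterior and the row of
#' \code{A} is reset to a single fresh draw at the new factor.
#'
#' @inheritParams update_mu
#' @return The updated state.
#' @export
update_membership <- function(state, data, hyper) {
  if (hyper$mixture) {
    stop("membership updates are disabled in mixture mode", call. = FALSE)
  }
  ss <- membership_suffstats(state, data)
  lw <- membership_logweights(ss$S1, ss$S2, state$tau, data$alpha, hyper$v0)
  state$z <- sample_rows_log(lw)
  # Dirichlet posterior for q given the single multinomial observation z_i
  shape <- data$alpha
  shape[cbind(seq_len(data$P), state$z)] <-
    shape[cbind(seq_len(data$P), state$z)] + 1
  g <- matrix(stats::rgamma(length(shape), shape = shape), data$P, data$K)
  state$q <- g / rowSums(g)
  state <- draw_A_at_z(state, ss, data, hyper)
  state
}

# categorical draw per row of a matrix of unnormalized log weights
sample_rows_log <- function(lw) {
  w <- exp(lw - apply(lw, 1, max))
  u <- stats::runif(nrow(w)) * rowSums(w)
  cw <- t(apply(w, 1, cumsum))
  as.integer(max.col(cw >= u, ties.method = "first"))
}

draw_A_at_z <- function(state, ss, data, hyper) {
  idx <- cbind(seq_len(data$P), state$z)
  pv <- 1 / hyper$v0 + state$tau * ss$S2[idx]
  mn <- state$tau * ss$S1[idx] / pv
  state$A <- matrix(0, data$P, data$K)
  state$A[idx] <- stats::rnorm(data$P, mn, 1 / sqrt(pv))
  state
}

#' Gibbs update of the non-zero metaprotein loadings
#'
#' Each \eqn{a_{i,z_i}} is redrawn from its Gaussian full conditional (prior
#' N(0, v0), design = the \eqn{\Lambda} column of its factor over observed
#' cells); all other entries of the row stay zero.
#'
#' @inheritParams update_mu
#' @return The updated state.
#' @export
update_loadings <- function(state, data, hyper) {
  ss <- membership_suffstats(state, data)
  draw_A_at_z(state, ss, data, hyper)
}

a_conditional <- function(s1, s2, tau, hyper) {
  prec <- 1 / hyper$v0 + tau * s2
  list(mean = tau * s1 / prec, var = 1 / prec)
}

#' Gibbs update of the metaprotein factor scores Lambda
#'
#' Each column is drawn from its Gaussian full conditional with prior
#' N(0, I) over samples, using the rows currently loading on that factor and
#' their observed cells.  Factors with no assigned rows draw from the prior.
#' With \code{sphere_constraint} the freshly drawn column is rescaled to
#' norm \eqn{\sqrt{N}}.
#'
#' @inheritParams update_mu
#' @return The updated state.
#' @export
update_factors <- function(state, data, hyper) {
  E <- (data$Xo - state$mu - fit_BH(state) - fit_AL(state)) * data$M
  for (k in seq_len(state$K)) {
    a <- state$A[, k]
    Rk <- E + outer(a, state$Lambda[, k]) * data$M
    cl <- lambda_conditional(Rk, data$M, a, state$tau)
    lam <- stats::rnorm(data$N, cl$mean, sqrt(cl$var))
    if (hyper$sphere_constraint) {
      nrm <- sqrt(sum(lam^2))
      if (nrm > 0) lam <- lam * sqrt(data$N) / nrm
    }
    state$Lambda[, k] <- lam
    E <- Rk - outer(a, lam) * data$M
  }
  state
}

lambda_conditional <- function(Rk, M, a, tau) {
  prec <- 1 + as.vector(t(M) %*% (tau * a^2))
  list(mean = as.vector(t(Rk) %*% (tau * a)) / prec, var = 1 / prec)
}

#' Gibbs update of the residual precisions tau
#'
#' Conjugate draw \eqn{\tau_i \sim Gamma(\nu_0 + n_i/2, \delta_0 + SSR_i/2)}
#' with \eqn{SSR_i} the squared-residual sum of row i over observed cells.
#'
#' @inheritParams update_mu
#' @return The updated state.
#' @export
update_precisions <- function(state, data, hyper) {
  E <- (data$Xo - state$mu - fit_BH(state) - fit_AL(state)) * data$M
  ssr <- rowSums(E^2)
  state$tau <- stats::rgamma(data$P, shape = hyper$nu0 + data$n_obs / 2,
                             rate = hyper$delta0 + ssr / 2)
  state
}

#' Gibbs update of spike-and-slab loadings (overlapping-peaks extension)
#'
#' Every entry \eqn{a_{i,k}} carries the mixture prior
#' \eqn{(1-q_k)\delta_0(a) + q_k N(a \mid 0, v_0)}, so a row may load on
#' several metaproteins (overlapping chromatographic peaks, homologous
#' peptides).  Inclusion is resampled from the two-component posterior via
#' the closed-form Bayes factor of slab vs. point mass, the included
#' loadings from their Gaussian conditionals, and each \eqn{q_k} from its
#' Beta posterior.  The single-membership bookkeeping (z, q) is not updated
#' in this mode.
#'
#' @inheritParams update_mu
#' @return The updated state.
#' @export
update_mixture_loadings <- function(state, data, hyper) {
  if (!hyper$mixture) {
    stop("mixture hyperparameters unset: construct mp_hyper(mixture = TRUE)",
         call. = FALSE)
  }
  E <- (data$Xo - state$mu - fit_BH(state) - fit_AL(state)) * data$M
  for (k in seq_len(state$K)) {
    Rk <- E + outer(state$A[, k], state$Lambda[, k]) * data$M
    s2 <- as.vector(data$M %*% (state$Lambda[, k]^2))
    s1 <- as.vector(Rk %*% state$Lambda[, k])
    pv <- 1 / hyper$v0 + state$tau * s2
    log_bf <- -0.5 * log(hyper$v0) - 0.5 * log(pv) +
      0.5 * (state$tau * s1)^2 / pv
    qk <- state$qk_mix[k]
    p_incl <- stats::plogis(log(qk / (1 - qk)) + log_bf)
    incl <- stats::runif(data$P) < p_incl
    anew <- numeric(data$P)
    if (any(incl)) {
      anew[incl] <- stats::rnorm(sum(incl), (state$tau * s1 / pv)[incl],
                                 1 / sqrt(pv[incl]))
    }
    state$A[, k] <- anew
    state$qk_mix[k] <- stats::rbeta(1, hyper$mixture_nu0 + sum(incl),
                                    hyper$mixture_gamma0 + data$P - sum(incl))
    E <- Rk - outer(anew, state$Lambda[, k]) * data$M
  }
  state
}

#' Log unnormalized joint density of the model
#'
#' Likelihood over observed cells times all priors; used to monitor the
#' chain and to detect divergence.
#'
#' @inheritParams update_mu
#' @return A finite scalar.
#' @export
log_joint <- function(state, data, hyper) {
  if (!all(is.finite(unlist(state[c("mu", "B", "H", "A", "Lambda", "tau")])))) {
    stop("non-finite values in model state", call. = FALSE)
  }
  E <- (data$Xo - state$mu - fit_BH(state) - fit_AL(state)) * data$M
  ll <- sum(0.5 * data$n_obs * (log(state$tau) - log(2 * pi)) -
              0.5 * state$tau * rowSums(E^2))
  lp <- sum(stats::dnorm(state$mu, hyper$mu0, sqrt(hyper$phi0), log = TRUE)) +
    sum(stats::dnorm(state$H, 0, 1, log = TRUE)) +
    sum(stats::dnorm(state$Lambda, 0, 1, log = TRUE)) +
    sum(stats::dgamma(state$tau, hyper$nu0, rate = hyper$delta0, log = TRUE))
  if (state$J > 0) {
    lp <- lp + sum(stats::dnorm(state$B, 0, sqrt(hyper$v0), log = TRUE))
  }
  nz <- state$A != 0
  lp <- lp + sum(stats::dnorm(state$A[nz], 0, sqrt(hyper$v0), log = TRUE))
  if (hyper$mixture) {
    n_in <- colSums(nz)
    lp <- lp + sum(n_in * log(state$qk_mix) +
                     (data$P - n_in) * log1p(-state$qk_mix)) +
      sum(stats::dbeta(state$qk_mix, hyper$mixture_nu0, hyper$mixture_gamma0,
                       log = TRUE))
  } else {
    # z | q and q | alpha (Dirichlet)
    lq <- log(pmax(state$q, .Machine$double.xmin))
    lp <- lp + sum(lq[cbind(seq_len(data$P), state$z)])
    lp <- lp + sum((data$alpha - 1) * lq) +
      data$P * lgamma(sum(data$alpha[1, ])) -
      sum(lgamma(data$alpha))
  }
  out <- ll + lp
  if (!is.finite(out)) stop("non-finite log joint", call. = FALSE)
  out
}

# Flip the sign of each factor column so that the summed loading of its
# current members (identified members for labeled factors) is non-negative;
# prevents sign-switching from corrupting posterior means.
fix_signs <- function(state, data) {
  for (k in seq_len(state$K)) {
    members <- which(data$id_factor == k)
    if (length(members) == 0) members <- which(state$A[, k] != 0)
    s <- sum(state$A[members, k])
    if (isTRUE(s < 0)) {
      state$A[, k] <- -state$A[, k]
      state$Lambda[, k] <- -state$Lambda[, k]
    }
  }
  if (state$J > 0) {
    for (j in seq_len(state$J)) {
      if (sum(state$B[, j]) < 0) {
        state$B[, j] <- -state$B[, j]
        state$H[, j] <- -state$H[, j]
      }
    }
  }
  state
}

# One full Gibbs sweep in the spec's cycle order.
gibbs_sweep <- function(state, data, hyper) {
  state <- update_mu(state, data, hyper)
  state <- update_systematic(state, data, hyper)
  if (hyper$mixture) {
    state <- update_mixture_loadings(state, data, hyper)
  } else {
    state <- update_membership(state, data, hyper)
    state <- update_loadings(state, data, hyper)
  }
  state <- update_factors(state, data, hyper)
  state <- update_precisions(state, data, hyper)
  fix_signs(state, data)
}

# Draw a fresh data matrix X from the likelihood given the current state;
# used by the joint-distribution (successive-conditional) sampler check.
simulate_from_state <- function(state, data) {
  mean_mat <- state$mu + fit_BH(state) + fit_AL(state)
  X <- mean_mat + stats::rnorm(length(mean_mat)) /
    sqrt(state$tau)[row(mean_mat)]
  X <- X * data$M
  data$Xo <- X
  data
}
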