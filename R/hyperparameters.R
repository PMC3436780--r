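#' Hyperparameters of the metaprotein factor model
#'
#' All constants of the hierarchical model
#' \deqn{X = \mu 1' + B H' + A \Lambda' + \epsilon}
#' with \eqn{\mu_i \sim N(\mu_0, \phi_0)}, \eqn{b_{i,j} \sim N(0, v_0)},
#' \eqn{h_{n,j}, \lambda_{n,k} \sim N(0,1)},
#' \eqn{\epsilon_{i,n} \sim N(0, \tau_i^{-1})},
#' \eqn{\tau_i \sim Gamma(\nu_0, \delta_0)},
#' \eqn{a_{i,k} \sim N(0, v_0)} on the single non-zero entry selected by
#' \eqn{z_i \sim Multinomial(1, q_i)},
#' \eqn{q_i \sim Dir(\alpha_0, \ldots, \alpha_k, \ldots, \alpha_0)}.
#'
#' The defaults are deliberately diffuse: \code{mu0 = 8}, \code{phi0 = 100}
#' puts a two-sigma interval of (-12, 28) on row means of natural-log AUC
#' intensities; \code{v0 = 100} admits fold changes beyond 1e8;
#' \code{nu0 = delta0 = 0.001} gives the residual precision prior mean 1 and
#' variance 1000.  The only strongly informative constant is the
#' identification pseudocount \code{alphak = 500} against a baseline
#' \code{alpha0 = 1}: prior odds of 500:1 that an identified isotope group
#' loads on its annotated protein's factor.  The ratio, not the absolute
#' pseudocounts, is what the membership update feels; 500:1 is strong but
#' can still be overturned by co-expression evidence, which caps near
#' \eqn{n/2} nats for a row observed in \eqn{n} samples once its residual
#' variance has adapted.
#'
#' @param mu0,phi0 Prior mean and variance of isotope-group mean intensities.
#' @param v0 Prior variance of loadings in \code{A} and \code{B}.
#' @param nu0,delta0 Shape and rate of the Gamma prior on residual precisions.
#' @param alpha0 Baseline Dirichlet pseudocount for factor membership.
#' @param alphak Pseudocount placed on the factor matching an isotope group's
#'   identification.
#' @param J Number of dense systematic (batch/sensitivity) factors.
#' @param K_noise Number of unlabeled "noise" metaprotein factors.
#' @param sphere_constraint If \code{TRUE}, each stored \eqn{\Lambda} column
#'   is rescaled to norm \eqn{\sqrt{N}} after its draw (the uniform-on-sphere
#'   reading of the factor prior); default off, using the i.i.d. N(0,1) form.
#' @param mixture Enable the overlapping-peaks extension: a point-mass
#'   spike-and-slab prior on every entry of \code{A}, allowing an isotope
#'   group to load on several metaproteins.
#' @param mixture_nu0,mixture_gamma0 Beta pseudocounts of the per-factor
#'   inclusion probability \eqn{q_k \sim Be(\nu_0, \gamma_0)} in mixture
#'   mode.  Defaults expect about 1\% inclusion per factor.
#' @return A list of class \code{mp_hyper}.
#' @export
mp_hyper <- function(mu0 = 8, phi0 = 100, v0 = 100,
                     nu0 = 0.001, delta0 = 0.001,
                     alpha0 = 1, alphak = 500,
                     J = 3, K_noise = 10,
                     sphere_constraint = FALSE,
                     mixture = FALSE,
                     mixture_nu0 = 1, mixture_gamma0 = 99) {
  stopifnot(phi0 > 0, v0 > 0, nu0 > 0, delta0 > 0, alpha0 > 0,
            alphak >= alpha0, J >= 0, K_noise >= 0,
            mixture_nu0 > 0, mixture_gamma0 > 0)
  structure(
    list(mu0 = mu0, phi0 = phi0, v0 = v0, nu0 = nu0, delta0 = delta0,
         alpha0 = alpha0, alphak = alphak, J = as.integer(J),
         K_noise = as.integer(K_noise),
         sphere_constraint = isTRUE(sphere_constraint),
         mixture = isTRUE(mixture),
         mixture_nu0 = mixture_nu0, mixture_gamma0 = mixture_gamma0),
    class = "mp_hyper"
  )
}

#' MCMC chain configuration
#'
#' @param n_iterations Total Gibbs sweeps.
#' @param n_burnin Sweeps discarded before summarization.
#' @param thin Keep every \code{thin}-th post-burn-in sweep.
#' @param seed Integer RNG seed; every run is fully reproducible given it.
#' @param record_membership Store per-draw membership vectors
#'   (\code{z_draws}).
#' @param record_factors Store per-draw \eqn{\Lambda} matrices
#'   (\code{Lambda_draws}); needed for draw-wise predictor construction.
#' @return A list of class \code{mp_chain}.
#' @export
mp_chain <- function(n_iterations = 2000, n_burnin = 1000, thin = 2,
                     seed = 1, record_membership = TRUE,
                     record_factors = FALSE) {
  stopifnot(n_iterations > n_burnin, n_burnin >= 0, thin >= 1)
  structure(
    list(n_iterations = as.integer(n_iterations),
         n_burnin = as.integer(n_burnin), thin = as.integer(thin),
         seed = as.integer(seed),
         record_membership = isTRUE(record_membership),
         record_factors = isTRUE(record_factors)),
    class = "mp_chain"
  )
}
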