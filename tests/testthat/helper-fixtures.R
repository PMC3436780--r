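# Shared fixture builders and independent numerical oracles.

# posterior mean/variance of a 1-d density by trapezoid integration on a grid
grid_moments <- function(log_dens, lower, upper, n = 20001) {
  x <- seq(lower, upper, length.out = n)
  ld <- vapply(x, log_dens, numeric(1))
  w <- exp(ld - max(ld))
  dx <- x[2] - x[1]
  z <- sum(w) * dx
  m <- sum(x * w) * dx / z
  v <- sum((x - m)^2 * w) * dx / z
  list(mean = m, var = v)
}

# small intensity matrix with explicit values (raw counts)
tiny_raw <- function(values, ids = NULL, samples = NULL) {
  values <- as.matrix(values)
  if (!is.null(ids)) rownames(values) <- ids
  mp_intensity(values, raw = TRUE, samples = samples)
}

# a model-data/state pair for conditional-correctness checks:
# tiny log-scale instance with controlled latent values
tiny_model <- function(X, ids = NULL, hyper = mp_hyper(J = 1, K_noise = 1),
                       missing = NULL) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("g", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("s", seq_len(ncol(X)))
  x <- mp_intensity(X, missing = missing, raw = FALSE, log_base = exp(1))
  if (is.null(ids)) {
    ids <- tibble::tibble(isotope_group_id = character(),
                          peptide_sequence = character(),
                          protein_accession = character(),
                          identified = logical())
  }
  data <- metaprotein:::mp_model_data(x, ids, hyper)
  state <- metaprotein:::init_state_impl(data, hyper, seed = 1)
  list(x = x, data = data, state = state, hyper = hyper)
}

# minimal mp_fit for bookkeeping tests: map assignments given directly
fake_fit <- function(map_factor, factor_labels, sample_ids = NULL,
                     Lambda_mean = NULL) {
  ids <- names(map_factor)
  K <- length(factor_labels)
  mf <- matrix(0, length(map_factor), K,
               dimnames = list(ids, factor_labels))
  mf[cbind(seq_along(map_factor), map_factor)] <- 1
  if (is.null(Lambda_mean)) {
    sample_ids <- sample_ids %||% paste0("s", 1:4)
    Lambda_mean <- matrix(0, length(sample_ids), K,
                          dimnames = list(sample_ids, factor_labels))
  }
  structure(
    list(membership_freq = mf,
         map_assignment = stats::setNames(map_factor, ids),
         Lambda_mean = Lambda_mean, H_mean = NULL,
         log_joint_trace = 0, factor_labels = factor_labels,
         isotope_group_ids = ids, sample_ids = rownames(Lambda_mean),
         samples = tibble::tibble(sample_id = rownames(Lambda_mean)),
         n_draws = 1, hyper = mp_hyper(), chain = mp_chain(n_iterations = 2,
                                                           n_burnin = 1)),
    class = "mp_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# identification tibble shorthand
make_ids <- function(group, protein, peptide = NULL) {
  tibble::tibble(
    isotope_group_id = group,
    peptide_sequence = peptide %||% rep("ACDEFGHIK", length(group)),
    protein_accession = protein,
    identified = TRUE)
}

# all permutations of 1..n (tiny n), for exhaustive assignment oracles
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (i in 1:n) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  unname(out)
}

# one small-preset dataset + fit, computed once per test session
.fixture_cache <- new.env(parent = emptyenv())
get_small_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- generate_dataset(sim_preset("small", seed = 42))
  }
  .fixture_cache$sim
}
get_small_fit <- function() {
  if (is.null(.fixture_cache$fit)) {
    sim <- get_small_sim()
    .fixture_cache$fit <- run_mcmc(
      sim$intensity, sim$ids, mp_hyper(),
      mp_chain(n_iterations = 400, n_burnin = 200, thin = 2, seed = 11))
  }
  .fixture_cache$fit
}
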