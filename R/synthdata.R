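# Generative simulator: samples datasets forward from the factor model so
# that recovery of memberships, batch structure and predictors can be
# checked against known truth.

#' Simulation configuration
#'
#' Describes a synthetic label-free LC-MS dataset drawn forward from the
#' metaprotein factor model.  The default scale mirrors a serum shotgun
#' study: ~6700 isotope groups over ~96 analyses in 3 runblocks, ~109
#' proteins carrying two or more identified isotope groups, about half the
#' isotope groups identified, ~1\% misidentifications and a small minority
#' of PTM-divergent peptides, with intensity-dependent missingness.  Use
#' [sim_preset()] for the reduced sizes the test-suite runs at.
#'
#' @param P,N Number of isotope groups and samples.
#' @param K_true Number of true metaprotein factors (= simulated proteins).
#' @param J_true Number of systematic (batch) factors; the first is the
#'   runblock sensitivity shift.
#' @param snr Signal-to-noise scale: loadings are drawn N(0, snr^2) against
#'   residual precision of mean 1, so snr is the typical loading magnitude
#'   in residual-sd units.
#' @param frac_identified Fraction of isotope groups carrying an MS/MS
#'   identification.
#' @param frac_misidentified Fraction of identifications pointing at the
#'   wrong protein (the ~1\% peptide false-discovery rate of a filtered
#'   database search).
#' @param frac_ptm_divergent Fraction of identified isotope groups whose
#'   true expression follows a different factor than their (correct) protein
#'   label -- the PTM signature: label says protein k, abundance tracks
#'   factor k'.
#' @param mu_mean,mu_sd Mean and sd of true row means on the natural-log
#'   scale (ln of typical AUC counts ~3000 gives 8).
#' @param tau_shape,tau_rate Gamma parameters of true residual precisions
#'   (defaults give mean 1 with moderate spread).
#' @param missing_midpoint,missing_slope Logistic intensity-dependent
#'   missingness: a cell with true log intensity x is missing with
#'   probability \code{plogis(missing_slope * (missing_midpoint - x))}.
#' @param n_runblocks Number of batches the analyses are split into.
#' @param batch_effect Mean loading of the runblock sensitivity factor (0
#'   disables it); the factor scores are +1 for the first
#'   \code{n_runblocks - 1} blocks and -1 for the last.
#' @param phenotype_factor Optional list \code{list(factor =, shift =)}:
#'   samples get a balanced binary phenotype and the named factor's scores
#'   are shifted by \code{+shift/2} in class 1 and \code{-shift/2} in class
#'   0 (so \code{shift} is the class separation in factor-score sd units).
#' @param seed Integer seed; the emitted triple is a deterministic function
#'   of the configuration.
#' @return A list of class \code{mp_sim_config}.
#' @export
mp_sim_config <- function(P = 6729, N = 96, K_true = 109, J_true = 1,
                          snr = 5, frac_identified = 0.5,
                          frac_misidentified = 0.01,
                          frac_ptm_divergent = 0.02,
                          mu_mean = 8, mu_sd = 1.5,
                          tau_shape = 20, tau_rate = 20,
                          missing_midpoint = 5, missing_slope = 1,
                          n_runblocks = 3, batch_effect = 0.5,
                          phenotype_factor = NULL, seed = 1) {
  stopifnot(P >= 1, N >= 2, K_true >= 1, K_true <= P, J_true >= 0,
            snr > 0, frac_identified >= 0, frac_identified <= 1,
            frac_misidentified >= 0, frac_misidentified <= 1,
            frac_ptm_divergent >= 0, frac_ptm_divergent <= 1,
            mu_sd > 0, tau_shape > 0, tau_rate > 0, n_runblocks >= 1)
  if (!is.null(phenotype_factor)) {
    stopifnot(is.list(phenotype_factor),
              phenotype_factor$factor >= 1,
              phenotype_factor$factor <= K_true)
  }
  structure(
    list(P = as.integer(P), N = as.integer(N), K_true = as.integer(K_true),
         J_true = as.integer(J_true), snr = snr,
         frac_identified = frac_identified,
         frac_misidentified = frac_misidentified,
         frac_ptm_divergent = frac_ptm_divergent,
         mu_mean = mu_mean, mu_sd = mu_sd,
         tau_shape = tau_shape, tau_rate = tau_rate,
         missing_midpoint = missing_midpoint, missing_slope = missing_slope,
         n_runblocks = as.integer(n_runblocks), batch_effect = batch_effect,
         phenotype_factor = phenotype_factor, seed = as.integer(seed)),
    class = "mp_sim_config"
  )
}

#' Named simulation presets
#'
#' \code{"full_scale"} is the full default configuration (a
#' clinical-cohort-sized serum study); \code{"small"} (P = 300, N = 48,
#' K = 10) is the reduced preset used throughout the test suite.
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [mp_sim_config()].
#' @return An \code{mp_sim_config}.
#' @export
sim_preset <- function(name = c("small", "full_scale"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    small = list(P = 300L, N = 48L, K_true = 10L, J_true = 1L),
    full_scale = list()
  )
  do.call(mp_sim_config, utils::modifyList(args, list(...)))
}

random_peptides <- function(n) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
          "N", "P", "Q", "S", "T", "V", "W", "Y")
  vapply(seq_len(n), function(i) {
    len <- sample(7:14, 1)
    paste0(paste(sample(aa, len, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1))
  }, character(1))
}

#' Generate a synthetic dataset from the factor model
#'
#' Draws all latent quantities forward (memberships, loadings, factor
#' scores, batch structure, row means, precisions), assembles the
#' log-intensity matrix, applies logistic intensity-dependent missingness,
#' assigns protein labels, corrupts a fraction of identifications to wrong
#' proteins, and re-routes a fraction of identified groups to a different
#' true factor than their label (PTM divergence).
#'
#' @param config An [mp_sim_config()].
#' @return A list with elements \code{intensity} (log-scale
#'   [mp_intensity]), \code{raw_intensity} (the same data exponentiated to
#'   AUC counts), \code{ids} (identification tibble) and \code{truth}
#'   (all latent quantities plus corruption records).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "mp_sim_config"))
  set.seed(config$seed)
  P <- config$P; N <- config$N; K <- config$K_true; J <- config$J_true

  sample_ids <- sprintf("s%03d", seq_len(N))
  group_ids <- sprintf("ig%05d", seq_len(P))
  runblock <- sprintf("rb%d", 1 + (seq_len(N) - 1) %% config$n_runblocks)
  runblock <- sort(runblock)

  phenotype <- rep(NA_integer_, N)
  if (!is.null(config$phenotype_factor)) {
    phenotype <- rep(c(0L, 1L), length.out = N)
  }

  z <- sample(rep(seq_len(K), length.out = P))
  mu <- stats::rnorm(P, config$mu_mean, config$mu_sd)
  tau <- stats::rgamma(P, config$tau_shape, rate = config$tau_rate)
  Lambda <- matrix(stats::rnorm(N * K), N, K)
  if (!is.null(config$phenotype_factor)) {
    pf <- config$phenotype_factor
    Lambda[, pf$factor] <- Lambda[, pf$factor] +
      ifelse(phenotype == 1L, pf$shift / 2, -pf$shift / 2)
  }
  # loadings are half-normal: peptides from one protein co-express with a
  # common sign (ionization sensitivity scales, but does not invert, the
  # shared concentration signal); E[a^2] = snr^2
  a <- abs(stats::rnorm(P, 0, config$snr))
  A <- matrix(0, P, K)
  A[cbind(seq_len(P), z)] <- a

  B <- matrix(0, P, max(J, 1))[, seq_len(J), drop = FALSE]
  H <- matrix(0, N, max(J, 1))[, seq_len(J), drop = FALSE]
  if (J >= 1 && config$batch_effect != 0 && config$n_runblocks > 1) {
    last <- runblock == sprintf("rb%d", config$n_runblocks)
    H[, 1] <- ifelse(last, -1, 1)
    B[, 1] <- stats::rnorm(P, config$batch_effect, abs(config$batch_effect) / 3)
  }
  if (J >= 2) {
    for (j in 2:J) {
      H[, j] <- stats::rnorm(N)
      B[, j] <- stats::rnorm(P, 0, abs(config$batch_effect) / 2)
    }
  }

  X <- mu + B %*% t(H) + A %*% t(Lambda) +
    matrix(stats::rnorm(P * N), P, N) / sqrt(tau)
  dimnames(X) <- list(group_ids, sample_ids)

  # identifications: protein label = true factor, then PTM re-routing and
  # misidentification corruption
  proteins <- sprintf("PROT%03d", seq_len(K))
  n_id <- round(config$frac_identified * P)
  id_rows <- sort(sample(seq_len(P), n_id))
  label <- proteins[z[id_rows]]

  ptm_rows <- integer(0)
  if (config$frac_ptm_divergent > 0 && n_id > 0 && K > 1) {
    n_ptm <- round(config$frac_ptm_divergent * n_id)
    ptm_idx <- sample(seq_len(n_id), n_ptm)
    ptm_rows <- id_rows[ptm_idx]
    # label keeps the original protein; the row's true factor moves
    for (r in ptm_rows) {
      newk <- sample(setdiff(seq_len(K), z[r]), 1)
      X[r, ] <- X[r, ] - A[r, z[r]] * Lambda[, z[r]] +
        A[r, z[r]] * Lambda[, newk]
      A[r, newk] <- A[r, z[r]]; A[r, z[r]] <- 0
      z[r] <- newk
    }
  }

  misid_rows <- integer(0)
  if (config$frac_misidentified > 0 && n_id > 0 && K > 1) {
    n_mis <- round(config$frac_misidentified * n_id)
    mis_idx <- sample(seq_len(n_id), n_mis)
    misid_rows <- id_rows[mis_idx]
    label[mis_idx] <- vapply(mis_idx, function(i) {
      sample(setdiff(proteins, label[i]), 1)
    }, character(1))
  }

  ids <- tibble::tibble(
    isotope_group_id = group_ids[id_rows],
    peptide_sequence = random_peptides(n_id),
    protein_accession = label,
    identified = TRUE)

  p_miss <- stats::plogis(config$missing_slope * (config$missing_midpoint - X))
  missing <- matrix(stats::runif(P * N) < p_miss, P, N)
  # never blank out an entire row
  allmiss <- rowSums(!missing) == 0
  if (any(allmiss)) missing[allmiss, 1] <- FALSE

  samples <- tibble::tibble(sample_id = sample_ids, runblock = runblock,
                            phenotype = phenotype)
  intensity <- mp_intensity(X, missing = missing, raw = FALSE,
                            log_base = exp(1), samples = samples)
  raw_vals <- exp(X)
  raw_vals[missing] <- NA_real_
  raw_intensity <- mp_intensity(raw_vals, missing = missing, raw = TRUE,
                                samples = samples)

  truth <- list(z = stats::setNames(z, group_ids),
                protein = stats::setNames(proteins[z], group_ids),
                factor_proteins = proteins,
                A = A, Lambda = Lambda, B = B, H = H, mu = mu, tau = tau,
                runblock = runblock, phenotype = phenotype,
                misidentified = group_ids[misid_rows],
                ptm_divergent = group_ids[ptm_rows],
                config = config)
  list(intensity = intensity, raw_intensity = raw_intensity,
       ids = ids, truth = truth)
}

#' Generate a spike-in latin-square analog dataset
#'
#' Emulates a spike-in benchmark: a constant-in-expectation background plus
#' \code{n_spike} spike proteins whose concentrations follow a latin-square
#' design over \code{n_levels} conditions measured in \code{n_replicates}
#' replicate blocks (18 analyses for the 6x6x3 default).  AUC intensity is
#' monotone in analyte concentration, so a spike row's log intensity tracks
#' the log-concentration profile with slope near 1: factor scores are the
#' centered log-concentration profiles (a 2-fold step over 6 levels spans a
#' 32-fold, ~3.5 natural-log-unit range) and loadings are sensitivity
#' jitter around 1.  Replicate measurement noise is \code{spike_cv} on the
#' log scale for spike peptides (label-free replicate CVs of ~20\%) and
#' \code{background_cv} for the background.  Intensity-dependent
#' missingness then censors mostly the lowest spike levels, which is why
#' low levels are underestimated in such designs.
#'
#' @param n_spike Number of spiked proteins (= latin-square rows).
#' @param n_levels Number of concentration levels (= conditions); must
#'   equal \code{n_spike} for a proper latin square.
#' @param n_replicates Replicate measurements per condition.
#' @param groups_per_spike Identified isotope groups per spike protein.
#' @param P_background Unidentified background isotope groups.
#' @param spike_cv Residual sd of spike rows on the natural-log scale.
#' @param background_cv Residual sd of background rows.
#' @param fold_step Fold change between consecutive concentration levels.
#' @param mu_mean,mu_sd,missing_midpoint,missing_slope,seed As in
#'   [mp_sim_config()].
#' @return A list \code{(intensity, raw_intensity, ids, truth)}; truth
#'   contains the latin square, the level concentrations and per-group true
#'   factors (background rows have factor \code{NA}).
#' @export
generate_latin_square <- function(n_spike = 6, n_levels = 6,
                                  n_replicates = 3, groups_per_spike = 10,
                                  P_background = 120, spike_cv = 0.2,
                                  background_cv = 0.5, fold_step = 2,
                                  mu_mean = 8, mu_sd = 1.5,
                                  missing_midpoint = 5, missing_slope = 1,
                                  seed = 1) {
  stopifnot(n_spike == n_levels, n_replicates >= 1, groups_per_spike >= 2)
  set.seed(as.integer(seed))
  N <- n_levels * n_replicates
  P <- n_spike * groups_per_spike + P_background
  K <- n_spike

  sample_ids <- sprintf("s%03d", seq_len(N))
  condition <- rep(seq_len(n_levels), times = n_replicates)
  replicate <- rep(seq_len(n_replicates), each = n_levels)

  # latin square: spike protein r at condition c gets level L[r, c]
  L <- outer(seq_len(n_spike), seq_len(n_levels),
             function(r, c) ((r + c - 2L) %% n_levels) + 1L)
  conc <- fold_step^(seq_len(n_levels) - 1)
  log_conc <- log(conc)

  # factor score of spike k in sample n: centered log concentration
  Lambda <- matrix(0, N, K)
  for (k in seq_len(K)) {
    prof <- log_conc[L[k, condition]]
    Lambda[, k] <- prof - mean(prof)
  }

  z <- c(rep(seq_len(K), each = groups_per_spike), rep(NA_integer_, P_background))
  group_ids <- sprintf("ig%05d", seq_len(P))
  mu <- stats::rnorm(P, mu_mean, mu_sd)
  spike_rows <- which(!is.na(z))
  tau <- rep(1 / background_cv^2, P)
  tau[spike_rows] <- 1 / spike_cv^2
  a <- numeric(P)
  a[spike_rows] <- stats::runif(length(spike_rows), 0.8, 1.2)
  A <- matrix(0, P, K)
  A[cbind(spike_rows, z[spike_rows])] <- a[spike_rows]

  X <- mu + A %*% t(Lambda) + matrix(stats::rnorm(P * N), P, N) / sqrt(tau)
  dimnames(X) <- list(group_ids, sample_ids)

  proteins <- sprintf("SPIKE%02d", seq_len(K))
  ids <- tibble::tibble(
    isotope_group_id = group_ids[spike_rows],
    peptide_sequence = random_peptides(length(spike_rows)),
    protein_accession = proteins[z[spike_rows]],
    identified = TRUE)

  p_miss <- stats::plogis(missing_slope * (missing_midpoint - X))
  missing <- matrix(stats::runif(P * N) < p_miss, P, N)
  allmiss <- rowSums(!missing) == 0
  if (any(allmiss)) missing[allmiss, 1] <- FALSE

  samples <- tibble::tibble(sample_id = sample_ids,
                            runblock = sprintf("rep%d", replicate),
                            phenotype = NA_integer_)
  intensity <- mp_intensity(X, missing = missing, raw = FALSE,
                            log_base = exp(1), samples = samples)
  raw_vals <- exp(X)
  raw_vals[missing] <- NA_real_
  raw_intensity <- mp_intensity(raw_vals, missing = missing, raw = TRUE,
                                samples = samples)

  truth <- list(z = stats::setNames(z, group_ids),
                factor_proteins = proteins,
                latin_square = L, concentrations = conc,
                condition = condition, replicate = replicate,
                A = A, Lambda = Lambda, mu = mu, tau = tau)
  list(intensity = intensity, raw_intensity = raw_intensity,
       ids = ids, truth = truth)
}

#' Randomly permute a fraction of identifications
#'
#' Replaces the protein label of exactly \code{round(fraction * n)}
#' identified records with a different protein drawn uniformly from the
#' proteins present, and returns the corruption record -- the input to
#' relabel-recovery experiments.
#'
#' @param ids Identification tibble.
#' @param fraction Fraction of identified records to corrupt (0 < f < 1).
#' @param seed Integer seed.
#' @return A list with \code{ids} (corrupted table) and \code{corrupted}
#'   (tibble of isotope_group_id, original, corrupted labels).
#' @export
permute_identifications <- function(ids, fraction = 0.1, seed = 1) {
  stopifnot(fraction > 0, fraction < 1)
  ids <- validate_identifications(ids)
  set.seed(as.integer(seed))
  idd <- which(ids$identified)
  proteins <- unique(ids$protein_accession[idd])
  if (length(proteins) < 2) {
    stop("cannot permute identifications with a single protein", call. = FALSE)
  }
  n_corrupt <- round(fraction * length(idd))
  pick <- sample(idd, n_corrupt)
  original <- ids$protein_accession[pick]
  new_label <- vapply(original, function(p) sample(setdiff(proteins, p), 1),
                      character(1), USE.NAMES = FALSE)
  ids$protein_accession[pick] <- new_label
  list(ids = ids,
       corrupted = tibble::tibble(
         isotope_group_id = ids$isotope_group_id[pick],
         original = original, corrupted = new_label))
}
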