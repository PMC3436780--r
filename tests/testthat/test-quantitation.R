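# Protein-level baselines, metaprotein expression extraction and
# dominant-metaprotein bookkeeping.

test_that("summation adds raw intensities with missing cells contributing zero", {
  vals <- rbind(g1 = c(1, 2), g2 = c(3, 4), g3 = c(10, 20))
  x <- tiny_raw(vals)
  ids <- make_ids(c("g1", "g2", "g3"), c("P1", "P1", "P2"))
  expect_equal(unname(protein_summation(x, ids, "P1")$values), c(4, 6))
  expect_equal(unname(protein_summation(x, ids, "P2")$values), c(10, 20))

  miss <- matrix(FALSE, 3, 2, dimnames = dimnames(vals))
  miss["g1", 2] <- TRUE
  xm <- mp_intensity(vals, missing = miss, raw = TRUE)
  expect_equal(unname(protein_summation(xm, ids, "P1")$values), c(4, 4))

  expect_error(protein_summation(x, ids, "P9"), "unknown")
})

test_that("top3 ranks by mean intensity with a stable tie-break", {
  vals <- rbind(g1 = c(5, 5), g2 = c(4, 4), g3 = c(3, 3), g4 = c(2, 2))
  x <- tiny_raw(vals)
  ids <- make_ids(paste0("g", 1:4), rep("P1", 4))
  t3 <- protein_top3(x, ids, "P1")
  expect_setequal(t3$contributing_groups, c("g1", "g2", "g3"))
  expect_equal(unname(t3$values), c(4, 4))
  expect_null(t3$flag)

  # exactly three groups: mean of all three
  t3b <- protein_top3(x, ids[1:3, ], "P1")
  expect_equal(unname(t3b$values), c(4, 4))

  # fewer than three: all-available mean, flagged
  t2 <- protein_top3(x, ids[1:2, ], "P1")
  expect_equal(t2$flag, "fewer_than_3_groups")
  expect_equal(unname(t2$values), c(4.5, 4.5))

  # tie at rank 3 breaks to the lower row index; brute-force re-ranking
  # oracle on permuted fixtures
  vals_tie <- rbind(a = c(6, 6), b = c(5, 5), c = c(4, 4), d = c(4, 4))
  set.seed(12)
  for (i in 1:6) {
    perm <- sample(4)
    xp <- tiny_raw(vals_tie[perm, , drop = FALSE])
    idp <- make_ids(rownames(vals_tie)[perm], rep("P1", 4))
    tp <- protein_top3(xp, idp, "P1")
    # oracle: stable ranking of the permuted fixture
    means <- rowMeans(vals_tie[perm, ])
    expected <- rownames(vals_tie)[perm][order(-means)][1:3]
    expect_identical(tp$contributing_groups, expected)
    expect_equal(unname(tp$values),
                 unname(colMeans(vals_tie[expected, ])))
  }
})

test_that("metaprotein expression returns factor score columns with members", {
  fit <- get_small_fit()
  K <- ncol(fit$Lambda_mean)
  expect_error(metaprotein_expression(fit, K + 1), "range")
  pe <- metaprotein_expression(fit, 1)
  expect_equal(unname(pe$values), unname(fit$Lambda_mean[, 1]))
  expect_true(all(fit$map_assignment[pe$contributing_groups] == 1))

  # planted-factor synthetic data: scores track the planted truth
  sim <- get_small_sim()
  for (k in 1:3) {
    prot <- sim$truth$factor_proteins[k]
    kk <- match(prot, colnames(fit$Lambda_mean))
    expect_gt(abs(cor(fit$Lambda_mean[, kk], sim$truth$Lambda[, k])), 0.95)
  }

  # an empty factor warns and flags
  ff <- fake_fit(c(a = 1L, b = 1L), c("P1", "P2"),
                 Lambda_mean = matrix(0, 4, 2,
                                      dimnames = list(paste0("s", 1:4),
                                                      c("P1", "P2"))))
  expect_warning(pe2 <- metaprotein_expression(ff, 2), "no MAP members")
  expect_equal(pe2$flag, "empty_factor")
})

test_that("dominant metaproteins require a strict majority", {
  map <- c(g1 = 7L, g2 = 7L, g3 = 7L, g4 = 1L, g5 = 2L,   # P1: 3/5 in f7
           h1 = 1L, h2 = 1L, h3 = 2L, h4 = 2L)            # P2: 2/2 split
  labels <- c(paste0("f", 1:6), "f7")
  ff <- fake_fit(map, labels)
  ids <- make_ids(names(map), c(rep("P1", 5), rep("P2", 4)))
  dom <- dominant_metaproteins(ff, ids)
  p1 <- dom[dom$protein_accession == "P1", ]
  expect_equal(p1$dominant_metaprotein, "f7")
  expect_equal(p1$fraction_in_dominant, 0.6)
  p2 <- dom[dom$protein_accession == "P2", ]
  expect_true(is.na(p2$dominant_metaprotein))
  expect_equal(p2$fraction_in_dominant, 0.5)

  memb <- dominant_membership(ff, ids)
  expect_setequal(unique(memb$protein_accession), "P1")
  expect_equal(sum(memb$in_dominant), 3)
})

test_that("expected misidentification counts follow the error-rate arithmetic", {
  expect_equal(expected_misidentifications(3398, 0.01), 34L)
  expect_equal(expected_misidentifications(100, 0), 0L)
  expect_equal(expected_misidentifications(1000, 0.05), 50L)
  expect_error(expected_misidentifications(10, 2), "error_rate")
})

test_that("dominant-metaprotein coverage moves with the identification pseudocount", {
  # with a large minority of PTM-divergent peptides, the fraction of
  # identified groups sitting inside their protein's dominant metaprotein
  # stays near one half and grows with the identification prior weight
  sim <- generate_dataset(sim_preset("small", frac_ptm_divergent = 0.4,
                                     seed = 77))
  frac_in_dominant <- function(alphak) {
    fit <- run_mcmc(sim$intensity, sim$ids, mp_hyper(alphak = alphak),
                    mp_chain(n_iterations = 400, n_burnin = 200, thin = 2,
                             seed = 5))
    dom <- dominant_metaproteins(fit, sim$ids)
    memb <- dominant_membership(fit, sim$ids)
    n_identified <- sum(sim$ids$isotope_group_id %in%
                          names(fit$map_assignment))
    sum(memb$in_dominant) / n_identified
  }
  fr <- vapply(c(1, 50, 1000), frac_in_dominant, numeric(1))
  expect_true(all(fr >= 0.4 & fr <= 0.6))
  expect_true(all(diff(fr) >= 0))
})

test_that("quantitation methods agree on coherent proteins and diverge under PTM", {
  # a protein whose groups share one pattern: summation tracks the factor
  set.seed(14)
  N <- 36
  lam <- rnorm(N)
  P <- 40
  X <- matrix(rnorm(P * N, 8, 0.3), P, N)
  X[1:8, ] <- 8 + 3 * matrix(lam, 8, N, byrow = TRUE) +
    matrix(rnorm(8 * N, 0, 0.3), 8, N)
  X[9:16, ] <- 8 - 0 + 3 * matrix(rnorm(N), 8, N, byrow = TRUE) +
    matrix(rnorm(8 * N, 0, 0.3), 8, N)
  rownames(X) <- sprintf("g%02d", 1:P)
  colnames(X) <- sprintf("s%02d", 1:N)
  ids <- make_ids(sprintf("g%02d", 1:16), rep(c("PA", "PB"), each = 8))
  x <- mp_intensity(X, raw = FALSE, log_base = exp(1))
  fit <- run_mcmc(x, ids, mp_hyper(J = 0, K_noise = 2),
                  mp_chain(n_iterations = 150, n_burnin = 75, thin = 1,
                           seed = 3))
  kk <- match("PA", colnames(fit$Lambda_mean))
  score <- fit$Lambda_mean[, kk]
  s_log <- log(protein_summation(x, ids, "PA")$values)
  expect_gt(abs(cor(score, lam)), 0.95)
  expect_gt(abs(cor(s_log, lam)), 0.95)
  expect_gt(abs(cor(s_log, score)), 0.95)

  # add a bright PTM-divergent group labeled PA but following another pattern
  div <- 9 + 3 * rnorm(N)
  X2 <- rbind(X, g99 = div)
  ids2 <- dplyr::bind_rows(ids, make_ids("g99", "PA"))
  x2 <- mp_intensity(X2, raw = FALSE, log_base = exp(1))
  fit2 <- run_mcmc(x2, ids2, mp_hyper(J = 0, K_noise = 2),
                   mp_chain(n_iterations = 150, n_burnin = 75, thin = 1,
                            seed = 3))
  kk2 <- match("PA", colnames(fit2$Lambda_mean))
  score2 <- fit2$Lambda_mean[, kk2]
  s2_log <- log(protein_summation(x2, ids2, "PA")$values)
  # the factor score shrugs off the divergent group; summation degrades
  expect_gt(abs(cor(score2, lam)), 0.95)
  expect_lt(abs(cor(s2_log, lam)), abs(cor(s_log, lam)))
})
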