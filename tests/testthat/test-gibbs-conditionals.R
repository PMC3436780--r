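# Every full conditional is checked against brute-force numerical
# integration of prior x likelihood on 1-d grids for tiny instances.

hy <- mp_hyper()  # mu0 8, phi0 100, v0 100, nu0 = delta0 = 0.001

test_that("mu full conditional matches grid integration of prior x likelihood", {
  # residuals (10, 10), tau = 1
  cond <- metaprotein:::mu_conditional(rsum = 20, n_obs = 2, tau = 1, hy)
  expect_equal(cond$mean, (8 / 100 + 20) / (1 / 100 + 2), tolerance = 1e-12)
  expect_equal(cond$var, 1 / 2.01, tolerance = 1e-12)
  oracle <- grid_moments(function(m) {
    dnorm(m, 8, 10, log = TRUE) + sum(dnorm(c(10, 10), m, 1, log = TRUE))
  }, lower = 0, upper = 20)
  expect_equal(cond$mean, oracle$mean, tolerance = 1e-6)
  expect_equal(cond$var, oracle$var, tolerance = 1e-6)

  # no observed cells: conditional reverts to the N(8, 100) prior
  cond0 <- metaprotein:::mu_conditional(rsum = 0, n_obs = 0, tau = 1, hy)
  expect_equal(cond0$mean, 8)
  expect_equal(cond0$var, 100)

  # flat-prior limit: conditional mean -> sample mean of residuals
  hy_flat <- mp_hyper(phi0 = 1e12)
  cond_f <- metaprotein:::mu_conditional(rsum = 14, n_obs = 2, tau = 1, hy_flat)
  expect_equal(cond_f$mean, 7, tolerance = 1e-9)
})

test_that("systematic loading and factor conditionals match the grid oracle", {
  # single isotope group, tau = 1, H column (1, 1), residuals (2, 2)
  Rj <- matrix(c(2, 2), 1, 2)
  M <- matrix(1, 1, 2)
  cb <- metaprotein:::b_conditional(Rj, M, h = c(1, 1), tau = 1, hy)
  expect_equal(cb$mean, 4 / 2.01, tolerance = 1e-12)
  oracle <- grid_moments(function(b) {
    dnorm(b, 0, 10, log = TRUE) + sum(dnorm(c(2, 2), b, 1, log = TRUE))
  }, lower = -8, upper = 12)
  expect_equal(cb$mean, oracle$mean, tolerance = 1e-6)
  expect_equal(cb$var, oracle$var, tolerance = 1e-6)

  # H column with no informative rows (all loadings zero): prior N(0, 1)
  ch <- metaprotein:::h_conditional(matrix(0, 1, 2), M, b = 0, tau = 1)
  expect_equal(ch$mean, c(0, 0))
  expect_equal(ch$var, c(1, 1))
})

test_that("metaprotein loading conditional matches the grid oracle", {
  # Lambda column (1, -1), residuals (3, -3), tau = 1: s1 = 6, s2 = 2
  ca <- metaprotein:::a_conditional(s1 = 6, s2 = 2, tau = 1, hy)
  expect_equal(ca$mean, 6 / 2.01, tolerance = 1e-12)
  oracle <- grid_moments(function(a) {
    dnorm(a, 0, 10, log = TRUE) +
      sum(dnorm(c(3, -3), a * c(1, -1), 1, log = TRUE))
  }, lower = -6, upper = 12)
  expect_equal(ca$mean, oracle$mean, tolerance = 1e-6)
  expect_equal(ca$var, oracle$var, tolerance = 1e-6)

  # Lambda column all zeros: posterior = prior N(0, 100)
  ca0 <- metaprotein:::a_conditional(s1 = 0, s2 = 0, tau = 1, hy)
  expect_equal(ca0$mean, 0)
  expect_equal(ca0$var, 100)

  # v0 -> 0 pins the loading at zero
  hy0 <- mp_hyper(v0 = 1e-12)
  caz <- metaprotein:::a_conditional(s1 = 6, s2 = 2, tau = 1, hy0)
  expect_lt(abs(caz$mean), 1e-10)
  expect_lt(caz$var, 1e-11)
})

test_that("factor-score conditional matches the closed form and grid oracle", {
  # one assigned row with a = 1, tau = 4, residual r: mean 4r/5, var 1/5
  r <- 0.7
  Rk <- matrix(r, 1, 1)
  cl <- metaprotein:::lambda_conditional(Rk, matrix(1, 1, 1), a = 1, tau = 4)
  expect_equal(cl$mean, 4 * r / 5, tolerance = 1e-12)
  expect_equal(cl$var, 1 / 5, tolerance = 1e-12)
  oracle <- grid_moments(function(l) {
    dnorm(l, 0, 1, log = TRUE) + dnorm(r, l, 1 / 2, log = TRUE)
  }, lower = -5, upper = 5)
  expect_equal(cl$mean, oracle$mean, tolerance = 1e-6)
  expect_equal(cl$var, oracle$var, tolerance = 1e-6)

  # factor with no assigned rows: prior N(0, I)
  cl0 <- metaprotein:::lambda_conditional(matrix(0, 1, 2), matrix(1, 1, 2),
                                          a = 0, tau = 1)
  expect_equal(cl0$mean, c(0, 0))
  expect_equal(cl0$var, c(1, 1))
})

test_that("precision conditional is the conjugate Gamma, verified by integration", {
  # prior moments at nu0 = delta0 = 0.001: mean 1, variance 1000
  expect_equal(0.001 / 0.001, 1)
  expect_equal(0.001 / 0.001^2, 1000)
  # n = 4, SSR = 4 -> Gamma(2.001, 2.001), mean ~ 1
  shape <- hy$nu0 + 4 / 2; rate <- hy$delta0 + 4 / 2
  expect_equal(shape / rate, 1, tolerance = 1e-9)
  oracle <- grid_moments(function(tau) {
    if (tau <= 0) return(-Inf)
    dgamma(tau, hy$nu0, rate = hy$delta0, log = TRUE) +
      2 * log(tau) - tau * 4 / 2   # Gaussian likelihood kernel, n = 4
  }, lower = 1e-9, upper = 15, n = 200001)
  expect_equal(oracle$mean, shape / rate, tolerance = 1e-5)
  expect_equal(oracle$var, shape / rate^2, tolerance = 1e-4)
})

test_that("membership weights combine identification prior and marginal likelihood", {
  v0 <- hy$v0
  # equal marginal likelihoods (identical Lambda columns): posterior equals
  # the normalized pseudocounts, 500/500.01 on the identified factor
  S1 <- matrix(c(3, 3), 1, 2)
  S2 <- matrix(c(2, 2), 1, 2)
  alpha <- matrix(c(500, 0.01), 1, 2)
  lw <- metaprotein:::membership_logweights(S1, S2, tau = 1, alpha, v0)
  p <- exp(lw - max(lw)); p <- p / sum(p)
  expect_equal(p[1], 500 / 500.01, tolerance = 1e-9)

  # unidentified group, equal likelihoods, K = 7: uniform 1/7
  lw7 <- metaprotein:::membership_logweights(
    matrix(1, 1, 7), matrix(2, 1, 7), tau = 1,
    matrix(0.01, 1, 7), v0)
  p7 <- exp(lw7 - max(lw7)); p7 <- p7 / sum(p7)
  expect_equal(as.vector(p7), rep(1 / 7, 7), tolerance = 1e-12)

  # the closed-form marginal matches 1-d numerical integration over a
  set.seed(4)
  lam <- rnorm(10); r <- 2.5 * lam + rnorm(10, 0, 0.5); tau <- 4
  s1 <- sum(lam * r); s2 <- sum(lam^2)
  lw1 <- metaprotein:::membership_logweights(
    matrix(s1, 1, 1), matrix(s2, 1, 1), tau, matrix(1, 1, 1), v0)
  grid <- seq(-15, 20, length.out = 200001)
  integ <- log(sum(exp(
    dnorm(grid, 0, sqrt(v0), log = TRUE) +
      vapply(grid, function(a) sum(dnorm(r, a * lam, 1 / sqrt(tau),
                                         log = TRUE)), numeric(1))
  )) * (grid[2] - grid[1]))
  # compare after adding back the row-constant terms dropped in the weights
  const <- 0.5 * length(r) * (log(tau) - log(2 * pi)) - 0.5 * tau * sum(r^2)
  expect_equal(as.vector(lw1), integ - const, tolerance = 1e-6)
})

test_that("strong co-expression overturns the 500:1 identification prior", {
  # a factor whose scores correlate ~0.99 with the residual row at SNR 10
  # wins even when the identification points at another factor
  set.seed(7)
  N <- 30
  lam2 <- rnorm(N)
  lam1 <- rnorm(N)  # unrelated factor carrying the (wrong) identification
  r <- 10 * lam2 + rnorm(N, 0, 1)
  expect_gt(abs(cor(r, lam2)), 0.98)
  S1 <- matrix(c(sum(lam1 * r), sum(lam2 * r)), 1, 2)
  S2 <- matrix(c(sum(lam1^2), sum(lam2^2)), 1, 2)
  alpha <- matrix(c(500, 0.01), 1, 2)   # identified on factor 1
  lw <- metaprotein:::membership_logweights(S1, S2, tau = 1, alpha, hy$v0)
  p <- exp(lw - max(lw)); p <- p / sum(p)
  expect_gt(p[2], 0.99)
})

test_that("spike-and-slab inclusion follows the two-component posterior", {
  set.seed(21)
  hyx <- mp_hyper(mixture = TRUE, mixture_nu0 = 1, mixture_gamma0 = 1,
                  J = 0, K_noise = 0)
  N <- 12
  lam <- rnorm(N)
  X <- rbind(5 * lam, rnorm(N, 0, 1)) + 0.0
  rownames(X) <- c("g1", "g2")
  ids <- make_ids(c("g1", "g2"), c("P1", "P1"))
  tm <- tiny_model(X, ids, hyper = hyx)
  st <- tm$state
  st$mu <- rep(0, 2); st$tau <- c(1, 1)
  st$A <- matrix(0, 2, st$K)
  st$Lambda[, 1] <- lam

  # uninformative data (zero factor column): inclusion stays at prior odds
  st0 <- st; st0$Lambda[, 1] <- 0
  incl <- logical(400)
  for (i in 1:400) {
    st0$qk_mix <- rep(0.5, st0$K)
    out <- update_mixture_loadings(st0, tm$data, hyx)
    incl[i] <- out$A[2, 1] != 0
  }
  expect_gt(mean(incl), 0.5 - 0.09)
  expect_lt(mean(incl), 0.5 + 0.09)

  # strong signal row: inclusion probability > 0.99
  hits <- logical(60)
  for (i in 1:60) {
    st$qk_mix <- rep(0.5, st$K)
    out <- update_mixture_loadings(st, tm$data, hyx)
    hits[i] <- out$A[1, 1] != 0
  }
  expect_true(all(hits))

  # membership updates are refused in mixture mode
  expect_error(update_membership(st, tm$data, hyx), "mixture")
})

test_that("log joint matches an independent term-by-term evaluation", {
  set.seed(5)
  hy2 <- mp_hyper(J = 1, K_noise = 0)
  X <- matrix(rnorm(4, 8, 1), 2, 2, dimnames = list(c("g1", "g2"), NULL))
  ids <- make_ids(c("g1", "g2"), c("P1", "P1"))
  tm <- tiny_model(X, ids, hyper = hy2)
  st <- tm$state
  st$mu <- c(7.5, 8.5); st$tau <- c(1.2, 0.8)
  st$B <- matrix(c(0.3, -0.2), 2, 1)
  st$H <- matrix(c(0.5, -1), 2, 1)
  st$Lambda <- matrix(c(1, -0.4), 2, 1)
  st$A <- matrix(c(2, 0.5), 2, 1)
  st$z <- c(1L, 1L)
  st$q <- matrix(1, 2, 1)

  lj <- log_joint(st, tm$data, hy2)

  # independent evaluation written straight from the model density
  fit <- st$mu %*% t(rep(1, 2)) + st$B %*% t(st$H) + st$A %*% t(st$Lambda)
  ll <- 0
  for (i in 1:2) for (n in 1:2) {
    ll <- ll + dnorm(X[i, n], fit[i, n], 1 / sqrt(st$tau[i]), log = TRUE)
  }
  pri <- sum(dnorm(st$mu, 8, 10, log = TRUE)) +
    sum(dnorm(st$B, 0, 10, log = TRUE)) +
    sum(dnorm(st$H, 0, 1, log = TRUE)) +
    sum(dnorm(st$Lambda, 0, 1, log = TRUE)) +
    sum(dnorm(c(2, 0.5), 0, 10, log = TRUE)) +
    sum(dgamma(st$tau, 0.001, rate = 0.001, log = TRUE))
  # z | q is certain (q = 1) and the Dir(alpha) density of q at the vertex
  alpha <- tm$data$alpha
  dir_term <- sum((alpha - 1) * log(1)) + 2 * (lgamma(sum(alpha[1, ])) -
                                                 sum(lgamma(alpha[1, ])))
  expect_equal(lj, unname(ll + pri + dir_term), tolerance = 1e-10)

  st_bad <- st; st_bad$mu[1] <- Inf
  expect_error(log_joint(st_bad, tm$data, hy2), "non-finite")
})
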