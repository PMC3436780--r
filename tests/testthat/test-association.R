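# ANOVA and Kruskal-Wallis association tests and PTM-motif enrichment.

test_that("ANOVA association handles degenerate and textbook cases", {
  pheno <- rep(c(0, 1), each = 6)
  # identical values in both classes: F = 0, p = 1
  col0 <- rep(c(1, 2, 3, 4, 5, 6), 2)
  res <- anova_association(matrix(col0, ncol = 1), pheno)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)

  # two-group ANOVA F equals the squared pooled-variance t statistic
  set.seed(2)
  y <- rnorm(12) + pheno
  res2 <- anova_association(matrix(y, ncol = 1), pheno)
  tt <- t.test(y[pheno == 1], y[pheno == 0], var.equal = TRUE)
  expect_equal(res2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p_value, tt$p.value, tolerance = 1e-10)

  expect_error(anova_association(matrix(y, ncol = 1), rep(1, 12)),
               "single class")

  # Bonferroni adjustment across tested factors
  set.seed(3)
  L <- cbind(rnorm(12), rnorm(12), y)
  res3 <- anova_association(L, pheno)
  expect_equal(res3$p_adjusted, pmin(1, res3$p_value * 3))
  expect_true(all(res3$p_adjusted >= res3$p_value))
})

test_that("a planted 2-sd class shift is detected after Bonferroni almost always", {
  set.seed(7)
  hits <- vapply(1:50, function(r) {
    pheno <- rep(c(0, 1), each = 40)
    L <- matrix(rnorm(80 * 20), 80, 20)
    L[, 1] <- L[, 1] + ifelse(pheno == 1, 1, -1)  # 2 sd separation
    res <- anova_association(L, pheno)
    res$significant[1]
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("ANOVA type-I error is calibrated at the nominal level", {
  set.seed(11)
  p <- vapply(1:2000, function(r) {
    pheno <- rep(c(0, 1), each = 40)
    anova_association(matrix(rnorm(80), ncol = 1), pheno)$p_value
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("Kruskal-Wallis membership/intensity test behaves on edge cases", {
  # identical intensity multisets across membership groups: H = 0, p = 1
  map <- c(a1 = 1L, a2 = 1L, a3 = 2L, a4 = 2L,
           b1 = 1L, b2 = 1L, b3 = 1L)
  ff <- fake_fit(map, c("f1", "f2"))
  ids <- make_ids(names(map), c(rep("PA", 4), rep("PB", 3)))
  vals <- rbind(a1 = rep(4, 3), a2 = rep(6, 3), a3 = rep(4, 3),
                a4 = rep(6, 3), b1 = rep(1, 3), b2 = rep(2, 3),
                b3 = rep(3, 3))
  x <- mp_intensity(vals, raw = FALSE)
  kw <- kruskal_membership_intensity(ff, ids, x)
  pa <- kw[kw$protein_accession == "PA", ]
  expect_equal(pa$statistic, 0, tolerance = 1e-12)
  expect_equal(pa$p_value, 1, tolerance = 1e-12)
  # single-factor protein is not applicable
  pb <- kw[kw$protein_accession == "PB", ]
  expect_false(pb$applicable)
  expect_true(is.na(pb$p_value))

  # H on a 3-vs-3 example matches the rank-formula oracle
  map2 <- stats::setNames(rep(c(1L, 2L), each = 3), paste0("c", 1:6))
  ff2 <- fake_fit(map2, c("f1", "f2"))
  ids2 <- make_ids(names(map2), rep("PC", 6))
  iv <- c(1.1, 3.2, 2.5, 4.7, 5.9, 5.1)
  x2 <- mp_intensity(matrix(rep(iv, 3), 6, 3,
                            dimnames = list(names(map2), NULL)),
                     raw = FALSE)
  kw2 <- kruskal_membership_intensity(ff2, ids2, x2)
  r <- rank(iv); n <- 6
  H <- 12 / (n * (n + 1)) * (sum(r[1:3])^2 / 3 + sum(r[4:6])^2 / 3) -
    3 * (n + 1)
  expect_equal(kw2$statistic, H, tolerance = 1e-10)
})

test_that("membership independent of intensity yields nominal false positives", {
  set.seed(13)
  n_prot <- 109; per <- 10
  map <- sample(1:8, n_prot * per, replace = TRUE)
  names(map) <- sprintf("g%04d", seq_along(map))
  ff <- fake_fit(map, paste0("f", 1:8))
  ids <- make_ids(names(map), rep(sprintf("P%03d", 1:n_prot), each = per))
  vals <- matrix(rnorm(length(map) * 4, 8, 1), length(map), 4,
                 dimnames = list(names(map), NULL))
  x <- mp_intensity(vals, raw = FALSE)
  kw <- kruskal_membership_intensity(ff, ids, x)
  sig <- sum(kw$p_value < 0.01, na.rm = TRUE)
  expect_lte(sig, 5)  # ~1% of 109 expected under the null
})

test_that("motif enrichment builds the 2x2 table and matches Fisher exactly", {
  # balanced table: odds ratio 1, p = 1
  peps <- c(replicate(20, "QAAAK"), replicate(20, "AAAAK"))
  map <- c(rep(c(1L, 2L), each = 10), rep(c(1L, 2L), each = 10))
  names(map) <- sprintf("g%02d", 1:40)
  ff <- fake_fit(map, c("fdom", "fother"))
  ids <- make_ids(names(map), rep("PA", 40), peptide = peps)
  # PA's dominant metaprotein is fdom (20/40 is not strict majority), so
  # tilt it: 21 in fdom
  map[40] <- 1L
  ff <- fake_fit(map, c("fdom", "fother"))
  me <- motif_enrichment(ff, ids, "Q")
  expect_equal(sum(me$table), 40)
  expect_gt(me$p_value, 0.5)

  # worked table [[20, 5], [5, 20]]: odds ratio 16, verified against
  # exhaustive hypergeometric enumeration
  peps2 <- c(rep("QAAAK", 25), rep("AAAAK", 25))
  out2 <- c(rep(c(2L, 1L), c(20, 5)), rep(c(2L, 1L), c(5, 20)))
  names(out2) <- sprintf("h%02d", 1:50)
  # make factor 1 dominant: add extra motif-free members in factor 1
  extra <- stats::setNames(rep(1L, 30), sprintf("x%02d", 1:30))
  map2 <- c(out2, extra)
  ff2 <- fake_fit(map2, c("fdom", "fother"))
  ids2 <- make_ids(names(map2), rep("PB", 80),
                   peptide = c(peps2, rep("AAAAK", 30)))
  me2 <- motif_enrichment(ff2, ids2, "Q")
  expect_equal(me2$table["yes", "outside"], 20)
  expect_equal(me2$table["yes", "inside"], 5)
  tab <- me2$table
  expect_equal(me2$odds_ratio,
               (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]))
  # hypergeometric enumeration oracle for the two-sided Fisher p
  m_out <- sum(tab[, 1]); m_in <- sum(tab[, 2]); k_mot <- sum(tab[1, ])
  probs <- dhyper(0:k_mot, m_out, m_in, k_mot)
  p_oracle <- sum(probs[probs <= probs[tab[1, 1] + 1] * (1 + 1e-7)])
  expect_equal(me2$p_value, p_oracle, tolerance = 1e-9)

  # sequon patterns and alphabet validation
  expect_silent(motif_enrichment(ff2, ids2, "NxS"))
  expect_error(motif_enrichment(ff2, ids2, "ZxQ"), "unsupported")
})

test_that("fisher p matches hypergeometric enumeration across small tables", {
  set.seed(17)
  for (rep in 1:30) {
    a <- sample(0:8, 1); b <- sample(0:8, 1)
    c_ <- sample(0:8, 1); d <- sample(0:8, 1)
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
    tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE)
    p_pkg <- fisher.test(tab)$p.value
    k <- a + b
    probs <- dhyper(0:k, a + c_, b + d, k)
    obs <- dhyper(a, a + c_, b + d, k)
    p_oracle <- sum(probs[probs <= obs * (1 + 1e-7)])
    expect_equal(p_pkg, min(p_oracle, 1), tolerance = 1e-7)
  }
})

test_that("a planted 2x outside-rate motif recovers its odds ratio at n = 3000", {
  set.seed(19)
  n <- 3000
  has_motif <- runif(n) < 0.3
  base_odds <- 0.5           # odds of sitting outside the dominant factor
  odds <- ifelse(has_motif, 2 * base_odds, base_odds)
  outside <- runif(n) < odds / (1 + odds)
  map <- ifelse(outside, 2L, 1L)
  names(map) <- sprintf("g%04d", 1:n)
  ff <- fake_fit(map, c("fdom", "fother"))
  ids <- make_ids(names(map), rep("PZ", n),
                  peptide = ifelse(has_motif, "AQAAK", "AAAAK"))
  me <- motif_enrichment(ff, ids, "Q")
  expect_gt(me$odds_ratio, 2 * 0.8)
  expect_lt(me$odds_ratio, 2 * 1.2)
  expect_lt(me$p_value, 1e-10)
})
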