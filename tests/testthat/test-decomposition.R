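test_that("single-locus inbred effects follow the printed identities", {
  # F = 0 reduces to the textbook noninbred decomposition
  e <- single_locus_inbred_effects(0.3, 1.2, 0.5, F = 0)
  expect_equal(e$alpha, 1.2 + 0.4 * 0.5)
  expect_equal(e$alpha_A, e$q * e$alpha)
  expect_equal(e$M_F, e$M)
  expect_equal(unname(e$An), unname(e$A0))
  # p = q = 0.5, F = 1: A shifts by d, D by d/2
  e2 <- single_locus_inbred_effects(0.5, 1, 0.8, F = 1)
  expect_equal(unname(e2$An - e2$A0), rep(4 * 0.25 * 0.8, 3))
  expect_equal(unname(e2$Dn - e2$D0), rep(2 * 0.25 * 0.8, 3))
  set.seed(41)
  for (k in 1:50) {
    p <- runif(1, 0.05, 0.95); a <- runif(1, 0.2, 2)
    d <- runif(1, -1, 1); F <- runif(1)
    e <- single_locus_inbred_effects(p, a, d, F, m = runif(1, -1, 1))
    G <- e$m + c(aa = -a, Aa = d, AA = a)
    # E(G) = M_F over the inbred genotype distribution
    expect_equal(unname(sum(e$freqs * G)), e$M_F, tolerance = 1e-12)
    expect_equal(e$M_F, e$M - 2 * F * e$p * e$q * d, tolerance = 1e-12)
    # E(A^(0)) = 0 and E(D^(0)) = -2Fpqd under the inbred distribution
    expect_equal(unname(sum(e$freqs * e$A0)), 0, tolerance = 1e-12)
    expect_equal(unname(sum(e$freqs * e$D0)), -2 * F * p * (1 - p) * d,
                 tolerance = 1e-12)
    # genotypic value reconstruction G = M_F + A0 + Dn
    expect_equal(unname(e$M_F + e$A0 + e$Dn), unname(G), tolerance = 1e-12)
  }
})

test_that("Cockerham's D1 and D2 vanish when p equals q", {
  d <- cockerham_components(c(0.5, 0.5), c(1, 2), c(0.5, 0.7))
  expect_equal(d$D1, 0)
  expect_equal(d$D2, 0)
  d2 <- cockerham_components(0.7, 1, 0.5)
  expect_equal(d2$D1, 2 * 0.21 * 0.4 * (1 + (0.3 - 0.7) * 0.5) * 0.5)
  expect_equal(d2$D2, 4 * 0.21 * 0.16 * 0.25)
})

test_that("the constrained Kempthorne fit is exact and saturates the grid", {
  set.seed(42)
  for (k in 1:20) {
    hap <- random_hap_freqs()
    dist <- selfing_two_locus_recursion(
      two_locus_dist(hap, runif(1, 0, 0.5)), n = sample(0:5, 1))
    pe <- random_pair_effects(hap)
    # nonepistatic grid: all 16 interaction effects vanish
    N <- ldepivar:::nonepistatic_grid(pe$m_a, pe$a_a, pe$d_a,
                                      pe$m_b, pe$a_b, pe$d_b)
    es <- kempthorne_effects(dist, N)
    expect_lt(max(abs(es$cells[, c("AA", "AD", "DA", "DD")])), 1e-9)
    expect_equal(rowSums(es$cells[, 1:6]) + es$M, es$cells[, "G"],
                 tolerance = 1e-10, ignore_attr = TRUE)
    # epistatic grid: still an exact fit
    g <- build_epistatic_grid(pe, sample(epistasis_types(), 1), 1,
                              two_locus_dist(hap, dist$r))
    es2 <- kempthorne_effects(dist, g)
    expect_equal(rowSums(es2$cells[, 1:6]) + es2$M, unname(g$G),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  fixed <- two_locus_dist(c(0.6, 0.4, 0, 0), 0.2)
  expect_error(kempthorne_effects(fixed, 1:9), "fixed")
})

test_that("component expectations satisfy the inbreeding and LD identities", {
  set.seed(43)
  for (k in 1:100) {
    hap <- random_hap_freqs()
    r <- runif(1, 0, 0.5)
    n <- sample(0:8, 1)
    dist <- selfing_two_locus_recursion(two_locus_dist(hap, r), r, n)
    pe <- random_pair_effects(hap)
    g <- build_epistatic_grid(pe, sample(epistasis_types(), 1),
                              runif(1, 0.2, 2), two_locus_dist(hap, r))
    es <- kempthorne_effects(dist, g)
    mom <- parametric_components(es, dist)
    F <- 1 - 0.5^n
    # (a) E(A) = 0 regardless of inbreeding
    expect_lt(abs(mom$means["A"]), 1e-9)
    # (b) E(D) matches the delta-contrast formula
    dA <- es$beta[6:8]; dB <- es$beta[9:11]
    ED <- es$p_a * (1 - es$p_a) * F * (dA[1] - 2 * dA[2] + dA[3]) +
      es$p_b * (1 - es$p_b) * F * (dB[1] - 2 * dB[2] + dB[3])
    expect_equal(unname(mom$means["D"]), unname(ED), tolerance = 1e-9)
    # reconstruction: E(G) = M + sum of component means
    expect_equal(unname(sum(mom$means[1:6]) + es$M),
                 unname(mom$means["G"]), tolerance = 1e-9)
    if (n == 0) {
      # (d), (e): E(AD) = E(DA) = 0 when F = 0
      expect_lt(abs(mom$means["AD"]), 1e-9)
      expect_lt(abs(mom$means["DA"]), 1e-9)
      # (c), (f): E(AA), E(DD) follow the printed Delta contrasts
      D <- ld_metrics(hap)$Delta
      aa <- es$beta[12:15]
      expect_equal(unname(mom$means["AA"]),
                   2 * D * (aa[1] - aa[2] - aa[3] + aa[4]),
                   tolerance = 1e-9, ignore_attr = TRUE)
      dd <- es$beta[28:36]
      expect_equal(unname(mom$means["DD"]),
                   D^2 * sum(dd * c(1, -2, 1, -2, 4, -2, 1, -2, 1)),
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
  # E(AA) = 0 and E(DD) = 0 in linkage equilibrium at F = 0
  hap_le <- c(0.35 * 0.6, 0.35 * 0.4, 0.65 * 0.6, 0.65 * 0.4)
  dist_le <- two_locus_dist(hap_le, 0.3)
  pe <- list(m_a = 0, a_a = 1, d_a = 0.4, m_b = 0, a_b = 1.5, d_b = 0.9,
             p_a = 0.35, p_b = 0.6)
  g <- build_epistatic_grid(pe, "recessive", 1, dist_le)
  mom <- parametric_components(kempthorne_effects(dist_le, g), dist_le)
  expect_lt(max(abs(mom$means[c("AA", "AD", "DA", "DD")])), 1e-9)
})

test_that("closed-form variances match the enumeration oracle to 1e-8", {
  set.seed(44)
  for (k in 1:200) {
    hap <- random_hap_freqs()
    r <- runif(1, 0, 0.5)
    n <- sample(0:10, 1)
    m <- ld_metrics(hap)
    ea <- single_locus_inbred_effects(m$p_a, runif(1, 0.3, 2), runif(1, -1, 1))
    eb <- single_locus_inbred_effects(m$p_b, runif(1, 0.3, 2), runif(1, -1, 1))
    cf <- closed_form_two_locus_variances(ea, eb, m$Delta, r, n)
    dist <- selfing_two_locus_recursion(two_locus_dist(hap, r), r, n)
    N <- ldepivar:::nonepistatic_grid(0, ea$a, ea$d, 0, eb$a, eb$d)
    mom <- parametric_components(kempthorne_effects(dist, N), dist)
    scale <- max(abs(cf$sigma2_A), abs(cf$sigma2_D), abs(cf$cov_A_D), 1e-6)
    expect_equal(cf$sigma2_A, unname(mom$cov["A", "A"]),
                 tolerance = 1e-8 * scale / max(abs(cf$sigma2_A), 1e-12))
    expect_lt(abs(cf$sigma2_D - mom$cov["D", "D"]) / scale, 1e-8)
    expect_lt(abs(cf$cov_A_D - mom$cov["A", "D"]) / scale, 1e-8)
  }
})

test_that("the additive-dominance covariance vanishes when p equals q", {
  set.seed(45)
  for (k in 1:20) {
    delta <- runif(1, -0.2, 0.2)
    hap <- c(0.25 + delta, 0.25 - delta, 0.25 - delta, 0.25 + delta)
    r <- runif(1, 0, 0.5)
    ea <- single_locus_inbred_effects(0.5, runif(1, 0.3, 2), runif(1, -1, 1))
    eb <- single_locus_inbred_effects(0.5, runif(1, 0.3, 2), runif(1, -1, 1))
    cf <- closed_form_two_locus_variances(ea, eb, delta, r, sample(0:10, 1))
    expect_lt(abs(cf$cov_A_D), 1e-12)
  }
})

test_that("random-mating closed forms track the decayed LD", {
  set.seed(46)
  for (k in 1:20) {
    hap <- random_hap_freqs()
    r <- runif(1, 0, 0.5)
    n <- sample(0:10, 1)
    m <- ld_metrics(hap)
    ea <- single_locus_inbred_effects(m$p_a, runif(1, 0.3, 2), runif(1, 0, 1))
    eb <- single_locus_inbred_effects(m$p_b, runif(1, 0.3, 2), runif(1, 0, 1))
    cf <- random_mating_two_locus_variances(ea, eb, m$Delta, r, n)
    dn <- delta_random_mating(m$Delta, r, n)
    hapn <- c(m$p_a * m$p_b + dn, m$p_a * (1 - m$p_b) - dn,
              (1 - m$p_a) * m$p_b - dn, (1 - m$p_a) * (1 - m$p_b) + dn)
    distn <- two_locus_dist(hapn, r)
    N <- ldepivar:::nonepistatic_grid(0, ea$a, ea$d, 0, eb$a, eb$d)
    mom <- parametric_components(kempthorne_effects(distn, N), distn)
    expect_equal(cf$sigma2_A, unname(mom$cov["A", "A"]), tolerance = 1e-8)
    expect_equal(cf$sigma2_D, unname(mom$cov["D", "D"]), tolerance = 1e-8)
  }
})

test_that("printed F=0 LD covariances with AA match the fit", {
  set.seed(47)
  for (k in 1:30) {
    hap <- random_hap_freqs()
    d0 <- two_locus_dist(hap, runif(1, 0, 0.5))
    pe <- random_pair_effects(hap)
    g <- build_epistatic_grid(pe, sample(epistasis_types(), 1), 1, d0)
    es <- kempthorne_effects(d0, g)
    mom <- parametric_components(es, d0)
    D <- ld_metrics(hap)$Delta
    qa <- 1 - es$p_a; qb <- 1 - es$p_b
    aa <- es$beta[12:15]
    alA <- es$beta[2] / qa; alB <- es$beta[4] / qb  # fitted substitution effects
    da <- -es$beta[6] / (2 * qa^2); db <- -es$beta[9] / (2 * qb^2)
    K <- aa[1] - aa[2] - aa[3] + aa[4]
    s_A_AA <- 2 * D * (alA * (aa[1] - aa[2] + aa[3] - aa[4]) +
                       alB * (aa[1] - aa[3] + aa[2] - aa[4]))
    s_D_AA <- -4 * D * (es$p_a * qa * da + es$p_b * qb * db) * K
    expect_equal(unname(mom$cov["A", "AA"]), unname(s_A_AA),
                 tolerance = 1e-8)
    expect_equal(unname(mom$cov["D", "AA"]), unname(s_D_AA),
                 tolerance = 1e-8)
    # sigma2_AA printed form is the enumeration variance of the AA values
    f <- cell_probabilities(d0)
    expect_equal(unname(mom$cov["AA", "AA"]),
                 unname(sum(f * es$cells[, "AA"]^2) -
                          sum(f * es$cells[, "AA"])^2),
                 tolerance = 1e-10)
  }
})

test_that("sample variance components obey the exact sum identity", {
  set.seed(48)
  vals <- data.frame(A = rnorm(500), D = rnorm(500), AA = rnorm(500),
                     AD = rnorm(500), DA = rnorm(500), DD = rnorm(500))
  vals$G <- 3 + rowSums(vals)
  vc <- variance_components_from_sample(vals)
  tot <- sum(vc[paste0("sigma2_", c("A", "D", "AA", "AD", "DA", "DD"))]) +
    2 * sum(vc[grep("^cov_", names(vc))])
  expect_equal(vc$sigma2_G, tot, tolerance = 1e-10)
  # identical individuals give all-zero components
  one <- vals[rep(1, 10), ]
  expect_true(all(abs(as.numeric(variance_components_from_sample(one)[
    1:21])) < 1e-12))
})
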