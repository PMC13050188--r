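test_that("random-mating mean depends only on direct and parental effects", {
  expect_equal(mean_rm(locus_params(0.5, 1, 1, 1, beta_i = 7)), 3.0)
  expect_equal(mean_rm(locus_params(0.3, beta_i = 2, beta_s = 5)), 0)
  # enumeration cross-check for a mixed-sign case
  l <- locus_params(0.3, 1, 0.5, -0.5)
  expect_equal(mean_rm(l), 0.6)
  expect_equal(mean_rm(l), unname(enumerate_moments(trio_table(l))["mean"]))
})

test_that("random-mating variance matches its closed form and enumeration", {
  expect_equal(var_rm(locus_params(0.5, beta_c = 1)), 0.5)
  expect_equal(var_rm(locus_params(0.5, beta_i = 1)), 0.5)
  l <- locus_params(0.3, 1, 0.5, -0.5, 0.2)
  expect_equal(var_rm(l), 0.7308)
  expect_equal(var_rm(l),
               unname(enumerate_moments(trio_table(l))["variance"]))
  # textbook special case: only direct effects
  l2 <- locus_params(0.17, beta_c = 0.8)
  expect_equal(var_rm(l2), 2 * 0.83 * 0.17 * 0.8^2)
})

test_that("sibling-difference variance cancels parental effects", {
  expect_equal(var_sibdiff_rm(locus_params(0.5, beta_c = 1, beta_s = 1)), 0)
  expect_equal(var_sibdiff_rm(locus_params(0.5, beta_c = 1, beta_s = 0.5)),
               0.125)
  expect_equal(var_sibdiff_rm(locus_params(0.5, beta_m = 5, beta_f = -3)), 0)
  l <- locus_params(0.5, beta_c = 1, beta_s = 0.5)
  expect_equal(var_sibdiff_rm(l),
               unname(enumerate_moments(sibling_table(l),
                                        design = "sibdiff")["variance"]))
})

test_that("assortative-mating variance reduces to RM at rho 0 and matches enumeration", {
  set.seed(1)
  for (i in 1:200) {
    l <- random_locus()
    expect_identical(var_am(l, 0), var_rm(l))
  }
  expect_equal(var_am(locus_params(0.5, beta_c = 1), rho = 1), 1.0)
  l <- locus_params(0.3, 1, 0.5, -0.5, 0.2)
  tab <- trio_table(l)
  v_enum <- unname(enumerate_moments(tab, am_frequency(tab, 0.2))["variance"])
  expect_equal(var_am(l, 0.2), v_enum, tolerance = 1e-12)
  expect_error(var_am(l, -0.1), "rho")
  expect_error(var_am(l, 1.2), "rho")
})

test_that("sibling-difference AM variance is (1-rho) times the RM one", {
  l <- locus_params(0.5, beta_c = 1, beta_s = 0.5)
  expect_identical(var_sibdiff_am(l, 0), var_sibdiff_rm(l))
  expect_equal(var_sibdiff_am(random_locus(), 1), 0)
  expect_equal(var_sibdiff_am(l, 0.2), 0.1)
  set.seed(2)
  for (i in 1:100) {
    l <- random_locus()
    rho <- runif(1)
    v0 <- var_sibdiff_rm(l)
    if (v0 > 0) expect_equal(var_sibdiff_am(l, rho) / v0, 1 - rho)
  }
})

test_that("all variance forms are invariant under allele relabeling", {
  set.seed(3)
  for (i in 1:200) {
    l <- random_locus()
    l2 <- relabel_locus(l)
    rho <- runif(1)
    expect_equal(var_rm(l), var_rm(l2))
    expect_equal(var_am(l, rho), var_am(l2, rho))
    expect_equal(var_sibdiff_rm(l), var_sibdiff_rm(l2))
    expect_equal(var_sibdiff_am(l, rho), var_sibdiff_am(l2, rho))
  }
})

test_that("multilocus total combines per-locus variances through k_ij", {
  l2 <- locus_params(c(0.4, 0.4), beta_c = 1, beta_m = 0.3)
  v <- var_rm(l2)[1]
  expect_equal(var_total(l2, matrix(0, 2, 2)), 2 * v)
  expect_equal(var_total(l2, matrix(c(0, 1, 1, 0), 2)), 4 * v)
  expect_equal(var_total(l2), 2 * v)  # NULL k = independent loci
  # Monte-Carlo oracle: per-locus genotypic values as correlated Gaussians
  set.seed(4)
  l3 <- locus_params(runif(3, 0.2, 0.8), beta_c = runif(3, -1, 1),
                     beta_m = runif(3, -1, 1), beta_i = runif(3, -1, 1))
  k <- matrix(0, 3, 3)
  k[upper.tri(k)] <- c(0.3, -0.2, 0.1)
  k <- k + t(k)
  v3 <- var_rm(l3)
  cv <- diag(sqrt(v3)) %*% (k + diag(3)) %*% diag(sqrt(v3))
  z <- matrix(rnorm(3 * 2e5), ncol = 3) %*% chol(cv)
  mc <- var(rowSums(z))
  expect_equal(var_total(l3, k), mc, tolerance = 0.02)
  # asymmetric or out-of-range k matrices are rejected
  expect_error(var_total(l2, matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(var_total(l2, matrix(c(0, 2, 2, 0), 2)), "k_ij")
})

test_that("single-allele variances follow the two-point distribution", {
  av <- allele_variances(locus_params(0.5, beta_c = 1, beta_m = 1))
  expect_equal(unname(av[1, ]), c(1.0, 0.25))
  expect_equal(allele_variances(
    locus_params(0.4, beta_c = 1, beta_m = -1))[1, "maternal"],
    c(maternal = 0))
  # direct enumeration of the Bernoulli two-point distribution
  q2 <- 0.3; e <- 1 + 0.5
  mu <- (1 - q2) * e
  v_enum <- (1 - q2) * (e - mu)^2 + q2 * mu^2
  expect_equal(allele_variances(
    locus_params(0.3, beta_c = 1, beta_m = 0.5))[1, "maternal"],
    c(maternal = v_enum))
  expect_equal(v_enum, 0.4725)
})

test_that("allele-level multilocus covariance terms follow the f/k/s decomposition", {
  l <- locus_params(0.5, beta_c = 1)
  a0 <- assortment_params()
  r0 <- am_multilocus_covariance(l, a0, n_loci = 4)
  expect_equal(r0$cov_total, 0)
  lq <- locus_params(0.3, beta_c = 1, beta_m = 0.5, beta_f = -0.2)
  q12 <- 0.3 * 0.7
  expect_equal(am_multilocus_covariance(lq, a0, 5)$v_base,
               2 * 5 * q12 * (1 + 0.5^2 / 2 + 0.2^2 / 2 +
                                0.5 - 0.2))
  r1 <- am_multilocus_covariance(l, assortment_params(f = .2, k = .1, s = .05),
                                 n_loci = 1)
  expect_equal(r1$k_term, 0)
  expect_equal(r1$s_term, 0)
  r2 <- am_multilocus_covariance(l, assortment_params(f = .2, k = .1, s = .05),
                                 n_loci = 2)
  expect_equal(r2$f_term, 0.1)
  expect_equal(r2$k_term, 0.05)
  expect_equal(r2$s_term, 0.025)
  expect_equal(r2$v_x, r2$v_base + 2 * (0.1 + 0.05 + 0.025))
  expect_error(am_multilocus_covariance(l, a0, 0), "n_loci")
})

test_that("allele-level variance matches a correlated-Bernoulli simulation", {
  # q2 = 0.5 lets the Gaussian-copula threshold model hit exact Bernoulli
  # correlations via the arcsine law: r_gauss = sin(pi * r_bern / 2)
  l <- locus_params(0.5, beta_c = 1, beta_m = 0.4, beta_f = -0.3)
  ap <- assortment_params(f = 0.2, k = 0.1, s = 0.05)
  n_loci <- 3
  th <- am_multilocus_covariance(l, ap, n_loci)
  # build the 2l x 2l Bernoulli correlation target (maternal block first)
  rb <- diag(2 * n_loci)
  for (i in 1:n_loci) for (j in 1:n_loci) {
    if (i != j) {
      rb[i, j] <- ap$k; rb[n_loci + i, n_loci + j] <- ap$k
      rb[i, n_loci + j] <- ap$s; rb[n_loci + i, j] <- ap$s
    } else {
      rb[i, n_loci + j] <- ap$f; rb[n_loci + i, j] <- ap$f
    }
  }
  rg <- sin(pi * rb / 2); diag(rg) <- 1
  set.seed(5)
  zz <- matrix(rnorm(2 * n_loci * 4e5), ncol = 2 * n_loci) %*% chol(rg)
  alleles <- (zz > 0) * 1
  w <- c(rep(l$beta_c + l$beta_m, n_loci), rep(l$beta_c + l$beta_f, n_loci))
  mc <- var(alleles %*% w)[1, 1]
  expect_equal(th$v_x, mc, tolerance = 0.02)
})

test_that("the labeled variance table sums to the matching closed form", {
  l <- locus_params(0.3, 1, 0.5, -0.5, 0.2, 0.3)
  for (rg in c("rm", "am", "sibdiff-rm", "sibdiff-am")) {
    tab <- run_variance_table(l, regime = rg, rho = 0.25)
    target <- switch(rg, rm = var_rm(l), am = var_am(l, 0.25),
                     `sibdiff-rm` = var_sibdiff_rm(l),
                     `sibdiff-am` = var_sibdiff_am(l, 0.25))
    expect_equal(sum(tab$value), target)
  }
})
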