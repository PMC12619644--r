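test_that("trace statistic matches the brute-force double loop", {
  set.seed(31)
  n <- 5
  KZ <- crossprod(matrix(rnorm(25), n, n))
  KX <- crossprod(matrix(rnorm(25), n, n))
  T1 <- hsic_statistic(KZ, KX)
  acc <- 0
  for (j in 1:n) for (jp in 1:n) acc <- acc + KZ[j, jp] * KX[jp, j]
  expect_equal(T1, acc / n, tolerance = 1e-12)

  expect_equal(hsic_statistic(matrix(0, 3, 3), diag(3)), 0)
  expect_equal(hsic_statistic(diag(4), diag(4)), 1)
  expect_error(hsic_statistic(diag(3), diag(4)), "dimension")
})

test_that("empirical p-value follows the printed formula", {
  expect_equal(empirical_pvalue(5, c(1, 2, 3, 4)), 1 / 5)
  expect_equal(empirical_pvalue(0, c(1, 2, 3, 4)), 1)
  expect_equal(empirical_pvalue(2, rep(2, 10)), 1)  # ties are exceedances
  expect_equal(empirical_pvalue(10, rep(0, 1000)), 1 / 1001)
  expect_error(empirical_pvalue(1, numeric(0)), "empty")
})

test_that("permuted reconstruction preserves means, variances, correlations", {
  set.seed(32)
  n <- 80
  g <- factor(rbinom(n, 1, 0.5))
  Y <- matrix(rnorm(n * 4, sd = 2), n, 4) + as.numeric(g == "1") * 0.5
  res <- standardize(estimate_variance_groupwise(
    fit_mean_model(design_inputs(Y, g))))

  expect_equal(permute_and_reconstruct(res, seq_len(n)), Y,
               tolerance = 1e-10, ignore_attr = TRUE)

  perm <- sample(n)
  Yb <- permute_and_reconstruct(res, perm)
  # the residual correlation structure is untouched by a row-wise shuffle
  expect_equal(cor(res$e_std[perm, ]), cor(res$e_std), tolerance = 1e-12)
  # the fitted mean surface is carried over unchanged
  expect_equal(colMeans(Yb - res$s * res$e_std[perm, ]),
               colMeans(res$fitted), tolerance = 1e-12, ignore_attr = TRUE)
  # under a pooled variance model s is constant per gene, so the column
  # means of the reconstruction equal the original column means exactly
  resc <- standardize(estimate_variance_constant(
    fit_mean_model(design_inputs(Y, g))))
  Ybc <- permute_and_reconstruct(resc, perm)
  expect_equal(colMeans(Ybc), colMeans(Y), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(permute_and_reconstruct(res, c(1, 1, 3:n)), "permutation")
})

test_that("compiled and reference permutation engines agree exactly", {
  set.seed(33)
  for (setup in list(
    list(risk = "categorical", variance = "groupwise", delta = 0.1),
    list(risk = "continuous", variance = "dglm", delta = 0.3),
    list(risk = "continuous", variance = "constant", delta = 0))) {
    cfg <- mvn_sim_config(n = 60, r = 4, risk_type = setup$risk, tau = 0,
                          delta_max = setup$delta, seed = 330)
    sim <- simulate_mvn_pathway(cfg)
    d <- design_inputs(sim$Y, sim$X, C = sim$C)
    a <- permutation_null(d, B = 25, seed = 9, variance = setup$variance,
                          eigengene = TRUE, engine = "cpp")
    b <- permutation_null(d, B = 25, seed = 9, variance = setup$variance,
                          eigengene = TRUE, engine = "r")
    for (nm in names(a)) {
      expect_equal(a[[nm]]$T_null, b[[nm]]$T_null, tolerance = 1e-8)
      expect_equal(a[[nm]]$T_obs, b[[nm]]$T_obs, tolerance = 1e-10)
      expect_equal(a[[nm]]$p_empirical, b[[nm]]$p_empirical)
    }
  }
})

test_that("results are deterministic under a fixed seed", {
  set.seed(34)
  cfg <- mvn_sim_config(n = 50, r = 4, risk_type = "categorical", tau = 0,
                        seed = 34)
  sim <- simulate_mvn_pathway(cfg)
  a <- kdca_test(sim$Y, sim$X, C = sim$C, B = 60, seed = 5,
                 eigengene = TRUE)
  b <- kdca_test(sim$Y, sim$X, C = sim$C, B = 60, seed = 5,
                 eigengene = TRUE)
  expect_identical(a$per_kernel, b$per_kernel)
  expect_identical(a$p_combined, b$p_combined)
  expect_identical(a$eigengene$p_empirical, b$eigengene$p_empirical)
})

test_that("Fisher combination reproduces the closed-form arithmetic", {
  mk <- function(p, Tn) structure(list(kernel_name = "k", T_obs = 1,
                                       T_null = Tn, B = length(Tn),
                                       seed = 1, p_empirical = p),
                                  class = "kdca_perm")
  r1 <- lapply(1:3, function(i) mk(1, c(2, 3, 4)))
  expect_equal(fisher_combine(r1)$T_prime_obs, 0)
  r2 <- lapply(1:3, function(i) mk(0.5, c(2, 3, 4)))
  expect_equal(fisher_combine(r2)$T_prime_obs, -6 * log(0.5))
  expect_error(fisher_combine(r1[1]), "at least two")
  r3 <- list(mk(0.5, c(1, 2)), mk(0.5, c(1, 2, 3)))
  expect_error(fisher_combine(r3), "mismatched")
})

test_that("combining fully dependent kernels stays calibrated", {
  # three kernels with identical null statistics: the combined test should
  # behave like the single test, never anticonservatively
  set.seed(35)
  n_rep <- 2000
  B <- 99
  p_comb <- p_single <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    Tn <- rchisq(B, df = 2)
    To <- rchisq(1, df = 2)
    pr <- structure(list(kernel_name = "k", T_obs = To, T_null = Tn, B = B,
                         seed = 1, p_empirical = empirical_pvalue(To, Tn)),
                    class = "kdca_perm")
    cmb <- fisher_combine(list(pr, pr, pr))
    p_comb[i] <- cmb$p_combined
    p_single[i] <- pr$p_empirical
  }
  rej <- mean(p_comb <= 0.05)
  expect_lte(rej, binom_2se_bound(0.05, n_rep))
  expect_gt(cor(p_comb, p_single), 0.99)
})

test_that("no reported p-value falls below the permutation floor", {
  st <- null_mvn_categorical()
  expect_gte(min(st$p), 1 / (st$B + 1))
  # forced extreme: observed above every null
  expect_equal(empirical_pvalue(Inf, rnorm(st$B)), 1 / (st$B + 1))
})

test_that("null p-values are uniform under the exchangeable null", {
  st <- null_mvn_categorical()
  for (k in colnames(st$p)) {
    ks <- suppressWarnings(ks.test(st$p[, k], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("eigengene test matches the linear kernel for rank-1 signal and
           misses signal in lower singular vectors", {
  set.seed(36)
  n <- 150
  x <- rbinom(n, 1, 0.5)
  # rank-1 structure: one shared latent component interacting with x
  u <- rnorm(n)
  Y <- sapply(1:5, function(k) 0.9 * u * (0.4 + 0.6 * x) + rnorm(n, sd = 0.5))
  d <- design_inputs(Y, factor(x))
  pn <- permutation_null(d, kernels = "linear", B = 150, seed = 7,
                         variance = "groupwise", eigengene = TRUE)
  expect_lt(pn$eigengene$p_empirical, 0.05)
  expect_lt(abs(pn$linear$p_empirical - pn$eigengene$p_empirical), 0.1)
})

test_that("Gamma approximation matches closed forms and permutations", {
  set.seed(37)
  n <- 200
  # rank-1 kernels: the null is an exactly scaled chi-squared_1 with scale
  # a*b/n^2 (a, b the single non-zero eigenvalues of the centered kernels)
  unit <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  x <- unit(rnorm(n)); z <- unit(rnorm(n))
  KZ <- 3 * tcrossprod(z)   # eigenvalue a = 3n
  KX <- tcrossprod(x)       # eigenvalue b = n
  for (Tq in c(0.5, 2, 5)) {
    p_gamma <- suppressWarnings(gamma_approx_pvalue(Tq, KZ, KX))
    p_exact <- pchisq(Tq / 3, df = 1, lower.tail = FALSE)
    expect_equal(p_gamma, p_exact, tolerance = 1e-3)
  }
  expect_equal(suppressWarnings(gamma_approx_pvalue(0, KZ, KX)), 1)

  # cross-check against a plain label-permutation null for the linear kernel
  set.seed(38)
  nn <- 600
  Z <- center_columns(matrix(rnorm(nn * 10), nn, 10))
  xc <- encode_risk_factor(matrix(rnorm(nn)))
  KZl <- linear_kernel(Z)
  KXl <- tcrossprod(xc)
  Tobs <- hsic_statistic(KZl, KXl)
  xv <- drop(xc)
  Tn <- replicate(2000, {
    p <- sample(nn)
    sum(colSums(xv[p] * Z)^2) / nn
  })
  p_perm <- empirical_pvalue(Tobs, Tn)
  p_gam <- suppressWarnings(gamma_approx_pvalue(Tobs, KZl, KXl))
  expect_lt(abs(p_perm - p_gam), 0.05)
  expect_warning(gamma_approx_pvalue(Tobs, KZl, KXl), "unreliable")
})

test_that("failed variance refits are redrawn and degenerate runs abort", {
  # a tiny group makes some permutations produce near-degenerate groups;
  # the machinery must either redraw successfully or error informatively
  set.seed(39)
  g <- factor(c(rep(0, 20), rep(1, 3)))
  Y <- matrix(rnorm(23 * 3), 23, 3)
  d <- design_inputs(Y, g)
  pn <- permutation_null(d, kernels = "linear", B = 30, seed = 2,
                         variance = "groupwise")
  expect_length(pn$linear$T_null, 30)
  expect_true(all(is.finite(pn$linear$T_null)))
})

test_that("multiple risk factors stay calibrated under the null", {
  p <- numeric(100)
  for (i in 1:100) {
    cfg <- mvn_sim_config(n = 150, r = 6, n_factors = 3, tau = 0,
                          delta_max = 0.1, seed = 96000 + i)
    sim <- simulate_multifactor(cfg)
    p[i] <- kdca_test(sim$Y, sim$X, C = sim$C, B = 199, seed = 96000 + i,
                      variance = "dglm")$p_combined
  }
  expect_lte(mean(p <= 0.05), binom_2se_bound(0.05, 100))
})
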