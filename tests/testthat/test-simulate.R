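test_that("simulators are deterministic given a seed", {
  cfg <- mvn_sim_config(n = 40, r = 5, seed = 41, delta_max = 0.2,
                        sign_scheme = "mixed")
  a <- simulate_mvn_pathway(cfg)
  b <- simulate_mvn_pathway(cfg)
  expect_identical(a$Y, b$Y)
  expect_identical(a$truth, b$truth)

  ncfg <- nb_sim_config(n = 20, genes = 30, pathway_size = 10, seed = 42)
  expect_identical(simulate_nb_counts(ncfg)$counts,
                   simulate_nb_counts(ncfg)$counts)
})

test_that("the Gaussian model reproduces its configured moments", {
  # condition on the design by residualizing on the true mean model, then
  # compare group-wise moments of the residuals with the generator's
  # parameters (the independent oracle is plain least squares)
  cfg <- mvn_sim_config(n = 1e5, r = 5, risk_type = "categorical",
                        delta_max = 0.1, tau = 0.15, seed = 43)
  sim <- simulate_mvn_pathway(cfg)
  x <- as.numeric(sim$X == "1")
  D <- cbind(1, x, sim$C)
  e <- sim$Y - D %*% solve(crossprod(D), crossprod(D, sim$Y))
  # variances: Var = exp(1 + delta_k * x); ratio across groups = exp(delta_k)
  v0 <- apply(e[x == 0, ], 2, var)
  v1 <- apply(e[x == 1, ], 2, var)
  se_logratio <- sqrt(2 / (sum(x == 0) - 1) + 2 / (sum(x == 1) - 1))
  expect_lt(max(abs(log(v0) - 1)), 3 * sqrt(2 / (sum(x == 0) - 1)) + 0.01)
  # recovered delta_k within 3 MC SEs of the drawn values
  expect_lt(max(abs(log(v1 / v0) - sim$params$delta)), 3 * se_logratio)
  # correlations: mean rho_j + tau * x within each group
  rho_mean <- mean(cfg$rho_range)
  for (g in 0:1) {
    cors <- cor(e[x == g, ])
    off <- cors[upper.tri(cors)]
    expect_lt(abs(mean(off) - (rho_mean + cfg$tau * g)), 0.02)
  }
})

test_that("degenerate continuous risk factor reduces to exchangeable noise", {
  cfg <- mvn_sim_config(n = 3000, r = 4, risk_type = "continuous", tau = 0.2,
                        delta_max = 0.5, seed = 44)
  sim <- simulate_mvn_pathway(cfg)
  # with tau fixed to 0 and delta_max 0 the generator collapses to the
  # baseline-correlation model whatever X is
  cfg0 <- mvn_sim_config(n = 3000, r = 4, risk_type = "continuous", tau = 0,
                         delta_max = 0, seed = 44)
  sim0 <- simulate_mvn_pathway(cfg0)
  D <- cbind(1, sim0$X, sim0$C)
  e <- sim0$Y - D %*% solve(crossprod(D), crossprod(D, sim0$Y))
  v <- apply(e, 2, var)
  expect_lt(max(abs(v / exp(1) - 1)), 0.15)
  co <- cor(e)
  expect_true(all(co[upper.tri(co)] > 0.2 & co[upper.tri(co)] < 0.55))
})

test_that("null genes carry no differential co-expression", {
  cfg <- mvn_sim_config(n = 8000, r = 6, risk_type = "continuous",
                        null_fraction = 0.5, tau = 0.2, seed = 45)
  sim <- simulate_mvn_pathway(cfg)
  x <- sim$X
  D <- cbind(1, x, sim$C)
  e <- sim$Y - D %*% solve(crossprod(D), crossprod(D, sim$Y))
  es <- scale(e)
  pr <- sim$truth$pairs
  slopes <- vapply(seq_len(nrow(pr)), function(i) {
    z <- es[, pr$k1[i]] * es[, pr$k2[i]]
    unname(coef(lm(z ~ x))[2])
  }, numeric(1))
  active <- pr$tau_signed != 0
  expect_gt(sum(active), 0)
  expect_gt(sum(!active), 0)
  # per-pair product-on-X regression: slope tracks tau for active pairs only
  expect_lt(max(abs(slopes[!active])), 0.08)
  expect_gt(min(abs(slopes[active])), 0.05)
})

test_that("PSD repair never activates in the positive-sign scheme", {
  for (s in 1:5) {
    cfg <- mvn_sim_config(n = 100, r = 8, risk_type = "continuous",
                          sign_scheme = "positive", delta_max = 0.5,
                          seed = 450 + s)
    expect_identical(simulate_mvn_pathway(cfg)$n_clipped, 0L)
  }
  # mixed signs with a continuous factor can require repair; it must
  # produce draws without error
  cfgm <- mvn_sim_config(n = 100, r = 8, risk_type = "continuous",
                         sign_scheme = "mixed", seed = 456)
  expect_s3_class(simulate_mvn_pathway(cfgm), "kdca_sim")
})

test_that("negative-binomial counts match the dispersion model", {
  # constant per-gene means isolate the count-level mean/variance law;
  # after multinomial library scaling the quadratic term dominates, so the
  # recovered dispersion (v - m) / m^2 should sit near 0.25
  cfg <- nb_sim_config(n = 4000, genes = 150, pathway_size = 10,
                       beta_sd = 0, gamma_sd = 0, delta_sd = 0,
                       library_sizes = 2e6, seed = 46)
  sim <- simulate_nb_counts(cfg)
  m <- colMeans(sim$counts)
  v <- apply(sim$counts, 2, var)
  disp <- (v - m) / m^2
  expect_lt(abs(median(disp) - 0.25), 0.03)
})

test_that("library scaling hits the target totals exactly", {
  cfg <- nb_sim_config(n = 25, genes = 60, pathway_size = 10,
                       library_sizes = 2e6, seed = 47)
  sim <- simulate_nb_counts(cfg)
  expect_true(all(rowSums(sim$counts) == 2e6))
  cfg2 <- nb_sim_config(n = 25, genes = 60, pathway_size = 10, seed = 48)
  sim2 <- simulate_nb_counts(cfg2)
  expect_true(all(rowSums(sim2$counts) %in% c(2e6, 1e7)))
  expect_length(sim2$pathways, 6)
  expect_true(all(lengths(sim2$pathways) == 10))
})

test_that("multifactor simulation returns the factor matrix and reduces
           to a rank-deficient design when factors coincide", {
  cfg <- mvn_sim_config(n = 60, r = 4, n_factors = 3, seed = 49)
  sim <- simulate_multifactor(cfg)
  expect_true(is.matrix(sim$X) && ncol(sim$X) == 3)
  expect_true(all(sim$X %in% 0:1))
  d <- design_inputs(sim$Y, sim$X, C = sim$C)
  expect_s3_class(d, "kdca_design")
  # identical factors are collinear and must be flagged by the design
  Xdup <- cbind(X1 = sim$X[, 1], X2 = sim$X[, 1], X3 = sim$X[, 1])
  expect_error(design_inputs(sim$Y, Xdup), "rank deficient")
})

test_that("inadmissible correlation parameters raise an informative error", {
  cfg <- mvn_sim_config(n = 30, r = 3, risk_type = "continuous",
                        tau = 0.5, rho_range = c(0.45, 0.5), seed = 50)
  # rho + tau * x can approach 1.45 for x near 2
  expect_error(simulate_mvn_pathway(cfg), "outside \\(-1, 1\\)")
})
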