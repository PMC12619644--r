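# Fixture builders and cached simulation studies shared across test files.
# Studies are computed once per session; the cache avoids repeating the
# heavier permutation runs for tests that look at different properties of
# the same experiment.

.study_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .study_cache)) {
    assign(key, force(expr), envir = .study_cache)
  }
  get(key, envir = .study_cache)
}

# small random design with a continuous risk factor and one covariate
make_design <- function(n = 40, r = 3, seed = 1) {
  set.seed(seed)
  X <- runif(n, 0, 2)
  C <- matrix(runif(n), n, 1, dimnames = list(NULL, "C1"))
  Y <- matrix(rnorm(n * r), n, r, dimnames = list(NULL, paste0("g", 1:r)))
  design_inputs(Y, X, C = C)
}

# null study under the Gaussian pathway model with a categorical risk
# factor carrying mean and variance effects (tau = 0, delta' = 0.1)
null_mvn_categorical <- function(n_path = 200, B = 400) {
  cached("null_mvn_cat", {
    p <- matrix(NA_real_, n_path, 4,
                dimnames = list(NULL, c("linear", "projection", "gaussian",
                                        "combined")))
    for (i in seq_len(n_path)) {
      cfg <- mvn_sim_config(n = 300, r = 10, risk_type = "categorical",
                            tau = 0, delta_max = 0.1, seed = 10000 + i)
      sim <- simulate_mvn_pathway(cfg)
      fit <- kdca_test(sim$Y, sim$X, C = sim$C, B = B, seed = 20000 + i)
      p[i, ] <- c(fit$per_kernel, fit$p_combined)
    }
    list(p = p, B = B, n_path = n_path)
  })
}

# null study with a continuous risk factor and a strong variance effect
# (delta' = 0.5), tested with and without double-GLM variance adjustment
null_mvn_continuous <- function(n_path = 150, B = 400) {
  cached("null_mvn_cont", {
    p_adj <- p_off <- numeric(n_path)
    for (i in seq_len(n_path)) {
      cfg <- mvn_sim_config(n = 300, r = 10, risk_type = "continuous",
                            tau = 0, delta_max = 0.5, seed = 30000 + i)
      sim <- simulate_mvn_pathway(cfg)
      p_adj[i] <- kdca_test(sim$Y, sim$X, C = sim$C, B = B,
                            seed = 40000 + i, variance = "dglm")$p_combined
      p_off[i] <- kdca_test(sim$Y, sim$X, C = sim$C, B = B,
                            seed = 40000 + i,
                            variance = "constant")$p_combined
    }
    list(p_adj = p_adj, p_off = p_off, B = B, n_path = n_path)
  })
}

# null study on log-transformed negative-binomial counts with
# gene-independent latent interactions
null_nb_study <- function(n_path = 120, B = 300) {
  cached("null_nb", {
    cfg <- nb_sim_config(n = 300, genes = n_path * 10L, pathway_size = 10L,
                         seed = 77)
    sim <- simulate_nb_counts(cfg)
    tc <- transform_counts(sim$counts)
    p <- numeric(n_path)
    for (i in seq_len(n_path)) {
      genes <- sim$pathways[[i]]
      p[i] <- kdca_test(tc$expression[, genes, drop = FALSE], sim$X,
                        C = cbind(C = sim$C, log_lib = tc$log_lib),
                        B = B, seed = 50000 + i,
                        variance = "dglm")$p_combined
    }
    list(p = p, B = B, n_path = n_path)
  })
}

# power study at a given configuration; returns per-kernel, combined and
# eigengene p-values over replicates
power_study <- function(key, risk_type, sign_scheme, n_rep = 200, B = 300,
                        seed0 = 0) {
  cached(key, {
    p <- matrix(NA_real_, n_rep, 5,
                dimnames = list(NULL, c("linear", "projection", "gaussian",
                                        "combined", "eigengene")))
    for (i in seq_len(n_rep)) {
      cfg <- mvn_sim_config(n = 300, r = 10, risk_type = risk_type,
                            null_fraction = 0, sign_scheme = sign_scheme,
                            delta_max = 0.1, seed = seed0 + i)
      sim <- simulate_mvn_pathway(cfg)
      fit <- kdca_test(sim$Y, sim$X, C = sim$C, B = B, seed = seed0 + i,
                       eigengene = TRUE)
      p[i, ] <- c(fit$per_kernel, fit$p_combined,
                  fit$eigengene$p_empirical)
    }
    list(p = p, B = B, n_rep = n_rep)
  })
}

binom_2se_bound <- function(alpha, n) alpha + 2 * sqrt(alpha * (1 - alpha) / n)
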