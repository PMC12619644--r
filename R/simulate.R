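#' Configuration for the multivariate-normal pathway simulator
#'
#' Parameters of the Gaussian pathway model used in the power and type-I
#' error experiments: gene means `alpha_k + X_j + C_j`, log conditional
#' variances `1 + delta_k X_j` with `delta_k ~ Uniform(0, delta_max)`, and
#' pairwise correlations `rho_j + tau X_j` (per-individual baseline
#' `rho_j ~ Uniform(rho_range)`), with `tau` the differential co-expression
#' effect size.
#'
#' @param n sample size (default 300).
#' @param r pathway size (default 10; 50 reflects larger pathways).
#' @param risk_type `"categorical"` (`X ~ Bernoulli(0.5)`) or
#'   `"continuous"` (`X ~ Uniform(0, 2)`).
#' @param null_fraction proportion of genes carrying no differential
#'   co-expression (0, 0.2, 0.4, 0.6, 0.8 in the study grid).
#' @param sign_scheme `"positive"` (all pair effects `+tau`) or `"mixed"`
#'   (each pair's sign drawn once as +/-1).
#' @param tau_range range of the correlation effect size (default
#'   `(0.1, 0.2)`); one `tau` is drawn per replicate.
#' @param tau optional fixed value overriding `tau_range`; `tau = 0` is the
#'   global null.
#' @param rho_range range of the per-individual baseline correlation
#'   (default `(0.25, 0.50)`).
#' @param delta_max upper end `delta'` of the variance-effect range
#'   `delta_k ~ Uniform(0, delta_max)` (0, 0.1, 0.25, 0.5 in the grid).
#' @param n_factors number of Bernoulli risk factors (1 or 3); with 3, the
#'   model uses the average effect `Xbar_j = (2/3) sum_l X_jl`.
#' @param seed optional RNG seed.
#' @return A list of class `"mvn_sim_config"`.
#' @export
mvn_sim_config <- function(n = 300L, r = 10L,
                           risk_type = c("categorical", "continuous"),
                           null_fraction = 0, sign_scheme = c("positive",
                                                              "mixed"),
                           tau_range = c(0.1, 0.2), tau = NULL,
                           rho_range = c(0.25, 0.50), delta_max = 0,
                           n_factors = 1L, seed = NULL) {
  risk_type <- match.arg(risk_type)
  sign_scheme <- match.arg(sign_scheme)
  stopifnot(n >= 4L, r >= 2L, null_fraction >= 0, null_fraction <= 1,
            diff(tau_range) >= 0, diff(rho_range) >= 0, delta_max >= 0,
            n_factors %in% c(1L, 3L))
  structure(list(n = as.integer(n), r = as.integer(r), risk_type = risk_type,
                 null_fraction = null_fraction, sign_scheme = sign_scheme,
                 tau_range = tau_range, tau = tau, rho_range = rho_range,
                 delta_max = delta_max, n_factors = as.integer(n_factors),
                 seed = seed),
            class = "mvn_sim_config")
}

#' Simulate one pathway from the multivariate-normal model
#'
#' Draws each individual's expression vector from a multivariate normal
#' whose mean, variances, and pairwise correlations depend on that
#' individual's risk factor value: the correlation of a gene pair is
#' `rho_j + tau_signed * X_j` when both genes are non-null and `rho_j`
#' otherwise, converted to a covariance via the per-gene conditional
#' standard deviations `exp((1 + delta_k X_j) / 2)`. Under the mixed-sign
#' scheme the per-individual correlation matrix may lose positive
#' semidefiniteness; it is then repaired by eigenvalue clipping at 1e-8
#' followed by rescaling to unit diagonal (clipping events are counted in
#' the output).
#'
#' @param cfg an `"mvn_sim_config"`.
#' @return A list of class `"kdca_sim"`: `Y` (n x r), `X` (factor for a
#'   categorical factor, numeric vector for a continuous one, or an n x L
#'   0/1 matrix for multiple factors), `C`, `truth` (gene labels and pair
#'   effects), `n_clipped`, and `config`.
#' @export
simulate_mvn_pathway <- function(cfg) {
  stopifnot(inherits(cfg, "mvn_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n; r <- cfg$r

  if (cfg$n_factors == 3L) {
    Xmat <- matrix(rbinom(n * 3L, 1L, 0.5), n, 3L,
                   dimnames = list(NULL, paste0("X", 1:3)))
    x_eff <- (2 / 3) * rowSums(Xmat)
    X_out <- Xmat
  } else if (cfg$risk_type == "categorical") {
    xnum <- rbinom(n, 1L, 0.5)
    x_eff <- as.numeric(xnum)
    X_out <- factor(xnum)
  } else {
    x_eff <- runif(n, 0, 2)
    X_out <- x_eff
  }
  C <- runif(n, 0, 2)
  alpha <- rnorm(r)
  delta <- runif(r, 0, cfg$delta_max)
  rho <- runif(n, cfg$rho_range[1L], cfg$rho_range[2L])
  tau <- if (!is.null(cfg$tau)) cfg$tau else runif(1, cfg$tau_range[1L],
                                                   cfg$tau_range[2L])

  n_null <- round(cfg$null_fraction * r)
  null_genes <- if (n_null > 0) sample.int(r, n_null) else integer(0)
  is_dca <- !(seq_len(r) %in% null_genes)

  pairs <- t(combn(r, 2L))
  q <- nrow(pairs)
  sign_pair <- if (cfg$sign_scheme == "mixed") {
    sample(c(-1, 1), q, replace = TRUE)
  } else {
    rep(1, q)
  }
  active <- is_dca[pairs[, 1L]] & is_dca[pairs[, 2L]]
  tau_signed <- ifelse(active, sign_pair * tau, 0)

  Zmat <- matrix(rnorm(n * r), n, r)
  Y <- matrix(0, n, r, dimnames = list(NULL, paste0("g", seq_len(r))))
  n_clipped <- 0L
  for (j in seq_len(n)) {
    off <- rho[j] + tau_signed * x_eff[j]
    bad <- abs(off) >= 1
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf(paste0("correlation %.3f outside (-1, 1) for individual ",
                          "%d, pair (%d, %d)"),
                   off[i], j, pairs[i, 1L], pairs[i, 2L]))
    }
    R <- diag(r)
    R[cbind(pairs[, 1L], pairs[, 2L])] <- off
    R[cbind(pairs[, 2L], pairs[, 1L])] <- off
    sd_j <- exp((1 + delta * x_eff[j]) / 2)
    Sigma <- R * tcrossprod(sd_j)
    U <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(U)) {
      # eigenvalue clipping + correlation rescale, diagonal reset to target
      ei <- eigen(R, symmetric = TRUE)
      ei$values[ei$values < 1e-8] <- 1e-8
      Rr <- ei$vectors %*% (ei$values * t(ei$vectors))
      d <- sqrt(diag(Rr))
      Rr <- Rr / tcrossprod(d)
      Sigma <- Rr * tcrossprod(sd_j)
      U <- chol(Sigma)
      n_clipped <- n_clipped + 1L
    }
    Y[j, ] <- alpha + x_eff[j] + C[j] + drop(Zmat[j, ] %*% U)
  }

  structure(list(Y = Y, X = X_out, C = C,
                 truth = list(genes = data.frame(gene = colnames(Y),
                                                 is_dca = is_dca),
                              pairs = data.frame(k1 = pairs[, 1L],
                                                 k2 = pairs[, 2L],
                                                 tau_signed = tau_signed),
                              tau = tau),
                 params = list(alpha = alpha, delta = delta, rho = rho,
                               tau = tau),
                 n_clipped = n_clipped, config = cfg),
            class = "kdca_sim")
}

#' Simulate a pathway with three Bernoulli risk factors
#'
#' Convenience wrapper around [simulate_mvn_pathway()] with
#' `n_factors = 3`: mean, variance, and correlation terms use the average
#' effect `Xbar_j = (2/3) sum_l X_jl`, and the full n x 3 risk-factor
#' matrix is returned for multivariate kernel testing.
#'
#' @param cfg an `"mvn_sim_config"`; `n_factors` is forced to 3.
#' @return See [simulate_mvn_pathway()].
#' @export
simulate_multifactor <- function(cfg) {
  stopifnot(inherits(cfg, "mvn_sim_config"))
  cfg$n_factors <- 3L
  simulate_mvn_pathway(cfg)
}

#' Configuration for the negative-binomial count simulator
#'
#' Parameters of the RNA-seq count model used for the transformation-induced
#' variance-effect null: per-gene log means
#' `log(alpha_k) + beta_k X_j + gamma_k C_j + delta_k X_j U_jk` with a
#' gene-independent latent factor `U_jk ~ Normal(0, 1)`, negative-binomial
#' dispersion 0.25, and per-sample library sizes drawn from
#' `{2e6, 1e7}`. Because the latent interaction is not shared across genes,
#' pathways assembled from these genes satisfy the differential
#' co-expression null while acquiring risk-factor variance effects after
#' log transformation.
#'
#' @param n sample size.
#' @param genes number of genes simulated (default 10000).
#' @param pathway_size genes per pathway (10 or 50).
#' @param alpha_meanlog,alpha_sdlog log-normal parameters of the baseline
#'   count size `alpha_k` (defaults 5.54 and 0.697).
#' @param beta_sd,gamma_sd standard deviations of the risk-factor and
#'   covariate effect sizes (default 0.1, i.e. variance 0.01).
#' @param delta_sd standard deviation of the latent-interaction effect size
#'   (default 0.025, i.e. variance 6.25e-4).
#' @param dispersion negative-binomial dispersion (default 0.25; variance
#'   `mu + dispersion * mu^2`).
#' @param library_sizes per-sample total-count targets, chosen uniformly at
#'   random per sample.
#' @param risk_type `"continuous"` (`Uniform(0, 2)`) or `"categorical"`
#'   (`Bernoulli(0.5)`).
#' @param seed optional RNG seed.
#' @return A list of class `"nb_sim_config"`.
#' @export
nb_sim_config <- function(n = 300L, genes = 10000L, pathway_size = 10L,
                          alpha_meanlog = 5.54, alpha_sdlog = 0.697,
                          beta_sd = 0.1, gamma_sd = 0.1, delta_sd = 0.025,
                          dispersion = 0.25, library_sizes = c(2e6, 1e7),
                          risk_type = c("continuous", "categorical"),
                          seed = NULL) {
  risk_type <- match.arg(risk_type)
  stopifnot(n >= 4L, genes >= pathway_size, pathway_size >= 2L,
            dispersion > 0, all(library_sizes > 0))
  structure(list(n = as.integer(n), genes = as.integer(genes),
                 pathway_size = as.integer(pathway_size),
                 alpha_meanlog = alpha_meanlog, alpha_sdlog = alpha_sdlog,
                 beta_sd = beta_sd, gamma_sd = gamma_sd,
                 delta_sd = delta_sd, dispersion = dispersion,
                 library_sizes = library_sizes, risk_type = risk_type,
                 seed = seed),
            class = "nb_sim_config")
}

#' Simulate negative-binomial counts with latent interactions
#'
#' Draws counts per [nb_sim_config()], then rescales each sample to its
#' drawn library size by multinomial resampling (preserving integer counts
#' and negative-binomial-like marginals). Genes are grouped into
#' consecutive pathways of `pathway_size`.
#'
#' @param cfg an `"nb_sim_config"`.
#' @return A list of class `"kdca_nb_sim"`: `counts` (n x genes integer
#'   matrix), `X`, `C`, `library_sizes` (length n), `pathways` (list of
#'   gene-index vectors), and `config`.
#' @export
simulate_nb_counts <- function(cfg) {
  stopifnot(inherits(cfg, "nb_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n; G <- cfg$genes

  x <- if (cfg$risk_type == "continuous") runif(n, 0, 2) else
    as.numeric(rbinom(n, 1L, 0.5))
  C <- runif(n, 0, 2)
  log_alpha <- rnorm(G, cfg$alpha_meanlog, cfg$alpha_sdlog)
  beta <- rnorm(G, 0, cfg$beta_sd)
  gam <- rnorm(G, 0, cfg$gamma_sd)
  delta <- rnorm(G, 0, cfg$delta_sd)
  U <- matrix(rnorm(n * G), n, G)

  logmu <- matrix(log_alpha, n, G, byrow = TRUE) +
    outer(x, beta) + outer(C, gam) + (x * U) * matrix(delta, n, G,
                                                      byrow = TRUE)
  counts <- matrix(rnbinom(n * G, mu = exp(logmu), size = 1 / cfg$dispersion),
                   n, G)

  lib <- cfg$library_sizes[sample.int(length(cfg$library_sizes), n,
                                      replace = TRUE)]
  for (j in seq_len(n)) {
    tot <- sum(counts[j, ])
    if (tot == 0) stop("sample ", j, " has zero total count")
    counts[j, ] <- drop(rmultinom(1L, lib[j], counts[j, ] / tot))
  }
  colnames(counts) <- paste0("g", seq_len(G))

  n_path <- G %/% cfg$pathway_size
  pathways <- split(seq_len(n_path * cfg$pathway_size),
                    rep(seq_len(n_path), each = cfg$pathway_size))
  names(pathways) <- paste0("pathway", seq_len(n_path))

  X_out <- if (cfg$risk_type == "categorical") factor(x) else x
  structure(list(counts = counts, X = X_out, C = C, library_sizes = lib,
                 pathways = pathways, config = cfg),
            class = "kdca_nb_sim")
}
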