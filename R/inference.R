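#' Hilbert-Schmidt independence criterion trace statistic
#'
#' `T = tr(K_Z K_X) / n`, computed as the elementwise sum of the two kernel
#' matrices without forming their product. Small values suggest the two
#' similarity structures are independent; large values indicate shared
#' signal, i.e. differential co-expression.
#'
#' @param K_Z kernel matrix for the cross products (n x n).
#' @param K_X kernel matrix for the risk factor(s) (n x n).
#' @return The scalar statistic.
#' @export
hsic_statistic <- function(K_Z, K_X) {
  if (!all(dim(K_Z) == dim(K_X))) {
    stop("kernel matrices must have identical dimensions")
  }
  sum(K_Z * K_X) / nrow(K_Z)
}

#' Empirical permutation p-value
#'
#' `p = (#\{b : T(b) >= T\} + 1) / (B + 1)`; ties count as exceedances, and
#' the smallest attainable p-value is `1 / (B + 1)`.
#'
#' @param T_obs observed statistic.
#' @param T_null numeric vector of null statistics.
#' @return The empirical p-value.
#' @export
empirical_pvalue <- function(T_obs, T_null) {
  if (length(T_null) < 1L) stop("empty permutation null vector")
  (sum(T_null >= T_obs) + 1) / (length(T_null) + 1)
}

#' Reconstruct a null expression matrix from permuted residuals
#'
#' Applies a row permutation to the standardized residuals of every gene
#' simultaneously and adds back the fitted mean and the conditional standard
#' deviations: `Y(b)[j, k] = fitted[j, k] + s[j, k] * e_std[perm(j), k]`.
#' Mean effects and variance structure are preserved and gene-gene
#' correlations of the residuals are untouched, while any association
#' between the residuals and the risk factor is broken.
#'
#' @param res a standardized `"kdca_residuals"`.
#' @param perm integer permutation of `1:n`.
#' @return The reconstructed expression matrix.
#' @export
permute_and_reconstruct <- function(res, perm) {
  stopifnot(inherits(res, "kdca_residuals"))
  if (is.null(res$e_std) || is.null(res$s)) {
    stop("residual set must be standardized first")
  }
  n <- nrow(res$e_std)
  if (length(perm) != n || !identical(sort(as.integer(perm)), seq_len(n))) {
    stop("perm must be a permutation of 1..n")
  }
  res$fitted + res$s * res$e_std[perm, , drop = FALSE]
}

# observed per-kernel statistics through the exported kernel functions
.observed_stats <- function(Zc, Xc, KX, kernels, nu, proj_tol,
                            eigengene = FALSE, gaussian_form = "rbf") {
  out <- numeric(0)
  if ("linear" %in% kernels) {
    out["linear"] <- hsic_statistic(linear_kernel(Zc), KX)
  }
  if ("projection" %in% kernels) {
    out["projection"] <- hsic_statistic(projection_kernel(Zc, proj_tol), KX)
  }
  if ("gaussian" %in% kernels) {
    out["gaussian"] <- hsic_statistic(gaussian_kernel(Zc, nu,
                                                      gaussian_form), KX)
  }
  if (eigengene) out["eigengene"] <- .eigengene_stat(Zc$Z, Xc)
  out
}

# n * R^2 of the top left singular vector of centered Z on the risk factors
.eigengene_stat <- function(Z, Xc) {
  u1 <- svd(Z, nu = 1L, nv = 0L)$u[, 1L]
  u1 <- u1 - mean(u1)
  tss <- sum(u1^2)
  if (tss <= 0) return(0)
  Qx <- qr.Q(qr(Xc))
  nrow(Z) * sum(crossprod(Qx, u1)^2) / tss
}

#' Permutation null distribution of the trace statistics
#'
#' Runs the mean/variance-preserving permutation algorithm: for each of `B`
#' permutations the null expression matrix is reconstructed with
#' [permute_and_reconstruct()] and the complete pipeline (mean fit,
#' variance fit, standardization, cross products, kernels) is re-run before
#' the statistic is computed against the fixed risk-factor kernel. All
#' kernels share the same permutation stream, so per-permutation statistics
#' are comparable across kernels.
#'
#' @inheritParams residualize
#' @param kernels character subset of `"linear"`, `"projection"`,
#'   `"gaussian"`.
#' @param B number of permutations (>= 1).
#' @param seed master RNG seed; all permutation index vectors are drawn from
#'   it up front, so results do not depend on execution order.
#' @param nu Gaussian kernel tuning parameter.
#' @param gaussian_form Gaussian kernel form (see [gaussian_kernel()]).
#' @param proj_tol relative singular-value threshold of the projection
#'   kernel.
#' @param eigengene also compute the eigengene baseline statistic under the
#'   identical permutation scheme.
#' @param refit `"full"` re-estimates mean and variance models inside every
#'   permutation (the default, matching the logic of the algorithm);
#'   `"recycle"` reuses the observed conditional standard deviations for
#'   speed comparisons.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation looping over the exported module functions; identical
#'   results, used for validation).
#' @param res optionally, the standardized `"kdca_residuals"` for `design`
#'   (recomputed when `NULL`).
#' @return A named list of `"kdca_perm"` results (one per kernel, plus
#'   `eigengene` if requested), each holding `kernel_name`, `T_obs`,
#'   `T_null`, `p_empirical`, `B`, and `seed`.
#' @export
permutation_null <- function(design,
                             kernels = c("linear", "projection", "gaussian"),
                             B = 1000L, seed = 1L,
                             variance = c("auto", "groupwise", "dglm",
                                          "constant"),
                             variance_covariates = NULL, x_cat = NULL,
                             nu = 1e-4,
                             gaussian_form = c("rbf", "inner-product"),
                             proj_tol = 1e-8, eigengene = FALSE,
                             refit = c("full", "recycle"),
                             engine = c("cpp", "r"), res = NULL) {
  stopifnot(inherits(design, "kdca_design"))
  kernels <- match.arg(kernels, c("linear", "projection", "gaussian"),
                       several.ok = TRUE)
  if (B < 1L) stop("B must be at least 1")
  refit <- match.arg(refit)
  engine <- match.arg(engine)
  variance <- match.arg(variance)
  gaussian_form <- match.arg(gaussian_form)

  if (is.null(res)) {
    res <- residualize(design, variance, variance_covariates, x_cat)
  }
  mode_used <- res$variance_model$mode

  Zc <- center_columns(cross_products(res))
  Xc <- encode_risk_factor(design)
  KX <- .kernel_matrix(tcrossprod(Xc), "linear", "X")
  obs <- .observed_stats(Zc, Xc, KX, kernels, nu, proj_tol, eigengene,
                         gaussian_form)

  n <- design$n
  set.seed(as.integer(seed))
  perms <- matrix(0L, n, B)
  for (b in seq_len(B)) perms[, b] <- sample.int(n)

  run <- if (engine == "cpp") {
    .engine_cpp(design, res, mode_used, Xc, KX, perms, kernels, nu,
                gaussian_form, proj_tol, eigengene, refit)
  } else {
    .engine_r(design, res, mode_used, Xc, perms, kernels, nu, gaussian_form,
              proj_tol, eigengene, refit, variance_covariates, x_cat)
  }
  stats <- run$stats
  if (length(run$failed)) {
    # redraw failed permutations once; a second failure aborts
    redo <- matrix(0L, n, length(run$failed))
    for (i in seq_along(run$failed)) redo[, i] <- sample.int(n)
    run2 <- if (engine == "cpp") {
      .engine_cpp(design, res, mode_used, Xc, KX, redo, kernels, nu,
                  gaussian_form, proj_tol, eigengene, refit)
    } else {
      .engine_r(design, res, mode_used, Xc, redo, kernels, nu,
                gaussian_form, proj_tol, eigengene, refit,
                variance_covariates, x_cat)
    }
    if (length(run2$failed)) {
      stop("permutation refit failed twice (", length(run2$failed),
           " permutation(s)); variance model may be degenerate for this ",
           "pathway (n = ", n, ", r = ", design$r, ")")
    }
    stats[run$failed, ] <- run2$stats
  }

  cols <- c(kernels, if (eigengene) "eigengene")
  out <- lapply(seq_along(cols), function(d) {
    structure(list(kernel_name = cols[d], T_obs = unname(obs[cols[d]]),
                   T_null = stats[, d], B = B, seed = seed,
                   p_empirical = empirical_pvalue(obs[cols[d]], stats[, d])),
              class = "kdca_perm")
  })
  names(out) <- cols
  out
}

.engine_cpp <- function(design, res, mode_used, Xc, KX, perms, kernels, nu,
                        gaussian_form, proj_tol, eigengene, refit) {
  var_mode <- match(mode_used, c("constant", "groupwise", "dglm")) - 1L
  if (var_mode == 1L) {
    grp <- as.integer(res$variance_model$group) - 1L
    ngroups <- nlevels(res$variance_model$group)
  } else {
    grp <- integer(0)
    ngroups <- 0L
  }
  if (var_mode == 2L) {
    Xv <- res$variance_model$Xv
    Pv <- solve(crossprod(Xv), t(Xv))
  } else {
    Xv <- Pv <- matrix(0, 0L, 0L)
  }
  do_gauss <- "gaussian" %in% kernels
  out <- .null_stats_engine(
    res$fitted, res$s, res$e_std, qr.Q(design$qr), design$D, Xv, Pv,
    grp, ngroups, var_mode, Xc,
    if (do_gauss) unclass(KX) else matrix(0, 0L, 0L),
    perms - 1L, cross_products(res)$pair_index - 1L, nu,
    gaussian_form == "rbf", proj_tol,
    "linear" %in% kernels, "projection" %in% kernels, do_gauss, eigengene,
    if (eigengene) qr.Q(qr(Xc)) else matrix(0, 0L, 0L),
    refit == "recycle", 25L, 1e-6, 25L, 1e-8)
  # engine column order: linear, projection, gaussian, eigengene
  order_all <- c("linear", "projection", "gaussian", "eigengene")
  want <- c(kernels, if (eigengene) "eigengene")
  have <- order_all[order_all %in% want]
  stats <- out$stats[, match(want, have), drop = FALSE]
  list(stats = stats, failed = out$failed)
}

.engine_r <- function(design, res, mode_used, Xc, perms, kernels, nu,
                      gaussian_form, proj_tol, eigengene, refit,
                      variance_covariates, x_cat) {
  B <- ncol(perms)
  cols <- c(kernels, if (eigengene) "eigengene")
  stats <- matrix(NA_real_, B, length(cols))
  KX <- .kernel_matrix(tcrossprod(Xc), "linear", "X")
  failed <- integer(0)
  for (b in seq_len(B)) {
    Yb <- permute_and_reconstruct(res, perms[, b])
    design_b <- design
    design_b$Y <- Yb
    res_b <- tryCatch({
      if (refit == "recycle") {
        rb <- fit_mean_model(design_b)
        rb$s <- res$s
        rb$variance_model <- res$variance_model
        standardize(rb)
      } else {
        suppressWarnings(
          residualize(design_b, mode_used, variance_covariates, x_cat))
      }
    }, error = function(e) NULL)
    if (is.null(res_b)) {
      failed <- c(failed, b)
      next
    }
    Zb <- center_columns(cross_products(res_b))
    stats[b, ] <- .observed_stats(Zb, Xc, KX, kernels, nu, proj_tol,
                                  eigengene, gaussian_form)[cols]
  }
  list(stats = stats, failed = failed)
}

#' Combine per-kernel empirical p-values with Fisher's method
#'
#' `T' = -2 * sum_d log(p_d)` over the observed per-kernel empirical
#' p-values. The null distribution of `T'` is built from the shared
#' permutation stream: within permutation `b`, each kernel's statistic is
#' converted to a self-inclusive rank-based p-value
#' `p_d(b) = #\{b' : T_d(b') >= T_d(b)\} / B` (so `p_d(b) >= 1/B` and the
#' logarithm is finite), and `T'(b) = -2 * sum_d log p_d(b)`. The combined
#' p-value is the empirical p-value of `T'` against the `T'(b)`. Using the
#' empirical null of the combined statistic makes the procedure robust to
#' arbitrary dependence between kernels.
#'
#' @param results list of `"kdca_perm"` objects sharing the same `B` and
#'   permutation stream.
#' @return An object of class `"kdca_combined"`: list with `per_kernel`,
#'   `T_prime_obs`, `T_prime_null`, and `p_combined`.
#' @export
fisher_combine <- function(results) {
  if (length(results) < 2L) stop("at least two kernels are required")
  stopifnot(all(vapply(results, inherits, logical(1), "kdca_perm")))
  Bs <- vapply(results, function(x) x$B, numeric(1))
  if (length(unique(Bs)) != 1L) stop("mismatched permutation counts B")
  B <- Bs[[1L]]
  Tnull <- vapply(results, function(x) x$T_null, numeric(B))
  Tnull <- matrix(Tnull, nrow = B)
  p_obs <- vapply(results, function(x) x$p_empirical, numeric(1))
  T_prime_obs <- -2 * sum(log(p_obs))
  p_null <- apply(Tnull, 2L, function(v) {
    (B - rank(v, ties.method = "min") + 1) / B
  })
  p_null <- matrix(p_null, nrow = B)
  T_prime_null <- -2 * rowSums(log(p_null))
  structure(list(per_kernel = results, T_prime_obs = T_prime_obs,
                 T_prime_null = T_prime_null,
                 p_combined = empirical_pvalue(T_prime_obs, T_prime_null)),
            class = "kdca_combined")
}

#' Eigengene baseline test
#'
#' Tests the association between the top left singular vector of the
#' centered cross-product matrix (the pathway "eigengene" of the
#' individual-specific correlations) and the risk factor(s), using the
#' statistic `n * R^2` and the identical mean/variance-preserving
#' permutation scheme as the kernel test, so that only the statistic
#' differs. Signal carried by lower-variance singular vectors is invisible
#' to this baseline.
#'
#' @inheritParams permutation_null
#' @return A `"kdca_perm"` result for the eigengene statistic.
#' @export
eigengene_test <- function(design, B = 1000L, seed = 1L,
                           variance = c("auto", "groupwise", "dglm",
                                        "constant"),
                           variance_covariates = NULL, x_cat = NULL,
                           refit = c("full", "recycle"),
                           engine = c("cpp", "r"), res = NULL) {
  pn <- permutation_null(design, kernels = "linear", B = B, seed = seed,
                         variance = variance,
                         variance_covariates = variance_covariates,
                         x_cat = x_cat, eigengene = TRUE, refit = refit,
                         engine = engine, res = res)
  pn$eigengene
}

#' Large-sample Gamma approximation to the permutation p-value
#'
#' Moment-matched Gamma tail probability for the trace statistic, using the
#' doubly-centered kernels: with eigenvalues `a_i` of the centered `K_Z` and
#' `b_j` of the centered `K_X`, the null is asymptotically
#' `sum_ij (a_i b_j / n^2) chi^2_1`, with mean `tr(Kz~) tr(Kx~) / n^2` and
#' variance `2 tr(Kz~^2) tr(Kx~^2) / n^4`. Because the risk-factor kernel is
#' built from centered columns (zero row sums), the trace statistic is
#' unchanged by the double-centering, so the approximation applies directly
#' to the pipeline statistic. Only intended for large sample sizes; most
#' expression studies should use the permutation algorithm.
#'
#' @param T_obs observed trace statistic.
#' @param K_Z,K_X kernel matrices.
#' @param min_n sample-size guard; a warning is issued below it.
#' @param psd_tol tolerance for negative eigenvalues of the centered
#'   kernels.
#' @return The approximate p-value.
#' @export
gamma_approx_pvalue <- function(T_obs, K_Z, K_X, min_n = 1000L,
                                psd_tol = 1e-8) {
  n <- nrow(K_Z)
  if (!all(dim(K_Z) == dim(K_X))) stop("kernel dimension mismatch")
  if (n < min_n) {
    warning("Gamma approximation is unreliable for n = ", n, " (< ", min_n,
            "); prefer the permutation algorithm")
  }
  center <- function(K) {
    rm <- rowMeans(K)
    K - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(K)
  }
  KZc <- center(unclass(K_Z))
  KXc <- center(unclass(K_X))
  for (K in list(KZc, KXc)) {
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -psd_tol * max(abs(ev))) {
      stop("centered kernel is not positive semidefinite beyond tolerance")
    }
  }
  m <- sum(diag(KZc)) * sum(diag(KXc)) / n^2
  v <- 2 * sum(KZc^2) * sum(KXc^2) / n^4
  if (m <= 0 || v <= 0) stop("degenerate kernel moments")
  pgamma(T_obs, shape = m^2 / v, rate = m / v, lower.tail = FALSE)
}

#' Kernel-based differential co-expression test of a pathway
#'
#' Full orchestration: residualization (mean fit plus group-wise or double
#' GLM variance adjustment), individual-specific correlation cross
#' products, per-kernel trace statistics, the mean/variance-preserving
#' permutation null, and Fisher combination of the per-kernel empirical
#' p-values. Optionally also runs the eigengene baseline under the same
#' permutations, or (for large samples) the moment-matched Gamma
#' approximation in place of permutations.
#'
#' @inheritParams permutation_null
#' @param Y expression matrix (samples x genes, approximately normal scale)
#'   or a ready-made `"kdca_design"`.
#' @param X,C,M risk factor(s), covariates, batch variables (ignored when
#'   `Y` is a design).
#' @param mode `"permutation"` (default) or `"asymptotic"` (Gamma
#'   approximation, large n only; per-kernel p-values are then combined by
#'   the chi-squared form of Fisher's method, which assumes independent
#'   kernels).
#' @param min_n sample-size guard for the asymptotic mode.
#' @return An object of class `"kdca_result"`: list with `per_kernel`
#'   (named p-values), `p_combined`, the underlying `combined`
#'   (`"kdca_combined"`) and `permutations` objects, the optional
#'   `eigengene` result, and `diagnostics` (variance mode and convergence,
#'   effective rank of the cross-product matrix, n, r, B, seed).
#' @export
kdca_test <- function(Y, X = NULL, C = NULL, M = NULL,
                      kernels = c("linear", "projection", "gaussian"),
                      variance = c("auto", "groupwise", "dglm", "constant"),
                      variance_covariates = NULL, x_cat = NULL,
                      B = 1000L, seed = 1L, nu = 1e-4,
                      gaussian_form = c("rbf", "inner-product"),
                      proj_tol = 1e-8, eigengene = FALSE,
                      mode = c("permutation", "asymptotic"),
                      refit = c("full", "recycle"), engine = c("cpp", "r"),
                      min_n = 1000L) {
  mode <- match.arg(mode)
  design <- if (inherits(Y, "kdca_design")) Y else design_inputs(Y, X, C, M)
  variance <- match.arg(variance)
  gaussian_form <- match.arg(gaussian_form)
  res <- residualize(design, variance, variance_covariates, x_cat)
  Zc <- center_columns(cross_products(res))
  sv <- svd(Zc$Z, nu = 0L, nv = 0L)$d
  eff_rank <- sum(sv > proj_tol * sv[1L])

  if (mode == "asymptotic") {
    Xc <- encode_risk_factor(design)
    KX <- .kernel_matrix(tcrossprod(Xc), "linear", "X")
    p_k <- vapply(kernels, function(kn) {
      K <- switch(kn, linear = linear_kernel(Zc),
                  projection = projection_kernel(Zc, proj_tol),
                  gaussian = gaussian_kernel(Zc, nu, gaussian_form))
      gamma_approx_pvalue(hsic_statistic(K, KX), K, KX, min_n = min_n)
    }, numeric(1))
    p_comb <- pchisq(-2 * sum(log(p_k)), df = 2 * length(p_k),
                     lower.tail = FALSE)
    return(structure(list(per_kernel = p_k, p_combined = p_comb,
                          combined = NULL, permutations = NULL,
                          eigengene = NULL,
                          diagnostics = .kdca_diag(res, eff_rank, design,
                                                   NA_integer_, NA_integer_,
                                                   mode)),
                     class = "kdca_result"))
  }

  pn <- permutation_null(design, kernels = kernels, B = B, seed = seed,
                         variance = variance,
                         variance_covariates = variance_covariates,
                         x_cat = x_cat, nu = nu,
                         gaussian_form = gaussian_form, proj_tol = proj_tol,
                         eigengene = eigengene, refit = refit,
                         engine = engine, res = res)
  kr <- pn[kernels]
  comb <- if (length(kernels) >= 2L) fisher_combine(kr) else NULL
  p_k <- vapply(kr, function(x) x$p_empirical, numeric(1))
  structure(list(
    per_kernel = p_k,
    p_combined = if (is.null(comb)) p_k[[1L]] else comb$p_combined,
    combined = comb, permutations = kr,
    eigengene = if (eigengene) pn$eigengene else NULL,
    diagnostics = .kdca_diag(res, eff_rank, design, B, seed, mode)),
    class = "kdca_result")
}

.kdca_diag <- function(res, eff_rank, design, B, seed, mode) {
  list(variance_mode = res$variance_model$mode,
       variance_converged = all(res$variance_model$converged %||% TRUE),
       effective_rank = eff_rank, n = design$n, r = design$r,
       B = B, seed = seed, mode = mode)
}

#' @export
print.kdca_result <- function(x, ...) {
  d <- x$diagnostics
  cat("Kernel differential co-expression test\n")
  cat(sprintf("  n = %d samples, r = %d genes, variance model: %s\n",
              d$n, d$r, d$variance_mode))
  if (!is.na(d$B)) cat(sprintf("  B = %d permutations (seed %d)\n", d$B,
                               d$seed))
  cat("  per-kernel p-values:\n")
  for (nm in names(x$per_kernel)) {
    cat(sprintf("    %-10s %.4g\n", nm, x$per_kernel[[nm]]))
  }
  cat(sprintf("  combined p-value: %.4g\n", x$p_combined))
  if (!is.null(x$eigengene)) {
    cat(sprintf("  eigengene p-value: %.4g\n", x$eigengene$p_empirical))
  }
  invisible(x)
}

#' @importFrom stats pchisq
NULL
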