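#' Assemble design inputs for a pathway test
#'
#' Bundles the expression matrix for a pathway together with the risk
#' factor(s), covariates, and batch variables, validates dimensions, and
#' builds the numeric design matrices used downstream. Categorical risk
#' factors may be supplied as factors or character vectors; they are one-hot
#' encoded (first level as reference) in the mean model, while the full
#' factor drives group-wise variance estimation and the kernel encoding.
#'
#' @param Y numeric matrix, samples in rows and genes in columns
#'   (approximately normal scale, e.g. logCPM or `log2(count + offset)`).
#'   At least two genes are required.
#' @param X risk factor(s): a vector, factor, matrix, or data frame with one
#'   column per factor. Factor/character columns are treated as categorical;
#'   numeric columns as continuous/discrete.
#' @param C optional covariate matrix (samples in rows).
#' @param M optional batch-variable matrix (samples in rows).
#' @return An object of class `"kdca_design"`: a list with elements `Y`,
#'   `x_df` (risk factors as a data frame), `X_mean` (numeric encoding used
#'   in the mean model), `X_kernel` (full one-hot encoding used for the
#'   risk-factor kernel), `C`, `M`, and `D` (the column-augmented design
#'   `[1, X, C, M]`).
#' @export
design_inputs <- function(Y, X, C = NULL, M = NULL) {
  Y <- .as_matrix(Y, what = "Y")
  n <- nrow(Y)
  if (ncol(Y) < 2L) stop("Y must contain at least two genes (r >= 2)")
  .check_no_na(Y, "Y")

  x_df <- .risk_factor_frame(X, n)
  C <- .as_matrix(C, n = n, what = "C")
  M <- .as_matrix(M, n = n, what = "M")
  if (nrow(C) != n || nrow(M) != n) {
    stop("Y, X, C, and M must share the same number of rows")
  }
  .check_no_na(C, "C"); .check_no_na(M, "M")

  for (nm in names(x_df)) {
    x <- x_df[[nm]]
    if (is.factor(x)) {
      tab <- table(x)
      if (length(tab) < 2L) {
        stop("categorical risk factor '", nm, "' must have at least 2 levels")
      }
      if (any(tab < 2L)) {
        stop("categorical risk factor '", nm, "' has levels with fewer than ",
             "2 samples: ", paste(names(tab)[tab < 2L], collapse = ", "))
      }
    }
  }

  X_mean <- .encode_risk_factors(x_df, drop_first = TRUE)
  X_kernel <- .encode_risk_factors(x_df, drop_first = FALSE)

  D <- cbind(`(Intercept)` = 1, X_mean, C, M)
  if (n <= ncol(D)) {
    stop("sample size (", n, ") must exceed the number of design columns (",
         ncol(D), ")")
  }
  qrd <- qr(D)
  if (qrd$rank < ncol(D)) {
    bad <- colnames(D)[qrd$pivot[(qrd$rank + 1L):ncol(D)]]
    stop("mean-model design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }

  structure(list(Y = Y, x_df = x_df, X_mean = X_mean, X_kernel = X_kernel,
                 C = C, M = M, D = D, qr = qrd, n = n, r = ncol(Y)),
            class = "kdca_design")
}

# risk factors as a data frame with declared types
.risk_factor_frame <- function(X, n) {
  if (is.null(X)) stop("a risk factor X is required")
  if (is.factor(X) || is.character(X)) X <- data.frame(X = factor(X))
  if (is.vector(X) && is.numeric(X)) X <- data.frame(X = X)
  if (is.matrix(X)) X <- as.data.frame(X)
  if (!is.data.frame(X)) stop("X must be a vector, factor, matrix, or data frame")
  if (nrow(X) != n) stop("X must have the same number of rows as Y")
  if (is.null(names(X)) || any(names(X) == "")) {
    names(X) <- paste0("X", seq_along(X))
  }
  for (nm in names(X)) {
    if (is.character(X[[nm]]) || is.logical(X[[nm]])) X[[nm]] <- factor(X[[nm]])
    if (anyNA(X[[nm]])) stop("missing values are not allowed in X")
  }
  X
}

# numeric encoding of the risk-factor frame; categorical columns one-hot
.encode_risk_factors <- function(x_df, drop_first = TRUE) {
  cols <- lapply(names(x_df), function(nm) {
    x <- x_df[[nm]]
    if (is.factor(x)) {
      lev <- levels(x)
      keep <- if (drop_first) lev[-1L] else lev
      m <- sapply(keep, function(l) as.numeric(x == l))
      m <- matrix(m, nrow = length(x))
      colnames(m) <- paste0(nm, ".", keep)
      m
    } else {
      m <- matrix(as.numeric(x), ncol = 1)
      colnames(m) <- nm
      m
    }
  })
  do.call(cbind, cols)
}

#' Fit the per-gene mean model by least squares
#'
#' Regresses each gene on the intercept, risk factor(s), covariates, and
#' batch variables, returning raw residuals and fitted coefficients. The
#' conditional standard deviations are left unfilled until a variance
#' estimator ([estimate_variance_groupwise()], [fit_double_glm()], or the
#' pooled fallback) is applied.
#'
#' @param design a `"kdca_design"` from [design_inputs()].
#' @return An object of class `"kdca_residuals"`: list with `e` (raw
#'   residuals), `fitted`, `mean_coef` (design columns x genes), `s` (NULL
#'   until filled), `e_std` (NULL), `variance_model`, and the `design`.
#' @export
fit_mean_model <- function(design) {
  stopifnot(inherits(design, "kdca_design"))
  qrd <- design$qr
  coef <- qr.coef(qrd, design$Y)
  fitted <- qr.fitted(qrd, design$Y)
  e <- design$Y - fitted
  structure(list(e = e, fitted = fitted, mean_coef = coef,
                 s = NULL, e_std = NULL,
                 variance_model = list(mode = NULL),
                 design = design),
            class = "kdca_residuals")
}

#' Estimate conditional variances within risk-factor groups
#'
#' For a categorical risk factor, estimates the conditional variance of each
#' gene separately within each level of the factor, using the unbiased
#' (n_g - 1) denominator, and fills the per-sample conditional standard
#' deviations.
#'
#' @param residuals a `"kdca_residuals"` with `e` filled.
#' @param x_cat name of the categorical risk-factor column to group by;
#'   defaults to the single categorical column of the design.
#' @return The residual set with `s` filled and
#'   `variance_model$mode == "groupwise"`.
#' @export
estimate_variance_groupwise <- function(residuals, x_cat = NULL) {
  stopifnot(inherits(residuals, "kdca_residuals"))
  x_df <- residuals$design$x_df
  if (is.null(x_cat)) {
    cat_cols <- names(x_df)[vapply(x_df, is.factor, logical(1))]
    if (length(cat_cols) != 1L) {
      stop("x_cat must be given when the design does not have exactly one ",
           "categorical risk factor")
    }
    x_cat <- cat_cols
  }
  g <- x_df[[x_cat]]
  if (is.null(g) || !is.factor(g)) {
    stop("'", x_cat, "' is not a categorical risk-factor column")
  }
  tab <- table(g)
  if (any(tab < 2L)) {
    stop("group-wise variance needs >= 2 samples per level; offending: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  e <- residuals$e
  s2 <- matrix(NA_real_, nrow(e), ncol(e), dimnames = dimnames(e))
  for (lev in levels(g)) {
    idx <- which(g == lev)
    v <- apply(e[idx, , drop = FALSE], 2L, var)
    if (any(v <= 0)) {
      k <- which(v <= 0)[1L]
      stop("zero within-group residual variance for gene ",
           colnames(e)[k] %||% k, " in group '", lev, "'")
    }
    s2[idx, ] <- rep(v, each = length(idx))
  }
  residuals$s <- sqrt(s2)
  residuals$variance_model <- list(mode = "groupwise", group = g,
                                   by = x_cat, converged = TRUE)
  residuals
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Joint mean/variance fit by a double generalized linear model
#'
#' For continuous or discrete risk factors, models the conditional variance
#' of each gene as log-linear in the variance covariates. The fit iterates
#' (i) weighted least squares for the mean model with weights equal to the
#' inverse fitted variances and (ii) a gamma GLM with log link regressing the
#' squared residuals on `[1, variance covariates]`, until the relative change
#' in the gamma deviance falls below `tol` or `max_iter` is reached. The
#' first mean fit uses unit weights, so a one-iteration run reproduces the
#' ordinary-least-squares residuals.
#'
#' @param design a `"kdca_design"`.
#' @param variance_covariates matrix of covariates for the variance model
#'   (samples in rows). Defaults to the numeric encoding of the risk
#'   factor(s); columns of `C`/`M` may be appended by the caller.
#' @param max_iter maximum outer iterations (default 25).
#' @param tol relative gamma-deviance tolerance (default 1e-6).
#' @return A `"kdca_residuals"` with `e` and `s` filled,
#'   `variance_model$mode == "dglm"`, per-gene variance coefficients in
#'   `variance_model$coef`, and a per-gene convergence flag.
#' @export
fit_double_glm <- function(design, variance_covariates = NULL,
                           max_iter = 25L, tol = 1e-6) {
  stopifnot(inherits(design, "kdca_design"))
  if (is.null(variance_covariates)) variance_covariates <- design$X_mean
  Vc <- .as_matrix(variance_covariates, n = design$n, what = "variance_covariates")
  if (nrow(Vc) != design$n) stop("variance_covariates must have n rows")
  Xv <- cbind(`(Intercept)` = 1, Vc)
  if (qr(Xv)$rank < ncol(Xv)) stop("variance-model design is rank deficient")
  Pv <- solve(crossprod(Xv), t(Xv))

  D <- design$D
  Y <- design$Y
  r <- ncol(Y)
  e <- fitted <- matrix(0, design$n, r, dimnames = dimnames(Y))
  s2 <- matrix(0, design$n, r, dimnames = dimnames(Y))
  coef <- matrix(0, ncol(D), r, dimnames = list(colnames(D), colnames(Y)))
  vcoef <- matrix(0, ncol(Xv), r, dimnames = list(colnames(Xv), colnames(Y)))
  conv <- logical(r)
  for (k in seq_len(r)) {
    fk <- .dglm_gene(Y[, k], D, Xv, Pv, max_iter = max_iter, tol = tol)
    e[, k] <- fk$e
    fitted[, k] <- Y[, k] - fk$e
    s2[, k] <- fk$s2
    coef[, k] <- fk$coef
    vcoef[, k] <- fk$gamma
    conv[k] <- fk$converged
  }
  if (!all(conv)) {
    warning("double GLM did not converge for ", sum(!conv), " gene(s); ",
            "last iterate returned")
  }
  res <- fit_mean_model(design)
  res$e <- e
  res$fitted <- fitted
  res$mean_coef <- coef
  res$s <- sqrt(s2)
  res$variance_model <- list(mode = "dglm", coef = vcoef, converged = conv,
                             Xv = Xv)
  res
}

# gamma deviance with the standard guard at y == 0
.gamma_deviance <- function(y, mu) {
  r <- ifelse(y == 0, 1, y / mu)
  2 * sum((y - mu) / mu - log(r))
}

# IRLS for a gamma GLM with log link; the working weights are identically 1,
# so each update is an unweighted least-squares solve with the fixed design
.gamma_irls <- function(y2, Xv, Pv, eta, max_iter = 25L, tol = 1e-8) {
  dev_old <- Inf
  gam <- NULL
  dev <- NA_real_
  for (it in seq_len(max_iter)) {
    mu <- exp(eta)
    z <- eta + (y2 - mu) / mu
    gam <- drop(Pv %*% z)
    eta <- drop(Xv %*% gam)
    dev <- .gamma_deviance(y2, exp(eta))
    if (is.finite(dev_old) &&
        abs(dev - dev_old) / (abs(dev) + 0.1) < tol) break
    dev_old <- dev
  }
  list(gamma = gam, eta = eta, deviance = dev)
}

.dglm_gene <- function(y, D, Xv, Pv, max_iter = 25L, tol = 1e-6) {
  n <- length(y)
  w <- rep(1, n)
  eta <- NULL
  dev_old <- Inf
  converged <- FALSE
  beta <- NULL; e <- NULL; g <- NULL
  for (it in seq_len(max_iter)) {
    Dw <- D * w
    beta <- solve(crossprod(Dw, D), crossprod(Dw, y))
    e <- y - drop(D %*% beta)
    y2 <- e^2
    if (is.null(eta)) eta <- rep(log(mean(y2)), n)
    g <- .gamma_irls(y2, Xv, Pv, eta)
    eta <- g$eta
    w <- exp(-eta)
    if (is.finite(dev_old) &&
        abs(g$deviance - dev_old) / (abs(g$deviance) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- g$deviance
  }
  list(coef = drop(beta), e = e, s2 = exp(eta), gamma = g$gamma,
       converged = converged, iterations = it)
}

#' Pooled (constant) variance estimate per gene
#'
#' Single conditional variance per gene, for users certain the design has no
#' variance-specific effects. Disabling variance adjustment this way is
#' anticonservative when the risk factor does influence expression variance.
#'
#' @param residuals a `"kdca_residuals"` with `e` filled.
#' @return The residual set with `s` filled (constant per gene).
#' @export
estimate_variance_constant <- function(residuals) {
  stopifnot(inherits(residuals, "kdca_residuals"))
  v <- apply(residuals$e, 2L, var)
  if (any(v <= 0)) stop("zero residual variance for gene ", which(v <= 0)[1L])
  residuals$s <- matrix(sqrt(v), nrow(residuals$e), ncol(residuals$e),
                        byrow = TRUE)
  residuals$variance_model <- list(mode = "constant", converged = TRUE)
  residuals
}

#' Standardize residuals by their conditional standard deviations
#'
#' Divides each raw residual by its estimated conditional standard deviation.
#' Removing the variance effects of the risk factor this way is what shields
#' the downstream co-expression test from false discoveries driven by
#' variance-specific (rather than correlation-specific) effects.
#'
#' @param residuals a `"kdca_residuals"` with `e` and `s` filled.
#' @return The residual set with `e_std = e / s` filled.
#' @export
standardize <- function(residuals) {
  stopifnot(inherits(residuals, "kdca_residuals"))
  if (is.null(residuals$s)) stop("conditional standard deviations not filled")
  if (any(residuals$s <= 0)) stop("conditional standard deviations must be > 0")
  residuals$e_std <- residuals$e / residuals$s
  residuals
}

#' Residualize a pathway (mean fit, variance fit, standardization)
#'
#' Convenience orchestrator: mean model by least squares (or inside the
#' double GLM), conditional variances by the requested mode, then
#' standardization. Mode `"auto"` picks `"groupwise"` when every risk-factor
#' column is categorical and `"dglm"` otherwise.
#'
#' @inheritParams fit_double_glm
#' @param variance one of `"auto"`, `"groupwise"`, `"dglm"`, `"constant"`.
#' @param x_cat group column for `"groupwise"` (see
#'   [estimate_variance_groupwise()]).
#' @return A standardized `"kdca_residuals"`.
#' @export
residualize <- function(design,
                        variance = c("auto", "groupwise", "dglm", "constant"),
                        variance_covariates = NULL, x_cat = NULL,
                        max_iter = 25L, tol = 1e-6) {
  variance <- match.arg(variance)
  if (variance == "auto") {
    all_cat <- all(vapply(design$x_df, is.factor, logical(1)))
    variance <- if (all_cat) "groupwise" else "dglm"
  }
  res <- switch(variance,
    groupwise = estimate_variance_groupwise(fit_mean_model(design), x_cat),
    constant = estimate_variance_constant(fit_mean_model(design)),
    dglm = fit_double_glm(design, variance_covariates,
                          max_iter = max_iter, tol = tol))
  standardize(res)
}
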