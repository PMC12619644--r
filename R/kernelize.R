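#' Cross products of standardized residuals (individual-specific correlations)
#'
#' For each sample, multiplies the standardized residuals of every pair of
#' genes, giving a per-sample estimate of that pair's correlation. Pairs are
#' ordered lexicographically in (k, k') with k < k', so a pathway of r genes
#' yields q = r(r-1)/2 columns.
#'
#' @param e_std numeric matrix of standardized residuals (samples x genes),
#'   or a `"kdca_residuals"` with `e_std` filled.
#' @return An object of class `"kdca_crossprod"`: list with `Z` (n x q
#'   matrix) and `pair_index` (q x 2 integer matrix of gene indices).
#' @export
cross_products <- function(e_std) {
  if (inherits(e_std, "kdca_residuals")) e_std <- e_std$e_std
  e_std <- .as_matrix(e_std, what = "e_std")
  r <- ncol(e_std)
  if (r < 2L) stop("at least two genes are required to form cross products")
  pairs <- t(combn(r, 2L))
  Z <- e_std[, pairs[, 1L], drop = FALSE] * e_std[, pairs[, 2L], drop = FALSE]
  colnames(Z) <- paste0(pairs[, 1L], ":", pairs[, 2L])
  structure(list(Z = Z, pair_index = pairs), class = "kdca_crossprod")
}

#' Center the columns of a cross-product matrix
#'
#' Mean-centers each column. Centering one side makes the linear-kernel
#' trace statistic equal the standard HSIC numerator; the permutation null
#' is computed under the identical transformation, so validity is
#' unaffected.
#'
#' @param Z a `"kdca_crossprod"` or plain numeric matrix.
#' @return Same type as the input, columns centered.
#' @export
center_columns <- function(Z) {
  if (inherits(Z, "kdca_crossprod")) {
    Z$Z <- sweep(Z$Z, 2L, colMeans(Z$Z))
    return(Z)
  }
  sweep(Z, 2L, colMeans(Z))
}

.kernel_input <- function(Z) {
  if (inherits(Z, "kdca_crossprod")) Z$Z else .as_matrix(Z, what = "Z")
}

.kernel_matrix <- function(K, name, source, spec = list()) {
  structure(K, class = c("kdca_kernel", class(K)),
            kernel = name, source = source, spec = spec)
}

#' Linear kernel for cross products
#'
#' Similarity of two samples as the inner product of their (column-centered)
#' cross-product rows: `K = Z Z'`, a scaled covariance.
#'
#' @param Z column-centered cross products (`"kdca_crossprod"` or matrix).
#' @return n x n kernel matrix of class `"kdca_kernel"`.
#' @export
linear_kernel <- function(Z) {
  Zm <- .kernel_input(Z)
  .kernel_matrix(tcrossprod(Zm), "linear", "Z")
}

#' Projection kernel for cross products
#'
#' `K = U U'` where `U` holds the left singular vectors of the centered
#' cross-product matrix whose singular values exceed `tol` times the largest
#' one. `K` is the orthogonal projector onto the retained column space and
#' weighs every retained direction equally.
#'
#' @inheritParams linear_kernel
#' @param tol relative singular-value threshold (default 1e-8).
#' @return n x n idempotent kernel matrix of class `"kdca_kernel"`.
#' @export
projection_kernel <- function(Z, tol = 1e-8) {
  Zm <- .kernel_input(Z)
  sv <- svd(Zm)
  if (sv$d[1L] <= 0 || all(sv$d <= tol * sv$d[1L])) {
    stop("degenerate cross-product matrix: no singular value above threshold")
  }
  keep <- sv$d > tol * sv$d[1L]
  U <- sv$u[, keep, drop = FALSE]
  .kernel_matrix(tcrossprod(U), "projection", "Z", list(tol = tol,
                                                        rank = sum(keep)))
}

#' Gaussian kernel for cross products
#'
#' Non-linear co-expression similarity between two samples' cross-product
#' rows. The default `"rbf"` form is the radial basis kernel on the squared
#' Euclidean distance, `K[j, j'] = exp(-nu * ||Z_j - Z_j'||^2)`, which is
#' positive semidefinite and whose trace statistic grows under differential
#' co-expression. The `"inner-product"` form,
#' `K[j, j'] = exp(-nu * (Z_j . Z_j')^2)`, squares the inner product
#' instead of the distance; it is retained for comparison but is not
#' positive semidefinite and has essentially no power under the one-sided
#' permutation test (see the methods vignette).
#'
#' @inheritParams linear_kernel
#' @param nu positive tuning parameter; the default 1e-4 is a fixed choice
#'   that works well across pathway architectures (no data-adaptive
#'   bandwidth is used).
#' @param form `"rbf"` (default) or `"inner-product"`.
#' @return n x n kernel matrix of class `"kdca_kernel"`, entries in (0, 1].
#' @export
gaussian_kernel <- function(Z, nu = 1e-4, form = c("rbf", "inner-product")) {
  if (nu <= 0) stop("nu must be positive")
  form <- match.arg(form)
  Zm <- .kernel_input(Z)
  G <- tcrossprod(Zm)
  K <- if (form == "rbf") {
    d <- diag(G)
    exp(-nu * pmax(outer(d, d, `+`) - 2 * G, 0))
  } else {
    exp(-nu * G^2)
  }
  .kernel_matrix(K, "gaussian", "Z", list(nu = nu, form = form))
}

#' Encode risk factors for kernel construction
#'
#' One-hot encodes categorical columns (all levels), then centers every
#' column and scales it to unit population variance (denominator n). The
#' scaling makes the trace statistic comparable across risk-factor
#' encodings.
#'
#' @param X risk factor(s) as accepted by [design_inputs()], or a
#'   `"kdca_design"`.
#' @return n x L numeric matrix of centered, scaled risk-factor columns.
#' @export
encode_risk_factor <- function(X) {
  onehot <- inherits(X, "kdca_design") || is.data.frame(X) ||
    is.factor(X) || is.character(X)
  Xenc <- if (inherits(X, "kdca_design")) {
    X$X_kernel
  } else if (onehot) {
    .encode_risk_factors(.risk_factor_frame(X, NROW(X)), drop_first = FALSE)
  } else {
    .as_matrix(X, what = "X")
  }
  cols <- lapply(seq_len(ncol(Xenc)), function(i) .scale_unit(Xenc[, i]))
  bad <- vapply(cols, is.null, logical(1))
  if (all(bad) || (any(bad) && !onehot)) {
    stop("risk factor column constant after centering: ",
         paste(colnames(Xenc)[bad], collapse = ", "))
  }
  Xc <- do.call(cbind, cols[!bad])
  colnames(Xc) <- colnames(Xenc)[!bad]
  Xc
}

#' Linear kernel for the risk factor(s)
#'
#' `K_X = X X'` on the centered, unit-variance-scaled risk-factor columns;
#' with several risk factors the kernel is the sum of the single-factor
#' kernels.
#'
#' @inheritParams encode_risk_factor
#' @return n x n kernel matrix of class `"kdca_kernel"`.
#' @export
risk_factor_kernel <- function(X) {
  if (is.numeric(X) && is.vector(X) && length(unique(X)) == 1L) {
    stop("risk factor is constant after centering")
  }
  Xc <- encode_risk_factor(X)
  .kernel_matrix(tcrossprod(Xc), "linear", "X")
}
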