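#' @useDynLib kerndca, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd rnorm runif rbinom rnbinom rmultinom pgamma p.adjust
#' @importFrom utils read.delim write.table combn
NULL

# coerce to a numeric matrix, keeping dimnames; NULL allowed -> n x 0
.as_matrix <- function(x, n = NULL, what = "matrix") {
  if (is.null(x)) {
    if (is.null(n)) stop("cannot build empty ", what, " without row count")
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(what, " must be a numeric matrix, data frame, or vector")
  }
  storage.mode(x) <- "double"
  x
}

.check_no_na <- function(x, what) {
  if (anyNA(x)) stop("missing values are not allowed in ", what)
  invisible(x)
}

# deterministic sub-seed from a master seed and a pathway name, so that
# adding or removing pathways never changes another pathway's p-values
pathway_seed <- function(seed, name) {
  stopifnot(length(name) == 1L)
  h <- as.double(as.integer(seed) %% 2147483647)
  for (ch in utf8ToInt(as.character(name))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

# population-variance column scale (see risk_factor_kernel docs)
.scale_unit <- function(x) {
  xc <- x - mean(x)
  s <- sqrt(mean(xc^2))
  if (s < .Machine$double.eps^0.5) return(NULL)
  xc / s
}
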