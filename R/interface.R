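#' Read an expression matrix from TSV
#'
#' Expects samples in rows and genes in columns: a header row of gene
#' identifiers and a first column of sample IDs.
#'
#' @param path file path.
#' @return Numeric matrix with sample IDs as row names.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample IDs in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()].
#'
#' @param Y matrix, samples in rows.
#' @param path file path.
#' @export
write_expression <- function(Y, path) {
  df <- data.frame(sample_id = rownames(Y) %||% paste0("s", seq_len(nrow(Y))),
                   Y, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample table with declared column roles
#'
#' The table is TSV keyed by sample ID (first column). `config` declares
#' the role of each used column (`risk_factor`, `covariate`, `batch`) and
#' the type of each risk factor (`continuous` or `categorical`).
#'
#' @param path file path.
#' @param config list with character vectors `risk_factor`, optionally
#'   `covariate` and `batch`, and an optional named vector `types` mapping
#'   risk-factor columns to `"continuous"`/`"categorical"` (default:
#'   non-numeric columns are categorical).
#' @return A list of class `"kdca_samples"`: `samples` (data frame with
#'   sample IDs as row names) and `roles` (the validated config).
#' @export
read_samples <- function(path, config) {
  if (is.null(config$risk_factor)) stop("config$risk_factor is required")
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample IDs in ", path)
  df <- df[, -1L, drop = FALSE]
  rownames(df) <- ids
  used <- c(config$risk_factor, config$covariate, config$batch)
  missing_cols <- setdiff(used, names(df))
  if (length(missing_cols)) {
    stop("sample table lacks declared columns: ",
         paste(missing_cols, collapse = ", "))
  }
  for (nm in config$risk_factor) {
    type <- config$types[nm] %||% NA_character_
    if (identical(unname(type), "categorical") || !is.numeric(df[[nm]])) {
      df[[nm]] <- factor(df[[nm]])
    }
  }
  structure(list(samples = df, roles = config), class = "kdca_samples")
}

#' Read gene sets from a GMT file
#'
#' One pathway per line: name, description, then member genes, tab
#' separated. Duplicate genes within a pathway are removed with a warning;
#' pathways smaller than `min_size` are excluded.
#'
#' @param path file path.
#' @param min_size minimum pathway size kept (default 5, matching the usual
#'   filtering of small canonical pathways).
#' @return A named list of class `"kdca_pathways"` mapping pathway name to
#'   a character vector of gene identifiers; excluded pathway names are in
#'   `attr(, "excluded")`.
#' @export
read_gmt <- function(path, min_size = 5L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  excluded <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(ln, 1, 60))
    name <- parts[1L]
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in pathway '", name, "' removed")
      genes <- unique(genes)
    }
    if (length(genes) < min_size) {
      excluded <- c(excluded, name)
      next
    }
    sets[[name]] <- genes
  }
  structure(sets, class = "kdca_pathways", excluded = excluded,
            min_size = min_size)
}

#' Log-transform counts and derive the library-size covariate
#'
#' `log2(count + offset)` with the log of each sample's total count
#' returned as a fixed covariate for the mean model.
#'
#' @param counts non-negative integer matrix, samples in rows.
#' @param offset pseudo-count added before the log (default 2).
#' @return List with `expression` (transformed matrix) and `log_lib`
#'   (length-n numeric vector of log library sizes).
#' @export
transform_counts <- function(counts, offset = 2) {
  counts <- .as_matrix(counts, what = "counts")
  if (any(counts < 0)) stop("counts must be non-negative")
  list(expression = log2(counts + offset),
       log_lib = log(rowSums(counts)))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate control via [stats::p.adjust()]. A Storey
#' null-proportion estimate (fixed lambda = 0.5) can be applied on top for
#' a less conservative q-value.
#'
#' @param p vector of p-values.
#' @param method `"BH"` (default) or `"storey"`.
#' @return Monotone q-values.
#' @export
bh_fdr <- function(p, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  if (method == "storey") {
    lambda <- 0.5
    pi0 <- min(1, mean(p > lambda, na.rm = TRUE) / (1 - lambda))
    q <- pmin(1, q * pi0)
  }
  q
}

#' Run a differential co-expression study across pathways
#'
#' Iterates the pathway list, runs [kdca_test()] (and the eigengene
#' baseline if requested) on the genes of each pathway present in the
#' expression matrix, and assembles a result table with
#' Benjamini-Hochberg q-values on the combined p-values. Each pathway uses
#' a deterministic sub-seed derived from the master seed and the pathway
#' name, so adding or removing pathways never changes other pathways'
#' p-values. Per-pathway failures are recorded and the run continues.
#'
#' @param expression numeric matrix, samples in rows, genes in columns.
#' @param samples a `"kdca_samples"` object from [read_samples()], or a
#'   data frame with sample IDs as row names plus a `roles` list passed via
#'   `roles`.
#' @param pathways a `"kdca_pathways"` list (or any named list of gene-ID
#'   vectors).
#' @param roles column roles when `samples` is a plain data frame.
#' @inheritParams kdca_test
#' @param alpha significance level used for the permutation-count warning:
#'   testing R pathways at level alpha needs at least `R / alpha`
#'   permutations.
#' @param verbose emit one log line per pathway to `stderr`.
#' @return A data frame of class `"kdca_results"`, one row per pathway:
#'   name, size, tested size, per-kernel p-values, combined p-value,
#'   optional eigengene p-value, BH q-value, convergence flag, and status.
#' @export
run_study <- function(expression, samples, pathways, roles = NULL,
                      kernels = c("linear", "projection", "gaussian"),
                      variance = c("auto", "groupwise", "dglm", "constant"),
                      B = 1000L, seed = 1L, nu = 1e-4, eigengene = FALSE,
                      engine = c("cpp", "r"), alpha = 0.05,
                      verbose = FALSE) {
  variance <- match.arg(variance)
  engine <- match.arg(engine)
  if (inherits(samples, "kdca_samples")) {
    roles <- samples$roles
    samples <- samples$samples
  }
  if (is.null(roles) || is.null(roles$risk_factor)) {
    stop("column roles with at least one risk_factor are required")
  }
  ids_expr <- rownames(expression)
  ids_samp <- rownames(samples)
  if (!setequal(ids_expr, ids_samp)) {
    off <- c(setdiff(ids_expr, ids_samp), setdiff(ids_samp, ids_expr))
    stop("sample-ID mismatch between expression and sample table: ",
         paste(utils::head(off, 10L), collapse = ", "))
  }
  samples <- samples[ids_expr, , drop = FALSE]
  X <- samples[, roles$risk_factor, drop = FALSE]
  C <- if (length(roles$covariate)) {
    .as_matrix(samples[, roles$covariate, drop = FALSE], what = "C")
  } else NULL
  M <- if (length(roles$batch)) {
    .as_matrix(samples[, roles$batch, drop = FALSE], what = "M")
  } else NULL

  R <- length(pathways)
  if (B < R / alpha) {
    warning("B = ", B, " permutations is below the minimum R/alpha = ",
            ceiling(R / alpha), " needed to control the type I error over ",
            R, " pathways at level ", alpha)
  }

  rows <- vector("list", R)
  for (i in seq_len(R)) {
    name <- names(pathways)[i] %||% paste0("pathway", i)
    genes <- unique(pathways[[i]])
    present <- intersect(genes, colnames(expression))
    dropped <- length(genes) - length(present)
    row <- list(pathway = name, size = length(genes),
                tested_size = length(present))
    if (length(present) < 2L) {
      row$status <- "skipped: fewer than 2 genes present"
      rows[[i]] <- row
      if (verbose) message(name, ": ", row$status)
      next
    }
    sub_seed <- pathway_seed(seed, name)
    t0 <- proc.time()[["elapsed"]]
    fit <- tryCatch(
      kdca_test(expression[, present, drop = FALSE], X, C, M,
                kernels = kernels, variance = variance, B = B,
                seed = sub_seed, nu = nu, eigengene = eigengene,
                engine = engine),
      error = function(e) e)
    if (inherits(fit, "error")) {
      row$status <- paste0("error: ", conditionMessage(fit))
      rows[[i]] <- row
      if (verbose) message(name, ": ", row$status)
      next
    }
    for (kn in names(fit$per_kernel)) {
      row[[paste0("p_", kn)]] <- unname(fit$per_kernel[[kn]])
    }
    row$p_combined <- fit$p_combined
    if (eigengene) row$p_eigengene <- fit$eigengene$p_empirical
    row$converged <- fit$diagnostics$variance_converged
    row$status <- "ok"
    rows[[i]] <- row
    if (verbose) {
      message(sprintf("%s: tested_size=%d p_combined=%.4g (%.2fs)", name,
                      length(present), fit$p_combined,
                      proc.time()[["elapsed"]] - t0))
    }
  }

  all_names <- unique(unlist(lapply(rows, names)))
  tab <- do.call(rbind, lapply(rows, function(r) {
    r <- r[all_names]
    names(r) <- all_names
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v))
  }))
  tab$q_combined <- NA_real_
  ok <- tab$status == "ok"
  tab$q_combined[ok] <- bh_fdr(tab$p_combined[ok])
  class(tab) <- c("kdca_results", "data.frame")
  tab
}

#' Write a result table to TSV
#'
#' @param results a `"kdca_results"` data frame.
#' @param path file path.
#' @export
write_results <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated pathway to the study file formats
#'
#' Emits the same TSV expression and sample-table formats the readers
#' accept, plus a truth-label TSV (per-gene differential co-expression
#' indicator and per-pair signed effect), so simulations double as
#' end-to-end fixtures.
#'
#' @param sim a `"kdca_sim"` from [simulate_mvn_pathway()].
#' @param prefix output path prefix; writes `<prefix>expression.tsv`,
#'   `<prefix>samples.tsv`, `<prefix>truth_genes.tsv`,
#'   `<prefix>truth_pairs.tsv`.
#' @return Invisibly, the vector of written paths.
#' @export
write_simulation <- function(sim, prefix) {
  stopifnot(inherits(sim, "kdca_sim"))
  n <- nrow(sim$Y)
  ids <- paste0("s", seq_len(n))
  Y <- sim$Y
  rownames(Y) <- ids
  paths <- paste0(prefix, c("expression.tsv", "samples.tsv",
                            "truth_genes.tsv", "truth_pairs.tsv"))
  write_expression(Y, paths[1L])
  Xdf <- if (is.matrix(sim$X)) as.data.frame(sim$X) else data.frame(X = sim$X)
  samp <- data.frame(sample_id = ids, Xdf, C = sim$C, check.names = FALSE)
  write.table(samp, paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$genes, paths[3L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth$pairs, paths[4L], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
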