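#' Expression set container
#'
#' A lightweight container pairing a genes x libraries count matrix with its
#' sample sheet and, after normalization, log2-cpm values, voom precision
#' weights and TMM normalization factors.
#'
#' @param counts non-negative integer matrix, genes x libraries, with
#'   rownames (gene ids) and colnames (library ids).
#' @param samples `data.frame` with one row per library (in column order of
#'   `counts`) and columns `library_id`, `individual`, `assay` (`"rna"` or
#'   `"ribo"`), `replicate`.
#' @return An object of class `expr_set`.
#' @export
expr_set <- function(counts, samples) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)),
            all(c("library_id", "individual", "assay", "replicate") %in%
                  names(samples)),
            nrow(samples) == ncol(counts),
            identical(as.character(samples$library_id), colnames(counts)),
            all(samples$assay %in% c("rna", "ribo")))
  samples$lib_size <- colSums(counts)
  structure(list(counts = counts, samples = samples,
                 logcpm = NULL, weights = NULL, norm_factors = NULL),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$counts), "genes x", ncol(x$counts), "libraries (",
      sum(x$samples$assay == "rna"), "rna /",
      sum(x$samples$assay == "ribo"), "ribo );",
      if (is.null(x$logcpm)) "raw counts" else "voom-transformed", "\n")
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$counts)

#' Subset an expression set by gene and/or library
#' @param x an `expr_set`.
#' @param genes,libraries index vectors (logical, integer or names).
#' @return A subsetted `expr_set`.
#' @export
subset_expr <- function(x, genes = NULL, libraries = NULL) {
  if (is.null(genes)) genes <- seq_len(nrow(x$counts))
  if (is.null(libraries)) libraries <- seq_len(ncol(x$counts))
  for (slot in c("counts", "logcpm", "weights"))
    if (!is.null(x[[slot]])) x[[slot]] <- x[[slot]][genes, libraries, drop = FALSE]
  if (!is.null(x$norm_factors)) x$norm_factors <- x$norm_factors[libraries]
  x$samples <- x$samples[libraries, , drop = FALSE]
  x
}

#' Expression filter on counts-per-million
#'
#' Keeps genes with cpm above `min_cpm` in at least `min_libraries_rna`
#' RNA-seq libraries AND at least `min_libraries_ribo` ribosome profiling
#' libraries. The defaults require ~90% of the libraries of each assay,
#' mirroring study-scale absolute thresholds proportionally.
#'
#' @param expr an [expr_set()].
#' @param min_cpm cpm threshold (default 1).
#' @param min_libraries_rna,min_libraries_ribo required library counts;
#'   `NULL` means `ceiling(0.9 * n_libraries)` for that assay.
#' @return The filtered `expr_set`, with attribute `"filter_report"` holding
#'   kept/dropped gene counts.
#' @export
cpm_filter <- function(expr, min_cpm = 1,
                       min_libraries_rna = NULL, min_libraries_ribo = NULL) {
  is_rna <- expr$samples$assay == "rna"
  n_rna <- sum(is_rna); n_ribo <- sum(!is_rna)
  if (is.null(min_libraries_rna)) min_libraries_rna <- ceiling(0.9 * n_rna)
  if (is.null(min_libraries_ribo)) min_libraries_ribo <- ceiling(0.9 * n_ribo)
  if (min_libraries_rna > n_rna || min_libraries_ribo > n_ribo)
    stop("library-count threshold exceeds the number of libraries")
  cpm <- edgeR::cpm(expr$counts)
  keep <- rowSums(cpm[, is_rna, drop = FALSE] > min_cpm) >= min_libraries_rna &
    rowSums(cpm[, !is_rna, drop = FALSE] > min_cpm) >= min_libraries_ribo
  out <- subset_expr(expr, genes = keep)
  attr(out, "filter_report") <- c(kept = sum(keep), dropped = sum(!keep))
  out
}

#' Trimmed mean of M-values normalization factors
#'
#' Between-library scaling factors computed by the TMM method (via edgeR):
#' the reference library is the one whose 75th-percentile cpm is closest to
#' the mean of those; each library's factor is 2^(weighted mean of M-values
#' doubly trimmed on M and A, weights = inverse asymptotic binomial
#' variances), rescaled so the factors have geometric mean 1. RNA and ribo
#' libraries are pooled into a single reference pool by default because
#' translation efficiency contrasts the two assays.
#'
#' @param expr an [expr_set()].
#' @param trim_M,trim_A trim fractions for M and A values (defaults 0.30 /
#'   0.05).
#' @param per_assay if `TRUE`, compute factors separately within each assay.
#' @return The `expr_set` with `norm_factors` filled.
#' @export
tmm_factors <- function(expr, trim_M = 0.30, trim_A = 0.05,
                        per_assay = FALSE) {
  if (any(colSums(expr$counts) == 0)) stop("all-zero library")
  calc <- function(m) edgeR::calcNormFactors(m, method = "TMM",
                                             logratioTrim = trim_M,
                                             sumTrim = trim_A)
  if (per_assay) {
    nf <- numeric(ncol(expr$counts))
    for (a in unique(expr$samples$assay)) {
      idx <- expr$samples$assay == a
      nf[idx] <- calc(expr$counts[, idx, drop = FALSE])
    }
  } else {
    nf <- calc(expr$counts)
  }
  expr$norm_factors <- unname(nf)
  expr
}

#' voom transformation: log2-cpm and precision weights
#'
#' Computes `logcpm = log2((count + 0.5) / (lib_size * factor + 1) * 1e6)`
#' and observation-level inverse-variance weights from the fitted
#' mean-variance trend (lowess of sqrt residual sd against mean log2-count,
#' weights = trend^-4), with the individual identifier in the design so
#' replicate libraries of one individual do not inflate the residual
#' variance. Weights are floored at `weight_floor`.
#'
#' @param expr an [expr_set()] with TMM factors computed.
#' @param weight_floor positive lower clip for the weights (default 1e-4).
#' @return The `expr_set` with `logcpm` and `weights` filled.
#' @export
voom_transform <- function(expr, weight_floor = 1e-4) {
  if (is.null(expr$norm_factors))
    stop("run tmm_factors() before voom_transform()")
  grp <- factor(paste(expr$samples$individual, expr$samples$assay, sep = "."))
  design <- model.matrix(~ 0 + grp)
  v <- limma::voom(expr$counts, design = design,
                   lib.size = expr$samples$lib_size * expr$norm_factors)
  expr$logcpm <- v$E
  expr$weights <- pmax(v$weights, weight_floor)
  dimnames(expr$weights) <- dimnames(expr$logcpm)
  expr
}

#' One-call normalization pipeline
#'
#' `cpm_filter` + `tmm_factors` + `voom_transform` with default settings.
#'
#' @param expr an [expr_set()].
#' @param ... passed to [cpm_filter()].
#' @return A voom-transformed `expr_set`.
#' @export
normalize_expr <- function(expr, ...) {
  voom_transform(tmm_factors(cpm_filter(expr, ...)))
}

#' Per-individual mean expression
#'
#' Averages `logcpm` over the replicate libraries of each individual within
#' one assay; used for cis-QTL mapping and protein correlation analyses.
#'
#' @param expr a voom-transformed [expr_set()].
#' @param assay `"rna"` or `"ribo"`.
#' @return A genes x individuals matrix.
#' @export
individual_means <- function(expr, assay = c("ribo", "rna")) {
  assay <- match.arg(assay)
  idx <- expr$samples$assay == assay
  ind <- factor(expr$samples$individual[idx])
  m <- expr$logcpm[, idx, drop = FALSE]
  res <- t(rowsum(t(m), ind) / as.vector(table(ind)))
  res[, levels(ind), drop = FALSE]
}
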