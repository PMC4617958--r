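#' Estimate translation efficiency per gene and individual
#'
#' Fits, per gene, a weighted least squares model of normalized
#' log2-expression on individual indicators (cell means) plus a
#' ribo-vs-RNA contrast for each individual, using the voom precision
#' weights. Because the design blocks are disjoint across individuals the
#' fit decouples: the TE of individual i is the weighted mean ribosome
#' occupancy log2-cpm minus the weighted mean RNA log2-cpm of that
#' individual, with a pooled residual variance across the full model.
#'
#' The global TE of a gene is the precision-weighted mean of the
#' per-individual TEs, which coincides with the generalized least squares
#' estimate of a single common ribo-vs-RNA effect (the "common assay
#' effect" parameterization used for Kozak per-position tests).
#'
#' @param expr a voom-transformed [expr_set()].
#' @return An object of class `te_result`: a list with
#'   * `te`: genes x individuals matrix of per-individual log2 TE,
#'   * `se`: matching standard-error matrix,
#'   * `te_global`: named vector of global log2 TE per gene,
#'   * `se_global`: its standard error,
#'   * `sigma2`: per-gene residual variance of the WLS fit,
#'   * `residual_df`: residual degrees of freedom.
#'   Individuals missing either assay get `NA` TE (with a warning).
#' @export
estimate_te <- function(expr) {
  if (is.null(expr$logcpm)) stop("expr must be voom-transformed")
  s <- expr$samples
  ind <- factor(s$individual)
  m <- nlevels(ind)
  grp <- interaction(ind, factor(s$assay, levels = c("rna", "ribo")),
                     drop = FALSE)
  G <- model.matrix(~ 0 + grp)                      # n_lib x 2m indicators
  colnames(G) <- levels(grp)

  w <- expr$weights
  y <- expr$logcpm
  S <- w %*% G                                       # summed weights per cell
  B <- (w * y) %*% G
  has_cell <- colSums(G) > 0
  missing_cells <- !has_cell
  wmean <- B / S
  wmean[, missing_cells] <- NA_real_

  rna_cols <- paste0(levels(ind), ".rna")
  ribo_cols <- paste0(levels(ind), ".ribo")
  te <- wmean[, ribo_cols, drop = FALSE] - wmean[, rna_cols, drop = FALSE]
  colnames(te) <- levels(ind)

  # residual variance of the full (2m-parameter) fit
  cell_of_lib <- as.integer(grp)
  fitted <- wmean[, cell_of_lib, drop = FALSE]
  resid <- y - fitted
  df <- ncol(y) - sum(has_cell)
  if (df < 1) stop("no residual degrees of freedom for the TE model")
  sigma2 <- rowSums(w * resid^2, na.rm = TRUE) / df

  inv_prec <- 1 / S[, ribo_cols, drop = FALSE] + 1 / S[, rna_cols, drop = FALSE]
  se <- sqrt(sigma2 * inv_prec)
  colnames(se) <- levels(ind)

  incomplete <- levels(ind)[!(paste0(levels(ind), ".rna") %in%
                                levels(grp)[has_cell]) |
                              !(paste0(levels(ind), ".ribo") %in%
                                  levels(grp)[has_cell])]
  if (length(incomplete))
    warning("individual(s) missing an assay, TE set to NA: ",
            paste(incomplete, collapse = ", "), call. = FALSE)

  # the common residual variance cancels from the precision weights, so the
  # global TE stays defined even for exact (zero-residual) fits
  prec <- 1 / inv_prec
  prec[is.na(te)] <- NA
  te_global <- rowSums(te * prec, na.rm = TRUE) / rowSums(prec, na.rm = TRUE)
  se_global <- sqrt(sigma2 / rowSums(prec, na.rm = TRUE))

  structure(list(te = te, se = se,
                 te_global = setNames(te_global, rownames(y)),
                 se_global = setNames(se_global, rownames(y)),
                 sigma2 = sigma2, residual_df = df),
            class = "te_result")
}

#' @export
print.te_result <- function(x, ...) {
  cat("te_result:", nrow(x$te), "genes x", ncol(x$te), "individuals;",
      "residual df =", x$residual_df, "\n")
  invisible(x)
}

#' Write TE tables
#'
#' @param te a `te_result`.
#' @param per_individual_path,global_path output TSV paths.
#' @return Invisibly, `te`.
#' @export
write_te <- function(te, per_individual_path, global_path) {
  write.table(data.frame(gene_id = rownames(te$te), te$te,
                         check.names = FALSE),
              per_individual_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene_id = names(te$te_global),
                         te_global = te$te_global,
                         se_global = te$se_global),
              global_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(te)
}
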