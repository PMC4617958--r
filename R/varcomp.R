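#' Maximum-likelihood fit of a single variance component
#'
#' Fits the one-random-effect Gaussian model
#' `y_ij = mu + b_i + e_ij`, with `b_i ~ N(0, sigma2_individual)` and
#' `e_ij ~ N(0, sigma2_residual / w_ij)`, by maximum likelihood (not REML).
#' The observation weights are treated as fixed known precisions, as when
#' they come from voom. `sigma2_individual` is constrained to be
#' non-negative; the boundary estimate 0 is allowed.
#'
#' @param y numeric vector of per-library log-expression.
#' @param weights positive precision weights, same length as `y`.
#' @param individuals factor (or coercible) of individual identifiers.
#' @return A list with `sigma2_individual`, `sigma2_residual`, `loglik`
#'   (full model), `loglik_null` (no random effect) and `lrt`
#'   (`2 * (loglik - loglik_null)`, floored at 0).
#' @export
fit_varcomp <- function(y, weights = rep(1, length(y)), individuals) {
  stopifnot(length(y) == length(weights),
            length(y) == length(individuals), all(weights > 0))
  ind <- factor(individuals)
  if (nlevels(ind) < 2 || sum(table(ind) >= 2) < 2)
    stop("need >= 2 individuals with >= 2 libraries each")
  ord <- order(ind)
  gstart <- c(0L, cumsum(as.integer(table(ind))))
  f <- fit_varcomp_cpp(as.numeric(y[ord]), as.numeric(weights[ord]), gstart)
  list(sigma2_individual = f$sigma2_individual,
       sigma2_residual = f$sigma2_residual,
       loglik = f$loglik_full, loglik_null = f$loglik_null, lrt = f$lrt)
}

#' Exact likelihood ratio test for a zero variance component
#'
#' Tests the null hypothesis `sigma2_individual = 0` with a finite-sample
#' (simulation-based) null distribution: responses are simulated from the
#' fitted null model (a parametric bootstrap with the same design and
#' weights; the LRT statistic is location/scale invariant, so the simulation
#' uses mean 0 and unit residual variance), both models are refitted per
#' replicate, and `p = (1 + #\{sim >= observed\}) / (1 + n_sim)`. An
#' observed statistic of 0 therefore yields p = 1, respecting the boundary
#' point mass (asymptotically the null is the 1/2 chi2_0 + 1/2 chi2_1
#' mixture).
#'
#' @inheritParams fit_varcomp
#' @param n_sim number of null simulations (default 10000).
#' @param seed integer seed (mandatory).
#' @param null_stats optional pre-computed vector of null statistics for this
#'   design/weights (see [rlrt_null_stats()]); when supplied, `n_sim` and
#'   `seed` are ignored.
#' @return A list with `lrt_stat`, `p_value`, and the `fit_varcomp` fields.
#' @export
exact_lrt <- function(y, weights = rep(1, length(y)), individuals,
                      n_sim = 10000, seed = NULL, null_stats = NULL) {
  fit <- fit_varcomp(y, weights, individuals)
  if (is.null(null_stats)) {
    stopifnot(n_sim >= 1000, !is.null(seed))
    null_stats <- rlrt_null_stats(weights, individuals, n_sim, seed)
  }
  p <- (1 + sum(null_stats >= fit$lrt)) / (1 + length(null_stats))
  c(list(lrt_stat = fit$lrt, p_value = p), fit)
}

#' Simulate the null distribution of the variance-component LRT
#'
#' @inheritParams exact_lrt
#' @return Numeric vector of `n_sim` simulated LRT statistics.
#' @export
rlrt_null_stats <- function(weights, individuals, n_sim, seed) {
  ind <- factor(individuals)
  ord <- order(ind)
  gstart <- c(0L, cumsum(as.integer(table(ind))))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  rlrt_null_stats_cpp(as.numeric(weights[ord]), gstart, as.integer(n_sim))
}

#' Per-gene inter-individual variance test for one assay
#'
#' Runs [exact_lrt()] for every gene of one assay of a voom-transformed
#' expression set. Genes whose fit degenerates get `p_value = NA` and are
#' excluded from downstream Holm families.
#'
#' @param expr a voom-transformed [expr_set()].
#' @param assay `"rna"` or `"ribo"`.
#' @param n_sim null simulations per gene.
#' @param seed integer seed.
#' @param share_null if `TRUE` (default `FALSE`), simulate one null
#'   reference distribution from unit weights and reuse it for all genes
#'   (fast approximation; exact when the voom weights are flat).
#' @return A `data.frame` with columns `gene_id`, `assay`,
#'   `sigma2_individual`, `sigma2_residual`, `lrt_stat`, `p_value`.
#' @export
varcomp_assay <- function(expr, assay = c("rna", "ribo"), n_sim = 2000,
                          seed = 1, share_null = FALSE) {
  assay <- match.arg(assay)
  idx <- expr$samples$assay == assay
  ind <- factor(expr$samples$individual[idx])
  y <- expr$logcpm[, idx, drop = FALSE]
  w <- expr$weights[, idx, drop = FALSE]
  genes <- rownames(y)
  shared <- if (share_null)
    rlrt_null_stats(rep(1, sum(idx)), ind, n_sim, seed) else NULL
  res <- vector("list", length(genes))
  for (g in seq_along(genes)) {
    r <- tryCatch(
      exact_lrt(y[g, ], w[g, ], ind, n_sim = n_sim,
                seed = if (share_null) NULL else seed + g,
                null_stats = shared),
      error = function(e) NULL)
    res[[g]] <- if (is.null(r)) {
      list(sigma2_individual = NA_real_, sigma2_residual = NA_real_,
           lrt_stat = NA_real_, p_value = NA_real_)
    } else r
  }
  data.frame(
    gene_id = genes, assay = assay,
    sigma2_individual = vapply(res, function(r) r$sigma2_individual, 0),
    sigma2_residual = vapply(res, function(r) r$sigma2_residual, 0),
    lrt_stat = vapply(res, function(r) r$lrt_stat, 0),
    p_value = vapply(res, function(r) r$p_value, 0),
    stringsAsFactors = FALSE
  )
}

#' Classify genes by inter-individual variability
#'
#' Applies Holm's correction separately within each assay family
#' (non-converged genes excluded from the family), flags significance at
#' `alpha`, and assigns each gene a class: `none`, `rna_only`, `ribo_only`
#' or `both`. Genes in class `both` additionally get a dominance subset:
#' `rna_dominant` / `ribo_dominant` when one assay's estimated individual
#' variance exceeds the other's by at least `dominance_ratio`, else
#' `comparable`.
#'
#' @param results_rna,results_ribo outputs of [varcomp_assay()] covering the
#'   same genes.
#' @param alpha adjusted significance level (default 0.05).
#' @param dominance_ratio variance-ratio threshold for dominance (default 2).
#' @return A `data.frame` with `gene_id`, per-assay Holm-adjusted p-values
#'   and significance flags, `class` and `subset`.
#' @export
classify_variability <- function(results_rna, results_ribo, alpha = 0.05,
                                 dominance_ratio = 2) {
  stopifnot(identical(results_rna$gene_id, results_ribo$gene_id))
  holm <- function(p) {
    adj <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    adj[ok] <- p.adjust(p[ok], method = "holm")
    adj
  }
  p_rna <- holm(results_rna$p_value)
  p_ribo <- holm(results_ribo$p_value)
  sig_rna <- !is.na(p_rna) & p_rna < alpha
  sig_ribo <- !is.na(p_ribo) & p_ribo < alpha
  class <- ifelse(sig_rna & sig_ribo, "both",
                  ifelse(sig_rna, "rna_only",
                         ifelse(sig_ribo, "ribo_only", "none")))
  ratio <- results_rna$sigma2_individual /
    pmax(results_ribo$sigma2_individual, .Machine$double.xmin)
  subset <- rep(NA_character_, length(class))
  is_both <- class == "both"
  subset[is_both] <- ifelse(ratio[is_both] >= dominance_ratio, "rna_dominant",
                            ifelse(ratio[is_both] <= 1 / dominance_ratio,
                                   "ribo_dominant", "comparable"))
  data.frame(gene_id = results_rna$gene_id,
             p_holm_rna = p_rna, p_holm_ribo = p_ribo,
             sig_rna = sig_rna, sig_ribo = sig_ribo,
             class = class, subset = subset,
             stringsAsFactors = FALSE)
}
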