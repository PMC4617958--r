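#' Rank-percentile integration profiles
#'
#' Converts each measure (ribosome occupancy, RNA expression, TE, protein
#' level) to percentiles via its empirical cumulative distribution function
#' over genes, so all four enter the SOM on an equal footing. Only genes
#' present in every measure are kept (dropped genes are counted in an
#' attribute). Ties share a percentile and any monotone transform of a
#' measure leaves its percentiles unchanged.
#'
#' @param measures named list of named numeric vectors, e.g.
#'   `list(ro = ..., rna = ..., te = ..., protein = ...)`.
#' @return A genes x measures matrix of percentiles in (0, 1], with
#'   attribute `"n_dropped"`.
#' @export
rank_transform <- function(measures) {
  stopifnot(is.list(measures), length(measures) >= 2,
            !is.null(names(measures)))
  common <- Reduce(intersect, lapply(measures, names))
  n_dropped <- length(Reduce(union, lapply(measures, names))) - length(common)
  prof <- vapply(measures, function(v) ecdf(v[common])(v[common]),
                 numeric(length(common)))
  rownames(prof) <- common
  attr(prof, "n_dropped") <- n_dropped
  prof
}

hex_grid <- function(nx, ny) {
  g <- expand.grid(col = seq_len(nx) - 1L, row = seq_len(ny) - 1L)
  data.frame(unit = seq_len(nx * ny),
             x = g$col + 0.5 * (g$row %% 2),
             y = g$row * sqrt(3) / 2)
}

#' Train a self-organizing map
#'
#' Classic online SOM on a hexagonal grid: the codebook is initialized by
#' sampling data points (seeded), then for each presented profile the best
#' matching unit (Euclidean distance) and its Gaussian neighborhood are
#' pulled toward the profile, with linearly decaying learning rate and
#' radius. Deterministic given the seed. The 14 x 10 default grid gives the
#' 140 units used for the integrative map.
#'
#' @param profiles genes x measures matrix (e.g. from [rank_transform()]).
#' @param grid_shape `c(nx, ny)` grid dimensions (default `c(14, 10)`).
#' @param rlen number of presentation epochs (default 100).
#' @param alpha learning rate start/end (default `c(0.05, 0.01)`).
#' @param radius neighborhood radius start/end; default starts at 2/3 of
#'   the grid diagonal and ends at 0.1 (effectively best-matching-unit-only
#'   fine tuning in the last phase).
#' @param seed integer seed (mandatory).
#' @return Object of class `som_model`: `codebook` (units x measures),
#'   `grid` (unit coordinates), `unit_of_gene`, `quantization_error`, plus
#'   the training settings.
#' @export
train_som <- function(profiles, grid_shape = c(14, 10), rlen = 100,
                      alpha = c(0.05, 0.01), radius = NULL, seed) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= prod(grid_shape),
            !missing(seed))
  grid <- hex_grid(grid_shape[1], grid_shape[2])
  if (is.null(radius))
    radius <- c(sqrt(max(grid$x)^2 + max(grid$y)^2) * 2 / 3, 0.1)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  n <- nrow(profiles)
  init_idx <- sample.int(n, nrow(grid), replace = nrow(grid) > n)
  codebook0 <- profiles[init_idx, , drop = FALSE]
  order0 <- as.integer(replicate(rlen, sample.int(n)) - 1L)
  qe0 <- mean(som_map_cpp(profiles, codebook0)$dist)
  codebook <- som_train_cpp(profiles, codebook0, grid$x, grid$y, order0,
                            alpha[1], alpha[2], radius[1], radius[2])
  rownames(codebook) <- paste0("u", grid$unit)
  colnames(codebook) <- colnames(profiles)
  mapped <- som_map_cpp(profiles, codebook)
  structure(list(codebook = codebook, grid = grid,
                 unit_of_gene = setNames(mapped$unit + 1L, rownames(profiles)),
                 quantization_error = mean(mapped$dist),
                 quantization_error_init = qe0,
                 grid_shape = grid_shape, rlen = rlen, alpha = alpha,
                 radius = radius, seed = seed),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat("som_model:", nrow(x$codebook), "units (",
      paste(x$grid_shape, collapse = " x "), "hex );",
      length(x$unit_of_gene), "genes mapped; quantization error",
      signif(x$quantization_error, 4), "\n")
  invisible(x)
}

#' Affinity propagation clustering
#'
#' Exemplar-based clustering by message passing on a similarity matrix
#' (responsibilities and availabilities, damped updates). Deterministic
#' given its inputs.
#'
#' @param S similarity matrix (larger = more similar); diagonal is replaced
#'   by `preference`.
#' @param preference scalar or vector; default = median off-diagonal
#'   similarity.
#' @param damping damping factor in (0.5, 1) (default 0.9).
#' @param max_iter,stable_iter iteration caps: stop when exemplars are
#'   unchanged for `stable_iter` iterations, or at `max_iter` with a
#'   non-convergence flag.
#' @return List with `exemplars` (indices), `cluster` (exemplar index per
#'   point), `converged`, `iterations`.
#' @export
affinity_propagation <- function(S, preference = NULL, damping = 0.9,
                                 max_iter = 1000, stable_iter = 50) {
  n <- nrow(S)
  if (is.null(preference))
    preference <- median(S[row(S) != col(S)])
  diag(S) <- preference
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  last_ex <- NULL; stable <- 0L; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    max1_idx <- max.col(AS, ties.method = "first")
    max1 <- AS[cbind(seq_len(n), max1_idx)]
    AS2 <- AS; AS2[cbind(seq_len(n), max1_idx)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), max1_idx)] <- S[cbind(seq_len(n), max1_idx)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0); diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dAnew <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dAnew
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A + R) > 0)
    if (identical(ex, last_ex)) stable <- stable + 1L else stable <- 0L
    last_ex <- ex
    if (stable >= stable_iter && length(ex) > 0) break
  }
  converged <- stable >= stable_iter && length(last_ex) > 0
  if (!length(last_ex)) last_ex <- which.max(diag(A + R))
  assign_to <- last_ex[max.col(S[, last_ex, drop = FALSE],
                               ties.method = "first")]
  assign_to[last_ex] <- last_ex
  if (!converged)
    warning("affinity propagation did not converge in ", max_iter,
            " iterations; returning current labels", call. = FALSE)
  list(exemplars = last_ex, cluster = assign_to, converged = converged,
       iterations = it)
}

#' Cluster SOM codebook vectors by affinity propagation
#'
#' Similarities are negative squared Euclidean distances between codebook
#' vectors; the preference defaults to the median similarity. Emits a
#' per-cluster summary: the exemplar unit's mean rank in each measure and
#' the number of genes mapped to the cluster's units.
#'
#' @param som a [train_som()] model.
#' @param damping,preference passed to [affinity_propagation()].
#' @return The `som_model` with `cluster_of_unit`, `exemplar_of_cluster`,
#'   `ap_converged` and `cluster_summary` filled in.
#' @export
cluster_codebook <- function(som, damping = 0.9, preference = NULL) {
  D2 <- as.matrix(dist(som$codebook))^2
  ap <- affinity_propagation(-D2, preference = preference, damping = damping)
  cluster_id <- match(ap$cluster, ap$exemplars)
  som$cluster_of_unit <- cluster_id
  som$exemplar_of_cluster <- ap$exemplars
  som$ap_converged <- ap$converged
  genes_per_unit <- tabulate(som$unit_of_gene, nbins = nrow(som$codebook))
  summ <- data.frame(
    cluster = seq_along(ap$exemplars),
    exemplar_unit = ap$exemplars,
    n_genes = vapply(seq_along(ap$exemplars), function(k)
      sum(genes_per_unit[cluster_id == k]), 0L))
  summ <- cbind(summ, som$codebook[ap$exemplars, , drop = FALSE])
  rownames(summ) <- NULL
  som$cluster_summary <- summ
  som
}

#' Per-gene expression-protein correlation across individuals
#'
#' For each gene, the Spearman correlation between individual-specific
#' expression (RNA or ribosome occupancy) and relative protein levels,
#' with BH FDR across genes. When a per-gene stratum is supplied (e.g. the
#' variability classes), a stratified summary of median rho and fraction
#' significant is attached.
#'
#' @param expr_by_individual genes x individuals expression matrix (see
#'   [individual_means()]).
#' @param protein_by_individual genes x individuals protein-level matrix.
#' @param min_n minimum individuals with both measures (default 8).
#' @param fdr BH FDR level (default 0.05).
#' @param strata optional named character vector of per-gene strata.
#' @return `data.frame` with `gene_id`, `rho`, `p`, `fdr_sig`; stratified
#'   summary in attribute `"strata_summary"` when `strata` is given.
#' @export
gene_protein_correlation <- function(expr_by_individual,
                                     protein_by_individual,
                                     min_n = 8, fdr = 0.05, strata = NULL) {
  genes <- intersect(rownames(expr_by_individual),
                     rownames(protein_by_individual))
  inds <- intersect(colnames(expr_by_individual),
                    colnames(protein_by_individual))
  rows <- lapply(genes, function(g) {
    e <- expr_by_individual[g, inds]
    p <- protein_by_individual[g, inds]
    ok <- complete.cases(e, p)
    if (sum(ok) < min_n) return(NULL)
    ct <- suppressWarnings(cor.test(e[ok], p[ok], method = "spearman"))
    data.frame(gene_id = g, rho = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame())
  res$fdr_sig <- p.adjust(res$p, method = "BH") < fdr
  if (!is.null(strata)) {
    res$stratum <- strata[res$gene_id]
    by_str <- split(res, res$stratum)
    attr(res, "strata_summary") <- do.call(rbind, lapply(names(by_str),
      function(s) data.frame(
        stratum = s, n_genes = nrow(by_str[[s]]),
        median_rho = median(by_str[[s]]$rho),
        frac_significant = mean(by_str[[s]]$fdr_sig))))
  }
  rownames(res) <- NULL
  res
}
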