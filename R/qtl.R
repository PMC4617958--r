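#' Cis-QTL mapping by additive regression
#'
#' Per gene x variant pair, ordinary least squares of replicate-averaged
#' expression on genotype coded as 0/1/2 copies of the alternate allele,
#' restricted to variants with minor allele frequency above `maf_min` in the
#' tested panel (intended to be an unrelated-individual subset chosen by the
#' caller). BH FDR across all tested pairs.
#'
#' @param expr_avg genes x individuals matrix of replicate-averaged
#'   expression (see [individual_means()]).
#' @param genotypes variants x individuals dosage matrix (see
#'   [dosage_matrix()]).
#' @param variant_gene `data.frame` with columns `variant_id`, `gene_id`
#'   defining the cis pairs to test.
#' @param maf_min minor-allele-frequency threshold (default 0.10).
#' @param phenotype label recorded in the output (`"ribo"` or `"rna"`).
#' @return `data.frame` with `gene_id`, `variant_id`, `maf`, `beta`,
#'   `p_value`, `fdr`, `phenotype`.
#' @export
cis_qtl <- function(expr_avg, genotypes, variant_gene, maf_min = 0.10,
                    phenotype = "ribo") {
  inds <- intersect(colnames(expr_avg), colnames(genotypes))
  if (length(inds) < 3) stop("fewer than 3 shared individuals")
  pairs <- variant_gene[variant_gene$gene_id %in% rownames(expr_avg) &
                          variant_gene$variant_id %in% rownames(genotypes), ,
                        drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    g <- genotypes[pairs$variant_id[k], inds]
    af <- mean(g) / 2
    maf <- min(af, 1 - af)
    if (maf <= maf_min || var(g) == 0) return(NULL)
    y <- expr_avg[pairs$gene_id[k], inds]
    fit <- suppressWarnings(summary(lm(y ~ g)))$coefficients
    if (!"g" %in% rownames(fit)) return(NULL)
    data.frame(gene_id = pairs$gene_id[k], variant_id = pairs$variant_id[k],
               maf = maf, beta = fit["g", "Estimate"],
               p_value = fit["g", "Pr(>|t|)"], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(gene_id = character(0), variant_id = character(0),
                      maf = numeric(0), beta = numeric(0),
                      p_value = numeric(0), fdr = numeric(0),
                      phenotype = character(0)))
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res$phenotype <- phenotype
  rownames(res) <- NULL
  res
}
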