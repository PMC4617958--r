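test_that("rank transform gives ECDF percentiles, ties and rank invariance", {
  m <- list(a = setNames(c(3, 1, 4, 1, 5), paste0("g", 1:5)),
            b = setNames(1:5, paste0("g", 1:5)))
  p <- rank_transform(m)
  expect_equal(unname(p[, "b"]), c(0.2, 0.4, 0.6, 0.8, 1.0))
  expect_equal(p["g2", "a"], p["g4", "a"])         # ties share a percentile

  # monotone transform leaves percentiles unchanged
  m2 <- m; m2$a <- exp(m$a)
  expect_equal(rank_transform(m2), rank_transform(m),
               ignore_attr = "n_dropped")

  # intersection only, dropped genes counted
  m3 <- m; m3$b <- m$b[1:3]
  p3 <- rank_transform(m3)
  expect_equal(nrow(p3), 3)
  expect_equal(attr(p3, "n_dropped"), 2)
})

test_that("SOM training converges and improves quantization", {
  set.seed(30)
  # identical profiles: every codebook vector converges to that point
  one <- matrix(0.5, 200, 4, dimnames = list(paste0("g", 1:200), NULL))
  som1 <- train_som(one, grid_shape = c(4, 3), rlen = 30, seed = 1)
  expect_lt(som1$quantization_error, 1e-8)
  expect_lt(max(abs(som1$codebook - 0.5)), 1e-6)

  # quantization error after training never exceeds its initial value
  for (s in 1:20) {
    X <- matrix(runif(150 * 4), 150, 4, dimnames = list(paste0("g", 1:150),
                                                        NULL))
    som <- train_som(X, grid_shape = c(5, 4), rlen = 50, seed = s)
    expect_lte(som$quantization_error, som$quantization_error_init)
  }

  # two well-separated blobs map to disjoint unit sets
  X2 <- rbind(matrix(rnorm(100 * 4, 0, 0.05), 100, 4),
              matrix(rnorm(100 * 4, 1, 0.05), 100, 4))
  rownames(X2) <- paste0("g", 1:200)
  som2 <- train_som(X2, grid_shape = c(5, 4), rlen = 50, seed = 2)
  u_a <- unique(som2$unit_of_gene[1:100])
  u_b <- unique(som2$unit_of_gene[101:200])
  expect_length(intersect(u_a, u_b), 0)

  # bit-reproducible under a fixed seed
  som3 <- train_som(X2, grid_shape = c(5, 4), rlen = 50, seed = 2)
  expect_identical(som2$codebook, som3$codebook)
  expect_identical(som2$unit_of_gene, som3$unit_of_gene)
})

test_that("affinity propagation recovers planted structure deterministically", {
  set.seed(31)
  # three nearby points with a workable preference: one exemplar
  P <- matrix(c(0, 0, 0.1, 0, 0, 0.1), 3, 2, byrow = TRUE)
  S <- -as.matrix(dist(P))^2
  ap1 <- affinity_propagation(S, preference = -1)
  expect_length(ap1$exemplars, 1)
  expect_true(all(ap1$cluster == ap1$exemplars))

  # two far blobs: exactly two clusters matching the blobs
  P2 <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
              matrix(rnorm(20, 10, 0.1), 10, 2))
  S2 <- -as.matrix(dist(P2))^2
  ap2 <- affinity_propagation(S2)
  expect_length(ap2$exemplars, 2)
  expect_length(unique(ap2$cluster[1:10]), 1)
  expect_length(unique(ap2$cluster[11:20]), 1)
  expect_false(ap2$cluster[1] == ap2$cluster[11])

  # deterministic given inputs
  ap3 <- affinity_propagation(S2)
  expect_identical(ap2$cluster, ap3$cluster)

  # cluster count is non-increasing as the preference decreases
  prefs <- quantile(S2[row(S2) != col(S2)], c(0.9, 0.5, 0.1, 0.01))
  ncl <- sapply(prefs, function(p)
    length(affinity_propagation(S2, preference = p)$exemplars))
  expect_true(all(diff(ncl) <= 0))
})

test_that("codebook clustering emits the cluster summary table", {
  set.seed(32)
  X <- rbind(matrix(rnorm(300 * 4, 0, 0.05), 300, 4),
             matrix(rnorm(300 * 4, 1, 0.05), 300, 4))
  rownames(X) <- paste0("g", 1:600)
  som <- train_som(X, grid_shape = c(5, 4), rlen = 40, seed = 3)
  som <- cluster_codebook(som)
  expect_equal(length(som$cluster_of_unit), 20)
  expect_true(all(som$cluster_of_unit %in%
                    seq_along(som$exemplar_of_cluster)))
  summ <- som$cluster_summary
  expect_equal(sum(summ$n_genes), 600)
  expect_true(all(c("cluster", "exemplar_unit", "n_genes") %in% names(summ)))
  # exemplar rows carry the codebook's measure columns
  expect_equal(unname(as.matrix(summ[, 4:7])),
               unname(som$codebook[summ$exemplar_unit, ]))
})

test_that("gene-protein correlation: perfect monotone, null calibration", {
  set.seed(33)
  inds <- sprintf("i%02d", 1:20)
  e <- matrix(rnorm(50 * 20), 50, 20, dimnames = list(paste0("g", 1:50), inds))
  p_perf <- exp(e)                       # monotone function of expression
  res <- gene_protein_correlation(e, p_perf)
  expect_equal(res$rho, rep(1, 50))

  # independent vectors: ~5% raw p < 0.05, median rho ~ 0
  e2 <- matrix(rnorm(1000 * 20), 1000, 20,
               dimnames = list(paste0("g", 1:1000), inds))
  p2 <- matrix(rnorm(1000 * 20), 1000, 20, dimnames = dimnames(e2))
  res2 <- gene_protein_correlation(e2, p2)
  expect_lt(abs(mean(res2$p < 0.05) - 0.05), 0.025)
  expect_lt(abs(median(res2$rho)), 0.05)
  expect_lt(mean(res2$fdr_sig), 0.01)

  # too few shared individuals: gene dropped
  e3 <- e[, 1:5]
  expect_equal(nrow(gene_protein_correlation(e3, p_perf[, 1:5])), 0)

  # strata summary reports per-stratum medians
  strata <- setNames(rep(c("x", "y"), each = 25), rownames(e))
  res4 <- gene_protein_correlation(e, p_perf, strata = strata)
  ss <- attr(res4, "strata_summary")
  expect_equal(sort(ss$stratum), c("x", "y"))
  expect_equal(ss$median_rho, c(1, 1))
})

test_that("protein tracks ribosome occupancy more than RNA on generator output", {
  study <- demo_study(seed = 55, n_individuals = 20, n_transcripts = 120,
                      frac_genes_rna_variable = 0.35,
                      frac_genes_ro_variable = 0.35)
  expr <- normalize_expr(study$expr)
  ro <- individual_means(expr, "ribo")
  rna <- individual_means(expr, "rna")
  res_ro <- gene_protein_correlation(ro, study$protein)
  res_rna <- gene_protein_correlation(rna, study$protein)
  expect_gt(median(res_ro$rho), median(res_rna$rho))

  # genes variable in both assays correlate more than the rest
  tr <- study$truth$genes
  both <- tr$gene_id[tr$rna_variable & tr$ro_variable]
  other <- setdiff(tr$gene_id, both)
  expect_gt(median(res_ro$rho[res_ro$gene_id %in% both]),
            median(res_ro$rho[res_ro$gene_id %in% other]))
})
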