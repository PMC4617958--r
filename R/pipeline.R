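# End-to-end orchestration: simulate -> normalize -> te -> varcomp -> uorf
# -> kozak -> som/protcor -> qtl -> enrich, with plain files per stage and a
# manifest recording seeds, decisions in effect, and file checksums.

#' Default pipeline configuration
#'
#' @param seed master seed; per-stage seeds derive from it.
#' @param ... overrides for any configuration entry (see the returned list).
#' @return A nested list understood by [run_all()].
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    simulate = list(n_individuals = 30, n_transcripts = 150),
    varcomp = list(n_sim = 10000, alpha = 0.05),
    uorf = list(min_carriers = 3, fdr = 0.05),
    kozak = list(pseudocount = 0.5, fdr = 0.10, min_carriers = 3),
    som = list(grid = c(14, 10), rlen = 50),
    qtl = list(maf_min = 0.10, n_unrelated = 21),
    enrich = list(n_perm = 1000, or_min = 2, alpha = 0.05, kappa_min = 0.1))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes every stage in order, writing each stage's tables under
#' `outdir` and returning a run manifest with the seeds, the labeled
#' decisions in effect (thresholds, pseudocount, grid shape, FDR levels) and
#' an md5 checksum per output file. A stage whose output files already
#' exist is skipped unless `force = TRUE`, so a partially deleted `outdir`
#' recomputes only downstream stages. Re-running with the same config and
#' seed reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()] list (or a path to a YAML file of
#'   the same shape).
#' @param outdir output directory.
#' @param force recompute every stage even if outputs exist.
#' @return The manifest (also written to `manifest.json` in `outdir`),
#'   invisibly.
#' @export
run_all <- function(config = pipeline_config(), outdir, force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  written <- character(0)
  note <- function(...) message("[ribovar] ", ...)

  stage_done <- function(files) !force && all(file.exists(files))
  out <- function(...) file.path(outdir, ...)
  wtsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
    path
  }

  # ---- simulate ----
  sim_files <- out(c("transcripts.fa", "annotation.tsv", "variants.vcf",
                     "counts.tsv", "samples.tsv", "protein.tsv",
                     "truth.json", "terms.tsv"))
  scfg <- do.call(sim_config, c(config$simulate, list(seed = seed)))
  study <- simulate_study(scfg)
  if (!stage_done(sim_files)) {
    note("simulate: ", nrow(study$transcripts), " transcripts, ",
         nrow(study$variants), " variants")
    write_study(study, outdir)
    terms <- simulate_go_terms(study$truth, seed = seed + 2)
    wtsv(terms, out("terms.tsv"))
    written <- c(written, sim_files[1:7])
  }
  terms <- utils::read.delim(out("terms.tsv"), stringsAsFactors = FALSE)

  # ---- normalize ----
  study$haplotypes <- resolve_phase(study$haplotypes, seed + 3)
  expr <- normalize_expr(study$expr)
  if (!stage_done(out(c("logcpm.tsv", "weights.tsv", "norm_factors.tsv")))) {
    note("normalize: kept ", nrow(expr$counts), " genes")
    wtsv(data.frame(gene_id = rownames(expr$logcpm), expr$logcpm,
                    check.names = FALSE), out("logcpm.tsv"))
    wtsv(data.frame(gene_id = rownames(expr$weights), expr$weights,
                    check.names = FALSE), out("weights.tsv"))
    wtsv(data.frame(library_id = expr$samples$library_id,
                    norm_factor = expr$norm_factors), out("norm_factors.tsv"))
  }

  # ---- translation efficiency ----
  te <- estimate_te(expr)
  if (!stage_done(out(c("te_by_individual.tsv", "te_global.tsv")))) {
    note("te: ", nrow(te$te), " genes")
    write_te(te, out("te_by_individual.tsv"), out("te_global.tsv"))
    written <- c(written, out(c("te_by_individual.tsv", "te_global.tsv")))
  }

  # ---- variance components ----
  vc_files <- out(c("varcomp.tsv", "variability_classes.tsv"))
  vc_rna <- varcomp_assay(expr, "rna", n_sim = config$varcomp$n_sim,
                          seed = seed + 10)
  vc_ribo <- varcomp_assay(expr, "ribo", n_sim = config$varcomp$n_sim,
                           seed = seed + 11)
  classes <- classify_variability(vc_rna, vc_ribo,
                                  alpha = config$varcomp$alpha)
  if (!stage_done(vc_files)) {
    note("varcomp: ", sum(classes$class != "none"), " variable genes")
    wtsv(rbind(vc_rna, vc_ribo), vc_files[1])
    wtsv(classes, vc_files[2])
  }

  # ---- uORF events ----
  events <- enumerate_events(study$transcripts, study$variants,
                             study$haplotypes,
                             min_carriers = config$uorf$min_carriers)
  uorf_assoc <- test_uorf_association(events, expr, fdr = config$uorf$fdr)
  if (!stage_done(out(c("uorf_events.tsv", "uorf_associations.tsv")))) {
    note("uorf: ", nrow(events$events), " events")
    wtsv(events$events, out("uorf_events.tsv"))
    wtsv(uorf_assoc, out("uorf_associations.tsv"))
  }

  # ---- Kozak ----
  pwm <- build_pwm(study$transcripts, pseudocount = config$kozak$pseudocount)
  kvars <- kozak_variants(study$variants, study$transcripts)
  kscores <- score_kozak_variants(kvars, pwm, study$transcripts,
                                  study$haplotypes,
                                  min_carriers = config$kozak$min_carriers)
  pos_tests <- test_position_effects(study$transcripts, te$te_global)
  kozak_assoc <- test_kozak_association(kscores, study$transcripts, expr,
                                        fdr = config$kozak$fdr)
  if (!stage_done(out(c("kozak_pwm.tsv", "kozak_positions.tsv",
                        "kozak_scores.tsv", "kozak_associations.tsv")))) {
    note("kozak: ", sum(kscores$scores$tested), " scored variants tested")
    wtsv(data.frame(position = rownames(pwm$log_odds),
                    counts = pwm$counts, probs = pwm$probs,
                    log_odds = pwm$log_odds, check.names = FALSE),
         out("kozak_pwm.tsv"))
    wtsv(pos_tests, out("kozak_positions.tsv"))
    wtsv(kscores$scores, out("kozak_scores.tsv"))
    wtsv(kozak_assoc, out("kozak_associations.tsv"))
  }

  # ---- SOM + protein correlation ----
  ro_ind <- individual_means(expr, "ribo")
  rna_ind <- individual_means(expr, "rna")
  prof <- rank_transform(list(
    ro = rowMeans(ro_ind), rna = rowMeans(rna_ind),
    te = te$te_global, protein = rowMeans(study$protein)))
  grid <- config$som$grid
  if (nrow(prof) < prod(grid)) {
    # small studies cannot populate the full map; shrink proportionally
    shrink <- sqrt(nrow(prof) / (2 * prod(grid)))
    grid <- pmax(c(2, 2), floor(grid * shrink))
    note("som: grid reduced to ", grid[1], " x ", grid[2],
         " for ", nrow(prof), " genes")
  }
  som <- train_som(prof, grid_shape = grid,
                   rlen = config$som$rlen, seed = seed + 20)
  som <- cluster_codebook(som)
  strata <- setNames(classes$class, classes$gene_id)
  cor_ro <- gene_protein_correlation(ro_ind, study$protein, strata = strata)
  cor_rna <- gene_protein_correlation(rna_ind, study$protein, strata = strata)
  if (!stage_done(out(c("som_codebook.tsv", "som_clusters.tsv",
                        "cluster_summary.tsv", "protein_correlation.tsv")))) {
    note("som: ", length(som$exemplar_of_cluster), " clusters")
    wtsv(data.frame(unit = rownames(som$codebook), som$codebook,
                    cluster = som$cluster_of_unit, check.names = FALSE),
         out("som_codebook.tsv"))
    wtsv(data.frame(gene_id = names(som$unit_of_gene),
                    unit = som$unit_of_gene,
                    cluster = som$cluster_of_unit[som$unit_of_gene]),
         out("som_clusters.tsv"))
    wtsv(som$cluster_summary, out("cluster_summary.tsv"))
    wtsv(rbind(cbind(measure = "ribo", cor_ro),
               cbind(measure = "rna", cor_rna)),
         out("protein_correlation.tsv"))
  }

  # ---- cis-QTL ----
  n_unrel <- min(config$qtl$n_unrelated, length(study$truth$individuals))
  panel <- study$truth$individuals[seq_len(n_unrel)]
  vg <- data.frame(variant_id = study$variants$variant_id,
                   gene_id = study$transcripts$gene_id[
                     match(study$variants$transcript_id,
                           study$transcripts$transcript_id)])
  geno <- dosage_matrix(study$haplotypes)
  qtl_ribo <- cis_qtl(ro_ind[, panel, drop = FALSE],
                      geno[, panel, drop = FALSE], vg,
                      maf_min = config$qtl$maf_min, phenotype = "ribo")
  qtl_rna <- cis_qtl(rna_ind[, panel, drop = FALSE],
                     geno[, panel, drop = FALSE], vg,
                     maf_min = config$qtl$maf_min, phenotype = "rna")
  if (!stage_done(out("qtl.tsv"))) {
    note("qtl: ", nrow(qtl_ribo), " ribo pairs tested")
    wtsv(rbind(qtl_ribo, qtl_rna), out("qtl.tsv"))
  }

  # ---- enrichment ----
  background <- rownames(expr$logcpm)
  query <- classes$gene_id[classes$class == "both"]
  enr_files <- out(c("enrichment.tsv", "term_graph.tsv"))
  if (length(query) >= 3) {
    enr <- go_enrichment(query, background,
                         terms[terms$gene_id %in% background, ],
                         n_perm = config$enrich$n_perm, seed = seed + 30,
                         or_min = config$enrich$or_min,
                         alpha = config$enrich$alpha,
                         kappa_min = config$enrich$kappa_min)
    if (!stage_done(enr_files)) {
      note("enrich: ", sum(enr$terms$significant), " significant terms")
      wtsv(enr$terms, enr_files[1])
      wtsv(enr$edges, enr_files[2])
    }
  }

  # ---- manifest ----
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    package = "ribovar",
    version = as.character(utils::packageVersion("ribovar")),
    seed = seed,
    stage_seeds = list(simulate = seed, counts = seed + 1, terms = seed + 2,
                       phase = seed + 3, varcomp_rna = seed + 10,
                       varcomp_ribo = seed + 11, som = seed + 20,
                       enrich = seed + 30),
    decisions = list(
      cpm_filter = "cpm>1 in >=90% of libraries per assay",
      tmm = "pooled assays, trim_M=0.30, trim_A=0.05",
      voom = "individual.assay design, weight floor 1e-4",
      varcomp = config$varcomp,
      uorf = config$uorf, kozak = config$kozak,
      som = config$som, qtl = config$qtl, enrich = config$enrich),
    config = config,
    checksums = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
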