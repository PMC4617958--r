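# Synthetic multi-individual, multi-assay study generator. Sequence grammar:
# 5' UTR pads use only A/C, so ATG/CTG starts and TAA/TAG/TGA stops can only
# occur where the generator plants them; planted architectures are therefore
# exactly recoverable by the scanner. Kozak regions are sampled from an
# A/C/G consensus-like composition (no T, so they cannot create motifs).

#' Simulation configuration
#'
#' Defaults encode the emulated study design: ~30 individuals, 3 RNA-seq and
#' 2 ribosome-profiling replicates each, negative-binomial counts with
#' gene-specific dispersion, a planted subset of genes with inter-individual
#' variance in RNA and/or ribosome occupancy, planted uORF- and Kozak-variant
#' effects acting on ribosome occupancy only, and protein levels generated as
#' a noisy monotone function of ribosome occupancy.
#'
#' @param n_individuals number of individuals (default 30).
#' @param n_transcripts number of transcripts/genes (default 150).
#' @param replicates_rna,replicates_ribo replicate libraries per individual.
#' @param utr5_length_range min/max 5' UTR length in nt.
#' @param baseline_log2cpm_mean,baseline_log2cpm_sd gene baseline abundance
#'   (log2 cpm).
#' @param dispersion_meanlog,dispersion_sdlog log-normal parameters of the
#'   per-gene NB dispersion.
#' @param frac_genes_rna_variable,frac_genes_ro_variable fractions of genes
#'   flagged with inter-individual variance in RNA / ribosome occupancy
#'   (drawn independently; the overlap is the "both" class).
#' @param individual_sd_log2 sd of the per-individual effect for flagged
#'   genes (default 0.8 log2, about twice the typical replicate-level sd at
#'   these depths).
#' @param te_sd_log2 sd of the gene-level global TE offset.
#' @param kozak_te_effect TE bonus (log2) for transcripts with A at Kozak
#'   position -3, emulating the strong -3 context effect (default 0.3).
#' @param planted_uorf_effects list of uORF plants; each element is
#'   `list(class = "gain"|"loss"|"premature_stop"|"merge", beta_ro =, maf =)`.
#'   The default plants each class once, the merge via two distinct
#'   stop-ablating SNVs whose carriers pool into one event.
#' @param planted_kozak_effects list of Kozak plants:
#'   `list(offset =, weakening =, beta_ro =, maf =)`.
#' @param n_kozak_neutral number of effect-free Kozak variants.
#' @param frac_kozak_weakening probability that a neutral Kozak variant
#'   lowers the PWM score (default 0.65).
#' @param neutral_utr_variants_per_tx,neutral_cds_variants_per_tx expected
#'   effect-free variants per transcript (UTR pads / CDS body).
#' @param maf_range minor allele frequencies drawn uniformly in this range.
#' @param frac_unphased fraction of genotypes emitted unphased (default
#'   0.08).
#' @param library_size_range log-uniform library-size range (3x span).
#' @param protein_scale,protein_noise_sd protein model: `scale * rank
#'   percentile of true ribosome occupancy + N(0, sd)`.
#' @param seed integer seed (mandatory); per-stage sub-seeds derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 30,
                       n_transcripts = 150,
                       replicates_rna = 3,
                       replicates_ribo = 2,
                       utr5_length_range = c(60, 150),
                       baseline_log2cpm_mean = 5,
                       baseline_log2cpm_sd = 1.5,
                       dispersion_meanlog = log(0.05),
                       dispersion_sdlog = 0.4,
                       frac_genes_rna_variable = 0.20,
                       frac_genes_ro_variable = 0.10,
                       individual_sd_log2 = 0.8,
                       te_sd_log2 = 0.5,
                       kozak_te_effect = 0.3,
                       planted_uorf_effects = NULL,
                       planted_kozak_effects = NULL,
                       n_kozak_neutral = 20,
                       frac_kozak_weakening = 0.65,
                       neutral_utr_variants_per_tx = 1,
                       neutral_cds_variants_per_tx = 1,
                       maf_range = c(0.10, 0.40),
                       frac_unphased = 0.08,
                       library_size_range = c(8e5, 2.4e6),
                       protein_scale = 2,
                       protein_noise_sd = 0.5,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(planted_uorf_effects))
    planted_uorf_effects <- list(
      list(class = "gain", beta_ro = 0.8, maf = 0.30),
      list(class = "loss", beta_ro = -0.8, maf = 0.30),
      list(class = "premature_stop", beta_ro = -0.7, maf = 0.30),
      list(class = "merge", beta_ro = 0.8, maf = 0.15))
  if (is.null(planted_kozak_effects))
    planted_kozak_effects <- list(
      list(offset = -3, weakening = TRUE, beta_ro = -0.8, maf = 0.30),
      list(offset = -1, weakening = TRUE, beta_ro = -0.6, maf = 0.30))
  cfg <- as.list(environment())
  stopifnot(frac_genes_rna_variable >= 0, frac_genes_rna_variable <= 1,
            frac_genes_ro_variable >= 0, frac_genes_ro_variable <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  n_planted <- length(cfg$planted_uorf_effects) +
    length(cfg$planted_kozak_effects)
  if (n_planted > n_transcripts)
    stop("more planted events than transcripts")
  class(cfg) <- "sim_config"
  cfg
}

# Kozak composition over A/C/G (no T: cannot create start/stop motifs),
# loosely following the known gccAcc|ATG|Gc consensus.
KOZAK_COMPOSITION <- rbind(
  "-6" = c(A = 0.25, C = 0.30, G = 0.45),
  "-5" = c(A = 0.25, C = 0.50, G = 0.25),
  "-4" = c(A = 0.30, C = 0.50, G = 0.20),
  "-3" = c(A = 0.50, C = 0.15, G = 0.35),
  "-2" = c(A = 0.30, C = 0.50, G = 0.20),
  "-1" = c(A = 0.30, C = 0.45, G = 0.25),
  "+4" = c(A = 0.25, C = 0.30, G = 0.45),
  "+5" = c(A = 0.30, C = 0.40, G = 0.30))

pad_seq <- function(n) {
  if (n <= 0) return(character(0))
  sample(c("A", "C"), n, replace = TRUE)
}

uorf_motif <- function(n_body, body_codons = c("CAA", "CAC", "CCA")) {
  body <- sample(body_codons, n_body, replace = TRUE)
  c("ATG", body, "TAA")
}

SENSE_CODONS <- {
  all3 <- as.vector(outer(as.vector(outer(c("A","C","G","T"), c("A","C","G","T"),
                                          paste0)), c("A","C","G","T"), paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

#' Simulate a synthetic transcriptome with planted variants
#'
#' Generates transcript models whose 5' UTRs contain 0-3 uORFs built from
#' the ATG/CTG start and TAA/TAG/TGA stop grammar, plants one transcript per
#' configured uORF event class (the merge via two distinct stop-ablating
#' SNVs), plants Kozak-region variants at offsets -6..-1/+4/+5, scatters
#' effect-free UTR and CDS variants, and draws Hardy-Weinberg phased
#' genotypes at allele frequencies from `maf_range` (a fraction emitted
#' unphased to exercise phase resolution).
#'
#' @param config a [sim_config()].
#' @return A list with `transcripts`, `variants`, `haplotypes` (a
#'   [haplotype_set()]), and `truth` (see Details). `truth` carries per-gene
#'   flags and effects (`genes`, `b_rna`, `b_ro`), the planted variant table
#'   (`variant_effects`), planted uORF events with their event-dosage matrix
#'   (`events`, `event_dosage`), and per-gene/per-individual deterministic
#'   signal matrices used by [simulate_counts()].
#' @export
simulate_transcriptome <- function(config) {
  old <- local_seed(config$seed)
  on.exit(restore_seed(old))
  n_tx <- config$n_transcripts
  n_ind <- config$n_individuals
  tx_ids <- sprintf("t%03d", seq_len(n_tx))
  gene_ids <- sprintf("g%03d", seq_len(n_tx))
  individuals <- sprintf("ind%02d", seq_len(n_ind))

  # assign planted roles to distinct transcripts
  plants <- c(lapply(config$planted_uorf_effects, function(p)
                c(p, list(kind = "uorf"))),
              lapply(config$planted_kozak_effects, function(p)
                c(p, list(kind = "kozak"))))
  plant_tx <- sample.int(n_tx, length(plants))

  variants <- list()
  var_truth <- list()
  seqs <- character(n_tx)
  cds_start <- integer(n_tx)
  cds_end <- integer(n_tx)
  uorf_plan <- vector("list", n_tx)   # planted variant specs per transcript

  for (t in seq_len(n_tx)) {
    plant <- NULL
    pk <- match(t, plant_tx)
    if (!is.na(pk)) plant <- plants[[pk]]
    plant_class <- if (!is.null(plant) && plant$kind == "uorf")
      plant$class else NULL

    # ---- motifs to embed in the UTR ----
    motifs <- list()        # each: list(codons, specs = variant specs rel.
    if (is.null(plant_class)) {
      for (u in seq_len(sample(0:3, 1)))
        motifs[[u]] <- list(codons = uorf_motif(sample(1:4, 1)), specs = NULL)
    } else if (plant_class == "gain") {
      g3 <- 3 * sample(1:3, 1)
      motifs[[1]] <- list(
        codons = c("AAG", pad_codons(g3 / 3), "TAA"),
        specs = list(list(rel = 1L, ref = "A", alt = "T", role = "uorf",
                          class = "gain")))
    } else if (plant_class == "loss") {
      nb <- sample(2:4, 1)
      motifs[[1]] <- list(
        codons = uorf_motif(nb),
        specs = list(list(rel = 1L, ref = "T", alt = "A", role = "uorf",
                          class = "loss")))
    } else if (plant_class == "premature_stop") {
      nb <- sample(3:5, 1)
      body <- rep("CAA", nb)
      j <- sample(2:nb, 1)          # not the first body codon
      motifs[[1]] <- list(
        codons = c("ATG", body, "TAA"),
        specs = list(list(rel = 3L * j, ref = "C", alt = "T", role = "uorf",
                          class = "premature_stop")))
    } else if (plant_class == "merge") {
      b1 <- sample(2:3, 1); gap <- 3 * sample(1:2, 1); b2 <- sample(2:3, 1)
      codons <- c("ATG", rep("CAA", b1), "TAA", pad_codons(gap / 3),
                  "ATG", rep("CAC", b2), "TAA")
      stop1_rel <- 3L * (1L + b1)   # offset of uORF1 stop within motif
      motifs[[1]] <- list(
        codons = codons,
        specs = list(
          list(rel = stop1_rel, ref = "T", alt = "C", role = "uorf",
               class = "merge"),
          list(rel = stop1_rel + 2L, ref = "A", alt = "C", role = "uorf",
               class = "merge")))
    }

    motif_nt <- vapply(motifs, function(m) 3L * length(m$codons), 0L)
    utr_len <- sample(config$utr5_length_range[1]:config$utr5_length_range[2], 1)
    need <- sum(motif_nt) + 6L + length(motifs) + 1L
    if (utr_len < need) utr_len <- need

    # distribute pad space around the motifs
    free <- utr_len - 6L - sum(motif_nt)
    k <- length(motifs)
    cuts <- sort(sample.int(free + 1L, k, replace = TRUE) - 1L)
    pads <- diff(c(0L, cuts, free))
    chars <- character(0)
    specs_abs <- list()
    pos <- 0L
    for (u in seq_len(k)) {
      chars <- c(chars, pad_seq(pads[u]))
      pos <- pos + pads[u]
      m <- motifs[[u]]
      for (sp in m$specs) {
        sp$position <- pos + sp$rel
        specs_abs[[length(specs_abs) + 1]] <- sp
      }
      chars <- c(chars, strsplit(paste(m$codons, collapse = ""), "")[[1]])
      pos <- pos + 3L * length(m$codons)
    }
    chars <- c(chars, pad_seq(pads[k + 1]))

    # Kozak region: last 6 nt of the UTR
    koz <- vapply(1:6, function(j)
      sample(names(KOZAK_COMPOSITION[j, ]), 1, prob = KOZAK_COMPOSITION[j, ]),
      "")
    chars <- c(chars, koz)
    stopifnot(length(chars) == utr_len)

    # CDS: ATG + second codon with Kozak-composed +4/+5 + body + stop
    plus45 <- vapply(7:8, function(j)
      sample(names(KOZAK_COMPOSITION[j, ]), 1, prob = KOZAK_COMPOSITION[j, ]),
      "")
    codon2 <- paste0(plus45[1], plus45[2],
                     sample(c("A", "C", "G"), 1))
    n_body <- sample(10:25, 1)
    cds_codons <- c("ATG", codon2, sample(SENSE_CODONS, n_body, replace = TRUE),
                    "TAA")
    seqs[t] <- paste0(paste(chars, collapse = ""),
                      paste(cds_codons, collapse = ""))
    cds_start[t] <- utr_len
    cds_end[t] <- utr_len + 3L * length(cds_codons)
    uorf_plan[[t]] <- list(specs = specs_abs, plant = plant)
  }

  tx <- transcript_models(tx_ids, gene_ids, seqs, cds_start, cds_end)
  stopifnot(nrow(tx) == n_tx)

  # ---- variants ----
  add_variant <- function(transcript, position, ref, alt, role, class,
                          beta_ro, beta_rna, maf, weakening = NA) {
    id <- sprintf("v%04d", length(variants) + 1L)
    variants[[length(variants) + 1L]] <<- data.frame(
      variant_id = id, transcript_id = transcript, position = position,
      ref = ref, alt = alt, stringsAsFactors = FALSE)
    var_truth[[length(var_truth) + 1L]] <<- data.frame(
      variant_id = id, transcript_id = transcript, role = role,
      class = class, beta_ro = beta_ro, beta_rna = beta_rna, maf = maf,
      weakening = weakening, stringsAsFactors = FALSE)
    id
  }

  # planted uORF variants
  for (t in seq_len(n_tx)) {
    plan <- uorf_plan[[t]]
    for (sp in plan$specs) {
      stopifnot(substr(seqs[t], sp$position + 1, sp$position + 1) == sp$ref)
      add_variant(tx_ids[t], sp$position, sp$ref, sp$alt, "uorf", sp$class,
                  plan$plant$beta_ro, 0, plan$plant$maf)
    }
  }

  # Kozak PWM from the generated transcript set, for choosing variant signs
  pwm <- build_pwm(tx)
  pick_kozak_alt <- function(t, offset, weakening) {
    pos <- cds_start[t] + offset
    ref <- substr(seqs[t], pos + 1, pos + 1)
    lab <- KOZAK_LABELS[match(offset, KOZAK_OFFSETS)]
    cand <- setdiff(c("A", "C", "G"), ref)
    delta <- pwm$log_odds[lab, cand] - pwm$log_odds[lab, ref]
    want <- if (weakening) delta < 0 else delta > 0
    if (!any(want)) return(NULL)
    list(pos = pos, ref = ref, alt = cand[want][which.max(abs(delta[want]))])
  }

  for (pk in seq_along(plants)) {
    p <- plants[[pk]]
    if (p$kind != "kozak") next
    t <- plant_tx[pk]
    ka <- pick_kozak_alt(t, p$offset, p$weakening)
    if (is.null(ka)) {          # ref already extreme; flip direction of base
      ka <- pick_kozak_alt(t, p$offset, !p$weakening)
      if (is.null(ka)) next
    }
    add_variant(tx_ids[t], ka$pos, ka$ref, ka$alt, "kozak", "kozak_effect",
                p$beta_ro, 0, p$maf, weakening = p$weakening)
  }

  # neutral Kozak variants (no expression effect; direction controlled)
  neutral_ok <- setdiff(seq_len(n_tx), plant_tx)
  koz_tx <- sample(neutral_ok, min(config$n_kozak_neutral, length(neutral_ok)))
  for (t in koz_tx) {
    offset <- sample(KOZAK_OFFSETS, 1)
    weakening <- runif(1) < config$frac_kozak_weakening
    ka <- pick_kozak_alt(t, offset, weakening)
    if (is.null(ka)) next
    add_variant(tx_ids[t], ka$pos, ka$ref, ka$alt, "kozak", "kozak_neutral",
                0, 0, runif(1, config$maf_range[1], config$maf_range[2]),
                weakening = weakening)
  }

  # neutral UTR variants: A<->C swaps in pad space (cannot touch motifs)
  reserved <- lapply(seq_len(n_tx), function(t) {
    r <- (cds_start[t] - 6):(cds_start[t] - 1)   # Kozak region
    for (sp in uorf_plan[[t]]$specs) r <- c(r, sp$position)
    r
  })
  for (t in seq_len(n_tx)) {
    n_v <- rpois_capped(config$neutral_utr_variants_per_tx)
    if (!n_v) next
    chars <- strsplit(substr(seqs[t], 1, cds_start[t]), "")[[1]]
    ok <- which(chars %in% c("A", "C"))
    ok <- setdiff(ok - 1L, reserved[[t]])       # 0-based
    # pads only: exclude every position inside any planted/embedded motif
    ok <- ok[!utr_pos_in_motif(seqs[t], ok)]
    if (!length(ok)) next
    for (p in sample_vec(ok, min(n_v, length(ok)))) {
      ref <- chars[p + 1]
      add_variant(tx_ids[t], p, ref, if (ref == "A") "C" else "A",
                  "neutral_utr", NA, 0, 0,
                  runif(1, config$maf_range[1], config$maf_range[2]))
    }
  }

  # neutral CDS variants (cis-QTL fodder; offsets >= +6 so they are neither
  # Kozak nor start-codon positions)
  for (t in seq_len(n_tx)) {
    n_v <- rpois_capped(config$neutral_cds_variants_per_tx)
    if (!n_v) next
    lo <- cds_start[t] + 6L
    hi <- cds_end[t] - 4L
    if (hi <= lo) next
    for (p in sample_vec(lo:hi, min(n_v, hi - lo + 1L))) {
      ref <- substr(seqs[t], p + 1, p + 1)
      add_variant(tx_ids[t], p, ref, sample(setdiff(NUCS, ref), 1),
                  "neutral_cds", NA, 0, 0,
                  runif(1, config$maf_range[1], config$maf_range[2]))
    }
  }

  variants <- do.call(rbind, variants)
  var_truth <- do.call(rbind, var_truth)

  # ---- genotypes: Hardy-Weinberg, phased; a fraction emitted unphased ----
  n_v <- nrow(variants)
  maf <- var_truth$maf
  hapA <- matrix(rbinom(n_v * n_ind, 1, rep(maf, n_ind)), n_v, n_ind)
  hapB <- matrix(rbinom(n_v * n_ind, 1, rep(maf, n_ind)), n_v, n_ind)
  phased <- matrix(runif(n_v * n_ind) >= config$frac_unphased, n_v, n_ind)
  dimnames(hapA) <- dimnames(hapB) <- dimnames(phased) <-
    list(variants$variant_id, individuals)
  haps <- haplotype_set(hapA, hapB, phased)

  # ---- per-gene truth ----
  mu <- rnorm(n_tx, config$baseline_log2cpm_mean, config$baseline_log2cpm_sd)
  phi <- exp(rnorm(n_tx, config$dispersion_meanlog, config$dispersion_sdlog))
  te <- rnorm(n_tx, 0, config$te_sd_log2)
  minus3 <- substr(seqs, cds_start - 3 + 1, cds_start - 3 + 1)
  te <- te + config$kozak_te_effect * (minus3 == "A")
  rna_variable <- runif(n_tx) < config$frac_genes_rna_variable
  ro_variable <- runif(n_tx) < config$frac_genes_ro_variable
  b_rna <- matrix(0, n_tx, n_ind, dimnames = list(gene_ids, individuals))
  b_ro <- b_rna
  b_rna[rna_variable, ] <- rnorm(sum(rna_variable) * n_ind, 0,
                                 config$individual_sd_log2)
  b_ro[ro_variable, ] <- rnorm(sum(ro_variable) * n_ind, 0,
                               config$individual_sd_log2)

  # planted-event dosage (configuration dosage: haplotypes carrying any
  # defining alt allele)
  ev_rows <- list(); ev_dos <- list()
  uorf_truth <- var_truth[var_truth$role == "uorf", , drop = FALSE]
  for (txid in unique(uorf_truth$transcript_id)) {
    vt <- uorf_truth[uorf_truth$transcript_id == txid, , drop = FALSE]
    carrA <- colSums(hapA[vt$variant_id, , drop = FALSE]) > 0
    carrB <- colSums(hapB[vt$variant_id, , drop = FALSE]) > 0
    ev_rows[[length(ev_rows) + 1]] <- data.frame(
      transcript_id = txid, gene_id = gene_ids[match(txid, tx_ids)],
      event_class = vt$class[1],
      variant_ids = paste(vt$variant_id, collapse = ","),
      beta_ro = vt$beta_ro[1], stringsAsFactors = FALSE)
    ev_dos[[length(ev_rows)]] <- as.integer(carrA) + as.integer(carrB)
  }
  events <- do.call(rbind, ev_rows)
  event_dosage <- do.call(rbind, ev_dos)
  if (!is.null(event_dosage))
    dimnames(event_dosage) <- list(events$transcript_id, individuals)

  # deterministic per-gene x individual variant effects on RO / RNA
  eff_ro <- matrix(0, n_tx, n_ind, dimnames = list(gene_ids, individuals))
  eff_rna <- eff_ro
  if (!is.null(events))
    for (k in seq_len(nrow(events)))
      eff_ro[events$gene_id[k], ] <- eff_ro[events$gene_id[k], ] +
        events$beta_ro[k] * event_dosage[k, ]
  koz_eff <- var_truth[var_truth$class %in% "kozak_effect" &
                         var_truth$beta_ro != 0, , drop = FALSE]
  dos <- hapA + hapB
  for (k in seq_len(nrow(koz_eff))) {
    g <- gene_ids[match(koz_eff$transcript_id[k], tx_ids)]
    eff_ro[g, ] <- eff_ro[g, ] + koz_eff$beta_ro[k] *
      dos[koz_eff$variant_id[k], ]
  }

  truth <- list(
    genes = data.frame(gene_id = gene_ids, transcript_id = tx_ids,
                       mu = mu, phi = phi, te = te,
                       rna_variable = rna_variable,
                       ro_variable = ro_variable, stringsAsFactors = FALSE),
    b_rna = b_rna, b_ro = b_ro,
    eff_ro = eff_ro, eff_rna = eff_rna,
    variant_effects = var_truth,
    events = events, event_dosage = event_dosage,
    individuals = individuals)

  list(transcripts = tx, variants = variants, haplotypes = haps,
       truth = truth)
}

pad_codons <- function(n) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C"), 3, replace = TRUE), collapse = ""), "")
}

rpois_capped <- function(lambda, cap = 3) min(stats::rpois(1, lambda), cap)

sample_vec <- function(x, n) if (length(x) == 1) x else sample(x, n)

# TRUE for 0-based UTR positions that fall inside an embedded motif
# (anything containing G or T in the pre-Kozak UTR is motif territory).
utr_pos_in_motif <- function(sequence, pos0) {
  ch <- strsplit(sequence, "")[[1]]
  gt <- which(ch %in% c("G", "T")) - 1L
  if (!length(gt)) return(rep(FALSE, length(pos0)))
  # motif codons are 3 nt; guard 2 nt on each side
  bad <- unique(unlist(lapply(gt, function(p) (p - 2L):(p + 2L))))
  pos0 %in% bad
}

#' Simulate count libraries and protein levels
#'
#' Counts for gene g in library l are negative binomial with mean
#' `lib_size_l * 2^(mu_g + te_g * [ribo] + b_{g,i(l)} + planted effects *
#' dosage) / 1e6` and gene-specific dispersion; planted uORF/Kozak effects
#' act on ribosome-profiling libraries only. Protein level per individual is
#' `protein_scale * rank percentile of the individual's true ribosome
#' occupancy + N(0, protein_noise_sd)`. Deterministic given the config seed.
#'
#' @param sim output of [simulate_transcriptome()].
#' @param config the same [sim_config()].
#' @return A list with `expr` (an [expr_set()] holding both assays) and
#'   `protein` (genes x individuals matrix).
#' @export
simulate_counts <- function(sim, config) {
  old <- local_seed(config$seed + 1L)
  on.exit(restore_seed(old))
  truth <- sim$truth
  genes <- truth$genes$gene_id
  n_g <- length(genes)
  inds <- truth$individuals
  n_ind <- length(inds)

  samples <- do.call(rbind, lapply(inds, function(i) {
    rbind(
      data.frame(individual = i, assay = "rna",
                 replicate = seq_len(config$replicates_rna)),
      data.frame(individual = i, assay = "ribo",
                 replicate = seq_len(config$replicates_ribo)))
  }))
  samples$library_id <- sprintf("%s.%s.r%d", samples$individual,
                                samples$assay, samples$replicate)
  n_lib <- nrow(samples)
  lsz <- exp(runif(n_lib, log(config$library_size_range[1]),
                   log(config$library_size_range[2])))

  is_ribo <- samples$assay == "ribo"
  ind_of <- match(samples$individual, inds)
  logcpm <- matrix(truth$genes$mu, n_g, n_lib)
  logcpm[, is_ribo] <- logcpm[, is_ribo] + truth$genes$te
  logcpm[, is_ribo] <- logcpm[, is_ribo] +
    (truth$b_ro + truth$eff_ro)[, ind_of[is_ribo], drop = FALSE]
  logcpm[, !is_ribo] <- logcpm[, !is_ribo] +
    (truth$b_rna + truth$eff_rna)[, ind_of[!is_ribo], drop = FALSE]

  mu <- sweep(2^logcpm / 1e6, 2, lsz, "*")
  counts <- matrix(rnbinom(n_g * n_lib, mu = mu,
                           size = rep(1 / truth$genes$phi, n_lib)),
                   n_g, n_lib, dimnames = list(genes, samples$library_id))

  expr <- expr_set(counts, samples[, c("library_id", "individual", "assay",
                                       "replicate")])

  true_ro <- truth$genes$mu + truth$genes$te + truth$b_ro + truth$eff_ro
  ranks <- t(apply(true_ro, 1, rank, ties.method = "average")) / n_ind
  protein <- config$protein_scale * ranks +
    matrix(rnorm(n_g * n_ind, 0, config$protein_noise_sd), n_g, n_ind)
  dimnames(protein) <- list(genes, inds)

  list(expr = expr, protein = protein)
}

#' Run the full synthetic study
#'
#' [simulate_transcriptome()] followed by [simulate_counts()].
#'
#' @param config a [sim_config()].
#' @return A list with `transcripts`, `variants`, `haplotypes`, `truth`,
#'   `expr`, `protein`, and the `config`.
#' @export
simulate_study <- function(config) {
  sim <- simulate_transcriptome(config)
  cn <- simulate_counts(sim, config)
  c(sim, cn, list(config = config))
}

#' Simulate a synthetic term-to-gene map
#'
#' Random gene sets over the study's genes, plus one term deliberately
#' enriched in the genes flagged variable in both assays (planted
#' enrichment signal for the term-graph stage).
#'
#' @param truth the `truth` component of [simulate_transcriptome()].
#' @param n_terms number of random terms (default 30).
#' @param term_size_range genes per term (default 5..30).
#' @param seed integer seed.
#' @return `data.frame` with columns `term_id`, `gene_id`.
#' @export
simulate_go_terms <- function(truth, n_terms = 30, term_size_range = c(5, 30),
                              seed = 1) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  genes <- truth$genes$gene_id
  rows <- lapply(seq_len(n_terms), function(k) {
    sz <- sample(term_size_range[1]:term_size_range[2], 1)
    data.frame(term_id = sprintf("TERM%03d", k),
               gene_id = sample(genes, min(sz, length(genes))),
               stringsAsFactors = FALSE)
  })
  var_genes <- genes[truth$genes$rna_variable & truth$genes$ro_variable]
  if (length(var_genes) >= 3)
    rows[[length(rows) + 1]] <- data.frame(
      term_id = "TERM_VARIABLE", gene_id = var_genes,
      stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Write all study files to a directory
#'
#' Emits FASTA, annotation TSV, VCF, counts TSV, sample sheet TSV, protein
#' TSV and a ground-truth JSON into `dir`.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "transcripts.fa"),
    annotation = file.path(dir, "annotation.tsv"),
    vcf = file.path(dir, "variants.vcf"),
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    protein = file.path(dir, "protein.tsv"),
    truth = file.path(dir, "truth.json"))
  write_transcripts(study$transcripts, paths["fasta"], paths["annotation"])
  write_vcf(study$variants, study$haplotypes, paths["vcf"])
  write.table(data.frame(gene_id = rownames(study$expr$counts),
                         study$expr$counts, check.names = FALSE),
              paths["counts"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$expr$samples, paths["samples"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = rownames(study$protein), study$protein,
                         check.names = FALSE),
              paths["protein"], sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- study$truth
  truth$b_rna <- NULL; truth$b_ro <- NULL
  truth$eff_ro <- NULL; truth$eff_rna <- NULL
  truth$event_dosage <- NULL
  jsonlite::write_json(truth, paths["truth"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
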