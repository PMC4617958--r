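KOZAK_OFFSETS <- c(-6L, -5L, -4L, -3L, -2L, -1L, 3L, 4L)
KOZAK_LABELS <- c("-6", "-5", "-4", "-3", "-2", "-1", "+4", "+5")
NUCS <- c("A", "C", "G", "T")

# Extract the 8-nt Kozak context (6 nt upstream of the start codon, 2 nt
# after it; +1 = A of the ATG) for every transcript able to provide it.
kozak_context <- function(tx) {
  usable <- tx$utr5_length >= 6 & nchar(tx$sequence) >= tx$cds_start + 5
  ctx <- t(vapply(which(usable), function(i) {
    p <- tx$cds_start[i]
    substring(tx$sequence[i], p + KOZAK_OFFSETS + 1, p + KOZAK_OFFSETS + 1)
  }, character(8)))
  colnames(ctx) <- KOZAK_LABELS
  rownames(ctx) <- tx$transcript_id[usable]
  attr(ctx, "n_excluded") <- sum(!usable)
  ctx
}

#' Build the Kozak position weight matrix
#'
#' Accumulates per-position nucleotide counts over the Kozak regions of all
#' usable transcripts (those with a 5' UTR of at least 6 nt and at least
#' 2 nt after the start codon), converts to probabilities with a
#' pseudocount, and forms log2 odds against a uniform background. The start
#' codon itself (+1..+3) is invariant and excluded.
#'
#' @param transcripts transcript model `data.frame`.
#' @param pseudocount added per cell (default 0.5).
#' @return An object of class `kozak_pwm`: list with `counts`, `probs`,
#'   `log_odds` (8 positions x 4 nucleotides), `pseudocount`,
#'   `n_transcripts`, `n_excluded`.
#' @export
build_pwm <- function(transcripts, pseudocount = 0.5) {
  ctx <- kozak_context(transcripts)
  if (!nrow(ctx)) stop("no transcript provides a full Kozak region")
  counts <- t(apply(ctx, 2, function(col) table(factor(col, levels = NUCS))))
  dimnames(counts) <- list(KOZAK_LABELS, NUCS)
  probs <- (counts + pseudocount) / (rowSums(counts) + 4 * pseudocount)
  structure(list(counts = counts, probs = probs,
                 log_odds = log2(probs / 0.25),
                 pseudocount = pseudocount,
                 n_transcripts = nrow(ctx),
                 n_excluded = attr(ctx, "n_excluded")),
            class = "kozak_pwm")
}

#' @export
print.kozak_pwm <- function(x, ...) {
  cat("kozak_pwm built from", x$n_transcripts, "transcripts (",
      x$n_excluded, "excluded ); consensus:",
      paste(NUCS[apply(x$probs, 1, which.max)], collapse = ""), "\n")
  invisible(x)
}

#' Score an 8-nt Kozak context with the PWM
#'
#' The score is the sum of independent per-position log2 odds (additive by
#' construction).
#'
#' @param pwm a [build_pwm()] object.
#' @param context character vector of 8-letter Kozak contexts, or an
#'   8-column character matrix.
#' @return Numeric score(s).
#' @export
pwm_score <- function(pwm, context) {
  if (is.character(context) && !is.matrix(context))
    context <- do.call(rbind, strsplit(context, ""))
  stopifnot(ncol(context) == 8)
  vapply(seq_len(nrow(context)), function(i)
    sum(pwm$log_odds[cbind(KOZAK_LABELS, context[i, ])]), 0)
}

#' Per-position Kruskal-Wallis test of Kozak nucleotide effects on TE
#'
#' For each of the 8 Kozak positions, tests whether transcripts split by the
#' nucleotide at that position share the same global translation efficiency
#' (Kruskal-Wallis), with Bonferroni correction across the 8 positions. A
#' position with fewer than two observed nucleotide groups yields `p = NA`
#' but still counts toward the correction.
#'
#' @param transcripts transcript model `data.frame`.
#' @param te_global named vector of per-gene (or per-transcript) global TE;
#'   names matched against transcript ids, falling back to gene ids.
#' @return `data.frame` with `position`, `H`, `p`, `p_bonferroni`, `n`.
#' @export
test_position_effects <- function(transcripts, te_global) {
  ctx <- kozak_context(transcripts)
  ids <- rownames(ctx)
  te <- te_global[ids]
  if (all(is.na(te))) {
    gmap <- setNames(transcripts$gene_id, transcripts$transcript_id)
    te <- te_global[gmap[ids]]
  }
  ok <- !is.na(te)
  ctx <- ctx[ok, , drop = FALSE]
  te <- te[ok]
  res <- lapply(seq_len(8), function(j) {
    g <- factor(ctx[, j], levels = NUCS)
    g <- droplevels(g)
    if (nlevels(g) < 2 || length(te) < 2)
      return(data.frame(position = KOZAK_LABELS[j], H = NA_real_,
                        p = NA_real_, n = length(te)))
    kt <- kruskal.test(te, g)
    data.frame(position = KOZAK_LABELS[j], H = unname(kt$statistic),
               p = kt$p.value, n = length(te))
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(out$p * 8, 1)
  out
}

#' Score Kozak-region variants by PWM change
#'
#' Each variant lying at a Kozak position (-6..-1, +4, +5; variants in the
#' start codon are rejected as a caller filter bug) is scored by
#' `delta_pwm = log_odds(alt) - log_odds(ref)` at its position; additivity
#' across positions means a transcript's per-individual predictor is the sum
#' over its Kozak variants of `delta_pwm * alt-allele copies`. Variants
#' carried by fewer than `min_carriers` individuals are excluded from
#' association but reported with a direction flag (`delta_pwm < 0` =
#' weakening).
#'
#' @param variants variant `data.frame` restricted to Kozak positions (see
#'   [kozak_variants()]).
#' @param pwm a [build_pwm()] object.
#' @param transcripts transcript model `data.frame`.
#' @param haps a phase-resolved [haplotype_set()].
#' @param min_carriers minimum carrier individuals (default 3).
#' @return A list with `scores` (`data.frame`: `variant_id`,
#'   `transcript_id`, `position_label`, `delta_pwm`, `n_carriers`,
#'   `weakening`, `tested`) and `predictor` (transcripts x individuals
#'   matrix of summed `delta_pwm * dosage`, over tested variants only).
#' @export
score_kozak_variants <- function(variants, pwm, transcripts, haps,
                                 min_carriers = 3) {
  cds <- setNames(transcripts$cds_start, transcripts$transcript_id)
  off <- variants$position - cds[variants$transcript_id]
  if (any(off %in% 0:2))
    stop("variant(s) inside the start codon passed to score_kozak_variants")
  if (!all(off %in% KOZAK_OFFSETS))
    stop("variant(s) at non-Kozak positions passed to score_kozak_variants")
  lab <- KOZAK_LABELS[match(off, KOZAK_OFFSETS)]
  delta <- pwm$log_odds[cbind(lab, variants$alt)] -
    pwm$log_odds[cbind(lab, variants$ref)]
  dose <- dosage_matrix(haps)[variants$variant_id, , drop = FALSE]
  n_carriers <- rowSums(dose > 0)
  scores <- data.frame(
    variant_id = variants$variant_id,
    transcript_id = variants$transcript_id,
    position_label = lab, delta_pwm = delta,
    n_carriers = n_carriers,
    weakening = delta < 0,
    tested = n_carriers >= min_carriers,
    stringsAsFactors = FALSE)

  tx_ids <- unique(variants$transcript_id)
  predictor <- matrix(0, length(tx_ids), length(haps$individuals),
                      dimnames = list(tx_ids, haps$individuals))
  use <- which(scores$tested)
  for (k in use)
    predictor[variants$transcript_id[k], ] <-
      predictor[variants$transcript_id[k], ] + delta[k] * dose[k, ]
  list(scores = scores, predictor = predictor)
}

#' Select variants falling in annotated Kozak regions
#'
#' @param variants variant `data.frame`.
#' @param transcripts transcript model `data.frame`.
#' @return The subset of `variants` at offsets -6..-1, +4, +5 relative to
#'   the start codon (start-codon positions excluded).
#' @export
kozak_variants <- function(variants, transcripts) {
  cds <- setNames(transcripts$cds_start, transcripts$transcript_id)
  off <- variants$position - cds[variants$transcript_id]
  variants[!is.na(off) & off %in% KOZAK_OFFSETS, , drop = FALSE]
}

#' Test Kozak variant scores for association with ribosome occupancy
#'
#' Linear model of per-library ribosome occupancy log2-cpm on the
#' delta-PWM-coded additive predictor (voom-weighted OLS), with a
#' conservative random-intercept LMM alongside, and the same regression on
#' RNA expression. BH FDR at `fdr` (default 10%); translation-specific
#' requires RNA nominal p above `rna_p_threshold` (default 0.01 — stricter
#' than the uORF rule) or an opposite-signed RNA coefficient.
#'
#' @param kozak output of [score_kozak_variants()].
#' @param transcripts transcript model `data.frame` (to map transcript to
#'   gene).
#' @param expr a voom-transformed [expr_set()].
#' @param fdr BH FDR level (default 0.10).
#' @param rna_p_threshold nominal RNA p-value threshold (default 0.01).
#' @return `data.frame` of per-transcript association results.
#' @export
test_kozak_association <- function(kozak, transcripts, expr, fdr = 0.10,
                                   rna_p_threshold = 0.01) {
  gmap <- setNames(transcripts$gene_id, transcripts$transcript_id)
  rows <- list()
  for (txid in rownames(kozak$predictor)) {
    x <- kozak$predictor[txid, ]
    if (var(x) == 0) next
    gene <- gmap[[txid]]
    if (!gene %in% rownames(expr$logcpm)) next
    ribo <- assoc_one(expr, gene, x, "ribo", lmm = TRUE)
    rna <- assoc_one(expr, gene, x, "rna", lmm = FALSE)
    if (is.null(ribo) || is.null(rna)) next
    rows[[length(rows) + 1]] <- data.frame(
      unit_id = txid, gene_id = gene,
      beta_ribo = ribo$beta, p_ribo = ribo$p, p_lmm = ribo$p_lmm,
      beta_rna = rna$beta, p_rna = rna$p, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame())
  res <- do.call(rbind, rows)
  res$fdr <- p.adjust(res$p_ribo, method = "BH")
  res$significant <- res$fdr < fdr
  res$translation_specific <- res$p_rna > rna_p_threshold |
    sign(res$beta_rna) != sign(res$beta_ribo)
  rownames(res) <- NULL
  res
}
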