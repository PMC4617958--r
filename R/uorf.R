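#' Scan a transcript sequence for upstream open reading frames
#'
#' A uORF initiates at an ATG or CTG strictly upstream of the annotated CDS
#' start and ends at the first in-frame stop codon (TAA, TAG or TGA)
#' downstream. The stop search extends into the CDS region; uORFs whose
#' stop begins at or beyond the CDS start are flagged `overlaps_cds`.
#' Starts with no in-frame stop anywhere in the transcript are dropped by
#' default, or reported with `stop = NA` when `keep_no_stop = TRUE`.
#'
#' @param sequence transcript DNA sequence (character scalar).
#' @param cds_start 0-based offset of the main ORF start codon.
#' @param start_codons,stop_codons codon sets for initiation/termination.
#' @param require_stop_in_utr5 if `TRUE`, drop uORFs whose stop codon
#'   extends past the CDS start (both conventions exist in the literature).
#' @param min_length minimum uORF length in nt, measured start-to-stop
#'   inclusive of the stop codon (default 0 = no constraint beyond
#'   start + stop).
#' @param keep_no_stop report starts lacking any in-frame stop.
#' @return `data.frame` with 0-based columns `start`, `stop` (first base of
#'   the stop codon), plus `start_codon`, `frame`, `overlaps_cds`.
#' @export
scan_uorfs <- function(sequence, cds_start,
                       start_codons = c("ATG", "CTG"),
                       stop_codons = c("TAA", "TAG", "TGA"),
                       require_stop_in_utr5 = FALSE,
                       min_length = 0, keep_no_stop = FALSE) {
  L <- nchar(sequence)
  empty <- data.frame(start = integer(0), stop = integer(0),
                      start_codon = character(0), frame = integer(0),
                      overlaps_cds = logical(0))
  if (L < 3 || cds_start < 1) return(empty)
  codons <- substring(sequence, 1:(L - 2), 3:L)
  pos0 <- 0:(L - 3)
  starts <- pos0[codons %in% start_codons & pos0 < cds_start]
  if (!length(starts)) return(empty)
  stop_pos <- pos0[codons %in% stop_codons]
  stops_by_frame <- split(stop_pos, stop_pos %% 3)

  stop_of <- vapply(starts, function(s) {
    cand <- stops_by_frame[[as.character(s %% 3)]]
    cand <- cand[cand >= s + 3]
    if (length(cand)) cand[1] else NA_integer_
  }, 0L)

  out <- data.frame(
    start = starts, stop = stop_of,
    start_codon = substring(sequence, starts + 1, starts + 3),
    frame = starts %% 3L,
    overlaps_cds = !is.na(stop_of) & stop_of >= cds_start,
    stringsAsFactors = FALSE
  )
  if (!keep_no_stop) out <- out[!is.na(out$stop), , drop = FALSE]
  if (require_stop_in_utr5)
    out <- out[is.na(out$stop) | out$stop + 3 <= cds_start, , drop = FALSE]
  if (min_length > 0)
    out <- out[is.na(out$stop) | (out$stop + 3 - out$start) >= min_length, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Canonical signature of a uORF configuration
#'
#' Injective over configurations; haplotypes sharing a signature carry the
#' same uORF architecture.
#'
#' @param uorfs output of [scan_uorfs()].
#' @return Character scalar.
#' @export
uorf_signature <- function(uorfs) {
  if (!nrow(uorfs)) return("")
  o <- order(uorfs$start, uorfs$stop)
  paste(sprintf("%d-%d:%s", uorfs$start[o], uorfs$stop[o],
                uorfs$start_codon[o]), collapse = ";")
}

#' Classify reference-to-alternate uORF architecture changes
#'
#' Compares two uORF configurations of the same transcript by their
#' (start, stop) pairs:
#' * `gain` — a start present only in the alternate configuration;
#' * `loss` — a start present only in the reference;
#' * `premature_stop` — same start, earlier stop;
#' * `merge` — same start, later stop that reaches at/past the stop of
#'   another reference uORF downstream (the extension swallows it);
#' * `stop_loss_extension` — same start, later stop, no uORF swallowed;
#' * `other` — any remaining difference (e.g. a start-codon identity change
#'   at an unchanged position).
#'
#' @param ref_config,alt_config outputs of [scan_uorfs()] for the reference
#'   and alternate haplotype sequences.
#' @return `data.frame` with columns `event_type`, `start`, `stop_ref`,
#'   `stop_alt`; zero rows when the configurations are identical.
#' @export
diff_configurations <- function(ref_config, alt_config) {
  ref <- ref_config[!is.na(ref_config$stop), , drop = FALSE]
  alt <- alt_config[!is.na(alt_config$stop), , drop = FALSE]
  events <- list()
  add <- function(type, start, stop_ref, stop_alt)
    events[[length(events) + 1]] <<- data.frame(
      event_type = type, start = start,
      stop_ref = stop_ref, stop_alt = stop_alt, stringsAsFactors = FALSE)

  gained <- setdiff(alt$start, ref$start)
  lost <- setdiff(ref$start, alt$start)
  for (s in gained) add("gain", s, NA_integer_, alt$stop[alt$start == s][1])
  for (s in lost) add("loss", s, ref$stop[ref$start == s][1], NA_integer_)

  common <- intersect(ref$start, alt$start)
  for (s in common) {
    r <- ref[ref$start == s, ][1, ]
    a <- alt[alt$start == s, ][1, ]
    if (r$stop == a$stop) {
      if (r$start_codon != a$start_codon)
        add("other", s, r$stop, a$stop)
      next
    }
    if (a$stop < r$stop) {
      add("premature_stop", s, r$stop, a$stop)
    } else {
      swallowed <- any(ref$start > s & ref$start != s & ref$stop <= a$stop &
                         ref$stop > r$stop)
      add(if (swallowed) "merge" else "stop_loss_extension", s,
          r$stop, a$stop)
    }
  }
  if (!length(events))
    return(data.frame(event_type = character(0), start = integer(0),
                      stop_ref = integer(0), stop_alt = integer(0)))
  do.call(rbind, events)
}

#' Enumerate uORF events across haplotypes
#'
#' For each transcript, every observed haplotype allele combination over its
#' 5' UTR variants is materialized as a sequence, scanned, and compared to
#' the reference configuration. Haplotypes sharing the same changed
#' configuration are pooled into one event, so multiple distinct variants
#' causing the same architecture change share an event and their carriers
#' are combined. Per-individual dosage is the number of haplotypes (0/1/2)
#' carrying the event's configuration.
#'
#' @param transcripts transcript model `data.frame`.
#' @param variants variant `data.frame`.
#' @param haps a phase-resolved [haplotype_set()].
#' @param min_carriers drop events carried by fewer individuals (default 3).
#' @param ... passed to [scan_uorfs()].
#' @return A list with `events` (`data.frame`: `event_id`, `transcript_id`,
#'   `gene_id`, `event_type`, `signature`, `defining_variants`,
#'   `n_carriers`) and `dosage` (events x individuals integer matrix).
#' @export
enumerate_events <- function(transcripts, variants, haps, min_carriers = 3,
                             ...) {
  inds <- haps$individuals
  ev_rows <- list()
  dos_rows <- list()
  for (t in seq_len(nrow(transcripts))) {
    tx <- transcripts[t, , drop = FALSE]
    vt <- variants[variants$transcript_id == tx$transcript_id &
                     variants$position < tx$cds_start, , drop = FALSE]
    if (!nrow(vt)) next
    vid <- vt$variant_id
    hapA <- haps$hapA[vid, , drop = FALSE]
    hapB <- haps$hapB[vid, , drop = FALSE]
    combos <- cbind(hapA, hapB)           # variants x 2N haplotypes
    keys <- apply(combos, 2, paste, collapse = "")
    ref_scan <- scan_uorfs(tx$sequence, tx$cds_start, ...)
    ref_sig <- uorf_signature(ref_scan)

    sig_of_key <- vapply(unique(keys), function(k) {
      alleles <- as.integer(strsplit(k, "")[[1]])
      uorf_signature(scan_uorfs(haplotype_sequence(tx, vt, alleles),
                                tx$cds_start, ...))
    }, "")
    hap_sigs <- sig_of_key[keys]
    alt_sigs <- setdiff(unique(hap_sigs), ref_sig)
    for (sig in alt_sigs) {
      carrier_keys <- unique(keys[hap_sigs == sig])
      alleles1 <- as.integer(strsplit(carrier_keys[1], "")[[1]])
      alt_scan <- scan_uorfs(haplotype_sequence(tx, vt, alleles1),
                             tx$cds_start, ...)
      ev <- diff_configurations(ref_scan, alt_scan)
      type <- if (nrow(ev) == 1) ev$event_type else "other"
      # dosage: count haplotypes per individual with this signature
      # (columns of `combos` are the N hapA then the N hapB haplotypes)
      hapmat <- matrix(hap_sigs == sig, ncol = 2)
      dosage <- as.integer(hapmat[, 1]) + as.integer(hapmat[, 2])
      # defining variants: alt in some carrier haplotype, and toggling the
      # allele off changes that haplotype's configuration (so passenger
      # alleles that ride along on a carrier haplotype are excluded)
      defining <- character(0)
      for (k in carrier_keys) {
        alle <- as.integer(strsplit(k, "")[[1]])
        for (j in which(alle == 1)) {
          if (vid[j] %in% defining) next
          toggled <- alle; toggled[j] <- 0L
          sig_t <- uorf_signature(scan_uorfs(
            haplotype_sequence(tx, vt, toggled), tx$cds_start, ...))
          if (!identical(sig_t, sig)) defining <- c(defining, vid[j])
        }
      }
      defining <- vid[vid %in% defining]
      n_carriers <- sum(dosage > 0)
      if (n_carriers < min_carriers) next
      ev_rows[[length(ev_rows) + 1]] <- data.frame(
        transcript_id = tx$transcript_id, gene_id = tx$gene_id,
        event_type = type, signature = sig,
        defining_variants = paste(defining, collapse = ","),
        n_carriers = n_carriers, stringsAsFactors = FALSE)
      dos_rows[[length(ev_rows)]] <- dosage
    }
  }
  if (!length(ev_rows))
    return(list(events = data.frame(), dosage = matrix(0L, 0, length(inds))))
  events <- do.call(rbind, ev_rows)
  events$event_id <- sprintf("%s.ev%d", events$transcript_id,
                             stats::ave(seq_len(nrow(events)),
                                        events$transcript_id,
                                        FUN = seq_along))
  events <- events[, c("event_id", setdiff(names(events), "event_id"))]
  dosage <- do.call(rbind, dos_rows)
  dimnames(dosage) <- list(events$event_id, inds)
  list(events = events, dosage = dosage)
}

# Weighted OLS + LMM association of one per-individual predictor with one
# gene's per-library expression in one assay. Returns beta, p (OLS) and
# Wald p from the random-intercept LMM.
assoc_one <- function(expr, gene, predictor, assay, lmm = TRUE) {
  idx <- expr$samples$assay == assay
  ind <- as.character(expr$samples$individual[idx])
  x <- predictor[ind]
  y <- expr$logcpm[gene, idx]
  w <- expr$weights[gene, idx]
  ok <- !is.na(x)
  x <- x[ok]; y <- y[ok]; w <- w[ok]; ind <- ind[ok]
  if (length(unique(x)) < 2) return(NULL)
  fit <- lm(y ~ x, weights = w)
  sm <- summary(fit)$coefficients
  out <- list(beta = sm["x", "Estimate"], p = sm["x", "Pr(>|t|)"])
  if (lmm) {
    p_lmm <- tryCatch({
      lfit <- suppressWarnings(suppressMessages(
        lme4::lmer(y ~ x + (1 | ind), weights = w, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular =
                     lme4::.makeCC(action = "ignore", tol = 1e-4)))))
      cf <- summary(lfit)$coefficients
      2 * pnorm(-abs(cf["x", "t value"]))
    }, error = function(e) NA_real_)
    out$p_lmm <- p_lmm
  }
  out
}

#' Test uORF events for association with ribosome occupancy
#'
#' Per event, regresses per-library ribosome occupancy log2-cpm of the main
#' coding region (voom-weighted) on the event dosage (0/1/2), plus a more
#' conservative linear mixed model with an individual random intercept
#' (replicate libraries of one individual treated as technical replicates;
#' Wald p). The same regression is run on RNA expression. BH FDR is applied
#' over events on the ribosome-occupancy p-values; an association is flagged
#' translation-specific when the RNA nominal p exceeds `rna_p_threshold` or
#' the RNA coefficient has the opposite sign.
#'
#' @param events output of [enumerate_events()].
#' @param expr a voom-transformed [expr_set()] containing both assays.
#' @param fdr BH FDR level on the ribo phenotype (default 0.05).
#' @param rna_p_threshold nominal RNA p-value threshold (default 0.05).
#' @return `data.frame` with one row per testable event: effect sizes,
#'   p-values (OLS and LMM), FDR, significance and translation-specificity.
#' @export
test_uorf_association <- function(events, expr, fdr = 0.05,
                                  rna_p_threshold = 0.05) {
  ev <- events$events
  rows <- list()
  for (k in seq_len(nrow(ev))) {
    gene <- ev$gene_id[k]
    if (!gene %in% rownames(expr$logcpm)) next
    dose <- events$dosage[ev$event_id[k], ]
    if (var(dose) == 0) {
      warning("event ", ev$event_id[k], " has zero dosage variance, skipped",
              call. = FALSE)
      next
    }
    ribo <- assoc_one(expr, gene, dose, "ribo", lmm = TRUE)
    rna <- assoc_one(expr, gene, dose, "rna", lmm = FALSE)
    if (is.null(ribo) || is.null(rna)) next
    rows[[length(rows) + 1]] <- data.frame(
      unit_id = ev$event_id[k], gene_id = gene,
      event_type = ev$event_type[k],
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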