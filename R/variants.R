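#' Construct a phased haplotype set
#'
#' A haplotype set holds diploid 0/1 allele matrices (variants x individuals)
#' for the two haplotypes of every individual, plus a phased flag per
#' genotype. Homozygous and phased-heterozygous entries are authoritative;
#' unphased heterozygotes carry an arbitrary A/B assignment until
#' [resolve_phase()] randomizes it.
#'
#' @param hapA,hapB integer matrices (variants x individuals) of 0/1 alleles,
#'   with rownames = variant ids and colnames = individual ids.
#' @param phased logical matrix of the same shape.
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(hapA, hapB, phased) {
  stopifnot(all(dim(hapA) == dim(hapB)), all(dim(hapA) == dim(phased)),
            !is.null(rownames(hapA)), !is.null(colnames(hapA)),
            all(hapA %in% 0:1), all(hapB %in% 0:1))
  structure(list(hapA = hapA, hapB = hapB, phased = phased,
                 variant_id = rownames(hapA),
                 individuals = colnames(hapA)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", length(x$variant_id), "variants x",
      length(x$individuals), "individuals;",
      sum(!x$phased), "unphased genotype entries\n")
  invisible(x)
}

#' Diploid alternate-allele dosage matrix
#'
#' @param haps a `haplotype_set`.
#' @return Integer matrix (variants x individuals) of 0/1/2 alt-allele copies.
#' @export
dosage_matrix <- function(haps) {
  d <- haps$hapA + haps$hapB
  dimnames(d) <- list(haps$variant_id, haps$individuals)
  d
}

#' Map VCF records to transcript coordinates
#'
#' Reads a VCF (v4.x) with GT fields, retains biallelic SNVs that fall on a
#' known transcript, converts 1-based VCF positions to 0-based transcript
#' offsets, and parses `|` as phased, `/` as unphased. Indels, multi-allelic
#' records, records on unknown contigs, and records whose REF allele
#' disagrees with the transcript sequence are dropped and counted.
#'
#' @param vcf_path path to a VCF file.
#' @param transcripts transcript model `data.frame`.
#' @param contig_map function mapping `(contig, pos1based)` to a list with
#'   `transcript_id` and `position` (0-based transcript offset). The default
#'   is the identity map used by the synthetic study: one contig per
#'   transcript, `position = pos - 1`.
#' @return A list with `variants` (data.frame: `variant_id`, `transcript_id`,
#'   `position`, `ref`, `alt`), `haplotypes` (a [haplotype_set()]), and
#'   `dropped` (named counts of discarded records).
#' @export
map_vcf_to_transcripts <- function(vcf_path, transcripts,
                                   contig_map = identity_contig_map) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- v@gt
  inds <- colnames(gt)[-1]
  gt_str <- sub(":.*$", "", gt[, -1, drop = FALSE])

  dropped <- c(indel = 0L, multiallelic = 0L, unknown_contig = 0L,
               ref_mismatch = 0L)
  n <- nrow(fix)
  keep <- rep(TRUE, n)
  tx_id <- character(n); pos0 <- integer(n)
  seq_by_tx <- setNames(transcripts$sequence, transcripts$transcript_id)

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  dropped["multiallelic"] <- sum(multi)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  dropped["indel"] <- sum(indel)
  keep <- !multi & !indel

  for (k in which(keep)) {
    m <- contig_map(fix[k, "CHROM"], as.integer(fix[k, "POS"]))
    if (is.null(m) || !m$transcript_id %in% names(seq_by_tx)) {
      dropped["unknown_contig"] <- dropped["unknown_contig"] + 1L
      keep[k] <- FALSE
      next
    }
    tx_id[k] <- m$transcript_id
    pos0[k] <- m$position
    base <- substr(seq_by_tx[[m$transcript_id]], m$position + 1L, m$position + 1L)
    if (!identical(base, ref[k])) {
      dropped["ref_mismatch"] <- dropped["ref_mismatch"] + 1L
      keep[k] <- FALSE
    }
  }
  if (sum(dropped) > 0)
    warning("dropped VCF records: ",
            paste(names(dropped), dropped, sep = "=", collapse = ", "),
            call. = FALSE)

  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  variants <- data.frame(
    variant_id = ids[keep], transcript_id = tx_id[keep],
    position = pos0[keep], ref = ref[keep], alt = alt[keep],
    stringsAsFactors = FALSE
  )

  gk <- gt_str[keep, , drop = FALSE]
  a1 <- suppressWarnings(as.integer(substr(gk, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gk, 3, 3)))
  ph <- substr(gk, 2, 2) == "|"
  shape <- function(x) matrix(x, nrow = nrow(gk), ncol = length(inds),
                              dimnames = list(variants$variant_id, inds))
  list(variants = variants,
       haplotypes = haplotype_set(shape(a1), shape(a2), shape(ph)),
       dropped = dropped)
}

#' @rdname map_vcf_to_transcripts
#' @param contig VCF CHROM field.
#' @param pos VCF POS field (1-based).
#' @export
identity_contig_map <- function(contig, pos) {
  list(transcript_id = contig, position = pos - 1L)
}

#' Write variants + genotypes as a VCF v4.2 file
#'
#' One contig per transcript (the synthetic-study convention); transcript
#' 0-based offsets become 1-based VCF positions. Phased genotypes are written
#' with `|`, unphased with `/`.
#'
#' @param variants variant `data.frame` as from [map_vcf_to_transcripts()].
#' @param haps a [haplotype_set()] over the same variants.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(variants, haps, path) {
  stopifnot(identical(variants$variant_id, haps$variant_id))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ribovar",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", haps$individuals), collapse = "\t")
  )
  sep <- ifelse(haps$phased, "|", "/")
  gt <- matrix(paste0(haps$hapA, sep, haps$hapB), nrow = nrow(haps$hapA))
  body <- apply(cbind(variants$transcript_id, variants$position + 1L,
                      variants$variant_id, variants$ref, variants$alt,
                      ".", "PASS", ".", "GT", gt),
                1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Randomly assign phase to unphased heterozygotes
#'
#' Unphased heterozygous genotypes get their alternate allele placed on
#' haplotype A or B uniformly at random; homozygotes and phased genotypes are
#' untouched. Deterministic given `seed`.
#'
#' @param haps a [haplotype_set()].
#' @param seed integer seed (mandatory).
#' @return A `haplotype_set` with all entries flagged phased.
#' @export
resolve_phase <- function(haps, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  het_unphased <- which(!haps$phased & (haps$hapA != haps$hapB))
  if (length(het_unphased)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    alt_on_A <- runif(length(het_unphased)) < 0.5
    haps$hapA[het_unphased] <- as.integer(alt_on_A)
    haps$hapB[het_unphased] <- as.integer(!alt_on_A)
  }
  haps$phased[] <- TRUE
  haps
}

#' Reconstruct a haplotype sequence
#'
#' Substitutes alternate alleles into the reference transcript sequence at
#' positions where the haplotype carries the alt allele. SNV-only, so length
#' is preserved. Two variants at the same position are an error.
#'
#' @param transcript one row of a transcript model `data.frame`.
#' @param variants variant `data.frame` rows lying on this transcript.
#' @param alleles 0/1 vector over `variants` (1 = alt on this haplotype).
#' @return The haplotype sequence as a character scalar.
#' @export
haplotype_sequence <- function(transcript, variants, alleles) {
  stopifnot(nrow(transcript) == 1, length(alleles) == nrow(variants))
  if (anyDuplicated(variants$position))
    stop("overlapping variants at the same transcript position")
  s <- transcript$sequence
  carry <- which(alleles == 1)
  for (k in carry) {
    p <- variants$position[k] + 1L
    if (substr(transcript$sequence, p, p) != variants$ref[k])
      stop("variant ", variants$variant_id[k],
           " REF disagrees with the reference transcript sequence")
    substr(s, p, p) <- variants$alt[k]
  }
  s
}

# Seed handling: run a block under a temporary RNG state without disturbing
# the caller's stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
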