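#' Build a transcript model table
#'
#' Transcript models are the substrate for uORF and Kozak scanning. All
#' coordinates are 0-based, half-open, in transcript orientation (5'->3'):
#' `cds_start` is the offset of the first base of the annotated start codon,
#' `cds_end` the exclusive offset of the end of the stop codon, and the
#' 5' UTR is `sequence[0:cds_start]`.
#'
#' @param transcript_id,gene_id character vectors.
#' @param sequence character vector of DNA sequences (A/C/G/T, transcript
#'   orientation).
#' @param cds_start,cds_end integer vectors, 0-based half-open CDS span.
#' @return A `data.frame` with one row per transcript and columns
#'   `transcript_id`, `gene_id`, `sequence`, `cds_start`, `cds_end`,
#'   `utr5_length`, validated against the model invariants.
#' @export
transcript_models <- function(transcript_id, gene_id, sequence,
                              cds_start, cds_end) {
  tx <- data.frame(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    sequence = toupper(as.character(sequence)),
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end),
    stringsAsFactors = FALSE
  )
  tx$utr5_length <- tx$cds_start
  validate_transcripts(tx)
}

validate_transcripts <- function(tx, warn = TRUE) {
  len <- nchar(tx$sequence)
  ok_coord <- tx$cds_start >= 0 & tx$cds_start < tx$cds_end & tx$cds_end <= len
  start_codon <- substr(tx$sequence, tx$cds_start + 1, tx$cds_start + 3)
  ok_start <- ok_coord & start_codon == "ATG"
  bad <- !ok_start
  if (any(bad) && warn) {
    warning(sum(bad), " transcript(s) failed validation (bad CDS coordinates ",
            "or CDS not starting with ATG) and were skipped: ",
            paste(utils::head(tx$transcript_id[bad], 5), collapse = ", "),
            call. = FALSE)
  }
  tx[ok_start, , drop = FALSE]
}

#' Load transcript models from FASTA + annotation
#'
#' The annotation is a tab-separated table with columns `transcript_id`,
#' `gene_id`, `cds_start`, `cds_end` (0-based, half-open, transcript
#' coordinates). FASTA record IDs must match `transcript_id`.
#'
#' Transcripts violating the model invariants (CDS out of range, CDS not
#' starting with ATG) are skipped with a warning; an annotated transcript
#' with no FASTA sequence is an error.
#'
#' @param fasta_path path to a FASTA file of transcript sequences.
#' @param annotation_path path to the annotation TSV.
#' @return A validated transcript model `data.frame` (see
#'   [transcript_models()]).
#' @export
load_transcripts <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  req <- c("transcript_id", "gene_id", "cds_start", "cds_end")
  if (!all(req %in% names(ann)))
    stop("annotation must have columns: ", paste(req, collapse = ", "))
  missing <- setdiff(ann$transcript_id, ids)
  if (length(missing))
    stop("no FASTA sequence for annotated transcript(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  seq_chr <- as.character(seqs)
  names(seq_chr) <- ids
  transcript_models(ann$transcript_id, ann$gene_id,
                    seq_chr[ann$transcript_id],
                    ann$cds_start, ann$cds_end)
}

#' Write transcript models to FASTA + annotation TSV
#'
#' Inverse of [load_transcripts()]; used by the synthetic-study generator.
#'
#' @param tx transcript model `data.frame`.
#' @param fasta_path,annotation_path output paths.
#' @return Invisibly, the input `tx`.
#' @export
write_transcripts <- function(tx, fasta_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(tx$sequence)
  names(seqs) <- tx$transcript_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  write.table(tx[, c("transcript_id", "gene_id", "cds_start", "cds_end")],
              annotation_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tx)
}
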