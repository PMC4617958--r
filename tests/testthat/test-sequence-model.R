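test_that("transcript loading validates coordinates and start codon", {
  fa <- tempfile(fileext = ".fa")
  ann <- tempfile(fileext = ".tsv")
  writeLines(c(">t1", "GGATGGCCTAA", ">t2", "GGCTGGCCTAA"), fa)
  write.table(data.frame(transcript_id = c("t1", "t2"),
                         gene_id = c("g1", "g2"),
                         cds_start = c(2, 2), cds_end = c(11, 11)),
              ann, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(tx <- load_transcripts(fa, ann), "skipped")
  expect_equal(nrow(tx), 1)                  # t2 CDS starts CTG -> skipped
  expect_equal(tx$transcript_id, "t1")
  expect_equal(tx$utr5_length, 2)

  # annotated transcript without sequence is a hard error
  write.table(data.frame(transcript_id = "t9", gene_id = "g9",
                         cds_start = 2, cds_end = 11),
              ann, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_transcripts(fa, ann), "no FASTA sequence")
})

test_that("transcripts round-trip through FASTA + annotation", {
  sim <- simulate_transcriptome(sim_config(n_individuals = 4,
                                           n_transcripts = 100, seed = 7))
  d <- tempfile(); dir.create(d)
  write_transcripts(sim$transcripts, file.path(d, "t.fa"),
                    file.path(d, "t.tsv"))
  back <- load_transcripts(file.path(d, "t.fa"), file.path(d, "t.tsv"))
  expect_equal(nrow(back), 100)
  expect_equal(back$sequence, sim$transcripts$sequence)
  expect_equal(back$cds_start, sim$transcripts$cds_start)
  expect_equal(back$cds_end, sim$transcripts$cds_end)
  expect_equal(back$utr5_length, sim$transcripts$utr5_length)
})

test_that("VCF records map to 0-based transcript coordinates", {
  tx <- tiny_transcripts()
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("t1", 3, "rs1", "A", "G", ".", "PASS", ".", "GT", "0|1", "1/1",
          sep = "\t"),
    paste("t1", 4, "rs2", "T", "TG", ".", "PASS", ".", "GT", "0|0", "0|1",
          sep = "\t"),                                  # indel -> dropped
    paste("t1", 5, "rs3", "C", "G", ".", "PASS", ".", "GT", "0|0", "0|1",
          sep = "\t")),                                 # REF mismatch (is G)
    vcf)
  expect_warning(m <- map_vcf_to_transcripts(vcf, tx), "dropped")
  expect_equal(nrow(m$variants), 1)
  expect_equal(m$variants$position, 2)                  # 1-based 3 -> 0-based 2
  expect_equal(m$variants$ref, "A")
  expect_equal(unname(m$dropped["indel"]), 1L)
  expect_equal(unname(m$dropped["ref_mismatch"]), 1L)
  expect_equal(unname(m$haplotypes$hapA[, "s1"]), 0L)
  expect_equal(unname(m$haplotypes$hapB[, "s1"]), 1L)
  expect_true(m$haplotypes$phased["rs1", "s1"])
  expect_false(m$haplotypes$phased["rs1", "s2"])        # "/" genotype
})

test_that("VCF write/read round-trips positions, alleles and genotypes", {
  sim <- simulate_transcriptome(sim_config(n_individuals = 20,
                                           n_transcripts = 80, seed = 11))
  expect_gt(nrow(sim$variants), 100)
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(sim$variants, sim$haplotypes, vcf)
  back <- map_vcf_to_transcripts(vcf, sim$transcripts)
  expect_equal(back$variants$position, sim$variants$position)
  expect_equal(back$variants$ref, sim$variants$ref)
  expect_equal(back$variants$alt, sim$variants$alt)
  expect_equal(back$haplotypes$hapA, sim$haplotypes$hapA)
  expect_equal(back$haplotypes$hapB, sim$haplotypes$hapB)
  expect_equal(back$haplotypes$phased, sim$haplotypes$phased)
})

test_that("phase resolution is seeded, leaves homozygotes, and is fair", {
  n <- 10000
  hapA <- matrix(1L, n, 1, dimnames = list(sprintf("v%d", 1:n), "i1"))
  hapB <- matrix(0L, n, 1, dimnames = dimnames(hapA))
  phased <- matrix(FALSE, n, 1, dimnames = dimnames(hapA))
  hs <- haplotype_set(hapA, hapB, phased)

  r1 <- resolve_phase(hs, seed = 1)
  r2 <- resolve_phase(hs, seed = 1)
  expect_identical(r1$hapA, r2$hapA)
  expect_true(all(r1$phased))
  expect_equal(r1$hapA + r1$hapB, hapA + hapB)          # dosage preserved

  # unphased hets land on hap A with probability 1/2
  frac <- mean(r1$hapA)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))

  # homozygotes never change
  hom <- haplotype_set(hapA, hapA, phased)
  rh <- resolve_phase(hom, seed = 3)
  expect_identical(rh$hapA, hapA)
  expect_identical(rh$hapB, hapA)
})

test_that("haplotype sequence substitution is an involution", {
  tx <- tiny_transcripts()[1, ]
  vars <- data.frame(variant_id = "v1", transcript_id = "t1", position = 0,
                     ref = "G", alt = "C", stringsAsFactors = FALSE)
  expect_equal(haplotype_sequence(tx, vars, 0), tx$sequence)
  expect_equal(haplotype_sequence(tx, vars, 1), "CGATGGCCTAA")

  # apply ref->alt then alt->ref restores the input, for random variant sets
  set.seed(5)
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
               collapse = "")
    t1 <- data.frame(transcript_id = "x", gene_id = "x", sequence = s,
                     cds_start = 40, cds_end = 49, utr5_length = 40,
                     stringsAsFactors = FALSE)
    pos <- sample(0:49, 5)
    ref <- substring(s, pos + 1, pos + 1)
    alt <- vapply(ref, function(r) sample(setdiff(c("A","C","G","T"), r), 1), "")
    v <- data.frame(variant_id = paste0("v", 1:5), transcript_id = "x",
                    position = pos, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
    s_alt <- haplotype_sequence(t1, v, rep(1, 5))
    t_alt <- t1; t_alt$sequence <- s_alt
    v_back <- v; v_back$ref <- v$alt; v_back$alt <- v$ref
    expect_equal(haplotype_sequence(t_alt, v_back, rep(1, 5)), s)
  }

  # overlapping variants at one position are rejected
  v2 <- rbind(vars, vars)
  expect_error(haplotype_sequence(tx, v2, c(1, 1)), "overlapping")
})
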