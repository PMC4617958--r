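test_that("scanner handles canonical architectures", {
  # single uORF right at the 5' end
  s <- paste0("ATGTAA", "CC", "ATGCCCTAA")
  u <- scan_uorfs(s, cds_start = 8)
  expect_equal(u$start, 0)
  expect_equal(u$stop, 3)
  expect_false(u$overlaps_cds)

  # two short uORFs: ATG xxx TGA ... ATG zzz TAA (x/y/z chosen so no
  # incidental start codon spans a boundary)
  s2 <- paste0("ATG", "CAG", "TGA", "CAC", "ATG", "CAC", "TAA",
               "ATGAAATAA")
  u2 <- scan_uorfs(s2, cds_start = 21)
  expect_equal(u2$start, c(0, 12))
  expect_equal(u2$stop, c(6, 18))
  expect_equal(u2$start_codon, c("ATG", "ATG"))

  # CTG initiation and a stop inside the CDS (overlap flagged)
  s3 <- paste0("CTGCCCCCC", "ATGTAACCC")
  u3 <- scan_uorfs(s3, cds_start = 9)
  expect_equal(u3$start, 0)
  expect_equal(u3$stop, 12)          # first in-frame stop lies in the CDS
  expect_true(u3$overlaps_cds)
  # excluded when stops are required inside the UTR
  expect_equal(nrow(scan_uorfs(s3, 9, require_stop_in_utr5 = TRUE)), 0)

  # start with no in-frame stop anywhere is dropped (or kept on request)
  s4 <- paste0("ATGCC", "ATGCCCCCC")
  expect_equal(nrow(scan_uorfs(s4, 5)), 0)
  kept <- scan_uorfs(s4, 5, keep_no_stop = TRUE)
  expect_equal(kept$start, 0)
  expect_true(is.na(kept$stop))
})

test_that("scanner equals exhaustive codon-walk enumeration on random UTRs", {
  set.seed(10)
  for (i in 1:1000) {
    s <- random_transcript_seq(300)
    cds_start <- nchar(s) - 33
    got <- scan_uorfs(s, cds_start)
    want <- brute_force_uorfs(s, cds_start)
    expect_identical(got, want)
  }
})

test_that("configuration diffs classify the canonical event types", {
  mk <- function(start, stop) data.frame(
    start = start, stop = stop,
    start_codon = rep("ATG", length(start)),
    frame = start %% 3, overlaps_cds = rep(FALSE, length(start)),
    stringsAsFactors = FALSE)

  # identical configurations: no events
  expect_equal(nrow(diff_configurations(mk(0, 9), mk(0, 9))), 0)

  # premature stop shortens an existing uORF
  d1 <- diff_configurations(mk(5, 20), mk(5, 11))
  expect_equal(d1$event_type, "premature_stop")

  # removing a stop merges two uORFs into one long uORF
  d2 <- diff_configurations(mk(c(0, 15), c(9, 24)), mk(c(0, 15), c(24, 24)))
  expect_equal(d2$event_type, "merge")

  # extension that swallows nothing
  d3 <- diff_configurations(mk(0, 9), mk(0, 18))
  expect_equal(d3$event_type, "stop_loss_extension")

  # gain and loss of starts
  expect_equal(diff_configurations(mk(integer(0), integer(0)),
                                   mk(3, 12))$event_type, "gain")
  expect_equal(diff_configurations(mk(3, 12),
                                   mk(integer(0), integer(0)))$event_type,
               "loss")
})

test_that("event enumeration pools convergent variants and recovers truth", {
  cfg <- sim_config(n_individuals = 25, n_transcripts = 50, seed = 17)
  sim <- simulate_transcriptome(cfg)
  haps <- resolve_phase(sim$haplotypes, seed = 1)
  ev <- enumerate_events(sim$transcripts, sim$variants, haps,
                         min_carriers = 1)
  # exactly the planted events, one per class, nothing else
  expect_equal(sort(ev$events$event_type),
               sort(sim$truth$events$event_class))
  expect_setequal(ev$events$transcript_id, sim$truth$events$transcript_id)

  # the merge event pools carriers of both stop-ablating SNVs
  mg <- ev$events[ev$events$event_type == "merge", ]
  expect_length(strsplit(mg$defining_variants, ",")[[1]], 2)
  truth_dos <- sim$truth$event_dosage[
    sim$truth$events$event_class == "merge", ]
  expect_equal(unname(ev$dosage[mg$event_id, ]), unname(truth_dos))

  # dosage is a haplotype count in {0, 1, 2}
  expect_true(all(ev$dosage %in% 0:2))
})

test_that("hand-built genotypes give the expected event dosage", {
  tx <- transcript_models("t1", "g1",
                          paste0("CCATGCACTAACC", "ATGAAATAA"), 13, 22)
  vars <- data.frame(variant_id = "v1", transcript_id = "t1", position = 3,
                     ref = "T", alt = "A", stringsAsFactors = FALSE)
  hapA <- matrix(c(1L, 0L, 1L), 1, 3,
                 dimnames = list("v1", c("i1", "i2", "i3")))
  hapB <- matrix(c(1L, 0L, 0L), 1, 3, dimnames = dimnames(hapA))
  haps <- haplotype_set(hapA, hapB,
                        matrix(TRUE, 1, 3, dimnames = dimnames(hapA)))
  ev <- enumerate_events(tx, vars, haps, min_carriers = 1)
  expect_equal(ev$events$event_type, "loss")
  expect_equal(unname(ev$dosage[1, ]), c(2L, 0L, 1L))

  # a pad variant that changes nothing creates no event
  vars2 <- data.frame(variant_id = "v2", transcript_id = "t1", position = 0,
                      ref = "C", alt = "A", stringsAsFactors = FALSE)
  haps2 <- haplotype_set(
    matrix(c(1L, 0L, 1L), 1, 3, dimnames = list("v2", c("i1", "i2", "i3"))),
    matrix(c(1L, 0L, 0L), 1, 3, dimnames = list("v2", c("i1", "i2", "i3"))),
    matrix(TRUE, 1, 3, dimnames = list("v2", c("i1", "i2", "i3"))))
  ev2 <- enumerate_events(tx, vars2, haps2, min_carriers = 1)
  expect_equal(nrow(ev2$events), 0)
})

test_that("association flags planted translation-specific effects", {
  study <- demo_study(seed = 101, n_individuals = 24, n_transcripts = 60)
  haps <- resolve_phase(study$haplotypes, seed = 2)
  expr <- normalize_expr(study$expr)
  ev <- enumerate_events(study$transcripts, study$variants, haps)
  res <- test_uorf_association(ev, expr)
  expect_true(all(c("beta_ribo", "p_ribo", "p_lmm", "fdr",
                    "translation_specific") %in% names(res)))
  # planted events (|beta| = 0.7-0.8 on RO only) should dominate the top
  planted_tx <- study$truth$events$transcript_id
  planted_rows <- res$unit_id %in%
    ev$events$event_id[ev$events$transcript_id %in% planted_tx]
  expect_gt(mean(res$significant[planted_rows]), 0.5)
  expect_true(all(!res$significant[!planted_rows]) ||
                mean(res$significant[!planted_rows]) < 0.2)

  # an event with zero dosage variance is skipped with a warning
  ev0 <- ev
  ev0$dosage[1, ] <- 0L
  expect_warning(test_uorf_association(ev0, expr), "zero dosage variance")
})
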