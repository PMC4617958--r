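# Transcripts with fully controlled Kozak 8-mers: utr = 6 Kozak nt,
# CDS = ATG + (two Kozak nt + pad) + stop.
kozak_tx <- function(contexts) {
  n <- nrow(contexts)
  seqs <- apply(contexts, 1, function(x)
    paste0(paste(x[1:6], collapse = ""), "ATG", x[7], x[8], "C", "TAA"))
  transcript_models(sprintf("t%05d", 1:n), sprintf("g%05d", 1:n),
                    seqs, rep(6, n), rep(15, n))
}

rand_contexts <- function(n, letters = c("A", "C", "G", "T")) {
  matrix(sample(letters, 8 * n, replace = TRUE), n, 8)
}

test_that("PWM rows are proper distributions and scores are additive", {
  set.seed(20)
  ctx <- rand_contexts(500)
  pwm <- build_pwm(kozak_tx(ctx))
  expect_equal(unname(rowSums(pwm$probs)), rep(1, 8), tolerance = 1e-12)

  # score = sum of per-position lookups, checked by hand on one fixture
  s8 <- c("G", "C", "C", "A", "C", "C", "G", "C")
  by_hand <- sum(sapply(1:8, function(j) pwm$log_odds[j, s8[j]]))
  expect_equal(pwm_score(pwm, paste(s8, collapse = "")), by_hand)

  # a single shared Kozak sequence concentrates the PWM on its letters
  same <- matrix(rep(s8, each = 300), 300, 8)
  pwm1 <- build_pwm(kozak_tx(same))
  expect_equal(unname(apply(pwm1$probs, 1, which.max)),
               match(s8, c("A", "C", "G", "T")))
  rand_scores <- pwm_score(pwm1, apply(rand_contexts(50), 1, paste,
                                       collapse = ""))
  expect_true(all(pwm_score(pwm1, paste(s8, collapse = "")) >= rand_scores))
})

test_that("log-odds vanish on uniform random sequences at large n", {
  # 1e4 expected observations per position x nucleotide cell; each cell's
  # log-odds then has sd ~ 0.0125, so the max over 32 cells stays < 0.05
  set.seed(21)
  pwm <- build_pwm(kozak_tx(rand_contexts(40000)))
  expect_lt(max(abs(pwm$log_odds)), 0.05)
})

test_that("short-UTR transcripts are excluded, empty input errors", {
  tx <- transcript_models(c("a", "b"), c("a", "b"),
                          c("ACATGCCCTAA",                 # utr5 = 2 < 6
                            "ACACACACATGGCCTAA"), c(2, 8), c(11, 17))
  pwm <- build_pwm(tx)
  expect_equal(pwm$n_transcripts, 1)
  expect_equal(pwm$n_excluded, 1)
  expect_error(build_pwm(tx[tx$utr5_length < 6, , drop = FALSE]),
               "no transcript")
})

test_that("delta-PWM scoring: antisymmetry, additivity, carrier filter", {
  set.seed(22)
  ctx <- rand_contexts(400, letters = c("A", "C", "G"))
  tx <- kozak_tx(ctx)
  pwm <- build_pwm(tx)

  ref1 <- ctx[1, 4]                      # position -3 of transcript 1
  alt1 <- setdiff(c("A", "C", "G"), ref1)[1]
  ref2 <- ctx[1, 7]                      # position +4 of the same transcript
  alt2 <- setdiff(c("A", "C", "G"), ref2)[1]
  vars <- data.frame(
    variant_id = c("kv1", "kv2", "kv3"),
    transcript_id = c("t00001", "t00001", "t00002"),
    position = c(3, 9, 6 + 3),           # -3, +4 on t1; +4 on t2
    ref = c(ref1, ref2, ctx[2, 7]),
    alt = c(alt1, alt2, setdiff(c("A", "C", "G"), ctx[2, 7])[1]),
    stringsAsFactors = FALSE)
  inds <- sprintf("i%02d", 1:10)
  hapA <- matrix(0L, 3, 10, dimnames = list(vars$variant_id, inds))
  hapB <- hapA
  hapA[1, 1:4] <- 1L; hapB[1, 1:2] <- 1L  # kv1: 2 hom + 2 het carriers
  hapA[2, 5:8] <- 1L                      # kv2: 4 het carriers
  hapA[3, 1:2] <- 1L                      # kv3: 2 carriers only
  haps <- haplotype_set(hapA, hapB, matrix(TRUE, 3, 10,
                                           dimnames = dimnames(hapA)))
  ks <- score_kozak_variants(vars, pwm, tx, haps, min_carriers = 3)

  d1 <- pwm$log_odds["-3", alt1] - pwm$log_odds["-3", ref1]
  expect_equal(ks$scores$delta_pwm[1], d1)
  expect_equal(ks$scores$weakening[1], d1 < 0)
  expect_false(ks$scores$tested[3])       # below min_carriers

  # swapping ref/alt negates delta exactly
  swapped <- vars; swapped$ref <- vars$alt; swapped$alt <- vars$ref
  ks2 <- score_kozak_variants(swapped, pwm, tx, haps, min_carriers = 3)
  expect_equal(ks2$scores$delta_pwm, -ks$scores$delta_pwm)

  # per-individual predictor sums delta * copies over a transcript's variants
  d2 <- pwm$log_odds["+4", alt2] - pwm$log_odds["+4", ref2]
  expect_equal(unname(ks$predictor["t00001", "i01"]), 2 * d1)  # homozygote
  expect_equal(unname(ks$predictor["t00001", "i03"]), 1 * d1)
  expect_equal(unname(ks$predictor["t00001", "i05"]), 1 * d2)
  # an individual carrying both variants would add both contributions
  hapB[2, 1] <- 1L
  haps2 <- haplotype_set(hapA, hapB, matrix(TRUE, 3, 10,
                                            dimnames = dimnames(hapA)))
  ks3 <- score_kozak_variants(vars, pwm, tx, haps2, min_carriers = 3)
  expect_equal(unname(ks3$predictor["t00001", "i01"]), 2 * d1 + d2)

  # start-codon or non-Kozak positions are a caller bug
  bad <- vars; bad$position[1] <- 6      # the A of ATG
  expect_error(score_kozak_variants(bad, pwm, tx, haps), "start codon")
  bad2 <- vars; bad2$position[1] <- 0:0 + 12
  expect_error(score_kozak_variants(bad2, pwm, tx, haps), "non-Kozak")
})

test_that("kozak_variants() selects exactly the -6..-1/+4/+5 offsets", {
  sim <- simulate_transcriptome(sim_config(n_individuals = 8,
                                           n_transcripts = 40, seed = 19))
  kv <- kozak_variants(sim$variants, sim$transcripts)
  tr <- sim$truth$variant_effects
  expect_setequal(kv$variant_id, tr$variant_id[tr$role == "kozak"])
})

test_that("per-position Kruskal-Wallis detects a planted -3 effect", {
  set.seed(23)
  ctx <- rand_contexts(600)
  tx <- kozak_tx(ctx)
  # TE responds only to the nucleotide at -3 (column 4)
  te <- setNames(0.5 * (ctx[, 4] == "A") + rnorm(600, 0, 0.4),
                 tx$transcript_id)
  res <- test_position_effects(tx, te)
  expect_equal(res$position, c("-6", "-5", "-4", "-3", "-2", "-1",
                               "+4", "+5"))
  expect_equal(which.min(res$p), 4)
  expect_lt(res$p_bonferroni[4], 0.05)

  # identical values in all groups: H = 0, p = 1
  te0 <- setNames(rep(1, 600), tx$transcript_id)
  res0 <- test_position_effects(tx, te0)
  expect_true(all(res0$p == 1 | is.na(res0$p)))

  # TE independent of sequence: raw rejections near nominal 5%
  set.seed(24)
  rej <- replicate(30, {
    te_null <- setNames(rnorm(600), tx$transcript_id)
    mean(test_position_effects(tx, te_null)$p < 0.05, na.rm = TRUE)
  })
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("Kozak association recovers the planted RO-only effect", {
  study <- demo_study(seed = 71, n_individuals = 24, n_transcripts = 80)
  haps <- resolve_phase(study$haplotypes, seed = 1)
  expr <- normalize_expr(study$expr)
  pwm <- build_pwm(study$transcripts)
  kv <- kozak_variants(study$variants, study$transcripts)
  ks <- score_kozak_variants(kv, pwm, study$transcripts, haps)
  res <- test_kozak_association(ks, study$transcripts, expr)
  tr <- study$truth$variant_effects
  eff_tx <- tr$transcript_id[tr$class %in% "kozak_effect"]
  hit <- res[res$unit_id %in% eff_tx, ]
  expect_gt(nrow(hit), 0)
  expect_true(any(hit$significant & hit$translation_specific))

  # a constant predictor is skipped
  ks0 <- ks
  ks0$predictor[, ] <- 0
  expect_equal(nrow(test_kozak_association(ks0, study$transcripts, expr)), 0)
})
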