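# Shared fixtures and independent oracles for the test suite.

# Minimal valid transcript table built in code.
tiny_transcripts <- function() {
  transcript_models(
    transcript_id = c("t1", "t2"),
    gene_id = c("g1", "g2"),
    sequence = c("GGATGGCCTAA",                       # utr5 = "GG"
                 "ACACACATGCCCAAATAA"),               # utr5 = "ACACAC"
    cds_start = c(2, 6),
    cds_end = c(11, 18))
}

# Exhaustive codon-walk uORF enumeration: for every upstream ATG/CTG, walk
# codon by codon to the first stop. Deliberately naive.
brute_force_uorfs <- function(sequence, cds_start) {
  starts <- c("ATG", "CTG"); stops <- c("TAA", "TAG", "TGA")
  L <- nchar(sequence)
  res <- list()
  for (s in seq_len(max(cds_start, 0))) {        # 1-based start candidates
    if (s - 1 >= cds_start) next
    if (!(substr(sequence, s, s + 2) %in% starts)) next
    q <- s + 3L
    stop0 <- NA_integer_
    while (q + 2 <= L) {
      if (substr(sequence, q, q + 2) %in% stops) { stop0 <- q - 1L; break }
      q <- q + 3L
    }
    if (is.na(stop0)) next
    res[[length(res) + 1]] <- data.frame(
      start = s - 1L, stop = stop0,
      start_codon = substr(sequence, s, s + 2),
      frame = (s - 1L) %% 3L,
      overlaps_cds = stop0 >= cds_start,
      stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(start = integer(0), stop = integer(0),
                      start_codon = character(0), frame = integer(0),
                      overlaps_cds = logical(0)))
  do.call(rbind, res)
}

# Random UTR + short CDS with motifs allowed anywhere (worst case for the
# scanner: overlapping starts, stops in all frames).
random_transcript_seq <- function(max_utr = 300) {
  utr_len <- sample(10:max_utr, 1)
  utr <- paste(sample(c("A", "C", "G", "T"), utr_len, replace = TRUE),
               collapse = "")
  paste0(utr, "ATG", paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                           collapse = ""), "TAA")
}

# Literal transcription of the TMM recipe (reference = library whose 75th
# percentile of cpm is closest to the mean 75th percentile; doubly trimmed
# weighted mean of M values; factors scaled to geometric mean 1).
tmm_oracle <- function(counts, logratioTrim = 0.3, sumTrim = 0.05) {
  lib <- colSums(counts)
  q75 <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(counts)), function(i) {
    obs <- counts[, i]; refc <- counts[, ref]
    nO <- lib[i]; nR <- lib[ref]
    keep <- obs > 0 & refc > 0
    obs <- obs[keep]; refc <- refc[keep]
    M <- log2((obs / nO) / (refc / nR))
    A <- (log2(obs / nO) + log2(refc / nR)) / 2
    w <- (nO - obs) / nO / obs + (nR - refc) / nR / refc
    fin <- is.finite(M) & is.finite(A) & abs(M) < 1e10
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * sumTrim) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, 0)
  f / exp(mean(log(f)))
}

# Dense-likelihood oracle for the one-way random effect model: direct
# multivariate normal log-likelihood via solve()/determinant(), maximized on
# a fine grid over the variance ratio.
dense_loglik <- function(y, w, ind, lambda) {
  n <- length(y)
  Z <- outer(ind, unique(ind), "==") * 1
  V <- diag(1 / w) + lambda * tcrossprod(Z)
  Vi <- solve(V)
  one <- rep(1, n)
  mu <- sum(Vi %*% y) / sum(Vi)
  r <- y - mu
  Q <- drop(t(r) %*% Vi %*% r)
  s2 <- Q / n
  -0.5 * (n * log(2 * pi) + n * log(s2) +
            determinant(V, logarithm = TRUE)$modulus + n)
}

grid_fit_oracle <- function(y, w, ind) {
  lams <- c(0, exp(seq(log(1e-4), log(1e4), length.out = 600)))
  ll <- vapply(lams, function(l) dense_loglik(y, w, ind, l), 0)
  k <- which.max(ll)
  list(lambda = lams[k], loglik = ll[k], loglik_null = ll[1],
       lrt = max(0, 2 * (ll[k] - ll[1])))
}

# Small voom-ready study used across tests.
demo_study <- function(seed = 42, n_individuals = 12, n_transcripts = 60,
                       ...) {
  simulate_study(sim_config(n_individuals = n_individuals,
                            n_transcripts = n_transcripts, seed = seed, ...))
}
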