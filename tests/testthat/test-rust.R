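test_that("binarization thresholds at the strict mean", {
  expect_equal(binarize(c(0, 2, 10, 0))$values, c(0L, 0L, 1L, 0L))
  expect_equal(binarize(c(4, 4, 4, 4))$values, c(0L, 0L, 0L, 0L))
  expect_equal(binarize(c(0, 0, 6))$values, c(0L, 0L, 1L))
  expect_equal(binarize(integer(5))$values, integer(5))
})

test_that("binarization mean is taken over the admissible region", {
  cnt <- integer(100)
  cnt[1:40] <- 100            # excluded from the threshold
  cnt[41:80] <- c(rep(2, 20), rep(0, 20))
  bz <- binarize(cnt)
  expect_equal(bz$admissible, 41:80)
  expect_equal(bz$mean_density, 1)
  expect_equal(bz$values[41:60], rep(1L, 20))
  expect_equal(bz$values[61:80], rep(0L, 20))
})

test_that("observed and expected RUST values follow the hand count", {
  # CDS of 64 codons -> admissible A-sites 40..43 (4 positions);
  # all four A-site codons are AAA, binary values engineered to 1,0,1,1
  inner <- rep("GGC", 62)
  inner[40:43] <- "AAA"        # codon indices 40..43 of the CDS
  ts <- toy_transcripts(list(c("ATG", inner, "TAA")))
  L <- unname(n_codons(ts))
  cnt <- integer(L)
  cnt[40:43 + 1] <- c(5, 0, 5, 5)   # mean over adm = 15/4 -> binary 1,0,1,1
  profiles <- structure(list(t01 = cnt), class = "codon_profiles")
  meta <- rust_metafootprint(profiles, ts, "codon", positions = 0L)
  expect_equal(meta$ro["AAA", "0"], 0.75)
  expect_equal(meta$re["AAA", "0"], 0.75)  # transcript mean binary = 3/4
  expect_equal(unname(meta$n_obs["AAA", "0"]), 4)
  expect_equal(meta$ratio["AAA", "0"], 1)
})

test_that("metafootprint equals the brute-force recount on a toy set", {
  set.seed(5)
  cods <- lapply(1:4, function(i) toy_cds(SENSE_CODONS, 70 + 10 * i))
  ts <- toy_transcripts(cods)
  profiles <- structure(lapply(n_codons(ts), function(L) {
    as.integer(rpois(L, 2))
  }), class = "codon_profiles")
  for (det in c("codon", "amino_acid")) {
    meta <- rust_metafootprint(profiles, ts, det, positions = -3:3)
    oracle <- brute_rust_meta(profiles, ts, positions = -3:3,
                              determinant = det)
    for (r in seq_len(nrow(oracle))) {
      d <- oracle$determinant[r]
      l <- as.character(oracle$position[r])
      expect_equal(meta$ro[d, l], oracle$ro[r], tolerance = 1e-12)
      expect_equal(meta$re[d, l], oracle$re[r], tolerance = 1e-12)
      expect_equal(unname(meta$n_obs[d, l]), oracle$n_obs[r])
    }
    expect_equal(sum(meta$n_obs > 0, na.rm = TRUE), nrow(oracle))
  }
})

test_that("RUST values are proportions and ratios tend to 1 without signal", {
  tw <- simulate_transcriptome(n = 50, seed = 21)
  flat_grid <- build_dwell_grid("custom", values = rep(1, 61))
  expect_equal(min(flat_grid), max(flat_grid))
  sim <- simulate_dataset(tw$transcripts, flat_grid, density = tw$density,
                          seed = 22)
  meta <- rust_metafootprint(sim$profiles, tw$transcripts, "codon")
  expect_true(all(meta$ro >= 0 & meta$ro <= 1, na.rm = TRUE))
  expect_true(all(meta$re >= 0 & meta$re <= 1, na.rm = TRUE))
  well <- meta$n_obs > 500 & !is.na(meta$ratio)
  expect_lt(max(abs(log2(meta$ratio[well]))), 0.5)
  expect_lt(abs(mean(log2(meta$ratio[well]))), 0.1)
})

test_that("occurrences whose context leaves the CDS are skipped", {
  cods <- list(toy_cds(c("AAA", "CCC", "GGG"), 80, seed = 7))
  ts <- toy_transcripts(cods)
  L <- unname(n_codons(ts))
  profiles <- structure(list(t01 = as.integer(rpois(L, 3))),
                        class = "codon_profiles")
  meta <- rust_metafootprint(profiles, ts, "codon", positions = c(-45L, 0L))
  n_adm <- length(admissible_codon_indices(L))
  # at l = -45 the first five A-sites (40..44) have no context
  expect_equal(sum(meta$n_obs[, "-45"], na.rm = TRUE), n_adm - 5)
  expect_equal(sum(meta$n_obs[, "0"], na.rm = TRUE), n_adm)
})

test_that("K-L divergence matches hand arithmetic and is zero iff p = q", {
  ro <- matrix(c(0.3, 0.1), 2, 1, dimnames = list(c("AAA", "CCC"), "0"))
  meta <- fake_meta(ro = ro, re = ro / 2, positions = 0L)
  # p = (0.75, 0.25) vs q = (0.75, 0.25): identical after renormalization
  expect_equal(kl_series(meta)$divergence, 0)
  re <- matrix(c(0.2, 0.2), 2, 1, dimnames = dimnames(ro))
  meta2 <- fake_meta(ro = ro, re = re, positions = 0L)
  hand <- 0.75 * log2(1.5) + 0.25 * log2(0.5)
  expect_equal(kl_series(meta2)$divergence, hand, tolerance = 1e-12)
  expect_equal(round(hand, 4), 0.1887)
})

test_that("K-L reaches log2(61) when one of 61 codons takes all mass", {
  ro <- matrix(c(1, rep(0, 60)), 61, 1,
               dimnames = list(SENSE_CODONS, "0"))
  re <- matrix(1 / 61, 61, 1, dimnames = dimnames(ro))
  meta <- fake_meta(ro = ro, re = re, positions = 0L)
  expect_equal(kl_series(meta)$divergence, log2(61), tolerance = 1e-12)
})

test_that("K-L is non-negative across random profiles", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    ro <- matrix(runif(n), n, 1,
                 dimnames = list(paste0("d", 1:n), "0"))
    re <- matrix(runif(n), n, 1, dimnames = dimnames(ro))
    d <- kl_series(fake_meta(ro = ro, re = re, positions = 0L))$divergence
    expect_gte(d, -1e-12)
  }
})

test_that("metafootprint halves of a split dataset agree", {
  w <- small_world(seed = 41, n = 80)
  ts <- w$tw$transcripts
  idx <- seq_len(nrow(ts))
  h1 <- ts[idx %% 2 == 1, ]; class(h1) <- class(ts)
  h2 <- ts[idx %% 2 == 0, ]; class(h2) <- class(ts)
  m1 <- rust_metafootprint(w$sim$profiles, h1, "codon", positions = 0L)
  m2 <- rust_metafootprint(w$sim$profiles, h2, "codon", positions = 0L)
  shared <- intersect(m1$alphabet, m2$alphabet)
  r1 <- m1$ratio[shared, 1]; r2 <- m2$ratio[shared, 1]
  ok <- is.finite(r1) & is.finite(r2)
  expect_gt(cor(r1[ok], r2[ok]), 0.9)
})

test_that("simulated A-site signal puts the K-L maximum at position 0", {
  w <- small_world(seed = 51, n = 60)
  meta <- rust_metafootprint(w$sim$profiles, w$tw$transcripts, "codon")
  kl <- kl_series(meta)
  expect_equal(kl$position[which.max(kl$divergence)], 0)
})

test_that("offset detection recovers the simulated offset", {
  w <- small_world(seed = 61, n = 60)
  aln <- simulate_alignments(w$sim, w$tw$transcripts, offset = 17,
                             seed = 62)
  off <- detect_a_site_offset(aln, w$tw$transcripts)
  expect_equal(as.integer(off), 17)
  expect_named(attr(off, "scores"), c("16", "17", "18"))
})

test_that("offset detection warns and takes the smallest on exact ties", {
  # a profile with no positional signal: uniform counts everywhere
  cods <- lapply(1:6, function(i) toy_cds(SENSE_CODONS, 120, seed = i))
  ts <- toy_transcripts(cods, utr = 30L)
  sim <- list(profiles = structure(
    lapply(n_codons(ts), function(L) rep(1L, L)),
    class = "codon_profiles"))
  aln <- simulate_alignments(sim, ts, offset = 17, read_length = 28,
                             frame_probs = c(1, 0, 0), seed = 3)
  expect_warning(off <- detect_a_site_offset(aln, ts,
                                             candidates = c(16, 17, 18)),
                 "tie")
  expect_equal(as.integer(off), 16)
})
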