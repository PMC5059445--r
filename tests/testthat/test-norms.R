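# Each normalization is checked against hand arithmetic on engineered
# profiles and against an independent brute-force recount on a toy set.

# Engineer a transcript whose admissible region is an exact codon sequence.
engineered <- function(adm_codons, pad = "GGC") {
  # 39 pads before and 19 after make the admissible region exactly
  # adm_codons for the default window rule
  inner <- c(rep(pad, 39), adm_codons, rep(pad, 19))
  toy_transcripts(list(c("ATG", inner, "TAA")))
}

test_that("CN divides by the transcript mean and averages per codon", {
  # admissible region: AAA CCC GGG with counts 2, 0, 4 (mean 2)
  ts <- engineered(c("AAA", "CCC", "GGG"))
  L <- unname(n_codons(ts))
  idx <- admissible_codon_indices(L) + 1
  expect_length(idx, 3)
  cnt <- integer(L)
  cnt[idx] <- c(2L, 0L, 4L)
  profiles <- structure(list(t01 = cnt), class = "codon_profiles")
  sc <- cn_scores(profiles, ts, min_density = 0)
  s <- setNames(sc$score, sc$codon)
  expect_equal(unname(s["AAA"]), 1)
  expect_equal(unname(s["CCC"]), 0)
  expect_equal(unname(s["GGG"]), 2)
  expect_true(is.na(s["GGC"]))  # padding codon never admissible here
})

test_that("uniform profiles give CN all ones and LMN all zeros", {
  cods <- lapply(1:3, function(i) toy_cds(SENSE_CODONS, 120, seed = i))
  ts <- toy_transcripts(cods)
  profiles <- structure(lapply(n_codons(ts), function(L) rep(4L, L)),
                        class = "codon_profiles")
  cn <- cn_scores(profiles, ts)
  expect_true(all(abs(cn$score[!is.na(cn$score)] - 1) < 1e-12))
  lmn <- suppressWarnings(lmn_scores(profiles, ts))
  expect_true(all(abs(lmn$score[!is.na(lmn$score)]) < 1e-12))
})

test_that("density thresholds trigger the insufficient-data error", {
  cods <- list(toy_cds(SENSE_CODONS, 120, seed = 4))
  ts <- toy_transcripts(cods)
  L <- unname(n_codons(ts))
  sparse <- integer(L)
  sparse[admissible_codon_indices(L) + 1][1:10] <- 1L  # ~0.05 reads/nt
  profiles <- structure(list(t01 = sparse), class = "codon_profiles")
  expect_error(cn_scores(profiles, ts, min_density = 1),
               "insufficient data")
  expect_error(lmn_scores(profiles, ts), "insufficient data")
  expect_silent(cn_scores(profiles, ts, min_density = 0))
})

test_that("LMN averages log2 densities over non-zero coordinates only", {
  # AAA occurs twice with d = 2 and 0.5 -> first term (1 - 1)/2 = 0;
  # a zero-count AAA occurrence must not enter N_c
  adm <- c("AAA", rep("CCC", 20), "AAA", rep("GGG", 20), "AAA")
  ts <- engineered(adm)
  L <- unname(n_codons(ts))
  cnt <- integer(L)
  idx <- admissible_codon_indices(L) + 1
  # engineer mean density > 1 read/nt over the window: mean count > 3
  cnt[idx] <- 4L
  a_pos <- idx[c(1, 22, 43)]
  cnt[a_pos] <- c(8L, 2L, 0L)   # d = 2, 0.5, 0 (last one excluded)
  profiles <- structure(list(t01 = cnt), class = "codon_profiles")
  suppressWarnings(sc <- lmn_scores(profiles, ts))
  s <- setNames(sc$score, sc$codon)
  n <- setNames(sc$n, sc$codon)
  expect_equal(unname(n["AAA"]), 2)   # zero-count occurrence not in N_c
  # grand mean subtraction: score differences preserve the first terms
  m <- mean(cnt[idx])
  expected_first_AAA <- mean(log2(c(8, 2) / m))
  expected_first_CCC <- log2(4 / m)
  expect_equal(unname(s["AAA"] - s["CCC"]),
               expected_first_AAA - expected_first_CCC, tolerance = 1e-12)
})

test_that("RRT window qualification follows the three rules", {
  # one transcript whose admissible region is exactly 19 codons
  adm <- c(SENSE_CODONS[1:9], "TGG", SENSE_CODONS[10:18])  # focal unique
  ts <- engineered(adm)
  L <- unname(n_codons(ts))
  idx <- admissible_codon_indices(L) + 1
  expect_length(idx, 19)
  base <- integer(L)
  # uniform 2 reads/codon: 38 > 19 reads, no empty codon, focal unique
  cnt <- base; cnt[idx] <- 2L
  profiles <- structure(list(t01 = cnt), class = "codon_profiles")
  sc <- rrt_scores(profiles, ts)
  s <- setNames(sc$score, sc$codon)
  expect_equal(unname(s["TGG"]), 2 / 38)
  # requirement (1): exactly 19 reads is rejected (strict >)
  cnt <- base; cnt[idx] <- 1L
  profiles <- structure(list(t01 = cnt), class = "codon_profiles")
  expect_error(rrt_scores(profiles, ts), "insufficient data")
  # requirement (2): 3 codons with no alignments is rejected
  cnt <- base; cnt[idx] <- 2L; cnt[idx[c(2, 5, 9)]] <- 0L
  profiles <- structure(list(t01 = cnt), class = "codon_profiles")
  expect_error(rrt_scores(profiles, ts), "insufficient data")
  # requirement (3): duplicated focal codon is rejected
  adm_dup <- adm; adm_dup[15] <- "TGG"
  ts_dup <- engineered(adm_dup)
  cnt <- integer(unname(n_codons(ts_dup)))
  cnt[admissible_codon_indices(unname(n_codons(ts_dup))) + 1] <- 2L
  profiles <- structure(list(t01 = cnt), class = "codon_profiles")
  expect_error(rrt_scores(profiles, ts_dup), "insufficient data")
})

test_that("all normalizations equal their brute-force recount", {
  set.seed(13)
  cods <- lapply(1:3, function(i) toy_cds(SENSE_CODONS, 100 + 10 * i))
  ts <- toy_transcripts(cods)
  profiles <- structure(lapply(n_codons(ts), function(L) {
    as.integer(rpois(L, 4))
  }), class = "codon_profiles")

  cn <- cn_scores(profiles, ts, min_density = 0)
  oracle <- brute_cn(profiles, ts, min_density = 0)
  s <- setNames(cn$score, cn$codon)
  expect_equal(s[names(oracle)], oracle, tolerance = 1e-12)

  cn1 <- cn_scores(profiles, ts, min_density = 1)
  oracle1 <- brute_cn(profiles, ts, min_density = 1)
  s1 <- setNames(cn1$score, cn1$codon)
  expect_equal(s1[names(oracle1)], oracle1, tolerance = 1e-12)

  suppressWarnings(lmn <- lmn_scores(profiles, ts))
  oracle_l <- brute_lmn(profiles, ts)
  sl <- setNames(lmn$score, lmn$codon)
  expect_equal(sl[names(oracle_l)], oracle_l, tolerance = 1e-12)

  rrt <- rrt_scores(profiles, ts)
  oracle_r <- brute_rrt(profiles, ts)
  sr <- setNames(rrt$score, rrt$codon)
  expect_equal(sr[names(oracle_r)], oracle_r, tolerance = 1e-12)

  rust <- rust_codon_scores(profiles, ts)
  oracle_m <- brute_rust_meta(profiles, ts, positions = 0L)
  sm <- setNames(rust$score, rust$codon)
  expect_equal(unname(sm[oracle_m$determinant]),
               oracle_m$ro / oracle_m$re, tolerance = 1e-12)
})

test_that("mean normalization yields mean exactly 1 over defined entries", {
  w <- small_world(seed = 71, n = 30)
  for (sc in list(cn_scores(w$sim$profiles, w$tw$transcripts),
                  rust_codon_scores(w$sim$profiles, w$tw$transcripts))) {
    v <- mean_normalize(sc)
    expect_equal(mean(v, na.rm = TRUE), 1, tolerance = 1e-12)
  }
  # log2-scale sets are exponentiated before normalization
  lmn <- suppressWarnings(lmn_scores(w$sim$profiles, w$tw$transcripts))
  v <- mean_normalize(lmn)
  expect_equal(mean(v, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_true(all(v > 0, na.rm = TRUE))
})
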