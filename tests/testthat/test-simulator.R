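test_that("dwell grids honour the published endpoints", {
  ten <- build_dwell_grid("tenfold")
  hun <- build_dwell_grid("hundredfold")
  expect_length(ten, 61)
  expect_length(hun, 61)
  expect_equal(min(ten), 1)
  expect_equal(max(ten), 10.15)
  expect_equal(min(hun), 1)
  expect_equal(max(hun), 92.5)
  # equal spacing
  expect_equal(diff(range(diff(sort(ten)))), 0, tolerance = 1e-12)
})

test_that("grid assignment follows codon-usage rank", {
  u <- human_codon_usage
  pos <- build_dwell_grid("tenfold", "positive", u)
  neg <- build_dwell_grid("tenfold", "negative", u)
  by_rarity <- SENSE_CODONS[order(u[SENSE_CODONS], SENSE_CODONS)]
  rarest <- by_rarity[1]
  commonest <- by_rarity[61]
  expect_equal(unname(pos[rarest]), 1)        # rarest = fastest
  expect_equal(unname(pos[commonest]), 10.15)
  expect_equal(unname(neg[rarest]), 10.15)
  expect_equal(unname(neg[commonest]), 1)
  expect_gt(cor(pos, u, method = "spearman"), 0.99)
  none <- build_dwell_grid("tenfold", "none", u)
  expect_equal(unname(none[SENSE_CODONS[1]]), 1)  # lexicographic order
  expect_error(build_dwell_grid("tenfold", usage = u[-1]),
               "61 sense codons")
})

test_that("simulated counts follow the closed-form Poisson expectations", {
  # admissible region of alternating AAA/CCC, dwell times 1 and 3:
  # with n1 = n2 = 30 occurrences, lambda_AAA = D/(n1 + 3 n2) = D/120
  adm <- rep(c("AAA", "CCC"), 30)
  inner <- c(rep("GGC", 39), adm, rep("GGC", 19))
  ts <- toy_transcripts(list(c("ATG", inner, "TAA")))
  vals <- rep(c(1, 3), length.out = 61)
  grid <- build_dwell_grid("custom", "none", values = vals)
  grid[] <- 1
  grid[c("AAA", "GGC")] <- 1
  grid["CCC"] <- 3
  D <- 1200
  tot_aaa <- tot_ccc <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    sim <- simulate_dataset(ts, grid,
                            reads_per_transcript = c(t01 = D), seed = r)
    cnt <- sim$profiles[["t01"]]
    idx <- admissible_codon_indices(length(cnt)) + 1
    cod <- cds_codons(ts)[[1]][idx]
    tot_aaa <- tot_aaa + sum(cnt[idx][cod == "AAA"])
    tot_ccc <- tot_ccc + sum(cnt[idx][cod == "CCC"])
  }
  # per replicate: E[AAA total] = 30 * D/120 = 300, E[CCC total] = 900
  se_aaa <- sqrt(300 * reps)  # Poisson variance
  se_ccc <- sqrt(900 * reps)
  expect_lt(abs(tot_aaa - 300 * reps), 4 * se_aaa)
  expect_lt(abs(tot_ccc - 900 * reps), 4 * se_ccc)
})

test_that("expected totals are conserved and equal grids give uniform rates", {
  tw <- simulate_transcriptome(n = 25, seed = 81)
  grid <- build_dwell_grid("custom", values = rep(2, 61))
  D <- setNames(rep(500, 25), tw$transcripts$id)
  sim <- simulate_dataset(tw$transcripts, grid,
                          reads_per_transcript = D, seed = 82)
  tot <- vapply(sim$profiles, sum, numeric(1))
  # sum over transcripts: expected 500 each, Poisson s.e. sqrt(500)
  expect_lt(abs(mean(tot) - 500), 4 * sqrt(500 / 25))
  # equal dwell times: per-codon counts are exchangeable across codons
  cnt <- sim$profiles[[1]]
  idx <- admissible_codon_indices(length(cnt)) + 1
  lam <- 500 / length(idx)
  expect_lt(abs(mean(cnt[idx]) - lam), 4 * sqrt(lam / length(idx)))
})

test_that("the simulator is deterministic under a fixed seed", {
  tw <- simulate_transcriptome(n = 10, seed = 91)
  tw2 <- simulate_transcriptome(n = 10, seed = 91)
  expect_identical(tw$transcripts$sequence, tw2$transcripts$sequence)
  grid <- build_dwell_grid("tenfold")
  s1 <- simulate_dataset(tw$transcripts, grid, density = tw$density,
                         seed = 7)
  s2 <- simulate_dataset(tw$transcripts, grid, density = tw$density,
                         seed = 7)
  expect_identical(s1$profiles, s2$profiles)
  n1 <- inject_noise(s1, "peaks", 0.2, seed = 8)
  n2 <- inject_noise(s2, "peaks", 0.2, seed = 8)
  expect_identical(n1$profiles, n2$profiles)
})

test_that("peak noise substitutes three times the profile maximum", {
  w <- small_world(seed = 95, n = 15)
  noisy <- inject_noise(w$sim, "peaks", 0.5, seed = 96)
  changed <- 0L
  for (id in names(w$sim$profiles)) {
    before <- w$sim$profiles[[id]]
    after <- noisy$profiles[[id]]
    d <- which(after != before)
    changed <- changed + length(d)
    if (length(d)) expect_true(all(after[d] == 3L * max(before)))
  }
  expect_gt(changed, 0)
  # fraction 0 leaves the dataset untouched
  same <- inject_noise(w$sim, "peaks", 0, seed = 97)
  expect_identical(same$profiles, w$sim$profiles)
})

test_that("dropout zeroes a binomial share of covered codons", {
  tw <- simulate_transcriptome(n = 1, seed = 98, median_codons = 400,
                               sd_log_length = 0)
  grid <- build_dwell_grid("custom", values = rep(1, 61))
  sim <- simulate_dataset(tw$transcripts, grid,
                          reads_per_transcript = setNames(5000,
                            tw$transcripts$id), seed = 99)
  cnt <- sim$profiles[[1]]
  cov <- sum(cnt > 0)
  zeroed <- numeric(50)
  for (r in 1:50) {
    noisy <- inject_noise(sim, "dropout", 0.2, seed = 100 + r)
    zeroed[r] <- cov - sum(noisy$profiles[[1]] > 0)
  }
  expect_lt(abs(mean(zeroed) - 0.2 * cov), 4 * sqrt(0.2 * 0.8 * cov / 50))
  expect_gt(var(zeroed), 0)   # probabilistic, not exact-count, selection
})

test_that("estimate evaluation is scale-invariant with exact identity", {
  grid <- build_dwell_grid("tenfold")
  perfect <- setNames(as.numeric(grid), names(grid))
  ev <- evaluate_estimates(perfect, grid)
  expect_equal(unname(ev$log_ratio), rep(0, 61))
  expect_equal(ev$r_squared, 1)
  doubled <- evaluate_estimates(perfect * 2, grid)
  expect_equal(unname(doubled$log_ratio), rep(0, 61))
  # hand-built toy: 3 codons off-truth, known ratios after normalization
  est <- perfect
  est["AAA"] <- perfect["AAA"] * 2
  ev3 <- evaluate_estimates(est, grid)
  scale_shift <- mean(est) / mean(perfect)
  expect_equal(unname(ev3$log_ratio["AAA"]),
               log2(2 / scale_shift), tolerance = 1e-12)
  expect_equal(unname(ev3$log_ratio["CCC"]),
               log2(1 / scale_shift), tolerance = 1e-12)
})

test_that("undefined estimates are excluded and flagged", {
  grid <- build_dwell_grid("tenfold")
  est <- setNames(as.numeric(grid), names(grid))
  est["AAA"] <- NA
  est["CCC"] <- 0
  ev <- evaluate_estimates(est, grid)
  expect_setequal(ev$excluded, c("AAA", "CCC"))
  expect_true(all(is.na(ev$log_ratio[c("AAA", "CCC")])))
})
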