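# Fixture builders and independent brute-force oracles. The oracles are
# deliberately naive double loops over transcripts and positions so they
# share no code path with the package's vectorized implementations.

# Build a transcript_set directly from lists of CDS codons (start/stop
# included by the caller), with fixed-length random-free UTRs of "A"s.
toy_transcripts <- function(codon_lists, utr = 30L) {
  n <- length(codon_lists)
  seqs <- vapply(codon_lists, function(cod) {
    paste0(strrep("A", utr), paste(cod, collapse = ""), strrep("A", utr))
  }, "")
  transcript_set(
    id = sprintf("t%02d", seq_len(n)),
    sequence = seqs,
    cds_start = rep(utr, n),
    cds_end = utr + 3L * lengths(codon_lists),
    min_codons = 1L)
}

# A reproducible CDS of n codons whose admissible region has known
# composition; wraps in start/stop.
toy_cds <- function(inner, n = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(n)) inner <- sample(inner, n, replace = TRUE)
  c("ATG", inner, "TAA")
}

# Brute-force RUST metafootprint: explicit loops over transcripts,
# admissible A-sites and relative positions.
brute_rust_meta <- function(profiles, transcripts, positions = -40:20,
                            determinant = "codon",
                            rule = analysis_window()) {
  codons <- cds_codons(transcripts)
  cells <- list()
  for (id in transcripts$id) {
    cod <- codons[[id]]
    cnt <- profiles[[id]]
    L <- length(cod)
    adm <- admissible_codon_indices(L, rule)
    if (!length(adm) || sum(cnt[adm + 1]) == 0) next
    m <- mean(cnt[adm + 1])
    b <- as.integer(cnt > m)
    mb <- mean(b[adm + 1])
    for (k in adm) {
      for (l in positions) {
        kk <- k + l
        if (kk < 0 || kk >= L) next
        d <- switch(determinant,
          codon = cod[kk + 1],
          amino_acid = translate_codons(cod[kk + 1]))
        if (is.na(d) || d %in% c("TAA", "TAG", "TGA", "*")) next
        key <- paste(d, l)
        cell <- cells[[key]]
        if (is.null(cell)) cell <- c(0, 0, 0)
        cells[[key]] <- cell + c(b[k + 1], mb, 1)
      }
    }
  }
  out <- do.call(rbind, lapply(names(cells), function(key) {
    parts <- strsplit(key, " ")[[1]]
    v <- cells[[key]]
    data.frame(determinant = parts[1], position = as.integer(parts[2]),
               ro = v[1] / v[3], re = v[2] / v[3], n_obs = v[3],
               stringsAsFactors = FALSE)
  }))
  out[order(out$determinant, out$position), ]
}

# Brute-force CN: per-transcript normalization then per-codon means.
brute_cn <- function(profiles, transcripts, min_density = 0,
                     rule = analysis_window()) {
  codons <- cds_codons(transcripts)
  vals <- list()
  for (id in transcripts$id) {
    cod <- codons[[id]]
    adm <- admissible_codon_indices(length(cod), rule) + 1
    cnt <- profiles[[id]][adm]
    dens <- sum(cnt) / (3 * length(adm))
    if (min_density <= 0) { if (sum(cnt) == 0) next } else
      if (dens <= min_density) next
    nrm <- cnt / mean(cnt)
    for (i in seq_along(adm)) {
      key <- cod[adm[i]]
      vals[[key]] <- c(vals[[key]], nrm[i])
    }
  }
  vapply(vals, mean, numeric(1))
}

# Brute-force LMN per the published two-term formula.
brute_lmn <- function(profiles, transcripts, rule = analysis_window()) {
  codons <- cds_codons(transcripts)
  vals <- list()
  for (id in transcripts$id) {
    cod <- codons[[id]]
    adm <- admissible_codon_indices(length(cod), rule) + 1
    cnt <- profiles[[id]][adm]
    if (sum(cnt) / (3 * length(adm)) <= 1) next
    d <- cnt / mean(cnt)
    for (i in seq_along(adm)) {
      if (cnt[i] == 0) next
      key <- cod[adm[i]]
      vals[[key]] <- c(vals[[key]], log2(d[i]))
    }
  }
  first <- vapply(vals, mean, numeric(1))
  first <- first[intersect(names(first), SENSE_CODONS)]
  first - mean(first)
}

# Brute-force RRT: explicit window qualification and focal fractions.
brute_rrt <- function(profiles, transcripts, rule = analysis_window()) {
  codons <- cds_codons(transcripts)
  vals <- list()
  for (id in transcripts$id) {
    cod <- codons[[id]]
    adm <- admissible_codon_indices(length(cod), rule) + 1
    cnt <- profiles[[id]][adm]
    cw <- cod[adm]
    if (length(cnt) < 19) next
    for (s in 1:(length(cnt) - 18)) {
      w <- s:(s + 18)
      if (sum(cnt[w]) <= 19) next
      if (sum(cnt[w] == 0) >= 3) next
      fc <- cw[s + 9]
      if (sum(cw[w] == fc) != 1) next
      vals[[fc]] <- c(vals[[fc]], cnt[s + 9] / sum(cnt[w]))
    }
  }
  vapply(vals, mean, numeric(1))
}

# Small simulated world reused by several tests.
small_world <- function(seed = 10, n = 40) {
  tw <- simulate_transcriptome(n = n, seed = seed)
  grid <- build_dwell_grid("tenfold")
  sim <- simulate_dataset(tw$transcripts, grid, density = tw$density,
                          seed = seed + 1)
  list(tw = tw, grid = grid, sim = sim)
}

# Minimal hand-made rust_meta object for direct formula checks.
fake_meta <- function(ro, re, positions, determinant = "codon",
                      n_obs = NULL) {
  if (is.null(n_obs)) n_obs <- matrix(100, nrow(ro), ncol(ro))
  dimnames(n_obs) <- dimnames(ro)
  ratio <- ro / re
  structure(list(determinant = determinant, positions = positions,
                 alphabet = rownames(ro), ro = ro, re = re,
                 ratio = ratio, n_obs = n_obs,
                 n_transcripts = 1L, n_occurrences = sum(n_obs),
                 rule = analysis_window()),
            class = "rust_meta")
}
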