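#' Codon usage of a transcript set
#'
#' Frequency per thousand CDS codons (sense codons only).
#'
#' @param transcripts A [transcript_set()].
#' @return Named numeric vector over the 61 sense codons.
#' @export
codon_usage <- function(transcripts) {
  tab <- table(unlist(cds_codons(transcripts), use.names = FALSE))
  u <- stats::setNames(numeric(61), SENSE_CODONS)
  hit <- intersect(names(tab), SENSE_CODONS)
  u[hit] <- as.numeric(tab[hit])
  1000 * u / sum(u)
}

#' Build a codon dwell-time grid
#'
#' Relative dwell times for the 61 sense codons: 61 equally spaced values
#' from 1 (fastest) to `1 + 61 * increment` -- 10.15 for the ~10-fold grid
#' (increment 0.15) and 92.5 for the ~100-fold grid (increment 1.5). Note
#' the printed endpoints imply an actual spacing of `(max - 1)/60`
#' (0.1525 / 1.525), slightly above the nominal increment; the endpoints
#' are honoured.
#'
#' Assignment follows codon-usage rank: with `usage_correlation =
#' "positive"` the rarest codon is the fastest and the most abundant the
#' slowest; `"negative"` reverses the order; `"none"` assigns in fixed
#' lexicographic codon order.
#'
#' @param range_kind `"tenfold"`, `"hundredfold"` or `"custom"`.
#' @param usage_correlation `"positive"`, `"negative"` or `"none"`.
#' @param usage Named codon-usage vector over the 61 sense codons
#'   (default [human_codon_usage]).
#' @param values For `range_kind = "custom"`, the 61 dwell times to assign
#'   (sorted ascending before assignment).
#' @return A `dwell_grid`: named numeric vector of length 61, all > 0.
#' @export
build_dwell_grid <- function(range_kind = c("tenfold", "hundredfold",
                                            "custom"),
                             usage_correlation = c("positive", "negative",
                                                   "none"),
                             usage = human_codon_usage, values = NULL) {
  range_kind <- match.arg(range_kind)
  usage_correlation <- match.arg(usage_correlation)
  if (!all(SENSE_CODONS %in% names(usage))) {
    stop("usage table must cover all 61 sense codons")
  }
  v <- switch(range_kind,
    tenfold = seq(1, 1 + 61 * 0.15, length.out = 61),
    hundredfold = seq(1, 1 + 61 * 1.5, length.out = 61),
    custom = {
      if (is.null(values) || length(values) != 61 || any(values <= 0)) {
        stop("custom grid needs 61 positive values")
      }
      sort(as.numeric(values))
    })
  by_rarity <- SENSE_CODONS[order(usage[SENSE_CODONS], SENSE_CODONS)]
  ord <- switch(usage_correlation,
    positive = by_rarity,
    negative = rev(by_rarity),
    none = SENSE_CODONS)
  t_c <- stats::setNames(v, ord)[SENSE_CODONS]
  structure(t_c, class = "dwell_grid", range_kind = range_kind,
            usage_correlation = usage_correlation)
}

#' @export
print.dwell_grid <- function(x, ...) {
  cat("Dwell-time grid (", attr(x, "range_kind"), ", usage correlation ",
      attr(x, "usage_correlation"), "): 61 codons, range ",
      round(min(x), 3), " - ", round(max(x), 3), "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic transcriptome
#'
#' Builds random transcripts emulating the salient statistics of a
#' mammalian mRNA catalogue: CDS lengths log-normal (median
#' `median_codons`, clipped to `length_range`); codon composition drawn
#' from a reference usage table; per-transcript expression (target read
#' density, reads/nt) log-normal and heavy-tailed; and codon usage coupled
#' to expression (`usage_expression_coupling` > 0 tilts highly expressed
#' transcripts toward abundant codons, as translational selection does in
#' real transcriptomes -- the confound RUST's expected value corrects).
#'
#' Each transcript is `utr_length` nt of random UTR, ATG, the sampled
#' internal codons, a stop codon, and `utr_length` nt of 3' UTR.
#'
#' @param n Number of transcripts.
#' @param seed Integer seed; the generator is fully reproducible given it.
#' @param median_codons Median CDS length in codons (including start/stop).
#' @param sd_log_length Log-scale standard deviation of CDS length.
#' @param length_range Clipping bounds for CDS length (codons).
#' @param usage Codon-usage table (default [human_codon_usage]).
#' @param density_meanlog,density_sdlog Parameters of the log-normal
#'   per-transcript read density (reads/nt). Defaults give a heavy-tailed
#'   distribution with median 0.15 and mean about 1.1 reads/nt.
#' @param usage_expression_coupling Strength of the composition/expression
#'   coupling (0 disables it).
#' @param utr_length UTR length in nt on each side.
#' @return List with `transcripts` (a [transcript_set()]) and `density`
#'   (named numeric, target reads/nt per transcript).
#' @export
simulate_transcriptome <- function(n = 500L, seed = 1L,
                                   median_codons = 350,
                                   sd_log_length = 0.5,
                                   length_range = c(100L, 1200L),
                                   usage = human_codon_usage,
                                   density_meanlog = log(0.15),
                                   density_sdlog = 2.0,
                                   usage_expression_coupling = 0.3,
                                   utr_length = 30L) {
  set.seed(seed)
  L <- pmin(pmax(round(stats::rlnorm(n, log(median_codons),
                                     sd_log_length)), length_range[1]),
            length_range[2])
  dens <- stats::rlnorm(n, density_meanlog, density_sdlog)
  z <- log(dens)
  z <- if (n > 1 && stats::sd(z) > 0) (z - mean(z)) / stats::sd(z) else
    rep(0, n)
  u <- usage[SENSE_CODONS] / sum(usage[SENSE_CODONS])
  s <- as.numeric(scale(log(u)))
  seqs <- character(n)
  for (i in seq_len(n)) {
    p <- u * exp(usage_expression_coupling * z[i] * s)
    internal <- sample(SENSE_CODONS, L[i] - 2L, replace = TRUE,
                       prob = p / sum(p))
    utr5 <- paste(sample(c("A", "C", "G", "T"), utr_length, TRUE),
                  collapse = "")
    utr3 <- paste(sample(c("A", "C", "G", "T"), utr_length, TRUE),
                  collapse = "")
    seqs[i] <- paste0(utr5, "ATG", paste(internal, collapse = ""),
                      sample(STOP_CODONS, 1L), utr3)
  }
  ids <- sprintf("tx%04d", seq_len(n))
  ts <- transcript_set(id = ids, sequence = seqs,
                       cds_start = rep(utr_length, n),
                       cds_end = utr_length + 3L * L,
                       gene_id = sprintf("gene%04d", seq_len(n)))
  list(transcripts = ts, density = stats::setNames(dens, ids))
}

#' Simulate ribo-seq codon profiles under a Poisson dwell-time model
#'
#' For every admissible codon position of codon `c` on mRNA `m`, the count
#' is drawn independently from `Poisson(lambda)` with
#' `lambda = D_m * t_c / sum(n_{c',m} * t_{c'})`, where `D_m` is the total
#' number of footprints on `m`, `t_c` the relative dwell time, and the
#' denominator sums over the admissible codon occurrences -- so decoding
#' rate depends exclusively on the A-site codon, and the expected total
#' per transcript is `D_m`. Positions outside the admissible region stay
#' zero.
#'
#' @param transcripts A [transcript_set()].
#' @param grid A [build_dwell_grid()] dwell grid.
#' @param density Named numeric, target reads/nt per transcript (as from
#'   [simulate_transcriptome()]). Ignored when `reads_per_transcript` is
#'   given.
#' @param reads_per_transcript Optional named numeric, expected total
#'   footprints `D_m` per transcript.
#' @param seed Integer seed.
#' @param rule An [analysis_window()].
#' @return A `simulated_dataset`: list with `profiles` (a
#'   `codon_profiles`), `truth` (the grid), `density`, `seed`.
#' @export
simulate_dataset <- function(transcripts, grid, density = NULL,
                             reads_per_transcript = NULL, seed = 1L,
                             rule = analysis_window()) {
  set.seed(seed)
  codons <- cds_codons(transcripts)
  n <- nrow(transcripts)
  if (is.null(reads_per_transcript)) {
    if (is.null(density)) {
      density <- stats::setNames(stats::rlnorm(n, log(0.15), 2.0),
                                 transcripts$id)
    }
  }
  profiles <- vector("list", n)
  names(profiles) <- transcripts$id
  skipped <- 0L
  for (i in seq_len(n)) {
    cod <- codons[[i]]
    adm <- admissible_codon_indices(length(cod), rule) + 1L
    cnt <- integer(length(cod))
    if (!length(adm)) {
      skipped <- skipped + 1L
      profiles[[i]] <- cnt
      next
    }
    t_adm <- unname(grid[cod[adm]])
    D <- if (!is.null(reads_per_transcript)) {
      reads_per_transcript[[transcripts$id[i]]]
    } else {
      density[[transcripts$id[i]]] * 3 * length(adm)
    }
    lam <- D * t_adm / sum(t_adm)
    cnt[adm] <- stats::rpois(length(adm), lam)
    profiles[[i]] <- cnt
  }
  profiles <- structure(profiles, class = "codon_profiles",
                        offset = NA_integer_, read_length = NA_integer_,
                        skipped = 0L)
  structure(list(profiles = profiles, truth = grid,
                 density = density, seed = seed, rule = rule,
                 transcripts_skipped = skipped),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  tot <- sum(vapply(x$profiles, sum, numeric(1)))
  cat("Simulated ribo-seq dataset: ", length(x$profiles), " transcripts, ",
      format(tot, big.mark = ","), " footprints, ",
      attr(x$truth, "range_kind"), " dwell grid (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Inject heterogeneous noise into a simulated dataset
#'
#' Two noise models. `"peaks"`: per transcript, a binomial number of codons
#' (expected `fraction` times the number of covered codons) is drawn from
#' *all* admissible coordinates -- previously empty ones included -- and
#' their counts are replaced by `peak_multiplier` times the highest count
#' of the original profile. `"dropout"`: each covered codon independently
#' loses its reads with probability `fraction`. Selection is probabilistic,
#' so the realized number of altered codons varies between transcripts.
#' Profiles with no mapped reads are returned unchanged.
#'
#' @param dataset A `simulated_dataset`.
#' @param mode `"peaks"`, `"dropout"` or `"none"`.
#' @param fraction Proportion of covered codons affected (e.g. 0.05, 0.20).
#' @param peak_multiplier Peak height as a multiple of the original profile
#'   maximum (default 3).
#' @param seed Integer seed.
#' @return The dataset with modified profiles.
#' @export
inject_noise <- function(dataset, mode = c("peaks", "dropout", "none"),
                         fraction = 0.2, peak_multiplier = 3,
                         seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(fraction >= 0, fraction <= 1)
  if (mode == "none" || fraction == 0) return(dataset)
  set.seed(seed)
  rule <- dataset$rule
  if (is.null(rule)) rule <- analysis_window()
  profiles <- dataset$profiles
  for (id in names(profiles)) {
    cnt <- profiles[[id]]
    adm <- admissible_codon_indices(length(cnt), rule) + 1L
    cov <- adm[cnt[adm] > 0L]
    if (!length(cov)) next
    if (mode == "peaks") {
      k <- stats::rbinom(1L, length(cov), fraction)
      if (k == 0L) next
      sel <- sample(adm, min(k, length(adm)))
      cnt[sel] <- as.integer(peak_multiplier * max(cnt))
    } else {
      drop <- cov[stats::runif(length(cov)) < fraction]
      cnt[drop] <- 0L
    }
    profiles[[id]] <- cnt
  }
  dataset$profiles <- profiles
  dataset
}

#' Expand simulated profiles into read alignments
#'
#' Inverse of the A-site attribution: every footprint counted at codon `k`
#' becomes one read whose 5' end lies at `cds_start + 3k - offset` plus a
#' small subcodon displacement drawn from `frame_probs` (the nuclease does
#' not trim footprints to a single nucleotide position). Reads that would
#' start before the transcript 5' end or run past its 3' end are dropped.
#'
#' @param dataset A `simulated_dataset`.
#' @param transcripts The [transcript_set()] the dataset was simulated on.
#' @param offset True A-site offset in nt (default 17).
#' @param read_length Read length in nt (default 28).
#' @param frame_probs Probabilities of a 0/+1/+2 nt displacement of the 5'
#'   end (default `c(0.5, 0.3, 0.2)`; the offset refers to the predominant,
#'   unshifted 5' position).
#' @param seed Integer seed.
#' @return An `alignment_table`.
#' @export
simulate_alignments <- function(dataset, transcripts, offset = 17L,
                                read_length = 28L,
                                frame_probs = c(0.5, 0.3, 0.2),
                                seed = 1L) {
  set.seed(seed)
  cds_start <- stats::setNames(transcripts$cds_start, transcripts$id)
  seqlen <- stats::setNames(nchar(transcripts$sequence), transcripts$id)
  out_id <- list()
  out_pos <- list()
  for (id in names(dataset$profiles)) {
    cnt <- dataset$profiles[[id]]
    nz <- which(cnt > 0L)
    if (!length(nz)) next
    k <- rep.int(nz - 1L, cnt[nz])
    j <- sample(0:2, length(k), replace = TRUE, prob = frame_probs)
    pos <- cds_start[[id]] + 3L * k - as.integer(offset) + j
    ok <- pos >= 0L & (pos + read_length) <= seqlen[[id]]
    out_id[[id]] <- rep(id, sum(ok))
    out_pos[[id]] <- pos[ok]
  }
  alignment_table(transcript_id = unlist(out_id, use.names = FALSE),
                  pos = unlist(out_pos, use.names = FALSE),
                  read_length = read_length, unique = TRUE)
}

#' Evaluate estimated dwell times against simulated truth
#'
#' Both the estimate and the truth are mean-normalized over the 61 sense
#' codons (log2-scale estimates are exponentiated first); the evaluation
#' reports per-codon `log2(estimated/simulated)` ratios, their summary,
#' and the coefficient of determination (squared Pearson correlation)
#' between the normalized values. Codons with undefined or non-positive
#' estimates are excluded and flagged.
#'
#' @param estimated A [codon_scores] object or named numeric vector.
#' @param truth A [build_dwell_grid()] grid (or named numeric, 61 codons).
#' @return A `dwell_eval` list: `log_ratio` (named numeric), `r_squared`,
#'   `spearman`, `excluded` (character), `method`.
#' @export
evaluate_estimates <- function(estimated, truth) {
  method <- if (inherits(estimated, "codon_scores")) {
    attr(estimated, "method")
  } else "custom"
  est <- mean_normalize(estimated)[SENSE_CODONS]
  tr <- unname(truth[SENSE_CODONS]) / mean(truth[SENSE_CODONS])
  bad <- is.na(est) | est <= 0
  excluded <- SENSE_CODONS[bad]
  lr <- stats::setNames(rep(NA_real_, 61), SENSE_CODONS)
  lr[!bad] <- log2(est[!bad] / tr[!bad])
  r2 <- stats::cor(est[!bad], tr[!bad])^2
  sp <- stats::cor(est[!bad], tr[!bad], method = "spearman")
  structure(list(log_ratio = lr, r_squared = r2, spearman = sp,
                 excluded = excluded, method = method),
            class = "dwell_eval")
}

#' @export
print.dwell_eval <- function(x, ...) {
  cat("Dwell-time estimate evaluation (", x$method, ")\n", sep = "")
  cat("  R-squared: ", round(x$r_squared, 4),
      "   Spearman: ", round(x$spearman, 4), "\n", sep = "")
  q <- stats::quantile(x$log_ratio, c(0.25, 0.5, 0.75), na.rm = TRUE)
  cat("  log2(est/sim) quartiles: ", paste(round(q, 3), collapse = " / "),
      if (length(x$excluded)) paste0("   (", length(x$excluded),
                                     " codons excluded)"), "\n", sep = "")
  invisible(x)
}
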