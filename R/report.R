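#' Triplet periodicity of footprint 5' ends
#'
#' For each read length, the fraction of read 5' ends falling in each of
#' the three frames relative to the CDS start -- the standard
#' library-quality signal of ribosome profiling. Fractions sum to 1 per
#' length; lengths with no reads are omitted.
#'
#' @param alignments An `alignment_table`.
#' @param transcripts A [transcript_set()].
#' @return Data frame with columns `read_length`, `frame0`, `frame1`,
#'   `frame2`, `n_reads`.
#' @export
triplet_periodicity <- function(alignments, transcripts) {
  aln <- alignments[alignments$transcript_id %in% transcripts$id, ,
                    drop = FALSE]
  cds_start <- stats::setNames(transcripts$cds_start, transcripts$id)
  frame <- (aln$pos - cds_start[aln$transcript_id]) %% 3L
  rows <- list()
  for (len in sort(unique(aln$read_length))) {
    f <- frame[aln$read_length == len]
    if (!length(f)) next
    tab <- tabulate(f + 1L, nbins = 3L)
    rows[[as.character(len)]] <- data.frame(
      read_length = len, frame0 = tab[1] / sum(tab),
      frame1 = tab[2] / sum(tab), frame2 = tab[3] / sum(tab),
      n_reads = sum(tab))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Values are kept
#' as strings; callers coerce as needed.
#'
#' @param path Path to the configuration file.
#' @return Named list of character values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                  vapply(kv, `[[`, "", 1))
}

#' Per-dataset report bundle
#'
#' Runs the full analysis suite on one dataset and writes a directory of
#' CSV tables and PNG figures: the codon metafootprint with single and
#' adjacent-pair K-L divergence, A-site codon ratios grouped by amino acid
#' with codon-usage marker sizes, the distribution of per-transcript
#' prediction correlations, the tripeptide synergy map, and (when
#' alignments are supplied) triplet periodicity per read length. A
#' machine-readable `summary.tsv` records the headline numbers. Outputs
#' are deterministic given identical inputs.
#'
#' @param profiles A `codon_profiles` object.
#' @param transcripts A [transcript_set()].
#' @param out_dir Output directory (created if absent).
#' @param alignments Optional `alignment_table` for periodicity.
#' @param offset Optional A-site offset to record (informational; when
#'   `alignments` are given and `offset` is `NULL` it is auto-detected).
#' @param sites Codon sites for the prediction section.
#' @param rule An [analysis_window()].
#' @param plots Write PNG figures (default TRUE).
#' @return Invisibly, a list with the computed sections.
#' @export
run_report <- function(profiles, transcripts, out_dir,
                       alignments = NULL, offset = NULL, sites = -6:5,
                       rule = analysis_window(), plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  status <- 0L
  # metafootprint + K-L
  meta <- rust_metafootprint(profiles, transcripts, "codon", rule = rule)
  kl <- kl_series(meta)
  pairs <- kl_adjacent_pairs(kl)
  mf <- data.frame(determinant = rep(meta$alphabet, ncol(meta$ratio)),
                   position = rep(meta$positions, each = nrow(meta$ratio)),
                   ro = as.vector(meta$ro), re = as.vector(meta$re),
                   ratio = as.vector(meta$ratio),
                   n_obs = as.vector(meta$n_obs))
  utils::write.csv(mf, file.path(out_dir, "metafootprint.csv"),
                   row.names = FALSE)
  utils::write.csv(cbind(kl, pair_divergence = c(pairs$divergence, NA)),
                   file.path(out_dir, "kl_divergence.csv"),
                   row.names = FALSE)
  # codon ratios by amino acid, usage-scaled
  a0 <- coef(meta)
  usage <- codon_usage(transcripts)
  byaa <- data.frame(codon = names(a0), amino_acid = translate_codons(names(a0)),
                     ratio = unname(a0),
                     usage_per_thousand = unname(usage[names(a0)]))
  byaa <- byaa[order(byaa$amino_acid, byaa$codon), ]
  utils::write.csv(byaa, file.path(out_dir, "codon_ratios_by_aa.csv"),
                   row.names = FALSE)
  # prediction
  pred <- predict(meta, transcripts, sites = sites, rule = rule)
  ev <- evaluate_prediction(pred, profiles, rule = rule)
  utils::write.csv(ev, file.path(out_dir, "prediction.csv"),
                   row.names = FALSE)
  # synergy
  aa_meta <- rust_metafootprint(profiles, transcripts, "amino_acid",
                                rule = rule)
  tri_meta <- rust_metafootprint(profiles, transcripts, "tripeptide",
                                 rule = rule)
  syn <- synergy_scores(tri_meta, aa_meta)
  utils::write.csv(syn[syn$flagged, , drop = FALSE],
                   file.path(out_dir, "synergy_flagged.csv"),
                   row.names = FALSE)
  # periodicity
  peri <- NULL
  if (!is.null(alignments)) {
    if (is.null(offset)) {
      offset <- tryCatch(
        as.integer(detect_a_site_offset(alignments, transcripts,
                                        rule = rule)),
        error = function(e) { status <<- 1L; NA_integer_ })
    }
    peri <- triplet_periodicity(alignments, transcripts)
    utils::write.csv(peri, file.path(out_dir, "periodicity.csv"),
                     row.names = FALSE)
  }
  # summary
  summ <- data.frame(
    key = c("n_transcripts", "n_footprints", "kl_max_position",
            "kl_max_bits", "median_prediction_pearson",
            "n_synergy_flagged", "a_site_offset"),
    value = c(length(profiles),
              sum(vapply(profiles, sum, numeric(1))),
              kl$position[which.max(kl$divergence)],
              round(max(kl$divergence, na.rm = TRUE), 4),
              round(stats::median(ev$pearson_r), 4),
              sum(syn$flagged),
              if (is.null(offset)) NA else offset))
  utils::write.table(summ, file.path(out_dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (plots) {
    grDevices::png(file.path(out_dir, "metafootprint.png"), 900, 700)
    plot(meta)
    grDevices::dev.off()
    grDevices::png(file.path(out_dir, "codon_ratios_by_aa.png"), 900, 500)
    graphics::plot(as.integer(factor(byaa$amino_acid)), byaa$ratio,
                   cex = sqrt(byaa$usage_per_thousand / 10), pch = 19,
                   col = "darkgreen", xaxt = "n",
                   xlab = "amino acid", ylab = "A-site RUST ratio")
    graphics::axis(1, at = seq_along(unique(byaa$amino_acid)),
                   labels = unique(byaa$amino_acid))
    grDevices::dev.off()
    if (nrow(ev)) {
      grDevices::png(file.path(out_dir, "prediction.png"), 600, 500)
      graphics::hist(ev$pearson_r, breaks = 20, col = "violet",
                     main = "Predicted vs observed densities",
                     xlab = "per-transcript Pearson r")
      grDevices::dev.off()
    }
    if (!is.null(peri)) {
      grDevices::png(file.path(out_dir, "periodicity.png"), 600, 500)
      graphics::barplot(t(as.matrix(peri[, c("frame0", "frame1",
                                             "frame2")])),
                        beside = TRUE, names.arg = peri$read_length,
                        xlab = "read length (nt)",
                        ylab = "fraction of 5' ends",
                        legend.text = c("frame 0", "frame 1", "frame 2"))
      grDevices::dev.off()
    }
  }
  res <- list(meta = meta, kl = kl, kl_pairs = pairs, by_aa = byaa,
              prediction = ev, synergy = syn, periodicity = peri,
              offset = offset, status = status)
  invisible(res)
}
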