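#' Binarize a codon count profile (unit step transformation)
#'
#' A codon scores 1 when its footprint count strictly exceeds the
#' transcript's average density, 0 otherwise. The average is taken over the
#' admissible (trimmed) region of the CDS so that the threshold and the
#' downstream statistics see the same data; when the CDS is too short to
#' have an admissible region the full CDS mean is used.
#'
#' @param counts Integer vector of per-codon footprint counts.
#' @param rule An [analysis_window()].
#' @return List with `values` (0/1 integer vector, same length as
#'   `counts`), `mean_density` (the threshold, reads per codon) and
#'   `admissible` (1-based indices the mean was computed over).
#' @export
binarize <- function(counts, rule = analysis_window()) {
  stopifnot(length(counts) >= 1)
  adm <- admissible_codon_indices(length(counts), rule) + 1L
  if (!length(adm)) adm <- seq_along(counts)
  m <- mean(counts[adm])
  list(values = as.integer(counts > m), mean_density = m, admissible = adm)
}

## Flattened per-occurrence view of the binarized data set: one row per
## admissible A-site position of every transcript with >= 1 read in its
## admissible region. Shared by the metafootprint, the normalizations and
## the predictor so they all see identical filtering.
.rust_flat <- function(profiles, transcripts, rule = analysis_window()) {
  ids <- intersect(transcripts$id, names(profiles))
  transcripts <- transcripts[match(ids, transcripts$id), , drop = FALSE]
  codons <- cds_codons(transcripts)
  Ls <- lengths(codons)
  keep <- logical(length(ids))
  b_list <- vector("list", length(ids))
  mb <- numeric(length(ids))
  adm_list <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cnt <- profiles[[ids[i]]]
    adm <- admissible_codon_indices(Ls[i], rule) + 1L
    if (!length(adm) || sum(cnt[adm]) == 0) next
    bz <- binarize(cnt, rule)
    keep[i] <- TRUE
    b_list[[i]] <- bz$values
    mb[i] <- mean(bz$values[adm])
    adm_list[[i]] <- adm
  }
  w <- which(keep)
  if (!length(w)) stop("no transcript has reads in its admissible region")
  offs <- cumsum(c(0L, Ls[w]))  # codon offsets into the flat arrays
  occ_n <- lengths(adm_list[w])
  list(
    ids = ids[w],
    codons = unlist(codons[w], use.names = FALSE),
    aa = translate_codons(unlist(codons[w], use.names = FALSE)),
    nt = paste(transcripts$sequence[w], collapse = ""),
    nt_off = cumsum(c(0L, nchar(transcripts$sequence[w]))),
    cds_start = transcripts$cds_start[w],
    L = unname(Ls[w]),
    tx_of_occ = rep.int(seq_along(w), occ_n),
    klocal = unlist(adm_list[w], use.names = FALSE) - 1L,   # 0-based
    gpos = unlist(Map(function(a, o) a + o, adm_list[w], offs[-length(offs)]),
                  use.names = FALSE),                        # 1-based flat
    B = unlist(Map(function(b, a) b[a], b_list[w], adm_list[w]),
               use.names = FALSE),
    MB = rep.int(mb[w], occ_n),
    counts = lapply(w, function(i) profiles[[ids[i]]]),
    rule = rule
  )
}

.det_arity <- function(determinant) {
  switch(determinant, codon = 1L, nucleotide = 1L, amino_acid = 1L,
         dipeptide = 2L, tripeptide = 3L,
         stop("unknown determinant: ", determinant))
}

## labels of a determinant at relative position l for every occurrence;
## NA where the context falls outside the transcript or hits a stop codon
.det_labels <- function(flat, determinant, l) {
  arity <- .det_arity(determinant)
  Lo <- flat$L[flat$tx_of_occ]
  if (determinant == "nucleotide") {
    ntpos <- 3L * flat$klocal + l          # nt offset within CDS
    ok <- ntpos >= 0L & ntpos < 3L * Lo
    g <- flat$nt_off[flat$tx_of_occ] + flat$cds_start[flat$tx_of_occ] +
      ntpos + 1L
    lab <- rep(NA_character_, length(g))
    lab[ok] <- substring(flat$nt, g[ok], g[ok])
    return(lab)
  }
  kl <- flat$klocal + l
  ok <- kl >= 0L & (kl + arity - 1L) <= (Lo - 1L)
  g <- flat$gpos + l
  lab <- rep(NA_character_, length(g))
  if (determinant == "codon") {
    cc <- flat$codons[g[ok]]
    cc[cc %in% STOP_CODONS] <- NA_character_  # 61 sense codons only
    lab[ok] <- cc
  } else {
    a1 <- flat$aa[g[ok]]
    if (arity >= 2L) a1 <- paste0(a1, flat$aa[g[ok] + 1L])
    if (arity == 3L) a1 <- paste0(a1, flat$aa[g[ok] + 2L])
    a1[grepl("*", a1, fixed = TRUE)] <- NA_character_  # stop codons excluded
    lab[ok] <- a1
  }
  lab
}

#' RUST metafootprint profile
#'
#' The central estimator of the package. Footprint profiles are first
#' binarized ([binarize()]); then, for every determinant value `d` (a codon,
#' nucleotide, amino acid, dipeptide or tripeptide) and every position `l`
#' relative to the A-site, the observed RUST value `ro(d, l)` is the mean of
#' the A-site binary indicator over all admissible A-site occurrences whose
#' context at `l` equals `d`, and the expected value `re(d, l)` is the mean,
#' over the same occurrences, of the transcript-level mean binary value.
#' The ratio `ro/re` measures enrichment (> 1, slow) or depletion (< 1,
#' fast) of footprints given the determinant, corrected for the non-random
#' distribution of determinants across genes of different expression.
#'
#' Transcripts with no reads in their admissible region are excluded.
#' Cells never observed are left `NA`, not zero-filled.
#'
#' @param profiles A `codon_profiles` object (see [build_codon_profiles()]).
#' @param transcripts A [transcript_set()].
#' @param determinant One of `"codon"`, `"nucleotide"`, `"amino_acid"`,
#'   `"dipeptide"`, `"tripeptide"`.
#' @param positions Integer vector of positions relative to the A-site
#'   (codons, or nt for the nucleotide determinant). Default `-40:20`
#'   (codon-level) or `-120:62` (nucleotide).
#' @param rule An [analysis_window()].
#' @return An object of class `rust_meta` with matrices `ro`, `re`,
#'   `ratio` and `n_obs` (determinant x position).
#' @seealso [kl_series()], [coef.rust_meta()], [predict.rust_meta()]
#' @export
rust_metafootprint <- function(profiles, transcripts,
                               determinant = c("codon", "nucleotide",
                                               "amino_acid", "dipeptide",
                                               "tripeptide"),
                               positions = NULL,
                               rule = analysis_window()) {
  determinant <- match.arg(determinant)
  if (is.null(positions)) {
    positions <- if (determinant == "nucleotide") -120:62 else -40:20
  }
  flat <- .rust_flat(profiles, transcripts, rule)
  .meta_from_flat(flat, determinant, positions)
}

.meta_from_flat <- function(flat, determinant, positions) {
  acc <- list()
  X <- cbind(flat$B, flat$MB, 1)
  for (j in seq_along(positions)) {
    lab <- .det_labels(flat, determinant, positions[j])
    ok <- !is.na(lab)
    s <- rowsum(X[ok, , drop = FALSE], lab[ok])
    acc[[j]] <- s
  }
  alphabet <- sort(unique(unlist(lapply(acc, rownames), use.names = FALSE)))
  ro <- re <- nmat <- matrix(NA_real_, length(alphabet), length(positions),
                             dimnames = list(alphabet, positions))
  for (j in seq_along(positions)) {
    s <- acc[[j]]
    i <- match(rownames(s), alphabet)
    nmat[i, j] <- s[, 3]
    ro[i, j] <- s[, 1] / s[, 3]
    re[i, j] <- s[, 2] / s[, 3]
  }
  ratio <- ro / re
  ratio[!is.finite(ratio)] <- NA_real_
  structure(list(determinant = determinant, positions = positions,
                 alphabet = alphabet, ro = ro, re = re, ratio = ratio,
                 n_obs = nmat, n_transcripts = length(flat$ids),
                 n_occurrences = length(flat$B), rule = flat$rule),
            class = "rust_meta")
}

#' @export
print.rust_meta <- function(x, ...) {
  cat("RUST metafootprint (", x$determinant, ")\n", sep = "")
  cat("  positions ", min(x$positions), "..", max(x$positions),
      " relative to the A-site, ", length(x$alphabet),
      " determinant values\n", sep = "")
  cat("  ", x$n_transcripts, " transcripts, ",
      format(x$n_occurrences, big.mark = ","),
      " A-site occurrences\n", sep = "")
  kl <- kl_series(x)
  if (any(is.finite(kl$divergence))) {
    pk <- kl$position[which.max(kl$divergence)]
    cat("  K-L divergence peaks at position ", pk, " (",
        round(max(kl$divergence, na.rm = TRUE), 3), " bits)\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.rust_meta <- function(object, ...) {
  kl <- kl_series(object)
  a0 <- coef(object)
  out <- list(determinant = object$determinant,
              n_transcripts = object$n_transcripts,
              kl = kl,
              a_site_range = range(a0, na.rm = TRUE),
              top = sort(a0, decreasing = TRUE)[1:5],
              bottom = sort(a0)[1:5])
  class(out) <- "summary.rust_meta"
  out
}

#' @export
print.summary.rust_meta <- function(x, ...) {
  cat("RUST metafootprint summary (", x$determinant, "), ",
      x$n_transcripts, " transcripts\n", sep = "")
  cat("A-site ratio range: ", round(x$a_site_range[1], 3), " - ",
      round(x$a_site_range[2], 3), "\n", sep = "")
  cat("Most enriched at the A-site (slowest):\n")
  print(round(x$top, 3))
  cat("Most depleted at the A-site (fastest):\n")
  print(round(x$bottom, 3))
  invisible(x)
}

#' A-site RUST ratios
#'
#' Extracts the observed/expected ratio at a given position (default the
#' A-site, position 0) as a named vector -- the package's per-codon (or
#' per-amino-acid, etc.) enrichment coefficients.
#'
#' @param object A `rust_meta` object.
#' @param position Relative position to extract (default 0).
#' @param ... Unused.
#' @return Named numeric vector over the determinant alphabet.
#' @export
coef.rust_meta <- function(object, position = 0L, ...) {
  j <- match(position, object$positions)
  if (is.na(j)) stop("position ", position, " not in the profile")
  stats::setNames(object$ratio[, j], object$alphabet)
}

#' @export
plot.rust_meta <- function(x, kl = TRUE, ...) {
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  if (kl) graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 1))
  graphics::matplot(x$positions, t(x$ratio), type = "l", lty = 1,
                    col = grDevices::grey(0.2, alpha = 0.25),
                    xlab = "codon position relative to A-site",
                    ylab = "RUST ratio (ro/re)",
                    main = paste0("RUST metafootprint (", x$determinant, ")"),
                    ...)
  graphics::abline(h = 1, col = "red", lty = 2)
  if (kl) {
    k <- kl_series(x)
    graphics::plot(k$position, k$divergence, type = "h", col = "blue",
                   xlab = "position", ylab = "K-L divergence (bits)")
  }
  invisible(x)
}

#' Kullback-Leibler divergence series of a metafootprint
#'
#' At each relative position the observed and expected RUST values over the
#' defined determinants are renormalized to probability vectors `p` and `q`
#' (each divided by its own sum), and the relative entropy
#' `D_l = sum(p * log2(p/q))` is returned in bits. Positions where fewer
#' than two determinants are defined yield `NA`.
#'
#' @param meta A `rust_meta` object.
#' @return Data frame with columns `position`, `divergence`,
#'   `n_determinants`.
#' @export
kl_series <- function(meta) {
  div <- ndef <- rep(NA_real_, length(meta$positions))
  for (j in seq_along(meta$positions)) {
    ro <- meta$ro[, j]
    re <- meta$re[, j]
    n <- meta$n_obs[, j]
    def <- !is.na(ro) & !is.na(re) & !is.na(n) & n > 0 & re > 0
    ndef[j] <- sum(def)
    if (sum(def) < 2 || sum(ro[def]) == 0) next
    p <- ro[def] / sum(ro[def])
    q <- re[def] / sum(re[def])
    term <- ifelse(p > 0, p * log2(p / q), 0)
    div[j] <- sum(term)
  }
  data.frame(position = meta$positions, divergence = div,
             n_determinants = ndef)
}

#' Combined K-L divergence of adjacent position pairs
#'
#' @param kl A data frame from [kl_series()].
#' @return Data frame with columns `position` (left member of the pair) and
#'   `divergence` (sum over the pair).
#' @export
kl_adjacent_pairs <- function(kl) {
  n <- nrow(kl)
  data.frame(position = kl$position[-n],
             divergence = kl$divergence[-n] + kl$divergence[-1])
}

#' Detect the A-site offset from the data
#'
#' For each candidate offset the codon metafootprint and its K-L divergence
#' series are computed; every adjacent codon pair not at the read termini is
#' scored by the sum of the two divergences (the pair is interpreted as the
#' P-site/A-site pair, whose combined identity has the greatest influence
#' on decoding). The offset whose best interior pair is largest wins; exact
#' ties fall to the smallest candidate with a warning.
#'
#' @param alignments An `alignment_table`.
#' @param transcripts A [transcript_set()].
#' @param candidates Candidate offsets in nt (default 16, 17, 18).
#' @param read_length Read length to use; default the predominant length.
#' @param unique_only Passed to [build_codon_profiles()].
#' @param rule An [analysis_window()].
#' @return The selected offset (integer), with attribute `scores` (named
#'   numeric vector of best interior pair K-L per candidate).
#' @export
detect_a_site_offset <- function(alignments, transcripts,
                                 candidates = c(16L, 17L, 18L),
                                 read_length = NULL, unique_only = TRUE,
                                 rule = analysis_window()) {
  stopifnot(length(candidates) >= 2)
  candidates <- sort(as.integer(candidates))
  if (is.null(read_length)) {
    read_length <- select_predominant_length(alignments)
  }
  lo_all <- -(max(candidates) %/% 3L) - 1L
  hi_all <- (read_length - 1L - min(candidates)) %/% 3L + 1L
  scores <- stats::setNames(numeric(length(candidates)),
                            as.character(candidates))
  for (i in seq_along(candidates)) {
    off <- candidates[i]
    prof <- build_codon_profiles(alignments, transcripts, offset = off,
                                 read_length = read_length,
                                 unique_only = unique_only)
    meta <- rust_metafootprint(prof, transcripts, determinant = "codon",
                               positions = lo_all:hi_all, rule = rule)
    kl <- kl_series(meta)
    # interior codons of the footprint for this offset: drop the codons
    # touching either read terminus
    int_lo <- -(off %/% 3L) + 1L
    int_hi <- (read_length - 1L - off) %/% 3L - 1L
    pairs <- kl_adjacent_pairs(kl)
    use <- pairs$position >= int_lo & (pairs$position + 1L) <= int_hi
    d <- pairs$divergence[use]
    scores[i] <- if (any(is.finite(d))) max(d, na.rm = TRUE) else 0
  }
  best <- which(scores == max(scores))
  if (length(best) > 1) {
    warning("candidate offsets tie on the interior pair K-L; ",
            "returning the smallest")
  }
  structure(candidates[min(best)], scores = scores)
}
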