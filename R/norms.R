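#' Codon score sets
#'
#' All normalization methods return a `codon_scores` object: a data frame
#' with columns `codon`, `score` and `n` (number of occurrences used),
#' carrying attributes `method` and `scale` (`"linear"` or `"log2"`).
#' Codons never observed have `NA` scores.
#'
#' @name codon_scores
NULL

.codon_scores <- function(score, n, method, scale = "linear",
                          extra = NULL) {
  out <- data.frame(codon = SENSE_CODONS,
                    score = unname(score[SENSE_CODONS]),
                    n = unname(n[SENSE_CODONS]),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "scale") <- scale
  if (!is.null(extra)) attr(out, "detail") <- extra
  class(out) <- c("codon_scores", "data.frame")
  out
}

#' @export
print.codon_scores <- function(x, ...) {
  cat("Codon scores (", attr(x, "method"), ", ", attr(x, "scale"),
      " scale): ", sum(!is.na(x$score)), "/61 codons defined\n", sep = "")
  s <- stats::setNames(x$score, x$codon)
  cat("  highest:", paste(names(sort(s, decreasing = TRUE))[1:3],
                          collapse = " "),
      " lowest:", paste(names(sort(s))[1:3], collapse = " "), "\n")
  invisible(x)
}

#' Mean-normalize a codon score set
#'
#' Divides the 61 scores by their mean over defined entries, so that the
#' normalized set has mean exactly 1 (log2-scale sets are first converted
#' to the linear scale).
#'
#' @param scores A `codon_scores` object or named numeric vector.
#' @return A named numeric vector with mean 1 over defined entries.
#' @export
mean_normalize <- function(scores) {
  if (inherits(scores, "codon_scores")) {
    v <- stats::setNames(scores$score, scores$codon)
    if (identical(attr(scores, "scale"), "log2")) v <- 2^v
  } else {
    v <- scores
  }
  v / mean(v, na.rm = TRUE)
}

## per-transcript admissible counts + density, shared by CN/LMN/RRT
.norm_view <- function(profiles, transcripts, rule) {
  ids <- intersect(transcripts$id, names(profiles))
  transcripts <- transcripts[match(ids, transcripts$id), , drop = FALSE]
  codons <- cds_codons(transcripts)
  out <- lapply(seq_along(ids), function(i) {
    adm <- admissible_codon_indices(length(codons[[i]]), rule) + 1L
    if (!length(adm)) return(NULL)
    cnt <- profiles[[ids[i]]][adm]
    list(counts = cnt, codons = codons[[i]][adm],
         density = sum(cnt) / (3 * length(adm)))
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Conventional normalization (CN) codon scores
#'
#' Each profile is divided by its own mean over the admissible region; the
#' per-codon score is the mean normalized density over all A-site
#' occurrences of that codon across included transcripts. With
#' `min_density = 0` all transcripts with at least one read are used
#' (CN>0); with `min_density = 1` only coding regions with average density
#' strictly above 1 read/nt are used (CN>1).
#'
#' @param profiles A `codon_profiles` object.
#' @param transcripts A [transcript_set()].
#' @param min_density Density threshold in reads/nt (0 or 1 typical).
#' @param rule An [analysis_window()].
#' @return A [codon_scores] object.
#' @export
cn_scores <- function(profiles, transcripts, min_density = 0,
                      rule = analysis_window()) {
  view <- .norm_view(profiles, transcripts, rule)
  num <- nn <- stats::setNames(numeric(64), .codon_alphabet())
  used <- 0L
  for (v in view) {
    if (min_density <= 0) {
      if (sum(v$counts) == 0) next
    } else if (v$density <= min_density) next
    used <- used + 1L
    d <- v$counts / mean(v$counts)
    s <- rowsum(cbind(d, 1), v$codons)
    i <- rownames(s)
    num[i] <- num[i] + s[, 1]
    nn[i] <- nn[i] + s[, 2]
  }
  if (used == 0L) stop("insufficient data: no transcript passes the ",
                       "density threshold (", min_density, " reads/nt)")
  score <- ifelse(nn > 0, num / nn, NA_real_)
  .codon_scores(score, nn, method = if (min_density > 0) "CN>1" else "CN>0")
}

#' Logarithmic mean normalization (LMN) codon scores
#'
#' Only coding regions with average density above 1 read/nt and only
#' coordinates with mapped reads enter. Per occurrence, the count is
#' divided by the transcript's mean density (`d`); the LMN value of a codon
#' is the mean of `log2(d)` over its non-zero occurrences minus the grand
#' mean of those codon means over the 61 sense codons. The returned scores
#' are therefore on the log2 scale (uniform data gives all zeros).
#'
#' @inheritParams cn_scores
#' @param min_density Density threshold in reads/nt (default 1).
#' @return A [codon_scores] object with `scale = "log2"`.
#' @export
lmn_scores <- function(profiles, transcripts, min_density = 1,
                       rule = analysis_window()) {
  view <- .norm_view(profiles, transcripts, rule)
  num <- nn <- stats::setNames(numeric(64), .codon_alphabet())
  used <- 0L
  for (v in view) {
    if (v$density <= min_density) next
    used <- used + 1L
    keep <- v$counts > 0
    if (!any(keep)) next
    d <- v$counts[keep] / mean(v$counts)
    s <- rowsum(cbind(log2(d), 1), v$codons[keep])
    i <- rownames(s)
    num[i] <- num[i] + s[, 1]
    nn[i] <- nn[i] + s[, 2]
  }
  if (used == 0L) stop("insufficient data: no transcript passes the ",
                       "density threshold (", min_density, " reads/nt)")
  first <- ifelse(nn > 0, num / nn, NA_real_)[SENSE_CODONS]
  if (anyNA(first)) {
    warning(sum(is.na(first)), " codon(s) with no non-zero occurrence ",
            "excluded from the 61-codon mean")
  }
  score <- first - mean(first, na.rm = TRUE)
  names(score) <- SENSE_CODONS
  .codon_scores(score, nn[SENSE_CODONS], method = "LMN", scale = "log2")
}

#' Ribosome residence time (RRT) codon scores
#'
#' Tiling 19-codon windows (step 1) over the admissible region are kept
#' when they hold strictly more than 19 aligned reads, fewer than 3 codons
#' with no alignment, and the codon at window position 10 (1-based) occurs
#' exactly once in the window. For each qualifying window the fraction of
#' window reads on each position is recorded; the score of a codon is the
#' mean fraction observed at window position 10 over windows whose focal
#' codon it is. The full 19-position fraction matrix is attached as the
#' `detail` attribute.
#'
#' @inheritParams cn_scores
#' @return A [codon_scores] object.
#' @export
rrt_scores <- function(profiles, transcripts, rule = analysis_window()) {
  view <- .norm_view(profiles, transcripts, rule)
  wlen <- 19L
  focal <- 10L
  num <- matrix(0, 64, wlen, dimnames = list(.codon_alphabet(), NULL))
  nn <- stats::setNames(numeric(64), .codon_alphabet())
  for (v in view) {
    n <- length(v$counts)
    if (n < wlen) next
    cs <- cumsum(v$counts)
    zs <- cumsum(v$counts == 0L)
    ends <- wlen:n
    tot <- cs[ends] - c(0, cs)[ends - wlen + 1L]
    nz <- zs[ends] - c(0, zs)[ends - wlen + 1L]
    cand <- ends[tot > 19 & nz < 3]
    for (e in cand) {
      s <- e - wlen + 1L
      fc <- v$codons[s + focal - 1L]
      if (sum(v$codons[s:e] == fc) != 1L) next
      w <- v$counts[s:e]
      fr <- w / sum(w)
      num[fc, ] <- num[fc, ] + fr
      nn[fc] <- nn[fc] + 1
    }
  }
  if (sum(nn) == 0) stop("insufficient data: no qualifying 19-codon window")
  score <- ifelse(nn > 0, num[, focal] / nn, NA_real_)
  detail <- sweep(num, 1, pmax(nn, 1), "/")
  .codon_scores(score, nn, method = "RRT", extra = detail)
}

#' RUST codon scores (A-site ratios)
#'
#' Convenience wrapper computing the codon metafootprint at the A-site only
#' and returning the observed/expected ratios as a [codon_scores] object --
#' RUST's estimate of relative codon dwell times.
#'
#' @inheritParams cn_scores
#' @return A [codon_scores] object.
#' @export
rust_codon_scores <- function(profiles, transcripts,
                              rule = analysis_window()) {
  meta <- rust_metafootprint(profiles, transcripts, determinant = "codon",
                             positions = 0L, rule = rule)
  score <- nn <- stats::setNames(rep(NA_real_, 64), .codon_alphabet())
  score[meta$alphabet] <- meta$ratio[, 1]
  nn[meta$alphabet] <- meta$n_obs[, 1]
  .codon_scores(score, nn, method = "RUST")
}
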