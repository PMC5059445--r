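#' Combine single-site RUST ratios multiplicatively
#'
#' Under positional independence the expected RUST ratio of a multi-site
#' context is the product of the single-site ratios; e.g. P-site and
#' A-site ratios of 0.339 and 1.646 combine to an expected di-codon ratio
#' of 0.558. Returns `NA` when any factor is undefined.
#'
#' @param ratios Numeric vector of single-site RUST ratios.
#' @return Their product, or `NA` if any is `NA`.
#' @export
combine_site_ratios <- function(ratios) {
  if (anyNA(ratios)) return(NA_real_)
  prod(ratios)
}

#' Expected tripeptide RUST ratio from single-residue ratios
#'
#' The independence expectation for tripeptide `ijk` whose first residue
#' sits at `position`: the product of the single-residue amino-acid
#' ratios at `position`, `position + 1` and `position + 2`.
#'
#' @param aa_meta An amino-acid `rust_meta` (from [rust_metafootprint()]
#'   with `determinant = "amino_acid"`).
#' @param tripeptide Three-letter string of one-letter residue codes.
#' @param position Codon offset of the first residue relative to the
#'   A-site.
#' @return Numeric expected ratio (`NA` when a factor is undefined).
#' @export
expected_tripeptide_ratio <- function(aa_meta, tripeptide, position) {
  res <- strsplit(tripeptide, "")[[1]]
  stopifnot(length(res) == 3)
  pos <- position + 0:2
  j <- match(pos, aa_meta$positions)
  i <- match(res, aa_meta$alphabet)
  if (anyNA(j) || anyNA(i)) return(NA_real_)
  combine_site_ratios(aa_meta$ratio[cbind(i, j)])
}

#' Tripeptide synergy scan
#'
#' Detects tripeptides whose footprint enrichment deviates from the
#' independence expectation of their residues. For each tripeptide and
#' first-residue position, the difference
#' `log2(observed ratio) - log2(expected ratio)` is computed; per
#' tripeptide, the differences over the background range are standardized
#' (standard score: subtract their mean, divide by their standard
#' deviation), and positions with `|S| > flag_threshold` are flagged.
#' Only adjacent residues are considered. With the default 20-residue
#' alphabet and 58 scan positions the scan covers 464,000 combinations.
#'
#' @param tri_meta A tripeptide `rust_meta` (same binary profiles as
#'   `aa_meta`).
#' @param aa_meta The matching amino-acid `rust_meta`.
#' @param scan_positions First-residue positions to score (default
#'   `-40:17`, 58 positions, so the 3-residue window stays within
#'   -40..+19 of the A-site).
#' @param background_range Positions whose differences form the
#'   standardization background (default `-40:18`).
#' @param flag_threshold Standard-score magnitude to flag (default 4).
#' @param min_background Minimum defined background positions per
#'   tripeptide (default 3; tripeptides below it are excluded).
#' @return A `synergy_table` data frame: `tripeptide`, `position`,
#'   `observed`, `expected`, `difference`, `S`, `flagged`; attribute
#'   `n_combinations` records the size of the full scan space.
#' @export
synergy_scores <- function(tri_meta, aa_meta, scan_positions = -40:17,
                           background_range = -40:18,
                           flag_threshold = 4, min_background = 3L) {
  stopifnot(identical(tri_meta$determinant, "tripeptide"),
            identical(aa_meta$determinant, "amino_acid"))
  bg_pos <- intersect(background_range, tri_meta$positions)
  all_pos <- sort(union(scan_positions, bg_pos))
  # expected log-ratio matrix over tripeptides present in the data
  tri <- tri_meta$alphabet
  r1 <- substr(tri, 1, 1)
  r2 <- substr(tri, 2, 2)
  r3 <- substr(tri, 3, 3)
  la <- log2(aa_meta$ratio)
  jj <- match(all_pos, tri_meta$positions)
  obs <- log2(tri_meta$ratio[, jj, drop = FALSE])
  exp_l <- matrix(NA_real_, length(tri), length(all_pos))
  for (j in seq_along(all_pos)) {
    p <- all_pos[j]
    ja <- match(p + 0:2, aa_meta$positions)
    if (anyNA(ja)) next
    exp_l[, j] <- la[cbind(match(r1, aa_meta$alphabet), ja[1])] +
      la[cbind(match(r2, aa_meta$alphabet), ja[2])] +
      la[cbind(match(r3, aa_meta$alphabet), ja[3])]
  }
  diff <- obs - exp_l
  bg_cols <- match(bg_pos, all_pos)
  bg <- diff[, bg_cols, drop = FALSE]
  n_bg <- rowSums(is.finite(bg))
  mu <- rowMeans(bg, na.rm = TRUE)
  sd_bg <- apply(bg, 1, stats::sd, na.rm = TRUE)
  keep <- n_bg >= min_background & is.finite(sd_bg) & sd_bg > 1e-9
  scan_cols <- match(intersect(scan_positions, all_pos), all_pos)
  S <- (diff[, scan_cols, drop = FALSE] - mu) / sd_bg
  rows <- which(keep)
  out <- do.call(rbind, lapply(scan_cols, function(j) {
    sj <- S[, match(j, scan_cols)]
    def <- rows[is.finite(sj[rows])]
    if (!length(def)) return(NULL)
    data.frame(tripeptide = tri[def], position = all_pos[j],
               observed = 2^obs[def, j], expected = 2^exp_l[def, j],
               difference = diff[def, j], S = sj[def],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(tripeptide = character(), position = integer(),
                      observed = numeric(), expected = numeric(),
                      difference = numeric(), S = numeric())
  }
  out$flagged <- abs(out$S) > flag_threshold
  rownames(out) <- NULL
  attr(out, "n_combinations") <- as.integer(20^3 * length(scan_positions))
  class(out) <- c("synergy_table", "data.frame")
  out
}

#' @export
print.synergy_table <- function(x, ...) {
  cat("Tripeptide synergy scan: ", nrow(x), " evaluated cells (of ",
      format(attr(x, "n_combinations"), big.mark = ","),
      " possible), ", sum(x$flagged), " flagged (|S| > 4)\n", sep = "")
  if (any(x$flagged)) {
    top <- x[order(-abs(x$S)), ][seq_len(min(5, sum(x$flagged))), ]
    cat("  strongest: ",
        paste(sprintf("%s@%+d (S=%.1f)", top$tripeptide, top$position,
                      top$S), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
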