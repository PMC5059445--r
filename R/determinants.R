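#' RUST profile of peptide physicochemical properties
#'
#' Measures RUST ratios for nascent-peptide fragments of `length` residues
#' with a given physicochemical property: the number of positively charged
#' residues (H, K, R), the net charge (positives minus D/E), or the number
#' of hydrophobic residues (A, V, I, L, M, F, Y, W). For every admissible
#' A-site occurrence and every window start position `l` (in codons
#' relative to the A-site; the reported position is the window's 5'-most
#' residue), the property of the encoded `length`-mer is computed and the
#' observed/expected RUST values are aggregated per integer property
#' value.
#'
#' @param profiles A `codon_profiles` object.
#' @param transcripts A [transcript_set()].
#' @param property One of `"positive_charges"`, `"net_charge"`,
#'   `"hydrophobic_count"`.
#' @param length Window length in residues (default 10).
#' @param positions Window start positions relative to the A-site
#'   (default `-40:11`, so the window stays inside the metafootprint
#'   span).
#' @param rule An [analysis_window()].
#' @return A `rust_meta`-like object whose alphabet is the observed
#'   integer property values (as character).
#' @export
peptide_property_profile <- function(profiles, transcripts,
                                     property = c("positive_charges",
                                                  "net_charge",
                                                  "hydrophobic_count"),
                                     length = 10L, positions = -40:11,
                                     rule = analysis_window()) {
  property <- match.arg(property)
  flat <- .rust_flat(profiles, transcripts, rule)
  X <- cbind(flat$B, flat$MB, 1)
  Lo <- flat$L[flat$tx_of_occ]
  acc <- list()
  for (j in seq_along(positions)) {
    l <- positions[j]
    kl <- flat$klocal + l
    ok <- kl >= 0L & (kl + length - 1L) <= (Lo - 1L)
    g <- flat$gpos + l
    val <- rep(0L, sum(ok))
    valid <- rep(TRUE, sum(ok))
    for (d in seq_len(length) - 1L) {
      a <- flat$aa[g[ok] + d]
      valid <- valid & a != "*"
      val <- val + switch(property,
        positive_charges = as.integer(a %in% .AA_POSITIVE),
        net_charge = as.integer(a %in% .AA_POSITIVE) -
          as.integer(a %in% .AA_NEGATIVE),
        hydrophobic_count = as.integer(a %in% .AA_HYDROPHOBIC))
    }
    lab <- rep(NA_character_, nrow(X))
    lab[ok][valid] <- as.character(val[valid])
    okl <- !is.na(lab)
    acc[[j]] <- rowsum(X[okl, , drop = FALSE], lab[okl])
  }
  alphabet <- as.character(sort(as.integer(
    unique(unlist(lapply(acc, rownames), use.names = FALSE)))))
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
  structure(list(determinant = property, positions = positions,
                 alphabet = alphabet, ro = ro, re = re, ratio = ratio,
                 n_obs = nmat, n_transcripts = length(flat$ids),
                 n_occurrences = nrow(X), rule = rule,
                 window_residues = length),
            class = "rust_meta")
}

#' Read per-window minimum free energies
#'
#' The adapter format for RNA-structure analysis: a TSV with columns
#' `transcript_id`, `window_start_nt` (0-based, transcript coordinates)
#' and `mfe_kcal_mol`.
#'
#' @param path Path to the TSV.
#' @return Data frame with those three columns.
#' @export
read_window_energies <- function(path) {
  en <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("transcript_id", "window_start_nt", "mfe_kcal_mol")
  if (!all(need %in% names(en))) {
    stop("energy TSV must have columns ", paste(need, collapse = ", "))
  }
  en
}

#' Compute sliding-window minimum free energies with RNAfold
#'
#' Shells out to the ViennaRNA `RNAfold` executable to fold every
#' `window_nt`-long window (step `step_nt`) of each transcript. This is the
#' production path of the structure-analysis adapter; precomputed energies
#' read with [read_window_energies()] are interchangeable.
#'
#' @param transcripts A [transcript_set()].
#' @param window_nt,step_nt Window length and step (nt).
#' @param rnafold Name or path of the RNAfold executable.
#' @return Data frame as in [read_window_energies()].
#' @export
mfe_windows_rnafold <- function(transcripts, window_nt = 80L,
                                step_nt = 10L, rnafold = "RNAfold") {
  if (Sys.which(rnafold) == "") stop("RNAfold executable not found")
  rows <- list()
  for (i in seq_len(nrow(transcripts))) {
    s <- transcripts$sequence[i]
    n <- nchar(s)
    if (n < window_nt) next
    starts <- seq.int(0L, n - window_nt, by = step_nt)
    fa <- tempfile(fileext = ".fa")
    writeLines(unlist(lapply(seq_along(starts), function(j) {
      c(paste0(">w", j),
        substr(s, starts[j] + 1L, starts[j] + window_nt))
    })), fa)
    out <- system2(rnafold, c("--noPS", "-i", fa), stdout = TRUE)
    unlink(fa)
    eline <- out[seq(3, length(out), by = 3)]
    mfe <- as.numeric(sub(".*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", eline))
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = transcripts$id[i], window_start_nt = starts,
      mfe_kcal_mol = mfe, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' RUST ratios around stable RNA secondary structure
#'
#' Windows of `window_nt` nucleotides (step `step_nt`) are classified as
#' "stable" when their minimum free energy falls below a percentile
#' threshold -- either recomputed from the supplied energies (`thresholds =
#' NULL`, percentiles 1/5/10 of the dataset) or fixed reference values such
#' as [human_mfe_thresholds]. For every stable window and every admissible
#' A-site within `offset_range` nucleotides, the observed/expected RUST
#' values are aggregated per (threshold, window-to-A-site offset); the
#' reported offset is `window_start - a_site_start` in nt (the window's
#' 5'-most nucleotide relative to the A-site).
#'
#' Transcripts shorter than the window, or missing from the energy table,
#' are skipped with a warning.
#'
#' @param profiles A `codon_profiles` object.
#' @param transcripts A [transcript_set()].
#' @param energies Data frame from [read_window_energies()] or
#'   [mfe_windows_rnafold()].
#' @param thresholds Named numeric vector of MFE thresholds (kcal/mol); by
#'   default the 1st/5th/10th percentiles of `energies$mfe_kcal_mol`.
#' @param offset_range Integer range of window-to-A-site offsets (nt).
#' @param rule An [analysis_window()].
#' @return Data frame with columns `threshold`, `offset_nt`, `ro`, `re`,
#'   `ratio`, `n_obs`; attribute `thresholds` records the cutoffs used.
#' @export
structure_window_profile <- function(profiles, transcripts, energies,
                                     thresholds = NULL,
                                     offset_range = c(-120L, 60L),
                                     rule = analysis_window()) {
  if (is.null(thresholds)) {
    q <- stats::quantile(energies$mfe_kcal_mol, c(0.01, 0.05, 0.10))
    thresholds <- stats::setNames(as.numeric(q), c("p1", "p5", "p10"))
  }
  flat <- .rust_flat(profiles, transcripts, rule)
  missing_en <- setdiff(flat$ids, unique(energies$transcript_id))
  if (length(missing_en)) {
    warning(length(missing_en),
            " transcript(s) without window energies skipped")
  }
  res <- list()
  for (tn in names(thresholds)) {
    acc_num <- list()
    for (i in seq_along(flat$ids)) {
      id <- flat$ids[i]
      en <- energies[energies$transcript_id == id, , drop = FALSE]
      if (!nrow(en)) next
      stable <- en$window_start_nt[en$mfe_kcal_mol <= thresholds[[tn]]]
      if (!length(stable)) next
      occ <- which(flat$tx_of_occ == i)
      a_nt <- flat$cds_start[i] + 3L * flat$klocal[occ]
      for (w in stable) {
        d <- w - a_nt
        sel <- d >= offset_range[1] & d <= offset_range[2]
        if (!any(sel)) next
        acc_num[[length(acc_num) + 1L]] <- cbind(
          off = d[sel], B = flat$B[occ][sel], MB = flat$MB[occ][sel])
      }
    }
    if (!length(acc_num)) next
    m <- do.call(rbind, acc_num)
    s <- rowsum(cbind(m[, "B"], m[, "MB"], 1), m[, "off"])
    res[[tn]] <- data.frame(threshold = tn,
                            offset_nt = as.integer(rownames(s)),
                            ro = s[, 1] / s[, 3], re = s[, 2] / s[, 3],
                            ratio = (s[, 1] / s[, 3]) / (s[, 2] / s[, 3]),
                            n_obs = s[, 3], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(threshold = character(), offset_nt = integer(),
                      ro = numeric(), re = numeric(), ratio = numeric(),
                      n_obs = numeric())
  }
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  out
}

#' Synonymous vs nonsynonymous variance in A-site RUST ratios
#'
#' One-way analysis of variance of per-codon A-site RUST ratios with the
#' encoded amino acid as the grouping factor: the between-group variance
#' captures nonsynonymous differences and the within-group variance
#' synonymous ones. A small p-value indicates that decoding rates track
#' the amino acid rather than the codon.
#'
#' @param ratios Named numeric vector of A-site RUST ratios (names are
#'   codons), e.g. `coef(meta)`.
#' @return List with `statistic` (F), `p_value`, `df` (numerator,
#'   denominator), and the fitted `aov` object.
#' @export
synonymous_variance_test <- function(ratios) {
  codons <- names(ratios)
  aa <- translate_codons(codons)
  keep <- !is.na(ratios) & !is.na(aa) & aa != "*"
  d <- data.frame(ratio = unname(ratios[keep]), aa = factor(aa[keep]))
  if (nlevels(d$aa) < 2 || sum(table(d$aa) >= 2) < 2) {
    stop("degenerate grouping: need >= 2 amino acids with >= 2 codons")
  }
  fit <- stats::aov(ratio ~ aa, data = d)
  s <- summary(fit)[[1]]
  f <- s[["F value"]][1]
  p <- s[["Pr(>F)"]][1]
  if (s[["Sum Sq"]][1] < .Machine$double.eps^0.5 * sum(d$ratio^2)) {
    f <- 0  # no between-group variance at all
    p <- 1
  }
  list(statistic = f, p_value = p,
       df = c(s[["Df"]][1], s[["Df"]][2]), fit = fit)
}
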