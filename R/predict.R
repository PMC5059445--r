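#' Predict a footprint density profile from RUST ratios
#'
#' The predicted probability of observing a footprint at admissible codon
#' position `k` is proportional to the product of the codon RUST ratios of
#' the codons surrounding `k` at the chosen sites:
#' `w_k = prod_i ratio(codon[k + i], i)`, normalized over the `M`
#' admissible codons so that the profile is a discrete probability density
#' (`sum(p) = 1`). Sites are codon offsets relative to the A-site; the
#' default `-6:5` covers the 12 codons centred on the P-site/A-site
#' boundary (the footprint codons plus one flanking codon on each side).
#' Ratios undefined for a (codon, site) cell are imputed as 1 (neutral)
#' and tallied.
#'
#' @param transcript One row of a [transcript_set()] (or a single-row
#'   subset).
#' @param meta A codon `rust_meta` whose positions cover `sites`.
#' @param sites Integer codon offsets to use (default `-6:5`).
#' @param rule An [analysis_window()].
#' @return A `predicted_profile`: list with `transcript_id`, `p` (named
#'   numeric over 0-based admissible codon indices, summing to 1),
#'   `sites`, `n_imputed`.
#' @export
predict_density <- function(transcript, meta, sites = -6:5,
                            rule = analysis_window()) {
  stopifnot(nrow(transcript) == 1, identical(meta$determinant, "codon"))
  js <- match(sites, meta$positions)
  if (anyNA(js)) {
    stop("metafootprint does not cover sites ",
         paste(sites[is.na(js)], collapse = ", "))
  }
  cod <- cds_codons(transcript)[[1]]
  adm0 <- admissible_codon_indices(length(cod), rule)
  if (!length(adm0)) stop("transcript too short for the analysis window")
  logw <- numeric(length(adm0))
  n_imputed <- 0L
  for (s in seq_along(sites)) {
    ctx <- cod[adm0 + sites[s] + 1L]
    r <- meta$ratio[cbind(match(ctx, meta$alphabet), js[s])]
    miss <- is.na(r)
    n_imputed <- n_imputed + sum(miss)
    r[miss] <- 1
    logw <- logw + log(r)
  }
  w <- exp(logw - max(logw))
  p <- w / sum(w)
  structure(list(transcript_id = transcript$id,
                 p = stats::setNames(p, adm0), sites = sites,
                 n_imputed = n_imputed),
            class = "predicted_profile")
}

#' @export
print.predicted_profile <- function(x, ...) {
  cat("Predicted footprint density for ", x$transcript_id, ": ",
      length(x$p), " codons, sites ", min(x$sites), "..", max(x$sites),
      if (x$n_imputed) paste0(", ", x$n_imputed, " ratios imputed"),
      "\n", sep = "")
  invisible(x)
}

#' Predict footprint densities for a transcript set
#'
#' Applies [predict_density()] to each transcript; transcripts too short
#' for the analysis window are skipped.
#'
#' @param object A codon `rust_meta`.
#' @param transcripts A [transcript_set()].
#' @param sites,rule Passed to [predict_density()].
#' @param ... Unused.
#' @return Named list of `predicted_profile` objects.
#' @export
predict.rust_meta <- function(object, transcripts, sites = -6:5,
                              rule = analysis_window(), ...) {
  out <- list()
  for (i in seq_len(nrow(transcripts))) {
    tr <- transcripts[i, , drop = FALSE]
    class(tr) <- c("transcript_set", "data.frame")
    L <- (tr$cds_end - tr$cds_start) %/% 3L
    if (!length(admissible_codon_indices(L, rule))) next
    out[[tr$id]] <- predict_density(tr, object, sites = sites, rule = rule)
  }
  out
}

#' Compare predicted and observed footprint densities
#'
#' Per transcript with observed density above `min_density` reads/nt over
#' the admissible region, the Pearson and Spearman correlations between
#' the predicted probabilities and the observed counts are computed.
#' Transcripts with constant observed counts are excluded (correlation
#' undefined).
#'
#' @param predicted Named list of `predicted_profile` objects (from
#'   [predict.rust_meta()]).
#' @param profiles Observed `codon_profiles`.
#' @param min_density Density threshold, reads/nt (default 1).
#' @param rule An [analysis_window()].
#' @return Data frame with columns `transcript_id`, `pearson_r`,
#'   `spearman_r`, `n_codons`, `density`; attribute `excluded` lists
#'   transcripts dropped and why.
#' @export
evaluate_prediction <- function(predicted, profiles, min_density = 1,
                                rule = analysis_window()) {
  rows <- list()
  excl <- character(0)
  for (id in names(predicted)) {
    cnt <- profiles[[id]]
    if (is.null(cnt)) next
    p <- predicted[[id]]$p
    idx <- as.integer(names(p)) + 1L
    obs <- cnt[idx]
    dens <- sum(obs) / (3 * length(obs))
    if (dens <= min_density) {
      excl <- c(excl, stats::setNames("below density threshold", id))
      next
    }
    if (stats::sd(obs) == 0) {
      excl <- c(excl, stats::setNames("constant observed profile", id))
      next
    }
    rows[[id]] <- data.frame(
      transcript_id = id,
      pearson_r = stats::cor(p, obs),
      spearman_r = stats::cor(p, obs, method = "spearman"),
      n_codons = length(obs), density = dens,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(), pearson_r = numeric(),
                      spearman_r = numeric(), n_codons = integer(),
                      density = numeric())
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excl
  out
}
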