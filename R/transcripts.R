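#' Construct a transcript set
#'
#' A transcript set is the unit of analysis: one row per transcript, holding
#' the nucleotide sequence and the CDS location in 0-based half-open
#' coordinates (`cds_start` is the first nt of the start codon, `cds_end` is
#' one past the last nt of the stop codon).
#'
#' Transcripts whose CDS length is not divisible by 3 are rejected with an
#' error; transcripts whose CDS holds fewer than `min_codons` codons are
#' dropped with a warning (they cannot accommodate a full metafootprint
#' window).
#'
#' @param id Character vector of transcript identifiers.
#' @param sequence Character vector of nucleotide sequences (A/C/G/T/N).
#' @param cds_start,cds_end Integer vectors, 0-based half-open CDS bounds.
#' @param gene_id Character vector of gene identifiers (defaults to `id`).
#' @param min_codons Minimum CDS length in codons to retain a transcript.
#' @return A `transcript_set`: a data frame with columns `id`, `gene_id`,
#'   `sequence`, `cds_start`, `cds_end`.
#' @export
transcript_set <- function(id, sequence, cds_start, cds_end,
                           gene_id = id, min_codons = 61L) {
  stopifnot(length(id) == length(sequence),
            length(id) == length(cds_start),
            length(id) == length(cds_end))
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  cds_len <- cds_end - cds_start
  bad_frame <- cds_len %% 3L != 0L
  if (any(bad_frame)) {
    stop("CDS length not divisible by 3 for: ",
         paste(id[bad_frame], collapse = ", "))
  }
  too_long <- cds_end > nchar(sequence)
  if (any(too_long)) {
    stop("cds_end exceeds sequence length for: ",
         paste(id[too_long], collapse = ", "))
  }
  short <- cds_len %/% 3L < min_codons
  if (any(short)) {
    warning(sum(short), " transcript(s) with CDS shorter than ", min_codons,
            " codons dropped")
  }
  out <- data.frame(id = as.character(id), gene_id = as.character(gene_id),
                    sequence = toupper(as.character(sequence)),
                    cds_start = cds_start, cds_end = cds_end,
                    stringsAsFactors = FALSE)[!short, , drop = FALSE]
  rownames(out) <- out$id
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' @export
print.transcript_set <- function(x, ...) {
  L <- n_codons(x)
  cat("Transcript set: ", nrow(x), " transcripts, CDS length ",
      if (nrow(x)) paste0(min(L), "-", max(L)) else "-",
      " codons (median ", if (nrow(x)) stats::median(L) else "-", ")\n",
      sep = "")
  invisible(x)
}

#' CDS length in codons for each transcript
#' @param transcripts A `transcript_set`.
#' @return Named integer vector.
#' @export
n_codons <- function(transcripts) {
  stats::setNames((transcripts$cds_end - transcripts$cds_start) %/% 3L,
                  transcripts$id)
}

#' Split the CDS of each transcript into codons
#'
#' @param transcripts A `transcript_set`.
#' @return Named list of character vectors, one codon per CDS position
#'   (index 1 = start codon).
#' @export
cds_codons <- function(transcripts) {
  out <- lapply(seq_len(nrow(transcripts)), function(i) {
    s <- transcripts$cds_start[i]
    e <- transcripts$cds_end[i]
    starts <- seq.int(s + 1L, e - 2L, by = 3L)
    substring(transcripts$sequence[i], starts, starts + 2L)
  })
  names(out) <- transcripts$id
  out
}

#' Analysis window rule for trimming coding regions
#'
#' Positions too close to the start or the stop codon are excluded from all
#' aggregate statistics because initiating and terminating ribosomes behave
#' atypically. The defaults keep A-site positions at least 120 nt (40
#' codons) after the start codon and at least 60 nt (20 codons) before the
#' stop codon.
#'
#' @param min_nt_after_start Non-negative multiple of 3 (nt).
#' @param min_nt_before_stop Non-negative multiple of 3 (nt).
#' @return A list with the two fields, class `analysis_window`.
#' @export
analysis_window <- function(min_nt_after_start = 120L,
                            min_nt_before_stop = 60L) {
  stopifnot(min_nt_after_start >= 0, min_nt_before_stop >= 0,
            min_nt_after_start %% 3 == 0, min_nt_before_stop %% 3 == 0)
  structure(list(min_nt_after_start = as.integer(min_nt_after_start),
                 min_nt_before_stop = as.integer(min_nt_before_stop)),
            class = "analysis_window")
}

#' Admissible A-site codon indices of a coding region
#'
#' For a CDS of `L` codons and the default window rule, returns the 0-based
#' codon indices `[40, L - 20)`: at least 40 codons after the start and 20
#' codons (including the stop) before the CDS end. An integer vector of
#' length `max(0, L - 60)`; empty when the CDS is too short.
#'
#' @param cds_codons_n CDS length in codons (integer, possibly vectorized is
#'   not supported; one transcript at a time).
#' @param rule An [analysis_window()].
#' @return Integer vector of 0-based codon indices (possibly empty).
#' @export
admissible_codon_indices <- function(cds_codons_n,
                                     rule = analysis_window()) {
  lo <- rule$min_nt_after_start %/% 3L
  hi <- cds_codons_n - rule$min_nt_before_stop %/% 3L - 1L
  if (hi < lo) return(integer(0))
  seq.int(lo, hi)
}

#' Load a transcriptome from FASTA plus CDS annotation
#'
#' Sequences are read from `fasta_path`; CDS coordinates come from a
#' tab-separated annotation with columns `transcript_id`, `cds_start`,
#' `cds_end` (0-based half-open, nt) and optionally `gene_id`, or from a GTF
#' file whose `CDS` features are in transcript coordinates (1-based, closed;
#' converted on load, and extended by 3 nt to include the stop codon when
#' the feature excludes it is *not* attempted -- GTF CDS features are taken
#' verbatim).
#'
#' FASTA records without an annotation row are skipped with a warning.
#' When `longest_per_gene` is `TRUE`, only the transcript with the longest
#' CDS is kept for each gene (ties broken by transcript id).
#'
#' @param fasta_path Path to a FASTA file of transcript sequences.
#' @param annotation_path Path to the annotation (TSV or `.gtf`).
#' @param longest_per_gene Keep only the longest-CDS isoform per gene.
#' @param min_codons Passed to [transcript_set()].
#' @return A [transcript_set()].
#' @export
load_transcriptome <- function(fasta_path, annotation_path,
                               longest_per_gene = TRUE, min_codons = 61L) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- if (grepl("\\.gtf(\\.gz)?$", annotation_path, ignore.case = TRUE)) {
    .read_gtf_cds(annotation_path)
  } else {
    .read_annotation_tsv(annotation_path)
  }
  hit <- match(ids, ann$transcript_id)
  if (anyNA(hit)) {
    warning(sum(is.na(hit)), " FASTA record(s) without CDS annotation skipped")
  }
  keep <- !is.na(hit)
  ann <- ann[hit[keep], , drop = FALSE]
  ts <- transcript_set(id = ids[keep],
                       sequence = as.character(seqs[keep]),
                       cds_start = ann$cds_start, cds_end = ann$cds_end,
                       gene_id = ann$gene_id, min_codons = min_codons)
  if (longest_per_gene && nrow(ts)) {
    len <- ts$cds_end - ts$cds_start
    ord <- order(ts$gene_id, -len, ts$id)
    ts <- ts[ord, , drop = FALSE]
    ts <- ts[!duplicated(ts$gene_id), , drop = FALSE]
    ts <- ts[order(ts$id), , drop = FALSE]
    class(ts) <- c("transcript_set", "data.frame")
  }
  ts
}

.read_annotation_tsv <- function(path) {
  ann <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("transcript_id", "cds_start", "cds_end")
  if (!all(need %in% names(ann))) {
    stop("annotation TSV must have columns transcript_id, cds_start, cds_end")
  }
  if (is.null(ann$gene_id)) ann$gene_id <- ann$transcript_id
  ann
}

.read_gtf_cds <- function(path) {
  gtf <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  cds <- gtf[gtf[[3]] == "CDS", , drop = FALSE]
  if (!nrow(cds)) stop("no CDS features in GTF")
  gid <- sub('.*gene_id "([^"]+)".*', "\\1", cds[[9]])
  gid[!grepl('gene_id "', cds[[9]], fixed = TRUE)] <- NA
  # seqname column carries the transcript id for transcript-space GTF
  tid <- cds[[1]]
  agg_s <- tapply(cds[[4]], tid, min)
  agg_e <- tapply(cds[[5]], tid, max)
  g1 <- tapply(gid, tid, function(g) g[1])
  data.frame(transcript_id = names(agg_s),
             cds_start = as.integer(agg_s) - 1L,  # GTF is 1-based closed
             cds_end = as.integer(agg_e),
             gene_id = ifelse(is.na(g1), names(agg_s), g1),
             stringsAsFactors = FALSE)
}
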