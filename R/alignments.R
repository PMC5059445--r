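#' Read transcript-space alignments from SAM/BAM
#'
#' Alignments must be in transcript coordinates. Reverse-strand and unmapped
#' records are discarded (libraries are aligned to the sense strand only).
#' Uniqueness is taken from the `NH` tag when present (`NH == 1`), otherwise
#' every retained primary alignment is treated as unique.
#'
#' @param path Path to a BAM file or an uncompressed SAM file (converted
#'   on the fly).
#' @return An alignment table: data frame with columns `transcript_id`,
#'   `pos` (0-based 5'-end position on the transcript), `read_length`,
#'   `unique` (logical).
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else {
    bam <- path
  }
  par <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "strand", "qwidth", "flag"),
    tag = "NH",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  res <- Rsamtools::scanBam(bam, param = par)[[1]]
  keep <- res$strand == "+"
  nh <- res$tag$NH
  unique_flag <- if (is.null(nh)) rep(TRUE, length(res$pos)) else
    (is.na(nh) | nh == 1L)
  alignment_table(transcript_id = as.character(res$rname)[keep],
                  pos = res$pos[keep] - 1L,  # BAM pos is 1-based
                  read_length = res$qwidth[keep],
                  unique = unique_flag[keep])
}

#' Construct an alignment table
#'
#' @param transcript_id Character vector.
#' @param pos Integer vector, 0-based position of the read 5' end on the
#'   transcript.
#' @param read_length Integer vector (nt).
#' @param unique Logical vector; whether the aligner reported the read as
#'   uniquely mapping.
#' @return Data frame of class `alignment_table`.
#' @export
alignment_table <- function(transcript_id, pos, read_length,
                            unique = TRUE) {
  out <- data.frame(transcript_id = as.character(transcript_id),
                    pos = as.integer(pos),
                    read_length = as.integer(read_length),
                    unique = rep_len(as.logical(unique), length(pos)),
                    stringsAsFactors = FALSE)
  class(out) <- c("alignment_table", "data.frame")
  out
}

#' Histogram of read lengths
#' @param alignments An `alignment_table`.
#' @return Named integer vector (names are read lengths in nt).
#' @export
read_length_histogram <- function(alignments) {
  tab <- table(alignments$read_length)
  stats::setNames(as.integer(tab), names(tab))
}

#' Select the predominant read length
#'
#' Returns the modal read length of a histogram; ties are broken in favour
#' of the smaller length so the choice is deterministic.
#'
#' @param histogram Named integer vector as returned by
#'   [read_length_histogram()], or an `alignment_table`.
#' @return Integer read length (nt).
#' @export
select_predominant_length <- function(histogram) {
  if (inherits(histogram, "alignment_table")) {
    histogram <- read_length_histogram(histogram)
  }
  if (!length(histogram) || sum(histogram) == 0) {
    stop("no usable reads: empty read-length histogram")
  }
  lens <- as.integer(names(histogram))
  best <- lens[histogram == max(histogram)]
  min(best)
}

#' Build per-codon footprint count profiles
#'
#' Each retained read contributes one count at the codon index
#' `floor((pos + offset - cds_start) / 3)` of its transcript, i.e. reads
#' are attributed by their 5' end plus a fixed A-site offset, irrespective
#' of the subcodon position. Reads of other lengths, reads failing the
#' uniqueness policy, and reads whose inferred A-site falls outside the CDS
#' are discarded (the latter are counted in the `skipped` attribute).
#'
#' @param alignments An `alignment_table`.
#' @param transcripts A [transcript_set()].
#' @param offset A-site offset from the read 5' end (nt, >= 0).
#' @param read_length Read length to retain (nt); default the predominant
#'   length of `alignments`.
#' @param unique_only Require the aligner-reported uniqueness flag
#'   (default `TRUE`).
#' @return A `codon_profiles` object: named list of integer count vectors
#'   (one entry per CDS codon, index 1 = start codon), with attributes
#'   `offset`, `read_length` and `skipped` (reads mapping outside the CDS
#'   after offsetting).
#' @export
build_codon_profiles <- function(alignments, transcripts, offset,
                                 read_length = NULL, unique_only = TRUE) {
  stopifnot(offset >= 0)
  if (is.null(read_length)) {
    read_length <- select_predominant_length(alignments)
  }
  aln <- alignments[alignments$read_length == read_length, , drop = FALSE]
  if (unique_only) aln <- aln[aln$unique, , drop = FALSE]
  aln <- aln[aln$transcript_id %in% transcripts$id, , drop = FALSE]

  L <- n_codons(transcripts)
  cds_start <- stats::setNames(transcripts$cds_start, transcripts$id)
  idx <- (aln$pos + as.integer(offset) -
            cds_start[aln$transcript_id]) %/% 3L
  inside <- !is.na(idx) & idx >= 0L & idx < L[aln$transcript_id]
  skipped <- sum(!inside)
  aln <- aln[inside, , drop = FALSE]
  idx <- idx[inside]

  profiles <- lapply(transcripts$id, function(id) integer(L[[id]]))
  names(profiles) <- transcripts$id
  if (nrow(aln)) {
    key <- split(idx, aln$transcript_id)
    for (id in names(key)) {
      tab <- tabulate(key[[id]] + 1L, nbins = L[[id]])
      profiles[[id]] <- as.integer(tab)
    }
  }
  structure(profiles, class = "codon_profiles",
            offset = as.integer(offset),
            read_length = as.integer(read_length),
            skipped = skipped)
}

#' @export
print.codon_profiles <- function(x, ...) {
  tot <- sum(vapply(x, sum, numeric(1)))
  cat("Codon profiles: ", length(x), " transcripts, ",
      format(tot, big.mark = ","), " footprints (offset ",
      attr(x, "offset"), " nt, read length ", attr(x, "read_length"),
      " nt, ", attr(x, "skipped"), " reads outside CDS)\n", sep = "")
  invisible(x)
}

#' Write / read sparse codon-profile TSV
#'
#' The on-disk dialect is sparse: columns `transcript_id`, `codon_index`
#' (0-based) and `count`; absent indices are zero.
#'
#' @param profiles A `codon_profiles` object.
#' @param path Output path.
#' @export
write_profiles_tsv <- function(profiles, path) {
  rows <- lapply(names(profiles), function(id) {
    cnt <- profiles[[id]]
    nz <- which(cnt > 0L)
    if (!length(nz)) return(NULL)
    data.frame(transcript_id = id, codon_index = nz - 1L,
               count = cnt[nz], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(), codon_index = integer(),
                      count = integer())
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_tsv
#' @param transcripts A [transcript_set()] supplying CDS lengths.
#' @param offset,read_length Metadata to attach (informational).
#' @export
read_profiles_tsv <- function(path, transcripts, offset = NA_integer_,
                              read_length = NA_integer_) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  L <- n_codons(transcripts)
  profiles <- lapply(transcripts$id, function(id) integer(L[[id]]))
  names(profiles) <- transcripts$id
  tab <- tab[tab$transcript_id %in% transcripts$id, , drop = FALSE]
  for (id in unique(tab$transcript_id)) {
    sub <- tab[tab$transcript_id == id, , drop = FALSE]
    v <- profiles[[id]]
    v[sub$codon_index + 1L] <- as.integer(sub$count)
    profiles[[id]] <- v
  }
  structure(profiles, class = "codon_profiles",
            offset = as.integer(offset),
            read_length = as.integer(read_length), skipped = 0L)
}
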