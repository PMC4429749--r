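# Strand-aware interval arithmetic around pre-miRNA loci and TSSs.

#' Default organelle blacklist
#'
#' Sequence names treated as chloroplast/mitochondrial DNA and excluded from
#' TSS training (no TSS-relevant sequencing exists for organelles).
#' @export
organelleSeqids <- function() c("ChrC", "ChrM", "Pt", "Mt")

#' Upstream window of a locus
#'
#' Returns the `length`-base window immediately upstream (5') of a locus,
#' strand-aware: upstream of the start for `+` loci, upstream of the end for
#' `-` loci. The window is clipped at sequence boundaries rather than
#' erroring; a window clipped to nothing is an error.
#'
#' @param locus a `GRanges` of length 1 with strand `+` or `-`.
#' @param length window length in bases (> 0).
#' @param seqLengths named vector of sequence lengths (needed to clip minus-
#'   strand windows; optional when the locus carries seqlengths).
#' @return a `GRanges` of length 1, strand preserved.
#' @export
upstreamWindow <- function(locus, length, seqLengths = NULL) {
  stopifnot(is(locus, "GRanges"), base::length(locus) == 1L)
  if (length <= 0) stop("'length' must be positive")
  str <- as.character(strand(locus))
  if (!str %in% c("+", "-")) stop("locus strand must be '+' or '-'")
  sid <- as.character(seqnames(locus))
  if (is.null(seqLengths)) seqLengths <- seqlengths(locus)
  if (str == "+") {
    to <- start(locus) - 1L
    from <- max(1L, start(locus) - as.integer(length))
    if (to < from)
      stop("empty upstream window: locus at sequence start")
  } else {
    from <- end(locus) + 1L
    to <- from + as.integer(length) - 1L
    sl <- seqLengths[sid]
    if (!is.na(sl)) to <- min(to, as.integer(sl))
    if (is.na(sl) && is.null(seqLengths))
      stop("minus-strand window needs sequence lengths")
    if (to < from)
      stop("empty upstream window: locus at sequence end")
  }
  GRanges(sid, IRanges(from, to), strand = str)
}

#' Extract a promoter sequence upstream of a TSS
#'
#' For strand `+`, the `length` bases ending immediately before the TSS; for
#' strand `-`, the `length` bases starting immediately after the TSS,
#' reverse-complemented. The sequence is truncated (with a warning) when the
#' window is clipped at a sequence boundary.
#'
#' @param genome a `DNAStringSet`.
#' @param seqid sequence name.
#' @param tssPos 1-based TSS position.
#' @param strand `"+"` or `"-"`.
#' @param length promoter length in bases (1000 for TFBS scanning, 5000 for
#'   export, by convention).
#' @return a `DNAString` (possibly shorter than `length`).
#' @export
extractPromoter <- function(genome, seqid, tssPos, strand, length = 1000L) {
  if (!seqid %in% names(genome)) stop("unknown sequence: ", seqid)
  sl <- length(genome[[seqid]])
  tssPos <- as.integer(tssPos)
  if (tssPos < 1L || tssPos > sl)
    stop("TSS position ", tssPos, " outside sequence ", seqid)
  if (strand == "+") {
    from <- tssPos - as.integer(length)
    to <- tssPos - 1L
    if (from < 1L) {
      warning("promoter truncated at sequence start")
      from <- 1L
    }
    if (to < from) return(DNAString(""))
    subseq(genome[[seqid]], from, to)
  } else if (strand == "-") {
    from <- tssPos + 1L
    to <- tssPos + as.integer(length)
    if (to > sl) {
      warning("promoter truncated at sequence end")
      to <- sl
    }
    if (to < from) return(DNAString(""))
    reverseComplement(subseq(genome[[seqid]], from, to))
  } else stop("strand must be '+' or '-'")
}

#' Export promoter sequences of TSS positions as FASTA
#'
#' @param genome a `DNAStringSet`.
#' @param tss `GRanges` of 1-bp TSS positions with a metadata column naming
#'   each record (`id` or `name`).
#' @param length promoter length (default 1000; use 5000 for the long export).
#' @param path output FASTA file.
#' @return the promoter `DNAStringSet`, invisibly; written to `path` when
#'   given.
#' @export
exportPromoters <- function(genome, tss, length = 1000L, path = NULL) {
  ids <- mcols(tss)$id
  if (is.null(ids)) ids <- mcols(tss)$name
  if (is.null(ids)) ids <- paste0("tss_", seq_along(tss))
  seqs <- DNAStringSet(lapply(seq_along(tss), function(i)
    extractPromoter(genome, as.character(seqnames(tss))[i], start(tss)[i],
                    as.character(strand(tss))[i], length)))
  names(seqs) <- ids
  if (!is.null(path)) writeXStringSet(seqs, path)
  invisible(seqs)
}
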