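# Readers and writers for the standard formats consumed by the pipeline.
# All genomic files go through Biostrings / rtracklayer (gzip handled there);
# coordinates are 1-based closed GRanges internally, BED/bedGraph conversion
# is rtracklayer's.

#' Read a genome FASTA
#'
#' @param path FASTA file (optionally gzipped).
#' @return a [Biostrings::DNAStringSet], sequences upper-cased, names taken
#'   from the first whitespace-delimited token of each header.
#' @details Duplicate sequence ids and empty files are errors.
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("no such FASTA file: ", path)
  seqs <- tryCatch(readDNAStringSet(path),
                   error = function(e) stop("FASTA parse error in '", path,
                                            "': ", conditionMessage(e)))
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence id(s) in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs
}

#' Sequence lengths of a genome
#' @param genome a `DNAStringSet`.
#' @return named integer vector of sequence lengths.
#' @export
genomeLengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Read a bedGraph signal file into a SignalTrack
#'
#' Expands the interval records to per-base values over the given genome.
#' Overlapping records are summed (coverage semantics).
#'
#' @param path 4-column bedGraph file.
#' @param genomeLengths named integer vector of sequence lengths.
#' @param feature feature label for the track.
#' @return a [SignalTrack-class].
#' @export
readSignalBedGraph <- function(path, genomeLengths, feature = "custom") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(gr$score < 0)) {
    i <- which(gr$score < 0)[1]
    stop("negative signal value in bedGraph record ", i, " of '", path, "'")
  }
  unknown <- setdiff(as.character(seqnames(gr)), names(genomeLengths))
  if (length(unknown))
    stop("bedGraph sequence(s) not in genome: ", paste(unknown, collapse = ", "))
  beyond <- end(gr) > genomeLengths[as.character(seqnames(gr))]
  if (any(beyond))
    stop("bedGraph record ", which(beyond)[1], " extends beyond sequence end")
  GenomeInfoDb::seqlevels(gr) <- names(genomeLengths)
  cov <- coverage(gr, weight = gr$score, width = as.list(genomeLengths))
  SignalTrack(feature, cov)
}

#' Write a SignalTrack as bedGraph
#'
#' @param track a [SignalTrack-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSignalBedGraph <- function(track, path) {
  gr <- as(trackValues(track), "GRanges")
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a BED file of positions or motif sites
#'
#' @param path BED file (0-based half-open on disk; converted on read).
#' @param motifClass optional motif class label attached to every site
#'   (metadata column `motif_class`).
#' @return a `GRanges`; the BED name column, when present, is kept in
#'   metadata column `name`.
#' @export
readBedSites <- function(path, motifClass = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(motifClass)) mcols(gr)$motif_class <- motifClass
  gr
}

#' Write positions or sites as BED
#' @param gr a `GRanges`; metadata column `name` (if present) becomes the BED
#'   name, `score` the BED score.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeBedSites <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read miRNA precursor annotations from GFF3
#'
#' @param path GFF3 file.
#' @param featureType GFF3 `type` to keep (default
#'   `"miRNA_primary_transcript"`).
#' @return `GRanges` with metadata columns `id`, `intragenic` (logical) and
#'   `host_gene` (`NA` where intergenic). `intragenic` is `TRUE` iff a host
#'   gene is recorded.
#' @export
readMirnaAnnotations <- function(path, featureType = "miRNA_primary_transcript") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == featureType]
  if (length(gr) == 0L)
    warning("no '", featureType, "' features in ", path)
  id <- mcols(gr)$Name
  if (is.null(id)) id <- mcols(gr)$ID
  host <- mcols(gr)$host_gene
  if (is.null(host)) host <- rep(NA_character_, length(gr))
  out <- granges(gr)
  mcols(out) <- DataFrame(id = as.character(id),
                          intragenic = !is.na(host) & nzchar(host),
                          host_gene = as.character(host))
  out
}

#' Read gene annotations from GFF3
#' @param path GFF3 file.
#' @param featureType GFF3 `type` to keep (default `"gene"`).
#' @return `GRanges` with metadata column `id`.
#' @export
readGeneAnnotations <- function(path, featureType = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == featureType]
  id <- mcols(gr)$Name
  if (is.null(id)) id <- mcols(gr)$ID
  out <- granges(gr)
  mcols(out) <- DataFrame(id = as.character(id))
  out
}

#' Read position weight matrices
#'
#' Two plain-text formats are supported: JASPAR (a `>id name` header followed
#' by four `A [ ... ]` rows) and a 4-column TSV (`A C G T` header, one row per
#' motif position, one matrix per file, id from the file name).
#'
#' @param path PWM file.
#' @param format `"jaspar"` or `"tsv"`.
#' @param pseudocount added to every cell of a column containing an exact
#'   zero, before normalization (avoids zero frequencies in the information
#'   weights).
#' @return named list of 4 x L numeric matrices (rows A, C, G, T; columns sum
#'   to 1).
#' @export
readPwms <- function(path, format = c("jaspar", "tsv"), pseudocount = 0.01) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path)
    if (!all(c("A", "C", "G", "T") %in% names(tab)))
      stop("PWM TSV needs columns A, C, G, T")
    m <- t(as.matrix(tab[, c("A", "C", "G", "T")]))
    out <- list(normalizePwm(m, pseudocount))
    names(out) <- sub("\\.[^.]*$", "", basename(path))
    return(out)
  }
  lines <- readLines(path)
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no JASPAR headers ('>') in ", path)
  out <- list()
  for (s in starts) {
    id <- strsplit(sub("^>\\s*", "", lines[s]), "\\s+")[[1]][1]
    rows <- lines[s + 1:4]
    parseRow <- function(l) {
      stripped <- sub("^\\s*[ACGT]", "", l)
      as.numeric(regmatches(stripped,
                            gregexpr("[-0-9.eE+]+", stripped))[[1]])
    }
    m <- t(vapply(rows, parseRow, numeric(length(parseRow(rows[1])))))
    rownames(m) <- c("A", "C", "G", "T")
    out[[id]] <- normalizePwm(m, pseudocount)
  }
  out
}

#' Normalize a PWM to per-position frequencies
#'
#' @param m 4 x L matrix of counts or frequencies (rows A, C, G, T).
#' @param pseudocount added to all cells of columns containing an exact zero.
#' @return 4 x L frequency matrix with columns summing to 1.
#' @export
normalizePwm <- function(m, pseudocount = 0.01) {
  if (nrow(m) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  rownames(m) <- c("A", "C", "G", "T")
  hasZero <- apply(m == 0, 2, any)
  m[, hasZero] <- m[, hasZero, drop = FALSE] + pseudocount
  sweep(m, 2, colSums(m), "/")
}

#' Write PWMs in JASPAR format
#' @param pwms named list of 4 x L matrices.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePwmsJaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(pwms)) {
    m <- pwms[[id]]
    writeLines(paste0(">", id), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(paste0(b, " [ ", paste(format(m[b, ], trim = TRUE),
                                        collapse = " "), " ]"), con)
  }
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' @param path TSV with a header row of condition labels; first column holds
#'   entity ids (miRNAs or genes).
#' @return numeric matrix, rows = entities, columns = conditions.
#' @export
readExpressionMatrix <- function(path) {
  tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(tab)
}

#' Write an expression matrix as TSV
#' @param mat numeric matrix with row and column names.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeExpressionMatrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read miRNA-target interactions from TSV
#'
#' @param path TSV with columns `mirna`, `target`, `evidence`
#'   (`verified`/`putative`), `source`, and optional `score`.
#' @return `data.frame` of the interactions.
#' @export
readMti <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna", "target", "evidence", "source")
  if (!all(need %in% names(tab)))
    stop("MTI table needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(tab$evidence), c("verified", "putative"))
  if (length(bad))
    stop("MTI evidence must be 'verified' or 'putative'; found: ",
         paste(bad, collapse = ", "))
  tab
}

#' Read gene-gene interaction edges
#'
#' Accepts a 2+-column TSV (`from`, `to`) or a SIF file
#' (`from interaction to`). Undirected input can be expanded to both
#' directions.
#'
#' @param path edge file.
#' @param format `"tsv"` or `"sif"`.
#' @param undirected if `TRUE`, each input edge is emitted in both directions
#'   (flagged in column `expanded`).
#' @return `data.frame` with columns `from`, `to`.
#' @export
readGeneGraph <- function(path, format = c("tsv", "sif"), undirected = FALSE) {
  format <- match.arg(format)
  if (format == "sif") {
    tab <- utils::read.table(path, stringsAsFactors = FALSE)
    edges <- data.frame(from = tab[[1]], to = tab[[3]],
                        stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("from", "to") %in% names(tab)))
      stop("gene-graph TSV needs columns 'from' and 'to'")
    edges <- tab[, c("from", "to")]
  }
  if (undirected) {
    rev <- data.frame(from = edges$to, to = edges$from,
                      stringsAsFactors = FALSE)
    edges <- unique(rbind(edges, rev))
    edges$expanded <- TRUE
  }
  unique(edges)
}

#' Read GO annotations
#'
#' @param path 2+-column TSV mapping `gene` to `term` (optional columns
#'   `term_name`, `namespace` are carried through).
#' @return `data.frame` with at least columns `gene`, `term`.
#' @export
readGoAnnotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(tab)))
    stop("GO annotation TSV needs columns 'gene' and 'term'")
  tab
}
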