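#' Construct a transcript collection
#'
#' A transcript collection is the package's central annotation container: a
#' data frame with one row per transcript and list-columns holding the exon
#' block structure.  All coordinates are 0-based half-open, the native
#' convention of the genePred and PSL formats this package reads.
#'
#' @param transcript_id character, unique within the collection.
#' @param source_db character, one of `"GENBANK"`, `"REFSEQ"`, `"ENSEMBL"`,
#'   `"OTHER"` (recycled if length 1).
#' @param chrom,strand character; strand is `"+"` or `"-"`.
#' @param tx_start,tx_end integer transcript bounds.
#' @param cds_start,cds_end integer coding-region bounds; `cds_start ==
#'   cds_end` encodes a non-coding transcript.
#' @param exon_starts,exon_ends lists of integer vectors, one per transcript,
#'   sorted ascending and pairwise disjoint.
#' @param name optional collection name, stored as an attribute.
#' @return A `transcript_collection` (data frame subclass).
#' @examples
#' tc <- transcript_collection(
#'   transcript_id = "t1", source_db = "OTHER", chrom = "chr1", strand = "+",
#'   tx_start = 100L, tx_end = 400L, cds_start = 150L, cds_end = 380L,
#'   exon_starts = list(c(100L, 300L)), exon_ends = list(c(200L, 400L)))
#' @export
transcript_collection <- function(transcript_id, source_db, chrom, strand,
                                  tx_start, tx_end, cds_start, cds_end,
                                  exon_starts, exon_ends, name = "collection") {
  n <- length(transcript_id)
  df <- data.frame(
    transcript_id = as.character(transcript_id),
    source_db     = rep_len(as.character(source_db), n),
    chrom         = as.character(chrom),
    strand        = as.character(strand),
    tx_start      = as.integer(tx_start),
    tx_end        = as.integer(tx_end),
    cds_start     = as.integer(cds_start),
    cds_end       = as.integer(cds_end),
    stringsAsFactors = FALSE
  )
  df$exon_starts <- lapply(exon_starts, as.integer)
  df$exon_ends   <- lapply(exon_ends, as.integer)
  attr(df, "name") <- name
  class(df) <- c("transcript_collection", "data.frame")
  validate_transcripts(df)
  df
}

SOURCE_DBS <- c("GENBANK", "REFSEQ", "ENSEMBL", "OTHER")

#' Validate a transcript collection's structural invariants
#'
#' Checks ID uniqueness, exon ordering/disjointness, containment of exons in
#' the transcript bounds, and containment of the CDS interval.  Called by all
#' constructors; exported so callers can re-check after manual edits.
#'
#' @param tc a `transcript_collection`.
#' @return `tc`, invisibly; errors on the first violated invariant.
#' @export
validate_transcripts <- function(tc) {
  stopifnot(is.data.frame(tc))
  if (anyDuplicated(tc$transcript_id))
    stop("duplicate transcript_id: ",
         paste(unique(tc$transcript_id[duplicated(tc$transcript_id)]),
               collapse = ", "))
  bad_db <- setdiff(unique(tc$source_db), SOURCE_DBS)
  if (length(bad_db))
    stop("unknown source_db: ", paste(bad_db, collapse = ", "))
  if (!all(tc$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  for (i in seq_len(nrow(tc))) {
    es <- tc$exon_starts[[i]]; ee <- tc$exon_ends[[i]]
    id <- tc$transcript_id[i]
    if (length(es) == 0L || length(es) != length(ee))
      stop(id, ": exon start/end lists empty or of unequal length")
    if (any(es >= ee)) stop(id, ": exon with start >= end")
    if (is.unsorted(es, strictly = TRUE))
      stop(id, ": exon starts not strictly ascending")
    if (any(ee[-length(ee)] > es[-1L]))
      stop(id, ": overlapping exons")
    if (tc$tx_start[i] > es[1L] || ee[length(ee)] > tc$tx_end[i])
      stop(id, ": exons outside transcript bounds")
    cs <- tc$cds_start[i]; ce <- tc$cds_end[i]
    if (cs > ce) stop(id, ": cds_start > cds_end")
    if (cs != ce && (cs < tc$tx_start[i] || ce > tc$tx_end[i]))
      stop(id, ": CDS outside transcript bounds")
  }
  invisible(tc)
}

#' @export
print.transcript_collection <- function(x, ...) {
  cat(sprintf("transcript_collection '%s': %d transcripts on %d chromosome(s)\n",
              attr(x, "name") %||% "?", nrow(x),
              length(unique(x$chrom))))
  if (nrow(x)) {
    tab <- table(x$source_db)
    cat("  by source:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

# Exon intervals restricted to the CDS; empty for non-coding transcripts.
cds_exons <- function(tc, i) {
  cs <- tc$cds_start[i]; ce <- tc$cds_end[i]
  if (cs == ce) return(list(start = integer(0), end = integer(0)))
  s <- pmax(tc$exon_starts[[i]], cs)
  e <- pmin(tc$exon_ends[[i]], ce)
  keep <- s < e
  list(start = s[keep], end = e[keep])
}

# Intron boundary keys: intron starts (exon ends except last) and intron ends
# (exon starts except first), tagged by side.  Single-exon transcripts have
# none.  The side tag keeps a donor coordinate from matching an acceptor
# coordinate at the same position, which would link transcripts whose exons
# do not even overlap.
intron_boundaries <- function(tc, i) {
  es <- tc$exon_starts[[i]]; ee <- tc$exon_ends[[i]]
  k <- length(es)
  if (k < 2L) return(character(0))
  c(paste0("D", ee[-k]), paste0("A", es[-1L]))
}
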