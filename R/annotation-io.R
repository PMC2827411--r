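#' Parse transcript structures in genePred format
#'
#' Reads the tab-separated genePred dialect distributed by genome browsers:
#' 10 mandatory fields (name, chrom, strand, txStart, txEnd, cdsStart,
#' cdsEnd, exonCount, exonStarts, exonEnds); the 15-field extended dialect is
#' accepted and the extra columns ignored.  Coordinates are 0-based
#' half-open; exon lists are comma-separated with an optional trailing comma.
#'
#' @param file a file path, a connection, or a character vector of lines.
#' @param source_db database tag applied to every record
#'   (`"GENBANK"`, `"REFSEQ"`, `"ENSEMBL"` or `"OTHER"`).
#' @param name collection name.
#' @return A [transcript_collection()].
#' @seealso [write_genepred()] for the inverse operation.
#' @export
parse_genepred <- function(file, source_db = "OTHER", name = NULL) {
  source_db <- match.arg(source_db, SOURCE_DBS)
  lines <- if (is.character(file) && length(file) > 1L) file
           else if (is.character(file) && !file.exists(file) &&
                    grepl("\t", file)) strsplit(file, "\n")[[1]]
           else readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(transcript_collection(character(0), character(0), character(0),
                                 character(0), integer(0), integer(0),
                                 integer(0), integer(0), list(), list(),
                                 name = name %||% source_db))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10L))
    stop("genePred parse error: line ", which(nf < 10L)[1L],
         " has ", nf[which(nf < 10L)[1L]], " fields (need >= 10)")

  int_or_stop <- function(x, line, what) {
    v <- suppressWarnings(as.integer(x))
    if (anyNA(v)) stop("genePred parse error: line ", line,
                       ": non-integer ", what, " '", x[is.na(v)][1L], "'")
    v
  }
  parse_list <- function(x, line, what) {
    parts <- strsplit(sub(",$", "", x), ",", fixed = TRUE)[[1]]
    int_or_stop(parts, line, what)
  }

  n <- length(lines)
  ids <- vapply(fields, `[[`, character(1), 1L)
  dup <- duplicated(ids)
  if (any(dup))
    stop("genePred parse error: duplicate transcript_id '", ids[dup][1L],
         "' at line ", which(dup)[1L])
  chrom  <- vapply(fields, `[[`, character(1), 2L)
  strand <- vapply(fields, `[[`, character(1), 3L)
  exon_starts <- vector("list", n); exon_ends <- vector("list", n)
  tx_start <- tx_end <- cds_start <- cds_end <- integer(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    tx_start[i]  <- int_or_stop(f[4L], i, "txStart")
    tx_end[i]    <- int_or_stop(f[5L], i, "txEnd")
    cds_start[i] <- int_or_stop(f[6L], i, "cdsStart")
    cds_end[i]   <- int_or_stop(f[7L], i, "cdsEnd")
    if (tx_start[i] >= tx_end[i])
      stop("genePred parse error: line ", i, ": txStart >= txEnd")
    cnt <- int_or_stop(f[8L], i, "exonCount")
    es <- parse_list(f[9L], i, "exonStarts")
    ee <- parse_list(f[10L], i, "exonEnds")
    if (length(es) != cnt || length(ee) != cnt)
      stop("genePred parse error: line ", i, ": exonCount=", cnt,
           " but ", length(es), " starts / ", length(ee), " ends")
    exon_starts[[i]] <- es; exon_ends[[i]] <- ee
  }
  tryCatch(
    transcript_collection(ids, source_db, chrom, strand, tx_start, tx_end,
                          cds_start, cds_end, exon_starts, exon_ends,
                          name = name %||% source_db),
    error = function(e) stop("genePred parse error: ", conditionMessage(e)))
}

#' Write a transcript collection as genePred
#'
#' @param tc a [transcript_collection()].
#' @param file output path or connection.
#' @param header logical; write `#`-prefixed provenance lines first.
#' @return `file`, invisibly.
#' @export
write_genepred <- function(tc, file, header = TRUE) {
  con <- if (inherits(file, "connection")) file else file(file, open = "wt")
  if (!inherits(file, "connection")) on.exit(close(con))
  if (header)
    writeLines(paste0("# ", provenance_header(params = list(
      format = "genePred", records = nrow(tc)))), con)
  for (i in seq_len(nrow(tc))) {
    writeLines(paste(
      tc$transcript_id[i], tc$chrom[i], tc$strand[i],
      tc$tx_start[i], tc$tx_end[i], tc$cds_start[i], tc$cds_end[i],
      length(tc$exon_starts[[i]]),
      paste0(paste(tc$exon_starts[[i]], collapse = ","), ","),
      paste0(paste(tc$exon_ends[[i]], collapse = ","), ","),
      sep = "\t"), con)
  }
  invisible(file)
}

#' Parse BLAT/Exonerate-style alignments in PSL format
#'
#' Reads the 21-column PSL layout; the optional `psLayout` header block is
#' skipped.  Per-placement base identity is computed as
#' `matches / (matches + misMatches + repMatches)` by default; the
#' `"with_insertions"` convention adds the query-insert gap count to the
#' denominator.  The convention used is recorded in the result's
#' `identity_convention` attribute.
#'
#' @param file path, connection or character vector of lines.
#' @param source_db database tag for every alignment.
#' @param identity identity denominator convention.
#' @return A data frame of class `transcript_alignments`: one row per
#'   placement with `transcript_id`, `source_db`, `base_identity`, `chrom`,
#'   `strand`, `tx_start`, `tx_end` and exon block list-columns.
#' @export
parse_psl <- function(file, source_db = "OTHER",
                      identity = c("match_only", "with_insertions")) {
  identity <- match.arg(identity)
  source_db <- match.arg(source_db, SOURCE_DBS)
  lines <- if (is.character(file) && length(file) > 1L) file
           else if (is.character(file) && !file.exists(file) &&
                    grepl("\t", file)) strsplit(file, "\n")[[1]]
           else readLines(file)
  lines <- lines[nzchar(lines)]
  # Header block: any leading lines whose first field is not an integer.
  is_data <- grepl("^[0-9]+\t", lines)
  if (any(is_data) && any(!is_data[seq(which(is_data)[1L], length(lines))]))
    stop("PSL parse error: non-data line after data began")
  lines <- lines[is_data]
  empty <- data.frame(transcript_id = character(0), source_db = character(0),
                      base_identity = numeric(0), chrom = character(0),
                      strand = character(0), tx_start = integer(0),
                      tx_end = integer(0), stringsAsFactors = FALSE)
  if (length(lines) == 0L) {
    empty$exon_starts <- list(); empty$exon_ends <- list()
    class(empty) <- c("transcript_alignments", "data.frame")
    attr(empty, "identity_convention") <- identity
    return(empty)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 21L))
    stop("PSL parse error: line ", which(nf != 21L)[1L], " has ",
         nf[nf != 21L][1L], " columns, expected 21")
  num <- function(k) vapply(fields, function(f) as.numeric(f[k]), numeric(1))
  chr <- function(k) vapply(fields, `[[`, character(1), k)
  matches <- num(1); mism <- num(2); rep_m <- num(3)
  q_ins <- num(5)
  denom <- matches + mism + rep_m + if (identity == "with_insertions") q_ins else 0
  strand <- substr(chr(9), 1L, 1L)
  block_sizes <- lapply(fields, function(f)
    as.integer(strsplit(sub(",$", "", f[19L]), ",")[[1]]))
  t_starts <- lapply(fields, function(f)
    as.integer(strsplit(sub(",$", "", f[21L]), ",")[[1]]))
  out <- data.frame(
    transcript_id = chr(10), source_db = source_db,
    base_identity = ifelse(denom > 0, matches / denom, 0),
    chrom = chr(14), strand = strand,
    tx_start = as.integer(num(16)), tx_end = as.integer(num(17)),
    stringsAsFactors = FALSE)
  out$exon_starts <- t_starts
  out$exon_ends <- mapply(function(s, w) s + w, t_starts, block_sizes,
                          SIMPLIFY = FALSE)
  class(out) <- c("transcript_alignments", "data.frame")
  attr(out, "identity_convention") <- identity
  out
}

#' Filter transcript alignments by identity and near-best placement
#'
#' Placements below `min_identity` are dropped.  For transcripts with
#' several surviving placements, only those within the source database's
#' near-best window of the transcript's best identity are kept (windows in
#' identity fraction units: 0.1 percentage points = 0.001).
#'
#' @param alignments a `transcript_alignments` data frame from [parse_psl()].
#' @param min_identity minimum base identity, default 0.96.
#' @param near_best_window named numeric vector of per-database windows.
#' @return A [transcript_collection()] of the retained placements (CDS
#'   unset, i.e. recorded as non-coding; genePred input supplies CDS).  When
#'   a transcript retains more than one placement the placements receive
#'   `#1`, `#2`, ... suffixes to keep IDs unique.
#' @export
filter_transcript_alignments <- function(alignments, min_identity = 0.96,
                                         near_best_window = c(
                                           REFSEQ = 0.001, GENBANK = 0.005,
                                           ENSEMBL = 0, OTHER = 0)) {
  stopifnot(is.data.frame(alignments))
  missing_db <- setdiff(unique(alignments$source_db), names(near_best_window))
  if (length(missing_db))
    stop("no near-best window configured for source_db: ",
         paste(missing_db, collapse = ", "))
  keep <- alignments$base_identity >= min_identity
  al <- alignments[keep, , drop = FALSE]
  if (nrow(al)) {
    best <- tapply(al$base_identity, al$transcript_id, max)
    window <- near_best_window[al$source_db]
    al <- al[al$base_identity >= best[al$transcript_id] - window, ,
             drop = FALSE]
  }
  ids <- al$transcript_id
  multi <- ids %in% ids[duplicated(ids)]
  if (any(multi)) {
    idx <- stats::ave(seq_along(ids), ids, FUN = seq_along)
    ids[multi] <- paste0(ids[multi], "#", idx[multi])
  }
  transcript_collection(
    ids, al$source_db, al$chrom, al$strand, al$tx_start, al$tx_end,
    cds_start = al$tx_start, cds_end = al$tx_start,
    exon_starts = al$exon_starts, exon_ends = al$exon_ends,
    name = "filtered_alignments")
}

#' Merge transcript collections from several databases
#'
#' Records are unioned; when the same `transcript_id` occurs in more than
#' one input, every colliding record is kept under a `sourcedb:`-prefixed
#' ID.  Per-source record counts are attached as the `source_counts`
#' attribute.
#'
#' @param collections list of [transcript_collection()] objects.
#' @param name name for the merged collection.
#' @return A [transcript_collection()].
#' @export
integrate_collections <- function(collections, name = "integrated") {
  if (length(collections) == 0L)
    return(transcript_collection(character(0), character(0), character(0),
                                 character(0), integer(0), integer(0),
                                 integer(0), integer(0), list(), list(),
                                 name = name))
  df <- do.call(rbind, lapply(collections, function(x) {
    class(x) <- "data.frame"
    x
  }))
  dup_ids <- unique(df$transcript_id[duplicated(df$transcript_id)])
  hit <- df$transcript_id %in% dup_ids
  df$transcript_id[hit] <- paste0(tolower(df$source_db[hit]), ":",
                                  df$transcript_id[hit])
  if (anyDuplicated(df$transcript_id))
    stop("transcript_id collision within one source database")
  out <- transcript_collection(
    df$transcript_id, df$source_db, df$chrom, df$strand,
    df$tx_start, df$tx_end, df$cds_start, df$cds_end,
    df$exon_starts, df$exon_ends, name = name)
  attr(out, "source_counts") <- table(df$source_db)
  out
}

#' Read a transcript-to-gene cross-reference table
#'
#' @param file TSV with columns `transcript_id` and `gene_id` (header
#'   optional; two unnamed columns are taken in that order).
#' @return Named character vector mapping transcript IDs to gene IDs.
#' @export
read_xref <- function(file) {
  df <- utils::read.delim(file, comment.char = "#", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "gene_id") %in% names(df))) {
    df <- utils::read.delim(file, comment.char = "#", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("cross-reference table needs two columns")
    names(df)[1:2] <- c("transcript_id", "gene_id")
  }
  if (anyDuplicated(df$transcript_id))
    stop("cross-reference maps a transcript_id to more than one gene_id")
  stats::setNames(as.character(df$gene_id), df$transcript_id)
}
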