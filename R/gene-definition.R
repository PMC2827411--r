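#' Linkage rules for clustering transcripts into genes
#'
#' Four rules decide whether two transcripts belong to the same gene locus:
#' \describe{
#'   \item{`exlink`}{their coding (CDS-restricted) exon intervals overlap by
#'     at least one base — the Ensembl-style default.}
#'   \item{`exbd`}{they share both boundaries of at least one exon, i.e. an
#'     identical (start, end) exon — the most stringent rule.}
#'   \item{`itbd`}{they share at least one intron boundary: an internal exon
#'     edge adjacent to an intron, matched by coordinate *and* side (intron
#'     start vs intron end).}
#'   \item{`overlap_0`}{their exon intervals overlap by at least one base,
#'     UTRs included — the coarsest rule.}
#' }
#' Transcripts on different chromosomes or strands are never linked.
#'
#' @name linkage-methods
#' @keywords internal
NULL

LINKAGE_METHODS <- c("exlink", "exbd", "itbd", "overlap_0")

as_record <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    list(chrom = x$chrom, strand = x$strand,
         tx_start = x$tx_start, tx_end = x$tx_end,
         cds_start = x$cds_start, cds_end = x$cds_end,
         exon_starts = x$exon_starts[[1]], exon_ends = x$exon_ends[[1]])
  } else x
}

#' Test whether two transcripts are linked under a gene-definition rule
#'
#' @param a,b single transcript records: one-row subsets of a
#'   [transcript_collection()] (or lists with the same fields).
#' @param method one of `"exlink"`, `"exbd"`, `"itbd"`, `"overlap_0"`.
#' @return `TRUE` if the rule links the two transcripts.
#' @seealso [cluster_transcripts()] for the transitive closure.
#' @export
linked <- function(a, b, method = LINKAGE_METHODS) {
  method <- match.arg(method)
  a <- as_record(a); b <- as_record(b)
  if (a$chrom != b$chrom || a$strand != b$strand) return(FALSE)
  switch(method,
    exlink = {
      ca <- cds_exons_rec(a); cb <- cds_exons_rec(b)
      intervals_overlap(ca$start, ca$end, cb$start, cb$end)
    },
    overlap_0 = intervals_overlap(a$exon_starts, a$exon_ends,
                                  b$exon_starts, b$exon_ends),
    exbd = {
      ka <- paste(a$exon_starts, a$exon_ends)
      kb <- paste(b$exon_starts, b$exon_ends)
      any(ka %in% kb)
    },
    itbd = {
      ba <- intron_boundaries_rec(a)
      bb <- intron_boundaries_rec(b)
      length(ba) > 0L && any(ba %in% bb)
    })
}

cds_exons_rec <- function(r) {
  if (r$cds_start == r$cds_end)
    return(list(start = integer(0), end = integer(0)))
  s <- pmax(r$exon_starts, r$cds_start)
  e <- pmin(r$exon_ends, r$cds_end)
  keep <- s < e
  list(start = s[keep], end = e[keep])
}

intron_boundaries_rec <- function(r) {
  k <- length(r$exon_starts)
  if (k < 2L) return(character(0))
  c(paste0("D", r$exon_ends[-k]), paste0("A", r$exon_starts[-1L]))
}

#' Cluster transcripts into gene models
#'
#' Genes are the connected components of the graph whose edges are given by
#' [linked()] under the chosen rule.  The default algorithm links
#' transcripts through shared features (merged overlapping intervals for the
#' overlap rules, exact exon or intron-boundary keys for the boundary rules)
#' and is near-linear; `algorithm = "naive"` evaluates all transcript pairs
#' and exists as an independent cross-check.
#'
#' Gene IDs are assigned after clustering by sorting components on
#' (chrom, span start, span end, smallest member transcript ID) and
#' numbering sequentially, so memberships and IDs do not depend on the input
#' row order.
#'
#' @param tc a [transcript_collection()].
#' @param method linkage rule, see [linkage-methods].
#' @param algorithm `"fast"` (feature-key linkage) or `"naive"`
#'   (all-pairs [linked()]).
#' @param prefix gene ID prefix; IDs are `sprintf("%s%06d", prefix, k)`.
#' @return A `gene_models` data frame: `gene_id`, `chrom`, `strand`,
#'   `span_start`, `span_end`, `n_transcripts`, plus list-columns
#'   `transcript_ids`, `exon_union_starts/ends`, `cds_union_starts/ends`.
#' @export
cluster_transcripts <- function(tc, method = LINKAGE_METHODS,
                                algorithm = c("fast", "naive"),
                                prefix = "g") {
  method <- match.arg(method)
  algorithm <- match.arg(algorithm)
  n <- nrow(tc)
  if (n == 0L) return(empty_gene_models(method))
  comp <- if (algorithm == "naive") components_naive(tc, method)
          else components_fast(tc, method)
  build_gene_models(tc, comp, method, prefix)
}

# All-pairs clustering: every same-(chrom, strand) transcript pair is tested
# with the linkage predicate.  Per-transcript features are extracted once;
# the pair test itself is the plain definition.
components_naive <- function(tc, method) {
  n <- nrow(tc)
  uf <- make_uf(n)
  groups <- split(seq_len(n), paste(tc$chrom, tc$strand))
  feat <- switch(method,
    exlink = lapply(seq_len(n), function(i) cds_exons(tc, i)),
    overlap_0 = lapply(seq_len(n), function(i)
      list(start = tc$exon_starts[[i]], end = tc$exon_ends[[i]])),
    exbd = lapply(seq_len(n), function(i)
      paste(tc$exon_starts[[i]], tc$exon_ends[[i]])),
    itbd = lapply(seq_len(n), function(i) intron_boundaries(tc, i)))
  pair_linked <- if (method %in% c("exlink", "overlap_0")) {
    function(a, b) intervals_overlap(a$start, a$end, b$start, b$end)
  } else {
    function(a, b) length(a) > 0L && any(a %in% b)
  }
  for (g in groups) {
    m <- length(g)
    if (m < 2L) next
    for (ii in seq_len(m - 1L)) for (jj in seq((ii + 1L), m)) {
      i <- g[ii]; j <- g[jj]
      if (pair_linked(feat[[i]], feat[[j]])) uf$union(i, j)
    }
  }
  uf$components()
}

components_fast <- function(tc, method) {
  n <- nrow(tc)
  uf <- make_uf(n)
  if (method %in% c("exbd", "itbd")) {
    keys <- lapply(seq_len(n), function(i) {
      base <- paste(tc$chrom[i], tc$strand[i])
      k <- if (method == "exbd")
        paste(tc$exon_starts[[i]], tc$exon_ends[[i]])
      else intron_boundaries(tc, i)
      if (length(k)) paste(base, k) else character(0)
    })
    flat <- unlist(keys, use.names = FALSE)
    owner <- rep.int(seq_len(n), lengths(keys))
    union_runs(uf, match(flat, unique(flat)), owner)
  } else {
    # Overlap linkage, interval-sorted sweep: within each (chrom, strand)
    # group, sort the relevant exon intervals by start and open a new block
    # whenever an interval starts at or after the running maximum end
    # (touching intervals do not overlap under half-open coordinates).
    # Transcripts contributing to one block are linked.
    ivs <- lapply(seq_len(n), function(i) {
      if (method == "exlink") cds_exons(tc, i)
      else list(start = tc$exon_starts[[i]], end = tc$exon_ends[[i]])
    })
    owner <- rep.int(seq_len(n), vapply(ivs, function(x) length(x$start), 0L))
    if (length(owner)) {
      starts <- unlist(lapply(ivs, `[[`, "start"), use.names = FALSE)
      ends <- unlist(lapply(ivs, `[[`, "end"), use.names = FALSE)
      grp <- paste(tc$chrom[owner], tc$strand[owner])
      for (g in unique(grp)) {
        sel <- which(grp == g)
        o <- sel[order(starts[sel], ends[sel])]
        s <- starts[o]; e <- ends[o]
        cmax <- cummax(e)
        blk <- cumsum(c(TRUE, s[-1L] >= cmax[-length(s)]))
        union_runs(uf, blk, owner[o])
      }
    }
  }
  uf$components()
}

build_gene_models <- function(tc, comp, method, prefix) {
  idx <- split(seq_len(nrow(tc)), comp)
  info <- lapply(idx, function(ix) {
    chrom <- unique(tc$chrom[ix]); strand <- unique(tc$strand[ix])
    stopifnot(length(chrom) == 1L, length(strand) == 1L)
    ex <- merge_intervals(unlist(tc$exon_starts[ix]),
                          unlist(tc$exon_ends[ix]))
    cds <- lapply(ix, function(i) cds_exons(tc, i))
    cdsu <- merge_intervals(unlist(lapply(cds, `[[`, "start")),
                            unlist(lapply(cds, `[[`, "end")))
    list(chrom = chrom, strand = strand,
         span_start = min(tc$tx_start[ix]), span_end = max(tc$tx_end[ix]),
         members = sort(tc$transcript_id[ix]),
         exon_union = ex, cds_union = cdsu)
  })
  ord <- order(vapply(info, `[[`, character(1), "chrom"),
               vapply(info, `[[`, numeric(1), "span_start"),
               vapply(info, `[[`, numeric(1), "span_end"),
               vapply(info, function(x) x$members[1L], character(1)))
  info <- unname(info[ord])
  gm <- data.frame(
    gene_id = sprintf("%s%06d", prefix, seq_along(info)),
    chrom = vapply(info, `[[`, character(1), "chrom"),
    strand = vapply(info, `[[`, character(1), "strand"),
    span_start = vapply(info, `[[`, numeric(1), "span_start"),
    span_end = vapply(info, `[[`, numeric(1), "span_end"),
    n_transcripts = vapply(info, function(x) length(x$members), 0L),
    stringsAsFactors = FALSE)
  gm$transcript_ids <- lapply(info, `[[`, "members")
  gm$exon_union_starts <- lapply(info, function(x) x$exon_union$start)
  gm$exon_union_ends <- lapply(info, function(x) x$exon_union$end)
  gm$cds_union_starts <- lapply(info, function(x) x$cds_union$start)
  gm$cds_union_ends <- lapply(info, function(x) x$cds_union$end)
  attr(gm, "method") <- method
  class(gm) <- c("gene_models", "data.frame")
  gm
}

empty_gene_models <- function(method) {
  gm <- data.frame(gene_id = character(0), chrom = character(0),
                   strand = character(0), span_start = numeric(0),
                   span_end = numeric(0), n_transcripts = integer(0),
                   stringsAsFactors = FALSE)
  gm$transcript_ids <- list(); gm$exon_union_starts <- list()
  gm$exon_union_ends <- list(); gm$cds_union_starts <- list()
  gm$cds_union_ends <- list()
  attr(gm, "method") <- method
  class(gm) <- c("gene_models", "data.frame")
  gm
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models (%s): %d genes, %d transcripts\n",
              attr(x, "method") %||% "?", nrow(x), sum(x$n_transcripts)))
  invisible(x)
}

#' Cluster transcripts into genes using a cross-reference table
#'
#' Genes are the equivalence classes of the external `transcript -> gene`
#' mapping.  Transcripts missing from the table become singleton genes with
#' a synthesized ID.  An external gene whose member transcripts sit on more
#' than one (chromosome, strand) locus is split per locus, with `@locusN`
#' suffixes, so that every gene model keeps the single-locus invariant the
#' downstream probe classification relies on.
#'
#' @param tc a [transcript_collection()].
#' @param xref named character vector from [read_xref()].
#' @return A `gene_models` data frame (see [cluster_transcripts()]); gene
#'   IDs are the external IDs.
#' @export
cluster_by_xref <- function(tc, xref) {
  n <- nrow(tc)
  if (n == 0L) return(empty_gene_models("xref"))
  gid <- unname(xref[tc$transcript_id])
  missing <- is.na(gid)
  if (any(missing)) {
    message(sum(missing), " transcript(s) absent from cross-reference; ",
            "kept as singleton genes")
    gid[missing] <- paste0("unassigned:", tc$transcript_id[missing])
  }
  locus <- paste(gid, tc$chrom, tc$strand)
  split_genes <- names(which(tapply(locus, gid, function(x)
    length(unique(x))) > 1L))
  if (length(split_genes)) {
    for (g in split_genes) {
      sel <- gid == g
      sub <- match(locus[sel], unique(locus[sel]))
      gid[sel] <- paste0(g, "@locus", sub)
    }
  }
  comp <- match(gid, unique(gid))
  gm <- build_gene_models(tc, comp, "xref", prefix = "x")
  # Replace positional IDs with the external ones, keeping the sorted order.
  ext <- vapply(gm$transcript_ids, function(m)
    gid[match(m[1L], tc$transcript_id)], character(1))
  gm$gene_id <- ext
  gm
}

#' Write gene models as TSV
#'
#' One row per gene with the span and the semicolon-joined member
#' transcripts; `#` provenance header included.
#'
#' @param gm a `gene_models` data frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_gene_models <- function(gm, file) {
  df <- data.frame(
    gene_id = gm$gene_id, chrom = gm$chrom, strand = gm$strand,
    span_start = gm$span_start, span_end = gm$span_end,
    n_transcripts = gm$n_transcripts,
    transcript_ids = vapply(gm$transcript_ids, paste, character(1),
                            collapse = ";"),
    stringsAsFactors = FALSE)
  write_tsv_header(df, file, provenance_header(params = list(
    method = attr(gm, "method") %||% "?", genes = nrow(gm))))
}

#' Write gene exon unions as BED12
#'
#' @param gm a `gene_models` data frame.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_gene_bed12 <- function(gm, file) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(gm))) {
    s <- gm$exon_union_starts[[i]]; e <- gm$exon_union_ends[[i]]
    if (length(s) == 0L) { s <- gm$span_start[i]; e <- gm$span_end[i] }
    cs <- gm$cds_union_starts[[i]]
    thick_s <- if (length(cs)) min(cs) else gm$span_start[i]
    thick_e <- if (length(cs)) max(gm$cds_union_ends[[i]]) else gm$span_start[i]
    writeLines(paste(gm$chrom[i], gm$span_start[i], gm$span_end[i],
                     gm$gene_id[i], 0L, gm$strand[i], thick_s, thick_e,
                     "0", length(s),
                     paste0(paste(e - s, collapse = ","), ","),
                     paste0(paste(s - gm$span_start[i], collapse = ","), ","),
                     sep = "\t"), con)
  }
  invisible(file)
}
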