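#' @importFrom S4Vectors queryHits subjectHits
NULL

PROBE_CLASSES <- c("MULTI_GENOME", "NO_GENOME", "MULTI_GENE",
                   "INTERGENIC", "INTRONIC", "UNDERPOPULATED_SET", "GOOD")

accounting_labels <- function(min_probes = 3L) {
  c(MULTI_GENOME       = "Probes with multiple alignments to the genome",
    NO_GENOME          = "Probes with no alignment to the genome",
    MULTI_GENE         = "Probes matching multiple genes",
    INTERGENIC         = "Probes matching intergenic region",
    INTRONIC           = "Probes matching intron region",
    UNDERPOPULATED_SET = sprintf("< %d probes per probe set", min_probes),
    GOOD               = "Good probes")
}

#' Read a probe table
#'
#' @param file TSV with columns `probe_id`, `sequence` and optionally
#'   `original_probe_set`.
#' @return Data frame of probe records.
#' @export
read_probes <- function(file) {
  df <- read_tsv_header(file)
  if (!all(c("probe_id", "sequence") %in% names(df)))
    stop("probe table needs columns probe_id and sequence")
  df$sequence <- toupper(df$sequence)
  df
}

as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a named DNAStringSet or a FASTA path")
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

# Probes usable for exact matching: 25-mers over ACGT.  Others are warned
# about and fall through to NO_GENOME.
valid_probe_mask <- function(probes) {
  ok_len <- nchar(probes$sequence) == 25L
  if (any(!ok_len))
    stop("probe(s) not 25 bases long: ",
         paste(utils::head(probes$probe_id[!ok_len], 3L), collapse = ", "))
  ok <- grepl("^[ACGT]{25}$", probes$sequence)
  if (any(!ok))
    warning(sum(!ok), " probe(s) with non-ACGT characters rejected ",
            "(counted as having no genome alignment)")
  ok
}

#' Find all perfect genomic matches of 25-mer probes
#'
#' Every exact occurrence of each probe sequence, and of its reverse
#' complement, is reported; matches of the reverse complement are hits on
#' the minus strand.  Only perfect-identity placements exist in the output
#' by construction.
#'
#' @param probes data frame with `probe_id` and `sequence` (25-mers).
#' @param genome named `DNAStringSet` or FASTA path.
#' @return Data frame of hits: `probe_id`, `chrom`, `strand`, `start`,
#'   `end` (0-based half-open, `end - start == 25`), `match_type`
#'   (`"GENOMIC"`), `transcript_id` (`NA` for genomic hits).
#' @export
match_probes <- function(probes, genome) {
  genome <- as_genome(genome)
  ok <- valid_probe_mask(probes)
  pr <- probes[ok, , drop = FALSE]
  if (nrow(pr) == 0L) return(empty_hits())
  fwd <- Biostrings::DNAStringSet(pr$sequence)
  rev <- Biostrings::reverseComplement(fwd)
  pd_f <- Biostrings::PDict(fwd)
  pd_r <- Biostrings::PDict(rev)
  out <- list()
  for (chrom in names(genome)) {
    subject <- genome[[chrom]]
    for (dir in c("+", "-")) {
      m <- Biostrings::matchPDict(if (dir == "+") pd_f else pd_r, subject)
      cnt <- S4Vectors::elementNROWS(m)
      if (sum(cnt) == 0L) next
      starts <- unlist(IRanges::start(m), use.names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        probe_id = rep.int(pr$probe_id, cnt),
        chrom = chrom, strand = dir,
        start = starts - 1L, end = starts + 24L,
        match_type = "GENOMIC", transcript_id = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty_hits())
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$probe_id, hits$chrom, hits$start, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(probe_id = character(0), chrom = character(0),
             strand = character(0), start = integer(0), end = integer(0),
             match_type = character(0), transcript_id = character(0),
             stringsAsFactors = FALSE)
}

# Spliced (exon-concatenated) sequence of one transcript, 5'->3'.
spliced_sequence <- function(tc, i, genome) {
  chromseq <- genome[[tc$chrom[i]]]
  seqs <- Biostrings::extractAt(chromseq,
                                ir0(tc$exon_starts[[i]], tc$exon_ends[[i]]))
  s <- Biostrings::DNAString(paste(as.character(seqs), collapse = ""))
  if (tc$strand[i] == "-") s <- Biostrings::reverseComplement(s)
  s
}

# Genomic 0-based coordinate of the k-th exonic base (1-based k counted on
# the + strand of the genome, i.e. on the sense spliced sequence for a +
# transcript).
exonic_coord <- function(exon_starts, exon_ends, k) {
  lens <- exon_ends - exon_starts
  cum <- cumsum(lens)
  e <- which(k <= cum)[1L]
  offset <- k - (if (e > 1L) cum[e - 1L] else 0L)
  exon_starts[e] + offset - 1L
}

#' Rescue exon-junction probes via spliced transcript sequences
#'
#' Probes with no genomic match may still match the mRNA: their 25-mer can
#' straddle an exon-exon junction.  Each transcript's spliced sequence is
#' assembled from its exons (reverse-complemented for minus-strand
#' transcripts) and searched for exact matches of the unmatched probes and
#' of their reverse complements.
#'
#' @param probes data frame of probes that had zero genomic hits.
#' @param tc a [transcript_collection()].
#' @param genome named `DNAStringSet` or FASTA path.
#' @return Hit data frame as in [match_probes()] with `match_type`
#'   `"SPLICED"` and `transcript_id` naming the matched transcript; `start`
#'   holds the leftmost genomic base of the probe footprint and `strand` the
#'   genomic strand the probe sequence corresponds to.
#' @export
rescue_junction_probes <- function(probes, tc, genome) {
  genome <- as_genome(genome)
  ok <- suppressWarnings(valid_probe_mask(probes))
  pr <- probes[ok, , drop = FALSE]
  if (nrow(pr) == 0L || nrow(tc) == 0L) return(empty_hits())
  fwd <- Biostrings::DNAStringSet(pr$sequence)
  pd_f <- Biostrings::PDict(fwd)
  pd_r <- Biostrings::PDict(Biostrings::reverseComplement(fwd))
  out <- list()
  for (i in seq_len(nrow(tc))) {
    if (!tc$chrom[i] %in% names(genome)) {
      warning("transcript ", tc$transcript_id[i], " references absent ",
              "chromosome ", tc$chrom[i], "; skipped")
      next
    }
    txseq <- spliced_sequence(tc, i, genome)
    L <- length(txseq)
    if (L < 25L) next
    for (dir in c("sense", "antisense")) {
      m <- Biostrings::matchPDict(if (dir == "sense") pd_f else pd_r, txseq)
      cnt <- S4Vectors::elementNROWS(m)
      if (sum(cnt) == 0L) next
      p <- unlist(IRanges::start(m), use.names = FALSE)  # 1-based in txseq
      # Leftmost genomic base of the footprint: for '-' transcripts the
      # spliced sequence runs right-to-left along the genome.
      sense_idx <- if (tc$strand[i] == "+") p else L - (p + 24L) + 1L
      gstart <- vapply(sense_idx, function(k)
        exonic_coord(tc$exon_starts[[i]], tc$exon_ends[[i]], k), numeric(1))
      hit_strand <- if (dir == "sense") tc$strand[i]
                    else setdiff(c("+", "-"), tc$strand[i])
      out[[length(out) + 1L]] <- data.frame(
        probe_id = rep.int(pr$probe_id, cnt),
        chrom = tc$chrom[i], strand = hit_strand,
        start = as.integer(gstart), end = as.integer(gstart) + 25L,
        match_type = "SPLICED", transcript_id = tc$transcript_id[i],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty_hits())
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$probe_id, hits$transcript_id, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

#' Transcript signature of a uniquely placed probe
#'
#' For a genomic hit the signature is the set of transcripts with an exon
#' fully containing the 25-base footprint (partial exon overlap does not
#' count: the probe must interrogate the transcript).  For a spliced hit it
#' is the set of matched transcripts.  The probe is sense with respect to a
#' transcript when the hit strand equals the transcript strand.
#'
#' @param hits hit rows (from [match_probes()] / [rescue_junction_probes()])
#'   belonging to one probe.
#' @param genes `gene_models` from [cluster_transcripts()] or
#'   [cluster_by_xref()].
#' @param tc the [transcript_collection()] the genes were built from.
#' @return A list with `signature` (character, possibly empty), `gene_ids`,
#'   and `sense` (`"SENSE"`, `"ANTISENSE"`, or `"MIXED"`); `NULL` when the
#'   signature is empty.
#' @export
assign_signature <- function(hits, genes, tc) {
  tx2gene <- transcript_gene_map(genes)
  sig <- signature_of_hits(hits, tc)
  if (length(sig$transcripts) == 0L) return(NULL)
  list(signature = sort(sig$transcripts),
       gene_ids = sort(unique(unname(tx2gene[sig$transcripts]))),
       sense = sig$sense)
}

transcript_gene_map <- function(genes) {
  stats::setNames(rep.int(genes$gene_id, lengths(genes$transcript_ids)),
                  unlist(genes$transcript_ids))
}

# Signature + sense for one probe's hits (single genomic hit or >=1 spliced
# hits).  Sense is per signature transcript; "MIXED" when both occur.
signature_of_hits <- function(hits, tc) {
  if (hits$match_type[1L] == "SPLICED") {
    ids <- unique(hits$transcript_id)
    strands <- tc$strand[match(ids, tc$transcript_id)]
    hstr <- hits$strand[match(ids, hits$transcript_id)]
    sense_v <- ifelse(hstr == strands, "SENSE", "ANTISENSE")
  } else {
    sel <- tc$chrom == hits$chrom[1L]
    ids <- character(0); sense_v <- character(0)
    if (any(sel)) {
      idx <- which(sel)
      exn <- lengths(tc$exon_starts[idx])
      owner <- rep.int(idx, exn)
      ex <- ir0(unlist(tc$exon_starts[idx]), unlist(tc$exon_ends[idx]))
      ov <- IRanges::findOverlaps(ir0(hits$start[1L], hits$end[1L]), ex,
                                  type = "within")
      ids <- unique(tc$transcript_id[owner[S4Vectors::subjectHits(ov)]])
      strands <- tc$strand[match(ids, tc$transcript_id)]
      sense_v <- ifelse(strands == hits$strand[1L], "SENSE", "ANTISENSE")
    }
  }
  sense <- if (length(unique(sense_v)) > 1L) "MIXED"
           else if (length(sense_v)) sense_v[1L] else NA_character_
  list(transcripts = ids, sense = sense)
}

#' Classify probes and regroup them into transcript-signature probe sets
#'
#' Applies the remapping decision cascade to every probe:
#' \enumerate{
#'   \item two or more genomic placements: `MULTI_GENOME`;
#'   \item no placement at all (after junction rescue): `NO_GENOME`;
#'   \item signature spanning two or more genes (or mixed sense):
#'     `MULTI_GENE`;
#'   \item empty signature but footprint inside some gene span: `INTRONIC`;
#'   \item empty signature elsewhere: `INTERGENIC`;
#'   \item probes grouped by (gene, signature, sense); groups smaller than
#'     `min_probes`: `UNDERPOPULATED_SET`;
#'   \item everything else: `GOOD`, and each group becomes a probe set
#'     `"{gene_id}_{k}"` (k by ascending genomic start of the group's
#'     leftmost probe; antisense sets get an `"_RC"` suffix).
#' }
#' The seven categories are exhaustive and mutually exclusive, so the
#' accounting counts always sum to the number of input probes.
#'
#' @param probes probe data frame (`probe_id`, `sequence`).
#' @param hits combined hits from [match_probes()] and
#'   [rescue_junction_probes()].
#' @param genes `gene_models`.
#' @param tc the [transcript_collection()] behind `genes`.
#' @param min_probes minimum probes per retained set (default 3: sets with
#'   fewer than 3 probes are removed).
#' @param keep_antisense keep reverse-complementary probe sets (flagged
#'   `_RC`)?  If `FALSE`, antisense placements are treated as unannotated
#'   and fall through to the intronic/intergenic rules.
#' @return A `remapping_result`: list with `probes` (per-probe class and
#'   probe-set assignment), `probe_sets`, `probe_details` (per good probe:
#'   sequence and placement, for the file writers), `accounting`, `params`.
#' @export
classify_and_group <- function(probes, hits, genes, tc, min_probes = 3L,
                               keep_antisense = TRUE) {
  stopifnot(is.data.frame(probes), is.data.frame(hits))
  if (anyDuplicated(probes$probe_id)) stop("duplicate probe_id in input")
  unknown <- setdiff(hits$probe_id, probes$probe_id)
  if (length(unknown))
    stop("hits reference probes absent from input: ",
         paste(utils::head(unknown, 3L), collapse = ", "))

  n <- nrow(probes)
  cls <- rep(NA_character_, n)
  names(cls) <- probes$probe_id
  genomic <- hits[hits$match_type == "GENOMIC", , drop = FALSE]
  spliced <- hits[hits$match_type == "SPLICED", , drop = FALSE]
  gcount <- table(genomic$probe_id)
  ngen <- as.integer(gcount[probes$probe_id]); ngen[is.na(ngen)] <- 0L
  has_spliced <- probes$probe_id %in% spliced$probe_id

  cls[ngen >= 2L] <- "MULTI_GENOME"
  cls[ngen == 0L & !has_spliced] <- "NO_GENOME"

  tx2gene <- transcript_gene_map(genes)
  gene_ir <- ir0(genes$span_start, genes$span_end)

  sig_key <- rep(NA_character_, n)      # gene|signature|sense for grouping
  sig_gene <- rep(NA_character_, n)
  sig_sense <- rep(NA_character_, n)
  sig_txt <- rep(NA_character_, n)
  rep_start <- rep(NA_integer_, n)      # representative genomic start
  gen_by_probe <- split(seq_len(nrow(genomic)), genomic$probe_id)
  spl_by_probe <- split(seq_len(nrow(spliced)), spliced$probe_id)

  todo <- which(is.na(cls))
  for (i in todo) {
    pid <- probes$probe_id[i]
    h <- if (ngen[i] == 1L) genomic[gen_by_probe[[pid]], , drop = FALSE]
         else spliced[spl_by_probe[[pid]], , drop = FALSE]
    rep_start[i] <- min(h$start)
    sig <- signature_of_hits(h, tc)
    if (length(sig$transcripts) && !keep_antisense &&
        sig$sense != "SENSE") sig$transcripts <- character(0)
    if (length(sig$transcripts) == 0L) {
      ov <- IRanges::findOverlaps(ir0(h$start[1L], h$end[1L]), gene_ir,
                                  type = "within")
      same_chrom <- genes$chrom[S4Vectors::subjectHits(ov)] == h$chrom[1L]
      cls[i] <- if (any(same_chrom)) "INTRONIC" else "INTERGENIC"
      next
    }
    gids <- unique(unname(tx2gene[sig$transcripts]))
    if (anyNA(gids))
      stop("signature transcript not present in any gene model")
    if (length(gids) >= 2L || sig$sense == "MIXED") {
      cls[i] <- "MULTI_GENE"
      next
    }
    sig_gene[i] <- gids
    sig_sense[i] <- sig$sense
    sig_txt[i] <- paste(sort(sig$transcripts), collapse = ";")
    sig_key[i] <- paste(gids, sig_txt[i], sig$sense, sep = "|")
  }

  # Group retained probes and apply the minimum-probe rule.
  grouped <- which(!is.na(sig_key))
  probe_set_id <- rep(NA_character_, n)
  sets <- list()
  if (length(grouped)) {
    by_key <- split(grouped, sig_key[grouped])
    sizes <- lengths(by_key)
    small <- names(sizes)[sizes < min_probes]
    for (k in small) cls[by_key[[k]]] <- "UNDERPOPULATED_SET"
    keep_keys <- setdiff(names(by_key), small)
    if (length(keep_keys)) {
      meta <- data.frame(
        key = keep_keys,
        gene_id = vapply(by_key[keep_keys], function(ix) sig_gene[ix[1L]],
                         character(1)),
        sense = vapply(by_key[keep_keys], function(ix) sig_sense[ix[1L]],
                       character(1)),
        signature = vapply(by_key[keep_keys], function(ix) sig_txt[ix[1L]],
                           character(1)),
        min_start = vapply(by_key[keep_keys], function(ix)
          min(rep_start[ix]), numeric(1)),
        stringsAsFactors = FALSE)
      meta <- meta[order(meta$gene_id, meta$min_start, meta$signature,
                         meta$sense), ]
      k_in_gene <- stats::ave(seq_len(nrow(meta)), meta$gene_id,
                              FUN = seq_along)
      meta$probe_set_id <- paste0(meta$gene_id, "_", k_in_gene,
                                  ifelse(meta$sense == "ANTISENSE", "_RC", ""))
      for (r in seq_len(nrow(meta))) {
        ix <- by_key[[meta$key[r]]]
        cls[ix] <- "GOOD"
        probe_set_id[ix] <- meta$probe_set_id[r]
      }
      meta$n_probes <- lengths(by_key[meta$key])
      meta$probe_ids <- lapply(by_key[meta$key], function(ix)
        sort(probes$probe_id[ix]))
      sets <- meta[, c("probe_set_id", "gene_id", "sense", "signature",
                       "n_probes", "min_start", "probe_ids")]
      rownames(sets) <- NULL
    }
  }
  if (length(sets) == 0L) {
    sets <- data.frame(probe_set_id = character(0), gene_id = character(0),
                       sense = character(0), signature = character(0),
                       n_probes = integer(0), min_start = numeric(0),
                       stringsAsFactors = FALSE)
    sets$probe_ids <- list()
  }

  stopifnot(!anyNA(cls))
  probe_df <- data.frame(probe_id = probes$probe_id, class = cls,
                         probe_set_id = probe_set_id,
                         stringsAsFactors = FALSE)
  good <- which(cls == "GOOD")
  details <- data.frame(
    probe_set_id = probe_set_id[good],
    gene_id = sig_gene[good], sense = sig_sense[good],
    signature = sig_txt[good],
    probe_id = probes$probe_id[good],
    sequence = probes$sequence[good],
    chrom = vapply(good, function(i) {
      pid <- probes$probe_id[i]
      h <- if (ngen[i] == 1L) genomic[gen_by_probe[[pid]][1L], ]
           else spliced[spl_by_probe[[pid]][1L], ]
      h$chrom
    }, character(1)),
    strand = vapply(good, function(i) {
      pid <- probes$probe_id[i]
      h <- if (ngen[i] == 1L) genomic[gen_by_probe[[pid]][1L], ]
           else spliced[spl_by_probe[[pid]][1L], ]
      h$strand
    }, character(1)),
    start = rep_start[good],
    stringsAsFactors = FALSE)
  details <- details[order(details$probe_set_id, details$start,
                           details$probe_id), ]
  rownames(details) <- NULL

  res <- list(probes = probe_df, probe_sets = sets, probe_details = details,
              accounting = accounting_table(cls, nrow(sets), min_probes),
              params = list(min_probes = min_probes,
                            keep_antisense = keep_antisense,
                            gene_method = attr(genes, "method") %||% "?"))
  class(res) <- "remapping_result"
  res
}

# Accounting data frame in the canonical category order.
accounting_table <- function(cls, n_sets, min_probes) {
  labels <- accounting_labels(min_probes)
  counts <- vapply(PROBE_CLASSES, function(k) sum(cls == k), integer(1))
  acc <- data.frame(category = PROBE_CLASSES, label = unname(labels),
                    count = unname(counts), stringsAsFactors = FALSE)
  attr(acc, "total") <- sum(counts)
  attr(acc, "pct_good") <- round(100 * counts[["GOOD"]] / sum(counts), 3L)
  attr(acc, "n_probe_sets") <- n_sets
  acc
}

#' Derived accounting fields from a category-count vector
#'
#' Computes the probe total and the percentage of good probes (three
#' decimals, on the percent scale) from a named vector of category counts.
#' Accepts the full seven-category vector or the merged five-category form
#' in which the two genome-location issues and the two no-gene categories
#' are pooled; the only requirement is a `GOOD` entry.
#'
#' @param counts named numeric vector of probe-category counts.
#' @return List with `total` and `pct_good`.
#' @export
accounting_from_counts <- function(counts) {
  if (!"GOOD" %in% names(counts))
    stop("counts must include a GOOD entry")
  if (any(counts < 0)) stop("negative category count")
  total <- sum(counts)
  list(total = total,
       pct_good = round(100 * unname(counts[["GOOD"]]) / total, 3L))
}

#' Probe-set summary ratios
#'
#' The two headline ratios of a remapping: average probe sets per matched
#' gene and average transcripts per probe set, both to three decimals.
#'
#' @param n_transcripts transcripts matched by good probe sets.
#' @param n_genes genes matched by good probe sets.
#' @param n_probe_sets number of probe sets.
#' @return List with `probe_sets_per_gene` and `transcripts_per_probe_set`.
#' @export
probe_set_ratios <- function(n_transcripts, n_genes, n_probe_sets) {
  list(probe_sets_per_gene = round(n_probe_sets / n_genes, 3L),
       transcripts_per_probe_set = round(n_transcripts / n_probe_sets, 3L))
}

#' Gene/transcript coverage statistics of a remapping result
#'
#' @param result a `remapping_result`.
#' @return List with counts of matched transcripts, matched genes, genes
#'   with two or more probe sets, probe sets, and the ratios of
#'   [probe_set_ratios()].
#' @export
remap_gene_stats <- function(result) {
  sets <- result$probe_sets
  n_tx <- length(unique(unlist(strsplit(sets$signature, ";", fixed = TRUE))))
  n_genes <- length(unique(sets$gene_id))
  per_gene <- table(sets$gene_id)
  c(list(n_transcripts = n_tx, n_genes = n_genes,
         n_genes_multi_set = sum(per_gene >= 2L),
         n_probe_sets = nrow(sets)),
    probe_set_ratios(n_tx, n_genes, nrow(sets)))
}

#' @export
print.remapping_result <- function(x, ...) {
  cat("remapping_result:", attr(x$accounting, "total"), "probes,",
      attr(x$accounting, "n_probe_sets"), "probe sets,",
      paste0(attr(x$accounting, "pct_good"), "%"), "good\n")
  acc <- x$accounting
  for (i in seq_len(nrow(acc)))
    cat(sprintf("  %-45s %d\n", acc$label[i], acc$count[i]))
  invisible(x)
}

#' Compare two remapping results gene by gene
#'
#' Genes are paired across the two results when they share at least one
#' good probe.  A one-to-one pair is `SAME` when the two genes' good probes
#' are partitioned into identical probe sets (set labels ignored), `DIFF`
#' otherwise; many-to-many pairings count as `DIFF`; genes with good probes
#' in only one result are `UNIQUE_A` / `UNIQUE_B`.
#'
#' @param a,b `remapping_result` objects built from the same probe universe.
#' @return List with `counts` (`same`, `diff`, `unique_a`, `unique_b`) and a
#'   data frame `pairs` of one-to-one gene pairings.
#' @export
compare_remappings <- function(a, b) {
  if (!setequal(a$probes$probe_id, b$probes$probe_id))
    stop("remapping results built from different probe universes")
  part <- function(res) {
    good <- res$probes[res$probes$class == "GOOD", , drop = FALSE]
    sets <- split(good$probe_id, good$probe_set_id)
    gene_of_set <- stats::setNames(res$probe_sets$gene_id,
                                   res$probe_sets$probe_set_id)
    split(sets, unname(gene_of_set[names(sets)]))
  }
  probe_gene <- function(res) {
    good <- res$probes[res$probes$class == "GOOD", , drop = FALSE]
    gene_of_set <- stats::setNames(res$probe_sets$gene_id,
                                   res$probe_sets$probe_set_id)
    stats::setNames(unname(gene_of_set[good$probe_set_id]), good$probe_id)
  }
  pa <- part(a); pb <- part(b)
  ga <- probe_gene(a); gb <- probe_gene(b)
  shared <- intersect(names(ga), names(gb))
  edges <- unique(data.frame(a = unname(ga[shared]), b = unname(gb[shared]),
                             stringsAsFactors = FALSE))
  unique_a <- setdiff(names(pa), edges$a)
  unique_b <- setdiff(names(pb), edges$b)
  same <- 0L; diff <- 0L
  if (nrow(edges)) {
    deg_a <- table(edges$a); deg_b <- table(edges$b)
    one2one <- deg_a[edges$a] == 1L & deg_b[edges$b] == 1L
    canon <- function(sets) {
      x <- lapply(unname(sets), function(s) sort(unlist(s)))
      x[order(vapply(x, `[[`, character(1), 1L))]
    }
    for (r in which(one2one)) {
      if (identical(canon(pa[[edges$a[r]]]), canon(pb[[edges$b[r]]])))
        same <- same + 1L else diff <- diff + 1L
    }
    # Many-to-many components: count the larger side, all DIFF.
    mm <- edges[!one2one, , drop = FALSE]
    if (nrow(mm)) {
      comp_a <- unique(mm$a); comp_b <- unique(mm$b)
      diff <- diff + max(length(comp_a), length(comp_b))
    }
  }
  list(counts = c(same = same, diff = diff,
                  unique_a = length(unique_a), unique_b = length(unique_b)),
       pairs = edges)
}

#' Write probe-set definition, accounting, and annotation files
#'
#' Emits three TSVs with provenance headers: the per-probe definition table
#' (probe set, gene, sense, signature, probe sequence and placement), the
#' accounting table (category labels, counts, percentage of good probes,
#' probe-set count, total) and the per-probe-set annotation table.
#'
#' @param result a `remapping_result`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_probeset_files <- function(result, dir, prefix = "remap") {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", dir)
  hdr <- provenance_header(params = result$params)
  def_file <- file.path(dir, paste0(prefix, "_probesets.tsv"))
  acc_file <- file.path(dir, paste0(prefix, "_accounting.tsv"))
  ann_file <- file.path(dir, paste0(prefix, "_annotation.tsv"))
  write_tsv_header(result$probe_details, def_file, hdr)
  acc <- result$accounting[, c("label", "count")]
  acc$count <- as.character(acc$count)
  acc <- rbind(acc,
               data.frame(label = "Percentage of good probes",
                          count = sprintf("%.3f%%",
                                          attr(result$accounting, "pct_good")),
                          stringsAsFactors = FALSE),
               data.frame(label = "Probe sets",
                          count = as.character(
                            attr(result$accounting, "n_probe_sets")),
                          stringsAsFactors = FALSE),
               data.frame(label = "Total probes",
                          count = as.character(
                            attr(result$accounting, "total")),
                          stringsAsFactors = FALSE))
  write_tsv_header(acc, acc_file, hdr)
  ann <- result$probe_sets[, c("probe_set_id", "gene_id", "sense",
                               "signature", "n_probes")]
  write_tsv_header(ann, ann_file, hdr)
  invisible(c(definitions = def_file, accounting = acc_file,
              annotation = ann_file))
}

#' Re-read a probe-set definition file
#'
#' Inverse of the definition table written by [write_probeset_files()]:
#' reconstructs the probe-set table (with member probe IDs) and the
#' per-probe detail rows.
#'
#' @param file path to a `*_probesets.tsv`.
#' @return List with `probe_sets` and `probe_details` data frames matching
#'   the corresponding fields of a `remapping_result`.
#' @export
read_probeset_defs <- function(file) {
  det <- read_tsv_header(file, colClasses = c(
    probe_set_id = "character", gene_id = "character", sense = "character",
    signature = "character", probe_id = "character", sequence = "character",
    chrom = "character", strand = "character", start = "integer"))
  by_set <- split(seq_len(nrow(det)), det$probe_set_id)
  sets <- data.frame(
    probe_set_id = names(by_set),
    gene_id = vapply(by_set, function(ix) det$gene_id[ix[1L]], character(1)),
    sense = vapply(by_set, function(ix) det$sense[ix[1L]], character(1)),
    signature = vapply(by_set, function(ix) det$signature[ix[1L]],
                       character(1)),
    n_probes = lengths(by_set),
    min_start = vapply(by_set, function(ix) min(det$start[ix]), numeric(1)),
    stringsAsFactors = FALSE)
  sets$probe_ids <- lapply(by_set, function(ix) sort(det$probe_id[ix]))
  sets <- sets[order(sets$gene_id, sets$min_start, sets$signature,
                     sets$sense), ]
  rownames(sets) <- NULL
  list(probe_sets = sets, probe_details = det)
}
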