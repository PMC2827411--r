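#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator.  The defaults
#' describe a compact but fully featured locus layout: multi-exon genes with
#' a cassette-exon isoform each, a UTR-overlap decoy gene pair (which the
#' coding-exon and any-exon-overlap linkage rules cluster differently), and
#' planted probes for each of the seven remapping categories so that the
#' classification truth is known exactly by construction.
#'
#' @param seed integer; fully determines all generator output.
#' @param n_genes number of standard multi-exon genes.
#' @param transcripts_per_gene 1, 2 or 3 isoforms per gene (2 adds a
#'   cassette-exon skip isoform, 3 adds a short 3'-truncated isoform).
#' @param n_exons,exon_length,intron_length exon/intron layout (bases).
#' @param gene_gap intergenic distance between gene blocks (bases).
#' @param cds_inset UTR length trimmed from each transcript end to form the
#'   CDS.
#' @param dropout named per-database transcript dropout probabilities for
#'   the three single-source database views.
#' @param planted named integer vector: how many probes to plant per
#'   remapping category (`multi_genome`, `no_genome`, `multi_gene`,
#'   `intergenic`, `intronic`, `underpopulated`, `good`).
#' @param n_junction exon-junction probes (rescued via spliced transcript
#'   sequences, counted good); 0 or at least `min_probes`.
#' @param min_probes minimum probes per retained set assumed by the planted
#'   layout.
#' @param expression list of expression-simulation parameters: `n_genes`,
#'   `n_sets_per_gene`, `n_replicates`, `baseline_meanlog`,
#'   `baseline_sdlog`, `as_fraction`, `fold`, `sigma` (multiplicative
#'   log-normal noise, natural-log sd).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 8L,
                       transcripts_per_gene = 2L,
                       n_exons = 3L, exon_length = 200L,
                       intron_length = 200L,
                       gene_gap = 1000L, cds_inset = 50L,
                       dropout = c(GENBANK = 0.3, REFSEQ = 0.6,
                                   ENSEMBL = 0.4),
                       planted = c(multi_genome = 5L, no_genome = 5L,
                                   multi_gene = 5L, intergenic = 5L,
                                   intronic = 5L, underpopulated = 5L,
                                   good = 15L),
                       n_junction = 3L,
                       min_probes = 3L,
                       expression = list()) {
  expr_defaults <- list(n_genes = 200L, n_sets_per_gene = 2L,
                        n_replicates = 3L, baseline_meanlog = log(500),
                        baseline_sdlog = 1, as_fraction = 0.5,
                        fold = 4, sigma = 0.1)
  expression <- utils::modifyList(expr_defaults, expression)
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              transcripts_per_gene = as.integer(transcripts_per_gene),
              n_exons = as.integer(n_exons),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              gene_gap = as.integer(gene_gap),
              cds_inset = as.integer(cds_inset),
              dropout = dropout, planted = planted,
              n_junction = as.integer(n_junction),
              min_probes = as.integer(min_probes),
              expression = expression)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  p <- cfg$planted
  need <- c("multi_genome", "no_genome", "multi_gene", "intergenic",
            "intronic", "underpopulated", "good")
  if (!all(need %in% names(p)))
    stop("planted must name all of: ", paste(need, collapse = ", "))
  if (any(p < 0) || cfg$n_junction < 0) stop("planted counts must be >= 0")
  if (cfg$n_junction > 0 && cfg$n_junction < cfg$min_probes)
    stop("n_junction must be 0 or >= min_probes (junction probes form ",
         "one probe set)")
  if (!cfg$transcripts_per_gene %in% 1:3)
    stop("transcripts_per_gene must be 1, 2 or 3")
  if (cfg$n_exons < 3L) stop("layout needs at least 3 exons per gene")
  if (cfg$exon_length < 60L || cfg$intron_length < 60L)
    stop("exons and introns must be at least 60 bases for probe planting")
  if (cfg$n_genes == 0L &&
      (sum(p[c("good", "underpopulated", "intronic")]) > 0 ||
       cfg$n_junction > 0))
    stop("gene-anchored probe categories need n_genes > 0")
  if (cfg$transcripts_per_gene < 2L &&
      (p[["underpopulated"]] > 0 || cfg$n_junction > 0))
    stop("underpopulated and junction planting need >= 2 isoforms per gene")
  e <- cfg$expression
  if (e$sigma < 0) stop("expression noise sigma must be >= 0")
  if (e$fold <= 0) stop("expression fold must be > 0")
  invisible(cfg)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome with multi-database transcript annotation
#'
#' Lays out `n_genes` standard genes (each with a full-length isoform, a
#' cassette-exon skip isoform, and optionally a truncated isoform), plus a
#' single-exon decoy gene pair whose exons overlap only in their UTRs —
#' linked under the any-exon-overlap rule but not under coding-exon
#' overlap.  Three single-source database views are produced by dropping
#' transcripts at the per-database dropout rates; the full collection is
#' their union.  True gene partitions under all four linkage rules are
#' computed with the naive all-pairs clustering.
#'
#' @param config a [sim_config()].
#' @return List (class `sim_annotation`) with `genome` (`DNAStringSet`),
#'   `transcripts` (full [transcript_collection()]), `collections`
#'   (per-database views), `truth` (per-method gene counts and
#'   memberships) and `layout` (region coordinates used by
#'   [simulate_probes()]).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$planted
  exl <- config$exon_length; itl <- config$intron_length
  gene_w <- config$n_exons * exl + (config$n_exons - 1L) * itl

  dup_w <- max(p[["multi_genome"]], 1L) * 30L
  iz_w <- max(p[["intergenic"]], 1L) * 30L + 100L
  pos <- 0L
  dupA <- pos; pos <- pos + dup_w + 200L
  dupB <- pos; pos <- pos + dup_w + 500L
  izone <- pos; pos <- pos + iz_w + 500L
  gene_starts <- integer(config$n_genes)
  for (i in seq_len(config$n_genes)) {
    gene_starts[i] <- pos
    pos <- pos + gene_w + config$gene_gap
  }
  decoy <- pos; pos <- pos + 550L + 500L
  genome_len <- pos

  starts_rel <- (seq_len(config$n_exons) - 1L) * (exl + itl)
  ends_rel <- starts_rel + exl

  ids <- list(); chrom <- list(); strand <- list()
  txs <- list(); txe <- list(); cs <- list(); ce <- list()
  es <- list(); ee <- list()
  add_tx <- function(id, str, s, e, cds_s, cds_e, xs, xe) {
    k <- length(ids) + 1L
    ids[[k]] <<- id; chrom[[k]] <<- "chr1"; strand[[k]] <<- str
    txs[[k]] <<- s; txe[[k]] <<- e; cs[[k]] <<- cds_s; ce[[k]] <<- cds_e
    es[[k]] <<- xs; ee[[k]] <<- xe
  }
  for (i in seq_len(config$n_genes)) {
    g <- gene_starts[i]
    str <- if (i %% 2L == 1L) "+" else "-"
    xs <- g + starts_rel; xe <- g + ends_rel
    cds_s <- g + config$cds_inset; cds_e <- g + gene_w - config$cds_inset
    add_tx(sprintf("t%03d_full", i), str, xs[1L], xe[length(xe)],
           cds_s, cds_e, xs, xe)
    if (config$transcripts_per_gene >= 2L)
      add_tx(sprintf("t%03d_skip", i), str, xs[1L], xe[length(xe)],
             cds_s, cds_e, xs[-2L], xe[-2L])
    if (config$transcripts_per_gene >= 3L) {
      k <- config$n_exons - 1L
      add_tx(sprintf("t%03d_alt", i), str, xs[1L], xe[k],
             cds_s, min(cds_e, xe[k]), xs[seq_len(k)], xe[seq_len(k)])
    }
  }
  # UTR-overlap decoy pair: exons overlap in [decoy+250, decoy+300), which
  # is untranslated in both genes.  Only present when multi-gene probes are
  # planted there.
  if (p[["multi_gene"]] > 0L) {
    add_tx("decoyA", "+", decoy, decoy + 300L, decoy, decoy + 200L,
           decoy, decoy + 300L)
    add_tx("decoyB", "+", decoy + 250L, decoy + 550L, decoy + 350L,
           decoy + 550L, decoy + 250L, decoy + 550L)
  }

  n <- length(ids)
  src <- rep_len(c("GENBANK", "REFSEQ", "ENSEMBL"), n)
  full <- transcript_collection(unlist(ids), src, unlist(chrom),
                                unlist(strand), unlist(txs), unlist(txe),
                                unlist(cs), unlist(ce), es, ee,
                                name = "simulated_full")
  views <- lapply(names(config$dropout), function(db) {
    keep <- stats::runif(n) >= config$dropout[[db]]
    v <- full[keep, , drop = FALSE]
    v$source_db <- rep_len(db, nrow(v))
    transcript_collection(v$transcript_id, v$source_db, v$chrom, v$strand,
                          v$tx_start, v$tx_end, v$cds_start, v$cds_end,
                          v$exon_starts, v$exon_ends, name = db)
  })
  names(views) <- names(config$dropout)

  gseq <- random_dna(genome_len)
  genome <- Biostrings::DNAStringSet(stats::setNames(gseq, "chr1"))

  truth <- lapply(stats::setNames(LINKAGE_METHODS, LINKAGE_METHODS),
                  function(m) {
    comp <- components_naive(full, m)
    canon <- match(comp, unique(comp))
    list(n_genes = length(unique(canon)),
         membership = stats::setNames(canon, full$transcript_id))
  })

  layout <- list(dupA = dupA, dupB = dupB, dup_w = dup_w,
                 izone = izone, iz_w = iz_w,
                 gene_starts = gene_starts, gene_w = gene_w,
                 starts_rel = starts_rel, ends_rel = ends_rel,
                 decoy = decoy, genome_len = genome_len)
  out <- list(genome = genome, transcripts = full, collections = views,
              truth = truth, layout = layout, config = config)
  class(out) <- "sim_annotation"
  out
}

# Split a planted count into group sizes within [lo, hi].
chunk_sizes <- function(total, lo, hi) {
  if (total == 0L) return(integer(0))
  if (total < lo) stop("cannot form a group of at least ", lo,
                       " from ", total, " probes")
  k <- total %/% lo
  sizes <- rep(lo, k)
  rem <- total - sum(sizes)
  i <- 1L
  while (rem > 0L) {
    add <- min(rem, hi - sizes[i])
    sizes[i] <- sizes[i] + add
    rem <- rem - add
    i <- i + 1L
    if (i > length(sizes) && rem > 0L) stop("group size limits infeasible")
  }
  sizes
}

#' Plant probes with known remapping categories
#'
#' Constructs (never rejection-samples) the exact numbers of probes
#' requested per category: duplicated-locus 25-mers (two genomic copies),
#' random non-genomic 25-mers, probes in the decoy genes' overlapping UTR
#' (multi-gene), intronic and intergenic probes, 1-2-probe orphan groups in
#' cassette exons, multi-probe groups in constitutive exons, and
#' exon-junction probes matching only spliced transcript sequence.  A
#' verification pass re-matches every probe against the genome and errors
#' if any planted invariant is violated.
#'
#' @param config a [sim_config()].
#' @param ann result of [simulate_annotation()] under the same config.
#' @param verify re-match all probes and check planted hit counts.
#' @return List (class `sim_probes`) with `probes` (data frame of
#'   `probe_id`, `sequence`), `truth` (per-probe planted category, plus a
#'   `rescued` flag for junction probes) and `expected_counts` (the
#'   category count vector [classify_and_group()] must reproduce under the
#'   config's `min_probes` and the coding-exon-overlap gene definition).
#' @export
simulate_probes <- function(config, ann, verify = TRUE) {
  stopifnot(inherits(config, "sim_config"), inherits(ann, "sim_annotation"))
  set.seed(config$seed + 1L)
  p <- config$planted
  lay <- ann$layout
  gseq <- as.character(ann$genome[[1L]])
  tc <- ann$transcripts
  exl <- config$exon_length

  seqs <- character(0); cats <- character(0); note <- character(0)
  rescued <- logical(0)
  take <- function(start0, n = 25L) substr(gseq, start0 + 1L, start0 + n)
  plant <- function(s, category, why, resc = FALSE) {
    seqs <<- c(seqs, s); cats <<- c(cats, category)
    note <<- c(note, why); rescued <<- c(rescued, resc)
  }

  # GOOD: groups in constitutive first exons, one gene per group.
  good_sizes <- chunk_sizes(p[["good"]], config$min_probes,
                            max(config$min_probes, (exl - 25L) %/% 30L + 1L))
  if (length(good_sizes) > config$n_genes)
    stop("planted good probes need more genes than configured")
  for (k in seq_along(good_sizes)) {
    g <- lay$gene_starts[k]
    for (j in seq_len(good_sizes[k])) {
      s0 <- g + (j - 1L) * 30L
      if (s0 + 25L > g + exl) stop("good probe exceeds exon")
      plant(take(s0), "GOOD", sprintf("gene%d/exon1", k))
    }
  }

  # Junction probes: cross the skip isoform's exon1-exon3 junction of gene 1.
  if (config$n_junction > 0L) {
    i <- match(sprintf("t%03d_skip", 1L), tc$transcript_id)
    xs <- tc$exon_starts[[i]]; xe <- tc$exon_ends[[i]]
    ex_seqs <- vapply(seq_along(xs), function(e)
      substr(gseq, xs[e] + 1L, xe[e]), character(1))
    spl <- paste(ex_seqs, collapse = "")
    if (tc$strand[i] == "-") spl <- reverse_complement_chr(spl)
    junction_at <- if (tc$strand[i] == "-") nchar(spl) - (xe[1L] - xs[1L])
                   else xe[1L] - xs[1L]
    for (j in seq_len(config$n_junction)) {
      left <- 12L + j                      # bases on the 5' side of the join
      if (left > 24L) stop("too many junction probes for one junction")
      s1 <- junction_at - left + 1L        # 1-based within spliced sequence
      plant(substr(spl, s1, s1 + 24L), "GOOD",
            sprintf("junction/%s", tc$transcript_id[i]), resc = TRUE)
    }
  }

  # Underpopulated: 1-2 probe orphan groups in cassette exons (signature =
  # the full-length isoform only, distinct from the good groups' signature).
  up_sizes <- chunk_sizes(p[["underpopulated"]], 1L,
                          min(2L, config$min_probes - 1L))
  if (length(up_sizes) > config$n_genes)
    stop("planted underpopulated groups need more genes than configured")
  for (k in seq_along(up_sizes)) {
    g <- lay$gene_starts[k] + lay$starts_rel[2L]
    for (j in seq_len(up_sizes[k]))
      plant(take(g + (j - 1L) * 30L), "UNDERPOPULATED_SET",
            sprintf("gene%d/exon2", k))
  }

  # Intronic: inside the first intron, within the gene span.
  if (p[["intronic"]] > 0L) {
    per_gene <- (config$intron_length - 35L) %/% 30L + 1L
    if (p[["intronic"]] > per_gene * config$n_genes)
      stop("planted intronic probes exceed intron capacity")
    for (j in seq_len(p[["intronic"]])) {
      k <- (j - 1L) %% config$n_genes + 1L
      slot <- (j - 1L) %/% config$n_genes
      s0 <- lay$gene_starts[k] + exl + 10L + slot * 30L
      plant(take(s0), "INTRONIC", sprintf("gene%d/intron1", k))
    }
  }

  # Intergenic: a reserved zone between the duplication scratch and genes.
  for (j in seq_len(p[["intergenic"]]))
    plant(take(lay$izone + (j - 1L) * 30L), "INTERGENIC", "izone")

  # Multi-gene: the decoys' overlapping UTR; footprint inside both exons.
  if (p[["multi_gene"]] > 0L) {
    if (p[["multi_gene"]] > 6L)
      stop("at most 6 multi-gene probes fit the decoy UTR overlap")
    for (j in seq_len(p[["multi_gene"]]))
      plant(take(lay$decoy + 250L + (j - 1L) * 5L), "MULTI_GENE", "decoyUTR")
  }

  # Multi-genome: copy 25-mers from scratch region A into scratch region B.
  if (p[["multi_genome"]] > 0L) {
    for (j in seq_len(p[["multi_genome"]])) {
      off <- (j - 1L) * 30L
      s <- take(lay$dupA + off)
      substr(gseq, lay$dupB + off + 1L, lay$dupB + off + 25L) <- s
      plant(s, "MULTI_GENOME", "dup")
    }
  }

  # No-genome: random 25-mers (verified absent below).
  for (j in seq_len(p[["no_genome"]]))
    plant(random_dna(25L), "NO_GENOME", "random")

  genome <- Biostrings::DNAStringSet(stats::setNames(gseq, "chr1"))
  probes <- data.frame(
    probe_id = sprintf("p%04d", seq_along(seqs)),
    sequence = seqs, stringsAsFactors = FALSE)
  truth <- data.frame(probe_id = probes$probe_id, category = cats,
                      note = note, rescued = rescued,
                      stringsAsFactors = FALSE)

  if (verify && nrow(probes)) {
    hits <- match_probes(probes, genome)
    cnt <- table(factor(hits$probe_id, levels = probes$probe_id))
    expect_n <- ifelse(cats == "MULTI_GENOME", 2L,
                ifelse(cats == "NO_GENOME" | rescued, 0L, 1L))
    if (!all(as.integer(cnt) == expect_n))
      stop("planted probe hit counts violated (astronomically unlikely ",
           "sequence collision); change the seed")
    if (anyDuplicated(probes$sequence))
      stop("planted probe sequences collide; change the seed")
  }

  expected <- c(MULTI_GENOME = unname(p[["multi_genome"]]),
                NO_GENOME = unname(p[["no_genome"]]),
                MULTI_GENE = unname(p[["multi_gene"]]),
                INTERGENIC = unname(p[["intergenic"]]),
                INTRONIC = unname(p[["intronic"]]),
                UNDERPOPULATED_SET = unname(p[["underpopulated"]]),
                GOOD = unname(p[["good"]]) + config$n_junction)
  out <- list(probes = probes, truth = truth, expected_counts = expected,
              genome = genome)
  class(out) <- "sim_probes"
  out
}

#' Simulate a probe-set expression matrix with planted splicing
#'
#' Per-gene baseline intensities are log-normal; within a gene every probe
#' set shares the gene baseline (balanced isoform abundance), so a planted
#' fold change on one probe set translates into a Splicing Index of
#' `log2((1 + fold) / 2)` for two-set genes at zero noise.  Alternatively
#' spliced genes get their last probe set multiplied by `fold` in the
#' second condition; replicates receive multiplicative log-normal noise
#' `exp(N(0, sigma^2))`.
#'
#' @param config a [sim_config()]; see the `expression` element.
#' @param mapping optional data frame (`probe_set_id`, `gene_id`) or a
#'   `remapping_result`; when omitted, a nominal mapping of
#'   `expression$n_genes` genes with `expression$n_sets_per_gene` probe
#'   sets each is synthesized.
#' @return List (class `sim_expression`) with `expr` (matrix), `conditions`,
#'   `mapping` and `truth` (per-gene AS status, fold and affected set).
#' @export
simulate_expression <- function(config, mapping = NULL) {
  stopifnot(inherits(config, "sim_config"))
  e <- config$expression
  set.seed(config$seed + 2L)
  if (inherits(mapping, "remapping_result"))
    mapping <- mapping$probe_sets[, c("probe_set_id", "gene_id")]
  if (is.null(mapping)) {
    gid <- sprintf("simg%04d", seq_len(e$n_genes))
    mapping <- data.frame(
      probe_set_id = paste0(rep(gid, each = e$n_sets_per_gene), "_",
                            seq_len(e$n_sets_per_gene)),
      gene_id = rep(gid, each = e$n_sets_per_gene),
      stringsAsFactors = FALSE)
  }
  genes <- unique(mapping$gene_id)
  sets_of <- split(mapping$probe_set_id, mapping$gene_id)[genes]
  multi <- genes[lengths(sets_of) >= 2L]
  n_as <- round(e$as_fraction * length(multi))
  as_genes <- if (n_as > 0L) sort(sample(multi, n_as)) else character(0)
  affected <- vapply(sets_of[as_genes], function(s) s[length(s)],
                     character(1))

  baseline <- stats::setNames(
    stats::rlnorm(length(genes), e$baseline_meanlog, e$baseline_sdlog),
    genes)
  n_rep <- e$n_replicates
  samples <- paste0("s", seq_len(2L * n_rep))
  conditions <- rep(c("c1", "c2"), each = n_rep)
  expr <- matrix(NA_real_, nrow = nrow(mapping), ncol = 2L * n_rep,
                 dimnames = list(mapping$probe_set_id, samples))
  fold_of <- rep(1, nrow(mapping))
  fold_of[mapping$probe_set_id %in% affected] <- e$fold
  for (j in seq_len(2L * n_rep)) {
    mu <- baseline[mapping$gene_id]
    if (conditions[j] == "c2") mu <- mu * fold_of
    noise <- if (e$sigma > 0) exp(stats::rnorm(nrow(mapping), 0, e$sigma))
             else 1
    expr[, j] <- mu * noise
  }
  truth <- data.frame(
    gene_id = genes,
    as = genes %in% as_genes,
    fold = ifelse(genes %in% as_genes, e$fold, 1),
    affected_set = ifelse(genes %in% as_genes,
                          unname(affected[match(genes, names(affected))]),
                          NA_character_),
    n_probe_sets = lengths(sets_of)[genes],
    stringsAsFactors = FALSE)
  out <- list(expr = expr, conditions = conditions, mapping = mapping,
              truth = truth)
  class(out) <- "sim_expression"
  out
}
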