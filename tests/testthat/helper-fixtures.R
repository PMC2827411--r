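# Shared fixture builders.  Everything is generated in code; no binary data.

# Hand-built transcript: exons as list of c(start, end) pairs.
mk_tx <- function(id, exons, cds = NULL, chrom = "chr1", strand = "+",
                  source_db = "OTHER") {
  es <- vapply(exons, `[[`, numeric(1), 1L)
  ee <- vapply(exons, `[[`, numeric(1), 2L)
  if (is.null(cds)) cds <- c(min(es), max(ee))
  list(transcript_id = id, source_db = source_db, chrom = chrom,
       strand = strand, tx_start = min(es), tx_end = max(ee),
       cds_start = cds[1L], cds_end = cds[2L],
       exon_starts = es, exon_ends = ee)
}

mk_collection <- function(..., name = "test") {
  txs <- list(...)
  transcript_collection(
    vapply(txs, `[[`, character(1), "transcript_id"),
    vapply(txs, `[[`, character(1), "source_db"),
    vapply(txs, `[[`, character(1), "chrom"),
    vapply(txs, `[[`, character(1), "strand"),
    vapply(txs, `[[`, numeric(1), "tx_start"),
    vapply(txs, `[[`, numeric(1), "tx_end"),
    vapply(txs, `[[`, numeric(1), "cds_start"),
    vapply(txs, `[[`, numeric(1), "cds_end"),
    lapply(txs, `[[`, "exon_starts"), lapply(txs, `[[`, "exon_ends"),
    name = name)
}

# Random toy transcript collections for the clustering oracle and the
# coarseness-ordering property: dense enough to force overlaps.
random_transcript_collection <- function(n, seed, n_chrom = 4L,
                                         span = 4000L) {
  set.seed(seed)
  chrom <- sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tx_start <- sample.int(span, n, replace = TRUE)
  es <- vector("list", n); ee <- vector("list", n)
  cs <- ce <- txe <- integer(n)
  for (i in seq_len(n)) {
    k <- sample.int(4L, 1L)
    s <- tx_start[i]; xs <- integer(k); xe <- integer(k)
    for (e in seq_len(k)) {
      xs[e] <- s
      xe[e] <- s + sample(50:300, 1L)
      s <- xe[e] + sample(20:200, 1L)
    }
    es[[i]] <- xs; ee[[i]] <- xe; txe[i] <- xe[k]
    if (stats::runif(1) < 0.15) {
      cs[i] <- ce[i] <- tx_start[i]            # non-coding
    } else {
      cs[i] <- xs[1L] + sample(0:40, 1L)
      ce[i] <- xe[k] - sample(0:40, 1L)
      if (cs[i] >= ce[i]) { cs[i] <- tx_start[i]; ce[i] <- txe[i] }
    }
  }
  transcript_collection(sprintf("t%03d", seq_len(n)), "OTHER", chrom,
                        strand, tx_start, txe, cs, ce, es, ee,
                        name = paste0("random", seed))
}

# Canonical representation of a clustering: list of sorted member sets,
# ordered by first member, independent of gene IDs.
partition_of <- function(gm) {
  p <- lapply(gm$transcript_ids, sort)
  unname(p[order(vapply(p, `[[`, character(1), 1L))])
}

# Membership-vector version for comparing against simulation truth.
partition_from_membership <- function(membership) {
  p <- lapply(split(names(membership), membership), sort)
  unname(p[order(vapply(p, `[[`, character(1), 1L))])
}

# One small end-to-end remapping fixture, built once per test run.
pipeline_fixture <- local({
  cache <- NULL
  function(seed = 11L) {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(seed = seed)
    ann <- simulate_annotation(cfg)
    sim <- simulate_probes(cfg, ann)
    genes <- cluster_transcripts(ann$transcripts, "exlink")
    hits <- match_probes(sim$probes, sim$genome)
    unmatched <- sim$probes[!sim$probes$probe_id %in% hits$probe_id, ,
                            drop = FALSE]
    hits <- rbind(hits,
                  rescue_junction_probes(unmatched, ann$transcripts,
                                         sim$genome))
    res <- classify_and_group(sim$probes, hits, genes, ann$transcripts)
    cache <<- list(cfg = cfg, ann = ann, sim = sim, genes = genes,
                   hits = hits, res = res)
    cache
  }
})

# Independent step-up FDR oracle for cross-checking bh_adjust.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(n)
  running <- 1
  for (k in seq_along(o)) {
    i <- o[k]
    rank <- n - k + 1L
    running <- min(running, p[i] * n / rank)
    adj[i] <- running
  }
  adj
}
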