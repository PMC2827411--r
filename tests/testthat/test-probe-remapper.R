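# A small deterministic genome for the matcher tests.
toy_genome <- function(len = 2000L, seed = 99L) {
  set.seed(seed)
  Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")))
}

gslice <- function(genome, start0, n = 25L)
  as.character(Biostrings::subseq(genome[[1]], start0 + 1L, start0 + n))

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

test_that("exact genomic matching reports both strands and every locus", {
  g <- toy_genome()
  probes <- data.frame(
    probe_id = c("fwd", "rev", "none"),
    sequence = c(gslice(g, 100L), revcomp(gslice(g, 200L)),
                 paste(rep("ACGTT", 5L), collapse = "")),
    stringsAsFactors = FALSE)
  hits <- match_probes(probes, g)
  fwd <- hits[hits$probe_id == "fwd", ]
  expect_equal(fwd[, c("chrom", "strand", "start", "end")],
               data.frame(chrom = "chr1", strand = "+", start = 100L,
                          end = 125L), ignore_attr = TRUE)
  rev <- hits[hits$probe_id == "rev", ]
  expect_equal(rev$strand, "-")
  expect_equal(rev$start, 200L)
  expect_false("none" %in% hits$probe_id)

  # A probe planted at two loci yields two hits.
  gs <- as.character(g[[1]])
  substr(gs, 501L, 525L) <- gslice(g, 100L)
  g2 <- Biostrings::DNAStringSet(c(chr1 = gs))
  hits2 <- match_probes(probes[1L, ], g2)
  expect_equal(nrow(hits2), 2L)
  expect_setequal(hits2$start, c(100L, 500L))
})

test_that("probes with non-nucleotide characters are rejected with a warning", {
  g <- toy_genome()
  probes <- data.frame(probe_id = c("ok", "bad"),
                       sequence = c(gslice(g, 0L),
                                    sub("^.", "N", gslice(g, 50L))),
                       stringsAsFactors = FALSE)
  expect_warning(hits <- match_probes(probes, g), "non-ACGT")
  expect_equal(hits$probe_id, "ok")
  expect_error(match_probes(data.frame(probe_id = "short", sequence = "ACGT"),
                            g), "25 bases")
})

# Two-gene fixture with a shared junction: t1/t2 in gene A (t2 skips the
# middle exon), t3 in gene B with the same skip-junction sequence absent.
junction_fixture <- function(seed = 7L) {
  g <- toy_genome(4000L, seed)
  t1 <- mk_tx("t1", list(c(100, 300), c(500, 700), c(900, 1100)),
              cds = c(150, 1050))
  t2 <- mk_tx("t2", list(c(100, 300), c(900, 1100)), cds = c(150, 1050))
  t3 <- mk_tx("t3", list(c(2000, 2200), c(2400, 2600)), cds = c(2050, 2550))
  tc <- mk_collection(t1, t2, t3)
  genes <- cluster_transcripts(tc, "exlink")
  list(g = g, tc = tc, genes = genes)
}

test_that("junction rescue matches spliced but not genomic sequence", {
  fx <- junction_fixture()
  # 13 bases from the end of t2's first exon + 12 from its last exon.
  jseq <- paste0(gslice(fx$g, 300L - 13L, 13L), gslice(fx$g, 900L, 12L))
  probes <- data.frame(probe_id = "jp", sequence = jseq,
                       stringsAsFactors = FALSE)
  expect_equal(nrow(match_probes(probes, fx$g)), 0L)
  hits <- rescue_junction_probes(probes, fx$tc, fx$g)
  expect_equal(hits$transcript_id, "t2")
  expect_equal(hits$match_type, "SPLICED")
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, 287L)   # leftmost genomic base of the footprint
})

test_that("signatures are all transcripts whose exons contain the footprint", {
  fx <- junction_fixture()
  tx2 <- fx$tc
  # Inside the constitutive first exon: both t1 and t2.
  h_const <- data.frame(probe_id = "p", chrom = "chr1", strand = "+",
                        start = 150L, end = 175L, match_type = "GENOMIC",
                        transcript_id = NA_character_,
                        stringsAsFactors = FALSE)
  sig <- assign_signature(h_const, fx$genes, tx2)
  expect_equal(sig$signature, c("t1", "t2"))
  expect_equal(sig$sense, "SENSE")
  expect_equal(length(sig$gene_ids), 1L)

  # Inside the cassette exon: t1 only.
  h_cass <- transform(h_const, start = 550L, end = 575L)
  expect_equal(assign_signature(h_cass, fx$genes, tx2)$signature, "t1")

  # Straddling the exon/intron edge (13 exonic bases): contained nowhere.
  h_edge <- transform(h_const, start = 288L, end = 313L)
  expect_null(assign_signature(h_edge, fx$genes, tx2))

  # Minus-strand placement in the constitutive exon: antisense signature.
  h_rc <- transform(h_const, strand = "-")
  expect_equal(assign_signature(h_rc, fx$genes, tx2)$sense, "ANTISENSE")
})

test_that("classification follows the precedence cascade on a planted fixture", {
  fx <- pipeline_fixture()
  got <- stats::setNames(fx$res$accounting$count, fx$res$accounting$category)
  expect_identical(got[names(fx$sim$expected_counts)],
                   fx$sim$expected_counts)
  expect_equal(attr(fx$res$accounting, "total"), nrow(fx$sim$probes))

  # Per-probe classes match the planted truth.
  merged <- merge(fx$res$probes, fx$sim$truth, by = "probe_id")
  expect_true(all(merged$class == merged$category))

  # Junction probes were classified through rescue, not genomic matching.
  resc <- merged$probe_id[merged$rescued]
  expect_true(all(merged$class[merged$probe_id %in% resc] == "GOOD"))
})

test_that("probes matching junctions of two genes are multi-gene", {
  fx <- junction_fixture()
  # Plant the t2 junction sequence also across t3's junction.
  gs <- as.character(fx$g[[1]])
  left <- substr(gs, 288L, 300L)
  right <- substr(gs, 901L, 912L)
  substr(gs, 2188L, 2200L) <- left
  substr(gs, 2401L, 2412L) <- right
  g2 <- Biostrings::DNAStringSet(c(chr1 = gs))
  probes <- data.frame(probe_id = "jp", sequence = paste0(left, right),
                       stringsAsFactors = FALSE)
  expect_equal(nrow(match_probes(probes, g2)), 0L)
  hits <- rescue_junction_probes(probes, fx$tc, g2)
  expect_setequal(hits$transcript_id, c("t2", "t3"))
  res <- classify_and_group(probes, hits, fx$genes, fx$tc)
  expect_equal(res$probes$class, "MULTI_GENE")
})

test_that("disabling the minimum-probe rule promotes orphan groups to good", {
  fx <- pipeline_fixture()
  res1 <- classify_and_group(fx$sim$probes, fx$hits, fx$genes,
                             fx$ann$transcripts, min_probes = 1L)
  acc1 <- stats::setNames(res1$accounting$count, res1$accounting$category)
  expect_equal(acc1[["UNDERPOPULATED_SET"]], 0L)
  expect_equal(acc1[["GOOD"]],
               fx$sim$expected_counts[["GOOD"]] +
                 fx$sim$expected_counts[["UNDERPOPULATED_SET"]])

  # Raising min_probes never increases the good count; counts always sum.
  prev <- Inf
  for (mp in c(1L, 3L, 5L, 10L)) {
    r <- classify_and_group(fx$sim$probes, fx$hits, fx$genes,
                            fx$ann$transcripts, min_probes = mp)
    good <- r$accounting$count[r$accounting$category == "GOOD"]
    expect_lte(good, prev)
    expect_equal(sum(r$accounting$count), nrow(fx$sim$probes))
    prev <- good
  }
})

test_that("no probe belongs to two probe sets and output is order-stable", {
  fx <- pipeline_fixture()
  all_members <- unlist(fx$res$probe_sets$probe_ids)
  expect_equal(anyDuplicated(all_members), 0L)

  # Permuting the probe input leaves classes and set memberships unchanged.
  set.seed(1)
  perm <- fx$sim$probes[sample.int(nrow(fx$sim$probes)), , drop = FALSE]
  res_perm <- classify_and_group(perm, fx$hits, fx$genes,
                                 fx$ann$transcripts)
  a <- fx$res$probes[order(fx$res$probes$probe_id), ]
  b <- res_perm$probes[order(res_perm$probes$probe_id), ]
  expect_equal(a$class, b$class)
  expect_equal(a$probe_set_id, b$probe_set_id)
})

test_that("antisense sets are flagged _RC and can be dropped", {
  fx <- pipeline_fixture()
  sets <- fx$res$probe_sets
  expect_true(all(grepl("_RC$", sets$probe_set_id[sets$sense == "ANTISENSE"])))
  expect_false(any(grepl("_RC$", sets$probe_set_id[sets$sense == "SENSE"])))

  res_drop <- classify_and_group(fx$sim$probes, fx$hits, fx$genes,
                                 fx$ann$transcripts, keep_antisense = FALSE)
  expect_equal(sum(res_drop$probe_sets$sense == "ANTISENSE"), 0L)
  expect_equal(sum(res_drop$accounting$count), nrow(fx$sim$probes))
})

test_that("remapping comparison distinguishes same, split and unique genes", {
  fx <- pipeline_fixture()
  cmp <- compare_remappings(fx$res, fx$res)
  expect_equal(unname(cmp$counts["same"]),
               length(unique(fx$res$probe_sets$gene_id)))
  expect_equal(unname(cmp$counts[c("diff", "unique_a", "unique_b")]),
               c(0L, 0L, 0L))

  # Split one 3-probe set into 2+1 in result b: that gene becomes DIFF.
  b <- fx$res
  big <- which(b$probe_sets$n_probes >= 3L)[1L]
  victim <- b$probe_sets$probe_set_id[big]
  members <- b$probe_sets$probe_ids[[big]]
  newset <- paste0(victim, "b")
  b$probe_sets <- rbind(b$probe_sets[-big, ],
                        transform(b$probe_sets[big, ], n_probes = 2L),
                        transform(b$probe_sets[big, ],
                                  probe_set_id = newset, n_probes = 1L))
  n <- nrow(b$probe_sets)
  b$probe_sets$probe_ids[[n - 1L]] <- members[1:2]
  b$probe_sets$probe_ids[[n]] <- members[3L]
  move <- b$probes$probe_id %in% members[3L]
  b$probes$probe_set_id[move] <- newset
  cmp2 <- compare_remappings(fx$res, b)
  expect_equal(unname(cmp2$counts["diff"]), 1L)
  expect_equal(unname(cmp2$counts["same"]), unname(cmp$counts["same"]) - 1L)

  # Remove a gene's probes from b entirely: unique to a.
  b2 <- fx$res
  gene_gone <- b2$probe_sets$gene_id[1L]
  gone_sets <- b2$probe_sets$probe_set_id[b2$probe_sets$gene_id == gene_gone]
  b2$probes$class[b2$probes$probe_set_id %in% gone_sets] <- "INTERGENIC"
  b2$probes$probe_set_id[b2$probes$probe_set_id %in% gone_sets] <- NA
  b2$probe_sets <- b2$probe_sets[b2$probe_sets$gene_id != gene_gone, ]
  cmp3 <- compare_remappings(fx$res, b2)
  expect_equal(unname(cmp3$counts["unique_a"]), 1L)

  bad <- fx$res
  bad$probes <- bad$probes[-1L, ]
  expect_error(compare_remappings(fx$res, bad), "universe")
})

test_that("probe-set files round-trip and accounting labels are canonical", {
  fx <- pipeline_fixture()
  dir <- withr::local_tempdir()
  paths <- write_probeset_files(fx$res, dir)
  expect_equal(nrow(utils::read.delim(paths[["definitions"]],
                                      comment.char = "#")),
               sum(fx$res$probes$class == "GOOD"))

  back <- read_probeset_defs(paths[["definitions"]])
  expect_equal(back$probe_sets$probe_set_id, fx$res$probe_sets$probe_set_id)
  expect_equal(back$probe_sets$signature, fx$res$probe_sets$signature)
  expect_identical(back$probe_sets$probe_ids, fx$res$probe_sets$probe_ids,
                   ignore_attr = TRUE)

  acc <- utils::read.delim(paths[["accounting"]], comment.char = "#",
                           stringsAsFactors = FALSE)
  expect_equal(acc$label[1:7],
               c("Probes with multiple alignments to the genome",
                 "Probes with no alignment to the genome",
                 "Probes matching multiple genes",
                 "Probes matching intergenic region",
                 "Probes matching intron region",
                 "< 3 probes per probe set",
                 "Good probes"))

  # Byte-identical re-emission.
  dir2 <- withr::local_tempdir()
  paths2 <- write_probeset_files(fx$res, dir2)
  for (k in names(paths))
    expect_identical(readLines(paths[[k]]), readLines(paths2[[k]]))
})
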