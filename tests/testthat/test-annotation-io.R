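test_that("genePred lines map to transcript records field by field", {
  line <- "t1\tchr1\t+\t100\t200\t100\t200\t1\t100,\t200,"
  tc <- parse_genepred(c(line, ""), source_db = "REFSEQ")
  expect_equal(nrow(tc), 1L)
  expect_equal(tc$transcript_id, "t1")
  expect_equal(tc$exon_starts[[1]], 100L)
  expect_equal(tc$exon_ends[[1]], 200L)
  expect_equal(tc$cds_start, 100L)
  expect_equal(tc$cds_end, 200L)
  expect_equal(tc$source_db, "REFSEQ")

  # 15-field extended dialect: extra columns ignored.
  ext <- paste(c("t2\tchr1\t-\t0\t500\t50\t450\t2\t0,300,\t100,500,",
                 "0", "gene2", "cmpl", "cmpl", "0,1,"), collapse = "\t")
  tc2 <- parse_genepred(c(ext, ""))
  expect_equal(tc2$exon_starts[[1]], c(0L, 300L))
})

test_that("malformed genePred input is rejected with the offending line", {
  two_starts <- "t1\tchr1\t+\t0\t400\t0\t400\t2\t0,200,300,\t100,400,"
  expect_error(parse_genepred(c(two_starts, "")), "line 1")
  expect_error(parse_genepred(c("t1\tchr1\t+\tX\t200\t100\t200\t1\t100,\t200,",
                                "")), "non-integer")
  expect_error(parse_genepred(c("t1\tchr1\t+\t300\t200\t300\t300\t1\t100,\t200,",
                                "")), "txStart")
  line <- "t1\tchr1\t+\t100\t200\t100\t200\t1\t100,\t200,"
  expect_error(parse_genepred(c(line, line)), "duplicate")
})

test_that("genePred serializer and parser round-trip random collections", {
  for (seed in c(3L, 17L)) {
    tc <- random_transcript_collection(40L, seed)
    f <- withr::local_tempfile(fileext = ".genepred")
    write_genepred(tc, f)
    back <- parse_genepred(f, source_db = "OTHER",
                           name = attr(tc, "name"))
    expect_equal(as.data.frame(back), as.data.frame(tc))
  }
})

psl_line <- function(matches, mism, qname = "q1", tname = "chr1",
                     tstart = 1000L, strand = "+") {
  size <- matches + mism
  paste(matches, mism, 0, 0, 0, 0, 0, 0, strand, qname, size, 0, size,
        tname, 100000, tstart, tstart + size, 1,
        paste0(size, ","), "0,", paste0(tstart, ","), sep = "\t")
}

test_that("PSL identity is matches over aligned bases and headers are skipped", {
  al <- parse_psl(c(psl_line(960L, 40L), ""))
  expect_equal(al$base_identity, 0.96)
  expect_equal(attr(al, "identity_convention"), "match_only")

  headered <- c("psLayout version 3", "",
                "match\tmis- \trep. ", "---------------",
                psl_line(960L, 40L))
  expect_equal(parse_psl(headered)$base_identity, 0.96)

  expect_equal(nrow(parse_psl(c("", ""))), 0L)
  bad <- paste(rep("1", 20L), collapse = "\t")
  expect_error(parse_psl(c(bad, "")), "21")
})

test_that("identity filter applies the 96% floor and near-best windows", {
  al <- parse_psl(c(psl_line(959L, 41L, "qA"),
                    psl_line(960L, 40L, "qB"), ""), source_db = "GENBANK")
  kept <- filter_transcript_alignments(al)
  expect_equal(kept$transcript_id, "qB")

  # RefSeq window 0.001: 0.9895 survives next to 0.990, 0.988 does not.
  refseq <- parse_psl(c(psl_line(9900L, 100L, "r1"),
                        psl_line(9895L, 105L, "r1", tstart = 5000L),
                        psl_line(9900L, 100L, "r2"),
                        psl_line(9880L, 120L, "r2", tstart = 5000L), ""),
                      source_db = "REFSEQ")
  kept <- filter_transcript_alignments(refseq)
  expect_setequal(kept$transcript_id[startsWith(kept$transcript_id, "r1")],
                  c("r1#1", "r1#2"))
  expect_equal(sum(startsWith(kept$transcript_id, "r2")), 1L)

  single <- parse_psl(c(psl_line(970L, 30L, "s1"), ""))
  expect_equal(filter_transcript_alignments(single)$transcript_id, "s1")

  al$source_db <- "GENBANK"
  expect_error(filter_transcript_alignments(al, near_best_window = c(REFSEQ = 0.001)),
               "window")
})

test_that("raising the identity floor never adds records and refiltering is stable", {
  set.seed(5)
  lines <- vapply(1:30, function(i) {
    m <- sample(930:1000, 1L)
    psl_line(m, 1000L - m, paste0("q", sample(1:10, 1L)),
             tstart = sample.int(50000L, 1L))
  }, character(1))
  al <- parse_psl(c(lines, ""), source_db = "GENBANK")
  prev <- Inf
  for (cut in c(0.94, 0.96, 0.98)) {
    kept <- filter_transcript_alignments(al, min_identity = cut)
    expect_lte(nrow(kept), prev)
    prev <- nrow(kept)
  }
})

test_that("integration unions collections and resolves ID collisions", {
  a <- random_transcript_collection(2L, 1L)
  b <- random_transcript_collection(3L, 2L)
  c3 <- random_transcript_collection(4L, 3L)
  b$transcript_id <- paste0("b", b$transcript_id)
  c3$transcript_id <- paste0("c", c3$transcript_id)
  merged <- integrate_collections(list(a, b, c3))
  expect_equal(nrow(merged), 9L)
  expect_gte(nrow(merged), max(nrow(a), nrow(b), nrow(c3)))

  dup <- a
  dup$source_db <- rep("REFSEQ", nrow(dup))
  a$source_db <- rep("GENBANK", nrow(a))
  both <- integrate_collections(list(
    transcript_collection(a$transcript_id, a$source_db, a$chrom, a$strand,
                          a$tx_start, a$tx_end, a$cds_start, a$cds_end,
                          a$exon_starts, a$exon_ends),
    transcript_collection(dup$transcript_id, dup$source_db, dup$chrom,
                          dup$strand, dup$tx_start, dup$tx_end,
                          dup$cds_start, dup$cds_end, dup$exon_starts,
                          dup$exon_ends)))
  expect_equal(nrow(both), 4L)
  expect_true(all(grepl("^(genbank|refseq):", both$transcript_id)))

  expect_equal(nrow(integrate_collections(list())), 0L)
})

test_that("cross-reference tables reject one-to-many transcript mappings", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tgene_id", "t1\tgA", "t2\tgA", "t3\tgB"), f)
  xref <- read_xref(f)
  expect_equal(unname(xref[c("t1", "t2", "t3")]), c("gA", "gA", "gB"))
  writeLines(c("transcript_id\tgene_id", "t1\tgA", "t1\tgB"), f)
  expect_error(read_xref(f), "more than one")
})
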