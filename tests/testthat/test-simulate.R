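test_that("the same seed reproduces every generator output exactly", {
  cfg <- sim_config(seed = 5L)
  a1 <- simulate_annotation(cfg); a2 <- simulate_annotation(cfg)
  expect_identical(as.character(a1$genome), as.character(a2$genome))
  expect_identical(as.data.frame(a1$transcripts),
                   as.data.frame(a2$transcripts))
  p1 <- simulate_probes(cfg, a1); p2 <- simulate_probes(cfg, a2)
  expect_identical(p1$probes, p2$probes)
  e1 <- simulate_expression(cfg); e2 <- simulate_expression(cfg)
  expect_identical(e1$expr, e2$expr)
  expect_identical(e1$truth, e2$truth)
})

test_that("an empty configuration yields empty collections", {
  cfg <- sim_config(seed = 1L, n_genes = 0L,
                    planted = c(multi_genome = 0L, no_genome = 2L,
                                multi_gene = 0L, intergenic = 2L,
                                intronic = 0L, underpopulated = 0L,
                                good = 0L),
                    n_junction = 0L)
  ann <- simulate_annotation(cfg)
  expect_equal(sum(!ann$transcripts$transcript_id %in%
                     c("decoyA", "decoyB")), 0L)
  cfg0 <- sim_config(seed = 1L)
  expect_error(sim_config(seed = 1L, n_genes = 0L), "n_genes > 0")
})

test_that("generator truth partitions agree with the clustering module", {
  ann <- simulate_annotation(sim_config(seed = 13L))
  for (m in c("exlink", "exbd", "itbd", "overlap_0")) {
    gm <- cluster_transcripts(ann$transcripts, m)
    expect_equal(nrow(gm), ann$truth[[m]]$n_genes)
    expect_identical(partition_of(gm),
                     partition_from_membership(ann$truth[[m]]$membership))
  }
  # The decoy pair separates the coding-exon rule from plain exon overlap.
  expect_equal(ann$truth$exlink$n_genes, ann$truth$overlap_0$n_genes + 1L)
})

test_that("planted probes respect their construction guarantees", {
  cfg <- sim_config(seed = 29L)
  ann <- simulate_annotation(cfg)
  sim <- simulate_probes(cfg, ann)
  hits <- match_probes(sim$probes, sim$genome)
  n_hits <- table(factor(hits$probe_id, levels = sim$probes$probe_id))
  tr <- sim$truth
  expect_true(all(n_hits[tr$category == "MULTI_GENOME"] == 2L))
  expect_true(all(n_hits[tr$category == "NO_GENOME"] == 0L))
  expect_true(all(n_hits[tr$rescued] == 0L))      # junction probes
  expect_true(all(n_hits[tr$category %in% c("INTRONIC", "INTERGENIC",
                                            "MULTI_GENE")] == 1L))

  # Zero planted no-genome probes propagate to a zero accounting row.
  cfg0 <- sim_config(seed = 29L,
                     planted = c(multi_genome = 2L, no_genome = 0L,
                                 multi_gene = 2L, intergenic = 2L,
                                 intronic = 2L, underpopulated = 2L,
                                 good = 6L), n_junction = 0L)
  ann0 <- simulate_annotation(cfg0)
  sim0 <- simulate_probes(cfg0, ann0)
  genes0 <- cluster_transcripts(ann0$transcripts, "exlink")
  res0 <- classify_and_group(sim0$probes,
                             match_probes(sim0$probes, sim0$genome),
                             genes0, ann0$transcripts)
  expect_equal(res0$accounting$count[res0$accounting$category == "NO_GENOME"],
               0L)
})

test_that("noise-free expression with a planted fold has closed-form SI", {
  cfg <- sim_config(seed = 4L, expression = list(
    n_genes = 30L, sigma = 0, fold = 4, as_fraction = 0.5))
  fx <- simulate_expression(cfg)
  sc <- splice_calls(fx$expr, fx$conditions, fx$mapping)
  si <- sc$calls
  as_genes <- fx$truth$gene_id[fx$truth$as]
  # Two balanced probe sets, one multiplied by f in condition 2:
  # unaffected set SI = log2((1+f)/2), affected set SI = log2((1+f)/(2f)).
  f <- 4
  for (g in as_genes) {
    rows <- si[si$gene_id == g, ]
    aff <- rows$probe_set_id == fx$truth$affected_set[fx$truth$gene_id == g]
    expect_equal(rows$SI[!aff], log2((1 + f) / 2), tolerance = 1e-9)
    expect_equal(rows$SI[aff], log2((1 + f) / (2 * f)), tolerance = 1e-9)
  }
  null_si <- si$SI[!si$gene_id %in% as_genes]
  expect_equal(null_si, rep(0, length(null_si)), tolerance = 1e-12)

  # fold = 1 with zero noise: every SI is exactly zero.
  cfg1 <- sim_config(seed = 4L, expression = list(
    n_genes = 10L, sigma = 0, fold = 1))
  fx1 <- simulate_expression(cfg1)
  sc1 <- splice_calls(fx1$expr, fx1$conditions, fx1$mapping)
  expect_equal(sc1$calls$SI, rep(0, nrow(sc1$calls)), tolerance = 1e-12)
})

test_that("configuration validation rejects infeasible requests", {
  expect_error(sim_config(planted = c(multi_genome = -1L, no_genome = 0L,
                                      multi_gene = 0L, intergenic = 0L,
                                      intronic = 0L, underpopulated = 0L,
                                      good = 3L)), ">= 0")
  expect_error(sim_config(n_junction = 2L), "n_junction")
  expect_error(sim_config(expression = list(sigma = -0.1)), "sigma")
  expect_error(sim_config(transcripts_per_gene = 1L), "isoforms")
  cfg <- sim_config(seed = 2L, n_genes = 2L)
  expect_error(simulate_probes(cfg, simulate_annotation(cfg)), "genes")
})
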