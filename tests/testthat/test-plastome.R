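test_that("composition statistics exclude ambiguity and sum to 100", {
  expect_equal(composition_stats("ATATAT")[["gc"]], 0)
  cs <- composition_stats("ACGTNNRY")
  expect_equal(cs[["gc"]] + cs[["at"]], 100)
  expect_equal(cs[["gc"]], 50)
  expect_error(composition_stats("NNNN"), "no countable bases")
})

test_that("IR detection recovers toy quadripartite structure exactly", {
  set.seed(101)
  for (i in 1:25) {
    L <- sample(3000:6000, 1)
    S <- sample(800:2000, 1)
    I <- sample(1200:3500, 1)
    toy <- make_toy_plastome(L, S, I, seed = i)
    p <- detect_ir(toy$record, min_len = 1000, max_mismatch_rate = 0)
    expect_equal(p$ir_len, I)
    expect_equal(p$lsc_len, L)
    expect_equal(p$ssc_len, S)
    expect_equal(p$total_len, p$lsc_len + p$ssc_len + 2L * p$ir_len)
  }
})

test_that("a genome without a long repeat reports ir_len = 0", {
  set.seed(7)
  seq <- paste0(sample(NT, 8000, TRUE), collapse = "")
  rec <- plastome(seq, data.frame(gene = character(0), start = integer(0),
                                  end = integer(0), strand = character(0),
                                  kind = character(0)))
  p <- detect_ir(rec, min_len = 1000)
  expect_equal(p$ir_len, 0L)
  expect_equal(p$lsc_len, 8000L)
})

test_that("gene classification follows ORF structure and the editing whitelist", {
  feats <- data.frame(gene = "gX", start = 0L, end = 9L, strand = "+",
                      kind = "CDS", stringsAsFactors = FALSE)
  rec <- plastome("ATGAAATAACCCCC", feats, id = "r")
  expect_equal(classify_gene(rec, "gX"), "intact")
  expect_equal(classify_gene(rec, "missing_gene"), "absent")
  # internal stop -> pseudogene
  rec2 <- plastome("ATGTAAAAATAACC",
                   data.frame(gene = "gX", start = 0L, end = 12L,
                              strand = "+", kind = "CDS"))
  expect_equal(classify_gene(rec2, "gX"), "pseudogene")
  # ACG start rescued only for whitelisted genes
  rec3 <- plastome("ACGAAATAACC",
                   data.frame(gene = "rpl2", start = 0L, end = 9L,
                              strand = "+", kind = "CDS"))
  expect_equal(classify_gene(rec3, "rpl2", editing_whitelist = "rpl2"),
               "intact")
  expect_equal(classify_gene(rec3, "rpl2", editing_whitelist = character(0)),
               "pseudogene")
  # toy operators drive classification end to end
  toy <- make_toy_plastome(5000, 1200, 1500, gene_order = c("rps2", "rps18"),
                           seed = 3)
  expect_equal(classify_gene(toy$record, "rps2"), "intact")
  expect_equal(classify_gene(inject_internal_stop(toy$record, "rps2"),
                             "rps2"), "pseudogene")
  expect_equal(classify_gene(delete_gene(toy$record, "rps18"), "rps18"),
               "absent")
})

test_that("classification is invariant under rotation of a circular genome", {
  toy <- make_toy_plastome(5000, 1200, 1500, gene_order = c("rps2"), seed = 9)
  rec <- toy$record
  rot <- 1234L
  n <- nchar(rec$seq)
  rec2 <- rec
  rec2$seq <- paste0(substr(rec$seq, rot + 1L, n), substr(rec$seq, 1L, rot))
  rec2$features$start <- (rec2$features$start - rot) %% n
  rec2$features$end <- rec2$features$start +
    (rec$features$end - rec$features$start)
  expect_equal(classify_gene(rec2, "rps2"), classify_gene(rec, "rps2"))
})

test_that("the worked-example core gene set has the five expected genes", {
  gm <- thismia_gene_states()
  core <- core_gene_set(gm, thismia_complete_taxa())
  expect_setequal(core, c("accD", "rpl2", "rrn16", "rrn23", "trnE"))
  expect_length(core, 5L)
  # a pseudogene in one complete taxon excludes the gene
  st <- gm$states
  st["Thismia_puberula", "accD"] <- "pseudogene"
  gm2 <- gene_matrix(st, partial_taxa = gm$partial_taxa)
  expect_false("accD" %in% core_gene_set(gm2, thismia_complete_taxa()))
})

test_that("synteny-based absence inference needs both flanks on one contig", {
  gm <- thismia_gene_states()
  ref <- c("rrn16", "rrn23", "rps3", "rps8", "rps4", "rps12", "rps18", "accD")
  # rps3 and rps4 adjacent on the contig, rps8 missing between them
  gm2 <- infer_absence_by_synteny(gm, "Thismia_kelabitiana",
                                  c("rrn23", "rps3", "rps4", "rps12"), ref)
  expect_equal(gm2$states["Thismia_kelabitiana", "rps8"], "absent")
  # one flank unobserved (contig end): stays unsampled
  gm3 <- infer_absence_by_synteny(gm, "Thismia_kelabitiana",
                                  c("rps4", "rps12"), ref)
  expect_equal(gm3$states["Thismia_kelabitiana", "rps8"], "unsampled")
})
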