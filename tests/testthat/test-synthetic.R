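test_that("toy genes are deterministic per seed and differ across seeds", {
  g1 <- make_toy_gene(5); g2 <- make_toy_gene(5); g3 <- make_toy_gene(6)
  expect_identical(g1, g2)
  expect_false(identical(g1$genome_seq, g3$genome_seq))
})

test_that("two-exon minus-strand genes are strand-symmetric by construction", {
  gp <- make_toy_gene(9, n_exons = 2, strand = "+")
  gm <- make_toy_gene(9, n_exons = 2, strand = "-")
  expect_equal(transcript_seq(gm), transcript_seq(gp))
  plus_concat <- paste0(
    mapply(function(s, e) substr(gm$genome_seq, s + 1, e),
           gm$exon_starts, gm$exon_ends),
    collapse = "")
  expect_equal(transcript_seq(gm), revcomp(plus_concat))
})

test_that("generated genes satisfy the gene-model invariants in bulk", {
  for (i in 1:100) {
    g <- make_toy_gene(1000 + i, n_exons = 2 + i %% 4,
                       exon_len_range = c(60, 150),
                       intron_len_range = c(200, 600),
                       strand = if (i %% 2 == 0) "-" else "+")
    expect_s3_class(g, "gene_model")
    tx <- transcript_seq(g)
    expect_equal(substr(tx, 1, 3), "ATG")
    expect_true(substr(tx, nchar(tx) - 2, nchar(tx)) %in%
                  c("TAA", "TAG", "TGA"))
    expect_equal(nchar(tx) %% 3, 0)
    # no internal in-frame stops
    codons <- substring(tx, seq(1, nchar(tx) - 3, 3),
                        seq(3, nchar(tx) - 3, 3))
    expect_false(any(codons[-1] %in% c("TAA", "TAG", "TGA")))
    # canonical introns
    for (k in seq_len(n_exons(g) - 1)) {
      iseq <- pseudoexonr:::intron_seq_tx(g, k)
      expect_equal(substr(iseq, 1, 2), "GT")
      expect_equal(substr(iseq, nchar(iseq) - 1, nchar(iseq)), "AG")
    }
  }
})

test_that("infeasible generator constraints fail loudly", {
  expect_error(make_toy_gene(1, n_exons = 1), "n_exons")
  expect_error(make_toy_gene(1, intron_len_range = c(50, 100)),
               "deep-intronic")
  g <- make_toy_gene(2)
  expect_error(plant_pseudoexon_cassette(g, 1, pe_len = 10, depth = 300,
                                         mode = "donor-created"),
               "pe_len")
  expect_error(plant_pseudoexon_cassette(g, 1, pe_len = 87, depth = 400,
                                         mode = "donor-created",
                                         in_frame = TRUE, n_stops = 0,
                                         seed = 1),
               NA)
  expect_error(plant_pseudoexon_cassette(g, 1, pe_len = 88, depth = 400,
                                         mode = "donor-created",
                                         in_frame = TRUE),
               "divisible by 3")
  expect_error(plant_pseudoexon_cassette(g, 1, pe_len = 60, depth = 1e6,
                                         mode = "donor-created"),
               "does not fit")
})

test_that("a patient-2-shaped cassette records the expected truth geometry", {
  g <- make_toy_gene(404, n_exons = 3, exon_len_range = c(200, 400),
                     intron_len_range = c(7000, 9000))
  case <- plant_pseudoexon_cassette(g, 1, pe_len = 88, depth = 3164,
                                    mode = "donor-created", seed = 10)
  X <- case$truth$insertion_point_cds
  expect_equal(case$truth$hgvs_rna,
               sprintf("c.%d_%dins%d+3164_%d+3251", X, X + 1, X, X))
  expect_equal(span_length(case$truth$span), 88L)
  expect_equal(parse_ins_range(case$truth$hgvs_rna)$length, 88L)
  # variant at the first intronic base of the created donor GT
  expect_equal(case$variant$ref, "C")
  expect_equal(case$variant$alt, "G")
  expect_equal(case$truth$side, "donor-created")
})

test_that("the reference cassette is splice-dead and the mutant splice-ready", {
  for (mode in c("donor-created", "acceptor-created",
                 "donor-strengthened", "acceptor-strengthened")) {
    case <- local({
      g <- make_toy_gene(500, n_exons = 3)
      plant_pseudoexon_cassette(g, 1, pe_len = 66, depth = 300, mode = mode,
                                seed = 11)
    })
    sl <- case$truth$span_local
    ref_i <- pseudoexonr:::intron_seq_tx(case$gene, case$truth$intron_index)
    mut_i <- pseudoexonr:::mutant_intron_seq(case)
    mut_ok <- substr(mut_i, sl[["start"]] - 2, sl[["start"]] - 1) == "AG" &&
      substr(mut_i, sl[["end"]] + 1, sl[["end"]] + 2) == "GT"
    ref_ok <- substr(ref_i, sl[["start"]] - 2, sl[["start"]] - 1) == "AG" &&
      substr(ref_i, sl[["end"]] + 1, sl[["end"]] + 2) == "GT"
    expect_true(mut_ok, info = mode)
    if (grepl("created", mode)) {
      expect_false(ref_ok, info = mode)
    } else {
      expect_true(ref_ok, info = mode)  # strengthened: site exists, weaker
    }
  }
})

test_that("the spurious-donor scrub leaves no strong donor window outside the cassette", {
  g <- make_toy_gene(601, n_exons = 3, intron_len_range = c(4000, 8000))
  case <- plant_pseudoexon_cassette(g, 1, pe_len = 72, depth = 1500,
                                    mode = "donor-created", seed = 12,
                                    scrub_threshold = 85)
  iseq <- pseudoexonr:::intron_seq_tx(case$gene, case$truth$intron_index)
  fm <- ss_frequency_matrix("donor")
  sl <- case$truth$span_local
  gts <- gregexpr("GT", iseq, fixed = TRUE)[[1]]
  gts <- gts[gts - 3 >= 1 & gts + 5 <= nchar(iseq)]
  cassette <- seq(sl[["start"]] - 24, sl[["end"]] + 8)
  gts <- gts[!(gts %in% cassette | (gts + 1) %in% cassette)]
  if (length(gts)) {
    scores <- vapply(substring(iseq, gts - 3, gts + 5),
                     function(w) oracle_ss_percent(w, fm), numeric(1))
    expect_true(all(scores < 85))
  }
})

test_that("isoform simulation labels mixtures and conserves lengths", {
  g <- make_toy_gene(701, n_exons = 3)
  case <- plant_pseudoexon_cassette(g, 1, pe_len = 45, depth = 280,
                                    mode = "acceptor-created", seed = 13)
  solo <- simulate_transcripts(case, 0)
  expect_equal(nrow(solo), 1L)
  expect_equal(solo$label, "pseudoexon")
  expect_equal(nchar(solo$seq), tx_length(case$gene) + 45L)
  mix <- simulate_transcripts(case, 0.3)
  expect_equal(mix$label, c("pseudoexon", "normal"))
  expect_equal(mix$fraction, c(0.7, 0.3))
  expect_equal(mix$seq[2], transcript_seq(case$gene))
  expect_error(simulate_transcripts(case, 1), "fraction")
})

test_that("fixtures are byte-deterministic and reload to the same case", {
  g <- make_toy_gene(801, n_exons = 3, strand = "-")
  case <- plant_pseudoexon_cassette(g, 2, pe_len = 58, depth = 480,
                                    mode = "acceptor-created", seed = 14)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_fixtures(case, d1); p2 <- write_fixtures(case, d2)
  for (f in names(p1)) {
    expect_equal(unname(tools::md5sum(p1[[f]])),
                 unname(tools::md5sum(p2[[f]])), info = f)
  }
  back <- read_fixtures(d1, "TOY1")
  expect_equal(back$model$exon_starts, case$gene$exon_starts)
  expect_equal(back$model$genome_seq, case$gene$genome_seq)
  expect_equal(format_cdna_variant(back$variant),
               format_cdna_variant(case$variant))
  expect_equal(back$transcripts$seq[1], case$truth$mutant_transcript)
  expect_equal(back$truth$hgvs_dna, case$truth$hgvs_dna)
  # VCF record matches the mapped truth variant
  vcf <- readLines(p1[["vcf"]])
  rec <- strsplit(vcf[length(vcf)], "\t")[[1]]
  expect_equal(as.integer(rec[2]) - 1L,
               cdna_to_genomic(case$gene, case$variant$coord))
  # different seeds give different genomes
  case2 <- plant_pseudoexon_cassette(
    make_toy_gene(802, n_exons = 3, strand = "-"), 2, pe_len = 58,
    depth = 480, mode = "acceptor-created", seed = 15)
  expect_false(identical(case$gene$genome_seq, case2$gene$genome_seq))
})
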