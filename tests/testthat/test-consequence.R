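test_that("mutant transcripts splice the pseudoexon between the flanking exons", {
  for (strand in c("+", "-")) {
    g <- make_toy_gene(101, n_exons = 3, strand = strand)
    case <- plant_pseudoexon_cassette(g, 2, pe_len = 51, depth = 260,
                                      mode = "acceptor-created", seed = 6)
    call <- pseudoexon_call(case$truth$intron_index, case$truth$span,
                            NULL, NULL)
    mut <- build_mutant_transcript(case$gene, call)
    expect_equal(mut, case$truth$mutant_transcript)
    expect_equal(nchar(mut),
                 tx_length(case$gene) + span_length(case$truth$span))
  }
})

test_that("pseudoexon spans outside their intron are rejected", {
  g <- make_toy_gene(103, n_exons = 3)
  b <- pseudoexonr:::intron_bounds(g)
  bad <- pseudoexon_call(1L,
                         genomic_interval(g$chrom, b$start[1] - 5L,
                                          b$start[1] + 40L),
                         NULL, NULL)
  expect_error(build_mutant_transcript(g, bad), "outside its host intron")
  expect_error(genomic_interval(g$chrom, 10L, 10L), "start < end")
})

test_that("a pseudoexon entering in frame 0 with a leading stop is caught at offset 0", {
  # hand-built: reference CDS ATG AAA TAA, insertion after c.6 (codon
  # boundary), pseudoexon TAAGGG -> stop at offset 0
  mut <- paste0("ATGAAA", "TAAGGG", "TAA")
  stops <- find_premature_stops(mut, cds_start = 1, insertion_point = 6,
                                pe_len = 6)
  inside <- stops[stops$within_pseudoexon, ]
  expect_equal(inside$offset, 0L)
  expect_equal(inside$codon, "TAA")
})

test_that("stop scanning agrees with a naive frame-scan oracle on synthetic cases", {
  for (i in 1:10) {
    strand <- if (i %% 2 == 0) "-" else "+"
    g <- make_toy_gene(200 + i, n_exons = 3, strand = strand)
    case <- plant_pseudoexon_cassette(g, 1 + i %% 2, pe_len = 40 + 3 * i,
                                      depth = 300 + 10 * i,
                                      mode = "donor-created", seed = i)
    truth <- case$truth
    stops <- find_premature_stops(truth$mutant_transcript,
                                  case$gene$cds_start,
                                  truth$insertion_point_cds, truth$pe_len)
    inside <- stops$offset[stops$within_pseudoexon]
    oracle <- oracle_stops_in_pe(truth$mutant_transcript,
                                 case$gene$cds_start,
                                 truth$insertion_point_cds, truth$pe_len)
    expect_equal(inside, oracle)
    expect_equal(inside, truth$stop_offsets)
    if (length(inside) > 1) {
      expect_true(all(diff(inside) %% 3 == 0))
    }
  }
})

test_that("frameshift-start residues follow the floor rule and first-changed-residue naming", {
  expect_equal(frameshift_start_residue(3), 2L)
  expect_equal(frameshift_start_residue(1331), 444L)
  expect_equal(frameshift_start_residue(2803), 935L)
  expect_equal(frameshift_start_residue(5739), 1914L)
  g <- make_toy_gene(301, n_exons = 3)
  case <- plant_pseudoexon_cassette(g, 1, pe_len = 50, depth = 300,
                                    mode = "donor-created", seed = 7)
  fs <- frameshift_annotation(case$gene, case$truth$insertion_point_cds,
                              case$truth$mutant_transcript)
  expect_equal(fs$protein_hgvs, case$truth$hgvs_protein)
  expect_equal(fs$first_affected_residue,
               case$truth$first_affected_residue)
  expect_equal(fs$normal_residue_count, fs$first_affected_residue - 1L)
  expect_match(fs$protein_hgvs, "^p\\.[A-Z][a-z]{2}\\d+[A-Z][a-z]{2}fs$")
})

test_that("in-frame pseudoexons without stops are not called frameshifts", {
  g <- make_toy_gene(307, n_exons = 3)
  case <- plant_pseudoexon_cassette(g, 1, pe_len = 87, depth = 400,
                                    mode = "donor-created", in_frame = TRUE,
                                    seed = 8)
  expect_true(case$in_frame)
  cons <- consequence_report(
    case$gene, pseudoexon_call(case$truth$intron_index, case$truth$span,
                               NULL, NULL))
  expect_equal(cons$classification, "in-frame insertion, no PTC")
  expect_equal(cons$frame_shift, 0L)
  expect_length(cons$stop_offsets, 0L)
  expect_true(is.na(cons$protein_hgvs))
})

test_that("reported stop positions are frame coherent, including printed coordinates", {
  expect_true(stop_frame_coherent(c(1000, 1051, 1087)))
  expect_false(stop_frame_coherent(c(1000, 1052)))
  expect_true(stop_frame_coherent(c(5)))
})

test_that("case reports assemble, degrade without panels, and round-trip JSON", {
  g <- make_toy_gene(311, n_exons = 3)
  case <- plant_pseudoexon_cassette(g, 1, pe_len = 61, depth = 350,
                                    mode = "donor-created", seed = 9)
  an <- analyze_case(case$gene, case$truth$mutant_transcript,
                     patient_intron_seq = pseudoexonr:::mutant_intron_seq(case))
  rep1 <- an$report
  expect_equal(rep1$derivation,
               sprintf("Intron %d; %d nt", case$truth$intron_index,
                       case$truth$pe_len))
  expect_equal(rep1$dna, case$truth$hgvs_dna)
  expect_equal(rep1$rna, case$truth$hgvs_rna)
  expect_equal(rep1$protein, case$truth$hgvs_protein)
  # degraded mode: no panel
  expect_warning(
    rep2 <- render_case_report(an$call, NULL, an$consequence),
    "no score panel")
  expect_true(is.na(rep2$ss_percent_delta))
  # JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_case_report(rep1, path)
  back <- read_case_report(path)
  for (col in names(rep1)) {
    expect_equal(back[[col]], rep1[[col]], info = col, tolerance = 1e-12)
  }
})
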