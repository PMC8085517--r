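make_case <- function(seed = 3, strand = "+", mode = "donor-created",
                      pe_len = 88, depth = 400, k = 1) {
  g <- make_toy_gene(seed, n_exons = 3, strand = strand,
                     intron_len_range = c(1500, 2500))
  plant_pseudoexon_cassette(g, k, pe_len = pe_len, depth = depth,
                            mode = mode, seed = seed)
}

test_that("a planted cassette is located at exactly its planted interval", {
  for (strand in c("+", "-")) {
    case <- make_case(seed = 41, strand = strand)
    ev <- find_insertion(transcript_seq(case$gene),
                         case$truth$mutant_transcript)
    loc <- locate_in_intron(case$gene, ev)
    expect_equal(loc$intron_index, case$truth$intron_index)
    expect_length(loc$candidates, 1L)
    expect_equal(loc$candidates[[1]]$start, case$truth$span$start)
    expect_equal(loc$candidates[[1]]$end, case$truth$span$end)
    expect_true(is.na(loc$warning))
  }
})

test_that("a repeat-bearing intron yields multiple candidates, resolved by mutant AG...GT", {
  case <- make_case(seed = 43)
  truth <- case$truth
  g <- case$gene
  # duplicate the interior elsewhere in the same intron, far from the
  # cassette and without splice-ready flanks
  iseq <- pseudoexonr:::intron_seq_tx(g, truth$intron_index)
  dup_at <- truth$span_local[["end"]] + 150L
  stopifnot(dup_at + truth$pe_len < nchar(iseq) - 210L)
  substr(iseq, dup_at, dup_at + truth$pe_len - 1L) <- truth$interior
  # make sure the duplicate is NOT flanked by AG...GT
  substr(iseq, dup_at - 2L, dup_at - 1L) <- "CC"
  substr(iseq, dup_at + truth$pe_len, dup_at + truth$pe_len + 1L) <- "CC"
  g2 <- pseudoexonr:::replace_intron(g, truth$intron_index, iseq)
  ev <- find_insertion(transcript_seq(g2), truth$mutant_transcript)
  loc <- locate_in_intron(g2, ev)
  expect_length(loc$candidates, 2L)
  # mutant intron: apply the same duplication on the patient side
  mut_iseq <- iseq
  vloc <- pseudoexonr:::genomic_to_locus(g2, truth$variant_genomic)
  call <- resolve_candidates(g2, loc, variant = case$variant)
  expect_equal(call$span$start, truth$span$start)
  expect_equal(call$span$end, truth$span$end)
})

test_that("two splice-ready candidates surface as ambiguity, not a guess", {
  case <- make_case(seed = 47)
  truth <- case$truth
  g <- case$gene
  iseq <- pseudoexonr:::intron_seq_tx(g, truth$intron_index)
  dup_at <- truth$span_local[["end"]] + 150L
  substr(iseq, dup_at, dup_at + truth$pe_len - 1L) <- truth$interior
  substr(iseq, dup_at - 2L, dup_at - 1L) <- "AG"
  substr(iseq, dup_at + truth$pe_len, dup_at + truth$pe_len + 1L) <- "GT"
  g2 <- pseudoexonr:::replace_intron(g, truth$intron_index, iseq)
  ev <- find_insertion(transcript_seq(g2), truth$mutant_transcript)
  loc <- locate_in_intron(g2, ev)
  expect_length(loc$candidates, 2L)
  expect_error(resolve_candidates(g2, loc, variant = case$variant),
               "ambiguous placement")
})

test_that("inserts absent from all introns are reported as not intronic", {
  case <- make_case(seed = 53)
  g <- case$gene
  ref <- transcript_seq(g)
  cum <- cumsum(pseudoexonr:::tx_exon_widths(g))
  alien <- "TTACGGATCCGGAATTCCTTAAGGCTAGCTAGGT"
  obs <- paste0(substr(ref, 1, cum[1]), alien,
                substr(ref, cum[1] + 1, nchar(ref)))
  ev <- find_insertion(ref, obs)
  expect_error(locate_in_intron(g, ev), "not of intronic origin")
})

test_that("an insert found only in a different intron carries a warning", {
  case <- make_case(seed = 59, k = 2)
  g <- case$gene
  truth <- case$truth
  ref <- transcript_seq(g)
  cum <- cumsum(pseudoexonr:::tx_exon_widths(g))
  # splice the intron-2 interior at the WRONG junction (exon1|exon2)
  obs <- paste0(substr(ref, 1, cum[1]), truth$interior,
                substr(ref, cum[1] + 1, nchar(ref)))
  ev <- find_insertion(ref, obs)
  loc <- locate_in_intron(g, ev)
  expect_equal(loc$intron_index, 2L)
  expect_match(loc$warning, "intron 2")
})

test_that("insertions away from exon junctions violate the junction precondition", {
  case <- make_case(seed = 61)
  g <- case$gene
  ref <- transcript_seq(g)
  obs <- paste0(substr(ref, 1, 40), case$truth$interior,
                substr(ref, 41, nchar(ref)))
  ev <- find_insertion(ref, obs)
  expect_error(locate_in_intron(g, ev), "junction")
})

test_that("causal variants are inferred with the right side classification", {
  modes <- c("donor-created", "acceptor-created", "donor-strengthened",
             "acceptor-strengthened")
  for (m in modes) {
    case <- make_case(seed = 67, mode = m)
    truth <- case$truth
    ev <- find_insertion(transcript_seq(case$gene), truth$mutant_transcript)
    loc <- locate_in_intron(case$gene, ev)
    pint <- pseudoexonr:::mutant_intron_seq(case)
    call <- resolve_candidates(case$gene, loc, patient_intron_seq = pint)
    call <- infer_causal_variant(case$gene, call, pint)
    expect_equal(call$side, m)
    expect_equal(format_cdna_variant(call$causal_variant), truth$hgvs_dna)
  }
})

test_that("identical patient and reference introns cannot yield a variant call", {
  case <- make_case(seed = 71)
  ev <- find_insertion(transcript_seq(case$gene),
                       case$truth$mutant_transcript)
  loc <- locate_in_intron(case$gene, ev)
  pint <- pseudoexonr:::mutant_intron_seq(case)
  call <- resolve_candidates(case$gene, loc, patient_intron_seq = pint)
  ref_intron <- pseudoexonr:::intron_seq_tx(case$gene,
                                            case$truth$intron_index)
  expect_error(infer_causal_variant(case$gene, call, ref_intron),
               "no causal variant")
})

test_that("multiple window mismatches refuse a single-variant call", {
  case <- make_case(seed = 73, mode = "donor-created")
  truth <- case$truth
  ev <- find_insertion(transcript_seq(case$gene), truth$mutant_transcript)
  loc <- locate_in_intron(case$gene, ev)
  pint <- pseudoexonr:::mutant_intron_seq(case)
  call <- resolve_candidates(case$gene, loc, patient_intron_seq = pint)
  # second edit inside the donor window
  extra <- truth$span_local[["end"]] + 4L
  substr(pint, extra, extra) <- if (substr(pint, extra, extra) == "A") "C" else "A"
  expect_error(infer_causal_variant(case$gene, call, pint),
               "multiple mismatches")
})

test_that("reference-boundary scan reports which splice site is missing", {
  case <- make_case(seed = 79, mode = "donor-created")
  ev <- find_insertion(transcript_seq(case$gene),
                       case$truth$mutant_transcript)
  loc <- locate_in_intron(case$gene, ev)
  call <- resolve_candidates(case$gene, loc, variant = case$variant)
  scan <- scan_reference_boundaries(case$gene, call)
  expect_true(scan$canonical[scan$boundary == "acceptor"])
  expect_false(scan$canonical[scan$boundary == "donor"])
})
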