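NON_STOP_CODONS <- local({
  all64 <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0),
                           DNA_BASES, paste0))
  setdiff(all64, STOP_CODONS)
})

#' Generate a reproducible toy gene
#'
#' Builds a multi-exon gene with canonical GT...AG introns and a fully
#' coding transcript (ATG start, terminal stop, no internal in-frame
#' stops), on either strand, with i.i.d. background sequence of a chosen GC
#' content. The same seed always yields the same gene.
#'
#' @param seed Integer seed.
#' @param n_exons Number of exons (>= 2).
#' @param exon_len_range,intron_len_range Length ranges (nt); intron
#'   lengths must allow deep-intronic placement (minimum 200).
#' @param strand `"+"` or `"-"`.
#' @param gc GC fraction of the background sequence (default 0.40,
#'   intron-like).
#' @param gene_id,chrom Identifiers.
#' @param pad Flanking genomic padding (nt).
#' @return A [gene_model()].
#' @export
make_toy_gene <- function(seed, n_exons = 3L,
                          exon_len_range = c(150L, 400L),
                          intron_len_range = c(500L, 3000L),
                          strand = "+", gc = 0.40,
                          gene_id = "TOY1", chrom = "chrT", pad = 100L) {
  n_exons <- as.integer(n_exons)
  if (n_exons < 2L) stop("infeasible constraints: n_exons must be >= 2")
  if (intron_len_range[1L] < 200L) {
    stop("infeasible constraints: intron lengths must be >= 200 for deep-intronic placement")
  }
  if (exon_len_range[1L] < 10L) {
    stop("infeasible constraints: exons shorter than 10 nt")
  }
  set.seed(as.integer(seed %% 2147483647))
  exon_lens <- sample(seq(exon_len_range[1L], exon_len_range[2L]), n_exons,
                      replace = TRUE)
  tx_len <- sum(exon_lens)
  exon_lens[n_exons] <- exon_lens[n_exons] + (3L - tx_len %% 3L) %% 3L
  tx_len <- sum(exon_lens)
  tx <- random_dna(tx_len, gc)
  substr(tx, 1L, 3L) <- "ATG"
  substr(tx, tx_len - 2L, tx_len) <- "TAA"
  # purge accidental internal in-frame stops
  for (ci in seq.int(2L, tx_len %/% 3L - 1L)) {
    at <- (ci - 1L) * 3L + 1L
    if (substr(tx, at, at + 2L) %in% STOP_CODONS) {
      substr(tx, at, at) <- "C"
    }
  }
  intron_lens <- sample(seq(intron_len_range[1L], intron_len_range[2L]),
                        n_exons - 1L, replace = TRUE)
  ends <- cumsum(exon_lens)
  starts <- ends - exon_lens + 1L
  exon_seqs <- substring(tx, starts, ends)
  intron_seqs <- vapply(intron_lens, function(L) {
    paste0("GT", random_dna(L - 4L, gc), "AG")
  }, character(1L))
  pieces <- character(2L * n_exons - 1L)
  pieces[seq(1L, by = 2L, length.out = n_exons)] <- exon_seqs
  if (n_exons > 1L) {
    pieces[seq(2L, by = 2L, length.out = n_exons - 1L)] <- intron_seqs
  }
  gene_dir <- paste0(random_dna(pad, gc), paste0(pieces, collapse = ""),
                     random_dna(pad, gc))
  # gene-direction exon bounds (0-based half-open)
  seg_lens <- c(exon_lens, intron_lens)[order(c(
    seq(1L, by = 2L, length.out = n_exons),
    if (n_exons > 1L) seq(2L, by = 2L, length.out = n_exons - 1L)))]
  seg_ends <- pad + cumsum(seg_lens)
  seg_starts <- seg_ends - seg_lens
  exon_idx <- seq(1L, by = 2L, length.out = n_exons)
  gd_starts <- seg_starts[exon_idx]
  gd_ends <- seg_ends[exon_idx]
  if (strand == "+") {
    genome <- gene_dir
    ex_starts <- gd_starts; ex_ends <- gd_ends
  } else {
    genome <- revcomp(gene_dir)
    Lg <- nchar(genome)
    ex_starts <- rev(Lg - gd_ends)
    ex_ends <- rev(Lg - gd_starts)
  }
  gene_model(gene_id, chrom, strand, ex_starts, ex_ends, genome,
             cds_start = 1L, cds_end = tx_len)
}

# Replace the transcript-oriented sequence of intron k, returning a new model.
replace_intron <- function(model, k, new_iseq_tx) {
  b <- intron_bounds(model)
  row <- b[b$index == k, ]
  stopifnot(nchar(new_iseq_tx) == row$end - row$start)
  plus <- if (model$strand == "-") revcomp(new_iseq_tx) else new_iseq_tx
  model$genome_seq <- paste0(
    substr(model$genome_seq, 1L, row$start),
    plus,
    substr(model$genome_seq, row$end + 1L, nchar(model$genome_seq)))
  model
}

# Vectorised consensus value for many equal-length windows.
ss_percent_many <- function(seqs, fm) {
  if (length(seqs) == 0L) return(numeric())
  L <- nrow(fm)
  m <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)),
                    colnames(fm)), ncol = L, byrow = TRUE)
  vals <- matrix(fm[cbind(rep(seq_len(L), each = nrow(m)), as.vector(m))],
                 ncol = L)
  s <- rowSums(vals)
  lo <- sum(apply(fm, 1L, min)); hi <- sum(apply(fm, 1L, max))
  100 * (s - lo) / (hi - lo)
}

# Break spurious high-scoring donor-like windows in a transcript-oriented
# intron, leaving positions in `protect` (local coords) untouched.
scrub_spurious_donors <- function(iseq, protect, threshold = 85) {
  fm <- ss_frequency_matrix("donor")
  repeat {
    Li <- nchar(iseq)
    gts <- gregexpr("GT", iseq, fixed = TRUE)[[1L]]
    gts <- gts[gts > 0L]
    # GT at local g,g+1 -> donor window starts at g-3 (3 exonic-like bases)
    gts <- gts[gts - 3L >= 1L & gts + 5L <= Li]
    gts <- setdiff(gts, protect$keep_gt %||% integer())
    gts <- gts[!(gts %in% protect$region | (gts + 1L) %in% protect$region)]
    if (length(gts) == 0L) return(iseq)
    wins <- substring(iseq, gts - 3L, gts + 5L)
    bad <- gts[ss_percent_many(wins, fm) >= threshold]
    if (length(bad) == 0L) return(iseq)
    for (g in bad) substr(iseq, g + 1L, g + 1L) <- "C"  # GT -> GC
  }
}

#' Plant a pseudoexon cassette and its causal variant in a toy gene
#'
#' Writes into the chosen intron a splice-ready cassette -- polypyrimidine
#' tract + AG acceptor, interior pseudoexon sequence, GT donor with
#' consensus tail -- in which exactly one base deviates from functionality
#' in the reference; the returned variant restores or creates it, depending
#' on `mode`. The complete ground truth (span, variant, HGVS strings,
#' frameshift residue, in-frame stop offsets) is recorded for pipeline
#' round-trip testing. Spurious donor-like signals in the rest of the
#' intron are scrubbed below the consensus-value threshold.
#'
#' @param gene A [make_toy_gene()] model (fully coding).
#' @param intron_index Host intron (transcript-order index).
#' @param pe_len Pseudoexon length (nt, >= 20).
#' @param depth Transcript-directed offset of the first pseudoexon base
#'   from the upstream exon end (>= `min_flank`).
#' @param mode One of `"donor-created"`, `"acceptor-created"`,
#'   `"donor-strengthened"`, `"acceptor-strengthened"`.
#' @param in_frame Generate an in-frame, no-PTC case (requires
#'   `pe_len %% 3 == 0`; forces `n_stops = 0`).
#' @param n_stops Number of in-frame stop codons planted in the interior
#'   (default: 0 when `in_frame`, otherwise 1-3 depending on room).
#' @param seed Integer seed for the cassette's own randomness.
#' @param min_flank Minimum distance of the cassette from both exons
#'   (default 200, deep-intronic).
#' @param scrub_threshold Consensus-value threshold for the spurious-donor
#'   scrub.
#' @return An object of class `synthetic_case`; see Details.
#' @details Fields: `gene` (reference model after cassette write + scrub),
#'   `mutant_genome` (plus-strand), `variant`, `truth` (list of planted
#'   values), `mode`, `in_frame`, `seed`. Observed transcripts come from
#'   [simulate_transcripts()].
#' @export
plant_pseudoexon_cassette <- function(gene, intron_index, pe_len, depth,
                                      mode = c("donor-created",
                                               "acceptor-created",
                                               "donor-strengthened",
                                               "acceptor-strengthened"),
                                      in_frame = FALSE, n_stops = NULL,
                                      seed = 1L, min_flank = 200L,
                                      scrub_threshold = 85) {
  mode <- match.arg(mode)
  stopifnot(inherits(gene, "gene_model"))
  pe_len <- as.integer(pe_len); depth <- as.integer(depth)
  if (pe_len < 20L) stop("pe_len must be >= 20")
  if (in_frame && pe_len %% 3L != 0L) {
    stop("in_frame cassettes need pe_len divisible by 3")
  }
  k <- as.integer(intron_index)
  iseq0 <- intron_seq_tx(gene, k)
  Li <- nchar(iseq0)
  s <- depth; e <- depth + pe_len - 1L
  if (s < max(min_flank, 21L) || Li - e < max(min_flank, 7L)) {
    stop("cassette does not fit: need >= min_flank intronic sequence on both sides")
  }
  set.seed(as.integer(child_seed(seed, 17L) %% 2147483647))
  cum <- cumsum(tx_exon_widths(gene))
  X <- tx_to_cds(gene, cum[k])          # last coding base before insertion
  f0 <- (3L - X %% 3L) %% 3L            # pe bases completing the entry codon
  r0 <- frameshift_start_residue(X)
  ref_aa <- seq_chars(translate_cds(cds_seq(gene)))
  tx <- transcript_seq(gene)
  exon_tail <- if (f0 > 0L) substr(tx, cum[k] - (3L - f0) + 1L, cum[k]) else ""

  if (is.null(n_stops)) {
    n_stops <- if (in_frame) 0L else min(3L, max(1L, (pe_len - f0) %/% 30L))
  }
  n_stops <- as.integer(n_stops)
  m_codons <- (pe_len - f0) %/% 3L
  tail_len <- (pe_len - f0) %% 3L
  if (n_stops > max(0L, m_codons - 1L)) {
    stop("not enough room in the interior for the requested stop codons")
  }

  build_interior <- function() {
    entry <- ""
    force_body1 <- f0 == 0L   # first full codon carries the residue change
    r_eff <- r0
    if (f0 > 0L) {
      opts <- expand.grid(rep(list(DNA_BASES), f0))
      cand <- apply(opts, 1L, paste0, collapse = "")
      codons <- paste0(exon_tail, cand)
      non_stop <- !(codons %in% STOP_CODONS)
      ok <- non_stop & unname(Biostrings::GENETIC_CODE[codons]) != ref_aa[r0]
      if (any(ok)) {
        entry <- sample(cand[ok], 1L)
      } else {
        # degenerate codon family: every completion is synonymous, so the
        # first residue whose identity changes is the next (fully internal)
        # codon
        entry <- sample(cand[non_stop], 1L)
        force_body1 <- TRUE
        r_eff <- r0 + 1L
      }
    }
    if (force_body1 && m_codons < 1L) {
      stop("interior too short to place the first changed residue")
    }
    body <- sample(NON_STOP_CODONS, m_codons, replace = TRUE)
    if (force_body1) {
      ok <- unname(Biostrings::GENETIC_CODE[NON_STOP_CODONS]) != ref_aa[r_eff]
      body[1L] <- sample(NON_STOP_CODONS[ok], 1L)
    }
    stop_slots <- integer()
    if (n_stops > 0L) {
      first_ok <- if (force_body1) 2L else 1L  # keep that codon missense
      stop_slots <- sort(sample(seq.int(first_ok, m_codons), n_stops))
      body[stop_slots] <- sample(STOP_CODONS, n_stops, replace = TRUE)
    }
    tail_bases <- if (tail_len > 0L) random_dna(tail_len, 0.4) else ""
    if (tail_len > 0L && n_stops == 0L && pe_len %% 3L == 0L) {
      # keep the 3' straddle codon stop-free (every stop starts with T)
      substr(tail_bases, 1L, 1L) <- sample(c("A", "C", "G"), 1L)
    }
    mut_codon <- if (f0 > 0L && r_eff == r0) paste0(exon_tail, entry)
                 else body[1L]
    list(seq = paste0(entry, paste0(body, collapse = ""), tail_bases),
         stop_offsets = f0 + 3L * (stop_slots - 1L),
         entry = entry, body = body, r_eff = r_eff,
         mut_aa = unname(Biostrings::GENETIC_CODE[mut_codon]))
  }

  ref_intron <- NULL; interior <- NULL; vlocal <- NULL
  vref <- NULL; valt <- NULL
  for (attempt in 1:25) {
    it <- build_interior()
    ic <- seq_chars(iseq0)
    ic[s:e] <- seq_chars(it$seq)
    ppt <- sample(c("C", "T"), 16L, replace = TRUE)
    ic[(s - 18L):(s - 3L)] <- ppt
    ic[(s - 2L):(s - 1L)] <- c("A", "G")
    ic[(e + 1L):(e + 6L)] <- c("G", "T", "A", "A", "G", "T")
    if (mode == "donor-created") {
      vlocal <- e + 1L; vref <- "C"; valt <- "G"
    } else if (mode == "donor-strengthened") {
      vlocal <- e + 5L; vref <- "C"; valt <- "G"
    } else if (mode == "acceptor-created") {
      vlocal <- s - 1L; vref <- "A"; valt <- "G"
    } else {
      vlocal <- s - 7L; vref <- "G"; valt <- "T"
      ic[vlocal] <- vref  # purine interrupting the polypyrimidine tract
    }
    ic[vlocal] <- vref
    cand_intron <- paste0(ic, collapse = "")
    # interior must occur exactly once, and the mutant cassette must be the
    # unique AG...GT-flanked placement
    n_occ <- length(gregexpr(it$seq, cand_intron, fixed = TRUE)[[1L]])
    hit <- gregexpr(it$seq, cand_intron, fixed = TRUE)[[1L]][1L]
    if (hit == -1L || n_occ != 1L) next
    interior <- it
    ref_intron <- cand_intron
    break
  }
  if (is.null(ref_intron)) {
    stop("could not place a unique cassette in this intron (repeat collision)")
  }
  protect <- list(region = seq.int(max(1L, s - 24L), min(Li, e + 8L)),
                  keep_gt = e + 1L)
  ref_intron <- scrub_spurious_donors(ref_intron, protect, scrub_threshold)
  gene_ref <- replace_intron(gene, k, ref_intron)

  g_var <- intron_local_to_genomic(gene_ref, k, vlocal)
  coord <- genomic_to_cdna(gene_ref, g_var)
  variant <- cdna_variant(coord, vref, valt)
  mutant_genome <- apply_variant_to_genome(gene_ref, variant)

  b <- intron_bounds(gene_ref)
  row <- b[b$index == k, ]
  span <- if (gene_ref$strand == "+") {
    genomic_interval(gene_ref$chrom, row$start + s - 1L, row$start + e, "+")
  } else {
    genomic_interval(gene_ref$chrom, row$end - e, row$end - (s - 1L), "-")
  }
  mutant_tx <- paste0(substr(tx, 1L, cum[k]), interior$seq,
                      substr(tx, cum[k] + 1L, nchar(tx)))
  r_eff <- interior$r_eff
  mut_aa_r <- interior$mut_aa
  classification <- if (pe_len %% 3L != 0L) "frameshift"
                    else if (n_stops == 0L) "in-frame insertion, no PTC"
                    else "in-frame insertion with PTC"
  truth <- list(
    intron_index = k,
    span = span,
    span_local = c(start = s, end = e),
    pe_len = pe_len,
    interior = interior$seq,
    insertion_point_cds = X,
    hgvs_dna = format_cdna_variant(variant),
    hgvs_rna = sprintf("c.%d_%dins%d+%d_%d+%d", X, X + 1L, X, s, X, e),
    hgvs_protein = if (classification == "in-frame insertion, no PTC")
        NA_character_
      else sprintf("p.%s%d%sfs", aa3(ref_aa[r_eff]), r_eff, aa3(mut_aa_r)),
    first_affected_residue = r_eff,
    stop_offsets = interior$stop_offsets,
    stop_genomic = if (gene_ref$strand == "+") span$start + interior$stop_offsets
                   else span$end - 1L - interior$stop_offsets,
    side = mode,
    variant_genomic = g_var,
    classification = classification,
    mutant_transcript = mutant_tx
  )
  structure(
    list(seed = seed, gene = gene_ref, mutant_genome = mutant_genome,
         variant = variant, truth = truth, mode = mode,
         in_frame = (classification == "in-frame insertion, no PTC")),
    class = "synthetic_case"
  )
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("<synthetic_case> %s; intron %d; %d nt; %s; %s\n",
              x$gene$gene_id, x$truth$intron_index, x$truth$pe_len,
              x$mode, x$truth$hgvs_dna))
  invisible(x)
}

#' Transcript-oriented mutant host-intron sequence of a synthetic case
#'
#' The reference intron with the planted causal variant applied; this is
#' what a patient's targeted intron sequencing would return, and the input
#' expected by [infer_causal_variant()] and [analyze_case()].
#'
#' @param case A `synthetic_case`.
#' @return Character scalar.
#' @export
mutant_intron_seq <- function(case) {
  mut_model <- case$gene
  mut_model$genome_seq <- case$mutant_genome
  intron_seq_tx(mut_model, case$truth$intron_index)
}

#' Observed transcript isoforms for a synthetic case
#'
#' The pseudoexon-containing isoform is always emitted; a normal isoform is
#' added when `include_normal_fraction > 0`. Mixture proportions are labels
#' only -- no signal-level trace simulation is attempted.
#'
#' @param case A `synthetic_case`.
#' @param include_normal_fraction Fraction assigned to the normal isoform,
#'   in `[0, 1)`.
#' @return A tibble with columns `label`, `fraction`, `seq`.
#' @export
simulate_transcripts <- function(case, include_normal_fraction = 0) {
  stopifnot(inherits(case, "synthetic_case"))
  f <- include_normal_fraction
  if (f < 0 || f >= 1) stop("include_normal_fraction must be in [0, 1)")
  out <- tibble::tibble(label = "pseudoexon", fraction = 1 - f,
                        seq = case$truth$mutant_transcript)
  if (f > 0) {
    out <- rbind(out, tibble::tibble(label = "normal", fraction = f,
                                     seq = transcript_seq(case$gene)))
  }
  out
}

#' Write a synthetic case to standard-format fixture files
#'
#' Writes `genome.fa` (reference genome), `gene.gff3`, `variant.vcf`
#' (minimal VCF 4.2 SNV record, plus-strand), `transcripts.fa` (observed
#' isoforms), `patient_intron.fa` (transcript-oriented mutant host intron)
#' and `truth.json`. Output bytes are deterministic for a given case.
#'
#' @param case A `synthetic_case`.
#' @param out_dir Writable output directory (created if needed).
#' @param include_normal_fraction Passed to [simulate_transcripts()].
#' @return Named character vector of file paths, invisibly.
#' @export
write_fixtures <- function(case, out_dir, include_normal_fraction = 0) {
  stopifnot(inherits(case, "synthetic_case"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- case$gene
  paths <- c(
    genome = file.path(out_dir, "genome.fa"),
    gff3 = file.path(out_dir, "gene.gff3"),
    vcf = file.path(out_dir, "variant.vcf"),
    transcripts = file.path(out_dir, "transcripts.fa"),
    patient_intron = file.path(out_dir, "patient_intron.fa"),
    truth = file.path(out_dir, "truth.json")
  )
  genome <- Biostrings::DNAStringSet(model$genome_seq)
  names(genome) <- model$chrom
  Biostrings::writeXStringSet(genome, paths[["genome"]], width = 70L)

  n <- n_exons(model)
  sp <- gene_span(model)
  lines <- c(
    "##gff-version 3",
    sprintf("%s\tpseudoexonr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            model$chrom, sp[["start"]] + 1L, sp[["end"]], model$strand,
            model$gene_id),
    sprintf("%s\tpseudoexonr\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
            model$chrom, sp[["start"]] + 1L, sp[["end"]], model$strand,
            model$gene_id, model$gene_id)
  )
  ord <- tx_exon_order(model)
  w <- tx_exon_widths(model)
  cum_before <- c(0L, head(cumsum(w), -1L))
  phase <- (3L - (cum_before %% 3L)) %% 3L   # transcript order
  for (i in seq_len(n)) {
    ex <- ord[i]
    lines <- c(lines,
      sprintf("%s\tpseudoexonr\texon\t%d\t%d\t.\t%s\t.\tID=%s.t1.exon%d;Parent=%s.t1",
              model$chrom, model$exon_starts[ex] + 1L, model$exon_ends[ex],
              model$strand, model$gene_id, i, model$gene_id),
      sprintf("%s\tpseudoexonr\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.t1.cds%d;Parent=%s.t1",
              model$chrom, model$exon_starts[ex] + 1L, model$exon_ends[ex],
              model$strand, phase[i], model$gene_id, i, model$gene_id))
  }
  writeLines(lines, paths[["gff3"]])

  g <- cdna_to_genomic(model, case$variant$coord)
  ref_plus <- genome_subseq(model, g, g + 1L)
  alt_plus <- if (model$strand == "-") revcomp(case$variant$alt)
              else case$variant$alt
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", model$chrom,
            nchar(model$genome_seq)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", model$chrom, g + 1L,
            ref_plus, alt_plus)
  ), paths[["vcf"]])

  iso <- simulate_transcripts(case, include_normal_fraction)
  txs <- Biostrings::DNAStringSet(iso$seq)
  names(txs) <- sprintf("%s|fraction=%g", iso$label, iso$fraction)
  Biostrings::writeXStringSet(txs, paths[["transcripts"]], width = 70L)

  pint <- Biostrings::DNAStringSet(mutant_intron_seq(case))
  names(pint) <- sprintf("patient_intron_%d", case$truth$intron_index)
  Biostrings::writeXStringSet(pint, paths[["patient_intron"]], width = 70L)

  truth <- case$truth
  truth$span <- list(chrom = truth$span$chrom, start = truth$span$start,
                     end = truth$span$end, strand = truth$span$strand)
  truth$span_local <- as.list(truth$span_local)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(paths)
}

#' Reload a fixture directory written by [write_fixtures()]
#'
#' @param dir Fixture directory.
#' @param gene_id Gene identifier inside the GFF3.
#' @return A list with `model`, `variant` ([cdna_variant()] mapped back
#'   from the VCF record), `transcripts` (tibble), `patient_intron`,
#'   `truth`.
#' @export
read_fixtures <- function(dir, gene_id = "TOY1") {
  model <- load_gene_model(file.path(dir, "gene.gff3"),
                           file.path(dir, "genome.fa"), gene_id)
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading fixture VCFs requires the vcfR package")
  }
  v <- vcfR::read.vcfR(file.path(dir, "variant.vcf"), verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- if (is.matrix(fix)) fix[1L, ] else fix
  g <- as.integer(fix[["POS"]]) - 1L
  ref <- fix[["REF"]]; alt <- fix[["ALT"]]
  if (model$strand == "-") { ref <- revcomp(ref); alt <- revcomp(alt) }
  variant <- cdna_variant(genomic_to_cdna(model, g), ref, alt)
  txs <- Biostrings::readDNAStringSet(file.path(dir, "transcripts.fa"))
  meta <- strsplit(names(txs), "|", fixed = TRUE)
  transcripts <- tibble::tibble(
    label = vapply(meta, `[[`, character(1L), 1L),
    fraction = as.numeric(sub("^fraction=", "",
                              vapply(meta, `[[`, character(1L), 2L))),
    seq = unname(as.character(txs))
  )
  pint <- as.character(Biostrings::readDNAStringSet(
    file.path(dir, "patient_intron.fa")))[[1L]]
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(model = model, variant = variant, transcripts = transcripts,
       patient_intron = pint, truth = truth)
}
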