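#' Pseudoexon call record
#'
#' Produced by [resolve_candidates()] and enriched downstream. The span
#' excludes the flanking AG/GT dinucleotides: in the mutant sequence the
#' acceptor AG immediately precedes the span and the donor GT immediately
#' follows it, both in transcript direction.
#'
#' @param intron_index 1-based intron number in transcript order.
#' @param span,donor_site,acceptor_site [genomic_interval()] records.
#' @param causal_variant A [cdna_variant()] or `NULL`.
#' @param side One of `"donor-created"`, `"acceptor-created"`,
#'   `"donor-strengthened"`, `"acceptor-strengthened"`, or `NA`.
#' @param hgvs_dna,hgvs_rna,hgvs_protein Annotation strings (may be `NA`).
#' @return An object of class `pseudoexon_call`.
#' @export
pseudoexon_call <- function(intron_index, span, donor_site, acceptor_site,
                            causal_variant = NULL, side = NA_character_,
                            hgvs_dna = NA_character_,
                            hgvs_rna = NA_character_,
                            hgvs_protein = NA_character_) {
  stopifnot(inherits(span, "genomic_interval"))
  structure(
    list(intron_index = as.integer(intron_index), span = span,
         donor_site = donor_site, acceptor_site = acceptor_site,
         causal_variant = causal_variant, side = side,
         hgvs_dna = hgvs_dna, hgvs_rna = hgvs_rna,
         hgvs_protein = hgvs_protein),
    class = "pseudoexon_call"
  )
}

#' @export
print.pseudoexon_call <- function(x, ...) {
  cat(sprintf("<pseudoexon_call> intron %d; %d nt; %s\n", x$intron_index,
              span_length(x$span),
              if (is.na(x$side)) "side undetermined" else x$side))
  if (!is.null(x$causal_variant)) {
    cat("  causal variant:", format_cdna_variant(x$causal_variant), "\n")
  }
  invisible(x)
}

# Transcript-order intron index implied by a junction position, or NA.
junction_intron <- function(model, ref_pos) {
  cum <- cumsum(tx_exon_widths(model))
  match(as.integer(ref_pos), head(cum, -1L))
}

# Shift an insertion event rightwards to an equivalent placement at `target`
# (must lie within the event's ambiguity span). Rotates the inserted
# sequence using reference bases, preserving observed = ref[1..p] + I + rest.
shift_event <- function(event, ref_mrna, target) {
  d <- target - event$ref_pos
  stopifnot(d >= 0L, d < event$ambiguity_span)
  if (d == 0L) return(event)
  ins <- event$inserted_seq
  for (step in seq_len(d)) {
    nxt <- substr(ref_mrna, event$ref_pos + step, event$ref_pos + step)
    ins <- paste0(substr(ins, 2L, nchar(ins)), nxt)
  }
  event$ref_pos <- target
  event$inserted_seq <- ins
  event$left_flank_len <- event$left_flank_len + d
  event$right_flank_len <- event$right_flank_len - d
  event$ambiguity_span <- event$ambiguity_span - d
  event
}

#' Locate an inserted segment in its intron of origin
#'
#' The insertion must sit at an exon-exon junction of the reference mRNA
#' (any equivalent placement within the event's ambiguity span counts; the
#' event is re-anchored there). The inserted sequence is then searched as an
#' exact, strand-adjusted substring of the intron between those exons.
#'
#' @param model A [gene_model()].
#' @param event An `insertion_event` from [find_insertion()].
#' @return A list with `intron_index`, `candidates` (list of
#'   [genomic_interval()] in ascending genomic order), the junction-anchored
#'   `event`, and `warning` (`NA` or text; set when the segment was found
#'   only in a different intron than the junction implies).
#' @export
locate_in_intron <- function(model, event) {
  stopifnot(inherits(model, "gene_model"),
            inherits(event, "insertion_event"))
  if (nchar(event$inserted_seq) < 10L) {
    stop("inserted segment shorter than 10 nt: too short to localize")
  }
  ref <- transcript_seq(model)
  cum <- cumsum(tx_exon_widths(model))
  junctions <- head(cum, -1L)
  placements <- event$ref_pos + seq_len(event$ambiguity_span) - 1L
  hit <- intersect(placements, junctions)
  if (length(hit) == 0L) {
    stop("insertion does not sit at an exon-exon junction of the reference mRNA")
  }
  event <- shift_event(event, ref, hit[1L])
  k <- junction_intron(model, event$ref_pos)
  found_k <- k
  cands <- find_in_intron(model, k, event$inserted_seq)
  warn <- NA_character_
  if (length(cands) == 0L) {
    others <- setdiff(seq_len(n_exons(model) - 1L), k)
    for (k2 in others) {
      cands <- find_in_intron(model, k2, event$inserted_seq)
      if (length(cands) > 0L) {
        found_k <- k2
        warn <- sprintf(
          "inserted segment found in intron %d, not intron %d implied by the junction",
          k2, k)
        break
      }
    }
  }
  if (length(cands) == 0L) {
    stop("inserted segment not of intronic origin (no exact occurrence in any intron)")
  }
  ord <- order(vapply(cands, function(x) x$start, integer(1L)))
  list(intron_index = found_k, candidates = cands[ord], event = event,
       warning = warn)
}

# All exact occurrences of `pattern` (transcript-oriented) in intron k,
# returned as genomic intervals.
find_in_intron <- function(model, k, pattern) {
  iseq <- intron_seq_tx(model, k)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                   Biostrings::DNAString(iseq))
  starts <- Biostrings::start(hits)
  L <- nchar(pattern)
  b <- intron_bounds(model)
  row <- b[b$index == k, ]
  lapply(starts, function(s) {
    if (model$strand == "+") {
      genomic_interval(model$chrom, row$start + s - 1L,
                       row$start + s - 1L + L, "+")
    } else {
      genomic_interval(model$chrom, row$end - (s - 1L) - L,
                       row$end - (s - 1L), "-")
    }
  })
}

# Transcript-directed local bounds (1-based, inclusive) of a genomic span
# within intron k.
span_local_bounds <- function(model, k, span) {
  b <- intron_bounds(model)
  row <- b[b$index == k, ]
  if (span$start < row$start || span$end > row$end) {
    stop("span lies outside the host intron")
  }
  if (model$strand == "+") {
    c(start = span$start - row$start + 1L, end = span$end - row$start)
  } else {
    c(start = row$end - span$end + 1L, end = row$end - span$start)
  }
}

# Apply a cdna_variant to the plus-strand genome of a model, returning the
# modified genome string.
apply_variant_to_genome <- function(model, variant) {
  validate_cdna_variant(model, variant)
  g <- cdna_to_genomic(model, variant$coord)
  alt <- if (model$strand == "-") revcomp(variant$alt) else variant$alt
  paste0(substr(model$genome_seq, 1L, g),
         alt,
         substr(model$genome_seq, g + 2L, nchar(model$genome_seq)))
}

#' Resolve candidate pseudoexon placements with mutant splice dinucleotides
#'
#' A candidate is accepted only if, in the MUTANT intron sequence (reference
#' plus the supplied variant, or the supplied patient intron sequence), a
#' canonical AG immediately precedes the span and a GT immediately follows
#' it, in transcript direction. Zero or multiple surviving candidates are
#' errors, never guesses.
#'
#' @param model A [gene_model()].
#' @param located Result of [locate_in_intron()] (or a bare list of
#'   candidate [genomic_interval()]s plus `intron_index`).
#' @param patient_intron_seq Optional patient intron sequence, transcript
#'   oriented, same length as the reference intron.
#' @param variant Optional [cdna_variant()] to apply to the reference.
#' @return A `pseudoexon_call` skeleton (no consequence annotation yet).
#' @export
resolve_candidates <- function(model, located, patient_intron_seq = NULL,
                               variant = NULL) {
  k <- located$intron_index
  cands <- located$candidates
  if (length(cands) == 0L) stop("no candidates to resolve")
  if (is.null(patient_intron_seq) && is.null(variant)) {
    stop("supply a patient intron sequence or a candidate causal variant")
  }
  if (!is.null(patient_intron_seq)) {
    assert_dna(patient_intron_seq, "patient_intron_seq")
    mut_intron <- patient_intron_seq
    if (nchar(mut_intron) != nchar(intron_seq_tx(model, k))) {
      stop("patient intron sequence length differs from the reference intron")
    }
  } else {
    mut_model <- model
    mut_model$genome_seq <- apply_variant_to_genome(model, variant)
    mut_intron <- intron_seq_tx(mut_model, k)
  }
  ok <- vapply(cands, function(cand) {
    loc <- span_local_bounds(model, k, cand)
    s <- loc[["start"]]; e <- loc[["end"]]
    s > 2L && e + 2L <= nchar(mut_intron) &&
      substr(mut_intron, s - 2L, s - 1L) == "AG" &&
      substr(mut_intron, e + 1L, e + 2L) == "GT"
  }, logical(1L))
  if (sum(ok) == 0L) {
    stop("no candidate is flanked by AG...GT in the mutant intron")
  }
  if (sum(ok) > 1L) {
    stop(sprintf("ambiguous placement: %d candidates satisfy the AG...GT constraint",
                 sum(ok)))
  }
  span <- cands[[which(ok)]]
  loc <- span_local_bounds(model, k, span)
  donor <- intron_interval(model, k, loc[["end"]] + 1L, loc[["end"]] + 2L)
  acceptor <- intron_interval(model, k, loc[["start"]] - 2L, loc[["start"]] - 1L)
  pseudoexon_call(k, span, donor, acceptor, causal_variant = variant)
}

# Genomic interval of transcript-directed local range [s,e] in intron k.
intron_interval <- function(model, k, s, e) {
  g1 <- intron_local_to_genomic(model, k, s)
  g2 <- intron_local_to_genomic(model, k, e)
  genomic_interval(model$chrom, min(g1, g2), max(g1, g2) + 1L, model$strand)
}

#' Infer the causal deep-intronic variant from a patient intron sequence
#'
#' Compares the patient intron to the reference and requires exactly one
#' mismatch inside the donor 9-mer window (last 3 pseudoexon bases + first 6
#' intronic bases past the span) or the acceptor 23-mer window (20 intronic
#' bases before the span + first 3 pseudoexon bases). A mismatch at the GT /
#' AG dinucleotide itself classifies as `"-created"`, anywhere else in the
#' window as `"-strengthened"`.
#'
#' @param model A [gene_model()].
#' @param call A `pseudoexon_call`.
#' @param patient_intron_seq Patient intron sequence, transcript oriented.
#' @param max_mismatches Maximum tolerated mismatches across the whole
#'   intron before the comparison is declared unusable (default 3).
#' @return The input `call` with `causal_variant` and `side` filled in.
#' @export
infer_causal_variant <- function(model, call, patient_intron_seq,
                                 max_mismatches = 3L) {
  stopifnot(inherits(call, "pseudoexon_call"))
  assert_dna(patient_intron_seq, "patient_intron_seq")
  k <- call$intron_index
  ref_intron <- intron_seq_tx(model, k)
  if (nchar(patient_intron_seq) != nchar(ref_intron)) {
    stop("patient intron sequence length differs from the reference intron")
  }
  r <- seq_chars(ref_intron); p <- seq_chars(patient_intron_seq)
  mism <- which(r != p)
  if (length(mism) > max_mismatches) {
    stop(sprintf("%d mismatches in the intron exceed max_mismatches = %d",
                 length(mism), max_mismatches))
  }
  loc <- span_local_bounds(model, k, call$span)
  s <- loc[["start"]]; e <- loc[["end"]]
  donor_win <- seq.int(e - 2L, e + 6L)
  acceptor_win <- seq.int(s - 20L, s + 2L)
  in_donor <- mism[mism %in% donor_win]
  in_acceptor <- mism[mism %in% acceptor_win]
  if (length(in_donor) == 0L && length(in_acceptor) == 0L) {
    stop("no causal variant in splice windows")
  }
  if (length(in_donor) > 1L || length(in_acceptor) > 1L ||
      (length(in_donor) == 1L && length(in_acceptor) == 1L)) {
    stop("multiple mismatches in splice windows: cannot call a single causal variant")
  }
  if (length(in_donor) == 1L) {
    pos <- in_donor
    side <- if (pos %in% c(e + 1L, e + 2L)) "donor-created" else "donor-strengthened"
  } else {
    pos <- in_acceptor
    side <- if (pos %in% c(s - 2L, s - 1L)) "acceptor-created" else "acceptor-strengthened"
  }
  g <- intron_local_to_genomic(model, k, pos)
  coord <- genomic_to_cdna(model, g)
  variant <- cdna_variant(coord, r[pos], p[pos])
  call$causal_variant <- variant
  call$side <- side
  call
}

#' Diagnostic splice-window scan when no patient data is available
#'
#' Without patient genomic data no variant can be called; instead both span
#' boundaries are checked against the REFERENCE intron for canonical AG /
#' GT, reporting which boundary lacks a functional site. This is a hint for
#' targeted sequencing, not a variant call.
#'
#' @param model A [gene_model()].
#' @param call A `pseudoexon_call`.
#' @return A tibble with one row per boundary: `boundary`, `dinucleotide`,
#'   `canonical`.
#' @export
scan_reference_boundaries <- function(model, call) {
  k <- call$intron_index
  ref_intron <- intron_seq_tx(model, k)
  loc <- span_local_bounds(model, k, call$span)
  s <- loc[["start"]]; e <- loc[["end"]]
  acc <- substr(ref_intron, s - 2L, s - 1L)
  don <- substr(ref_intron, e + 1L, e + 2L)
  tibble::tibble(
    boundary = c("acceptor", "donor"),
    dinucleotide = c(acc, don),
    canonical = c(acc == "AG", don == "GT")
  )
}
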