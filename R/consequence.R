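#' Build the mutant (pseudoexon-containing) transcript
#'
#' Splices the pseudoexon sequence (strand-adjusted) between the two exons
#' flanking its host intron, on top of the reference mRNA.
#'
#' @param model A [gene_model()].
#' @param pseudoexon A `pseudoexon_call`.
#' @return Character scalar: the mutant transcript sequence.
#' @export
build_mutant_transcript <- function(model, pseudoexon) {
  stopifnot(inherits(model, "gene_model"),
            inherits(pseudoexon, "pseudoexon_call"))
  k <- pseudoexon$intron_index
  b <- intron_bounds(model)
  row <- b[b$index == k, ]
  if (nrow(row) != 1L || pseudoexon$span$start < row$start ||
      pseudoexon$span$end > row$end) {
    stop("pseudoexon span lies outside its host intron")
  }
  pe <- genome_subseq(model, pseudoexon$span$start, pseudoexon$span$end)
  if (model$strand == "-") pe <- revcomp(pe)
  ref <- transcript_seq(model)
  cum <- cumsum(tx_exon_widths(model))
  j <- cum[k]
  paste0(substr(ref, 1L, j), pe, substr(ref, j + 1L, nchar(ref)))
}

#' Find premature termination codons introduced by a pseudoexon
#'
#' Scans codons (`TAA`, `TAG`, `TGA`) in the translation frame of the
#' mutant transcript from the insertion junction onwards, reporting every
#' stop wholly inside the pseudoexon plus the first stop downstream of it.
#'
#' @param mutant_transcript Mutant transcript sequence.
#' @param cds_start 1-based transcript position of the first coding base.
#' @param insertion_point 1-based coding position of the last reference
#'   base before the insertion.
#' @param pe_len Pseudoexon length (nt).
#' @return A tibble with columns `offset` (0-based offset of the stop-codon
#'   start within the pseudoexon; downstream stops count past its end),
#'   `codon`, `within_pseudoexon`, `tx_pos` (1-based position in the mutant
#'   transcript).
#' @export
find_premature_stops <- function(mutant_transcript, cds_start,
                                 insertion_point, pe_len) {
  assert_dna(mutant_transcript, "mutant_transcript")
  cds_start <- as.integer(cds_start)
  insertion_point <- as.integer(insertion_point)
  pe_len <- as.integer(pe_len)
  junction_tx <- cds_start + insertion_point - 1L  # last normal base
  # first codon that can contain pseudoexon bases (0-based codon index)
  first_codon <- insertion_point %/% 3L
  pe_first_tx <- junction_tx + 1L
  pe_last_tx <- junction_tx + pe_len
  n <- nchar(mutant_transcript)
  out <- list()
  codon0 <- first_codon
  repeat {
    start_tx <- cds_start + codon0 * 3L
    if (start_tx + 2L > n) break
    codon <- substr(mutant_transcript, start_tx, start_tx + 2L)
    if (codon %in% STOP_CODONS) {
      inside <- start_tx >= pe_first_tx && start_tx + 2L <= pe_last_tx
      out[[length(out) + 1L]] <- tibble::tibble(
        offset = start_tx - pe_first_tx,
        codon = codon,
        within_pseudoexon = inside,
        tx_pos = start_tx
      )
      if (!inside && start_tx > pe_last_tx) break  # first downstream stop
      if (!inside && start_tx + 2L > pe_last_tx && start_tx >= pe_first_tx) {
        # straddles the 3' junction: keep scanning for a downstream stop
      }
    }
    codon0 <- codon0 + 1L
  }
  if (length(out) == 0L) {
    return(tibble::tibble(offset = integer(), codon = character(),
                          within_pseudoexon = logical(), tx_pos = integer()))
  }
  do.call(rbind, out)
}

#' Map pseudoexon-internal stop offsets to genomic coordinates
#'
#' @param model A [gene_model()].
#' @param call A `pseudoexon_call`.
#' @param offsets 0-based offsets of stop-codon starts within the
#'   pseudoexon (transcript direction).
#' @return Integer vector of 0-based genomic positions of the stop-codon
#'   start bases.
#' @export
stop_offsets_to_genomic <- function(model, call, offsets) {
  offsets <- as.integer(offsets)
  if (model$strand == "+") {
    call$span$start + offsets
  } else {
    call$span$end - 1L - offsets
  }
}

#' Check reading-frame coherence of printed stop-codon coordinates
#'
#' Stops read in one frame must have pairwise genomic distances that are
#' multiples of 3; a violated check flags an internally inconsistent
#' report.
#'
#' @param genomic_positions Integer vector of stop-codon start coordinates
#'   (any consistent base convention).
#' @return `TRUE` if all pairwise differences are congruent 0 mod 3.
#' @export
stop_frame_coherent <- function(genomic_positions) {
  g <- as.numeric(genomic_positions)
  if (length(g) < 2L) return(TRUE)
  all(diff(sort(g)) %% 3 == 0)
}

#' Naive frameshift start residue from an insertion point
#'
#' The first residue whose codon can contain inserted bases:
#' `floor(insertion_point_cds / 3) + 1`. The full annotation
#' ([frameshift_annotation()]) advances past residues whose identity is
#' unchanged, which can exceed this value when the first altered codon is
#' synonymous.
#'
#' @param insertion_point_cds 1-based coding position of the last reference
#'   base before the insertion.
#' @return Integer residue number.
#' @export
frameshift_start_residue <- function(insertion_point_cds) {
  as.integer(insertion_point_cds) %/% 3L + 1L
}

#' Protein-level annotation of a pseudoexon insertion
#'
#' Translates the reference and mutant transcripts and names the first
#' residue whose identity changes, in `p.<Ref3><Pos><Alt3>fs` form
#' (or `p.<Ref3><Pos>Ter` when the first changed codon is itself a stop).
#' In-frame insertions (length a multiple of 3) containing no stop codon
#' are labeled `in-frame insertion, no PTC` and carry no fs annotation.
#'
#' @param model A [gene_model()].
#' @param insertion_point_cds 1-based coding position of the last reference
#'   base before the insertion.
#' @param mutant_transcript Mutant transcript from
#'   [build_mutant_transcript()].
#' @return A list: `protein_hgvs`, `first_affected_residue`,
#'   `normal_residue_count`, `classification`.
#' @export
frameshift_annotation <- function(model, insertion_point_cds,
                                  mutant_transcript) {
  insertion_point_cds <- as.integer(insertion_point_cds)
  if (insertion_point_cds < 1L) {
    return(list(protein_hgvs = NA_character_,
                first_affected_residue = NA_integer_,
                normal_residue_count = NA_integer_,
                classification = "5' UTR insertion"))
  }
  pe_len <- nchar(mutant_transcript) - tx_length(model)
  ref_aa <- seq_chars(translate_cds(cds_seq(model)))
  mut_cds <- substr(mutant_transcript, model$cds_start,
                    nchar(mutant_transcript))
  mut_aa <- seq_chars(translate_cds(mut_cds))
  r <- frameshift_start_residue(insertion_point_cds)
  in_frame <- pe_len %% 3L == 0L
  # advance past residues whose identity is unchanged
  while (r <= length(ref_aa) && r <= length(mut_aa) &&
         mut_aa[r] == ref_aa[r]) {
    r <- r + 1L
  }
  if (r > length(mut_aa) || r > length(ref_aa)) {
    return(list(protein_hgvs = NA_character_,
                first_affected_residue = NA_integer_,
                normal_residue_count = NA_integer_,
                classification = if (in_frame) "in-frame insertion, no PTC"
                                 else "no changed residue found"))
  }
  if (in_frame) {
    # does the pseudoexon (or anything downstream of it) introduce a stop
    # before the reference terminator shifts? in-frame + no new stop means
    # an internal peptide insertion, not a frameshift
    first_stop <- which(mut_aa == "*")[1L]
    ref_stop <- which(ref_aa == "*")[1L]
    if (!is.na(first_stop) && !is.na(ref_stop) &&
        first_stop - ref_stop == pe_len %/% 3L) {
      return(list(protein_hgvs = NA_character_,
                  first_affected_residue = r,
                  normal_residue_count = r - 1L,
                  classification = "in-frame insertion, no PTC"))
    }
  }
  alt <- mut_aa[r]
  hgvs <- if (alt == "*") {
    sprintf("p.%s%dTer", aa3(ref_aa[r]), r)
  } else {
    sprintf("p.%s%d%sfs", aa3(ref_aa[r]), r, aa3(alt))
  }
  list(protein_hgvs = hgvs,
       first_affected_residue = r,
       normal_residue_count = r - 1L,
       classification = if (in_frame) "in-frame insertion with PTC"
                        else "frameshift")
}

#' Assemble a full consequence report
#'
#' @param model A [gene_model()].
#' @param call A `pseudoexon_call`.
#' @return An object of class `consequence_report`: insertion point,
#'   pseudoexon length, frame shift, stop offsets (with genomic
#'   coordinates), and the protein annotation fields.
#' @export
consequence_report <- function(model, call) {
  mutant <- build_mutant_transcript(model, call)
  pe_len <- span_length(call$span)
  cum <- cumsum(tx_exon_widths(model))
  insertion_point <- tx_to_cds(model, cum[call$intron_index])
  stops <- find_premature_stops(mutant, model$cds_start, insertion_point,
                                pe_len)
  inside <- stops[stops$within_pseudoexon, , drop = FALSE]
  if (nrow(inside) > 1L) {
    stopifnot(all(diff(inside$offset) %% 3L == 0L))
  }
  fs <- frameshift_annotation(model, insertion_point, mutant)
  structure(
    list(insertion_point_cds = insertion_point,
         pseudoexon_len = pe_len,
         frame_shift = pe_len %% 3L,
         stops = stops,
         stop_offsets = inside$offset,
         stop_genomic = stop_offsets_to_genomic(model, call, inside$offset),
         first_affected_residue = fs$first_affected_residue,
         protein_hgvs = fs$protein_hgvs,
         normal_residue_count = fs$normal_residue_count,
         classification = fs$classification,
         mutant_transcript = mutant),
    class = "consequence_report"
  )
}

#' @export
print.consequence_report <- function(x, ...) {
  cat(sprintf("<consequence_report> ins after c.%d; %d nt pseudoexon (frame %d); %s\n",
              x$insertion_point_cds, x$pseudoexon_len, x$frame_shift,
              x$classification))
  if (!is.na(x$protein_hgvs)) cat("  protein:", x$protein_hgvs, "\n")
  if (length(x$stop_offsets)) {
    cat("  PTC offsets in pseudoexon:",
        paste(x$stop_offsets, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Render a one-row case report
#'
#' Combines the pseudoexon call, the splice-score panel and the consequence
#' annotation into a single flat record mirroring a clinical case-table
#' row, with inconsistency flags carried alongside.
#'
#' @param call A `pseudoexon_call` (with HGVS fields filled).
#' @param panel A `score_panel` tibble or `NULL`.
#' @param consequence A `consequence_report`.
#' @param flags Character vector of inconsistency notes (optional).
#' @return A one-row tibble of class `case_report`.
#' @export
render_case_report <- function(call, panel, consequence, flags = character()) {
  stopifnot(inherits(call, "pseudoexon_call"),
            inherits(consequence, "consequence_report"))
  if (is.null(panel)) {
    warning("no score panel supplied; panel fields reported as NA",
            call. = FALSE)
  }
  pick <- function(metric, col) {
    if (is.null(panel)) return(NA_real_)
    i <- match(metric, panel$metric)
    if (is.na(i)) NA_real_ else panel[[col]][i]
  }
  out <- tibble::tibble(
    derivation = sprintf("Intron %d; %d nt", call$intron_index,
                         consequence$pseudoexon_len),
    intron_index = call$intron_index,
    pseudoexon_len = consequence$pseudoexon_len,
    span_start_g1 = call$span$start + 1L,
    span_end_g1 = call$span$end,
    dna = if (is.null(call$causal_variant)) NA_character_
          else format_cdna_variant(call$causal_variant),
    rna = call$hgvs_rna,
    protein = consequence$protein_hgvs,
    side = call$side,
    classification = consequence$classification,
    first_affected_residue = consequence$first_affected_residue,
    normal_residue_count = consequence$normal_residue_count,
    n_ptc_in_pseudoexon = length(consequence$stop_offsets),
    stop_offsets = paste(consequence$stop_offsets, collapse = ","),
    stop_genomic_1based = paste(consequence$stop_genomic + 1L, collapse = ","),
    ss_percent_delta = pick("ss_percent", "delta"),
    wmm_delta = pick("wmm_logodds", "delta"),
    mm1_delta = pick("mm1_logodds", "delta"),
    maxent_delta = pick("maxent_logodds", "delta"),
    flags = paste(flags, collapse = "; ")
  )
  class(out) <- c("case_report", class(out))
  out
}

#' Write / read a case report as JSON
#'
#' @param report A `case_report` tibble.
#' @param path Output path.
#' @return `path` invisibly; [read_case_report()] returns the tibble.
#' @export
write_case_report <- function(report, path) {
  jsonlite::write_json(as.list(report[1L, ]), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_case_report
#' @export
read_case_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x[vapply(x, is.null, logical(1L))] <- NA
  num_cols <- c("intron_index", "pseudoexon_len", "span_start_g1",
                "span_end_g1", "first_affected_residue",
                "normal_residue_count", "n_ptc_in_pseudoexon",
                "ss_percent_delta", "wmm_delta", "mm1_delta",
                "maxent_delta")
  for (k in intersect(num_cols, names(x))) x[[k]] <- as.numeric(x[[k]])
  chr_cols <- c("derivation", "dna", "rna", "protein", "side",
                "classification", "stop_offsets", "stop_genomic_1based",
                "flags")
  for (k in intersect(chr_cols, names(x))) x[[k]] <- as.character(x[[k]])
  out <- tibble::as_tibble(x)
  class(out) <- c("case_report", class(out))
  out
}
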