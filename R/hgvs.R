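#' Parse a c. substitution with optional intronic offset
#'
#' Accepts strings such as `"c.1331+17811C>G"`, `"c.9225-285A>G"` or
#' `"c.100A>T"`. Whitespace inside tokens is tolerated (reports often print
#' `"c.2803 + 3252A > G"`); the canonical rendering returned by
#' [format_cdna_variant()] is space-free.
#'
#' @param text HGVS-like c. substitution string.
#' @return An object of class `cdna_variant` with fields `coord`
#'   ([cdna_coord()]), `ref` and `alt`.
#' @export
parse_cdna_variant <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- gsub("[[:space:]]+", "", text)
  m <- regmatches(x, regexec(
    "^c\\.(\\d+)([+-]\\d+)?([ACGT])>([ACGT])$", x))[[1L]]
  if (length(m) == 0L) {
    stop(sprintf("malformed c. substitution: '%s'", text))
  }
  offset <- if (m[3L] == "") 0L else as.integer(m[3L])
  if (m[4L] == m[5L]) {
    stop(sprintf("ref and alt are identical in '%s'", text))
  }
  cdna_variant(cdna_coord(as.integer(m[2L]), offset), m[4L], m[5L])
}

#' @rdname parse_cdna_variant
#' @param coord A [cdna_coord()].
#' @param ref,alt Single reference / alternate nucleotides.
#' @export
cdna_variant <- function(coord, ref, alt) {
  stopifnot(inherits(coord, "cdna_coord"))
  if (!ref %in% DNA_BASES || !alt %in% DNA_BASES) {
    stop("ref and alt must be single bases in {A,C,G,T}")
  }
  if (ref == alt) stop("ref and alt must differ")
  structure(list(coord = coord, ref = ref, alt = alt),
            class = "cdna_variant")
}

#' @rdname parse_cdna_variant
#' @param variant A `cdna_variant`.
#' @export
format_cdna_variant <- function(variant) {
  stopifnot(inherits(variant, "cdna_variant"))
  sprintf("%s%s>%s", format_cdna_coord(variant$coord), variant$ref,
          variant$alt)
}

#' @export
print.cdna_variant <- function(x, ...) {
  cat("<cdna_variant>", format_cdna_variant(x), "\n")
  invisible(x)
}

#' Check a c. variant's reference base against the genome
#'
#' The stated `ref` must match the genome base at the mapped genomic
#' position, read on the transcript strand.
#'
#' @param model A [gene_model()].
#' @param variant A [cdna_variant()].
#' @return `TRUE` invisibly; error if the base disagrees.
#' @export
validate_cdna_variant <- function(model, variant) {
  g <- cdna_to_genomic(model, variant$coord)
  base <- genome_subseq(model, g, g + 1L)
  if (model$strand == "-") base <- revcomp(base)
  if (base != variant$ref) {
    stop(sprintf("%s: reference base is %s, not %s",
                 format_cdna_variant(variant), base, variant$ref))
  }
  invisible(TRUE)
}

#' Parse an intronic insertion source range
#'
#' Parses the source-range part of RNA-level insertion HGVS such as
#' `"2803+3164_2803+3251"`, or a full
#' `"c.2803_2804ins2803+3164_2803+3251"` string. Both endpoints must lie in
#' the same intron (same anchor and offset sign) and the range must read
#' forward in transcript direction.
#'
#' @param text Range text, with or without the `c.X_Yins` prefix; embedded
#'   whitespace tolerated.
#' @return A list with `start` and `end` ([cdna_coord()]) and the inclusive
#'   `length` of the range.
#' @export
parse_ins_range <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- gsub("[[:space:]]+", "", text)
  x <- sub("^c\\.\\d+_\\d+ins", "", x)
  m <- regmatches(x, regexec(
    "^(\\d+)([+-]\\d+)_(\\d+)([+-]\\d+)$", x))[[1L]]
  if (length(m) == 0L) {
    stop(sprintf("malformed insertion source range: '%s'", text))
  }
  a_pos <- as.integer(m[2L]); a_off <- as.integer(m[3L])
  b_pos <- as.integer(m[4L]); b_off <- as.integer(m[5L])
  if (a_pos != b_pos || sign(a_off) != sign(b_off)) {
    stop(sprintf("endpoints of '%s' lie in different introns", text))
  }
  len <- b_off - a_off + 1L
  if (len < 1L) stop(sprintf("reversed range: '%s'", text))
  list(start = cdna_coord(a_pos, a_off),
       end = cdna_coord(b_pos, b_off),
       length = len)
}

#' Flag an inconsistent printed insertion range
#'
#' Compares the inclusive length of a printed RNA ins range against an
#' independently stated pseudoexon size. Published case tables occasionally
#' disagree with themselves; such records are flagged, never silently
#' corrected.
#'
#' @param rna_text RNA-level insertion HGVS (or bare source range).
#' @param stated_len The independently stated pseudoexon length (nt).
#' @return A list: `range_length`, `stated_len`, `consistent`, `note`.
#' @export
check_ins_range_consistency <- function(rna_text, stated_len) {
  r <- parse_ins_range(rna_text)
  ok <- r$length == stated_len
  list(
    range_length = r$length,
    stated_len = as.integer(stated_len),
    consistent = ok,
    note = if (ok) NA_character_ else sprintf(
      "printed range '%s' has inclusive length %d but the stated size is %d nt",
      gsub("[[:space:]]+", "", rna_text), r$length, stated_len)
  )
}

#' Render the RNA-level insertion HGVS for a pseudoexon call
#'
#' Emits `c.<X>_<X+1>ins<X>+<s>_<X>+<e>` where `X` is the last coding base
#' of the exon upstream of the host intron and `s..e` are the
#' transcript-directed intron offsets of the pseudoexon span.
#'
#' @param model A [gene_model()].
#' @param pseudoexon A `pseudoexon_call` (see [resolve_candidates()]).
#' @return Canonical space-free HGVS string.
#' @export
format_rna_insertion <- function(model, pseudoexon) {
  stopifnot(inherits(model, "gene_model"),
            inherits(pseudoexon, "pseudoexon_call"))
  k <- pseudoexon$intron_index
  b <- intron_bounds(model)
  row <- b[b$index == k, ]
  if (pseudoexon$span$start < row$start || pseudoexon$span$end > row$end) {
    stop("pseudoexon span is not wholly inside its host intron")
  }
  cum <- cumsum(tx_exon_widths(model))
  X <- tx_to_cds(model, cum[k])
  # transcript-directed 1-based local offsets of span start/end in intron k
  if (model$strand == "+") {
    s <- pseudoexon$span$start - row$start + 1L
    e <- pseudoexon$span$end - row$start
  } else {
    s <- row$end - pseudoexon$span$end + 1L
    e <- row$end - pseudoexon$span$start
  }
  sprintf("c.%d_%dins%d+%d_%d+%d", X, X + 1L, X, s, X, e)
}
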