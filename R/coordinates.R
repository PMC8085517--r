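#' Coding-DNA coordinate with intronic offset
#'
#' Represents an HGVS-style c. position: a 1-based coding position plus a
#' signed intronic offset. Offset 0 means exonic; `+N` lies N bases into the
#' intron downstream of an exon end, `-N` lies N bases upstream of an exon
#' start, both counted in transcript direction.
#'
#' @param cds_pos Positive integer coding position.
#' @param offset Signed integer intronic offset (default 0).
#' @return An object of class `cdna_coord`.
#' @export
cdna_coord <- function(cds_pos, offset = 0L) {
  cds_pos <- as.integer(cds_pos)
  offset <- as.integer(offset)
  if (is.na(cds_pos) || cds_pos < 1L) stop("cds_pos must be a positive integer")
  structure(list(cds_pos = cds_pos, offset = offset), class = "cdna_coord")
}

#' @export
print.cdna_coord <- function(x, ...) {
  cat("<cdna_coord>", format_cdna_coord(x), "\n")
  invisible(x)
}

#' @rdname cdna_coord
#' @param coord A `cdna_coord`.
#' @export
format_cdna_coord <- function(coord) {
  if (coord$offset == 0L) {
    sprintf("c.%d", coord$cds_pos)
  } else {
    sprintf("c.%d%+d", coord$cds_pos, coord$offset)
  }
}

#' Genomic interval record
#'
#' Internal convention is 0-based half-open on the plus strand; use
#' [genomic_interval_1based()] to construct from 1-based inclusive endpoints
#' as printed in reports.
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open bounds, `start < end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start >= end) {
    stop("genomic_interval requires start < end (0-based half-open)")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @rdname genomic_interval
#' @param start1,end1 1-based inclusive endpoints.
#' @export
genomic_interval_1based <- function(chrom, start1, end1, strand = "+") {
  genomic_interval(chrom, as.integer(start1) - 1L, as.integer(end1), strand)
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:%d-%d (%s), %d nt\n",
              x$chrom, x$start + 1L, x$end, x$strand, span_length(x)))
  invisible(x)
}

#' Length of a genomic interval
#'
#' For an interval built from 1-based inclusive endpoints this is the
#' familiar `end - start + 1`.
#'
#' @param interval A [genomic_interval()].
#' @return Integer width.
#' @export
span_length <- function(interval) {
  stopifnot(inherits(interval, "genomic_interval"))
  interval$end - interval$start
}

# --- c. <-> genomic mapping -------------------------------------------------

# cds position -> 1-based transcript position
cds_to_tx <- function(model, cds_pos) model$cds_start + cds_pos - 1L

tx_to_cds <- function(model, tpos) tpos - model$cds_start + 1L

# Transcript-order exon index whose LAST transcript base is tpos, or NA.
exon_ending_at <- function(model, tpos) {
  cum <- cumsum(tx_exon_widths(model))
  i <- match(tpos, cum)
  if (is.na(i) || i == length(cum)) NA_integer_ else i
}

# Transcript-order exon index whose FIRST transcript base is tpos, or NA.
exon_starting_at <- function(model, tpos) {
  cum <- cumsum(tx_exon_widths(model))
  starts <- c(1L, head(cum, -1L) + 1L)
  i <- match(tpos, starts)
  if (is.na(i) || i == 1L) NA_integer_ else i
}

#' Map a c. coordinate to a genomic position
#'
#' Strand-aware: on a minus-strand gene a `+N` offset walks toward
#' numerically smaller genomic coordinates, because offsets are counted in
#' transcript direction.
#'
#' @param model A [gene_model()].
#' @param coord A [cdna_coord()].
#' @return 0-based genomic position (integer).
#' @export
cdna_to_genomic <- function(model, coord) {
  stopifnot(inherits(model, "gene_model"), inherits(coord, "cdna_coord"))
  if (coord$cds_pos > cds_length(model)) {
    stop(sprintf("cds position %d exceeds CDS length %d",
                 coord$cds_pos, cds_length(model)))
  }
  tpos <- cds_to_tx(model, coord$cds_pos)
  if (coord$offset == 0L) return(tx_to_genomic(model, tpos))
  if (coord$offset > 0L) {
    j <- exon_ending_at(model, tpos)
    if (is.na(j)) {
      stop(sprintf("%s: '+' offset must anchor at the last base of an exon",
                   format_cdna_coord(coord)))
    }
    if (coord$offset > intron_width(model, j)) {
      stop(sprintf("%s: offset walks past intron %d boundary",
                   format_cdna_coord(coord), j))
    }
    intron_local_to_genomic(model, j, coord$offset)
  } else {
    j <- exon_starting_at(model, tpos)
    if (is.na(j)) {
      stop(sprintf("%s: '-' offset must anchor at the first base of an exon",
                   format_cdna_coord(coord)))
    }
    k <- j - 1L
    w <- intron_width(model, k)
    if (-coord$offset > w) {
      stop(sprintf("%s: offset walks past intron %d boundary",
                   format_cdna_coord(coord), k))
    }
    intron_local_to_genomic(model, k, w + coord$offset + 1L)
  }
}

#' Map a genomic position to a c. coordinate
#'
#' Exonic positions get offset 0. Intronic positions are anchored to the
#' nearer exon edge (measured in transcript direction); ties go to the
#' upstream exon's `+` form, matching the usual c.X+N / c.Y-N conventions.
#'
#' @param model A [gene_model()].
#' @param gpos 0-based genomic position inside the gene span.
#' @return A [cdna_coord()].
#' @export
genomic_to_cdna <- function(model, gpos) {
  stopifnot(inherits(model, "gene_model"))
  gpos <- as.integer(gpos)
  sp <- gene_span(model)
  if (gpos < sp[["start"]] || gpos >= sp[["end"]]) {
    stop(sprintf("genomic position %d outside gene span [%d,%d)",
                 gpos, sp[["start"]], sp[["end"]]))
  }
  tpos <- genomic_to_tx(model, gpos)
  if (!is.na(tpos)) return(cdna_coord(tx_to_cds(model, tpos), 0L))
  b <- intron_bounds(model)
  k <- b$index[gpos >= b$start & gpos < b$end]
  row <- b[b$index == k, ]
  w <- row$end - row$start
  local <- if (model$strand == "+") gpos - row$start + 1L else row$end - gpos
  d_up <- local            # distance from upstream exon end (tx direction)
  d_down <- w - local + 1L # distance to downstream exon start
  cum <- cumsum(tx_exon_widths(model))
  if (d_up <= d_down) {
    cdna_coord(tx_to_cds(model, cum[k]), d_up)
  } else {
    cdna_coord(tx_to_cds(model, cum[k] + 1L), -d_down)
  }
}
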