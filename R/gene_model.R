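#' Construct a gene model
#'
#' A gene model is the coordinate authority for everything downstream: an
#' ordered set of exons on one strand of one chromosome, a coding region
#' given in transcript coordinates, and the underlying genomic sequence.
#' Internally all genomic coordinates are 0-based half-open on the plus
#' strand; transcript and CDS coordinates are 1-based.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of 0-based half-open exon
#'   bounds in ascending genomic order.
#' @param genome_seq Character scalar: the plus-strand sequence of `chrom`
#'   (or at least covering all exons).
#' @param cds_start,cds_end 1-based transcript positions of the first and
#'   last coding base.
#' @return An object of class `gene_model`.
#' @details Invariants enforced: exons sorted, non-overlapping; every intron
#'   at least 4 nt (room for GT...AG); CDS length at least 3. A CDS whose
#'   length is not a multiple of 3 triggers a warning, not an error, so
#'   partial models remain loadable.
#' @export
gene_model <- function(gene_id, chrom, strand, exon_starts, exon_ends,
                       genome_seq, cds_start = 1L,
                       cds_end = NULL) {
  stopifnot(length(exon_starts) == length(exon_ends),
            length(exon_starts) >= 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  if (any(exon_ends <= exon_starts)) stop("empty or inverted exon interval")
  if (is.unsorted(exon_starts, strictly = TRUE)) {
    stop("exons must be in strictly ascending genomic order")
  }
  n <- length(exon_starts)
  if (n > 1L) {
    gaps <- exon_starts[-1L] - exon_ends[-n]
    if (any(gaps <= 0L)) stop("overlapping or abutting exons")
    if (any(gaps < 4L)) stop("intron shorter than 4 nt")
  }
  assert_dna(genome_seq, "genome_seq")
  if (nchar(genome_seq) < max(exon_ends)) {
    stop("genome sequence shorter than gene features")
  }
  tx_len <- sum(exon_ends - exon_starts)
  if (is.null(cds_end)) cds_end <- tx_len
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (cds_start < 1L || cds_end > tx_len || cds_end < cds_start) {
    stop("CDS bounds outside transcript")
  }
  cds_len <- cds_end - cds_start + 1L
  if (cds_len < 3L) stop("CDS shorter than 3 nt")
  if (cds_len %% 3L != 0L) {
    warning(sprintf("CDS length %d is not a multiple of 3 (partial model?)",
                    cds_len), call. = FALSE)
  }
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         exon_starts = exon_starts, exon_ends = exon_ends,
         genome_seq = genome_seq, cds_start = cds_start, cds_end = cds_end),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)  %d exon(s), tx %d nt, CDS %d nt\n",
              x$gene_id, x$chrom, min(x$exon_starts), max(x$exon_ends),
              x$strand, n_exons(x), tx_length(x),
              x$cds_end - x$cds_start + 1L))
  invisible(x)
}

#' @rdname gene_model
#' @param model A `gene_model`.
#' @export
n_exons <- function(model) length(model$exon_starts)

#' @rdname gene_model
#' @export
tx_length <- function(model) sum(model$exon_ends - model$exon_starts)

cds_length <- function(model) model$cds_end - model$cds_start + 1L

# Exon indices in transcript order (1..n for "+", n..1 for "-").
tx_exon_order <- function(model) {
  n <- n_exons(model)
  if (model$strand == "+") seq_len(n) else rev(seq_len(n))
}

# Exon widths in transcript order.
tx_exon_widths <- function(model) {
  (model$exon_ends - model$exon_starts)[tx_exon_order(model)]
}

# Intron bounds (0-based half-open, genomic) indexed in TRANSCRIPT order.
intron_bounds <- function(model) {
  n <- n_exons(model)
  if (n < 2L) {
    return(data.frame(index = integer(), start = integer(),
                      end = integer()))
  }
  starts <- model$exon_ends[-n]
  ends <- model$exon_starts[-1L]
  idx <- if (model$strand == "+") seq_len(n - 1L) else rev(seq_len(n - 1L))
  ord <- order(idx)
  data.frame(index = idx[ord], start = starts[ord], end = ends[ord])
}

intron_width <- function(model, k) {
  b <- intron_bounds(model)
  row <- b[b$index == k, ]
  if (nrow(row) != 1L) stop(sprintf("no intron %d in model", k))
  row$end - row$start
}

# Genomic span of the gene (0-based half-open).
gene_span <- function(model) {
  c(start = min(model$exon_starts), end = max(model$exon_ends))
}

genome_subseq <- function(model, start0, end0) {
  substr(model$genome_seq, start0 + 1L, end0)
}

#' Spliced transcript sequence of a gene model
#'
#' Concatenates exon sequences in genomic order and reverse-complements for
#' minus-strand genes, so the result always reads 5' to 3' in transcript
#' direction.
#'
#' @param model A [gene_model()].
#' @return Character scalar.
#' @export
transcript_seq <- function(model) {
  pieces <- mapply(function(s, e) genome_subseq(model, s, e),
                   model$exon_starts, model$exon_ends)
  out <- paste0(pieces, collapse = "")
  if (model$strand == "-") out <- revcomp(out)
  out
}

cds_seq <- function(model) {
  substr(transcript_seq(model), model$cds_start, model$cds_end)
}

# The whole gene locus read in transcript direction; local coordinate 1 is
# the first transcript base.  Mapping helpers below keep this invertible.
gene_locus_tx <- function(model) {
  sp <- gene_span(model)
  out <- genome_subseq(model, sp[["start"]], sp[["end"]])
  if (model$strand == "-") out <- revcomp(out)
  out
}

# 1-based locus-local (transcript-direction) position -> 0-based genomic.
locus_to_genomic <- function(model, lpos) {
  sp <- gene_span(model)
  if (model$strand == "+") sp[["start"]] + lpos - 1L else sp[["end"]] - lpos
}

genomic_to_locus <- function(model, gpos) {
  sp <- gene_span(model)
  if (gpos < sp[["start"]] || gpos >= sp[["end"]]) {
    stop(sprintf("genomic position %d outside gene span", gpos))
  }
  if (model$strand == "+") gpos - sp[["start"]] + 1L else sp[["end"]] - gpos
}

# Transcript-oriented sequence of intron k (transcript-order index).
intron_seq_tx <- function(model, k) {
  b <- intron_bounds(model)
  row <- b[b$index == k, ]
  if (nrow(row) != 1L) stop(sprintf("no intron %d in model", k))
  out <- genome_subseq(model, row$start, row$end)
  if (model$strand == "-") out <- revcomp(out)
  out
}

# 1-based position within transcript-oriented intron k -> 0-based genomic.
intron_local_to_genomic <- function(model, k, pos) {
  b <- intron_bounds(model)
  row <- b[b$index == k, ]
  w <- row$end - row$start
  if (pos < 1L || pos > w) stop("position outside intron")
  if (model$strand == "+") row$start + pos - 1L else row$end - pos
}

#' Map a transcript position to a genomic position
#'
#' @param model A [gene_model()].
#' @param tpos 1-based transcript position.
#' @return 0-based genomic position.
#' @export
tx_to_genomic <- function(model, tpos) {
  tpos <- as.integer(tpos)
  if (tpos < 1L || tpos > tx_length(model)) {
    stop(sprintf("transcript position %d outside transcript", tpos))
  }
  ord <- tx_exon_order(model)
  w <- tx_exon_widths(model)
  cum <- cumsum(w)
  i <- which(tpos <= cum)[1L]
  within <- tpos - c(0L, cum)[i] - 1L  # 0-based offset in exon i (tx order)
  ex <- ord[i]
  if (model$strand == "+") {
    model$exon_starts[ex] + within
  } else {
    model$exon_ends[ex] - 1L - within
  }
}

# Inverse of tx_to_genomic for exonic positions; NA when intronic/outside.
genomic_to_tx <- function(model, gpos) {
  gpos <- as.integer(gpos)
  ex <- which(gpos >= model$exon_starts & gpos < model$exon_ends)
  if (length(ex) != 1L) return(NA_integer_)
  ord <- tx_exon_order(model)
  i <- match(ex, ord)
  w <- tx_exon_widths(model)
  before <- if (i > 1L) sum(w[seq_len(i - 1L)]) else 0L
  within <- if (model$strand == "+") gpos - model$exon_starts[ex]
            else model$exon_ends[ex] - 1L - gpos
  before + within + 1L
}

#' Load a gene model from GFF3 + FASTA
#'
#' Reads exon and CDS features for one gene from a GFF3 file and the
#' corresponding chromosome sequence from a FASTA file.
#'
#' @param gff3_path Path to a GFF3 file with gene/mRNA/exon/CDS records.
#' @param fasta_path Path to the genome FASTA.
#' @param gene_id Gene identifier to extract (matched against GFF3 `ID` /
#'   `Parent` attributes).
#' @return A validated [gene_model()].
#' @export
load_gene_model <- function(gff3_path, fasta_path, gene_id) {
  gr <- rtracklayer::import(gff3_path)
  df <- as.data.frame(gr)
  hit <- grepl(gene_id, paste(df$ID, df$Parent, sep = ";"), fixed = TRUE)
  df <- df[hit, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop(sprintf("gene '%s' not found in %s", gene_id, gff3_path))
  }
  exons <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(exons) == 0L) stop(sprintf("no exon records for '%s'", gene_id))
  exons <- exons[order(exons$start), , drop = FALSE]
  chrom <- as.character(exons$seqnames[1L])
  strand <- as.character(exons$strand[1L])
  fa <- Biostrings::readDNAStringSet(fasta_path)
  names(fa) <- sub("\\s.*$", "", names(fa))
  if (!chrom %in% names(fa)) {
    stop(sprintf("chromosome '%s' absent from %s", chrom, fasta_path))
  }
  model <- gene_model(
    gene_id = gene_id, chrom = chrom, strand = strand,
    exon_starts = exons$start - 1L, exon_ends = exons$end,
    genome_seq = as.character(fa[[chrom]]),
    cds_start = 1L, cds_end = NULL
  )
  if (nrow(cds) > 0L) {
    # CDS genomic extremes -> transcript-relative bounds.
    gmin <- min(cds$start) - 1L
    gmax <- max(cds$end) - 1L
    t1 <- genomic_to_tx(model, gmin)
    t2 <- genomic_to_tx(model, gmax)
    if (is.na(t1) || is.na(t2)) stop("CDS bounds fall outside exons")
    model <- gene_model(
      gene_id = gene_id, chrom = chrom, strand = strand,
      exon_starts = exons$start - 1L, exon_ends = exons$end,
      genome_seq = as.character(fa[[chrom]]),
      cds_start = min(t1, t2), cds_end = max(t1, t2)
    )
  }
  model
}
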