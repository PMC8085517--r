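#' Splice-site window record
#'
#' Donor windows are 9-mers (last 3 exonic + first 6 intronic bases);
#' acceptor windows are 23-mers (last 20 intronic + first 3 exonic bases),
#' both read in transcript direction. Input case is ignored (reports often
#' print mixed case to mark the exon/intron boundary and the mutated base).
#'
#' @param kind `"donor"` or `"acceptor"`.
#' @param seq Window sequence of matching length.
#' @param mutated_pos Optional 1-based index of a mutated base within the
#'   window.
#' @return An object of class `splice_window`.
#' @export
splice_window <- function(kind, seq, mutated_pos = NA_integer_) {
  kind <- match.arg(kind, c("donor", "acceptor"))
  seq <- toupper(seq)
  assert_dna(seq, "window sequence", allow_n = FALSE)
  want <- window_length(kind)
  if (nchar(seq) != want) {
    stop(sprintf("%s window must be %d nt, got %d", kind, want, nchar(seq)))
  }
  mutated_pos <- as.integer(mutated_pos)
  if (!is.na(mutated_pos) && (mutated_pos < 1L || mutated_pos > want)) {
    stop("mutated_pos outside window")
  }
  structure(list(kind = kind, seq = seq, mutated_pos = mutated_pos),
            class = "splice_window")
}

window_length <- function(kind) if (kind == "donor") 9L else 23L

#' @export
print.splice_window <- function(x, ...) {
  cat(sprintf("<splice_window> %s %s\n", x$kind, x$seq))
  invisible(x)
}

#' Extract a splice-site window at a boundary
#'
#' For a raw sequence, `boundary` is the 1-based position of the last
#' exonic base (donor) or the first exonic base (acceptor), read in
#' transcript direction. For a [gene_model()], `boundary` is an exon index
#' in transcript order and the window is taken at that exon's annotated
#' donor (3' end) or acceptor (5' start) junction.
#'
#' @param x A character sequence or a [gene_model()].
#' @param boundary Boundary position (sequence) or exon index (model).
#' @param kind `"donor"` or `"acceptor"`.
#' @return A [splice_window()].
#' @export
extract_window <- function(x, boundary, kind) {
  UseMethod("extract_window")
}

#' @export
extract_window.character <- function(x, boundary, kind) {
  kind <- match.arg(kind, c("donor", "acceptor"))
  x <- toupper(x)
  boundary <- as.integer(boundary)
  if (kind == "donor") {
    from <- boundary - 2L; to <- boundary + 6L
  } else {
    from <- boundary - 20L; to <- boundary + 2L
  }
  if (from < 1L || to > nchar(x)) {
    stop("boundary too close to the sequence end for this window kind")
  }
  splice_window(kind, substr(x, from, to))
}

#' @export
extract_window.gene_model <- function(x, boundary, kind) {
  kind <- match.arg(kind, c("donor", "acceptor"))
  boundary <- as.integer(boundary)
  n <- n_exons(x)
  locus <- gene_locus_tx(x)
  cum_ex <- cumsum(tx_exon_widths(x))
  b <- intron_bounds(x)
  iw <- (b$end - b$start)[order(b$index)]
  # locus-local position of the last base of exon j (transcript order)
  exon_end_local <- cumsum(tx_exon_widths(x) + c(head(iw, n - 1L), 0L)) -
    c(head(iw, n - 1L), 0L)
  if (kind == "donor") {
    if (boundary < 1L || boundary >= n) stop("no donor junction at this exon")
    extract_window.character(locus, exon_end_local[boundary], "donor")
  } else {
    if (boundary < 2L || boundary > n) stop("no acceptor junction at this exon")
    start_local <- exon_end_local[boundary - 1L] + iw[boundary - 1L] + 1L
    extract_window.character(locus, start_local, "acceptor")
  }
}

#' Pseudoexon splice windows from reference and mutant sequence
#'
#' Extracts the donor and acceptor windows flanking a pseudoexon span from
#' the reference gene and, when given, from a mutant intron sequence, with
#' the mutated position marked.
#'
#' @param model A [gene_model()].
#' @param call A `pseudoexon_call`.
#' @param mutant_intron_seq Optional transcript-oriented mutant intron.
#' @return A list with `donor` and `acceptor`, each a list of `reference`
#'   and (optionally) `mutant` [splice_window()]s.
#' @export
pseudoexon_windows <- function(model, call, mutant_intron_seq = NULL) {
  k <- call$intron_index
  ref_intron <- intron_seq_tx(model, k)
  loc <- span_local_bounds(model, k, call$span)
  s <- loc[["start"]]; e <- loc[["end"]]
  take <- function(intron, boundary, kind) {
    extract_window.character(intron, boundary, kind)
  }
  out <- list(
    donor = list(reference = take(ref_intron, e, "donor")),
    acceptor = list(reference = take(ref_intron, s, "acceptor"))
  )
  if (!is.null(mutant_intron_seq)) {
    out$donor$mutant <- take(toupper(mutant_intron_seq), e, "donor")
    out$acceptor$mutant <- take(toupper(mutant_intron_seq), s, "acceptor")
    mark <- function(ref, mut) {
      d <- which(seq_chars(ref$seq) != seq_chars(mut$seq))
      if (length(d) == 1L) mut$mutated_pos <- d
      mut
    }
    out$donor$mutant <- mark(out$donor$reference, out$donor$mutant)
    out$acceptor$mutant <- mark(out$acceptor$reference, out$acceptor$mutant)
  }
  out
}

#' Per-position splice-site base-frequency matrix
#'
#' Returns the package's consensus base-frequency table for the given
#' window kind (percent scale, one row per window position, columns
#' A/C/G/T), or reads a user-supplied table of the same plain-text layout.
#' The shipped tables are representative human splice-site frequencies
#' compiled from the splice-signal literature; users holding an exact
#' published matrix can pass its path instead.
#'
#' @param kind `"donor"` or `"acceptor"`.
#' @param path Optional path to a tab-separated matrix file (columns
#'   `pos`, `A`, `C`, `G`, `T`).
#' @return Numeric matrix with columns A, C, G, T.
#' @export
ss_frequency_matrix <- function(kind, path = NULL) {
  kind <- match.arg(kind, c("donor", "acceptor"))
  if (is.null(path)) {
    path <- system.file("extdata",
                        sprintf("ss_%s_freq.tsv", kind),
                        package = "pseudoexonr")
  }
  df <- utils::read.delim(path, comment.char = "#")
  m <- as.matrix(df[, c("A", "C", "G", "T")])
  rownames(m) <- df$pos
  if (nrow(m) != window_length(kind)) {
    stop(sprintf("frequency matrix has %d rows; %s windows need %d",
                 nrow(m), kind, window_length(kind)))
  }
  m
}

#' Shapiro-Senapathy style consensus value
#'
#' `100 * (s - min) / (max - min)` where `s` sums the per-position
#' frequencies of the window's bases and `min`/`max` sum the per-position
#' minima/maxima of the frequency matrix. The consensus window scores 100,
#' the anti-consensus window 0.
#'
#' @param window A [splice_window()] (or character; `kind` then required).
#' @param frequency_matrix Matrix from [ss_frequency_matrix()]; defaults to
#'   the shipped table for the window's kind.
#' @param kind Window kind when `window` is a bare string.
#' @return Percent in `[0, 100]`.
#' @export
ss_percent <- function(window, frequency_matrix = NULL, kind = NULL) {
  if (is.character(window)) window <- splice_window(kind, window)
  stopifnot(inherits(window, "splice_window"))
  if (is.null(frequency_matrix)) {
    frequency_matrix <- ss_frequency_matrix(window$kind)
  }
  L <- nchar(window$seq)
  if (nrow(frequency_matrix) != L) {
    stop("frequency matrix length does not match window")
  }
  idx <- match(seq_chars(window$seq), colnames(frequency_matrix))
  s <- sum(frequency_matrix[cbind(seq_len(L), idx)])
  lo <- sum(apply(frequency_matrix, 1L, min))
  hi <- sum(apply(frequency_matrix, 1L, max))
  100 * (s - lo) / (hi - lo)
}
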