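#' Detect a single inserted segment in an observed transcript
#'
#' Compares an observed transcript (or merged amplicon) sequence to the
#' reference mRNA under a single-insertion model: the observed sequence must
#' be the reference with one contiguous segment spliced in. The divergence
#' window is found exactly from the longest common prefix and suffix; no
#' heuristic alignment is involved. When the insertion abuts a repeat the
#' event is reported at its leftmost equivalent placement.
#'
#' `N` bases match nothing (conservative for Sanger-derived input), so a
#' stray `N` in a flank surfaces as a complex event rather than silently
#' anchoring.
#'
#' @param ref_mrna Reference mRNA sequence.
#' @param observed Observed transcript sequence.
#' @param min_anchor Minimum exact-match flank length on each side
#'   (default 15, must be >= 8).
#' @return An object of class `insertion_event` with fields `ref_pos`
#'   (0-based reference position after which the insertion occurs),
#'   `inserted_seq`, `left_flank_len`, `right_flank_len` and
#'   `ambiguity_span` (number of equivalent placements); or `NULL` when the
#'   observed sequence equals the reference.
#' @export
find_insertion <- function(ref_mrna, observed, min_anchor = 15L) {
  assert_dna(ref_mrna, "ref_mrna")
  assert_dna(observed, "observed")
  min_anchor <- as.integer(min_anchor)
  if (min_anchor < 8L) stop("min_anchor must be >= 8")
  if (identical(ref_mrna, observed)) return(NULL)
  nr <- nchar(ref_mrna); no <- nchar(observed)
  if (no <= nr) {
    stop("complex event: observed sequence is not longer than the reference")
  }
  check_orientation(ref_mrna, observed)
  r <- utf8ToInt(ref_mrna); o <- utf8ToInt(observed)
  n_code <- utf8ToInt("N")
  # longest common prefix / suffix with N matching nothing
  eq_p <- r[seq_len(nr)] == o[seq_len(nr)] & r[seq_len(nr)] != n_code
  lcp <- match(FALSE, eq_p, nomatch = nr + 1L) - 1L
  eq_s <- rev(r) == rev(o)[seq_len(nr)] & rev(r) != n_code
  lcs <- match(FALSE, eq_s, nomatch = nr + 1L) - 1L
  if (lcp + lcs < nr) {
    stop("complex event: flank mismatches beyond a single insertion")
  }
  ins_len <- no - nr
  p_min <- max(0L, nr - lcs)
  p_max <- min(lcp, nr)
  if (p_min < min_anchor || nr - p_max < min_anchor) {
    stop(sprintf("insufficient anchor: flanks shorter than min_anchor = %d",
                 min_anchor))
  }
  structure(
    list(ref_pos = p_min,
         inserted_seq = substr(observed, p_min + 1L, p_min + ins_len),
         left_flank_len = p_min,
         right_flank_len = nr - p_min,
         ambiguity_span = p_max - p_min + 1L),
    class = "insertion_event"
  )
}

#' @export
print.insertion_event <- function(x, ...) {
  cat(sprintf("<insertion_event> %d nt after ref position %d (%d equivalent placement%s)\n",
              nchar(x$inserted_seq), x$ref_pos, x$ambiguity_span,
              if (x$ambiguity_span == 1L) "" else "s"))
  invisible(x)
}

# k-mer pre-check of orientation only: if the observed sequence shares no
# seeds with the reference but its reverse complement does, refuse early
# with a clear message instead of reporting a bogus complex event.
check_orientation <- function(ref, obs, k = 12L) {
  if (nchar(obs) < 4L * k || nchar(ref) < 4L * k) return(invisible(TRUE))
  kmers <- function(x) {
    starts <- seq.int(1L, nchar(x) - k + 1L, by = k)
    unique(substring(x, starts, starts + k - 1L))
  }
  rk <- kmers(ref)
  fwd <- sum(kmers(obs) %in% rk)
  rc <- sum(kmers(revcomp(obs)) %in% rk)
  if (fwd == 0L && rc > 0L) {
    stop("observed sequence appears to be reverse-complemented relative to the reference")
  }
  invisible(TRUE)
}

#' Merge tiled amplicon sequences into one transcript
#'
#' Orders amplicons by exact suffix-prefix overlaps (>= `min_overlap`) and
#' requires the overlap graph to be a simple path; anything else (no
#' overlap, branching, conflicting overlaps) is an error rather than a
#' guess.
#'
#' @param amplicons Character vector or list of amplicon sequences.
#' @param min_overlap Minimum exact overlap between adjacent amplicons
#'   (default 30).
#' @return The merged sequence (character scalar).
#' @export
merge_amplicons <- function(amplicons, min_overlap = 30L) {
  amplicons <- as.character(unlist(amplicons))
  if (length(amplicons) == 0L) stop("no amplicons supplied")
  for (a in amplicons) assert_dna(a, "amplicon")
  n <- length(amplicons)
  if (n == 1L) return(amplicons)
  min_overlap <- as.integer(min_overlap)
  best_overlap <- function(a, b) {
    # largest k with suffix(a, k) == prefix(b, k)
    kmax <- min(nchar(a), nchar(b)) - 1L
    if (kmax >= min_overlap) {
      for (k in seq(kmax, min_overlap, by = -1L)) {
        if (substr(a, nchar(a) - k + 1L, nchar(a)) == substr(b, 1L, k)) {
          return(k)
        }
      }
    }
    0L
  }
  ov <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) ov[i, j] <- best_overlap(amplicons[i], amplicons[j])
  }
  succ <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    hits <- which(ov[i, ] > 0L)
    if (length(hits) > 1L) {
      stop("conflicting overlaps: no unique overlap path")
    }
    if (length(hits) == 1L) succ[i] <- hits
  }
  if (anyDuplicated(succ[!is.na(succ)])) {
    stop("conflicting overlaps: no unique overlap path")
  }
  starts <- setdiff(seq_len(n), succ[!is.na(succ)])
  if (length(starts) != 1L) {
    stop("amplicons do not form a single overlap path")
  }
  path <- starts
  while (!is.na(succ[path[length(path)]])) {
    path <- c(path, succ[path[length(path)]])
  }
  if (length(path) != n) {
    stop("amplicons do not form a single overlap path")
  }
  out <- amplicons[path[1L]]
  for (i in seq_len(n - 1L)) {
    a <- path[i]; b <- path[i + 1L]
    out <- paste0(out, substr(amplicons[b], ov[a, b] + 1L, nchar(amplicons[b])))
  }
  out
}
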