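# Independent oracles and hand-built fixtures used across the suite.
# Everything here is deliberately naive (enumeration, brute force) and
# shares no code path with the implementation it checks.

# A small 3-exon gene assembled from explicit strings. Transcript:
# ATG GCC ATT GCT GAC CTA GGA TTG TAA (9 codons, no internal stop).
hand_gene <- function(strand = "+") {
  e1 <- "ATGGCCATT"; i1 <- "GTAAGTTTCCAG"
  e2 <- "GCTGACCTA"; i2 <- "GTTTTTCTAG"
  e3 <- "GGATTGTAA"
  pad5 <- "CCCCC"; pad3 <- "GGGGG"
  gene_dir <- paste0(pad5, e1, i1, e2, i2, e3, pad3)
  lens <- nchar(c(e1, i1, e2, i2, e3))
  ends <- nchar(pad5) + cumsum(lens)
  starts <- ends - lens
  gd_starts <- starts[c(1, 3, 5)]; gd_ends <- ends[c(1, 3, 5)]
  if (strand == "+") {
    gene_model("HAND1", "chrH", "+", gd_starts, gd_ends, gene_dir)
  } else {
    Lg <- nchar(gene_dir)
    gene_model("HAND1", "chrH", "-", rev(Lg - gd_ends), rev(Lg - gd_starts),
               revcomp(gene_dir))
  }
}

hand_tx <- "ATGGCCATTGCTGACCTAGGATTGTAA"

# Exhaustive walk oracle: genomic position of every transcript base, built
# by enumerating exon positions directly (no shared code with tx_to_genomic).
oracle_tx_map <- function(model) {
  pos <- unlist(mapply(function(s, e) seq.int(s, e - 1L),
                       model$exon_starts, model$exon_ends,
                       SIMPLIFY = FALSE))
  if (model$strand == "-") pos <- rev(pos)
  pos
}

# Brute-force single-insertion finder: tries every split point, returns all
# placements explaining observed as ref-prefix + insert + ref-suffix.
oracle_insertions <- function(ref, obs) {
  nr <- nchar(ref); L <- nchar(obs) - nr
  if (L <= 0) return(integer())
  hits <- integer()
  for (p in 0:nr) {
    cand <- paste0(substr(ref, 1, p), substr(obs, p + 1, p + L),
                   substr(ref, p + 1, nr))
    if (cand == obs) hits <- c(hits, p)
  }
  hits
}

# Independent consensus-value computation from first principles.
oracle_ss_percent <- function(seq, fm) {
  ch <- strsplit(toupper(seq), "")[[1]]
  s <- 0; lo <- 0; hi <- 0
  for (i in seq_along(ch)) {
    row <- fm[i, ]
    s <- s + row[[ch[i]]]
    lo <- lo + min(row); hi <- hi + max(row)
  }
  100 * (s - lo) / (hi - lo)
}

# Sliding scan for stop codons in a fixed frame, independent of the
# implementation's codon bookkeeping.
oracle_stops_in_pe <- function(mutant_tx, cds_start, X, pe_len) {
  pe_first <- cds_start + X  # 1-based tx position of first pe base
  offs <- integer()
  for (o in 0:(pe_len - 3)) {
    at <- pe_first + o
    if ((at - cds_start) %% 3 == 0 &&
        substr(mutant_tx, at, at + 2) %in% c("TAA", "TAG", "TGA")) {
      offs <- c(offs, o)
    }
  }
  offs
}

all_kmers <- function(L) {
  apply(expand.grid(rep(list(c("A", "C", "G", "T")), L)), 1,
        paste0, collapse = "")
}

random_seq <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
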