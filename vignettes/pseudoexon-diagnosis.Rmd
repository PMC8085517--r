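---
title: "Detecting and scoring pseudoexon activation by deep intronic variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and scoring pseudoexon activation by deep intronic variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoexonr)
```

## The model

A pseudoexon event is modeled as a single contiguous intronic segment
spliced into an otherwise intact mRNA. Three assumptions follow from the
diagnostic setting and define the package's contracts:

* **Single clean insertion.** Observed transcripts are Sanger-derived
  consensus sequences, so the observed sequence must equal the reference
  mRNA with exactly one inserted segment; substitutions or deletions in
  the flanks are surfaced as "complex event" errors rather than absorbed
  by fuzzy alignment. The divergence window is computed exactly from the
  longest common prefix and suffix, which is optimal for this model and
  fully deterministic. `N` bases match nothing — a conservative choice for
  chromatogram-derived input. A k-mer comparison is used only to detect
  reverse-complemented input early.
* **Exact intronic origin.** The insert is searched as an exact,
  strand-adjusted substring of the intron at the affected junction,
  replacing the heuristic similarity search a human analyst would run.
  Inserts in this workflow are tens of bases and error-free, so exact
  matching is both faster and honest about ambiguity: repeat-induced
  multiple hits are returned as candidate lists, and a placement is
  accepted only if the *mutant* intron shows AG immediately 5' and GT
  immediately 3' of it (transcript direction). Two surviving candidates
  are an error, never a silent choice of the first.
* **Span convention.** The pseudoexon span *excludes* the flanking AG/GT
  dinucleotides. All genomic arithmetic is 0-based half-open on the plus
  strand internally; all rendered coordinates (HGVS-style c. strings,
  report columns) are 1-based inclusive. Intron offsets are
  transcript-directed, so on a minus-strand gene `+N` walks toward
  numerically smaller genomic positions. When a genomic position is
  re-expressed in c. notation, it anchors to the nearer exon edge, with
  ties going to the upstream exon's `+` form; both `c.X+N` and `c.Y-N`
  therefore occur in reports, as they do in practice.

## Causal-variant inference

Given a resolved span and a patient intron sequence, the causal variant
must be the single mismatch inside either splice window: the donor 9-mer
(last 3 pseudoexon bases + 6 intronic) or the acceptor 23-mer (20 intronic
+ first 3 pseudoexon bases). A mismatch at the GT/AG dinucleotide itself is
classified `-created`; elsewhere in a window, `-strengthened`. Zero
mismatches, more than one mismatch in a window, or mismatches in both
windows abort with specific errors: a diagnostic pipeline should refuse to
over-interpret. Without patient genomic data the package only reports
which boundary of the span lacks a canonical site in the reference
(`scan_reference_boundaries()`) — a sequencing hint, not a call.

## Splice-site strength models

Three trainable model families score windows as log2 odds against a
background (uniform by default, overridable with an intronic base
composition):

* **Position-weight matrix** — independent per-position probabilities with
  Laplace pseudocount `(count + a) / (n + 4a)`; default `a = 1`, `a = 0`
  allowed for textbook examples. Score: `sum_i log2(p_i(x_i) / q(x_i))`.
* **First-order Markov** — an initial distribution plus position-specific
  transition matrices, capturing adjacent dependencies. Transition rows
  with no observations (possible only at pseudocount 0) fall back to the
  uniform distribution.
* **Maximum entropy** — the least-committed distribution matching
  empirical marginals on chosen position subsets (all pairs by default),
  capturing adjacent and non-adjacent dependencies. Fitting is cyclic
  iterative proportional fitting over the enumerated `4^L` state space,
  stopping when the largest marginal deviation falls below `tolerance`
  (default 1e-6) or after `max_iter` sweeps (default 1000), with
  convergence diagnostics stored on the model. With singleton constraints
  the fit provably collapses to the position-weight matrix — a useful
  cross-check that the tests exercise exhaustively over all 4^5 windows.

Exact enumeration bounds the maximum-entropy fit at window length 9, i.e.
donors. Acceptor 23-mers are deliberately **not** fitted approximately:
`4^23` states cannot be enumerated, and silently substituting an
approximation would misrepresent the method. Acceptors are scored with the
PWM and Markov models, and a documented hook
(`load_maxent_score_table()`) accepts externally published score tables
(two tab-separated columns, sequence and score) for either window kind,
which are then looked up verbatim.

The 0–100 consensus value normalizes a summed per-position frequency:
`100 (s - min) / (max - min)`. The shipped donor/acceptor frequency tables
(`inst/extdata/ss_*_freq.tsv`) are representative human splice-site
compilations; because published variants of this matrix differ across
sources and tool versions, exact reproduction of any specific published
panel requires supplying that source's table via
`ss_frequency_matrix(kind, path =)`. Deep-network gain scores are out of
scope as computation: they are accepted as `external_scores`, passed
through unmodified, and labeled with the conventional 0.2 / 0.5 / 0.8
bands.

## Consequence annotation

The mutant transcript is the reference mRNA with the strand-adjusted
pseudoexon sequence spliced between the flanking exons. Stop codons
(`TAA`, `TAG`, `TGA`; standard nuclear code) are scanned in the
translation frame from the insertion junction; all stops wholly inside the
pseudoexon are reported (their starts are necessarily congruent modulo 3)
plus the first stop downstream. Frameshift naming starts from the floor
rule — residue `floor(X/3) + 1` for an insertion after coding position `X`
— and advances past residues whose identity is unchanged, so a synonymous
first codon moves the named residue one on; the report carries both the
first affected residue and the count of preceding normal residues, because
published case tables conflate the two. In-frame insertions (length
divisible by 3) with no internal stop are labeled `in-frame insertion, no
PTC` and get no frameshift string. Termination-distance suffixes (`fs*N`),
readthrough and transcript-abundance effects (e.g. nonsense-mediated
decay) are out of scope.

## The synthetic generator

`make_toy_gene()` builds a fully coding multi-exon gene (ATG start,
terminal stop, no internal in-frame stops, canonical GT…AG introns) on
either strand over an i.i.d. background with configurable GC (default
0.40, intron-like). `plant_pseudoexon_cassette()` writes a splice-ready
cassette — 16-nt polypyrimidine tract + AG, interior sequence, GT +
consensus tail — into a chosen intron at a chosen depth, with exactly one
base deviating from functionality in the reference; the returned variant
restores it according to the chosen mode (donor/acceptor ×
created/strengthened). Ground truth (span, variant, HGVS strings,
frameshift residue, stop offsets, classification) is recorded from the
construction itself, not recomputed by the pipeline under test.

Generator defaults mirror the diagnostic setting: cassettes sit at least
200 nt from both exons (the "deep intronic" regime), interiors are at
least 20 nt, and the end-to-end suites span intron lengths from 1 kb to
70 kb, both strands, all four activation modes, frameshift and in-frame
cases — matching the offset range seen in real case series (from a few
hundred bases to >60 kb). Two constructions keep truth records exact: the
codon straddling the 5' junction is forced missense where the genetic code
allows it (for fourfold-degenerate families the first changed residue
moves to the next, fully internal codon and the truth moves with it), and
in no-PTC cases the 3' straddle codon is kept stop-free. A scrub pass
breaks any spurious donor-like signal elsewhere in the target intron whose
consensus value reaches the cassette threshold (default 85), so recovery
failures cannot hide behind accidental decoys; the scrub is itself
verified by an independent scan in the tests.

What the generator does *not* emulate: sequencing error, chromatogram
mixtures (isoform fractions are labels only), repeat families (an
adversarial duplicated-insert path is exercised explicitly in tests
instead), and real splice-site sequence composition beyond the planted
windows. Passing the synthetic suites therefore demonstrates coordinate
and inference correctness, not performance on noisy clinical data.

## Numerical and design choices

* Log base 2 everywhere; scores are comparable across models.
* Maximum-entropy fitting starts from the uniform distribution, so the
  fixed point is the maximum-entropy (not minimum-KL-to-background)
  distribution; the background enters only at scoring time.
* Empirical marginals use the same pseudocount as the other models
  (default 1), guaranteeing strictly positive, mutually consistent
  targets, hence IPF convergence.
* Insertion events report `ambiguity_span`, the number of equivalent
  placements; downstream junction anchoring re-aligns the event to the
  junction inside that span by rotating the inserted sequence, which is
  exact.
* Problem sizes in the shipped suites (100 end-to-end cases, exhaustive
  enumerations up to 4^5, one 2-kb exhaustive coordinate bijection per
  strand) were chosen to finish comfortably on a laptop while still
  exercising every mode and both strands.
* `merge_amplicons()` requires the overlap graph to be a simple path with
  unique successors; tiling ambiguity is an input problem, not something
  to resolve by majority.

## Known limitations

* Only single-SNV causal variants are inferred; multi-variant haplotypes,
  structural events and pseudoexons spanning annotated exons are out of
  scope.
* One transcript per gene model; no liftover between assemblies.
* The HGVS subset covers substitutions and the insertion range notation
  used in case tables — not duplications, delins, or protein extensions.
* Published score panels depend on their generating tools' training sets
  and versions; without those exact tables, implemented scores are
  comparable *within* this package (reference vs mutant deltas) but not
  numerically identical to any specific publication. Where one published
  value is internally inconsistent (a printed range length disagreeing
  with a stated size), the package flags the inconsistency and refuses to
  pick a side.
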