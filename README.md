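# pseudoexonr

Diagnosis of pseudoexon-activating deep intronic variants from transcript
and targeted genomic sequencing.

## The problem

Deep intronic single-nucleotide variants — hundreds of bases or tens of
kilobases away from any annotated exon — are invisible to exon-targeted
sequencing, yet they can create or strengthen cryptic splice sites. When an
intronic segment acquires a usable 3' acceptor (AG) upstream and a 5' donor
(GT) downstream, the spliceosome includes it in the mature mRNA as a
**pseudoexon**. The inserted segment typically carries in-frame premature
termination codons (PTCs) or shifts the reading frame, truncating the
protein. This mechanism is a recurrent cause of disease in very large
genes (the dystrophin gene, with ~2.4 Mb and 99% intron, is the canonical
example), and diagnosing it requires combining cDNA sequencing (which shows
the inserted segment) with targeted DNA sequencing (which finds the causal
base change).

`pseudoexonr` implements that diagnostic chain as reusable, tested R
functions, for geneticists and method developers who want the analysis
steps to be explicit and reproducible rather than buried in one-off
scripts:

1. **Insertion detection** — compare an observed transcript (or merged
   amplicon tiling) to the reference mRNA under an exact single-insertion
   model; events are left-aligned and ambiguity is reported, never guessed
   away (`find_insertion()`, `merge_amplicons()`).
2. **Intronic mapping** — locate the inserted segment as an exact,
   strand-adjusted substring of the intron at the affected exon–exon
   junction (`locate_in_intron()`).
3. **Resolution and variant inference** — keep only candidate placements
   flanked by AG…GT in the *mutant* intron, and call the causal variant as
   the single mismatch inside the donor 9-mer (3 exonic + 6 intronic) or
   acceptor 23-mer (20 intronic + 3 exonic) window
   (`resolve_candidates()`, `infer_causal_variant()`).
4. **Splice-site strength** — score reference vs mutant windows with three
   models trained from user-supplied signal sets: a position-weight matrix
   (summed log2 odds), an inhomogeneous first-order Markov model (adjacent
   dependencies), and a maximum-entropy model fitted by iterative
   proportional scaling to marginal constraints on arbitrary position
   subsets (adjacent *and* non-adjacent dependencies); plus the classic
   0–100 consensus value `100·(s−min)/(max−min)` over a per-position
   frequency matrix (`train_wmm()`, `train_mm1()`, `fit_maxent()`,
   `ss_percent()`, `score_panel()`).
5. **Consequence annotation** — HGVS-style c./p. strings with intronic
   offsets (`c.X+N`, `c.Y−N`), PTC scanning in the translation frame, and
   frameshift naming at the first residue whose identity changes
   (`consequence_report()`, `frameshift_annotation()`).

A deterministic synthetic-case generator (`make_toy_gene()`,
`plant_pseudoexon_cassette()`) builds multi-exon genes on either strand
with planted cassettes and complete ground truth, so the entire pipeline is
testable end to end without any external data.

Deep-network splice scores (e.g. SpliceAI gains) are **not** computed;
user-supplied values are passed through to reports untouched, labeled with
the conventional 0.2 / 0.5 / 0.8 recall/precision bands. Likewise, the
shipped consensus-value frequency tables are representative compilations —
supply your own published matrix via `ss_frequency_matrix(kind, path=)`
for exact conformance.

## Worked example

```r
library(pseudoexonr)

# a minus-strand toy gene whose intron 1 carries an 88-nt pseudoexon
# cassette 3164 nt deep, activated by a donor-creating C>G variant
gene <- make_toy_gene(seed = 404, n_exons = 3,
                      intron_len_range = c(7000, 9000), strand = "-")
case <- plant_pseudoexon_cassette(gene, intron_index = 1, pe_len = 88,
                                  depth = 3164, mode = "donor-created",
                                  seed = 10)
case
#> <synthetic_case> TOY1; intron 1; 88 nt; donor-created; c.352+3252C>G

an <- analyze_case(case$gene,
                   observed = simulate_transcripts(case)$seq[1],
                   patient_intron_seq = mutant_intron_seq(case))
an
#> <pseudoexon_call> intron 1; 88 nt; donor-created
#>   causal variant: c.352+3252C>G
#>   RNA: c.352_353ins352+3164_352+3251
#>   protein: p.Thr118Metfs

an$consequence
#> <consequence_report> ins after c.352; 88 nt pseudoexon (frame 1); frameshift
#>   protein: p.Thr118Metfs
#>   PTC offsets in pseudoexon: 14, 20
```

Reading the output: the 88-nt segment spliced in after coding position 352
originates 3164–3251 nt into intron 1; the patient intron differs from the
reference by a single C>G at position +3252 — the first base of the
created GT donor — so the call is "donor-created". The insertion shifts
the frame (88 mod 3 = 1) starting at residue 118 and the pseudoexon itself
carries premature stops at offsets 14 and 20.

`an$panels$donor` holds the reference/mutant/delta score panel; pass
trained models via `analyze_case(models = list(wmm = ..., mm1 = ...,
maxent = ...))` to add log-odds columns, and `external_scores = c(...)`
to carry through network scores.

A thin command-line wrapper with `simulate`, `analyze` and `score`
subcommands lives at `inst/cli/pexpipe.R`.

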