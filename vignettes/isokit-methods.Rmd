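---
title: "Methods and design of isokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of isokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`isokit` analyses polished full-length transcript reads (Iso-seq/ONT) from
alignment through annotation, quantification, differential isoform usage,
and somatic fusion calling. This vignette explains the models and the
choices behind them: what each stage assumes, which parameters matter, what
the synthetic data emulate, and where the design was genuinely open.

## Hybrid alignment assembly

Long-read spliced aligners optimize for contiguity and may absorb a short
exon into a neighbouring intron; spliced short-read aligners are sensitive
to junctions but fragment alignments. The assembly stage therefore combines
both: the read is scanned with sliding windows (length `h = 250` bp, step
`t = 100` bp; a read of length `L` produces `⌈(L−h+t)/t⌉` windows, the last
anchored at the read end), the windows are aligned as short reads, and each
read position collects the union of its long-read and window mapping
positions. A position with a single candidate is uniquely mapped; all
candidates at a position with `n` of them carry weight `1/n`.

The read is partitioned into maximal uniquely/multiply mapped blocks.
Multiply-mapped blocks of at most 10 bp adopt the long-read mapping;
longer ones are resolved in two steps. First, maximal consecutive candidate
runs are enumerated greedily: seed at the first unconsumed candidate
(scanning read positions left to right, candidates in chromosome/coordinate
order), extend while the next position offers a candidate exactly one base
downstream on the same chromosome, and repeat until every candidate belongs
to a run; a run's quality is the sum of its members' weights. Second, the
best combination of runs maximizes

$$\sum_h Q_{i_h} \;-\; \mu_1 O \;-\; \mu_2 k \;-\; \mu_3 D_1(A) \;-\; \mu_4 D_2(A)$$

with defaults $\mu = (2, 2, 1, 1)$; `O` is the total pairwise overlap of the
chosen runs in read coordinates and `k` their number. The search is
exhaustive for up to 12 runs and switches to a dynamic program over
read-sorted runs beyond that (there `O` is accumulated over consecutive
chosen pairs); ties prefer fewer runs, then the leftmost genome start.

Two points were open and are settled as follows:

* **Distance scale of `D1`/`D2`.** Raw genomic distances (intron scale, kb)
  would swamp the quality term, so the distance to a same-chromosome,
  correctly ordered anchor is `log10(1 + gap)`; a cross-chromosome or
  out-of-order anchor costs the constant 1000. The constant and the
  transform are configurable in `align_params()`.
* **Overlap coordinates.** `O` is measured in read coordinates: two runs
  explaining the same read bases are redundant regardless of where they sit
  on the genome.

The `−μ2·k` term is what rescues a merged exon: a long-read alignment that
forces a short exon into an intron carries the small indel scars of a forced
alignment and fragments into several runs, while the window mappings supply
one consistent run — which then wins despite being farther from its anchors.

Exon blocks and the junction chain are read off the resolved per-base
mapping; genomic gaps of at least 20 bp (`min_intron`) between consecutive
blocks become junctions, smaller gaps are treated as deletions inside an
exon, and chromosome changes or coordinate reversals open a new segment
(retained for fusion calling, not as junctions). Assembly operates on reads
in genome-forward orientation — the orientation in which an aligner reports
them — with the transcript strand carried alongside.

## Splice-site correction

Even a correct assembly can place a junction at the wrong end of a repeated
motif ("wobble"): when the bases entering the exon on one side equal the
bases leaving it on the other, several placements explain the read equally
well. Correction enumerates exactly these sequence-preserving placements
within ±15 bp (`radius`; no smaller set is safe, no larger one is useful
because wobble runs are short in practice) and picks one of them.

With the model, each candidate is scored by the product of its donor-window
and acceptor-window boundary probabilities. Windows are 21 bp in
transcription orientation; at scoring time they hold 10 exonic and 11
intronic bases, so the correct donor label is offset 10 and the correct
acceptor label offset 11. Ties fall to annotated junctions, then canonical
motifs, then the leftmost placement. Without the model — the deterministic
fallback mode, which is also the pipeline's behaviour when the network is
disabled — candidates are ranked by annotated-junction match, then canonical
motif (default set GT-AG, GC-AG, AT-AC; restrictable to GT-AG), then the
original placement. The fallback is fully deterministic, and correction
never changes the number of junctions or the read's chromosome segments.

The network is a three-block convolutional classifier — per block a 3×3
convolution with 50 channels, ReLU, and batch normalization — over the
21×4 one-hot matrix (A, C, G, T as unit vectors, N as zero), with a dense
softmax head over the 21 boundary offsets. There is no "not a splice site"
class: candidate generation guarantees a boundary lies in the window, and
the head scores *where* it is. Whether donor and acceptor should be scored
jointly was open; they are scored independently and multiplied, which keeps
the training target a single 21-way classification. Training uses Adam at
learning rate 0.01 with categorical cross-entropy on minibatches of 64.
Because no deep-learning backend is part of the package's dependency set,
the convolution, batch normalization, backpropagation, and Adam updates are
implemented directly on BLAS matrix products (an im2col formulation); the
implementation is exact, just small.

Training windows are sampled around every annotated splice site with `N`
exonic bases, `N` uniform on 1…10, so the boundary never sits at a fixed
offset; 90% of windows train the model and 10% validate it. Desk-scale
defaults are 50 epochs and a single repeat — on the synthetic annotations
the loss plateaus within a handful of epochs, so this is already generous —
while the large-scale settings (1000 epochs, 10 repeats, genome-wide
annotation) remain reachable through the `train_model()` arguments.
Checkpoints serialize to plain JSON so they stay text and portable.

## The synthetic world, and what it does not emulate

`make_world()` builds a multi-gene genome: 50 genes by default on two
chromosomes, 2–12 exons of 80–300 bp per gene, introns of 60–400 bp, up to
3 isoforms per gene where the extra isoforms are internal exon-skip
variants (so isoforms share junction subsets, which is what makes unique
counting and DIU non-trivial). Every intron carries an extended splice-site
consensus — donor `GTAAGT`, then random interior, then a 7-base
polypyrimidine tract and `CAG` — because real splice sites carry U1/U2
consensus well beyond the bare dinucleotides, and boundary-offset learning
is ill-posed on i.i.d. random intron sequence. This is the single most
consequential generator choice: it makes the correction benchmark
meaningful, and it was fixed before any benchmark was run.

`simulate_reads()` emits full-length reads and junction-preserving
5′-truncations (trimmed beyond the 100-bp end window so their truth class is
ISM), with per-read CCS support counts and optional substitution (default
0.5% where enabled) and 1–3 bp indel corruption (0.2%) applied jointly to
the sequence and the per-base truth mapping. Reads are in genome-forward
orientation with the source strand recorded, and truth mappings can be
written as SAM (`write_sam()`) so every test can bypass external aligners.
`corrupt_junctions()` shifts junctions within the ambiguity-preserving
wobble set (±5 bp by default) — the only corruption a mapper can make
without creating mismatches — and drives the correction-benefit protocol.

What the generator does **not** emulate: empirical PacBio/ONT error
profiles, quality scores, expression heterogeneity beyond a per-isoform read
count, degradation biases, antisense transcription, or overlapping gene
loci. Passing tests therefore demonstrate algorithmic correctness under
clean, well-specified conditions, not performance on tissue data.

## Annotation

The best reference match maximizes `L_TI − θ1·L_I − θ2·L_T`
(`θ1 = θ2 = 0.5`), computed on exonic bases, not genomic spans — span-based
overlap would reward intron coverage. Classification then proceeds in a
fixed order: no isoform overlap → Intergenic; a novel junction or breakpoint
joining two distinct genes, each side mapped with at least 20 bp and
overlapping exactly one gene → Fusion (checked before the novelty classes,
whose conditions a fusion read typically also meets); full junction-chain
match with both ends within 100 bp and no intron retention → FSM;
consecutive sub-chain without retention → ISM; only known donors and
acceptors (including retention of known introns, which uses only known
boundaries) → NIC; otherwise → NNC. Monoexonic reads: FSM against a
monoexonic reference using the same 100-bp end rule (the multi-exon rule,
reused rather than inventing a second threshold), ISM when both ends match
an exon of a multi-exon isoform exactly (those boundaries are splice sites,
which correction makes exact), else Genic. Junction matching after
correction is exact-coordinate; junction equality throughout the package is
(chromosome, donor, acceptor).

## Quantification and differential isoform usage

A read's junction chain counts for a known isoform only when it matches
consecutive junctions of exactly that one isoform; chains matching several
isoforms are excluded from expression. Novel reads cluster per class (NIC
with NIC, NNC with NNC) by chain containment, greedily in descending
junction-count order; the cluster id is derived from the seed chain so that
identical novel isoforms agree across samples. Expression is TPT — count ×
100,000 / total retained transcripts, each retained transcript counted once
regardless of classification (the CCS-weighted alternative is a flag, not
the default, since the totals the method quotes are transcript counts).
The `≥2` CCS filter (`filter_ccs()`) defines "retained".

The DIU filter operates on TPT as stated (both condition sums ≥ `Q = 4`,
every isoform's combined TPT ≥ `Q`, every isoform's share ≥ `P = 5%`), but
the test itself runs on the underlying integer counts, because Fisher's
exact test needs counts and TPT is a fixed within-sample rescaling. 2×2
tables use the exact hypergeometric test; m×2 tables use the exact network
algorithm with a seeded 100,000-draw Monte-Carlo fallback if the exact path
is infeasible. Adjustment is Benjamini–Hochberg ("the FDR method" made
concrete). The gene-level differential-expression helper (`deg_binomial()`)
applies the exact two-sided binomial test to gene counts — a deliberately
simple count-based method, documented as such.

## Fusion calling

Fusion-class reads group by ordered gene pair and breakpoint pair within
±10 bp (no tolerance is prescribed anywhere, so it is configurable;
10 bp absorbs indel jitter near breakpoints without merging distinct
isoforms of a fusion). Opposite orientations of the same gene pair remain
separate calls. The somatic filter keeps calls with at least one supporting
transcript whose CCS count is ≥2 — the "cluster" in that rule is one
polished transcript's CCS support — and removes calls the matched normal
supports with even a single CCS read; without a normal, calls are returned
flagged unfiltered. The fusion simulator concatenates random-breakpoint
prefixes and suffixes of transcripts from distinct genes, adds SNPs and
short indels, assigns 1–5 supporting reads per fusion, and samples
backgrounds from genes not used as fusion partners (standing in for the
public-cell-line backgrounds with known-fusion transcripts removed that the
full-scale protocol would use; no external data are downloaded).

## Evaluation protocols and problem sizes

The junction-recovery protocol deletes X% of genes from the annotation,
reruns annotation against the reduced reference, and scores the junctions
reported as novel against the deleted genes' junctions: sensitivity
TP/(TP+FN), precision TP/(TP+FP). The packaged checks run it at X = 10 on a
30-gene world; the acceptance suite further uses a 50-gene world for the
noise-free round trip, 1000 random instances for the exhaustive-search
equivalence of the combiner, an 80-gene world (≈1100 windows) for network
training, and two simulated fusion datasets of 25 fusions over 200
background transcripts. These sizes are chosen so the full suite documents
every guarantee in minutes on a laptop; all of them scale up through the
respective `*_config()` arguments.

## Numerical and degenerate-input choices

* Coordinates are 1-based closed internally (the IRanges convention of the
  R genomics stack); BED12 output converts to 0-based half-open.
* Combination-score ties break toward fewer alignments, then leftmost
  genome start; score comparisons use a 1e-9 tolerance.
* Unmapped bases inside a block carry weight 0 and never extend runs; a
  read with no candidate anywhere is reported unmapped, never an error.
* Degenerate contingency tables (a zero margin) return p = 1; the exact
  network algorithm's p-values are clamped at 1 (they can overshoot by an
  ulp).
* An empty positive set makes sensitivity NaN with a warning rather than an
  error.
* All generators and the trainer take explicit integer seeds and restore
  the caller's RNG state.

## Known limitations

* The DP regime of combination selection (beyond 12 runs) approximates the
  pairwise overlap term by consecutive-pair overlaps; exhaustive search is
  authoritative and covers every instance the protocols generate.
* Position-matrix candidates are not filtered against the genome sequence,
  so a systematically wrong but internally consistent long-read mapping
  with no short-read dissent is accepted as mapped.
* Monoexonic ISM detection requires exact exon-boundary agreement; a
  1-bp-off monoexonic read falls to Genic.
* The CNN scores donor and acceptor windows independently; cooperative
  donor-acceptor effects are not modelled.
* DIU compares exactly two samples; replicate-aware dispersion modelling is
  out of scope.
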