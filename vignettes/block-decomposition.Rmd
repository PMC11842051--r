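---
title: "Block decomposition of repeat-rich genomes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block decomposition of repeat-rich genomes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdblocks)
```

## The model

A genome (one or more chromosomes, possibly from several labelled
genomes) is viewed as a traversal of its condensed de Bruijn graph
DB~k~: vertices are (k−1)-mers, edges are maximal non-branching paths,
and each chromosome is a walk that visits every edge at least once. The
graph is *bidirected over canonical k-mers*: a k-mer and its reverse
complement are one object, so an inverted duplication appears as a single
edge traversed in both orientations, and reverse tandem duplications are
ordinary multiplicity-2 edges. Edges carry per-genome multiplicities
recomputed from the walks, which makes multiplicity conservation hold by
construction after every transformation.

If all duplications were exact, the repeated edges of DB~K~ (for K = the
minimum block size of interest) would directly be the duplication blocks.
Because real copies have diverged, the package first *untangles* the
genome: for each k in an increasing schedule it rebuilds DB~k~, finds
**bubbles** — two walk subpaths that start at the same vertex, end at the
same vertex and share no other vertex or edge — and collapses the
similar ones by rewriting the genome text, until a fixpoint is reached;
then k advances. A 1–1 bubble is *simple*; an N–M bubble is *complex*
with complexity max(N, M), considered only up to `bubble_max`. Percent
identity is defined globally and indel-aware,
PI(a,b) = 1 − d~edit~(a,b)/max(|a|,|b|), computed with a bit-parallel
(Myers) edit-distance kernel with an early-exit bound, so dissimilar long
path pairs are rejected cheaply. A simple bubble collapses when
PI > `sim_strong` (default 0.90); a complex one when PI > `sim_weak`
(default 0.65). The spelled paths enter the comparison with their shared
terminal (k−1)-mers trimmed to at most 50 bp of context per side: at
small k the flanks are legitimate alignment context, but at large k they
would dominate the comparison and make any two parallel paths look
similar (two unrelated 3 kb insertions share 2 × 1999 bp of flank at
K = 2000). Collapsing substitutes every genomic occurrence of the path
with the shorter spelling by the longer spelling (on ties, the
lexicographically smaller canonical spelling survives; comparing
canonical spellings makes the choice independent of the orientation in
which the bubble happened to be enumerated).

### Why the fixpoint terminates

The raw definitions permit pathological rewriting at small k: almost any
two short paths share endpoints in a dense graph, and replacing shorter
spellings by longer ones can grow the genome indefinitely. Two
restrictions make every applied collapse strictly reduce the number of
distinct k-mers in the genome, which bounds the whole procedure:

* a bubble is applied only when **all** occurrences of the rewritten path
  can be rewritten in the current scan (occurrences conflicting with an
  earlier rewrite defer the whole bubble to the next scan), and
* at least one edge of the rewritten path must be used **exclusively**
  inside those occurrences, so its k-mers vanish; the replacement
  introduces no new k-mers because its text, junctions included, spells
  k-mers of the surviving path.

Rewrites preserve the left-flank (k−1)-mer in place, so occurrences that
merely touch at a shared vertex do not conflict. As a belt-and-braces
guard the scan loop also stops at a given k when the distinct-k-mer count
fails to decrease. The k schedule doubles geometrically from `k_init`
(default 21) and always ends exactly at `K`; `K` has no universal default
and is required per run (1–2 kb is the usual choice for
segmental-duplication analysis at locus scale).

## Block inference

In DB~K~ of the untangled genome, the *block graph* keeps exactly the
edges of total multiplicity ≥ 2. Maximal non-branching paths of the block
graph are merged into single blocks — the rule that keeps the block
alphabet small. Crucially, merging ignores multiplicity disagreements
along the path: a walk that enters or leaves a merged path midway simply
produces a *partial instance* with recorded consensus offsets, which is
why instances of one block may have very different lengths. (An earlier
stricter rule — merge only edges that are always traversed together —
fragments a block whenever one copy has residual divergence within the
first few bases, and was rejected for that reason.) Tandem arrays close
the chain into a cycle; walks split into one instance per period because
an instance only extends while the chain position advances by one.

Adjacent instances overlap by exactly K−1 characters at a shared vertex;
the overlap is assigned to the *later* instance, which therefore starts on
its underlying repeat boundary — in a tandem array the instance grid then
lines up with the periods (assigning the overlap to the earlier instance
would shift every start by K−1). At a junction between a block and
non-repetitive sequence the block instance keeps the overlap for the same
reason. An instance is folded back into non-repetitive sequence when its
raw extent is below `min_block_len` (default K) or when overlap
resolution consumed more than two thirds of it — the signature of a
boundary-artifact block (a few class-specific bases plus a K−1 flank)
riding on a real one. Trimming is recomputed from the raw coordinates
until stable, so folded instances stop claiming space. Blocks are lettered A, B, … (then AA, AB, …) by first
genomic occurrence; reverse-strand instances are marked with a prime in
`block_string()` and partial instances as `A[start,end]`.

## Lift-over

Untangling only rewrites bubble regions, so the original and untangled
chromosomes are globally colinear. Each chromosome pair is split at
shared unique 64-mer anchors (thinned to roughly one per kilobase and
chained colinearly with each diagonal jump penalized by its size, so a
run of anchors relocated by a repeat period — untangling moves text
between copies — cannot drag the chain off phase) and each piece is
aligned exactly by an adaptive banded dynamic program with deterministic
tie-breaking (match > mismatch > delete > insert). Instance boundaries
map through the transcript; a boundary inside an inserted run maps to the
run's left edge, which keeps the half-open tiling exact. Percent identity
of every lifted instance against its block consensus is recomputed on the
original sequence.

## Comparing genomes

Joint decomposition simply runs the same pipeline on the combined
string-set, so all genomes share one block alphabet (a genome analysed
alone may legitimately get a different alphabet — the graphs differ). An
edge is *imbalanced* when its per-genome multiplicities are not all
equal, and a block is imbalanced when any edge on its path is. The
differential report adds per-genome instance counts, total instance
lengths and — when annotations are supplied — the number of genes fully
contained in an instance of each block; a gene straddling an instance
boundary is deliberately not counted, containment being the only
unambiguous rule.

## Gene windows

For each annotated gene inside a block instance, a window of
`window_len` (default 100) bp centred on the gene midpoint (clipped at
the instance edges, and widened if the gene itself is longer) is cut from
the anchor instance, placed onto every other instance of the same block
through the global instance-to-instance alignment, and re-aligned there.
The *window PI* is the identity of that alignment; the *gene PI* is the
identity of the sub-alignment of the columns touching the gene
(insertions strictly inside the gene count against it). A copy is
*disrupted* when the window PI falls below `min_pi` (default 0.60) or the
RSS heptamer plus nonamer differ by more than `max_diff` (default 2)
substitutions; RSS motifs are compared gap-free at their aligned
positions and an indel in either motif is an automatic fail. RSS
coordinates must be supplied with the annotations (extra BED columns);
motif discovery is out of scope. Whether gene PI should count indels is
not settled usage; the package uses the same edit-distance PI as
everywhere else.

## The simulator

`plant()` emulates the duplication landscape the decomposer targets:
kilobase-scale blocks planted on an i.i.d.-uniform random backbone as
dispersed copies, tandem arrays or reverse-tandem (inverted) arrays, each
copy independently mutated from its progenitor with per-site
substitutions and single-base indels (defaults: blocks of 3–10 kb, 2–5
copies, 1–5% substitution divergence, indel rate one tenth of the
substitution rate, on a 200 kb backbone — the scale and divergence of
recent segmental duplications in loci such as IGH). Gene intervals
inside a block can carry an elevated local substitution rate to emulate
gene-local divergence. Every planted copy is recorded in a truth table
with its realized identity to the progenitor, and `pair_variant()`
derives a second genome with known copy-number changes. A reverse-tandem
pair is separated by a short unique spacer (default 100 bp): an exactly
adjacent copy and its reverse complement form a perfect palindrome whose
hairpin walk hides the repeat from any k-mer representation, and real
inverted duplications carry spacers too. The backbone is uniform random,
so it contains no repeat families, no GC structure and no
mutation-rate heterogeneity beyond the planted genes; passing tests show
that the algorithm recovers planted architectures, not that it handles
Alu/LINE-saturated sequence.

## Numerical and design choices

* **Boundary accuracy.** A de Bruijn decomposition carries an inherent
  boundary ambiguity of up to K−1 from the overlap-assignment convention
  (clearest at tandem-array junctions); dispersed-copy boundaries
  typically land within a few tens of bases of the truth, limited by
  divergence within `k_init` of a copy end, which no bubble can anchor.
* **Degenerate inputs.** N runs split walks; fragments shorter than k are
  carried as clips and rejoin at lift-over. Sequences shorter than k are
  an error. Empty strings have PI 1 to each other and 0 to anything else.
* **Determinism.** There is no randomness anywhere in the pipeline; all
  orderings use locale-independent (radix) comparisons; the simulator is
  deterministic given its seed.
* **The toy example.** `toy_genome()` reproduces the pedagogical
  two-repeat example at `k_init = 4`: at k = 3 only ten canonical 2-mer
  vertices exist, so the graph of any ~90 bp sequence is saturated with
  aliasing and no clean bubble structure can exist; k = 4 is the smallest
  usable size. Its spacers are constructed so that no canonical 4-mer
  outside the planted repeats occurs twice, and the simple-bubble
  threshold is relaxed to 0.75 because one substitution in an 8 bp repeat
  leaves only 87.5% identity. In the bidirected graph two of the three
  pairwise variant bubbles are representable (the C- and G-variant paths
  alias through reverse complement); the forward-strand graph
  (`strands = "forward"`) shows all three.
* **Problem sizes.** The test-suite simulations use 200 kb backbones with
  five planted blocks for recovery checks, 30 kb two-genome pairs for
  imbalance checks, and 20 kb fixtures for the gene-window analysis —
  sizes at which every property of interest is already expressed.

## Limitations

Blocks more diverged than `sim_weak` at every bubble are (by design)
never merged; ancient, highly diverged SDs are out of reach of the
similarity thresholds. Complex bubbles beyond `bubble_max` edges are not
collapsed, so extremely mosaic regions may stay fragmented. The
chromosome-scale aligner assumes colinearity between the original and
untangled sequence, which untangling guarantees, but it is not a general
rearrangement-aware aligner, and alignment of two genomes' block strings
to each other is left to the user.
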