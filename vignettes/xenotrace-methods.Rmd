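---
title: "Detecting MGE dissemination by subtractive metagenomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting MGE dissemination by subtractive metagenomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Parallel microbial communities that exchange only sub-cellular material
(phages, plasmids, vesicle-borne or naked DNA — material passing a 0.2 µm
filter) offer a way to observe mobile genetic elements (MGEs) without
reference databases: an element that arrives in a community and amplifies
there becomes detectable as *new sequence* relative to that community's own
past. Two different processes, however, produce new sequence in a
longitudinal metagenome:

1. **demographic change** — a resident taxon, initially below the
   metagenomic detection limit, grows until its genome assembles; and
2. **horizontal dissemination** — an element genuinely arrives from an
   allopatric (different-lineage) community.

The method separates these with three stages:

* **find** — reads of a derived sample are mapped against contigs
  assembled from the same community's *ancestral* sample (the bait).
  Unmapped reads are assembled into **unique contigs**: sequence novel to
  the community. Both processes above produce unique contigs.
* **link** — unique contigs are aligned against the ancestral assemblies
  of all *other* communities. A contig with at least one high-scoring
  local alignment of **≥ 300 bp at ≥ 99% nucleotide identity** to an
  allopatric ancestry is a **xenotypic contig**, and the matching
  community its candidate **donor**. Demographic amplification cannot
  produce such links when community ancestries are distinct, so the
  contrast between unique and xenotypic counts — and between horizontal
  and no-transfer (vertical) control communities — isolates genuine
  dissemination.
* **trace** — reads from every sample are mapped onto the xenotypic
  contigs, yielding per (contig, sample) **depth** (mean per-base
  coverage) and **breadth** (fraction of positions covered), the
  dissemination matrix over communities and timepoints.

The 300 bp / 99% thresholds deliberately target sequences that diverged
recently and are still nearly identical; the method is not designed for
transfer detection across larger evolutionary distances.

## Pipeline parameters

| parameter | default | unit | role |
|---|---|---|---|
| `k_map` | 21 | bases | seed k-mer for read mapping; tolerant of read errors |
| `k_link` | 31 | bases | seed k-mer for contig linking; enforces the near-identity regime |
| `k_assembly` | 31 | bases | de Bruijn graph order (single-k assembly) |
| `min_identity` | 0.90 | fraction | mapping identity floor for "read belongs to ancestry" |
| `min_aligned_frac` | 0.60 | fraction | minimum read fraction aligned |
| `link_min_len` | 300 | bases | minimum qualifying HSP window |
| `link_min_id` | 0.99 | fraction | minimum qualifying window identity |
| `min_query_len` | 300 | bases | contigs shorter than this are not linkable; set 10000 for a >10 kb analysis preset |
| `trim_window`, `trim_min_q`, `trim_min_len` | 4, 20, 40 | bases, Phred, bases | 3' sliding-window trimming |
| `min_edge_cov` | 2 | count | absolute k-mer multiplicity floor |
| `tip_len_factor` | 2 | × k | tips shorter than this are removed |
| `min_contig_len` | 200 | bases | assembly output floor |

The subtraction thresholds (`min_identity`, `min_aligned_frac`) are
surrogates for the effective stringency of a general-purpose short-read
mapper run with defaults. They are deliberately permissive: a read
spanning an insertion junction still aligns to ancestry over most of its
length and is therefore *removed*, so only reads fully inside novel
sequence survive subtraction. Both remain configurable because no single
pair of values reproduces any particular mapper exactly.

The reference ("ancestral") sample for a derived sample at timepoint *t*
is, by default, the same community's sample at the largest timepoint
earlier than *t* (serial chaining); `ancestor_mode = "first"` instead
always compares against the earliest sample. Serial chaining matches a
serial-transfer experiment in which each sampling round seeds the next.

## The alignment engine

One canonical k-mer index (a k-mer and its reverse complement share an
entry; k ≤ 31, packed 2 bits/base) serves both mapping and linking.

**Read mapping** collects seed hits, groups them by (contig, strand,
diagonal band), and scores up to 32 candidate groups with a banded local
alignment (match +1, mismatch −2, linear gap −3, band half-width 16).
A read is mapped when some candidate reaches the identity and
aligned-fraction thresholds; the reported placement maximises score with
deterministic tie-breaking (lexicographic contig id, then smallest
position). Each mate of a pair is classified independently, mirroring
per-read unmapped flags. N never matches anything and never seeds.

**HSP discovery** chains seeds along diagonals (drift up to the band,
query gaps up to 400 bp) and extends each chain with the same banded
local alignment; overlapping same-(subject, strand) HSPs keep the highest
score. Subject coordinates are always reported on the subject forward
strand; everything is 0-based half-open internally, and 1-based inclusive
only in the BLAST-style tabular export.

**Window qualification.** The maximal-*scoring* local alignment of a
shared block legitimately extends a few chance-matching flank columns
(any net-positive excursion), which dilutes identity: a 300 bp block with
3 substitutions (identity exactly 0.99) reported as a 310-column HSP
falls below the 99% threshold even though the block itself qualifies.
Each HSP therefore also carries the longest alignment window whose
identity is at least the linking threshold (computed exactly with integer
arithmetic by a prefix-sum monotonic stack, O(columns)), and linking
qualifies on `win_len ≥ 300` and `win_identity ≥ 0.99`. This preserves
the boundary semantics: a 299 bp exact block or a 300 bp block with 4
substitutions never qualifies.

## The assembler

A single-k (default 31) canonical de Bruijn graph with unitig output:
maximal non-branching walks, canonically oriented (lexicographically
smaller of sequence/reverse complement) and sorted, so identical read
multisets give byte-identical FASTA in any input order. Cleaning iterates
three rules to a fixpoint (hence it is idempotent):

* drop edges with multiplicity `< min_edge_cov` (isolated errors);
* drop edges weaker than **1/8 of their strongest sibling** at a branch
  point. At high coverage, the same error recurs (two reads with the same
  substitution at the same position) and passes any small absolute
  cutoff; only a coverage-relative rule removes these without harming
  genuinely low-abundance replicons, whose branch-free edges have no
  dominant sibling. The ratio is exposed (`junction_rel`);
* remove tips (walks dangling at exactly one end) shorter than
  `tip_len_factor × k` bases. Isolated short walks are kept and handled
  by the output length floor.

A single-k assembler cannot reproduce the exact contig set of a multi-k
metagenome assembler; equivalence is claimed only at the reconstruction
level: a repeat-free source covered ≥ 20× by error-free reads returns one
unitig equal to the source (up to reverse complement, length within
±(k−1) from ragged end coverage).

## Read trimming

Quality trimming is reduced to 3' sliding-window mean-quality trimming
(window 4, threshold Q20, floor 40 bp): while the trailing window's mean
quality is below threshold the whole window is cut, then the next
trailing window is inspected. This captures the quality-dependent read
shortening that matters for mapping without reproducing a full read-QC
stack; adapter removal is omitted because simulated reads are
adapter-free. Surviving bases are never altered — output is always a
prefix of the input. Only derived (query) reads are trimmed; ancestral
reads enter assembly as given, and trace maps reads as given, with the
same thresholds as subtraction ("a read supports a contig" has a single
definition).

## The mock-community simulator

The generator defines the study conditions for all end-to-end checks:

* **communities** from disjoint pools of i.i.d. random genomes (default
  6 × 100 kb per community, GC 0.5). Random genomes are repeat-free at
  k = 31 with overwhelming probability, which makes assembly truth
  unambiguous; a loader accepts user FASTA genomes when realistic genome
  structure is wanted.
* **abundances** either even (1/G) or skewed geometrically
  (a_i ∝ 0.3^i — "highly skewed": the top two genomes carry ~91% of the
  community; the ratio is exposed).
* **transfer events**: each element is a random slice of a *donor*
  genome — so the donor's ancestral assembly provably contains it — and
  enters the recipient's derived community either **integratively**
  (spliced into a host genome at a random position) or **episomally**
  (an extra replicon at the host's abundance × copy number).
* **reads**: paired 2 × 150 bp, fragments ∝ abundance × replicon length,
  positions uniform, insert 400 ± 50 (truncated Gaussian), i.i.d.
  substitution errors at 0.1% (default) or 1% (ten-fold elevated), constant
  Phred quality equal to the error rate's Phred equivalent, no indels
  (flag reserved). Default 40,000 pairs/sample ≈ 20× community coverage.
  Read ids record replicon, fragment start and strand, so subtraction
  behaviour can be audited read by read.
* an optional **demographic confounder**: a rare taxon present
  ancestrally at 0.05× expected depth (far below any assembler's
  reconstruction threshold) amplifying to 30× in the derived sample —
  new sequence without transfer.

What the simulator does *not* emulate: real genome repeat structure,
GC-dependent coverage bias, Illumina error profiles (position- and
context-dependent, with indels), PCR duplicates, strain-level variation
within a community, and overlapping community ancestries. Passing the
benchmark therefore demonstrates the pipeline's logic — subtraction,
linking thresholds, donor attribution, confounder rejection — not its
performance on real compost metagenomes, where shared ancestry between
communities is known to produce a low rate of spurious links.

Scoring: an event is *recovered* when xenotypic contigs of the recipient
cover ≥ 50% of the element at ≥ 99% identity **and** at least one link
names the true donor. The 50% coverage threshold is a documented choice
(no published pass/fail criterion exists for this); recovery at the
default conditions is in practice insensitive to it because observed
element coverage is ≈ 99%. Precision is the fraction of linked-contig
bases matching any true element; with zero events and zero calls both
precision and recall are reported `NA`, never 0.

## Statistics

Enrichment of MGE annotation categories (phage, plasmid, IS, ICE,
integron — free strings in the implementation) in xenotypic contigs is
tested against length-matched control sets drawn from the whole-community
contig pool: reference lengths are binned into 10 log-spaced bins and
each of 4 control sets samples, per bin and without replacement, the same
count (mutually disjoint sets; an under-filled bin borrows from the
nearest non-empty bin and flags the set). Counts of *annotations* (not
proportions) are compared — matching an annotation-count readout — with
the Crawford–Howell single-case t-test,

t = (x* − mean(controls)) / (sd(controls) · sqrt((n+1)/n)),  df = n − 1,

whose inflation factor keeps the type-I error calibrated at small n
(verified at α = 0.05 over 10,000 null replicates). The test is two-sided
by default — both over- and under-representation are of interest — with
one-sided alternatives available. Bonferroni adjustment across categories
is applied via `stats::p.adjust`. Degenerate controls (sd = 0) return
p = 1 when the case equals the control mean, and otherwise the machine
floor with an explicit degeneracy flag rather than a fabricated zero.

## Numerical and determinism choices

* Coordinates are 0-based half-open everywhere internally.
* All k-mer structures are canonical; odd k makes reverse-complement
  palindromes impossible.
* Every traversal iterates sorted keys, all outputs are sorted, and
  unitigs/contigs are canonically oriented: identical inputs give
  byte-identical outputs regardless of read order or worker count.
  Parallelism (forked workers over per-sample work units) is therefore an
  implementation freedom; sample work units share no state.
* A single global seed is expanded into per-sample and per-genome streams
  by a deterministic polynomial hash of (seed, label), keeping all seeds
  below 2^31.
* k is limited to 31 (2-bit packing in 64-bit words); all defaults sit
  well inside this.
* Identity thresholds are compared with a 1e-12 slack so that exact
  rational boundaries (297/300 = 0.99) are decided by arithmetic, not by
  floating-point representation.
* Degenerate inputs: an empty contig set yields an empty index (reads
  are then trivially unmapped); zero unmapped reads yield an empty — and
  valid — unique contig set; an empty xenotypic set yields a header-only
  trace table.

## Problem sizes used in the checks

The packaged tests run the full default benchmark (4 communities,
6 × 100 kb genomes, 40,000 pairs/sample), the hard benchmark (ten-fold
error, skewed), and the confounder scenario (2 communities, 3 × 50 kb
genomes) end to end; mapper correctness is checked against an unbanded
Smith–Waterman oracle on 1000 random read/contig cases (reads ≤ 100 bp,
contigs ≤ 2 kb); assembler reconstruction on a 10 kb source at 30×.
These sizes were chosen so that each property is exercised at full
fidelity while a complete run stays desk-scale.

## Known limitations

* Linking presumes distinct community ancestries; overlapping ancestral
  pools produce spurious links that the vertical-control contrast can
  bound but not remove.
* The 99%/300 bp regime misses anciently diverged homologs by design.
* The subtraction thresholds are surrogates for a specific short-read
  mapper's behaviour and the single-k assembler for a multi-k one;
  absolute unique-contig counts therefore depend on these choices even
  when the horizontal/vertical contrast does not.
* Episomal elements are simulated at a fixed copy number relative to
  their host; real copy-number dynamics (and hence detection power for
  low-copy plasmids) are not modelled.
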