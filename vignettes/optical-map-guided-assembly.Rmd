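---
title: "Optical-map-guided assembly: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical-map-guided assembly: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omguide)
library(dplyr)
```

`omguide` assembles long sequencing reads under the guidance of a
genome-wide optical map. This vignette explains the underlying model and
the assumptions it makes, the parameters that matter and why their
defaults are what they are, what the built-in simulator does and does not
emulate, and the design decisions taken where the procedure left genuine
freedom.

## The guidance model

An optical map reduces a DNA molecule to the ordered lengths of the
fragments between restriction sites. For a known sequence the map is
computed exactly (*in silico digestion*); for a genome it is measured.
The central idea is a change of currency: instead of asking whether two
reads overlap by sequence alone, every read is stamped with an
approximate genomic address — a *color* — derived from the map, and the
overlap graph is then cleaned with those addresses.

Reads are too short (and their own maps too fragment-poor) to place on
the genome-wide map directly. The pipeline therefore bootstraps:
unguided (pre-coloring) contigs are assembled first, placed on the map,
colored, and the colors are handed down to the reads through ordinary
read-to-contig alignments. The guided (post-coloring) assembly then
removes *inconsistent* edges — overlaps whose endpoint colors run
backwards or jump too far — so that each surviving maximal non-branching
path is a *rainbow path*: its colors appear in non-decreasing order.

Assumptions worth stating explicitly:

* fragments of the reference map are long enough that neighboring reads
  usually share a color or sit one color apart (the consistency rule
  compares colors at resolution `d`, default 1);
* contigs span enough map fragments that their placement is determined
  by fragment-length (sizing) evidence;
* read errors are low enough (error-corrected reads) that restriction
  sites survive in contig sequences.

## Map alignment and the s-score

A contig map is aligned to each chromosome map by dynamic programming
over *monotone block decompositions*: consecutive query fragments (at
most `max_block_span` of them) match consecutive reference fragments,
blocks advance strictly in both maps, the query must be fully covered,
and the reference window is free. A block with query length $q$ and
reference length $r$ (kb) contributes

$$\text{match\_score} \;-\; \frac{1}{2}\Big(\frac{q-r}{\sigma\sqrt{r}}\Big)^{2}
\;-\; \text{missed\_cut}\cdot(M-1) \;-\; \text{false\_cut}\cdot(N-1),$$

where $\sigma$ = `sizing_sd_per_kb`. Sizing noise is modeled with a
standard deviation growing like $\sqrt{r}$, the usual behavior of
length-measurement error on restriction maps. Merging $M$ reference
fragments hides $M-1$ reference cuts (missed cuts in the query); merging
$N$ query fragments introduces $N-1$ spurious query cuts. The total is
the alignment's **s-score**; the scoring is a likelihood-flavored fit
designed so that *higher is better and a perfect identity alignment is
maximal* — numerical agreement with any particular external aligner is
not a goal.

Two refinements matter in practice:

* **Boundary fragments.** A contig begins and ends mid-fragment, so its
  first and last blocks are truncations; they are penalized only for
  overshoot ($q > r$). Without this, every correct global placement of a
  contig is rejected as soon as the sizing term is tight.
* **Tight default sizing.** `sizing_sd_per_kb = 0.1` reflects maps
  digested in silico from lightly erroneous (~0.5 %) sequence, where
  interior fragment lengths are accurate to a few hundred bp. Real
  measured optical maps need a substantially larger value (0.5 or more);
  the parameter, like all scoring constants, lives in
  `inst/extdata/default_config.yaml`.

Defaults `match_score = 5`, `missed_cut_penalty = 3`,
`false_cut_penalty = 3` keep a genuine multi-fragment placement well
above zero while making each unexplained cut expensive relative to the
per-block bonus. `min_s_score = 0` by default: every contig that aligns
at all is used for coloring, which experimentally beats discarding
low-scoring placements. Ties between equally scoring placements resolve
deterministically (reference order, then forward orientation, then the
leftmost reference window).

## Coloring

Reference fragments are numbered $k \cdot s + i$ for chromosome $k$ and
fragment $i$, with $s$ the smallest power of ten exceeding the largest
fragment count, so colors are unique genome-wide and the $k \cdot s$
term identifies the chromosome. Colors transfer to contigs blockwise:
$N$ contig fragments of total length $n$ matched to $M$ reference
fragments of total length $m$ are replaced by $M$ fragments of lengths
$\mathrm{ref}_u \cdot n / m$ carrying the reference colors — reference
proportions are kept, block length is conserved (machine-checked to
$10^{-9}$ relative).

Reads are colored from their best read-to-contig alignment (most
matching bases; ties by longer alignment, then target name). The default
policy is the strict one: if the globally best alignment lands on an
uncolored contig, the read stays uncolored, and in every mode a read is
only colored when its matching bases reach `match_fraction` (default
0.8) of its length. The aligned contig interval, optionally extended by
the read's unaligned tails (clamped at contig ends — colors cannot
extend past existing fragments), is converted to colors by cumulative
fragment length: the start (end) color belongs to the first fragment
whose cumulative length *strictly exceeds* the interval start (end).
The strict inequality is a deliberate convention; a coordinate equal to
a boundary selects the next fragment.

Unused colors (regions not covered by any colored read) would leave gaps
that make physically adjacent reads look distant, so used colors are
renumbered order-preservingly onto consecutive integers per chromosome;
every color inside a read's `[start, end]` interval counts as used. The
renumbering is a bijection on used colors and idempotent. Internally
chromosome blocks start at $k \cdot s$; a configurable `base` offset
accommodates 1-based numbering conventions.

## Guided graph cleaning

The overlap graph is bidirected — two oriented vertices per read, twin
edges in mirrored orientations — following the standard assembly-graph
convention. Construction is miniasm-style: overhang classification of
PAF records, containment and internal-match removal, an overlap-length
floor, and fuzz-tolerant transitive reduction (an edge implied by a
two-edge path of consistent total length is dropped; `reduce_fuzz`
absorbs coordinate noise).

An edge $(u, v)$ survives color filtering iff

1. some color of $v$ equals or exceeds some color of $u$ by at most `d`
   (`max_color_step`, default 1), and
2. the color interval does not move backwards:
   $\mathrm{start}_v \ge \mathrm{start}_u$ and
   $\mathrm{end}_v \ge \mathrm{end}_u$.

Condition 1 is the classical consistent-edge rule. Condition 2 is this
package's interpretation of "the colors of $v_i$ must not be larger"
for two-color vertices: without it, an edge such as
$\{5,9\} \to \{5,6\}$ survives through the $9 \to 9$ pair, and paths
exist on which no non-decreasing color assignment is possible — the
rainbow guarantee would be false. With condition 2 the end colors are
always one witness assignment, so the guarantee holds; it is also
asserted at run time on every colored unitig, turning any future
filtering regression into a hard error rather than a silent
misassembly.

Uncolored reads take no part in guided assembly: with propagation
disabled (the default, which was also the best-performing configuration)
they are simply removed. Optionally (`propagation_limit = L`, the
guided assembler's own default being 5) an uncolored read collects the
colors of colored reads reachable within $L$ hops through uncolored
reads; a contiguous collected interval colors the read with its
`{min, max}`, anything else (including collecting nothing) deletes it —
an incoherent propagated coloring is not trusted.

Unitig extraction consumes each *read* (not each oriented vertex) once,
realizing longest paths first, so a unitig's reverse-complement twin —
whose arcs color filtering may have removed asymmetrically, since the
reverse traversal runs against the genome — is never emitted alongside
it. Layout is consensus-free: the first oriented read plus each
successor's non-overlapping suffix, disagreements resolved in favor of
the earlier read.

## The simulator

The generator exists to make every stage testable offline, under the
regimes of the original study scaled to desk size:

* **Genome**: uniform random DNA, 2 chromosomes of 150 kb, XhoI motifs
  planted at exponential spacing with mean 10 kb. Spontaneous motif
  occurrences in the background are disrupted (one base changed), so the
  realized map density equals the configured one — in a real genome this
  quantity is pinned by the sequence; a simulator must control it or the
  `site_density` parameter would be meaningless. The 10 kb default keeps
  the two scale relations the method relies on: fragments several times
  longer than the typical spacing of containment-surviving reads (~3 kb
  at 20x), and contigs (tens of kb) spanning many fragments, mirroring
  the genome-scale setting where contigs span hundreds.
* **Reads**: log-normal lengths with mean 8.2 kb (the simulated PacBio
  regime) and sd 3 kb, coverage 40x by default, drawn uniformly with
  fair strands; substitutions then indels at 0.3 %/0.1 %/0.1 % — a 0.5 %
  total standing in for error-corrected reads (error correction itself
  is out of scope). Ground truth records exact intervals.
* **Maps**: noise-free by default, reproducing the error-free in-silico
  setting of the original experiments; `perturb_map()` adds sizing
  noise, missed cuts, and Poisson false cuts for robustness studies.

What the simulator does **not** emulate: realistic PacBio error
profiles (burst indels, quality-dependent rates), chimeric reads,
coverage biases, heterozygosity, and real optical-map artifacts
(molecule stretch, limited label efficiency). Passing tests therefore
demonstrate the correctness of the algorithms and the behavior of the
method under its own stated assumptions — not performance on real
sequencing data, for which an external overlapper via the PAF interface
and re-estimated scoring constants would be the starting point.

The built-in overlapper is likewise a deliberately simple exact-seed
device (window minimizers, diagonal voting, banded global verification
with unit scores; band 48 covers the indel drift of low-error reads;
overlaps below 90 % identity are rejected, separating true overlaps at
~98 % from repeat-plus-flank artifacts at ~75 %). It exists so the test
suite needs no external tools; any overlapper producing PAF can replace
it.

## Numerical choices and degenerate inputs

* Cut coordinates are 0-based prefix lengths; a cut at `motif_start +
  cut_offset`. `N` never matches a motif base. Cuts at position 0 or at
  the sequence end would create empty fragments and are discarded.
* Motifs longer than the sequence yield a single whole-length fragment,
  not an error; empty sequences and empty maps are errors.
* Map-alignment ties take the smallest reference end index; query pairs
  with no feasible decomposition (more query fragments than
  `max_block_span` times the reference) return no alignment.
* Block-length conservation is exact up to floating point; the test
  suite bounds the relative error at $10^{-9}$.
* All simulator functions are pure functions of (inputs, seed); the
  global RNG state is saved and restored around them.

## Worked sizes

The test suite and the acceptance script use: 1000 random sequences for
digestion conservation, 200 random map pairs (at most 6 fragments each,
span 3) for the brute-force alignment oracle, 100 random colored graphs
(6–12 vertices) for the exhaustive rainbow check, a 100 kb genome at 20x
for the unicolored-equivalence experiment, and a 2 x 150 kb genome at
20x with a planted 3 kb cross-chromosome repeat for the end-to-end
guidance experiment. These sizes keep each experiment's purpose sharp —
oracle checks exhaustive, end-to-end runs large enough for ~700 reads
and spurious repeat overlaps to arise.

## Known limitations

* Contigs whose maps carry almost no information (one or two fragments)
  can be placed arbitrarily; with the default `min_s_score = 0` they are
  still used for coloring, following the finding that using every
  placement beats filtering by score. Their reads are the main source of
  residual coloring error.
* A read lying almost entirely inside a repeat longer than
  `match_fraction` times its length can be colored onto the wrong copy;
  guidance inherits the usual ambiguity of repeats longer than reads.
* Split (chimeric) contig placements are not modeled: a contig gets at
  most one placement, so a badly chimeric pre-coloring contig colors
  some of its reads wrongly. In practice such contigs are rare because
  the repeat-induced branches that would create them also terminate
  unitigs.
* The rainbow condition is enforced through the `{start, end}` color
  pair only; the interval in between is treated as implied.
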