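---
title: "Enumerating length-bounded bubbles in de Bruijn graphs"
author: "DBGbubbles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating length-bounded bubbles in de Bruijn graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A sample of RNA-seq reads contains, mixed together, the transcripts of both
alleles of every expressed locus and of every splicing isoform.  Without a
reference genome, variants can still be recognized purely combinatorially:
any two processes that generate sequences `awb` and `aw'b` — common flanks
`a` and `b` of length at least k around alternative inner segments `w` and
`w'` that share no k-mer — create a *bubble* in the de Bruijn graph (DBG) of
the reads: two internally vertex-disjoint directed paths from a common
source s (the last k-mer of the shared prefix) to a common target t (the
first k-mer of the shared suffix).  SNPs, indels and alternative-splicing
(AS) events all take this shape; they differ only in the lengths of the two
paths.  For an exon skipping, one path spells the inclusion isoform and the
other the exclusion junction, whose path has at most k−1 vertices.

Because path lengths are what discriminates event classes from
repeat-induced artifacts, the practically useful object is the
**(s,t,α1,α2)-bubble**: a bubble whose first path has length at most α1 and
second path at most α2, lengths being sums of non-negative arc weights (in
nucleotides for DBGs).  A lower bound β on both paths is additionally
imposed for specificity.  The number of such bubbles can be exponential in
the graph size, so the quality bar for an enumeration algorithm is
*polynomial delay*: the time between two consecutive outputs is polynomial
in the input size, here O(n(m + n log n)) for a graph with n vertices and
m arcs.

## Graph model and preprocessing

`WeightedDigraph` is a simple digraph (no parallel arcs, no self-loops)
with non-negative numeric arc weights and dense integer vertex ids; string
labels (k-mers or unitig sequences) are carried alongside for output.
Weights are kept integral in every pipeline this package builds (DBG arc
weights are nucleotide counts), so length comparisons against α are exact
in double arithmetic; the loaders accept any non-negative numeric weight,
but the radix queue refuses non-integers.

The DBG front-end follows the standard construction:

* `countKmers()` slides a window over each sequence, skips windows
  containing N, and applies an abundance filter (default `minCount = 3`,
  the usual guard against sequencing errors; use 1 for curated input).
* `buildDBG()` draws an arc for **every** ordered pair of retained k-mers
  whose (k−1)-suffix equals the other's (k−1)-prefix — not only pairs
  observed adjacently in a read.  This is the definitional DBG; the
  observed-adjacency graph is a stricter variant we do not implement.  No
  reverse-complement canonicalization is applied: the model is
  single-stranded, as in the worked example below; a canonical mode could
  be added later without touching the enumeration.
* `compressDBG()` merges maximal non-branching linear paths (unitigs) into
  single labeled vertices with arc weight `nchar(label(v)) − (k−1)`, so a
  path's weight in the compressed graph equals its arc count in the
  uncompressed one.  Isolated directed cycles whose every vertex has in-
  and out-degree 1 have no canonical start and are left uncompressed; they
  cannot contain a bubble.  Note that a vertex with in- and out-degree 1
  can survive compression when both its neighbors branch (the junction
  k-mer TGC in the example below does exactly that).
* `bccDecompose()` splits the underlying undirected graph into biconnected
  components (via igraph) and drops components with fewer than 4 vertices.
  A bubble's two paths close an undirected cycle, so every bubble lies
  entirely inside one component: per-component enumeration is lossless.
  One related preprocessing used by downstream callers — merging
  non-branching bubbles with equal path lengths — is defined in earlier
  tooling rather than here, and is intentionally not implemented.

A worked example with k = 3 on the sequence pair `ACTGGAGCG` / `ACTGCG`:
the DBG has 8 k-mers and 8 arcs, and exactly one bubble, from `CTG` to
`GCG`, with path lengths 5 (`CTG,TGG,GGA,GAG,AGC,GCG`) and 2
(`CTG,TGC,GCG`); the junction path has a single internal vertex.  This
example is frozen in the test suite and recomputed by
`scripts/acceptance.R`.

## The enumeration algorithm

For a fixed source s, the solution space is generalized to *pairs of
compatible paths*: two internally vertex-disjoint paths from endpoints
(s1, s2) to a common end, within budgets (rem1, rem2).  The recursion is a
binary partition of this space.  While the second endpoint s2 has out-arcs
in the working graph, the space splits into:

* for each out-arc (s2, v): the pairs whose second path continues with
  that arc — recursed with s2 **removed from the graph** (its vertex
  becomes prefix interior, which no other path may touch), endpoint v, and
  budget rem2 − w(s2, v);
* the pairs using none of them — the second path stops at s2, so the
  common end is s2 itself; recursed with the out-neighborhood of s2
  removed, after which the first path is extended instead.

A leaf is reached when an extension arc lands on the *other* endpoint: the
two prefixes meet and the singleton class is output.  Three emptiness
certificates keep the recursion from entering dead subspaces, which is
what yields polynomial delay:

* **Compatible-pair test**: a pair for (s1, s2) exists iff some t has
  d(s1,t) ≤ rem1 and d(s2,t) ≤ rem2 — two truncated Dijkstra trees and an
  intersection test.  (Truncating two within-budget paths at their first
  common vertex makes them internally disjoint without increasing either
  length, so the distance criterion is exact.)
* **Extension feasibility** for all out-neighbors of the pivot u at once:
  one truncated tree from the other endpoint in G − u gives the candidate
  meeting set V; one multi-source Dijkstra on the reverse view, seeded at
  V with distance 0 (equivalently, a virtual sink r with zero-weight arcs
  from V), gives d(v, r) for every v; each neighbor is then answered in
  O(1) by d(v, r) ≤ rem_u − w(u, v).
* **Root case**: the recursion cannot start at s1 = s2 = s (removing s
  would destroy both paths), so the top level branches over ordered pairs
  of distinct first arcs, reusing the same two-tree structure per
  second-path arc.  A naive per-arc test at the root would also accept
  degenerate "pairs" that only realize as a cycle back to s or as a path
  equal to its own partner arc (a two-cycle s ⇄ v is the smallest
  example), which is why the root test enumerates arc pairs rather than
  single arcs.

All removals go through a checkpointed deletion log: each recursive call
records only its difference and restores it on return, so one shared graph
copy suffices (linear space) and the input graph is bit-identical after
every call — asserted for every enumeration in the test suite.

### Output conventions and instrumentation

The two paths of a bubble are reported once as an unordered pair.  A
bubble whose lengths fit the bounds under both role assignments would be
found by two root branches; the package keeps the orientation whose first
path starts with the smaller vertex id.  This dedup, like the β lower
bound, is applied at output: every recursion leaf still yields exactly one
candidate, and the `stats` slot of the returned `BubbleSet` accounts for
each leaf as emitted, dropped-by-orientation, or dropped-by-β.  The delay
instrumentation (`maxGap`) records the largest number of recursion-node
visits between consecutive leaves; the tests assert it never exceeds 4n,
the bound that the linear recursion depth implies.

β must remain an output filter: pruning on the lower bound inside the
recursion would require deciding "does a bubble with both paths ≥ β
exist?", which is NP-hard (the test suite exercises this boundary with a
Hamiltonian-path construction: two fresh endpoints and a fresh |V|-vertex
path make a bubble with both paths of |V|+2 vertices exist exactly when
the base graph has a Hamiltonian s,t-path; in arc-length units the
equivalent bound is |V|+1, which is how the generator reports it).

Two stop conditions mirror production callers: a cap of 10,000 reported
bubbles (components with more are repeat-dominated and of little biological
value) and a 900 s timeout; hitting either is a reported status, not an
error.

### Shortest-path machinery

Dijkstra's algorithm dominates the running time, so the priority queue is
pluggable: a binary heap with decrease-key (`bin`), a binary heap with
lazy duplicates and no decrease-key (`bin-no-dec`, the default — in
practice the fastest on sparse bounded-degree compressed DBGs), and a
monotone integer bucket queue in the radix-heap family (`radix`), whose
key bound is the truncation bound; combined with `pruneHeavyArcs()`
(arcs heavier than α1 can sit on no bubble path) this realizes the
O(m + n log α1) variant.  A Fibonacci-heap variant is deliberately
omitted: its asymptotics are better but it is dominated in practice on
these graphs.  All variants settle equal-distance vertices in ascending
vertex-id order (the comparison key is the pair (distance, id)), so
distances, parents and all downstream output are deterministic; the tests
require bit-identical distance vectors across the three variants and
against an independent Bellman-Ford oracle.

## d-bubbles: more than two disjoint paths

Loci with more than two variants (double exon skipping, triallelic SNPs)
motivate the **(s,t)-d-bubble**: d pairwise internally vertex-disjoint
s→t paths, *without* length constraints — adding per-path length bounds
makes even the decision problem NP-hard (it generalizes the min-max
two-disjoint-paths problem), so `enumerateDBubbles()` refuses a
`lengthBounds` argument explicitly rather than silently ignoring it.

Existence and extraction reduce to unit-capacity max-flow on the
vertex-split network (v becomes v_in → v_out with capacity 1; arcs become
u_out → v_in): arc-disjoint flow paths correspond to internally
vertex-disjoint original paths, so d paths exist iff the max flow reaches
d, found with at most d BFS augmentations and read off by flow
decomposition.  Enumeration reuses the binary-partition scheme, expanding
the smallest-id unfinished endpoint and certifying each branch with a
super-source flow test; flows themselves are never enumerated, because
adding a circulation changes the flow but not the path set, so flow
enumeration would overcount.  Two conventions are made explicit where the
flow formulation leaves them open: the endpoints s and t are granted
internal capacity d (paths may share their endpoints), and the current
path *starts* are entered at their split-out node with their own internal
capacity withheld, so no path can route through another path's start.  At
the root, the multiset {s × d} is handled by branching over unordered
d-subsets of distinct first arcs, which also canonicalizes the output
order.  Correctness of every piece is asserted against exhaustive
brute-force search (all simple-path families) on small instances, and the
flow values additionally against igraph's independent max-flow.

## Synthetic data: what it does and does not emulate

The generators are pure functions of their seed.  `randomDigraph(n, p)`
draws each ordered pair independently with integer weights (default 1–3)
— a structureless stress model whose purpose is oracle equivalence, not
realism.  `plantASEvent()` emulates the sequence-level signature of a
variant: flanks of length ≥ k around inner segments sharing no k-mer,
rejection-sampled until every k-mer is unique within each sequence and
the two variable regions (including flank-straddling windows) share no
k-mer, so the planted bubble's endpoints are exactly the last k-mer of
`a` and the first k-mer of `b`.  Real read data differ in every way that
matters for the *front-end* — sequencing errors, coverage fluctuation,
repeats, reverse strands — which is why the abundance filter exists and
why passing these tests validates the graph algorithms and the planted
correspondence, not error robustness.  Error models, coverage simulation
and precision/recall benchmarking are out of scope here, as is
genome-scale disk-based k-mer counting.

Default generator dimensions (k = 5, flanks 8, w = 6, w' = 3 or empty)
are the smallest sizes at which all boundary effects of the construction
(straddling k-mers on both junctions) are present; the tests run 100
seeded instances, half with w' empty, and require the planted bubble to
be recovered between the predicted endpoints in every one, with the
junction path obeying its ≤ k−1 internal-vertex bound.

## Problem sizes and numerical choices in the test suite

The oracle suites run on sizes where exhaustive search is exact ground
truth: 500 random digraphs with 4–10 vertices (all sources, four
(α1, α2, β) settings) for the bubble enumerator; 200 digraphs with up to
7 vertices, all source/target pairs, for the Menger counts; 25 instances
with up to 8 vertices for full d-bubble family enumeration; 200 graphs
for the heap-variant agreement and 100 for pruning invariance.  These
sizes make the brute-force oracles (whose cost is exponential) exact and
fast while exercising every branch of the recursion; the algorithms
themselves have no small-size assumptions.

Degenerate inputs are pinned down explicitly: self-loops are dropped at
load (they cannot lie on a simple bubble path), parallel arcs are
rejected, a bubble may not have t = s (that would be a cycle) nor a
zero-arc path, vertices unreachable within a truncation bound are absent
from distance mappings rather than carrying sentinel infinities, and
empty out-neighborhood removals are no-ops.

## Known limitations

* The enumeration is exact for fixed-source bubbles with two paths; the
  lower bound β is a filter, so a component whose every bubble fails β
  still costs enumeration time proportional to its bubble count (capped
  by the stop conditions).
* Unordered-pair deduplication slightly weakens the theoretical delay
  statement: the 4n leaf-to-leaf bound holds at candidate level, and a
  long run of orientation-duplicate leaves between two reported bubbles
  is possible under strongly asymmetric (α1, α2); the instrumentation
  measures exactly this and the randomized suites include an asymmetric
  setting.
* Pure R implementation: per-node costs are dominated by interpreter
  overhead, so absolute throughput is far below a C implementation even
  though the asymptotics and the delay structure are the same; wall-clock
  benchmarking against other tools is explicitly not a goal.
* Single-stranded model; reverse-complement canonicalization would be a
  front-end extension.
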