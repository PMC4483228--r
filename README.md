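# DBGbubbles

Reference-free detection of alternative-splicing events and small variants
from RNA-seq data, by enumerating **length-bounded bubbles** in the de
Bruijn graph (DBG) of the reads.

Any variant process that produces sequences `awb` and `aw'b` — shared
flanks `a`, `b` (each ≥ k) around alternative inner segments sharing no
k-mer — creates a bubble in the DBG: two internally vertex-disjoint paths
from a source s to a target t.  Event classes are separated by path
lengths, so the object of interest is the **(s,t,α1,α2)-bubble**, a bubble
with `|p1| ≤ α1` and `|p2| ≤ α2` (lengths = sums of non-negative arc
weights, i.e. nucleotides), optionally filtered by a lower bound β on both
paths.  The package implements:

* a **polynomial-delay binary-partition enumeration** of all
  (s,t,α1,α2)-bubbles for a fixed source — O(n(m + n log n)) delay, linear
  space via a reversible deletion log — built on truncated Dijkstra
  shortest-path trees with selectable priority queues (binary heap, binary
  heap without decrease-key, integer radix/bucket queue);
* the **DBG front-end**: k-mer counting with an abundance filter,
  all-(k−1)-overlap arc construction, unitig compression (lossless for
  path lengths), biconnected-component decomposition;
* the **d-bubble generalization**: d pairwise internally vertex-disjoint
  (s,t)-paths, decided and extracted with unit-capacity max-flow on the
  vertex-split network, and enumerated with the same partition scheme
  (length-constrained d-bubbles are refused: NP-hard);
* **seeded generators** (random digraphs, planted variant events,
  Hamiltonian-path stress instances) and **exhaustive brute-force
  oracles** that define ground truth on small instances.

See `vignettes/bubble-enumeration.Rmd` for the model, the algorithm and
all design decisions.

## Worked example

Two transcript fragments differing by a skipped segment, k = 3:

```r
library(DBGbubbles)

dbg <- buildDBG(countKmers(c("ACTGGAGCG", "ACTGCG"), k = 3, minCount = 1))
dbg
#> WeightedDigraph: 8 vertices, 8 arcs, labeled

s <- match("CTG", vertexLabels(dbg))
bs <- enumerateBubbles(dbg, s, alpha1 = 5, alpha2 = 2)
bubbleTable(bs, labels = vertexLabels(dbg))
#>     s   t len1 len2                   path1       path2
#> 1 CTG GCG    5    2 CTG,TGG,GGA,GAG,AGC,GCG CTG,TGC,GCG
```

The single bubble runs from the branch k-mer `CTG` to the rejoin k-mer
`GCG`; the long path (length 5 nt) spells the inclusion variant
`CTGGAGCG`, the short path (length 2 nt) the exclusion junction `CTGCG`,
whose one internal vertex (`TGC`) is the k-mer straddling the junction —
for a pure junction path there are at most k−1 = 2 of them.  The same
pipeline is exposed on the command line by
`inst/scripts/bubbletool.R` (`build-graph`, `enumerate`, `d-bubbles`,
`simulate`).

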