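---
title: "Methods: analyzing antibody panning campaigns with repanner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analyzing antibody panning campaigns with repanner}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Antibody phage display selects binders from a large naive library by
iterative biopanning: each round enriches phages displaying antibodies that
bind the target antigen. High-throughput sequencing of the library after
each round replaces the classical pick-and-screen approach with a complete
census of the clone pool, but turns the analysis into a sequence-informatics
problem. `repanner` takes the clonotype tables produced by upstream
aligners (MiXCR-style exports or AIRR Rearrangement TSVs), one per sample
or panning round, and computes the standard analytical surface of such a
campaign: read accounting, rarefaction, clonal diversity, sample overlap,
CDR composition, edit-distance clustering, sequence embedding, and the
integration of per-clone binding measurements.

The unit of analysis is the clonotype: a distinct CDR sequence (HCDR3 by
default, the most variable antigen-contact loop) with its read count and
read fraction within a sample. All cross-sequence analyses operate on
amino-acid sequences after collapsing synonymous nucleotide clones
(`aggregate_by_aa()`).

## Trimming

Upstream aligners emit many technical artifacts: out-of-frame junctions,
singleton noise reads, truncated CDRs. `apply_default_trimming()` keeps a
record only if the nucleotide sequence length is divisible by 3, the read
count is at least 3, and the sequence is at least 18 nt long. All three
thresholds are arguments. Two reporting conventions are fixed so that
filter reports are deterministic:

* a record that violates several rules is attributed to the first failing
  rule in the order frame, count, length (the keep/remove decision itself
  is order-independent);
* trimming never touches read fractions. Diversity indices interpret
  fractions as clone probabilities, so they renormalize from counts by
  default (`normalize = TRUE`), and `recompute_fractions()` makes the
  renormalized repertoire explicit. The stored fractions are kept verbatim
  on ingest because the upstream tool computed them on its own pre-trim
  totals; discarding that provenance silently would hide upstream losses.

## Rarefaction

`rarefaction_curve()` divides a sample's reads at random into `n_bins`
bins (default 100, sizes differing by at most one read) and counts unique
amino-acid sequences cumulatively bin by bin. A curve that still rises
linearly at the final bin means sequencing depth is insufficient; a
plateau means the sample's diversity is covered. Two weightings are
offered because "dividing a sample" is ambiguous: `by_read` (default)
expands each clone to its read count, making the curve a statement about
sequencing depth, and `by_clone` shuffles distinct sequences once, probing
richness only. The shuffle seed is an explicit argument; when omitted, a
generated seed is reported so the stochastic QC plot stays reproducible.

## Diversity

With clone probabilities \(p_i\) (read fractions over the analyzed set),
`shannon_index()` computes \(H = -\sum_i p_i \ln p_i\) and
`inverse_simpson()` computes \(D = 1 / \sum_i p_i^2\), the effective
number of equally abundant clones. Shannon uses natural logarithms (the
ecology convention; a `base` argument provides bits), and both indices are
maximized exactly at the uniform distribution (\(\ln n\) and \(n\)).
Falling diversity across successive rounds is the canonical signature of
enrichment.

## Sample overlap

`pairwise_matrix()` builds symmetric sample-by-sample matrices with four
indices, all in \([0,1]\): Jaccard \(|A\cap B|/|A\cup B|\), Sørensen–Dice
\(2|A\cap B|/(|A|+|B|)\), the count-free relative index, and the
abundance-weighted Morisita–Horn index

\[
MH = \frac{2\sum_i x_i y_i}{\left(\frac{\sum_i x_i^2}{X^2} +
\frac{\sum_i y_i^2}{Y^2}\right) X Y}.
\]

The relative index is implemented as the overlap coefficient
\(|A\cap B|/\min(|A|,|B|)\). The denominator was a genuinely open design
choice: the index is described only as comparing identical sequences
"without considering how many times each sequence was present", which any
presence/absence index satisfies; the min-denominator form is the standard
count-free "relative overlap" and is the only common choice that both
differs from Jaccard/Dice and saturates when one repertoire contains the
other. For every pair, jaccard ≤ dice ≤ relative, and Morisita–Horn is
invariant to rescaling one sample's counts — which is why it is the
default for cross-round heatmaps where depths differ.

## Composition

`length_distribution()` histograms CDR lengths per sample (distinct
sequences or read-weighted). `positional_aa_matrix()` tallies per-position
amino-acid fractions among sequences of one fixed length; mixing lengths
is refused by design because CDR loops are conserved at the ends and
variable in the middle, so end positions of short sequences would be
systematically overcounted. Two further conventions:

* the default weighting is one vote per distinct sequence, not per read —
  in an enriched pool a single dominant clone would otherwise flatten the
  logo into its own sequence; read weighting remains available;
* translation-artifact symbols (`*`, `_`, `X`) disqualify a sequence from
  the matrix and are reported instead (`n_excluded`); they are QC signals,
  not composition.

`information_content()` uses the uncorrected logo convention
\(IC_p = \log_2 20 - H_p\); no small-sample correction is applied, keeping
the contract simple and matching the common logo default.

## Edit-distance clustering

`levenshtein()` is the unit-cost dynamic program, implemented in C++ and
verified in the test suite against an exhaustive naive recursion on every
pair of strings up to length 6 over a 3-letter alphabet, and against
`utils::adist` on random sequences. All-pairs analyses (`ld_matrix()`,
`ld_dendrogram()`, `ld_graph()`) cap the input at the `top_n = 200`
highest-count sequences (ties broken lexicographically, override
available) because the computation is quadratic and panning analyses care
about the enriched tail of the distribution. The dendrogram is UPGMA by
default (`stats::hclust`, whose tie handling makes results deterministic);
merge heights are in edit-distance units and export to Newick via `ape`.
The cutoff graph connects sequences at distance ≤ cutoff and labels
connected components (`igraph`); raising the cutoff only merges
components.

## Sequence embedding

`sgt_embed()` implements the sequence graph transform: for every ordered
symbol pair \((u,v)\),

\[
\psi(u,v) = \left(\frac{\sum_{l<m,\, s_l=u,\, s_m=v}
e^{-\kappa (m-l)}}{Z}\right)^{1/\kappa},
\]

a 400-dimensional vector over the 20-letter alphabet that captures the
characteristic relative placement of residues and therefore compares
sequences of different lengths — exactly the regime where plain edit
distance is weakest. The length-insensitive normalization
\(Z = |\{l : s_l = u\}|\) is the default (it reproduces the closed form
\(\psi(A,B) = e^{-1}\) for the sequence `AB` at \(\kappa = 1\)); the
length-sensitive variant multiplies \(Z\) by the sequence length. The
decay rate \(\kappa = 1\) is the neutral default; larger values localize
the features.

`reduce_to_2d()` standardizes the vectors, reduces them with PCA (at most
50 components), and runs t-SNE on the scores. Composition order (PCA
first, then t-SNE) is the standard pairing for high-dimensional sparse
features. The t-SNE is an exact \(O(n^2)\) implementation written for
this package: per-point Gaussian bandwidths calibrated to the target
perplexity by binary search, Student-t output kernel, 500 gradient-descent
iterations with early exaggeration (12× for 100 iterations), momentum
0.5→0.8, and adaptive per-parameter gains. Exact t-SNE is entirely
adequate at the post-cap problem sizes (≤ 200 points) and keeps the run
deterministic given the seed. Two numerical choices matter:

* perplexity must stay below \((n-1)/3\); too-large values are lowered
  automatically with a warning rather than erroring, since small panning
  panels are common;
* exactly duplicated input vectors are collapsed before the projection
  and share one output coordinate. Identical sequences must land on
  identical points, and zero-distance pairs otherwise degrade the
  bandwidth calibration (some t-SNE implementations refuse duplicates
  outright for the same reason).

## Binding integration

`overlay_binding()` joins immunoassay values onto any per-sequence table
by amino-acid sequence; unmatched assay rows are reported, not fatal,
because assays typically cover a small subset.
`nearest_labeled_neighbors()` inverts the join: it nominates unlabeled
sequences within a small edit distance of any labeled sequence whose
binding exceeds a threshold — the screening shortlist of "sequences highly
similar to known strong binders". Candidates are sorted by ascending
distance, then descending neighbor binding; neighbor ties resolve toward
the higher-binding neighbor, then lexicographically.

## The panning simulator

`simulate_panning()` provides ground-truth campaigns for validation. Round
0 draws clone abundances from a flat Dirichlet prior (concentration 1) and
samples read counts multinomially; each later round multiplies clone
frequencies by \(e^{s_i}\) (per-clone selection coefficient \(s_i\)) and
resamples at the same depth. Coefficients are Normal(0, 0.5) with 5 clones
spiked to 3 by default — the neutral bulk plus a handful of strong binders
that a real campaign is run to find. CDR3s are distinct random amino-acid
strings of length 8–20, reverse-translated through random synonymous
codons so every record is in frame and passes default trimming. Defaults
(5000 clones, 3 selection rounds, 100000 reads per round) emulate a small
campaign; validation tests use scaled-down instances (tens to hundreds of
clones, 2000–10000 reads, 20 replicate seeds for the expectation-level
properties), which is ample for the qualitative contracts they check.

`simulate_binding()` labels a configurable fraction of clones with the
logistic transform of their selection coefficient plus Gaussian noise. The
top-coefficient clone is always labeled, mirroring real campaigns where
the most enriched clone is invariably assayed; this also anchors the
planted-neighbor recovery check (`plant_neighbor = TRUE` adds an unlabeled
clone one substitution from the top binder to the final round).

The simulator emulates selection and multinomial sampling noise only. It
does not model PCR amplification bias, sequencing error (no artifactual
near-duplicate reads), chimeras, or paired-chain structure — so passing
its tests demonstrates correctness of the analytical pipeline under clean
selection dynamics, not robustness to those artifacts in real libraries.

## Degenerate inputs and edge conventions

Empty repertoires are parameter errors naming the sample wherever a
quantity is undefined (diversity, overlap, rarefaction). A rarefaction
request with more bins than reads errors with instructions to lower
`n_bins`. Zero-count records are dropped before diversity. The AIRR
reader's fallback for a missing `duplicate_count` column (unit counts,
uniform fractions) is flagged in the load report rather than silent.
Master tables round-trip exactly: strings and integers bit-for-bit,
fractions to better than 1e-9.

## Limitations

* The top-N cap means dendrograms, graphs and embeddings describe the
  enriched tail, not the full library; raise `top_n` deliberately.
* Pretrained protein-language-model embeddings are not shipped; any
  function mapping sequences to vectors can be substituted for
  `sgt_embed()` ahead of `reduce_to_2d()`.
* Overlap indices are not corrected for unequal repertoire sizes beyond
  Morisita–Horn's scale invariance.
* The pipeline consumes aligned clonotype tables; FASTQ processing, UMI
  handling and aligner presets are upstream concerns.
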