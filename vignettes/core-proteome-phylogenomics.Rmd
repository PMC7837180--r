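---
title: "Core-proteome phylogenomics: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-proteome phylogenomics: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocore)
```

# The problem

Placing a newly sequenced bacterial strain within its species group is
unreliable from a single marker gene: 16S rRNA barely resolves below the
genus, and any one protein family can mislead. The standard remedy is a
*core-proteome supermatrix*: anchor on the new strain's proteome, find the
proteins it shares single-copy with every comparison strain, align each
shared family, concatenate the alignments into one long matrix, discard
ambiguously aligned columns, and infer one tree from the combined signal.
`phylocore` implements that whole chain as composable, seedable R
functions, together with a proteome-evolution simulator that makes every
stage testable against a known ground truth.

# The pipeline stage by stage

## Ortholog calling: reciprocal best hits

For reference proteome $R$ and each other proteome $S$, every protein pair
is scored with exact Smith–Waterman local alignment (affine gaps: a gap of
length $k$ costs $g_o + k\,g_e$; BLOSUM62; defaults $g_o = 11$,
$g_e = 1$). No heuristic seeding is used — at the scale of simulated or
curated proteome sets, full dynamic programming is affordable and removes
one source of irreproducibility. Raw scores are converted to expectations
with the Karlin–Altschul formula

$$E = K\,m\,n\,e^{-\lambda S},$$

with the classic gapped-BLOSUM62 constants $\lambda = 0.267$ nats,
$K = 0.041$, both configurable via `scoring_scheme()`. A pair $(r, s)$ is
an ortholog call iff $s$ is $r$'s best hit in $S$ and $r$ is $s$'s best
hit in $R$, both passing $E \le 10^{-5}$; `extract_core_groups()` keeps
the reference proteins with a partner in *every* other proteome. Strict
reciprocal best hits are one-to-one by construction, which the code
asserts rather than repairs. Ties on score are broken toward the
lexicographically smaller subject id, so results are order-independent.

Finite-size edge corrections to $E$ are deliberately omitted: the cutoff
acts as a permissive filter, not a significance claim, and on short genes
the practical effect is conservative (a marginal ortholog pair may drop a
gene from the core, never admit a wrong one into every strain).

## Per-group alignment

Each ortholog group is aligned with a progressive aligner in the style of
MUSCLE's first pass: pairwise $k$-mer dissimilarities
($k = 3$; $1 - \text{shared}/\min$ distinct counts) feed a UPGMA guide
tree, and profiles are merged bottom-up by global profile–profile
alignment with mean-of-pairs BLOSUM62 column scores and affine gaps
(profile stage: open 10, extend 0.5; terminal gaps penalized like
internal ones; gap symbols score zero). Iterative refinement and
tree-dependent partitioning are intentionally out of scope: the
supermatrix signal, not column-perfect alignment, carries the result, and
the package's guarantees are stated as properties — de-gapping any output
row reproduces its input; for two sequences the result attains the global
affine-gap optimum (checked against an exhaustive enumeration oracle);
output is deterministic for a fixed input order. Order sensitivity for
three or more sequences is inherent to progressive alignment and is
documented rather than hidden.

## Concatenation and variable sites

`concatenate()` appends group alignments column-wise, recording 0-based
half-open partitions. A strain missing from any group is an error naming
the group and strain — core-group construction guarantees full occupancy,
so silent gap-padding would mask a bug. A *variable site* is a column
with at least two distinct non-gap, non-X residues; this definition is
invariant to how gaps are coded, which matters because downstream counts
are quoted as headline numbers.

## Conserved-block filtering

The column filter re-implements the classic conserved-block selection with
its published default arithmetic, pinned explicitly because rounding
direction changes results: for $N$ sequences, a column needs
$IS = \lfloor N/2\rfloor + 1$ identical residues to count as conserved and
$FS = \lceil 0.85N\rceil$ to count as highly conserved; runs of more than
$CP = 8$ contiguous nonconserved columns are removed; any gap column and
its adjacent nonconserved run is removed; surviving segments are trimmed
to their first and last highly-conserved column and kept only at length
$\ge BL = 10$. The four steps run in that fixed order. X matches only
itself, so ambiguity can never fake conservation in realistic data. The
concatenated super-alignment is filtered as one block, not per gene.
Empty retention is legal and surfaces as a warning plus an empty mask.

## Distances, tree, support

Pairwise distances use pairwise deletion (columns where both rows carry a
non-gap, non-X residue, within the retained mask) and the Kimura protein
correction

$$d = -\ln(1 - p - 0.2\,p^2),$$

the correction protein NJ pipelines conventionally apply to observed
difference proportions. Its domain ends near $p \approx 0.854$; beyond
it the distance is capped at a configurable 10.0 substitutions/site with
a warning — a simple, monotone policy chosen over empirical lookup
tables. The tree is built by Saitou–Nei neighbor joining with the
Studier–Keppler $Q$ criterion; on an additive matrix the output
reproduces the input path-length metric exactly (the test suite checks
200 random trees to within $10^{-9}$). Negative branch-length estimates
are clamped to zero, which can affect lengths but never topology. $Q$
ties break toward the lexicographically smallest cluster pair.

Bootstrap support resamples retained columns with replacement, recomputes
distances and the NJ tree per replicate, and writes the percentage of
replicates containing each reference bipartition onto the full-data tree
(no majority-rule consensus is built — the product is one tree annotated
with support). A single seeded generator drives the whole run: replicate
$r$ consumes the next draws in sequence, so one integer seed fixes every
support value and the emitted Newick byte-for-byte. For the same reason
the JSON run report contains only deterministic fields; timing goes to
the console log.

## Genome composition tracks

`gc_content()` and `gc_skew_profile()` provide the standard
chromosome-level summaries: overall GC fraction (ambiguous bases excluded
from numerator and denominator) and windowed skew $(G-C)/(G+C)$ with its
cumulative series, whose extremes conventionally mark replication origin
and terminus. The default window is 10 kb, non-overlapping, a common
choice for circular-plot tracks; the chromosome is treated as linear (no
wraparound window), which perturbs only the final partial window.

# The simulator and what it does (not) show

`simulate_proteomes()` evolves proteomes along a known tree: random
sequential addition topology, Exp(1) branch lengths rescaled so the mean
root-to-tip path equals `tree_depth`, and per-site substitution under the
uniform 20-state Markov model, where a branch of length $b$ changes a
site with probability

$$P(b) = \tfrac{19}{20}\left(1 - e^{-\tfrac{20}{19}b}\right)$$

to a uniformly chosen different residue. The uniform model is chosen
*because* this closed form exists: calibration tests compare observed
divergence against it directly. Under this model the Kimura correction is
a biased but topology-consistent estimator at the divergences used —
acceptable because topology, not branch length, is the recovery claim.
Each strain also receives lineage-specific decoy genes (fresh random
sequences, same residue distribution as roots) so reciprocal-best-hit
rejection is exercised, and protein ids are shuffled per strain so record
order carries no orthology signal.

Default conditions are 12 taxa, 20 core genes of 200 residues, 5 decoys
per strain, and depth 0.3 substitutions/site — a desk-scale stand-in for
a within-species-group proteome comparison, where typical pairwise
identities land in the 60–85% band. There is no indel process by default
(an optional rate exists for stress tests), no rate heterogeneity across
sites, no BLOSUM-weighted exchangeability, and no horizontal transfer or
gene gain/loss. Passing tests therefore demonstrate that the machinery is
correct and well calibrated under substitution noise; they do not
demonstrate robustness to alignment-hostile indel patterns or
compositional heterogeneity in real proteomes.

# Problem sizes and numerical choices

The test and acceptance workloads use: the 12-taxon configuration above
over five seeds with 100 bootstrap replicates for end-to-end recovery;
8-taxon configurations for pipeline plumbing; 200 random 4–15-taxon trees
for NJ exactness; exhaustive alignment-oracle enumeration for short
sequences plus sampled cross-checks against an independently authored
aligner for longer ones; and 10,000-site genes for simulator calibration
(99% binomial intervals). These sizes were chosen so each property is
tested at meaningful power while the whole suite stays fast enough to run
routinely.

Other numerical decisions worth knowing:

- Scores are integer-valued for the default scheme but carried as
  doubles; the profile stage legitimately uses half-integer gap costs.
- `X`/`N` are accepted on input and excluded from every comparison that
  matters (variable sites, p-distances, conservation counts).
- `*` stop characters are stripped from protein input with a warning,
  matching common proteome exports.
- Newick output writes branch lengths to six decimals and support as
  integer-percent internal labels; parsing accepts anything standard.

# Known limitations

- Bootstrap support of very short internal edges is modest by nature in
  distance-based pipelines: an edge contributing ~0.006 substitutions per
  site is comparable to the sampling noise of per-pair distances at a few
  thousand columns, and such edges draw 50–60% support even when the
  full-data topology is recovered correctly. This is a property of the
  method, reproduced identically by independent NJ implementations, not
  an artifact of this package.
- The aligner is a first-pass progressive method; heavily gapped or
  low-identity families would deserve a refinement-capable aligner.
- E-values use asymptotic Karlin–Altschul statistics without finite-size
  correction; on very short genes the effective cutoff is stricter than
  BLAST's, and marginal orthologs of short genes may drop out of the
  core (visible in the simulator at 80-residue genes).
- The Gblocks-style "half" gap mode is not implemented; filtering is
  strict gap-free block selection with the published defaults.

# A minimal run

```{r example, eval = FALSE}
sim <- simulate_proteomes(sim_config(n_taxa = 8, n_core_genes = 10,
                                     gene_length = 150, n_decoy_genes = 3,
                                     seed = 42))
report <- run_pipeline(sim$proteomes, reference = "S01",
                       out_dir = "run_out", bootstrap = 100, seed = 42)
report
robinson_foulds(report$tree, sim$truth$true_tree)
```
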