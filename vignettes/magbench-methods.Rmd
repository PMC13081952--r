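---
title: "Mirroring metagenomes and evaluating MAG pipelines at base-pair resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mirroring metagenomes and evaluating MAG pipelines at base-pair resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magbench)
```

## The problem

Evaluating an assembly-plus-binning pipeline requires knowing, for every
contig, which genome it came from and, for every genome, how many of its
basepairs ended up in which bin. Real samples cannot provide this; naive
simulations provide it but misrepresent the ecosystem (wrong diversity,
no strain structure, reference genomes that are trivially easy to bin).
`magbench` takes the middle road: it *mirrors* real samples — reproducing
their species composition, detected strain structure, and sequencing depth
using genomes from a clustered reference collection — and then scores
pipeline outputs against the resulting exact ground truth.

This vignette documents the model and procedure, the parameters that
matter, the numerical choices, and what the synthetic fixtures do and do
not demonstrate.

## The reference database

The collection is clustered on two nested levels: species at 95% ANI
(supplied with the input metadata, one designated representative per
cluster) and strains at 98% ANI, assigned by `cluster_strains()`. Strain
assignment is greedy and seed-based: within a species cluster, genomes are
visited in descending total length (ties by genome id); each genome joins
the first existing strain cluster whose *seed* genome is ≥ 98% ANI to it,
else it seeds a new cluster. This is deterministic, O(n²) in the cluster
size, and intentionally simple: at full scale users supply a pairwise-ANI
table computed by a dedicated dereplication tool (the `ani_table` adapter
accepts it verbatim, and that path is authoritative for replicating
published clusterings); the built-in estimator exists so the whole system
runs without external tools.

The built-in estimator is containment-based: with canonical k-mer sets
$K_a, K_b$ (a k-mer pooled with its reverse complement, $k = 21$) and
$c = |K_a \cap K_b| / \min(|K_a|, |K_b|)$,

$$\widehat{\mathrm{ANI}} = 100\left(1 + \frac{\ln\frac{2c}{1+c}}{k}\right),$$

clamped to $[0, 100]$, with $c = 0$ mapped to 0. Two properties matter
here: identity gives exactly 100 ($c = 1$), and the estimate decreases
monotonically in the substitution rate. The estimate runs slightly *above*
the true nucleotide identity at strain-scale divergence (for example,
2% substitution estimates near 98.9 rather than 98.0), which is why the
fixtures use a 3.5% substitution rate when they need genomes that are the
same species but clearly distinct 98%-level strains. N50 uses the standard
convention: sort lengths descending and report the length at which the
cumulative sum first reaches half the total.

## The mirror specification

A sample enters as two profiler tables (the tabular dialect of a k-mer
profiler, column names pinned in one overridable descriptor because they
drift across tool versions): a species-level profile (relative abundances)
and a per-genome query (coverage-adjusted ANI, its confidence interval,
and an effective-coverage token). For each species with nonzero abundance:

* **Strain gate.** A genome is strain evidence iff its coverage token is
  not `LOW`, its adjusted ANI is ≥ 99.8, and — unless the token is `HIGH` —
  the CI lower bound is ≥ 99.5. All three thresholds are inclusive and
  live in `run_config()`. The token is treated as an opaque three-state
  signal (`LOW` / `HIGH` / anything else) because only those two values
  change behavior.
* **Cluster cap.** Passing genomes are grouped by strain cluster; at most
  three clusters are kept, chosen uniformly at random when more pass. One
  seeded RNG per sample drives both this choice and the abundance split,
  and the seed is recorded inside the specification file, so the manifest
  is exactly reproducible.
* **Representative per cluster.** Isolates beat MAGs; then higher N50,
  then higher adjusted ANI, then lexicographically smaller id. The
  isolate preference is total: whenever an isolate passes the gate in a
  cluster, no MAG from that cluster can be selected.
* **Abundance split.** Each selected strain receives the species abundance
  times $d_i / S$ where $d_i \sim \mathrm{logNormal}(\mu = 1, \sigma = 2)$
  and $S = \sum_i d_i$. We interpret the parameters on the natural-log
  scale (`exp` of a Normal with mean 1, sd 2) — the standard reading of
  this notation; the `meanlog`/`sdlog` arguments are exposed in case the
  distribution-scale reading is wanted. Note the split is a prior draw,
  not an estimate: species-level abundance is preserved exactly, the
  within-species split is random.
* **Fallback.** If nothing passes the gate, one genome of the species
  cluster is chosen — isolates first, then adjusted ANI (genomes absent
  from the query rank as $-\infty$), then N50 — at the full species
  abundance.

Finally all entries are renormalized to sum to one. Profiles need not sum
to one (unclassified mass), but the downstream read sampler needs a proper
distribution; since the specification file records the final numbers, the
truth remains exact.

## Read simulation

The built-in sampler draws per-genome pair counts multinomially from the
specification abundances, picks a sequence length-weighted within the
genome, a fragment start uniformly among valid positions, a fragment
length Normal(300, 25) truncated below at twice the read length
(default read length 126 bp), and emits mate 1 as the fragment's leading
bases and mate 2 as the reverse complement of its trailing bases.
Qualities are constant Phred 30 and substitution errors (default 0) are
i.i.d.; indels, quality models, and duplicates are deliberately out of
scope — realistic error profiles belong to the external simulator, for
which `emit_insilicoseq_command()` writes the draft/abundance lists and
the exact command (model HiSeq, `--n_reads` from the specification).

Specification abundances are passed through as sequence abundances by
default, matching the external simulator's abundance-file semantics; a
`length_weighted` switch converts taxonomic to sequence abundance for
users whose profiles are taxonomic. `num_reads` counts read pairs by
default (`count_mode = "reads"` halves it). Every read carries provenance
(genome, sequence, 0-based fragment interval), so with zero error rate
100% of reads map back exactly — the identity the tests exploit.

## Ground truth and the evaluator

Assembly contigs are aligned to the specification genomes (externally via
nucleotide BLAST, outfmt 6; at fixture scale via the exact-substring
`oracle_align()`), and alignments qualify as ground truth when identity is
≥ 99% and the alignment length is within 99–101% of the contig length.
Internally all intervals are 0-based half-open; the 1-based inclusive,
possibly strand-reversed alignment coordinates are normalized once at the
parser boundary.

Per ground-truth genome and bin, TP is the *union* of genome basepairs
covered by qualifying hits of the bin's contigs (multiple hits of one
contig to one genome are unioned rather than best-hit-only, so split and
repeat hits count covered bases correctly — a configurable choice), FN is
the remainder of the genome. The representative bin maximizes recall, with
ties broken by lexicographically smallest bin id (the choice is otherwise
arbitrary and must be deterministic); a representative is assigned even at
zero recall, and several genomes may share one bin. FP counts the
representative bin's contig-side bases not covered by any qualifying hit
of that contig to the genome — so a contig with no hit contributes its
full length, and a shared contig mapping to two genomes contributes TP to
both and FP to neither. With the 99–101% length gate this per-base reading
differs from the all-or-nothing per-contig reading by at most 1% per
mapped contig. Precision is defined as 0 when TP = FP = 0, and such
degenerate rows are flagged. An equivalence test backs the interval
arithmetic with a brute-force per-base boolean-array oracle on randomized
instances.

Downstream filters follow the same inclusive-threshold convention:
recoverable genomes need recall ≥ 0.7 *and* precision ≥ 0.9 from at least
one pipeline; the expected-coverage filter keeps genomes at
$\mathrm{abundance} \times \mathrm{reads} \times \mathrm{readlen} \times 2
/ \mathrm{genome\ length} \ge 2.5$; MIMAG-style classes are HQ
(completeness > 90, contamination < 5), MQ (≥ 50, < 10), LQ (< 10
contamination), else unclassified — contamination estimates above 100 are
legal and land in unclassified. GUNC filtering drops rows whose
representative bin fails, and reports the removed fraction plus the mean
recall and 1−precision of what was removed.

## Contig-level bias

Each contig–genome item (a shared contig yields one item per mapped
recoverable genome) gets two distances: the cosine distance between its
canonical tetranucleotide composition (136 features, reverse-complement
pooled, windows with non-ACGT bases skipped) and its genome's, and the
Euclidean distance between its per-sample coverage vector and the
unweighted mean vector of the genome's contigs. Coverage defaults to
truth-derived depth (provenance fragments overlapping the contig's source
interval divided by contig length) because at fixture scale the truth is
exact and no alignment step is needed; an adapter ingests external depth
tables instead.

Items pooled across samples are sorted by distance (ties broken
deterministically by sample, contig, genome) and discretized into 100
base-pair percentiles: with $s_c$ the cumulative length of preceding items
and $\mathit{bases}$ one hundredth of the total, item $c$ lands in the $p$
satisfying $p \cdot \mathit{bases} < s_c + l_c/2 \le (p+1) \cdot
\mathit{bases}$. The implementation computes $p$ by a ceiling expression
and then fixes it up against the inequality verbatim, so floating-point
rounding can never produce an item violating its own defining inequality;
$p$ is finally clamped to $[0, 99]$. Percentile pooling is done once per
assembler and reused across binners, so binner curves share their x-axis.
Per percentile, recall is correct basepairs over total, where an item is
correct iff its contig's bin equals the representative bin of its genome
in its sample (unbinned = incorrect).

A contig is a *prophage* contig if, in any genome it maps to, it is
contained in a provirus interval, contains one, or covers at least 25% of
one (inclusive); provirus intervals come from a provirus-table adapter
that keeps annotations with virus score ≥ 0.9. A contig is *shared* if it
has qualifying hits to two or more recoverable genomes.

## Fidelity metrics and binning context

Shannon α and Bray–Curtis β diversity are delegated to `vegan` (profiles
renormalized over nonzero taxa first); the paired β-diversity check
regresses simulated-pair on original-pair dissimilarities with OLS and
reports slope, intercept, and R², plus a through-origin fit alongside —
whether the intercept should be forced to zero is a judgment call, so both
numbers are reported and the free-intercept fit is primary.

Sample similarity for the partial multi-sample binning context uses
bottom-$s$ MinHash sketches ($k = 21$, $s = 1000$) and the standard
Mash-style distance $-\frac{1}{k}\ln\frac{2j}{1+j}$ from the Jaccard
estimate $j$ over the bottom-$s$ of the merged hash union; $j = 0$ is
reported as the sentinel distance 1. The hash is a seeded modular hash
over 2-bit k-mer encodings with a 31-bit range — chosen because every
intermediate stays exact in double arithmetic without compiled code or a
64-bit integer type; at sketch scale the collision probability is
negligible for nearest-neighbor ranking, which is the only consumer of
these distances. The D nearest non-target samples (default D = 20, ties
by sample id) form the context.

## Synthetic fixtures: what they show and what they cannot

`generate_collection()` plants every structure the analyses look for:
species from i.i.d. ancestral sequence, strains by i.i.d. substitution,
shared segments copied verbatim (ANI 100, so shared-contig truth is
unambiguous), and prophage-like insertions with GC elevated 15 points over
the background (which guarantees a composition-distance separation the
bias machinery can detect). `fragment_assembly()` cuts genomes into
roughly geometric contigs (default mean 2 kb, minimum 500 bp) and
withholds a seeded subset covering a requested loss fraction;
`make_bins()` produces truth-faithful bins or controlled corruptions
(swapped/unbinned basepair budgets); `make_quality_tables()` emits
completeness/contamination reports as noisy linear functions of true
recall/precision in the external tools' dialects.

These fixtures validate *accounting*: that the evaluator, filters, and
discretization are exact, that corruption of d basepairs moves TP by
exactly d, that a planted distance–misbinning relationship produces a
declining percentile-recall curve. They deliberately do not emulate real
assembler chimerism, repeat structure, phage biology, or profiler error —
conclusions about how real binners rank on real ecosystems require the
external-tool path at full scale.

## Problem sizes and defaults used by the shipped checks

The test suite and `scripts/acceptance.R` run on collections of 2–3
species × 1–2 strains of 12–40 kb genomes, samples of 1,500–4,000 read
pairs (one statistical check uses 100,000 pairs over 50 seeds), 50
randomized evaluator instances, and 1,000-item percentile inputs over 20
seeds — sizes chosen so the full loop, including the per-base oracle
comparisons, completes in minutes on one CPU while every planted quantity
is still measured with comfortable statistical margins.

## Known limitations

* The built-in ANI estimator is biased upward at strain-scale divergence;
  the external pairwise-ANI adapter is the reference path.
* The built-in profiler is an oracle stand-in (read assignment by k-mer
  containment), not a replica of any published profiler's statistical
  model; its CI is a simple binomial bound on containment.
* Within-species strain abundances are drawn, not estimated — mirroring
  preserves species abundance and strain *presence*, not strain ratios.
* Single-sequence coverage vectors at fixture scale exercise the distance
  machinery but not multi-sample co-abundance structure unless multiple
  simulated samples are supplied.
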