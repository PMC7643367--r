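---
title: "Tracing introgression with structural variants: methods and design"
author: "introscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing introgression with structural variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

# The problem

Large X-linked haplotype blocks in Eurasian pigs segregate almost perfectly
between population groups: one block differs between European and Asian
breeds, an adjacent one between south-Asian and all other breeds. Because
the region recombines very little, the transposable-element (TE) insertions
and deletions inside it behave as stable, essentially irreversible markers
shared by identity-by-descent. That makes them unusually good clocks and
tracers: where a marker is present tells you *on which branch of the
population tree it arose*, and markers whose distribution contradicts the
tree point to gene flow between already-diverged populations.

`introscan` implements that chain of reasoning end to end on desk-scale
data:

1. **SV discovery** between genome assemblies (`find_anchors()`,
   `chain_anchors()`, `call_svs()`, `merge_catalog()`);
2. **pattern classification** of the merged catalog into the four
   population-specific presence/absence classes, with enrichment testing and
   gene-model annotation (`classify_catalog()`, `enrichment()`,
   `region_annotate()`);
3. **read-backed genotyping** of panel SVs in sequenced individuals
   (`qc_reads()`, `build_local_reference()`, `map_reads()`, `genotype()`,
   `concordance()`);
4. **TE attribution and subfamily structure** (`assign_family()`,
   `greedy_cluster()`, `split_subfamilies()`);
5. **divergence dating** of TE copies with CpG correction (`kimura2p()`,
   `cpg_correct()`, `divergence_to_age()`);
6. **timeline inference** on a dated population tree
   (`origination_interval()`, `min_origins()`, `simulate_phases()`).

A first-class synthetic-data module (`sim_config()`, `simulate_study()`)
generates every input with full ground truth, so each stage is testable
against what was actually planted.

# SV discovery from assemblies

## Anchoring

Two assemblies are compared by seeding at k-mers (`seed_k = 21`) that occur
exactly once in *both* sequences, then extending each seed to the maximal
exact match on its alignment diagonal. Diagonals are compared as whole raw
vectors, so extension is vectorised and deterministic. Anchors shorter than
`min_match_len = 100` bp are dropped, and chains whose total anchored length
falls below `min_cluster_len = 500` bp are discarded — these two knobs play
the role of the classical whole-genome aligner's `-l` and `-c` parameters.
Unique-k-mer seeding intentionally skips repetitive regions: on this
package's synthetic chromosomes the SV flanks are unique by construction,
which is exactly the regime in which the anchoring is trustworthy.

## Chaining and gap arithmetic

Anchors are chained by a maximal-weight longest-increasing-subsequence
dynamic programme on both coordinate axes. One subtlety matters: around an
insertion or deletion, *maximal* exact matches systematically over-extend
into each other by however many bases the novel sequence happens to share
with the reference continuation (a geometric number, typically 0-3 bp).
Consecutive chain anchors may therefore overlap slightly. Because anchors
are exact matches, the downstream anchor can be trimmed by the overlap on
both coordinates without losing exactness; gap arithmetic then runs on
clean, non-negative gaps. Only an overlap that would consume a whole anchor
rejects the chain. The practical consequence is that planted SVs are
recovered with exact type and length, while the reported breakpoint may sit
a few bases right of the planted one — the familiar indel placement
ambiguity, not an error.

Between consecutive anchors with reference gap $g_r$ and query gap $g_q$:
$g_r = 0, g_q > 0$ is an insertion of $g_q$ bp; $g_q = 0, g_r > 0$ a
deletion of $g_r$ bp; both positive an `indel` of $|g_q - g_r|$ bp. Records
outside 1 bp - 10 kb are dropped.

## Merging

Per-genome calls are collapsed into a nonoverlapping catalog: deletions and
indels merge at reciprocal overlap $\ge$ 0.5; insertions merge when their
breakpoints sit within 10 bp and their lengths agree within 20%. The merge
is transitive (union-find over the pairwise rule), the representative is the
longest then leftmost record, and a canonical pre-sort makes the result
independent of the order in which genomes are supplied. The merge rule
itself is a declared convention of this package — common SV-merging
practice — exposed as arguments rather than hidden constants.

# Pattern classification

The four classes are defined on **sequence presence**: `A-a` means the
sequence occurs in all European and no Asian genomes, `A-p` the reverse;
`SA-a` in all non-south and no south genomes, `SA-p` the reverse. The
catalog, however, records **variant presence** (which genomes deviate from
the reference), so `sequence_presence()` inverts deletion columns before
classification and `indel` records are excluded. The rules are strict
all-or-none — one discordant genome voids the call — because the assembly
panel is small and clean; quantifying deviation in noisy data is the
genotyping stage's job, not the classifier's. When both an SA and an A rule
match, SA takes precedence (configurable). The crossbreed group `CROSS` is
counted with the south-Asian set and with the Asian set by default, both as
flags.

Enrichment of pattern SVs on a chromosome is a 1-df goodness-of-fit
chi-squared against an expectation proportional to that chromosome's share
of the *whole* catalog (all SVs, patterned or not) — catalog share, not
chromosome length, so assembly-specific detection biases cancel.

Panel selection keeps pattern SVs strictly longer than 100 bp, inside the
window matching their pattern. Two window presets for the real X chromosome
ship in `pattern_regions()` (`"methods"`: 44-58 / 58-92 Mb; `"results"`:
45-57 / 57-87 Mb, two slightly different statements of the same blocks);
`"methods"` is the default, and synthetic studies pass their own windows.

# Read-backed genotyping

Each panel SV gets a **local reference**: 200 bp of flank on either side of
the SV sequence, taken from a genome that *carries* it (the reference
genome for deletions, a carrier for insertions). Five regions partition it:

| region | extent | criterion |
|---|---|---|
| R1 | left 195 bp | covered $\ge$ 50% |
| R2 | 5 bp left of the breakpoint | covered completely |
| R3 | the SV span | covered $\ge$ 60% |
| R4 | 5 bp right of the breakpoint | covered completely |
| R5 | right 195 bp | covered $\ge$ 50% |

Reads are quality-controlled (adapter removal, 3' trim below Q20, discard
at >30% of bases at Q $\le$ 20 or N), then mapped ungapped end-to-end with
at most 2 mismatches. The mapper proposes placements by pigeonhole — with
$\le m$ mismatches at least one of $m+1$ disjoint read blocks matches
exactly, so a k-mer index of the 700-bp local reference proposes every
valid placement — and verifies each proposal by raw byte comparison. The
decision rule consumes only the per-base coverage union, which is why an
ungapped mapper suffices. All thresholds are inclusive; the call is binary
(present/absent) with a low-coverage warning flag that is deliberately not
part of the decision. Concordance compares calls to what each SV's pattern
predicts for the individual's population group.

Why this works at 20x error-free coverage: interior bases of the local
reference are uncovered with probability $e^{-20}$, and the only systematic
coverage taper is within a read length of the local reference's outer
edges, which the 50% R1/R5 thresholds absorb comfortably.

# TE attribution and subfamilies

Queries are aligned to each library consensus by optimal local alignment
(match +1, mismatch -1, gap -2 per column, via `pairwiseAlignment`).
Status: `complete` iff identity > 0.90 *and* query coverage > 0.80;
`partial` iff identity > 0.80; else `unassigned`. Two supporting choices:

* **Poly-A soft-trimming.** 3'-terminal poly-A tails (detected as $\ge$ 12
  adenines in the terminal 15 bp; tail length allows one non-A per 10) vary
  freely between copies and would depress coverage, so they are trimmed
  before alignment. Flag-controlled.
* **Minimum alignment length (30 columns).** The optimal local alignment of
  two unrelated sequences is always a short near-perfect match, so identity
  is only meaningful over a qualified alignment length; without this guard
  random sequence would systematically classify as `partial`.

Library consensi are grouped by greedy incremental clustering at 95% global
identity (length-sorted, first-fit — the CD-HIT strategy), deterministic
and order-independent.

Subfamilies are split recursively on **cosegregating mutations**: over all
pairs of (consensus position, non-consensus state), the number of copies
carrying both states is tested against the binomial tail expected if the
two single-site frequencies were independent. The best pair splits the
family if $p < 10^{-4}$ and both halves hold at least 30 copies; consensi
are recomputed and both halves recurse. Only the two-site variant is
implemented, and only states with at least `min_subfamily_size` carriers
enter the candidate set (a state rarer than the smallest admissible
subfamily cannot define one) — this also bounds the pair scan to a handful
of sites in practice. The independence null is deliberately conservative:
planted diagnostic pairs sit dozens of standard deviations above it, while
site pairs that merely drift never accumulate 30 co-carriers at realistic
within-family noise.

# Divergence dating

For a copy aligned to its consensus, transitions $P$ and transversions $Q$
are counted over comparable columns (gaps and ambiguity codes excluded) and

$$D = -\tfrac{1}{2}\,\ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big),$$

with an explicit saturation error when the argument leaves the domain.
CpG dinucleotides hypermutate roughly tenfold, so the corrected divergence
is $D_{CpG} = D / (1 + 9 F_{CpG})$ where $F_{CpG}$ is twice the number of
CG dinucleotides over the consensus length — computed on the consensus, not
per copy, so every copy of a family is corrected identically. Ages follow
as $\mathrm{age} = (D/r)\,g$ with $r = 2.5\times10^{-8}$
substitutions/site/generation and $g = 5$ years. Divergence landscapes are
half-open histograms at bin width 0.01.

The calibration note worth knowing: at these defaults, $D = 0.004$
corresponds to 0.8 Ma and $D = 0.025$ to 5.0 Ma; the arithmetic is exact
and the package reports whatever the formula gives.

# Timelines on a dated tree

A `dated_tree` wraps an `ape` phylogeny whose internal node labels carry
ages in Ma. The packaged fixture encodes the Sus species/population tree
with the published divergence ages (warthog 11, other Sus species 3.5,
Sumatra 2, Europe/Asia 1, south/north Asia 0.6, Tibet/north-China 0.2 Ma).
Ages not fixed by those divergences — inside the outgroup species clade and
the domestic/wild splits (set to 0.01 Ma, the order of domestication) — are
synthetic placeholders that sit strictly inside the printed bounds; no
inference in this package depends on them.

**Origination interval.** A single-origin, never-lost marker must have
arisen on the stem branch of its carrier clade, so the interval runs from
the age of the clade's parent node down to its crown age (0 for a single
leaf; unbounded above when every leaf carries it). Carriers that are not
monophyletic have no such branch and are rejected with a pointer to
`min_origins()`. The identity-by-descent argument is what licenses the
no-loss assumption: TE presence/absence markers in a low-recombination
region are effectively irreversible. A loss-allowing mode is deliberately
out of scope.

```{r}
dt <- sus_dated_tree()
asian <- c("SouthChina_wild", "SouthChina_domestic", "Tibetan_wild",
           "NorthChina_wild", "NorthChina_domestic")
origination_interval(dt, asian)
```

For the south-Asia pattern the interval argument lives inside the Asian
subtree (European populations also carry the non-south state, which under a
two-locus reading is a property of the other locus); the caller chooses the
subtree explicitly via `extract_dated_clade()`.

**Minimum origins.** Gains-only small parsimony: the minimal explanation of
a profile is one gain on the stem of each maximal all-carrier subtree; more
than one gain flags the profile as tree-incompatible — candidate
introgression or homoplasy. Unknown-state leaves are wildcards.

**Phase simulation.** Population histories are simulated as deterministic
set algebra over haplotype sets: `split` copies a set to two daughters,
`fix` replaces one, `admix` with recombination replaces the target by every
recombinant of the pooled alleles, and `select` keeps haplotypes carrying a
favoured allele (emptying a population is an error, not a silent state).
Sets rather than frequencies are a deliberate modelling floor: the
four-phase Eurasian scenario reasons about which haplotypes *remain*, and
set algebra makes that reasoning exact and reproducible. The canonical
scenario ships both as code (`fig_scenario_eurasia()`) and as YAML.

```{r}
fs <- fig_scenario_eurasia()
res <- simulate_phases(fs$scenario, fs$initial)
res$final
res$census
```

# The synthetic-data generator

`simulate_study()` emulates the study design, not just arbitrary data:

* a random reference chromosome (default 200 kb, GC 0.42 — porcine-like);
* two adjacent pattern windows (defaults: 5-35% and 35-95% of the
  chromosome for the SA and A windows; generous relative to the real
  14 + 34 Mb blocks so that a 60-SV panel fits with $\ge$ 600 bp of unique
  flank around every breakpoint);
* populations `EUR`, `ASIA_N`, `ASIA_S`, `TIBET` with 3/3/2/2 genomes,
  each genome of a carrier population carrying its SVs — the clean
  all-or-none carriage the assembly classifier assumes;
* pattern-structured SVs: absence patterns planted as deletions carried by
  the sequence-lacking populations, presence patterns as insertions, plus
  single-population private SVs that must classify as `none`;
* TE-derived insertion sequences drawn from a synthetic consensus library
  (`make_te_library()` — random consensi, labelled in the
  `name#class/family` header style; *not* real repeat-library entries),
  evolved to 1-8% divergence and given a 12-bp poly-A tail;
* single-end reads at 20x, 100 bp, with i.i.d. substitution errors
  (default 0.001) and constant qualities encoding the error rate.
  Single-end suffices because the genotyping criteria consume only
  per-base coverage; read pairing would add nothing they can see.

TE copies evolve under a continuous-time two-parameter process: each site
accrues a Poisson($d$) number of substitution events, each a transition
with probability 2/3, with CpG sites of the consensus running at
`cpg_multiplier` (default 10) times the base rate. Multiple hits and back
mutations therefore occur, the *observed* per-site difference sits slightly
below the planted event rate, and the Kimura two-parameter estimator is
consistent for it — which is the property the dating module's
parameter-recovery tests rely on. The generator records the planted events
per copy as its ground truth. The CpG multiplier of 10 is a modelling
choice (large enough that the CpG correction visibly matters), not a
measured value.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: repetitive or low-complexity flanks (anchoring is
exercised only in its trustworthy unique-flank regime), indel sequencing
errors, paired-end structure, diploidy (the real region is X-linked and
treated haploid), population-level polymorphism within carrier groups, and
assembly errors. The concordance achieved on synthetic cohorts is
accordingly an upper bound; the published-scale analyses this package
models report concordance well below 100% on real resequencing data.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open (BED convention) everywhere; read
  placements on local references use the same convention.
* Merge, clustering and chaining tie-breaks are all deterministic
  (longest-then-leftmost; length-then-name; fixed scan order), so every
  pipeline stage is bit-reproducible and order-independent.
* `kimura2p()` errors on saturation and on zero comparable columns rather
  than returning `NaN`; `genotype()` has no no-call state by design;
  selection emptying a population, non-monophyletic carriers, overlapping
  panel entries, and flanks that do not fit all raise immediate errors.
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state.

# Problem sizes

The shipped tests and the acceptance script run the pipeline at sizes
chosen to exercise every code path while staying desk-scale: 200-kb
chromosomes with 10 derived genomes and 60 planted SVs for discovery
round-trips; 60-kb cohorts at 20x for genotyping; 200-500 TE copies of
~300 bp for dating and subfamily recovery; the 13-leaf dated tree and the
four-phase scenario for timeline inference. The full suite runs in well
under a minute.

# Known limitations

* Reverse-strand anchoring is off by default and inversions,
  translocations and tandem-repeat subtypes are out of scope.
* The internal mapper is ungapped with $\le$ 2 mismatches; it is not a
  general-purpose aligner and reads spanning novel junctions simply do not
  map, which is precisely the signal the genotyper uses.
* The cosegregation test is the two-site variant only; three-site
  diagnostics are not implemented.
* Ages are point estimates; no confidence intervals are reported.
* `local_align()` returns one optimal alignment (deterministic, via
  `pairwiseAlignment`); co-optimal alignments are not enumerated.
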