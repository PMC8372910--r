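---
title: "Methods: plastome hotspot discovery and barcode utility scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastome hotspot discovery and barcode utility scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomeHotspots)
```

## The problem

Given a set of annotated plastomes from closely related species, the package
quantifies where the variation sits (sliding-window nucleotide diversity,
per-region proportions of variable and parsimony-informative sites), how far
apart the samples are (K2P distances), and — the part that actually decides
whether a region is a usable barcode — whether a tree built from a candidate
region alone reproduces the clade structure of the whole-plastome reference
tree. A simulator generates plastome sets with known truth so every stage is
testable offline, without GenBank access.

## Statistics and their conventions

**Nucleotide diversity.** π is the average over unordered taxon pairs of
(pairwise differences / pairwise compared sites). Gap handling is
*pairwise deletion* by default: per pair, only columns where both rows carry
an unambiguous base are compared, and pairs with no comparable column are
dropped from the average. The popular desktop implementation of windowed π
uses complete deletion within windows; the choice matters in indel-rich
spacers, where complete deletion can discard most columns. Both modes are
exposed (`gap_mode`); pairwise deletion is the default because it retains
signal in exactly the regions this analysis cares about. Windows are
`window_length` = 500 columns advanced by `step` = 100 (both in *alignment*
columns, not ungapped genomic positions); only full windows are reported,
and a window with no comparable pair yields `NA` with a warning rather than
an error, so one gappy window does not kill a genome-scale profile.

**Site classes.** A column is *variable* if at least two distinct
unambiguous bases occur, *parsimony-informative* if at least two distinct
unambiguous bases each occur in at least two taxa. Gaps and IUPAC ambiguity
codes never count as states (determinism over cleverness). Proportions are
reported relative to alignment length.

**K2P distance.** With transition proportion P and transversion proportion Q
over the pairwise-comparable columns, `d = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q)`.
When a log argument is non-positive the pair is *saturated*: the distance is
flagged `NA` with a warning, never silently clamped, and the NJ builder
refuses matrices containing undefined entries. Reported precision in TSV
output is 4 decimals, matching how such distances are conventionally printed.
Gap handling is again pairwise deletion by default, with a `complete`
option.

**Trees.** The container is ape's `phylo`. Newick serialization is
canonical: children are ordered by their minimal descendant leaf label, so
topologically equal trees print identically and round-trip byte-identically
— this is what makes "deterministic outputs" testable. The internal tree
builder is plain Saitou–Nei neighbor joining with two pinned-down details:
ties in the Q criterion break at the lowest (row, col) index pair, and
negative branch lengths are clamped to zero with the deficit moved to the
sister edge. NJ is deliberately simple; externally inferred ML trees plug in
through Newick at every scoring interface.

**Monophyly and backbone.** Monophyly of a taxon set is assessed on the tree
rooted by the designated outgroup: true iff some node's descendant leaf set
equals the set exactly (a polytomy counts only via exact equality). The
"overall topology" point needed an operational definition, since "matches
the reference" is not formal: every defined clade must be monophyletic in
both trees; each clade (and the outgroup) is collapsed to a placeholder
leaf, leaves outside all groups are pruned, and the point is awarded iff the
two collapsed unrooted topologies have Robinson–Foulds distance zero. A
candidate in which the outgroup itself is not separable cannot be rooted
consistently, scores zero for the outgroup-coincident clade, and cannot earn
the topology point.

**Utility score.** One point per defined clade recovered (canonically:
ingroup clades I–IV plus the near-outgroup genus, whose monophyly is scored
even though it also serves as the rooting outgroup) plus the topology point:
maximum six. Excluded taxa — e.g. a clade represented by accessions of a
single species deliberately left unscored — are pruned before any
indicator is computed. Ranking sorts by total, then PI proportion, then
name; the tie-break is invented for determinism, nothing more.

**Gene-content events.** Loss/pseudogenization mapping is unordered 3-state
parsimony (intact, pseudogene, absent) with equal unit costs — the data
provide no cost scheme, and an intact→pseudogene→absent ordering is *not*
enforced because losses and pseudogenizations are mapped as distinct event
types. The root state is fixed to intact whenever every outgroup leaf is
intact. Among equally parsimonious assignments the DELTRAN rule (prefer the
parent's state, pushing changes toward the tips) is applied and the number
of ambiguous nodes is logged, so a user can see when the reconstruction was
a choice rather than a fact.

**Inverted repeats.** `find_ir()` seeds on exact 31-mer matches between the
sequence and its reverse complement, merges seed runs per diagonal into
maximal exact matches, and keeps the longest disjoint pair at least
`min_len` = 1000 bp long (real plastome IRs are tens of kb; 1000 avoids
tRNA-scale false hits). The shorter arc between the copies is SSC, the
longer LSC, and coordinates are reported rotated so the LSC starts at 0,
the conventional plastome presentation; `origin_offset` records the
rotation. The search is exact-match and linear (an IR straddling the
sequence origin is not found) — mismatch-tolerant extension was considered
and deferred as out of proportion for the detection task.

## The simulator and what a green test establishes

Sequences evolve along a species tree under the Kimura two-parameter model
(default transition/transversion rate ratio κ = 2, a typical plastid value):
the same model family the K2P distance inverts, which is the point — the
distance estimator is consistent for the simulated path lengths, so
parameter-recovery tests have an exact analytic target
(`expected_site_difference()`, `expected_pi()`). Richer models (Γ rate
variation among sites, indels, GTR) are deliberately out of scope; an
optional gap injector exists only in the tests' fixtures. Genomes are
assembled per taxon by concatenating per-region sequences in config order
into LSC / IRb / SSC / IRa, with the IR block inserted once forward and once
reverse-complemented, planted losses removing or pseudogene-marking features
on all taxa under the event branch. Two fixed two-base linkers flank the
simulated SSC so that the *maximal* exact inverted repeat equals the
*planted* one in every taxon (otherwise a chance matching base at a boundary
would extend the repeat in ~44% of genomes and "recovered exactly" would be
untestable).

**The default world.** The benchmark emulates the motivating mistletoe system: 29 ingroup
accessions in five clades (9/6/5/4 plus a five-accession clade excluded from
scoring) and a three-taxon near-outgroup genus; 19 regions including slow
PCGs (0.5–1.5× the plastome-average rate), fast spacers (4–8×), an rRNA in
the IR (0.3×) and two SSC genes; planted events mirroring the gene-content pattern of the motivating
system (loss of *infA* independently on the outgroup stem and in one
clade-I taxon, loss of *trnH* in that same taxon — which drops the
*trnH–psbA* spacer from the shared set — and pseudogenization of *rpl32* on
the clade-IV stem). Branch lengths were chosen once to sit inside every
statistic reported for the motivating system: within-clade distances < 0.01, maximum
within-ingroup distance ≈ 0.017, ingroup–outgroup distances 0.029–0.035,
plastome-average expected π ≈ 0.013, spacer PI proportions ≈ 0.17–0.25 and
PCG PI proportions ≈ 0.02–0.07. The one intentional exception: the 305 bp
spacer at 8× reaches PI ≈ 0.32–0.38, above the ~0.17 reported for its real counterpart —
it is the "too variable to be useful" region and the clean substitution
model needs the extra heat to reproduce that behavior, because the forces
that actually degraded the real region (microstructural mutation,
alignment ambiguity, homoplasy concentrated at a few sites) are not
simulated.

**Calibration of the scored edges.** The seven edges the utility test can
detect (four clade stems, the near-outgroup stem, two ingroup backbone
edges) all carry 8e-4 substitutions/site. The reasoning, fixed before the
final choice and then frozen: in the motivating system the scored clades and
backbone are strongly supported by long regions while short spacers
intermittently miss them; with a 1.66 kb region at 5× each scored edge
expects ≈ 6.6 substitutions (recovery nearly certain), while a 305 bp
region at 8× expects ≈ 2.0 (a real chance of zero informative change per
edge), and spreading the signal over seven independent scored edges — not
concentrating it on a weak backbone — is what separates the two honestly. In
120-replicate simulations the long fast spacer scores 6/6 in ≈ 97% of seeds
and the short hypervariable spacer drops at least one point in ≈ 57%; the
acceptance test asserts exactly this qualitative pattern over its 20 fixed
seeds. A green run therefore establishes that the pipeline ranks long/fast
regions above short/hypervariable ones *under this model*; it does not
establish anything about alignment quality, indel handling, or rate
variation in real spacers.

## Numerical and degenerate-input choices

- Internal coordinates are 0-based half-open everywhere; GenBank's 1-based
  inclusive convention is converted only at the file boundary. Circular
  arithmetic (origin-crossing spacers, origin-crossing features as
  same-name parts) is tested explicitly.
- Ambiguity codes are kept on input and handled per statistic (always as
  missing, never as partial matches).
- Duplicate gene copies in the IR: `ir_policy = "first"` (first in feature
  order) by default, since the source analyses do not say which copy they
  used; `"lsc-copy"` resolves via a detected IR structure when available.
- An intergenic spacer is strictly between its flanking features (no flank
  bases); a zero-length spacer is legal; overlapping flanks are an error.
- Empty alignments concatenate as identities; concatenation matches rows by
  taxon label, not row order.
- `score_region` on a candidate whose outgroup is non-separable falls back
  to rooting on the first outgroup taxon so the remaining indicators are
  still well-defined.
- Seeds: every simulation entry point takes an explicit integer seed;
  identical seeds give byte-identical fixture directories.

## Known limitations

- The GenBank reader covers the feature-table subset this pipeline needs
  (gene/CDS/tRNA/rRNA/misc_feature, join/complement, /gene, /pseudo); it is
  not a general GenBank parser.
- `find_ir()` is exact-match and does not wrap the origin; genomes should be
  rotated so the IR does not straddle position 0 (the simulator guarantees
  this).
- NJ is a testing and quick-scoring device, not a replacement for ML
  inference on real data; the scoring interfaces accept external trees for
  that reason.
- The simulator's clean-clock, site-homogeneous model understates the
  homoplasy of real hypervariable spacers; conclusions about *specific* real
  regions must come from real alignments fed through the same interfaces.
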