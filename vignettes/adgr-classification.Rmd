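---
title: "Classifying adhesion GPCRs from 7TM phylogenies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying adhesion GPCRs from 7TM phylogenies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adgrevo)
```

## The problem

Adhesion G protein-coupled receptors (aGPCRs) are a class of 33 human
receptors whose historical names (BAI1, CD97, GPR56, latrophilins, ...)
carry no phylogenetic information. A cluster-based hierarchy fixes this:
receptors are ordered into *levels* named by taxonomic analogy — level 5
(class: aGPCRs plus secretin-like receptors), level 4 (order: `ADGR` vs.
secretin-like), level 3 (family: a capital letter), level 2 (genus: a
number), level 1 (species-private subtype: a lowercase letter), with
splice variants as `.1`, `.2`, ... appended. Assignments are driven by
bootstrap-supported clustering of the seven-transmembrane (7TM) domain,
the only region alignable across the whole class.

`adgrevo` implements that workflow end to end: alignment I/O,
Poisson-corrected distances, neighbor-joining trees with bootstrap
bipartition support, outgroup rooting, the nomenclature rules, a
conservation-based generic residue numbering of the 7TM helices, a
Nei–Gojobori dN/dS selection screen, a loss-of-function (LoF) constraint
comparison, and a gene-family simulator that provides ground truth for
every stage.

## Distances and trees

Pairwise dissimilarity between aligned amino-acid sequences is the
mismatch proportion $p$ over comparable sites. Under *pairwise deletion*
(the default) a site is comparable for a pair when neither sequence has a
gap or an ambiguous `X` there; *complete deletion* restricts all pairs to
columns that are unambiguous in every sequence. The Poisson correction

$$d = -\ln(1 - p)$$

converts $p$ into expected substitutions per site, assuming equal rates
across sites and no back-substitution bias. $p = 1$ cannot be corrected;
by default this is an error. Deliberately short sub-alignments (the TM
fragment analyses) may legitimately contain such pairs, so the distance
functions also offer `saturation = "cap"`, which caps $p$ at the
resolution limit $1 - 1/(2m)$ for $m$ compared sites; fragment trees use
this mode.

Trees are built by classical neighbor joining. Two numerical conventions
make results reproducible: negative branch-length estimates are clamped
to zero, and when several pairs tie on the Q criterion the
lexicographically smallest label pair is joined, so the tree is invariant
to input order. On an additive matrix the generating topology and branch
lengths are recovered exactly; the test suite verifies this against an
exhaustive least-squares topology search on small instances and against
an independent NJ implementation.

Bootstrap support resamples alignment columns with replacement, rebuilds
the tree, and counts for every internal edge the percentage of replicate
trees containing the same bipartition (compared as leaf sets; branch
lengths are ignored). The resampling stream is controlled by a single
seed, so supports are exactly reproducible. Rooting on a monophyletic
outgroup never changes any support value, because supports are keyed by
bipartition, not by node.

## Nomenclature rules

Given a rooted, support-annotated tree and a support threshold (default
50%), the classifier applies the level rules:

* **Families (level 3)** are the *maximal* supported clusters that
  partition the non-outgroup leaves, lettered `A`, `B`, ... in
  root-to-tip, depth-first encounter order. The cluster spanning the
  entire ingroup is the order, not a family. Leaves outside any supported
  cluster remain unassigned. An override map can pin historical letters
  so that curated panels keep their published names. The published
  threshold is stated as "(≤50%)"; supports are *retained* at or above
  the threshold here, which is how the criterion is used in practice —
  the threshold is configurable for readers of the literal text.
* **Genera (level 2)** are the minimal supported clades within a family
  whose membership spans at least one fish and one mammal — the
  operational meaning of "clustering supports direct orthology in fishes
  and in mammals". Numbering follows depth-first order from the family
  root (the traversal is a package choice; no canonical order is
  defined elsewhere).
* **Subtype letters (level 1)** are added per species whenever one
  species carries several members of a genus (e.g. a teleost-specific
  duplication yields `dr ADGRF1a` / `dr ADGRF1b`). The letters are
  private to the species: equality of letters across species carries no
  orthology claim, which is why the species code always prefixes a name
  containing a level-1 letter.

A practical consequence of the maximality rule: when a clade containing
two historically separate families is itself supported, the two merge
into one letter with internal genus numbers, exactly as the historical E
and L families merged. This is a renaming, not a misclustering — the
partition of receptors into orthology groups is unchanged.
`classification_groups()` therefore reports each receptor's finest
recovered group (genus where defined, else family), and recovery
experiments compare that partition, not the letters, with simulation
truth.

One-to-one orthology (`detect_one_to_one`) requires exactly one member
per species and a species set spanning fish and mammals. The minimum
ancestral repertoire adds one gene per one-to-one group plus the stated
ancestral multiplicity of each unresolved group; on the bundled curated
tables this yields 19 one-to-one groups and a repertoire of 25 for the 33
human receptors.

## Generic residue numbering

Within each TM helix, the most conserved alignment column is elected the
reference position `h.50` and all other columns are labelled by their
integer offset (`h.49`, `h.51`, ...), the convention used for rhodopsin-
like receptors. Conservation of a column is the frequency of its modal
unambiguous residue over *all* sequences of the chosen subset, so gaps
and `X` count against conservation; this matches quoting a percentage
over a fixed receptor panel, and the per-column depth is reported
alongside for readers who prefer the other convention. Ties are broken
toward the segment midpoint, then the lower column index — deterministic
and biologically neutral. Offsets beyond ±49 are refused to preserve the
two-digit convention.

Signature motifs are consensus strings over the window running from the
most N-terminal column at or above the conservation cutoff (default
80%) through the helix reference, with `x` marking free positions — the
form in which aGPCR motifs such as `GxGxP` ending at 4.50 are quoted.

## The simulator and what it does (not) emulate

`simulate_families()` evolves gene families on a fixed vertebrate-like
species tree — (fish,(amphibian,(reptile,(bird,mammal)))) plus an
outgroup — with branch lengths in substitutions per site (fish to mammal
path 0.50). Families descend from ancestors evolved from a common master
sequence; the default inter-ancestor divergence of 2.0 substitutions/site
makes families roughly five times farther apart than the deepest
within-family path, i.e. clearly separated but not random with respect to
each other. Duplications and losses follow a birth–death process per
lineage (rates in events per unit branch length, optionally restricting
duplications to chosen branches such as the fish stem, emulating the
teleost genome duplication). Amino-acid evolution is Poisson-uniform;
codon mode proposes nucleotide changes and accepts synonymous versus
nonsynonymous ones in ratio $1{:}\omega$ per branch, rejecting stop
codons. The true alignment is emitted directly — no indels and no
realignment, because the analysis consumes curated alignments. Chimeric
sequences can be spliced from two donor families at a column boundary,
with the donor map recorded as truth.

Ground truth records every gene's family, the event counts, per-branch
$\omega$, survival of each ancestral gene, and chimera donors — so family
recovery, orthology flags, duplication naming, fragment sister-group
shifts, and selection detection are all testable without any downloads.

What the simulator does *not* emulate: empirical substitution matrices
and compositional bias, rate variation across sites, indels, alignment
error, and genome-assembly artefacts. Passing recovery tests therefore
demonstrates correctness of the algorithms under the stated model, not
robustness to real-data curation problems.

For numbering experiments, `plant_conservation_features()` installs a
by-construction truth: each helix's tie-break-preferred column is made
invariant (and optional motif residues likewise), and every other TM
column is perturbed below the cutoff, making the planted signal the
unique signal an extractor should find. Reference and motif recovery is
exact across seeds under these conditions.

## Selection screen

The screen implements Nei–Gojobori (1986) counting: each codon position
contributes its fraction of synonymous one-step changes to the
synonymous site count $S$ (changes creating stop codons count as
nonsynonymous, so $N + S$ equals three times the compared codons
exactly); observed differences in multi-hit codons are averaged over all
substitution pathways, excluding pathways through stop codons.
Proportions are Jukes–Cantor corrected and $\omega = dN/dS$; the
classification rule is purifying for $\omega < 1$ and positive for
$\omega \ge 1$ (boundary included). A proportion at or above 3/4
saturates: a saturated $dS$ with finite $dN$ drives $\omega$ to 0 (the
limit of the correction), while a saturated $dN$ leaves the estimate
undefined rather than silently dropped.

`branch_screen()` estimates a per-terminal-branch $\omega$ by comparing
each leaf with the plurality-consensus codons of its sister clade (ties
resolved to the earliest sequence in alignment order). This is a
deliberate desk-scale proxy for branch-site likelihood models: it needs
no ancestral reconstruction, but it has weaker power and its terminal
estimates mix the focal branch with its sister's history — a cherry's
two leaves share one comparison, which is why screens should run on an
outgroup-rooted tree and why planted-selection experiments put the
signal on a branch whose sister is a clade. Calibration on neutral
simulations (500 codons) gives mean $\omega$ within a few percent of 1
(slightly below, because stop-adjacent nonsynonymous sites are counted
as opportunity but never realized), and a planted $\omega = 2$ fish
branch outranks all background branches in essentially every replicate.

## Constraint comparison

LoF observed/expected (o/e) ratios are inputs — computing expectations
from sequence context is a genome-pipeline task, not part of this
package. `family_constraint()` compares each family's mean o/e with the
grand mean over genes and attaches a two-sided label-permutation p-value
(default 10,000 permutations, seeded, order-invariant), calling families
below or above average at α = 0.05. A permutation test was chosen
because no distributional form for o/e ratios is assumed anywhere in the
workflow; the test statistic is the family mean, the simplest reading of
"significantly below the average ratio". Exact enumeration on small
tables agrees with the sampled p-values within Monte-Carlo error.

## Numerical and design choices, collected

* 0-based half-open coordinates in files and internal objects; 1-based
  inclusive columns in every user-facing table.
* `X` residues are allowed in input and treated as missing for distances
  and conservation denominators' *numerators* (they count against
  conservation, like gaps).
* Metadata travels in a sidecar TSV, never parsed from FASTA headers;
  two-letter species codes are user-supplied (they are not unique across
  taxonomy, so deriving them is unsafe).
* NJ tie-break: lexicographically smallest pair; negative branch lengths
  clamped to zero.
* Reference-position tie-break: conservation, then proximity to segment
  midpoint, then lowest column.
* Bootstrap default 1000 replicates; classification threshold default
  50%; motif cutoff default 80%; high-conservation threshold default
  95% — the workflow's entire tunable surface, all surfaced in
  `pipeline_config()`.
* Test and example problem sizes (16-sequence panels, 100–200 bootstrap
  replicates, 400–500 codons, 20 seeds) are chosen so the full suite
  runs in about a minute while keeping every stochastic margin wide;
  the defaults users see are the full-size ones.

## Known limitations

* Maximum-likelihood tree search and empirical rate matrices are out of
  scope; NJ with Poisson correction is the implemented path.
* The branch screen is a counting proxy; it does not reproduce
  branch-site likelihood significance calls, and none are reported.
* Whether TM5's reference position is re-elected or inherited from the
  older scheme is ambiguous in the field's usage when both give the same
  residue; both code paths exist (`assign_reference_positions` always
  re-elects; an override of the segment map reproduces inheritance) and
  neither is asserted in tests.
* Pseudogene status and LoF o/e ratios are user inputs; the package
  never infers them from sequence.
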