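# adgrevo

Phylogenetic classification, generic residue numbering, and selection
analysis of vertebrate adhesion G protein-coupled receptors (aGPCRs).

## For whom, and why

Adhesion GPCRs — 33 receptors in the human genome, most of them orphans —
carry historical names (BAI1, CD97, GPR56, latrophilins, ...) that say
nothing about their relationships. A cluster-based hierarchy replaces
them with names of the form `ADGR<family letter><genus number><subtype
letter>[.variant]`, where each level is defined by bootstrap-supported
clustering of the seven-transmembrane (7TM) domain: families are the
maximal supported clusters, genera the minimal supported clades with
fish-to-mammal orthology, and lowercase subtype letters are private to a
species (a zebrafish duplication becomes `dr ADGRF1a` / `dr ADGRF1b`).
`adgrevo` is for molecular evolutionists and receptor biologists who want
to run, test, or extend that workflow: from an aligned 7TM FASTA to
supported trees, nomenclature tables, presence matrices, X.50 residue
numbering with signature motifs, a dN/dS selection screen, and a
loss-of-function constraint comparison — plus a gene-family simulator
with complete ground truth, so every stage is verifiable offline.

The core quantities, in the field's notation:

* Poisson-corrected distance `d = -ln(1 - p)` over pairwise-deleted
  comparable sites; neighbor-joining trees; bootstrap bipartition
  support in percent.
* Generic numbering: the most conserved column of helix `h` is `h.50`;
  all helix columns are labelled by offset (`6.55` is five residues
  C-terminal of `6.50`). Signature motifs are consensus windows ending
  at `h.50` with `x` for positions below the conservation cutoff.
* Nei–Gojobori dN/dS with Jukes–Cantor correction;
  `ω = dN/dS < 1` is read as purifying and `ω ≥ 1` as positive
  selection.
* LoF constraint: a family's mean observed/expected ratio versus the
  grand mean, with a label-permutation p-value.

## Worked example

Simulate three receptor families on a vertebrate species tree with a
burst of duplication on the fish stem, build a supported tree, and
classify:

```r
library(adgrevo)

sim <- simulate_families(sim_config(n_families = 3, duplication_rate = 3,
                                    duplication_branches = "dr", seed = 21))
tr  <- bootstrap_support(sim$msa, n_replicates = 100, seed = 3)
tr  <- root_with_outgroup(tr, sim$truth$outgroup_id)
sp  <- setNames(sim$msa$species_code, sim$msa$id)
rec <- classify_tree(tr, sp, sim$msa$clade_of_species)
head(rec[, c("id", "species_code", "level3", "level2", "level1", "full_name")], 5)
#>        id species_code level3 level2 level1 full_name
#> 1 xt_F2_1           xt      A      1   <NA>    ADGRA1
#> 2 gg_F2_1           gg      A      1   <NA>    ADGRA1
#> 3 hs_F2_1           hs      A      1   <NA>    ADGRA1
#> 4 ac_F2_1           ac      A      1   <NA>    ADGRA1
#> 5 dr_F3_1           dr      B      1   <NA>    ADGRB1
attr(rec, "groups")
#>   group n_members one_to_one
#> 1    A1         6      FALSE
#> 2    B1         5       TRUE
#> 3    B2         6      FALSE
```

Each receptor gets its level assignments and composed name; the group
summary shows which recovered orthology groups are strict fish–mammal
one-to-one (here the two groups that caught a fish paralog pair are
flagged `FALSE`, and their zebrafish members carry `dr ... a` / `dr
... b` subtype names).

Conservation numbering on a panel with planted reference residues:

```r
segmap <- read_segment_map(system.file("extdata", "tm_segments_example.tsv",
                                       package = "adgrevo"), 200)
pl   <- plant_conservation_features(sim$msa, segmap, motifs = c(TM4 = "GxGxP"))
prof <- conservation_profile(pl$msa)
assign_reference_positions(prof, segmap)
#> reference positions:
#>   L1.50 (100.0% conserved, column 23)
#>   N2.50 (100.0% conserved, column 53)
#>   W3.50 (100.0% conserved, column 83)
#>   P4.50 (100.0% conserved, column 110)
#>   N5.50 (100.0% conserved, column 138)
#>   L6.50 (100.0% conserved, column 165)
#>   G7.50 (100.0% conserved, column 190)
```

Each helix elects its most conserved column as the `h.50` anchor; the
planted `GxGxP` motif is returned verbatim by
`signature_motifs(..., cutoff = 1, regions = "TM4")`.

A pairwise selection estimate:

```r
ng86_dnds("TTTGCTAAAGGG", "TTCGCTAGAGGC")
#> selection_estimate a vs b: 4 codons, N=9.17 S=2.83 Nd=1.00 Sd=2.00
#>   dN=0.1179 dS=2.1249 omega=0.055 (purifying)
```

Nonsynonymous and synonymous sites partition the 12 positions (N + S =
12); the two synonymous and one nonsynonymous differences give
ω = 0.055, called purifying.

`run_pipeline(pipeline_config(...))` chains all stages (alignment →
tree → classification → numbering → selection → constraint) and writes
deterministic TSV/newick outputs plus a run log.

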