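test_that("p-distance counts comparable sites with pairwise deletion", {
  expect_equal(p_distance("ACDE", "ACDE")$p, 0)
  r <- p_distance("AAAA", "AAAT")
  expect_equal(r$p, 0.25)
  expect_equal(r$compared_sites, 4)
  # gaps on either side remove the column from the comparison
  r2 <- p_distance("A-CD", "AB-D")
  expect_equal(r2$compared_sites, 2)
  expect_equal(r2$p, 0)
  expect_error(p_distance("--", "AA"), "zero comparable")
})

test_that("Poisson correction matches its closed form and inverts", {
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.5), log(2), tolerance = 1e-12)
  expect_equal(poisson_correct(1 - exp(-2)), 2, tolerance = 1e-12)
  expect_error(poisson_correct(1), "saturated")
  d <- seq(0, 5, by = 0.25)
  expect_equal(poisson_correct(1 - exp(-d)), d, tolerance = 1e-9)
})

test_that("neighbor joining solves small additive cases exactly", {
  expect_error(neighbor_joining(matrix(0, 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "at least 3")
  # three taxa: the unique star with three-point branch lengths
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(d3)
  expect_equal(ape::cophenetic.phylo(t3$phy)[rownames(d3), colnames(d3)],
               d3)
  # four taxa: split ab|cd, internal edge 1, leaf edges 1,2,3,4
  d4 <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t4 <- neighbor_joining(d4)
  expect_true("A\tB" %in% tree_bipartitions(t4$phy) ||
                "C\tD" %in% tree_bipartitions(t4$phy))
  expect_equal(ape::cophenetic.phylo(t4$phy)[rownames(d4), colnames(d4)],
               d4, tolerance = 1e-9)
})

test_that("NJ agrees with the exhaustive least-squares oracle", {
  skip_if_not_installed("phangorn")
  withr::local_seed(71)
  for (r in 1:15) {
    ra <- random_additive(5)
    nj <- neighbor_joining(ra$d)
    oracle <- ls_best_topology(ra$d)
    expect_identical(bip_set(nj$phy), bip_set(oracle))
  }
})

test_that("NJ output is invariant to input label order", {
  withr::local_seed(42)
  ra <- random_additive(6)
  ref <- neighbor_joining(ra$d)
  for (r in 1:5) {
    perm <- sample(rownames(ra$d))
    t2 <- neighbor_joining(ra$d[perm, perm])
    expect_identical(bip_set(ref$phy), bip_set(t2$phy))
    expect_equal(ape::cophenetic.phylo(t2$phy)[perm, perm],
                 ra$d[perm, perm], tolerance = 1e-9)
  }
})

test_that("NJ topology matches the independent ape implementation", {
  sim <- simulate_families(sim_config(seed = 88))
  dm <- msa_distances(sim$msa)
  ours <- neighbor_joining(dm)
  theirs <- ape::nj(as.dist(dm$d))
  expect_equal(ape::dist.topo(ape::unroot(ours$phy),
                              ape::unroot(theirs)), 0,
               ignore_attr = TRUE)
})

test_that("pairwise and complete deletion differ only via gapped columns", {
  msa <- make_msa(c("AAAAC", "AA-AC", "AATAG"))
  dp <- msa_distances(msa, deletion = "pairwise")
  dc <- msa_distances(msa, deletion = "complete")
  expect_equal(dc$compared_sites[1, 2], 4)  # gap column dropped for all
  expect_equal(dp$compared_sites[1, 3], 5)
  expect_equal(dp$p[1, 3], 2 / 5)
  # the gapped column (a genuine mismatch for the 1-3 pair) is dropped
  # from everyone under complete deletion
  expect_equal(dc$p[1, 3], 1 / 4)
})

test_that("bootstrap gives certainty on tree-consistent data, reproducibly", {
  msa <- consistent_msa()
  tr <- bootstrap_support(msa, n_replicates = 50, seed = 11)
  expect_true(all(tr$support == 100))
  tr2 <- bootstrap_support(msa, n_replicates = 50, seed = 11)
  expect_identical(tr$support, tr2$support)
  tr1 <- bootstrap_support(msa, n_replicates = 1, seed = 3)
  expect_true(all(tr1$support %in% c(0, 100)))
  expect_error(bootstrap_support(make_msa(c("A", "C", "G"))), "2 columns")
})

test_that("outgroup rooting validates monophyly and preserves supports", {
  msa <- consistent_msa()
  tr <- bootstrap_support(msa, n_replicates = 25, seed = 2)
  rooted <- root_with_outgroup(tr, "t6")
  expect_true(ape::is.rooted(rooted$phy))
  expect_identical(rooted$support, tr$support)
  # t5,t6 form a cherry; t1 with t6 crosses a resolved bipartition
  expect_silent(root_with_outgroup(tr, c("t5", "t6")))
  expect_error(root_with_outgroup(tr, c("t1", "t6")), "not monophyletic")
  sim <- simulate_families(sim_config(seed = 55))
  trs <- bootstrap_support(sim$msa, n_replicates = 25, seed = 5)
  rt <- root_with_outgroup(trs, sim$truth$outgroup_id)
  # outgroup sits as sister to everything else
  og_edge <- which(rt$phy$tip.label == sim$truth$outgroup_id)
  root_children <- rt$phy$edge[rt$phy$edge[, 1] ==
                                 length(rt$phy$tip.label) + 1, 2]
  expect_true(og_edge %in% root_children)
})

test_that("a fragment spanning the full alignment reproduces the full tree", {
  sim <- simulate_families(sim_config(seed = 19))
  sm <- segment_map("TM1", 0, 200, 200)
  full <- bootstrap_support(sim$msa, n_replicates = 10, seed = 4)
  frag <- fragment_trees(sim$msa, sm, groups = list(all = "TM1"),
                         n_replicates = 10, seed = 3)
  expect_identical(bip_set(full$phy), bip_set(frag$trees$all$phy))
})

test_that("chimeric sequences switch sister families between fragments", {
  cfg <- sim_config(n_families = 3, seed = 11,
                    chimera = list(donor_a = 1, donor_b = 2,
                                   boundary = 150, species = "hs"))
  sim <- simulate_families(cfg)
  segmap <- read_segment_map(
    system.file("extdata", "tm_segments_example.tsv", package = "adgrevo"),
    200)
  fam_of <- setNames(paste0("F", sim$truth$genes$family),
                     sim$truth$genes$id)
  ft <- fragment_trees(sim$msa, segmap, n_replicates = 30, seed = 5,
                       query_ids = sim$truth$chimera$id,
                       family_of = fam_of)
  sis <- setNames(ft$sister$sister_family, ft$sister$fragment)
  expect_identical(unname(sis[c("TM1-2", "TM3-5")]), c("F1", "F1"))
  expect_identical(unname(sis["TM6-7"]), "F2")
})
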