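# hand-built supported tree: two families of three species each plus
# outgroup, with controllable supports
two_family_tree <- function(supports = 100) {
  nwk <- "(((a1:1,(a2:1,a3:1):1):1,((b1:1,b2:1):1,b3:1):1):1,og:3);"
  phy <- ape::read.tree(text = nwk)
  keys <- tree_bipartitions(phy)
  supported_tree(phy, support = setNames(rep(supports, length(keys)),
                                         keys),
                 outgroup = "og")
}

test_that("supported clusters honour the threshold, largest first", {
  tr <- two_family_tree(0)
  expect_length(supported_clusters(tr, threshold = 50), 0)
  tr100 <- two_family_tree(100)
  cl <- supported_clusters(tr100, threshold = 50)
  expect_length(cl, length(tree_bipartitions(tr100$phy)))
  expect_true(all(diff(lengths(cl)) <= 0))
  expect_error(supported_clusters(supported_tree(tr100$phy)),
               "no bootstrap")
})

test_that("families are maximal supported clusters below the order", {
  tr <- two_family_tree(100)
  fam <- assign_families(tr)
  f <- setNames(fam$family, fam$id)
  expect_identical(unname(f[c("a1", "a2", "a3")]), rep("A", 3))
  expect_identical(unname(f[c("b1", "b2", "b3")]), rep("B", 3))
  # dropping the family-B clade support leaves b3 unassigned while the
  # still-supported b1/b2 cherry becomes the maximal cluster
  tr2 <- two_family_tree(100)
  kb <- adgrevo:::bip_key(c("b1", "b2", "b3"), tr2$phy$tip.label)
  tr2$support[kb] <- 0
  fam2 <- assign_families(tr2)
  f2 <- setNames(fam2$family, fam2$id)
  expect_true(is.na(f2[["b3"]]))
  expect_identical(unname(f2[c("b1", "b2")]), rep("B", 2))
})

test_that("historical letters can be pinned through the override map", {
  tr <- two_family_tree(100)
  fam <- assign_families(tr, override = c(b2 = "L"))
  f <- setNames(fam$family, fam$id)
  expect_identical(unname(f[["b1"]]), "L")
  expect_identical(unname(f[["a1"]]), "A")
  expect_error(assign_families(tr, override = c(a1 = "L", a2 = "Q")),
               "conflict")
})

test_that("one-to-one orthology needs one member per species, fish to mammal", {
  sp <- c(x1 = "dr", x2 = "xt", x3 = "hs", y1 = "dr", y2 = "dr",
          z1 = "xt", z2 = "hs")
  expect_true(detect_one_to_one(c("x1", "x2", "x3"), sp,
                                toy_clades)$one_to_one)
  # a fish duplication breaks it
  expect_false(detect_one_to_one(c("y1", "y2", "x3"), sp,
                                 toy_clades)$one_to_one)
  # spanning amphibian..mammal without fish is not enough
  expect_false(detect_one_to_one(c("z1", "z2"), sp, toy_clades)$one_to_one)
})

test_that("names compose deterministically across all levels", {
  assign <- data.frame(
    id = c("h1", "d1", "d2", "h2"),
    species_code = c("hs", "dr", "dr", "hs"),
    family = c("F", "F", "F", NA),
    genus = c(2L, 1L, 1L, NA),
    letter = c(NA, "a", "b", NA),
    stringsAsFactors = FALSE)
  rec <- generate_names(assign)
  expect_identical(rec$full_name,
                   c("ADGRF2", "dr ADGRF1a", "dr ADGRF1b", NA))
  # splice variants are period-numbered in input order
  recv <- generate_names(assign, variants = c(h1 = 2L))
  expect_identical(recv$full_name[recv$id == "h1"],
                   c("ADGRF2.1", "ADGRF2.2"))
  bad <- assign
  bad$letter <- c(NA, "a", "a", NA)
  expect_error(generate_names(bad), "duplicate full name")
})

test_that("classification of a simulated panel assigns genera and letters", {
  cfg <- sim_config(n_families = 3, duplication_rate = 3,
                    duplication_branches = "dr", seed = 21)
  sim <- simulate_families(cfg)
  expect_true(sum(sim$truth$events$duplications) > 0)
  tr <- bootstrap_support(sim$msa, n_replicates = 50, seed = 3)
  tr <- root_with_outgroup(tr, sim$truth$outgroup_id)
  sp_of <- setNames(sim$msa$species_code, sim$msa$id)
  rec <- classify_tree(tr, sp_of, sim$msa$clade_of_species)
  # fish paralogs carry species-prefixed a/b subtype letters
  dupf <- sim$truth$families$family[!sim$truth$families$one_to_one][1]
  dr_names <- rec$full_name[rec$species_code == "dr" &
                              grepl(paste0("^dr_F", dupf), rec$id)]
  expect_true(all(grepl("^dr ADGR[A-Z][0-9]*[a-z]$", dr_names)))
  expect_true(any(grepl("a$", dr_names)) && any(grepl("b$", dr_names)))
  # names are unique per species and idempotent under re-run
  rec2 <- classify_tree(tr, sp_of, sim$msa$clade_of_species)
  expect_identical(rec$full_name, rec2$full_name)
})

test_that("presence matrices reflect assignments and pseudogene flags", {
  groups <- c("G1", "G1", "G1", "G2", "G2")
  species <- c("dr", "xt", "hs", "dr", "hs")
  pm <- presence_matrix(groups, species, toy_clades)
  expect_identical(unname(pm["G1", c("fish", "mammal", "bird")]),
                   c("present", "present", "absent"))
  expect_identical(unname(pm["G2", "amphibian"]), "absent")
  pm2 <- presence_matrix(groups, species, toy_clades,
                         pseudogene = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(unname(pm2["G1", "mammal"]), "pseudogene")
  # a simulated clade-restricted loss shows up as an absent cell
  cfg <- sim_config(n_families = 1, loss_rate = 2.5, seed = 133)
  sim <- simulate_families(cfg)
  gtab <- sim$truth$genes[!is.na(sim$truth$genes$family), ]
  lost <- setdiff(c("dr", "xt", "ac", "gg", "hs"), gtab$species)
  expect_gt(length(lost), 0)  # this history loses the gene in >=1 lineage
  pml <- presence_matrix(rep("F1", nrow(gtab)), gtab$species, toy_clades)
  expect_identical(unname(pml["F1", toy_clades[lost[1]]]), "absent")
})

test_that("ancestral repertoire adds one-to-one groups and multiplicities", {
  g <- data.frame(one_to_one = c(TRUE, TRUE, FALSE),
                  multiplicity = c(1, 1, 3))
  expect_equal(ancestral_repertoire(g), 5)
  g2 <- data.frame(one_to_one = rep(TRUE, 7), multiplicity = rep(1, 7))
  expect_equal(ancestral_repertoire(g2), 7)
  g$multiplicity[3] <- NA
  expect_error(ancestral_repertoire(g), "multiplicity")
  # a simulated history with k surviving ancestral genes recovers k
  # (every family starts from a single ancestral gene)
  sim <- simulate_families(sim_config(n_families = 4, duplication_rate = 1,
                                      seed = 61))
  fams <- sim$truth$families[sim$truth$families$survived, ]
  grp <- data.frame(one_to_one = fams$one_to_one, multiplicity = 1)
  expect_equal(ancestral_repertoire(grp), sim$truth$ancestral_repertoire)
})

test_that("bundled tables carry the curated repertoire", {
  nom <- read_nomenclature_table()
  expect_equal(nrow(nom), 33)
  expect_equal(sum(nom$pseudogene), 1)
  expect_setequal(unique(nom$family_v3),
                  paste0("ADGR", c("A", "B", "C", "D", "E", "F", "G",
                                   "L", "V")))
  # the revised scheme merges the historical E family into L and moves
  # the former G7 into its own family E
  expect_identical(nom$family_v3[nom$name_v2 == "ADGRE5"], "ADGRL")
  expect_identical(nom$family_v3[nom$name_v2 == "ADGRG7"], "ADGRE")
  pres <- read_presence_table()
  expect_identical(unname(pres["ADGRE5",
                               c("fish", "amphibian", "reptile",
                                 "bird", "mammal")]),
                   c("present", "present", "present", "absent",
                     "present"))
})
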