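test_that("without duplication or loss every species carries one copy", {
  sim <- simulate_families(sim_config(n_families = 3, seed = 8))
  g <- sim$truth$genes[!is.na(sim$truth$genes$family), ]
  counts <- table(g$family, g$species)
  expect_true(all(counts == 1))
  expect_true(all(sim$truth$families$one_to_one))
  expect_equal(sim$truth$ancestral_repertoire, 3)
  expect_equal(sim$msa$alignment_length, 200)
})

test_that("fixed seeds give bit-identical output, different seeds differ", {
  a <- simulate_families(sim_config(seed = 99))
  b <- simulate_families(sim_config(seed = 99))
  expect_identical(a$msa$seq, b$msa$seq)
  expect_identical(a$truth, b$truth)
  c <- simulate_families(sim_config(seed = 100))
  expect_false(identical(a$msa$seq, c$msa$seq))
})

test_that("event counts follow the birth-death expectation", {
  cfg0 <- sim_config(duplication_rate = 0, seed = 1)
  expect_equal(unname(expected_event_counts(cfg0)["duplications"]), 0)
  # closed form: rate x applicable tree length
  st <- default_species_tree()
  phy <- ape::drop.tip(st$phy, "og")
  L <- sum(phy$edge.length)
  cfg <- sim_config(duplication_rate = 0.4, loss_rate = 0.3, seed = 1)
  ee <- expected_event_counts(cfg)
  expect_equal(unname(ee["duplications"]), 0.4 * L)
  expect_equal(unname(ee["losses"]), 0.3 * L)
  # Monte-Carlo agreement within 3 standard errors
  sims <- vapply(1:150, function(s) {
    x <- simulate_families(sim_config(n_families = 1,
                                      duplication_rate = 0.4,
                                      loss_rate = 0.3, seed = 7000 + s))
    c(x$truth$events$duplications, x$truth$events$losses)
  }, c(0, 0))
  for (k in 1:2) {
    se <- sd(sims[k, ]) / sqrt(ncol(sims))
    expect_lt(abs(mean(sims[k, ]) - ee[k]), 3 * se + 0.05)
  }
})

test_that("duplications restricted to the fish stem stay in fish", {
  sim <- simulate_families(sim_config(n_families = 3, duplication_rate = 3,
                                      duplication_branches = "dr",
                                      seed = 21))
  g <- sim$truth$genes[!is.na(sim$truth$genes$family), ]
  counts <- table(factor(g$species, levels = c("dr", "xt", "ac", "gg",
                                               "hs")), g$family)
  expect_true(any(counts["dr", ] > 1))
  expect_true(all(counts[c("xt", "ac", "gg", "hs"), ] == 1))
  ee <- expected_event_counts(sim$config)
  expect_equal(unname(ee["duplications"]), 3 * 0.25)  # fish stem length
})

test_that("chimeras carry their donor map by construction", {
  cfg <- sim_config(n_families = 2, seed = 5,
                    chimera = list(donor_a = 2, donor_b = 1,
                                   boundary = 120, species = "gg"))
  sim <- simulate_families(cfg)
  ch <- sim$truth$chimera
  expect_identical(ch$id, "gg_chimera_1")
  m <- msa_matrix(sim$msa)
  a <- m[paste0("gg_F2_1"), ]
  b <- m[paste0("gg_F1_1"), ]
  x <- m[ch$id, ]
  expect_identical(x[1:120], a[1:120])
  expect_identical(x[121:200], b[121:200])
})

test_that("p-distances grow with path length in the species tree", {
  sim <- simulate_families(sim_config(n_families = 1, seed = 12))
  dm <- msa_distances(sim$msa)
  ids <- paste0(c("dr", "xt", "ac", "gg", "hs"), "_F1_1")
  st <- default_species_tree()
  paths <- ape::cophenetic.phylo(st$phy)[c("dr", "xt", "ac", "gg", "hs"),
                                         c("dr", "xt", "ac", "gg", "hs")]
  p <- dm$p[ids, ids]
  expect_gt(cor(p[lower.tri(p)], paths[lower.tri(paths)],
                method = "spearman"), 0)
})

test_that("configs validate their study conditions", {
  expect_error(sim_config(sequence_length = 10, seed = 1), ">= 30")
  expect_error(sim_config(duplication_rate = -1, seed = 1), ">= 0")
  expect_error(sim_config(), "seed")
})
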