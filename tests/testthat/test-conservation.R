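test_that("conservation profiles count modal residues over the subset", {
  msa <- make_msa(c("AAG-", "AAG-", "AAGA", "ADGC"))
  prof <- conservation_profile(msa)
  expect_equal(prof$conservation[1], 1.0)
  expect_equal(prof$conservation[2], 0.75)   # A,A,A,B
  expect_identical(prof$modal_residue[2], "A")
  # gaps count against conservation but not depth
  expect_equal(prof$conservation[4], 0.25)
  expect_equal(prof$depth[4], 2)
  # all-gap column: undefined modal residue, zero conservation
  msa2 <- make_msa(c("A-", "C-"))
  prof2 <- conservation_profile(msa2)
  expect_true(is.na(prof2$modal_residue[2]))
  expect_equal(prof2$conservation[2], 0)
  expect_error(conservation_profile(msa, character(0)), "non-empty")
})

test_that("subsetting never increases column depth", {
  sim <- simulate_families(sim_config(seed = 77))
  full <- conservation_profile(sim$msa)
  sub <- conservation_profile(sim$msa, sim$msa$id[1:5])
  expect_true(all(sub$depth <= full$depth))
})

test_that("reference election, labeling, and the X.50 bijection hold", {
  # 7 segments of width 5; invariant column planted mid-segment
  withr::local_seed(9)
  n_col <- 35
  base <- strsplit(paste(rep("ACDEF", 7), collapse = ""), "")[[1]]
  rows <- replicate(6, {
    r <- base
    mut <- sample(n_col, 10)
    r[mut] <- sample(AA20, 10, replace = TRUE)
    paste(r, collapse = "")
  })
  msa <- make_msa(rows)
  segmap <- segment_map(paste0("TM", 1:7), seq(0, 30, 5), seq(5, 35, 5),
                        n_col)
  m <- msa_matrix(msa)
  planted <- seq(3, 33, by = 5)  # midpoint of each width-5 segment
  for (k in seq_along(planted)) m[, planted[k]] <- "W"
  msa <- make_msa(apply(m, 1, paste, collapse = ""))
  prof <- conservation_profile(msa)
  refmap <- assign_reference_positions(prof, segmap)
  expect_equal(refmap$references$column, planted)
  expect_identical(refmap$references$residue, rep("W", 7))
  # labeling is a bijection and references map to exactly h.50
  expect_identical(sort(refmap$labels$label[refmap$labels$column %in%
                                              planted]),
                   sort(sprintf("%d.50", 1:7)))
  expect_false(anyDuplicated(refmap$labels$label) > 0)
  expect_equal(nrow(refmap$labels), n_col)
})

test_that("generic labels offset from the reference (6.50 + 5 = 6.55)", {
  msa <- make_msa(rep(paste(rep("A", 80), collapse = ""), 4))
  m <- msa_matrix(msa)
  segmap <- segment_map(paste0("TM", 1:7),
                        c(0, 10, 20, 30, 40, 50, 70),
                        c(10, 20, 30, 40, 50, 70, 80), 80)
  # make column 52 (3rd of TM6, 0-based 51) the unique TM6 maximum
  for (h in 1:7) {
    cols <- adgrevo:::seg_columns(segmap, paste0("TM", h))
    m[1, cols] <- "C"  # degrade every column a little
  }
  m[, 52] <- "W"
  msa <- make_msa(apply(m, 1, paste, collapse = ""))
  refmap <- assign_reference_positions(conservation_profile(msa), segmap)
  expect_equal(refmap$references$column[6], 52)
  expect_identical(generic_label(refmap, 52), "6.50")
  expect_identical(generic_label(refmap, 57), "6.55")
  expect_identical(generic_label(refmap, 51), "6.49")
})

test_that("signature motifs report conserved windows ending at X.50", {
  # single helix equivalent: conservations 1, 0.9, 0.5, 0.9, 1 on G,A,P
  seqs <- c("GGAPG", "GGCPG", "GGAPG", "GGAPG", "GGTPG", "GACPG",
            "GGAPG", "GGAPG", "GGAPG", "GGAPG")
  msa <- make_msa(vapply(seqs, function(s)
    paste(rep(s, 7), collapse = ""), ""))
  segmap <- segment_map(paste0("TM", 1:7), seq(0, 30, 5), seq(5, 35, 5), 35)
  prof <- conservation_profile(msa)
  refmap <- assign_reference_positions(prof, segmap)
  mot <- signature_motifs(prof, segmap, refmap, cutoff = 0.8,
                          regions = "TM1")
  # reference is the fully conserved column nearest the midpoint (the P);
  # the window runs from the first conserved column through it
  expect_identical(mot$motif, "GGxP")
  full <- signature_motifs(prof, segmap, refmap, cutoff = 1.0,
                           regions = "TM1")
  expect_identical(full$motif, "GxxP")
})

test_that("conserved-position counting is strict and windowed to TMs", {
  msa <- make_msa(rep(paste(rep("A", 35), collapse = ""), 10))
  segmap <- segment_map(paste0("TM", 1:7), seq(0, 30, 5), seq(5, 35, 5), 35)
  prof <- conservation_profile(msa)
  expect_equal(count_conserved_positions(prof, segmap, 0.95), 35)
  m <- msa_matrix(msa)
  m[1, 1:33] <- "C"  # 33 columns drop to 0.9
  prof2 <- conservation_profile(make_msa(apply(m, 1, paste, collapse = "")))
  expect_equal(count_conserved_positions(prof2, segmap, 0.95), 2)
  expect_error(count_conserved_positions(prof, segmap, 1), "threshold")
})

test_that("planted invariant columns are recovered exactly at cutoff 1", {
  sim <- simulate_families(sim_config(seed = 202))
  segmap <- read_segment_map(
    system.file("extdata", "tm_segments_example.tsv", package = "adgrevo"),
    200)
  pl <- plant_conservation_features(
    sim$msa, segmap, motifs = c(TM3 = "LHxxxLxxFxW", TM4 = "GxGxP"))
  prof <- conservation_profile(pl$msa)
  refmap <- assign_reference_positions(prof, segmap)
  expect_equal(refmap$references$column, pl$truth$references$column)
  expect_identical(refmap$references$residue, pl$truth$references$residue)
  mot <- signature_motifs(prof, segmap, refmap, cutoff = 1.0,
                          regions = c("TM3", "TM4"))
  expect_identical(mot$motif, pl$truth$motifs$motif)
})
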