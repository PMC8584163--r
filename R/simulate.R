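# Gene-family simulator: birth-death duplication/loss on a vertebrate-like
# species tree, Poisson-uniform amino-acid evolution (or codon evolution
# with branch-specific omega), chimeric recombinants, and full ground
# truth for validating every pipeline stage.

#' Default vertebrate-like species tree
#'
#' A six-leaf tree (fish,(amphibian,(reptile,(bird,mammal)))) plus an
#' outgroup, with branch lengths in expected substitutions per site.
#' Species codes: dr (fish), xt (amphibian), ac (reptile), gg (bird),
#' hs (mammal), og (outgroup).
#'
#' @return list with `phy` (`ape::phylo`) and `clade_of_species`.
#' @export
default_species_tree <- function() {
  nwk <- "(og:0.40,(dr:0.25,(xt:0.18,(ac:0.12,(gg:0.08,hs:0.08):0.04):0.06):0.07):0.15);"
  list(phy = ape::read.tree(text = nwk),
       clade_of_species = c(dr = "fish", xt = "amphibian", ac = "reptile",
                            gg = "bird", hs = "mammal", og = "outgroup"))
}

#' Simulation configuration
#'
#' Defines the study conditions for a gene-family simulation: the species
#' tree, the number of families and their ancestral divergence, birth-death
#' duplication/loss rates, the substitution mode, branch-specific omega
#' (codon mode), and an optional chimera specification.
#'
#' @param n_families number of gene families (default 3).
#' @param sequence_length residues (amino-acid mode) or codons (codon
#'   mode); at least 30 (default 200).
#' @param inter_family_divergence expected substitutions per site between
#'   family ancestors (default 2.0, roughly five times the deepest
#'   within-family path of the default species tree).
#' @param duplication_rate,loss_rate birth-death rates in events per gene
#'   lineage per unit branch length (defaults 0).
#' @param duplication_branches optional branch labels (tip codes, e.g.
#'   `"dr"` for the fish stem) to which duplications are restricted;
#'   `NULL` applies the rate everywhere. Losses always apply everywhere.
#' @param mode `"aa"` (Poisson-uniform amino-acid substitution) or
#'   `"codon"` (nucleotide proposals with omega-dependent acceptance).
#' @param omega background dN/dS used on every branch in codon mode
#'   (default 0.2).
#' @param omega_map optional named numeric vector branch label -> omega
#'   overriding `omega` on specific branches.
#' @param chimera optional list(`donor_a`, `donor_b`, `boundary`,
#'   `species`): emit one extra sequence whose columns `1..boundary` come
#'   from a `donor_a`-family sequence of `species` and the rest from a
#'   `donor_b`-family sequence (boundary in residues or codons).
#' @param species_tree list as returned by [default_species_tree].
#' @param seed mandatory integer seed; fixed seeds give bit-identical
#'   output.
#' @return a `sim_config`.
#' @export
sim_config <- function(n_families = 3, sequence_length = 200,
                       inter_family_divergence = 2.0,
                       duplication_rate = 0, loss_rate = 0,
                       duplication_branches = NULL,
                       mode = c("aa", "codon"),
                       omega = 0.2, omega_map = NULL,
                       chimera = NULL, species_tree = NULL, seed) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (sequence_length < 30) stop("sequence_length must be >= 30")
  if (duplication_rate < 0 || loss_rate < 0) stop("rates must be >= 0")
  if (inter_family_divergence < 0) stop("divergence must be >= 0")
  if (is.null(species_tree)) species_tree <- default_species_tree()
  structure(list(n_families = n_families,
                 sequence_length = sequence_length,
                 inter_family_divergence = inter_family_divergence,
                 duplication_rate = duplication_rate,
                 loss_rate = loss_rate,
                 duplication_branches = duplication_branches,
                 mode = mode, omega = omega, omega_map = omega_map,
                 chimera = chimera, species_tree = species_tree,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# ---- substitution processes -------------------------------------------

# Poisson-uniform amino-acid substitution: Poisson(d * L) substitutions,
# each at a uniform site, to a uniform different residue
mutate_aa <- function(seq, d) {
  if (d <= 0) return(seq)
  m <- rpois(1, d * length(seq))
  if (m == 0) return(seq)
  pos <- sample.int(length(seq), m, replace = TRUE)
  for (p in pos) {
    seq[p] <- sample(setdiff(AA20, seq[p]), 1)
  }
  seq
}

# codon substitution with selective thinning: nucleotide proposals at rate
# d per nt site; proposals creating stops are rejected; synonymous and
# nonsynonymous proposals are accepted with probabilities in ratio 1:omega
mutate_codons <- function(seq, d, omega) {
  if (d <= 0) return(seq)
  gc <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  a_s <- min(1, 1 / omega)
  a_n <- min(1, omega)
  m <- rpois(1, d * 3 * length(seq))
  if (m == 0) return(seq)
  for (k in seq_len(m)) {
    ci <- sample.int(length(seq), 1)
    pos <- sample.int(3, 1)
    cur <- strsplit(seq[ci], "", fixed = TRUE)[[1]]
    alt <- sample(setdiff(nts, cur[pos]), 1)
    nxt <- cur; nxt[pos] <- alt
    nxt <- paste(nxt, collapse = "")
    if (gc[[nxt]] == "*") next
    syn <- gc[[nxt]] == gc[[seq[ci]]]
    if (runif(1) <= (if (syn) a_s else a_n)) seq[ci] <- nxt
  }
  seq
}

random_root_seq <- function(mode, len) {
  if (mode == "aa") sample(AA20, len, replace = TRUE)
  else {
    gc <- Biostrings::GENETIC_CODE
    sample(names(gc)[gc != "*"], len, replace = TRUE)
  }
}

# ---- birth-death gene evolution ---------------------------------------

# evolve one gene lineage along a branch of length b; duplications at rate
# lam, losses at rate mu; returns surviving sequences; events tallied in env
sim_branch <- function(seq, b, lam, mu, mutate, env) {
  rate <- lam + mu
  t <- if (rate > 0) rexp(1, rate) else Inf
  if (t >= b) return(list(mutate(seq, b)))
  seq <- mutate(seq, t)
  if (runif(1) < lam / rate) {
    env$duplications <- env$duplications + 1
    c(sim_branch(seq, b - t, lam, mu, mutate, env),
      sim_branch(seq, b - t, lam, mu, mutate, env))
  } else {
    env$losses <- env$losses + 1
    list()
  }
}

#' Simulate gene families on the species tree
#'
#' Gene trees are generated by a birth-death process within the species
#' tree; sequences evolve site-independently along the gene trees
#' (Poisson-uniform amino-acid substitution, or codon substitution with
#' branch-specific omega); the true alignment is emitted directly (no
#' indels, no realignment). One divergent outgroup sequence is emitted
#' for rooting. Fixed seeds give bit-identical output.
#'
#' @param config a [sim_config].
#' @return an `agpcr_simulation`: list with
#'   * `msa` -- a [labeled_msa] (amino acids; translated in codon mode),
#'   * `codon_aln` -- a [codon_alignment] (codon mode only),
#'   * `truth` -- list: `genes` (id, species, family, copy), `families`
#'     (family, n_genes, one_to_one, survived), `events` (family,
#'     duplications, losses), `ancestral_repertoire`, `outgroup_id`,
#'     `omega` (branch, omega; codon mode), `chimera` (donor map),
#'   * `config`.
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, sim_run(config))
}

sim_run <- function(config) {
  st <- config$species_tree
  clade_of_species <- st$clade_of_species
  og_tip <- names(clade_of_species)[clade_of_species == "outgroup"]
  phy <- st$phy
  if (length(og_tip)) phy <- ape::drop.tip(phy, og_tip)
  L <- config$sequence_length
  mode <- config$mode
  omega_of <- function(branch) {
    if (!is.null(config$omega_map) && branch %in% names(config$omega_map))
      unname(config$omega_map[branch]) else config$omega
  }
  mutate_for <- function(branch) {
    if (mode == "aa") function(seq, d) mutate_aa(seq, d)
    else {
      w <- omega_of(branch)
      function(seq, d) mutate_codons(seq, d, w)
    }
  }
  master <- random_root_seq(mode, L)
  neutral_mut <- if (mode == "aa") mutate_aa
    else function(seq, d) mutate_codons(seq, d, 1)
  half <- config$inter_family_divergence / 2
  genes <- list()   # per emitted gene: id, species, family, copy, seq
  events <- data.frame(family = integer(), duplications = integer(),
                       losses = integer())
  fam_survived <- logical(config$n_families)
  ntip <- length(phy$tip.label)
  root <- ntip + 1
  for (f in seq_len(config$n_families)) {
    anc <- neutral_mut(master, half)
    env <- new.env(); env$duplications <- 0L; env$losses <- 0L
    tip_genes <- list()  # species -> list of seqs, in arrival order
    walk <- function(node, pool) {
      kids <- phy$edge[phy$edge[, 1] == node, 2]
      for (ch in kids) {
        b <- phy$edge.length[which(phy$edge[, 1] == node &
                                     phy$edge[, 2] == ch)]
        branch <- if (ch <= ntip) phy$tip.label[ch] else
          paste0("node", ch)
        lam <- if (is.null(config$duplication_branches) ||
                   branch %in% config$duplication_branches)
          config$duplication_rate else 0
        out <- list()
        for (g in pool)
          out <- c(out, sim_branch(g, b, lam, config$loss_rate,
                                   mutate_for(branch), env))
        if (ch <= ntip) {
          sp <- phy$tip.label[ch]
          tip_genes[[sp]] <<- out
        } else {
          walk(ch, out)
        }
      }
    }
    walk(root, list(anc))
    for (sp in names(tip_genes)) {
      gs <- tip_genes[[sp]]
      for (k in seq_along(gs)) {
        genes[[length(genes) + 1]] <- list(
          id = sprintf("%s_F%d_%d", sp, f, k),
          species = sp, family = f, copy = k, seq = gs[[k]])
      }
    }
    fam_survived[f] <- length(tip_genes) > 0 && any(lengths(tip_genes) > 0)
    events <- rbind(events, data.frame(family = f,
                                       duplications = env$duplications,
                                       losses = env$losses))
  }
  # outgroup sequence for rooting, evolved independently from the master
  og_id <- NULL
  if (length(og_tip)) {
    og_seq <- neutral_mut(master, config$inter_family_divergence)
    og_id <- paste0(og_tip[1], "_out_1")
    genes[[length(genes) + 1]] <- list(id = og_id, species = og_tip[1],
                                       family = NA_integer_, copy = 1,
                                       seq = og_seq)
  }
  # chimera: TM1-5-like head from donor_a, TM6-7-like tail from donor_b
  chim <- NULL
  if (!is.null(config$chimera)) {
    cs <- config$chimera
    sp <- if (is.null(cs$species)) "hs" else cs$species
    pick <- function(fam) {
      hit <- vapply(genes, function(g)
        identical(g$species, sp) && isTRUE(g$family == fam), TRUE)
      if (!any(hit)) stop("chimera donor family ", fam,
                          " has no gene in species ", sp)
      genes[[which(hit)[1]]]$seq
    }
    a <- pick(cs$donor_a); b <- pick(cs$donor_b)
    stopifnot(cs$boundary >= 1, cs$boundary < L)
    cseq <- c(a[1:cs$boundary], b[(cs$boundary + 1):L])
    cid <- sprintf("%s_chimera_1", sp)
    genes[[length(genes) + 1]] <- list(id = cid, species = sp,
                                       family = NA_integer_, copy = 1,
                                       seq = cseq)
    chim <- data.frame(id = cid, donor_a = cs$donor_a,
                       donor_b = cs$donor_b, boundary = cs$boundary,
                       stringsAsFactors = FALSE)
  }
  ids <- vapply(genes, `[[`, "", "id")
  spv <- vapply(genes, `[[`, "", "species")
  seqs <- lapply(genes, `[[`, "seq")
  gene_df <- data.frame(id = ids, species = spv,
                        family = vapply(genes, function(g)
                          as.integer(g$family), 0L),
                        copy = vapply(genes, function(g)
                          as.integer(g$copy), 0L),
                        stringsAsFactors = FALSE)
  fam_df <- do.call(rbind, lapply(seq_len(config$n_families), function(f) {
    sub <- gene_df[!is.na(gene_df$family) & gene_df$family == f, ]
    cls <- clade_of_species[unique(sub$species)]
    data.frame(family = f, n_genes = nrow(sub),
               one_to_one = nrow(sub) > 0 &&
                 all(table(sub$species) == 1) &&
                 "fish" %in% cls && "mammal" %in% cls,
               survived = fam_survived[f])
  }))
  truth <- list(genes = gene_df, families = fam_df, events = events,
                ancestral_repertoire = sum(fam_survived),
                outgroup_id = og_id, chimera = chim)
  if (mode == "aa") {
    msa <- labeled_msa(ids, spv,
                       vapply(seqs, paste, "", collapse = ""),
                       clade_of_species)
    out <- list(msa = msa, truth = truth, config = config)
  } else {
    caln <- codon_alignment(ids, vapply(seqs, paste, "", collapse = ""))
    sp_of <- setNames(spv, ids)
    msa <- translate_codon_alignment(caln, sp_of, clade_of_species)
    branches <- phy$tip.label
    truth$omega <- data.frame(branch = branches,
                              omega = vapply(branches, omega_of, 0),
                              stringsAsFactors = FALSE)
    out <- list(msa = msa, codon_aln = caln, truth = truth,
                config = config)
  }
  class(out) <- "agpcr_simulation"
  out
}

#' @export
print.agpcr_simulation <- function(x, ...) {
  cat("agpcr_simulation:", nrow(x$truth$genes), "genes,",
      x$config$n_families, "families, mode", x$config$mode,
      ", seed", x$config$seed, "\n")
  invisible(x)
}

#' Expected duplication and loss counts per family
#'
#' First-order birth-death expectations: events per family are rate times
#' the total branch length over which the rate applies (duplications may
#' be restricted to specific branches).
#'
#' @param config a [sim_config].
#' @return named numeric vector `c(duplications=, losses=)` per family.
#' @export
expected_event_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  st <- config$species_tree
  og <- names(st$clade_of_species)[st$clade_of_species == "outgroup"]
  phy <- st$phy
  if (length(og)) phy <- ape::drop.tip(phy, og)
  ntip <- length(phy$tip.label)
  branch_names <- ifelse(phy$edge[, 2] <= ntip,
                         phy$tip.label[phy$edge[, 2]],
                         paste0("node", phy$edge[, 2]))
  L_all <- sum(phy$edge.length)
  L_dup <- if (is.null(config$duplication_branches)) L_all
    else sum(phy$edge.length[branch_names %in% config$duplication_branches])
  c(duplications = config$duplication_rate * L_dup,
    losses = config$loss_rate * L_all)
}

#' Plant reference positions and signature motifs into a simulated MSA
#'
#' Installs a by-construction ground truth for the numbering operations:
#' in each TM segment the column that the reference tie-break would elect
#' (nearest the segment midpoint) is made invariant with the given
#' residue; optional motif strings (ending at the reference, `x` = free
#' position) are likewise planted. Every other in-segment column is then
#' perturbed, if needed, so that no unplanted column reaches the cutoff --
#' making the planted signal the unique signal the extractor should
#' recover.
#'
#' @param msa a [labeled_msa].
#' @param segmap a [segment_map] with TM1..TM7.
#' @param references named character vector TM1..TM7 -> reference residue
#'   (defaults to the field-standard L, N, W, P, N, L, G).
#' @param motifs optional named character vector, e.g.
#'   `c(TM4 = "GxGxP")`; each motif ends at its helix reference.
#' @param cutoff conservation level the planted columns sit at (planted
#'   columns are fully conserved; unplanted ones are forced below this;
#'   default 1.0).
#' @return list with `msa` (modified alignment) and `truth` (data frames
#'   `references`: helix, column, residue; `motifs`: region, motif).
#' @export
plant_conservation_features <- function(msa, segmap,
                                        references = c(TM1 = "L", TM2 = "N",
                                                       TM3 = "W", TM4 = "P",
                                                       TM5 = "N", TM6 = "L",
                                                       TM7 = "G"),
                                        motifs = NULL, cutoff = 1.0) {
  require_seven_tm(segmap)
  m <- msa_matrix(msa)
  n <- nrow(m)
  planted <- integer()
  refs <- data.frame(helix = integer(), column = integer(),
                     residue = character(), stringsAsFactors = FALSE)
  mot_truth <- data.frame(region = character(), motif = character(),
                          stringsAsFactors = FALSE)
  for (h in 1:7) {
    tm <- paste0("TM", h)
    cols <- seg_columns(segmap, tm)
    mid <- (min(cols) + max(cols)) / 2
    ref <- cols[order(abs(cols - mid), cols)][1]
    res <- references[[tm]]
    m[, ref] <- res
    planted <- c(planted, ref)
    refs <- rbind(refs, data.frame(helix = h, column = ref, residue = res,
                                   stringsAsFactors = FALSE))
    if (!is.null(motifs) && tm %in% names(motifs)) {
      chars <- strsplit(motifs[[tm]], "", fixed = TRUE)[[1]]
      span <- (ref - length(chars) + 1):ref
      if (min(span) < min(cols))
        stop("motif for ", tm, " longer than the span up to the reference")
      for (k in seq_along(chars)) {
        if (chars[k] == "x") next
        m[, span[k]] <- chars[k]
        planted <- c(planted, span[k])
      }
      mot_truth <- rbind(mot_truth, data.frame(region = tm,
                                               motif = motifs[[tm]],
                                               stringsAsFactors = FALSE))
    }
  }
  # force every unplanted TM column below the cutoff
  limit <- ceiling(n * cutoff) - 1
  all_tm <- unlist(lapply(tm_names, seg_columns, segmap = segmap))
  for (cc in setdiff(all_tm, planted)) {
    repeat {
      tab <- sort(table(m[, cc]), decreasing = TRUE)
      if (tab[1] <= limit) break
      modal <- names(tab)[1]
      rows <- which(m[, cc] == modal)
      excess <- length(rows) - limit
      repl <- setdiff(AA20, modal)
      m[rows[seq_len(excess)], cc] <-
        repl[((seq_len(excess) - 1) %% length(repl)) + 1]
    }
  }
  out <- labeled_msa(msa$id, msa$species_code,
                     apply(m, 1, paste, collapse = ""),
                     msa$clade_of_species)
  list(msa = out, truth = list(references = refs, motifs = mot_truth))
}
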