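# Shared builders and independent oracles for the test suite.

toy_clades <- c(dr = "fish", xt = "amphibian", ac = "reptile",
                gg = "bird", hs = "mammal", og = "outgroup")

# quick alignment from raw sequences; species cycle through the ingroup
make_msa <- function(seqs, species = NULL, ids = NULL) {
  n <- length(seqs)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  if (is.null(species))
    species <- rep(c("dr", "xt", "ac", "gg", "hs"), length.out = n)
  labeled_msa(ids, species, seqs, toy_clades)
}

# alignment whose every column is consistent with one 6-taxon tree:
# ((((t1,t2),t3),t4),(t5,t6)); `reps` columns per internal split,
# `private` per tip, plus invariant padding
consistent_msa <- function(reps = 12, private = 1, pad = 150) {
  taxa <- paste0("t", 1:6)
  splits <- list(c("t1", "t2"), c("t1", "t2", "t3"),
                 c("t1", "t2", "t3", "t4"))
  cols <- list()
  for (s in splits) for (r in seq_len(reps))
    cols[[length(cols) + 1]] <- ifelse(taxa %in% s, "K", "E")
  for (t in taxa) for (r in seq_len(private))
    cols[[length(cols) + 1]] <- ifelse(taxa == t, "W", "G")
  for (r in seq_len(pad)) cols[[length(cols) + 1]] <- rep("A", 6)
  m <- do.call(cbind, cols)
  labeled_msa(taxa, rep(c("dr", "xt", "ac", "gg", "hs", "dr"),
                        length.out = 6),
              apply(m, 1, paste, collapse = ""), toy_clades)
}

# random unrooted binary tree with branch lengths; returns phy + distances
random_additive <- function(n) {
  phy <- ape::unroot(ape::rtree(n, br = NULL))
  phy$edge.length <- runif(nrow(phy$edge), 0.1, 1)
  list(phy = phy, d = ape::cophenetic.phylo(phy))
}

bip_set <- function(phy) sort(tree_bipartitions(phy))

# --- independent least-squares topology oracle (exhaustive enumeration) ---

# pairs x edges path-indicator matrix for a topology
path_design <- function(phy, labs) {
  ne <- nrow(phy$edge)
  cols <- lapply(seq_len(ne), function(e) {
    p2 <- phy
    p2$edge.length <- rep(0, ne)
    p2$edge.length[e] <- 1
    co <- ape::cophenetic.phylo(p2)[labs, labs]
    co[lower.tri(co)]
  })
  do.call(cbind, cols)
}

# best-fitting topology over all unrooted topologies, by least squares
ls_best_topology <- function(d) {
  labs <- rownames(d)
  tops <- phangorn::allTrees(length(labs), rooted = FALSE,
                             tip.label = labs)
  dv <- d[labs, labs][lower.tri(d)]
  rss <- vapply(tops, function(tp) {
    A <- path_design(tp, labs)
    fit <- qr(A)
    sum((A %*% qr.coef(fit, dv) - dv)^2)
  }, 0)
  tops[[which.min(rss)]]
}

# --- independent brute-force NG86 oracle for one codon pair -------------

oracle_codon_pair <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  if (!length(pos)) return(c(s = 0, n = 0))
  perm_list <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perm_list(v[-i]), function(p) c(v[i], p))))
  }
  walk <- function(ord, allow_stop) {
    cur <- a; s <- 0; n <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      if (gc[[paste(nxt, collapse = "")]] == "*" && !allow_stop)
        return(NULL)
      same <- gc[[paste(cur, collapse = "")]] ==
        gc[[paste(nxt, collapse = "")]]
      if (same && gc[[paste(nxt, collapse = "")]] != "*") s <- s + 1
      else n <- n + 1
      cur <- nxt
    }
    c(s = s, n = n)
  }
  res <- Filter(Negate(is.null),
                lapply(perm_list(pos), walk, allow_stop = FALSE))
  if (!length(res))
    res <- lapply(perm_list(pos), walk, allow_stop = TRUE)
  Reduce(`+`, res) / length(res)
}

# --- leaf-level grouping accuracy against simulation truth --------------

group_accuracy <- function(pred_groups, truth_genes) {
  ids <- truth_genes$id[!is.na(truth_genes$family)]
  tf <- setNames(truth_genes$family, truth_genes$id)
  tab <- table(true = tf[ids],
               pred = factor(pred_groups[ids], exclude = NULL))
  ok <- 0; used <- character()
  for (f in rownames(tab)[order(-apply(tab, 1, max))]) {
    cands <- setdiff(colnames(tab)[order(-tab[f, ])], used)
    if (length(cands)) {
      ok <- ok + tab[f, cands[1]]
      used <- c(used, cands[1])
    }
  }
  ok / length(ids)
}
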