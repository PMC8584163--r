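# Distance computation, neighbor joining, bootstrap bipartition support,
# outgroup rooting, and TM-fragment phylogenies.

# ---- distances ---------------------------------------------------------

# integer-encode an alignment matrix: 1..20 for amino acids, NA for gap/X
encode_aa <- function(m) {
  e <- match(m, AA20)
  dim(e) <- dim(m)
  rownames(e) <- rownames(m)
  e
}

#' Proportion of differing sites between two aligned sequences
#'
#' Sites where either sequence has a gap or an ambiguous residue (`X`) are
#' excluded. With `deletion = "pairwise"` the comparable-site set is chosen
#' per pair (the default); `"complete"` is meaningful only for whole-matrix
#' computation ([msa_distances]) and is treated identically here.
#'
#' @param seq_a,seq_b gapped amino-acid strings of equal length.
#' @param deletion `"pairwise"` or `"complete"`.
#' @return list with elements `p` (mismatch proportion) and
#'   `compared_sites`.
#' @export
p_distance <- function(seq_a, seq_b, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("sequences differ in gapped length")
  ia <- match(a, AA20); ib <- match(b, AA20)
  ok <- !is.na(ia) & !is.na(ib)
  n <- sum(ok)
  if (n == 0) stop("zero comparable sites: pair is uncomputable")
  list(p = sum(ia[ok] != ib[ok]) / n, compared_sites = n)
}

#' Poisson-corrected amino-acid distance
#'
#' Converts a mismatch proportion into expected substitutions per site
#' under the Poisson correction, d = -ln(1 - p).
#'
#' @param p mismatch proportion(s) in `[0, 1)`.
#' @return corrected distance(s), nonnegative and monotone in `p`.
#' @export
poisson_correct <- function(p) {
  if (any(p < 0)) stop("p must be nonnegative")
  if (any(p >= 1)) stop("saturated distance: p >= 1 cannot be corrected")
  -log(1 - p)
}

# internal: p / d / compared-site matrices from an encoded alignment
dist_from_encoded <- function(e, labels, clamp = FALSE) {
  valid <- !is.na(e)
  storage.mode(valid) <- "double"
  cs <- tcrossprod(valid)
  eq <- matrix(0, nrow(e), nrow(e))
  for (l in seq_along(AA20)) {
    a <- (e == l) & valid
    storage.mode(a) <- "double"
    a[is.na(a)] <- 0
    eq <- eq + tcrossprod(a)
  }
  p <- 1 - eq / cs
  diag(p) <- 0
  off <- upper.tri(cs)
  if (any(cs[off] < 1)) {
    if (!clamp) {
      ij <- which(cs < 1 & upper.tri(cs), arr.ind = TRUE)[1, ]
      stop("zero comparable sites between '", labels[ij[1]], "' and '",
           labels[ij[2]], "'")
    }
    p[cs < 1] <- NA
  }
  if (clamp) {
    # bootstrap replicates may saturate by resampling; cap just below 1
    cap <- 1 - 1 / (2 * pmax(cs, 1))
    p <- pmin(p, cap)
    p[is.na(p)] <- max(p, na.rm = TRUE)
  } else if (any(p[off] >= 1)) {
    ij <- which(p >= 1 & upper.tri(p), arr.ind = TRUE)[1, ]
    stop("saturated distance (p = 1) between '", labels[ij[1]], "' and '",
         labels[ij[2]], "'")
  }
  d <- -log(1 - p)
  diag(d) <- 0
  dimnames(d) <- dimnames(p) <- dimnames(cs) <- list(labels, labels)
  structure(list(labels = labels, d = d, p = p, compared_sites = cs),
            class = "aa_dist")
}

#' Pairwise Poisson-corrected distance matrix of an alignment
#'
#' Computes, for every sequence pair, the mismatch proportion over
#' comparable sites and its Poisson correction. With
#' `deletion = "pairwise"` each pair uses its own comparable-site set; with
#' `"complete"` only columns without gaps or ambiguities in any sequence
#' are used for all pairs.
#'
#' @param msa a [labeled_msa].
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @param saturation `"error"` aborts when a pair differs at every
#'   comparable site (p = 1, Poisson-uncorrectable); `"cap"` caps p at the
#'   resolution limit `1 - 1/(2m)` for `m` compared sites, which short
#'   sub-alignments of deeply diverged sequences routinely need.
#' @return an object of class `aa_dist`: fields `labels`, `d` (corrected),
#'   `p` (raw proportions), `compared_sites`.
#' @export
msa_distances <- function(msa, deletion = c("pairwise", "complete"),
                          saturation = c("error", "cap")) {
  deletion <- match.arg(deletion)
  saturation <- match.arg(saturation)
  e <- encode_aa(msa_matrix(msa))
  if (deletion == "complete") {
    keep <- colSums(is.na(e)) == 0
    if (!any(keep)) stop("complete deletion leaves zero columns")
    e <- e[, keep, drop = FALSE]
  }
  dist_from_encoded(e, msa$id, clamp = saturation == "cap")
}

# ---- neighbor joining --------------------------------------------------

quote_label <- function(x) {
  bad <- !grepl("^[A-Za-z0-9_.|-]+$", x)
  if (any(grepl("'", x[bad], fixed = TRUE)))
    stop("labels may not contain single quotes")
  x[bad] <- paste0("'", x[bad], "'")
  x
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei neighbor joining. On an additive (tree-metric)
#' input the generating unrooted topology and branch lengths are recovered
#' exactly. Negative branch-length estimates are clamped to zero. When two
#' or more pairs tie on the Q criterion the lexicographically smallest
#' label pair is joined, making the result independent of input order.
#'
#' @param dm an `aa_dist` (from [msa_distances]) or a symmetric numeric
#'   matrix with row names.
#' @return a `supported_tree` whose `support` slot is empty (see
#'   [bootstrap_support]).
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "aa_dist")) {
    d <- dm$d; labels <- dm$labels
  } else if (is.matrix(dm)) {
    d <- unname(dm); labels <- rownames(dm)
    if (is.null(labels)) stop("distance matrix needs row names")
  } else stop("dm must be an aa_dist or a labelled matrix")
  if (any(!is.finite(d))) stop("non-finite distances")
  n <- length(labels)
  if (n < 3) stop("neighbor joining needs at least 3 labels")
  node <- quote_label(labels)  # newick fragment per active cluster
  repr <- labels               # smallest member label, for tie-breaking
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  while (n > 3) {
    rs <- rowSums(d)
    q <- (n - 2) * d - outer(rs, rs, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-9 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1, function(ij)
      paste(sort(c(repr[ij[1]], repr[ij[2]])), collapse = "\r"))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    newd <- (d[i, ] + d[j, ] - d[i, j]) / 2
    new_node <- sprintf("(%s:%s,%s:%s)", node[i], fmt(li), node[j], fmt(lj))
    new_repr <- min(repr[i], repr[j])
    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    node <- c(node[keep], new_node)
    repr <- c(repr[keep], new_repr)
    n <- n - 1L
  }
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- d[1, 2] - l1
  l3 <- d[1, 3] - l1
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 node[1], fmt(l1), node[2], fmt(l2), node[3], fmt(l3))
  phy <- ape::read.tree(text = nwk)
  supported_tree(phy)
}

# ---- supported trees ---------------------------------------------------

#' Construct a supported_tree
#'
#' Couples an `ape::phylo` tree with per-bipartition bootstrap support
#' (percentages in `[0, 100]`, keyed by canonical leaf set) and an optional
#' outgroup used for rooting.
#'
#' @param phy an `ape::phylo`.
#' @param support named numeric vector of bipartition supports, or `NULL`.
#' @param outgroup character vector of outgroup tip labels, or `NULL`.
#' @return object of class `supported_tree`.
#' @export
supported_tree <- function(phy, support = NULL, outgroup = NULL) {
  stopifnot(inherits(phy, "phylo"))
  structure(list(phy = phy, support = support, outgroup = outgroup),
            class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  cat("supported_tree:", length(x$phy$tip.label), "tips,",
      if (is.null(x$support)) "no bootstrap supports"
      else paste0(length(x$support), " supported bipartitions"),
      if (!is.null(x$outgroup))
        paste0("; rooted on {", paste(x$outgroup, collapse = ","), "}")
      else "", "\n")
  invisible(x)
}

# canonical key of a bipartition: the side not containing the reference
# (alphabetically first) tip, sorted and tab-joined
bip_key <- function(side, tips) {
  if (sort(tips)[1] %in% side) side <- setdiff(tips, side)
  paste(sort(side), collapse = "\t")
}

# clades (tip-label sets) of every internal node, in node-number order;
# element 1 is the root clade (all tips)
node_clades <- function(phy) {
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  lapply(pp, function(ix) labs[ix])
}

#' Non-trivial bipartitions of a tree
#'
#' @param phy an `ape::phylo`.
#' @return character vector of canonical bipartition keys (internal edges
#'   only), suitable for support counting.
#' @export
tree_bipartitions <- function(phy) {
  tips <- phy$tip.label
  n <- length(tips)
  keys <- vapply(node_clades(phy), function(s) {
    if (sort(tips)[1] %in% s) s <- setdiff(tips, s)
    if (length(s) < 2 || length(s) > n - 2) return(NA_character_)
    paste(sort(s), collapse = "\t")
  }, "")
  unique(keys[!is.na(keys)])
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the reference tree on the full alignment, then resamples
#' alignment columns with replacement `n_replicates` times, rebuilds a tree
#' from each resample, and reports for every internal edge the percentage
#' of replicate trees containing the same bipartition (compared as leaf
#' sets; branch lengths are ignored). Saturated or uncomputable pairs
#' within a replicate are capped rather than aborting the replicate.
#'
#' @param msa a [labeled_msa] with at least 2 columns.
#' @param n_replicates number of bootstrap replicates (default 1000).
#' @param seed optional integer fixing the column-resampling stream; the
#'   same seed reproduces supports exactly.
#' @param deletion passed to [msa_distances].
#' @param tree_builder function mapping an `aa_dist` to a
#'   `supported_tree`; defaults to [neighbor_joining].
#' @param saturation how the reference-tree distances treat saturated
#'   pairs (see [msa_distances]); replicates always cap.
#' @return a `supported_tree` with a filled `support` slot.
#' @export
bootstrap_support <- function(msa, n_replicates = 1000, seed = NULL,
                              deletion = c("pairwise", "complete"),
                              tree_builder = neighbor_joining,
                              saturation = c("error", "cap")) {
  deletion <- match.arg(deletion)
  saturation <- match.arg(saturation)
  if (msa$alignment_length < 2) stop("alignment has fewer than 2 columns")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  e <- encode_aa(msa_matrix(msa))
  if (deletion == "complete") {
    keep <- colSums(is.na(e)) == 0
    if (!any(keep)) stop("complete deletion leaves zero columns")
    e <- e[, keep, drop = FALSE]
  }
  ref <- tree_builder(dist_from_encoded(e, msa$id,
                                        clamp = saturation == "cap"))
  ref_keys <- tree_bipartitions(ref$phy)
  ncol_e <- ncol(e)
  run <- function() {
    counts <- setNames(numeric(length(ref_keys)), ref_keys)
    for (r in seq_len(n_replicates)) {
      cols <- sample.int(ncol_e, ncol_e, replace = TRUE)
      bt <- tree_builder(dist_from_encoded(e[, cols, drop = FALSE],
                                           msa$id, clamp = TRUE))
      hit <- ref_keys %in% tree_bipartitions(bt$phy)
      counts[hit] <- counts[hit] + 1
    }
    counts
  }
  counts <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  ref$support <- 100 * counts / n_replicates
  ref
}

#' Root a tree on an outgroup
#'
#' The outgroup must be monophyletic in the unrooted tree; the rooted tree
#' places it as sister to all remaining taxa. Bipartition supports are
#' keyed by leaf sets and are unchanged by rooting.
#'
#' @param stree a `supported_tree`.
#' @param outgroup_ids tip labels of the outgroup.
#' @return the rooted `supported_tree`.
#' @export
root_with_outgroup <- function(stree, outgroup_ids) {
  phy <- stree$phy
  tips <- phy$tip.label
  miss <- setdiff(outgroup_ids, tips)
  if (length(miss)) stop("outgroup tip(s) not in tree: ",
                         paste(miss, collapse = ", "))
  if (length(outgroup_ids) > 1 &&
      length(outgroup_ids) < length(tips) - 1) {
    key <- bip_key(outgroup_ids, tips)
    if (!key %in% tree_bipartitions(phy)) {
      cl <- node_clades(phy)
      conflict <- Filter(function(s) {
        length(intersect(s, outgroup_ids)) > 0 &&
          length(setdiff(s, outgroup_ids)) > 0 &&
          !all(outgroup_ids %in% s)
      }, cl)
      msg <- if (length(conflict))
        paste0("; conflicting bipartition {",
               paste(conflict[[1]], collapse = ","), "}") else ""
      stop("outgroup is not monophyletic", msg)
    }
  }
  rooted <- ape::root(phy, outgroup = outgroup_ids, resolve.root = TRUE)
  supported_tree(rooted, support = stree$support, outgroup = outgroup_ids)
}

#' Write a supported tree as newick with supports as node labels
#'
#' @param stree a `supported_tree`.
#' @param path output file; if `NULL` the newick string is returned.
#' @return the newick string, invisibly when written to file.
#' @export
write_supported_tree <- function(stree, path = NULL) {
  phy <- stree$phy
  if (!is.null(stree$support)) {
    tips <- phy$tip.label
    cl <- node_clades(phy)
    labs <- vapply(cl, function(s) {
      key <- bip_key(s, tips)
      if (key %in% names(stree$support))
        sprintf("%g", unname(stree$support[key])) else ""
    }, "")
    phy$node.label <- labs
  }
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# ---- fragment trees ----------------------------------------------------

#' Default TM fragment grouping (TM1-2, TM3-5, TM6-7)
#' @export
default_fragments <- function() {
  list(`TM1-2` = c("TM1", "TM2"),
       `TM3-5` = c("TM3", "TM4", "TM5"),
       `TM6-7` = c("TM6", "TM7"))
}

# smallest clade strictly containing all query tips; majority family of the
# extra members is the sister group
sister_group <- function(stree, query_ids, family_of) {
  phy <- stree$phy
  tips <- phy$tip.label
  if (!all(query_ids %in% tips)) stop("query ids not all in tree")
  anchor <- setdiff(tips, query_ids)
  anchor <- anchor[1]
  rphy <- ape::root(phy, outgroup = anchor, resolve.root = TRUE)
  cl <- node_clades(rphy)
  cands <- Filter(function(s) all(query_ids %in% s) &&
                    length(s) > length(query_ids), cl)
  # also consider complements (the query may sit astride the root)
  comps <- lapply(cl, function(s) setdiff(tips, s))
  cands <- c(cands, Filter(function(s) all(query_ids %in% s) &&
                             length(s) > length(query_ids), comps))
  if (!length(cands)) return(NA_character_)
  best <- cands[[which.min(lengths(cands))]]
  extra <- setdiff(best, query_ids)
  fams <- family_of[extra]
  fams <- fams[!is.na(fams)]
  if (!length(fams)) return(NA_character_)
  names(sort(table(fams), decreasing = TRUE))[1]
}

#' Phylogenies of 7TM fragments with a sister-group report
#'
#' Builds one bootstrap-supported tree per fragment of the 7TM domain
#' (default TM1-2, TM3-5, TM6-7) and, when a query set is given, reports
#' for each fragment which family forms the closest neighbouring cluster
#' of the query. Chimeric sequences assembled from two donor families are
#' expected to switch sister groups between fragments.
#'
#' @param msa a [labeled_msa].
#' @param segmap a [segment_map] containing the grouped segment names.
#' @param groups named list of segment-name vectors (default
#'   [default_fragments]).
#' @param n_replicates,seed,deletion passed to [bootstrap_support]; each
#'   fragment uses an independent deterministic sub-seed derived from
#'   `seed`.
#' @param query_ids optional tip ids whose sister family is reported.
#' @param family_of optional named character vector id -> family label used
#'   for the sister report.
#' @return list with `trees` (named list of `supported_tree`) and `sister`
#'   (data frame: fragment, sister_family) when a query was given.
#' @export
fragment_trees <- function(msa, segmap, groups = default_fragments(),
                           n_replicates = 100, seed = NULL,
                           deletion = "pairwise",
                           query_ids = NULL, family_of = NULL) {
  trees <- list()
  sister <- data.frame(fragment = character(), sister_family = character(),
                       stringsAsFactors = FALSE)
  for (g in seq_along(groups)) {
    cols <- unlist(lapply(groups[[g]], seg_columns, segmap = segmap))
    if (!length(cols)) stop("fragment '", names(groups)[g],
                            "' has zero columns")
    sub <- msa_subset(msa, columns = cols)
    sd <- if (is.null(seed)) NULL else seed + g
    trees[[names(groups)[g]]] <-
      bootstrap_support(sub, n_replicates = n_replicates, seed = sd,
                        deletion = deletion, saturation = "cap")
    if (!is.null(query_ids) && !is.null(family_of)) {
      sister <- rbind(sister, data.frame(
        fragment = names(groups)[g],
        sister_family = sister_group(trees[[g]], query_ids, family_of),
        stringsAsFactors = FALSE))
    }
  }
  out <- list(trees = trees)
  if (nrow(sister)) out$sister <- sister
  out
}
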