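# Codon-level selection screen: Nei-Gojobori (NG86) site and difference
# counting with Jukes-Cantor correction, the omega classification rule,
# and a per-branch screen against sister-group consensus sequences.

.codon_cache <- new.env(parent = emptyenv())

all_orders <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_orders(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# Precomputed NG86 tables over the 61 sense codons:
#  - s_sites: synonymous site count per codon (changes to stop codons count
#    as nonsynonymous, so every codon contributes exactly 3 sites)
#  - nd/sd: pathway-averaged nonsynonymous/synonymous differences per codon
#    pair; pathways passing through a stop codon are excluded (when every
#    pathway is blocked, all pathways are used with stop steps counted as
#    nonsynonymous)
codon_tables <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  nts <- c("A", "C", "G", "T")
  chars <- strsplit(codons, "", fixed = TRUE)
  s_sites <- vapply(seq_along(codons), function(i) {
    s <- 0
    for (pos in 1:3) for (alt in setdiff(nts, chars[[i]][pos])) {
      mut <- chars[[i]]; mut[pos] <- alt
      mut <- paste(mut, collapse = "")
      if (gc[[mut]] != "*" && gc[[mut]] == gc[[codons[i]]]) s <- s + 1 / 3
    }
    s
  }, 0)
  nc <- length(codons)
  sd <- matrix(0, nc, nc, dimnames = list(codons, codons))
  nd <- matrix(0, nc, nc, dimnames = list(codons, codons))
  path_steps <- function(c1, c2, allow_stop) {
    pos <- which(c1 != c2)
    res <- c(s = 0, n = 0); nvalid <- 0
    for (ord in all_orders(pos)) {
      cur <- c1; s <- 0; n <- 0; valid <- TRUE
      for (p in ord) {
        nxt <- cur; nxt[p] <- c2[p]
        aa1 <- gc[[paste(cur, collapse = "")]]
        aa2 <- gc[[paste(nxt, collapse = "")]]
        if (aa2 == "*" && !allow_stop) { valid <- FALSE; break }
        if (aa1 == aa2 && aa1 != "*") s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      if (valid) { res <- res + c(s = s, n = n); nvalid <- nvalid + 1 }
    }
    if (nvalid == 0) return(NULL)
    res / nvalid
  }
  for (i in seq_len(nc - 1)) for (j in (i + 1):nc) {
    if (!any(chars[[i]] != chars[[j]])) next
    st <- path_steps(chars[[i]], chars[[j]], allow_stop = FALSE)
    if (is.null(st)) st <- path_steps(chars[[i]], chars[[j]],
                                      allow_stop = TRUE)
    sd[i, j] <- sd[j, i] <- st["s"]
    nd[i, j] <- nd[j, i] <- st["n"]
  }
  .codon_cache$tab <- list(codons = codons, s_sites = s_sites,
                           sd = sd, nd = nd)
  .codon_cache$tab
}

split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0) stop("sequence length not a multiple of 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

jc_correct <- function(p) {
  if (is.nan(p)) return(NA_real_)
  if (p >= 0.75) return(Inf)
  0.75 * -log(1 - 4 * p / 3)
}

#' Classify selective pressure from an omega value
#'
#' dN/dS below 1 is read as purifying (negative) selection; at or above 1
#' as positive selection; an undefined omega yields an undefined call.
#'
#' @param omega dN/dS ratio (nonnegative) or `NA`.
#' @return `"purifying"`, `"positive"`, or `"undefined"`.
#' @export
classify_selection <- function(omega) {
  if (is.na(omega)) return("undefined")
  if (omega < 0) stop("omega must be nonnegative")
  if (omega >= 1) "positive" else "purifying"
}

#' Pairwise dN/dS by Nei-Gojobori counting
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per sequence (each
#' codon position contributes its fraction of synonymous one-step changes;
#' substitutions creating stop codons count as nonsynonymous, so
#' N + S = 3 x compared codons exactly) and averages the two sequences'
#' site counts. Observed differences in multi-difference codons are
#' averaged over all substitution pathways, excluding pathways that pass
#' through a stop codon. Proportions are Jukes-Cantor corrected; a
#' proportion at or above 3/4 saturates (the corrected rate is infinite),
#' which drives omega to 0 when only dS saturates and leaves it undefined
#' when dN does.
#'
#' Codons are compared only where both sequences carry an ungapped,
#' unambiguous sense codon.
#'
#' @param seq_a,seq_b in-frame gapped codon sequences of equal length.
#' @param id_a,id_b labels used in the output (optional).
#' @return a `selection_estimate`: list with `pair`, `codons`, `N`, `S`,
#'   `Nd`, `Sd`, `pN`, `pS`, `dN`, `dS`, `omega`, `call`, `saturated`.
#' @export
ng86_dnds <- function(seq_a, seq_b, id_a = "a", id_b = "b") {
  tab <- codon_tables()
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  if (length(ca) != length(cb)) stop("codon sequences differ in length")
  ia <- match(ca, tab$codons)
  ib <- match(cb, tab$codons)
  ok <- !is.na(ia) & !is.na(ib)
  if (!any(ok)) stop("zero comparable codons")
  ia <- ia[ok]; ib <- ib[ok]
  ncod <- length(ia)
  S <- (sum(tab$s_sites[ia]) + sum(tab$s_sites[ib])) / 2
  N <- 3 * ncod - S
  Sd <- sum(tab$sd[cbind(ia, ib)])
  Nd <- sum(tab$nd[cbind(ia, ib)])
  pS <- if (S > 0) Sd / S else NaN
  pN <- if (N > 0) Nd / N else NaN
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  saturated <- isTRUE(is.infinite(dS)) || isTRUE(is.infinite(dN))
  omega <- if (Nd + Sd == 0 || is.na(dS) || dS == 0) {
    NA_real_
  } else if (is.infinite(dS)) {
    if (is.infinite(dN)) NA_real_ else 0
  } else if (is.infinite(dN)) {
    NA_real_
  } else dN / dS
  structure(list(pair = c(id_a, id_b), codons = ncod,
                 N = N, S = S, Nd = Nd, Sd = Sd,
                 pN = pN, pS = pS, dN = dN, dS = dS,
                 omega = omega, call = classify_selection(omega),
                 saturated = saturated),
            class = "selection_estimate")
}

#' @export
print.selection_estimate <- function(x, ...) {
  cat(sprintf(
    "selection_estimate %s vs %s: %d codons, N=%.2f S=%.2f Nd=%.2f Sd=%.2f dN=%.4f dS=%.4f omega=%s (%s)\n",
    x$pair[1], x$pair[2], x$codons, x$N, x$S, x$Nd, x$Sd,
    x$dN, x$dS, ifelse(is.na(x$omega), "NA", sprintf("%.3f", x$omega)),
    x$call))
  invisible(x)
}

#' Construct an in-frame codon alignment
#'
#' @param id character vector of unique ids.
#' @param seq character vector of equal-length gapped nucleotide
#'   sequences; length divisible by 3, gaps in whole-codon units
#'   (`"---"`), no stop codons.
#' @return a `codon_alignment`: list with `id`, `seq`, `n_codons`.
#' @export
codon_alignment <- function(id, seq) {
  id <- as.character(id); seq <- toupper(as.character(seq))
  if (anyDuplicated(id)) stop("duplicated ids")
  lens <- unique(nchar(seq))
  if (length(lens) > 1) stop("ragged codon alignment")
  if (lens %% 3 != 0) stop("alignment length not a multiple of 3")
  gc <- Biostrings::GENETIC_CODE
  stops <- names(gc)[gc == "*"]
  for (i in seq_along(seq)) {
    cods <- split_codons(seq[i])
    partial <- grepl("-", cods, fixed = TRUE) & cods != "---"
    if (any(partial))
      stop("gaps not in whole-codon units in record '", id[i], "'")
    if (any(cods %in% stops))
      stop("stop codon in record '", id[i], "'")
  }
  structure(list(id = id, seq = seq, n_codons = lens / 3),
            class = "codon_alignment")
}

#' Read an in-frame codon FASTA
#'
#' @param path nucleotide FASTA of aligned in-frame coding sequences.
#' @return a [codon_alignment].
#' @export
read_codon_alignment <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  codon_alignment(sub("\\s.*$", "", names(xs)), as.character(xs))
}

#' Translate a codon alignment to a labeled amino-acid alignment
#'
#' @param caln a [codon_alignment].
#' @param species_of named character vector id -> species code.
#' @param clade_of_species named character vector species code -> clade.
#' @return a [labeled_msa]; gap codons become `-`, ambiguous codons `X`.
#' @export
translate_codon_alignment <- function(caln, species_of, clade_of_species) {
  gc <- Biostrings::GENETIC_CODE
  aa <- vapply(caln$seq, function(s) {
    cods <- split_codons(s)
    out <- ifelse(cods == "---", "-",
                  ifelse(cods %in% names(gc), unname(gc[cods]), "X"))
    paste(out, collapse = "")
  }, "", USE.NAMES = FALSE)
  labeled_msa(caln$id, unname(species_of[caln$id]), aa, clade_of_species)
}

# plurality codon per column over a set of sequences; ties resolved by the
# earliest sequence (in alignment input order) carrying a tied codon
consensus_codons <- function(caln, ids) {
  rows <- match(ids, caln$id)
  rows <- sort(rows)  # input order of the alignment
  mats <- lapply(caln$seq[rows], split_codons)
  m <- do.call(rbind, mats)
  vapply(seq_len(ncol(m)), function(j) {
    tb <- table(m[, j])
    tied <- names(tb)[tb == max(tb)]
    if (length(tied) == 1) return(tied)
    m[which(m[, j] %in% tied)[1], j]
  }, "")
}

#' Per-branch selection screen
#'
#' For every terminal branch, omega is estimated by NG86 between the leaf
#' sequence and the plurality-consensus codon sequence of its sister group
#' (the remaining members of its parent clade) -- a deliberate,
#' desk-scale simplification of branch models that needs no ancestral
#' reconstruction. Branches whose comparison saturates are flagged
#' `uncomputable` rather than dropped.
#'
#' The tree should be rooted (see [root_with_outgroup]) so that every
#' terminal branch has a well-defined sister clade; on an arbitrarily
#' rooted tree, leaves falling next to the storage root get degenerate
#' single-leaf sisters.
#'
#' @param caln a [codon_alignment] covering all tree leaves.
#' @param stree a `supported_tree` whose leaves are alignment ids.
#' @return data frame, one row per terminal branch: `branch`, `sister_n`,
#'   `N`, `S`, `Nd`, `Sd`, `dN`, `dS`, `omega`, `call`.
#' @export
branch_screen <- function(caln, stree) {
  phy <- stree$phy
  tips <- phy$tip.label
  if (!all(tips %in% caln$id))
    stop("tree leaves missing from codon alignment: ",
         paste(setdiff(tips, caln$id), collapse = ", "))
  if (length(tips) == 2) {
    est <- ng86_dnds(caln$seq[match(tips[1], caln$id)],
                     caln$seq[match(tips[2], caln$id)],
                     tips[1], tips[2])
    return(data.frame(branch = paste(tips, collapse = "--"),
                      sister_n = 1, N = est$N, S = est$S, Nd = est$Nd,
                      Sd = est$Sd, dN = est$dN, dS = est$dS,
                      omega = est$omega, call = est$call,
                      stringsAsFactors = FALSE))
  }
  cl <- node_clades(phy)
  ntip <- length(tips)
  out <- NULL
  for (t in seq_len(ntip)) {
    parent <- phy$edge[phy$edge[, 2] == t, 1]
    sisters <- setdiff(cl[[parent - ntip]], tips[t])
    if (!length(sisters)) sisters <- setdiff(tips, tips[t])
    cons <- paste(consensus_codons(caln, sisters), collapse = "")
    row <- tryCatch({
      est <- ng86_dnds(caln$seq[match(tips[t], caln$id)], cons,
                       tips[t], "sister-consensus")
      data.frame(branch = tips[t], sister_n = length(sisters),
                 N = est$N, S = est$S, Nd = est$Nd, Sd = est$Sd,
                 dN = est$dN, dS = est$dS, omega = est$omega,
                 call = est$call, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(branch = tips[t], sister_n = length(sisters),
                 N = NA, S = NA, Nd = NA, Sd = NA, dN = NA, dS = NA,
                 omega = NA, call = "uncomputable",
                 stringsAsFactors = FALSE))
    out <- rbind(out, row)
  }
  out
}
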