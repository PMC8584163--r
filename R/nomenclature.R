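# Level-based ADGR nomenclature: supported clusters, family letters, genus
# numbers, species-private subtype letters, splice-variant labels,
# one-to-one orthology, presence matrices, ancestral repertoire counts.

# internal nodes of a rooted tree in preorder (root first, depth first)
preorder_nodes <- function(phy) {
  ed <- ape::reorder.phylo(phy, "cladewise")$edge
  unique(c(ed[1, 1], ed[, 2][ed[, 2] > length(phy$tip.label)]))
}

# tip labels in left-to-right (cladewise) order
tip_order <- function(phy) {
  ed <- ape::reorder.phylo(phy, "cladewise")$edge
  phy$tip.label[ed[, 2][ed[, 2] <= length(phy$tip.label)]]
}

# support (percentage) of each internal node's clade, NA for trivial
# bipartitions (e.g. the root, or the complement of a single outgroup tip)
node_supports <- function(stree) {
  phy <- stree$phy
  tips <- phy$tip.label
  cl <- node_clades(phy)
  vapply(cl, function(s) {
    key <- bip_key(s, tips)
    if (key %in% names(stree$support)) unname(stree$support[key])
    else NA_real_
  }, 0)
}

#' Bootstrap-supported clusters of a tree
#'
#' Returns every non-trivial clade whose bipartition support reaches the
#' threshold, largest first. Clades are taken from the tree as stored, so
#' the tree should be rooted (see [root_with_outgroup]) before
#' classification.
#'
#' @param stree a `supported_tree` carrying bootstrap supports.
#' @param threshold minimum support percentage (default 50).
#' @return list of clusters; each element is a character vector of tip ids
#'   with attributes `support` and `node`.
#' @export
supported_clusters <- function(stree, threshold = 50) {
  if (is.null(stree$support))
    stop("tree has no bootstrap supports; run bootstrap_support() first")
  phy <- stree$phy
  ntip <- length(phy$tip.label)
  cl <- node_clades(phy)
  sup <- node_supports(stree)
  nodes <- ntip + seq_along(cl)
  keep <- which(!is.na(sup) & sup >= threshold &
                  lengths(cl) >= 2 & lengths(cl) <= ntip - 1)
  keep <- keep[order(-lengths(cl)[keep])]
  lapply(keep, function(i)
    structure(cl[[i]], support = sup[i], node = nodes[i]))
}

#' Assign level-3 family letters from a rooted supported tree
#'
#' Families are the maximal supported clusters that partition the
#' non-outgroup leaves: walking the tree root-to-tip (depth first), the
#' first supported cluster met on each path becomes a family; nested
#' supported clusters stay inside it. The cluster spanning the entire
#' ingroup is the order, not a family, and is skipped. Letters are
#' assigned A, B, C, ... in encounter order unless an override map
#' (id -> letter) pins historical letters; leaves outside any supported
#' cluster remain unassigned (`NA`).
#'
#' @param stree a rooted `supported_tree` with supports and (optionally)
#'   an outgroup recorded by [root_with_outgroup].
#' @param threshold minimum bootstrap support (default 50).
#' @param override optional named character vector, names = leaf ids,
#'   values = family letters to preserve.
#' @return data frame with columns `id`, `family` (letter or `NA`); the
#'   attribute `family_clades` lists the member ids per family letter.
#' @export
assign_families <- function(stree, threshold = 50, override = NULL) {
  phy <- stree$phy
  tips <- phy$tip.label
  outgroup <- stree$outgroup
  ingroup <- setdiff(tips, outgroup)
  cl <- node_clades(phy)
  sup <- node_supports(stree)
  ntip <- length(tips)
  ok_node <- vapply(seq_along(cl), function(i) {
    s <- cl[[i]]
    !is.na(sup[i]) && sup[i] >= threshold &&
      length(s) >= 2 && !any(s %in% outgroup) && !setequal(s, ingroup)
  }, TRUE)
  accepted <- list()
  assigned <- character()
  for (nd in preorder_nodes(phy)) {
    i <- nd - ntip
    if (!ok_node[i]) next
    if (any(cl[[i]] %in% assigned)) next  # nested inside an accepted family
    accepted[[length(accepted) + 1]] <- structure(cl[[i]], node = nd,
                                                  support = sup[i])
    assigned <- c(assigned, cl[[i]])
  }
  letters_used <- character(length(accepted))
  if (!is.null(override)) {
    for (k in seq_along(accepted)) {
      ov <- unique(override[intersect(names(override), accepted[[k]])])
      ov <- ov[!is.na(ov)]
      if (length(ov) > 1)
        stop("override letters conflict within one family cluster: ",
             paste(ov, collapse = ", "))
      if (length(ov) == 1) letters_used[k] <- ov
    }
  }
  pool <- setdiff(LETTERS, letters_used)
  for (k in seq_along(accepted)) {
    if (letters_used[k] == "") {
      letters_used[k] <- pool[1]
      pool <- pool[-1]
    }
  }
  fam <- setNames(rep(NA_character_, length(ingroup)), ingroup)
  for (k in seq_along(accepted)) fam[accepted[[k]]] <- letters_used[k]
  out <- data.frame(id = ingroup, family = unname(fam),
                    stringsAsFactors = FALSE)
  attr(out, "family_clades") <- setNames(accepted, letters_used)
  out
}

#' Test a clade for fish-mammal one-to-one orthology
#'
#' A cluster is a one-to-one orthology group when every species contributes
#' exactly one member and the species set spans at least one fish and one
#' mammal.
#'
#' @param members leaf ids of the clade.
#' @param species_of named character vector id -> species code.
#' @param clade_of_species named character vector species code -> clade.
#' @param support bootstrap support of the defining clade (optional).
#' @return an `orthology_group`: list with `members`, `species`, `clades`,
#'   `one_to_one`, `support`.
#' @export
detect_one_to_one <- function(members, species_of, clade_of_species,
                              support = NA_real_) {
  sp <- species_of[members]
  if (anyNA(sp)) stop("species unknown for some members")
  cls <- unique(unname(clade_of_species[unique(sp)]))
  oto <- all(table(sp) == 1) && "fish" %in% cls && "mammal" %in% cls
  structure(list(members = members, species = sort(unique(unname(sp))),
                 clades = sort(cls), one_to_one = oto,
                 support = unname(support)),
            class = "orthology_group")
}

# minimal supported clades spanning fish and mammal within a family clade;
# these are the genus (level 2) clusters
find_genus_clades <- function(stree, family_members, species_of,
                              clade_of_species, threshold) {
  phy <- stree$phy
  ntip <- length(phy$tip.label)
  cl <- node_clades(phy)
  sup <- node_supports(stree)
  spans <- function(s) {
    cls <- clade_of_species[species_of[s]]
    "fish" %in% cls && "mammal" %in% cls
  }
  cand <- which(vapply(seq_along(cl), function(i) {
    s <- cl[[i]]
    all(s %in% family_members) && !is.na(sup[i]) && sup[i] >= threshold &&
      spans(s)
  }, TRUE))
  # minimal: no other candidate is a proper subset
  minimal <- cand[vapply(cand, function(i) {
    !any(vapply(cand, function(j)
      j != i && all(cl[[j]] %in% cl[[i]]) &&
        length(cl[[j]]) < length(cl[[i]]), TRUE))
  }, TRUE)]
  pre <- preorder_nodes(phy)
  minimal <- minimal[order(match(minimal + ntip, pre))]
  lapply(minimal, function(i) structure(cl[[i]], support = sup[i]))
}

#' Full nomenclature assignment from a classified tree
#'
#' Applies the level rules to a rooted, bootstrap-supported tree:
#' families are maximal supported clusters (level 3, letters); genera are
#' the minimal supported clades within a family whose membership spans
#' fish and mammals (level 2, numbers in depth-first phylogenetic order);
#' species-private subtype letters (level 1) are added whenever one
#' species carries several members of the same genus (or several
#' genus-less members of the same family), in depth-first order within
#' the species. Names are composed as
#' `ADGR<family><genus><letter>`, prefixed by the species code whenever a
#' level-1 letter is present.
#'
#' @param stree a rooted `supported_tree` with supports.
#' @param species_of named character vector id -> species code.
#' @param clade_of_species named character vector species code -> clade.
#' @param threshold minimum bootstrap support (default 50).
#' @param override optional historical-letter override map for
#'   [assign_families].
#' @param variants optional named integer vector id -> number of splice
#'   variants; each variant is reported as `<name>.<k>`.
#' @return data frame of nomenclature records (one row per receptor, or
#'   per variant when `variants` is given): `id`, `species_code`,
#'   `level5`, `level4`, `level3`, `level2`, `level1`, `variant`,
#'   `full_name`. Attribute `families` summarises each family (letter,
#'   members, n_genera, one_to_one).
#' @export
classify_tree <- function(stree, species_of, clade_of_species,
                          threshold = 50, override = NULL, variants = NULL) {
  fam <- assign_families(stree, threshold = threshold, override = override)
  fam_clades <- attr(fam, "family_clades")
  phy <- stree$phy
  ids <- fam$id
  genus <- setNames(rep(NA_integer_, length(ids)), ids)
  letter <- setNames(rep(NA_character_, length(ids)), ids)
  torder <- tip_order(phy)
  fam_summary <- data.frame(family = character(), n_members = integer(),
                            n_genera = integer(), one_to_one = logical(),
                            stringsAsFactors = FALSE)
  for (fl in names(fam_clades)) {
    members <- fam_clades[[fl]]
    gcl <- find_genus_clades(stree, members, species_of, clade_of_species,
                             threshold)
    for (g in seq_along(gcl)) genus[gcl[[g]]] <- g
    # level-1 letters: per species within each genus, and within the
    # genus-less remainder of the family
    groups <- c(gcl, list(setdiff(members, unlist(gcl))))
    for (grp in groups) {
      if (!length(grp)) next
      grp <- grp[order(match(grp, torder))]
      for (sp in unique(species_of[grp])) {
        own <- grp[species_of[grp] == sp]
        if (length(own) >= 2) letter[own] <- letters[seq_along(own)]
      }
    }
    og <- detect_one_to_one(members, species_of, clade_of_species)
    fam_summary <- rbind(fam_summary, data.frame(
      family = fl, n_members = length(members), n_genera = length(gcl),
      one_to_one = og$one_to_one, stringsAsFactors = FALSE))
  }
  group <- ifelse(is.na(fam$family), NA_character_,
                  paste0(fam$family, ifelse(is.na(genus[ids]), "",
                                            genus[ids])))
  names(group) <- ids
  assign <- data.frame(id = ids,
                       species_code = unname(species_of[ids]),
                       family = fam$family,
                       genus = unname(genus[ids]),
                       letter = unname(letter[ids]),
                       stringsAsFactors = FALSE)
  rec <- generate_names(assign, variants = variants)
  grp_summary <- do.call(rbind, lapply(
    unique(group[!is.na(group)]), function(g) {
      mem <- names(group)[!is.na(group) & group == g]
      og <- detect_one_to_one(mem, species_of, clade_of_species)
      data.frame(group = g, n_members = length(mem),
                 one_to_one = og$one_to_one, stringsAsFactors = FALSE)
    }))
  attr(rec, "families") <- fam_summary
  attr(rec, "family_clades") <- fam_clades
  attr(rec, "groups") <- grp_summary
  rec
}

#' Finest classification grouping of each receptor
#'
#' The grouping a classified tree implies at its finest supported level:
#' the genus where one is defined, otherwise the family. This is the
#' natural unit for orthology-group comparisons -- hierarchical renaming
#' (e.g. two historical families merging into one letter with two genus
#' numbers) changes letters but not this partition.
#'
#' @param records output of [classify_tree].
#' @return named character vector id -> group label (e.g. `"A1"`, or
#'   `"B"` for genus-less family members; `NA` when unclassified).
#' @export
classification_groups <- function(records) {
  grp <- ifelse(is.na(records$level3), NA_character_,
                paste0(records$level3,
                       ifelse(is.na(records$level2), "", records$level2)))
  setNames(grp, records$id)
}

#' Compose full receptor names from level assignments
#'
#' Deterministic composition of `ADGR<family><genus><letter>[.variant]`,
#' prefixed with the species code whenever a level-1 letter is present
#' (level-1 letters are private to a species, so the bare name would be
#' ambiguous). Receptors without an assigned family yield `NA` names.
#'
#' @param assign data frame with columns `id`, `species_code`, `family`,
#'   `genus`, `letter` (`NA` where a level is unassigned).
#' @param variants optional named integer vector id -> number of splice
#'   variants; rows are expanded and suffixed `.1`, `.2`, ...
#' @return data frame of nomenclature records (see [classify_tree]).
#' @export
generate_names <- function(assign, variants = NULL) {
  base <- ifelse(is.na(assign$family), NA_character_,
                 paste0("ADGR", assign$family,
                        ifelse(is.na(assign$genus), "", assign$genus),
                        ifelse(is.na(assign$letter), "", assign$letter)))
  full <- ifelse(is.na(base), NA_character_,
                 ifelse(is.na(assign$letter), base,
                        paste(assign$species_code, base)))
  dup <- !is.na(full) & duplicated(paste(assign$species_code, full))
  if (any(dup))
    stop("duplicate full name within one species: ",
         paste(unique(full[dup]), collapse = ", "))
  rec <- data.frame(id = assign$id,
                    species_code = assign$species_code,
                    level5 = "aGPCR/secretin-like",
                    level4 = "ADGR",
                    level3 = assign$family,
                    level2 = assign$genus,
                    level1 = assign$letter,
                    variant = NA_integer_,
                    full_name = full,
                    stringsAsFactors = FALSE)
  if (!is.null(variants)) {
    ex <- lapply(seq_len(nrow(rec)), function(i) {
      k <- variants[rec$id[i]]
      if (is.na(k) || is.null(k) || k < 1) return(rec[i, ])
      out <- rec[rep(i, k), ]
      out$variant <- seq_len(k)
      out$full_name <- paste0(out$full_name, ".", seq_len(k))
      out
    })
    rec <- do.call(rbind, ex)
    rownames(rec) <- NULL
  }
  rec
}

#' Presence matrix of receptor groups across vertebrate clades
#'
#' @param groups character vector: group label of each receptor (e.g.
#'   `"ADGRF2"`).
#' @param species character vector: species code of each receptor.
#' @param clade_of_species named character vector species code -> clade.
#' @param pseudogene logical vector flagging pseudogenes (user-supplied;
#'   frameshift/stop detection is out of scope).
#' @param clades column order (default fish, amphibian, reptile, bird,
#'   mammal).
#' @return character matrix (`present`, `absent`, `pseudogene`), rows =
#'   groups, columns = clades; class `presence_matrix`.
#' @export
presence_matrix <- function(groups, species, clade_of_species,
                            pseudogene = rep(FALSE, length(groups)),
                            clades = c("fish", "amphibian", "reptile",
                                       "bird", "mammal")) {
  stopifnot(length(groups) == length(species),
            length(groups) == length(pseudogene))
  gl <- unique(groups)
  m <- matrix("absent", nrow = length(gl), ncol = length(clades),
              dimnames = list(gl, clades))
  cl <- unname(clade_of_species[species])
  for (g in gl) for (cc in clades) {
    hit <- groups == g & cl == cc
    if (!any(hit)) next
    m[g, cc] <- if (all(pseudogene[hit])) "pseudogene" else "present"
  }
  class(m) <- c("presence_matrix", class(m))
  m
}

#' Minimum ancestral repertoire implied by orthology groups
#'
#' Each fish-mammal one-to-one group contributes one ancestral gene;
#' unresolved groups contribute their stated ancestral multiplicity.
#'
#' @param groups data frame with columns `one_to_one` (logical) and
#'   `multiplicity` (numeric; required where `one_to_one` is `FALSE`).
#' @return integer count of ancestral genes.
#' @export
ancestral_repertoire <- function(groups) {
  stopifnot(is.data.frame(groups),
            all(c("one_to_one", "multiplicity") %in% names(groups)))
  un <- !groups$one_to_one
  if (any(un & is.na(groups$multiplicity)))
    stop("unresolved group(s) without multiplicity annotation: ",
         paste(which(un & is.na(groups$multiplicity)), collapse = ", "))
  as.integer(sum(groups$one_to_one) + sum(groups$multiplicity[un]))
}

# ---- bundled fixtures --------------------------------------------------

#' Bundled human aGPCR nomenclature table
#'
#' The curated mapping between historical symbols, the consortium (v2.0)
#' names, and the revised cluster-based (v3.0) names for all 33 human
#' aGPCRs, including the human ADGRE4/EMR4 pseudogene.
#'
#' @param path TSV path; defaults to the bundled table.
#' @return data frame: `name_v3`, `family_v3`, `name_v2`, `old_symbol`,
#'   `pseudogene`.
#' @export
read_nomenclature_table <- function(path = system.file(
  "extdata", "human_agpcr_nomenclature.tsv", package = "adgrevo")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name_v3", "family_v3", "name_v2", "old_symbol", "pseudogene")
  if (!all(need %in% names(df))) stop("malformed nomenclature table")
  df$pseudogene <- as.logical(df$pseudogene)
  df
}

#' Bundled fish-mammal orthology group table
#'
#' The curated vertebrate orthology groups of the human aGPCR repertoire:
#' 19 groups with strict fish-mammal one-to-one orthology, plus the
#' unresolved E, F, and G1/3/5 groups each annotated with ancestral
#' multiplicity 2.
#'
#' @param path TSV path; defaults to the bundled table.
#' @return data frame: `group`, `one_to_one`, `multiplicity`.
#' @export
read_orthology_table <- function(path = system.file(
  "extdata", "fish_mammal_orthology.tsv", package = "adgrevo")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("group", "one_to_one", "multiplicity") %in% names(df)))
    stop("malformed orthology table")
  df$one_to_one <- as.logical(df$one_to_one)
  df
}

#' Bundled aGPCR presence-by-clade table
#'
#' Presence of each human-repertoire receptor across the five bony
#' vertebrate classes (curated; `present`, `absent`, or `pseudogene`).
#'
#' @param path TSV path; defaults to the bundled table.
#' @return a `presence_matrix` (rows = receptors, columns = clades).
#' @export
read_presence_table <- function(path = system.file(
  "extdata", "agpcr_presence.tsv", package = "adgrevo")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  clades <- c("fish", "amphibian", "reptile", "bird", "mammal")
  if (!all(c("group", clades) %in% names(df)))
    stop("malformed presence table")
  m <- as.matrix(df[, clades])
  rownames(m) <- df$group
  class(m) <- c("presence_matrix", class(m))
  m
}
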