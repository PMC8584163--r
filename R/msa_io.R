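# Alignment data model and file I/O.
#
# Coordinates are 0-based half-open in files and in segment_map objects
# (bioinformatics convention); user-facing reports are 1-based inclusive.

#' The twenty standard amino acids
#'
#' One-letter codes in alphabetical order. `"X"` (ambiguous) and `"-"` (gap)
#' are additionally permitted in alignments but are treated as missing data
#' for distance and conservation calculations.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

VERTEBRATE_CLADES <- c("fish", "amphibian", "reptile", "bird", "mammal", "outgroup")

#' Construct a labeled multiple sequence alignment
#'
#' A `labeled_msa` holds equal-length gapped amino-acid sequences together
#' with per-sequence species codes and a species-to-clade map (fish,
#' amphibian, reptile, bird, mammal, or outgroup). All downstream stages
#' (distances, trees, conservation, nomenclature) consume this container.
#'
#' @param id character vector of unique sequence identifiers.
#' @param species_code character vector (same length as `id`) of two-letter
#'   lowercase species codes, e.g. `"hs"` for *Homo sapiens*.
#' @param seq character vector of gapped amino-acid sequences, all of
#'   identical length; alphabet restricted to the 20 amino acids, `"X"`,
#'   and `"-"`.
#' @param clade_of_species named character vector mapping every species code
#'   to one of `fish`, `amphibian`, `reptile`, `bird`, `mammal`, `outgroup`.
#' @return an object of class `labeled_msa` with fields `id`,
#'   `species_code`, `seq`, `clade_of_species`, `alignment_length`.
#' @export
labeled_msa <- function(id, species_code, seq, clade_of_species) {
  id <- as.character(id)
  species_code <- as.character(species_code)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq) || length(id) != length(species_code))
    stop("id, species_code and seq must have equal length")
  if (anyDuplicated(id))
    stop("duplicated sequence ids: ", paste(id[duplicated(id)], collapse = ", "))
  lens <- nchar(seq)
  if (length(unique(lens)) > 1L)
    stop("ragged alignment: sequence lengths differ (",
         paste(unique(lens), collapse = ", "), ")")
  allowed <- c(AA20, "X", "-")
  for (i in seq_along(seq)) {
    bad <- setdiff(unique(strsplit(seq[i], "", fixed = TRUE)[[1]]), allowed)
    if (length(bad))
      stop("illegal character(s) ", paste(bad, collapse = ", "),
           " in record '", id[i], "'")
  }
  missing_sp <- setdiff(unique(species_code), names(clade_of_species))
  if (length(missing_sp))
    stop("species code(s) without clade entry: ",
         paste(missing_sp, collapse = ", "))
  bad_clade <- setdiff(unique(clade_of_species), VERTEBRATE_CLADES)
  if (length(bad_clade))
    stop("unknown clade label(s): ", paste(bad_clade, collapse = ", "))
  structure(list(id = id,
                 species_code = species_code,
                 seq = seq,
                 clade_of_species = clade_of_species[unique(species_code)],
                 alignment_length = lens[1]),
            class = "labeled_msa")
}

#' @export
print.labeled_msa <- function(x, ...) {
  cat("labeled_msa:", length(x$id), "sequences x", x$alignment_length,
      "columns\n")
  cl <- x$clade_of_species[x$species_code]
  cat("  clades:", paste(names(table(cl)), table(cl), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Alignment as a character matrix
#'
#' @param msa a [labeled_msa].
#' @return character matrix, rows named by sequence id.
#' @export
msa_matrix <- function(msa) {
  m <- matrix(unlist(strsplit(msa$seq, "", fixed = TRUE), use.names = FALSE),
              nrow = length(msa$id), byrow = TRUE)
  rownames(m) <- msa$id
  m
}

#' Subset an alignment by sequences and/or columns
#'
#' @param msa a [labeled_msa].
#' @param ids sequence ids to keep (default all).
#' @param columns 1-based column indices to keep (default all).
#' @return a [labeled_msa].
#' @export
msa_subset <- function(msa, ids = NULL, columns = NULL) {
  keep <- if (is.null(ids)) seq_along(msa$id) else match(ids, msa$id)
  if (anyNA(keep)) stop("unknown sequence id(s): ",
                        paste(ids[is.na(keep)], collapse = ", "))
  m <- msa_matrix(msa)[keep, , drop = FALSE]
  if (!is.null(columns)) {
    if (any(columns < 1 | columns > msa$alignment_length))
      stop("column indices out of range")
    m <- m[, columns, drop = FALSE]
  }
  labeled_msa(msa$id[keep], msa$species_code[keep],
              apply(m, 1, paste, collapse = ""),
              msa$clade_of_species)
}

#' Read an aligned FASTA plus sidecar metadata
#'
#' Sequence metadata is carried in a tab-separated sidecar file (columns
#' `id`, `species_code`, `clade`) rather than parsed from FASTA headers,
#' which are unreliable in public databases. FASTA ids are truncated at the
#' first whitespace.
#'
#' @param path aligned (gapped) amino-acid FASTA file.
#' @param metadata_path TSV with columns `id`, `species_code`, `clade`
#'   covering every FASTA record.
#' @return a [labeled_msa] preserving FASTA record order.
#' @export
read_fasta_msa <- function(path, metadata_path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- c("id", "species_code", "clade")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  miss <- setdiff(ids, meta$id)
  if (length(miss))
    stop("record(s) missing from metadata: ", paste(miss, collapse = ", "))
  i <- match(ids, meta$id)
  sp <- meta$species_code[i]
  cl <- meta$clade[i]
  cm <- tapply(cl, sp, unique)
  if (any(lengths(cm) > 1))
    stop("conflicting clade assignments for species: ",
         paste(names(cm)[lengths(cm) > 1], collapse = ", "))
  clade_of_species <- vapply(cm, `[`, "", 1)
  labeled_msa(ids, sp, as.character(aa), clade_of_species)
}

#' Write a labeled alignment to FASTA (and optionally its metadata TSV)
#'
#' @param msa a [labeled_msa].
#' @param fasta_path output FASTA path.
#' @param metadata_path optional output TSV path (`id`, `species_code`,
#'   `clade`).
#' @return `fasta_path`, invisibly.
#' @export
write_labeled_msa <- function(msa, fasta_path, metadata_path = NULL) {
  xs <- Biostrings::AAStringSet(setNames(msa$seq, msa$id))
  Biostrings::writeXStringSet(xs, fasta_path)
  if (!is.null(metadata_path)) {
    meta <- data.frame(id = msa$id,
                       species_code = msa$species_code,
                       clade = unname(msa$clade_of_species[msa$species_code]))
    write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Construct a TM-segment map
#'
#' Named, ordered, non-overlapping column intervals over the alignment,
#' 0-based half-open. Seven segments named `TM1`..`TM7` are required by the
#' numbering operations; loop segments may be interleaved.
#'
#' @param name character vector of segment names.
#' @param start,end integer vectors, 0-based half-open.
#' @param alignment_length number of alignment columns the map refers to.
#' @return an object of class `segment_map` (a data frame with attributes).
#' @export
segment_map <- function(name, start, end, alignment_length) {
  df <- data.frame(name = as.character(name),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$name)) stop("duplicated segment names")
  if (any(is.na(df$start) | is.na(df$end))) stop("non-numeric segment bounds")
  if (any(df$start < 0) || any(df$end > alignment_length))
    stop("segment out of alignment range [0, ", alignment_length, ")")
  if (any(df$end <= df$start)) stop("empty or inverted segment(s): ",
                                    paste(df$name[df$end <= df$start],
                                          collapse = ", "))
  o <- order(df$start)
  if (!identical(o, seq_len(nrow(df))))
    stop("segments must be given in increasing column order")
  if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)])) {
    i <- which(df$start[-1] < df$end[-nrow(df)])[1]
    stop("overlapping segments: ", df$name[i], " and ", df$name[i + 1])
  }
  attr(df, "alignment_length") <- alignment_length
  class(df) <- c("segment_map", "data.frame")
  df
}

#' Read a TM-segment map from TSV or JSON
#'
#' TSV needs columns `name`, `start`, `end`; JSON an array of objects with
#' the same fields. Coordinates are 0-based half-open.
#'
#' @param path file path (`.json` triggers the JSON reader).
#' @param alignment_length alignment width used for range validation.
#' @return a [segment_map].
#' @export
read_segment_map <- function(path, alignment_length) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
  }
  if (!all(c("name", "start", "end") %in% names(df)))
    stop("segment map must have fields name, start, end")
  segment_map(df$name, df$start, df$end, alignment_length)
}

# 1-based R column indices of one named segment
seg_columns <- function(segmap, name) {
  i <- match(name, segmap$name)
  if (is.na(i)) stop("segment '", name, "' not in segment map")
  (segmap$start[i] + 1L):segmap$end[i]
}

tm_names <- paste0("TM", 1:7)

require_seven_tm <- function(segmap) {
  miss <- setdiff(tm_names, segmap$name)
  if (length(miss))
    stop("segment map lacks TM segment(s) required for numbering: ",
         paste(miss, collapse = ", "))
  invisible(segmap)
}

#' @export
print.segment_map <- function(x, ...) {
  cat("segment_map over", attr(x, "alignment_length"), "columns\n")
  print.data.frame(x, ...)
  invisible(x)
}
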