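# Conservation profiling of the 7TM alignment, election of X.50 reference
# positions, generic relabeling, and signature-motif extraction.

#' Per-column conservation profile
#'
#' For each alignment column the modal (most frequent) unambiguous residue
#' and its conservation are computed over a sequence subset. The
#' denominator is the full subset size, so gaps and `X` count against
#' conservation; `depth` records how many subset sequences carry an
#' unambiguous residue in the column. Modal-residue ties are broken
#' alphabetically.
#'
#' @param msa a [labeled_msa].
#' @param subset_ids sequence ids to profile (default: all sequences).
#' @return a `conservation_profile`: data frame with columns `column`
#'   (1-based), `modal_residue` (`NA` for all-gap columns), `conservation`
#'   (fraction in `[0, 1]`), `depth`; attribute `n_seqs`.
#' @export
conservation_profile <- function(msa, subset_ids = NULL) {
  if (is.null(subset_ids)) subset_ids <- msa$id
  if (!length(subset_ids)) stop("subset must be non-empty")
  m <- msa_matrix(msa)[match(subset_ids, msa$id), , drop = FALSE]
  if (anyNA(match(subset_ids, msa$id)))
    stop("unknown subset id(s)")
  n <- nrow(m)
  counts <- vapply(AA20, function(l) colSums(m == l), numeric(ncol(m)))
  if (ncol(m) == 1) counts <- matrix(counts, nrow = 1,
                                     dimnames = list(NULL, AA20))
  best <- apply(counts, 1, which.max)  # ties -> alphabetically first
  maxn <- counts[cbind(seq_len(ncol(m)), best)]
  prof <- data.frame(
    column = seq_len(ncol(m)),
    modal_residue = ifelse(maxn > 0, AA20[best], NA_character_),
    conservation = maxn / n,
    depth = rowSums(counts),
    stringsAsFactors = FALSE)
  attr(prof, "n_seqs") <- n
  class(prof) <- c("conservation_profile", "data.frame")
  prof
}

#' Elect X.50 reference positions and label all TM columns
#'
#' Within each of the seven TM segments the most conserved column is
#' designated the reference position h.50; every other column of the helix
#' is labelled by its integer offset from the reference (h.49, h.51, ...).
#' Conservation ties are broken by proximity to the segment midpoint, then
#' by the lower column index. Offsets beyond +-49 are refused (two-digit
#' generic numbering).
#'
#' @param profile a [conservation_profile].
#' @param segmap a [segment_map] containing all of TM1..TM7.
#' @return a `reference_position_map`: list with `references` (data frame:
#'   helix, column, residue, conservation) and `labels` (data frame:
#'   column, helix, label, offset). Columns are 1-based.
#' @export
assign_reference_positions <- function(profile, segmap) {
  require_seven_tm(segmap)
  refs <- data.frame(helix = integer(), column = integer(),
                     residue = character(), conservation = numeric(),
                     stringsAsFactors = FALSE)
  labels <- data.frame(column = integer(), helix = integer(),
                       label = character(), offset = integer(),
                       stringsAsFactors = FALSE)
  for (h in 1:7) {
    cols <- seg_columns(segmap, paste0("TM", h))
    cons <- profile$conservation[cols]
    if (all(profile$depth[cols] == 0))
      stop("TM", h, " segment is empty (all-gap)")
    mid <- (min(cols) + max(cols)) / 2
    cand <- cols[cons >= max(cons) - 1e-12]
    ref <- cand[order(abs(cand - mid), cand)][1]
    off <- cols - ref
    if (any(abs(off) > 49))
      stop("TM", h, ": offsets beyond +-49 are not representable")
    refs <- rbind(refs, data.frame(
      helix = h, column = ref,
      residue = profile$modal_residue[ref],
      conservation = profile$conservation[ref],
      stringsAsFactors = FALSE))
    labels <- rbind(labels, data.frame(
      column = cols, helix = h,
      label = sprintf("%d.%d", h, 50 + off), offset = off,
      stringsAsFactors = FALSE))
  }
  structure(list(references = refs, labels = labels),
            class = "reference_position_map")
}

#' @export
print.reference_position_map <- function(x, ...) {
  cat("reference positions:\n")
  r <- x$references
  cat(paste0("  ", r$residue, r$helix, ".50 (",
             sprintf("%.1f", 100 * r$conservation), "% conserved, column ",
             r$column, ")", collapse = "\n"), "\n")
  invisible(x)
}

#' Generic label of an alignment column
#'
#' @param refmap a `reference_position_map`.
#' @param column 1-based alignment column(s).
#' @return character label(s), `NA` for columns outside all TM segments.
#' @export
generic_label <- function(refmap, column) {
  refmap$labels$label[match(column, refmap$labels$column)]
}

#' Extract signature motifs of the TM helices
#'
#' Per helix, a consensus string over the window ending at the reference
#' position: positions with conservation at or above `cutoff` show the
#' modal residue, all others show `x`. The window runs from the most
#' N-terminal conserved column of the helix through the reference (so
#' reported motifs end at X.50); helices with no conserved column up to
#' the reference yield an empty motif.
#'
#' @param profile a [conservation_profile].
#' @param segmap a [segment_map] with TM1..TM7.
#' @param refmap optional precomputed [assign_reference_positions] result.
#' @param cutoff conservation cutoff in `(0, 1]` (default 0.80).
#' @param regions helices to report (default all seven).
#' @return data frame: region, motif, start_column, end_column, cutoff.
#' @export
signature_motifs <- function(profile, segmap, refmap = NULL, cutoff = 0.80,
                             regions = paste0("TM", 1:7)) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  if (is.null(refmap)) refmap <- assign_reference_positions(profile, segmap)
  out <- data.frame(region = character(), motif = character(),
                    start_column = integer(), end_column = integer(),
                    cutoff = numeric(), stringsAsFactors = FALSE)
  for (rg in regions) {
    h <- as.integer(sub("TM", "", rg))
    cols <- seg_columns(segmap, rg)
    ref <- refmap$references$column[refmap$references$helix == h]
    cons <- profile$conservation[cols]
    keep <- cons >= cutoff - 1e-12
    upto <- cols <= ref
    if (!any(keep & upto)) {
      out <- rbind(out, data.frame(region = rg, motif = "",
                                   start_column = NA_integer_,
                                   end_column = ref, cutoff = cutoff,
                                   stringsAsFactors = FALSE))
      next
    }
    from <- min(cols[keep & upto])
    win <- from:ref
    chars <- ifelse(profile$conservation[win] >= cutoff - 1e-12,
                    profile$modal_residue[win], "x")
    out <- rbind(out, data.frame(region = rg,
                                 motif = paste(chars, collapse = ""),
                                 start_column = from, end_column = ref,
                                 cutoff = cutoff, stringsAsFactors = FALSE))
  }
  out
}

#' Count highly conserved TM positions
#'
#' @param profile a [conservation_profile].
#' @param segmap a [segment_map] with TM1..TM7.
#' @param threshold conservation threshold in `(0, 1)`; columns strictly
#'   above it are counted (default 0.95).
#' @return integer count over all TM-segment columns.
#' @export
count_conserved_positions <- function(profile, segmap, threshold = 0.95) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  cols <- unlist(lapply(tm_names, seg_columns, segmap = segmap))
  sum(profile$conservation[cols] > threshold)
}

#' Export a numbering table
#'
#' One row per TM column: 1-based column, segment, generic label, modal
#' residue, conservation.
#'
#' @param profile a [conservation_profile].
#' @param segmap a [segment_map].
#' @param refmap a `reference_position_map` (computed if `NULL`).
#' @return data frame.
#' @export
numbering_table <- function(profile, segmap, refmap = NULL) {
  if (is.null(refmap)) refmap <- assign_reference_positions(profile, segmap)
  lab <- refmap$labels
  data.frame(column = lab$column,
             segment = paste0("TM", lab$helix),
             label = lab$label,
             modal_residue = profile$modal_residue[lab$column],
             conservation = profile$conservation[lab$column],
             stringsAsFactors = FALSE)
}
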