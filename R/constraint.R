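# Loss-of-function constraint comparison across receptor families.

#' Read a LoF constraint table
#'
#' @param path TSV with columns `gene`, `family`, and either `oe` or both
#'   `lof_obs` and `lof_exp`.
#' @return data frame with an `oe` column filled in.
#' @export
read_constraint_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "family") %in% names(df)))
    stop("constraint table needs columns gene, family")
  if (!"oe" %in% names(df)) {
    if (!all(c("lof_obs", "lof_exp") %in% names(df)))
      stop("constraint table needs oe, or lof_obs and lof_exp")
    if (any(df$lof_exp <= 0)) stop("lof_exp must be positive")
    df$oe <- df$lof_obs / df$lof_exp
  }
  if (any(df$oe < 0)) stop("o/e ratios must be nonnegative")
  df
}

#' Family-level LoF constraint comparison
#'
#' For each family the mean observed/expected (o/e) LoF ratio is compared
#' with the grand mean over all genes. Significance is assessed by a
#' label-permutation test: gene family labels are shuffled
#' `n_permutations` times and the two-sided p-value is the proportion of
#' permutations whose family-mean deviation is at least as extreme as the
#' observed one (with the +1 correction). Families with p at or below
#' `alpha` are called `below average` or `above average` by the sign of
#' their deviation.
#'
#' @param records data frame with columns `gene`, `family`, and `oe` (or
#'   `lof_obs`/`lof_exp`, from which `oe` is derived).
#' @param n_permutations number of label permutations (default 10000).
#' @param seed optional integer seed; fixed seeds reproduce p-values
#'   exactly and results are invariant to gene input order.
#' @param alpha significance level for the deviation call (default 0.05).
#' @return data frame: `family`, `n_genes`, `mean_oe`, `delta`
#'   (family mean minus grand mean), `p_value`, `call`.
#' @export
family_constraint <- function(records, n_permutations = 10000, seed = NULL,
                              alpha = 0.05) {
  stopifnot(is.data.frame(records))
  if (!"oe" %in% names(records)) {
    if (!all(c("lof_obs", "lof_exp") %in% names(records)))
      stop("records need oe, or lof_obs and lof_exp")
    if (any(records$lof_exp <= 0)) stop("lof_exp must be positive")
    records$oe <- records$lof_obs / records$lof_exp
  }
  if (any(records$oe < 0)) stop("o/e ratios must be nonnegative")
  o <- order(records$family, records$gene)  # order invariance
  oe <- records$oe[o]
  fam <- factor(records$family[o])
  if (nlevels(fam) < 2) stop("need at least 2 families")
  if (any(tabulate(fam) == 0)) stop("family with zero genes")
  grand <- mean(oe)
  obs_delta <- tapply(oe, fam, mean) - grand
  run <- function() {
    counts <- setNames(numeric(nlevels(fam)), levels(fam))
    for (r in seq_len(n_permutations)) {
      pd <- tapply(oe, sample(fam), mean) - grand
      hit <- abs(pd) >= abs(obs_delta) - 1e-12
      counts[hit] <- counts[hit] + 1
    }
    counts
  }
  counts <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  p <- (1 + counts) / (1 + n_permutations)
  call <- ifelse(p <= alpha,
                 ifelse(obs_delta < 0, "below average", "above average"),
                 "none")
  data.frame(family = levels(fam),
             n_genes = as.integer(tabulate(fam)),
             mean_oe = as.numeric(obs_delta + grand),
             delta = as.numeric(obs_delta),
             p_value = as.numeric(p),
             call = as.character(call),
             stringsAsFactors = FALSE, row.names = NULL)
}
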