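## Pull-down enrichment from spectral-count tables: abundance filter,
## pseudocounted log2 ratios, ranked enrichment tables.

.spectral_samples <- function(tab) setdiff(names(tab), c("protein_id", "origin"))

#' Filter proteins by maximum spectral count
#'
#' Retains exactly the proteins whose maximum count across samples is at
#' least `min_count` (the reporting convention for pull-down ratio plots),
#' preserving row order. The filter is idempotent and never alters counts.
#'
#' @param tab Spectral-count data frame (see [read_spectral_table()]).
#' @param min_count Threshold applied to the per-protein maximum (default
#'   50).
#' @return The filtered table.
#' @export
filter_min_counts <- function(tab, min_count = 50) {
  stopifnot(min_count >= 0)
  samples <- .spectral_samples(tab)
  if (!length(samples)) stop("table has no sample columns")
  if (!nrow(tab)) return(tab)
  mx <- do.call(pmax, tab[samples])
  out <- tab[mx >= min_count, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pseudocounted log2 ratio of two spectral counts
#'
#' `log2((count_a + pseudocount) / (count_b + pseudocount))`. The
#' pseudocount (1 for proximity-labelling tables, 0.5 for crosslinking
#' tables by convention) keeps the ratio finite for zero counts; equal
#' counts always give 0.
#'
#' @param count_a,count_b Non-negative counts (vectorized).
#' @param pseudocount Positive pseudocount.
#' @return Numeric log2 ratio(s).
#' @export
log2_ratio <- function(count_a, count_b, pseudocount = 1) {
  stopifnot(pseudocount > 0)
  if (any(count_a < 0) || any(count_b < 0)) stop("counts must be non-negative")
  ## difference of logs, so swapping the samples negates the ratio exactly
  log2(count_a + pseudocount) - log2(count_b + pseudocount)
}

#' Ranked enrichment table between two samples
#'
#' Applies the abundance filter, computes the pseudocounted log2 ratio of
#' `numerator_sample` over `denominator_sample` for every retained protein,
#' and sorts by ratio descending (ties by protein_id ascending). Swapping
#' the two samples negates every ratio exactly.
#'
#' @param tab Spectral-count data frame.
#' @param numerator_sample,denominator_sample Sample column names.
#' @param pseudocount Positive pseudocount (default 1).
#' @param min_count Abundance filter threshold (default 50); set to 0 to
#'   report all proteins.
#' @return Data frame: protein_id, origin, the two count columns,
#'   log2_ratio.
#' @export
enrichment_table <- function(tab, numerator_sample, denominator_sample,
                             pseudocount = 1, min_count = 50) {
  samples <- .spectral_samples(tab)
  missing <- setdiff(c(numerator_sample, denominator_sample), samples)
  if (length(missing))
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  kept <- filter_min_counts(tab, min_count)
  out <- data.frame(protein_id = kept$protein_id, origin = kept$origin,
                    stringsAsFactors = FALSE)
  out[[numerator_sample]] <- kept[[numerator_sample]]
  out[[denominator_sample]] <- kept[[denominator_sample]]
  out$log2_ratio <- log2_ratio(kept[[numerator_sample]],
                               kept[[denominator_sample]], pseudocount)
  out <- out[order(-out$log2_ratio, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
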