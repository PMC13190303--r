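## The screen statistic: log2-CPM normalization, per-phage OLS regression
## against the no-phage condition, per-barcode residuals and per-gene mean
## residuals ("log2 enrichment scores").

#' log2-CPM normalization of one condition
#'
#' Each count becomes `log2((count / column_total) * 1e6 + 1)`, computed in
#' double precision. Zero counts map to exactly 0, and the transform is
#' strictly monotone in the raw count.
#'
#' @param counts Non-negative integer vector (one condition column).
#' @param total Column total; defaults to `sum(counts)` and must be > 0.
#' @return Numeric vector of normalized values (names preserved).
#' @export
log2_cpm <- function(counts, total = sum(counts)) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(total) != 1 || total <= 0)
    stop("empty condition: column total must be > 0")
  log2(counts / total * 1e6 + 1)
}

#' Fit the control-vs-phage regression
#'
#' Ordinary least squares with intercept of the phage condition's normalized
#' counts (dependent) on the no-phage condition's (independent). Each
#' barcode's residual is its deviation from the expectation set by the
#' no-phage library composition.
#'
#' @param x Normalized no-phage values (independent variable).
#' @param y Normalized phage values, same barcode order.
#' @return Object of class `control_fit`: `slope`, `intercept`, `residuals`
#'   (named by barcode when `x` is named).
#' @export
fit_control_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3) stop("need at least 3 barcodes to fit")
  if (isTRUE(all.equal(stats::var(x), 0)) || stats::var(x) == 0)
    stop("degenerate design: no-phage values are constant")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  names(res) <- names(x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residuals = res),
            class = "control_fit")
}

#' @export
print.control_fit <- function(x, ...) {
  cat(sprintf("control_fit: y = %.4f x + %.4f over %d barcodes\n",
              x$slope, x$intercept, length(x$residuals)))
  invisible(x)
}

#' Average residuals per gene into enrichment scores
#'
#' Maps each barcode's residual to its gene through the pool (intergenic
#' barcodes are excluded) and averages residuals within genes. Output is
#' sorted by score descending, ties broken by gene_id ascending, and
#' carries a 1-based rank.
#'
#' @param fit A [fit_control_regression()] result with barcode-named
#'   residuals.
#' @param pool Barcode pool data frame.
#' @return Data frame with columns gene_id, n_barcodes, score, rank.
#' @export
gene_enrichment <- function(fit, pool) {
  stopifnot(inherits(fit, "control_fit"))
  res <- fit$residuals
  if (is.null(names(res))) stop("residuals must be named by barcode")
  idx <- match(names(res), pool$barcode)
  if (anyNA(idx)) stop("barcodes missing from pool: ",
                       paste(utils::head(names(res)[is.na(idx)], 3), collapse = ", "))
  gene <- pool$gene_id[idx]
  keep <- !is.na(gene) & gene != "-"
  if (!any(keep))
    return(data.frame(gene_id = character(0), n_barcodes = integer(0),
                      score = numeric(0), rank = integer(0)))
  score <- tapply(res[keep], gene[keep], mean)
  n_bc <- tapply(rep(1L, sum(keep)), gene[keep], sum)
  out <- data.frame(gene_id = names(score), n_barcodes = as.integer(n_bc),
                    score = as.numeric(score), stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run the full enrichment screen
#'
#' Applies [log2_cpm()] per condition, fits one regression per phage
#' condition against the shared no-phage control, and averages residuals
#' into per-gene scores.
#'
#' @param counts A [count_table()].
#' @param pool Barcode pool covering every barcode in `counts`.
#' @param control Name of the no-phage condition column.
#' @param phage_conditions Character vector of phage condition columns.
#' @param min_total Optional filter: drop barcodes whose summed raw count
#'   across the control and the phage condition is below this value
#'   (default 0 = keep all barcodes).
#' @return Named list (one element per phage condition) of gene-score data
#'   frames, plus attribute `fits` holding each `control_fit`.
#' @export
run_screen <- function(counts, pool, control, phage_conditions, min_total = 0) {
  stopifnot(inherits(counts, "count_table"))
  missing <- setdiff(c(control, phage_conditions), counts$conditions)
  if (length(missing))
    stop("condition(s) not in count table: ", paste(missing, collapse = ", "))
  x_raw <- counts$counts[, control]
  x <- log2_cpm(x_raw, counts$totals[[control]])
  names(x) <- counts$barcodes
  fits <- list()
  scores <- lapply(phage_conditions, function(ph) {
    y_raw <- counts$counts[, ph]
    y <- log2_cpm(y_raw, counts$totals[[ph]])
    keep <- (x_raw + y_raw) >= min_total
    fit <- fit_control_regression(x[keep], y[keep])
    fits[[ph]] <<- fit
    gene_enrichment(fit, pool)
  })
  names(scores) <- phage_conditions
  attr(scores, "fits") <- fits
  scores
}
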