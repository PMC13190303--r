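#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that returns plain
#' uppercase character vectors, which is the sequence representation used
#' throughout this package. Wrapped and unwrapped FASTA are both accepted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids")
  Biostrings::writeXStringSet(Biostrings::BStringSet(toupper(seqs)), path)
  invisible(path)
}

## Typed TSV reading with line-numbered diagnostics. `schema` maps column
## name -> one of "character", "integer", "numeric". Extra columns pass
## through untouched.
read_tsv_typed <- function(path, schema) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop(path, ": missing required column(s): ", paste(missing, collapse = ", "))
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type == "character") next
    raw <- df[[col]]
    conv <- suppressWarnings(if (type == "integer") as.integer(raw) else as.numeric(raw))
    bad <- which(is.na(conv) & !is.na(raw) & nzchar(raw))
    if (length(bad))
      stop(path, ", line ", bad[1] + 1L, ": cannot parse '", raw[bad[1]],
           "' in column '", col, "' as ", type)
    df[[col]] <- conv
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a barcode pool table
#'
#' A barcode pool maps each transposon barcode to its genomic insertion
#' position and the gene it disrupts (the screen's mapping resource).
#' The on-disk format is TSV with columns `barcode`, `position`, `gene_id`
#' (`-` for intergenic insertions) and `abundance`; intergenic entries are
#' represented as `NA` in memory.
#'
#' @param path Path to a pool TSV.
#' @return A data frame with columns barcode, position, gene_id, abundance.
#' @export
read_pool <- function(path) {
  df <- read_tsv_typed(path, list(barcode = "character", position = "integer",
                                  gene_id = "character", abundance = "numeric"))
  df$gene_id[df$gene_id == "-"] <- NA_character_
  if (anyDuplicated(df$barcode)) stop(path, ": duplicate barcodes in pool")
  if (any(df$position < 0)) stop(path, ": negative insertion position")
  df[c("barcode", "position", "gene_id", "abundance")]
}

#' @rdname read_pool
#' @param pool A barcode pool data frame.
#' @export
write_pool <- function(pool, path) {
  out <- pool
  out$gene_id[is.na(out$gene_id)] <- "-"
  write_tsv(out, path)
}

#' Barcode-by-condition count table
#'
#' Container for BarSeq read counts: an integer matrix with one row per
#' barcode and one column per condition, plus per-condition totals (the
#' column sums, i.e. the sequencing depth entering CPM normalization).
#'
#' @param counts Integer matrix with rownames (barcodes) and colnames
#'   (conditions).
#' @return An object of class `count_table` with fields `barcodes`,
#'   `conditions`, `counts` and `totals`.
#' @export
count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix must have barcode rownames and condition colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  structure(list(barcodes = rownames(counts), conditions = colnames(counts),
                 counts = counts, totals = colSums(counts)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", length(x$barcodes), "barcodes x",
      length(x$conditions), "conditions\n")
  cat("totals:", paste(sprintf("%s=%d", x$conditions, x$totals), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname count_table
#' @param path Path to a count-table TSV (column `barcode`, then one integer
#'   column per condition).
#' @export
read_count_table <- function(path) {
  df <- read_tsv_typed(path, list(barcode = "character"))
  conds <- setdiff(names(df), "barcode")
  if (!length(conds)) stop(path, ": no condition columns")
  for (cc in conds) {
    conv <- suppressWarnings(as.integer(df[[cc]]))
    bad <- which(is.na(conv) | conv < 0)
    if (length(bad))
      stop(path, ", line ", bad[1] + 1L, ": invalid count '", df[[cc]][bad[1]],
           "' in condition '", cc, "'")
    df[[cc]] <- conv
  }
  m <- as.matrix(df[conds])
  rownames(m) <- df$barcode
  count_table(m)
}

#' @rdname count_table
#' @param tab A `count_table`.
#' @export
write_count_table <- function(tab, path) {
  stopifnot(inherits(tab, "count_table"))
  df <- data.frame(barcode = tab$barcodes, tab$counts,
                   check.names = FALSE, row.names = NULL)
  write_tsv(df, path)
}

#' Read and write spectral-count tables
#'
#' Protein-by-sample spectral counts from pull-down mass spectrometry.
#' TSV columns: `protein_id`, `origin` (host/phage/construct), then one
#' non-negative integer column per sample.
#'
#' @param path Path to a spectral-count TSV.
#' @return Data frame with `protein_id`, `origin` and sample count columns.
#' @export
read_spectral_table <- function(path) {
  df <- read_tsv_typed(path, list(protein_id = "character", origin = "character"))
  samples <- setdiff(names(df), c("protein_id", "origin"))
  if (!length(samples)) stop(path, ": no sample columns")
  for (s in samples) {
    conv <- suppressWarnings(as.numeric(df[[s]]))
    bad <- which(is.na(conv) | conv < 0)
    if (length(bad))
      stop(path, ", line ", bad[1] + 1L, ": invalid spectral count '",
           df[[s]][bad[1]], "' in sample '", s, "'")
    df[[s]] <- conv
  }
  if (anyDuplicated(df$protein_id)) stop(path, ": duplicate protein_id")
  df
}

#' @rdname read_spectral_table
#' @param tab Spectral-count data frame.
#' @export
write_spectral_table <- function(tab, path) write_tsv(tab, path)

#' Read transmembrane-segment annotations
#'
#' One row per predicted segment: `homolog_id`, `start`, `end` (1-based,
#' inclusive, in homolog coordinates). Homologs without a row have zero
#' segments.
#'
#' @param path Path to a TSV.
#' @return Data frame with columns homolog_id, start, end.
#' @export
read_tm_annotations <- function(path) {
  df <- read_tsv_typed(path, list(homolog_id = "character",
                                  start = "integer", end = "integer"))
  if (any(df$start < 1 | df$end < df$start))
    stop(path, ": segment coordinates must satisfy 1 <= start <= end")
  df[c("homolog_id", "start", "end")]
}

#' Read a domain-hit table
#'
#' Profile-search hits against homolog N-terminal regions, consumed as an
#' annotation input: `homolog_id`, `hit_name`, `p_value`.
#'
#' @param path Path to a TSV.
#' @return Data frame with columns homolog_id, hit_name, p_value.
#' @export
read_domain_hits <- function(path) {
  df <- read_tsv_typed(path, list(homolog_id = "character",
                                  hit_name = "character", p_value = "numeric"))
  if (any(df$p_value <= 0 | df$p_value > 1))
    stop(path, ": p_value must lie in (0, 1]")
  df[c("homolog_id", "hit_name", "p_value")]
}

#' Run-configuration echo
#'
#' Every pipeline stage can persist the fully resolved configuration it ran
#' under (seed, paths, thresholds) as JSON; re-running the stage from that
#' echo reproduces its outputs byte-identically for deterministic stages.
#'
#' @param config Named list of parameters (must include any `seed` used).
#' @param path JSON path to write to / read from.
#' @return `save_run_config()` returns `path` invisibly; `load_run_config()`
#'   the restored list.
#' @export
save_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)), all(nzchar(names(config))))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
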