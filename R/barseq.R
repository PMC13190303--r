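## Barcode extraction from BarSeq amplicon reads and closed-pool counting.

.POST_ANCHOR_MAX <- 8L

.hamming <- function(a_chars, b_chars) sum(a_chars != b_chars)

## Scan one read for the pre-flank at any offset, allowing up to `max_mm`
## substitutions per anchor. Candidates are ranked by (pre mismatches,
## offset); the first whose post anchor also fits wins.
.scan_read <- function(chars, pre_chars, post_chars, bl, max_mm) {
  np <- length(pre_chars)
  na <- min(length(post_chars), .POST_ANCHOR_MAX)
  n <- length(chars)
  last_off <- n - (np + bl + na)
  if (last_off < 0) return(NULL)
  offs <- 0:last_off
  pre_mm <- vapply(offs, function(o) .hamming(chars[o + seq_len(np)], pre_chars),
                   integer(1))
  ok <- which(pre_mm <= max_mm)
  if (!length(ok)) return(NULL)
  for (i in ok[order(pre_mm[ok], offs[ok])]) {
    o <- offs[i]
    post_mm <- .hamming(chars[o + np + bl + seq_len(na)], post_chars[seq_len(na)])
    if (post_mm <= max_mm) {
      return(list(barcode = paste(chars[o + np + seq_len(bl)], collapse = ""),
                  offset = o, flank_mismatches = pre_mm[i] + post_mm))
    }
  }
  NULL
}

#' Extract a transposon barcode from one read
#'
#' Locates the pre-flank anchor allowing up to `max_flank_mismatch`
#' substitutions at any offset (fewest mismatches first, ties broken by the
#' smallest offset), takes the following `barcode_length` bases as the
#' barcode, and verifies the first `min(nchar(post_flank), 8)` bases of the
#' post-flank under the same mismatch budget. Returns `NULL` when no
#' placement satisfies both anchors.
#'
#' @param read_sequence Read as a character string.
#' @param rs A [read_structure()].
#' @param max_flank_mismatch Per-anchor substitution budget (default 0).
#' @return List with `barcode`, `offset` (0-based) and `flank_mismatches`
#'   (pre + post anchor mismatches combined), or `NULL`.
#' @export
extract_barcode <- function(read_sequence, rs, max_flank_mismatch = 0) {
  stopifnot(inherits(rs, "read_structure"))
  .scan_read(strsplit(toupper(read_sequence), "")[[1]],
             strsplit(rs$pre_flank, "")[[1]],
             strsplit(rs$post_flank, "")[[1]],
             rs$barcode_length, max_flank_mismatch)
}

## Vectorized extraction over many reads. Fast path: anchors match exactly
## at offset 0 (the amplicon layout); remaining reads go through the full
## scanner. Returns NA for reads where extraction fails.
.extract_barcodes <- function(reads, rs, max_flank_mismatch = 0) {
  np <- nchar(rs$pre_flank)
  bl <- rs$barcode_length
  na <- min(nchar(rs$post_flank), .POST_ANCHOR_MAX)
  out <- rep(NA_character_, length(reads))
  if (!length(reads)) return(out)
  reads <- toupper(reads)
  fast <- substr(reads, 1L, np) == rs$pre_flank &
    substr(reads, np + bl + 1L, np + bl + na) == substr(rs$post_flank, 1L, na) &
    nchar(reads) >= np + bl + na
  out[fast] <- substr(reads[fast], np + 1L, np + bl)
  slow <- which(!fast)
  if (length(slow)) {
    pre_chars <- strsplit(rs$pre_flank, "")[[1]]
    post_chars <- strsplit(rs$post_flank, "")[[1]]
    for (i in slow) {
      hit <- .scan_read(strsplit(reads[i], "")[[1]], pre_chars, post_chars,
                        bl, max_flank_mismatch)
      if (!is.null(hit)) out[i] <- hit$barcode
    }
  }
  out
}

## All Hamming-distance-1 neighbours of each pool barcode, as a lookup
## table. Neighbours shared by two pool barcodes are marked ambiguous (NA).
.hamming1_index <- function(barcodes) {
  bl <- nchar(barcodes[1])
  neigh <- character(0)
  owner <- character(0)
  for (pos in seq_len(bl)) {
    for (b in .BASES) {
      mut <- barcodes
      substr(mut, pos, pos) <- b
      keep <- mut != barcodes
      neigh <- c(neigh, mut[keep])
      owner <- c(owner, barcodes[keep])
    }
  }
  dup <- neigh %in% neigh[duplicated(neigh)]
  owner[dup] <- NA_character_
  keep <- !duplicated(neigh)
  stats::setNames(owner[keep], neigh[keep])
}

#' Count pool barcodes across conditions
#'
#' Reads FASTQ files (one or more per condition), extracts barcodes and
#' counts matches against a characterized pool (closed-pool counting:
#' observed barcodes absent from the pool are never added as rows). Policy
#' `"exact"` counts exact matches only; `"correct1"` additionally assigns
#' an observed barcode to a pool barcode when exactly one pool barcode lies
#' within Hamming distance 1 (ambiguous neighbours are discarded).
#'
#' @param fastq_by_condition Named list/vector: condition name -> FASTQ
#'   path(s).
#' @param pool Barcode pool data frame (barcodes must be unique).
#' @param rs A [read_structure()].
#' @param policy `"exact"` (default) or `"correct1"`.
#' @param max_flank_mismatch Per-anchor substitution budget for extraction.
#' @return List with `counts` (a [count_table()] over all pool barcodes) and
#'   `report` (per-condition read accounting: total, extracted, assigned,
#'   discarded, unextracted; always total = assigned + discarded +
#'   unextracted).
#' @export
count_barcodes <- function(fastq_by_condition, pool, rs,
                           policy = c("exact", "correct1"),
                           max_flank_mismatch = 0) {
  policy <- match.arg(policy)
  stopifnot(inherits(rs, "read_structure"))
  if (anyDuplicated(pool$barcode)) stop("pool barcodes must be unique")
  conds <- names(fastq_by_condition)
  if (is.null(conds) || any(!nzchar(conds)))
    stop("fastq_by_condition must be a named list of conditions")
  h1 <- if (policy == "correct1") .hamming1_index(pool$barcode) else NULL

  m <- matrix(0L, nrow = nrow(pool), ncol = length(conds),
              dimnames = list(pool$barcode, conds))
  report <- stats::setNames(vector("list", length(conds)), conds)
  for (cond in conds) {
    reads <- character(0)
    for (fq in fastq_by_condition[[cond]]) {
      set <- tryCatch(Biostrings::readDNAStringSet(fq, format = "fastq"),
                      error = function(e)
                        stop("cannot read FASTQ '", fq, "': ", conditionMessage(e)))
      reads <- c(reads, as.character(set))
    }
    bc <- .extract_barcodes(reads, rs, max_flank_mismatch)
    extracted <- sum(!is.na(bc))
    obs <- bc[!is.na(bc)]
    assigned_to <- ifelse(obs %in% pool$barcode, obs, NA_character_)
    if (policy == "correct1") {
      miss <- which(is.na(assigned_to))
      if (length(miss)) assigned_to[miss] <- unname(h1[obs[miss]])
    }
    tab <- table(assigned_to[!is.na(assigned_to)])
    m[names(tab), cond] <- m[names(tab), cond] + as.integer(tab)
    assigned <- sum(!is.na(assigned_to))
    report[[cond]] <- list(total = length(reads), extracted = extracted,
                           assigned = assigned,
                           discarded = extracted - assigned,
                           unextracted = length(reads) - extracted)
  }
  list(counts = count_table(m), report = report)
}
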