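## Homolog-family analytics: global-alignment identity, greedy
## dereplication, reference-coordinate identity profiles, region lengths,
## transmembrane summaries, hydropathy prediction, greedy domain-hit
## coverage and clade grouping.

#' Aligned homolog family
#'
#' A multiple alignment in reference coordinates: equal-length gapped rows,
#' one of which is the reference. The reference's non-gap columns define
#' the mapping from alignment columns to 1-based reference positions.
#'
#' @param rows Named character vector of gapped sequences of equal length.
#' @param reference_id Name of the reference row.
#' @return Object of class `aligned_family` with fields `rows`,
#'   `reference_id`, `reference_length` and `column_to_refpos` (alignment
#'   column index of each reference position).
#' @export
aligned_family <- function(rows, reference_id) {
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("rows must be uniquely named")
  if (!reference_id %in% names(rows))
    stop("reference_id '", reference_id, "' not among rows")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1) stop("all rows must have equal length")
  ref_chars <- strsplit(rows[[reference_id]], "")[[1]]
  ref_cols <- which(ref_chars != "-")
  if (!length(ref_cols)) stop("reference row is all gaps")
  structure(list(rows = rows, reference_id = reference_id,
                 reference_length = length(ref_cols),
                 column_to_refpos = ref_cols),
            class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat("aligned_family:", length(x$rows), "rows, width", nchar(x$rows[[1]]),
      "| reference", x$reference_id, "(", x$reference_length, "aa )\n")
  invisible(x)
}

#' Read an aligned family from aligned FASTA
#'
#' @param path Aligned FASTA path (gap character `-`).
#' @param reference_id Id of the reference record.
#' @return An [aligned_family()].
#' @export
read_aligned_family <- function(path, reference_id) {
  aligned_family(read_fasta(path), reference_id)
}

#' @rdname read_aligned_family
#' @param family An `aligned_family`.
#' @export
write_aligned_family <- function(family, path) {
  write_fasta(family$rows, path)
}

#' Global-alignment identity and coverage of two sequences
#'
#' Needleman-Wunsch global alignment under a fixed, documented scoring:
#' match +1, mismatch 0, linear gap penalty -1. Among maximum-score
#' alignments, the one with the most identical columns is used. Identity is
#' identical columns divided by all alignment columns (global alignments
#' have no double-gap columns); coverage is the number of residue-residue
#' columns divided by the shorter sequence length.
#'
#' @param seq_a,seq_b Non-empty sequences (character strings).
#' @return Named numeric vector `c(identity =, coverage =)`.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  la <- nchar(seq_a); lb <- nchar(seq_b)
  if (la == 0 || lb == 0) stop("sequences must be non-empty")
  st <- .nw_align_stats(toupper(seq_a), toupper(seq_b))
  score <- st[1]; matches <- st[2]
  gaps <- matches - score
  aligned <- (la + lb - gaps) / 2
  c(identity = matches / (aligned + gaps), coverage = aligned / min(la, lb))
}

#' Greedy dereplication of a sequence set
#'
#' Sequences are scanned by length descending (ties by id ascending); each
#' joins the first existing representative it matches at both thresholds
#' ([pairwise_identity()] identity >= `id_threshold` and coverage >=
#' `cov_threshold`), otherwise it founds a new representative. Defaults are
#' the conventional 0.95 identity / 0.9 coverage used to collapse
#' near-identical homologs before family-level analysis.
#'
#' @param seqs Named character vector of sequences.
#' @param id_threshold,cov_threshold Thresholds in (0, 1].
#' @return List with `representatives` (ids, in founding order) and
#'   `membership` (named character vector: member id -> representative id).
#' @export
dereplicate <- function(seqs, id_threshold = 0.95, cov_threshold = 0.9) {
  stopifnot(id_threshold > 0, id_threshold <= 1,
            cov_threshold > 0, cov_threshold <= 1)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must be uniquely named")
  ord <- order(-nchar(seqs), names(seqs))
  reps <- character(0)
  membership <- stats::setNames(character(length(seqs)), names(seqs)[ord])
  for (id in names(seqs)[ord]) {
    assigned <- NA_character_
    for (r in reps) {
      pi <- pairwise_identity(seqs[[r]], seqs[[id]])
      if (pi[["identity"]] >= id_threshold && pi[["coverage"]] >= cov_threshold) {
        assigned <- r
        break
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, id)
      assigned <- id
    }
    membership[[id]] <- assigned
  }
  list(representatives = reps, membership = membership)
}

#' Per-reference-position identity profile
#'
#' Raw identity at reference position p is the fraction of non-reference
#' rows whose residue in that alignment column equals the reference residue
#' (a gap counts as a mismatch). A centred rolling mean of width `window`
#' is then applied, truncated (not padded) at the ends, so the profile has
#' exactly `reference_length` values.
#'
#' @param family An [aligned_family()].
#' @param window Odd rolling-mean width >= 1 (default 5, the conventional
#'   five-residue smoothing).
#' @return List with `position`, `raw` and `smoothed` numeric vectors of
#'   length `reference_length`.
#' @export
column_identity_profile <- function(family, window = 5) {
  stopifnot(inherits(family, "aligned_family"),
            window >= 1, window %% 2 == 1)
  others <- setdiff(names(family$rows), family$reference_id)
  if (!length(others)) stop("family has no non-reference rows")
  mat <- do.call(rbind, strsplit(family$rows[others], ""))
  ref <- strsplit(family$rows[[family$reference_id]], "")[[1]]
  cols <- family$column_to_refpos
  raw <- colMeans(mat[, cols, drop = FALSE] ==
                    matrix(ref[cols], nrow = length(others),
                           ncol = length(cols), byrow = TRUE))
  L <- family$reference_length
  h <- (window - 1) / 2
  smoothed <- vapply(seq_len(L), function(p)
    mean(raw[max(1, p - h):min(L, p + h)]), numeric(1))
  list(position = seq_len(L), raw = unname(raw), smoothed = smoothed)
}

#' Per-homolog lengths of reference-defined regions
#'
#' For each homolog and region, the length is the number of the homolog's
#' non-gap characters within the alignment columns spanning the region's
#' reference positions (1-based, inclusive).
#'
#' @param family An [aligned_family()].
#' @param regions Data frame with columns `region`, `start`, `end` on the
#'   reference.
#' @return Data frame: homolog_id, region, length.
#' @export
region_lengths <- function(family, regions) {
  stopifnot(inherits(family, "aligned_family"),
            all(c("region", "start", "end") %in% names(regions)))
  if (any(regions$start < 1 | regions$end > family$reference_length |
            regions$start > regions$end))
    stop("regions must lie within [1, reference_length]")
  others <- setdiff(names(family$rows), family$reference_id)
  mat <- do.call(rbind, strsplit(family$rows[others], ""))
  out <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    c1 <- family$column_to_refpos[regions$start[i]]
    c2 <- family$column_to_refpos[regions$end[i]]
    data.frame(homolog_id = others, region = regions$region[i],
               length = as.integer(rowSums(mat[, c1:c2, drop = FALSE] != "-")),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(match(out$homolog_id, others),
                   match(out$region, regions$region)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize transmembrane segments across a family
#'
#' Tallies homologs with 0, 1 or 2+ predicted segments (homologs with no
#' annotation row count as zero) and collects start positions and lengths
#' of first and second segments separately.
#'
#' @param annotations Data frame of segments (homolog_id, start, end;
#'   1-based inclusive), one row per segment.
#' @param family_ids Character vector of all homolog ids in the family.
#' @return List: `percent` (named vector over `"0"`, `"1"`, `"2+"`),
#'   `counts`, `first_tm` and `second_tm` (data frames with homolog_id,
#'   start, length), `n_first`, `n_second`.
#' @export
summarize_tm <- function(annotations, family_ids) {
  if (!all(annotations$homolog_id %in% family_ids))
    stop("annotations cover homologs outside the family")
  key <- paste(annotations$homolog_id, annotations$start, annotations$end)
  if (anyDuplicated(key)) stop("duplicate segment for homolog ",
                               annotations$homolog_id[duplicated(key)][1])
  ann <- annotations[order(annotations$homolog_id, annotations$start), , drop = FALSE]
  ## segments within a homolog must be sorted and non-overlapping
  by_h <- split(ann, ann$homolog_id)
  for (h in names(by_h)) {
    s <- by_h[[h]]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("overlapping segments for homolog ", h)
  }
  n_seg <- stats::setNames(integer(length(family_ids)), family_ids)
  tab <- table(ann$homolog_id)
  n_seg[names(tab)] <- as.integer(tab)
  cat3 <- cut(n_seg, breaks = c(-0.5, 0.5, 1.5, Inf), labels = c("0", "1", "2+"))
  counts <- table(cat3)
  rank_in_h <- unlist(lapply(by_h, function(s) seq_len(nrow(s))), use.names = FALSE)
  ann$rank <- rank_in_h
  seg_df <- function(r) {
    s <- ann[ann$rank == r, , drop = FALSE]
    data.frame(homolog_id = s$homolog_id, start = s$start,
               length = s$end - s$start + 1L, stringsAsFactors = FALSE,
               row.names = NULL)
  }
  first_tm <- seg_df(1L)
  second_tm <- seg_df(2L)
  pct <- stats::setNames(100 * as.numeric(counts) / length(family_ids),
                         names(counts))
  list(percent = pct,
       counts = stats::setNames(as.integer(counts), names(counts)),
       first_tm = first_tm, second_tm = second_tm,
       n_first = nrow(first_tm), n_second = nrow(second_tm))
}

## Kyte-Doolittle hydropathy scale
.KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

#' Sliding-window hydropathy prediction of transmembrane segments
#'
#' Mean Kyte-Doolittle hydropathy over a sliding window; maximal runs of
#' windows whose mean exceeds `threshold` are merged, and each run's full
#' residue span (first window start to last window end) is reported as one
#' segment. The defaults (window 19, threshold 1.6) are the classic
#' membrane-span settings for this scale.
#'
#' @param sequence Protein sequence.
#' @param window Window width in residues.
#' @param threshold Mean-hydropathy cutoff.
#' @return Data frame of segments (start, end; 1-based inclusive), sorted
#'   and non-overlapping; empty when the sequence is shorter than the
#'   window.
#' @export
hydropathy_tm_predict <- function(sequence, window = 19, threshold = 1.6) {
  window <- as.integer(window)
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  if (n < window) return(data.frame(start = integer(0), end = integer(0)))
  h <- unname(.KD_SCALE[chars])
  h[is.na(h)] <- 0  # unknown residues treated as neutral
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 1))
  means <- means[window:n]  # means[k] = mean over positions k..k+window-1
  above <- means > threshold
  if (!any(above)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(above)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts_idx[keep],
             end = ends_idx[keep] + window - 1L)
}

#' Greedy most-common-hit coverage of domain hits
#'
#' After discarding hits with p-value >= `p_cutoff`, iteratively picks the
#' hit present in the most remaining homologs (ties broken by
#' lexicographically smallest hit name), records how many homologs it
#' covers, and removes every homolog containing it, until no annotated
#' homolog remains. Each homolog is therefore counted at most once.
#'
#' @param hits Data frame with columns homolog_id, hit_name, p_value.
#' @param p_cutoff Significance cutoff in (0, 1]; hits with p-value
#'   strictly below it are kept (default 1e-5).
#' @return Data frame with columns hit_name, n_homologs_covered, in
#'   selection order.
#' @export
greedy_hit_cover <- function(hits, p_cutoff = 1e-5) {
  stopifnot(p_cutoff > 0, p_cutoff <= 1)
  sig <- hits[hits$p_value < p_cutoff, , drop = FALSE]
  sig <- unique(sig[c("homolog_id", "hit_name")])
  out_hit <- character(0)
  out_n <- integer(0)
  while (nrow(sig)) {
    tab <- table(sig$hit_name)
    best <- sort(names(tab)[tab == max(tab)])[1]
    covered <- unique(sig$homolog_id[sig$hit_name == best])
    out_hit <- c(out_hit, best)
    out_n <- c(out_n, length(covered))
    sig <- sig[!sig$homolog_id %in% covered, , drop = FALSE]
  }
  data.frame(hit_name = out_hit, n_homologs_covered = out_n,
             stringsAsFactors = FALSE)
}

#' All-vs-all identity matrix
#'
#' Symmetric matrix of [pairwise_identity()] identities, optionally
#' restricted to a reference-independent residue window of each sequence
#' (e.g. a conserved core) before alignment.
#'
#' @param seqs Named character vector of sequences.
#' @param region Optional `c(start, end)` (1-based inclusive) substring
#'   applied to every sequence before comparison; sequences shorter than
#'   `start` are compared in full.
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
identity_matrix <- function(seqs, region = NULL) {
  if (!is.null(region)) {
    stopifnot(length(region) == 2, region[1] >= 1, region[2] >= region[1])
    seqs <- vapply(seqs, function(s)
      if (nchar(s) >= region[1]) substr(s, region[1], min(region[2], nchar(s))) else s,
      character(1))
  }
  n <- length(seqs)
  m <- diag(1, n)
  dimnames(m) <- list(names(seqs), names(seqs))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- pairwise_identity(seqs[[i]], seqs[[j]])[["identity"]]
      }
    }
  }
  m
}

#' Group sequences into clades by pairwise identity
#'
#' Single-linkage components of the graph connecting pairs with identity
#' strictly above `within_threshold`. Cross-clade pairs with identity at or
#' above `between_threshold` are reported as violations and both clades
#' are flagged non-conforming (they are never merged). Defaults (0.90,
#' 0.20) encode the convention that members of a clade share > 90%
#' identity and < 20% identity with anything outside it.
#'
#' @param mat Symmetric identity matrix (e.g. from [identity_matrix()]).
#' @param within_threshold,between_threshold Thresholds with
#'   0 <= between < within <= 1.
#' @return List: `clades` (named integer labels), `violations` (data frame
#'   id_a, id_b, identity), `conforming` (named logical per clade label).
#' @export
clade_grouping <- function(mat, within_threshold = 0.90, between_threshold = 0.20) {
  stopifnot(within_threshold <= 1, between_threshold >= 0,
            between_threshold < within_threshold)
  if (!isTRUE(all.equal(mat, t(mat))))
    stop("identity matrix must be symmetric")
  n <- nrow(mat)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  adj <- mat > within_threshold
  clade <- integer(n)
  label <- 0L
  for (i in seq_len(n)) {
    if (clade[i] != 0L) next
    label <- label + 1L
    queue <- i
    clade[i] <- label
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & clade == 0L)
      clade[nb] <- label
      queue <- c(queue, nb)
    }
  }
  names(clade) <- ids
  pair_i <- integer(0); pair_j <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (clade[i] != clade[j] && mat[i, j] >= between_threshold) {
          pair_i <- c(pair_i, i); pair_j <- c(pair_j, j)
        }
      }
    }
  }
  violations <- data.frame(id_a = ids[pair_i], id_b = ids[pair_j],
                           identity = mat[cbind(pair_i, pair_j)],
                           stringsAsFactors = FALSE)
  conforming <- stats::setNames(rep(TRUE, label), as.character(seq_len(label)))
  bad <- unique(c(clade[pair_i], clade[pair_j]))
  conforming[as.character(bad)] <- FALSE
  list(clades = clade, violations = violations, conforming = conforming)
}
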