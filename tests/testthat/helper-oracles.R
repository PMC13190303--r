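# Independent oracles and small fixture builders shared across tests.

# Exhaustive global-alignment oracle: enumerates every alignment as a path
# of diagonal / gap-in-b / gap-in-a moves and keeps the lexicographic
# maximum of (score, matches, -columns is implied), tracking columns and
# residue-residue pairs explicitly. Scoring: match +1, mismatch 0, gap -1.
# Exponential; only for sequences of length <= 8.
nw_enumerate <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  # state: c(score, matches, columns, aligned_pairs)
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(c(0, 0, 0, 0))
    best <- NULL
    take <- function(st) {
      if (is.null(best) || st[1] > best[1] ||
          (st[1] == best[1] && st[2] > best[2])) best <<- st
    }
    if (i > 0 && j > 0) {
      m <- as.numeric(A[i] == B[j])
      take(rec(i - 1, j - 1) + c(m, m, 1, 1))
    }
    if (i > 0) take(rec(i - 1, j) + c(-1, 0, 1, 0))
    if (j > 0) take(rec(i, j - 1) + c(-1, 0, 1, 0))
    best
  }
  st <- rec(length(A), length(B))
  c(identity = st[2] / st[3],
    coverage = st[4] / min(length(A), length(B)))
}

# Independent greedy hit-cover oracle over per-homolog hit sets.
cover_enumerate <- function(hits, p_cutoff = 1e-5) {
  hits <- hits[hits$p_value < p_cutoff, , drop = FALSE]
  sets <- lapply(split(hits$hit_name, hits$homolog_id), unique)
  res_hit <- character(0)
  res_n <- integer(0)
  while (length(sets)) {
    all_hits <- sort(unique(unlist(sets)))
    cnt <- vapply(all_hits, function(h)
      sum(vapply(sets, function(s) h %in% s, logical(1))), integer(1))
    best <- all_hits[which.max(cnt)]  # sorted, so first max is lexicographic
    res_hit <- c(res_hit, best)
    res_n <- c(res_n, max(cnt))
    sets <- sets[!vapply(sets, function(s) best %in% s, logical(1))]
  }
  data.frame(hit_name = res_hit, n_homologs_covered = res_n,
             stringsAsFactors = FALSE)
}

random_domain_hits <- function(n_homologs, n_hits, seed) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(seq_len(n_homologs), function(h) {
    k <- sample.int(n_hits, 1)
    data.frame(homolog_id = sprintf("H%02d", h),
               hit_name = sprintf("hit%02d", sample.int(n_hits, k)),
               p_value = 10^-stats::runif(k, 2, 9),
               stringsAsFactors = FALSE)
  }))
  rows
}

random_dna <- function(n, len_range = c(1, 8)) {
  vapply(seq_len(n), function(i) {
    L <- sample(len_range[1]:len_range[2], 1)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# Canonical BarSeq read structure used in fixtures.
fixture_read_structure <- function(per_base_error = 0, barcode_length = 12) {
  read_structure(pre_flank = "GATGTCCACGAG", post_flank = "AGAGACCTCGTG",
                 barcode_length = barcode_length,
                 per_base_error = per_base_error)
}

# Gene models tiling most of a small genome, and the derived screen
# conditions used in recovery simulations: 200 genes of 950 bp spaced
# 1 kb over 200 kb, 3000 insertions, two phage-required genes,
# escape rate 1e-3, depths 1e6.
screen_gene_models <- function(n_genes = 200) {
  gene_models(sprintf("g%03d", seq_len(n_genes)),
              start = seq(0, by = 1000, length.out = n_genes),
              end = seq(950, by = 1000, length.out = n_genes))
}

run_recovery_screen <- function(seed, escape_rate = 1e-3,
                                required = c("g010", "g020")) {
  genes <- screen_gene_models()
  pool <- simulate_tn_library(200000, genes, n_insertions = 3000,
                              barcode_length = 20, abundance_dispersion = 1,
                              seed = seed)
  sel <- simulate_selection(pool, selection_model(required, escape_rate, "phage"),
                            depth_control = 1e6, depth_phage = 1e6,
                            seed = seed + 1)
  run_screen(sel$counts, pool, "no_phage", "phage")$phage
}
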