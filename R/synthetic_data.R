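## Synthetic inputs with ground truth: transposon libraries under phage
## selection, BarSeq amplicon reads, spectral-count tables and homolog
## families. Every generator is a pure function of its seed and parameters.

.BASES <- c("A", "C", "G", "T")
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.random_strings <- function(n, len, alphabet) {
  m <- matrix(sample(alphabet, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Gene models for a simulated genome
#'
#' @param gene_id Character vector of gene identifiers.
#' @param start,end 0-based half-open genomic coordinates.
#' @param strand `"+"` or `"-"` (recorded but not used for insertion
#'   assignment, which is purely positional).
#' @return Data frame of validated, non-overlapping gene models sorted by
#'   start.
#' @export
gene_models <- function(gene_id, start, end, strand = "+") {
  df <- data.frame(gene_id = as.character(gene_id), start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(gene_id)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id")
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("gene coordinates must satisfy 0 <= start < end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)]))
    stop("gene models overlap")
  rownames(df) <- NULL
  df
}

#' Phage-selection model
#'
#' Cells carrying a transposon insertion in a gene required for phage
#' infection survive selection; all other cells survive only at a small
#' escape rate.
#'
#' @param required_genes Character vector of phage-required gene ids.
#' @param escape_rate Probability in \[0, 1\] that a cell without a
#'   protective insertion survives phage challenge.
#' @param moi_label Free-text condition name for the phage column.
#' @return A `selection_model` list.
#' @export
selection_model <- function(required_genes, escape_rate, moi_label = "phage") {
  stopifnot(is.numeric(escape_rate), length(escape_rate) == 1,
            escape_rate >= 0, escape_rate <= 1)
  structure(list(required_genes = as.character(required_genes),
                 escape_rate = escape_rate, moi_label = as.character(moi_label)),
            class = "selection_model")
}

#' BarSeq amplicon read structure
#'
#' Reads are `pre_flank + barcode + post_flank`; both flanks anchor barcode
#' extraction.
#'
#' @param pre_flank,post_flank Non-empty, unambiguous (ACGT-only) nucleotide
#'   strings flanking the barcode.
#' @param barcode_length Barcode length in nt (>= 8).
#' @param per_base_error Per-base substitution probability of the simulated
#'   sequencer.
#' @return A `read_structure` list.
#' @export
read_structure <- function(pre_flank, post_flank, barcode_length = 20,
                           per_base_error = 0) {
  pre_flank <- toupper(pre_flank); post_flank <- toupper(post_flank)
  if (!nzchar(pre_flank) || !nzchar(post_flank))
    stop("flanks must be non-empty")
  if (grepl("[^ACGT]", pre_flank) || grepl("[^ACGT]", post_flank))
    stop("flanks must contain only A, C, G, T")
  stopifnot(barcode_length >= 8, per_base_error >= 0, per_base_error < 1)
  structure(list(pre_flank = pre_flank, post_flank = post_flank,
                 barcode_length = as.integer(barcode_length),
                 per_base_error = per_base_error),
            class = "read_structure")
}

#' Simulate a barcoded transposon library
#'
#' Draws `n_insertions` uniform-random insertion sites on a genome, assigns
#' each a unique random barcode and a log-normal pre-selection abundance,
#' and labels each insertion with the gene model containing it (or
#' intergenic, recorded as `NA`).
#'
#' @param genome_length Genome length in bp.
#' @param genes Gene models from [gene_models()], or `NULL` for none.
#' @param n_insertions Number of insertion clones.
#' @param barcode_length Barcode length (nt); barcode uniqueness is enforced
#'   by rejection sampling.
#' @param abundance_dispersion sdlog of the log-normal clone-abundance law
#'   (library skew).
#' @param seed Integer seed; the pool is a pure function of seed and
#'   parameters.
#' @return A barcode-pool data frame (barcode, position, gene_id, abundance);
#'   this table is its own ground truth and is written with [write_pool()].
#' @export
simulate_tn_library <- function(genome_length, genes = NULL, n_insertions,
                                barcode_length = 20, abundance_dispersion = 1,
                                seed) {
  stopifnot(n_insertions >= 1, genome_length >= 1)
  if (barcode_length * log(4) < log(n_insertions))
    stop("barcode space exhausted: 4^", barcode_length, " < ", n_insertions)
  if (!is.null(genes)) {
    if (any(genes$end > genome_length)) stop("gene extends past genome end")
  }
  set.seed(seed)
  barcodes <- .random_strings(n_insertions, barcode_length, .BASES)
  while (anyDuplicated(barcodes)) {
    dup <- duplicated(barcodes)
    barcodes[dup] <- .random_strings(sum(dup), barcode_length, .BASES)
  }
  position <- sample.int(genome_length, n_insertions, replace = TRUE) - 1L
  gene_id <- rep(NA_character_, n_insertions)
  if (!is.null(genes) && nrow(genes)) {
    idx <- findInterval(position, genes$start)
    hit <- idx >= 1 & position < genes$end[pmax(idx, 1L)]
    gene_id[hit] <- genes$gene_id[idx[hit]]
  }
  abundance <- stats::rlnorm(n_insertions, meanlog = 0, sdlog = abundance_dispersion)
  data.frame(barcode = barcodes, position = position, gene_id = gene_id,
             abundance = abundance, stringsAsFactors = FALSE)
}

#' Simulate phage selection and BarSeq sequencing depth
#'
#' The control column is a multinomial draw over pre-selection abundances;
#' the phage column is a multinomial draw over abundances reweighted by
#' survival (weight 1 for insertions in required genes, the escape rate
#' otherwise). Column sums equal the requested depths exactly.
#'
#' @param pool Barcode pool from [simulate_tn_library()].
#' @param model A [selection_model()].
#' @param depth_control,depth_phage Sequencing depths (reads) per condition.
#' @param control_label Condition name for the no-phage column.
#' @param seed Integer seed.
#' @return List with `counts` (a [count_table()]) and `truth` (data frame of
#'   per-barcode survival weights).
#' @export
simulate_selection <- function(pool, model, depth_control = 1e6,
                               depth_phage = 1e6, control_label = "no_phage",
                               seed) {
  stopifnot(inherits(model, "selection_model"),
            depth_control >= 1, depth_phage >= 1)
  bad <- setdiff(model$required_genes, pool$gene_id)
  if (length(bad))
    stop("required genes absent from pool: ", paste(bad, collapse = ", "))
  weight <- ifelse(!is.na(pool$gene_id) & pool$gene_id %in% model$required_genes,
                   1, model$escape_rate)
  w_phage <- pool$abundance * weight
  if (all(w_phage == 0) && depth_phage > 0)
    stop("no surviving population: all survival weights are zero")
  set.seed(seed)
  ctrl <- stats::rmultinom(1, size = depth_control, prob = pool$abundance)[, 1]
  phage <- stats::rmultinom(1, size = depth_phage, prob = w_phage)[, 1]
  m <- cbind(ctrl, phage)
  dimnames(m) <- list(pool$barcode, c(control_label, model$moi_label))
  list(counts = count_table(m),
       truth = data.frame(barcode = pool$barcode, gene_id = pool$gene_id,
                          survival_weight = weight, stringsAsFactors = FALSE))
}

.mutate_bases <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(stats::runif(length(flat)) < rate)
  if (length(hit)) {
    ## substitute with a uniformly chosen *different* base
    shift <- sample.int(3, length(hit), replace = TRUE)
    cur <- match(flat[hit], .BASES)
    flat[hit] <- .BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  grp <- rep.int(seq_along(seqs), lens)
  vapply(split(flat, grp), paste, character(1), collapse = "")
}

#' Emit synthetic BarSeq reads as FASTQ
#'
#' Writes exactly one read per count unit: `pre_flank + barcode +
#' post_flank`, with independent per-base substitution errors at the read
#' structure's rate and a constant placeholder quality.
#'
#' @param counts Named integer vector (barcode -> read count), e.g. one
#'   column of a simulated [count_table()].
#' @param pool Barcode pool; every counted barcode must be present.
#' @param rs A [read_structure()].
#' @param path Output FASTQ path.
#' @param seed Integer seed.
#' @return Invisibly, the number of reads written.
#' @export
emit_barseq_reads <- function(counts, pool, rs, path, seed) {
  stopifnot(inherits(rs, "read_structure"))
  counts <- counts[counts > 0]
  if (length(counts) && !all(names(counts) %in% pool$barcode))
    stop("counted barcodes missing from pool")
  if (length(counts) && any(nchar(names(counts)) != rs$barcode_length))
    stop("barcode length does not match read structure")
  set.seed(seed)
  bcs <- if (length(counts)) rep.int(names(counts), counts) else character(0)
  if (length(bcs)) bcs <- sample(bcs)  # shuffle read order
  reads <- .mutate_bases(paste0(rs$pre_flank, bcs, rs$post_flank,
                                recycle0 = TRUE),
                         rs$per_base_error)
  n <- length(reads)
  dna <- Biostrings::DNAStringSet(if (n) reads else character(0))
  names(dna) <- if (n) sprintf("read_%06d", seq_len(n)) else character(0)
  qual <- Biostrings::PhredQuality(strrep("I", Biostrings::width(dna)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(n)
}

#' Simulate a protein-by-sample spectral-count table
#'
#' Per-protein baseline means are gamma-distributed across proteins (shape
#' `baseline_shape`, mean `baseline_mean`); counts are Poisson draws around
#' the baseline, multiplied by the planted fold change in bait samples.
#'
#' @param n_proteins Number of host background proteins.
#' @param baseline_mean Mean spectral count of the baseline law.
#' @param planted Optional data frame with columns `protein_id`,
#'   `fold_change` (> 0) and optionally `origin`, naming proteins enriched in
#'   bait samples.
#' @param n_bait,n_control Number of bait / control samples (columns are
#'   named `bait`, `control`, or `bait_1`, ... when more than one).
#' @param baseline_shape Gamma shape of the across-protein baseline law.
#' @param seed Integer seed.
#' @return List with `table` (spectral-count data frame) and `truth`
#'   (the planted data frame).
#' @export
simulate_spectral_counts <- function(n_proteins, baseline_mean = 100,
                                     planted = NULL, n_bait = 1, n_control = 1,
                                     baseline_shape = 2, seed) {
  stopifnot(n_proteins >= 1, baseline_mean > 0, n_bait >= 1, n_control >= 1)
  if (!is.null(planted)) {
    stopifnot(all(c("protein_id", "fold_change") %in% names(planted)),
              all(planted$fold_change > 0))
  }
  set.seed(seed)
  ids <- sprintf("P%04d", seq_len(n_proteins))
  origin <- rep("host", n_proteins)
  base <- stats::rgamma(n_proteins, shape = baseline_shape,
                        rate = baseline_shape / baseline_mean)
  fold <- rep(1, n_proteins)
  if (!is.null(planted) && nrow(planted)) {
    idx <- match(planted$protein_id, ids)
    if (anyNA(idx)) stop("planted protein_id not among generated proteins")
    fold[idx] <- planted$fold_change
    if ("origin" %in% names(planted)) origin[idx] <- planted$origin
  }
  sample_names <- function(stem, k) if (k == 1) stem else paste0(stem, "_", seq_len(k))
  samples <- c(sample_names("bait", n_bait), sample_names("control", n_control))
  is_bait <- rep(c(TRUE, FALSE), c(n_bait, n_control))
  m <- vapply(seq_along(samples), function(j) {
    stats::rpois(n_proteins, base * if (is_bait[j]) fold else 1)
  }, numeric(n_proteins))
  colnames(m) <- samples
  tab <- data.frame(protein_id = ids, origin = origin, m,
                    check.names = FALSE, stringsAsFactors = FALSE)
  list(table = tab, truth = if (is.null(planted))
    data.frame(protein_id = character(0), fold_change = numeric(0)) else planted)
}

#' Homolog-family specification
#'
#' Defaults describe a membrane-anchored nuclease family: a 500-residue
#' reference tiled by a poorly conserved N-terminal region (1-190), a
#' moderately conserved DUF4041-like middle domain (191-330) and a highly
#' conserved C-terminal nuclease domain (331-500), with most homologs
#' carrying one N-terminal transmembrane segment and a few carrying two.
#'
#' @param reference_length Reference length (aa).
#' @param region_boundaries Data frame (`region`, `start`, `end`; 1-based
#'   inclusive) tiling `[1, reference_length]` without overlap.
#' @param per_region_substitution_rate Named per-site substitution
#'   probabilities, one per region.
#' @param nterm_length_jitter Maximum N-terminal insertion/deletion length.
#' @param tm_fraction_one,tm_fraction_two Probabilities that a homolog
#'   carries one / two transmembrane segments (sum <= 1).
#' @return A `homolog_family_spec` list.
#' @export
homolog_family_spec <- function(reference_length = 500,
                                region_boundaries = data.frame(
                                  region = c("nterm", "duf4041", "nuclease"),
                                  start = c(1L, 191L, 331L),
                                  end = c(190L, 330L, 500L)),
                                per_region_substitution_rate = c(
                                  nterm = 0.6, duf4041 = 0.3, nuclease = 0.1),
                                nterm_length_jitter = 60,
                                tm_fraction_one = 0.59, tm_fraction_two = 0.07) {
  rb <- region_boundaries[order(region_boundaries$start), , drop = FALSE]
  if (rb$start[1] != 1 || rb$end[nrow(rb)] != reference_length ||
      (nrow(rb) > 1 && any(rb$start[-1] != rb$end[-nrow(rb)] + 1L)))
    stop("regions must tile [1, reference_length] without overlap")
  rates <- per_region_substitution_rate[rb$region]
  if (anyNA(rates) || any(rates < 0 | rates > 1))
    stop("per_region_substitution_rate must name every region with a rate in [0,1]")
  stopifnot(tm_fraction_one >= 0, tm_fraction_two >= 0,
            tm_fraction_one + tm_fraction_two <= 1,
            nterm_length_jitter >= 0, nterm_length_jitter < rb$end[1])
  structure(list(reference_length = as.integer(reference_length),
                 region_boundaries = rb,
                 per_region_substitution_rate = rates,
                 nterm_length_jitter = as.integer(nterm_length_jitter),
                 tm_fraction_one = tm_fraction_one,
                 tm_fraction_two = tm_fraction_two),
            class = "homolog_family_spec")
}

.place_tm_segments <- function(n_seg, seq_len, zone = 70L) {
  if (n_seg == 0) return(data.frame(start = integer(0), end = integer(0)))
  zone <- min(zone, seq_len)
  lens <- sample(10:20, n_seg, replace = TRUE)
  if (n_seg == 1) {
    s1 <- sample.int(max(zone - lens[1] + 1L, 1L), 1)
    return(data.frame(start = s1, end = pmin(s1 + lens[1] - 1L, seq_len)))
  }
  ## two segments, both within the N-terminal zone, separated by >= 1 aa
  top <- max(zone - lens[1] - lens[2] - 1L, 1L)
  s1 <- sample.int(top, 1)
  lo <- s1 + lens[1] + 1L
  hi <- max(zone - lens[2] + 1L, lo)
  s2 <- if (hi > lo) sample(lo:hi, 1) else lo
  data.frame(start = c(s1, s2), end = pmin(c(s1 + lens[1] - 1L, s2 + lens[2] - 1L), seq_len))
}

#' Simulate a homolog family with a known alignment
#'
#' Each homolog is derived from a random reference by per-region
#' substitutions plus one N-terminal indel (extension or truncation of up
#' to `nterm_length_jitter` residues), so the true alignment is induced by
#' construction. Transmembrane segments, when present, are placed within
#' the first 70 residues with lengths drawn from 10-20 aa.
#'
#' @param spec A [homolog_family_spec()].
#' @param n_homologs Number of homologs (>= 2), excluding the reference.
#' @param seed Integer seed.
#' @return List with `sequences` (named ungapped character vector including
#'   the reference), `alignment` (an [aligned_family()]), `region_truth`
#'   (per-homolog true region lengths), `tm_truth` (segment table) and
#'   `reference_id`.
#' @export
simulate_homolog_family <- function(spec, n_homologs, seed) {
  stopifnot(inherits(spec, "homolog_family_spec"), n_homologs >= 2)
  set.seed(seed)
  L <- spec$reference_length
  rb <- spec$region_boundaries
  ref_id <- "reference"
  ref <- sample(.AA20, L, replace = TRUE)
  site_rate <- numeric(L)
  for (i in seq_len(nrow(rb)))
    site_rate[rb$start[i]:rb$end[i]] <- spec$per_region_substitution_rate[i]

  ids <- sprintf("hom_%03d", seq_len(n_homologs))
  jit <- spec$nterm_length_jitter
  core <- matrix("", nrow = n_homologs, ncol = L)  # homolog residues at ref columns
  ins <- vector("list", n_homologs)                # N-terminal extensions
  for (h in seq_len(n_homologs)) {
    row <- ref
    mut <- which(stats::runif(L) < site_rate)
    if (length(mut)) {
      cur <- match(row[mut], .AA20)
      shift <- sample.int(19, length(mut), replace = TRUE)
      row[mut] <- .AA20[((cur - 1L + shift) %% 20L) + 1L]
    }
    j <- if (jit > 0) sample(seq(-jit, jit), 1) else 0L
    if (j < 0) row[seq_len(-j)] <- "-"                       # N-terminal truncation
    ins[[h]] <- if (j > 0) sample(.AA20, j, replace = TRUE) else character(0)
    core[h, ] <- row
  }

  ## Build the induced MSA: reference column 1, then one insertion block
  ## per extended homolog (in homolog order), then reference columns 2..L.
  ## Placing extensions just after the first reference position keeps them
  ## inside the alignment span of the first region.
  ins_len <- lengths(ins)
  total_ins <- sum(ins_len)
  width <- total_ins + L
  aln <- matrix("-", nrow = n_homologs + 1L, ncol = width,
                dimnames = list(c(ref_id, ids), NULL))
  ref_cols <- c(1L, total_ins + 2:L)
  aln[1L, ref_cols] <- ref
  off <- c(1L, 1L + cumsum(ins_len))
  for (h in seq_len(n_homologs)) {
    if (ins_len[h] > 0) aln[h + 1L, off[h] + seq_len(ins_len[h])] <- ins[[h]]
    aln[h + 1L, ref_cols] <- core[h, ]
  }
  rows <- apply(aln, 1, paste, collapse = "")
  fam <- aligned_family(rows, reference_id = ref_id)

  sequences <- vapply(rows, function(s) gsub("-", "", s, fixed = TRUE), character(1))
  names(sequences) <- names(rows)

  ## true region lengths per homolog (N-terminal extension counts toward
  ## the first region, truncation subtracts from it)
  region_truth <- do.call(rbind, lapply(seq_len(n_homologs), function(h) {
    ungapped <- vapply(seq_len(nrow(rb)), function(i)
      sum(core[h, rb$start[i]:rb$end[i]] != "-"), integer(1))
    ungapped[1] <- ungapped[1] + ins_len[h]
    data.frame(homolog_id = ids[h], region = rb$region, length = ungapped,
               stringsAsFactors = FALSE)
  }))

  n_tm <- sample(0:2, n_homologs, replace = TRUE,
                 prob = c(1 - spec$tm_fraction_one - spec$tm_fraction_two,
                          spec$tm_fraction_one, spec$tm_fraction_two))
  tm_truth <- do.call(rbind, lapply(seq_len(n_homologs), function(h) {
    seg <- .place_tm_segments(n_tm[h], nchar(sequences[[ids[h]]]))
    if (!nrow(seg)) return(NULL)
    data.frame(homolog_id = ids[h], start = seg$start, end = seg$end,
               stringsAsFactors = FALSE)
  }))
  if (is.null(tm_truth))
    tm_truth <- data.frame(homolog_id = character(0), start = integer(0),
                           end = integer(0))

  list(sequences = sequences, alignment = fam, region_truth = region_truth,
       tm_truth = tm_truth, reference_id = ref_id)
}
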