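test_that("insertion-to-gene labelling follows gene models positionally", {
  whole <- gene_models("gA", 0, 10000)
  pool <- simulate_tn_library(10000, whole, n_insertions = 10, seed = 7)
  expect_true(all(pool$gene_id == "gA"))

  pool2 <- simulate_tn_library(10000, NULL, n_insertions = 10, seed = 7)
  expect_true(all(is.na(pool2$gene_id)))

  expect_true(all(pool$position >= 0 & pool$position < 10000))
  expect_false(anyDuplicated(pool$barcode) > 0)
})

test_that("library generation is a pure function of seed and parameters", {
  genes <- screen_gene_models(20)
  a <- simulate_tn_library(20000, genes, 100, barcode_length = 20, seed = 11)
  b <- simulate_tn_library(20000, genes, 100, barcode_length = 20, seed = 11)
  expect_identical(a, b)
  c <- simulate_tn_library(20000, genes, 100, barcode_length = 20, seed = 12)
  expect_false(identical(a$barcode, c$barcode))
})

test_that("barcode space exhaustion and overlapping genes are hard errors", {
  expect_error(simulate_tn_library(1000, NULL, 70000, barcode_length = 8, seed = 1),
               "barcode space")
  expect_error(gene_models(c("a", "b"), c(0, 50), c(100, 150)), "overlap")
})

test_that("selection reweights survival and conserves sequencing depth", {
  # one required gene holding 1% of pre-selection abundance, escape 1e-3:
  # expected phage-column share of required barcodes is
  # 0.01 / (0.01 + 0.99 * 1e-3) = 0.909918...
  pool <- data.frame(barcode = sprintf("BC%03d", 1:100),
                     position = seq(0, 990, 10),
                     gene_id = c("gReq", rep(NA, 99)),
                     abundance = c(0.01, rep(0.99 / 99, 99)))
  sel <- simulate_selection(pool, selection_model("gReq", 1e-3, "phage"),
                            depth_control = 1e6, depth_phage = 1e6, seed = 3)
  expect_identical(unname(sel$counts$totals), c(1e6, 1e6))
  p <- 0.01 / (0.01 + 0.99 * 1e-3)
  share <- sel$counts$counts["BC001", "phage"] / 1e6
  expect_lt(abs(share - p), 3 * sqrt(p * (1 - p) / 1e6))
  expect_identical(sel$truth$survival_weight, c(1, rep(1e-3, 99)))

  # zero escape: every nonzero phage count lies in the required gene
  sel0 <- simulate_selection(pool, selection_model("gReq", 0, "phage"),
                             depth_control = 1000, depth_phage = 1000, seed = 4)
  nz <- sel0$counts$counts[, "phage"] > 0
  expect_true(all(pool$gene_id[nz] == "gReq"))

  # no survivors at all is a hard error
  pool_nogene <- transform(pool, gene_id = NA_character_)
  expect_error(simulate_selection(pool_nogene, selection_model(character(0), 0, "p"),
                                  1000, 1000, seed = 5),
               "requir|surviv")
})

test_that("emitted reads carry substitution errors at the stated rate", {
  rs <- fixture_read_structure(per_base_error = 0.01)
  pool <- simulate_tn_library(1000, NULL, 50, barcode_length = 12, seed = 21)
  counts <- stats::setNames(rep(400L, 50), pool$barcode)  # 20k reads
  fq <- withr::local_tempfile(fileext = ".fastq")
  n <- emit_barseq_reads(counts, pool, rs, fq, seed = 22)
  expect_identical(n, 20000L)
  reads <- as.character(Biostrings::readDNAStringSet(fq, format = "fastq"))
  L <- nchar(rs$pre_flank) + 12 + nchar(rs$post_flank)
  clean <- paste0(rs$pre_flank, rep(pool$barcode, each = 400), rs$post_flank)
  # reads are shuffled; compare per-read against all clean templates
  p_err <- 1 - 0.99^L
  frac <- mean(!reads %in% clean)
  expect_lt(abs(frac - p_err), 3 * sqrt(p_err * (1 - p_err) / n))

  # zero counts give an empty but readable FASTQ
  n0 <- emit_barseq_reads(integer(0), pool, rs, fq, seed = 23)
  expect_identical(n0, 0L)
  expect_length(Biostrings::readDNAStringSet(fq, format = "fastq"), 0)
})

test_that("spectral-count simulation plants recoverable fold changes", {
  planted <- data.frame(protein_id = "P0010", fold_change = 16, origin = "phage")
  sim <- simulate_spectral_counts(200, baseline_mean = 100, planted = planted,
                                  seed = 31)
  sim2 <- simulate_spectral_counts(200, baseline_mean = 100, planted = planted,
                                   seed = 31)
  expect_identical(sim, sim2)
  row <- sim$table[sim$table$protein_id == "P0010", ]
  expect_identical(row$origin, "phage")
  ratio <- log2_ratio(row$bait, row$control, 1)
  expect_lt(abs(ratio - 4), 1)  # Poisson concentration at these means
})

test_that("homolog families honour rates, jitter and the induced alignment", {
  flat <- homolog_family_spec(per_region_substitution_rate = c(
    nterm = 0, duf4041 = 0, nuclease = 0), nterm_length_jitter = 0)
  fam0 <- simulate_homolog_family(flat, 5, seed = 41)
  expect_true(all(fam0$sequences == fam0$sequences[["reference"]]))
  prof0 <- column_identity_profile(fam0$alignment)
  expect_true(all(prof0$raw == 1) && all(prof0$smoothed == 1))

  spec <- homolog_family_spec()
  for (s in 1:5) {
    fam <- simulate_homolog_family(spec, 20, seed = 100 + s)
    prof <- column_identity_profile(fam$alignment)
    expect_gt(mean(prof$raw[331:500]), mean(prof$raw[1:190]))
  }

  # truth region lengths equal what region_lengths extracts from the MSA
  fam <- simulate_homolog_family(spec, 15, seed = 55)
  measured <- region_lengths(fam$alignment, spec$region_boundaries)
  truth <- fam$region_truth
  key <- function(d) d[order(d$homolog_id, d$region), "length"]
  expect_identical(key(measured), key(truth))
})

test_that("transmembrane category fractions match the generative fractions", {
  spec <- homolog_family_spec()  # tm fractions 0.59 / 0.07
  fam <- simulate_homolog_family(spec, 800, seed = 61)
  ids <- setdiff(names(fam$sequences), fam$reference_id)
  tm <- summarize_tm(fam$tm_truth, ids)
  expected <- c(`0` = 34, `1` = 59, `2+` = 7)
  for (k in names(expected)) {
    p <- expected[[k]] / 100
    expect_lt(abs(tm$percent[[k]] / 100 - p), 3 * sqrt(p * (1 - p) / 800))
  }
  expect_true(all(fam$tm_truth$end <= 70))
  lens <- fam$tm_truth$end - fam$tm_truth$start + 1
  expect_true(all(lens >= 10 & lens <= 20))
  expect_true(all(fam$tm_truth$start >= 1 & fam$tm_truth$start <= 70))
})
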