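test_that("pairwise identity follows the fixed global-alignment scoring", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"),
               c(identity = 1, coverage = 1))
  expect_equal(pairwise_identity("AAAA", "AATA")[["identity"]], 0.75)
  # prefix: 50 matched + 50 gap columns; coverage against the shorter is 1
  long <- strrep("ACGTA", 20)
  pre <- substr(long, 1, 50)
  pi <- pairwise_identity(long, pre)
  expect_equal(pi[["coverage"]], 1)
  expect_equal(pi[["identity"]], 50 / 100)
  # symmetry
  expect_equal(pairwise_identity("ACGGT", "AGT"), pairwise_identity("AGT", "ACGGT"))
  expect_error(pairwise_identity("", "A"), "non-empty")
})

test_that("identity and coverage agree with exhaustive alignment enumeration", {
  set.seed(101)
  for (i in 1:15) {
    a <- random_dna(1, c(1, 6))
    b <- random_dna(1, c(1, 6))
    expect_equal(pairwise_identity(a, b), nw_enumerate(a, b), tolerance = 1e-12)
  }
})

test_that("greedy dereplication respects identity and coverage thresholds", {
  expect_identical(dereplicate(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))$representatives,
                   "a")

  # constructed pair at 94% identity survives the 0.95/0.9 defaults
  set.seed(102)
  base <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  mut <- base
  for (p in c(5, 20, 35, 50, 65, 80)) {
    cur <- substr(mut, p, p)
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  expect_equal(pairwise_identity(base, mut)[["identity"]], 0.94)
  dr <- dereplicate(c(s1 = base, s2 = mut), 0.95, 0.9)
  expect_length(dr$representatives, 2)

  # every non-representative meets both thresholds against its representative
  fam <- simulate_homolog_family(homolog_family_spec(
    per_region_substitution_rate = c(nterm = 0.3, duf4041 = 0.02, nuclease = 0.02),
    nterm_length_jitter = 10), 12, seed = 103)
  dr2 <- dereplicate(fam$sequences, 0.9, 0.8)
  for (id in names(dr2$membership)) {
    rep_id <- dr2$membership[[id]]
    if (rep_id == id) next
    pi <- pairwise_identity(fam$sequences[[rep_id]], fam$sequences[[id]])
    expect_gte(pi[["identity"]], 0.9)
    expect_gte(pi[["coverage"]], 0.8)
  }
})

test_that("identity profiles match hand-computed toy-MSA values", {
  fam <- aligned_family(c(ref = "ACDEF", h1 = "ACDEF", h2 = "AC-EF",
                          h3 = "AADEF"), reference_id = "ref")
  prof <- column_identity_profile(fam, window = 5)
  expect_equal(prof$raw, c(1, 2/3, 2/3, 1, 1), tolerance = 1e-12)
  # truncated centred windows: mean(raw[max(1,p-2):min(5,p+2)])
  expect_equal(prof$smoothed, c(7/9, 5/6, 13/15, 5/6, 8/9), tolerance = 1e-12)

  same <- aligned_family(c(ref = "MKLV", a = "MKLV", b = "MKLV"), "ref")
  p2 <- column_identity_profile(same, window = 5)
  expect_true(all(p2$raw == 1) && all(p2$smoothed == 1))
  expect_error(column_identity_profile(fam, window = 4), "window")
})

test_that("region lengths count non-gap residues within region spans", {
  regions <- data.frame(region = c("r1", "r2"), start = c(1L, 5L), end = c(4L, 8L))
  flat <- aligned_family(c(ref = "ACDEFGHI", h1 = "ACDEFGHI"), "ref")
  rl <- region_lengths(flat, regions)
  expect_identical(rl$length, c(4L, 4L))

  # a 7-residue insertion between reference positions 2 and 3 extends r1
  ref <- paste0("AC", strrep("-", 7), "DEFGHI")
  h <- paste0("AC", strrep("W", 7), "DEFGHI")
  ins <- aligned_family(c(ref = ref, h1 = h), "ref")
  expect_identical(region_lengths(ins, regions)$length, c(11L, 4L))

  # fully gapped region
  gap <- aligned_family(c(ref = "ACDEFGHI", h1 = "----FGHI"), "ref")
  expect_identical(region_lengths(gap, regions)$length, c(0L, 4L))

  # tiling invariant: lengths sum to the homolog's residues within the
  # reference span
  fam <- simulate_homolog_family(homolog_family_spec(), 10, seed = 104)
  rl2 <- region_lengths(fam$alignment, homolog_family_spec()$region_boundaries)
  per_h <- tapply(rl2$length, rl2$homolog_id, sum)
  cols <- fam$alignment$column_to_refpos
  span <- cols[1]:cols[length(cols)]
  for (id in names(per_h)) {
    chars <- strsplit(fam$alignment$rows[[id]], "")[[1]]
    expect_identical(unname(per_h[[id]]), sum(chars[span] != "-"))
  }
})

test_that("TM summaries tally categories and per-rank segment geometry", {
  ann <- data.frame(homolog_id = c("h2", "h3", "h3"),
                    start = c(5L, 3L, 30L), end = c(23L, 14L, 44L))
  tm <- summarize_tm(ann, c("h1", "h2", "h3"))
  expect_equal(unname(tm$percent), rep(100 / 3, 3), tolerance = 1e-12)
  expect_identical(tm$n_first, 2L)
  expect_identical(tm$n_second, 1L)
  expect_identical(tm$first_tm$length[tm$first_tm$homolog_id == "h2"], 19L)
  expect_identical(tm$second_tm$start, 30L)

  dup <- rbind(ann, ann[1, ])
  expect_error(summarize_tm(dup, c("h1", "h2", "h3")), "duplicate")
  overlap <- data.frame(homolog_id = "h1", start = c(1L, 5L), end = c(10L, 12L))
  expect_error(summarize_tm(overlap, "h1"), "overlap")
})

test_that("hydropathy prediction finds hydrophobic runs and nothing else", {
  seq <- paste0(strrep("D", 10), strrep("I", 19), strrep("D", 10))
  seg <- hydropathy_tm_predict(seq)
  # window means exceed 1.6 only for starts 5..17 (>= 13 of 19 residues
  # inside the I-run), giving one merged span 5..35 that covers the run
  expect_identical(nrow(seg), 1L)
  expect_identical(c(seg$start, seg$end), c(5L, 35L))
  expect_true(seg$start <= 11 && seg$end >= 29)

  expect_identical(nrow(hydropathy_tm_predict(strrep("D", 60))), 0L)
  expect_identical(nrow(hydropathy_tm_predict("MKLV")), 0L)  # shorter than window

  # segments are sorted and non-overlapping by construction
  two <- paste0(strrep("D", 5), strrep("L", 25), strrep("D", 30), strrep("V", 25))
  seg2 <- hydropathy_tm_predict(two)
  expect_gte(nrow(seg2), 2L)
  expect_true(all(diff(seg2$start) > 0))
  expect_true(all(seg2$start[-1] > seg2$end[-nrow(seg2)]))
})

test_that("greedy hit cover matches the independent oracle", {
  toy <- data.frame(homolog_id = c("A", "B", "C"),
                    hit_name = c("h1", "h1", "h2"), p_value = 1e-8)
  expect_identical(greedy_hit_cover(toy),
                   data.frame(hit_name = c("h1", "h2"),
                              n_homologs_covered = c(2L, 1L),
                              stringsAsFactors = FALSE))
  empty <- toy[0, ]
  expect_identical(nrow(greedy_hit_cover(empty)), 0L)
  # the cutoff is strict: p exactly at 1e-5 is not significant
  at_cut <- data.frame(homolog_id = "A", hit_name = "h1", p_value = 1e-5)
  expect_identical(nrow(greedy_hit_cover(at_cut)), 0L)

  for (s in 1:20) {
    hits <- random_domain_hits(sample(3:12, 1), sample(2:6, 1), seed = 200 + s)
    expect_identical(greedy_hit_cover(hits), cover_enumerate(hits))
  }

  # sum of covered homologs never exceeds the number with significant hits
  hits <- random_domain_hits(12, 6, seed = 300)
  cov <- greedy_hit_cover(hits)
  n_sig <- length(unique(hits$homolog_id[hits$p_value < 1e-5]))
  expect_lte(sum(cov$n_homologs_covered), n_sig)
})

test_that("clade grouping separates blocks and flags between-clade leakage", {
  ids <- c("a1", "a2", "a3", "b1", "b2", "c1")
  m <- matrix(0.05, 6, 6, dimnames = list(ids, ids))
  m[1:3, 1:3] <- 0.95
  m[4:5, 4:5] <- 0.93
  diag(m) <- 1
  cg <- clade_grouping(m, 0.90, 0.20)
  expect_identical(unname(cg$clades), c(1L, 1L, 1L, 2L, 2L, 3L))
  expect_identical(nrow(cg$violations), 0L)
  expect_true(all(cg$conforming))

  # a cross-block pair at 0.25 flags both clades without merging them
  m2 <- m
  m2["a1", "b1"] <- m2["b1", "a1"] <- 0.25
  cg2 <- clade_grouping(m2, 0.90, 0.20)
  expect_identical(unname(cg2$clades), c(1L, 1L, 1L, 2L, 2L, 3L))
  expect_identical(nrow(cg2$violations), 1L)
  expect_identical(unname(cg2$conforming), c(FALSE, FALSE, TRUE))

  m3 <- m
  m3[1, 2] <- 0.5
  expect_error(clade_grouping(m3), "symmetric")
})

test_that("identity matrices support region-restricted comparisons", {
  set.seed(105)
  core <- paste(sample(c("A","C","G","T"), 60, replace = TRUE), collapse = "")
  s1 <- paste0(strrep("A", 40), core)
  s2 <- paste0(strrep("C", 40), core)
  full <- identity_matrix(c(x = s1, y = s2))
  regional <- identity_matrix(c(x = s1, y = s2), region = c(41, 100))
  expect_identical(unname(regional["x", "y"]), 1)
  expect_lt(full["x", "y"], 1)
  expect_identical(diag(full), c(x = 1, y = 1))
})
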