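test_that("the synthetic genome is a pure function of its seed", {
  g1 <- simulate_genome(n_chrom = 2, chrom_length = 30000, seed = 7)
  g2 <- simulate_genome(n_chrom = 2, chrom_length = 30000, seed = 7)
  expect_identical(as.character(g1$assembly$sequences),
                   as.character(g2$assembly$sequences))
  g3 <- simulate_genome(n_chrom = 2, chrom_length = 30000, seed = 8)
  expect_false(identical(as.character(g1$assembly$sequences),
                         as.character(g3$assembly$sequences)))
})

test_that("the scanner finds exactly the planted arrays and terminal tracts", {
  g <- simulate_genome(n_chrom = 2, chrom_length = 100000, seed = 7)
  found <- scan_arrays(g$assembly) |>
    classify_arrays(g$assembly$chrom_sizes, terminal_margin = 10000)
  term <- dplyr::filter(found, array_class == "terminal")
  its <- dplyr::filter(found, array_class == "interstitial")
  expect_equal(nrow(term), 4L) # both ends of both chromosomes
  want <- dplyr::arrange(g$its_truth, chrom, start)
  expect_equal(its$chrom, want$chrom)
  expect_equal(its$start, want$start)
  expect_equal(its$end, want$end)
  expect_equal(its$strand, want$strand)
  expect_equal(its$unit_count, want$unit_count)
  wt <- dplyr::arrange(g$terminal_truth, chrom, start)
  expect_equal(dplyr::arrange(term, chrom, start)$start, wt$start)
  expect_equal(dplyr::arrange(term, chrom, start)$end, wt$end)
})

test_that("without terminal tracts only interstitial arrays are found", {
  g <- simulate_genome(n_chrom = 1, chrom_length = 50000,
                       terminal_tract_units = 0, seed = 3)
  found <- scan_arrays(g$assembly) |>
    classify_arrays(g$assembly$chrom_sizes, terminal_margin = 5000)
  expect_true(all(found$array_class == "interstitial"))
  expect_equal(nrow(found), nrow(g$its_truth))
})

test_that("planted degenerate arrays carry the requested mismatches", {
  spec <- tibble::tibble(chrom = "chr1", position_fraction = 0.5,
                         units = 6L, mismatches = 2L)
  g <- simulate_genome(n_chrom = 1, chrom_length = 40000, its_spec = spec,
                       seed = 2)
  # exact scan splits the array at the degenerate units
  exact <- dplyr::filter(scan_arrays(g$assembly),
                         start >= 19000, end <= 21100)
  expect_true(all(exact$unit_count < 6))
  # mismatch-tolerant scan recovers it whole
  fuzzy <- scan_arrays(g$assembly, scan_config(max_mismatches_per_unit = 1))
  hit <- dplyr::filter(fuzzy, start == g$its_truth$start)
  expect_equal(hit$end, g$its_truth$end)
  expect_equal(hit$unit_count, 6L)
  expect_equal(hit$matched_bases, 34L) # 36 bases, 2 planted substitutions
})

test_that("overlapping plant requests are rejected", {
  spec <- tibble::tibble(chrom = "chr1",
                         position_fraction = c(0.5, 0.5001),
                         units = c(10L, 10L), mismatches = 0L)
  expect_error(simulate_genome(n_chrom = 1, chrom_length = 100000,
                               its_spec = spec, seed = 1), "overlapping")
})

test_that("annotations avoid overlaps and honour pinned placements", {
  sizes <- tibble::tibble(chrom = c("chr1", "chr2"), length = 800000L)
  ann <- simulate_annotation(
    sizes, genes_per_chrom = 30,
    placements = tibble::tibble(gene_id = "pinned", chrom = "chr2",
                                distance = 150000L, end = "high",
                                length = 5000L),
    seed = 13)
  g <- ann$genes
  for (ch in unique(g$chrom)) {
    s <- dplyr::arrange(dplyr::filter(g, chrom == ch), start)
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
  d <- distance_to_telomere(g, sizes)
  expect_equal(d$distance_bp[d$gene_id == "pinned"], 150000L)
  expect_equal(d$nearer_end[d$gene_id == "pinned"], "high_coordinate")
  expect_error(
    simulate_annotation(sizes, 5, placements = tibble::tibble(
      gene_id = "bad", chrom = "chr1", distance = 500000L, end = "low",
      length = 5000L), seed = 1),
    "half the chromosome")
})

test_that("peak simulation is deterministic and honours zero counts", {
  sizes <- tibble::tibble(chrom = "chr1", length = 2000000L)
  s1 <- simulate_peaks(sizes, 5, 4, 3, seed = 21)
  s2 <- simulate_peaks(sizes, 5, 4, 3, seed = 21)
  expect_identical(s1$peaks_a, s2$peaks_a)
  expect_identical(s1$peaks_b, s2$peaks_b)
  s0 <- simulate_peaks(sizes, 0, 0, 0, seed = 1)
  expect_equal(nrow(s0$peaks_a), 0L)
  expect_equal(nrow(s0$peaks_b), 0L)
})

test_that("noise-free null tables plant fold 1 everywhere", {
  sim <- simulate_ct_table("null", n_per_group = 4, ct_noise_sd = 0, seed = 5)
  fc <- qpcr_fold_change(sim$table, "GENE1", reference_group = "shScramble")
  expect_equal(fc$summary$fold_change, c(1, 1), tolerance = 1e-12)
  sim2 <- simulate_ct_table("null", n_per_group = 4, ct_noise_sd = 0, seed = 6)
  expect_equal(sim$table$ct, sim2$table$ct) # zero noise: seed-independent
})

test_that("ct tables are deterministic under a seed and structured per group", {
  s1 <- simulate_ct_table("mtdna_shTERF2", n_per_group = 6, seed = 1)
  s2 <- simulate_ct_table("mtdna_shTERF2", n_per_group = 6, seed = 1)
  expect_identical(s1$table, s2$table)
  counts <- dplyr::count(s1$table, group, target)
  expect_true(all(counts$n == 12L)) # 6 samples x 2 technical replicates
})

test_that("the screen fixture regenerates identically and stores its truth", {
  f1 <- simulate_screen_fixture(seed = 5, n_genes = 80, n_candidates = 8)
  f2 <- simulate_screen_fixture(seed = 5, n_genes = 80, n_candidates = 8)
  expect_identical(f1$genes, f2$genes)
  expect_identical(f1$peaks_a, f2$peaks_a)
  expect_identical(f1$its, f2$its)
  expect_identical(f1$candidate_truth, f2$candidate_truth)
  expect_length(f1$candidate_truth, 8L)
  expect_true(all(f1$its$end <= max(f1$chrom_sizes$length)))
  # terminal decoys really fall inside the default terminal margin
  term <- dplyr::filter(f1$its, array_class == "terminal")
  lens <- setNames(f1$chrom_sizes$length, f1$chrom_sizes$chrom)
  expect_true(all(term$start < 10000 | (lens[term$chrom] - term$end) < 10000))
})
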