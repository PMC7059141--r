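test_that("exact tandem arrays are found on both strands with full purity", {
  a <- scan_arrays("TTAGGGTTAGGGTTAGGG")
  expect_equal(nrow(a), 1L)
  expect_equal(a$start, 0L)
  expect_equal(a$end, 18L)
  expect_equal(a$strand, "+")
  expect_equal(a$unit_count, 3L)
  expect_equal(a$purity, 1)

  b <- scan_arrays("CCCTAACCCTAACCCTAA")
  expect_equal(nrow(b), 1L)
  expect_equal(b$strand, "-")
  expect_equal(b$unit_count, 3L)

  expect_equal(nrow(scan_arrays("TTAGGGTTAGGG")), 0L) # below min_units
})

test_that("motif validation rejects non-ACGT characters", {
  expect_error(scan_config(motif = "TTAGGN"), "A, C, G, T")
  expect_error(scan_config(motif = "TTAGG"), "6-mer")
})

test_that("planted arrays in a 10-kb sequence match the enumeration oracle", {
  fx <- make_planted_seq(seed = 101, L = 10000, n_arrays = 7)
  got <- scan_arrays(fx$seq)
  want <- oracle_scan(fx$seq)
  expect_same_arrays(got, want)
  expect_equal(nrow(got), 7L)
})

test_that("scanner equals the oracle on random sequences with plants", {
  for (seed in 1:40) {
    fx <- make_planted_seq(seed, L = 4000, n_arrays = seed %% 5)
    got <- scan_arrays(fx$seq)
    want <- oracle_scan(fx$seq)
    expect_same_arrays(got, want)
  }
})

test_that("degenerate units chain only when anchored by an exact unit", {
  cfg1 <- scan_config(max_mismatches_per_unit = 1)
  # exact-degenerate-exact chain: one array of 3 units, 17/18 bases matched
  s <- paste0("CATCAT", "TTAGGG", "TTCGGG", "TTAGGG", "CATCAT")
  a <- scan_arrays(s, cfg1)
  expect_equal(a$unit_count, 3L)
  expect_equal(a$matched_bases, 17L)
  expect_equal(a$purity, 17 / 18)
  # same sequence, exact mode: no array (run broken by the degenerate unit)
  expect_equal(nrow(scan_arrays(s)), 0L)
  # all-degenerate run: no exact anchor, no array
  s2 <- paste0("CATCAT", strrep("TTCGGG", 4), "CATCAT")
  expect_equal(nrow(scan_arrays(s2, cfg1)), 0L)
})

test_that("mismatch-tolerant scanning matches the oracle", {
  for (seed in 1:15) {
    fx <- make_planted_seq(seed + 500, L = 3000, n_arrays = 4, mismatches = 2)
    cfg <- scan_config(max_mismatches_per_unit = 1)
    got <- scan_arrays(fx$seq, cfg)
    want <- oracle_scan(fx$seq, max_mm = 1)
    expect_same_arrays(got, want)
  }
})

test_that("scanning the reverse complement mirrors coordinates and strands", {
  for (seed in 1:20) {
    fx <- make_planted_seq(seed + 900, L = 3000, n_arrays = 4)
    L <- nchar(fx$seq)
    fwd <- scan_arrays(fx$seq)
    rev <- scan_arrays(revcomp_chr(fx$seq))
    mirrored <- tibble::tibble(
      start = L - rev$end, end = L - rev$start,
      strand = ifelse(rev$strand == "+", "-", "+"),
      unit_count = rev$unit_count
    )
    mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
    expect_equal(fwd$start, mirrored$start)
    expect_equal(fwd$end, mirrored$end)
    expect_equal(fwd$strand, mirrored$strand)
    expect_equal(fwd$unit_count, mirrored$unit_count)
  }
})

test_that("min_units is restrictive and mismatch tolerance is permissive", {
  for (seed in 1:10) {
    fx <- make_planted_seq(seed + 300, L = 3000, n_arrays = 5,
                           unit_range = c(2, 8), mismatches = 1)
    keyset <- function(a) paste(a$start, a$strand)
    loose <- scan_arrays(fx$seq, scan_config(min_units = 2))
    strict <- scan_arrays(fx$seq, scan_config(min_units = 4))
    expect_true(all(keyset(strict) %in% keyset(loose)))
    exact <- scan_arrays(fx$seq)
    fuzzy <- scan_arrays(fx$seq, scan_config(max_mismatches_per_unit = 1))
    # every exact-mode array survives (possibly extended) in fuzzy mode
    covered <- vapply(seq_len(nrow(exact)), function(i) {
      any(fuzzy$strand == exact$strand[i] &
            fuzzy$start <= exact$start[i] & fuzzy$end >= exact$end[i])
    }, logical(1))
    expect_true(all(covered))
  }
})

test_that("reported arrays are pairwise disjoint per strand", {
  for (seed in 1:10) {
    fx <- make_planted_seq(seed + 700, L = 5000, n_arrays = 6,
                           mismatches = 1)
    a <- scan_arrays(fx$seq, scan_config(max_mismatches_per_unit = 1))
    for (st in c("+", "-")) {
      s <- a[a$strand == st, ]
      if (nrow(s) > 1) {
        s <- s[order(s$start), ]
        expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
      }
    }
  }
})

test_that("N bases never match", {
  expect_equal(nrow(scan_arrays("TTAGGGTTAGGGTTANGG")), 0L)
  a <- scan_arrays(paste0("TTAGGGTTAGGGTTAGGG", "N", "TTAGGGTTAGGGTTAGGG"))
  expect_equal(nrow(a), 2L)
})

test_that("terminal classification uses strict margins on both ends", {
  sizes <- tibble::tibble(chrom = "chr1", length = 1000000L)
  arrays <- tibble::tibble(
    chrom = "chr1",
    start = c(0L, 500000L, 980000L, 999970L),
    end = c(30L, 500030L, 990000L, 1000000L),
    strand = "+", unit_count = 5L, matched_bases = 30L, purity = 1
  )
  cl <- classify_arrays(arrays, sizes, terminal_margin = 10000)
  expect_equal(cl$array_class,
               c("terminal", "interstitial", "interstitial", "terminal"))
  # array ending exactly at chrom_length - margin stays interstitial
  edge <- tibble::tibble(chrom = "chr1", start = 989970L, end = 990000L,
                         strand = "+", unit_count = 5L, matched_bases = 30L,
                         purity = 1)
  expect_equal(classify_arrays(edge, sizes, 10000)$array_class, "interstitial")
  expect_error(classify_arrays(dplyr::mutate(edge, chrom = "chrX"), sizes),
               "chrX")
})

test_that("array BED files round-trip and encode unit-count scores", {
  g <- simulate_genome(n_chrom = 2, chrom_length = 30000,
                       terminal_tract_units = 4, seed = 9)
  arrays <- scan_arrays(g$assembly) |>
    classify_arrays(g$assembly$chrom_sizes, terminal_margin = 1000)
  path <- withr::local_tempfile(fileext = ".bed")
  write_arrays_bed(arrays, path)
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "#"))
  score <- as.integer(vapply(strsplit(lines[-1], "\t"), `[`, "", 5))
  expect_equal(score, pmin(1000L, arrays$unit_count * 100L))
  back <- read_arrays_bed(path)
  expect_equal(back$start, arrays$start)
  expect_equal(back$end, arrays$end)
  expect_equal(back$unit_count, arrays$unit_count)
  expect_equal(back$array_class, arrays$array_class)

  empty <- withr::local_tempfile(fileext = ".bed")
  write_arrays_bed(arrays[0, ], empty)
  expect_equal(nrow(read_arrays_bed(empty)), 0L)
})
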