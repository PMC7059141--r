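# Test-side sequence builder, independent of the package's generator:
# plain string surgery over an i.i.d. background. Planted arrays are
# flanked with CATCAT guards so they stay maximal.

make_planted_seq <- function(seed, L = 10000, n_arrays = 5,
                             unit_range = c(3, 9), minus_frac = 0.4,
                             mismatches = 0) {
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  truth <- list()
  if (n_arrays > 0) {
    slot <- L %/% n_arrays
    for (i in seq_len(n_arrays)) {
      u <- sample(unit_range[1]:unit_range[2], 1)
      span <- 6 * u + 12
      if (span + 2 >= slot) next
      pos <- (i - 1) * slot + sample.int(slot - span - 1, 1) # 0-based, guard incl
      strand <- if (runif(1) < minus_frac) "-" else "+"
      unit <- if (strand == "+") "TTAGGG" else "CCCTAA"
      units <- rep(unit, u)
      mm <- min(mismatches, u - 1)
      if (mm > 0) {
        # one substitution per degenerate unit, first unit kept exact
        units[1 + seq_len(mm)] <- if (strand == "+") "TTCGGG" else "CCGTAA"
      }
      arr <- paste(units, collapse = "")
      frag <- paste0("CATCAT", arr, "CATCAT")
      bases[(pos + 1):(pos + nchar(frag))] <- strsplit(frag, "")[[1]]
      truth[[length(truth) + 1]] <- data.frame(
        start = pos + 6, end = pos + 6 + 6 * u, strand = strand,
        unit_count = u, mismatches = mm)
    }
  }
  list(
    seq = paste(bases, collapse = ""),
    truth = if (length(truth)) do.call(rbind, truth) else
      data.frame(start = integer(), end = integer(), strand = character(),
                 unit_count = integer(), mismatches = integer())
  )
}

random_intervals <- function(seed, n, max_pos = 100000, width_range = c(50, 500),
                             chroms = "chr1") {
  set.seed(seed)
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  s <- sample.int(max_pos, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = s, end = s + w
  )
}

expect_same_arrays <- function(got, want_df) {
  got <- got[order(got$start, got$strand), ]
  want_df <- want_df[order(want_df$start, want_df$strand), ]
  expect_equal(nrow(got), nrow(want_df))
  expect_equal(got$start, want_df$start, ignore_attr = TRUE)
  expect_equal(got$end, want_df$end, ignore_attr = TRUE)
  expect_equal(got$strand, want_df$strand, ignore_attr = TRUE)
  expect_equal(got$unit_count, want_df$unit_count, ignore_attr = TRUE)
}
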