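# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no Biostrings, no GenomicRanges): plain character and integer
# arithmetic only.

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chr <- function(s) {
  paste(rev(DNA_COMP[strsplit(s, "")[[1]]]), collapse = "")
}

# Hamming distance of every 6-mer window of `seq` to `motif`; windows are
# 0-based starts 0..L-6. Any non-matching letter (including N) counts.
oracle_window_mismatches <- function(seq, motif) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L < 6) return(integer())
  m <- strsplit(motif, "")[[1]]
  n_win <- L - 5L
  mm <- integer(n_win)
  for (k in 0:5) mm <- mm + as.integer(chars[(1:n_win) + k] != m[k + 1])
  mm
}

# Exhaustive enumeration of maximal repeat arrays on one strand motif,
# walking the sequence base by base: at each unscanned match, extend
# unit-by-unit taking the leftmost next match within the spacer.
oracle_scan_strand <- function(seq, motif, min_units, max_spacer, max_mm) {
  mm <- oracle_window_mismatches(seq, motif)
  is_match <- mm <= max_mm
  n_win <- length(mm)
  out <- list()
  p <- 1L
  while (p <= n_win) {
    if (!is_match[p]) { p <- p + 1L; next }
    units <- p
    end <- p + 6L # one past the array end, 1-based window index space
    repeat {
      nxt <- NA_integer_
      for (s in end:(end + max_spacer)) {
        if (s <= n_win && is_match[s]) { nxt <- s; break }
      }
      if (is.na(nxt)) break
      units <- c(units, nxt)
      end <- nxt + 6L
    }
    if (length(units) >= min_units && any(mm[units] == 0L)) {
      matched <- sum(6L - mm[units])
      out[[length(out) + 1]] <- data.frame(
        start = p - 1L, end = end - 1L, unit_count = length(units),
        matched_bases = matched,
        purity = matched / (end - p))
    }
    # resume at the first window at or beyond the array end
    p <- end
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      unit_count = integer(), matched_bases = integer(),
                      purity = double()))
  }
  do.call(rbind, out)
}

oracle_scan <- function(seq, motif = "TTAGGG", min_units = 3, max_spacer = 0,
                        max_mm = 0) {
  plus <- oracle_scan_strand(seq, motif, min_units, max_spacer, max_mm)
  plus$strand <- rep("+", nrow(plus))
  minus <- oracle_scan_strand(seq, revcomp_chr(motif), min_units, max_spacer,
                              max_mm)
  minus$strand <- rep("-", nrow(minus))
  out <- rbind(plus, minus)
  out[order(out$start, out$strand),
      c("start", "end", "strand", "unit_count", "matched_bases", "purity")]
}

# O(n^2) closure: repeatedly union any two intervals with gap <= max_gap.
oracle_merge <- function(starts, ends, max_gap) {
  repeat {
    n <- length(starts)
    merged <- FALSE
    for (i in seq_len(n)) {
      if (merged) break
      for (j in seq_len(n)) {
        if (i == j) next
        gap <- max(starts[j] - ends[i], starts[i] - ends[j])
        if (gap <= max_gap) {
          s <- min(starts[i], starts[j]); e <- max(ends[i], ends[j])
          keep <- setdiff(seq_len(n), c(i, j))
          starts <- c(starts[keep], s); ends <- c(ends[keep], e)
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  o <- order(starts, ends)
  data.frame(start = starts[o], end = ends[o])
}

# All-pairs gene-feature association by explicit loops.
oracle_associate <- function(genes, features, window) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(features))) {
      if (genes$chrom[i] != features$chrom[j]) next
      gap <- max(0, features$start[j] - genes$end[i],
                 genes$start[i] - features$end[j])
      if (gap <= window) {
        out[[length(out) + 1]] <- data.frame(
          gene_id = genes$gene_id[i], feature_idx = j, distance = gap)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_id = character(), feature_idx = integer(),
                      distance = numeric()))
  }
  do.call(rbind, out)
}

# Screen truth from planted features, by definition and explicit loops.
oracle_candidates <- function(genes, lost, gained, its_interstitial, window,
                              modulated_mode = "union") {
  near <- function(features) {
    unique(oracle_associate(genes, features, window)$gene_id)
  }
  lost_g <- near(lost)
  gained_g <- near(gained)
  its_g <- near(its_interstitial)
  modulated <- if (modulated_mode == "union") union(lost_g, gained_g) else
    intersect(lost_g, gained_g)
  sort(intersect(modulated, its_g))
}

# Spreadsheet-style delta-delta-Ct recomputation with base R only.
oracle_fold_changes <- function(table, target, hkg, reference_group) {
  agg <- aggregate(ct ~ sample_id + group + target, data = table, FUN = mean)
  samples <- unique(agg[, c("sample_id", "group")])
  dct <- vapply(samples$sample_id, function(s) {
    sub <- agg[agg$sample_id == s, ]
    sub$ct[sub$target == target] -
      mean(sub$ct[sub$target %in% hkg])
  }, numeric(1))
  ref <- mean(dct[samples$group == reference_group])
  groups <- unique(samples$group)
  setNames(vapply(groups, function(g) {
    2^-(mean(dct[samples$group == g]) - ref)
  }, numeric(1)), groups)
}
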