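# Internal interval helpers. Every interval tibble in the package carries
# 0-based half-open `start`/`end` columns plus `chrom`; strand is optional
# and "." means unstranded.

check_interval_cols <- function(x, what = "interval table") {
  needed <- c("chrom", "start", "end")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s must have columns %s (missing: %s)",
                  what, paste(needed, collapse = ", "),
                  paste(missing, collapse = ", ")))
  }
  bad <- which(!(x$start < x$end))
  if (length(bad) > 0) {
    abort(sprintf("%s has start >= end at row(s) %s",
                  what, paste(head(bad, 5), collapse = ", ")))
  }
  if (any(x$start < 0)) abort(sprintf("%s has negative start coordinates", what))
  invisible(x)
}

check_chroms_known <- function(x, chrom_sizes, what = "interval table") {
  unknown <- setdiff(unique(x$chrom), chrom_sizes$chrom)
  if (length(unknown) > 0) {
    abort(sprintf("%s refers to chromosome(s) absent from the length table: %s",
                  what, paste(unknown, collapse = ", ")))
  }
  lens <- setNames(chrom_sizes$length, chrom_sizes$chrom)
  over <- which(x$end > lens[x$chrom])
  if (length(over) > 0) {
    abort(sprintf("%s has interval(s) beyond chromosome end at row(s) %s",
                  what, paste(head(over, 5), collapse = ", ")))
  }
  invisible(x)
}

# 0-based half-open tibble -> GRanges (1-based closed). Strand is dropped
# unless keep_strand: peak/gene overlap algebra here is strand-blind.
as_granges <- function(x, keep_strand = FALSE, seqlevels = NULL) {
  strand <- if (keep_strand && "strand" %in% names(x)) {
    s <- x$strand
    s[is.na(s) | s == "."] <- "*"
    s
  } else "*"
  lv <- seqlevels %||% unique(x$chrom)
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = lv),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

sort_intervals <- function(x) arrange(x, .data$chrom, .data$start, .data$end)

# Gap in bp between two half-open intervals on the same chromosome:
# 0 when they overlap or touch, otherwise the number of bases between them.
interval_gap <- function(start1, end1, start2, end2) {
  pmax(0, pmax(start2 - end1, start1 - end2))
}
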