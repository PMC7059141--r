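#' Merge peaks separated by at most a given gap
#'
#' Intervals whose gap is `<= max_gap` bp (0 for touching half-open
#' intervals) are unioned; scores of merged peaks are combined by taking
#' the maximum. Input need not be sorted.
#'
#' @param peaks Peak tibble (`chrom`, `start`, `end`, optional `score`).
#' @param max_gap Maximum gap in bp to bridge (default 0: merge
#'   overlapping or touching peaks only).
#' @return A merged, sorted peak tibble; the `condition` column is carried
#'   through when it is constant.
#' @export
merge_peaks <- function(peaks, max_gap = 0L) {
  if (max_gap < 0) abort("max_gap must be >= 0")
  check_interval_cols(peaks, "peak table")
  if (nrow(peaks) == 0) return(peaks)
  gr <- as_granges(peaks)
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L,
                               with.revmap = TRUE, ignore.strand = TRUE)
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red)
  )
  if ("score" %in% names(peaks)) {
    out$score <- map_dbl_safe(red$revmap, function(i) max(peaks$score[i]))
  }
  cond <- unique(peaks[["condition"]])
  if (length(cond) == 1) out$condition <- cond
  sort_intervals(out)
}

map_dbl_safe <- function(x, f) vapply(x, f, numeric(1))

#' Compare peak sets between two conditions
#'
#' A peak of A is *shared* iff it overlaps at least one peak of B by
#' `>= min_overlap` bp, and vice versa; classification is per whole input
#' peak (peaks are never split). `only_in_a` / `only_in_b` are the
#' condition-specific complements, so `only_in_a` and `shared_a` always
#' partition A.
#'
#' @param a,b Peak tibbles for the two conditions (same assembly).
#' @param min_overlap Minimum overlap in bp to call two peaks shared
#'   (default 1: any overlap).
#' @param labels Length-2 character vector naming the conditions,
#'   defaulting to the peaks' `condition` columns or `c("A", "B")`.
#' @return An object of class `peak_differential`: a list with peak
#'   tibbles `only_in_a`, `only_in_b`, `shared_a`, `shared_b`, the
#'   condition `labels`, and `params`.
#' @export
compare_conditions <- function(a, b, min_overlap = 1L, labels = NULL) {
  if (min_overlap < 1) abort("min_overlap must be >= 1")
  check_interval_cols(a, "peak set A")
  check_interval_cols(b, "peak set B")
  labels <- labels %||% c(
    unique(a[["condition"]]) %||% "A",
    unique(b[["condition"]]) %||% "B"
  )
  lv <- union(unique(a$chrom), unique(b$chrom))
  shared_in <- function(x, y) {
    if (nrow(x) == 0 || nrow(y) == 0) return(logical(nrow(x)))
    hits <- GenomicRanges::findOverlaps(
      as_granges(x, seqlevels = lv), as_granges(y, seqlevels = lv),
      minoverlap = min_overlap, ignore.strand = TRUE)
    seq_len(nrow(x)) %in% S4Vectors::queryHits(hits)
  }
  in_b <- shared_in(a, b)
  in_a <- shared_in(b, a)
  structure(
    list(
      only_in_a = a[!in_b, , drop = FALSE],
      only_in_b = b[!in_a, , drop = FALSE],
      shared_a = a[in_b, , drop = FALSE],
      shared_b = b[in_a, , drop = FALSE],
      labels = labels,
      params = list(min_overlap = as.integer(min_overlap))
    ),
    class = "peak_differential"
  )
}

#' @export
print.peak_differential <- function(x, ...) {
  cat(sprintf("<peak_differential> %s vs %s (min_overlap = %d bp)\n",
              x$labels[1], x$labels[2], x$params$min_overlap))
  cat(sprintf("  only in %s: %d   only in %s: %d   shared: %d / %d\n",
              x$labels[1], nrow(x$only_in_a), x$labels[2], nrow(x$only_in_b),
              nrow(x$shared_a), nrow(x$shared_b)))
  invisible(x)
}

#' Label condition-specific peaks as lost or gained
#'
#' With A declared as the control (e.g. a scrambled-shRNA condition) and B
#' as the factor-overexpressing condition, peaks found only in A are
#' *lost* upon overexpression and peaks found only in B are *gained*. The
#' orientation is never inferred: the caller states it.
#'
#' @param diff A [compare_conditions()] result.
#' @param a_is_control Logical; if `FALSE` the roles are swapped.
#' @return A list with peak tibbles `lost` and `gained`; each carries a
#'   `modulation` column and the originating condition label.
#' @export
label_modulated <- function(diff, a_is_control = TRUE) {
  stopifnot(inherits(diff, "peak_differential"))
  lost <- if (a_is_control) diff$only_in_a else diff$only_in_b
  gained <- if (a_is_control) diff$only_in_b else diff$only_in_a
  lab <- if (a_is_control) diff$labels else rev(diff$labels)
  lost$modulation <- rep("lost", nrow(lost))
  gained$modulation <- rep("gained", nrow(gained))
  list(lost = lost, gained = gained,
       control = lab[1], treatment = lab[2])
}

#' @method tidy peak_differential
#' @export
tidy.peak_differential <- function(x, ...) {
  bind_rows(
    mutate(x$only_in_a, category = "only_in_a", condition = x$labels[1]),
    mutate(x$only_in_b, category = "only_in_b", condition = x$labels[2]),
    mutate(x$shared_a, category = "shared_a", condition = x$labels[1]),
    mutate(x$shared_b, category = "shared_b", condition = x$labels[2])
  ) |> as_tibble()
}

#' @method glance peak_differential
#' @export
glance.peak_differential <- function(x, ...) {
  tibble(
    condition_a = x$labels[1], condition_b = x$labels[2],
    n_a = nrow(x$only_in_a) + nrow(x$shared_a),
    n_b = nrow(x$only_in_b) + nrow(x$shared_b),
    n_only_a = nrow(x$only_in_a), n_only_b = nrow(x$only_in_b),
    n_shared_a = nrow(x$shared_a), n_shared_b = nrow(x$shared_b),
    min_overlap = x$params$min_overlap
  )
}

#' Plot the composition of a differential peak comparison
#' @param object A `peak_differential` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot peak_differential
#' @export
autoplot.peak_differential <- function(object, ...) {
  d <- tibble(
    category = factor(
      c("only_in_a", "shared_a", "shared_b", "only_in_b"),
      levels = c("only_in_a", "shared_a", "shared_b", "only_in_b")),
    n = c(nrow(object$only_in_a), nrow(object$shared_a),
          nrow(object$shared_b), nrow(object$only_in_b))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "peaks",
      title = sprintf("%s vs %s", object$labels[1], object$labels[2])) +
    ggplot2::theme_minimal()
}
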