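#' Associate genomic features to genes within a distance window
#'
#' A gene is associated to a feature iff the gap between the gene body
#' interval and the feature interval is `<= window` bp; the gap is 0 when
#' they overlap or touch. The comparison is inclusive: a feature exactly
#' `window` bp away is retained, one at `window + 1` is not. One record is
#' produced per (gene, feature) pair.
#'
#' Distances are measured between whole intervals (gene body to feature),
#' not TSS to summit; set `anchor = "tss"` to measure from the gene's
#' transcription start (strand-aware 1-bp anchor) instead.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`, optional
#'   `gene_name`, `strand`).
#' @param features Feature tibble (`chrom`, `start`, `end`, optional
#'   `name`).
#' @param window Maximum gap in bp (default 100,000).
#' @param kind Label stored in `feature_kind` (e.g. `"peak_lost"`,
#'   `"peak_gained"`, `"its"`).
#' @param anchor `"body"` (default) or `"tss"`.
#' @return A tibble with one row per associated (gene, feature) pair:
#'   `gene_id`, `gene_name`, `feature_id`, `feature_kind`, `chrom`,
#'   `feature_start`, `feature_end`, `distance`.
#' @export
associate_features <- function(genes, features, window = 100000L,
                               kind = "feature", anchor = c("body", "tss")) {
  if (window < 0) abort("window must be >= 0")
  anchor <- match.arg(anchor)
  check_interval_cols(genes, "gene table")
  check_interval_cols(features, "feature table")
  empty <- tibble(gene_id = character(), gene_name = character(),
                  feature_id = character(), feature_kind = character(),
                  chrom = character(), feature_start = integer(),
                  feature_end = integer(), distance = integer())
  if (nrow(genes) == 0 || nrow(features) == 0) return(empty)

  g <- genes
  if (anchor == "tss") {
    tss <- if_else(!is.na(g$strand) & g$strand == "-", g$end - 1L, g$start)
    g$start <- tss
    g$end <- tss + 1L
  }
  feature_id <- features[["name"]] %||% sprintf("%s_%d", kind, seq_len(nrow(features)))
  lv <- union(unique(g$chrom), unique(features$chrom))
  # maxgap + 1 then exact arithmetic: the filter below, not findOverlaps'
  # boundary semantics, decides inclusion at exactly `window`.
  hits <- GenomicRanges::findOverlaps(
    as_granges(g, seqlevels = lv), as_granges(features, seqlevels = lv),
    maxgap = window + 1L, ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  gap <- interval_gap(g$start[qi], g$end[qi],
                      features$start[si], features$end[si])
  keep <- gap <= window
  if (!any(keep)) return(empty)
  qi <- qi[keep]; si <- si[keep]; gap <- gap[keep]
  gene_name <- genes[["gene_name"]] %||% genes$gene_id
  tibble(
    gene_id = genes$gene_id[qi],
    gene_name = gene_name[qi],
    feature_id = feature_id[si],
    feature_kind = kind,
    chrom = features$chrom[si],
    feature_start = features$start[si],
    feature_end = features$end[si],
    distance = as.integer(gap)
  ) |> arrange(.data$gene_id, .data$distance, .data$feature_start)
}

#' Gene IDs associated to any feature
#' @param associations Output of [associate_features()].
#' @return Character vector of unique gene IDs, sorted.
#' @export
associated_genes <- function(associations) {
  sort(unique(associations$gene_id))
}

#' Distance from each gene to the closest telomere
#'
#' The closest telomere is the nearer chromosome end of the assembly
#' sequence: `distance_bp = min(gene_start, chrom_length - gene_end)`.
#' Ties report the low-coordinate end, which is the p-arm side in standard
#' human and mouse assemblies; for scaffolds or acrocentric chromosomes
#' the assembly-end interpretation is all that is available.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param chrom_sizes Chromosome-length tibble (`chrom`, `length`).
#' @return A tibble with `gene_id`, `chrom`, `distance_bp`, `nearer_end`
#'   (`"low_coordinate"` or `"high_coordinate"`).
#' @examples
#' genes <- tibble::tibble(gene_id = "g1", chrom = "chr1",
#'                         start = 100L, end = 200L)
#' sizes <- tibble::tibble(chrom = "chr1", length = 1000000L)
#' distance_to_telomere(genes, sizes)
#' @export
distance_to_telomere <- function(genes, chrom_sizes) {
  check_interval_cols(genes, "gene table")
  check_chroms_known(genes, chrom_sizes, "gene table")
  genes |>
    left_join(chrom_sizes, by = "chrom") |>
    mutate(
      dist_low = .data$start,
      dist_high = .data$length - .data$end,
      distance_bp = pmin(.data$dist_low, .data$dist_high),
      nearer_end = if_else(.data$dist_low <= .data$dist_high,
                           "low_coordinate", "high_coordinate")
    ) |>
    select("gene_id", "chrom", "distance_bp", "nearer_end")
}
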