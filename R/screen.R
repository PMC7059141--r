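#' Venn region counts for three gene sets
#'
#' Region order is fixed: lost-only, gained-only, its-only,
#' lost-and-gained-only, lost-and-its-only, gained-and-its-only, all three.
#' The seven counts partition the union of the three sets.
#'
#' @param lost,gained,its Character vectors of gene IDs.
#' @return A named integer vector of length 7.
#' @examples
#' venn_regions(c("a", "b"), c("b", "c"), c("c", "a"))
#' @export
venn_regions <- function(lost, gained, its) {
  lost <- unique(lost); gained <- unique(gained); its <- unique(its)
  all_ids <- union(union(lost, gained), its)
  in_l <- all_ids %in% lost
  in_g <- all_ids %in% gained
  in_i <- all_ids %in% its
  c(
    lost_only = sum(in_l & !in_g & !in_i),
    gained_only = sum(!in_l & in_g & !in_i),
    its_only = sum(!in_l & !in_g & in_i),
    lost_gained = sum(in_l & in_g & !in_i),
    lost_its = sum(in_l & !in_g & in_i),
    gained_its = sum(!in_l & in_g & in_i),
    lost_gained_its = sum(in_l & in_g & in_i)
  )
}

#' Run the subtelomeric candidate gene screen
#'
#' Reproduces the intersection logic of a three-way Venn screen: genes
#' within `window` bp of a lost peak, genes within `window` bp of a gained
#' peak, and genes within `window` bp of an interstitial telomeric
#' sequence, each produced by [associate_features()] with the same window.
#' The final candidates are the modulated genes (union or intersection of
#' the lost and gained gene sets, per `modulated_mode`) that also carry at
#' least one ITS association.
#'
#' @param lost,gained Peak tibbles of condition-specific peaks (see
#'   [label_modulated()]).
#' @param its Tibble of repeat arrays with an `array_class` column; every
#'   row must be classified `interstitial` (run [classify_arrays()] first
#'   — passing terminal tracts is an error, not a silent filter).
#' @param genes Gene tibble.
#' @param window Association window in bp (default 100,000, inclusive).
#' @param modulated_mode `"union"` (default: modulated = lost-genes OR
#'   gained-genes) or `"intersection"`.
#' @param anchor Passed to [associate_features()].
#' @return An object of class `candidate_screen`: gene-ID sets
#'   (`lost_genes`, `gained_genes`, `its_genes`, `modulated_genes`,
#'   `final_candidates`), `venn_counts`, the full `associations` table,
#'   a per-candidate `candidates` evidence tibble, and `params`.
#' @export
run_screen <- function(lost, gained, its, genes, window = 100000L,
                       modulated_mode = c("union", "intersection"),
                       anchor = c("body", "tss")) {
  modulated_mode <- match.arg(modulated_mode)
  anchor <- match.arg(anchor)
  if (!"array_class" %in% names(its)) {
    abort("its must carry an array_class column; run classify_arrays() first")
  }
  n_term <- sum(its$array_class != "interstitial")
  if (n_term > 0) {
    abort(sprintf(
      "%d non-interstitial array(s) in its input; filter to array_class == 'interstitial' first",
      n_term))
  }
  assoc <- bind_rows(
    associate_features(genes, lost, window, kind = "peak_lost", anchor = anchor),
    associate_features(genes, gained, window, kind = "peak_gained", anchor = anchor),
    associate_features(genes, its, window, kind = "its", anchor = anchor)
  )
  set_of <- function(k) {
    sort(unique(assoc$gene_id[assoc$feature_kind == k]))
  }
  lost_genes <- set_of("peak_lost")
  gained_genes <- set_of("peak_gained")
  its_genes <- set_of("its")
  modulated_genes <- if (modulated_mode == "union") {
    sort(union(lost_genes, gained_genes))
  } else {
    sort(intersect(lost_genes, gained_genes))
  }
  final_candidates <- sort(intersect(modulated_genes, its_genes))
  candidates <- assoc |>
    filter(.data$gene_id %in% final_candidates) |>
    arrange(.data$gene_id, .data$feature_kind, .data$distance)
  structure(
    list(
      lost_genes = lost_genes,
      gained_genes = gained_genes,
      its_genes = its_genes,
      modulated_genes = modulated_genes,
      final_candidates = final_candidates,
      venn_counts = venn_regions(lost_genes, gained_genes, its_genes),
      associations = assoc,
      candidates = candidates,
      params = list(window = as.integer(window),
                    modulated_mode = modulated_mode, anchor = anchor)
    ),
    class = "candidate_screen"
  )
}

#' Venn region counts of a screen
#' @param x A `candidate_screen` object.
#' @return Named integer vector of the seven region counts (see
#'   [venn_regions()] for the order).
#' @export
venn_counts <- function(x) {
  stopifnot(inherits(x, "candidate_screen"))
  x$venn_counts
}

#' @export
print.candidate_screen <- function(x, ...) {
  cat(sprintf(
    "<candidate_screen> window = %s bp, modulated = %s\n",
    format(x$params$window, big.mark = ","), x$params$modulated_mode))
  cat(sprintf("  lost genes: %d   gained genes: %d   ITS genes: %d\n",
              length(x$lost_genes), length(x$gained_genes), length(x$its_genes)))
  cat(sprintf("  final candidates (modulated AND >=1 ITS): %d\n",
              length(x$final_candidates)))
  invisible(x)
}

#' @method tidy candidate_screen
#' @export
tidy.candidate_screen <- function(x, ...) {
  as_tibble(x$candidates)
}

#' @method glance candidate_screen
#' @export
glance.candidate_screen <- function(x, ...) {
  vc <- x$venn_counts
  tibble(
    n_lost_genes = length(x$lost_genes),
    n_gained_genes = length(x$gained_genes),
    n_its_genes = length(x$its_genes),
    n_modulated_genes = length(x$modulated_genes),
    n_final_candidates = length(x$final_candidates),
    window = x$params$window,
    modulated_mode = x$params$modulated_mode,
    !!!as.list(vc)
  )
}

#' Bar chart of the seven Venn regions of a screen
#' @param object A `candidate_screen` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot candidate_screen
#' @export
autoplot.candidate_screen <- function(object, ...) {
  vc <- object$venn_counts
  d <- tibble(region = factor(names(vc), levels = names(vc)),
              n = as.integer(vc))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "genes",
                  title = sprintf("Candidate screen: %d final candidates",
                                  length(object$final_candidates))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Write a candidate screen report (TSV plus JSON sidecar)
#'
#' The TSV holds one row per (candidate gene, supporting feature) pair with
#' distances, headed by `#`-prefixed metadata lines. The JSON sidecar
#' (`<path>.json`) records parameters, gene-set sizes, Venn counts and
#' optional input provenance, enough to re-derive the report.
#'
#' @param x A `candidate_screen` object.
#' @param path Output TSV path; the sidecar goes to `paste0(path, ".json")`.
#' @param provenance Optional named list recorded verbatim in the sidecar
#'   (e.g. input paths and hashes, assembly/annotation identifiers).
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, provenance = NULL) {
  stopifnot(inherits(x, "candidate_screen"))
  header <- c(
    sprintf("# subteloscreen candidate report (v%s)",
            as.character(packageVersion("subteloscreen"))),
    sprintf("# window=%d modulated_mode=%s anchor=%s", x$params$window,
            x$params$modulated_mode, x$params$anchor),
    sprintf("# final_candidates=%d", length(x$final_candidates)),
    paste0("# ", paste(names(x$candidates), collapse = "\t"))
  )
  body <- do.call(paste, c(lapply(x$candidates, as.character), sep = "\t"))
  writeLines(c(header, body), path)
  sidecar <- list(
    tool = "subteloscreen",
    version = as.character(packageVersion("subteloscreen")),
    params = x$params,
    counts = list(
      lost_genes = length(x$lost_genes),
      gained_genes = length(x$gained_genes),
      its_genes = length(x$its_genes),
      modulated_genes = length(x$modulated_genes),
      final_candidates = length(x$final_candidates)
    ),
    venn_counts = as.list(x$venn_counts),
    final_candidates = x$final_candidates,
    provenance = provenance
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read back the candidate rows of a report written by [write_report()]
#' @param path TSV path.
#' @return Tibble of candidate evidence rows.
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  cols <- strsplit(sub("^# ", "", tail(lines[grepl("^# ", lines)], 1)),
                   "\t", fixed = TRUE)[[1]]
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) {
    out <- as_tibble(setNames(rep(list(character()), length(cols)), cols))
  } else {
    f <- strsplit(body, "\t", fixed = TRUE)
    out <- as_tibble(setNames(
      lapply(seq_along(cols), function(j) map_chr(f, j)), cols))
  }
  for (col in intersect(c("feature_start", "feature_end", "distance"), names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  out
}
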