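#' Run the full candidate screen from a configuration
#'
#' Executes scan (or ITS-BED load) → classify → differential peak
#' comparison → association → screen → report in one call. All inputs are
#' validated before any stage runs, outputs are written to a staging
#' directory and moved into place only on success (no partial outputs),
#' and a run manifest with input content hashes is emitted so identical
#' configuration plus identical inputs reproduce identical outputs.
#'
#' Configuration keys (a named list, or a YAML file path):
#' \describe{
#'   \item{genes}{Gene annotation GTF path (required).}
#'   \item{peaks_a, peaks_b}{Peak files for the two conditions (required).}
#'   \item{condition_a, condition_b}{Condition labels; `condition_a` is the
#'     control — never inferred (required).}
#'   \item{fasta}{Genome FASTA to scan for telomeric arrays; or}
#'   \item{its_bed}{Precomputed array BED (as written by
#'     [write_arrays_bed()]); scanning is skipped. Exactly one of `fasta` /
#'     `its_bed` is required.}
#'   \item{chrom_sizes}{Chromosome-size TSV; required with `its_bed` when
#'     the BED is unclassified, optional with `fasta` (derived).}
#'   \item{window}{Association window in bp (default 100000).}
#'   \item{modulated_mode}{`union` (default) or `intersection`.}
#'   \item{min_overlap}{Shared-peak overlap in bp (default 1).}
#'   \item{motif, min_units, max_spacer, max_mismatches_per_unit,
#'     terminal_margin}{Scanner settings (see [scan_config()]).}
#'   \item{assembly_name, annotation_name}{Free-text build identifiers
#'     recorded in the manifest; the pipeline never assumes a build.}
#' }
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Output directory (created if needed). Writes `its.bed`,
#'   `lost.bed`, `gained.bed`, `shared_a.bed`, `shared_b.bed`,
#'   `report.tsv`, `report.tsv.json`, and `manifest.json`.
#' @return The `candidate_screen` object, invisibly, with the manifest
#'   attached as attribute `"manifest"`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a named list or a YAML file path")

  required <- c("genes", "peaks_a", "peaks_b", "condition_a", "condition_b")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    abort(sprintf("config is missing required key(s): %s",
                  paste(missing, collapse = ", ")))
  }
  has_fasta <- !is.null(config$fasta)
  has_its <- !is.null(config$its_bed)
  if (has_fasta == has_its) {
    abort("config must set exactly one of: fasta, its_bed")
  }
  input_keys <- c("genes", "peaks_a", "peaks_b",
                  if (has_fasta) "fasta" else "its_bed",
                  if (!is.null(config$chrom_sizes)) "chrom_sizes")
  input_paths <- unlist(config[input_keys])
  absent <- input_paths[!file.exists(input_paths)]
  if (length(absent) > 0) {
    abort(sprintf("input file(s) not found: %s", paste(absent, collapse = ", ")))
  }

  cfg <- scan_config(
    motif = config$motif %||% "TTAGGG",
    min_units = config$min_units %||% 3L,
    max_spacer = config$max_spacer %||% 0L,
    max_mismatches_per_unit = config$max_mismatches_per_unit %||% 0L,
    terminal_margin = config$terminal_margin %||% 10000L
  )
  window <- as.integer(config$window %||% 100000L)
  modulated_mode <- config$modulated_mode %||% "union"
  min_overlap <- as.integer(config$min_overlap %||% 1L)

  stage_msg <- function(stage, detail) {
    message(sprintf("[subteloscreen] %-12s %s", stage, detail))
  }

  stage_msg("genes", config$genes)
  genes <- read_gtf_genes(config$genes)

  chrom_sizes <- if (!is.null(config$chrom_sizes)) {
    read_chrom_sizes(config$chrom_sizes)
  } else NULL

  if (has_fasta) {
    stage_msg("scan", config$fasta)
    assembly <- read_fasta(config$fasta)
    chrom_sizes <- chrom_sizes %||% assembly$chrom_sizes
    arrays <- scan_arrays(assembly, cfg) |>
      classify_arrays(chrom_sizes, config = cfg)
  } else {
    stage_msg("its", config$its_bed)
    arrays <- read_arrays_bed(config$its_bed)
    if (all(arrays$array_class == "unclassified")) {
      if (is.null(chrom_sizes)) {
        abort("unclassified its_bed requires a chrom_sizes table")
      }
      arrays <- classify_arrays(select(arrays, -"array_class"),
                                chrom_sizes, config = cfg)
    }
  }
  its <- filter(arrays, .data$array_class == "interstitial")
  stage_msg("its", sprintf("%d interstitial / %d total arrays",
                           nrow(its), nrow(arrays)))

  peaks_a <- read_peaks(config$peaks_a, chrom_sizes = chrom_sizes,
                        condition = config$condition_a)
  peaks_b <- read_peaks(config$peaks_b, chrom_sizes = chrom_sizes,
                        condition = config$condition_b)
  diff <- compare_conditions(peaks_a, peaks_b, min_overlap = min_overlap,
                             labels = c(config$condition_a, config$condition_b))
  mod <- label_modulated(diff, a_is_control = TRUE)
  stage_msg("diff", sprintf("lost %d, gained %d, shared %d",
                            nrow(mod$lost), nrow(mod$gained),
                            nrow(diff$shared_a)))

  screen <- run_screen(mod$lost, mod$gained, its, genes, window = window,
                       modulated_mode = modulated_mode)
  stage_msg("screen", sprintf("%d final candidates",
                              length(screen$final_candidates)))

  manifest <- list(
    tool = "subteloscreen",
    version = as.character(packageVersion("subteloscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = list(window = window, modulated_mode = modulated_mode,
                  min_overlap = min_overlap,
                  scan = unclass(cfg),
                  condition_a = config$condition_a,
                  condition_b = config$condition_b,
                  assembly_name = config$assembly_name %||% "unspecified",
                  annotation_name = config$annotation_name %||% "unspecified"),
    inputs = lapply(setNames(input_paths, input_keys), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )

  # stage outputs, then move into place atomically-enough on success
  staging <- tempfile("subteloscreen_stage_")
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  write_arrays_bed(arrays, file.path(staging, "its.bed"))
  write_peaks(mod$lost, file.path(staging, "lost.bed"), format = "bed")
  write_peaks(mod$gained, file.path(staging, "gained.bed"), format = "bed")
  write_peaks(diff$shared_a, file.path(staging, "shared_a.bed"), format = "bed")
  write_peaks(diff$shared_b, file.path(staging, "shared_b.bed"), format = "bed")
  write_report(screen, file.path(staging, "report.tsv"),
               provenance = manifest$inputs)
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (f in list.files(staging)) {
    file.copy(file.path(staging, f), file.path(out_dir, f), overwrite = TRUE)
  }
  attr(screen, "manifest") <- manifest
  invisible(screen)
}
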