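#' Read a multi-record FASTA file into a genome assembly
#'
#' Sequences are uppercased on read; soft-masked (lowercase) stretches are
#' preserved as a table of masked intervals so downstream scanners can decide
#' how to treat them. A chromosome-length table is derived from the records.
#' Record names are truncated at the first whitespace, as is conventional.
#'
#' @param path Path to a FASTA file (plain text, multi-record allowed).
#' @return An object of class `genome_assembly`: a list with
#'   * `sequences` — a [Biostrings::DNAStringSet] of uppercase sequences,
#'   * `chrom_sizes` — a tibble with columns `chrom`, `length`,
#'   * `softmask` — a tibble of 0-based half-open soft-masked intervals.
#' @examples
#' g <- simulate_genome(n_chrom = 1, chrom_length = 5000, seed = 1)
#' fa <- tempfile(fileext = ".fa")
#' write_fasta(g$assembly, fa)
#' read_fasta(fa)$chrom_sizes
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) abort(sprintf("FASTA file has no records: %s", path))
  nm <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nm)) {
    abort(sprintf("duplicate FASTA record name(s): %s",
                  paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  chars <- as.character(raw)
  softmask <- map(seq_along(chars), function(i) {
    m <- gregexpr("[a-z]+", chars[[i]])[[1]]
    if (m[1] == -1) return(NULL)
    tibble(chrom = nm[i], start = as.integer(m) - 1L,
           end = as.integer(m) + attr(m, "match.length") - 1L)
  }) |> list_rbind()
  if (nrow(softmask) == 0) {
    softmask <- tibble(chrom = character(), start = integer(), end = integer())
  }
  seqs <- Biostrings::DNAStringSet(toupper(chars))
  names(seqs) <- nm
  structure(
    list(
      sequences = seqs,
      chrom_sizes = tibble(chrom = nm, length = Biostrings::width(seqs)),
      softmask = softmask
    ),
    class = "genome_assembly"
  )
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %d sequence(s), %s bp total\n",
              nrow(x$chrom_sizes),
              format(sum(x$chrom_sizes$length), big.mark = ",")))
  print(x$chrom_sizes, n = 10)
  invisible(x)
}

#' Write a genome assembly (or named sequences) to FASTA
#'
#' @param x A `genome_assembly`, a [Biostrings::DNAStringSet], or a named
#'   character vector of sequences.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  seqs <- if (inherits(x, "genome_assembly")) x$sequences
          else if (inherits(x, "DNAStringSet")) x
          else Biostrings::DNAStringSet(x)
  if (is.null(names(seqs))) abort("sequences must be named")
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

#' Read a chromosome-length table
#'
#' Two tab-separated columns, chromosome name and length in bp; lines
#' starting with `#` are ignored.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, comment = "#", col_names = c("chrom", "length"),
                       col_types = "ci", progress = FALSE)
  if (nrow(x) == 0) abort(sprintf("empty chromosome-size table: %s", path))
  if (anyDuplicated(x$chrom)) abort("duplicate chromosome names in size table")
  x
}

#' Write a chromosome-length table
#' @param chrom_sizes Tibble with columns `chrom`, `length`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  writeLines(c("# chrom\tlength",
               sprintf("%s\t%d", chrom_sizes$chrom, chrom_sizes$length)), path)
  invisible(path)
}

peak_columns <- list(
  bed = c("chrom", "start", "end", "name", "score", "strand"),
  narrowpeak = c("chrom", "start", "end", "name", "score", "strand",
                 "signal_value", "p_value", "q_value", "peak")
)

#' Read ChIP-seq peaks from BED or narrowPeak
#'
#' Coordinates are kept 0-based half-open as in BED. Rows are returned
#' sorted by (chrom, start, end); duplicated rows are kept (deduplication,
#' if wanted, is [merge_peaks()]'s job). Lines beginning with `#`, `track`
#' or `browser` are skipped.
#'
#' @param path Path to a BED3+ or ENCODE narrowPeak (10-column) file.
#' @param format `"auto"` (by column count), `"bed"`, or `"narrowPeak"`.
#' @param chrom_sizes Optional chromosome-length tibble; when supplied,
#'   unknown chromosomes and out-of-bounds intervals raise an error.
#' @param condition Optional condition label stored in a `condition` column.
#' @return A tibble of peaks sorted by (chrom, start, end).
#' @export
read_peaks <- function(path, format = c("auto", "bed", "narrowPeak"),
                       chrom_sizes = NULL, condition = NULL) {
  format <- tolower(match.arg(format))
  if (!file.exists(path)) abort(sprintf("peak file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer())
    if (!is.null(condition)) out$condition <- character()
    return(out)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol <- map_int(fields, length)
  if (min(ncol) < 3) {
    abort(sprintf("line %d of %s has fewer than 3 tab-separated fields",
                  idx[which.min(ncol)], path))
  }
  if (format == "auto") format <- if (all(ncol >= 10)) "narrowpeak" else "bed"
  cols <- peak_columns[[format]]
  n_use <- min(max(ncol), length(cols))
  grab <- function(j) map_chr(fields, function(f) if (length(f) >= j) f[j] else NA_character_)
  out <- as_tibble(setNames(lapply(seq_len(n_use), grab), cols[seq_len(n_use)]))
  out$start <- suppressWarnings(as.integer(out$start))
  out$end <- suppressWarnings(as.integer(out$end))
  if (anyNA(out$start) || anyNA(out$end)) {
    bad <- which(is.na(out$start) | is.na(out$end))[1]
    abort(sprintf("non-numeric coordinates at line %d of %s", idx[bad], path))
  }
  bad <- which(out$start >= out$end)
  if (length(bad) > 0) {
    abort(sprintf("start >= end at line %d of %s", idx[bad[1]], path))
  }
  for (col in intersect(c("score", "signal_value", "p_value", "q_value"), names(out))) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  if ("peak" %in% names(out)) out$peak <- suppressWarnings(as.integer(out$peak))
  if (!is.null(chrom_sizes)) check_chroms_known(out, chrom_sizes, path)
  if (!is.null(condition)) out$condition <- condition
  sort_intervals(out)
}

#' Write peaks to BED or narrowPeak
#'
#' Emits a `#`-prefixed header naming the columns, then tab-separated rows
#' with LF line endings.
#'
#' @param peaks Peak tibble (0-based half-open coordinates).
#' @param path Output path.
#' @param format `"auto"` (narrowPeak when the extra columns are present),
#'   `"bed"`, or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("auto", "bed", "narrowPeak")) {
  format <- tolower(match.arg(format))
  if (format == "auto") {
    format <- if (all(c("signal_value", "p_value", "q_value", "peak") %in%
                      names(peaks))) "narrowpeak" else "bed"
  }
  cols <- peak_columns[[format]]
  x <- peaks
  defaults <- list(name = ".", score = 0, strand = ".",
                   signal_value = 0, p_value = -1, q_value = -1, peak = -1L)
  for (col in cols) {
    if (!col %in% names(x)) x[[col]] <- defaults[[col]] %||% "."
  }
  x <- x[, cols, drop = FALSE]
  body <- do.call(paste, c(lapply(x, as.character), sep = "\t"))
  writeLines(c(paste0("# ", paste(cols, collapse = "\t")), body), path, sep = "\n")
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Only rows with feature type `gene` are consumed. GTF coordinates
#' (1-based, inclusive) are converted to the package's 0-based half-open
#' convention: `start = gtf_start - 1`, `end = gtf_end`.
#'
#' @param path Path to a GTF file.
#' @return A tibble with columns `gene_id`, `gene_name`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
read_gtf_genes <- function(path) {
  if (!file.exists(path)) abort(sprintf("GTF file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0) {
    return(tibble(gene_id = character(), gene_name = character(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  gene_id <- gr$gene_id
  if (is.null(gene_id) || anyNA(gene_id) || any(gene_id == "")) {
    abort(sprintf("gene feature(s) without a gene_id attribute in %s", path))
  }
  if (anyDuplicated(gene_id)) {
    abort(sprintf("duplicate gene_id in %s: %s", path,
                  paste(unique(gene_id[duplicated(gene_id)]), collapse = ", ")))
  }
  gene_name <- gr$gene_name %||% gene_id
  gene_name[is.na(gene_name)] <- gene_id[is.na(gene_name)]
  tibble(
    gene_id = gene_id,
    gene_name = gene_name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) |> sort_intervals()
}

#' Write gene models to GTF
#'
#' Inverse of [read_gtf_genes()]: internal 0-based half-open coordinates are
#' written as 1-based inclusive GTF `gene` rows.
#'
#' @param genes Gene tibble with `gene_id`, `chrom`, `start`, `end`, and
#'   optional `gene_name`, `strand`.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf_genes <- function(genes, path, source = "subteloscreen") {
  check_interval_cols(genes, "gene table")
  strand <- if ("strand" %in% names(genes)) genes$strand else "+"
  strand[is.na(strand) | strand == "."] <- "+"
  gene_name <- if ("gene_name" %in% names(genes)) genes$gene_name else genes$gene_id
  lines <- sprintf(
    '%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
    genes$chrom, source, genes$start + 1L, genes$end, strand,
    genes$gene_id, gene_name
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Tab-separated with header columns `sample_id`, `group`, `target`,
#' `replicate`, `ct`; `#`-prefixed comment lines are skipped.
#'
#' @param path Path to a TSV file.
#' @return A validated Ct tibble.
#' @export
read_ct_table <- function(path) {
  x <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    sample_id = readr::col_character(), group = readr::col_character(),
    target = readr::col_character(), replicate = readr::col_integer(),
    ct = readr::col_double()
  ), progress = FALSE)
  validate_ct_table(x)
}

#' Write a qPCR Ct table
#' @param table Ct tibble (see [read_ct_table()] for columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

validate_ct_table <- function(x) {
  needed <- c("sample_id", "group", "target", "replicate", "ct")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    abort(sprintf("Ct table missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(x$ct)) || any(x$ct <= 0)) {
    abort("Ct values must be finite and > 0")
  }
  x
}
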