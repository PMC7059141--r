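# Synthetic inputs with known ground truth. Every generator is a pure
# function of (parameters, seed): the same call regenerates byte-identical
# artifacts. Background sequence is i.i.d. at the requested GC content with
# no repeat families beyond the planted ones, which keeps brute-force
# scanner oracles exact.

GUARD <- "CATCAT" # planted-array flank; no 6-mer spanning it matches TTAGGG/CCCTAA

#' Simulate a genome with terminal telomeric tracts and planted ITSs
#'
#' Chromosomes receive i.i.d. background bases at the stated GC content,
#' terminal telomeric tracts with real-telomere polarity (CCCTAA repeats at
#' the low-coordinate end, TTAGGG at the high-coordinate end, i.e. the
#' G-strand runs 5'→3' toward each end), and interstitial TTAGGG arrays at
#' the requested positions. Each planted array is flanked by short guard
#' bases so it cannot be extended by chance, making the planted truth the
#' exact expected scanner output.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of every chromosome in bp.
#' @param gc Background GC fraction.
#' @param terminal_tract_units Telomeric units per terminal tract (0 for
#'   none).
#' @param its_spec Tibble with columns `chrom`, `position_fraction`,
#'   `units`, `mismatches` describing the interstitial plants; default
#'   plants two exact arrays (5 and 8 units at fractions 0.3 and 0.7) per
#'   chromosome. `mismatches` degenerate units carry one substitution each
#'   (the first unit always stays exact).
#' @param seed Integer seed.
#' @return An object of class `synthetic_genome`: `assembly` (a
#'   `genome_assembly`), `its_truth` and `terminal_truth` array tibbles,
#'   and `params`.
#' @export
simulate_genome <- function(n_chrom = 2L, chrom_length = 100000L, gc = 0.41,
                            terminal_tract_units = 25L, its_spec = NULL,
                            seed = 1L) {
  withr::local_seed(seed)
  chroms <- paste0("chr", seq_len(n_chrom))
  if (is.null(its_spec)) {
    its_spec <- tidyr::crossing(
      chrom = chroms,
      tibble(position_fraction = c(0.3, 0.7), units = c(5L, 8L),
             mismatches = 0L))
  }
  stopifnot(all(its_spec$chrom %in% chroms),
            all(its_spec$position_fraction > 0 & its_spec$position_fraction < 1),
            all(its_spec$units >= 2), all(its_spec$mismatches >= 0),
            all(its_spec$mismatches < its_spec$units))
  L <- as.integer(chrom_length)
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  guard <- strsplit(GUARD, "")[[1]]

  its_rows <- list()
  term_rows <- list()
  seqs <- setNames(vector("list", n_chrom), chroms)
  for (k in seq_len(n_chrom)) {
    ch <- chroms[k]
    bases <- sample(names(base_prob), L, replace = TRUE, prob = base_prob)
    footprints <- list()
    plant <- function(pos0, chars) {
      stopifnot(pos0 >= 0, pos0 + length(chars) <= L)
      bases[(pos0 + 1):(pos0 + length(chars))] <<- chars
    }
    tu <- as.integer(terminal_tract_units)
    if (tu > 0) {
      low <- strsplit(strrep("CCCTAA", tu), "")[[1]]
      plant(0L, c(low, guard))
      footprints[[length(footprints) + 1]] <- c(0L, 6L * tu + 6L)
      high <- strsplit(strrep("TTAGGG", tu), "")[[1]]
      plant(L - 6L * tu - 6L, c(guard, high))
      footprints[[length(footprints) + 1]] <- c(L - 6L * tu - 6L, L)
      term_rows[[length(term_rows) + 1]] <- tibble(
        chrom = ch, start = c(0L, L - 6L * tu), end = c(6L * tu, L),
        strand = c("-", "+"), unit_count = tu, matched_bases = 6L * tu,
        purity = 1, array_class = "terminal")
    }
    spec_k <- its_spec[its_spec$chrom == ch, , drop = FALSE]
    for (r in seq_len(nrow(spec_k))) {
      u <- as.integer(spec_k$units[r])
      mm <- as.integer(spec_k$mismatches[r])
      pos <- as.integer(round(spec_k$position_fraction[r] * L))
      units <- rep("TTAGGG", u)
      if (mm > 0) units[1 + seq_len(mm)] <- "TTCGGG" # one substitution each
      arr <- strsplit(paste(units, collapse = ""), "")[[1]]
      plant(pos - 6L, c(guard, arr, guard))
      footprints[[length(footprints) + 1]] <- c(pos - 6L, pos + 6L * u + 6L)
      its_rows[[length(its_rows) + 1]] <- tibble(
        chrom = ch, start = pos, end = pos + 6L * u, strand = "+",
        unit_count = u, matched_bases = 6L * u - mm,
        purity = (6 * u - mm) / (6 * u), array_class = "interstitial")
    }
    fp <- do.call(rbind, footprints)
    if (!is.null(fp) && nrow(fp) > 1) {
      fp <- fp[order(fp[, 1]), , drop = FALSE]
      if (any(fp[-1, 1] < fp[-nrow(fp), 2])) {
        abort(sprintf("overlapping plant requests on %s", ch))
      }
    }
    seqs[[ch]] <- paste(bases, collapse = "")
  }
  sequences <- Biostrings::DNAStringSet(unlist(seqs))
  assembly <- structure(
    list(sequences = sequences,
         chrom_sizes = tibble(chrom = chroms, length = L),
         softmask = tibble(chrom = character(), start = integer(),
                           end = integer())),
    class = "genome_assembly")
  structure(
    list(assembly = assembly,
         its_truth = if (length(its_rows)) list_rbind(its_rows) else
           mutate(empty_arrays(), array_class = character()),
         terminal_truth = if (length(term_rows)) list_rbind(term_rows) else
           mutate(empty_arrays(), array_class = character()),
         params = list(n_chrom = n_chrom, chrom_length = L, gc = gc,
                       terminal_tract_units = terminal_tract_units,
                       seed = seed)),
    class = "synthetic_genome")
}

#' Simulate a gene annotation with controlled distances from chromosome ends
#'
#' Random non-overlapping genes are placed one per slot along each
#' chromosome; additional genes can be pinned at exact distances from a
#' chromosome end (for telomere-distance worked examples, e.g. a synthetic
#' SIRT3-like gene 200 kb from the low-coordinate end). Random genes that
#' would overlap a pinned gene are dropped.
#'
#' @param chrom_sizes Chromosome-length tibble.
#' @param genes_per_chrom Random genes per chromosome.
#' @param length_range Min/max random gene length in bp.
#' @param placements Optional tibble with columns `gene_id`, `chrom`,
#'   `distance`, `end` (`"low"` or `"high"`), `length`.
#' @param seed Integer seed.
#' @return An object of class `synthetic_annotation`: `genes` tibble and
#'   `placements`.
#' @export
simulate_annotation <- function(chrom_sizes, genes_per_chrom = 25L,
                                length_range = c(1000L, 3000L),
                                placements = NULL, seed = 1L) {
  withr::local_seed(seed)
  rows <- list()
  for (k in seq_len(nrow(chrom_sizes))) {
    ch <- chrom_sizes$chrom[k]
    L <- chrom_sizes$length[k]
    slot <- L %/% (genes_per_chrom + 1L)
    if (slot <= max(length_range)) {
      abort("chromosomes too short for genes_per_chrom at this length_range")
    }
    len <- sample(length_range[1]:length_range[2], genes_per_chrom, replace = TRUE)
    offset <- map_int(len, function(l) sample.int(slot - l, 1) - 1L)
    rows[[k]] <- tibble(
      gene_id = sprintf("%s_gene%02d", ch, seq_len(genes_per_chrom)),
      chrom = ch,
      start = (seq_len(genes_per_chrom) - 1L) * slot + offset,
      end = (seq_len(genes_per_chrom) - 1L) * slot + offset + len,
      strand = sample(c("+", "-"), genes_per_chrom, replace = TRUE))
  }
  genes <- list_rbind(rows)
  if (!is.null(placements)) {
    lens <- setNames(as.integer(chrom_sizes$length), chrom_sizes$chrom)
    placements <- mutate(placements, distance = as.integer(.data$distance),
                         length = as.integer(.data$length))
    placed <- placements |>
      mutate(
        L = lens[.data$chrom],
        start = if_else(.data$end == "low", .data$distance,
                        .data$L - .data$distance - .data$length),
        end = .data$start + .data$length,
        strand = "+") |>
      select("gene_id", "chrom", "start", "end", "strand")
    check_interval_cols(placed, "placements")
    # verify the pinned gene's nearer end really is the requested distance
    d <- pmin(placed$start, lens[placed$chrom] - placed$end)
    if (!all(d == placements$distance)) {
      abort("placement distance exceeds half the chromosome; nearer end would differ")
    }
    drop <- map_lgl(seq_len(nrow(genes)), function(i) {
      any(genes$chrom[i] == placed$chrom &
            genes$start[i] < placed$end & placed$start < genes$end[i])
    })
    genes <- bind_rows(genes[!drop, , drop = FALSE], placed)
  }
  genes <- genes |> mutate(gene_name = .data$gene_id) |> sort_intervals()
  structure(list(genes = genes, placements = placements,
                 params = list(seed = seed)),
            class = "synthetic_annotation")
}

#' Simulate two condition-labelled peak sets with known composition
#'
#' Peaks are laid out on well-separated slots: shared peaks appear in both
#' conditions with a small jitter that preserves at least 1 bp of overlap,
#' while condition-specific peaks never come near a peak of the other
#' condition, so [compare_conditions()] recovers the planted composition
#' exactly.
#'
#' @param chrom_sizes Chromosome-length tibble.
#' @param n_shared,n_only_a,n_only_b Planted composition.
#' @param width_range Min/max peak width in bp.
#' @param min_separation Minimum spacing between distinct peak slots.
#' @param conditions Length-2 character vector of condition labels.
#' @param seed Integer seed.
#' @return An object of class `synthetic_peaks`: `peaks_a`, `peaks_b`
#'   (tibbles with `condition`), and `labels` (per-slot truth).
#' @export
simulate_peaks <- function(chrom_sizes, n_shared = 20L, n_only_a = 15L,
                           n_only_b = 10L, width_range = c(200L, 400L),
                           min_separation = 1000L,
                           conditions = c("shScramble", "TRF2"), seed = 1L) {
  withr::local_seed(seed)
  n_total <- n_shared + n_only_a + n_only_b
  edge <- 20000L
  slot_size <- 2L * max(width_range) + min_separation
  slots <- list()
  for (k in seq_len(nrow(chrom_sizes))) {
    cap <- max(0L, (chrom_sizes$length[k] - 2L * edge) %/% slot_size)
    if (cap > 0) {
      slots[[k]] <- tibble(chrom = chrom_sizes$chrom[k],
                           pos = edge + (seq_len(cap) - 1L) * slot_size)
    }
  }
  slots <- list_rbind(slots)
  if (is.null(slots) || nrow(slots) < n_total) {
    abort("chromosomes too short for the requested number of peaks")
  }
  slots <- slots[seq_len(n_total), , drop = FALSE]
  lab <- sample(rep(c("shared", "only_a", "only_b"),
                    c(n_shared, n_only_a, n_only_b)))
  w <- sample(width_range[1]:width_range[2], n_total, replace = TRUE)
  labels <- slots |>
    mutate(label = lab, start = .data$pos, end = .data$pos + w) |>
    select("chrom", "start", "end", "label")
  mk <- function(rows, condition, prefix) {
    if (nrow(rows) == 0) {
      return(tibble(chrom = character(), start = integer(), end = integer(),
                    name = character(), score = numeric(),
                    condition = character()))
    }
    rows |>
      mutate(name = sprintf("%s_%03d", prefix, seq_len(nrow(rows))),
             score = round(stats::runif(nrow(rows), 100, 1000)),
             condition = condition) |>
      select("chrom", "start", "end", "name", "score", "condition")
  }
  sh <- labels[labels$label == "shared", , drop = FALSE]
  jitter <- if (nrow(sh) > 0) {
    map_int(sh$end - sh$start, function(wi) {
      sample.int(2L * (wi %/% 3L) + 1L, 1) - (wi %/% 3L) - 1L
    })
  } else integer()
  sh_b <- mutate(sh, start = .data$start + jitter, end = .data$end + jitter)
  peaks_a <- bind_rows(
    mk(sh, conditions[1], "shared_a"),
    mk(labels[labels$label == "only_a", , drop = FALSE], conditions[1], "onlyA")
  ) |> sort_intervals()
  peaks_b <- bind_rows(
    mk(sh_b, conditions[2], "shared_b"),
    mk(labels[labels$label == "only_b", , drop = FALSE], conditions[2], "onlyB")
  ) |> sort_intervals()
  structure(list(peaks_a = peaks_a, peaks_b = peaks_b, labels = labels,
                 conditions = conditions, params = list(seed = seed)),
            class = "synthetic_peaks")
}

ct_presets <- function() {
  hkg <- tibble(target = c("HPRT", "PPIA", "GAPDH"),
                baseline = c(20, 21, 19), fold = 1, role = "hkg")
  list(
    null = list(
      groups = c(control = "shScramble", treatment = "shTERF2"),
      targets = bind_rows(
        tibble(target = "GENE1", baseline = 25, fold = 1, role = "target"),
        hkg)),
    mtdna_shTERF2 = list(
      groups = c(control = "shScramble", treatment = "shTERF2"),
      targets = tibble(
        target = c("MT_AMP", "NUC_AMP"), baseline = c(15, 22),
        fold = c(8, 1), role = c("mito", "nuclear"))),
    sirt3_down = list(
      groups = c(control = "shScramble", treatment = "shTERF2"),
      targets = bind_rows(
        tibble(target = c("SIRT3", "SIRT1", "SIRT5", "PGC1A"),
               baseline = c(26, 24, 27, 25),
               fold = c(0.5, 1, 1, 2), role = "target"),
        hkg))
  )
}

#' Simulate replicate qPCR Ct tables with planted fold effects
#'
#' `Ct = baseline - log2(fold) * [group == treatment] + Normal(0,
#' ct_noise_sd)` independently per replicate well; housekeeping and
#' nuclear reference targets are unaffected by group (their planted fold
#' is 1). Presets: `"null"` (no effect), `"mtdna_shTERF2"` (eightfold
#' mitochondrial DNA increase in the knockdown group), `"sirt3_down"`
#' (SIRT3 halved, other sirtuins unchanged, PGC1A doubled).
#'
#' @param preset Preset name.
#' @param n_per_group Biological samples per group.
#' @param ct_noise_sd Gaussian noise SD in cycles, per replicate well.
#' @param replicates Technical replicates per (sample, target).
#' @param seed Integer seed.
#' @return An object of class `ct_simulation`: `table` (a Ct tibble),
#'   `planted` (target/fold/role truth), `groups`, and `params`.
#' @export
simulate_ct_table <- function(preset = "null", n_per_group = 6L,
                              ct_noise_sd = 0.2, replicates = 2L, seed = 1L) {
  presets <- ct_presets()
  if (!preset %in% names(presets)) {
    abort(sprintf("unknown preset '%s'; available: %s", preset,
                  paste(names(presets), collapse = ", ")))
  }
  p <- presets[[preset]]
  withr::local_seed(seed)
  grid <- tidyr::crossing(
    group = unname(p$groups),
    sample_no = seq_len(n_per_group),
    target = p$targets$target,
    replicate = seq_len(replicates)
  ) |>
    left_join(p$targets, by = "target") |>
    mutate(
      sample_id = sprintf("%s_s%d", .data$group, .data$sample_no),
      ct = .data$baseline -
        log2(.data$fold) * (.data$group == p$groups[["treatment"]]) +
        rnorm(n(), 0, ct_noise_sd)
    )
  table <- grid |>
    select("sample_id", "group", "target", "replicate", "ct") |>
    arrange(.data$group, .data$sample_id, .data$target, .data$replicate)
  structure(
    list(table = table, planted = p$targets, groups = p$groups,
         params = list(preset = preset, n_per_group = n_per_group,
                       ct_noise_sd = ct_noise_sd, replicates = replicates,
                       seed = seed)),
    class = "ct_simulation")
}

#' Simulate a complete screen fixture with known candidate truth
#'
#' Builds, at coordinate level, everything [run_screen()] consumes: genes
#' on an 8-chromosome layout, condition-specific and shared peaks, and
#' interstitial arrays, arranged so that exactly `n_candidates` genes
#' satisfy the screen definition. Negative controls are planted on
#' purpose: decoy genes whose modulated peak or ITS sits at exactly
#' `window + 1` bp, genes whose nearby peak is shared between conditions
#' (hence not modulated), and terminal telomeric tracts near chromosome
#' ends that must be excluded by classification.
#'
#' Each gene lives in its own 450-kb cell so associations never leak
#' between neighbouring genes at the default 100-kb window.
#'
#' @param seed Integer seed.
#' @param n_genes Total genes (default 400).
#' @param n_candidates Planted true candidates (default 40).
#' @param window Association window the truth is defined against.
#' @param conditions Length-2 condition labels (control first).
#' @return An object of class `screen_fixture`: `chrom_sizes`, `genes`,
#'   `gene_roles`, `peaks_a`, `peaks_b`, `its` (interstitial and terminal
#'   rows), `candidate_truth`, `window`, `params`.
#' @export
simulate_screen_fixture <- function(seed = 1L, n_genes = 400L,
                                    n_candidates = 40L, window = 100000L,
                                    conditions = c("shScramble", "TRF2")) {
  withr::local_seed(seed)
  n_chrom <- 8L
  cell <- 450000L
  offset <- 20000L
  gene_len <- 2000L
  its_len <- 60L # 10 exact units
  peak_w <- 300L
  cells_per_chrom <- as.integer(ceiling(n_genes / n_chrom))
  L <- 2L * offset + cells_per_chrom * cell
  chroms <- paste0("chr", seq_len(n_chrom))
  chrom_sizes <- tibble(chrom = chroms, length = L)

  n_both <- n_candidates %/% 3L
  n_lost <- as.integer(ceiling((n_candidates - n_both) / 2))
  n_gained <- n_candidates - n_both - n_lost
  budget <- n_genes - n_candidates
  base_counts <- c(decoy_peak_far = 30L, decoy_its_far = 30L,
                   shared_near = 30L, its_only = 60L, peak_only = 60L)
  if (budget < sum(base_counts)) {
    base_counts[] <- pmax(1L, as.integer(floor(base_counts * budget /
                                                 (sum(base_counts) + 10L))))
  }
  roles <- sample(rep(
    c("candidate_lost", "candidate_gained", "candidate_both",
      names(base_counts), "plain"),
    c(n_lost, n_gained, n_both, base_counts,
      n_genes - n_candidates - sum(base_counts))))

  gene_rows <- vector("list", n_genes)
  its_rows <- list()
  peak_rows <- list()
  peak_id <- 0L
  add_peak <- function(chrom, start, label) {
    peak_id <<- peak_id + 1L
    peak_rows[[peak_id]] <<- tibble(
      chrom = chrom, start = start, end = start + peak_w,
      name = sprintf("peak_%04d", peak_id),
      score = round(stats::runif(1, 100, 1000)), label = label)
  }
  add_its <- function(chrom, end0) {
    its_rows[[length(its_rows) + 1]] <<- tibble(
      chrom = chrom, start = end0 - its_len, end = end0, strand = "+",
      unit_count = 10L, matched_bases = its_len, purity = 1,
      array_class = "interstitial")
  }
  gap <- function() sample.int(window + 1L, 1) - 1L # uniform on 0..window

  for (i in seq_len(n_genes)) {
    ci <- (i - 1L) %/% cells_per_chrom + 1L
    cell_i <- (i - 1L) %% cells_per_chrom
    c0 <- offset + cell_i * cell
    gs <- c0 + 200000L
    ge <- gs + gene_len
    ch <- chroms[ci]
    gene_rows[[i]] <- tibble(
      gene_id = sprintf("gene_%03d", i), gene_name = sprintf("gene_%03d", i),
      chrom = ch, start = gs, end = ge, strand = "+")
    role <- roles[i]
    mod_label <- function() sample(c("lost", "gained"), 1)
    if (role == "candidate_lost") {
      add_peak(ch, ge + gap(), "lost"); add_its(ch, gs - gap())
    } else if (role == "candidate_gained") {
      add_peak(ch, ge + gap(), "gained"); add_its(ch, gs - gap())
    } else if (role == "candidate_both") {
      g1 <- sample.int(50000L, 1)
      add_peak(ch, ge + g1, "lost")
      add_peak(ch, ge + g1 + peak_w + sample.int(40000L, 1), "gained")
      add_its(ch, gs - gap())
    } else if (role == "decoy_peak_far") {
      add_peak(ch, ge + window + 1L, mod_label()); add_its(ch, gs - gap())
    } else if (role == "decoy_its_far") {
      add_peak(ch, ge + gap(), mod_label()); add_its(ch, gs - window - 1L)
    } else if (role == "shared_near") {
      add_peak(ch, ge + gap(), "shared"); add_its(ch, gs - gap())
    } else if (role == "its_only") {
      add_its(ch, gs - gap())
    } else if (role == "peak_only") {
      add_peak(ch, ge + gap(), mod_label())
    }
  }
  genes <- list_rbind(gene_rows)
  peaks <- list_rbind(peak_rows)

  shared <- peaks[peaks$label == "shared", , drop = FALSE]
  shared_b <- mutate(shared, start = .data$start + 50L, end = .data$end + 50L)
  peaks_a <- bind_rows(peaks[peaks$label == "lost", , drop = FALSE], shared) |>
    mutate(condition = conditions[1]) |> sort_intervals()
  peaks_b <- bind_rows(peaks[peaks$label == "gained", , drop = FALSE], shared_b) |>
    mutate(condition = conditions[2]) |> sort_intervals()

  terminal <- tidyr::crossing(chrom = chroms, side = c("low", "high")) |>
    mutate(start = if_else(.data$side == "low", 100L, L - 160L),
           end = .data$start + 60L,
           strand = if_else(.data$side == "low", "-", "+"),
           unit_count = 10L, matched_bases = 60L, purity = 1,
           array_class = "terminal") |>
    select(-"side")
  its <- bind_rows(list_rbind(its_rows), terminal) |> sort_intervals()

  gene_roles <- tibble(gene_id = genes$gene_id, role = roles)
  structure(
    list(chrom_sizes = chrom_sizes, genes = genes, gene_roles = gene_roles,
         peaks_a = peaks_a, peaks_b = peaks_b, peak_labels = peaks,
         its = its,
         candidate_truth = sort(genes$gene_id[startsWith(roles, "candidate")]),
         window = as.integer(window),
         params = list(seed = seed, n_genes = n_genes,
                       n_candidates = n_candidates,
                       conditions = conditions)),
    class = "screen_fixture")
}

#' Write a screen fixture's inputs to files
#'
#' Emits the file set [run_pipeline()] consumes: a gene GTF, two
#' condition-labelled peak BED files, an ITS BED (classified), and a
#' chromosome-size table.
#'
#' @param fixture A [simulate_screen_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_screen_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "screen_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genes = file.path(dir, "genes.gtf"),
    peaks_a = file.path(dir, "peaks_a.bed"),
    peaks_b = file.path(dir, "peaks_b.bed"),
    its = file.path(dir, "its.bed"),
    chrom_sizes = file.path(dir, "chrom.sizes")
  )
  write_gtf_genes(fixture$genes, paths$genes)
  write_peaks(fixture$peaks_a, paths$peaks_a, format = "bed")
  write_peaks(fixture$peaks_b, paths$peaks_b, format = "bed")
  write_arrays_bed(fixture$its, paths$its)
  write_chrom_sizes(fixture$chrom_sizes, paths$chrom_sizes)
  paths
}
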