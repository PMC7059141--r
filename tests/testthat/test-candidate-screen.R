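screen_toy <- function() {
  # 6 genes in separate 1-Mb neighbourhoods; G1 near a lost peak and an
  # ITS, G2 near a gained peak only, G3 near an ITS only, G4 near both a
  # gained peak and an ITS, G5 near nothing, G6 near a lost peak only.
  genes <- tibble::tibble(
    gene_id = paste0("G", 1:6), gene_name = paste0("G", 1:6),
    chrom = "chr1",
    start = (0:5) * 1000000L + 500000L,
    end = (0:5) * 1000000L + 502000L,
    strand = "+"
  )
  lost <- tibble::tibble(chrom = "chr1",
                         start = c(503000L, 5000000L + 540000L),
                         end = c(503300L, 5000000L + 540300L))
  gained <- tibble::tibble(chrom = "chr1",
                           start = c(1000000L + 510000L, 3000000L + 450000L),
                           end = c(1000000L + 510300L, 3000000L + 450300L))
  its <- tibble::tibble(chrom = "chr1",
                        start = c(480000L, 2000000L + 520000L,
                                  3000000L + 560000L),
                        end = c(480060L, 2000000L + 520060L,
                                3000000L + 560060L),
                        strand = "+", unit_count = 10L, matched_bases = 60L,
                        purity = 1, array_class = "interstitial")
  list(genes = genes, lost = lost, gained = gained, its = its)
}

test_that("empty modulated peak sets give an empty candidate list", {
  fx <- screen_toy()
  s <- run_screen(fx$lost[0, ], fx$gained[0, ], fx$its, fx$genes)
  expect_equal(s$final_candidates, character())
  expect_equal(s$its_genes, c("G1", "G3", "G4"))
})

test_that("a hand-checkable fixture yields the expected candidates", {
  fx <- screen_toy()
  s <- run_screen(fx$lost, fx$gained, fx$its, fx$genes)
  expect_equal(s$lost_genes, c("G1", "G6"))
  expect_equal(s$gained_genes, c("G2", "G4"))
  expect_equal(s$its_genes, c("G1", "G3", "G4"))
  expect_equal(s$modulated_genes, c("G1", "G2", "G4", "G6"))
  expect_equal(s$final_candidates, c("G1", "G4"))
  # intersection mode: no gene is near both a lost and a gained peak
  s2 <- run_screen(fx$lost, fx$gained, fx$its, fx$genes,
                   modulated_mode = "intersection")
  expect_equal(s2$final_candidates, character())
  # evidence rows cover every candidate with per-feature distances
  td <- tidy(s)
  expect_setequal(unique(td$gene_id), c("G1", "G4"))
  expect_true(all(td$distance <= 100000))
})

test_that("terminal arrays in the ITS input are rejected, not filtered", {
  fx <- screen_toy()
  its_bad <- dplyr::mutate(fx$its, array_class = c("interstitial", "terminal",
                                                   "interstitial"))
  expect_error(run_screen(fx$lost, fx$gained, its_bad, fx$genes),
               "non-interstitial")
  expect_error(run_screen(fx$lost, fx$gained,
                          dplyr::select(fx$its, -array_class), fx$genes),
               "classify_arrays")
})

test_that("venn regions partition the union in the documented order", {
  expect_equal(
    unname(venn_regions(c("a", "b"), c("b", "c"), c("c", "a"))),
    c(0L, 0L, 0L, 1L, 1L, 1L, 0L)
  )
  expect_equal(unname(venn_regions(character(), character(), character())),
               rep(0L, 7))
  ids <- paste0("g", 1:9)
  expect_equal(unname(venn_regions(ids, ids, ids)),
               c(0L, 0L, 0L, 0L, 0L, 0L, 9L))
  fx <- screen_toy()
  s <- run_screen(fx$lost, fx$gained, fx$its, fx$genes)
  expect_equal(sum(venn_counts(s)),
               length(union(union(s$lost_genes, s$gained_genes), s$its_genes)))
})

test_that("the planted screen fixture is recovered with perfect precision and recall", {
  fx <- simulate_screen_fixture(seed = 42)
  d <- compare_conditions(fx$peaks_a, fx$peaks_b)
  mod <- label_modulated(d, a_is_control = TRUE)
  its <- dplyr::filter(fx$its, array_class == "interstitial")
  s <- run_screen(mod$lost, mod$gained, its, fx$genes, window = fx$window)
  tp <- length(intersect(s$final_candidates, fx$candidate_truth))
  expect_equal(tp / length(s$final_candidates), 1) # precision
  expect_equal(tp / length(fx$candidate_truth), 1) # recall
  # decoys at window + 1 bp and shared-peak genes never leak in
  decoys <- fx$gene_roles$gene_id[fx$gene_roles$role %in%
                                    c("decoy_peak_far", "decoy_its_far",
                                      "shared_near")]
  expect_length(intersect(s$final_candidates, decoys), 0)
})

test_that("the fixture truth matches an independent brute-force evaluation", {
  fx <- simulate_screen_fixture(seed = 7, n_genes = 160, n_candidates = 16)
  lost <- fx$peak_labels[fx$peak_labels$label == "lost", ]
  gained <- fx$peak_labels[fx$peak_labels$label == "gained", ]
  its <- dplyr::filter(fx$its, array_class == "interstitial")
  want <- oracle_candidates(fx$genes, lost, gained, its, fx$window)
  expect_equal(fx$candidate_truth, want)
})

test_that("candidates are always a subset of ITS genes and modulated genes", {
  fx <- simulate_screen_fixture(seed = 3, n_genes = 120, n_candidates = 12)
  d <- compare_conditions(fx$peaks_a, fx$peaks_b)
  mod <- label_modulated(d)
  its <- dplyr::filter(fx$its, array_class == "interstitial")
  for (w in c(1000L, 50000L, 100000L, 150000L)) {
    s <- run_screen(mod$lost, mod$gained, its, fx$genes, window = w)
    expect_true(all(s$final_candidates %in% s$its_genes))
    expect_true(all(s$final_candidates %in% s$modulated_genes))
  }
  # gene sets grow monotonically with the window
  sets <- lapply(c(1000L, 50000L, 100000L), function(w) {
    s <- run_screen(mod$lost, mod$gained, its, fx$genes, window = w)
    list(l = s$lost_genes, g = s$gained_genes, i = s$its_genes,
         f = s$final_candidates)
  })
  for (k in 1:2) {
    expect_true(all(sets[[k]]$l %in% sets[[k + 1]]$l))
    expect_true(all(sets[[k]]$g %in% sets[[k + 1]]$g))
    expect_true(all(sets[[k]]$i %in% sets[[k + 1]]$i))
    expect_true(all(sets[[k]]$f %in% sets[[k + 1]]$f))
  }
})

test_that("reports round-trip through TSV and record parameters in JSON", {
  fx <- screen_toy()
  s <- run_screen(fx$lost, fx$gained, fx$its, fx$genes)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(s, path, provenance = list(assembly = "synthetic_toy_v1"))
  back <- read_report(path)
  expect_equal(nrow(back), nrow(s$candidates))
  expect_equal(back$gene_id, s$candidates$gene_id)
  expect_equal(back$distance, s$candidates$distance)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(as.numeric(side$params$window), 100000)
  expect_equal(as.numeric(side$counts$final_candidates), 2)
  expect_equal(unlist(side$final_candidates), c("G1", "G4"))
  expect_equal(side$provenance$assembly, "synthetic_toy_v1")
  # empty report still round-trips
  s0 <- run_screen(fx$lost[0, ], fx$gained[0, ], fx$its, fx$genes)
  write_report(s0, path)
  expect_equal(nrow(read_report(path)), 0L)
})
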