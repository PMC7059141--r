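# Replicate Ct measurements are averaged (arithmetic mean on the Ct scale)
# before any normalization; with three housekeeping genes the reference is
# the arithmetic mean of their mean Cts, i.e. geometric-mean normalization
# on the linear scale. Amplification efficiency is fixed at 2.0.

mean_ct_per_target <- function(table) {
  validate_ct_table(table)
  table |>
    group_by(.data$sample_id, .data$group, .data$target) |>
    summarise(ct = mean(.data$ct), n_replicates = n(), .groups = "drop")
}

#' Per-sample delta-Ct against a panel of housekeeping genes
#'
#' For each sample, replicates are averaged per target, then
#' `delta_ct = Ct(target) - mean(Ct(housekeeping genes))`.
#'
#' @param table Ct tibble with columns `sample_id`, `group`, `target`,
#'   `replicate`, `ct`.
#' @param target Target gene/amplicon label.
#' @param hkg Character vector of housekeeping targets (typically three,
#'   e.g. `c("HPRT", "PPIA", "GAPDH")`).
#' @return A tibble with `sample_id`, `group`, `target`, `delta_ct`.
#' @examples
#' tb <- tibble::tibble(
#'   sample_id = "s1", group = "control", replicate = 1L,
#'   target = c("SIRT3", "HPRT", "PPIA", "GAPDH"),
#'   ct = c(25, 20, 21, 22))
#' delta_ct(tb, "SIRT3", c("HPRT", "PPIA", "GAPDH"))  # delta_ct = 4
#' @export
delta_ct <- function(table, target, hkg = c("HPRT", "PPIA", "GAPDH")) {
  m <- mean_ct_per_target(table)
  samples <- distinct(m, .data$sample_id, .data$group)
  for (s in samples$sample_id) {
    present <- m$target[m$sample_id == s]
    miss_h <- setdiff(hkg, present)
    if (length(miss_h) > 0) {
      abort(sprintf("sample %s is missing housekeeping target(s): %s",
                    s, paste(miss_h, collapse = ", ")))
    }
    if (!target %in% present) {
      abort(sprintf("sample %s is missing target %s", s, target))
    }
  }
  hk <- m |>
    filter(.data$target %in% hkg) |>
    group_by(.data$sample_id) |>
    summarise(hkg_ct = mean(.data$ct), .groups = "drop")
  m |>
    filter(.data$target == !!target) |>
    left_join(hk, by = "sample_id") |>
    mutate(delta_ct = .data$ct - .data$hkg_ct) |>
    select("sample_id", "group", "target", "delta_ct")
}

#' Fold change between groups by the delta-delta-Ct method
#'
#' `delta_delta_ct = mean(delta_ct, group) - mean(delta_ct, reference)` and
#' `fold_change = 2^(-delta_delta_ct)`; the reference group's fold change
#' is 1 by construction. Per-sample fold changes
#' `2^-(delta_ct_i - mean(delta_ct, reference))` are kept for dispersion
#' (SEM) and for the alternative summary `fold_change_sample_mean`, the
#' arithmetic mean of per-sample folds.
#'
#' @param delta_cts Output of [delta_ct()] (one target).
#' @param reference_group Name of the reference group.
#' @return An object of class `fold_change_result` with a per-group
#'   `summary` tibble and a per-sample `samples` tibble.
#' @export
fold_change <- function(delta_cts, reference_group) {
  needed <- c("sample_id", "group", "target", "delta_ct")
  if (!all(needed %in% names(delta_cts))) {
    abort("delta_cts must come from delta_ct()")
  }
  groups <- unique(delta_cts$group)
  if (!reference_group %in% groups) {
    abort(sprintf("reference group '%s' has no samples", reference_group))
  }
  ref_mean <- mean(delta_cts$delta_ct[delta_cts$group == reference_group])
  samples <- delta_cts |>
    mutate(sample_fold = 2^-(.data$delta_ct - ref_mean))
  summary <- samples |>
    group_by(.data$target, .data$group) |>
    summarise(
      n = n(),
      mean_delta_ct = mean(.data$delta_ct),
      delta_delta_ct = mean(.data$delta_ct) - ref_mean,
      fold_change = 2^-(mean(.data$delta_ct) - ref_mean),
      fold_change_sample_mean = mean(.data$sample_fold),
      sem_fold = if (n() > 1) sd(.data$sample_fold) / sqrt(n()) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(is_reference = .data$group == reference_group)
  structure(
    list(summary = summary, samples = samples,
         reference_group = reference_group),
    class = "fold_change_result"
  )
}

#' Delta-delta-Ct fold changes for one or more targets
#'
#' Convenience wrapper chaining [delta_ct()] and [fold_change()] per
#' target and combining the results.
#'
#' @inheritParams delta_ct
#' @param targets Character vector of target labels.
#' @param reference_group Reference group name.
#' @return A `fold_change_result` covering all targets.
#' @export
qpcr_fold_change <- function(table, targets, hkg = c("HPRT", "PPIA", "GAPDH"),
                             reference_group) {
  parts <- map(targets, function(tg) {
    fold_change(delta_ct(table, tg, hkg), reference_group)
  })
  structure(
    list(
      summary = list_rbind(map(parts, "summary")),
      samples = list_rbind(map(parts, "samples")),
      reference_group = reference_group
    ),
    class = "fold_change_result"
  )
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("<fold_change_result> reference group: %s\n", x$reference_group))
  print(x$summary)
  invisible(x)
}

#' @method tidy fold_change_result
#' @export
tidy.fold_change_result <- function(x, ...) as_tibble(x$summary)

#' @method glance fold_change_result
#' @export
glance.fold_change_result <- function(x, ...) {
  tibble(
    n_targets = length(unique(x$summary$target)),
    n_groups = length(unique(x$summary$group)),
    n_samples = length(unique(x$samples$sample_id)),
    reference_group = x$reference_group
  )
}

#' Bar chart of fold changes per group and target
#' @param object A `fold_change_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fold_change_result
#' @export
autoplot.fold_change_result <- function(object, ...) {
  d <- object$summary
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$fold_change)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$fold_change - .data$sem_fold,
                   ymax = .data$fold_change + .data$sem_fold),
      width = 0.2, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$target)) +
    ggplot2::labs(x = NULL, y = "fold change (2^-ddCt)") +
    ggplot2::theme_minimal()
}

#' Relative mitochondrial DNA content from paired amplicons
#'
#' Per sample (replicates averaged first), relative content is
#' `2^-(Ct_mito - Ct_nuclear)`; all values are then divided by the
#' control-group mean, so the control group's mean normalized content is
#' exactly 1, and each group's fold change is its mean normalized content.
#'
#' @param table Ct tibble.
#' @param mito_amplicon Mitochondrial amplicon label.
#' @param nuclear_amplicon Single-copy nuclear amplicon label.
#' @param control_group Control group name.
#' @return An object of class `mtdna_result` with `samples` (per-sample
#'   normalized content) and `groups` (per-group fold change and SEM).
#' @export
mtdna_content <- function(table, mito_amplicon, nuclear_amplicon,
                          control_group) {
  m <- mean_ct_per_target(table)
  if (!control_group %in% m$group) {
    abort(sprintf("control group '%s' has no samples", control_group))
  }
  wide <- m |>
    filter(.data$target %in% c(mito_amplicon, nuclear_amplicon)) |>
    select("sample_id", "group", "target", "ct") |>
    tidyr::pivot_wider(names_from = "target", values_from = "ct")
  for (amp in c(mito_amplicon, nuclear_amplicon)) {
    if (!amp %in% names(wide) || anyNA(wide[[amp]])) {
      bad <- if (!amp %in% names(wide)) wide$sample_id else
        wide$sample_id[is.na(wide[[amp]])]
      abort(sprintf("amplicon %s missing for sample(s): %s",
                    amp, paste(bad, collapse = ", ")))
    }
  }
  wide$relative_content <- 2^-(wide[[mito_amplicon]] - wide[[nuclear_amplicon]])
  ctrl_mean <- mean(wide$relative_content[wide$group == control_group])
  samples <- wide |>
    mutate(normalized_content = .data$relative_content / ctrl_mean) |>
    select("sample_id", "group", "relative_content", "normalized_content")
  groups <- samples |>
    group_by(.data$group) |>
    summarise(
      n = n(),
      fold_change = mean(.data$normalized_content),
      sem = if (n() > 1) sd(.data$normalized_content) / sqrt(n()) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(is_control = .data$group == control_group)
  structure(
    list(samples = samples, groups = groups, control_group = control_group,
         mito_amplicon = mito_amplicon, nuclear_amplicon = nuclear_amplicon),
    class = "mtdna_result"
  )
}

#' @export
print.mtdna_result <- function(x, ...) {
  cat(sprintf("<mtdna_result> %s / %s, control = %s\n",
              x$mito_amplicon, x$nuclear_amplicon, x$control_group))
  print(x$groups)
  invisible(x)
}

#' @method tidy mtdna_result
#' @export
tidy.mtdna_result <- function(x, ...) as_tibble(x$samples)

#' @method glance mtdna_result
#' @export
glance.mtdna_result <- function(x, ...) {
  treat <- filter(x$groups, !.data$is_control)
  tibble(
    control_group = x$control_group,
    n_groups = nrow(x$groups),
    max_fold_change = if (nrow(treat) > 0) max(treat$fold_change) else 1
  )
}

#' Dot-and-bar plot of relative mitochondrial DNA content
#' @param object An `mtdna_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mtdna_result
#' @export
autoplot.mtdna_result <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$group, y = .data$normalized_content)) +
    ggplot2::geom_col(data = object$groups,
                      ggplot2::aes(y = .data$fold_change),
                      fill = "grey80", width = 0.6) +
    ggplot2::geom_jitter(width = 0.08, height = 0) +
    ggplot2::labs(x = NULL, y = "relative mtDNA content (control = 1)") +
    ggplot2::theme_minimal()
}
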