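#' Aggregate cross-sections into 3 mm sub-segments
#'
#' Combines consecutive cross-sections (six 0.5 mm-spaced sections by
#' default, i.e. 3 mm sub-segments, mirroring the CT slice thickness) and
#' reports per-segment mean lumen area, wall area and plaque burden
#' `100 * wall_area / (wall_area + lumen_area)` (wall + lumen = vessel
#' area bounded by the adventitia). A trailing partial segment is dropped.
#'
#' @param sections A `cross_sections` tibble from [extract_cross_sections()],
#'   ordered by axial position.
#' @param group_size Sections per segment (default 6).
#' @return A tibble of class `segment_metrics`: `segment`, `z_start_mm`,
#'   `lumen_area_mm2`, `wall_area_mm2`, `plaque_burden_pct`.
#' @export
segment_metrics <- function(sections, group_size = 6L) {
  stopifnot(is.data.frame(sections), group_size >= 1)
  if (nrow(sections) < group_size) {
    stop("need at least ", group_size, " cross-sections, got ", nrow(sections))
  }
  n_seg <- nrow(sections) %/% group_size
  out <- sections |>
    dplyr::slice_head(n = n_seg * group_size) |>
    dplyr::mutate(segment = rep(seq_len(n_seg), each = group_size)) |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(
      z_start_mm = min(.data$z_mm),
      lumen_area_mm2 = mean(.data$lumen_area_mm2),
      wall_area_mm2 = mean(.data$wall_area_mm2),
      .groups = "drop"
    ) |>
    dplyr::mutate(plaque_burden_pct = 100 * .data$wall_area_mm2 /
                    (.data$wall_area_mm2 + .data$lumen_area_mm2))
  class(out) <- c("segment_metrics", class(out))
  out
}

#' Compare two co-registered artery geometries segment by segment
#'
#' Extracts cross-sections on both meshes (which must share the centerline
#' parameterization), aggregates them into sub-segments, and reports
#' per-segment changes (`other` minus `baseline`) plus aggregate mean/SD
#' and the product-moment correlation of per-segment values. For identical
#' inputs the correlation is degenerate (zero variance) and reported as 1
#' by convention.
#'
#' @param baseline,other `artery_mesh` objects on the same centerline grid.
#' @param spacing_mm Cross-section spacing, mm.
#' @param group_size Sections per segment.
#' @return A list of class `geometry_comparison`: `segments` (per-segment
#'   tibble with baseline, other and change columns) and `summary` (tibble
#'   with mean change, SD and correlation per metric).
#' @export
compare_geometries <- function(baseline, other, spacing_mm = 0.5,
                               group_size = 6L) {
  sb <- segment_metrics(extract_cross_sections(baseline, spacing_mm), group_size)
  so <- segment_metrics(extract_cross_sections(other, spacing_mm), group_size)
  if (nrow(sb) != nrow(so)) {
    stop("segment counts differ: ", nrow(sb), " vs ", nrow(so),
         " (meshes are not co-registered)")
  }
  cor1 <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      if (isTRUE(all.equal(x, y))) 1 else NA_real_
    } else {
      stats::cor(x, y)
    }
  }
  segs <- tibble::tibble(
    segment = sb$segment,
    z_start_mm = sb$z_start_mm,
    lumen_area_baseline = sb$lumen_area_mm2,
    lumen_area_other = so$lumen_area_mm2,
    lumen_area_change = so$lumen_area_mm2 - sb$lumen_area_mm2,
    wall_area_baseline = sb$wall_area_mm2,
    wall_area_other = so$wall_area_mm2,
    wall_area_change = so$wall_area_mm2 - sb$wall_area_mm2,
    plaque_burden_baseline = sb$plaque_burden_pct,
    plaque_burden_other = so$plaque_burden_pct,
    plaque_burden_change = so$plaque_burden_pct - sb$plaque_burden_pct
  )
  summ <- tibble::tibble(
    metric = c("lumen_area", "wall_area", "plaque_burden"),
    mean_change = c(mean(segs$lumen_area_change), mean(segs$wall_area_change),
                    mean(segs$plaque_burden_change)),
    sd_change = c(stats::sd(segs$lumen_area_change),
                  stats::sd(segs$wall_area_change),
                  stats::sd(segs$plaque_burden_change)),
    correlation = c(
      cor1(segs$lumen_area_baseline, segs$lumen_area_other),
      cor1(segs$wall_area_baseline, segs$wall_area_other),
      cor1(segs$plaque_burden_baseline, segs$plaque_burden_other)
    )
  )
  structure(list(segments = segs, summary = summ),
            class = "geometry_comparison")
}

#' @export
print.geometry_comparison <- function(x, ...) {
  cat("<geometry_comparison>", nrow(x$segments), "sub-segments\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.geometry_comparison <- function(x, ...) x$segments

#' @export
glance.geometry_comparison <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean_change", "sd_change", "correlation"))
}

#' Binarize per-segment disease progression
#'
#' A segment is labelled progressive (1) when its relative change exceeds
#' the threshold in the progression direction: lumen area decrease, or
#' wall-area / plaque-burden increase. The threshold comparison is closed
#' (`>=`), and changes are interpreted relative (percent of baseline).
#'
#' @param relative_change_pct Per-segment relative changes, percent.
#' @param metric `"lumen"` (progression = decrease) or `"wall"` /
#'   `"plaque_burden"` (progression = increase).
#' @param threshold_percent Progression threshold (default 20).
#' @return Integer vector of 0/1 labels.
#' @export
binarize_progression <- function(relative_change_pct,
                                 metric = c("lumen", "wall", "plaque_burden"),
                                 threshold_percent = 20) {
  metric <- match.arg(metric)
  if (any(!is.finite(relative_change_pct))) stop("changes must be finite")
  prog <- if (metric == "lumen") -relative_change_pct else relative_change_pct
  as.integer(prog >= threshold_percent)
}
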