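#' Place approximate subclone territories in 2D
#'
#' Reconstructs approximate territories from per-biopsy subclone fractions
#' and a biopsy layout: a subclone detected in more than one biopsy is
#' centered at the midpoint of the involved biopsy centroids (it is assumed
#' to straddle their interface); a subclone private to one biopsy is packed
#' into the remaining space of that biopsy, at maximal distance from
#' already-placed territories; a nested subclone found only in a single
#' sample sits at the geographic center of its mother clone. Territory
#' areas are proportional to the subclone fraction times the biopsy area.
#'
#' @param fractions Tibble `subclone`, `sample_id`, `fraction` (own cell
#'   fractions, e.g. from [tidy.subclone_config()]).
#' @param layout Tibble `sample_id`, `x_mm`, `y_mm`, `area_mm2`.
#' @param parent Optional named character vector mapping each subclone to
#'   its mother clone (`NA` for top-level), enabling the nesting rule.
#' @param detect_threshold Minimum fraction counting as presence
#'   (default 0.1).
#' @return Tibble of territories: `subclone`, `x_mm`, `y_mm`, `area_mm2`,
#'   `radius_mm`, `placement` (`interface`/`packed`/`nested`).
#' @export
place_territories <- function(fractions, layout, parent = NULL,
                              detect_threshold = 0.1) {
  fractions <- as_tibble(fractions)
  layout <- as_tibble(layout)
  req <- c("sample_id", "x_mm", "y_mm", "area_mm2")
  if (!all(req %in% names(layout))) {
    abort("`layout` needs columns sample_id, x_mm, y_mm, area_mm2.",
          class = "clonetrace_validation_error")
  }
  if (any(layout$area_mm2 <= 0)) {
    abort("Biopsy areas must be positive.",
          class = "clonetrace_validation_error")
  }
  present <- fractions %>%
    filter(.data$fraction >= detect_threshold) %>%
    left_join(layout, by = "sample_id")
  if (nrow(present) == 0) {
    return(tibble(subclone = character(), x_mm = numeric(),
                  y_mm = numeric(), area_mm2 = numeric(),
                  radius_mm = numeric(), placement = character()))
  }
  summ <- present %>%
    group_by(.data$subclone) %>%
    summarise(
      n_biopsies = dplyr::n_distinct(.data$sample_id),
      biopsies = list(unique(.data$sample_id)),
      cx = mean(.data$x_mm), cy = mean(.data$y_mm),
      area = sum(.data$fraction * .data$area_mm2),
      .groups = "drop"
    ) %>%
    arrange(desc(.data$area), .data$subclone)
  over <- present %>%
    group_by(.data$sample_id) %>%
    summarise(tot = sum(.data$fraction), .groups = "drop") %>%
    filter(.data$tot > 1 + 0.1)
  if (nrow(over)) {
    warn(paste0("Subclone fractions exceed biopsy capacity in: ",
                paste(over$sample_id, collapse = ", ")))
  }
  placed <- list()
  for (i in seq_len(nrow(summ))) {
    sc <- summ$subclone[i]
    mother <- if (!is.null(parent) && sc %in% names(parent)) {
      parent[[sc]]
    } else {
      NA_character_
    }
    mother_t <- if (!is.na(mother) && mother %in% names(placed)) {
      placed[[mother]]
    } else {
      NULL
    }
    if (summ$n_biopsies[i] > 1) {
      x <- summ$cx[i]; y <- summ$cy[i]; how <- "interface"
    } else if (!is.null(mother_t)) {
      x <- mother_t$x_mm; y <- mother_t$y_mm; how <- "nested"
    } else {
      b <- layout[layout$sample_id == summ$biopsies[[i]][1], ]
      R <- sqrt(b$area_mm2 / pi)
      # deterministic polar grid; farthest point from placed centroids
      cand <- expand.grid(r = seq(0, 0.8 * R, length.out = 5),
                          a = seq(0, 2 * pi, length.out = 9)[-9])
      cx <- b$x_mm + cand$r * cos(cand$a)
      cy <- b$y_mm + cand$r * sin(cand$a)
      if (length(placed)) {
        px <- vapply(placed, function(p) p$x_mm, numeric(1))
        py <- vapply(placed, function(p) p$y_mm, numeric(1))
        score <- vapply(seq_along(cx), function(j) {
          min(sqrt((cx[j] - px)^2 + (cy[j] - py)^2))
        }, numeric(1))
      } else {
        score <- -((cx - b$x_mm)^2 + (cy - b$y_mm)^2)
      }
      best <- which.max(score)
      x <- cx[best]; y <- cy[best]; how <- "packed"
    }
    placed[[sc]] <- tibble(
      subclone = sc, x_mm = x, y_mm = y, area_mm2 = summ$area[i],
      radius_mm = sqrt(summ$area[i] / pi), placement = how
    )
  }
  bind_rows(placed)
}

#' Territory density and dispersion
#'
#' @param territories Output of [place_territories()].
#' @param total_area Total viable tumor area in mm^2.
#' @return Tibble with `n_territories`, `density_per_mm2` (subclones per
#'   mm^2) and `median_distance_mm` (median pairwise centroid distance;
#'   `NA` with a single territory).
#' @export
territory_stats <- function(territories, total_area) {
  territories <- as_tibble(territories)
  if (nrow(territories) == 0) {
    abort("No territories.", class = "clonetrace_validation_error")
  }
  if (total_area <= 0) {
    abort("`total_area` must be positive.",
          class = "clonetrace_validation_error")
  }
  n <- nrow(territories)
  md <- if (n >= 2) {
    d <- stats::dist(territories[, c("x_mm", "y_mm")])
    median(as.numeric(d))
  } else NA_real_
  tibble(n_territories = n,
         density_per_mm2 = n / total_area,
         median_distance_mm = md)
}
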