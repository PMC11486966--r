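#' Mutated sample fraction from a linear copy ratio
#'
#' Inverts the linear copy-ratio model of a mixed sample. A sample in which a
#' fraction MSF of all cells (tumor plus normal) carries `nt` copies of a
#' segment against a background of `nb` copies has linear ratio
#' `(MSF * nt + (1 - MSF) * nb) / np`, where `np` is the reference ploidy the
#' array is normalized against. Solving for MSF gives
#' `MSF = (np * ratio - nb) / (nt - nb)`.
#'
#' @param ratio Linear total-copy ratio relative to reference ploidy
#'   (strictly positive). Use [apply_platform_correction()] first if the
#'   platform reports compressed log2 values.
#' @param nt Integer copy number of the segment in the mutated cells.
#' @param nb Integer copy number in the background cells (parallel clone or
#'   sample ploidy). Must differ from `nt`.
#' @param np Reference ploidy (default 2).
#' @param clamp Clamp the result to `[0, 1.2]` and flag out-of-range inputs
#'   (default `TRUE`). The 1.2 ceiling mirrors the tolerance accepted for
#'   clone fractions before the number of mutated alleles is re-chosen.
#' @return A numeric vector of mutated sample fractions. When `clamp = TRUE`
#'   an attribute `"flagged"` marks elements that fell outside `[0, 1.2]`.
#' @examples
#' msf_from_ratio(1.25, nt = 3, nb = 2)   # 0.5
#' msf_from_ratio(1.0, nt = 3, nb = 2)    # 0 (background only)
#' @export
msf_from_ratio <- function(ratio, nt, nb, np = 2, clamp = TRUE) {
  if (any(np < 1)) abort("`np` must be >= 1.", class = "clonetrace_config_error")
  if (any(!is.na(ratio) & ratio <= 0)) {
    abort("`ratio` must be a positive linear copy ratio.",
          class = "clonetrace_validation_error")
  }
  if (any(nt == nb)) {
    abort("`nt` equals `nb`: the segment carries no dosage signal.",
          class = "clonetrace_no_signal_error")
  }
  msf <- (np * ratio - nb) / (nt - nb)
  if (!clamp) return(msf)
  cl <- clamp_fraction(msf)
  structure(cl$value, flagged = cl$flagged)
}

#' Linearize a platform log2 ratio
#'
#' Array platforms compress the dynamic range of log2 ratios; observed log2
#' values are divided by a compression factor (0.53-0.6 for Cytoscan HD
#' class arrays) before exponentiation to a linear ratio.
#'
#' @param observed_log2 Log2 ratio as reported by the platform.
#' @param factor Compression factor in `[0.53, 0.60]`; default 0.55, the
#'   midpoint of the supported range. Values outside the range are accepted
#'   with a warning so other platforms can be calibrated.
#' @return Linear copy ratio `2^(observed_log2 / factor)`.
#' @examples
#' apply_platform_correction(0, 0.55)     # 1 (neutral)
#' apply_platform_correction(0.55, 0.55)  # 2
#' @export
apply_platform_correction <- function(observed_log2, factor = 0.55) {
  if (!is.numeric(factor) || any(factor <= 0)) {
    abort("`factor` must be a positive compression factor.",
          class = "clonetrace_config_error")
  }
  if (any(factor < 0.53 | factor > 0.60)) {
    warn("`factor` outside the calibrated 0.53-0.6 range.")
  }
  2^(observed_log2 / factor)
}

#' Mutated sample fraction from mirrored B-allele frequency
#'
#' The mirrored BAF of a segment with `n_a` A-alleles and `n_b >= n_a`
#' B-alleles carried by a fraction MSF of cells (normal cells contributing
#' one allele of each) is `Btot / (Atot + Btot)` with
#' `Btot = n_b * MSF + (1 - MSF)` and `Atot = n_a * MSF + (1 - MSF)`.
#' Solving for MSF gives
#' `MSF = (1 - 2 mBAF) / (mBAF * (n_a + n_b - 2) - n_b + 1)`.
#'
#' @param mbaf Mirrored B-allele frequency in `[0.5, 1]`.
#' @param n_a,n_b Integer allele counts of the mutated composition,
#'   `n_b >= n_a`. A balanced composition (`n_a == n_b`) has no mBAF signal.
#' @param clamp Clamp to `[0, 1.2]` as in [msf_from_ratio()].
#' @return Numeric vector of mutated sample fractions.
#' @examples
#' msf_from_mbaf(2 / 3, 1, 2)   # 1: pure trisomy
#' msf_from_mbaf(0.75, 0, 2)    # 0.5
#' @export
msf_from_mbaf <- function(mbaf, n_a, n_b, clamp = TRUE) {
  if (any(!is.na(mbaf) & (mbaf < 0.5 | mbaf > 1))) {
    abort("`mbaf` must lie in [0.5, 1].", class = "clonetrace_validation_error")
  }
  if (any(n_b < n_a)) {
    abort("`n_b` must be >= `n_a` (mirrored convention).",
          class = "clonetrace_validation_error")
  }
  if (any(n_a == n_b)) {
    abort("Balanced composition (n_a == n_b) carries no allelic-imbalance signal.",
          class = "clonetrace_no_signal_error")
  }
  den <- mbaf * (n_a + n_b - 2) - n_b + 1
  if (any(!is.na(den) & abs(den) < 1e-12)) {
    abort("Degenerate composition: mBAF denominator is zero.",
          class = "clonetrace_no_signal_error")
  }
  msf <- (1 - 2 * mbaf) / den
  if (!clamp) return(msf)
  cl <- clamp_fraction(msf)
  structure(cl$value, flagged = cl$flagged)
}

#' Convert between allelic imbalance and mirrored BAF
#'
#' Allelic imbalance rescales mirrored BAF to `[0, 1]`:
#' `AI = (mBAF - 0.5) / 0.5`. The conversion is linear and invertible.
#'
#' @param value Numeric vector of AI (in `[0, 1]`) or mBAF (in `[0.5, 1]`)
#'   values.
#' @param direction `"mbaf_to_ai"` or `"ai_to_mbaf"`.
#' @return Converted numeric vector.
#' @examples
#' ai_mbaf_convert(0.75, "mbaf_to_ai")  # 0.5
#' ai_mbaf_convert(0.5, "ai_to_mbaf")   # 0.75
#' @export
ai_mbaf_convert <- function(value, direction = c("mbaf_to_ai", "ai_to_mbaf")) {
  direction <- match.arg(direction)
  if (direction == "mbaf_to_ai") {
    if (any(!is.na(value) & (value < 0.5 | value > 1))) {
      abort("mBAF must lie in [0.5, 1].", class = "clonetrace_validation_error")
    }
    (value - 0.5) / 0.5
  } else {
    if (any(!is.na(value) & (value < 0 | value > 1))) {
      abort("AI must lie in [0, 1].", class = "clonetrace_validation_error")
    }
    0.5 + 0.5 * value
  }
}

#' Forward models for a mutated sample fraction
#'
#' Given an MSF and an allele composition, return the expected linear copy
#' ratio and mirrored BAF. These are the generative counterparts of
#' [msf_from_ratio()] and [msf_from_mbaf()], used by the synthetic-data
#' renderer and by the round-trip tests.
#'
#' @param msf Mutated sample fraction in `[0, 1]`.
#' @param nt,nb,np As in [msf_from_ratio()].
#' @return `expected_ratio()`: linear copy ratio; `expected_mbaf()`:
#'   mirrored BAF in `[0.5, 1]`.
#' @export
expected_ratio <- function(msf, nt, nb, np = 2) {
  (msf * nt + (1 - msf) * nb) / np
}

#' @rdname expected_ratio
#' @param n_a,n_b Allele counts as in [msf_from_mbaf()].
#' @export
expected_mbaf <- function(msf, n_a, n_b) {
  btot <- n_b * msf + (1 - msf)
  atot <- n_a * msf + (1 - msf)
  btot / (atot + btot)
}

#' Quantify mutated sample fractions for a segment table
#'
#' Adds ratio-based and mBAF-based MSF columns to a per-sample segment table.
#' Segments shorter than `min_length` bp are dropped (allelic composition
#' cannot be assessed reliably for very small events), balanced compositions
#' get `NA` for the mBAF route, and `nt == nb` compositions (copy-number
#' neutral imbalance) get `NA` for the ratio route.
#'
#' @param segments Data frame with columns `sample_id`, `chrom`, `start`,
#'   `end`, `ratio` (or `log2` when `log2_input = TRUE`), `n_a`, `n_b`, and
#'   optionally `mbaf` (or `ai`), `n_bg_a`, `n_bg_b`, `clonal_hint`.
#' @param ploidy Reference ploidy `np` (default 2).
#' @param log2_input Set `TRUE` when `segments` carries a platform `log2`
#'   column that must be linearized with `correction`.
#' @param correction Platform compression factor, see
#'   [apply_platform_correction()].
#' @param min_length Minimum segment length in bp (default 1e5).
#' @param clamp Clamp MSF estimates to `[0, 1.2]` (default `TRUE`). Leave
#'   unclamped when the estimates feed further averaging: truncating noise
#'   at zero biases trace-level fractions upward.
#' @return The segment tibble with `msf_ratio`, `msf_baf` and `msf` (the
#'   preferred readout: ratio where informative, otherwise mBAF) columns.
#' @export
quantify_segments <- function(segments, ploidy = 2, log2_input = FALSE,
                              correction = 0.55, min_length = 1e5,
                              clamp = TRUE) {
  segments <- as_tibble(segments)
  req <- c("sample_id", "chrom", "start", "end", "n_a", "n_b")
  miss <- setdiff(req, names(segments))
  if (length(miss)) {
    abort(paste0("Segment table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "clonetrace_validation_error")
  }
  if (any(segments$end < segments$start)) {
    bad <- which(segments$end < segments$start)[1]
    abort(paste0("Segment end < start at row ", bad, "."),
          class = "clonetrace_validation_error")
  }
  if (log2_input) {
    if (!"log2" %in% names(segments)) {
      abort("`log2_input = TRUE` but no `log2` column present.",
            class = "clonetrace_validation_error")
    }
    segments$ratio <- apply_platform_correction(segments$log2, correction)
  }
  if (!"ratio" %in% names(segments)) {
    abort("Segment table needs a `ratio` (or `log2`) column.",
          class = "clonetrace_validation_error")
  }
  if (!"mbaf" %in% names(segments)) {
    segments$mbaf <- if ("ai" %in% names(segments)) {
      ai_mbaf_convert(segments$ai, "ai_to_mbaf")
    } else {
      NA_real_
    }
  }
  if (!"n_bg_a" %in% names(segments)) segments$n_bg_a <- ploidy / 2
  if (!"n_bg_b" %in% names(segments)) segments$n_bg_b <- ploidy / 2

  segments <- filter(segments, .data$end - .data$start + 1 >= min_length)

  nb <- segments$n_bg_a + segments$n_bg_b
  nt <- segments$n_a + segments$n_b
  msf_r <- rep(NA_real_, nrow(segments))
  ok_r <- !is.na(segments$ratio) & nt != nb
  if (any(ok_r)) {
    msf_r[ok_r] <- as.numeric(msf_from_ratio(segments$ratio[ok_r],
                                             nt[ok_r], nb[ok_r], np = ploidy,
                                             clamp = clamp))
  }
  msf_b <- rep(NA_real_, nrow(segments))
  ok_b <- !is.na(segments$mbaf) & segments$n_a != segments$n_b
  if (any(ok_b)) {
    msf_b[ok_b] <- as.numeric(msf_from_mbaf(pmin(pmax(segments$mbaf[ok_b], 0.5), 1),
                                            segments$n_a[ok_b],
                                            segments$n_b[ok_b], clamp = clamp))
  }
  segments$msf_ratio <- msf_r
  segments$msf_baf <- msf_b
  segments$msf <- dplyr::coalesce(msf_r, msf_b)
  segments
}

#' Estimate tumor cell fraction (purity) from clonal segments
#'
#' The purity of a sample is the median MSF of segments judged clonal, taken
#' separately over the ratio-based and imbalance-based readouts. Agreement of
#' the two medians (difference below 0.1) indicates a correct ploidy and
#' allele-composition assessment; the consensus purity is their mean.
#'
#' @param segments A quantified segment table (see [quantify_segments()])
#'   with a logical `clonal_hint` column marking clonal segments.
#' @return A tibble with one row per sample: `tcf_ratio`, `tcf_ai`, `tcf`
#'   (consensus) and `consistent`.
#' @export
estimate_tcf <- function(segments) {
  segments <- as_tibble(segments)
  if (!"clonal_hint" %in% names(segments)) {
    abort("`segments` needs a logical `clonal_hint` column.",
          class = "clonetrace_validation_error")
  }
  clonal <- filter(segments, .data$clonal_hint)
  if (nrow(clonal) == 0) {
    abort("No clonal segments: purity unavailable.",
          class = "clonetrace_purity_error")
  }
  out <- clonal %>%
    group_by(.data$sample_id) %>%
    summarise(
      tcf_ratio = median(.data$msf_ratio, na.rm = TRUE),
      tcf_ai = median(.data$msf_baf, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(
      tcf_ratio = ifelse(is.nan(.data$tcf_ratio), NA_real_, .data$tcf_ratio),
      tcf_ai = ifelse(is.nan(.data$tcf_ai), NA_real_, .data$tcf_ai),
      tcf = dplyr::case_when(
        is.na(.data$tcf_ratio) ~ .data$tcf_ai,
        is.na(.data$tcf_ai) ~ .data$tcf_ratio,
        TRUE ~ (.data$tcf_ratio + .data$tcf_ai) / 2
      ),
      consistent = !is.na(.data$tcf_ratio) & !is.na(.data$tcf_ai) &
        abs(.data$tcf_ratio - .data$tcf_ai) < 0.1
    )
  if (any(!out$consistent)) {
    warn(paste0("Ratio- and imbalance-based purity differ by >= 0.1 in: ",
                paste(out$sample_id[!out$consistent], collapse = ", "),
                ". Check ploidy / allele composition."))
  }
  if (any(!is.na(out$tcf) & (out$tcf <= 0 | out$tcf > 1.2))) {
    abort("Estimated purity outside (0, 1.2].", class = "clonetrace_purity_error")
  }
  out$tcf <- pmin(out$tcf, 1)
  out
}

#' Mutated clone fraction from MSF and purity
#'
#' `MCF = MSF / TCF`, the fraction of tumor cells carrying an event. Values
#' in `(1, 1.2]` are rounded down to 1 (kept but not allowed to induce false
#' heterogeneity); values above 1.2 are flagged for re-evaluation of the
#' number of mutated alleles.
#'
#' @param msf Mutated sample fraction(s), `>= 0`.
#' @param tcf Tumor cell fraction in `(0, 1]` (recycled).
#' @return Numeric vector of MCFs in `[0, 1]` with attributes `"rounded_down"`
#'   (was in `(1, 1.2]`) and `"flagged"` (was above 1.2; returned clamped to
#'   1 but the multiplicity or composition should be re-chosen).
#' @examples
#' mcf_from_msf(0.4, 0.8)   # 0.5
#' mcf_from_msf(0.88, 0.8)  # 1, rounded down
#' @export
mcf_from_msf <- function(msf, tcf) {
  if (any(is.na(tcf)) || any(tcf <= 0)) {
    abort("`tcf` must lie in (0, 1].", class = "clonetrace_purity_error")
  }
  mcf <- msf / tcf
  rounded <- !is.na(mcf) & mcf > 1 & mcf <= 1.2
  flagged <- !is.na(mcf) & mcf > 1.2
  structure(pmin(pmax(mcf, 0), 1), rounded_down = rounded, flagged = flagged)
}
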