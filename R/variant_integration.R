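#' Filter sequencing variants by source-specific quality rules
#'
#' Applies the study-wide inclusion rules to a per-sample variant table.
#' A variant (identified by `chrom` + `pos` + `ref` + `alt` across the
#' samples of one patient) is rejected when:
#'
#' * it is supported by fewer than 10 reads in every sample (`min_reads`);
#' * its VAF is below the source cutoff in *all* samples (0.1 default,
#'   0.2 for FFPE-extracted whole exomes);
#' * more than 1% of reads in the matched normal carry it;
#' * for targeted panels, it is covered by fewer than 100 total reads in
#'   every sample.
#'
#' @param variants Data frame with columns `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `depth`, `alt_reads`, `vaf`, `normal_fraction`, `source`
#'   (one of `wes_ffpe`, `wes_frozen`, `targeted`, `pdx_wes`).
#' @param vaf_cutoff Named override of the per-source VAF cutoffs, e.g.
#'   `c(wes_ffpe = 0.1)` for low-mutation-burden FFPE cases.
#' @return A list with tibbles `kept` and `rejected`; `rejected` carries a
#'   `reason` tag per rule. The filter is idempotent.
#' @export
filter_variants <- function(variants, vaf_cutoff = NULL) {
  variants <- as_tibble(variants)
  req <- c("sample_id", "chrom", "pos", "ref", "alt", "depth", "alt_reads",
           "vaf", "normal_fraction", "source")
  miss <- setdiff(req, names(variants))
  if (length(miss)) {
    abort(paste0("Variant table is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "clonetrace_validation_error")
  }
  cutoffs <- c(wes_ffpe = 0.2, wes_frozen = 0.1, targeted = 0.1, pdx_wes = 0.1)
  if (!is.null(vaf_cutoff)) cutoffs[names(vaf_cutoff)] <- vaf_cutoff
  unknown <- setdiff(unique(variants$source), names(cutoffs))
  if (length(unknown)) {
    abort(paste0("Unknown variant source(s): ", paste(unknown, collapse = ", ")),
          class = "clonetrace_config_error")
  }

  v <- variants %>%
    mutate(
      .vid = paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = ":"),
      .cut = unname(cutoffs[.data$source])
    ) %>%
    group_by(.data$.vid) %>%
    mutate(
      .max_alt = max(.data$alt_reads),
      .any_vaf_ok = any(.data$vaf >= .data$.cut),
      .max_normal = max(.data$normal_fraction),
      .targeted_cov_ok = !any(.data$source == "targeted") |
        any(.data$depth >= 100)
    ) %>%
    ungroup() %>%
    mutate(reason = dplyr::case_when(
      .data$.max_alt < 10 ~ "min_reads",
      !.data$.any_vaf_ok ~ "vaf_below_cutoff",
      .data$.max_normal > 0.01 ~ "normal_contamination",
      !.data$.targeted_cov_ok ~ "targeted_low_coverage",
      TRUE ~ NA_character_
    ))
  kept <- v %>% filter(is.na(.data$reason)) %>%
    select(-dplyr::starts_with("."), -"reason")
  rejected <- v %>% filter(!is.na(.data$reason)) %>%
    select(-dplyr::starts_with("."))
  list(kept = kept, rejected = rejected)
}

#' Mutated clone fraction from VAF with copy-number context
#'
#' A variant carried at multiplicity `m` by a clone of size MCF, lying on a
#' segment with total copy number `cn1` in the main tumor fraction `f1` and
#' `cn2` in a background fraction `f2` (`f1 + f2 = tcf`), has
#' `VAF = m * MSF / (cn1 f1 + cn2 f2 + 2 (1 - tcf))`. Inverting,
#' `MCF = VAF * (cn1 f1 + cn2 (tcf - f1) + 2 (1 - tcf)) / (m * tcf)`.
#'
#' @param vaf Variant allele frequency in `[0, 1]`.
#' @param m Number of mutated allele copies (may be a fractional effective
#'   value on mixed copy-number backgrounds); `> 0`.
#' @param cn1 Total copies in the main tumor fraction at the locus.
#' @param f1 Size of the main fraction (of the whole sample).
#' @param cn2 Total copies in the background clone (default `NULL` when
#'   `f2 = 0`).
#' @param f2 Size of the background fraction; `f1 + f2` must equal `tcf`.
#' @param tcf Tumor cell fraction in `(0, 1]`.
#' @param clamp Apply the `[0, 1.2]` clamp-and-flag policy of
#'   [mcf_from_msf()] (default `TRUE`).
#' @return Numeric MCF vector (attributes as in [mcf_from_msf()] when
#'   clamped).
#' @examples
#' mcf_from_vaf(0.4, m = 1, cn1 = 2, f1 = 0.8, tcf = 0.8)  # 1
#' @export
mcf_from_vaf <- function(vaf, m, cn1, f1, cn2 = NULL, f2 = 0, tcf,
                         clamp = TRUE) {
  if (any(tcf <= 0)) abort("`tcf` must be > 0.", class = "clonetrace_purity_error")
  if (any(m <= 0)) abort("`m` must be > 0.", class = "clonetrace_validation_error")
  if (is.null(cn2)) {
    if (any(f2 > 0)) {
      abort("`cn2` absent while `f2` > 0.", class = "clonetrace_context_error")
    }
    cn2 <- 0
  }
  if (any(abs(f1 + f2 - tcf) > 1e-9)) {
    abort("Copy-number context invalid: f1 + f2 must equal tcf.",
          class = "clonetrace_context_error")
  }
  mcf <- vaf * (cn1 * f1 + cn2 * (tcf - f1) + 2 * (1 - tcf)) / (m * tcf)
  if (!clamp) return(mcf)
  rounded <- !is.na(mcf) & mcf > 1 & mcf <= 1.2
  flagged <- !is.na(mcf) & mcf > 1.2
  structure(pmin(pmax(mcf, 0), 1), rounded_down = rounded, flagged = flagged)
}

#' Mutated clone fraction from VAF in a pure tumor sample
#'
#' For xenograft or cell-line material where host reads were removed the
#' tumor fraction is 1 and the main-fraction model collapses to
#' `MCF = VAF * CN / M`.
#'
#' @param vaf Variant allele frequency.
#' @param cn Total copy number at the locus (`>= 1`; a variant cannot reside
#'   on a homozygous deletion).
#' @param m Number of mutated allele copies.
#' @param clamp As in [mcf_from_vaf()].
#' @return Numeric MCF vector.
#' @examples
#' mcf_from_vaf_pure(0.25, cn = 2, m = 1)  # 0.5
#' @export
mcf_from_vaf_pure <- function(vaf, cn, m = 1, clamp = TRUE) {
  if (any(cn == 0)) {
    abort("Variant placed on a homozygous deletion (cn = 0).",
          class = "clonetrace_context_error")
  }
  if (any(m <= 0)) abort("`m` must be > 0.", class = "clonetrace_validation_error")
  mcf <- vaf * cn / m
  if (!clamp) return(mcf)
  rounded <- !is.na(mcf) & mcf > 1 & mcf <= 1.2
  flagged <- !is.na(mcf) & mcf > 1.2
  structure(pmin(pmax(mcf, 0), 1), rounded_down = rounded, flagged = flagged)
}

#' Enumerate admissible effective multiplicities
#'
#' On a homogeneous background the candidate multiplicities are the integer
#' copy options `1..max(copies of one allele)`. On a mixed background (two
#' subclonal allele compositions at the locus) the effective multiplicity
#' depends on the order of events: the mutation may be private to the major
#' composition (integer copies scaled by the major-fraction weight) or may
#' predate the split, residing on either parental allele (copy number summed
#' over compositions, weighted by their fractions).
#'
#' For the worked configuration 2+0 at 30% / 1+2 at 70% this yields
#' `{0.7, 1.4, 2}`.
#'
#' @param composition Integer allele counts `c(n_a, n_b)` of the (single)
#'   composition, or `NULL` when `mix` is given.
#' @param mix Optional mixed background: a data frame with columns `n_a`,
#'   `n_b`, `fraction` (two rows; fractions sum to 1 over the tumor).
#' @param ploidy Sample ploidy; a tetraploid stem defaults the starting
#'   multiplicity to 2, a diploid to 1.
#' @return Sorted numeric vector of candidate `m` values, with the
#'   conventional starting value as attribute `"default"`.
#' @export
enumerate_multiplicities <- function(composition = NULL, mix = NULL,
                                     ploidy = 2) {
  if (is.null(mix)) {
    if (is.null(composition)) composition <- c(ploidy / 2, ploidy / 2)
    # a variant may occupy up to every copy at the locus (e.g. M = 2 on a
    # diploid segment when the mutation preceded a duplication)
    cands <- seq_len(max(1, sum(composition)))
    default <- if (ploidy >= 4) 2 else 1
    return(structure(sort(unique(as.numeric(cands))),
                     default = min(default, max(cands))))
  }
  mix <- as_tibble(mix)
  if (!all(c("n_a", "n_b", "fraction") %in% names(mix)) || nrow(mix) != 2) {
    abort("`mix` must have two rows with columns n_a, n_b, fraction.",
          class = "clonetrace_validation_error")
  }
  w <- mix$fraction / sum(mix$fraction)
  major <- which.max(w)
  # mutation private to the major composition, at 1..max allele copies
  private <- seq_len(max(mix$n_a[major], mix$n_b[major])) * w[major]
  # mutation ancestral to the split, on the A or the B parental allele
  ancestral <- c(sum(mix$n_a * w), sum(mix$n_b * w))
  cands <- sort(unique(round(c(private, ancestral[ancestral > 0]), 10)))
  structure(cands, default = cands[1])
}

#' Choose the number of mutated alleles among candidates
#'
#' Applies the selection rules in order: (1) reject candidates whose MCF
#' exceeds 1.2 in the majority of carrying samples; (2) reject candidates
#' declared biologically impossible (a nullisomic allele cannot be regained);
#' (3) reject candidates violating the pigeonhole principle; (4) reject
#' candidates whose implied CNA/SNV event order differs between samples
#' sharing the aberrations. Among survivors the candidate introducing the
#' fewest novel subclones wins; exact ties resolve toward the larger
#' multiplicity (the conservative call on heterogeneity).
#'
#' @param candidates Numeric candidate multiplicities.
#' @param trial_mcfs Matrix or data frame of unclamped MCFs, one row per
#'   candidate (rownames/order matching `candidates`), one column per sample
#'   carrying the variant.
#' @param impossible Logical vector (per candidate): biologically impossible
#'   order of events.
#' @param pigeonhole_violation Logical vector (per candidate).
#' @param order_mismatch Logical vector (per candidate): event order differs
#'   across samples.
#' @param novel_subclones Integer vector (per candidate): number of novel
#'   subclones the candidate's MCF profile would introduce. Defaults to 0.
#' @return The chosen multiplicity (numeric scalar).
#' @export
choose_multiplicity <- function(candidates, trial_mcfs,
                                impossible = NULL,
                                pigeonhole_violation = NULL,
                                order_mismatch = NULL,
                                novel_subclones = NULL) {
  k <- length(candidates)
  if (k == 0) {
    abort("No candidate multiplicities.", class = "clonetrace_config_error")
  }
  trial_mcfs <- as.matrix(trial_mcfs)
  if (nrow(trial_mcfs) != k) {
    abort("`trial_mcfs` must have one row per candidate.",
          class = "clonetrace_validation_error")
  }
  if (is.null(impossible)) impossible <- rep(FALSE, k)
  if (is.null(pigeonhole_violation)) pigeonhole_violation <- rep(FALSE, k)
  if (is.null(order_mismatch)) order_mismatch <- rep(FALSE, k)
  if (is.null(novel_subclones)) novel_subclones <- rep(0L, k)

  over <- apply(trial_mcfs, 1, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && mean(x > 1.2) > 0.5
  })
  ok <- !over & !impossible & !pigeonhole_violation & !order_mismatch
  if (!any(ok)) {
    abort(paste0(
      "All candidate multiplicities rejected (",
      sum(over), " MCF>1.2, ", sum(impossible), " impossible order, ",
      sum(pigeonhole_violation), " pigeonhole, ",
      sum(order_mismatch), " order mismatch)."
    ), class = "clonetrace_unresolvable_multiplicity")
  }
  idx <- which(ok)
  best <- idx[novel_subclones[idx] == min(novel_subclones[idx])]
  # tie-break: larger m implies fewer mutated cells -- the conservative call
  candidates[best[which.max(candidates[best])]]
}

#' Drop shared variants that are clonal-sweep artifacts
#'
#' A shared variant observed at low frequency (VAF below 0.2) in a sample in
#' which a clonal sweep fixed a different lineage is treated as a technical
#' artifact in that sample.
#'
#' @param variants Variant tibble (per sample rows) with `vaf` and a logical
#'   `shared` column (variant observed in more than one sample).
#' @param swept Named logical vector: per `sample_id`, has a clonal sweep of
#'   a different lineage taken place.
#' @return The variant tibble with a logical `sweep_artifact` column; rows
#'   flagged `TRUE` should be dropped from deconvolution.
#' @export
sweep_artifact_filter <- function(variants, swept) {
  variants <- as_tibble(variants)
  if (!"shared" %in% names(variants)) {
    abort("`variants` needs a logical `shared` column.",
          class = "clonetrace_validation_error")
  }
  sw <- swept[variants$sample_id]
  sw[is.na(sw)] <- FALSE
  variants$sweep_artifact <- variants$shared & unname(sw) & variants$vaf < 0.20
  variants
}

#' Label variants as clonal from their MCF
#'
#' Pure-tumor (PDX) whole-exome variants with `MCF > 0.7` are labeled clonal.
#' For a variant on a balanced 1+1 segment that is shared between samples and
#' clonal in at least 90% of them, the cutoff is relaxed to `MCF > 0.6`.
#'
#' @param mcf Numeric MCF values (one per sample carrying the variant).
#' @param balanced_shared Is the variant on a 1+1 segment shared across
#'   samples and clonal in >= 90% of the carrying samples?
#' @return Logical vector, `TRUE` = clonal. Monotone in MCF.
#' @export
clonality_label <- function(mcf, balanced_shared = FALSE) {
  cutoff <- ifelse(balanced_shared, 0.6, 0.7)
  mcf > cutoff
}
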