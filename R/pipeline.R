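#' Choose the MSF readout per segment
#'
#' The ratio-based MSF is used for every segment where the total copy
#' number differs from the background; the mirrored-BAF readout serves the
#' copy-number-neutral imbalances that leave no dosage footprint. The
#' mirrored readout is avoided elsewhere because mirroring folds the BAF at
#' 0.5: for small clones the folded noise only ever pushes the apparent
#' imbalance upward, inflating trace-level fractions, whereas the linear
#' ratio is unbiased at any clone size.
#'
#' @param seg A quantified segment table (see [quantify_segments()]).
#' @param ploidy Reference ploidy (unused; kept for call compatibility).
#' @return Numeric MSF vector.
#' @export
select_msf_readout <- function(seg, ploidy = 2) {
  ifelse(is.na(seg$msf_ratio), seg$msf_baf, seg$msf_ratio)
}

#' Reconstruct subclonal architecture from bulk tables
#'
#' The core analysis chain: quantify per-segment mutated sample fractions,
#' estimate per-sample purity from clonal segments, convert segment and
#' variant readouts to mutated clone fractions (the ratio readout is used
#' where informative, the mirrored-BAF readout for copy-number-neutral
#' imbalances), group events by their MCF pattern across samples, resolve
#' the nesting/parallel configuration, and build the rooted
#' maximum-parsimony clone tree.
#'
#' @param segments Segment table, see [quantify_segments()]; an `event`
#'   identifier column is added from the coordinates when absent.
#' @param variants Optional variant table, see [filter_variants()]; when
#'   `NULL` the reconstruction runs on copy-number data alone.
#' @param ploidy,log2_input,correction Passed to [quantify_segments()].
#' @param tol Event-grouping tolerance (default 0.15).
#' @param nest_tol Containment tolerance for nesting (default 0.1).
#' @param no_nest Optional barred event pairs ("mixed" aberrations).
#' @param events_meta Optional event metadata enabling
#'   [infer_missing_events()].
#' @param vaf_cutoff Per-source VAF cutoff overrides for
#'   [filter_variants()].
#' @return A list of class `bulk_reconstruction`: `purity`, `mcf` (long
#'   tibble), `groups`, `config`, `event_matrix`, `tree`, and
#'   `rejected_variants`.
#' @export
reconstruct_bulk <- function(segments, variants = NULL, ploidy = 2,
                             log2_input = FALSE, correction = 0.55,
                             tol = 0.15, nest_tol = 0.1, no_nest = NULL,
                             events_meta = NULL, vaf_cutoff = NULL) {
  seg <- quantify_segments(segments, ploidy = ploidy,
                           log2_input = log2_input, correction = correction,
                           clamp = FALSE)
  if (!"event" %in% names(seg)) {
    seg$event <- paste0(seg$chrom, ":", seg$start, "-", seg$end, ":",
                        seg$n_a, "+", seg$n_b)
  }
  purity <- estimate_tcf(seg)
  tcf <- setNames(purity$tcf, purity$sample_id)
  seg$tcf <- tcf[seg$sample_id]
  seg$msf_used <- select_msf_readout(seg, ploidy = ploidy)
  # unclamped internally: truncation before averaging would bias the
  # grouped clone sizes; the reporting grid clamps later
  seg$mcf <- seg$msf_used / seg$tcf
  mcf_long <- seg %>% select("event", "sample_id", "mcf")

  rejected <- NULL
  if (!is.null(variants) && nrow(as_tibble(variants)) > 0) {
    fl <- filter_variants(variants, vaf_cutoff = vaf_cutoff)
    rejected <- fl$rejected
    v <- fl$kept
    if (nrow(v) > 0) {
      if (!"event" %in% names(v)) {
        v$event <- paste0(v$chrom, ":", v$pos, ":", v$ref, ">", v$alt)
      }
      v$tcf <- tcf[v$sample_id]
      if (!"m" %in% names(v)) v$m <- 1
      if (!"cn1" %in% names(v)) v$cn1 <- 2
      v$mcf <- mcf_from_vaf(v$vaf, m = v$m, cn1 = v$cn1,
                            f1 = v$tcf, f2 = 0, tcf = v$tcf, clamp = FALSE)
      mcf_long <- bind_rows(mcf_long,
                            v %>% select("event", "sample_id", "mcf"))
    }
  }

  # per-event clone-size noise, calibrated on the clonal segments whose
  # true MCF is 1 in every sample
  clonal_resid <- seg$mcf[seg$clonal_hint %in% TRUE] - 1
  sigma_event <- if (sum(seg$clonal_hint %in% TRUE) >= 6) {
    stats::mad(clonal_resid, center = 0)
  } else {
    NULL
  }
  groups <- group_events(mcf_long, tol = tol)
  config <- resolve_configuration(groups, no_nest = no_nest, tol = nest_tol,
                                  sigma_event = sigma_event)
  if (!is.null(events_meta)) {
    config <- infer_missing_events(config, events_meta, no_nest = no_nest)
  }
  em <- event_matrix(config)
  tree <- build_tree(em$matrix)

  structure(list(
    purity = purity,
    mcf = mcf_long,
    groups = config$groups,
    config = config,
    event_matrix = em,
    tree = tree,
    rejected_variants = rejected
  ), class = "bulk_reconstruction")
}

#' @export
print.bulk_reconstruction <- function(x, ...) {
  cat("<bulk_reconstruction> ", nrow(x$config$nodes), " subclones from ",
      nrow(x$mcf), " event-sample MCFs\n", sep = "")
  invisible(x)
}

#' Detection table of a reconstruction
#'
#' Per-subclone, per-sample own cell fractions from the unrounded group
#' means, joined to sample timepoints — the input
#' [classify_replacement()] expects. Unrounded fractions are used so that
#' the 10% detection limit, not the reporting grid, decides presence.
#'
#' @param recon A `bulk_reconstruction`.
#' @param sample_info Tibble `sample_id`, `timepoint`.
#' @return Tibble `taxon`, `sample_id`, `timepoint`, `fraction`.
#' @export
detection_table <- function(recon, sample_info) {
  sample_info <- as_tibble(sample_info)
  as_tibble(recon$config$own_raw, rownames = "taxon") %>%
    tidyr::pivot_longer(-"taxon", names_to = "sample_id",
                        values_to = "fraction") %>%
    left_join(sample_info, by = "sample_id")
}

#' Run the full bulk analysis pipeline
#'
#' Executes quantify - integrate - deconvolve - tree - metrics (and
#' optionally territories) from a single configuration and assembles a
#' report. The pipeline is deterministic given its inputs and `seed`.
#'
#' @param config A list: `segments` (data frame or TSV path), optional
#'   `variants`, optional `sample_info` (`sample_id`, `timepoint`),
#'   optional `layout` (biopsy layout for territories), `mode`
#'   (`"clinical"` or `"pdx"`), `tol`, `ploidy`, `seed`, and optional
#'   `timepoint_order`.
#' @return A report list: `purity`, `subclones`, `fractions`, `newick`,
#'   `stats` (per-timepoint IGD, irregularity, total branch length),
#'   `classification`, `territories` (when a layout is given), `seed`.
#' @export
run_pipeline <- function(config) {
  read_maybe <- function(x) {
    if (is.character(x) && length(x) == 1) {
      if (!file.exists(x)) {
        abort(paste0("Input file not found: ", x),
              class = "clonetrace_validation_error")
      }
      return(as_tibble(utils::read.delim(x, sep = "\t",
                                         stringsAsFactors = FALSE)))
    }
    if (is.null(x)) NULL else as_tibble(x)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  mode <- config$mode %||% "clinical"
  segments <- read_maybe(config$segments)
  variants <- read_maybe(config$variants)
  sample_info <- read_maybe(config$sample_info)
  layout <- read_maybe(config$layout)
  tol <- config$tol %||% 0.15

  if (mode == "pdx") {
    pd <- pdx_deconvolve(quantify_segments(segments,
                                           ploidy = config$ploidy %||% 2),
                         tol = tol)
    recon <- structure(list(
      purity = tibble(sample_id = colnames(pd$sizes), tcf = 1),
      mcf = NULL, config = pd$config,
      event_matrix = event_matrix(pd$config),
      tree = build_tree(event_matrix(pd$config)$matrix)
    ), class = "bulk_reconstruction")
    recon$config$own <- pd$sizes
  } else {
    recon <- reconstruct_bulk(segments, variants,
                              ploidy = config$ploidy %||% 2,
                              tol = tol,
                              no_nest = config$no_nest,
                              events_meta = config$events_meta)
  }
  tree <- recon$tree

  stats_tbl <- NULL
  classification <- NULL
  if (!is.null(sample_info)) {
    det <- detection_table(recon, sample_info)
    tps <- config$timepoint_order %||% unique(sample_info$timepoint)
    stats_tbl <- bind_rows(lapply(tps, function(tp) {
      taxa <- det %>%
        filter(.data$timepoint == tp, .data$fraction >= 0.1) %>%
        pull("taxon") %>% unique()
      if (!length(taxa)) {
        return(tibble(timepoint = tp, n_subclones = 0L, igd = NA_real_,
                      irregularity = NA_real_,
                      total_branch_length = total_branch_length(tree)))
      }
      igd_val <- tryCatch(igd(tree, taxa), error = function(e) NA_real_)
      tibble(timepoint = tp, n_subclones = length(taxa), igd = igd_val,
             irregularity = if (nrow(tree$taxa) >= 2)
               irregularity(tree) else NA_real_,
             total_branch_length = total_branch_length(tree))
    }))
    if (length(tps) >= 2) {
      classification <- classify_replacement(tree, det,
                                             timepoint_order = tps)
    }
  }
  territories <- NULL
  if (!is.null(layout)) {
    fr <- tidy(recon$config) %>%
      select("subclone", "sample_id", "fraction")
    parent <- setNames(recon$config$nodes$parent,
                       recon$config$nodes$subclone)
    territories <- place_territories(fr, layout, parent = parent)
  }
  list(
    purity = recon$purity,
    subclones = recon$config$nodes,
    fractions = tidy(recon$config),
    newick = write_newick(tree),
    stats = stats_tbl,
    classification = if (!is.null(classification))
      classification$classification else NA_character_,
    territories = territories,
    seed = config$seed %||% NA_integer_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
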