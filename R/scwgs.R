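#' Default designated amplicon regions
#'
#' Regions where short high-grade amplifications are accepted as true
#' events: the *MYCN* region on 2p24 and the *MAML3* region in
#' 4q28.3-q31.1, expressed in 1 Mb bins on the reference genome. Override
#' for custom genomes (e.g. the simulated one).
#'
#' @return Tibble with `chrom`, `start_bin`, `end_bin`, `name`.
#' @export
amplicon_regions <- function() {
  tibble(
    chrom = c("2", "4"),
    start_bin = c(12L, 134L),
    end_bin = c(17L, 151L),
    name = c("MYCN_2p24", "MAML3_4q28.3-q31.1")
  )
}

#' Call copy-number events from a single-cell bin profile
#'
#' Maximal runs of bins deviating from the baseline ploidy become events.
#' Runs shorter than five 1 Mb bins are excluded as unreliable, except
#' high-grade amplifications (copy number >= `amp_copy`) overlapping a
#' designated amplicon region, for which two consecutive bins suffice.
#'
#' @param cn Integer copy-number vector over the genome bins of one cell.
#' @param bins Tibble with `chrom` and `bin` describing `cn` positionally.
#' @param ploidy Baseline ploidy (default 2).
#' @param regions Designated amplicon regions, see [amplicon_regions()].
#' @param min_bins Minimum run length for ordinary events (default 5).
#' @param amp_min_bins Minimum run length for amplifications inside
#'   designated regions (default 2).
#' @param amp_copy Copy number at or above which a gain counts as an
#'   amplification (default 5).
#' @return Tibble of events: `chrom`, `start_bin`, `end_bin`, `copy`,
#'   `class` (`gain`/`loss`/`amplification`), `n_bins`.
#' @export
call_cell_events <- function(cn, bins, ploidy = 2,
                             regions = amplicon_regions(),
                             min_bins = 5, amp_min_bins = 2, amp_copy = 5) {
  if (length(cn) == 0) {
    abort("Empty cell profile.", class = "clonetrace_validation_error")
  }
  bins <- as_tibble(bins)
  if (nrow(bins) != length(cn)) {
    abort("`bins` must describe `cn` positionally.",
          class = "clonetrace_validation_error")
  }
  out <- list()
  for (chr in unique(bins$chrom)) {
    idx <- which(bins$chrom == chr)
    r <- rle(cn[idx])
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1
    for (i in seq_along(r$values)) {
      v <- r$values[i]
      if (v == ploidy) next
      len <- r$lengths[i]
      cls <- if (v >= amp_copy) "amplification" else if (v > ploidy) "gain" else "loss"
      keep <- len >= min_bins
      if (!keep && cls == "amplification" && len >= amp_min_bins) {
        b1 <- bins$bin[idx[starts[i]]]
        b2 <- bins$bin[idx[stops[i]]]
        hit <- regions$chrom == chr & regions$start_bin <= b2 &
          regions$end_bin >= b1
        keep <- any(hit)
      }
      if (keep) {
        out[[length(out) + 1]] <- tibble(
          chrom = chr,
          start_bin = bins$bin[idx[starts[i]]],
          end_bin = bins$bin[idx[stops[i]]],
          copy = v, class = cls, n_bins = len
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start_bin = integer(),
                  end_bin = integer(), copy = numeric(),
                  class = character(), n_bins = integer()))
  }
  bind_rows(out)
}

# snap a set of breakpoint values: values within `tol` of each other
# collapse onto the smallest member (deterministic)
snap_values <- function(x, tol = 1) {
  u <- sort(unique(x))
  if (!length(u)) return(setNames(numeric(), character()))
  anchor <- u[1]
  map <- setNames(numeric(length(u)), u)
  for (v in u) {
    if (v - anchor > tol) anchor <- v
    map[as.character(v)] <- anchor
  }
  map
}

#' Harmonize single-cell events into a shared catalog
#'
#' Combines per-cell event calls into catalog entries spanning overlapping
#' chromosomal segments: boundaries agreeing within `bin_tol` are snapped
#' together, and same-class events are decomposed along the remaining
#' breakpoints, so a shared core and a cell-specific extension become
#' separate catalog entries while identical events merge. Cells carrying a
#' catalog entry are marked in the binary cell-by-event matrix.
#'
#' @param cell_events Named list of per-cell event tibbles (output of
#'   [call_cell_events()]).
#' @param bin_tol Boundary agreement tolerance in bins (default 1, the
#'   binning granularity).
#' @return List with `catalog` (tibble `event`, `chrom`, `start_bin`,
#'   `end_bin`, `class`, `n_carriers`) and `matrix` (cells x events, 0/1).
#' @export
harmonize_events <- function(cell_events, bin_tol = 1) {
  if (length(cell_events) < 2) {
    abort("Need events from at least two cells.",
          class = "clonetrace_validation_error")
  }
  cells <- names(cell_events)
  if (is.null(cells)) cells <- paste0("cell", seq_along(cell_events))
  all_ev <- bind_rows(lapply(seq_along(cell_events), function(i) {
    ev <- cell_events[[i]]
    if (nrow(ev) == 0) return(NULL)
    ev$cell <- cells[i]
    ev
  }))
  if (is.null(all_ev) || nrow(all_ev) == 0) {
    return(list(
      catalog = tibble(event = character(), chrom = character(),
                       start_bin = integer(), end_bin = integer(),
                       class = character(), n_carriers = integer()),
      matrix = matrix(0L, nrow = length(cells), ncol = 0,
                      dimnames = list(cells, NULL))
    ))
  }
  catalog <- list()
  carriage <- list()
  for (key in unique(paste(all_ev$chrom, all_ev$class))) {
    sub <- all_ev[paste(all_ev$chrom, all_ev$class) == key, ]
    smap <- snap_values(sub$start_bin, bin_tol)
    emap <- snap_values(sub$end_bin, bin_tol)
    s <- unname(smap[as.character(sub$start_bin)])
    e <- unname(emap[as.character(sub$end_bin)])
    brk <- sort(unique(c(s, e + 1)))
    frag_start <- brk[-length(brk)]
    frag_end <- brk[-1] - 1
    # carrier set per fragment
    fr_carriers <- lapply(seq_along(frag_start), function(f) {
      sort(unique(sub$cell[s <= frag_start[f] & e >= frag_end[f]]))
    })
    keep <- lengths(fr_carriers) > 0
    frag_start <- frag_start[keep]; frag_end <- frag_end[keep]
    fr_carriers <- fr_carriers[keep]
    # merge adjacent fragments with identical carriers
    i <- 1
    while (i < length(frag_start)) {
      if (frag_end[i] + 1 == frag_start[i + 1] &&
          identical(fr_carriers[[i]], fr_carriers[[i + 1]])) {
        frag_end[i] <- frag_end[i + 1]
        frag_start <- frag_start[-(i + 1)]
        frag_end <- frag_end[-(i + 1)]
        fr_carriers <- fr_carriers[-(i + 1)]
      } else i <- i + 1
    }
    for (f in seq_along(frag_start)) {
      id <- paste0(sub$chrom[1], ":", frag_start[f], "-", frag_end[f], ":",
                   sub$class[1])
      catalog[[id]] <- tibble(
        event = id, chrom = sub$chrom[1],
        start_bin = frag_start[f], end_bin = frag_end[f],
        class = sub$class[1], n_carriers = length(fr_carriers[[f]])
      )
      carriage[[id]] <- fr_carriers[[f]]
    }
  }
  catalog <- bind_rows(catalog) %>%
    arrange(as.integer(.data$chrom), .data$start_bin, .data$class)
  m <- matrix(0L, nrow = length(cells), ncol = nrow(catalog),
              dimnames = list(cells, catalog$event))
  for (id in catalog$event) m[carriage[[id]], id] <- 1L
  list(catalog = catalog, matrix = m)
}

#' Build a phylogeny over single cells
#'
#' Cells with identical event profiles collapse into one clone taxon
#' carrying the cell count; the clone-by-event matrix is then passed to the
#' maximum-parsimony builder, rooted in a cell with no alterations.
#'
#' @param m Binary cell-by-event matrix from [harmonize_events()].
#' @return A `clone_tree` whose taxa carry `n_cells`; attribute
#'   `"cell_clone"` maps each cell to its clone taxon.
#' @export
build_cell_tree <- function(m) {
  m <- as.matrix(m)
  key <- apply(m, 1, paste, collapse = "")
  reps <- !duplicated(key)
  mm <- m[reps, , drop = FALSE]
  clone_names <- paste0("clone", seq_len(nrow(mm)))
  rownames(mm) <- clone_names
  assignment <- setNames(clone_names[match(key, key[reps])], rownames(m))
  counts <- table(assignment)
  tree <- build_tree(mm)
  tree$taxa$n_cells <- as.integer(counts[tree$taxa$taxon])
  attr(tree, "cell_clone") <- assignment
  tree
}

#' Proportion of progeny below branches with a given CNA profile
#'
#' The PoP statistic: the fraction of detected single cells descending from
#' branches whose acquired events satisfy a predicate (e.g. "contains a
#' whole-chromosome gain"). With several trees (tumors) the per-tree
#' fractions are averaged.
#'
#' @param trees A `clone_tree` with `n_cells` on its taxa, or a list of
#'   them.
#' @param predicate Function taking the character vector of events acquired
#'   on a branch and returning `TRUE` when the branch matches.
#' @return Fraction in `[0, 1]`.
#' @export
pop_statistic <- function(trees, predicate) {
  if (inherits(trees, "clone_tree")) trees <- list(trees)
  vals <- vapply(trees, function(tree) {
    if (!"n_cells" %in% names(tree$taxa) ||
        any(is.na(tree$taxa$n_cells))) {
      abort("Every taxon needs a cell count.",
            class = "clonetrace_validation_error")
    }
    total <- sum(tree$taxa$n_cells)
    if (total == 0) abort("Zero total cells.",
                          class = "clonetrace_validation_error")
    match_nodes <- tree$nodes$node[map_lgl(tree$nodes$events,
                                           ~ isTRUE(predicate(.x)))]
    if (!length(match_nodes)) return(0)
    below <- vapply(tree$taxa$node, function(n) {
      any(match_nodes %in% node_path(tree, n))
    }, logical(1))
    sum(tree$taxa$n_cells[below]) / total
  }, numeric(1))
  mean(vals)
}

#' Clone fractions over ordered timepoints
#'
#' Computes the per-timepoint fraction of cells in each clone (distinct
#' event profile) from cell-by-event matrices sharing one catalog — the
#' table a fishplot is drawn from.
#'
#' @param matrices Named list of cell-by-event matrices in temporal order
#'   (names = timepoints), all with identical catalog columns.
#' @return Tibble `clone`, `profile`, `timepoint`, `n_cells`, `fraction`.
#' @export
clone_dynamics <- function(matrices) {
  if (length(matrices) < 1) {
    abort("Need at least one matrix.", class = "clonetrace_validation_error")
  }
  cats <- lapply(matrices, colnames)
  if (!all(vapply(cats, identical, logical(1), y = cats[[1]]))) {
    abort("Matrices do not share a common event catalog.",
          class = "clonetrace_harmonization_error")
  }
  tps <- names(matrices)
  if (is.null(tps)) tps <- paste0("t", seq_along(matrices))
  keys <- sort(unique(unlist(lapply(matrices, function(m) {
    apply(as.matrix(m), 1, paste, collapse = "")
  }))))
  clone_ids <- setNames(paste0("clone", seq_along(keys)), keys)
  bind_rows(lapply(seq_along(matrices), function(i) {
    m <- as.matrix(matrices[[i]])
    key <- apply(m, 1, paste, collapse = "")
    tab <- table(factor(key, levels = keys))
    tibble(
      clone = unname(clone_ids),
      profile = keys,
      timepoint = tps[i],
      n_cells = as.integer(tab),
      fraction = as.numeric(tab) / nrow(m)
    )
  }))
}
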