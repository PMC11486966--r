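#' Simulated genome layout
#'
#' The synthetic genome is 22 autosomes of 100 bins of 1 Mb each — small
#' enough for seconds-scale tests, large enough that the 5-bin single-cell
#' filter and multi-event segment layouts are exercised.
#'
#' @return Tibble with `chrom` and `n_bins`.
#' @export
sim_genome <- function() {
  tibble(chrom = as.character(1:22), n_bins = 100L)
}

# CNA class -> allele composition (background is always 1+1 diploid)
cna_classes <- function() {
  tibble(
    class = c("gain", "loss", "cnni", "gain_hi"),
    n_a = c(1L, 0L, 0L, 1L),
    n_b = c(2L, 1L, 2L, 3L),
    prob = c(0.45, 0.25, 0.15, 0.15)
  )
}

#' Simulate a ground-truth tumor
#'
#' Draws a rooted clone tree with events on every branch and per-region
#' clone fractions. The fraction scheme mimics the territorial biology of
#' multi-region tumor sampling: each region is dominated by one lineage
#' (lineages branch from the stem; each lineage has a home region), which
#' makes parallel lineages distinguishable across regions — every pair of
#' parallel clones crosses by at least 0.25 somewhere and every
#' ancestor-descendant pair is separated by at least ~0.3 in the home
#' region. The seed fully determines the tumor.
#'
#' @param n_clones Total clones including the stem (>= 1). For `branched`
#'   mode, at most `3 * n_regions + 1` so that every lineage keeps an
#'   identifiable home region.
#' @param mode `"branched"` (>= 2 parallel lineages off the stem),
#'   `"linear"` (one chain) or `"star"` (every non-stem clone a direct
#'   child of the stem).
#' @param n_regions Number of sampled regions (default 3).
#' @param n_cna,n_snv Events per branch (defaults 2 CNAs + 1 SNV; the stem
#'   always receives at least one unbalanced gain and one loss so purity is
#'   estimable from both the ratio and the imbalance readout).
#' @param stem_cna CNAs on the stem branch (default `n_cna + 2`: the trunk
#'   of these tumors is typically rich in clonal aberrations, which is also
#'   what makes purity estimable from the clonal-segment medians).
#' @param purity Range the per-sample tumor cell fraction is drawn from.
#' @param jitter Uniform perturbation applied to the clone-fraction levels
#'   (default 0.02, small against the 0.1 reporting grid).
#' @param timepoint Label attached to the baseline samples.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An object of class `truth_tumor`: `tree` (a [clone_tree()] whose
#'   taxa are the clones), `clones`, `events`, `samples`, and the
#'   clone-by-sample matrix `fractions` of own cell fractions (columns sum
#'   to 1 over the tumor compartment).
#' @export
simulate_truth <- function(n_clones, mode = c("branched", "linear", "star"),
                           n_regions = 3, n_cna = 2, n_snv = 1,
                           stem_cna = n_cna + 2,
                           purity = c(0.7, 0.9), jitter = 0.02,
                           timepoint = "pre", seed = NULL) {
  mode <- match.arg(mode)
  if (n_clones < 1) abort("`n_clones` must be >= 1.",
                          class = "clonetrace_config_error")
  if (!is.null(seed)) set.seed(seed)

  # ---- tree shape: stem plus k lineage chains --------------------------
  n_sub <- n_clones - 1
  if (mode == "linear") {
    lineages <- if (n_sub > 0) list(seq_len(n_sub)) else list()
  } else if (mode == "star") {
    lineages <- if (n_sub > 0) as.list(seq_len(n_sub)) else list()
  } else {
    if (n_sub < 2) abort("Branched mode needs at least 3 clones.",
                         class = "clonetrace_config_error")
    k_min <- max(2, ceiling(n_sub / 3))
    k_max <- min(n_regions, n_sub)
    if (k_min > k_max) {
      abort(paste0("Branched mode supports at most ", 3 * n_regions + 1,
                   " clones for ", n_regions, " regions."),
            class = "clonetrace_config_error")
    }
    k <- if (k_min == k_max) k_min else sample(k_min:k_max, 1)
    sizes <- rep(n_sub %/% k, k)
    extra <- n_sub %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    if (any(sizes > 3)) {  # rebalance: chains capped at 3 for identifiability
      while (any(sizes > 3)) {
        hi <- which.max(sizes); lo <- which.min(sizes)
        sizes[hi] <- sizes[hi] - 1; sizes[lo] <- sizes[lo] + 1
      }
    }
    idx <- seq_len(n_sub)
    lineages <- vector("list", k)
    at <- 1
    for (j in seq_len(k)) {
      lineages[[j]] <- idx[at:(at + sizes[j] - 1)]
      at <- at + sizes[j]
    }
  }
  clone_ids <- paste0("C", seq_len(n_clones))
  parent_clone <- setNames(rep(NA_character_, n_clones), clone_ids)
  depth_in_lineage <- setNames(rep(0L, n_clones), clone_ids)
  lineage_of <- setNames(rep(0L, n_clones), clone_ids)
  if (n_sub > 0) {
    for (j in seq_along(lineages)) {
      chain <- clone_ids[lineages[[j]] + 1L]
      prev <- "C1"
      for (d in seq_along(chain)) {
        parent_clone[chain[d]] <- prev
        depth_in_lineage[chain[d]] <- d
        lineage_of[chain[d]] <- j
        prev <- chain[d]
      }
    }
  }

  # ---- region fractions ------------------------------------------------
  k <- length(lineages)
  samples <- tibble(
    sample_id = paste0(timepoint, "_R", seq_len(n_regions)),
    region = seq_len(n_regions),
    timepoint = timepoint,
    purity = runif(n_regions, purity[1], purity[2])
  )
  levels3 <- c(0.85, 0.55, 0.25)
  step_by_region <- c(0.3, 0.2, 0.45)
  profile <- matrix(0, nrow = n_clones, ncol = n_regions,
                    dimnames = list(clone_ids, samples$sample_id))
  profile["C1", ] <- 1
  for (r in seq_len(n_regions)) {
    if (k == 0) next
    if (mode == "linear") {
      step <- step_by_region[((r - 1) %% length(step_by_region)) + 1]
      for (cl in clone_ids[-1]) {
        d <- depth_in_lineage[cl]
        profile[cl, r] <- min(max(0.9 - step * (d - 1), 0), 0.9)
      }
    } else {
      home <- ((r - 1) %% k) + 1
      for (cl in clone_ids[-1]) {
        if (lineage_of[cl] == home) {
          profile[cl, r] <- levels3[depth_in_lineage[cl]]
        }
      }
    }
  }
  if (jitter > 0 && n_clones > 1) {
    jit <- matrix(runif((n_clones - 1) * n_regions, -jitter, jitter),
                  nrow = n_clones - 1)
    nz <- profile[-1, , drop = FALSE] > 0
    profile[-1, ][nz] <- pmin(pmax(profile[-1, ][nz] + jit[nz], 0.02), 0.95)
  }
  # own fractions: subtree profile minus the child chain's profile
  own <- profile
  for (cl in clone_ids[-1]) {
    kids <- clone_ids[which(parent_clone == cl)]
    if (length(kids)) {
      own[cl, ] <- pmax(profile[cl, ] -
                          colSums(profile[kids, , drop = FALSE]), 0)
    }
  }
  top <- clone_ids[which(parent_clone == "C1")]
  own["C1", ] <- pmax(1 - if (length(top))
    colSums(profile[top, , drop = FALSE]) else 0, 0)
  own <- sweep(own, 2, colSums(own), "/")

  # ---- events ----------------------------------------------------------
  classes <- cna_classes()
  n_events_total <- n_clones * (n_cna + n_snv) + (stem_cna - n_cna)
  n_slots <- 44                                     # 22 chroms x 2 halves
  if (n_events_total > n_slots) {
    abort(paste0("Too many events for the simulated genome (max ~", n_slots,
                 ")."), class = "clonetrace_config_error")
  }
  slot <- 0
  ev <- list()
  next_slot <- function() {
    slot <<- slot + 1
    list(chrom = as.character(((slot - 1) %% 22) + 1),
         half = (slot - 1) %/% 22)
  }
  add_cna <- function(clone, class_row) {
    s <- next_slot()
    size <- round(exp(runif(1, log(5), log(45))))
    start <- s$half * 50 + sample.int(50 - size + 1, 1)
    ev[[length(ev) + 1]] <<- tibble(
      event = paste0("cna_", length(ev) + 1, "_chr", s$chrom,
                     "_", class_row$class),
      clone = clone, class = ifelse(class_row$class == "gain_hi", "gain",
                                    class_row$class),
      chrom = s$chrom, start_bin = start, end_bin = start + size - 1,
      n_a = class_row$n_a, n_b = class_row$n_b, m = NA_real_,
      whole_chrom = FALSE
    )
  }
  add_snv <- function(clone) {
    s <- next_slot()
    bin <- s$half * 50 + sample.int(50, 1)
    ev[[length(ev) + 1]] <<- tibble(
      event = paste0("snv_", length(ev) + 1, "_chr", s$chrom),
      clone = clone, class = "snv", chrom = s$chrom,
      start_bin = bin, end_bin = bin, n_a = 1L, n_b = 1L, m = 1,
      whole_chrom = FALSE
    )
  }
  for (cl in clone_ids) {
    if (cl == "C1") {
      add_cna(cl, classes[classes$class == "gain", ])
      add_cna(cl, classes[classes$class == "loss", ])
      extra <- max(stem_cna, 2) - 2
      if (extra > 0) for (i in seq_len(extra)) {
        add_cna(cl, classes[sample.int(4, 1, prob = classes$prob), ])
      }
    } else {
      for (i in seq_len(n_cna)) {
        add_cna(cl, classes[sample.int(4, 1, prob = classes$prob), ])
      }
    }
    if (n_snv > 0) for (i in seq_len(n_snv)) add_snv(cl)
  }
  events <- bind_rows(ev)

  # ---- truth tree ------------------------------------------------------
  node_of <- setNames(seq_len(n_clones) + 1L, clone_ids)
  branch_events <- lapply(clone_ids,
                          function(cl) sort(events$event[events$clone == cl]))
  nodes <- tibble(
    node = c(1L, unname(node_of)),
    parent = c(NA_integer_,
               ifelse(is.na(parent_clone), 1L, node_of[parent_clone])),
    events = c(list(character()), branch_events),
    length = c(0L, lengths(branch_events))
  )
  tree <- clone_tree(nodes, tibble(taxon = clone_ids,
                                   node = unname(node_of)))

  structure(list(
    tree = tree,
    clones = tibble(clone = clone_ids,
                    parent = unname(parent_clone),
                    lineage = unname(lineage_of),
                    depth = unname(depth_in_lineage)),
    events = events,
    samples = samples,
    fractions = own,
    mode = mode,
    seed = seed
  ), class = "truth_tumor")
}

#' @export
print.truth_tumor <- function(x, ...) {
  cat("<truth_tumor> ", nrow(x$clones), " clones / ", nrow(x$events),
      " events / ", nrow(x$samples), " samples (", x$mode, ")\n", sep = "")
  invisible(x)
}

# clones carrying each event (the event's clone and all its descendants)
event_carrier_matrix <- function(truth) {
  clones <- truth$clones$clone
  anc <- setNames(truth$clones$parent, clones)
  carries <- matrix(FALSE, nrow = nrow(truth$events), ncol = length(clones),
                    dimnames = list(truth$events$event, clones))
  for (cl in clones) {
    path <- cl
    x <- cl
    while (!is.na(anc[[x]])) {
      x <- anc[[x]]
      path <- c(path, x)
    }
    carries[truth$events$clone %in% path, cl] <- TRUE
  }
  carries
}

#' True event-level mutated clone fractions
#'
#' @param truth A `truth_tumor`.
#' @return Matrix events x samples of true MCFs (fractions of tumor cells).
#' @export
truth_mcf <- function(truth) {
  carriers <- event_carrier_matrix(truth)
  carriers %*% truth$fractions[colnames(carriers), , drop = FALSE]
}

#' Render bulk segment and variant tables from a ground-truth tumor
#'
#' The forward models are the ones the estimation module inverts: the
#' linear copy ratio of a segment is `(MSF * Nt + (1 - MSF) * Nb) / Np`
#' plus Gaussian noise (optionally compressed to a platform log2 value),
#' the mirrored BAF follows the allele-count mixture model, and variant
#' alt-read counts are binomial at the stated depth around
#' `VAF = M * MSF / 2` for diploid-context SNVs.
#'
#' @param truth A `truth_tumor`.
#' @param depth Sequencing depth for variants (default 200).
#' @param noise_sd Gaussian noise on the linear ratio (default 0.05); the
#'   mirrored BAF receives half that, reflecting the relative stability of
#'   allelic ratios.
#' @param platform_factor When non-`NULL`, emit a compressed `log2` column
#'   (`factor * log2(ratio)`) instead of the linear `ratio`.
#' @param seed Optional seed.
#' @return List with `segments` and `variants` tibbles (all samples); both
#'   carry the generating `event` id and `truth_mcf` for recovery tests.
#' @export
render_bulk <- function(truth, depth = 200, noise_sd = 0.05,
                        platform_factor = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (depth < 1) abort("`depth` must be >= 1.",
                       class = "clonetrace_config_error")
  mcf <- truth_mcf(truth)
  ev <- truth$events
  segs <- list()
  vars <- list()
  for (i in seq_len(nrow(truth$samples))) {
    s <- truth$samples$sample_id[i]
    pur <- truth$samples$purity[i]
    msf <- mcf[, s] * pur
    cna <- ev$class != "snv"
    nt <- ev$n_a + ev$n_b
    ratio <- unname(expected_ratio(msf[ev$event], nt, 2, 2)[cna]) +
      rnorm(sum(cna), 0, noise_sd)
    mb <- unname(expected_mbaf(msf[ev$event], ev$n_a, ev$n_b)[cna]) +
      rnorm(sum(cna), 0, noise_sd / 2)
    segs[[s]] <- tibble(
      sample_id = s,
      event = ev$event[cna],
      chrom = ev$chrom[cna],
      start = (ev$start_bin[cna] - 1) * 1e6 + 1,
      end = ev$end_bin[cna] * 1e6,
      n_a = ev$n_a[cna], n_b = ev$n_b[cna],
      ratio = pmax(ratio, 0.01),
      mbaf = ifelse(ev$n_a[cna] == ev$n_b[cna], NA_real_,
                    pmin(pmax(mb, 0.5), 1)),
      clonal_hint = ev$clone[cna] == "C1",
      truth_mcf = unname(mcf[ev$event[cna], s])
    )
    snv <- which(!cna)
    if (length(snv)) {
      vaf_true <- ev$m[snv] * msf[ev$event[snv]] / 2
      alt_n <- rbinom(length(snv), depth, pmin(pmax(vaf_true, 0), 1))
      vars[[s]] <- tibble(
        sample_id = s,
        event = ev$event[snv],
        chrom = ev$chrom[snv],
        pos = (ev$start_bin[snv] - 1) * 1e6 + 500000,
        ref = "A", alt = "T",
        depth = !!depth, alt_reads = alt_n, vaf = alt_n / !!depth,
        normal_fraction = 0, source = "wes_frozen",
        truth_mcf = unname(mcf[ev$event[snv], s])
      )
    }
  }
  segments <- bind_rows(segs)
  if (!is.null(platform_factor)) {
    segments$log2 <- platform_factor * log2(segments$ratio)
    segments$ratio <- NULL
  }
  list(segments = segments, variants = bind_rows(vars))
}

#' Apply a treatment bottleneck to a ground-truth tumor
#'
#' Post-treatment clone fractions are proportional to the pre-treatment
#' fractions times per-clone survival weights, renormalized per region.
#' Setting the weights of the dominant lineage (and the residual stem
#' population) to zero while sparing a collateral branch constructs a
#' collateral-clonal-replacement truth; uniform weights leave the landscape
#' unchanged (linear continuity).
#'
#' @param truth A `truth_tumor`.
#' @param weights Named numeric vector in `[0, 1]` per clone; unnamed
#'   clones default to 1.
#' @param timepoint Label for the new samples (default `"post"`).
#' @param purity Purity range for the new samples.
#' @param seed Optional seed.
#' @return The `truth_tumor` with post-treatment samples appended.
#' @export
apply_treatment <- function(truth, weights, timepoint = "post",
                            purity = c(0.7, 0.9), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- setNames(rep(1, nrow(truth$clones)), truth$clones$clone)
  w[names(weights)] <- weights
  if (any(w < 0 | w > 1)) {
    abort("Survival weights must lie in [0, 1].",
          class = "clonetrace_config_error")
  }
  pre <- truth$samples$timepoint == truth$samples$timepoint[1]
  pre_samples <- truth$samples$sample_id[pre]
  post <- truth$fractions[, pre_samples, drop = FALSE] * w[rownames(truth$fractions)]
  tot <- colSums(post)
  if (all(tot == 0)) {
    abort("All clones extinct under these weights.",
          class = "clonetrace_extinction_error")
  }
  if (any(tot == 0)) {
    abort("A region lost every clone; give survivors nonzero presence.",
          class = "clonetrace_extinction_error")
  }
  post <- sweep(post, 2, tot, "/")
  new_ids <- sub(paste0("^", truth$samples$timepoint[1], "_"),
                 paste0(timepoint, "_"), pre_samples)
  colnames(post) <- new_ids
  truth$samples <- bind_rows(
    truth$samples,
    tibble(sample_id = new_ids,
           region = truth$samples$region[pre],
           timepoint = timepoint,
           purity = runif(length(new_ids), purity[1], purity[2]))
  )
  truth$fractions <- cbind(truth$fractions, post)
  truth
}

#' Construct a treatment scenario with known evolutionary pattern
#'
#' Builds a five-clone tumor (stem, a dominant two-clone lineage, a
#' collateral two-clone lineage kept below the 10% detection limit before
#' treatment) and applies treatment. Under `"ccr"` the dominant lineage and
#' the residual stem population are eradicated so the collateral branch
#' expands from a different most recent ancestor; under `"linear"` survival
#' is uniform and the dominant lineage persists.
#'
#' @param type `"ccr"` or `"linear"`.
#' @param n_regions Regions sampled at each timepoint (default 3).
#' @param purity Per-sample purity range.
#' @param seed Optional seed.
#' @return A `truth_tumor` with pre and post samples and attribute
#'   `"scenario"`.
#' @export
simulate_scenario <- function(type = c("ccr", "linear"), n_regions = 3,
                              purity = c(0.7, 0.9), seed = NULL) {
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  truth <- simulate_truth(5, mode = "branched", n_regions = n_regions,
                          n_cna = 3, n_snv = 1, purity = purity,
                          jitter = 0, seed = NULL)
  # force the intended shape: C2->C3 dominant chain, C4->C5 collateral chain
  truth$clones$parent <- c(NA, "C1", "C2", "C1", "C4")
  truth$clones$lineage <- c(0L, 1L, 1L, 2L, 2L)
  truth$clones$depth <- c(0L, 1L, 2L, 1L, 2L)
  branch_events <- lapply(paste0("C", 1:5), function(cl) {
    sort(truth$events$event[truth$events$clone == cl])
  })
  nodes <- tibble(
    node = 1:6,
    parent = c(NA_integer_, 1L, 2L, 3L, 2L, 5L),
    events = c(list(character()), branch_events),
    length = c(0L, lengths(branch_events))
  )
  truth$tree <- clone_tree(nodes, tibble(taxon = paste0("C", 1:5),
                                         node = 2:6))
  # pre-treatment fractions: dominant lineage rules every region; the
  # collateral lineage idles below the detection limit
  pre <- truth$samples$sample_id
  frac <- matrix(0, nrow = 5, ncol = length(pre),
                 dimnames = list(paste0("C", 1:5), pre))
  p2 <- 0.85 + runif(length(pre), -0.02, 0.02)
  p3 <- 0.55 + runif(length(pre), -0.02, 0.02)
  frac["C2", ] <- p2 - p3
  frac["C3", ] <- p3
  frac["C4", ] <- 0.015
  frac["C5", ] <- 0.010
  frac["C1", ] <- 1 - colSums(frac[-1, , drop = FALSE])
  truth$fractions <- frac
  weights <- if (type == "ccr") {
    c(C1 = 0, C2 = 0, C3 = 0, C4 = 1, C5 = 1)
  } else {
    c(C1 = 1, C2 = 1, C3 = 1, C4 = 1, C5 = 1)
  }
  out <- apply_treatment(truth, weights, timepoint = "post",
                         purity = purity)
  attr(out, "scenario") <- type
  out
}

#' Render single-cell copy-number profiles
#'
#' Cells are drawn multinomially from the clone fractions of one sample;
#' each cell's 1 Mb-bin profile is its clone's total copy number per bin
#' (diploid baseline). Per-bin flips at `bin_noise_rate` and injected short
#' (< 5 bin) runs exercise the event-length filters; both default off when
#' the noise rate is zero.
#'
#' @param truth A `truth_tumor`.
#' @param sample_id Sample whose clone fractions are used (default first).
#' @param n_cells Number of cells.
#' @param bin_noise_rate Per-bin probability of a +/-1 copy flip.
#' @param short_runs Number of injected sub-threshold noise runs per cell;
#'   `NULL` means 1 when `bin_noise_rate > 0`, else 0.
#' @param seed Optional seed.
#' @return A list: `profiles` (cells x bins integer matrix), `bins`
#'   (tibble `chrom`, `bin`), `cell_clone` (true clone per cell).
#' @export
render_cells <- function(truth, sample_id = NULL, n_cells = 100,
                         bin_noise_rate = 0, short_runs = NULL,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_cells < 1) abort("`n_cells` must be >= 1.",
                         class = "clonetrace_config_error")
  if (is.null(sample_id)) sample_id <- truth$samples$sample_id[1]
  if (is.null(short_runs)) short_runs <- if (bin_noise_rate > 0) 1L else 0L
  genome <- sim_genome()
  bins <- tidyr::uncount(genome, weights = .data$n_bins) %>%
    group_by(.data$chrom) %>%
    mutate(bin = row_number()) %>%
    ungroup() %>%
    select("chrom", "bin") %>%
    arrange(as.integer(.data$chrom), .data$bin)
  nb <- nrow(bins)

  carriers <- event_carrier_matrix(truth)
  clone_profiles <- sapply(truth$clones$clone, function(cl) {
    cn <- rep(2L, nb)
    evs <- truth$events %>%
      filter(.data$class != "snv",
             .data$event %in% rownames(carriers)[carriers[, cl]])
    for (i in seq_len(nrow(evs))) {
      idx <- which(bins$chrom == evs$chrom[i] &
                     bins$bin >= evs$start_bin[i] &
                     bins$bin <= evs$end_bin[i])
      cn[idx] <- evs$n_a[i] + evs$n_b[i]
    }
    cn
  })

  probs <- truth$fractions[truth$clones$clone, sample_id]
  cells <- sample(truth$clones$clone, n_cells, replace = TRUE, prob = probs)
  profiles <- t(clone_profiles[, cells, drop = FALSE])
  rownames(profiles) <- paste0("cell", seq_len(n_cells))
  colnames(profiles) <- paste0(bins$chrom, ":", bins$bin)

  if (bin_noise_rate > 0) {
    flips <- matrix(runif(n_cells * nb) < bin_noise_rate, n_cells, nb)
    delta <- matrix(sample(c(-1L, 1L), n_cells * nb, replace = TRUE),
                    n_cells, nb)
    profiles <- pmax(profiles + flips * delta, 0L)
  }
  if (short_runs > 0) {
    for (i in seq_len(n_cells)) for (j in seq_len(short_runs)) {
      len <- sample.int(4, 1)
      at <- sample.int(nb - len, 1)
      profiles[i, at:(at + len - 1)] <-
        pmax(profiles[i, at:(at + len - 1)] +
               sample(c(-1L, 1L), 1), 0L)
    }
  }
  list(profiles = profiles, bins = bins,
       cell_clone = setNames(cells, rownames(profiles)))
}
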