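toy_bins <- function(n_chrom = 2, n_bins = 60) {
  tibble::tibble(chrom = rep(as.character(seq_len(n_chrom)), each = n_bins),
                 bin = rep(seq_len(n_bins), n_chrom))
}

profile_with <- function(bins, ..., base = 2L) {
  cn <- rep(base, nrow(bins))
  for (ev in list(...)) {
    idx <- which(bins$chrom == ev$chrom & bins$bin >= ev$from &
                   bins$bin <= ev$to)
    cn[idx] <- ev$cn
  }
  cn
}

test_that("the five-bin rule gates ordinary events", {
  bins <- toy_bins()
  # 4-bin gain: excluded
  cn4 <- profile_with(bins, list(chrom = "1", from = 10, to = 13, cn = 3))
  expect_equal(nrow(call_cell_events(cn4, bins)), 0)
  # 5-bin loss: one event
  cn5 <- profile_with(bins, list(chrom = "1", from = 10, to = 14, cn = 1))
  ev <- call_cell_events(cn5, bins)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$class, "loss")
  expect_equal(c(ev$start_bin, ev$end_bin), c(10, 14))
  expect_error(call_cell_events(numeric(), bins[0, ]),
               class = "clonetrace_validation_error")
})

test_that("short high-grade amplifications pass only inside amplicons", {
  bins <- toy_bins()
  regions <- tibble::tibble(chrom = "1", start_bin = 10, end_bin = 20,
                            name = "amp_region")
  inside <- profile_with(bins, list(chrom = "1", from = 12, to = 13, cn = 12))
  outside <- profile_with(bins, list(chrom = "2", from = 12, to = 13, cn = 12))
  ev_in <- call_cell_events(inside, bins, regions = regions)
  ev_out <- call_cell_events(outside, bins, regions = regions)
  expect_equal(ev_in$class, "amplification")
  expect_equal(nrow(ev_out), 0)
})

test_that("sub-threshold events are never emitted on fuzzed profiles", {
  set.seed(12)
  bins <- toy_bins(4, 50)
  regions <- tibble::tibble(chrom = "3", start_bin = 5, end_bin = 15,
                            name = "amp")
  n_long <- 0
  for (i in 1:60) {
    cn <- rep(2L, nrow(bins))
    flips <- sample.int(nrow(bins), 25)
    cn[flips] <- pmax(cn[flips] + sample(c(-2L, -1L, 1L, 4L), 25,
                                         replace = TRUE), 0L)
    if (i %% 2 == 0) {           # guarantee some events above threshold
      at <- sample.int(nrow(bins) - 7, 1)
      cn[at:(at + 6)] <- 4L
    }
    ev <- call_cell_events(cn, bins, regions = regions)
    n_long <- n_long + sum(ev$n_bins >= 5)
    if (nrow(ev) == 0) next
    short <- which(ev$n_bins < 5)
    expect_true(all(ev$class[short] == "amplification" &
                      ev$chrom[short] == "3" & ev$n_bins[short] >= 2))
  }
  expect_gt(n_long, 0)
})

test_that("harmonization merges agreeing events and splits extensions", {
  bins <- toy_bins(1, 200)
  mk <- function(from, to, cn = 3) {
    call_cell_events(profile_with(bins, list(chrom = "1", from = from,
                                             to = to, cn = cn)), bins)
  }
  # identical 10-bin gains in six cells become one catalog event
  cells <- setNames(replicate(6, mk(50, 59), simplify = FALSE),
                    paste0("c", 1:6))
  h <- harmonize_events(cells)
  expect_equal(nrow(h$catalog), 1)
  expect_equal(h$catalog$n_carriers, 6)
  expect_true(all(h$matrix == 1))

  # gains 100-120 and 100-140: a shared core plus a private extension
  h2 <- harmonize_events(list(c1 = mk(100, 120), c2 = mk(100, 140)))
  expect_equal(nrow(h2$catalog), 2)
  expect_equal(sort(h2$catalog$n_carriers), c(1, 2))
  expect_equal(unname(rowSums(h2$matrix)), c(1, 2))

  # boundaries within one bin snap together
  h3 <- harmonize_events(list(c1 = mk(50, 59), c2 = mk(51, 60)))
  expect_equal(nrow(h3$catalog), 1)

  # disjoint events on different chromosomes stay separate
  bins2 <- toy_bins(2, 100)
  e1 <- call_cell_events(profile_with(bins2, list(chrom = "1", from = 10,
                                                  to = 20, cn = 3)), bins2)
  e2 <- call_cell_events(profile_with(bins2, list(chrom = "2", from = 10,
                                                  to = 20, cn = 1)), bins2)
  h4 <- harmonize_events(list(c1 = e1, c2 = e2))
  expect_equal(nrow(h4$catalog), 2)
})

test_that("cell trees collapse identical profiles into counted clones", {
  m <- rbind(matrix(rep(c(1L, 0L), c(3, 3)), 6, 1), matrix(1L, 4, 1))
  m <- cbind(m, c(rep(0L, 6), rep(1L, 4)))
  rownames(m) <- paste0("cell", 1:10)
  colnames(m) <- c("evA", "evB")
  tr <- build_cell_tree(m)
  expect_equal(sort(tr$taxa$n_cells), c(3, 3, 4))
  expect_equal(sum(tr$taxa$n_cells), 10)
  # collapsing does not change the topology over distinct profiles
  tr_dedup <- build_tree(unique(m))
  expect_equal(phangorn::RF.dist(genotype_phylo(tr), genotype_phylo(tr_dedup)),
               0)
})

test_that("PoP is the cell fraction below matching branches", {
  m <- rbind(A = c(1, 0), B = c(1, 1))
  colnames(m) <- c("whole_gain_1", "loss_2")
  tr <- build_tree(m)
  tr$taxa$n_cells <- c(6L, 4L)
  expect_equal(pop_statistic(tr, function(ev) any(grepl("whole_gain", ev))), 1)
  expect_equal(pop_statistic(tr, function(ev) any(grepl("loss", ev))), 0.4)
  expect_equal(pop_statistic(tr, function(ev) FALSE), 0)
  # a partition of branch classes accounts for every cell exactly once
  p1 <- pop_statistic(tr, function(ev) length(ev) > 0 && all(grepl("whole", ev)))
  expect_equal(p1, 1)   # root-adjacent branch holds all cells
})

test_that("clone dynamics tracks fractions over timepoints", {
  m1 <- rbind(matrix(1L, 6, 1), matrix(0L, 4, 1))
  m2 <- matrix(0L, 12, 1)
  colnames(m1) <- colnames(m2) <- "ev1"
  rownames(m1) <- paste0("a", 1:10)
  rownames(m2) <- paste0("b", 1:12)
  dyn <- clone_dynamics(list(t1 = m1, t2 = m2))
  carrier <- dyn[dyn$profile == "1", ]
  expect_equal(carrier$fraction, c(0.6, 0))
  expect_equal(sum(dyn$fraction[dyn$timepoint == "t1"]), 1)
  m3 <- m2
  colnames(m3) <- "other"
  expect_error(clone_dynamics(list(t1 = m1, t2 = m3)),
               class = "clonetrace_harmonization_error")
})

test_that("noise-free rendered cells recover their clone's events", {
  truth <- simulate_truth(5, "branched", seed = 77)
  cells <- render_cells(truth, n_cells = 30, bin_noise_rate = 0, seed = 78)
  genome_bins <- cells$bins
  carriers <- clonetrace:::event_carrier_matrix(truth)
  for (i in sample.int(30, 8)) {
    called <- call_cell_events(cells$profiles[i, ], genome_bins,
                               regions = tibble::tibble(
                                 chrom = character(), start_bin = integer(),
                                 end_bin = integer(), name = character()))
    cl <- cells$cell_clone[[i]]
    ev <- truth$events
    expected <- ev[ev$class != "snv" &
                     ev$event %in% rownames(carriers)[carriers[, cl]] &
                     ev$n_a + ev$n_b != 2, ]     # CNNI invisible in total CN
    expect_equal(nrow(called), nrow(expected))
    expect_setequal(paste(called$chrom, called$start_bin, called$end_bin),
                    paste(expected$chrom, expected$start_bin,
                          expected$end_bin))
  }
})

test_that("cell draws follow the clone fractions", {
  truth <- simulate_truth(3, "branched", seed = 5)
  truth$fractions[, 1] <- c(0, 0.5, 0.5)
  cells <- render_cells(truth, sample_id = truth$samples$sample_id[1],
                        n_cells = 500, bin_noise_rate = 0, seed = 6)
  counts <- table(cells$cell_clone)
  # binomial 3-sigma bound around 250
  expect_true(abs(counts[["C2"]] - 250) < 3 * sqrt(500 * 0.25))
})
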