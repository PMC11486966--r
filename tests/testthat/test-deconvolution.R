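pmat <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("e", seq_len(nrow(m)))
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  m
}

test_that("events with similar MCF patterns group and round to 0.1", {
  g <- group_events(pmat(c(1, 0.5, 0), c(0.95, 0.55, 0.05)), tol = 0.15)
  expect_equal(nrow(g$profile), 1)
  expect_equal(unname(g$profile[1, ]), c(1, 0.5, 0))
  # identical patterns collapse; clearly distinct ones never do
  g2 <- group_events(pmat(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0)), tol = 0.3)
  expect_equal(nrow(g2$profile), 2)
  # tol = 0 merges only patterns with identical rounded clone sizes
  g3 <- group_events(pmat(c(0.52, 0.3), c(0.50, 0.3), c(0.7, 0.3)), tol = 0)
  expect_equal(nrow(g3$profile), 2)
  expect_error(group_events(pmat(c(1, 0)), tol = -1),
               class = "clonetrace_config_error")
})

test_that("grouping is invariant under input row order", {
  set.seed(5)
  m <- pmat(c(1, 1, 1), c(0.97, 1, 0.95), c(0.5, 0.45, 0.5),
            c(0.1, 0, 0.05), c(0.52, 0.5, 0.48), c(0, 0, 0.02))
  ref <- group_events(m)
  sets <- function(g) {
    unname(sort(vapply(split(g$groups$event, g$groups$group),
                       function(x) paste(sort(x), collapse = ","),
                       character(1))))
  }
  for (i in 1:5) {
    perm <- m[sample.int(nrow(m)), , drop = FALSE]
    expect_equal(sets(group_events(perm)), sets(ref))
  }
})

test_that("pigeonhole forces nesting and capacity permits parallelism", {
  # 0.6 + 0.6 in one sample cannot be parallel; the cross-sample pattern
  # decides the direction (larger total becomes the parent)
  g <- group_events(pmat(c(0.6, 0.8), c(0.6, 0.1)), tol = 0.05)
  cfg <- resolve_configuration(g)
  expect_equal(cfg$nodes$parent[cfg$nodes$subclone == "G2"], "G1")
  # 0.5 + 0.5 exactly fills the sample: parallel is allowed
  g2 <- group_events(pmat(c(0.5, 0.8, 0), c(0.5, 0, 0.8)), tol = 0.05)
  cfg2 <- resolve_configuration(g2)
  expect_true(all(is.na(cfg2$nodes$parent)))
})

test_that("mixed aberrations are never nested even when fractions allow", {
  m <- pmat(c(0.4, 0.4), c(0.6, 0.6))
  rownames(m) <- c("seg1_comp13", "seg1_comp12")
  g <- group_events(m, tol = 0.05)
  cfg <- resolve_configuration(
    g, no_nest = tibble::tibble(a = "seg1_comp13", b = "seg1_comp12"))
  expect_true(all(is.na(cfg$nodes$parent)))
  # but if the pigeonhole then forces them together, that is a hard conflict
  m2 <- pmat(c(0.7, 0.4), c(0.6, 0.6))
  rownames(m2) <- c("seg1_comp13", "seg1_comp12")
  expect_error(
    resolve_configuration(group_events(m2, tol = 0.05),
                          no_nest = tibble::tibble(a = "seg1_comp13",
                                                   b = "seg1_comp12")),
    class = "clonetrace_constraint_conflict")
})

test_that("containment across samples produces chains, crossing parallels", {
  g <- group_events(pmat(c(1, 1, 1), c(0.9, 0.6, 1), c(0.5, 0.3, 0.4),
                         c(0, 0.3, 0.55)), tol = 0.05)
  cfg <- resolve_configuration(g)
  parent <- setNames(cfg$nodes$parent, cfg$nodes$subclone)
  expect_equal(unname(parent[c("G2", "G3")]), c("G1", "G2"))
  # e4 crosses e3 (bigger in S3, smaller in S1) -> sibling, not child
  expect_identical(parent[["G4"]], "G2")
})

test_that("inferred stem and inferred private reconcile conflicting calls", {
  # same-breakpoint gains with different allele counts: lowest becomes stem
  m <- pmat(c(1, 0, 0.1), c(0, 1, 0.2))
  rownames(m) <- c("gain_1q_12", "gain_1q_13")
  meta <- tibble::tibble(
    event = c("gain_1q_12", "gain_1q_13"),
    chrom = "1", start = 1e6, end = 9e6,
    class = "gain", n_a = c(1, 1), n_b = c(2, 3), whole_chrom = FALSE
  )
  cfg <- resolve_configuration(group_events(m, tol = 0.05))
  out <- suppressWarnings(infer_missing_events(cfg, meta))
  expect_true("inferred_stem" %in% out$annotations$annotation)
  stem_group <- out$membership$subclone[out$membership$event == "gain_1q_12"]
  expect_true(all(out$profile_raw[stem_group, ] >=
                    out$profile_raw[out$membership$subclone[
                      out$membership$event == "gain_1q_13"], ] - 1e-9))

  # an irreconcilable whole-chromosome event splits into private copies
  m2 <- pmat(c(1, 0.1, 0.6), c(0.05, 1, 0.6))
  rownames(m2) <- c("chr7_gain", "other")
  meta2 <- tibble::tibble(event = c("chr7_gain", "other"), chrom = "7",
                          start = 1, end = 1e8, class = "gain",
                          n_a = 1, n_b = 2,
                          whole_chrom = c(TRUE, FALSE))
  cfg2 <- suppressWarnings(resolve_configuration(group_events(m2, tol = 0.05)))
  out2 <- suppressWarnings(infer_missing_events(cfg2, meta2))
  expect_true(any(grepl("inferred_private", out2$annotations$annotation)))
  expect_true(any(grepl("chr7_gain@", out2$membership$event)))

  # a consistent configuration passes through unchanged
  cfg3 <- resolve_configuration(group_events(pmat(c(1, 1), c(0.5, 0.4)),
                                             tol = 0.05))
  out3 <- infer_missing_events(cfg3, meta[0, ])
  expect_equal(out3$nodes, cfg3$nodes)
})

test_that("pure-tumor deconvolution applies the clonal and rounding rules", {
  seg <- tibble::tibble(
    sample_id = rep(c("A", "B"), each = 3),
    chrom = rep(c("1", "2", "3"), 2),
    start = 1, end = 2e7,
    n_a = 1, n_b = 2,
    event = rep(c("ev_clonal", "ev_sub1", "ev_sub2"), 2),
    ratio = oracle_ratio(c(0.92, 0.57, 0.55, 0.95, 0.58, 0.54), 3, 2),
    mbaf = oracle_mbaf(c(0.92, 0.57, 0.55, 0.95, 0.58, 0.54), 1, 2),
    clonal_hint = FALSE
  )
  out <- pdx_deconvolve(seg, lineage = c(A = "T1", B = "T1"))
  # MCF >= 0.9 is clonal
  expect_true(all(out$sizes[, "A"] >= 0))
  ev_cl <- out$events[out$events$event == "ev_clonal", ]
  expect_true(ev_cl$clonal)
  # raw 0.57 + 0.55 round to 0.6 + 0.6 = 1.2 (allowed), then normalize
  tot <- colSums(out$sizes)
  expect_true(all(tot <= 1 + 1e-9))
})

test_that("CNNI against a majority-trisomy background is ordered as a loss", {
  seg <- tibble::tibble(
    sample_id = rep(c("A", "B", "C"), each = 1),
    chrom = "5", start = 1, end = 3e7,
    n_a = c(1, 1, 0), n_b = 2,
    event = c("tri_5", "tri_5", "cnni_5"),
    ratio = c(oracle_ratio(c(0.95, 0.92), 3, 2), 1.0),
    mbaf = c(oracle_mbaf(c(0.95, 0.92), 1, 2), oracle_mbaf(0.9, 0, 2)),
    clonal_hint = FALSE
  )
  out <- pdx_deconvolve(seg)
  expect_equal(out$cnni_from_trisomy, "cnni_5")
})

test_that("the event matrix closes each subclone over its root path", {
  g <- group_events(pmat(c(1, 1), c(0.6, 0.5), c(0.3, 0.25)), tol = 0.02)
  cfg <- resolve_configuration(g)
  em <- event_matrix(cfg)
  expect_equal(unname(em$matrix["G1", ]), c(1, 0, 0))
  expect_equal(unname(em$matrix["G2", ]), c(1, 1, 0))
  expect_equal(unname(em$matrix["G3", ]), c(1, 1, 1))
  # nested child rows contain their parent rows
  expect_true(all(em$matrix["G3", ] >= em$matrix["G2", ]))
  fr <- tidyr::pivot_wider(em$fractions, names_from = "sample_id",
                           values_from = "fraction")
  expect_equal(fr$S1[fr$subclone == "G1"], 0.4)  # own = 1 - 0.6
})

test_that("noise-free simulations are recovered exactly", {
  for (seed in 1:10) {
    truth <- simulate_truth(sample(4:10, 1), "branched", seed = seed,
                            jitter = 0.02)
    r <- render_bulk(truth, depth = 2000, noise_sd = 0, seed = seed + 500)
    rec <- reconstruct_bulk(r$segments, r$variants)
    expect_true(structure_matches(truth, rec),
                label = paste("structure recovery, seed", seed))
  }
})
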