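make_variants <- function(...) {
  base <- tibble::tibble(
    sample_id = "S1", chrom = "1", pos = 100, ref = "A", alt = "T",
    depth = 200L, alt_reads = 60L, vaf = 0.3, normal_fraction = 0,
    source = "wes_frozen"
  )
  dplyr::bind_rows(lapply(list(...), function(x) {
    row <- base
    for (nm in names(x)) row[[nm]] <- x[[nm]]
    row
  }))
}

test_that("variant filter applies the read, VAF, normal and coverage rules", {
  v <- make_variants(
    list(pos = 1, alt_reads = 8L, vaf = 0.04),            # < 10 reads
    list(pos = 2, vaf = 0.15, source = "wes_ffpe"),       # < 0.2 FFPE cutoff
    list(pos = 3, vaf = 0.15, source = "wes_frozen"),     # >= 0.1 frozen
    list(pos = 4, normal_fraction = 0.02),                # > 1% in normal
    list(pos = 5, depth = 80L, source = "targeted"),      # < 100x targeted
    list(pos = 6)
  )
  out <- filter_variants(v)
  expect_setequal(out$kept$pos, c(3, 6))
  reasons <- setNames(out$rejected$reason, out$rejected$pos)
  expect_equal(reasons[["1"]], "min_reads")
  expect_equal(reasons[["2"]], "vaf_below_cutoff")
  expect_equal(reasons[["4"]], "normal_contamination")
  expect_equal(reasons[["5"]], "targeted_low_coverage")
  expect_error(filter_variants(dplyr::mutate(v, source = "nanopore")),
               class = "clonetrace_config_error")
})

test_that("VAF cutoff and coverage rules pool across a patient's samples", {
  # below cutoff in one sample but not in all -> kept everywhere
  v <- make_variants(list(sample_id = "S1", vaf = 0.05, alt_reads = 10L),
                     list(sample_id = "S2", vaf = 0.30))
  expect_equal(nrow(filter_variants(v)$kept), 2)
  # targeted: >= 100 reads in at least one sample suffices
  v2 <- make_variants(list(sample_id = "S1", depth = 80L, source = "targeted"),
                      list(sample_id = "S2", depth = 400L, source = "targeted"))
  expect_equal(nrow(filter_variants(v2)$kept), 2)
  # per-patient FFPE override for low-burden cases
  v3 <- make_variants(list(vaf = 0.15, source = "wes_ffpe"))
  expect_equal(nrow(filter_variants(v3)$kept), 0)
  expect_equal(nrow(filter_variants(v3, vaf_cutoff = c(wes_ffpe = 0.1))$kept), 1)
})

test_that("variant filter is idempotent and partitions its input", {
  set.seed(7)
  v <- do.call(make_variants, lapply(1:20, function(i) {
    list(pos = i, alt_reads = sample(c(5L, 50L), 1),
         vaf = runif(1, 0, 0.5),
         normal_fraction = sample(c(0, 0.05), 1, prob = c(0.8, 0.2)))
  }))
  once <- filter_variants(v)
  twice <- filter_variants(once$kept)
  expect_equal(nrow(twice$rejected), 0)
  expect_equal(dplyr::arrange(once$kept, pos),
               dplyr::arrange(twice$kept, pos))
  expect_equal(nrow(once$kept) + nrow(once$rejected), nrow(v))
})

test_that("VAF-to-MCF conversion honors the copy-number context", {
  expect_equal(as.numeric(mcf_from_vaf(0, m = 1, cn1 = 2, f1 = 0.8,
                                       tcf = 0.8)), 0)
  # forward oracle: MCF 1 at purity 0.8 on diploid gives VAF 0.4
  expect_equal(oracle_vaf(1, 1, 2, 0.8), 0.4)
  expect_equal(as.numeric(mcf_from_vaf(0.4, m = 1, cn1 = 2, f1 = 0.8,
                                       tcf = 0.8)), 1)
  expect_equal(
    mcf_from_vaf(0.25, m = 1, cn1 = 3, f1 = 0.5, cn2 = 2, f2 = 0.3,
                 tcf = 0.8, clamp = FALSE),
    0.25 * (1.5 + 0.6 + 0.4) / 0.8)   # 0.78125
  expect_error(mcf_from_vaf(0.2, m = 1, cn1 = 2, f1 = 0.5, f2 = 0.2,
                            tcf = 0.7), class = "clonetrace_context_error")
  expect_error(mcf_from_vaf(0.2, m = 1, cn1 = 2, f1 = 0.5, f2 = 0.1,
                            tcf = 0.7), class = "clonetrace_context_error")
})

test_that("the pure-tumor formula is the general one at full purity", {
  expect_equal(as.numeric(mcf_from_vaf_pure(0.25, cn = 2)), 0.5)
  expect_equal(as.numeric(mcf_from_vaf_pure(0.5, cn = 2, m = 2)), 0.5)
  expect_equal(as.numeric(mcf_from_vaf_pure(0.3, cn = 3)), 0.9)
  set.seed(11)
  for (i in 1:200) {
    vaf <- runif(1, 0, 0.5)
    cn <- sample(1:5, 1)
    m <- sample(1:2, 1)
    expect_equal(
      mcf_from_vaf(vaf, m = m, cn1 = cn, f1 = 1, f2 = 0, tcf = 1,
                   clamp = FALSE),
      mcf_from_vaf_pure(vaf, cn, m, clamp = FALSE),
      tolerance = 1e-12)
  }
  expect_error(mcf_from_vaf_pure(0.1, cn = 0),
               class = "clonetrace_context_error")
})

test_that("MCF from VAF is linear in VAF and inverse in multiplicity", {
  v <- seq(0.05, 0.5, by = 0.05)
  out <- mcf_from_vaf(v, m = 1, cn1 = 2, f1 = 0.8, tcf = 0.8, clamp = FALSE)
  expect_equal(out / v, rep(out[1] / v[1], length(v)))
  expect_equal(mcf_from_vaf(0.2, m = 2, cn1 = 2, f1 = 0.8, tcf = 0.8,
                            clamp = FALSE),
               mcf_from_vaf(0.2, m = 1, cn1 = 2, f1 = 0.8, tcf = 0.8,
                            clamp = FALSE) / 2)
})

test_that("multiplicity candidates follow the order-of-events logic", {
  mix <- tibble::tibble(n_a = c(0, 1), n_b = c(2, 2),
                        fraction = c(0.3, 0.7))
  expect_equal(as.numeric(enumerate_multiplicities(mix = mix)),
               c(0.7, 1.4, 2))
  expect_equal(as.numeric(enumerate_multiplicities(c(1, 1))), c(1, 2))
  tetra <- enumerate_multiplicities(c(2, 2), ploidy = 4)
  expect_equal(attr(tetra, "default"), 2)
})

test_that("multiplicity choice applies the rejection rules in order", {
  # MCF > 1.2 in the majority of samples rejects the low candidate
  trial <- rbind(c(1.5, 1.4, 1.6, 0.9), c(0.75, 0.7, 0.8, 0.45))
  expect_equal(choose_multiplicity(c(1, 2), trial), 2)
  expect_equal(choose_multiplicity(1, matrix(0.5)), 1)
  # among valid candidates, fewest novel subclones wins
  trial3 <- rbind(c(0.9, 0.8), c(0.45, 0.4), c(0.3, 0.27))
  expect_equal(
    choose_multiplicity(c(0.7, 1.4, 2), trial3,
                        impossible = c(FALSE, FALSE, TRUE),
                        novel_subclones = c(1L, 0L, 0L)),
    1.4)
  # ties resolve toward the larger multiplicity
  expect_equal(choose_multiplicity(c(1, 2), rbind(c(0.8), c(0.4))), 2)
  expect_error(choose_multiplicity(c(1), matrix(c(1.5, 1.6, 1.7), 1),
                                   novel_subclones = 0L),
               class = "clonetrace_unresolvable_multiplicity")
})

test_that("clonal-sweep artifacts are dropped only in scope", {
  v <- tibble::tibble(
    sample_id = c("S1", "S1", "S2"),
    vaf = c(0.12, 0.35, 0.12),
    shared = c(TRUE, TRUE, FALSE)
  )
  out <- sweep_artifact_filter(v, swept = c(S1 = TRUE, S2 = FALSE))
  expect_equal(out$sweep_artifact, c(TRUE, FALSE, FALSE))
})

test_that("clonality labeling is monotone with the documented cutoffs", {
  expect_true(clonality_label(0.75))
  expect_false(clonality_label(0.65))
  expect_true(clonality_label(0.65, balanced_shared = TRUE))
  mcf <- seq(0, 1, by = 0.01)
  lab <- clonality_label(mcf)
  expect_true(all(diff(as.integer(lab)) >= 0))
})
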