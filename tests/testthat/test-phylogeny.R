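test_that("conflict-free matrices yield the unique perfect phylogeny", {
  m <- rbind(A = c(1, 0, 0), B = c(1, 1, 0), C = c(1, 0, 1))
  colnames(m) <- c("e1", "e2", "e3")
  tr <- build_tree(m)
  expect_equal(attr(tr, "score"), 3)
  expect_equal(attr(tr, "homoplasy"), 0)
  # A sits at the internal node carrying e1, below the root
  node_a <- tr$taxa$node[tr$taxa$taxon == "A"]
  expect_true(node_a %in% tr$nodes$parent)       # internal placement
  kids <- tr$nodes$node[!is.na(tr$nodes$parent) &
                          tr$nodes$parent == node_a]
  expect_length(kids, 2)

  # single subclone with k events: a chain of total length k
  m2 <- matrix(1, 1, 5, dimnames = list("S", paste0("e", 1:5)))
  tr2 <- build_tree(m2)
  expect_equal(total_branch_length(tr2), 5)

  # empty matrix: root-only tree
  tr3 <- build_tree(matrix(0L, 1, 0, dimnames = list("S", NULL)))
  expect_equal(total_branch_length(tr3), 0)
  expect_equal(tr3$taxa$node, tree_root(tr3))
})

test_that("parsimony score matches phangorn on conflict-free matrices", {
  skip_if_not_installed("phangorn")
  set.seed(23)
  for (i in 1:10) {
    truth <- simulate_truth(sample(4:9, 1), "branched", seed = i)
    em <- event_matrix(resolve_configuration(group_events(truth_mcf(truth),
                                                          tol = 0.02)))
    tr <- build_tree(em$matrix)
    expect_equal(attr(tr, "score"), ncol(em$matrix))
    # independent parsimony oracle on the same character data
    phy <- as.phylo(tr)
    states <- rbind(em$matrix,
                    ROOT = rep(0L, ncol(em$matrix)))[phy$tip.label, ,
                                                     drop = FALSE]
    pd <- phangorn::phyDat(states, type = "USER", levels = c(0, 1))
    expect_equal(phangorn::parsimony(phy, pd), ncol(em$matrix))
  }
})

test_that("character conflicts resolve by parallel acquisition", {
  m <- rbind(A = c(1, 1, 0), B = c(0, 1, 1), C = c(1, 0, 1))
  colnames(m) <- c("e1", "e2", "e3")
  w <- testthat::capture_warnings(tr <- build_tree(m))
  expect_true(any(grepl("parallel", w)))
  expect_gt(attr(tr, "homoplasy"), 0)
  expect_equal(attr(tr, "score"), 3 + attr(tr, "homoplasy"))
  # breakpoint-unique events must not be duplicated
  expect_error(
    build_tree(m, parallel_classes = c(e1 = "unique", e2 = "unique",
                                       e3 = "unique")),
    class = "clonetrace_infeasible_error")
})

test_that("IGD follows its closed forms", {
  m <- rbind(A = c(1, 1, 1, 1, 1, 0, 0), B = c(1, 1, 1, 1, 0, 1, 0),
             C = c(1, 1, 1, 1, 0, 0, 1))
  colnames(m) <- paste0("e", 1:7)
  tr <- build_tree(m)
  # two taxa one event below their MRCA, MRCA four events below the root
  expect_equal(igd(tr, c("A", "B")), (1 + 1) / (5 + 5))
  expect_equal(igd(tr, "A"), 0)
  # subset whose common node is the root
  m2 <- rbind(X = c(1, 1, 0, 0), Y = c(0, 0, 1, 1))
  colnames(m2) <- paste0("e", 1:4)
  tr2 <- build_tree(m2)
  expect_equal(igd(tr2, c("X", "Y")), 1)
  expect_error(igd(tr, character()), class = "clonetrace_validation_error")
  expect_error(igd(tr, "Z"), class = "clonetrace_validation_error")
})

test_that("IGD stays within [0, 1] on fuzzed trees and subsets", {
  set.seed(31)
  for (i in 1:40) {
    truth <- simulate_truth(sample(3:10, 1),
                            sample(c("branched", "linear"), 1), seed = i)
    tr <- truth$tree
    for (j in 1:5) {
      taxa <- sample(tr$taxa$taxon, sample.int(nrow(tr$taxa), 1))
      v <- igd(tr, taxa)
      expect_gte(v, 0)
      expect_lte(v, 1)
    }
  }
})

test_that("irregularity is the sample variance of root distances", {
  m <- rbind(A = c(1, 1, 0, 0, 0, 0), B = c(0, 0, 1, 1, 1, 1))
  colnames(m) <- paste0("e", 1:6)
  expect_equal(irregularity(build_tree(m)), var(c(2, 4)))  # = 2
  m2 <- rbind(A = c(1, 0, 0), B = c(0, 1, 0), C = c(0, 0, 1))
  colnames(m2) <- paste0("e", 1:3)
  expect_equal(irregularity(build_tree(m2)), 0)
  m3 <- rbind(A = 1, B = 1)
  colnames(m3) <- "e1"
  tr3 <- build_tree(m3)
  expect_error(irregularity(build_tree(matrix(1, 1, 1,
                                              dimnames = list("A", "e1")))),
               class = "clonetrace_validation_error")
})

test_that("maximum-parsimony trees reproduce the simulated topology", {
  skip_if_not_installed("phangorn")
  for (seed in 1:15) {
    truth <- simulate_truth(sample(4:10, 1), "branched", seed = seed)
    r <- render_bulk(truth, depth = 2000, noise_sd = 0, seed = seed + 99)
    rec <- reconstruct_bulk(r$segments, r$variants)
    universe <- unique(rec$config$membership$event)
    rf <- phangorn::RF.dist(genotype_phylo(rec$tree),
                            genotype_phylo(truth$tree, universe))
    expect_equal(rf, 0, label = paste("RF distance, seed", seed))
  }
})

test_that("replacement classification recognizes the canonical patterns", {
  # pre taxa on one branch, post taxa on a sibling branch, pre absent post
  m <- rbind(A = c(1, 1, 0, 0, 0), B = c(1, 1, 1, 0, 0),
             C = c(1, 0, 0, 1, 0), D = c(1, 0, 0, 1, 1))
  colnames(m) <- paste0("e", 1:5)
  tr <- build_tree(m)
  det <- tibble::tibble(
    taxon = rep(c("A", "B", "C", "D"), each = 2),
    sample_id = rep(c("pre_1", "post_1"), 4),
    timepoint = rep(c("pre", "post"), 4),
    fraction = c(0.5, 0, 0.4, 0, 0, 0.5, 0, 0.4)
  )
  out <- classify_replacement(tr, det, timepoint_order = c("pre", "post"))
  expect_equal(out$classification, "CCR")

  # a diagnostic taxon ancestral to the progression taxa: linear
  m2 <- rbind(X = c(1, 1, 0), Y = c(1, 1, 1))
  colnames(m2) <- paste0("e", 1:3)
  tr2 <- build_tree(m2)
  det2 <- tibble::tibble(
    taxon = c("X", "X", "Y", "Y"),
    sample_id = c("pre_1", "post_1", "pre_1", "post_1"),
    timepoint = c("pre", "post", "pre", "post"),
    fraction = c(0.9, 0.2, 0.05, 0.7)
  )
  out2 <- classify_replacement(tr2, det2, timepoint_order = c("pre", "post"))
  expect_equal(out2$classification, "linear")

  # a single timepoint cannot be classified
  det3 <- det2[det2$timepoint == "pre", ]
  expect_equal(classify_replacement(tr2, det3)$classification,
               "not_classifiable")
})

test_that("Newick export carries branch lengths and optional timepoints", {
  m <- rbind(A = c(1, 1, 0), B = c(1, 1, 1))
  colnames(m) <- paste0("e", 1:3)
  tr <- build_tree(m)
  txt <- write_newick(tr)
  expect_match(txt, "ROOT")
  expect_match(txt, "A")
  tp <- write_newick(tr, timepoints = c(A = "pre", B = "post"))
  expect_match(tp, "A\\|pre")
  phy <- ape::read.tree(text = txt)
  expect_s3_class(phy, "phylo")
  expect_equal(sum(phy$edge.length), 3)
})

test_that("tidy and glance summarize clone trees", {
  m <- rbind(A = c(1, 1, 0), B = c(1, 1, 1))
  colnames(m) <- paste0("e", 1:3)
  tr <- build_tree(m)
  td <- tidy(tr)
  expect_true(all(c("node", "depth", "n_events", "taxa") %in% names(td)))
  gl <- glance(tr)
  expect_equal(gl$n_taxa, 2)
  expect_equal(gl$total_branch_length, 3)
  expect_equal(gl$irregularity, var(c(2, 3)))
})
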