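# Independent oracles and fixtures used across the suite. The forward
# models here are written from the generative definitions, independently of
# the package's estimation code paths.

# forward model: linear copy ratio of a mixed sample
oracle_ratio <- function(msf, nt, nb, np = 2) {
  (msf * nt + (1 - msf) * nb) / np
}

# forward model: mirrored BAF via total allele counts
oracle_mbaf <- function(msf, n_a, n_b) {
  btot <- n_b * msf + 1 * (1 - msf)
  atot <- n_a * msf + 1 * (1 - msf)
  btot / (atot + btot)
}

# forward model: VAF given multiplicity and copy-number context
oracle_vaf <- function(mcf, m, cn1, f1, cn2 = 0, f2 = 0) {
  tcf <- f1 + f2
  msf <- mcf * tcf
  m * msf / (cn1 * f1 + cn2 * f2 + 2 * (1 - tcf))
}

# brute-force two-sided Fisher p: enumerate every table with the observed
# margins via the hypergeometric mass written out in binomial coefficients
oracle_fisher <- function(tab) {
  r <- rowSums(tab); cc <- colSums(tab); n <- sum(tab)
  a_min <- max(0, r[1] - cc[2]); a_max <- min(r[1], cc[1])
  mass <- vapply(a_min:a_max, function(a) {
    exp(lchoose(cc[1], a) + lchoose(cc[2], r[1] - a) - lchoose(n, r[1]))
  }, numeric(1))
  p_obs <- mass[tab[1, 1] - a_min + 1]
  sum(mass[mass <= p_obs + 1e-12])
}

# full-permutation two-sided Mann-Whitney p via rank-sum enumeration
oracle_mw <- function(x, y) {
  nx <- length(x); ny <- length(y)
  comb <- c(x, y)
  u_of <- function(xv, yv) {
    sum(outer(xv, yv, ">")) + 0.5 * sum(outer(xv, yv, "=="))
  }
  u_obs <- u_of(x, y)
  mu <- nx * ny / 2
  idx <- utils::combn(nx + ny, nx)
  us <- apply(idx, 2, function(ii) u_of(comb[ii], comb[-ii]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# relabel a clone tree's taxa by their genotype (sorted event set) and
# return an ape phylo, so trees from different pipelines are comparable;
# an optional universe restricts genotypes to shared (recoverable) events
genotype_phylo <- function(tree, universe = NULL) {
  ev <- stats::setNames(tree$nodes$events, tree$nodes$node)
  parent <- stats::setNames(tree$nodes$parent, tree$nodes$node)
  genotype <- function(node) {
    out <- character()
    n <- node
    repeat {
      out <- c(out, ev[[as.character(n)]])
      if (is.na(parent[[as.character(n)]])) break
      n <- parent[[as.character(n)]]
    }
    if (!is.null(universe)) out <- intersect(out, universe)
    paste(sort(out), collapse = "|")
  }
  tr2 <- tree
  tr2$taxa$taxon <- vapply(tr2$taxa$node, genotype, character(1))
  as.phylo(tr2)
}

# do the recovered event groups and parent relations equal the simulated
# clone structure? Events the study's own quality filters exclude (e.g.
# subclonal variants whose VAF stays below the cutoff in every sample) are
# compared on the recovered universe, but every clone must keep at least
# one recoverable event.
structure_matches <- function(truth, recon) {
  universe <- unique(recon$config$membership$event)
  truth_events <- truth$events[truth$events$event %in% universe, ]
  if (!all(truth$clones$clone %in% truth_events$clone)) return(FALSE)
  truth <- list(events = truth_events, clones = truth$clones)
  truth_sets <- lapply(split(truth$events$event, truth$events$clone), sort)
  rec_sets <- lapply(split(recon$config$membership$event,
                           recon$config$membership$subclone), sort)
  key <- function(sets) {
    unname(sort(vapply(sets, paste, character(1), collapse = ",")))
  }
  if (!identical(key(truth_sets), key(rec_sets))) return(FALSE)
  # map recovered subclone -> truth clone via the event sets
  rec_to_clone <- stats::setNames(
    names(truth_sets)[match(vapply(rec_sets, paste, character(1),
                                   collapse = ","),
                            vapply(truth_sets, paste, character(1),
                                   collapse = ","))],
    names(rec_sets))
  truth_parent <- stats::setNames(truth$clones$parent, truth$clones$clone)
  rec_parent <- stats::setNames(recon$config$nodes$parent,
                                recon$config$nodes$subclone)
  for (sc in names(rec_parent)) {
    tp <- truth_parent[[rec_to_clone[[sc]]]]
    rp <- rec_parent[[sc]]
    rp_clone <- if (is.na(rp)) NA_character_ else rec_to_clone[[rp]]
    if (!identical(is.na(tp), is.na(rp_clone))) return(FALSE)
    if (!is.na(tp) && tp != rp_clone) return(FALSE)
  }
  TRUE
}

# end-to-end scenario classification used by several tests
classify_scenario_run <- function(type, seed, depth = 200, noise_sd = 0.05) {
  tt <- simulate_scenario(type, seed = seed)
  r <- render_bulk(tt, depth = depth, noise_sd = noise_sd, seed = seed + 1000)
  rec <- suppressWarnings(reconstruct_bulk(r$segments, r$variants))
  det <- detection_table(rec, tt$samples[, c("sample_id", "timepoint")])
  classify_replacement(rec$tree, det,
                       timepoint_order = c("pre", "post"))$classification
}
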