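#' Rooted clone tree
#'
#' A light container for rooted subclone phylogenies. Nodes form a parent
#' table; every non-root node carries the set of events acquired on the
#' branch from its parent, and the branch length is the number of those
#' events. Taxa (observed subclones, or cells/clones in single-cell mode)
#' attach to nodes — internal placements are allowed, since an observed
#' subclone can be ancestral to others. The root is the unmutated cell.
#'
#' @param nodes Tibble with columns `node` (integer), `parent` (integer,
#'   `NA` for the root), `events` (list of character vectors), `length`
#'   (integer, number of events on the incoming branch).
#' @param taxa Tibble with columns `taxon` (character) and `node` (integer);
#'   optional `n_cells` for single-cell trees.
#' @return An object of class `clone_tree`.
#' @export
clone_tree <- function(nodes, taxa) {
  nodes <- as_tibble(nodes)
  taxa <- as_tibble(taxa)
  stopifnot(all(c("node", "parent", "events", "length") %in% names(nodes)),
            all(c("taxon", "node") %in% names(taxa)))
  if (sum(is.na(nodes$parent)) != 1) {
    abort("A clone tree has exactly one root.",
          class = "clonetrace_validation_error")
  }
  root <- nodes$node[is.na(nodes$parent)]
  if (length(nodes$events[[which(nodes$node == root)]]) > 0) {
    abort("The root carries no events (it is the unmutated cell).",
          class = "clonetrace_validation_error")
  }
  structure(list(nodes = nodes, taxa = taxa), class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("<clone_tree> ", nrow(x$taxa), " taxa / ", nrow(x$nodes), " nodes / ",
      "total branch length ", total_branch_length(x), "\n", sep = "")
  invisible(x)
}

tree_root <- function(tree) tree$nodes$node[is.na(tree$nodes$parent)]

tree_parent_vec <- function(tree) {
  setNames(tree$nodes$parent, tree$nodes$node)
}

# depth (summed branch lengths) of every node from the root
node_depths <- function(tree) {
  parent <- tree_parent_vec(tree)
  len <- setNames(tree$nodes$length, tree$nodes$node)
  depth <- setNames(rep(NA_real_, nrow(tree$nodes)), tree$nodes$node)
  depth[as.character(tree_root(tree))] <- 0
  todo <- tree$nodes$node[!is.na(tree$nodes$parent)]
  while (length(todo)) {
    ready <- todo[!is.na(depth[as.character(parent[as.character(todo)])])]
    if (!length(ready)) abort("Cyclic parent structure.",
                              class = "clonetrace_validation_error")
    depth[as.character(ready)] <-
      depth[as.character(parent[as.character(ready)])] +
      len[as.character(ready)]
    todo <- setdiff(todo, ready)
  }
  depth
}

# ancestors of a node (incl. itself), root last
node_path <- function(tree, node) {
  parent <- tree_parent_vec(tree)
  out <- node
  while (!is.na(parent[as.character(node)])) {
    node <- parent[[as.character(node)]]
    out <- c(out, node)
  }
  out
}

# most recent common ancestor node of a set of nodes
mrca_node <- function(tree, nodes) {
  paths <- lapply(unique(nodes), function(n) rev(node_path(tree, n)))
  common <- Reduce(function(a, b) a[seq_len(min(length(a), length(b)))][
    a[seq_len(min(length(a), length(b)))] == b[seq_len(min(length(a), length(b)))]],
    paths)
  tail(common, 1)
}

# events accumulated from the root to each taxon (genotype)
taxon_genotypes <- function(tree) {
  ev <- setNames(tree$nodes$events, tree$nodes$node)
  out <- lapply(tree$taxa$node, function(n) {
    sort(unique(unlist(ev[as.character(node_path(tree, n))])))
  })
  setNames(out, tree$taxa$taxon)
}

#' Build a rooted maximum-parsimony tree from a binary event matrix
#'
#' Characters (events) are treated as gains from the unmutated root.
#' Conflict-free matrices — every pair of event carrier sets nested or
#' disjoint — yield the unique perfect phylogeny with zero homoplasy. When
#' characters conflict (expected for whole-chromosome aberrations, which
#' recur in parallel), the most-conflicting character is split into
#' per-taxon parallel events until the family is laminar; breakpoint-defined
#' events are unique, so a conflict that can only be resolved by duplicating
#' a `unique`-class event is an error unless `allow_parallel` permits it.
#' Loss of heterozygosity is irreversible under this gains-only model by
#' construction (characters are never reverted).
#'
#' @param m Binary subclone-by-event matrix (rows: taxa, columns: events).
#' @param parallel_classes Optional named character vector mapping events to
#'   `"unique"` (breakpoint events, never duplicated) or `"parallel_ok"`
#'   (whole-chromosome events). Default: every event may be duplicated, with
#'   a warning.
#' @return A `clone_tree`; attribute `"score"` carries the parsimony score
#'   (total branch length) and `"homoplasy"` the number of extra event
#'   acquisitions introduced by conflict resolution.
#' @export
build_tree <- function(m, parallel_classes = NULL) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  taxa_names <- rownames(m)
  if (ncol(m) == 0 || nrow(m) == 0) {
    nodes <- tibble(node = 1L, parent = NA_integer_,
                    events = list(character()), length = 0L)
    taxa <- tibble(taxon = taxa_names, node = rep(1L, length(taxa_names)))
    tr <- clone_tree(nodes, taxa)
    attr(tr, "score") <- 0L
    attr(tr, "homoplasy") <- 0L
    return(tr)
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("e", seq_len(ncol(m)))
  m <- m[, colSums(m) > 0, drop = FALSE]
  n_original <- ncol(m)

  # group events by identical carrier sets
  carrier_key <- apply(m, 2, function(x) paste(which(x > 0), collapse = ","))
  patterns <- lapply(split(colnames(m), carrier_key), identity)
  sets <- lapply(names(patterns), function(k) as.integer(strsplit(k, ",")[[1]]))
  names(sets) <- names(patterns)

  conflicts <- function(sets) {
    k <- length(sets)
    cnt <- setNames(integer(k), names(sets))
    if (k < 2) return(cnt)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      a <- sets[[i]]; b <- sets[[j]]
      ov <- length(intersect(a, b))
      if (ov > 0 && ov < length(a) && ov < length(b)) {
        cnt[i] <- cnt[i] + 1L
        cnt[j] <- cnt[j] + 1L
      }
    }
    cnt
  }

  homoplasy <- 0L
  repeat {
    cnt <- conflicts(sets)
    if (!any(cnt > 0)) break
    # split the most-conflicting pattern (tie: fewest taxa, then name)
    ord <- order(-cnt, lengths(sets), names(sets))
    pick <- names(sets)[ord[1]]
    evs <- patterns[[pick]]
    if (!is.null(parallel_classes) &&
        any(parallel_classes[evs] == "unique", na.rm = TRUE)) {
      abort(paste0("Conflicting breakpoint-unique event(s) ",
                   paste(evs[parallel_classes[evs] == "unique"],
                         collapse = ", "),
                   " cannot be resolved by parallel acquisition."),
            class = "clonetrace_infeasible_error")
    }
    if (is.null(parallel_classes)) {
      warn(paste0("Character conflict: treating event(s) ",
                  paste(evs, collapse = ", "),
                  " as parallel acquisitions."))
    }
    members <- sets[[pick]]
    homoplasy <- homoplasy + length(evs) * (length(members) - 1L)
    sets[[pick]] <- NULL
    patterns[[pick]] <- NULL
    for (t in members) {
      key <- as.character(t)
      new_evs <- paste0(evs, "|", taxa_names[t])
      if (key %in% names(sets)) {
        patterns[[key]] <- c(patterns[[key]], new_evs)
      } else {
        sets[[key]] <- t
        patterns[[key]] <- new_evs
      }
    }
  }

  # laminar family -> containment tree
  ord <- order(-lengths(sets), names(sets))
  sets <- sets[ord]
  patterns <- patterns[ord]
  k <- length(sets)
  node_id <- seq_len(k) + 1L    # node 1 is the root
  parent <- integer(k)
  for (i in seq_len(k)) {
    parent[i] <- 1L
    best_size <- Inf
    for (j in seq_len(k)) {
      if (j != i && length(sets[[j]]) > length(sets[[i]]) &&
          all(sets[[i]] %in% sets[[j]]) &&
          length(sets[[j]]) < best_size) {
        parent[i] <- node_id[j]
        best_size <- length(sets[[j]])
      }
    }
  }
  nodes <- tibble(
    node = c(1L, node_id),
    parent = c(NA_integer_, parent),
    events = c(list(character()), lapply(patterns, sort)),
    length = c(0L, lengths(patterns))
  )
  # each taxon attaches at the smallest carrier set containing it
  taxa_node <- vapply(seq_along(taxa_names), function(t) {
    containing <- which(vapply(sets, function(s) t %in% s, logical(1)))
    if (!length(containing)) return(1L)
    node_id[containing[which.min(lengths(sets)[containing])]]
  }, integer(1))
  tr <- clone_tree(nodes, tibble(taxon = taxa_names, node = taxa_node))
  attr(tr, "score") <- sum(nodes$length)
  attr(tr, "homoplasy") <- homoplasy
  tr
}

#' Convert a clone tree to an ape phylogeny
#'
#' Taxa become tips; a taxon at an internal node is attached by a
#' zero-length pendant edge, and the unmutated root is included as the tip
#' `"ROOT"` so that rooted comparisons survive unrooted tree metrics.
#'
#' @param x A `clone_tree`.
#' @param suffix Optional named character vector (by taxon) appended to tip
#'   labels as `taxon|suffix`, e.g. timepoints.
#' @param ... Unused.
#' @return An object of class `phylo`.
#' @export
as.phylo.clone_tree <- function(x, suffix = NULL, ...) {
  nodes <- x$nodes
  taxa <- x$taxa
  labels <- taxa$taxon
  if (!is.null(suffix)) {
    labels <- paste0(labels, "|", suffix[taxa$taxon])
  }
  tip_labels <- c(labels, "ROOT")
  tip_node <- c(taxa$node, tree_root(x))
  n_tip <- length(tip_labels)

  # a node whose only attachment is a single taxon and no children becomes
  # that tip directly, avoiding degree-2 internal nodes
  has_child <- nodes$node %in% nodes$parent
  n_taxa_at <- table(factor(tip_node, levels = nodes$node))
  direct_tip <- !has_child & as.integer(n_taxa_at[as.character(nodes$node)]) == 1 &
    !is.na(nodes$parent)
  internal <- nodes$node[!direct_tip]
  internal_id <- setNames(seq_along(internal) + n_tip, internal)

  edges <- NULL
  lens <- numeric()
  for (i in seq_len(nrow(nodes))) {
    nd <- nodes$node[i]
    if (is.na(nodes$parent[i])) next
    par_id <- internal_id[[as.character(nodes$parent[i])]]
    if (direct_tip[i]) {
      tip <- which(tip_node == nd)
      edges <- rbind(edges, c(par_id, tip))
      lens <- c(lens, nodes$length[i])
    } else {
      edges <- rbind(edges, c(par_id, internal_id[[as.character(nd)]]))
      lens <- c(lens, nodes$length[i])
    }
  }
  for (t in seq_len(n_tip)) {
    nd <- tip_node[t]
    idx <- which(nodes$node == nd)
    if (direct_tip[idx]) next
    edges <- rbind(edges, c(internal_id[[as.character(nd)]], t))
    lens <- c(lens, 0)
  }
  phy <- list(edge = edges, edge.length = lens, tip.label = tip_labels,
              Nnode = length(internal))
  class(phy) <- "phylo"
  phy <- ape::collapse.singles(phy)
  phy
}

#' Write a clone tree to a Newick string or file
#'
#' Branch lengths are event counts; taxa can carry a timepoint suffix.
#'
#' @param tree A `clone_tree`.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @param timepoints Optional named character vector (taxon to timepoint).
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL, timepoints = NULL) {
  phy <- as.phylo.clone_tree(tree, suffix = timepoints)
  txt <- ape::write.tree(phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' @export
tidy.clone_tree <- function(x, ...) {
  depths <- node_depths(x)
  x$nodes %>%
    mutate(
      depth = unname(depths[as.character(.data$node)]),
      n_events = lengths(.data$events),
      taxa = map(.data$node, ~ x$taxa$taxon[x$taxa$node == .x])
    )
}

#' @export
glance.clone_tree <- function(x, ...) {
  depths <- node_depths(x)
  taxon_depths <- depths[as.character(x$taxa$node)]
  tibble(
    n_taxa = nrow(x$taxa),
    n_nodes = nrow(x$nodes),
    total_branch_length = total_branch_length(x),
    irregularity = if (nrow(x$taxa) >= 2) var(taxon_depths) else NA_real_,
    max_depth = max(depths)
  )
}
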